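---
title: "Consensus scanning and breakdown-product prediction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus scanning and breakdown-product prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cleavescan)
```

## The problem

Proteases recognize short positional consensus sequences in their
substrates and hydrolyze a specific peptide bond at a fixed offset within
each occurrence. In degradomics the resulting breakdown products (BDPs)
are candidate biomarkers: caspase-3 (an apoptosis executioner protease)
and calpain-2 (a calcium-dependent protease active in necrosis and some
apoptosis) each generate signature spectrin fragments whose presence on a
gel distinguishes neuronal cell-death modes. `cleavescan` predicts those
fragments: it finds every consensus occurrence in a substrate, derives the
cut sites, and enumerates the fragments obtainable from any combination of
cleavage events.

## The consensus model

A `protease_pattern` is an ordered list of residue sets over the 20
standard amino acids plus a cleavage offset. A singleton set fixes a
residue, the full set is the wildcard `X`, and intermediate sets express
alternatives such as `[LVI]`. The built-ins:

```{r}
builtin_patterns()
```

The caspase-3 consensus is written `DXXD↑`: hits require Asp at the first
and fourth positions, and the bond after the second Asp is cut. Its 400
literal instances are the 20 × 20 choices for the two wildcard positions.
Calpain-2's three published patterns LX, VX and IX collapse to the single
set pattern `[LVI]X↑` (60 instances), cut after the second residue. Some
published site listings include flanking context — e.g. the validated
calpain site in βII-spectrin is reported as the 4-mer `ETVD` although the
recognition core is the 2-mer `VD` — so the scan functions accept a
`context` width that symmetrically pads the *displayed* subsequence
without ever moving the reported `start`/`end` coordinates. We chose
symmetric padding because the convention behind such 4-mer displays is not
standardized; the coordinates, which are what downstream steps consume,
are unaffected by the choice.

Wildcards deliberately match only the 20 standard residues. Ambiguity and
non-standard codes (B, Z, J, U, O, X, `*`) never match a fixed position
and by default do not match a wildcard either — an unknown residue should
not fabricate a predicted cleavage site. A `permissive` flag relaxes the
wildcard (not the fixed positions) for users who prefer recall over
precision on ambiguous input.

## The scanner

Scanning embeds the consensus search in a Smith–Waterman-style local
alignment: a dynamic-programming scoring table with `m + 1` rows (pattern
positions) and `n + 1` columns (substrate residues). A residue scores +1
against a position iff it belongs to that position's residue set;
mismatches and gaps contribute −m; scores are floored at 0. Because every
cell is bounded by `m`, any alignment containing a substitution at a fixed
position or any insertion/deletion (INDEL) is pushed to or below zero and
can never attain the full score `m`. Extracting the cells of the last row
that equal `m`, and verifying the all-match diagonal traceback, therefore
prunes INDEL-containing and partial alignments exactly and reduces the
scan to exact consensus matching — which is what position-specific
proteases do. The same penalty bound lets each table row be computed from
the diagonal term alone, so the table builds in vectorized O(mn) time and
space per sequence; multi-sequence scans stream one protein at a time, so
peak table storage never exceeds one `(m+1) × (n+1)` table.

The scanner's contract is exact equivalence with `naive_scan()`, an
independent sliding-window implementation kept deliberately separate. The
suite checks this property on 1000+ seeded random sequences, a third of
them drawn from a D/E-rich alphabet that produces dense, overlapping
`DXXD` hits — the adversarial regime for overlap handling. Overlapping
occurrences are all retained as independent hits (no greedy masking): the
embedded worked-example record `"194"` has a `DEED` hit ending at 619 and
the next starting at 619, and both contribute cut sites.

```{r}
subset(scan_protein(table4_record(), builtin_patterns()$caspase3),
       consensus == "DEED")
```

Coordinates are 1-based and inclusive throughout, matching the published
position conventions (P1 … P2364). Hits abutting either terminus are
reported; a cut falling after the final residue is suppressed downstream
(an empty product is never emitted).

## Digestion

Each occurrence contributes the cut site `start + cleavage_offset − 1`;
sites are deduplicated within and across proteases (a bond targeted by two
proteases becomes one site whose provenance lists both — simultaneous
activation is modelled as this independent merge, not as kinetic
interference). With `k` sites, three generation modes are offered because
every subset of sites is a possible cleavage incidence:

* **per-site** — each site cut alone; mirrors the per-occurrence fragment
  tables in published outputs.
* **scenarios** — all `2^k − 1` non-empty subsets. The default guard
  `max_sites = 16` (65 535 scenarios) keeps the exponential enumeration
  deliberate rather than accidental; exceeding it raises a condition the
  CLI maps to exit code 3.
* **distinct** — the deduplicated union of fragments over all scenarios,
  computed directly: every pair of boundaries drawn from
  `{0} ∪ sites ∪ {n}` delimits one candidate, except the intact `(0, n)`
  pair, giving `(k+1)(k+2)/2 − 1` fragments in O(k²). The suite verifies
  this closed form against brute-force subset enumeration for `k ≤ 10`.

Every scenario's fragments partition the substrate exactly — lengths sum
to `n` and concatenated sequences reproduce it — and the intact protein is
never reported as a BDP.

## Masses

Fragments carry average and monoisotopic masses: the sum of standard
unmodified residue masses plus one water (18.0153 / 18.010565 Da). No
PTMs, terminal modifications, isotope distributions or charge states are
modelled; mass here is a signature label for matching predictions to
gel-observed weights, not an MS engine. Note that published SBDP names
(110/108/85/80 kDa) are *apparent* SDS-PAGE mobilities; computed chemical
masses are reported as such and are not reconciled with gel labels. The
conservation law — scenario fragment masses sum to the parent mass plus
one water per cut — is asserted to 1e-6 Da in the suite, which also pins
two monoisotopic reference values computed with an independent
proteomics library.

## Synthetic data

`random_proteome()` draws uniform-alphabet sequences of 50–500 residues;
`plant_motifs()` writes literal pattern instances at recorded positions
into such a background and returns the ground truth. In `collision_free`
mode accidental background hits are repaired by redrawing one residue of
each offending window from the complement of the pattern's residue set at
that position (respecting any planted constraints), so the planted set
becomes the complete truth set and scanner recovery can be asserted
exactly. What this emulates is motif placement and overlap, not biology:
real proteomes have non-uniform composition, homology structure and
length distributions, so passing these tests demonstrates scanner and
digest correctness, not field performance on real substrates. The
desk-scale stand-in for a whole-proteome run is a 1000-record seeded
synthetic proteome (the published run used ~30 k real sequences), chosen
because oracle equivalence — the property being tested — is
size-independent, and 1000 records already exercise the streaming path in
seconds.

## External validation data

The βII-spectrin substrate (GenBank M96803) is external data and is not
redistributed; its validation tests (DSID at 1251–1254 and DEVD at
1454–1457 for caspase-3; the calpain-2 cut after 2146 within `ETVD`
context) run only when the user supplies the FASTA via
`options(cleavescan.spectrin_fasta = ...)`. The multiple-overlap example
record `"194"` *is* embedded, since its full sequence is part of the
published record, which keeps the headline overlap behaviour testable
offline.

## Degenerate inputs and determinism

Empty substrates produce an all-zero table and no hits; records shorter
than the pattern produce no hits; a length-1 all-wildcard pattern hits
every residue. Occurrence and fragment tables have fixed column sets and
a total ordering (protein, pattern/scenario, start), so identical inputs
yield byte-identical reports. All generators take explicit integer seeds.

## Limitations

Fixed/wildcard/alternative positional patterns cannot express
position-weight-matrix or context-dependent cleavage preferences, and no
kinetics (cleavage order, protease competition, missed-cleavage
probabilities) is modelled: the scenario enumeration treats all cut-site
subsets as equally possible, which is a combinatorial statement, not a
rate model. Sequences are treated as linear strings; structural
accessibility of sites is out of scope.
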