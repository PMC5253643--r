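# cleavescan

In-silico prediction of protease breakdown products (BDPs). `cleavescan`
locates every occurrence of a protease consensus sequence — including
wildcard variants and overlapping hits — in a set of protein substrates,
then enumerates the fragments obtainable from single, combined and
overlapping cleavage events, annotated with coordinates and molecular
masses.

The motivating application is degradomics of neural injury: the proteases
calpain-2 and caspase-3 are activated in different modes of neuronal cell
death (necrosis vs. apoptosis) and cleave substrates such as βII-spectrin
into signature fragments (SBDPs) whose sequence and molecular weight mark
the injury mechanism. Predicting those fragments computationally lets
experimentalists know what to look for before running gels or MS.

## Method

A protease is modelled as an ordered list of residue sets with a cleavage
offset:

* **caspase-3** — consensus `DXXD↑` (fixed Asp at P1 and P4, any residue
  at P2/P3; cut after the second Asp). 20 × 20 = **400** literal instances.
* **calpain-2** — consensus `[LVI]X↑` (Leu/Val/Ile then any residue; cut
  after the second residue). 3 × 20 = **60** literal instances.
* user-defined patterns via a mini-language: `parse_pattern("[DE]X[FY]|A")`.

Scanning uses a modified Smith–Waterman local alignment: a dynamic
programming scoring table of `(m+1) × (n+1)` cells (pattern length `m`,
substrate length `n`) with match = +1, mismatch/gap = −m and a floor at 0.
Alignments containing insertions or deletions (INDELs) or partial matches
can never reach the full score `m`, so extracting full-score, gap-free
tracebacks prunes them exactly. The scan runs in O(mn) space and time per
sequence and O(NN′mn) over N sequences and N′ patterns; its contract —
verified property-style in the test suite — is exact equivalence with a
naive sliding-window oracle.

Each hit defines a cut site (deduplicated across overlapping hits and
across proteases). With `k` sites the digest module generates:

* `per-site` — each site cut alone (two fragments per site);
* `scenarios` — all `2^k − 1` cut-site combinations (guarded by
  `max_sites`, since every combination is a possible cleavage incidence);
* `distinct` — the union of all obtainable fragments in closed form,
  `(k+1)(k+2)/2 − 1` of them, without enumerating subsets.

Fragments carry average and monoisotopic masses (standard residue masses
plus one water); across any scenario the fragment masses sum to the parent
mass plus one water per cut.

## Worked example

The package embeds the 775-residue mouse protein (record `"194"`) from the
published worked example whose acidic stretch carries five `DEED` caspase-3
sites, two of them overlapping:

```r
library(cleavescan)
r   <- table4_record()
occ <- scan_protein(r, builtin_patterns()$caspase3)
subset(occ, consensus == "DEED")
#>   protein_id  pattern consensus start end cleavage_after
#> 4        194 caspase3      DEED   616 619            619
#> 5        194 caspase3      DEED   619 622            622
#> 6        194 caspase3      DEED   629 632            632
#> 7        194 caspase3      DEED   632 635            635
#> 8        194 caspase3      DEED   635 638            638
```

The first `DEED` ends at position 619 — exactly where the second one
starts: overlapping consensus occurrences are independent hits, each
contributing its own cut site. Cleaving at site 619 alone partitions the
protein into the two breakdown products:

```r
d <- annotate_fragments(combined_digest(r, builtin_patterns()$caspase3,
                                        mode = "per-site"))
d$scenarios[["619"]][, c("start", "end", "avg_mass")]
#>   start end avg_mass
#> 1     1 619 65786.02
#> 2   620 775 18005.82
```

i.e. a ~65.8 kDa N-terminal and ~18.0 kDa C-terminal product (their masses
sum to the 83.8 kDa parent plus one water of hydrolysis).

For the βII-spectrin validation case, supply the M96803 FASTA yourself
(`options(cleavescan.spectrin_fasta = "...")` or `inst/extdata/M96803.fasta`);
the corresponding tests skip when it is absent. The validated sites are the
caspase-3 hits `DSID` (1251–1254) and `DEVD` (1454–1457) and the calpain-2
cut after position 2146 (reported with context as `ETVD`, 2143–2146).

## Command line

```sh
inst/cli/cleavescan patterns
inst/cli/cleavescan scan   -i substrates.fasta -p caspase3 -p calpain2 -o hits.tsv
inst/cli/cleavescan digest -i substrates.fasta -p both --mode distinct -o out
inst/cli/cleavescan fixture --seed 1 --plant caspase3:40,calpain2:80 --length 120 -o fix
```

Exit codes: 0 success, 2 input error, 3 combination guard tripped.

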