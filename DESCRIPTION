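Package: cleavescan
Title: Protease Consensus Scanning and Breakdown-Product Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Locates protease consensus-sequence occurrences (including
    wildcard variants and overlapping hits) in protein substrates with a
    dynamic-programming local-alignment scanner that prunes gapped
    alignments, then enumerates the breakdown products obtainable from
    single, combined and overlapping cleavage events. Built-in models for
    caspase-3 (DXXD, cut after the second aspartate) and calpain-2
    ([LVI]X, cut after the second residue), plus a mini-language for
    user-defined patterns. Fragments are annotated with average and
    monoisotopic masses so predicted products can be compared with
    gel-observed signature weights. Includes a synthetic-substrate
    generator with recorded ground truth and a batch command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
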