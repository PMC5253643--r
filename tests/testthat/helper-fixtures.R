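# Shared fixtures for the suite. All data is generated in code; the only
# embedded sequence is the worked-example record exposed by
# table4_record().

builtins <- builtin_patterns()
cs3 <- builtins$caspase3
cp2 <- builtins$calpain2

# occurrence data frames restricted to the coordinate columns, for
# order-insensitive comparisons
occ_coords <- function(occ) {
  out <- occ[, c("pattern", "start", "end", "cleavage_after")]
  rownames(out) <- NULL
  out
}

expect_same_occurrences <- function(a, b) {
  expect_equal(occ_coords(a), occ_coords(b))
}

# an adversarial D/E-rich generator: long runs of D and E interspersed
# with other residues produce dense, overlapping DXXD hits
random_de_rich <- function(len) {
  paste(sample(c("D", "E", "A", "V"), len, replace = TRUE,
               prob = c(0.4, 0.4, 0.1, 0.1)), collapse = "")
}

write_temp_fasta <- function(records, width = 60L) {
  tf <- tempfile(fileext = ".fasta")
  write_fasta(records, tf, width = width)
  tf
}

# brute-force union of fragments over all non-empty cut-site subsets:
# the independent oracle for distinct_fragments()
brute_force_distinct <- function(protein, sites) {
  k <- length(sites)
  if (k == 0L) return(data.frame(start = integer(), end = integer()))
  pieces <- list()
  for (bits in seq_len(2^k - 1L)) {
    subset <- sites[bitwAnd(bits, 2^(seq_len(k) - 1L)) > 0L]
    fr <- fragments_for_subset(protein, subset)
    pieces[[length(pieces) + 1L]] <- fr[, c("start", "end")]
  }
  out <- unique(do.call(rbind, pieces))
  out <- out[order(out$start, out$end), ]
  rownames(out) <- NULL
  out
}

# beta-II-spectrin is external validation data (GenBank M96803), not
# shipped; validation tests run only when the user supplies it
spectrin_or_skip <- function() {
  path <- spectrin_fasta_path()
  testthat::skip_if(is.na(path),
                    "beta-II-spectrin FASTA (M96803) not supplied")
  read_fasta(path, strict = FALSE)[[1]]
}
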