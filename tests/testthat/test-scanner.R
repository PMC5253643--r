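test_that("scoring table follows the local-alignment recurrence", {
  # hand-computed 5x5 table for substrate DEED vs pattern D,X,X,D
  # (match +1, mismatch/gap -4, floor 0)
  tab <- build_scoring_table("DEED", cs3)
  expected <- matrix(c(
    0L, 0L, 0L, 0L, 0L,
    0L, 1L, 0L, 0L, 1L,
    0L, 1L, 2L, 1L, 1L,
    0L, 1L, 2L, 3L, 2L,
    0L, 1L, 0L, 0L, 4L
  ), nrow = 5, byrow = TRUE)
  expect_identical(matrix(as.vector(tab), nrow = 5L), expected)
  expect_equal(dim(tab), c(5L, 5L))
  # full score m reached exactly at the column of the last D
  expect_equal(which(tab[5, ] == 4L), 5L)

  empty <- build_scoring_table("", cs3)
  expect_equal(dim(empty), c(5L, 1L))
  expect_true(all(empty == 0L))

  # no full match: the maximum cell stays below m
  expect_lt(max(build_scoring_table("AAAA", cs3)), 4L)

  # invariants: non-negative, bounded by m, dimensions (m+1) x (n+1)
  for (n in c(10L, 100L, 1000L)) {
    s <- paste(sample(AA_STANDARD, n, replace = TRUE), collapse = "")
    t2 <- build_scoring_table(s, cs3)
    expect_equal(dim(t2), c(5L, n + 1L))
    expect_true(all(t2 >= 0L & t2 <= 4L))
  }
})

test_that("extraction keeps only full-length gap-free alignments", {
  # overlapping hits are both retained
  p <- protein_record("x", "DEEDEED")
  occ <- scan_protein(p, cs3)
  expect_equal(occ$start, c(1L, 4L))
  expect_equal(occ$end, c(4L, 7L))

  # near-misses with substitutions or INDELs relative to DXXD are pruned
  for (s in c("DEEAD",   # insertion inside the consensus
              "DED",     # deletion
              "DEEE",    # substitution at a fixed position
              "EEED")) {
    expect_equal(nrow(scan_protein(protein_record("x", s), cs3)), 0L)
  }

  # dimension mismatch between table and sequence is an error
  tab <- build_scoring_table("DEED", cs3)
  expect_error(extract_occurrences(tab, "DEEDA", cs3),
               class = "cleavescan_input_error")
})

test_that("every reported occurrence satisfies the window predicate and coordinate invariants", {
  set.seed(11)
  for (rep in 1:25) {
    seqstr <- random_de_rich(sample(20:300, 1))
    p <- protein_record("r", seqstr)
    for (pat in list(cs3, cp2)) {
      occ <- scan_protein(p, pat)
      if (nrow(occ) == 0L) next
      expect_true(all(diff(occ$start) > 0))                  # strictly increasing
      expect_equal(occ$end - occ$start + 1L, rep(pat$length, nrow(occ)))
      expect_equal(occ$cleavage_after, occ$start + pat$cleavage_offset - 1L)
      expect_equal(occ$consensus,
                   substring(seqstr, occ$start, occ$end))
      expect_true(all(vapply(occ$start, matches_at, logical(1),
                             sequence = seqstr, pattern = pat)))
    }
  }
})

test_that("DP scan equals the naive sliding-window oracle on random and adversarial sequences", {
  set.seed(42)
  for (rep in 1:120) {
    len <- sample(1:400, 1)
    seqstr <- if (rep %% 3 == 0) random_de_rich(len) else
      paste(sample(AA_STANDARD, len, replace = TRUE), collapse = "")
    p <- protein_record("r", seqstr)
    for (pat in list(cs3, cp2)) {
      expect_same_occurrences(scan_protein(p, pat), naive_scan(p, pat))
    }
  }
  # shorter-than-pattern records give empty results from both routes
  tiny <- protein_record("t", "DE")
  expect_equal(nrow(naive_scan(tiny, cs3)), 0L)
  expect_equal(nrow(scan_protein(tiny, cs3)), 0L)
})

test_that("degenerate single-wildcard pattern hits every residue", {
  any1 <- parse_pattern("X|", name = "any")
  p <- protein_record("x", "MKDEV")
  occ <- scan_protein(p, any1)
  expect_equal(occ$start, 1:5)
  expect_equal(occ$cleavage_after, 1:5)
})

test_that("context widening pads the displayed consensus without moving coordinates", {
  p <- protein_record("x", "AAETVDAA")
  plain <- scan_protein(p, cp2)
  wide <- scan_protein(p, cp2, context = 2)
  expect_equal(plain$start, wide$start)
  expect_equal(plain$end, wide$end)
  hit <- which(plain$consensus == "VD")
  expect_length(hit, 1L)
  expect_equal(wide$consensus[hit], "ETVDAA")
  # clipped at the sequence boundaries
  edge <- scan_protein(protein_record("y", "VDAA"), cp2, context = 3)
  expect_equal(edge$consensus[1], "VDAA")
  expect_equal(edge$start[1], 1L)
})

test_that("scan_many streams per-protein results identical to scan_protein", {
  set.seed(7)
  prots <- random_proteome(12, c(30, 120), seed = 99)
  res <- scan_many(prots, list(cs3, cp2))
  expect_named(res, unname(vapply(prots, `[[`, character(1), "id")))
  for (p in prots) {
    expect_named(res[[p$id]], c("caspase3", "calpain2"))
    expect_equal(res[[p$id]]$caspase3, scan_protein(p, cs3))
    expect_equal(res[[p$id]]$calpain2, naive_scan(p, cp2))
  }
  expect_equal(scan_many(list(), cs3), structure(list(), names = character()))
  dup <- list(prots[[1]], prots[[1]])
  expect_error(scan_many(dup, cs3), class = "cleavescan_input_error")
})
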