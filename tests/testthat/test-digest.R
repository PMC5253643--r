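test_that("cut sites are deduplicated, sorted, and terminal cuts suppressed", {
  # overlapping DEED hits contribute distinct sites
  p <- protein_record("x", paste0("AAA", "DEEDEED", strrep("A", 20)))
  occ <- scan_protein(p, cs3)
  expect_equal(occ$start, c(4L, 7L))
  expect_equal(cut_sites(occ, p), c(7L, 10L))

  # a hit ending at the final residue yields no usable cut
  pterm <- protein_record("t", "ADEED")
  expect_equal(cut_sites(scan_protein(pterm, cs3), pterm), integer())

  # two occurrences sharing one cleavage position collapse to one site
  pshare <- protein_record("s", "AVDAAA")
  both <- rbind(scan_protein(pshare, cp2),
                scan_protein(pshare, parse_pattern("[LVI]D|", name = "ld")))
  expect_equal(cut_sites(both, pshare), 3L)

  # occurrences must belong to the protein
  other <- scan_protein(protein_record("y", "ADEEDA"), cs3)
  expect_error(cut_sites(other, p), class = "cleavescan_input_error")
})

test_that("a k-site subset partitions the protein into k + 1 fragments", {
  p <- protein_record("x", paste(sample(AA_STANDARD, 60, replace = TRUE),
                                 collapse = ""))
  expect_equal(fragments_for_subset(p, integer())[, c("start", "end")],
               data.frame(start = 1L, end = 60L))
  two <- fragments_for_subset(p, c(40L, 12L))  # order-insensitive
  expect_equal(two$start, c(1L, 13L, 41L))
  expect_equal(two$end, c(12L, 40L, 60L))
  expect_equal(two$start, two$left_cut + 1L)
  expect_equal(two$end, two$right_cut)
  expect_identical(paste(two$sequence, collapse = ""), p$sequence)
  expect_error(fragments_for_subset(p, 60L), class = "cleavescan_input_error")
  expect_error(fragments_for_subset(p, 0L), class = "cleavescan_input_error")
})

test_that("scenario enumeration covers every non-empty cut-site combination", {
  p <- protein_record("x", strrep("A", 30))
  two <- enumerate_scenarios(p, c(10L, 20L))
  expect_length(two, 3L)  # cut at first, at second, at both
  expect_equal(sort(unname(vapply(two, nrow, integer(1)))), c(2L, 2L, 3L))
  both <- two[["10+20"]]
  expect_equal(both$start[2], 11L)   # middle fragment between the two cuts
  expect_equal(both$end[2], 20L)

  three <- enumerate_scenarios(p, c(5L, 10L, 20L))
  expect_length(three, 7L)
  # total fragment slots over all non-empty subsets: sum over subsets of
  # (|s| + 1) = k * 2^(k-1) + (2^k - 1) = 19 for k = 3
  slot_total <- sum(vapply(1:3, function(sz) choose(3, sz) * (sz + 1L),
                           numeric(1)))
  expect_equal(sum(vapply(three, nrow, integer(1))), slot_total)
  expect_equal(slot_total, 19)

  expect_length(enumerate_scenarios(p, 10L), 1L)
  expect_length(enumerate_scenarios(p, integer()), 0L)

  # every scenario partitions the substrate exactly
  for (fr in three) {
    expect_equal(sum(fr$end - fr$start + 1L), p$length)
    expect_identical(paste(fr$sequence, collapse = ""), p$sequence)
  }

  expect_error(enumerate_scenarios(p, seq(2, 28, by = 2), max_sites = 8),
               class = "cleavescan_guard_error")
})

test_that("distinct fragments match the closed form and the subset-union oracle", {
  set.seed(5)
  for (k in 0:10) {
    n <- 120L
    sites <- sort(sample(seq_len(n - 1L), k))
    p <- protein_record("x", paste(sample(AA_STANDARD, n, replace = TRUE),
                                   collapse = ""))
    df <- distinct_fragments(p, sites)
    expect_equal(nrow(df), (k + 1) * (k + 2) / 2 - 1)
    expect_false(any(duplicated(df[, c("start", "end")])))
    expect_true(all(df$end >= df$start))
    if (k <= 6) {  # brute-force subset union stays cheap at small k
      expect_equal(df[, c("start", "end")], brute_force_distinct(p, sites),
                   ignore_attr = TRUE)
    }
  }
  expect_equal(nrow(distinct_fragments(
    protein_record("e", strrep("A", 10)), integer())), 0L)
})

test_that("combined digestion merges cut sites across proteases with provenance", {
  # one caspase site and one calpain site -> k = 2 -> 5 distinct fragments
  pt <- plant_motifs(80, data.frame(pattern = c("caspase3", "calpain2"),
                                    start = c(20L, 50L)),
                     seed = 3, collision_free = TRUE)
  d <- combined_digest(pt$record, builtin_patterns(), mode = "distinct")
  expect_s3_class(d, "digest_result")
  expect_equal(d$cut_sites, sort(pt$truth$cleavage_after))
  expect_equal(nrow(d$fragments), 5L)

  # single-pattern digest is the one-protease special case
  dc <- combined_digest(pt$record, cs3, mode = "distinct")
  expect_equal(dc$cut_sites,
               cut_sites(scan_protein(pt$record, cs3), pt$record))

  # cut-site set of the combined digest is the union of the single digests
  dv <- combined_digest(pt$record, cp2, mode = "distinct")
  expect_equal(d$cut_sites, sort(union(dc$cut_sites, dv$cut_sites)))

  # a bond targeted by two proteases becomes one site with joint provenance
  pshare <- protein_record("s", "AVDAAA")
  dd <- combined_digest(pshare, list(cp2, parse_pattern("XD|", name = "xd")),
                        mode = "per-site")
  expect_equal(dd$cut_sites, 3L)
  expect_equal(dd$site_provenance$proteases, "calpain2,xd")

  expect_error(combined_digest(pshare, list()),
               class = "cleavescan_input_error")
})

test_that("per-site mode reports one two-fragment scenario per cleavage site", {
  p <- protein_record("x", paste0(strrep("A", 10), "DEED", strrep("A", 10)))
  d <- combined_digest(p, cs3, mode = "per-site")
  expect_equal(d$cut_sites, 14L)
  expect_length(d$scenarios, 1L)
  fr <- d$scenarios[["14"]]
  expect_equal(fr$start, c(1L, 15L))
  expect_equal(fr$end, c(14L, 24L))
})
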