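# Per-position membership of each substrate residue in each pattern
# position-set. Returns an n x m logical matrix; column i answers "does
# substrate residue j satisfy pattern position i".
pattern_membership <- function(sequence, pattern, permissive = FALSE) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  memb <- vapply(seq_len(pattern$length), function(i) {
    if (permissive && pattern$wildcard[[i]]) rep(TRUE, length(chars))
    else chars %in% pattern$positions[[i]]
  }, logical(length(chars)))
  matrix(memb, nrow = length(chars), ncol = pattern$length)
}

empty_occurrences <- function() {
  data.frame(protein_id = character(), pattern = character(),
             consensus = character(), start = integer(), end = integer(),
             cleavage_after = integer(), stringsAsFactors = FALSE)
}

occurrence_frame <- function(protein_id, pattern, starts, sequence,
                             context = 0L) {
  if (length(starts) == 0L) return(empty_occurrences())
  starts <- sort(as.integer(starts))
  m <- pattern$length
  n <- nchar(sequence)
  lo <- pmax(1L, starts - as.integer(context))
  hi <- pmin(n, starts + m - 1L + as.integer(context))
  data.frame(
    protein_id = protein_id,
    pattern = pattern$name,
    consensus = substring(sequence, lo, hi),
    start = starts,
    end = starts + m - 1L,
    cleavage_after = starts + pattern$cleavage_offset - 1L,
    stringsAsFactors = FALSE
  )
}

#' Build the local-alignment scoring table
#'
#' Dynamic-programming table of a modified Smith-Waterman local alignment
#' between a consensus pattern (rows, length `m`) and a substrate
#' (columns, length `n`). A substrate residue scores +1 against a pattern
#' position iff it belongs to that position's residue-set; mismatches and
#' gaps are penalized by `-m` so that no alignment containing a mismatch at
#' a fixed position or any insertion/deletion can reach the full score `m`.
#' Scores are floored at 0 (local alignment). The table occupies
#' `(m + 1) x (n + 1)` integer cells.
#'
#' @param sequence Amino-acid string (may be empty).
#' @param pattern A [protease_pattern].
#' @param permissive Wildcard matching of non-standard letters, see
#'   [matches_at()].
#' @return Integer matrix of class `scoring_table` with attributes
#'   `pattern_name` and `n` (substrate length); row `i + 1` / column
#'   `j + 1` holds the score for pattern prefix `i` vs substrate prefix `j`.
#' @seealso [extract_occurrences()], [scan_protein()]
#' @export
build_scoring_table <- function(sequence, pattern, permissive = FALSE) {
  stopifnot(inherits(pattern, "protease_pattern"))
  sequence <- toupper(sequence)
  m <- pattern$length
  n <- nchar(sequence)
  H <- matrix(0L, nrow = m + 1L, ncol = n + 1L)
  if (n > 0L) {
    memb <- pattern_membership(sequence, pattern, permissive)
    gap <- m  # gap/mismatch penalty magnitude
    for (i in seq_len(m)) {
      score <- ifelse(memb[, i], 1L, -gap)
      diag <- H[i, seq_len(n)] + score
      up <- H[i, seq_len(n) + 1L] - gap
      # the left (insertion) term H[i+1, j-1] - gap never exceeds the 0
      # floor because every cell is <= m = gap, so the row vectorizes
      H[i + 1L, seq_len(n) + 1L] <- pmax(0L, diag, up)
    }
  }
  structure(H, class = c("scoring_table", "matrix"),
            pattern_name = pattern$name, n = n)
}

#' Extract full-length, gap-free consensus occurrences from a scoring table
#'
#' Keeps exactly the alignments of full pattern length with the maximal
#' score `m` and a gap-free traceback; alignments containing insertions or
#' deletions, and partial alignments, are pruned. Overlapping occurrences
#' are all retained; output is ordered by start position.
#'
#' @param table A `scoring_table` built from `(sequence, pattern)`.
#' @param sequence The substrate the table was built from.
#' @param pattern The [protease_pattern] the table was built from.
#' @param protein_id Identifier recorded on each occurrence.
#' @param permissive,context See [scan_protein()].
#' @return Occurrence data frame with columns `protein_id`, `pattern`,
#'   `consensus`, `start`, `end`, `cleavage_after` (the residue index after
#'   which the bond is cut: `start + cleavage_offset - 1`).
#' @export
extract_occurrences <- function(table, sequence, pattern,
                                protein_id = "seq", permissive = FALSE,
                                context = 0L) {
  stopifnot(inherits(table, "scoring_table"),
            inherits(pattern, "protease_pattern"))
  sequence <- toupper(sequence)
  m <- pattern$length
  n <- nchar(sequence)
  if (nrow(table) != m + 1L || ncol(table) != n + 1L) {
    stop_input("scoring table dimensions do not match (sequence, pattern)")
  }
  if (n < m) return(empty_occurrences())
  ends <- which(table[m + 1L, -1L] == m)   # full score reached at column j
  starts <- ends - m + 1L
  if (length(starts) > 0L) {
    # gap-free traceback: the only way to score m in m pattern rows is the
    # all-match diagonal; verify each cell and residue along it
    gapfree <- vapply(starts, function(s) {
      js <- s:(s + m - 1L)
      all(table[cbind(2L:(m + 1L), js + 1L)] == seq_len(m)) &&
        matches_at(sequence, s, pattern, permissive = permissive)
    }, logical(1))
    starts <- starts[gapfree]
  }
  occurrence_frame(protein_id, pattern, starts, sequence, context)
}

#' Naive sliding-window consensus scan
#'
#' Independent reference scanner: slides a window of pattern length over
#' every start position and applies the per-window membership predicate.
#' Serves as the oracle the dynamic-programming scanner is verified
#' against; both must agree on every input.
#'
#' @inheritParams scan_protein
#' @return Occurrence data frame, sorted by start (see
#'   [extract_occurrences()]).
#' @export
naive_scan <- function(protein, pattern, permissive = FALSE, context = 0L) {
  stopifnot(inherits(protein, "protein_record"),
            inherits(pattern, "protease_pattern"))
  m <- pattern$length
  n <- protein$length
  if (n < m) return(empty_occurrences())
  memb <- pattern_membership(protein$sequence, pattern, permissive)
  idx <- seq_len(n - m + 1L)
  ok <- rep(TRUE, length(idx))
  for (i in seq_len(m)) ok <- ok & memb[idx + i - 1L, i]
  occurrence_frame(protein$id, pattern, idx[ok], protein$sequence, context)
}

#' Scan one protein for all occurrences of one consensus pattern
#'
#' Builds the local-alignment scoring table and extracts the full-score,
#' gap-free occurrences. Its contract is exact equivalence with
#' [naive_scan()] on every input: the alignment machinery reduces the scan
#' to exact consensus matching once gapped and partial alignments are
#' pruned.
#'
#' @param protein A [protein_record].
#' @param pattern A [protease_pattern].
#' @param permissive Let wildcard positions match non-standard letters.
#' @param context Non-negative display padding: the `consensus` column is
#'   widened by up to `context` residues on each side (the printed
#'   positions `start`/`end` are never altered). Useful to display a short
#'   calpain core such as `VD` with its N-terminal context, e.g. `ETVD`.
#' @return Occurrence data frame, sorted by start (see
#'   [extract_occurrences()]).
#' @examples
#' p <- protein_record("demo", "ADEEDEEDA")
#' scan_protein(p, builtin_patterns()$caspase3)
#' @export
scan_protein <- function(protein, pattern, permissive = FALSE, context = 0L) {
  stopifnot(inherits(protein, "protein_record"))
  tab <- build_scoring_table(protein$sequence, pattern, permissive)
  extract_occurrences(tab, protein$sequence, pattern,
                      protein_id = protein$id, permissive = permissive,
                      context = context)
}

#' Scan many proteins with many patterns
#'
#' Streams over proteins one at a time, so peak scoring-table storage stays
#' proportional to `m x n` for the current pair regardless of how many
#' sequences are processed.
#'
#' @param proteins List of [protein_record] objects with unique ids.
#' @param patterns List of [protease_pattern] objects (or a single one).
#' @param permissive,context See [scan_protein()].
#' @param progress Emit a per-protein progress message.
#' @return Nested named list: `result[[protein_id]][[pattern_name]]` is the
#'   occurrence data frame for that pair, identical to
#'   `scan_protein(protein, pattern)`.
#' @export
scan_many <- function(proteins, patterns, permissive = FALSE, context = 0L,
                      progress = FALSE) {
  if (inherits(patterns, "protease_pattern")) patterns <- list(patterns)
  ids <- vapply(proteins, function(p) p$id, character(1))
  if (anyDuplicated(ids)) {
    stop_input("duplicate protein id(s): ",
               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  pat_names <- vapply(patterns, function(p) p$name, character(1))
  out <- lapply(seq_along(proteins), function(k) {
    if (progress) message("scanning ", ids[[k]], " (", k, "/",
                          length(proteins), ")")
    hits <- lapply(patterns, function(pat) {
      scan_protein(proteins[[k]], pat, permissive = permissive,
                   context = context)
    })
    names(hits) <- pat_names
    hits
  })
  names(out) <- ids
  out
}
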