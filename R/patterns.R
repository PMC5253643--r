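#' The 20 standard amino acids
#'
#' One-letter codes of the standard proteinogenic amino acids, in
#' alphabetical order. Wildcard pattern positions match exactly this set.
#'
#' @export
AA_STANDARD <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

#' Construct a protease consensus pattern
#'
#' A `protease_pattern` models the positional specificity of a protease as
#' an ordered list of residue sets: a singleton set is a fixed residue, the
#' full 20-letter set is the wildcard `X`, and any intermediate subset is an
#' alternative group such as `[LVI]`. The scissile bond falls immediately
#' after pattern position `cleavage_offset`.
#'
#' @param name Text label for the protease (e.g. `"caspase3"`).
#' @param positions List of character vectors, each a non-empty subset of
#'   [AA_STANDARD]; element `i` is the residue set allowed at pattern
#'   position `i`.
#' @param cleavage_offset Integer in `[1, length(positions)]`: the bond is
#'   cut between pattern position `cleavage_offset` and the next substrate
#'   residue.
#' @return An object of class `protease_pattern` with elements `name`,
#'   `positions` (sorted residue sets), `cleavage_offset`, `length`, and
#'   `wildcard` (logical: which positions are full-alphabet wildcards).
#' @seealso [builtin_patterns()], [parse_pattern()], [count_instances()]
#' @examples
#' protease_pattern("caspase3",
#'   list("D", AA_STANDARD, AA_STANDARD, "D"),
#'   cleavage_offset = 4)
#' @export
protease_pattern <- function(name, positions, cleavage_offset) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop_input("pattern name must be a non-empty string")
  }
  if (!is.list(positions) || length(positions) == 0L) {
    stop_input("pattern '", name, "': positions must be a non-empty list")
  }
  positions <- lapply(positions, function(set) {
    set <- sort(unique(toupper(as.character(set))))
    if (length(set) == 0L || !all(set %in% AA_STANDARD)) {
      stop_input("pattern '", name, "': every position must be a non-empty ",
                 "subset of the 20 standard amino acids")
    }
    set
  })
  m <- length(positions)
  cleavage_offset <- as.integer(cleavage_offset)
  if (length(cleavage_offset) != 1L || is.na(cleavage_offset) ||
      cleavage_offset < 1L || cleavage_offset > m) {
    stop_input("pattern '", name, "': cleavage_offset must lie in [1, ", m, "]")
  }
  structure(
    list(
      name = name,
      positions = positions,
      cleavage_offset = cleavage_offset,
      length = m,
      wildcard = vapply(positions, function(s) length(s) == 20L, logical(1))
    ),
    class = "protease_pattern"
  )
}

#' @export
print.protease_pattern <- function(x, ...) {
  cat("<protease_pattern> ", x$name, ": ", format_pattern(x),
      "  (", count_instances(x), " literal instances)\n", sep = "")
  invisible(x)
}

#' Built-in protease consensus models
#'
#' Returns the two proteases whose activation distinguishes neural cell
#' death modes: caspase-3 (apoptosis executioner; consensus `DXXD` with the
#' cut after the final aspartate) and calpain-2 (calcium-dependent, active
#' in necrosis and some apoptosis; consensus `[LVI]X` with the cut after the
#' second residue, equivalent to the three patterns LX, VX and IX).
#'
#' @return Named list of [protease_pattern] objects with entries
#'   `caspase3` and `calpain2`.
#' @examples
#' builtin_patterns()$caspase3
#' @export
builtin_patterns <- function() {
  list(
    caspase3 = protease_pattern(
      "caspase3",
      list("D", AA_STANDARD, AA_STANDARD, "D"),
      cleavage_offset = 4L
    ),
    calpain2 = protease_pattern(
      "calpain2",
      list(c("L", "V", "I"), AA_STANDARD),
      cleavage_offset = 2L
    )
  )
}

#' Count the literal words matching a pattern
#'
#' The number of distinct literal amino-acid words a consensus pattern can
#' match: the product of the residue-set sizes over its positions. The
#' caspase-3 model `DXXD` has 400 instances (20 x 20 for the two wildcard
#' positions), the calpain-2 model `[LVI]X` has 60 (3 x 20).
#'
#' @param pattern A [protease_pattern].
#' @return Non-negative integer count.
#' @examples
#' count_instances(builtin_patterns()$caspase3)  # 400
#' count_instances(builtin_patterns()$calpain2)  # 60
#' @export
count_instances <- function(pattern) {
  stopifnot(inherits(pattern, "protease_pattern"))
  prod(vapply(pattern$positions, length, integer(1)))
}

#' Test a pattern against one substrate window
#'
#' True iff every substrate residue in the window starting at `start`
#' belongs to the corresponding pattern position-set. Non-standard letters
#' (B, Z, J, U, O, X, *) never match a fixed position; by default they do
#' not match a wildcard position either, so ambiguity codes cannot fabricate
#' cleavage sites. `permissive = TRUE` lets wildcard positions accept any
#' letter.
#'
#' @param sequence Amino-acid string (upper-cased internally).
#' @param start 1-based window start.
#' @param pattern A [protease_pattern].
#' @param permissive Should wildcard positions match non-standard letters?
#' @return Logical scalar.
#' @examples
#' cs3 <- builtin_patterns()$caspase3
#' matches_at("ADEEDA", 2, cs3)  # TRUE: DEED
#' matches_at("ADEEEA", 2, cs3)  # FALSE: position 4 is E
#' @export
matches_at <- function(sequence, start, pattern, permissive = FALSE) {
  stopifnot(inherits(pattern, "protease_pattern"))
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  start <- as.integer(start)
  if (length(start) != 1L || is.na(start) || start < 1L ||
      start + pattern$length - 1L > n) {
    stop_input("window [", start, ", ", start + pattern$length - 1L,
               "] falls outside sequence of length ", n)
  }
  window <- substring(sequence, start:(start + pattern$length - 1L),
                      start:(start + pattern$length - 1L))
  ok <- mapply(function(res, set) res %in% set, window, pattern$positions)
  if (permissive) ok <- ok | pattern$wildcard
  all(ok)
}

#' Parse a pattern specification string
#'
#' The mini-language uses one-letter amino-acid codes for fixed residues,
#' `X` (or `x`) for a wildcard, `[...]` for an alternative group, and a
#' single `|` marking the cut point. `"DXXD|"` is the caspase-3 model and
#' `"[LVI]X|"` the calpain-2 model. The cut mark may sit inside the pattern
#' (e.g. `"DX|XD"`) but not before its first position.
#'
#' @param spec Specification string.
#' @param name Label for the resulting pattern; defaults to the canonical
#'   formatted spec.
#' @return A [protease_pattern]. [format_pattern()] of the result
#'   reproduces the canonical spec string.
#' @examples
#' parse_pattern("DXXD|")
#' parse_pattern("[LVI]X|", name = "calpain2")
#' @export
parse_pattern <- function(spec, name = NULL) {
  if (!is.character(spec) || length(spec) != 1L || !nzchar(spec)) {
    stop_input("pattern spec must be a non-empty string")
  }
  chars <- strsplit(spec, "", fixed = TRUE)[[1]]
  positions <- list()
  cut_after <- NA_integer_
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[[i]]
    if (ch == "|") {
      if (!is.na(cut_after)) stop_input("spec '", spec, "': multiple '|' cut marks")
      if (length(positions) == 0L) {
        stop_input("spec '", spec, "': '|' before any pattern position")
      }
      cut_after <- length(positions)
      i <- i + 1L
    } else if (ch == "[") {
      close <- which(chars == "]" & seq_along(chars) > i)
      if (length(close) == 0L) stop_input("spec '", spec, "': unclosed '['")
      close <- close[[1]]
      group <- toupper(chars[(i + 1L):(close - 1L)])
      if (length(group) == 0L || !all(group %in% AA_STANDARD)) {
        stop_input("spec '", spec, "': invalid alternative group")
      }
      positions <- c(positions, list(group))
      i <- close + 1L
    } else if (toupper(ch) == "X") {
      positions <- c(positions, list(AA_STANDARD))
      i <- i + 1L
    } else if (toupper(ch) %in% AA_STANDARD) {
      positions <- c(positions, list(toupper(ch)))
      i <- i + 1L
    } else {
      stop_input("spec '", spec, "': unknown character '", ch, "'")
    }
  }
  if (length(positions) == 0L) stop_input("spec '", spec, "': no pattern positions")
  if (is.na(cut_after)) stop_input("spec '", spec, "': missing '|' cleavage mark")
  pat <- protease_pattern(name %||% "custom", positions, cut_after)
  if (is.null(name)) pat$name <- format_pattern(pat)
  pat
}

#' Format a pattern as its canonical specification string
#'
#' Inverse of [parse_pattern()] on canonical specs: singleton sets print as
#' their residue, the full alphabet prints as `X`, other subsets as
#' `[...]` in alphabetical order, with `|` at the cut point.
#'
#' @param pattern A [protease_pattern].
#' @return Canonical spec string.
#' @examples
#' format_pattern(builtin_patterns()$calpain2)  # "[LVI]X|"
#' @export
format_pattern <- function(pattern) {
  stopifnot(inherits(pattern, "protease_pattern"))
  parts <- vapply(seq_len(pattern$length), function(i) {
    set <- pattern$positions[[i]]
    if (length(set) == 20L) {
      "X"
    } else if (length(set) == 1L) {
      set
    } else {
      # builtin calpain-2 is conventionally written [LVI]; keep that order
      if (identical(set, c("I", "L", "V"))) set <- c("L", "V", "I")
      paste0("[", paste(set, collapse = ""), "]")
    }
  }, character(1))
  paste0(
    paste(parts[seq_len(pattern$cleavage_offset)], collapse = ""), "|",
    if (pattern$cleavage_offset < pattern$length) {
      paste(parts[(pattern$cleavage_offset + 1L):pattern$length], collapse = "")
    } else ""
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# condition helpers: input errors map to CLI exit 2, guard errors to exit 3
stop_input <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("cleavescan_input_error", "error")))
}

stop_guard <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("cleavescan_guard_error", "error")))
}
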