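# Fragment rows share one schema everywhere: protein_id, scenario label,
# start/end (1-based inclusive), sequence, and the bounding cut positions
# (left_cut = 0 at the N-terminus, right_cut = protein length at the
# C-terminus; start = left_cut + 1, end = right_cut).
empty_fragments <- function() {
  data.frame(protein_id = character(), scenario = character(),
             start = integer(), end = integer(), sequence = character(),
             left_cut = integer(), right_cut = integer(),
             stringsAsFactors = FALSE)
}

fragment_frame <- function(protein, bounds_lo, bounds_hi, scenario) {
  if (length(bounds_lo) == 0L) return(empty_fragments())
  data.frame(
    protein_id = protein$id,
    scenario = scenario,
    start = bounds_lo + 1L,
    end = bounds_hi,
    sequence = substring(protein$sequence, bounds_lo + 1L, bounds_hi),
    left_cut = bounds_lo,
    right_cut = bounds_hi,
    stringsAsFactors = FALSE
  )
}

#' Derive cut sites from consensus occurrences
#'
#' Deduplicated, sorted cleavage positions (`cleavage_after`) of the given
#' occurrences. A cut falling after the protein's final residue is dropped:
#' cleaving there would yield an empty C-terminal product.
#'
#' @param occurrences Occurrence data frame (possibly from several
#'   patterns, rbind-ed).
#' @param protein The [protein_record] the occurrences belong to.
#' @return Sorted unique integer positions, each strictly less than the
#'   protein length.
#' @examples
#' p <- protein_record("x", "ADEEDEEDA")
#' occ <- scan_protein(p, builtin_patterns()$caspase3)
#' cut_sites(occ, p)
#' @export
cut_sites <- function(occurrences, protein) {
  stopifnot(inherits(protein, "protein_record"))
  if (nrow(occurrences) == 0L) return(integer())
  if (!all(occurrences$protein_id == protein$id)) {
    stop_input("occurrences reference protein(s) other than '",
               protein$id, "'")
  }
  sites <- sort(unique(as.integer(occurrences$cleavage_after)))
  sites[sites < protein$length]
}

#' Fragments produced by cleaving at one subset of cut sites
#'
#' Cleaving a protein of length `n` at `k` positions partitions it into
#' `k + 1` contiguous fragments; the empty subset returns the intact
#' protein as a single fragment.
#'
#' @param protein A [protein_record].
#' @param subset Integer cut positions, each in `(0, length)`; cleavage is
#'   after the given residue.
#' @param scenario Label recorded on the rows (defaults to the site list,
#'   e.g. `"619+622"`, or `"intact"`).
#' @return Ordered fragment data frame (see package fragment schema);
#'   `length(subset) + 1` rows whose sequences concatenate to the protein.
#' @export
fragments_for_subset <- function(protein, subset, scenario = NULL) {
  stopifnot(inherits(protein, "protein_record"))
  n <- protein$length
  subset <- sort(unique(as.integer(subset)))
  if (length(subset) > 0L && (min(subset) < 1L || max(subset) >= n)) {
    stop_input("cut position(s) outside (0, ", n, ")")
  }
  scenario <- scenario %||%
    if (length(subset) == 0L) "intact" else paste(subset, collapse = "+")
  bounds <- c(0L, subset, n)
  fragment_frame(protein, bounds[-length(bounds)], bounds[-1L], scenario)
}

#' Enumerate all cleavage-combination scenarios
#'
#' Each non-empty subset of the cut sites is one biologically possible
#' cleavage incidence; with `k` sites there are `2^k - 1` scenarios. For
#' two sites this yields the three canonical cases: cut at the first site
#' only, at the second only, and at both (the latter producing the short
#' middle fragment between the two cuts).
#'
#' @param protein A [protein_record].
#' @param sites Sorted unique cut positions.
#' @param max_sites Combination-explosion guard: enumeration is refused for
#'   `k > max_sites` (default 16, i.e. at most 65535 scenarios); use
#'   [distinct_fragments()] at larger `k`.
#' @return Named list mapping each scenario label (`"c1+c2+..."`) to its
#'   fragment data frame; subsets ordered by size, then lexicographically.
#' @export
enumerate_scenarios <- function(protein, sites, max_sites = 16L) {
  stopifnot(inherits(protein, "protein_record"))
  sites <- sort(unique(as.integer(sites)))
  k <- length(sites)
  if (k > max_sites) {
    stop_guard("refusing to enumerate 2^", k, " - 1 cleavage scenarios ",
               "(k = ", k, " > max_sites = ", max_sites, "); raise ",
               "max_sites or use distinct_fragments()")
  }
  if (k == 0L) return(structure(list(), names = character()))
  subsets <- unlist(lapply(seq_len(k), function(sz) {
    lapply(utils::combn(seq_len(k), sz, simplify = FALSE),
           function(idx) sites[idx])
  }), recursive = FALSE)
  out <- lapply(subsets, function(s) fragments_for_subset(protein, s))
  names(out) <- vapply(subsets, paste, character(1), collapse = "+")
  out
}

#' All distinct breakdown products without subset enumeration
#'
#' The union of fragments over every non-empty cut-site subset, computed
#' directly: any pair of boundaries drawn from `{0} U sites U {length}`
#' delimits one candidate fragment, except the intact `(0, length)` pair
#' (the uncleaved protein is not a breakdown product). With `k` sites this
#' gives `(k + 1)(k + 2) / 2 - 1` distinct fragments in time polynomial in
#' `k`, versus the exponential scenario enumeration.
#'
#' @param protein A [protein_record].
#' @param sites Sorted unique cut positions.
#' @return Fragment data frame, scenario labelled `"distinct"`, ordered by
#'   (start, end); no duplicate `(start, end)` pairs, no empty fragments.
#' @export
distinct_fragments <- function(protein, sites) {
  stopifnot(inherits(protein, "protein_record"))
  sites <- sort(unique(as.integer(sites)))
  n <- protein$length
  if (length(sites) > 0L && (min(sites) < 1L || max(sites) >= n)) {
    stop_input("cut position(s) outside (0, ", n, ")")
  }
  bounds <- c(0L, sites, n)
  b <- length(bounds)
  if (b == 2L) return(empty_fragments())
  pairs <- utils::combn(seq_len(b), 2L)
  lo <- bounds[pairs[1L, ]]
  hi <- bounds[pairs[2L, ]]
  keep <- !(lo == 0L & hi == n)
  ord <- order(lo[keep], hi[keep])
  fragment_frame(protein, lo[keep][ord], hi[keep][ord], "distinct")
}

#' Digest a protein with one or more proteases
#'
#' Scans the substrate with every pattern, merges and deduplicates the cut
#' sites across proteases (a bond targeted by several proteases becomes a
#' single site with multi-protease provenance), then generates breakdown
#' products in the requested mode:
#' \describe{
#'   \item{`"per-site"`}{one scenario per single cut site (each site cut
#'     alone), as in the published per-occurrence fragment tables;}
#'   \item{`"scenarios"`}{every non-empty combination of cut sites, guarded
#'     by `max_sites`;}
#'   \item{`"distinct"`}{the deduplicated union of fragments over all
#'     combinations, in closed form.}
#' }
#'
#' @param protein A [protein_record].
#' @param patterns A [protease_pattern] or list of them.
#' @param mode Fragment-generation mode, see Details.
#' @param max_sites Scenario-enumeration guard, see
#'   [enumerate_scenarios()].
#' @param permissive,context Passed to [scan_protein()].
#' @return Object of class `digest_result`: list with `protein`,
#'   `occurrences` (one data frame over all patterns), `cut_sites`,
#'   `site_provenance` (data frame: position, proteases), `mode`,
#'   `scenarios` (named list, `"per-site"`/`"scenarios"` modes),
#'   and `fragments` (single data frame over all scenarios, or the
#'   distinct-fragment table).
#' @examples
#' p <- protein_record("x", "AADEEDAAVKAA")
#' d <- combined_digest(p, builtin_patterns(), mode = "distinct")
#' d$cut_sites
#' @export
combined_digest <- function(protein, patterns,
                            mode = c("distinct", "scenarios", "per-site"),
                            max_sites = 16L, permissive = FALSE,
                            context = 0L) {
  mode <- match.arg(mode)
  stopifnot(inherits(protein, "protein_record"))
  if (inherits(patterns, "protease_pattern")) patterns <- list(patterns)
  if (length(patterns) == 0L) stop_input("at least one pattern is required")
  occ <- do.call(rbind, lapply(patterns, function(pat) {
    scan_protein(protein, pat, permissive = permissive, context = context)
  }))
  sites <- cut_sites(occ, protein)
  prov <- if (length(sites) == 0L) {
    data.frame(position = integer(), proteases = character(),
               stringsAsFactors = FALSE)
  } else {
    usable <- occ[occ$cleavage_after %in% sites, , drop = FALSE]
    data.frame(
      position = sites,
      proteases = vapply(sites, function(s) {
        paste(sort(unique(usable$pattern[usable$cleavage_after == s])),
              collapse = ",")
      }, character(1)),
      stringsAsFactors = FALSE
    )
  }
  scenarios <- switch(
    mode,
    "per-site" = {
      out <- lapply(sites, function(s) fragments_for_subset(protein, s))
      names(out) <- as.character(sites)
      out
    },
    "scenarios" = enumerate_scenarios(protein, sites, max_sites = max_sites),
    "distinct" = NULL
  )
  fragments <- if (mode == "distinct") {
    distinct_fragments(protein, sites)
  } else if (length(scenarios) == 0L) {
    empty_fragments()
  } else {
    do.call(rbind, unname(scenarios))
  }
  structure(
    list(protein = protein, occurrences = occ, cut_sites = sites,
         site_provenance = prov, mode = mode, scenarios = scenarios,
         fragments = fragments),
    class = "digest_result"
  )
}

#' @export
print.digest_result <- function(x, ...) {
  cat("<digest_result> ", x$protein$id, " (", x$protein$length, " aa), ",
      nrow(x$occurrences), " occurrence(s), ", length(x$cut_sites),
      " cut site(s), mode '", x$mode, "', ", nrow(x$fragments),
      " fragment row(s)\n", sep = "")
  invisible(x)
}
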