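# Mouse protein sequence printed in full in the published worked example
# (record #194 of the mouse-proteome run): 775 residues, with an acidic
# E/D-rich stretch carrying five DEED caspase-3 consensus occurrences,
# two of them overlapping (the first ends at 619, the next starts at 619).
TABLE4_SEQ <- paste0(
  "MLQDSITGIVNSFNLFFPSTMSRPTLMPTCVAFCSILFLTLATGCQAFPKVERRETAQEY",
  "AEKEQSQKMNTDDQENISFAPKYMLQQMSSEAPMVLSEGPSEIPLIKVFSVNKESHLPGA",
  "GLLHPTSPGVYSSSEPVVSASEQEPGPSLLERMSSEHSLSKVMLTVAVSSPASLNPDQEG",
  "PYNSLSTQPIVAAVTDVTHGSLDYLDNQLFAAKSQEAVSLGNSPSSSINTKEPEIIKADA",
  "AMGTTVVPGVDSTGDMEPDRERPSEMAADDGQSTTTKYLVTIPNNFLTTEPTAGSILGDA",
  "KVTVSVSTAGPVSSIFNEEWDDTKFESISRGRPPEPGDNAETQMRTKPPHGTYESFEGTE",
  "ESPSSTAVLKVAPGHLGGEPALGTALVTALGDERSPVLTHQISFTPMSLAEDPEVSTMKL",
  "FPSAGGFRASTQGDRTQLSSETAFSTSQYESVPQQEAGNVLKDITQERKMATQAMNTTSP",
  "VVTQEHMATIEVPRGSGEPEEGMPSLSPVPAEVADAELSRRGESLATPASTTVVPLSLKL",
  "TSSMEDLMDTITGPSEEFIPVLGSPMAPPAMTVEAPTISSALPSEGRTSPSISRPNTAAS",
  "YGLEQLESEEVEDDEDEEDEEDEEEEEEDEEDEEDEEDKETDSLYKDFDGDTEPPGFTLP",
  "GITSQEPDIRSGSMDLLEVATYQVPETIEWEQQNQGLVRSWMEKLKDKAGYMSGMLVPVG",
  "VGIAGALFILGALYSIKVMNRRRRNGFKRHKRKQREFNSMQDRVMLLADSSEDEF"
)

#' The multiple-overlap worked-example substrate
#'
#' The 775-residue mouse protein (record id `"194"`) whose acidic stretch
#' contains five `DEED` caspase-3 consensus occurrences at starts 616,
#' 619, 629, 632 and 635 — including overlapping hits (the first `DEED`
#' ends at the residue where the second starts). It exercises both
#' multiple occurrences of one consensus word and occurrence overlap, and
#' is embedded so those behaviours are testable offline.
#'
#' @return A [protein_record] with id `"194"`.
#' @examples
#' subset(scan_protein(table4_record(), builtin_patterns()$caspase3),
#'        consensus == "DEED")
#' @export
table4_record <- function() {
  protein_record("194", TABLE4_SEQ,
                 description = "mouse protein, multiple/overlapping DEED consensus occurrences")
}

draw_residues <- function(k, freq = NULL) {
  if (is.null(freq)) {
    sample(AA_STANDARD, k, replace = TRUE)
  } else {
    stopifnot(identical(sort(names(freq)), sort(AA_STANDARD)))
    sample(names(freq), k, replace = TRUE, prob = freq)
  }
}

#' Generate a substrate with motifs planted at known positions
#'
#' Builds a random background sequence, then writes one literal instance
#' of each requested pattern at its recorded start. The returned ground
#' truth is exactly what a scanner must recover, which makes the generator
#' the reference for end-to-end scanner tests. In `collision_free` mode the
#' background is re-rolled until no accidental pattern match exists outside
#' the planted windows, so the truth set and the scan result coincide
#' exactly; without it, chance background matches are legitimate extra
#' hits.
#'
#' @param length Total sequence length.
#' @param placements Data frame with columns `pattern` (name into
#'   `patterns`) and `start` (1-based plant position). Overlapping
#'   placements are allowed only with `allow_overlap = TRUE` (planting is
#'   applied in row order, later rows overwrite earlier residues; the
#'   caller is responsible for choosing overlaps that remain consistent,
#'   e.g. `DEEDEED`).
#' @param seed Integer seed; generation is reproducible for a fixed seed.
#' @param patterns Named list of [protease_pattern] objects; defaults to
#'   [builtin_patterns()].
#' @param collision_free Re-roll background until the planted set is the
#'   complete truth set (at most `max_tries` attempts).
#' @param allow_overlap Permit overlapping planted windows.
#' @param freq Optional named residue-frequency vector for the background
#'   (names = [AA_STANDARD]); uniform when `NULL`.
#' @param id Record id.
#' @param max_tries Re-roll budget for `collision_free`.
#' @return List of class `planted_truth`: `record` (a [protein_record]),
#'   `truth` (data frame `pattern`, `start`, `end`, `cleavage_after`),
#'   `seed`, `collision_free`.
#' @examples
#' pt <- plant_motifs(200,
#'   data.frame(pattern = c("caspase3", "calpain2"), start = c(50, 120)),
#'   seed = 1, collision_free = TRUE)
#' pt$truth
#' @export
plant_motifs <- function(length, placements, seed,
                         patterns = builtin_patterns(),
                         collision_free = FALSE, allow_overlap = FALSE,
                         freq = NULL, id = "planted", max_tries = 200L) {
  stopifnot(is.data.frame(placements),
            all(c("pattern", "start") %in% names(placements)))
  length <- as.integer(length)
  pats <- patterns[placements$pattern]
  if (any(vapply(pats, is.null, logical(1)))) {
    stop_input("unknown pattern name(s) in placements")
  }
  m <- vapply(pats, function(p) p$length, integer(1))
  starts <- as.integer(placements$start)
  ends <- starts + m - 1L
  if (any(starts < 1L) || any(ends > length)) {
    stop_input("planted window(s) outside [1, ", length, "]")
  }
  if (!allow_overlap && nrow(placements) > 1L) {
    ord <- order(starts)
    if (any(starts[ord][-1L] <= ends[ord][-nrow(placements)])) {
      stop_input("planted windows overlap; set allow_overlap = TRUE")
    }
  }
  truth <- data.frame(
    pattern = placements$pattern,
    start = starts,
    end = ends,
    cleavage_after = starts +
      vapply(pats, function(p) p$cleavage_offset, integer(1)) - 1L,
    stringsAsFactors = FALSE
  )
  truth <- truth[order(truth$pattern, truth$start), , drop = FALSE]
  rownames(truth) <- NULL

  # per-position constraint sets: the full alphabet for background
  # positions, the (intersection of) planted residue-set(s) elsewhere
  cons <- rep(list(AA_STANDARD), length)
  for (r in seq_len(nrow(placements))) {
    for (o in seq_len(m[[r]])) {
      pos <- starts[[r]] + o - 1L
      cons[[pos]] <- intersect(cons[[pos]], pats[[r]]$positions[[o]])
      if (base::length(cons[[pos]]) == 0L) {
        stop_input("overlapping placements impose contradictory residues ",
                   "at position ", pos)
      }
    }
  }
  set.seed(as.integer(seed))
  chars <- vapply(seq_len(length), function(pos) {
    set <- cons[[pos]]
    if (base::length(set) == 20L) draw_residues(1L, freq)
    else set[sample.int(base::length(set), 1L)]
  }, character(1))
  record <- protein_record(id, paste(chars, collapse = ""))
  if (collision_free) {
    # Accidental hits are killed one at a time by redrawing one residue in
    # the hit window from its constraint set minus the offending pattern
    # position's residue-set (preferring the most constrained pattern
    # position). Planted hits always survive: redraws respect `cons`.
    repaired <- FALSE
    for (iter in seq_len(max_tries)) {
      found <- do.call(rbind, lapply(patterns, function(p) {
        naive_scan(record, p)
      }))
      extra <- !paste(found$pattern, found$start) %in%
        paste(truth$pattern, truth$start)
      if (!any(extra)) { repaired <- TRUE; break }
      bad <- found[extra, , drop = FALSE]
      fixed_any <- FALSE
      for (h in seq_len(nrow(bad))) {
        pat <- patterns[[bad$pattern[h]]]
        win <- bad$start[h]:bad$end[h]
        allowed <- lapply(seq_along(win), function(j) {
          setdiff(cons[[win[j]]], pat$positions[[j]])
        })
        cand <- which(lengths(allowed) > 0L)
        if (base::length(cand) == 0L) next
        j <- cand[which.min(lengths(pat$positions)[cand])]
        pick <- allowed[[j]]
        chars[win[j]] <- pick[sample.int(base::length(pick), 1L)]
        fixed_any <- TRUE
      }
      if (!fixed_any) break
      record <- protein_record(id, paste(chars, collapse = ""))
    }
    if (!repaired) {
      stop_input("could not make the background collision-free in ",
                 max_tries, " repair rounds; lower motif density or ",
                 "sequence length")
    }
  }
  structure(list(record = record, truth = truth, seed = seed,
                 collision_free = collision_free),
            class = "planted_truth")
}

#' Generate a random synthetic proteome
#'
#' Uniform residue sampling over the standard alphabet (optionally
#' weighted), deterministic under `seed`. A desk-scale stand-in for large
#' proteome scans: a thousand such records exercise the scanner/oracle
#' equivalence at a size a laptop handles in seconds.
#'
#' @param n_records Number of records (>= 0).
#' @param length_range Inclusive length bounds, drawn uniformly.
#' @param seed Integer seed.
#' @param freq Optional residue-frequency vector, see [plant_motifs()].
#' @param prefix Id prefix; ids are `prefix` + zero-padded index.
#' @return List of [protein_record] objects.
#' @examples
#' random_proteome(3, c(20, 40), seed = 7)
#' @export
random_proteome <- function(n_records, length_range = c(50L, 500L), seed,
                            freq = NULL, prefix = "SYN") {
  n_records <- as.integer(n_records)
  stopifnot(n_records >= 0L, length(length_range) == 2L,
            length_range[1] >= 1L, length_range[1] <= length_range[2])
  if (n_records == 0L) return(list())
  set.seed(as.integer(seed))
  lens <- sample(length_range[1]:length_range[2], n_records, replace = TRUE)
  ids <- sprintf("%s%0*d", prefix, max(4L, nchar(n_records)),
                 seq_len(n_records))
  out <- lapply(seq_len(n_records), function(k) {
    protein_record(ids[[k]], paste(draw_residues(lens[[k]], freq),
                                   collapse = ""))
  })
  names(out) <- ids
  out
}

#' Write a planted fixture as FASTA plus truth TSV
#'
#' Companion to the `fixture` CLI subcommand: emits the generated record
#' as FASTA and its ground-truth hit table as TSV.
#'
#' @param pt A `planted_truth` from [plant_motifs()].
#' @param fasta_path,truth_path Destinations.
#' @return Invisibly, the two paths.
#' @export
write_fixture <- function(pt, fasta_path, truth_path) {
  stopifnot(inherits(pt, "planted_truth"))
  write_fasta(list(pt$record), fasta_path)
  utils::write.table(
    data.frame(Sequence_ID = pt$record$id, Pattern = pt$truth$pattern,
               Start = pt$truth$start, End = pt$truth$end,
               Cleavage_After = pt$truth$cleavage_after),
    truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta_path, truth_path))
}
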