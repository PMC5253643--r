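#' Construct a protein record
#'
#' A minimal substrate container: identifier, optional description and the
#' upper-cased amino-acid sequence with 1-based residue coordinates.
#'
#' @param id Record identifier (first token of a FASTA definition line);
#'   must be non-empty.
#' @param sequence Amino-acid string; canonicalized to upper case, trailing
#'   `*` stop marks stripped.
#' @param description Remainder of the definition line (may be empty).
#' @param strict Reject letters outside the 20 standard amino acids? When
#'   `FALSE`, ambiguity codes (B, Z, X, ...) are kept; they never match a
#'   fixed pattern position (see [matches_at()]).
#' @return Object of class `protein_record`: list with `id`, `description`,
#'   `sequence`, `length`.
#' @examples
#' protein_record("p1", "mkdeedav")
#' @export
protein_record <- function(id, sequence, description = "", strict = TRUE) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop_input("protein id must be a non-empty string")
  }
  sequence <- toupper(gsub("[[:space:][:digit:]]", "", sequence))
  sequence <- sub("\\*+$", "", sequence)
  if (strict) {
    bad <- setdiff(unique(strsplit(sequence, "")[[1]]), AA_STANDARD)
    if (length(bad) > 0L) {
      stop_input("record '", id, "': non-standard residue letter(s) ",
                 paste(bad, collapse = ", "),
                 " (use strict = FALSE to keep ambiguity codes)")
    }
  }
  structure(
    list(id = id, description = description,
         sequence = sequence, length = nchar(sequence)),
    class = "protein_record"
  )
}

#' @export
print.protein_record <- function(x, ...) {
  cat("<protein_record> ", x$id, " (", x$length, " aa)",
      if (nzchar(x$description)) paste0(" ", x$description) else "",
      "\n", sep = "")
  cat(" ", abbreviate_seq(x$sequence, width = 40), "\n", sep = "")
  invisible(x)
}

#' Read protein substrates from a FASTA file
#'
#' Wrap-agnostic multi-record FASTA reader (any line width, optional
#' trailing `*`). The record id is the first whitespace-delimited token of
#' the definition line; the remainder becomes the description. Duplicate
#' ids and empty files are rejected.
#'
#' @param path Path to a FASTA file.
#' @param strict Reject non-standard residue letters? See [protein_record()].
#' @return List of [protein_record] objects, input order preserved.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 demo", "MKDE", "EDAV"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop_input("input file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop_input("cannot parse FASTA '", path, "': ",
                                   conditionMessage(e))
  )
  if (length(set) == 0L) stop_input("no FASTA records in ", path)
  defs <- names(set)
  ids <- sub("\\s.*$", "", defs)
  desc <- ifelse(grepl("\\s", defs), sub("^\\S+\\s+", "", defs), "")
  if (anyDuplicated(ids)) {
    stop_input("duplicate record id(s) in ", path, ": ",
               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  records <- Map(function(id, d, s) protein_record(id, s, d, strict = strict),
                 ids, desc, as.character(set))
  names(records) <- ids
  records
}

#' Write protein records (or fragments) as FASTA
#'
#' @param records List of [protein_record] objects, or a fragment
#'   data frame from the digest module (one record per fragment, id
#'   `proteinid_start_end`).
#' @param path Destination path.
#' @param width Sequence line width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (is.data.frame(records)) {
    stopifnot(all(c("protein_id", "start", "end", "sequence") %in% names(records)))
    seqs <- records$sequence
    names(seqs) <- paste(records$protein_id, records$start, records$end,
                         sep = "_")
  } else {
    seqs <- vapply(records, function(r) r$sequence, character(1))
    names(seqs) <- vapply(records, function(r) {
      if (nzchar(r$description)) paste(r$id, r$description) else r$id
    }, character(1))
  }
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = as.integer(width))
  invisible(path)
}

#' Abbreviate a long sequence for display
#'
#' Sequences longer than `width` are shown as first-4...last-4, the display
#' convention used for long breakdown products (e.g. `MTTT...DSID`).
#'
#' @param s Character vector of sequences.
#' @param width Maximum length shown unabbreviated.
#' @return Character vector.
#' @export
abbreviate_seq <- function(s, width = 20L) {
  long <- !is.na(s) & nchar(s) > width
  s[long] <- paste0(substr(s[long], 1L, 4L), "...",
                    substring(s[long], nchar(s[long]) - 3L))
  s
}

#' Serialize consensus occurrences as TSV
#'
#' Columns `Sequence_ID`, `Pattern`, `Consensus`, `Start`, `End`,
#' `Cleavage_After`, sorted by protein, pattern, start — the layout of the
#' published hit tables plus explicit pattern and cleavage columns.
#'
#' @param occurrences Occurrence data frame (see [scan_protein()]).
#' @param path Destination path.
#' @return Invisibly, `path`.
#' @export
write_occurrences_tsv <- function(occurrences, path) {
  out <- occurrence_report(occurrences)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

occurrence_report <- function(occurrences) {
  occ <- occurrences[order(occurrences$protein_id, occurrences$pattern,
                           occurrences$start), , drop = FALSE]
  data.frame(
    Sequence_ID = occ$protein_id,
    Pattern = occ$pattern,
    Consensus = occ$consensus,
    Start = occ$start,
    End = occ$end,
    Cleavage_After = occ$cleavage_after,
    stringsAsFactors = FALSE
  )
}

fragment_report <- function(fragments, display_width = 20L) {
  frag <- fragments[order(fragments$protein_id, fragments$scenario,
                          fragments$start), , drop = FALSE]
  out <- data.frame(
    Sequence_ID = frag$protein_id,
    Scenario = frag$scenario,
    Fragment_Seq = abbreviate_seq(frag$sequence, display_width),
    Start = frag$start,
    End = frag$end,
    stringsAsFactors = FALSE
  )
  if ("avg_mass" %in% names(frag)) out$Avg_Mass_Da <- round(frag$avg_mass, 4)
  if ("mono_mass" %in% names(frag)) out$Mono_Mass_Da <- round(frag$mono_mass, 4)
  out
}

#' Write a digest report
#'
#' Writes the occurrence and fragment tables of a [combined_digest()]
#' result. `format = "tsv"` writes two files, `<dest>_occurrences.tsv` and
#' `<dest>_fragments.tsv` (the report holds two relations);
#' `format = "json"` writes a single file mirroring both tables. Row and
#' column order are deterministic (protein, pattern/scenario, start), so
#' repeated runs on identical input are byte-identical.
#'
#' @param result A `digest_result` (see [combined_digest()]), ideally after
#'   [annotate_fragments()].
#' @param dest Destination path (prefix for TSV).
#' @param format `"tsv"` or `"json"`.
#' @param display_width Abbreviation threshold for fragment sequences in
#'   the tables; full sequences are available via [write_fasta()].
#' @return Invisibly, character vector of files written.
#' @export
write_report <- function(result, dest, format = c("tsv", "json"),
                         display_width = 20L) {
  format <- match.arg(format)
  stopifnot(inherits(result, "digest_result"))
  occ <- occurrence_report(result$occurrences)
  frag <- fragment_report(result$fragments, display_width)
  if (format == "tsv") {
    paths <- paste0(dest, c("_occurrences.tsv", "_fragments.tsv"))
    ok <- tryCatch({
      utils::write.table(occ, paths[1], sep = "\t", quote = FALSE,
                         row.names = FALSE)
      utils::write.table(frag, paths[2], sep = "\t", quote = FALSE,
                         row.names = FALSE)
      TRUE
    }, error = function(e) stop_input("cannot write report: ",
                                      conditionMessage(e)))
    invisible(paths)
  } else {
    payload <- list(
      protein_id = result$protein$id,
      protein_length = result$protein$length,
      mode = result$mode,
      cut_sites = result$cut_sites,
      occurrences = occ,
      fragments = frag
    )
    tryCatch(
      jsonlite::write_json(payload, dest, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows"),
      error = function(e) stop_input("cannot write report: ",
                                     conditionMessage(e))
    )
    invisible(dest)
  }
}

#' Path to a user-supplied beta-II-spectrin FASTA, if present
#'
#' The beta-II-spectrin substrate (GenBank M96803) is external data and is
#' not shipped with the package. Validation examples that need it look for
#' the file at `options(cleavescan.spectrin_fasta = ...)` or at
#' `inst/extdata/M96803.fasta`; they are skipped when it is absent.
#'
#' @return Path, or `NA_character_` when the file has not been supplied.
#' @export
spectrin_fasta_path <- function() {
  opt <- getOption("cleavescan.spectrin_fasta")
  if (!is.null(opt) && file.exists(opt)) return(opt)
  shipped <- system.file("extdata", "M96803.fasta", package = "cleavescan")
  if (nzchar(shipped) && file.exists(shipped)) return(shipped)
  NA_character_
}
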