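# Standard unmodified residue masses (Da), average and monoisotopic, for
# the 20 proteinogenic amino acids, plus the water added on hydrolysis.
# Peptide mass = sum of residue masses + one water; no PTMs or terminal
# modifications are modelled.
.residue_avg <- c(
  A = 71.0788, C = 103.1388, D = 115.0886, E = 129.1155, F = 147.1766,
  G = 57.0519, H = 137.1411, I = 113.1594, K = 128.1741, L = 113.1594,
  M = 131.1926, N = 114.1038, P = 97.1167, Q = 128.1307, R = 156.1875,
  S = 87.0782, T = 101.1051, V = 99.1326, W = 186.2132, Y = 163.1760
)
.residue_mono <- c(
  A = 71.03711, C = 103.00919, D = 115.02694, E = 129.04259, F = 147.06841,
  G = 57.02146, H = 137.05891, I = 113.08406, K = 128.09496, L = 113.08406,
  M = 131.04049, N = 114.04293, P = 97.05276, Q = 128.05858, R = 156.10111,
  S = 87.03203, T = 101.04768, V = 99.06841, W = 186.07931, Y = 163.06333
)
.water <- c(average = 18.0153, monoisotopic = 18.010565)

#' Residue mass table
#'
#' Average and monoisotopic masses (Da) of the 20 standard amino-acid
#' residues (i.e. amino acid minus water, as incorporated in a peptide
#' chain).
#'
#' @return Data frame with columns `residue`, `average`, `monoisotopic`.
#' @export
residue_mass_table <- function() {
  data.frame(residue = AA_STANDARD,
             average = unname(.residue_avg[AA_STANDARD]),
             monoisotopic = unname(.residue_mono[AA_STANDARD]),
             stringsAsFactors = FALSE)
}

#' Mass of one water molecule
#'
#' @param mode `"average"` or `"monoisotopic"`.
#' @return Mass in Da.
#' @export
water_mass <- function(mode = c("average", "monoisotopic")) {
  unname(.water[[match.arg(mode)]])
}

#' Molecular mass of a peptide
#'
#' Sum of the residue masses plus one water. Breakdown products are
#' distinguished on gels by their molecular weight, so both the average
#' mass (matching gel/SDS-PAGE-scale comparisons) and the monoisotopic
#' mass (matching MS measurements) are supported.
#'
#' @param sequence Amino-acid string(s); vectorized.
#' @param mode `"average"` or `"monoisotopic"`.
#' @param on_nonstandard `"error"` (default) or `"skip"`: skip drops
#'   non-standard letters from the sum with a warning.
#' @return Numeric mass(es) in Da.
#' @examples
#' peptide_mass("G")                     # glycine, ~75.07 Da
#' peptide_mass("DEVD", "monoisotopic")
#' @export
peptide_mass <- function(sequence, mode = c("average", "monoisotopic"),
                         on_nonstandard = c("error", "skip")) {
  mode <- match.arg(mode)
  on_nonstandard <- match.arg(on_nonstandard)
  tab <- if (mode == "average") .residue_avg else .residue_mono
  vapply(toupper(sequence), function(s) {
    if (is.na(s) || !nzchar(s)) stop_input("cannot compute mass of an empty sequence")
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    masses <- tab[chars]
    if (anyNA(masses)) {
      bad <- unique(chars[is.na(masses)])
      if (on_nonstandard == "error") {
        stop_input("non-standard residue(s) in sequence: ",
                   paste(bad, collapse = ", "))
      }
      warning("skipping non-standard residue(s): ", paste(bad, collapse = ", "))
      masses <- masses[!is.na(masses)]
    }
    sum(masses) + .water[[if (mode == "average") "average" else "monoisotopic"]]
  }, numeric(1), USE.NAMES = FALSE)
}

#' Annotate digest fragments with molecular masses
#'
#' Adds `avg_mass` and/or `mono_mass` columns (Da) to every fragment table
#' of a digest result, and records the parent protein's masses. Because
#' each cleavage is a hydrolysis, the fragment masses of any scenario sum
#' to the parent mass plus one water per cut — a conservation law the test
#' suite checks to 1e-6 Da.
#'
#' @param result A `digest_result` from [combined_digest()], or a plain
#'   fragment data frame.
#' @param mode `"both"` (default), `"average"`, or `"monoisotopic"`.
#' @param on_nonstandard See [peptide_mass()].
#' @return The input with mass columns added; for a `digest_result`, the
#'   parent masses are stored as `parent_mass` (named numeric).
#' @export
annotate_fragments <- function(result, mode = c("both", "average",
                                                "monoisotopic"),
                               on_nonstandard = c("error", "skip")) {
  mode <- match.arg(mode)
  on_nonstandard <- match.arg(on_nonstandard)
  add_cols <- function(df) {
    if (nrow(df) == 0L) {
      if (mode %in% c("both", "average")) df$avg_mass <- numeric(0)
      if (mode %in% c("both", "monoisotopic")) df$mono_mass <- numeric(0)
      return(df)
    }
    if (mode %in% c("both", "average")) {
      df$avg_mass <- peptide_mass(df$sequence, "average", on_nonstandard)
    }
    if (mode %in% c("both", "monoisotopic")) {
      df$mono_mass <- peptide_mass(df$sequence, "monoisotopic", on_nonstandard)
    }
    df
  }
  if (is.data.frame(result)) return(add_cols(result))
  stopifnot(inherits(result, "digest_result"))
  result$fragments <- add_cols(result$fragments)
  if (!is.null(result$scenarios)) {
    result$scenarios <- lapply(result$scenarios, add_cols)
  }
  pm <- numeric()
  if (mode %in% c("both", "average")) {
    pm[["average"]] <- peptide_mass(result$protein$sequence, "average",
                                    on_nonstandard)
  }
  if (mode %in% c("both", "monoisotopic")) {
    pm[["monoisotopic"]] <- peptide_mass(result$protein$sequence,
                                         "monoisotopic", on_nonstandard)
  }
  result$parent_mass <- pm
  result
}
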