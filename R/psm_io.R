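PSM_COLUMNS <- c("spectrum_id", "sample_id", "treatment_id", "fraction_id",
                 "engine", "peptide", "modifications", "charge",
                 "precursor_mz", "precursor_intensity", "score", "accessions")

#' Read a PSM table
#'
#' Reads the tab-separated PSM dialect (one row per candidate
#' peptide-to-spectrum correlation; columns `r paste(PSM_COLUMNS, collapse = ", ")`).
#' Every well-formed row becomes a record. Rows with a non-numeric or
#' non-positive precursor intensity, a non-numeric score, or a charge outside
#' {2, 3} are skipped and reported (with their line numbers) in the
#' `problems` attribute. A missing required column is a format error.
#'
#' @param path Path to a TSV file.
#' @return Tibble of PSM records; attribute `problems` holds a tibble with
#'   columns `line`, `spectrum_id`, `reason` for skipped rows.
#' @export
read_psm_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, na = character())
  missing <- setdiff(PSM_COLUMNS, names(raw))
  if (length(missing) > 0) {
    abort(paste0("PSM table is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  n <- nrow(raw)
  line <- seq_len(n) + 1L  # header is line 1
  intensity <- suppressWarnings(as.numeric(raw$precursor_intensity))
  score <- suppressWarnings(as.numeric(raw$score))
  mz <- suppressWarnings(as.numeric(raw$precursor_mz))
  charge <- suppressWarnings(as.integer(raw$charge))
  treatment <- suppressWarnings(as.integer(raw$treatment_id))
  fraction <- suppressWarnings(as.integer(raw$fraction_id))

  reason <- rep(NA_character_, n)
  reason[is.na(intensity)] <- "non-numeric precursor_intensity"
  reason[!is.na(intensity) & intensity <= 0] <- "non-positive precursor_intensity"
  reason[is.na(reason) & is.na(score)] <- "non-numeric score"
  reason[is.na(reason) & (is.na(charge) | !charge %in% c(2L, 3L))] <-
    "charge outside the accepted {+2, +3} domain"
  reason[is.na(reason) & (is.na(treatment) | is.na(fraction))] <-
    "non-integer treatment_id/fraction_id"

  bad <- !is.na(reason)
  problems <- tibble(line = line[bad], spectrum_id = raw$spectrum_id[bad],
                     reason = reason[bad])
  if (nrow(problems) > 0) {
    warn(sprintf("read_psm_table: skipped %d malformed row(s); see attr(x, \"problems\").",
                 nrow(problems)))
  }
  out <- tibble(
    spectrum_id = raw$spectrum_id,
    sample_id = raw$sample_id,
    treatment_id = treatment,
    fraction_id = fraction,
    engine = raw$engine,
    peptide = raw$peptide,
    modifications = raw$modifications,
    charge = charge,
    precursor_mz = mz,
    precursor_intensity = intensity,
    score = score,
    accessions = raw$accessions
  )[!bad, ]
  attr(out, "problems") <- problems
  out
}

#' Write a PSM table
#'
#' @param psms Tibble of PSM records.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psms, path) {
  readr::write_tsv(psms[PSM_COLUMNS], path, progress = FALSE)
  invisible(path)
}
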