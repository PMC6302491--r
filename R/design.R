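#' Clinical treatment table for the multi-disease plasma study
#'
#' The 26-treatment id convention used throughout: each physical condition
#' appears twice, once for the unmodified tryptic pool (TRYP) and once for the
#' phospho-tryptic pool (STYP). Classes are `disease`, `matched_normal` or
#' `ice_cold` (the pre-analytical control, in which most peptides go
#' undetected).
#'
#' @return Tibble with columns `treatment_id`, `label`, `class`, `pool`.
#' @export
study_treatments <- function() {
  base <- tribble(
    ~id, ~label, ~class,
    1L, "Alzheimer normal", "matched_normal",
    3L, "Alzheimer dementia", "disease",
    5L, "Cancer breast", "disease",
    7L, "Cancer control", "matched_normal",
    9L, "Cancer ovarian", "disease",
    11L, "Ice cold", "ice_cold",
    13L, "Heart attack arterial", "disease",
    15L, "Heart attack normal control", "matched_normal",
    17L, "Heart attack", "disease",
    19L, "Multiple sclerosis normal control", "matched_normal",
    21L, "Multiple sclerosis", "disease",
    23L, "Sepsis", "disease",
    25L, "Sepsis normal control", "matched_normal"
  )
  bind_rows(
    base |> mutate(treatment_id = .data$id, pool = "TRYP"),
    base |> mutate(treatment_id = .data$id + 1L,
                   label = paste(.data$label, "STYP"), pool = "STYP")
  ) |>
    select("treatment_id", "label", "class", "pool") |>
    arrange(.data$treatment_id)
}

#' Define a study design for cohort simulation
#'
#' @param treatments Tibble with columns `treatment_id`, `label`, `class`
#'   (`disease` / `matched_normal` / `ice_cold`) and `pool` (`TRYP` / `STYP`).
#'   Defaults to the ovarian-cancer core of [study_treatments()] (breast,
#'   cancer control, ovarian and ice-cold conditions in both pools).
#' @param samples_per_treatment Independent plasma samples per treatment.
#' @param fractions_per_sample Extraction step fractions per sample
#'   (default 10, the ten-step organic/water gradient).
#' @param spectra_per_fraction MS/MS spectra recorded per fraction.
#' @return A list of class `study_design`.
#' @export
study_design <- function(treatments = NULL,
                         samples_per_treatment = 10L,
                         fractions_per_sample = 10L,
                         spectra_per_fraction = 500L) {
  if (is.null(treatments)) {
    treatments <- study_treatments() |> filter(.data$treatment_id %in% 5:12)
  }
  req <- c("treatment_id", "label", "class", "pool")
  assert_that(all(req %in% names(treatments)),
              "`treatments` needs columns treatment_id, label, class, pool.")
  assert_that(!anyDuplicated(treatments$treatment_id),
              "treatment ids must be unique.")
  assert_that(all(treatments$class %in% c("disease", "matched_normal", "ice_cold")),
              "treatment class must be disease, matched_normal or ice_cold.")
  assert_that(all(treatments$pool %in% c("TRYP", "STYP")),
              "treatment pool must be TRYP or STYP.")
  assert_that(samples_per_treatment >= 1, "`samples_per_treatment` must be >= 1.")
  assert_that(fractions_per_sample >= 1, "`fractions_per_sample` must be >= 1.")
  assert_that(spectra_per_fraction >= 1, "`spectra_per_fraction` must be >= 1.")
  if (any(treatments$class == "disease") &&
      !any(treatments$class == "matched_normal")) {
    abort("designs with a disease treatment need at least one matched_normal treatment.")
  }
  structure(
    list(
      treatments = as_tibble(treatments[req]),
      samples_per_treatment = as.integer(samples_per_treatment),
      fractions_per_sample = as.integer(fractions_per_sample),
      spectra_per_fraction = as.integer(spectra_per_fraction)
    ),
    class = "study_design"
  )
}

#' Planted effects for cohort simulation
#'
#' @param enriched Tibble with columns `gene_symbol`, `treatment_id`,
#'   `freq_multiplier` (>= 1, multiplies the symbol's sampling weight in the
#'   target treatment) and `intensity_shift` (log10 units added to that
#'   symbol's precursor intensities in the target treatment). Empty by
#'   default.
#' @param acute_phase Character vector of gene symbols elevated in every
#'   `disease`-class treatment (the nonspecific acute-phase background).
#' @param acute_phase_multiplier Frequency multiplier applied to acute-phase
#'   symbols in disease treatments (default 2, the broad elevation scale seen
#'   for common plasma proteins).
#' @param ice_cold_detection_scale Fraction in (0, 1] multiplying the
#'   detection probability of assignable spectra in `ice_cold` treatments;
#'   small values reproduce the near-absence of peptides from ice-cold
#'   plasma.
#' @return A list of class `effect_spec`.
#' @export
effect_spec <- function(enriched = NULL,
                        acute_phase = character(0),
                        acute_phase_multiplier = 2,
                        ice_cold_detection_scale = 0.1) {
  if (is.null(enriched)) {
    enriched <- tibble(gene_symbol = character(0), treatment_id = integer(0),
                       freq_multiplier = numeric(0), intensity_shift = numeric(0))
  }
  enriched <- as_tibble(enriched)
  req <- c("gene_symbol", "treatment_id", "freq_multiplier", "intensity_shift")
  assert_that(all(req %in% names(enriched)),
              "`enriched` needs gene_symbol, treatment_id, freq_multiplier, intensity_shift.")
  assert_that(all(enriched$freq_multiplier >= 1), "frequency multipliers must be >= 1.")
  assert_that(acute_phase_multiplier >= 1, "`acute_phase_multiplier` must be >= 1.")
  assert_that(ice_cold_detection_scale > 0 && ice_cold_detection_scale <= 1,
              "`ice_cold_detection_scale` must be in (0, 1].")
  structure(
    list(
      enriched = enriched,
      acute_phase = acute_phase,
      acute_phase_multiplier = acute_phase_multiplier,
      ice_cold_detection_scale = ice_cold_detection_scale
    ),
    class = "effect_spec"
  )
}

#' Noise and signal intensity model for cohort simulation
#'
#' Noise (unassignable) spectra draw log-normal precursor intensities whose
#' 99th percentile is calibrated to the working acceptance threshold of 1e4
#' counts: `meanlog = log(threshold) - qnorm(0.99) * sdlog`. Assignable
#' spectra draw log-normal intensities whose median sits `snr` times above
#' the noise median (about one hundred), plus a fixed per-peptide log10
#' offset and a per-treatment planted shift.
#'
#' @param noise_fraction Fraction of recorded spectra that are unassignable
#'   noise (default 0.88, which reproduces a low-teens percent fit rate).
#' @param sdlog Natural-log scale of the noise intensity distribution.
#' @param threshold Intensity threshold the 99th noise percentile is
#'   calibrated to (counts).
#' @param snr Median signal / median noise intensity ratio.
#' @param peptide_sd Between-peptide SD of the fixed log10 intensity offsets.
#' @param within_sd Within-peptide residual SD of log10 intensities.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(noise_fraction = 0.88,
                        sdlog = 1,
                        threshold = 1e4,
                        snr = 100,
                        peptide_sd = 0.3,
                        within_sd = 0.25) {
  assert_that(noise_fraction >= 0 && noise_fraction <= 1,
              "`noise_fraction` must be in [0, 1].")
  assert_that(sdlog > 0 && threshold > 0 && snr > 0, "scale parameters must be positive.")
  meanlog <- log(threshold) - qnorm(0.99) * sdlog
  structure(
    list(
      noise_fraction = noise_fraction,
      noise_meanlog = meanlog,
      noise_sdlog = sdlog,
      signal_log10_median = log10(snr * exp(meanlog)),
      peptide_sd = peptide_sd,
      within_sd = within_sd,
      threshold = threshold,
      snr = snr
    ),
    class = "noise_model"
  )
}

#' Sample noise precursor intensities
#'
#' Draws from the calibrated noise intensity distribution of a
#' [noise_model()]; exposed so the calibration (99th percentile at the
#' working threshold) can be checked directly.
#'
#' @param noise A `noise_model`.
#' @param n Number of draws.
#' @return Numeric vector of intensities (counts).
#' @export
sample_noise_intensity <- function(noise, n) {
  rlnorm(n, meanlog = noise$noise_meanlog, sdlog = noise$noise_sdlog)
}
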