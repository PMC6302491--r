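#' Simulate a multi-treatment PSM cohort with known ground truth
#'
#' Emulates the redundant output of database search over randomly and
#' independently sampled LC-ESI-MS/MS spectra. For every (sample, fraction),
#' assignable spectra sample peptides without replacement from the library's
#' tryptic peptide pool with per-symbol weights (multinomial model); planted
#' effects multiply a symbol's weight in its target treatment; acute-phase
#' symbols are elevated in all disease-class treatments; ice-cold treatments
#' scale the detection probability down, converting most assignable spectra
#' into noise. Noise spectra carry no peptide and draw intensities from the
#' calibrated noise distribution. A fraction of assigned spectra carry a
#' second, lower-scoring candidate at the other charge state to exercise
#' best-fit filtering, and optionally a second search engine re-reports
#' candidates.
#'
#' @param library A `protein_library` (see [generate_protein_library()]).
#' @param design A [study_design()].
#' @param effects An [effect_spec()]; all referenced gene symbols must exist
#'   in `library`.
#' @param noise A [noise_model()].
#' @param seed Integer seed. One global seed fans out to deterministic
#'   per-sample substreams.
#' @param symbol_sdlog Natural-log SD of the between-symbol abundance
#'   weights (0 gives equal weights, used for null cohorts).
#' @param duplicate_fraction Fraction of assigned spectra that carry a second
#'   candidate peptide at the other charge state.
#' @param second_engine_fraction Fraction of assigned spectra whose
#'   candidates are re-reported by a second engine (SEQUEST) with jittered
#'   scores.
#' @return A list of class `psm_cohort` with elements `psm` (tibble in the
#'   PSM TSV dialect: spectrum_id, sample_id, treatment_id, fraction_id,
#'   engine, peptide, modifications, charge, precursor_mz,
#'   precursor_intensity, score, accessions) and `truth` (the planted-effect
#'   truth log).
#' @examples
#' lib <- generate_protein_library(10, seed = 1)
#' des <- study_design(samples_per_treatment = 1, spectra_per_fraction = 50)
#' cohort <- simulate_cohort(lib, des, seed = 1)
#' cohort$psm
#' @export
simulate_cohort <- function(library, design,
                            effects = effect_spec(),
                            noise = noise_model(),
                            seed = 1L,
                            symbol_sdlog = 0.5,
                            duplicate_fraction = 0.3,
                            second_engine_fraction = 0) {
  stopifnot(inherits(design, "study_design"), inherits(effects, "effect_spec"),
            inherits(noise, "noise_model"))
  symbols <- unique(library$gene_symbol)
  bad <- setdiff(unique(c(effects$enriched$gene_symbol, effects$acute_phase)),
                 symbols)
  if (length(bad) > 0) {
    abort(paste0("effects reference gene symbol(s) absent from the library: ",
                 paste(bad, collapse = ", ")))
  }
  bad_t <- setdiff(effects$enriched$treatment_id, design$treatments$treatment_id)
  if (length(bad_t) > 0) {
    abort(paste0("effects reference treatment id(s) absent from the design: ",
                 paste(bad_t, collapse = ", ")))
  }

  idx <- peptide_index(library)
  n_pep <- nrow(idx)
  pep_mass <- vapply(strsplit(idx$peptide, ""), function(aa) {
    sum(AA_RESIDUE_MASS[aa])
  }, numeric(1)) + MASS_WATER
  sty_pos <- stringr::str_locate_all(idx$peptide, "[STY]") |>
    purrr::map(~ .x[, 1])
  met_pos <- stringr::str_locate_all(idx$peptide, "M") |>
    purrr::map(~ .x[, 1])

  # global (cross-sample) latent structure: symbol abundances, peptide offsets
  glob <- withr::with_seed(seed, {
    list(
      w_sym = setNames(exp(rnorm(length(symbols), 0, symbol_sdlog)), symbols),
      pep_offset = rnorm(n_pep, 0, noise$peptide_sd)
    )
  })

  trts <- design$treatments
  samples <- tidyr::expand_grid(ti = seq_len(nrow(trts)),
                                s = seq_len(design$samples_per_treatment))

  rows <- purrr::pmap(samples, function(ti, s) {
    trt <- trts[ti, ]
    gi <- (ti - 1L) * design$samples_per_treatment + s
    withr::with_seed(substream_seed(seed, gi), {
      sim_one_sample(trt, s, design, effects, noise, idx, glob,
                     pep_mass, sty_pos, met_pos,
                     duplicate_fraction, second_engine_fraction)
    })
  }) |> purrr::list_rbind()

  truth <- build_truth_log(effects, trts, seed)
  structure(list(psm = rows, truth = truth), class = "psm_cohort",
            seed = seed)
}

# per-treatment peptide weights and intensity shifts
treatment_weights <- function(trt, effects, idx, w_sym) {
  w <- unname(w_sym[idx$gene_symbol])
  shift <- numeric(nrow(idx))
  if (trt$class == "disease" && length(effects$acute_phase) > 0) {
    hit <- idx$gene_symbol %in% effects$acute_phase
    w[hit] <- w[hit] * effects$acute_phase_multiplier
  }
  planted <- effects$enriched |> filter(.data$treatment_id == trt$treatment_id)
  if (nrow(planted) > 0) {
    for (i in seq_len(nrow(planted))) {
      hit <- idx$gene_symbol == planted$gene_symbol[i]
      w[hit] <- w[hit] * planted$freq_multiplier[i]
      shift[hit] <- shift[hit] + planted$intensity_shift[i]
    }
  }
  list(w = w, shift = shift)
}

sim_one_sample <- function(trt, s, design, effects, noise, idx, glob,
                           pep_mass, sty_pos, met_pos,
                           duplicate_fraction, second_engine_fraction) {
  npf <- design$spectra_per_fraction
  tw <- treatment_weights(trt, effects, idx, glob$w_sym)
  elig <- if (trt$pool == "STYP") which(idx$has_sty) else seq_len(nrow(idx))

  frac <- purrr::map(seq_len(design$fractions_per_sample), function(f) {
    n_noise <- rbinom(1L, npf, noise$noise_fraction)
    n_sig <- npf - n_noise
    detect <- if (trt$class == "ice_cold") {
      rbinom(1L, n_sig, effects$ice_cold_detection_scale)
    } else {
      n_sig
    }
    k <- min(detect, length(elig))
    sig <- if (k > 0) {
      sample(elig, k, replace = FALSE, prob = tw$w[elig])
    } else {
      integer(0)
    }
    list(sig = sig, n_noise = npf - k, fraction = f)
  })

  sample_id <- sprintf("T%02d_S%02d", trt$treatment_id, s)
  pi <- unlist(purrr::map(frac, "sig"))
  sig_frac <- rep(purrr::map_int(frac, "fraction"),
                  purrr::map_int(frac, ~ length(.x$sig)))
  n_sig <- length(pi)
  n_noise <- purrr::map_int(frac, "n_noise")

  # --- assigned (signal) candidate rows ---
  sig_rows <- NULL
  if (n_sig > 0) {
    log10I <- noise$signal_log10_median + glob$pep_offset[pi] + tw$shift[pi] +
      rnorm(n_sig, 0, noise$within_sd)
    intensity <- 10^log10I
    charge <- sample(c(2L, 3L), n_sig, replace = TRUE, prob = c(0.6, 0.4))
    mods <- character(n_sig)
    mshift <- numeric(n_sig)
    if (trt$pool == "STYP") {
      pos <- purrr::map_int(sty_pos[pi], ~ .x[sample.int(length(.x), 1L)])
      res <- substr(idx$peptide[pi], pos, pos)
      mods <- sprintf("Phospho-%s@%d", res, pos)
      mshift <- mshift + MOD_MASS[["Phospho-S"]]
    }
    has_m <- purrr::map_lgl(met_pos[pi], ~ length(.x) > 0)
    ox <- has_m & runif(n_sig) < 0.1
    if (any(ox)) {
      opos <- purrr::map_int(met_pos[pi][ox], ~ .x[sample.int(length(.x), 1L)])
      oxm <- sprintf("Oxidation-M@%d", opos)
      mods[ox] <- ifelse(nzchar(mods[ox]), paste(mods[ox], oxm, sep = ";"), oxm)
      mshift[ox] <- mshift[ox] + MOD_MASS[["Oxidation-M"]]
    }
    score <- round(runif(n_sig, 40, 100), 2)
    mz <- (pep_mass[pi] + mshift + charge * MASS_PROTON) / charge
    sig_rows <- tibble(
      spectrum_id = sprintf("%s.%05d", sample_id, seq_len(n_sig)),
      fraction_id = sig_frac,
      peptide = idx$peptide[pi],
      modifications = mods,
      charge = charge,
      precursor_mz = round(mz, 4),
      precursor_intensity = round(intensity, 1),
      score = score,
      accessions = idx$accessions[pi]
    )
    # redundant second candidate at the other charge state, lower score
    dup <- which(runif(n_sig) < duplicate_fraction)
    if (length(dup) > 0) {
      alt <- sample.int(nrow(idx), length(dup), replace = TRUE)
      dup_rows <- sig_rows[dup, ] |>
        mutate(
          peptide = idx$peptide[alt],
          modifications = "",
          charge = 5L - .data$charge,
          score = round(pmax(1, .data$score - runif(length(dup), 5, 30)), 2),
          accessions = idx$accessions[alt]
        )
      sig_rows <- bind_rows(sig_rows, dup_rows)
    }
  }

  # --- unassignable noise rows ---
  nn <- sum(n_noise)
  noise_rows <- NULL
  if (nn > 0) {
    noise_rows <- tibble(
      spectrum_id = sprintf("%s.%05d", sample_id, n_sig + seq_len(nn)),
      fraction_id = rep(purrr::map_int(frac, "fraction"), n_noise),
      peptide = "",
      modifications = "",
      charge = sample(c(2L, 3L), nn, replace = TRUE),
      precursor_mz = round(runif(nn, 300, 2000), 4),
      precursor_intensity = round(sample_noise_intensity(noise, nn), 1),
      score = round(runif(nn, 1, 15), 2),
      accessions = ""
    )
  }

  out <- bind_rows(sig_rows, noise_rows) |>
    mutate(
      sample_id = sample_id,
      treatment_id = trt$treatment_id,
      engine = "XTANDEM",
      .after = "spectrum_id"
    ) |>
    relocate("spectrum_id", "sample_id", "treatment_id", "fraction_id",
             "engine", "peptide", "modifications", "charge", "precursor_mz",
             "precursor_intensity", "score", "accessions")

  if (second_engine_fraction > 0 && !is.null(sig_rows)) {
    re <- unique(sig_rows$spectrum_id[
      runif(nrow(sig_rows)) < second_engine_fraction])
    if (length(re) > 0) {
      dup2 <- out |>
        filter(.data$spectrum_id %in% re) |>
        mutate(engine = "SEQUEST",
               score = round(pmax(1, .data$score + rnorm(n(), 0, 2)), 2))
      out <- bind_rows(out, dup2)
    }
  }
  out
}

build_truth_log <- function(effects, trts, seed) {
  truth <- effects$enriched |>
    mutate(kind = "enriched") |>
    select("gene_symbol", "treatment_id", multiplier = "freq_multiplier",
           "intensity_shift", "kind")
  if (length(effects$acute_phase) > 0) {
    dis <- trts$treatment_id[trts$class == "disease"]
    truth <- bind_rows(truth, tidyr::expand_grid(
      gene_symbol = effects$acute_phase, treatment_id = dis) |>
        mutate(multiplier = effects$acute_phase_multiplier,
               intensity_shift = 0, kind = "acute_phase"))
  }
  ice <- trts$treatment_id[trts$class == "ice_cold"]
  if (length(ice) > 0) {
    truth <- bind_rows(truth, tibble(
      gene_symbol = NA_character_, treatment_id = ice,
      multiplier = effects$ice_cold_detection_scale,
      intensity_shift = 0, kind = "ice_cold"))
  }
  attr(truth, "seed") <- seed
  truth
}

#' @export
print.psm_cohort <- function(x, ...) {
  cat(sprintf("<psm_cohort> %d candidate rows, %d spectra, %d treatments (seed %s)\n",
              nrow(x$psm), dplyr::n_distinct(x$psm$spectrum_id),
              dplyr::n_distinct(x$psm$treatment_id),
              format(attr(x, "seed"))))
  invisible(x)
}
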