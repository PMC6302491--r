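#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis: input mode, design and
#' effect/noise models (simulate mode) or file paths (ingest mode), the
#' disease/control contrasts, and the acceptance, selection and ANOVA
#' thresholds.
#'
#' @param mode `"simulate"` (generate a cohort) or `"ingest"` (read a PSM
#'   TSV and a FASTA library from `psm_path` / `library_path`).
#' @param library A `protein_library` for simulate mode; `NULL` generates a
#'   default library of `n_symbols` symbols.
#' @param n_symbols,accessions_per_symbol Library size when generating.
#' @param design A [study_design()].
#' @param effects An [effect_spec()].
#' @param noise A [noise_model()].
#' @param contrasts Tibble with `disease_t`, `control_t`, `pool`; defaults to
#'   ovarian (9) vs cancer control (7) in TRYP and 10 vs 8 in STYP.
#' @param psm_path,library_path Input paths for ingest mode.
#' @param intensity_threshold Strict precursor-intensity threshold (counts).
#' @param chi2_explore,chi2_table,delta_min Selection thresholds: the
#'   exploratory rule (chi2 strictly > `chi2_explore`, delta >
#'   `delta_min`) and the stringent rule (chi2 >= `chi2_table`).
#' @param alpha HSD family-wise error rate.
#' @param seed Integer seed for every stochastic step.
#' @param engine Restrict to one search engine (`NULL` = pool engines after
#'   within-engine best-fit selection).
#' @param combine Cumulative protein p-value strategy
#'   (`"fisher"`/`"stouffer"`).
#' @param min_obs Minimum observations per gene for the ANOVA stage.
#' @param error_model Error term for the HSD letters (see
#'   [run_gene_anova()]).
#' @param symbol_sdlog Between-symbol abundance spread for simulation.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "ingest"),
                            library = NULL,
                            n_symbols = 200L,
                            accessions_per_symbol = 2L,
                            design = study_design(),
                            effects = effect_spec(),
                            noise = noise_model(),
                            contrasts = NULL,
                            psm_path = NULL,
                            library_path = NULL,
                            intensity_threshold = 1e4,
                            chi2_explore = 15,
                            chi2_table = 60,
                            delta_min = 15,
                            alpha = 0.05,
                            seed = 1L,
                            engine = NULL,
                            combine = c("fisher", "stouffer"),
                            min_obs = 3L,
                            error_model = c("two_way", "one_way"),
                            symbol_sdlog = 0.5) {
  mode <- match.arg(mode)
  combine <- match.arg(combine)
  error_model <- match.arg(error_model)
  if (is.null(contrasts)) {
    contrasts <- tibble(disease_t = c(9L, 10L), control_t = c(7L, 8L),
                        pool = c("TRYP", "STYP"))
  }
  contrasts <- as_tibble(contrasts)
  assert_that(all(c("disease_t", "control_t", "pool") %in% names(contrasts)),
              "`contrasts` needs disease_t, control_t, pool.")
  assert_that(intensity_threshold > 0 && chi2_explore >= 0 && chi2_table >= 0 &&
                delta_min >= 0, "thresholds must be positive.")
  if (mode == "simulate") {
    ok <- contrasts$disease_t %in% design$treatments$treatment_id &
      contrasts$control_t %in% design$treatments$treatment_id
    assert_that(all(ok), "every contrast must reference treatments defined in the design.")
  }
  if (mode == "ingest") {
    assert_that(!is.null(psm_path) && !is.null(library_path),
                "ingest mode needs `psm_path` and `library_path`.")
  }
  structure(
    list(mode = mode, library = library, n_symbols = as.integer(n_symbols),
         accessions_per_symbol = as.integer(accessions_per_symbol),
         design = design, effects = effects, noise = noise,
         contrasts = contrasts, psm_path = psm_path,
         library_path = library_path,
         intensity_threshold = intensity_threshold,
         chi2_explore = chi2_explore, chi2_table = chi2_table,
         delta_min = delta_min, alpha = alpha, seed = as.integer(seed),
         engine = engine, combine = combine, min_obs = as.integer(min_obs),
         error_model = error_model, symbol_sdlog = symbol_sdlog),
    class = "pipeline_config"
  )
}

#' Run the full differential-analysis pipeline
#'
#' Simulates (or ingests) a PSM cohort, applies the acceptance cascade,
#' builds per-pool frequency matrices, computes each contrast's corrected
#' chi-square table, delta diagnostic, selections and cumulative protein
#' p-values, then runs the per-gene intensity ANOVA with Tukey-Kramer
#' letters over the exploratory-rule gene set. Deterministic for a fixed
#' config seed.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result` with elements `psm`, `truth`,
#'   `accepted`, `frequencies` (per pool), `contrasts` (per contrast: the
#'   chi-square table with selection flags, the delta diagnostic and the
#'   cumulative protein p table), `anova` (a `gene_anova_set`), and
#'   `manifest` (config echo, versions, fit rate, filter funnel).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (config$mode == "simulate") {
    lib <- config$library %||%
      generate_protein_library(config$n_symbols, config$accessions_per_symbol,
                               seed = config$seed)
    cohort <- simulate_cohort(lib, config$design, config$effects, config$noise,
                              seed = config$seed,
                              symbol_sdlog = config$symbol_sdlog)
    psm <- cohort$psm
    truth <- cohort$truth
  } else {
    lib <- read_library_fasta(config$library_path)
    psm <- read_psm_table(config$psm_path)
    truth <- NULL
  }

  accepted <- accept_psms(psm, lib,
                          intensity_threshold = config$intensity_threshold,
                          engine = config$engine)
  funnel <- attr(accepted, "funnel")
  total <- n_distinct(psm$spectrum_id)
  fitted <- n_distinct(accepted$spectrum_id)
  fit_rate <- report_fit_rate(total, fitted)

  pools <- unique(config$contrasts$pool)
  freqs <- setNames(purrr::map(pools, ~ count_frequencies(accepted, .x)), pools)

  contrast_results <- purrr::pmap(config$contrasts, function(disease_t, control_t, pool) {
    tab <- chi_square_contrast(freqs[[pool]], disease_t, control_t) |>
      mutate(
        selected_15 = .data$chi2 > config$chi2_explore & .data$delta > config$delta_min,
        selected_60 = .data$chi2 >= config$chi2_table & .data$delta > config$delta_min
      )
    list(
      disease_t = disease_t, control_t = control_t, pool = pool,
      table = tab,
      diagnostic = delta_quantile_diagnostic(tab),
      cumulative = cumulative_protein_pvalues(accepted, pool, disease_t,
                                              control_t, method = config$combine)
    )
  })
  names(contrast_results) <- sprintf("%s_%d_vs_%d", config$contrasts$pool,
                                     config$contrasts$disease_t,
                                     config$contrasts$control_t)

  selected_genes <- sort(unique(unlist(
    purrr::map(contrast_results, ~ .x$table$gene_symbol[.x$table$selected_15]))))
  obs <- intensity_observations(accepted)
  anova_set <- run_gene_anova(obs, genes = selected_genes,
                              min_obs = config$min_obs, alpha = config$alpha,
                              error_model = config$error_model)

  manifest <- list(
    package = as.character(packageVersion("pepdiff")),
    seed = config$seed,
    config = as_config_list(config),
    total_spectra = total,
    fitted_spectra = fitted,
    fit_rate_percent = fit_rate$fit_rate_percent,
    fit_rate_headline = fit_rate$fit_rate_headline,
    funnel = as.list(setNames(funnel$n, funnel$stage)),
    n_selected_explore = length(selected_genes),
    n_anova_genes = length(anova_set$results)
  )
  structure(
    list(psm = psm, truth = truth, accepted = accepted, frequencies = freqs,
         contrasts = contrast_results, anova = anova_set, manifest = manifest,
         library = lib),
    class = "pipeline_result"
  )
}

#' Fraction of MS/MS spectra assigned to peptides
#'
#' The headline fit rate: `100 * fitted / total`, reported both unrounded
#' and rounded to the nearest integer percent.
#'
#' @param total Total recorded MS/MS spectra (> 0).
#' @param fitted Spectra assigned to a distinct best-fit peptide.
#' @return One-row tibble `total_spectra`, `fitted_spectra`,
#'   `fit_rate_percent` (unrounded), `fit_rate_headline` (integer percent).
#' @examples
#' report_fit_rate(15968550, 1916672)
#' @export
report_fit_rate <- function(total, fitted) {
  if (total <= 0) abort("`total` must be positive: fit rate undefined.")
  pct <- 100 * fitted / total
  tibble(total_spectra = total, fitted_spectra = fitted,
         fit_rate_percent = pct, fit_rate_headline = as.integer(round(pct)))
}

#' Write pipeline artifacts to a directory
#'
#' Emits the accepted-PSM table, per-pool frequency matrices, per-contrast
#' chi-square tables, delta diagnostics, cumulative protein p-values and
#' exploratory gene-list exports, the per-gene ANOVA report, the truth log
#' (simulate mode) and a YAML run manifest. All tables are TSV and parse
#' back with the package's own readers.
#'
#' @param result A `pipeline_result`.
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  acc <- result$accepted |>
    mutate(gene_symbols = purrr::map_chr(.data$gene_symbols, paste, collapse = ";"))
  readr::write_tsv(acc, p("accepted_psms.tsv"), progress = FALSE)
  write_psm_table(result$psm, p("psm_table.tsv"))
  for (pool in names(result$frequencies)) {
    readr::write_tsv(result$frequencies[[pool]],
                     p(sprintf("frequency_%s.tsv", pool)), progress = FALSE)
  }
  for (nm in names(result$contrasts)) {
    ct <- result$contrasts[[nm]]
    readr::write_tsv(ct$table, p(sprintf("chisq_%s.tsv", nm)), progress = FALSE)
    readr::write_tsv(ct$diagnostic, p(sprintf("delta_diagnostic_%s.tsv", nm)),
                     progress = FALSE)
    readr::write_tsv(ct$cumulative, p(sprintf("cumulative_p_%s.tsv", nm)),
                     progress = FALSE)
    export_gene_list(ct$table$gene_symbol[ct$table$selected_15],
                     p(sprintf("gene_list_%s.txt", nm)))
  }
  if (length(result$anova$results) > 0) {
    write_gene_report(result$anova, p("gene_anova_report.tsv"))
  }
  if (!is.null(result$truth)) {
    readr::write_tsv(result$truth, p("truth_log.tsv"), progress = FALSE)
  }
  yaml::write_yaml(result$manifest, p("manifest.yaml"))
  invisible(out_dir)
}

# ---- config serialization (YAML round trip) --------------------------------

as_config_list <- function(config) {
  list(
    mode = config$mode,
    n_symbols = config$n_symbols,
    accessions_per_symbol = config$accessions_per_symbol,
    design = list(
      treatments = lapply(seq_len(nrow(config$design$treatments)), function(i) {
        as.list(config$design$treatments[i, ])
      }),
      samples_per_treatment = config$design$samples_per_treatment,
      fractions_per_sample = config$design$fractions_per_sample,
      spectra_per_fraction = config$design$spectra_per_fraction
    ),
    effects = list(
      enriched = lapply(seq_len(nrow(config$effects$enriched)), function(i) {
        as.list(config$effects$enriched[i, ])
      }),
      acute_phase = as.list(config$effects$acute_phase),
      acute_phase_multiplier = config$effects$acute_phase_multiplier,
      ice_cold_detection_scale = config$effects$ice_cold_detection_scale
    ),
    noise = list(
      noise_fraction = config$noise$noise_fraction,
      sdlog = config$noise$noise_sdlog,
      threshold = config$noise$threshold,
      snr = config$noise$snr,
      peptide_sd = config$noise$peptide_sd,
      within_sd = config$noise$within_sd
    ),
    contrasts = lapply(seq_len(nrow(config$contrasts)), function(i) {
      as.list(config$contrasts[i, ])
    }),
    psm_path = config$psm_path,
    library_path = config$library_path,
    intensity_threshold = config$intensity_threshold,
    chi2_explore = config$chi2_explore,
    chi2_table = config$chi2_table,
    delta_min = config$delta_min,
    alpha = config$alpha,
    seed = config$seed,
    engine = config$engine,
    combine = config$combine,
    min_obs = config$min_obs,
    error_model = config$error_model,
    symbol_sdlog = config$symbol_sdlog
  )
}

#' Write / read a pipeline config as YAML
#'
#' The YAML echo in the run manifest uses the same representation, so a
#' manifest is sufficient to re-run a pipeline identically.
#'
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @return `write_pipeline_config` returns `path` invisibly;
#'   `read_pipeline_config` returns a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(as_config_list(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  pipeline_config(
    mode = x$mode,
    n_symbols = x$n_symbols,
    accessions_per_symbol = x$accessions_per_symbol,
    design = study_design(
      treatments = purrr::list_rbind(purrr::map(x$design$treatments, as_tibble)),
      samples_per_treatment = x$design$samples_per_treatment,
      fractions_per_sample = x$design$fractions_per_sample,
      spectra_per_fraction = x$design$spectra_per_fraction
    ),
    effects = effect_spec(
      enriched = if (length(x$effects$enriched) > 0) {
        purrr::list_rbind(purrr::map(x$effects$enriched, as_tibble))
      } else {
        NULL
      },
      acute_phase = as.character(unlist(x$effects$acute_phase)),
      acute_phase_multiplier = x$effects$acute_phase_multiplier,
      ice_cold_detection_scale = x$effects$ice_cold_detection_scale
    ),
    noise = noise_model(
      noise_fraction = x$noise$noise_fraction,
      sdlog = x$noise$sdlog,
      threshold = x$noise$threshold,
      snr = x$noise$snr,
      peptide_sd = x$noise$peptide_sd,
      within_sd = x$noise$within_sd
    ),
    contrasts = purrr::list_rbind(purrr::map(x$contrasts, as_tibble)),
    psm_path = x$psm_path,
    library_path = x$library_path,
    intensity_threshold = x$intensity_threshold,
    chi2_explore = x$chi2_explore,
    chi2_table = x$chi2_table,
    delta_min = x$delta_min,
    alpha = x$alpha,
    seed = x$seed,
    engine = x$engine,
    combine = x$combine,
    min_obs = x$min_obs,
    error_model = x$error_model,
    symbol_sdlog = x$symbol_sdlog
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d spectra, %d accepted PSMs (fit rate %.1f%%), %d contrasts, %d ANOVA genes\n",
              x$manifest$total_spectra,
              x$manifest$funnel$accepted,
              x$manifest$fit_rate_percent,
              length(x$contrasts), x$manifest$n_anova_genes))
  invisible(x)
}
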