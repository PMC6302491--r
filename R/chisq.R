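#' Observation-frequency matrix per gene symbol and treatment
#'
#' Counts accepted PSMs per (gene symbol, treatment) within one pool,
#' completing absent combinations with zero. Degenerate PSMs (several gene
#' symbols) contribute one count to each symbol.
#'
#' @param accepted Accepted-PSM tibble from [accept_psms()].
#' @param pool `"TRYP"` or `"STYP"`.
#' @param symbols Optional symbol universe (e.g. the library's gene symbols);
#'   symbols never observed then appear with zero counts instead of being
#'   absent.
#' @return Long tibble of class `freq_matrix` with columns `gene_symbol`,
#'   `treatment_id`, `n`; the pool tag is kept in the `pool` attribute. Use
#'   [treatment_totals()] for the per-treatment sums used in frequency
#'   correction.
#' @export
count_frequencies <- function(accepted, pool = c("TRYP", "STYP"),
                              symbols = NULL) {
  pool <- match.arg(pool)
  long <- accepted |>
    filter(.data$pool == !!pool) |>
    select("gene_symbols", "treatment_id") |>
    tidyr::unnest("gene_symbols") |>
    rename(gene_symbol = "gene_symbols")
  out <- long |>
    count(.data$gene_symbol, .data$treatment_id) |>
    tidyr::complete(gene_symbol = union(symbols, unique(long$gene_symbol)),
                    treatment_id = unique(long$treatment_id),
                    fill = list(n = 0L)) |>
    arrange(.data$gene_symbol, .data$treatment_id)
  attr(out, "pool") <- pool
  class(out) <- c("freq_matrix", class(out))
  out
}

#' Per-treatment total accepted counts
#'
#' @param freq A `freq_matrix`.
#' @return Tibble with `treatment_id`, `total`.
#' @export
treatment_totals <- function(freq) {
  freq |>
    group_by(.data$treatment_id) |>
    summarise(total = sum(.data$n), .groups = "drop")
}

#' Correct control counts by treatment totals
#'
#' Scales the control column by the ratio of total accepted PSMs,
#' `total(disease) / total(control)`, leaving disease counts unscaled, so
#' count differences between the two treatments are comparable (the corrected
#' delta distribution is centred at zero on a null cohort).
#'
#' @param freq A `freq_matrix`.
#' @param disease_t,control_t Treatment ids of the disease and control
#'   columns.
#' @return Tibble with `gene_symbol`, `disease_count`, `control_raw`,
#'   `control_corrected`, `delta` (= disease - corrected control).
#' @export
correct_control <- function(freq, disease_t, control_t) {
  tot <- treatment_totals(freq)
  td <- tot$total[match(disease_t, tot$treatment_id)]
  tc <- tot$total[match(control_t, tot$treatment_id)]
  if (is.na(td) || is.na(tc)) {
    abort("disease_t/control_t not present in the frequency matrix.")
  }
  if (tc == 0) abort("control treatment total is zero: correction undefined.")
  ratio <- td / tc
  wide <- freq |>
    filter(.data$treatment_id %in% c(disease_t, control_t)) |>
    tidyr::pivot_wider(id_cols = "gene_symbol", names_from = "treatment_id",
                       values_from = "n", values_fill = 0L)
  tibble(
    gene_symbol = wide$gene_symbol,
    disease_count = as.numeric(wide[[as.character(disease_t)]]),
    control_raw = as.numeric(wide[[as.character(control_t)]])
  ) |>
    mutate(control_corrected = .data$control_raw * ratio,
           delta = .data$disease_count - .data$control_corrected)
}

#' Quantile diagnostic of corrected frequency differences
#'
#' Sorts the corrected deltas against standard-normal quantiles (the
#' standardized quantile axis, centred at the mean), the diagnostic used to
#' verify that frequency correction centres the difference distribution at
#' zero before chi-square comparison.
#'
#' @param corrected Output of [correct_control()].
#' @return Tibble (`quantile`, `delta`) sorted by delta, with attributes
#'   `mean_delta`, `sd_delta` and `standardized_mean` (= mean / SD).
#' @export
delta_quantile_diagnostic <- function(corrected) {
  d <- sort(corrected$delta)
  out <- tibble(quantile = qnorm(ppoints(length(d))), delta = d)
  attr(out, "mean_delta") <- mean(d)
  attr(out, "sd_delta") <- sd(d)
  attr(out, "standardized_mean") <-
    if (length(d) > 1 && sd(d) > 0) mean(d) / sd(d) else NA_real_
  out
}

#' Pseudocount chi-square statistic for spectral counts
#'
#' The pseudocount-protected goodness-of-fit statistic
#' `(disease - control)^2 / (control + 1)`, computed on the raw disease count
#' and the total-corrected control count. The `+1` pseudocount keeps the
#' statistic defined for symbols never observed in the control. By the
#' field's convention the value is referred to the chi-square distribution
#' with one degree of freedom ([chi2_pvalue()]), although with the
#' pseudocount it is not exactly chi-square distributed under the null; see
#' the methods vignette.
#'
#' @param disease,control Non-negative counts (control may be non-integer
#'   after correction). Vectorized.
#' @return Numeric vector of statistic values (0 iff disease == control).
#' @export
chi_square <- function(disease, control) {
  if (any(disease < 0) || any(control < 0)) {
    abort("`disease` and `control` counts must be non-negative.")
  }
  (disease - control)^2 / (control + 1)
}

#' Upper-tail p-value for the chi-square statistic (df = 1)
#'
#' @param chi2 Non-negative statistic values.
#' @return Upper-tail probabilities of the chi-square distribution, df = 1.
#' @export
chi2_pvalue <- function(chi2) {
  assert_that(all(chi2 >= 0), "`chi2` must be non-negative.")
  pchisq(chi2, df = 1, lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity; output
#' order matches input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values.
#' @export
bh_qvalues <- function(p) {
  assert_that(all(p >= 0 & p <= 1, na.rm = TRUE), "p-values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}

#' Combine peptide-level p-values into a cumulative protein p-value
#'
#' Fisher's combination (default): `-2 * sum(log(p))` referred to chi-square
#' with `2k` degrees of freedom; or Stouffer's z method. Zero p-values are
#' clamped to the smallest representable positive double with a warning,
#' never propagated as `-Inf`.
#'
#' @param p Numeric vector of per-peptide p-values in `(0, 1]` (non-empty).
#' @param method `"fisher"` (default) or `"stouffer"`.
#' @return A single combined p-value.
#' @export
combine_peptide_pvalues <- function(p, method = c("fisher", "stouffer")) {
  method <- match.arg(method)
  if (length(p) == 0) abort("cannot combine an empty p-value list.")
  assert_that(all(p >= 0 & p <= 1), "p-values must lie in [0, 1].")
  if (any(p == 0)) {
    warn("p-value(s) of 0 clamped to the smallest representable positive value.")
    p[p == 0] <- .Machine$double.xmin
  }
  k <- length(p)
  if (method == "fisher") {
    pchisq(-2 * sum(log(p)), df = 2 * k, lower.tail = FALSE)
  } else {
    pnorm(sum(qnorm(p, lower.tail = FALSE)) / sqrt(k), lower.tail = FALSE)
  }
}

#' Chi-square contrast table for one disease/control pair
#'
#' Corrects the control column by treatment totals, computes the pseudocount
#' chi-square statistic per gene symbol with its df = 1 p-value, and adjusts
#' p-values by Benjamini-Hochberg within the contrast (i.e. within pool,
#' since a `freq_matrix` is per pool).
#'
#' @inheritParams correct_control
#' @return Tibble with `gene_symbol`, `disease_count`, `control_corrected`,
#'   `delta`, `chi2`, `p`, `q`, sorted by `chi2` descending.
#' @export
chi_square_contrast <- function(freq, disease_t, control_t) {
  correct_control(freq, disease_t, control_t) |>
    mutate(
      chi2 = chi_square(.data$disease_count, .data$control_corrected),
      p = chi2_pvalue(.data$chi2),
      q = bh_qvalues(.data$p)
    ) |>
    arrange(desc(.data$chi2)) |>
    select("gene_symbol", "disease_count", "control_raw", "control_corrected",
           "delta", "chi2", "p", "q")
}

#' Cumulative protein p-values from peptide-level contrasts
#'
#' Counts accepted PSMs per (peptide, gene symbol), applies the same
#' total-based correction and pseudocount chi-square at the peptide level,
#' then combines each symbol's peptide p-values ([combine_peptide_pvalues()])
#' into a cumulative protein p-value with a BH q-value.
#'
#' @param accepted Accepted-PSM tibble.
#' @param pool `"TRYP"` or `"STYP"`.
#' @inheritParams correct_control
#' @inheritParams combine_peptide_pvalues
#' @return Tibble `gene_symbol`, `n_peptides`, `p_cumulative`, `q`.
#' @export
cumulative_protein_pvalues <- function(accepted, pool, disease_t, control_t,
                                       method = c("fisher", "stouffer")) {
  method <- match.arg(method)
  long <- accepted |>
    filter(.data$pool == !!pool,
           .data$treatment_id %in% c(disease_t, control_t)) |>
    select("peptide", "gene_symbols", "treatment_id") |>
    tidyr::unnest("gene_symbols") |>
    rename(gene_symbol = "gene_symbols")
  if (nrow(long) == 0) {
    return(tibble(gene_symbol = character(0), n_peptides = integer(0),
                  p_cumulative = numeric(0), q = numeric(0)))
  }
  tot <- long |> count(.data$treatment_id)
  td <- tot$n[match(disease_t, tot$treatment_id)] %||% NA_real_
  tc <- tot$n[match(control_t, tot$treatment_id)] %||% NA_real_
  if (is.na(tc) || tc == 0) abort("control treatment total is zero: correction undefined.")
  if (is.na(td)) td <- 0
  ratio <- td / tc
  per_pep <- long |>
    count(.data$gene_symbol, .data$peptide, .data$treatment_id) |>
    tidyr::pivot_wider(names_from = "treatment_id", values_from = "n",
                       values_fill = 0L)
  dcol <- as.character(disease_t); ccol <- as.character(control_t)
  if (!dcol %in% names(per_pep)) per_pep[[dcol]] <- 0L
  if (!ccol %in% names(per_pep)) per_pep[[ccol]] <- 0L
  per_pep |>
    mutate(p = chi2_pvalue(chi_square(.data[[dcol]], .data[[ccol]] * ratio))) |>
    group_by(.data$gene_symbol) |>
    summarise(n_peptides = n(),
              p_cumulative = combine_peptide_pvalues(.data$p, method = method),
              .groups = "drop") |>
    mutate(q = bh_qvalues(.data$p_cumulative)) |>
    arrange(.data$p_cumulative)
}

#' Select candidate gene symbols by chi-square and delta thresholds
#'
#' Implements the two selection rules: the exploratory rule (chi-square
#' strictly above 15 and corrected frequency difference strictly above 15)
#' and the stringent table rule (chi-square at or above 60), both exposed via
#' `chi2_strict`.
#'
#' @param results A [chi_square_contrast()] tibble.
#' @param chi2_min Chi-square threshold (15 or 60).
#' @param delta_min Corrected frequency-difference threshold (strict).
#' @param chi2_strict If `TRUE` the chi-square comparison is strict (`>`,
#'   the 15-rule); if `FALSE` it is inclusive (`>=`, the 60-rule).
#' @return Tibble of selected rows sorted by `chi2` descending.
#' @export
select_candidates <- function(results, chi2_min = 15, delta_min = 15,
                              chi2_strict = TRUE) {
  assert_that(chi2_min >= 0 && delta_min >= 0, "thresholds must be >= 0.")
  keep <- if (chi2_strict) results$chi2 > chi2_min else results$chi2 >= chi2_min
  results |>
    filter(keep & .data$delta > delta_min) |>
    arrange(desc(.data$chi2))
}

#' Export a gene list for external network/enrichment submission
#'
#' Newline-delimited gene symbols, the format accepted by protein-network
#' services such as STRING.
#'
#' @param gene_symbols Character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_gene_list <- function(gene_symbols, path) {
  writeLines(gene_symbols, path)
  invisible(path)
}
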