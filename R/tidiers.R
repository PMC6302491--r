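#' Tidy a per-gene ANOVA fit
#'
#' One row per model term (sequential sums of squares).
#'
#' @param x A `gene_anova`.
#' @param ... Unused.
#' @return Tibble `term`, `sum_sq`, `df`, `f_value`, `p_value` (plus
#'   `gene_symbol` when known).
#' @method tidy gene_anova
#' @export
tidy.gene_anova <- function(x, ...) {
  out <- x$table
  if (!is.null(x$gene_symbol)) out <- mutate(out, gene_symbol = x$gene_symbol, .before = 1)
  out
}

#' One-row model summary of a per-gene ANOVA fit
#'
#' @param x A `gene_anova`.
#' @param ... Unused.
#' @return Tibble with observation/treatment/peptide counts, residual
#'   df and mean square, and the treatment term's F and p.
#' @method glance gene_anova
#' @export
glance.gene_anova <- function(x, ...) {
  res <- residual_ms(x)
  trt <- x$table |> filter(.data$term == "Treatment_ID")
  tibble(
    gene_symbol = x$gene_symbol %||% NA_character_,
    n_obs = nrow(x$data),
    n_treatments = n_distinct(x$data$Treatment_ID),
    n_peptides = n_distinct(x$data$Peptide_Sequence),
    df_residual = res$df,
    ms_residual = res$ms,
    f_treatment = if (nrow(trt)) trt$f_value else NA_real_,
    p_treatment = if (nrow(trt)) trt$p_value else NA_real_
  )
}

#' Tidy all fits of a gene set
#'
#' @param x A `gene_anova_set`.
#' @param ... Unused.
#' @return Row-bound [tidy.gene_anova()] tables.
#' @method tidy gene_anova_set
#' @export
tidy.gene_anova_set <- function(x, ...) {
  purrr::map(x$results, tidy) |> purrr::list_rbind()
}

#' @rdname tidy.gene_anova_set
#' @method glance gene_anova_set
#' @export
glance.gene_anova_set <- function(x, ...) {
  purrr::map(x$results, glance) |> purrr::list_rbind()
}

#' Tidy Tukey-Kramer pairwise comparisons
#'
#' @param x A `tukey_hsd`.
#' @param ... Unused.
#' @return The pairwise-comparison tibble.
#' @method tidy tukey_hsd
#' @export
tidy.tukey_hsd <- function(x, ...) {
  x$pairs
}

#' One-row summary of a pipeline run
#'
#' @param x A `pipeline_result`.
#' @param ... Unused.
#' @return Tibble with spectra counts, fit rate and selection sizes.
#' @method glance pipeline_result
#' @export
glance.pipeline_result <- function(x, ...) {
  tibble(
    total_spectra = x$manifest$total_spectra,
    fitted_spectra = x$manifest$fitted_spectra,
    fit_rate_percent = x$manifest$fit_rate_percent,
    accepted_psms = x$manifest$funnel$accepted,
    n_selected_explore = x$manifest$n_selected_explore,
    n_anova_genes = x$manifest$n_anova_genes
  )
}
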