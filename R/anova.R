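#' Intensity observations from accepted PSMs
#'
#' One row per accepted PSM and owning gene symbol with the log10-transformed
#' precursor intensity (the quantification signal; intensities enter above
#' 1e4 counts, so log10 values exceed 4).
#'
#' @param accepted Accepted-PSM tibble from [accept_psms()].
#' @return Tibble `gene_symbol`, `peptide`, `treatment_id`, `log10_intensity`.
#' @export
intensity_observations <- function(accepted) {
  accepted |>
    select("gene_symbols", "peptide", "treatment_id", "precursor_intensity") |>
    tidyr::unnest("gene_symbols") |>
    rename(gene_symbol = "gene_symbols") |>
    mutate(log10_intensity = log10(.data$precursor_intensity)) |>
    select("gene_symbol", "peptide", "treatment_id", "log10_intensity")
}

#' Normal quantile-quantile diagnostic
#'
#' Standard-normal theoretical quantiles against the sorted sample, with the
#' QQ correlation coefficient as a scalar normality summary (1 for a perfect
#' Gaussian sample).
#'
#' @param x Numeric vector, `length(x) >= 3`.
#' @return Tibble (`theoretical`, `sample`) with attributes `correlation`
#'   and `degenerate` (`TRUE` for a zero-variance sample, where the
#'   correlation is undefined).
#' @export
qq_normality <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3) abort("qq_normality needs at least 3 observations.")
  s <- sort(x)
  theo <- qnorm(ppoints(length(s)))
  degenerate <- sd(s) == 0
  out <- tibble(theoretical = theo, sample = s)
  attr(out, "correlation") <- if (degenerate) NA_real_ else cor(theo, s)
  attr(out, "degenerate") <- degenerate
  if (degenerate) warn("constant sample: QQ correlation undefined (zero variance).")
  out
}

#' Per-treatment summaries of log10 intensity
#'
#' Mean, sample SD (n - 1 denominator), SE = SD / sqrt(n) and n per
#' treatment; SD and SE are `NA` for singleton treatments.
#'
#' @param observations Tibble with `treatment_id` and `log10_intensity`.
#' @return Tibble `treatment_id`, `mean`, `sd`, `se`, `n`.
#' @export
summarize_treatments <- function(observations) {
  observations |>
    group_by(.data$treatment_id) |>
    summarise(
      mean = mean(.data$log10_intensity),
      sd = if (n() >= 2) sd(.data$log10_intensity) else NA_real_,
      n = n(),
      .groups = "drop"
    ) |>
    mutate(se = .data$sd / sqrt(.data$n)) |>
    select("treatment_id", "mean", "sd", "se", "n")
}

#' Sequential two-way ANOVA of log10 intensities for one gene symbol
#'
#' Fits `log10_intensity ~ Peptide_Sequence * Treatment_ID` with sequential
#' (type-I) sums of squares in that order, the convention of standard R
#' `anova()` output. With a single peptide the peptide term (and interaction)
#' is dropped and a one-way treatment model is fitted. Inestimable
#' interaction cells (unbalanced, missing-cell data are the norm) are dropped
#' by the rank-revealing fit with degrees of freedom adjusted accordingly.
#' With zero residual degrees of freedom, F and p are `NA` with a warning.
#'
#' @param observations Tibble with `peptide`, `treatment_id`,
#'   `log10_intensity` for one gene symbol; needs >= 2 treatments.
#' @return Object of class `gene_anova`: list with `table` (tibble `term`,
#'   `sum_sq`, `df`, `f_value`, `p_value`, terms ordered Peptide_Sequence,
#'   Treatment_ID, interaction, Residuals), `fit` (the `lm`), `data`, and
#'   `summaries` (per-treatment mean/SD/SE/n).
#' @export
fit_two_way_anova <- function(observations) {
  d <- observations |>
    mutate(Peptide_Sequence = factor(.data$peptide),
           Treatment_ID = factor(.data$treatment_id))
  if (n_distinct(d$Treatment_ID) < 2) {
    abort("fit_two_way_anova needs >= 2 treatments with observations.")
  }
  two_way <- n_distinct(d$Peptide_Sequence) > 1
  form <- if (two_way) {
    log10_intensity ~ Peptide_Sequence * Treatment_ID
  } else {
    log10_intensity ~ Treatment_ID
  }
  fit <- lm(form, data = d)
  at <- suppressWarnings(anova(fit))
  tab <- tibble(
    term = rownames(at),
    sum_sq = at$`Sum Sq`,
    df = at$Df,
    f_value = at$`F value`,
    p_value = at$`Pr(>F)`
  )
  if (df.residual(fit) < 1) {
    warn("zero residual degrees of freedom: F and p undefined.")
    tab$f_value[tab$term != "Residuals"] <- NA_real_
    tab$p_value[tab$term != "Residuals"] <- NA_real_
  }
  structure(
    list(
      table = tab,
      fit = fit,
      data = d,
      summaries = summarize_treatments(d)
    ),
    class = "gene_anova"
  )
}

#' @importFrom stats df.residual
residual_ms <- function(ga) {
  res <- ga$table |> filter(.data$term == "Residuals")
  if (res$df < 1) return(list(ms = NA_real_, df = 0L))
  list(ms = res$sum_sq / res$df, df = res$df)
}

#' Per-gene ANOVA with Tukey-Kramer letters across a gene list
#'
#' For each gene symbol (typically the chi-square-selected set), fits the
#' sequential two-way ANOVA, summarises each treatment, and runs the
#' Tukey-Kramer HSD on the treatment means using the model's residual mean
#' square as the shared error term, attaching compact-display letters to the
#' summaries. Genes with too few observations or a single treatment are
#' skipped with a reason.
#'
#' @param observations Tibble from [intensity_observations()].
#' @param genes Character vector of gene symbols to analyse; defaults to all
#'   symbols present.
#' @param min_obs Minimum observations per gene to attempt a fit.
#' @param alpha Family-wise error rate for the HSD letters.
#' @param error_model `"two_way"` (default) takes the residual mean square
#'   from the full two-way model; `"one_way"` re-fits
#'   `log10_intensity ~ Treatment_ID` for the error term.
#' @return Object of class `gene_anova_set`: list with `results` (named list
#'   of `gene_anova` objects, each with a `tukey` element and letters merged
#'   into `summaries`) and `skipped` (tibble `gene_symbol`, `reason`).
#' @export
run_gene_anova <- function(observations, genes = NULL, min_obs = 3,
                           alpha = 0.05,
                           error_model = c("two_way", "one_way")) {
  error_model <- match.arg(error_model)
  genes <- genes %||% sort(unique(observations$gene_symbol))
  results <- list()
  skipped <- tibble(gene_symbol = character(0), reason = character(0))
  for (g in genes) {
    obs <- observations |> filter(.data$gene_symbol == g)
    if (nrow(obs) < min_obs) {
      skipped <- add_row(skipped, gene_symbol = g, reason = "too few observations")
      next
    }
    if (n_distinct(obs$treatment_id) < 2) {
      skipped <- add_row(skipped, gene_symbol = g, reason = "single treatment")
      next
    }
    ga <- fit_two_way_anova(obs)
    err <- if (error_model == "one_way") {
      one <- lm(log10_intensity ~ factor(treatment_id), data = obs)
      list(ms = sum(one$residuals^2) / df.residual(one), df = df.residual(one))
    } else {
      residual_ms(ga)
    }
    ga$tukey <- NULL
    if (!is.na(err$ms) && err$df >= 1 && err$ms > 0) {
      s <- ga$summaries
      ga$tukey <- tukey_kramer_hsd(setNames(s$mean, s$treatment_id),
                                   setNames(s$n, s$treatment_id),
                                   ms_resid = err$ms, df_resid = err$df,
                                   alpha = alpha)
      ga$summaries <- s |>
        left_join(ga$tukey$letters, by = "treatment_id")
    }
    ga$gene_symbol <- g
    results[[g]] <- ga
  }
  structure(list(results = results, skipped = skipped, alpha = alpha),
            class = "gene_anova_set")
}

#' Write a Table-3-style per-gene report
#'
#' Two stacked panels per gene: the per-treatment summaries (mean, SD, SE,
#' n, Tukey letters) and the sequential ANOVA table.
#'
#' @param gene_set A `gene_anova_set`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_gene_report <- function(gene_set, path) {
  summaries <- purrr::imap(gene_set$results, function(ga, g) {
    ga$summaries |> mutate(gene_symbol = g, .before = 1)
  }) |> purrr::list_rbind()
  tables <- purrr::imap(gene_set$results, function(ga, g) {
    ga$table |> mutate(gene_symbol = g, .before = 1)
  }) |> purrr::list_rbind()
  lines <- c(
    "# Treatment summaries",
    sub("\n$", "", readr::format_tsv(summaries)),
    "# ANOVA tables",
    sub("\n$", "", readr::format_tsv(tables))
  )
  writeLines(unlist(strsplit(lines, "\n", fixed = TRUE)), path)
  invisible(path)
}

#' @export
print.gene_anova <- function(x, ...) {
  cat(sprintf("<gene_anova>%s %d observations, %d treatments\n",
              if (!is.null(x$gene_symbol)) paste0(" ", x$gene_symbol) else "",
              nrow(x$data), nrow(x$summaries)))
  print(x$table)
  invisible(x)
}

#' @export
print.gene_anova_set <- function(x, ...) {
  cat(sprintf("<gene_anova_set> %d genes analysed, %d skipped\n",
              length(x$results), nrow(x$skipped)))
  invisible(x)
}
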