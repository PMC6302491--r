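test_that("QQ diagnostic separates Gaussian from heavy-tailed samples", {
  x <- withr::with_seed(1, rnorm(1000, mean = 5, sd = 0.4))
  qq <- qq_normality(x)
  expect_gte(attr(qq, "correlation"), 0.995)
  expect_equal(nrow(qq), 1000)
  expect_equal(qq$sample, sort(x))
  # heavy-tailed (log-uniform) sample: lower QQ correlation at matched n
  y <- withr::with_seed(2, exp(runif(1000, 0, 4)))
  expect_lt(attr(qq_normality(y), "correlation"), attr(qq, "correlation"))
})

test_that("degenerate and undersized samples are flagged", {
  expect_warning(qq <- qq_normality(rep(2, 10)), "zero variance")
  expect_true(attr(qq, "degenerate"))
  expect_true(is.na(attr(qq, "correlation")))
  expect_error(qq_normality(c(1, 2)), "at least 3")
})

test_that("treatment summaries follow the SE = SD/sqrt(n) identity", {
  obs <- tibble::tibble(
    treatment_id = rep(c(1L, 2L, 3L), c(4, 1, 3)),
    log10_intensity = c(5.1, 5.3, 5.2, 5.4, 4.8, 6, 6, 6)
  )
  s <- summarize_treatments(obs)
  expect_equal(s$se[s$n >= 2], s$sd[s$n >= 2] / sqrt(s$n[s$n >= 2]))
  # singleton treatment: SD and SE undefined
  expect_true(is.na(s$sd[s$treatment_id == 2]) && is.na(s$se[s$treatment_id == 2]))
  expect_equal(s$mean[s$treatment_id == 2], 4.8)
  # constant treatment: SD = SE = 0
  expect_equal(s$sd[s$treatment_id == 3], 0)
  expect_equal(s$se[s$treatment_id == 3], 0)
})

test_that("equal group means give a null treatment F", {
  obs <- tibble::tibble(
    peptide = "PEPTIDEK",
    treatment_id = rep(c(1L, 2L), each = 3),
    log10_intensity = rep(c(4.5, 5.0, 5.5), 2)
  )
  ga <- fit_two_way_anova(obs)
  trt <- ga$table[ga$table$term == "Treatment_ID", ]
  expect_equal(trt$sum_sq, 0, tolerance = 1e-12)
  expect_equal(trt$f_value, 0, tolerance = 1e-12)
  expect_equal(trt$p_value, 1)
})

test_that("sequential sums of squares match the projection oracle on unbalanced data", {
  set.seed(11)
  for (rep in 1:20) {
    a <- sample(2:4, 1); b <- sample(2:5, 1)
    cells <- tidyr::expand_grid(peptide = sprintf("PEP%dK", 1:a),
                                treatment_id = seq_len(b)) |>
      dplyr::slice_sample(prop = 0.85)
    d <- cells[rep(seq_len(nrow(cells)), sample(1:4, nrow(cells), replace = TRUE)), ]
    # keep the design estimable: >= 2 levels of each factor present
    if (dplyr::n_distinct(d$treatment_id) < 2 ||
        dplyr::n_distinct(d$peptide) < 2) next
    d$log10_intensity <- 5 + rnorm(nrow(d), 0, 0.5)
    ga <- suppressWarnings(fit_two_way_anova(d))
    oracle <- oracle_sequential_ss(d)
    for (term in ga$table$term) {
      expect_equal(ga$table$sum_sq[ga$table$term == term],
                   unname(oracle[term]), tolerance = 1e-8)
    }
    # conservation: term SS + residual SS = total SS
    expect_equal(sum(ga$table$sum_sq), unname(oracle["Total"]), tolerance = 1e-8)
  }
})

test_that("complete balanced designs give the textbook interaction df", {
  a <- 3; b <- 4
  d <- tidyr::expand_grid(peptide = sprintf("PEP%dK", 1:a),
                          treatment_id = seq_len(b),
                          repl = 1:2)
  d$log10_intensity <- 5 + rnorm(nrow(d), 0, 0.3)
  ga <- fit_two_way_anova(d)
  expect_equal(ga$table$df[ga$table$term == "Peptide_Sequence"], a - 1)
  expect_equal(ga$table$df[ga$table$term == "Treatment_ID"], b - 1)
  expect_equal(ga$table$df[ga$table$term == "Peptide_Sequence:Treatment_ID"],
               (a - 1) * (b - 1))
  expect_equal(sum(ga$table$df), nrow(d) - 1)
})

test_that("single-peptide genes drop the peptide term gracefully", {
  d <- tibble::tibble(peptide = "ONLYONEK",
                      treatment_id = rep(1:3, each = 4),
                      log10_intensity = 5 + rnorm(12, 0, 0.2))
  ga <- fit_two_way_anova(d)
  expect_setequal(ga$table$term, c("Treatment_ID", "Residuals"))
})

test_that("zero residual df yields NA F and p with a warning", {
  d <- tibble::tibble(peptide = "ONLYONEK", treatment_id = c(1L, 2L),
                      log10_intensity = c(5, 6))
  expect_warning(ga <- fit_two_way_anova(d), "residual")
  expect_true(is.na(ga$table$f_value[ga$table$term == "Treatment_ID"]))
})

test_that("Tukey-Kramer at k = 2 coincides with the pooled t-test", {
  set.seed(3)
  agree <- vapply(1:200, function(i) {
    n1 <- sample(3:10, 1); n2 <- sample(3:10, 1)
    x <- rnorm(n1, 5, 0.3); y <- rnorm(n2, 5 + runif(1, 0, 0.6), 0.3)
    d <- tibble::tibble(peptide = "PK",
                        treatment_id = rep(1:2, c(n1, n2)),
                        log10_intensity = c(x, y))
    ga <- fit_two_way_anova(d)
    res <- ga$table[ga$table$term == "Residuals", ]
    tk <- tukey_kramer_hsd(setNames(c(mean(x), mean(y)), 1:2),
                           setNames(c(n1, n2), 1:2),
                           res$sum_sq / res$df, res$df)
    tt <- t.test(x, y, var.equal = TRUE)
    identical(tk$pairs$significant, tt$p.value < 0.05)
  }, logical(1))
  expect_true(all(agree))
})

test_that("identical means share one letter; an isolated mean gets its own", {
  tk <- tukey_kramer_hsd(setNames(c(5, 5, 5), 1:3), setNames(c(4, 4, 4), 1:3),
                         ms_resid = 0.1, df_resid = 9)
  expect_equal(unique(tk$letters$letters), "a")
  # one treatment shifted by 10 pooled SDs
  means <- setNames(c(5, 5.05, 8.2), 1:3)
  tk2 <- tukey_kramer_hsd(means, setNames(c(6, 6, 6), 1:3),
                          ms_resid = 0.09, df_resid = 15)
  shifted <- tk2$letters$letters[tk2$letters$treatment_id == 3]
  others <- tk2$letters$letters[tk2$letters$treatment_id != 3]
  expect_false(any(grepl(shifted, others, fixed = TRUE)))
})

test_that("letters agree exactly with pairwise non-significance", {
  set.seed(9)
  for (rep in 1:25) {
    k <- sample(3:8, 1)
    means <- setNames(rnorm(k, 5, 0.6), seq_len(k))
    ns <- setNames(sample(2:20, k, replace = TRUE), seq_len(k))
    tk <- tukey_kramer_hsd(means, ns, ms_resid = runif(1, 0.02, 0.3),
                           df_resid = sample(5:40, 1))
    lets <- strsplit(tk$letters$letters, "")
    share <- function(i, j) length(intersect(lets[[i]], lets[[j]])) > 0
    for (r in seq_len(nrow(tk$pairs))) {
      i <- match(tk$pairs$treatment_1[r], tk$letters$treatment_id)
      j <- match(tk$pairs$treatment_2[r], tk$letters$treatment_id)
      expect_identical(share(i, j), !tk$pairs$significant[r])
    }
  }
})

test_that("singleton treatments stay testable through the unequal-n formula", {
  tk <- tukey_kramer_hsd(setNames(c(5, 5.1, 9), 1:3), setNames(c(10, 10, 1), 1:3),
                         ms_resid = 0.1, df_resid = 18)
  expect_equal(nrow(tk$pairs), 3)
  expect_true(all(is.finite(tk$pairs$q_stat)))
})

test_that("per-gene analysis skips unusable genes with a reason", {
  obs <- tibble::tibble(
    gene_symbol = c(rep("GOOD", 12), rep("ONETREAT", 5), rep("SPARSE", 2)),
    peptide = "PK",
    treatment_id = c(rep(1:3, each = 4), rep(11L, 5), 1:2),
    log10_intensity = 5 + rnorm(19, 0, 0.2)
  )
  out <- run_gene_anova(obs)
  expect_setequal(names(out$results), "GOOD")
  expect_equal(out$skipped$reason[out$skipped$gene_symbol == "ONETREAT"],
               "single treatment")
  expect_equal(out$skipped$reason[out$skipped$gene_symbol == "SPARSE"],
               "too few observations")
  expect_equal(nrow(run_gene_anova(obs, genes = character(0))$skipped), 0)
  # letters merged into summaries
  expect_true("letters" %in% names(out$results$GOOD$summaries))
})

test_that("a planted intensity shift separates its treatment by Tukey letters", {
  lib <- generate_protein_library(6, seed = 21, peptides_mean = 6)
  target <- median_coverage_symbols(lib, 1)
  des <- two_arm_design(samples = 2L, fractions = 5L, spectra = 350L)
  eff <- effect_spec(enriched = tibble::tibble(
    gene_symbol = target, treatment_id = 9L,
    freq_multiplier = 1, intensity_shift = 0.5))
  separated <- vapply(1:20, function(s) {
    cohort <- simulate_cohort(lib, des, eff, seed = 100 + s, symbol_sdlog = 0)
    acc <- accept_psms(cohort$psm, lib)
    obs <- intensity_observations(acc)
    out <- run_gene_anova(obs, genes = target)
    ga <- out$results[[target]]
    if (is.null(ga$tukey)) return(NA)
    pair <- ga$tukey$pairs
    pair$significant[1]
  }, logical(1))
  expect_gte(mean(separated, na.rm = TRUE), 0.9)
})

test_that("treatment-difference estimates on synthetic data are unbiased", {
  lib <- generate_protein_library(6, seed = 31, peptides_mean = 6)
  target <- median_coverage_symbols(lib, 1)
  des <- two_arm_design(samples = 2L, fractions = 5L, spectra = 400L)
  shift <- 0.5
  eff <- effect_spec(enriched = tibble::tibble(
    gene_symbol = target, treatment_id = 9L,
    freq_multiplier = 1, intensity_shift = shift))
  est <- vapply(1:60, function(s) {
    cohort <- simulate_cohort(lib, des, eff, seed = 500 + s, symbol_sdlog = 0)
    acc <- accept_psms(cohort$psm, lib)
    obs <- intensity_observations(acc) |>
      dplyr::filter(gene_symbol == target)
    s9 <- mean(obs$log10_intensity[obs$treatment_id == 9L])
    s7 <- mean(obs$log10_intensity[obs$treatment_id == 7L])
    s9 - s7
  }, numeric(1))
  expect_lt(abs(mean(est) - shift), 0.02)
})

test_that("tidy and glance methods expose the fitted objects as tibbles", {
  d <- tidyr::expand_grid(peptide = sprintf("P%dK", 1:2), treatment_id = 1:3,
                          repl = 1:3)
  d$log10_intensity <- 5 + rnorm(nrow(d), 0, 0.2)
  ga <- fit_two_way_anova(d)
  ga$gene_symbol <- "DEMO"
  td <- tidy(ga)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$gene_symbol[1], "DEMO")
  gl <- glance(ga)
  expect_equal(gl$n_obs, nrow(d))
  expect_equal(gl$n_peptides, 2)
})
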