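test_that("frequency counting matches an independent tally of accepted PSMs", {
  lib <- generate_protein_library(15, seed = 3)
  des <- two_arm_design(samples = 1L, fractions = 3L, spectra = 300L)
  cohort <- simulate_cohort(lib, des, seed = 12)
  acc <- accept_psms(cohort$psm, lib)
  fr <- count_frequencies(acc, "TRYP")
  # independent tally: base-R table over manually expanded symbols
  tryp <- acc[acc$pool == "TRYP", ]
  expanded <- data.frame(
    gene_symbol = unlist(tryp$gene_symbols),
    treatment_id = rep(tryp$treatment_id, lengths(tryp$gene_symbols))
  )
  tab <- as.data.frame(table(expanded$gene_symbol, expanded$treatment_id),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(tab))) {
    expect_equal(
      fr$n[fr$gene_symbol == tab$Var1[i] & fr$treatment_id == as.integer(tab$Var2[i])],
      tab$Freq[i]
    )
  }
  expect_true(all(fr$n >= 0))
  tot <- treatment_totals(fr)
  expect_equal(sum(tot$total), sum(fr$n))
})

test_that("empty accepted input gives an empty, all-zero matrix", {
  lib <- tiny_library()
  acc <- accept_psms(psm_row()[0, ], lib)
  fr <- count_frequencies(acc, "TRYP")
  expect_equal(nrow(fr), 0)
  expect_equal(nrow(treatment_totals(fr)), 0)
})

test_that("three PSMs of one symbol in one treatment count as three", {
  lib <- tiny_library()
  rows <- dplyr::bind_rows(
    psm_row("S1"), psm_row("S2"), psm_row("S3"),
    psm_row("S4", treatment_id = 7L)
  )
  acc <- accept_psms(rows, lib)
  fr <- count_frequencies(acc, "TRYP")
  expect_equal(fr$n[fr$gene_symbol == "HP" & fr$treatment_id == 9L], 3L)
  expect_equal(fr$n[fr$gene_symbol == "HP" & fr$treatment_id == 7L], 1L)
})

test_that("control correction scales by the ratio of treatment totals", {
  fr <- structure(
    tibble::tibble(
      gene_symbol = rep(c("A", "B"), each = 2),
      treatment_id = rep(c(9L, 7L), 2),
      n = c(50L, 10L, 150L, 90L)
    ),
    class = c("freq_matrix", class(tibble::tibble()))
  )
  # totals: disease 200, control 100 -> ratio 2
  out <- correct_control(fr, 9L, 7L)
  expect_equal(out$control_corrected[out$gene_symbol == "A"], 20)
  expect_equal(out$delta[out$gene_symbol == "A"], 30)
  # corrected control column sums to the disease total
  expect_equal(sum(out$control_corrected), sum(out$disease_count), tolerance = 1e-9)
  # identity when disease and control are the same treatment
  same <- correct_control(fr, 9L, 9L)
  expect_equal(same$control_corrected, same$disease_count)
  expect_error(correct_control(fr, 9L, 99L), "not present")
})

test_that("correction with the published tryptic totals reproduces the scale factor", {
  # control total 269,371 and disease total 660,251: a control count of 1000
  # corrects to 2451.1
  fr <- structure(
    tibble::tibble(
      gene_symbol = c("X", "X", "REST", "REST"),
      treatment_id = c(9L, 7L, 9L, 7L),
      n = c(0L, 1000L, 660251L, 268371L)
    ),
    class = c("freq_matrix", class(tibble::tibble()))
  )
  out <- correct_control(fr, 9L, 7L)
  expect_equal(out$control_corrected[out$gene_symbol == "X"], 2451.1,
               tolerance = 0.1 / 2451.1)
})

test_that("zero control total is an undefined-correction error", {
  fr <- structure(
    tibble::tibble(gene_symbol = "A", treatment_id = c(9L, 7L), n = c(5L, 0L)),
    class = c("freq_matrix", class(tibble::tibble()))
  )
  expect_error(correct_control(fr, 9L, 7L), "zero")
})

test_that("the pseudocount chi-square follows its closed form exactly", {
  expect_equal(chi_square(100, 0), 10000)
  expect_equal(chi_square(7, 7), 0)
  expect_equal(chi_square(30, 10), 400 / 11)
  expect_equal(chi_square(c(1, 2), c(0, 0)), c(1, 4))
  expect_error(chi_square(-1, 0), "non-negative")
  expect_error(chi_square(0, -2), "non-negative")
})

test_that("chi-square p-values use the df = 1 upper tail", {
  expect_equal(chi2_pvalue(0), 1)
  expect_equal(chi2_pvalue(3.841459), 0.05, tolerance = 1e-6)
  grid <- seq(0, 40, by = 0.5)
  expect_true(all(diff(chi2_pvalue(grid)) < 0))
  expect_error(chi2_pvalue(-1), "non-negative")
})

test_that("Fisher combination matches its closed form; Stouffer is exposed", {
  expect_equal(combine_peptide_pvalues(0.2), 0.2)
  expect_equal(combine_peptide_pvalues(c(1, 1, 1)), 1)
  # k = 2 closed form: p* (1 - log(p*)) with p* = p1 p2
  pstar <- 0.05 * 0.05
  expect_equal(combine_peptide_pvalues(c(0.05, 0.05)),
               pstar * (1 - log(pstar)), tolerance = 1e-12)
  expect_equal(combine_peptide_pvalues(c(0.05, 0.05)), 0.017479,
               tolerance = 1e-4)
  expect_lt(combine_peptide_pvalues(c(0.05, 0.05), method = "stouffer"), 0.05)
  expect_error(combine_peptide_pvalues(numeric(0)), "empty")
  expect_warning(out <- combine_peptide_pvalues(c(0, 0.5)), "clamped")
  expect_true(is.finite(out) && out > 0)
})

test_that("BH q-values follow the step-up rule with enforced monotonicity", {
  expect_equal(bh_qvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_qvalues(rep(0.2, 5)), rep(0.2, 5))
  set.seed(42)
  for (i in 1:10) {
    p <- runif(50)
    q <- bh_qvalues(p)
    expect_true(all(q >= p - 1e-12))
    expect_true(all(q <= 1))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
  }
})

test_that("delta quantile diagnostic is centred at zero after correction", {
  fr <- structure(
    tibble::tibble(
      gene_symbol = rep(sprintf("G%02d", 1:10), each = 2),
      treatment_id = rep(c(9L, 7L), 10),
      n = rep(c(12L, 6L), 10)
    ),
    class = c("freq_matrix", class(tibble::tibble()))
  )
  out <- correct_control(fr, 9L, 7L)
  diag <- delta_quantile_diagnostic(out)
  expect_equal(attr(diag, "mean_delta"), 0, tolerance = 1e-12)
  expect_equal(diag$delta, sort(out$delta))
  expect_equal(nrow(diag), 10)
})

test_that("candidate selection respects strictness and threshold nesting", {
  res <- tibble::tibble(
    gene_symbol = c("A", "B", "C", "D"),
    disease_count = c(100, 80, 40, 5),
    control_raw = c(10, 20, 20, 5),
    control_corrected = c(10, 20, 20, 5),
    delta = c(90, 60, 20, 0),
    chi2 = c(736.4, 171.4, 19.0, 0),
    p = chi2_pvalue(c(736.4, 171.4, 19.0, 0)),
    q = rep(0.001, 4)
  )
  loose <- select_candidates(res, 15, 15, chi2_strict = TRUE)
  strict <- select_candidates(res, 60, 15, chi2_strict = FALSE)
  expect_setequal(loose$gene_symbol, c("A", "B", "C"))
  expect_setequal(strict$gene_symbol, c("A", "B"))
  expect_true(all(strict$gene_symbol %in% loose$gene_symbol))
  expect_equal(loose$gene_symbol, loose$gene_symbol[order(-loose$chi2)])
  none <- select_candidates(dplyr::mutate(res, chi2 = 0), 15, 15)
  expect_equal(nrow(none), 0)
})

test_that("chi-square boundary rules: exactly 15 is excluded, exactly 60 is included", {
  res <- tibble::tibble(
    gene_symbol = c("AT15", "AT60"),
    disease_count = c(40, 80), control_raw = c(20, 20),
    control_corrected = c(20, 20), delta = c(20, 60),
    chi2 = c(15, 60), p = chi2_pvalue(c(15, 60)), q = c(0.01, 0.001)
  )
  expect_false("AT15" %in% select_candidates(res, 15, 15, chi2_strict = TRUE)$gene_symbol)
  expect_true("AT60" %in% select_candidates(res, 60, 15, chi2_strict = FALSE)$gene_symbol)
})

test_that("cumulative protein p-values aggregate peptide-level evidence", {
  lib <- generate_protein_library(20, seed = 13)
  target <- median_coverage_symbols(lib, 1)
  des <- two_arm_design(samples = 2L, fractions = 5L, spectra = 400L)
  eff <- effect_spec(enriched = tibble::tibble(
    gene_symbol = target, treatment_id = 9L,
    freq_multiplier = 8, intensity_shift = 0))
  cohort <- simulate_cohort(lib, des, eff, seed = 14, symbol_sdlog = 0)
  acc <- accept_psms(cohort$psm, lib)
  cum <- cumulative_protein_pvalues(acc, "TRYP", 9L, 7L)
  expect_true(all(cum$p_cumulative >= 0 & cum$p_cumulative <= 1))
  expect_true(all(cum$q >= cum$p_cumulative - 1e-12))
  # the strongly enriched symbol carries decisive combined evidence
  expect_lt(cum$q[cum$gene_symbol == target], 1e-3)
  # strategy switch produces a (possibly different) valid probability
  cum2 <- cumulative_protein_pvalues(acc, "TRYP", 9L, 7L, method = "stouffer")
  expect_true(all(cum2$p_cumulative >= 0 & cum2$p_cumulative <= 1))
})
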