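#' Tukey-Kramer HSD over treatment means with a compact letter display
#'
#' All-pairs comparison of treatment means using the studentized range
#' distribution, with the Kramer unequal-n standard error
#' `sqrt((MS_resid / 2) * (1/n_i + 1/n_j))`. A pair is significantly
#' different when its studentized statistic exceeds `qtukey(1 - alpha, k,
#' df)`. Letters are assigned by insert-and-absorb so that two treatments
#' share a letter iff their difference is not significant. Singleton
#' treatments (n = 1) remain testable through the unequal-n formula.
#'
#' @param means Named numeric vector of treatment means (names = treatment
#'   ids).
#' @param ns Named numeric vector of group sizes, aligned with `means`.
#' @param ms_resid Residual mean square of the fitted model (shared error
#'   term).
#' @param df_resid Residual degrees of freedom (>= 1).
#' @param alpha Family-wise error rate.
#' @return Object of class `tukey_hsd`: list with `pairs` (tibble
#'   `treatment_1`, `treatment_2`, `diff`, `se`, `q_stat`, `p_adj`,
#'   `significant`), `letters` (tibble `treatment_id`, `letters`),
#'   `critical` (the studentized-range critical value) and `alpha`.
#' @export
tukey_kramer_hsd <- function(means, ns, ms_resid, df_resid, alpha = 0.05) {
  k <- length(means)
  assert_that(k >= 2, "tukey_kramer_hsd needs >= 2 treatments.")
  assert_that(length(ns) == k && all(names(ns) == names(means)),
              "`ns` must align with `means`.")
  assert_that(df_resid >= 1, "residual df must be >= 1 to test.")
  assert_that(ms_resid > 0, "residual mean square must be positive.")
  crit <- qtukey(1 - alpha, nmeans = k, df = df_resid)
  cmb <- combn(k, 2)
  i <- cmb[1, ]; j <- cmb[2, ]
  se <- sqrt((ms_resid / 2) * (1 / ns[i] + 1 / ns[j]))
  qs <- abs(means[i] - means[j]) / se
  pairs <- tibble(
    treatment_1 = names(means)[i],
    treatment_2 = names(means)[j],
    diff = unname(means[i] - means[j]),
    se = unname(se),
    q_stat = unname(qs),
    p_adj = ptukey(unname(qs), nmeans = k, df = df_resid, lower.tail = FALSE),
    significant = unname(qs) > crit
  )
  sig <- matrix(FALSE, k, k, dimnames = list(names(means), names(means)))
  sig[cbind(i, j)] <- pairs$significant
  sig[cbind(j, i)] <- pairs$significant
  letters_tbl <- tibble(
    treatment_id = names(means),
    letters = assign_cld_letters(sig, order(means, decreasing = TRUE))
  )
  # keep treatment_id type aligned with summaries (integer ids)
  suppressWarnings({
    as_int <- as.integer(letters_tbl$treatment_id)
    if (!anyNA(as_int)) {
      letters_tbl$treatment_id <- as_int
      pairs$treatment_1 <- as.integer(pairs$treatment_1)
      pairs$treatment_2 <- as.integer(pairs$treatment_2)
    }
  })
  structure(list(pairs = pairs, letters = letters_tbl, critical = crit,
                 alpha = alpha),
            class = "tukey_hsd")
}

# insert-and-absorb compact letter display. `sig` is a k x k logical matrix of
# pairwise significance; `ord` orders groups (by descending mean) for letter
# naming. Guarantees: groups share a letter iff not significantly different.
assign_cld_letters <- function(sig, ord = seq_len(nrow(sig))) {
  k <- nrow(sig)
  cols <- list(rep(TRUE, k))
  pairs <- which(sig & upper.tri(sig), arr.ind = TRUE)
  if (nrow(pairs) > 0) {
    for (r in seq_len(nrow(pairs))) {
      a <- pairs[r, 1]; b <- pairs[r, 2]
      new_cols <- list()
      for (col in cols) {
        if (col[a] && col[b]) {
          c1 <- col; c1[a] <- FALSE
          c2 <- col; c2[b] <- FALSE
          new_cols <- c(new_cols, list(c1, c2))
        } else {
          new_cols <- c(new_cols, list(col))
        }
      }
      cols <- absorb_subset_columns(new_cols)
    }
  }
  cols <- cols[purrr::map_lgl(cols, any)]
  if (length(cols) == 0) cols <- purrr::map(seq_len(k), ~ seq_len(k) == .x)
  # name letters in the order groups appear along `ord`
  first_member <- purrr::map_int(cols, ~ match(TRUE, .x[ord]))
  cols <- cols[order(first_member)]
  out <- character(k)
  for (ci in seq_along(cols)) {
    lab <- if (ci <= 26) letters[ci] else paste0(letters[(ci - 1) %% 26 + 1], ci %/% 26)
    out[cols[[ci]]] <- paste0(out[cols[[ci]]], lab)
  }
  out
}

# drop duplicate membership columns and columns that are strict subsets of
# another column
absorb_subset_columns <- function(cols) {
  keys <- vapply(cols, function(col) paste(which(col), collapse = ","), "")
  cols <- cols[!duplicated(keys)]
  n <- length(cols)
  keep <- rep(TRUE, n)
  for (x in seq_len(n)) {
    for (y in seq_len(n)) {
      if (x != y && keep[x] && keep[y] && all(cols[[y]][cols[[x]]])) {
        keep[x] <- FALSE
      }
    }
  }
  cols[keep]
}

#' @export
print.tukey_hsd <- function(x, ...) {
  cat(sprintf("<tukey_hsd> %d pairwise comparisons, alpha = %g, critical q = %.3f\n",
              nrow(x$pairs), x$alpha, x$critical))
  print(x$letters)
  invisible(x)
}
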