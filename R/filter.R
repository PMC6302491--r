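#' Retain precursors above the intensity threshold
#'
#' Keeps rows with `precursor_intensity` strictly greater than the threshold
#' (the working threshold of 1e4 counts sits at the 99th percentile of the
#' noise intensity distribution). Row order is preserved.
#'
#' @param psms Tibble of PSM records.
#' @param threshold Intensity threshold in counts (> 0); the comparison is
#'   strict (`>`).
#' @return Filtered tibble.
#' @export
apply_intensity_threshold <- function(psms, threshold = 1e4) {
  assert_that(threshold >= 0, "`threshold` must be non-negative.")
  psms |> filter(.data$precursor_intensity > threshold)
}

#' Keep one best-fit candidate per spectrum
#'
#' For every spectrum (within engine, by default) exactly one candidate row
#' survives: the one with the maximal score, with a deterministic tie-break of
#' charge +2 over +3 and then the lexicographically smaller peptide string.
#' This guarantees no MS/MS spectrum is re-used by several peptide
#' assignments.
#'
#' @param psms Tibble of PSM records.
#' @param by_engine If `TRUE` (default) selection runs within each engine and
#'   a spectrum searched by two engines keeps one row per engine; if `FALSE`
#'   selection runs across engines and spectrum ids become globally unique.
#' @return Tibble with one row per (engine,) spectrum.
#' @export
select_best_fit <- function(psms, by_engine = TRUE) {
  keys <- if (by_engine) c("engine", "spectrum_id") else "spectrum_id"
  psms |>
    arrange(across(all_of(keys)), desc(.data$score), .data$charge, .data$peptide) |>
    distinct(across(all_of(keys)), .keep_all = TRUE)
}

#' Classify accepted PSMs into TRYP / STYP pools
#'
#' Checks that each peptide is fully tryptic in at least one of its mapped
#' proteins (preceded by K/R or the protein N-terminus, and ending in K/R or
#' falling at the protein C-terminus) and tags the pool: `STYP` iff the row
#' carries at least one phospho-S/T/Y modification, else `TRYP`. Rows
#' non-tryptic in all mapped proteins are removed and reported.
#'
#' @param psms Tibble of PSM records (accessions resolvable in `library`).
#' @param library A `protein_library`.
#' @return `psms` with a `pool` column; attribute `rejections` is a tibble
#'   (`spectrum_id`, `reason`) of removed rows.
#' @export
classify_pool <- function(psms, library) {
  seqs <- setNames(library$sequence, library$accession)
  key <- distinct(psms, .data$peptide, .data$accessions)
  key$tryptic_ok <- purrr::map2_lgl(key$peptide, key$accessions, function(p, a) {
    accs <- strsplit(a, ";", fixed = TRUE)[[1]]
    any(vapply(seqs[accs], is_fully_tryptic, logical(1), peptide = p))
  })
  out <- psms |> left_join(key, by = c("peptide", "accessions"))
  rejected <- out |> filter(!.data$tryptic_ok)
  out <- out |>
    filter(.data$tryptic_ok) |>
    mutate(pool = ifelse(has_phospho(.data$modifications), "STYP", "TRYP")) |>
    select(-"tryptic_ok")
  attr(out, "rejections") <- tibble(
    spectrum_id = rejected$spectrum_id,
    reason = "peptide not fully tryptic in any mapped protein"
  )
  out
}

# fully tryptic context of `peptide` within one protein sequence
is_fully_tryptic <- function(sequence, peptide) {
  if (is.na(sequence)) return(FALSE)
  starts <- gregexpr(peptide, sequence, fixed = TRUE)[[1]]
  if (starts[1] == -1L) return(FALSE)
  len <- nchar(peptide)
  last <- substr(peptide, len, len)
  for (s in starts) {
    nterm_ok <- s == 1L || substr(sequence, s - 1L, s - 1L) %in% c("K", "R")
    cterm_ok <- last %in% c("K", "R") || (s + len - 1L) == nchar(sequence)
    if (nterm_ok && cterm_ok) return(TRUE)
  }
  FALSE
}

#' Collapse accessions to gene symbols
#'
#' Maps each row's accession list to the distinct gene symbols owning those
#' accessions; a peptide matching several accessions of one symbol
#' contributes the symbol once. Rows mapping to more than one symbol are
#' flagged `degenerate` (they contribute one count to each symbol
#' downstream).
#'
#' @param psms Tibble of PSM records with non-empty `accessions`.
#' @param library A `protein_library`.
#' @return `psms` with list-column `gene_symbols` and logical `degenerate`.
#' @export
map_to_gene_symbols <- function(psms, library) {
  lut <- setNames(library$gene_symbol, library$accession)
  key <- distinct(psms, .data$accessions)
  assert_that(all(nzchar(key$accessions)),
              "empty accession list: rows must carry >= 1 accession.")
  key$gene_symbols <- purrr::map(key$accessions, function(a) {
    accs <- strsplit(a, ";", fixed = TRUE)[[1]]
    unknown <- accs[!accs %in% names(lut)]
    if (length(unknown) > 0) {
      abort(paste0("unresolvable accession(s): ", paste(unknown, collapse = ", ")))
    }
    sort(unique(unname(lut[accs])))
  })
  psms |>
    left_join(key, by = "accessions") |>
    mutate(degenerate = lengths(.data$gene_symbols) > 1L)
}

#' Apply the full PSM acceptance cascade
#'
#' Composition of the acceptance rules, in order: drop unassignable spectra
#' (empty peptide), intensity threshold (strict `>`), optional restriction to
#' one engine, one best fit per spectrum, fully tryptic validation with
#' TRYP/STYP pool classification, and gene-symbol mapping. The stage-by-stage
#' row counts (the filter funnel) are attached for reporting.
#'
#' @param psms Tibble of PSM records.
#' @param library A `protein_library`.
#' @param intensity_threshold Counts threshold (strict).
#' @param engine Optional engine name to restrict to (e.g. `"XTANDEM"`);
#'   `NULL` keeps all engines with best-fit selection within engine.
#' @param by_engine Passed to [select_best_fit()].
#' @return Accepted-PSM tibble with `pool`, `gene_symbols`, `degenerate`
#'   columns; attributes `funnel` (stage, n) and `rejections`.
#' @export
accept_psms <- function(psms, library, intensity_threshold = 1e4,
                        engine = NULL, by_engine = TRUE) {
  funnel <- tibble(stage = "total", n = nrow(psms))
  x <- psms |> filter(!is.na(.data$peptide) & nzchar(.data$peptide))
  funnel <- add_row(funnel, stage = "assigned", n = nrow(x))
  x <- apply_intensity_threshold(x, intensity_threshold)
  funnel <- add_row(funnel, stage = "above_threshold", n = nrow(x))
  if (!is.null(engine)) {
    x <- x |> filter(.data$engine == !!engine)
    funnel <- add_row(funnel, stage = "engine", n = nrow(x))
  }
  x <- select_best_fit(x, by_engine = by_engine)
  funnel <- add_row(funnel, stage = "best_fit", n = nrow(x))
  x <- classify_pool(x, library)
  rej <- attr(x, "rejections")
  funnel <- add_row(funnel, stage = "tryptic", n = nrow(x))
  x <- map_to_gene_symbols(x, library)
  funnel <- add_row(funnel, stage = "accepted", n = nrow(x))
  attr(x, "funnel") <- funnel
  attr(x, "rejections") <- rej
  x
}
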