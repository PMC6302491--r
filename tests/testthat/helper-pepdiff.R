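# Shared fixtures and independent oracles. Oracles deliberately avoid the
# code paths they check.

# character-by-character fully tryptic digestion (oracle for digest_tryptic)
oracle_digest <- function(sequence, min_len = 6, max_len = 30) {
  aa <- strsplit(sequence, "")[[1]]
  peps <- character(0)
  cur <- character(0)
  for (ch in aa) {
    cur <- c(cur, ch)
    if (ch %in% c("K", "R")) {
      peps <- c(peps, paste(cur, collapse = ""))
      cur <- character(0)
    }
  }
  if (length(cur) > 0) peps <- c(peps, paste(cur, collapse = ""))
  peps[nchar(peps) >= min_len & nchar(peps) <= max_len]
}

# sequential (type-I) sums of squares by explicit design-matrix projection
oracle_sequential_ss <- function(d) {
  y <- d$log10_intensity
  P <- factor(d$peptide)
  T_ <- factor(d$treatment_id)
  rss <- function(X) {
    q <- qr(X)
    sum((y - qr.fitted(q, y))^2)
  }
  X0 <- matrix(1, nrow = length(y))
  Xp <- model.matrix(~P)
  Xpt <- model.matrix(~ P + T_)
  Xfull <- model.matrix(~ P * T_)
  r0 <- rss(X0); rp <- rss(Xp); rpt <- rss(Xpt); rf <- rss(Xfull)
  c(Peptide_Sequence = r0 - rp,
    Treatment_ID = rp - rpt,
    `Peptide_Sequence:Treatment_ID` = rpt - rf,
    Residuals = rf,
    Total = r0)
}

# hand-built miniature library with known tryptic contexts and shared /
# degenerate accessions
tiny_library <- function() {
  structure(
    tibble::tibble(
      accession = c("HP_A1", "HP_A2", "C4A_A1", "C4B_A1"),
      gene_symbol = c("HP", "HP", "C4A", "C4B"),
      # HP isoforms share SSSDDDR; ALALALK is shared by C4A and C4B
      sequence = c(
        "MMMAAAKSSSDDDRLPQPQPK",
        "SSSDDDRWWWCCCK",
        "ALALALKTTTYYYR",
        "ALALALKGGGFFFR"
      )
    ),
    class = c("protein_library", class(tibble::tibble()))
  )
}

# minimal well-formed PSM row builder
psm_row <- function(spectrum_id = "S1", sample_id = "T09_S01",
                    treatment_id = 9L, fraction_id = 1L, engine = "XTANDEM",
                    peptide = "SSSDDDR", modifications = "", charge = 2L,
                    precursor_mz = 500, precursor_intensity = 2e4,
                    score = 50, accessions = "HP_A1;HP_A2") {
  tibble::tibble(
    spectrum_id = spectrum_id, sample_id = sample_id,
    treatment_id = treatment_id, fraction_id = fraction_id, engine = engine,
    peptide = peptide, modifications = modifications, charge = charge,
    precursor_mz = precursor_mz, precursor_intensity = precursor_intensity,
    score = score, accessions = accessions
  )
}

# two-treatment disease/control design used across simulation tests
two_arm_design <- function(samples = 3L, fractions = 10L, spectra = 300L) {
  trts <- tibble::tribble(
    ~treatment_id, ~label, ~class, ~pool,
    9L, "Cancer ovarian", "disease", "TRYP",
    7L, "Cancer control", "matched_normal", "TRYP"
  )
  study_design(trts, samples_per_treatment = samples,
               fractions_per_sample = fractions,
               spectra_per_fraction = spectra)
}

# symbols whose peptide count is closest to the library median (stable,
# well-covered targets for planting effects)
median_coverage_symbols <- function(library, k = 2) {
  counts <- peptide_index(library) |>
    dplyr::count(gene_symbol)
  med <- stats::median(counts$n)
  counts[order(abs(counts$n - med), counts$gene_symbol), ]$gene_symbol[seq_len(k)]
}
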