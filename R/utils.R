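# Monoisotopic residue masses (Da); used only to emit plausible precursor m/z.
AA_RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
MASS_WATER <- 18.010565
MASS_PROTON <- 1.007276
MOD_MASS <- c(
  "Phospho-S" = 79.96633, "Phospho-T" = 79.96633, "Phospho-Y" = 79.96633,
  "Oxidation-M" = 15.99491, "Acetyl" = 42.01057,
  "Loss-water" = -18.010565, "Loss-ammonia" = -17.026549
)

#' Peptide precursor m/z
#'
#' Monoisotopic m/z of a peptide at a given charge, including any modification
#' mass shifts.
#'
#' @param peptide Character vector of peptide sequences (20-letter alphabet).
#' @param charge Integer vector of precursor charges.
#' @param mod_mass Numeric vector of summed modification mass shifts (Da).
#' @return Numeric vector of m/z values.
#' @export
peptide_mz <- function(peptide, charge, mod_mass = 0) {
  mass <- vapply(strsplit(peptide, ""), function(aa) {
    sum(AA_RESIDUE_MASS[aa])
  }, numeric(1)) + MASS_WATER + mod_mass
  (mass + charge * MASS_PROTON) / charge
}

# total mass shift encoded in a modifications string like "Phospho-S@4;Oxidation-M@7"
mod_mass_shift <- function(modifications) {
  vapply(strsplit(modifications, ";", fixed = TRUE), function(m) {
    m <- m[nzchar(m)]
    if (length(m) == 0L) return(0)
    sum(MOD_MASS[sub("@.*$", "", m)])
  }, numeric(1))
}

# TRUE where the modifications string carries >= 1 phospho on S/T/Y
has_phospho <- function(modifications) {
  stringr::str_detect(modifications %||% "", "Phospho-[STY]")
}

# deterministic per-sample substream seed derived from the global seed
substream_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647L)
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}
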