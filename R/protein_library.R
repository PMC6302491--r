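#' Generate a synthetic non-redundant protein library
#'
#' Builds a small analogue of the non-redundant protein library used for
#' peptide-to-spectrum correlation: each gene symbol owns one or more
#' accessions (isoforms), every sequence is a concatenation of fully tryptic
#' peptides (interior residues exclude K/R, each peptide ends in K or R), so
#' in-silico tryptic digestion recovers a known peptide pool. Accessions of
#' one symbol share a core set of peptides and add a few isoform-specific
#' ones, so that shared peptides map to several accessions of the same symbol.
#'
#' @param n_symbols Number of distinct gene symbols (>= 2; a single symbol
#'   cannot support a disease/control contrast).
#' @param accessions_per_symbol Accessions (isoforms) per gene symbol.
#' @param seed Integer seed; output is deterministic given the seed.
#' @param peptides_mean Mean of the (geometric, shifted) number of core
#'   tryptic peptides per symbol. The peptide-count distribution across
#'   proteins is a tunable of the generator, not an assertion about real
#'   plasma.
#' @param unique_peptides Isoform-specific peptides added per accession.
#' @param peptide_length Integer range of generated tryptic peptide lengths.
#' @return A tibble of class `protein_library` with columns `accession`,
#'   `gene_symbol`, `sequence`.
#' @examples
#' lib <- generate_protein_library(5, 2, seed = 1)
#' lib
#' @export
generate_protein_library <- function(n_symbols,
                                     accessions_per_symbol = 1,
                                     seed = 1L,
                                     peptides_mean = 8,
                                     unique_peptides = 2,
                                     peptide_length = c(6L, 30L)) {
  if (n_symbols < 2) {
    abort("`n_symbols` must be >= 2: a single symbol cannot support a disease/control contrast.")
  }
  assert_that(accessions_per_symbol >= 1, "`accessions_per_symbol` must be >= 1.")

  withr::with_seed(seed, {
    symbols <- sprintf("G%04d", seq_len(n_symbols))
    n_core <- pmax(2L, rgeom(n_symbols, 1 / peptides_mean) + 1L)
    lib <- purrr::map(seq_len(n_symbols), function(i) {
      core <- random_tryptic_peptides(n_core[i], peptide_length)
      purrr::map(seq_len(accessions_per_symbol), function(a) {
        extra <- if (unique_peptides > 0 && accessions_per_symbol > 1) {
          random_tryptic_peptides(unique_peptides, peptide_length)
        } else {
          character(0)
        }
        tibble(
          accession = sprintf("%s_A%02d", symbols[i], a),
          gene_symbol = symbols[i],
          sequence = paste(c(core, extra), collapse = "")
        )
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
    new_protein_library(lib)
  })
}

new_protein_library <- function(x) {
  class(x) <- c("protein_library", class(tibble()))
  x
}

# peptides with interior residues excluding K/R and a terminal K or R, so the
# concatenated protein digests back into exactly these peptides
random_tryptic_peptides <- function(n, peptide_length) {
  interior <- setdiff(names(AA_RESIDUE_MASS), c("K", "R"))
  lens <- sample(seq(peptide_length[1], peptide_length[2]), n, replace = TRUE)
  vapply(lens, function(L) {
    paste0(
      paste(sample(interior, L - 1L, replace = TRUE), collapse = ""),
      sample(c("K", "R"), 1L)
    )
  }, character(1))
}

#' In-silico fully tryptic digestion
#'
#' Cuts a protein sequence after every K or R (no enzyme-specificity
#' exceptions) and returns the fragments within a length window.
#'
#' @param sequence A single amino-acid string.
#' @param min_len,max_len Retained peptide length window.
#' @return Character vector of fully tryptic peptides.
#' @export
digest_tryptic <- function(sequence, min_len = 6L, max_len = 30L) {
  frags <- strsplit(gsub("(?<=[KR])", "\037", sequence, perl = TRUE), "\037",
                    fixed = TRUE)[[1]]
  frags[nchar(frags) >= min_len & nchar(frags) <= max_len]
}

#' Peptide index of a protein library
#'
#' Digests every accession and returns one row per distinct peptide with the
#' accessions (semicolon-separated, sorted) and gene symbols that own it.
#'
#' @param library A `protein_library` tibble.
#' @inheritParams digest_tryptic
#' @return Tibble with columns `peptide`, `accessions`, `gene_symbol`,
#'   `n_symbols`, `has_sty`.
#' @export
peptide_index <- function(library, min_len = 6L, max_len = 30L) {
  long <- library |>
    mutate(peptide = purrr::map(.data$sequence, digest_tryptic,
                                min_len = min_len, max_len = max_len)) |>
    select("accession", "gene_symbol", "peptide") |>
    tidyr::unnest("peptide")
  long |>
    group_by(.data$peptide) |>
    summarise(
      accessions = paste(sort(unique(.data$accession)), collapse = ";"),
      n_symbols = n_distinct(.data$gene_symbol),
      gene_symbol = sort(unique(.data$gene_symbol))[1],
      .groups = "drop"
    ) |>
    mutate(has_sty = stringr::str_detect(.data$peptide, "[STY]"))
}

#' Write / read a protein library as FASTA
#'
#' Header convention: `>ACCESSION GN=SYMBOL`.
#'
#' @param library A `protein_library` tibble.
#' @param path File path.
#' @return `write_library_fasta` returns `path` invisibly;
#'   `read_library_fasta` returns a `protein_library` tibble.
#' @export
write_library_fasta <- function(library, path) {
  seqs <- Biostrings::AAStringSet(library$sequence)
  names(seqs) <- paste0(library$accession, " GN=", library$gene_symbol)
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' @rdname write_library_fasta
#' @export
read_library_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  hdr <- names(seqs)
  gn <- stringr::str_match(hdr, "GN=(\\S+)")[, 2]
  if (anyNA(gn)) {
    abort("FASTA headers must carry a `GN=SYMBOL` tag (`>ACCESSION GN=SYMBOL`).")
  }
  new_protein_library(tibble(
    accession = sub("\\s.*$", "", hdr),
    gene_symbol = gn,
    sequence = as.character(seqs)
  ))
}
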