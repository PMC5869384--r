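# FASTA / TSV input-output ---------------------------------------------------
#
# Thin tibble-facing wrappers around Biostrings and readr so that every
# sequence set in the package is a two-column tibble (id, seq).

#' Read a FASTA file into a tibble
#'
#' @param path file path.
#' @param type `"AA"` for protein, `"DNA"` for nucleotide.
#' @return A tibble with columns `id` and `seq`.
#' @export
read_fasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  x <- if (type == "AA") Biostrings::readAAStringSet(path)
       else Biostrings::readDNAStringSet(path)
  tibble(id = names(x), seq = as.character(x))
}

#' Write a tibble of sequences to FASTA
#'
#' @param seqs tibble with columns `id` and `seq`.
#' @param path output path.
#' @param type `"AA"` or `"DNA"`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  x <- if (type == "AA") Biostrings::AAStringSet(setNames(seqs$seq, seqs$id))
       else Biostrings::DNAStringSet(setNames(seqs$seq, seqs$id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read / write plain TSV tables
#'
#' Deterministic TSV round-trip used for counts, truth, hits and annotation
#' sidecar tables.
#' @param x data frame to write.
#' @param path file path.
#' @return For `write_tox_tsv()`, `path` invisibly; for `read_tox_tsv()`, a
#'   tibble.
#' @export
write_tox_tsv <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_tox_tsv
#' @export
read_tox_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
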