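# Scoring scheme for protein homology search -------------------------------

#' BLOSUM62 substitution matrix
#'
#' Returns the BLOSUM62 scoring matrix (from \pkg{Biostrings}), the matrix
#' used by default blastp and by every alignment in this package.
#'
#' @return Integer matrix with amino-acid row/column names (includes `X` and
#'   `*`); unknown residues are scored through the `X` row.
#' @export
blosum62 <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
}

#' Construct a scoring scheme for local homology search
#'
#' Bundles the substitution matrix, affine gap costs and the Karlin-Altschul
#' statistical parameters used to convert raw Smith-Waterman scores to bit
#' scores and E-values. Defaults are the standard gapped BLOSUM62-11-1
#' constants used by blastp: a gap of length `g` costs
#' `gap_open + (g - 1) * gap_extend`.
#'
#' @param matrix substitution matrix (default [blosum62()]).
#' @param gap_open cost of the first residue of a gap (default 11).
#' @param gap_extend cost of each further gap residue (default 1).
#' @param lambda Karlin-Altschul scale parameter (default 0.267).
#' @param K Karlin-Altschul search-space constant (default 0.041).
#' @return An object of class `tox_scoring_scheme`.
#' @examples
#' sc <- scoring_scheme()
#' sc$gap_open
#' @export
scoring_scheme <- function(matrix = blosum62(), gap_open = 11, gap_extend = 1,
                           lambda = 0.267, K = 0.041) {
  stopifnot(is.matrix(matrix), identical(rownames(matrix), colnames(matrix)))
  if (gap_open <= 0 || gap_extend <= 0) {
    abort("gap costs must be positive", class = "toxaudit_config_error")
  }
  if (lambda <= 0 || K <= 0) {
    abort("lambda and K must be positive", class = "toxaudit_config_error")
  }
  if (!isTRUE(all(matrix == t(matrix)))) {
    abort("substitution matrix must be symmetric",
          class = "toxaudit_config_error")
  }
  structure(
    list(matrix = matrix, gap_open = gap_open, gap_extend = gap_extend,
         lambda = lambda, K = K),
    class = "tox_scoring_scheme"
  )
}

#' @export
print.tox_scoring_scheme <- function(x, ...) {
  cat("<tox_scoring_scheme> ", nrow(x$matrix), "x", ncol(x$matrix),
      " matrix, gap ", x$gap_open, "/", x$gap_extend,
      ", lambda=", x$lambda, ", K=", x$K, "\n", sep = "")
  invisible(x)
}
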