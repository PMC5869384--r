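# Local-alignment homology search and best-hit family assignment ------------
#
# The annotation engine: exact Smith-Waterman local alignment with affine
# gaps under BLOSUM62 replaces the seeded blastp heuristic (word size is
# ignored; exactness can only find at least the hits a seeded search would),
# with Karlin-Altschul statistics converting raw scores to bit scores and
# E-values.

#' Smith-Waterman local alignment
#'
#' Optimal local alignment of two proteins under the scheme's substitution
#' matrix and affine gap costs (a gap of length `g` costs
#' `gap_open + (g - 1) * gap_extend`). Unknown residues are scored through
#' the `X` row of the matrix.
#'
#' @param query,subject protein strings (non-empty).
#' @param scheme a [scoring_scheme()].
#' @return One-row tibble: `score` (raw score, >= 0), `qstart`, `qend`,
#'   `sstart`, `send` (0-based half-open residue spans of the optimal local
#'   alignment), `matches`, `aln_len`.
#' @examples
#' sw_align("ACDE", "ACDE")$score  # 24
#' sw_align("ACDE", "ACDF")$score  # 19
#' @export
sw_align <- function(query, subject, scheme = scoring_scheme()) {
  if (is.na(query) || is.na(subject) ||
      nchar(query) == 0 || nchar(subject) == 0) {
    abort("sw_align requires non-empty sequences",
          class = "toxaudit_input_error")
  }
  r <- sw_align_cpp(encode_protein(query, scheme$matrix),
                    encode_protein(subject, scheme$matrix),
                    scheme$matrix, scheme$gap_open, scheme$gap_extend)
  tibble(score = r$score, qstart = r$qstart, qend = r$qend,
         sstart = r$sstart, send = r$send, matches = r$matches,
         aln_len = r$aln_len)
}

#' Karlin-Altschul E-value and bit score
#'
#' `evalue()` computes the expected number of chance local alignments with
#' score at least `score`: `E = K * m * n * exp(-lambda * S)`. `bitscore()`
#' rescales a raw score to bits: `(lambda * S - ln K) / ln 2`.
#'
#' @param score raw alignment score(s).
#' @param m query length in residues (> 0).
#' @param n total database residues (> 0).
#' @param scheme a [scoring_scheme()] supplying `lambda` and `K`.
#' @return Numeric E-value(s) (> 0), decreasing in `score`, linear in `m`
#'   and `n`.
#' @examples
#' evalue(40, 100, 100)  # ~9.4e-3 with the gapped BLOSUM62-11-1 constants
#' @export
evalue <- function(score, m, n, scheme = scoring_scheme()) {
  if (any(m <= 0) || any(n <= 0)) {
    abort("sequence/database lengths must be positive",
          class = "toxaudit_input_error")
  }
  scheme$K * m * n * exp(-scheme$lambda * score)
}

#' @rdname evalue
#' @export
bitscore <- function(score, scheme = scoring_scheme()) {
  (scheme$lambda * score - log(scheme$K)) / log(2)
}

#' Search queries against a protein database
#'
#' Aligns every query against every database entry by full Smith-Waterman
#' and keeps pairs with E-value at or below `e_threshold`. There is no query
#' coverage filter (minimum query coverage 0). The database search space `n`
#' is the total residue count of the database tier.
#'
#' @param queries tibble with columns `id` and `aa_seq` (or `seq`).
#' @param database tibble with columns `family`, `id`, `seq`.
#' @param e_threshold E-value cutoff (default 0.001).
#' @param scheme a [scoring_scheme()].
#' @return Hits tibble in blastp outfmt-6-like column order: `query_id`,
#'   `subject_id`, `family`, `pident`, `length`, `qstart`, `qend`, `sstart`,
#'   `send` (0-based half-open), `evalue`, `bitscore`, `score`.
#' @export
homology_search <- function(queries, database, e_threshold = 0.001,
                            scheme = scoring_scheme()) {
  if (nrow(database) == 0) {
    abort("homology database is empty", class = "toxaudit_input_error")
  }
  qcol <- if ("aa_seq" %in% names(queries)) "aa_seq" else "seq"
  stopifnot(all(c("id", qcol) %in% names(queries)),
            all(c("family", "id", "seq") %in% names(database)))
  if (nrow(queries) == 0) return(empty_hits_tbl())
  n_db <- sum(nchar(database$seq))
  enc_s <- encode_protein_set(database$seq, scheme$matrix)
  out <- vector("list", nrow(queries))
  for (i in seq_len(nrow(queries))) {
    qseq <- queries[[qcol]][[i]]
    enc_q <- encode_protein(qseq, scheme$matrix)
    sc <- sw_score_many_cpp(enc_q, enc_s, scheme$matrix, scheme$gap_open,
                            scheme$gap_extend)
    ev <- evalue(sc, nchar(qseq), n_db, scheme)
    keep <- which(ev <= e_threshold)
    if (length(keep) == 0) next
    # full alignments (spans, identity) only for accepted hits
    d <- sw_align_many_cpp(enc_q, enc_s[keep], scheme$matrix,
                           scheme$gap_open, scheme$gap_extend)
    out[[i]] <- list(
      query_id = rep.int(queries$id[[i]], length(keep)),
      subject_id = database$id[keep],
      family = database$family[keep],
      pident = ifelse(d$aln_len > 0, d$matches / d$aln_len, 0),
      length = d$aln_len,
      qstart = d$qstart, qend = d$qend,
      sstart = d$sstart, send = d$send,
      evalue = ev[keep],
      bitscore = bitscore(d$score, scheme),
      score = d$score
    )
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) return(empty_hits_tbl())
  as_tibble(lapply(setNames(nm = names(out[[1]])), function(col) {
    unlist(lapply(out, `[[`, col), use.names = FALSE)
  }))
}

empty_hits_tbl <- function() {
  tibble(query_id = character(), subject_id = character(),
         family = character(), pident = double(), length = integer(),
         qstart = integer(), qend = integer(), sstart = integer(),
         send = integer(), evalue = double(), bitscore = double(),
         score = double())
}

#' Assign each query to the family of its best hit
#'
#' Per query, the hit with maximal bit score wins; ties are broken by lower
#' E-value, then lexicographic subject id. Queries without hits are simply
#' absent from the result.
#'
#' @param hits tibble as returned by [homology_search()].
#' @return Tibble with one row per query: `query_id`, `family`, plus the
#'   winning hit's columns.
#' @export
assign_families <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  hits |>
    arrange(.data$query_id, dplyr::desc(.data$bitscore), .data$evalue,
            .data$subject_id) |>
    group_by(.data$query_id) |>
    dplyr::slice(1) |>
    ungroup()
}

#' Annotate a CDS set against one database tier
#'
#' The full homology-tier annotation pipeline, in fixed order: homology
#' search, best-hit family assignment, retention of signal-peptide-positive
#' CDSs, removal of identical sequences. Returns the surviving family
#' assignments together with the four stage counts reported per tier
#' (unique contigs, unique CDS, unique CDS with signal peptide, unique
#' full-length CDS).
#'
#' @param cds tibble of coding sequences ([extract_orfs()] output, plus
#'   `sp_start`/`sp_end` columns when `sp_mode = "truth"`).
#' @param database tibble with columns `family`, `id`, `seq`.
#' @param e_threshold E-value cutoff (default 0.001).
#' @param scheme a [scoring_scheme()].
#' @param sp_mode signal-peptide mode passed to [detect_signal_peptide()].
#' @param exclude_ids optional character vector of CDS ids to drop before
#'   counting — the hook for a manual false-positive review list.
#' @return List with `assignments` (surviving CDS rows joined with their
#'   family assignment), `annotated_all` (all annotated CDSs after
#'   deduplication but before the signal-peptide filter — the alternative
#'   false-positive denominator), and `counts` (tibble `stage`, `count`
#'   with the four stages above).
#' @export
annotate_dataset <- function(cds, database, e_threshold = 0.001,
                             scheme = scoring_scheme(),
                             sp_mode = c("truth", "heuristic"),
                             exclude_ids = character()) {
  sp_mode <- match.arg(sp_mode)
  if (length(exclude_ids) > 0) cds <- filter(cds, !.data$id %in% exclude_ids)
  if (nrow(cds) == 0) {
    return(list(assignments = tibble(), annotated_all = tibble(),
                counts = stage_counts(0, 0, 0, 0)))
  }
  hits <- homology_search(cds, database, e_threshold, scheme)
  assign <- assign_families(hits)
  annotated <- cds |> filter(.data$id %in% assign$query_id)
  n_contigs <- dplyr::n_distinct(annotated$contig_id)
  n_cds <- dplyr::n_distinct(annotated$aa_seq)
  with_sp <- detect_signal_peptide(annotated, mode = sp_mode) |>
    filter(.data$has_signal_peptide)
  survivors <- dedupe_identical(with_sp)
  n_sp <- nrow(survivors)
  n_full <- sum(survivors$is_complete)
  assignments <- survivors |>
    left_join(select(assign, "query_id", "family", "subject_id",
                     "evalue", "bitscore"),
              by = c(id = "query_id"))
  list(
    assignments = assignments,
    annotated_all = dedupe_identical(annotated),
    counts = stage_counts(n_contigs, n_cds, n_sp, n_full)
  )
}

stage_counts <- function(n_contigs, n_cds, n_sp, n_full) {
  tibble(
    stage = c("unique_contigs", "unique_cds", "unique_cds_signal_peptide",
              "unique_full_length_cds"),
    count = as.integer(c(n_contigs, n_cds, n_sp, n_full))
  )
}
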