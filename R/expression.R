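# FPKM, the comparative-expression filter, detection-expression correlation -

#' Fragments per kilobase per million mapped fragments
#'
#' `FPKM = count * 1e9 / (length_bp * library_total)`. An empty library
#' (`library_total = 0`) yields 0 by convention rather than NaN.
#'
#' @param count fragment count(s), non-negative.
#' @param length_bp feature length(s) in nucleotides (> 0).
#' @param library_total total mapped fragments in the library (>= 0).
#' @return FPKM value(s).
#' @examples
#' fpkm(10, 1000, 1e6)  # 10
#' @export
fpkm <- function(count, length_bp, library_total) {
  if (any(length_bp <= 0)) {
    abort("length_bp must be positive", class = "toxaudit_input_error")
  }
  if (any(library_total < 0)) {
    abort("library_total must be non-negative",
          class = "toxaudit_input_error")
  }
  res <- count * 1e9 / (length_bp * library_total)
  res[!is.finite(res)] <- 0   # empty library -> 0 by convention
  res
}

#' Compute per-record FPKM for both tissues
#'
#' @param counts tibble with `id`, `length_bp`, `count_vg`, `count_muscle`.
#' @param library_vg,library_muscle library totals; default the column sums.
#' @return `counts` with `fpkm_vg` and `fpkm_muscle` added.
#' @export
compute_expression <- function(counts, library_vg = sum(counts$count_vg),
                               library_muscle = sum(counts$count_muscle)) {
  stopifnot(all(c("id", "length_bp", "count_vg", "count_muscle")
                %in% names(counts)))
  counts |>
    mutate(fpkm_vg = fpkm(.data$count_vg, .data$length_bp, library_vg),
           fpkm_muscle = fpkm(.data$count_muscle, .data$length_bp,
                              library_muscle))
}

#' Comparative-expression filter parameters
#'
#' Defaults are the filter used throughout: venom-gland FPKM at least 100
#' and at least 10-fold overexpression relative to muscle. The fold change
#' is computed with a small additive pseudocount in the denominator so that
#' contigs absent from muscle (muscle FPKM 0) pass the fold criterion.
#'
#' @param min_fpkm_vg minimum venom-gland FPKM (default 100).
#' @param min_fold minimum venom-gland/muscle fold (default 10).
#' @param pseudocount FPKM units added to the muscle denominator
#'   (default 0.01).
#' @return A list of class `tox_filter_params`.
#' @export
filter_params <- function(min_fpkm_vg = 100, min_fold = 10,
                          pseudocount = 0.01) {
  if (min_fpkm_vg < 0) abort("min_fpkm_vg must be >= 0",
                             class = "toxaudit_config_error")
  if (min_fold < 1) abort("min_fold must be >= 1",
                          class = "toxaudit_config_error")
  if (pseudocount <= 0) abort("pseudocount must be > 0",
                              class = "toxaudit_config_error")
  structure(list(min_fpkm_vg = min_fpkm_vg, min_fold = min_fold,
                 pseudocount = pseudocount),
            class = "tox_filter_params")
}

#' Apply the comparative-expression filter
#'
#' Retains a record iff `fpkm_vg >= min_fpkm_vg` and
#' `fpkm_vg / (fpkm_muscle + pseudocount) >= min_fold`.
#'
#' @param records tibble with `id`, `fpkm_vg`, `fpkm_muscle`.
#' @param params a [filter_params()].
#' @return Character vector of retained ids.
#' @export
expression_filter <- function(records, params = filter_params()) {
  stopifnot(all(c("id", "fpkm_vg", "fpkm_muscle") %in% names(records)))
  fold <- records$fpkm_vg / (records$fpkm_muscle + params$pseudocount)
  records$id[records$fpkm_vg >= params$min_fpkm_vg & fold >= params$min_fold]
}

#' Spearman rank correlation with a t-approximation p-value
#'
#' Ranks use averages for ties; the two-tailed p-value comes from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom, for
#' all sample sizes.
#'
#' @param x,y numeric vectors of equal length, `n >= 3`, each with nonzero
#'   rank variance.
#' @return One-row tibble `r`, `p`, `n`.
#' @examples
#' spearman_cor(1:5, c(2, 1, 4, 3, 5))  # r = 0.8
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) {
    abort("x and y must have equal length", class = "toxaudit_input_error")
  }
  n <- length(x)
  if (n < 3) {
    abort("spearman correlation undefined for n < 3",
          class = "toxaudit_undefined_error")
  }
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    abort("spearman correlation undefined for zero-variance input",
          class = "toxaudit_undefined_error")
  }
  r <- cor(rx, ry)
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tval), df = n - 2)
  }
  tibble(r = r, p = p, n = n)
}

#' Detection-expression correlations per annotation set and tissue
#'
#' For each annotation set, correlates the 0/1 membership indicator over all
#' expression records with FPKM in the venom gland and in muscle. Cells with
#' an undefined correlation (e.g. constant indicator) are reported with `NA`
#' and a reason rather than an error.
#'
#' @param sets named list of character id vectors (e.g. proteome, species,
#'   lineage, distant).
#' @param records expression tibble with `id`, `fpkm_vg`, `fpkm_muscle`.
#' @return Tibble `set`, `tissue`, `r`, `p`, `n`, `note`.
#' @export
detection_expression_table <- function(sets, records) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  purrr::imap(sets, function(ids, nm) {
    ind <- as.numeric(records$id %in% ids)
    purrr::map(c(vg = "fpkm_vg", muscle = "fpkm_muscle"), function(col) {
      res <- tryCatch(spearman_cor(ind, records[[col]]),
                      error = function(e) {
                        tibble(r = NA_real_, p = NA_real_,
                               n = length(ind))
                      })
      res$note <- if (is.na(res$r)) "undefined" else ""
      res
    }) |>
      bind_rows(.id = "tissue")
  }) |>
    bind_rows(.id = "set") |>
    select("set", "tissue", "r", "p", "n", "note")
}

#' Per-family expression summaries
#'
#' Five-number summaries (min, Q1, median, Q3, max; type-7 quantiles) plus
#' 5th/95th percentile whiskers of FPKM, per toxin family and tissue.
#'
#' @param assignments tibble with `id` and `family`.
#' @param records expression tibble with `id`, `fpkm_vg`, `fpkm_muscle`.
#' @return Tibble `family`, `tissue`, `n`, `min`, `q1`, `median`, `q3`,
#'   `max`, `p5`, `p95`.
#' @export
family_expression_summary <- function(assignments, records) {
  stopifnot(all(c("id", "family") %in% names(assignments)))
  if (nrow(assignments) == 0) {
    abort("assignments must be non-empty", class = "toxaudit_input_error")
  }
  assignments |>
    select("id", "family") |>
    left_join(records, by = "id") |>
    tidyr::pivot_longer(c("fpkm_vg", "fpkm_muscle"), names_to = "tissue",
                        names_prefix = "fpkm_", values_to = "fpkm") |>
    group_by(.data$family, .data$tissue) |>
    summarise(
      n = dplyr::n(),
      min = min(.data$fpkm), q1 = quantile(.data$fpkm, 0.25, names = FALSE),
      median = median(.data$fpkm),
      q3 = quantile(.data$fpkm, 0.75, names = FALSE), max = max(.data$fpkm),
      p5 = quantile(.data$fpkm, 0.05, names = FALSE),
      p95 = quantile(.data$fpkm, 0.95, names = FALSE),
      .groups = "drop"
    )
}
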