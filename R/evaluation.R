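# Accuracy audit: set comparisons, FP rates, diversity, precision/recall ----

#' Exclusive Venn region counts for 2 or 3 annotation sets
#'
#' @param sets named list of 2 or 3 character vectors (ids; duplicates are
#'   ignored).
#' @return Tibble `region`, `count` covering all `2^k - 1` exclusive
#'   regions; counts sum to the size of the union.
#' @export
venn_counts <- function(sets) {
  if (!is.list(sets) || length(sets) < 2 || length(sets) > 3) {
    abort("venn_counts needs 2 or 3 sets", class = "toxaudit_input_error")
  }
  if (is.null(names(sets)) || any(names(sets) == "")) {
    names(sets) <- paste0("set", seq_along(sets))
  }
  sets <- lapply(sets, unique)
  ids <- unique(unlist(sets))
  member <- vapply(sets, function(s) ids %in% s, logical(length(ids)))
  if (length(ids) == 1) member <- matrix(member, nrow = 1,
                                         dimnames = list(NULL, names(sets)))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))[-1, ,
                                                                 drop = FALSE]
  names(combos) <- names(sets)
  region <- apply(combos, 1, function(z) {
    paste(names(sets)[as.logical(z)], collapse = "&")
  })
  count <- apply(combos, 1, function(z) {
    z <- as.logical(z)
    if (length(ids) == 0) return(0L)
    sum(apply(member, 1, function(m) all(m == z)))
  })
  tibble(region = region, count = as.integer(count))
}

#' False-positive rate of a predicted toxin set against the proteome
#'
#' `|predicted \\ proteome| / |predicted|` — the fraction of predicted
#' putative toxins not backed by proteomic detection.
#'
#' @param predicted character vector of predicted ids (non-empty).
#' @param proteome character vector of proteome-detected ids.
#' @return Fraction in \[0, 1\].
#' @export
false_positive_rate <- function(predicted, proteome) {
  predicted <- unique(predicted)
  if (length(predicted) == 0) {
    abort("false-positive rate undefined for an empty predicted set",
          class = "toxaudit_undefined_error")
  }
  sum(!predicted %in% proteome) / length(predicted)
}

#' Per-family diversity profile and deltas against the proteome
#'
#' For each tier, the percentage of its CDSs in each family, and the
#' deviation from the proteome reference profile in both units used in
#' practice: percentage-point difference and fold ratio.
#'
#' @param tiers named list of assignment tibbles (`id`, `family`), the
#'   proteome reference first or passed via `reference`.
#' @param reference assignment tibble (`id`, `family`) for the proteome.
#' @return Tibble `tier`, `family`, `pct`, `ref_pct`, `delta_pp`, `fold`
#'   (fold is `NA` where the reference percentage is 0).
#' @export
family_diversity_profile <- function(tiers, reference) {
  stopifnot(is.list(tiers), !is.null(names(tiers)))
  if (nrow(reference) == 0) {
    abort("empty reference assignment set", class = "toxaudit_input_error")
  }
  pct_of <- function(df) {
    df |>
      dplyr::count(.data$family) |>
      mutate(pct = 100 * .data$n / sum(.data$n)) |>
      select("family", "pct")
  }
  ref <- pct_of(reference) |> rename(ref_pct = "pct")
  purrr::imap(tiers, function(df, nm) {
    if (nrow(df) == 0) {
      abort(paste0("empty tier: ", nm), class = "toxaudit_input_error")
    }
    pct_of(df) |>
      dplyr::full_join(ref, by = "family") |>
      mutate(pct = tidyr::replace_na(.data$pct, 0),
             ref_pct = tidyr::replace_na(.data$ref_pct, 0),
             delta_pp = .data$pct - .data$ref_pct,
             fold = ifelse(.data$ref_pct > 0, .data$pct / .data$ref_pct,
                           NA_real_))
  }) |>
    bind_rows(.id = "tier") |>
    arrange(.data$tier, .data$family)
}

#' Precision, recall and F1 against a ground-truth toxin set
#'
#' @param predicted character vector of predicted ids (non-empty).
#' @param truth character vector of true toxin ids.
#' @return One-row tibble `precision`, `recall`, `f1`, `tp`, `fp`, `fn`.
#' @export
precision_recall <- function(predicted, truth) {
  predicted <- unique(predicted); truth <- unique(truth)
  if (length(predicted) == 0) {
    abort("precision undefined for an empty predicted set",
          class = "toxaudit_undefined_error")
  }
  tp <- sum(predicted %in% truth)
  fp <- length(predicted) - tp
  fn <- sum(!truth %in% predicted)
  precision <- tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  tibble(precision = precision, recall = recall, f1 = f1,
         tp = tp, fp = fp, fn = fn)
}

#' Intraspecific overlap between two populations' mature peptides
#'
#' Pools the two populations' mature peptides (signal peptides already
#' removed by the caller) and clusters them at each identity threshold with
#' [cluster_by_identity()]; a cluster is shared when it contains at least
#' one member from each population.
#'
#' @param pop_a,pop_b tibbles with columns `id` and `seq`; ids must be
#'   disjoint between populations.
#' @param thresholds identity thresholds (default `c(0.95, 0.90)`).
#' @param scheme a [scoring_scheme()].
#' @return Tibble `threshold`, `n_clusters`, `n_shared`.
#' @export
intraspecific_overlap <- function(pop_a, pop_b,
                                  thresholds = c(0.95, 0.90),
                                  scheme = scoring_scheme()) {
  if (nrow(pop_a) == 0 || nrow(pop_b) == 0) {
    abort("both populations must be non-empty",
          class = "toxaudit_input_error")
  }
  pooled <- bind_rows(mutate(pop_a, population = "A"),
                      mutate(pop_b, population = "B"))
  purrr::map(thresholds, function(th) {
    cl <- cluster_by_identity(pooled, th, scheme) |>
      left_join(select(pooled, "id", "population"),
                by = c(member_id = "id"))
    shared <- cl |>
      group_by(.data$cluster) |>
      summarise(shared = dplyr::n_distinct(.data$population) == 2,
                .groups = "drop")
    tibble(threshold = th, n_clusters = nrow(shared),
           n_shared = sum(shared$shared))
  }) |> bind_rows()
}

#' Assemble the evaluation report
#'
#' Bundles every audit output of one pipeline run into a single object of
#' class `tox_report` that serializes deterministically to JSON (plus TSV
#' tables) via [write_report()].
#'
#' @param tier_counts named list (per tier) of stage-count tibbles from
#'   [annotate_dataset()].
#' @param venn tibble from [venn_counts()].
#' @param fp_rates named numeric vector of per-tier FP rates (unit: unique
#'   signal-peptide-positive CDS ids); `fp_rates_all_cds` the same over all
#'   annotated unique CDS ids (both denominators are reported because the
#'   choice is ambiguous in practice).
#' @param fp_rates_all_cds see `fp_rates`.
#' @param diversity tibble from [family_diversity_profile()].
#' @param pr tibble of precision/recall rows with a `set` column.
#' @param correlations tibble from [detection_expression_table()].
#' @param retention named list with `n_proteome`, `n_retained`, `fraction`.
#' @param overlap tibble from [intraspecific_overlap()].
#' @param clade_retention tibble (per family) of leaf counts
#'   before/after the clade-evidence filter.
#' @return A `tox_report` object.
#' @export
build_report <- function(tier_counts, venn, fp_rates, fp_rates_all_cds,
                         diversity, pr, correlations, retention, overlap,
                         clade_retention) {
  parts <- list(tier_counts = tier_counts, venn = venn,
                fp_rates = fp_rates, fp_rates_all_cds = fp_rates_all_cds,
                diversity = diversity, pr = pr,
                correlations = correlations, retention = retention,
                overlap = overlap, clade_retention = clade_retention)
  missing <- names(parts)[vapply(parts, is.null, logical(1))]
  if (length(missing) > 0) {
    abort(paste("missing report stages:", paste(missing, collapse = ", ")),
          class = "toxaudit_input_error")
  }
  structure(parts, class = "tox_report")
}

#' Write / validate a report
#'
#' `write_report()` writes `report.json` plus one TSV per table into `dir`;
#' identical inputs produce byte-identical files. `validate_report()`
#' checks the structural invariants promised by the shipped schema
#' (`inst/extdata/report-schema.json`): Venn regions sum to the union, all
#' rates lie in \[0, 1\], diversity percentages sum to 100 per tier.
#'
#' @param report a `tox_report`.
#' @param dir output directory.
#' @return `write_report()`: `dir` invisibly. `validate_report()`: `TRUE`,
#'   or an error describing the violated invariant.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(report),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (nm in c("venn", "diversity", "pr", "correlations", "overlap",
               "clade_retention")) {
    write_tox_tsv(report[[nm]], file.path(dir, paste0(nm, ".tsv")))
  }
  invisible(dir)
}

#' @rdname write_report
#' @export
validate_report <- function(report) {
  stopifnot(inherits(report, "tox_report"))
  rates <- c(report$fp_rates, report$fp_rates_all_cds,
             report$retention$fraction)
  if (any(rates < 0 | rates > 1, na.rm = TRUE)) {
    abort("rates outside [0, 1]", class = "toxaudit_report_error")
  }
  pct_sums <- report$diversity |>
    group_by(.data$tier) |>
    summarise(s = sum(.data$pct), .groups = "drop")
  if (any(abs(pct_sums$s - 100) > 1e-9)) {
    abort("diversity percentages do not sum to 100",
          class = "toxaudit_report_error")
  }
  if (any(report$venn$count < 0)) {
    abort("negative Venn region", class = "toxaudit_report_error")
  }
  TRUE
}

#' @export
print.tox_report <- function(x, ...) {
  cat("<tox_report>\n  FP rates:",
      paste(sprintf("%s=%.3f", names(x$fp_rates), x$fp_rates),
            collapse = " "),
      "\n  filter retention:", sprintf("%.1f%%", 100 * x$retention$fraction),
      "of proteome-detected ids\n")
  invisible(x)
}
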