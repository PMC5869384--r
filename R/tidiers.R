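# broom-style tidiers and ggplot2 views of the audit ------------------------

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an evaluation report
#'
#' Returns the report's scalar metrics as one long tibble
#' (`metric`, `set`, `value`), convenient for plotting and comparison
#' across runs.
#'
#' @param x a `tox_report`.
#' @param ... unused.
#' @return A tibble with columns `metric`, `set`, `value`.
#' @export
tidy.tox_report <- function(x, ...) {
  rows <- list(
    tibble(metric = "fp_rate", set = names(x$fp_rates),
           value = unname(x$fp_rates)),
    tibble(metric = "fp_rate_all_cds", set = names(x$fp_rates_all_cds),
           value = unname(x$fp_rates_all_cds)),
    tibble(metric = "filter_retention", set = "proteome",
           value = x$retention$fraction)
  )
  if (nrow(x$pr) > 0) {
    rows <- c(rows, list(
      x$pr |>
        mutate(set = paste0(.data$set,
                            ifelse(.data$filtered, "_filtered", ""))) |>
        select("set", "precision", "recall", "f1") |>
        tidyr::pivot_longer(c("precision", "recall", "f1"),
                            names_to = "metric", values_to = "value") |>
        select("metric", "set", "value")
    ))
  }
  bind_rows(rows)
}

#' Glance at an evaluation report
#'
#' One-row summary: per-tier FP rates, expression-filter retention, and the
#' venom-gland detection-expression correlation.
#'
#' @param x a `tox_report`.
#' @param ... unused.
#' @return A one-row tibble.
#' @export
glance.tox_report <- function(x, ...) {
  vg <- x$correlations |>
    filter(.data$set == "proteome", .data$tissue == "vg")
  tibble(
    fp_rate_distant = x$fp_rates[["distant"]] %||% NA_real_,
    fp_rate_lineage = x$fp_rates[["lineage"]] %||% NA_real_,
    fp_rate_species = x$fp_rates[["species"]] %||% NA_real_,
    filter_retention = x$retention$fraction,
    spearman_vg = if (nrow(vg) > 0) vg$r[[1]] else NA_real_,
    spearman_vg_p = if (nrow(vg) > 0) vg$p[[1]] else NA_real_
  )
}

#' Plot per-tier false-positive rates
#'
#' @param object a `tox_report`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.tox_report <- function(object, ...) {
  df <- tibble(tier = names(object$fp_rates),
               fp_rate = unname(object$fp_rates))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tier, y = .data$fp_rate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "database tier",
                  y = "false-positive rate vs proteome",
                  title = "Homology annotation audited against the proteome") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-family expression distributions in both tissues
#'
#' @param summary tibble from [family_expression_summary()].
#' @return A ggplot object (median and quartile ranges per family/tissue,
#'   log10 FPKM scale).
#' @export
plot_family_expression <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$family, colour = .data$tissue)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(y = .data$median, ymin = .data$q1, ymax = .data$q3),
      position = ggplot2::position_dodge(width = 0.5)
    ) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "toxin family", y = "FPKM",
                  title = "Family expression: venom gland vs muscle") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Scatter of venom-gland vs muscle expression, highlighting a set
#'
#' @param records expression tibble (`id`, `fpkm_vg`, `fpkm_muscle`).
#' @param highlight character vector of ids to emphasize (e.g. the
#'   proteome-detected set).
#' @return A ggplot object with the 1:1 line dashed.
#' @export
plot_detection_expression <- function(records, highlight = character()) {
  df <- mutate(records, detected = .data$id %in% highlight)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpkm_muscle + 0.01,
                                   y = .data$fpkm_vg + 0.01,
                                   colour = .data$detected)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "muscle FPKM", y = "venom gland FPKM") +
    ggplot2::theme_minimal()
}

#' Plot a family tree with evidence annotations
#'
#' Tip labels are coloured by proteomic detection and clade-filter
#' retention (base \pkg{ape} graphics, the field's standard tree view).
#'
#' @param family_tree one element of a pipeline run's `trees` list
#'   (`tree`, `evidence`, `retained`).
#' @param ... passed to [ape::plot.phylo()].
#' @return Invisibly, the tree.
#' @export
plot_family_tree <- function(family_tree, ...) {
  tr <- family_tree$tree
  ev <- family_tree$evidence
  col <- ifelse(!tr$tip.label %in% family_tree$retained, "grey50",
                ifelse(tr$tip.label %in% ev$id[ev$evidence],
                       "firebrick", "steelblue"))
  ape::plot.phylo(tr, tip.color = col, ...)
  invisible(tr)
}
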