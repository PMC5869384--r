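# Orchestration: simulate -> extract -> annotate -> express -> trees -> audit

#' Pipeline run configuration
#'
#' Exactly one of `sim` (a [sim_config()], synthetic mode) or `paths`
#' (real-data mode: named list with `contigs`, `counts`, `proteome`, and
#' `databases`, itself a named list of FASTA paths per tier with
#' `family|id` headers) must be provided. Synthetic mode carries ground
#' truth, so signal peptides default to truth mode and precision/recall and
#' intraspecific overlap are computed; real-data mode uses the heuristic
#' detector and skips truth-referenced metrics.
#'
#' @param sim a [sim_config()], or `NULL`.
#' @param paths named list of input paths, or `NULL`.
#' @param filter a [filter_params()].
#' @param scheme a [scoring_scheme()].
#' @param e_threshold homology E-value cutoff (default 0.001).
#' @param d_max clade-evidence radius (`"median"` or numeric).
#' @param thresholds identity thresholds for intraspecific overlap.
#' @param out_dir output directory for artifacts, or `NULL` for none.
#' @param log_level `"info"` or `"quiet"`.
#' @return A list of class `tox_run_config`.
#' @export
run_config <- function(sim = NULL, paths = NULL, filter = filter_params(),
                       scheme = scoring_scheme(), e_threshold = 0.001,
                       d_max = "median", thresholds = c(0.95, 0.90),
                       out_dir = NULL, log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  if (is.null(sim) == is.null(paths)) {
    abort("provide exactly one of `sim` or `paths`",
          class = "toxaudit_config_error")
  }
  if (!is.null(sim)) stopifnot(inherits(sim, "tox_sim_config"))
  if (!is.null(paths)) {
    need <- c("contigs", "counts", "proteome", "databases")
    miss <- setdiff(need, names(paths))
    if (length(miss) > 0) {
      abort(paste("missing input paths:", paste(miss, collapse = ", ")),
            class = "toxaudit_config_error")
    }
  }
  structure(list(sim = sim, paths = paths, filter = filter, scheme = scheme,
                 e_threshold = e_threshold, d_max = d_max,
                 thresholds = thresholds, out_dir = out_dir,
                 log_level = log_level),
            class = "tox_run_config")
}

pipe_log <- function(rc, ...) {
  if (rc$log_level == "info") message("[toxaudit] ", ...)
}

#' Run the full annotation-and-audit pipeline
#'
#' Executes every stage in fixed order: data (simulated or loaded), 6-frame
#' ORF extraction, homology annotation against each database tier (search,
#' best-hit family assignment, signal-peptide filter, deduplication),
#' expression computation and the comparative-expression filter, per-family
#' neighbor-joining trees with midpoint rooting and the clade-evidence
#' retention rule, and the evaluation report. Deterministic given the seed;
#' with `out_dir` set, every intermediate is written to disk.
#'
#' @param rc a [run_config()].
#' @return A list of class `tox_run` with the simulated/loaded data
#'   (`data`), per-tier annotation (`tiers`), CDS table (`cds`), expression
#'   records, retained id sets, per-family trees, and the `tox_report`
#'   (`report`).
#' @export
run_pipeline <- function(rc) {
  stopifnot(inherits(rc, "tox_run_config"))
  synthetic <- !is.null(rc$sim)

  # --- stage: input data ---
  if (synthetic) {
    pipe_log(rc, "simulating study (seed ", rc$sim$seed, ")")
    sim <- simulate_venom_study(rc$sim)
    contigs <- sim$contigs
    expression <- sim$expression
    proteome_genes <- sim$proteome
    databases <- sim$databases
    truth <- sim$truth
  } else {
    pipe_log(rc, "loading inputs")
    sim <- NULL
    contigs <- read_fasta(rc$paths$contigs, type = "DNA")
    expression <- compute_expression(read_tox_tsv(rc$paths$counts))
    proteome_genes <- readLines(rc$paths$proteome)
    databases <- purrr::map(rc$paths$databases, function(p) {
      db <- read_fasta(p, type = "AA")
      parts <- stringr::str_split_fixed(db$id, stringr::fixed("|"), 2)
      tibble(family = parts[, 1], id = parts[, 2], seq = db$seq)
    })
    truth <- NULL
  }
  for (tier in names(databases)) {
    if (nrow(databases[[tier]]) == 0) {
      abort(paste0("homology stage: database tier '", tier, "' is empty"),
            class = "toxaudit_stage_error")
    }
  }

  # --- stage: ORF extraction ---
  cds <- extract_orfs(contigs)
  pipe_log(rc, nrow(cds), " ORFs >= 40 aa from ", nrow(contigs), " contigs")
  if (synthetic) {
    cds <- cds |>
      left_join(select(truth, "id", true_family = "family", "is_toxin",
                       "is_secreted", "detected", "cds_start", "cds_end",
                       sp_start_gene = "sp_start", sp_end_gene = "sp_end"),
                by = c(contig_id = "id")) |>
      mutate(
        is_true_cds = .data$frame > 0 & .data$start == .data$cds_start &
          .data$end == .data$cds_end,
        sp_start = ifelse(.data$is_true_cds, .data$sp_start_gene,
                          NA_integer_),
        sp_end = ifelse(.data$is_true_cds, .data$sp_end_gene, NA_integer_)
      ) |>
      select(-"sp_start_gene", -"sp_end_gene")
    sp_mode <- "truth"
  } else {
    cds$is_true_cds <- NA
    sp_mode <- "heuristic"
  }

  # --- stage: homology annotation per tier ---
  tiers <- purrr::imap(databases, function(db, nm) {
    res <- annotate_dataset(cds, db, e_threshold = rc$e_threshold,
                            scheme = rc$scheme, sp_mode = sp_mode)
    pipe_log(rc, "tier ", nm, ": ",
             paste(res$counts$stage, res$counts$count, sep = "=",
                   collapse = ", "))
    res
  })
  tier_sets <- purrr::map(tiers, ~ .x$assignments$id %||% character(0))

  # --- stage: expression filter ---
  retained_genes <- expression_filter(expression, rc$filter)
  pipe_log(rc, length(retained_genes), "/", nrow(expression),
           " genes pass the expression filter")
  retained_cds_sets <- purrr::map(tiers, function(t) {
    a <- t$assignments
    if (nrow(a) == 0) return(character(0))
    a$id[a$contig_id %in% retained_genes]
  })

  # proteome and truth reference sets at CDS-id resolution
  if (synthetic) {
    true_cds <- filter(cds, .data$is_true_cds)
    proteome_cds <- true_cds$id[true_cds$detected]
    toxin_cds <- true_cds$id[true_cds$is_toxin]
  } else {
    # real data: the proteome list names CDS ids directly
    proteome_cds <- proteome_genes
    toxin_cds <- NULL
  }

  # --- stage: family trees + clade-evidence retention ---
  trees <- list()
  clade_rows <- list()
  if (synthetic) {
    fams <- unique(true_cds$true_family)
    for (fam in fams) {
      fc <- filter(true_cds, .data$true_family == fam)
      if (nrow(fc) < 4) next
      d <- identity_distance_matrix(
        tibble(id = fc$id, seq = fc$aa_seq), rc$scheme
      )
      tr <- midpoint_root(nj_tree(d))
      ev <- tibble(
        id = fc$id,
        evidence = fc$detected | fc$contig_id %in% retained_genes
      )
      kept <- withCallingHandlers(
        clade_evidence_filter(tr, ev, rc$d_max),
        warning = function(w) invokeRestart("muffleWarning")
      )
      trees[[fam]] <- list(tree = tr, evidence = ev, retained = kept)
      clade_rows[[fam]] <- tibble(
        family = fam, n_leaves = nrow(fc), n_evidence = sum(ev$evidence),
        n_retained = length(kept),
        n_detected_retained = sum(fc$id[fc$detected] %in% kept)
      )
    }
  }
  clade_retention <- bind_rows(clade_rows)
  if (nrow(clade_retention) == 0) {
    clade_retention <- tibble(family = character(), n_leaves = integer(),
                              n_evidence = integer(), n_retained = integer(),
                              n_detected_retained = integer())
  }

  # --- stage: evaluation ---
  venn <- venn_counts(tier_sets[intersect(
    c("species", "lineage", "distant"), names(tier_sets))] )
  fp_rates <- vapply(tier_sets, function(s) {
    if (length(s) == 0) NA_real_ else false_positive_rate(s, proteome_cds)
  }, numeric(1))
  fp_all <- vapply(tiers, function(t) {
    ids <- t$annotated_all$id %||% character(0)
    if (length(ids) == 0) NA_real_
    else false_positive_rate(ids, proteome_cds)
  }, numeric(1))
  pr <- tibble()
  if (synthetic) {
    pr <- bind_rows(c(
      purrr::imap(tier_sets, function(s, nm) {
        if (length(s) == 0) return(NULL)
        mutate(precision_recall(s, toxin_cds), set = nm,
               filtered = FALSE)
      }),
      purrr::imap(retained_cds_sets, function(s, nm) {
        if (length(s) == 0) return(NULL)
        mutate(precision_recall(s, toxin_cds), set = nm, filtered = TRUE)
      })
    ))
  }
  gene_sets <- c(
    list(proteome = proteome_genes),
    purrr::map(tiers, function(t) {
      if (nrow(t$assignments) == 0) character(0)
      else unique(t$assignments$contig_id)
    })
  )
  correlations <- detection_expression_table(gene_sets, expression)
  retention <- list(
    n_proteome = length(proteome_genes),
    n_retained = sum(proteome_genes %in% retained_genes),
    fraction = if (length(proteome_genes) == 0) NA_real_
               else mean(proteome_genes %in% retained_genes)
  )
  diversity_tiers <- purrr::map(tiers, function(t) {
    a <- t$assignments
    if (nrow(a) == 0) return(tibble(id = character(), family = character()))
    select(a, "id", "family")
  })
  reference <- if (synthetic) {
    filter(true_cds, .data$detected) |> select("id", family = "true_family")
  } else {
    tibble(id = proteome_cds, family = "unknown")
  }
  diversity <- tryCatch(
    family_diversity_profile(diversity_tiers, reference),
    error = function(e) tibble(tier = character(), family = character(),
                               pct = double(), ref_pct = double(),
                               delta_pp = double(), fold = double())
  )
  overlap <- tibble(threshold = double(), n_clusters = integer(),
                    n_shared = integer())
  if (synthetic && nrow(sim$pop_b_peptides) > 0) {
    pop_a <- purrr::map(sim$families, function(f) {
      keep <- f$truth$is_toxin & f$truth$is_secreted
      tibble(id = f$proteins$id[keep], seq = f$proteins$mature_seq[keep])
    }) |> bind_rows()
    if (nrow(pop_a) > 0) {
      overlap <- intraspecific_overlap(
        pop_a, select(sim$pop_b_peptides, "id", "seq"),
        thresholds = rc$thresholds, scheme = rc$scheme
      )
    }
  }

  report <- build_report(
    tier_counts = purrr::map(tiers, "counts"),
    venn = venn, fp_rates = fp_rates, fp_rates_all_cds = fp_all,
    diversity = diversity, pr = pr, correlations = correlations,
    retention = retention, overlap = overlap,
    clade_retention = clade_retention
  )

  run <- structure(
    list(data = if (synthetic) sim else
           list(contigs = contigs, expression = expression),
         cds = cds, tiers = tiers, tier_sets = tier_sets,
         retained_genes = retained_genes,
         retained_cds_sets = retained_cds_sets,
         proteome_cds = proteome_cds, toxin_cds = toxin_cds,
         expression = expression, trees = trees, report = report),
    class = "tox_run"
  )

  # --- stage: artifacts ---
  if (!is.null(rc$out_dir)) {
    dir.create(rc$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(tibble(id = cds$id, seq = cds$aa_seq),
                file.path(rc$out_dir, "orfs.fasta"), type = "AA")
    for (nm in names(tiers)) {
      write_tox_tsv(tiers[[nm]]$counts,
                    file.path(rc$out_dir, paste0("counts_", nm, ".tsv")))
      a <- tiers[[nm]]$assignments
      if (nrow(a) > 0) {
        write_tox_tsv(select(a, "id", "contig_id", "family", "subject_id",
                             "evalue", "bitscore"),
                      file.path(rc$out_dir,
                                paste0("assignments_", nm, ".tsv")))
      }
    }
    write_tox_tsv(expression, file.path(rc$out_dir, "expression.tsv"))
    cds_expr <- cds |>
      select("id", "contig_id") |>
      left_join(select(expression, "id", "fpkm_vg", "fpkm_muscle"),
                by = c(contig_id = "id")) |>
      select("id", "fpkm_vg", "fpkm_muscle")
    for (fam in names(trees)) {
      annotate_and_export(
        trees[[fam]]$tree, cds_expr,
        proteome_cds, trees[[fam]]$retained,
        file.path(rc$out_dir, paste0("tree_", fam))
      )
    }
    write_report(report, rc$out_dir)
  }
  run
}

#' @export
print.tox_run <- function(x, ...) {
  print(x$report)
  invisible(x)
}

# Config files ---------------------------------------------------------------

.known_keys <- list(
  top = c("seed", "simulation", "paths", "filter", "homology", "d_max",
          "thresholds", "out_dir", "log_level"),
  filter = c("min_fpkm_vg", "min_fold", "pseudocount"),
  homology = c("e_threshold", "gap_open", "gap_extend", "lambda", "K")
)

#' Validate a YAML run-configuration file
#'
#' Parses the file, rejects unknown keys (with a nearest-known-key
#' suggestion), validates values, and returns the normalized
#' [run_config()] with every default resolved. All problems are reported
#' at once.
#'
#' @param file path to a YAML config file.
#' @return A `tox_run_config` on success; otherwise an error listing every
#'   problem.
#' @export
validate_config <- function(file) {
  raw <- yaml::read_yaml(file)
  errs <- character(0)
  suggest <- function(key, known) {
    d <- utils::adist(key, known)
    if (min(d) <= 3) paste0(" (did you mean '", known[which.min(d)], "'?)")
    else ""
  }
  check_keys <- function(x, known, where) {
    for (k in setdiff(names(x), known)) {
      errs <<- c(errs, paste0("unknown key '", k, "' in ", where,
                              suggest(k, known)))
    }
  }
  check_keys(raw, .known_keys$top, "config")
  if (!is.null(raw$filter)) {
    check_keys(raw$filter, .known_keys$filter, "filter")
  }
  if (!is.null(raw$homology)) {
    check_keys(raw$homology, .known_keys$homology, "homology")
  }
  fp <- tryCatch(
    do.call(filter_params,
            raw$filter[intersect(names(raw$filter),
                                 .known_keys$filter)] %||% list()),
    error = function(e) {
      errs <<- c(errs, conditionMessage(e)); filter_params()
    }
  )
  hk <- raw$homology %||% list()
  sc <- tryCatch(
    scoring_scheme(gap_open = hk$gap_open %||% 11,
                   gap_extend = hk$gap_extend %||% 1,
                   lambda = hk$lambda %||% 0.267, K = hk$K %||% 0.041),
    error = function(e) {
      errs <<- c(errs, conditionMessage(e)); scoring_scheme()
    }
  )
  has_sim <- !is.null(raw$simulation)
  has_paths <- !is.null(raw$paths)
  if (has_sim == has_paths) {
    errs <- c(errs,
              "exactly one of 'simulation' or 'paths' must be provided")
  }
  sim <- NULL
  if (has_sim && !has_paths) {
    sim_args <- raw$simulation
    if (isTRUE(sim_args)) sim_args <- list()
    if (!is.null(raw$seed)) sim_args$seed <- raw$seed
    sim <- tryCatch(do.call(sim_config, sim_args),
                    error = function(e) {
                      errs <<- c(errs, conditionMessage(e)); NULL
                    })
  }
  if (length(errs) > 0) {
    abort(paste0("invalid config:\n  ", paste(errs, collapse = "\n  ")),
          class = "toxaudit_config_error")
  }
  run_config(sim = sim, paths = raw$paths, filter = fp, scheme = sc,
             e_threshold = hk$e_threshold %||% 0.001,
             d_max = raw$d_max %||% "median",
             thresholds = raw$thresholds %||% c(0.95, 0.90),
             out_dir = raw$out_dir,
             log_level = raw$log_level %||% "info")
}
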