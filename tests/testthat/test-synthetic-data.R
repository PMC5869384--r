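test_that("configuration validation rejects bad values, all at once", {
  expect_s3_class(sim_config(), "tox_sim_config")
  err <- tryCatch(sim_config(frag_prob = 2, birth_rate = -1),
                  error = function(e) conditionMessage(e))
  expect_match(err, "frag_prob")
  expect_match(err, "birth_rate")
  expect_error(simulate_family(sim_config(), 99),
               class = "toxaudit_config_error")
})

test_that("identical configs produce byte-identical studies", {
  cfg <- small_sim(seed = 5)
  s1 <- simulate_venom_study(cfg)
  s2 <- simulate_venom_study(cfg)
  expect_identical(s1$contigs, s2$contigs)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$expression, s2$expression)
  expect_identical(s1$proteome, s2$proteome)
  expect_identical(s1$databases, s2$databases)
  # on-disk form too
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(s1, d1); write_simulation(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7), label = f)
  }
})

test_that("zero substitution rate leaves every sequence at the root", {
  cfg <- sim_config(seed = 3, n_families = 1,
                    leaves_per_family = c(6L, 6L), subst_rate = 0)
  fam <- simulate_family(cfg, 1)
  expect_true(all(fam$proteins$mature_seq == fam$root_seq))
  expect_true(all(fam$tree$edge.length >= 0))
})

test_that("observed leaf divergence matches a Monte-Carlo site oracle", {
  cfg <- sim_config(seed = 8, n_families = 1,
                    leaves_per_family = c(8L, 8L), subst_rate = 0.5,
                    toxin_clade_fraction = 0, root_length_aa = 120)
  fam <- simulate_family(cfg, 1)
  pd <- ape::cophenetic.phylo(fam$tree)
  mats <- setNames(fam$proteins$mature_seq, fam$proteins$id)
  # independent oracle: replay the substitution process per site
  rp <- toxaudit:::replacement_probs()
  oracle_diff <- function(d, nrep = 500) {
    hits <- 0
    for (r in seq_len(nrep)) {
      a <- sample(rownames(rp), 1)
      b <- a
      for (k in seq_len(rpois(1, d))) b <- sample(colnames(rp), 1,
                                                  prob = rp[b, ])
      if (a != b) hits <- hits + 1
    }
    hits / nrep
  }
  set.seed(999)
  ids <- names(mats)
  obs <- c(); exp_p <- c()
  pairs <- utils::combn(ids, 2)
  for (k in sample(ncol(pairs), 8)) {
    i <- pairs[1, k]; j <- pairs[2, k]
    xi <- strsplit(mats[[i]], "")[[1]]; xj <- strsplit(mats[[j]], "")[[1]]
    obs <- c(obs, mean(xi != xj))
    exp_p <- c(exp_p, oracle_diff(pd[i, j]))
  }
  p <- mean(exp_p)
  sd3 <- 3 * sqrt(p * (1 - p) / (120 * length(obs)))
  expect_lt(abs(mean(obs) - p), sd3 + 3 * sqrt(p * (1 - p) / 500))
})

test_that("toxin expression dominates the venom gland, never muscle", {
  truth <- tibble::tibble(
    id = sprintf("g%03d", 1:120),
    is_toxin = rep(c(TRUE, FALSE), each = 60),
    is_secreted = rep(c(TRUE, FALSE), each = 60),
    length_bp = 500L)
  cfg <- sim_config(seed = 13, vg_logFPKM_toxin = c(2.5, 0.3),
                    vg_logFPKM_nontoxin = c(0.5, 0.3))
  e <- simulate_expression(truth, cfg)
  expect_true(all(e$count_vg >= 0 & e$count_vg == floor(e$count_vg)))
  expect_gt(median(e$fpkm_vg[truth$is_toxin]),
            median(e$fpkm_vg[!truth$is_toxin]))
  # library conservation including the background remainder
  expect_equal(sum(e$count_vg) + attr(e, "background_vg"),
               cfg$library_size_vg)
  # FPKM = 0 iff count = 0 given a nonzero library
  expect_equal(e$fpkm_vg == 0, e$count_vg == 0)
})

test_that("an empty library yields all-zero counts and FPKM", {
  truth <- tibble::tibble(id = c("a", "b"), is_toxin = c(TRUE, FALSE),
                          is_secreted = c(TRUE, FALSE), length_bp = 400L)
  e <- simulate_expression(truth, sim_config(seed = 1, library_size_vg = 0))
  expect_true(all(e$count_vg == 0))
  expect_true(all(e$fpkm_vg == 0))
})

test_that("proteomic detection follows the logistic model", {
  n <- 3000
  truth <- tibble::tibble(id = sprintf("t%04d", 1:n), is_toxin = TRUE,
                          is_secreted = TRUE, length_bp = 400L)
  fpkm_vals <- rep(c(1, 10, 100, 1000, 1e4, 1e5), length.out = n)
  expression <- tibble::tibble(id = truth$id, fpkm_vg = fpkm_vals)

  # saturating limits
  hi <- simulate_proteome(truth, expression,
                          sim_config(seed = 2, detection_slope = 0,
                                     detection_intercept = 50))
  expect_setequal(hi, truth$id)
  lo <- simulate_proteome(truth, expression,
                          sim_config(seed = 2, detection_slope = 0,
                                     detection_intercept = -50))
  expect_length(lo, 0)

  # per-decade detection fraction within 3 binomial SD of the closed form
  cfg <- sim_config(seed = 7, detection_slope = 1.5,
                    detection_intercept = -3)
  det <- simulate_proteome(truth, expression, cfg)
  for (v in unique(fpkm_vals)) {
    idx <- expression$fpkm_vg == v
    p <- plogis(-3 + 1.5 * log10(v + 1))
    obs <- mean(truth$id[idx] %in% det)
    expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / sum(idx)) + 1e-9)
  }

  # non-toxins are never detected
  nt <- dplyr::mutate(truth, is_toxin = FALSE)
  expect_length(simulate_proteome(nt, expression, cfg), 0)
})

test_that("fragmentation rates match their binomial expectation", {
  mk_prot <- function(n) tibble::tibble(
    id = sprintf("p%03d", 1:n),
    seq = replicate(n, random_peptide(90)),
    mature_seq = NA_character_, sp_len = NA_integer_)
  truth <- function(p) tibble::tibble(id = p$id, family = "F",
                                      is_toxin = FALSE,
                                      is_secreted = FALSE,
                                      population = "A")
  p0 <- mk_prot(50)
  none <- fragment_and_emit(p0, truth(p0), sim_config(seed = 4,
                                                      frag_prob = 0))
  expect_true(all(none$truth$complete))
  orfs <- extract_orfs(none$contigs)
  true_orfs <- dplyr::inner_join(orfs, none$truth,
                                 by = c(contig_id = "id")) |>
    dplyr::filter(.data$start == .data$cds_start,
                  .data$end == .data$cds_end)
  expect_equal(nrow(true_orfs), 50L)
  expect_true(all(true_orfs$length_aa == 90L))
  expect_true(all(true_orfs$is_complete))

  all_frag <- fragment_and_emit(p0, truth(p0),
                                sim_config(seed = 4, frag_prob = 1))
  expect_false(any(all_frag$truth$complete))

  p1 <- mk_prot(400)
  some <- fragment_and_emit(p1, truth(p1),
                            sim_config(seed = 6, frag_prob = 0.35))
  obs <- mean(!some$truth$complete)
  expect_lt(abs(obs - 0.35), 3 * sqrt(0.35 * 0.65 / 400))
})

test_that("database tiers have the promised structure", {
  cfg <- small_sim(seed = 11)
  sim <- simulate_venom_study(cfg)
  dbs <- sim$databases
  # species tier is exactly the detected precursors of population A
  detected_seqs <- sim$families |>
    purrr::map(~ .x$proteins$seq[.x$proteins$id %in% sim$proteome]) |>
    unlist()
  expect_setequal(dbs$species$seq, detected_seqs)
  # decoy families appear only in the distant tier, with disjoint labels
  true_fams <- unique(sim$truth$family)
  expect_true(any(grepl("^DECOY", dbs$distant$family)))
  expect_length(intersect(true_fams, grep("^DECOY", dbs$distant$family,
                                          value = TRUE)), 0)
  expect_false(any(grepl("^DECOY", c(dbs$lineage$family,
                                     dbs$species$family))))
  # zero extra divergence makes distant entries equal family roots
  cfg0 <- sim_config(seed = 11, n_families = 2,
                     leaves_per_family = c(8L, 10L), db_divergence = 0,
                     n_decoy_families = 0, distant_coverage = 1)
  sim0 <- simulate_venom_study(cfg0)
  roots <- purrr::map_chr(sim0$families, "root_seq")
  expect_true(all(sim0$databases$distant$seq %in% roots))
})

test_that("ground truth is internally consistent", {
  sim <- simulate_venom_study(small_sim(seed = 17))
  tr <- sim$truth
  expect_equal(anyDuplicated(tr$id), 0L)
  expect_setequal(tr$id, sim$contigs$id)
  # detected => toxin and secreted
  expect_true(all(tr$is_toxin[tr$detected] & tr$is_secreted[tr$detected]))
  # signal-peptide label => secreted
  expect_true(all(tr$is_secreted[!is.na(tr$sp_end)]))
  # population B carries mature toxin peptides only
  expect_true(all(grepl("^B_", sim$pop_b_peptides$id)))
})

test_that("detection correlates positively with venom-gland expression", {
  pos <- 0
  for (s in 1:12) {
    sim <- simulate_venom_study(small_sim(seed = 200 + s))
    if (length(sim$proteome) < 2) next
    ind <- as.numeric(sim$expression$id %in% sim$proteome)
    r <- spearman_cor(ind, sim$expression$fpkm_vg)
    if (r$r > 0) pos <- pos + 1
  }
  expect_gte(pos, 11)
})
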