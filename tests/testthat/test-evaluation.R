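test_that("Venn regions partition the union", {
  v <- venn_counts(list(A = c("a", "b"), B = c("b", "c")))
  counts <- setNames(v$count, v$region)
  expect_equal(unname(counts["A"]), 1L)
  expect_equal(unname(counts["B"]), 1L)
  expect_equal(unname(counts["A&B"]), 1L)

  disj <- venn_counts(list(A = c("a"), B = c("b"), C = c("c")))
  expect_equal(sum(disj$count[grepl("&", disj$region)]), 0L)

  expect_error(venn_counts(list(A = "a")), class = "toxaudit_input_error")
})

test_that("Venn counts equal brute-force membership enumeration", {
  set.seed(141)
  for (rep in 1:20) {
    ids <- sprintf("id%03d", 1:400)
    sets <- list(A = sample(ids, 200), B = sample(ids, 200),
                 C = sample(ids, 200))
    v <- venn_counts(sets)
    u <- unique(unlist(sets))
    expect_equal(sum(v$count), length(u))
    inA <- u %in% sets$A; inB <- u %in% sets$B; inC <- u %in% sets$C
    brute <- c(
      "A" = sum(inA & !inB & !inC), "B" = sum(!inA & inB & !inC),
      "A&B" = sum(inA & inB & !inC), "C" = sum(!inA & !inB & inC),
      "A&C" = sum(inA & !inB & inC), "B&C" = sum(!inA & inB & inC),
      "A&B&C" = sum(inA & inB & inC))
    got <- setNames(v$count, v$region)
    expect_equal(got[names(brute)], brute, ignore_attr = TRUE)
  }
})

test_that("false-positive rate is the unvalidated fraction", {
  expect_equal(false_positive_rate(c("a", "b", "c", "d"), "a"), 0.75)
  expect_equal(false_positive_rate(c("a", "b"), c("a", "b", "c")), 0)
  expect_error(false_positive_rate(character(0), "a"),
               class = "toxaudit_undefined_error")
  set.seed(151)
  for (i in 1:50) {
    pred <- sample(letters, sample(3:20, 1))
    prot <- sample(letters, sample(1:20, 1))
    fpr <- false_positive_rate(pred, prot)
    tpr <- length(intersect(pred, prot)) / length(unique(pred))
    expect_equal(fpr + tpr, 1)
  }
})

test_that("diversity profiles report percentage-point and fold deltas", {
  ref <- tibble::tibble(id = sprintf("r%02d", 1:10),
                        family = rep(c("F1", "F2"), each = 5))
  same <- family_diversity_profile(list(t = ref), ref)
  expect_true(all(same$delta_pp == 0))
  expect_true(all(same$fold == 1))

  tier <- tibble::tibble(id = sprintf("t%02d", 1:8),
                         family = rep(c("F1", "F2"), c(2, 6)))
  prof <- family_diversity_profile(list(t = tier), ref)
  expect_equal(prof$delta_pp[prof$family == "F1"], -25)
  expect_equal(prof$delta_pp[prof$family == "F2"], 25)
  expect_equal(prof$fold[prof$family == "F1"], 0.5)
  expect_equal(prof$fold[prof$family == "F2"], 1.5)
  expect_equal(sum(prof$pct), 100, tolerance = 1e-9)
  expect_error(family_diversity_profile(list(t = ref[0, ]), ref),
               class = "toxaudit_input_error")
})

test_that("precision/recall match a brute-force confusion matrix", {
  truth <- sprintf("x%03d", 1:50)
  expect_equal(unlist(precision_recall(truth, truth)[, 1:3]),
               c(precision = 1, recall = 1, f1 = 1))
  expect_equal(unlist(precision_recall("zzz", truth)[, 1:3]),
               c(precision = 0, recall = 0, f1 = 0))
  expect_error(precision_recall(character(0), truth),
               class = "toxaudit_undefined_error")
  set.seed(161)
  for (i in 1:30) {
    ids <- sprintf("s%03d", 1:500)
    pred <- sample(ids, sample(10:300, 1))
    tru <- sample(ids, sample(10:300, 1))
    pr <- precision_recall(pred, tru)
    tp <- sum(pred %in% tru)
    expect_equal(pr$precision, tp / length(pred))
    expect_equal(pr$recall, tp / length(tru))
    if (pr$precision + pr$recall > 0) {
      expect_equal(pr$f1, 2 * pr$precision * pr$recall /
                     (pr$precision + pr$recall))
    }
  }
})

test_that("intraspecific overlap counts shared identity clusters", {
  set.seed(171)
  seqs <- replicate(6, random_peptide(60))
  a <- tibble::tibble(id = paste0("A", 1:6), seq = seqs)
  b <- tibble::tibble(id = paste0("B", 1:6), seq = seqs)
  # identical populations: every cluster holds both populations
  ov <- intraspecific_overlap(a, b)
  expect_equal(ov$n_shared, ov$n_clusters)

  # engineered 94% pair across populations: shared at 0.90, not 0.95
  pair <- make_94pct_pair()
  a2 <- tibble::tibble(id = "A1", seq = pair[1])
  b2 <- tibble::tibble(id = "B1", seq = pair[2])
  ov2 <- intraspecific_overlap(a2, b2, thresholds = c(0.95, 0.90))
  expect_equal(ov2$n_shared[ov2$threshold == 0.95], 0L)
  expect_equal(ov2$n_shared[ov2$threshold == 0.90], 1L)

  # unrelated populations share nothing
  w <- tibble::tibble(id = "A1", seq = strrep("W", 50))
  p <- tibble::tibble(id = "B1", seq = strrep("P", 50))
  ov3 <- intraspecific_overlap(w, p)
  expect_true(all(ov3$n_shared == 0L))

  expect_error(intraspecific_overlap(a[0, ], b),
               class = "toxaudit_input_error")
})

test_that("reports serialize deterministically and validate", {
  mk <- function() build_report(
    tier_counts = list(species = toxaudit:::stage_counts(5, 4, 3, 2)),
    venn = venn_counts(list(A = c("a", "b"), B = c("b"))),
    fp_rates = c(species = 0.25),
    fp_rates_all_cds = c(species = 0.4),
    diversity = family_diversity_profile(
      list(t = tibble::tibble(id = "x", family = "F1")),
      tibble::tibble(id = "y", family = "F1")),
    pr = tibble::tibble(),
    correlations = tibble::tibble(set = "proteome", tissue = "vg",
                                  r = 0.5, p = 0.01, n = 10L, note = ""),
    retention = list(n_proteome = 10L, n_retained = 8L, fraction = 0.8),
    overlap = tibble::tibble(threshold = 0.95, n_clusters = 3L,
                             n_shared = 0L),
    clade_retention = tibble::tibble(family = "F1", n_leaves = 5L,
                                     n_evidence = 2L, n_retained = 4L,
                                     n_detected_retained = 2L))
  r <- mk()
  expect_true(validate_report(r))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_report(r, d1)
  write_report(mk(), d2)
  expect_identical(readBin(file.path(d1, "report.json"), "raw", 1e6),
                   readBin(file.path(d2, "report.json"), "raw", 1e6))
  # a missing stage is an error naming the stage
  expect_error(build_report(tier_counts = NULL, venn = r$venn,
                            fp_rates = r$fp_rates,
                            fp_rates_all_cds = r$fp_rates_all_cds,
                            diversity = r$diversity, pr = r$pr,
                            correlations = r$correlations,
                            retention = r$retention, overlap = r$overlap,
                            clade_retention = r$clade_retention),
               regexp = "tier_counts")
  # invariant violations are caught
  bad <- r; bad$fp_rates <- c(species = 1.5)
  expect_error(validate_report(bad), class = "toxaudit_report_error")
})
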