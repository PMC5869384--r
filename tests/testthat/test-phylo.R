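test_that("identity distances follow -ln(identity) with clamping", {
  seqs <- tibble::tibble(
    id = c("a", "b", "c"),
    seq = c(strrep("A", 40),
            strrep("A", 40),
            paste0(strrep("A", 20), strrep("C", 20))))
  d <- identity_distance_matrix(seqs)
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], log(2))  # identity exactly 0.5
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  # clamped maximum for (near-)zero identity
  far <- tibble::tibble(id = c("x", "y"),
                        seq = c(strrep("W", 30), strrep("P", 30)))
  dd <- suppressWarnings(identity_distance_matrix(far, max_dist = 5))
  expect_equal(dd["x", "y"], 5)
})

test_that("neighbor joining handles the small closed-form cases", {
  # n = 2: single split, half the distance on each side
  d2 <- matrix(c(0, 10, 10, 0), 2, dimnames = list(c("A", "B"),
                                                   c("A", "B")))
  t2 <- nj_tree(d2)
  expect_setequal(t2$tip.label, c("A", "B"))
  expect_equal(sort(t2$edge.length), c(5, 5))

  # n = 3: star with lengths (d_ab + d_ac - d_bc)/2 etc.
  d3 <- matrix(c(0, 3, 5, 3, 0, 4, 5, 4, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- nj_tree(d3)
  pd <- ape::cophenetic.phylo(t3)
  expect_equal(pd[c("A", "B", "C"), c("A", "B", "C")], d3, tolerance = 1e-12)

  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2)),
               class = "toxaudit_input_error")
})

test_that("NJ recovers a hand-drawn additive 4-taxon tree exactly", {
  # tree: ((A:1, B:2):1.5, C:0.75, D:2.25) with internal edge 1.5
  ref <- ape::read.tree(text = "((A:1,B:2):1.5,C:0.75,D:2.25);")
  d <- ape::cophenetic.phylo(ref)
  tr <- nj_tree(d)
  pd <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
  expect_equal(pd, d, tolerance = 1e-9)
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(ref)), 0,
               ignore_attr = TRUE)
})

test_that("NJ agrees with ape::nj on random additive matrices", {
  set.seed(91)
  for (i in 1:10) {
    n <- sample(4:10, 1)
    ref <- ape::rtree(n, br = function(k) runif(k, 0.1, 2))
    d <- ape::cophenetic.phylo(ref)
    d <- d[sort(rownames(d)), sort(colnames(d))]
    tr <- nj_tree(d)
    ref_nj <- ape::nj(as.dist(d))
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(ref_nj)), 0,
                 ignore_attr = TRUE)
    expect_equal(ape::cophenetic.phylo(tr)[rownames(d), colnames(d)], d,
                 tolerance = 1e-9)
  }
})

test_that("midpoint rooting equalizes the two deepest leaves", {
  t2 <- nj_tree(matrix(c(0, 10, 10, 0), 2,
                       dimnames = list(c("A", "B"), c("A", "B"))))
  r2 <- midpoint_root(t2)
  depths <- ape::node.depth.edgelength(r2)[1:2]
  expect_equal(depths, c(5, 5))

  set.seed(101)
  for (i in 1:10) {
    tr <- ape::rtree(sample(4:10, 1), br = function(k) runif(k, 0.1, 2))
    tr <- ape::unroot(tr)
    rooted <- midpoint_root(tr)
    # the root has exactly two children
    root <- length(rooted$tip.label) + 1L
    expect_equal(sum(rooted$edge[, 1] == root), 2L)
    # patristic distances preserved
    a <- ape::cophenetic.phylo(tr)
    b <- ape::cophenetic.phylo(rooted)[rownames(a), colnames(a)]
    expect_equal(a, b, tolerance = 1e-9)
    # the two maximally distant leaves are equidistant from the root
    mx <- which(a == max(a), arr.ind = TRUE)[1, ]
    dep <- ape::node.depth.edgelength(rooted)
    da <- dep[match(rownames(a)[mx[1]], rooted$tip.label)]
    db <- dep[match(colnames(a)[mx[2]], rooted$tip.label)]
    expect_equal(da, db, tolerance = 1e-9)
    expect_equal(da + db, max(a), tolerance = 1e-9)
  }
})

test_that("midpoint rooting agrees with phangorn on patristic depths", {
  skip_if_not_installed("phangorn")
  set.seed(111)
  tr <- ape::unroot(ape::rtree(8, br = function(k) runif(k, 0.1, 2)))
  mine <- midpoint_root(tr)
  ref <- phangorn::midpoint(tr)
  a <- ape::cophenetic.phylo(mine)
  b <- ape::cophenetic.phylo(ref)[rownames(a), colnames(a)]
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("clade-evidence filter follows the patristic-radius rule", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  ev <- tibble::tibble(id = c("A", "B", "C", "D"),
                       evidence = c(TRUE, FALSE, FALSE, FALSE))
  # all pairwise distances are 2 = median -> everything retained
  expect_setequal(clade_evidence_filter(star, ev, "median"),
                  c("A", "B", "C", "D"))
  # radius below 2 -> only the evidence leaf survives
  expect_equal(clade_evidence_filter(star, ev, 1.9), "A")
  # all leaves evidence -> all retained at any radius
  all_ev <- dplyr::mutate(ev, evidence = TRUE)
  expect_setequal(clade_evidence_filter(star, all_ev, 0), ev$id)
  # no evidence leaves -> empty with a warning
  none <- dplyr::mutate(ev, evidence = FALSE)
  expect_warning(out <- clade_evidence_filter(star, none, "median"))
  expect_length(out, 0)
})

test_that("retained set grows monotonically with the evidence radius", {
  set.seed(121)
  tr <- ape::rtree(12, br = function(k) runif(k, 0.1, 2))
  ev <- tibble::tibble(id = tr$tip.label,
                       evidence = runif(12) < 0.3)
  if (!any(ev$evidence)) ev$evidence[1] <- TRUE
  prev <- character(0)
  for (dm in c(0, 0.5, 1, 2, 4, 8)) {
    cur <- clade_evidence_filter(tr, ev, dm)
    expect_true(all(prev %in% cur))
    expect_true(all(ev$id[ev$evidence] %in% cur))
    prev <- cur
  }
})

test_that("annotated trees round-trip through newick + TSV", {
  set.seed(131)
  tr <- midpoint_root(ape::unroot(ape::rtree(6,
        br = function(k) runif(k, 0.1, 2))))
  rec <- tibble::tibble(id = tr$tip.label,
                        fpkm_vg = round(10^runif(6, 0, 3), 3),
                        fpkm_muscle = round(10^runif(6, 0, 2), 3))
  prefix <- file.path(withr::local_tempdir(), "fam")
  annotate_and_export(tr, rec, proteome = tr$tip.label[1:2],
                      retained = tr$tip.label[1:4], prefix = prefix)
  back <- read_annotated_tree(prefix)
  a <- ape::cophenetic.phylo(tr)
  b <- ape::cophenetic.phylo(back$tree)[rownames(a), colnames(a)]
  expect_equal(a, b, tolerance = 1e-9)
  expect_equal(nrow(back$annotations), length(tr$tip.label))
  expect_equal(back$annotations$detected,
               back$annotations$id %in% tr$tip.label[1:2])
  # empty proteome -> all detected flags false
  annotate_and_export(tr, rec, proteome = character(0),
                      retained = character(0), prefix = prefix)
  back2 <- read_annotated_tree(prefix)
  expect_false(any(back2$annotations$detected))
  # a leaf without an expression record is an error naming the leaf
  expect_error(
    annotate_and_export(tr, rec[-1, ], character(0), character(0), prefix),
    regexp = tr$tip.label[1], class = "toxaudit_input_error")
})
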