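# Family trees and clade-level evidence propagation -------------------------
#
# Trees are `ape::phylo` objects. Distances are -ln(global identity);
# topology comes from an exact neighbor-joining implementation with a
# deterministic tie-break, so identical inputs always give identical trees.

#' Identity-based distance matrix for a sequence family
#'
#' `d(a, b) = -ln(pairwise_identity(a, b))`, clamped at `max_dist`;
#' `d(a, a) = 0`. Zero identity is clamped to `max_dist` with a warning.
#'
#' @param seqs tibble with columns `id` and `seq` (protein), >= 2 rows.
#' @param scheme a [scoring_scheme()].
#' @param max_dist clamp for infinite/huge distances (default 5).
#' @return Symmetric numeric matrix with zero diagonal, dimnames = ids.
#' @export
identity_distance_matrix <- function(seqs, scheme = scoring_scheme(),
                                     max_dist = 5) {
  stopifnot(all(c("id", "seq") %in% names(seqs)))
  if (nrow(seqs) < 2) {
    abort("need at least two sequences", class = "toxaudit_input_error")
  }
  enc <- encode_protein_set(seqs$seq, scheme$matrix)
  idm <- identity_matrix_cpp(enc, scheme$matrix, scheme$gap_open,
                             scheme$gap_extend)
  # identity relative to shorter sequence uses character lengths
  if (any(idm[upper.tri(idm)] == 0)) {
    warn("zero pairwise identity clamped to max_dist")
  }
  d <- -log(idm)
  d[!is.finite(d) | d > max_dist] <- max_dist
  diag(d) <- 0
  dimnames(d) <- list(seqs$id, seqs$id)
  d
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei neighbor joining on a symmetric zero-diagonal
#' distance matrix. Deterministic: among pairs tying on the Q criterion the
#' lexicographically smallest label pair is joined. Negative branch lengths
#' are clamped to zero with the deficit moved to the sibling edge, so the
#' two-edge sum at each join is preserved. Exact on additive matrices.
#'
#' @param d symmetric numeric matrix with zero diagonal and dimnames.
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(d) {
  if (!is.matrix(d) || !isTRUE(all.equal(d, t(d), tolerance = 1e-12)) ||
      any(diag(d) != 0)) {
    abort("distance matrix must be symmetric with zero diagonal",
          class = "toxaudit_input_error")
  }
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(d)))
  n <- nrow(d)
  if (n < 2) abort("need >= 2 taxa", class = "toxaudit_input_error")
  repr <- labels                   # newick fragment per active node
  key <- labels                    # tie-break label per active node
  if (n == 2) {
    h <- d[1, 2] / 2
    nwk <- sprintf("(%s:%.12g,%s:%.12g);", repr[1], h, repr[2], h)
    return(ape::read.tree(text = nwk))
  }
  D <- d
  active <- seq_len(n)
  while (length(active) > 3) {
    r <- length(active)
    Dm <- D[active, active]
    R <- rowSums(Dm)
    Q <- (r - 2) * Dm - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    tol <- 1e-9 * max(1, abs(qmin))
    cand <- which(Q <= qmin + tol, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pk <- apply(cand, 1, function(ij) {
      ks <- sort(c(key[active[ij[1]]], key[active[ij[2]]]))
      paste(ks, collapse = "\r")
    })
    best <- cand[order(pk)[1], ]
    i <- active[best[1]]; j <- active[best[2]]
    dij <- D[i, j]
    bi <- dij / 2 + (R[best[1]] - R[best[2]]) / (2 * (r - 2))
    bj <- dij - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    # new node u replaces slot i
    newd <- (D[i, active] + D[j, active] - dij) / 2
    D[i, active] <- newd
    D[active, i] <- newd
    D[i, i] <- 0
    repr[i] <- sprintf("(%s:%.12g,%s:%.12g)", repr[i], bi, repr[j], bj)
    key[i] <- min(key[i], key[j])
    active <- setdiff(active, j)
  }
  # final three nodes: star join with closed-form lengths
  a <- active[1]; b <- active[2]; c <- active[3]
  la <- (D[a, b] + D[a, c] - D[b, c]) / 2
  lb <- (D[a, b] + D[b, c] - D[a, c]) / 2
  lc <- (D[a, c] + D[b, c] - D[a, b]) / 2
  la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0)
  nwk <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 repr[a], la, repr[b], lb, repr[c], lc)
  ape::read.tree(text = nwk)
}

# Undirected weighted adjacency list of a phylo object, over node numbers.
phylo_adjacency <- function(tree) {
  m <- max(tree$edge)
  adj <- vector("list", m)
  for (e in seq_len(nrow(tree$edge))) {
    u <- tree$edge[e, 1]; v <- tree$edge[e, 2]; w <- tree$edge.length[e]
    adj[[u]] <- rbind(adj[[u]], c(v, w))
    adj[[v]] <- rbind(adj[[v]], c(u, w))
  }
  adj
}

# Shortest (unique) path between two nodes of a tree; returns node sequence
# and cumulative distances.
tree_path <- function(adj, from, to) {
  m <- length(adj)
  prev <- rep(NA_integer_, m); dist <- rep(NA_real_, m)
  dist[from] <- 0
  queue <- from
  while (length(queue) > 0) {
    u <- queue[1]; queue <- queue[-1]
    if (u == to) break
    nb <- adj[[u]]
    for (k in seq_len(NROW(nb))) {
      v <- nb[k, 1]
      if (is.na(dist[v])) {
        dist[v] <- dist[u] + nb[k, 2]
        prev[v] <- u
        queue <- c(queue, v)
      }
    }
  }
  path <- to
  while (path[1] != from) path <- c(prev[path[1]], path)
  list(nodes = path, cum = dist[path])
}

#' Midpoint rooting
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path, so the
#' two maximally distant leaves become equidistant from the root. All
#' pairwise patristic distances are preserved; the root has degree 2.
#'
#' @param tree an `ape::phylo` tree (rooted or unrooted), >= 2 leaves.
#' @return A rooted `ape::phylo` tree.
#' @export
midpoint_root <- function(tree) {
  ntip <- length(tree$tip.label)
  if (ntip < 2) abort("need >= 2 leaves", class = "toxaudit_input_error")
  pd <- ape::cophenetic.phylo(tree)
  # deterministic choice of the maximally distant leaf pair
  mx <- max(pd)
  cand <- which(pd >= mx - 1e-12 * max(1, mx), arr.ind = TRUE)
  cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
  labs <- rownames(pd)
  ord <- order(labs[cand[, 1]], labs[cand[, 2]])
  a_lab <- labs[cand[ord[1], 1]]; b_lab <- labs[cand[ord[1], 2]]
  a <- match(a_lab, tree$tip.label); b <- match(b_lab, tree$tip.label)
  half <- pd[a_lab, b_lab] / 2

  adj <- phylo_adjacency(tree)
  pth <- tree_path(adj, a, b)
  # edge (u, v) on the path containing the midpoint
  k <- max(which(pth$cum <= half + 1e-12))
  k <- min(k, length(pth$nodes) - 1L)
  u <- pth$nodes[k]; v <- pth$nodes[k + 1]
  xu <- half - pth$cum[k]               # distance from u to the root point
  xv <- (pth$cum[k + 1] - pth$cum[k]) - xu

  # re-orient the tree away from the new root point on edge (u, v)
  tip_name <- function(node) {
    if (node <= ntip) tree$tip.label[node] else NULL
  }
  subtree_newick <- function(node, parent, len) {
    nb <- adj[[node]]
    kids <- nb[nb[, 1] != parent, , drop = FALSE]
    if (NROW(kids) == 0) {
      sprintf("%s:%.12g", tip_name(node), len)
    } else {
      inner <- vapply(seq_len(NROW(kids)), function(q) {
        subtree_newick(kids[q, 1], node, kids[q, 2])
      }, character(1))
      sprintf("(%s):%.12g", paste(inner, collapse = ","), len)
    }
  }
  nwk <- sprintf("(%s,%s);", subtree_newick(u, v, xu),
                 subtree_newick(v, u, xv))
  ape::read.tree(text = nwk)
}

#' Clade-evidence retention filter
#'
#' Formalizes the clade-level reading of family trees: a leaf backed by
#' direct evidence (proteomic detection or passing the comparative
#' expression filter) is always retained, and any other leaf is retained
#' iff its patristic distance to the nearest evidence leaf is at most
#' `d_max`. With `d_max = "median"` the radius is the median of all
#' pairwise patristic distances in the tree, so retention adapts to each
#' family's depth. Monotone: enlarging `d_max` never shrinks the retained
#' set.
#'
#' @param tree an `ape::phylo` tree whose tips are CDS ids.
#' @param evidence tibble with columns `id` and `evidence` (logical)
#'   covering every leaf.
#' @param d_max `"median"` or a non-negative number (patristic distance).
#' @return Character vector of retained leaf ids (possibly empty, with a
#'   warning, when the tree has no evidence leaves).
#' @export
clade_evidence_filter <- function(tree, evidence, d_max = "median") {
  tips <- tree$tip.label
  stopifnot(all(c("id", "evidence") %in% names(evidence)))
  ev <- evidence$evidence[match(tips, evidence$id)]
  if (anyNA(ev)) {
    abort(paste("leaves without evidence annotation:",
                paste(tips[is.na(ev)], collapse = ", ")),
          class = "toxaudit_input_error")
  }
  if (!any(ev)) {
    warn("tree has no evidence leaves; retaining nothing")
    return(character(0))
  }
  pd <- ape::cophenetic.phylo(tree)
  if (identical(d_max, "median")) {
    d_max <- median(pd[upper.tri(pd)])
  }
  nearest <- apply(pd[, ev, drop = FALSE], 1, min)
  tips[ev | nearest <= d_max]
}

#' Export and re-import an annotated family tree
#'
#' Writes the tree as newick plus a sidecar leaf-annotation TSV
#' (`id`, `fpkm_vg`, `fpkm_muscle`, `detected`, `retained`); the pair
#' round-trips losslessly through [read_annotated_tree()].
#'
#' @param tree an `ape::phylo` tree whose tips are CDS ids.
#' @param records expression tibble with `id`, `fpkm_vg`, `fpkm_muscle`.
#' @param proteome character vector of proteome-detected ids.
#' @param retained character vector of leaf ids kept by
#'   [clade_evidence_filter()].
#' @param prefix output path prefix; writes `<prefix>.nwk` and
#'   `<prefix>.tsv`.
#' @return Invisibly, a list with the two file paths.
#' @export
annotate_and_export <- function(tree, records, proteome, retained, prefix) {
  tips <- tree$tip.label
  missing <- setdiff(tips, records$id)
  if (length(missing) > 0) {
    abort(paste("leaves without expression records:",
                paste(missing, collapse = ", ")),
          class = "toxaudit_input_error")
  }
  ann <- tibble(id = tips) |>
    left_join(select(records, "id", "fpkm_vg", "fpkm_muscle"), by = "id") |>
    mutate(detected = .data$id %in% proteome,
           retained = .data$id %in% retained)
  nwk <- paste0(prefix, ".nwk")
  tsv <- paste0(prefix, ".tsv")
  ape::write.tree(tree, file = nwk, digits = 12)
  write_tox_tsv(ann, tsv)
  invisible(list(tree = nwk, annotations = tsv))
}

#' @rdname annotate_and_export
#' @export
read_annotated_tree <- function(prefix) {
  list(tree = ape::read.tree(paste0(prefix, ".nwk")),
       annotations = read_tox_tsv(paste0(prefix, ".tsv")))
}
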