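# Synthetic two-tissue venom transcriptomes with known ground truth ---------
#
# The generator emulates the statistical structure the analysis assumes:
# toxin gene families diversifying on birth-death trees, with one recruited
# (secreted, accelerated) toxin clade per family and secreted/non-secreted
# non-toxin paralogues; venom-gland-upregulated toxin expression; proteomic
# detection probability increasing with venom-gland expression; partial
# CDSs; and homology databases at three relatedness tiers. Everything is
# deterministic given the config seed.

#' Simulation configuration
#'
#' Parameters of the synthetic venom-gland/muscle study. All randomness in a
#' run derives from `seed`; per-family streams are sub-seeded by hashing the
#' family index with the run seed, so regenerating a single family
#' reproduces it exactly.
#'
#' Expression means/sds are on the log10 FPKM scale. `detection_slope` and
#' `detection_intercept` are logistic coefficients on `log10(FPKM_vg + 1)`.
#' `toxin_rate_multiplier` accelerates substitution within the recruited
#' toxin clade (venom toxins evolve under diversifying selection);
#' `secreted_nontoxin_fraction` is the per-sequence probability that a
#' non-toxin paralogue is nonetheless secreted — the main false-positive
#' class homology annotation has to contend with. `frag_prob` is a free
#' parameter of this generator, not a literature value.
#'
#' @param seed integer seed fixing all downstream randomness.
#' @param n_families number of gene families.
#' @param leaves_per_family integer range (length 2) of leaf counts.
#' @param birth_rate birth rate of the pure-birth family tree.
#' @param root_length_aa length of the root (mature) protein.
#' @param subst_rate expected substitutions/site from root to leaf.
#' @param toxin_clade_fraction probability a family has a recruited toxin
#'   clade.
#' @param toxin_rate_multiplier branch-length multiplier inside the toxin
#'   clade.
#' @param secreted_nontoxin_fraction probability a non-toxin leaf is
#'   secreted.
#' @param vg_logFPKM_toxin,vg_logFPKM_nontoxin,muscle_logFPKM length-2
#'   numeric `c(mean, sd)` of log10 FPKM models.
#' @param detection_slope,detection_intercept logistic detection model.
#' @param frag_prob probability a contig is emitted truncated.
#' @param db_divergence extra substitutions/site for the distant database
#'   tier (the lineage tier uses half of it).
#' @param distant_coverage probability the distant tier covers a family.
#' @param n_decoy_families decoy families present only in the distant tier.
#' @param population_divergence substitutions/site between the two
#'   simulated populations.
#' @param library_size_vg,library_size_muscle total fragments per library.
#' @return A validated list of class `tox_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_families = 3L,
                       leaves_per_family = c(16L, 24L),
                       birth_rate = 1,
                       root_length_aa = 120L,
                       subst_rate = 0.5,
                       toxin_clade_fraction = 0.7,
                       toxin_rate_multiplier = 3,
                       secreted_nontoxin_fraction = 0.5,
                       vg_logFPKM_toxin = c(2.5, 0.6),
                       vg_logFPKM_nontoxin = c(0.8, 0.6),
                       muscle_logFPKM = c(0.8, 0.6),
                       detection_slope = 1.5,
                       detection_intercept = -3,
                       frag_prob = 0.35,
                       db_divergence = 0.6,
                       distant_coverage = 0.9,
                       n_decoy_families = 4L,
                       population_divergence = 0.15,
                       library_size_vg = 2e6,
                       library_size_muscle = 2e6) {
  cfg <- as.list(environment())
  errs <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed must be scalar")
  chk(cfg$n_families >= 1, "n_families must be >= 1")
  chk(length(cfg$leaves_per_family) == 2 &&
        all(cfg$leaves_per_family >= 4) &&
        cfg$leaves_per_family[1] <= cfg$leaves_per_family[2],
      "leaves_per_family must be an increasing range >= 4")
  chk(cfg$birth_rate > 0, "birth_rate must be > 0")
  chk(cfg$root_length_aa >= 40, "root_length_aa must be >= 40")
  chk(cfg$subst_rate >= 0, "subst_rate must be >= 0")
  for (p in c("toxin_clade_fraction", "secreted_nontoxin_fraction",
              "frag_prob", "distant_coverage")) {
    chk(cfg[[p]] >= 0 && cfg[[p]] <= 1, paste(p, "must be in [0, 1]"))
  }
  chk(cfg$toxin_rate_multiplier > 0, "toxin_rate_multiplier must be > 0")
  for (p in c("vg_logFPKM_toxin", "vg_logFPKM_nontoxin", "muscle_logFPKM")) {
    chk(length(cfg[[p]]) == 2 && cfg[[p]][2] >= 0,
        paste(p, "must be c(mean, sd) with sd >= 0"))
  }
  chk(cfg$db_divergence >= 0, "db_divergence must be >= 0")
  chk(cfg$population_divergence >= 0,
      "population_divergence must be >= 0")
  chk(cfg$library_size_vg >= 0 && cfg$library_size_muscle >= 0,
      "library sizes must be >= 0")
  chk(cfg$n_decoy_families >= 0, "n_decoy_families must be >= 0")
  if (length(errs) > 0) {
    abort(paste0("invalid simulation config:\n  ",
                 paste(errs, collapse = "\n  ")),
          class = "toxaudit_config_error")
  }
  structure(cfg, class = "tox_sim_config")
}

#' @export
print.tox_sim_config <- function(x, ...) {
  cat("<tox_sim_config> seed", x$seed, "-", x$n_families, "families x",
      paste(x$leaves_per_family, collapse = "-"), "leaves\n")
  invisible(x)
}

# Amino-acid machinery -------------------------------------------------------

.aa20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# approximate background amino-acid frequencies (Robinson-Robinson)
.aa_freq <- c(A = 0.079, R = 0.051, N = 0.045, D = 0.054, C = 0.019,
              Q = 0.043, E = 0.063, G = 0.074, H = 0.022, I = 0.051,
              L = 0.091, K = 0.057, M = 0.022, F = 0.039, P = 0.052,
              S = 0.069, T = 0.059, W = 0.014, Y = 0.032, V = 0.065)

# Replacement distribution conditional on the current residue: Boltzmann
# weights exp(BLOSUM62 score / 2) over the 19 alternatives, so likely
# replacements are matrix-consistent (conservative changes preferred).
replacement_probs <- function() {
  m <- blosum62()[.aa20, .aa20]
  w <- exp(m / 2)
  diag(w) <- 0
  sweep(w, 1, rowSums(w), "/")
}

random_protein <- function(n) {
  paste(sample(.aa20, n, replace = TRUE, prob = .aa_freq), collapse = "")
}

# Evolve a protein along a branch of `dist` expected substitutions/site.
# Per site, the number of replacement events is Poisson(dist); each event
# draws the new residue from the BLOSUM62-conditional distribution (repeat
# substitution can revert, so observed divergence saturates below 1).
evolve_protein <- function(seq, dist, rp = replacement_probs()) {
  if (dist <= 0) return(seq)
  res <- strsplit(seq, "", fixed = TRUE)[[1]]
  nev <- rpois(length(res), dist)
  for (i in which(nev > 0)) {
    for (k in seq_len(nev[i])) {
      cur <- res[i]
      if (!cur %in% .aa20) break
      res[i] <- sample(.aa20, 1, prob = rp[cur, ])
    }
  }
  paste(res, collapse = "")
}

# Family signal peptide: charged n-region, hydrophobic h-region, small-residue
# c-region ending A-S-A, so the heuristic detector can recover it.
random_signal_peptide <- function() {
  core <- sample(c("L", "V", "I", "A", "F"), 12, replace = TRUE,
                 prob = c(0.4, 0.2, 0.15, 0.15, 0.1))
  paste0("MK", paste(core, collapse = ""), "ASA")
}

# Family simulation ----------------------------------------------------------

#' Simulate one toxin gene family
#'
#' Grows a pure-birth tree, scales it to `subst_rate` expected root-to-leaf
#' substitutions/site, evolves the root protein along it, and recruits (with
#' probability `toxin_clade_fraction`) one clade of roughly half the leaves
#' as a toxin clade: its members are secreted (family signal peptide
#' prepended) and evolve `toxin_rate_multiplier` times faster. Remaining
#' leaves are non-toxins; each is independently secreted with probability
#' `secreted_nontoxin_fraction`.
#'
#' @param config a [sim_config()].
#' @param family_index family number in `1..n_families`.
#' @param force_toxin_clade recruit a toxin clade regardless of
#'   `toxin_clade_fraction` (used to guarantee that a simulated venom-gland
#'   study contains at least one toxin family).
#' @return List with `tree` (`ape::phylo`, branch lengths in
#'   substitutions/site), `proteins` (tibble `id`, `seq`, `mature_seq`,
#'   `sp_len`), `truth` (tibble `id`, `family`, `is_toxin`, `is_secreted`,
#'   `population`), plus internal fields used by the database builder
#'   (`root_seq`, `toxin_mrca_seq`, `signal_peptide`, `has_toxin_clade`).
#' @export
simulate_family <- function(config, family_index,
                            force_toxin_clade = FALSE) {
  stopifnot(inherits(config, "tox_sim_config"))
  if (family_index < 1 || family_index > config$n_families) {
    abort("family_index out of range", class = "toxaudit_config_error")
  }
  set.seed(derive_seed(config$seed, "family", family_index))
  fam <- sprintf("FAM%02d", family_index)
  n_leaf <- if (config$leaves_per_family[1] == config$leaves_per_family[2]) {
    config$leaves_per_family[1]
  } else {
    sample(seq(config$leaves_per_family[1], config$leaves_per_family[2]), 1)
  }
  tree <- ape::rphylo(n_leaf, birth = config$birth_rate, death = 0)
  tree$tip.label <- sprintf("%s_L%02d", fam, seq_len(n_leaf))
  # rescale: mean root-to-leaf depth = subst_rate
  depths <- ape::node.depth.edgelength(tree)[seq_len(n_leaf)]
  if (mean(depths) > 0) {
    tree$edge.length <- tree$edge.length * config$subst_rate / mean(depths)
  }

  # candidate toxin clade: internal node whose clade holds 25-75% of leaves,
  # closest to half (deterministic choice)
  has_toxin <- runif(1) < config$toxin_clade_fraction || force_toxin_clade
  toxin_tips <- character(0)
  toxin_nodes <- integer(0)
  toxin_mrca <- NA_integer_
  if (has_toxin) {
    internal <- (n_leaf + 1L):(n_leaf + tree$Nnode)
    sizes <- vapply(internal, function(nd) {
      length(tip_indices_below(tree, nd))
    }, integer(1))
    ok <- internal[sizes >= ceiling(0.25 * n_leaf) &
                     sizes <= floor(0.75 * n_leaf)]
    if (length(ok) == 0) ok <- internal[which.min(abs(sizes - n_leaf / 2))]
    sz <- vapply(ok, function(nd) length(tip_indices_below(tree, nd)),
                 integer(1))
    toxin_mrca <- ok[order(abs(sz - n_leaf / 2), ok)][1]
    tix <- tip_indices_below(tree, toxin_mrca)
    toxin_tips <- tree$tip.label[tix]
    toxin_nodes <- nodes_below(tree, toxin_mrca)
    # accelerate branches inside the toxin clade (edges below its MRCA)
    inside <- tree$edge[, 1] %in% c(toxin_mrca, toxin_nodes)
    tree$edge.length[inside] <-
      tree$edge.length[inside] * config$toxin_rate_multiplier
  }

  root_seq <- random_protein(config$root_length_aa)
  sp <- random_signal_peptide()
  rp <- replacement_probs()
  node_seq <- evolve_on_tree(tree, root_seq, rp)
  toxin_mrca_seq <- if (has_toxin) node_seq[[toxin_mrca]] else NA_character_

  is_toxin <- tree$tip.label %in% toxin_tips
  is_secreted <- is_toxin |
    (runif(n_leaf) < config$secreted_nontoxin_fraction & !is_toxin)
  mature <- vapply(seq_len(n_leaf), function(i) node_seq[[i]], character(1))
  # signal peptides diverge along the tree like the mature region (they are
  # only weakly conserved in practice), so they cannot act as a shared
  # high-identity anchor between distant family members
  leaf_depth <- ape::node.depth.edgelength(tree)[seq_len(n_leaf)]
  sp_leaf <- vapply(seq_len(n_leaf), function(i) {
    if (!is_secreted[i]) return(NA_character_)
    evolve_protein(sp, leaf_depth[i], rp)
  }, character(1))
  full <- ifelse(is_secreted, paste0(sp_leaf, mature), mature)

  proteins <- tibble(id = tree$tip.label, seq = full, mature_seq = mature,
                     sp_len = ifelse(is_secreted, nchar(sp), NA_integer_))
  truth <- tibble(id = tree$tip.label, family = fam, is_toxin = is_toxin,
                  is_secreted = is_secreted, population = "A")
  list(tree = tree, proteins = proteins, truth = truth, root_seq = root_seq,
       toxin_mrca_seq = toxin_mrca_seq, signal_peptide = sp,
       has_toxin_clade = has_toxin, family = fam)
}

tip_indices_below <- function(tree, node) {
  ntip <- length(tree$tip.label)
  below <- c(node, nodes_below(tree, node))
  below[below <= ntip]
}

nodes_below <- function(tree, node) {
  out <- integer(0)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  while (length(kids) > 0) {
    out <- c(out, kids)
    kids <- tree$edge[tree$edge[, 1] %in% kids, 2]
  }
  out
}

# Evolve a root sequence down every edge; returns sequences for all nodes.
evolve_on_tree <- function(tree, root_seq, rp) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[root]] <- root_seq
  # edges in preorder: parents always precede children in rphylo edge
  # matrices is not guaranteed, so process reachable edges iteratively
  edges <- tree$edge
  done <- rep(FALSE, nrow(edges))
  repeat {
    ready <- which(!done & !vapply(seqs[edges[, 1]], is.null, logical(1)))
    if (length(ready) == 0) break
    for (e in ready) {
      seqs[[edges[e, 2]]] <- evolve_protein(seqs[[edges[e, 1]]],
                                            tree$edge.length[e], rp)
      done[e] <- TRUE
    }
  }
  seqs
}

# Expression, proteome, contigs ----------------------------------------------

#' Simulate per-tissue fragment counts and FPKM
#'
#' Draws an expected FPKM per sequence and tissue from the log-normal models
#' (toxins use the venom-gland toxin model; everything else the non-toxin
#' model; muscle is class-independent), then allocates each library's total
#' fragments by multinomial sampling with probabilities proportional to
#' `FPKM * length`, so counts are integers and the library size is conserved
#' exactly. The simulated families are a small slice of a whole-transcriptome
#' assembly, so the multinomial includes an explicit background bin holding
#' the remaining library mass (by the definition of FPKM, mass
#' `sum(FPKM * length)` over a whole transcriptome is `1e9`); fragments
#' falling in it represent reads mapped to contigs outside the simulated
#' families. This keeps realized FPKM unbiased for the model values. FPKM
#' columns are recomputed from the realized counts; the background fragment
#' counts are attached as attributes `background_vg` / `background_muscle`.
#'
#' @param truth ground-truth tibble including `id`, `is_toxin`, and
#'   `length_bp` (contig length; present after [fragment_and_emit()]).
#' @param config a [sim_config()].
#' @return Expression tibble: `id`, `length_bp`, `count_vg`,
#'   `count_muscle`, `fpkm_vg`, `fpkm_muscle`.
#' @export
simulate_expression <- function(truth, config) {
  stopifnot(all(c("id", "is_toxin", "length_bp") %in% names(truth)))
  set.seed(derive_seed(config$seed, "expression"))
  n <- nrow(truth)
  mu_vg <- ifelse(truth$is_toxin, config$vg_logFPKM_toxin[1],
                  config$vg_logFPKM_nontoxin[1])
  sd_vg <- ifelse(truth$is_toxin, config$vg_logFPKM_toxin[2],
                  config$vg_logFPKM_nontoxin[2])
  expected_vg <- 10^rnorm(n, mu_vg, sd_vg)
  expected_mu <- 10^rnorm(n, config$muscle_logFPKM[1],
                          config$muscle_logFPKM[2])
  alloc <- function(expected, total) {
    if (total <= 0) return(rep(0L, n + 1L))
    w <- expected * truth$length_bp
    background <- max(0, 1e9 - sum(w))
    as.integer(rmultinom(1, size = total, prob = c(w, background) / 1e9))
  }
  cnt_vg <- alloc(expected_vg, config$library_size_vg)
  cnt_mu <- alloc(expected_mu, config$library_size_muscle)
  counts <- tibble(
    id = truth$id, length_bp = truth$length_bp,
    count_vg = cnt_vg[seq_len(n)],
    count_muscle = cnt_mu[seq_len(n)]
  )
  out <- compute_expression(counts, config$library_size_vg,
                            config$library_size_muscle)
  attr(out, "background_vg") <- cnt_vg[n + 1L]
  attr(out, "background_muscle") <- cnt_mu[n + 1L]
  out
}

#' Simulate proteomic detection
#'
#' Each secreted toxin is detected with probability
#' `plogis(intercept + slope * log10(FPKM_vg + 1))`; nothing else is ever
#' detected (the venom proteome contains only translated, secreted venom
#' components).
#'
#' @param truth ground-truth tibble (`id`, `is_toxin`, `is_secreted`).
#' @param expression tibble from [simulate_expression()].
#' @param config a [sim_config()].
#' @return Character vector of detected sequence ids.
#' @export
simulate_proteome <- function(truth, expression, config) {
  stopifnot(all(truth$id %in% expression$id))
  set.seed(derive_seed(config$seed, "proteome"))
  fpkm_vg <- expression$fpkm_vg[match(truth$id, expression$id)]
  p <- plogis(config$detection_intercept +
                config$detection_slope * log10(fpkm_vg + 1))
  detected <- truth$is_toxin & truth$is_secreted & runif(nrow(truth)) < p
  truth$id[detected]
}

# most-frequent human-like codon per residue; ORF extraction only needs
# stop-free frames, so codon realism is irrelevant
.codon_table <- c(A = "GCC", R = "CGC", N = "AAC", D = "GAC", C = "TGC",
                  Q = "CAG", E = "GAG", G = "GGC", H = "CAC", I = "ATC",
                  L = "CTG", K = "AAG", M = "ATG", F = "TTC", P = "CCC",
                  S = "AGC", T = "ACC", W = "TGG", Y = "TAC", V = "GTG")

back_translate <- function(aa) {
  paste(.codon_table[strsplit(aa, "", fixed = TRUE)[[1]]], collapse = "")
}

random_utr <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Emit nucleotide contigs (with optional truncation) and the truth table
#'
#' Back-translates each protein with most-frequent codons and wraps the CDS
#' in random UTRs with in-frame stop codons on both sides. With probability
#' `frag_prob` the contig is truncated instead: a cut point uniform over the
#' first (5') or last (3') half of the CDS removes one flank, leaving a
#' partial CDS open at the contig end — a 5' cut usually removes the signal
#' peptide.
#'
#' @param proteins tibble from [simulate_family()] (`id`, `seq`, `sp_len`).
#' @param truth matching ground-truth tibble.
#' @param config a [sim_config()].
#' @return List with `contigs` (tibble `id`, `seq`) and `truth` extended
#'   with `length_bp`, `complete`, `cds_start`, `cds_end`, `frame_offset`,
#'   `sp_retained`, `sp_start`, `sp_end` (residue coordinates of the signal
#'   peptide within the emitted CDS, `NA` when absent/removed).
#' @export
fragment_and_emit <- function(proteins, truth, config) {
  set.seed(derive_seed(config$seed, "emit"))
  n <- nrow(proteins)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    aa <- proteins$seq[[i]]
    cds <- back_translate(aa)
    utr5 <- random_utr(sample(30:90, 1))
    utr3 <- random_utr(sample(30:90, 1))
    contig <- paste0(utr5, "TGA", cds, "TAA", utr3)
    cds_start <- nchar(utr5) + 3L       # 0-based start of CDS
    cds_end <- cds_start + nchar(cds)
    complete <- TRUE
    sp_len <- proteins$sp_len[[i]]
    sp_retained <- !is.na(sp_len)
    if (runif(1) < config$frag_prob) {
      complete <- FALSE
      n_codon <- nchar(aa)
      if (runif(1) < 0.5) {
        # 5' truncation: contig starts inside the first half of the CDS
        cut_codon <- sample(seq_len(max(1L, n_codon %/% 2L)), 1)
        cut_nt <- cds_start + 3L * cut_codon
        contig <- substring(contig, cut_nt + 1L)
        cds_start <- 0L
        cds_end <- cds_end - cut_nt
        if (sp_retained && cut_codon >= 1) sp_retained <- FALSE
      } else {
        # 3' truncation: contig ends inside the last half of the CDS
        cut_codon <- sample(seq_len(max(1L, n_codon %/% 2L)), 1)
        keep_nt <- cds_end - 3L * cut_codon
        contig <- substring(contig, 1L, keep_nt)
        cds_end <- keep_nt
      }
    }
    rows[[i]] <- tibble(
      id = proteins$id[[i]], contig_seq = contig,
      length_bp = nchar(contig), complete = complete,
      cds_start = cds_start, cds_end = cds_end,
      sp_retained = sp_retained,
      sp_start = ifelse(sp_retained, 0L, NA_integer_),
      sp_end = ifelse(sp_retained, sp_len, NA_integer_)
    )
  }
  emitted <- bind_rows(rows)
  list(
    contigs = tibble(id = emitted$id, seq = emitted$contig_seq),
    truth = left_join(truth, select(emitted, -"contig_seq"), by = "id")
  )
}

#' Build the three homology database tiers
#'
#' \describe{
#'   \item{species}{precursor proteins of the proteomically detected
#'     sequences of population A — a within-species reference.}
#'   \item{lineage}{for each family with a recruited toxin clade, one
#'     representative per simulated related species (two), derived from the
#'     toxin-clade ancestor with `db_divergence / 2` extra
#'     substitutions/site — a related-lineage known-toxin list.}
#'   \item{distant}{for a random subset of families (coverage
#'     `distant_coverage`), a representative derived from the family root
#'     with `db_divergence` extra substitutions/site, regardless of whether
#'     this species recruited the family as a toxin, plus decoy toxin
#'     families with no transcriptome homologue — a ToxProt-like pan-taxon
#'     toxin database.}
#' }
#'
#' @param families list of [simulate_family()] results.
#' @param proteome character vector of detected ids (population A).
#' @param config a [sim_config()].
#' @return Named list of tibbles (`distant`, `lineage`, `species`), each
#'   with columns `family`, `id`, `seq`.
#' @export
build_database_tiers <- function(families, proteome, config) {
  set.seed(derive_seed(config$seed, "databases"))
  rp <- replacement_probs()
  species <- purrr::map(families, function(f) {
    keep <- f$proteins$id %in% proteome
    if (!any(keep)) return(NULL)
    tibble(family = f$family, id = paste0("sp|", f$proteins$id[keep]),
           seq = f$proteins$seq[keep])
  }) |> bind_rows()
  lineage <- purrr::map(families, function(f) {
    if (!f$has_toxin_clade) return(NULL)
    purrr::map(1:2, function(rel) {
      seq <- evolve_protein(f$toxin_mrca_seq, config$db_divergence / 2, rp)
      sp <- evolve_protein(f$signal_peptide, config$db_divergence / 2, rp)
      tibble(family = f$family,
             id = sprintf("lin|%s_rel%d", f$family, rel),
             seq = paste0(sp, seq))
    }) |> bind_rows()
  }) |> bind_rows()
  covered <- runif(length(families)) < config$distant_coverage
  if (!any(covered)) covered[1] <- TRUE
  distant <- purrr::map(which(covered), function(i) {
    f <- families[[i]]
    tibble(family = f$family, id = sprintf("dist|%s_deep", f$family),
           seq = evolve_protein(f$root_seq, config$db_divergence, rp))
  }) |> bind_rows()
  if (config$n_decoy_families > 0) {
    decoys <- purrr::map(seq_len(config$n_decoy_families), function(k) {
      tibble(family = sprintf("DECOY%02d", k),
             id = sprintf("dist|DECOY%02d_rep", k),
             seq = random_protein(config$root_length_aa))
    }) |> bind_rows()
    distant <- bind_rows(distant, decoys)
  }
  if (is.null(species) || nrow(species) == 0) {
    species <- tibble(family = character(), id = character(),
                      seq = character())
  }
  list(distant = distant, lineage = lineage, species = species)
}

#' Simulate a complete two-tissue venom study
#'
#' Runs the whole generator: families, contig emission with fragmentation,
#' expression, proteomic detection, the three database tiers, and a second
#' diverged population's mature toxin peptides (for intraspecific-overlap
#' analyses). Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return A list of class `tox_sim` with elements `config`, `families`,
#'   `contigs`, `truth` (one row per emitted sequence, with `detected`
#'   column), `expression`, `proteome` (detected ids), `databases`,
#'   `pop_b_peptides` (tibble `id`, `seq`, `family`).
#' @export
simulate_venom_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "tox_sim_config"))
  families <- purrr::map(seq_len(config$n_families),
                         ~ simulate_family(config, .x))
  # a venom-gland study has venom toxins by construction: if no family drew
  # a recruited clade, re-simulate the first with one forced
  if (!any(vapply(families, `[[`, logical(1), "has_toxin_clade"))) {
    families[[1]] <- simulate_family(config, 1, force_toxin_clade = TRUE)
  }
  proteins <- bind_rows(purrr::map(families, "proteins"))
  truth0 <- bind_rows(purrr::map(families, "truth"))
  emit <- fragment_and_emit(proteins, truth0, config)
  expression <- simulate_expression(emit$truth, config)
  proteome <- simulate_proteome(emit$truth, expression, config)
  truth <- mutate(emit$truth, detected = .data$id %in% proteome)
  databases <- build_database_tiers(families, proteome, config)

  set.seed(derive_seed(config$seed, "population_b"))
  rp <- replacement_probs()
  pop_b <- purrr::map(families, function(f) {
    sec_tox <- f$truth$id[f$truth$is_toxin & f$truth$is_secreted]
    if (length(sec_tox) == 0) return(NULL)
    rows <- purrr::map(sec_tox, function(sid) {
      mat <- f$proteins$mature_seq[f$proteins$id == sid]
      tibble(id = paste0("B_", sid), family = f$family,
             seq = evolve_protein(mat, config$population_divergence, rp))
    })
    bind_rows(rows)
  }) |> bind_rows()

  structure(
    list(config = config, families = families, contigs = emit$contigs,
         truth = truth, expression = expression, proteome = proteome,
         databases = databases, pop_b_peptides = pop_b),
    class = "tox_sim"
  )
}

#' @export
print.tox_sim <- function(x, ...) {
  cat("<tox_sim>", nrow(x$contigs), "contigs,",
      sum(x$truth$is_toxin), "toxins,",
      length(x$proteome), "proteome-detected; seed", x$config$seed, "\n")
  invisible(x)
}

#' Write a simulated study to disk
#'
#' Emits the generator's on-disk form: contig FASTA, protein database
#' FASTAs per tier, a truth TSV, a counts TSV, and the proteome id list.
#'
#' @param sim a `tox_sim` from [simulate_venom_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(sim$contigs, file.path(dir, "contigs.fasta"), type = "DNA")
  for (tier in names(sim$databases)) {
    db <- sim$databases[[tier]]
    write_fasta(tibble(id = paste0(db$family, "|", db$id), seq = db$seq),
                file.path(dir, paste0("db_", tier, ".fasta")), type = "AA")
  }
  write_tox_tsv(sim$truth, file.path(dir, "truth.tsv"))
  write_tox_tsv(
    select(sim$expression, "id", "length_bp", "count_vg", "count_muscle"),
    file.path(dir, "counts.tsv")
  )
  writeLines(sim$proteome, file.path(dir, "proteome_ids.txt"))
  invisible(dir)
}
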