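# ORF extraction, signal peptides, deduplication and identity clustering ----

#' Extract open reading frames from nucleotide contigs
#'
#' Translates every contig in all six frames and reports each maximal
#' stop-free stretch of at least `min_len_aa` residues as a coding sequence.
#' No start codon is required: the unit is "any possible open reading frame",
#' so partial CDSs truncated by contig ends are reported too, flagged
#' incomplete. Codons containing `N` translate to `X`.
#'
#' Coordinates are 0-based half-open nucleotide intervals on the forward
#' strand of the contig; reverse-strand ORFs (frames -1..-3, read on the
#' reverse complement) are mapped back to forward coordinates. An ORF is
#' complete when a stop codon bounds it on both sides within the contig.
#'
#' @param contigs tibble with columns `id` and `seq` (alphabet `ACGTN`).
#' @param min_len_aa minimum ORF length in residues (default 40).
#' @return Tibble with one row per ORF: `id`, `contig_id`, `frame`
#'   (in -3..-1, 1..3), `start`, `end` (nt, forward strand), `aa_seq`,
#'   `length_aa`, `is_complete`.
#' @examples
#' extract_orfs(tibble::tibble(id = "c1", seq = strrep("GCT", 50)))
#' @export
extract_orfs <- function(contigs, min_len_aa = 40) {
  stopifnot(all(c("id", "seq") %in% names(contigs)))
  if (nrow(contigs) == 0) return(empty_orf_tbl())
  fwd <- Biostrings::DNAStringSet(setNames(contigs$seq, contigs$id))
  rev <- Biostrings::reverseComplement(fwd)
  lens <- Biostrings::width(fwd)

  fwd_chr <- as.character(fwd)
  rev_chr <- as.character(rev)
  rows <- vector("list", 6L)
  k <- 0L
  for (strand in c(1L, -1L)) {
    ss <- if (strand == 1L) fwd_chr else rev_chr
    for (off in 0:2) {
      k <- k + 1L
      n_codon <- pmax((lens - off) %/% 3L, 0L)
      keep <- n_codon > 0L
      if (!any(keep)) next
      aa <- translate_frame(ss[keep], off, n_codon[keep])
      rows[[k]] <- orf_rows_for_frame(
        aa, contig_id = contigs$id[keep], contig_len = lens[keep],
        offset = off, strand = strand, min_len_aa = min_len_aa
      )
    }
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) return(empty_orf_tbl())
  out <- out |>
    arrange(match(.data$contig_id, contigs$id), .data$frame, .data$start) |>
    group_by(.data$contig_id) |>
    mutate(id = paste0(.data$contig_id, "|orf", row_number())) |>
    ungroup() |>
    select("id", "contig_id", "frame", "start", "end", "aa_seq",
           "length_aa", "is_complete")
  out
}

# codon -> residue lookup from the standard genetic code; any codon not in
# the table (i.e. containing N) translates to X
.codon_map <- local({
  map <- NULL
  function() {
    if (is.null(map)) map <<- Biostrings::GENETIC_CODE
    map
  }
})

# Translate each sequence from `offset` (0-based) for n_codon codons.
translate_frame <- function(seqs, offset, n_codon) {
  map <- .codon_map()
  vapply(seq_along(seqs), function(i) {
    nc <- n_codon[[i]]
    pos <- offset + 1L + 3L * (seq_len(nc) - 1L)
    codons <- substring(seqs[[i]], pos, pos + 2L)
    aa <- map[codons]
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }, character(1))
}

empty_orf_tbl <- function() {
  tibble(id = character(), contig_id = character(), frame = integer(),
         start = integer(), end = integer(), aa_seq = character(),
         length_aa = integer(), is_complete = logical())
}

# Split translated frames on stops and map runs back to forward-strand
# nucleotide coordinates. Vectorized over all contigs of one frame.
orf_rows_for_frame <- function(aa, contig_id, contig_len, offset, strand,
                               min_len_aa) {
  runs <- gregexpr("[^*]+", aa)
  n_runs <- vapply(runs, function(m) if (m[1] == -1) 0L else length(m),
                   integer(1))
  if (sum(n_runs) == 0) return(NULL)
  idx <- rep.int(seq_along(aa), n_runs)
  starts <- unlist(lapply(runs, function(m) if (m[1] == -1) integer(0)
                          else as.integer(m)), use.names = FALSE)
  lens <- unlist(lapply(runs, function(m) if (m[1] == -1) integer(0)
                        else attr(m, "match.length")), use.names = FALSE)
  keep <- lens >= min_len_aa
  if (!any(keep)) return(NULL)
  idx <- idx[keep]; starts <- starts[keep]; lens <- lens[keep]
  ends <- starts + lens - 1L
  n_codon <- nchar(aa)[idx]
  # 0-based half-open nt span on the translated strand
  s_nt <- offset + 3L * (starts - 1L)
  e_nt <- offset + 3L * ends
  if (strand == 1L) {
    start <- s_nt; end <- e_nt
  } else {
    start <- contig_len[idx] - e_nt
    end <- contig_len[idx] - s_nt
  }
  tibble(
    contig_id = contig_id[idx],
    frame = strand * (offset + 1L),
    start = start, end = end,
    aa_seq = substring(aa[idx], starts, ends),
    length_aa = lens,
    # complete = a stop codon bounds the run on both sides inside the contig
    is_complete = starts > 1L & ends < n_codon
  )
}

# Signal peptides ------------------------------------------------------------

#' Kyte-Doolittle hydropathy values
#' @return Named numeric vector over the 20 standard residues.
#' @export
kyte_doolittle <- function() {
  c(I = 4.5, V = 4.2, L = 3.8, F = 2.8, C = 2.5, M = 1.9, A = 1.8,
    G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6,
    H = -3.2, E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9, R = -4.5)
}

#' Detect signal peptides on coding sequences
#'
#' Two modes. `"truth"` (the test default on synthetic data) reads the
#' generator's ground-truth label carried in the `sp_start`/`sp_end` columns
#' and errors if those columns are absent — a missing label is never silently
#' treated as "no signal peptide". `"heuristic"` is a deliberately simple
#' rule-based stand-in for a dedicated predictor such as SignalP: within the
#' first 30 residues it requires (i) at least one K/R in positions 1-5
#' (n-region charge), (ii) a window of 8 consecutive residues with mean
#' Kyte-Doolittle hydropathy >= 1.6 (h-region), and (iii) small residues
#' (A/G/S/C/T) at the -3 and -1 positions of the proposed cleavage site
#' (c-region); the earliest cleavage position from residue 10 onward that
#' satisfies (iii) with the hydrophobic window upstream is reported.
#'
#' @param cds tibble with column `aa_seq` (and `sp_start`/`sp_end` in truth
#'   mode; `NA` means no signal peptide).
#' @param mode `"truth"` or `"heuristic"`.
#' @return `cds` with logical `has_signal_peptide` and integer `sp_cleavage`
#'   (number of signal-peptide residues; `NA` when absent).
#' @export
detect_signal_peptide <- function(cds, mode = c("truth", "heuristic")) {
  mode <- match.arg(mode)
  stopifnot("aa_seq" %in% names(cds))
  if (mode == "truth") {
    if (!all(c("sp_start", "sp_end") %in% names(cds))) {
      abort(paste("truth-mode signal-peptide label missing:",
                  "columns sp_start/sp_end not found"),
            class = "toxaudit_label_error")
    }
    cds |>
      mutate(has_signal_peptide = !is.na(.data$sp_end),
             sp_cleavage = ifelse(is.na(.data$sp_end), NA_integer_,
                                  as.integer(.data$sp_end)))
  } else {
    cleave <- vapply(cds$aa_seq, sp_heuristic_cleavage, integer(1),
                     USE.NAMES = FALSE)
    cds |>
      mutate(has_signal_peptide = !is.na(cleave), sp_cleavage = cleave)
  }
}

# Heuristic cleavage position (residues in the signal peptide) or NA.
# Pure function of the string; tolerant of any input alphabet (unknown
# residues take hydropathy 0).
sp_heuristic_cleavage <- function(aa) {
  n <- nchar(aa)
  if (is.na(aa) || n < 12) return(NA_integer_)
  res <- strsplit(aa, "", fixed = TRUE)[[1]]
  lead <- res[seq_len(min(30L, n))]
  if (!any(lead[seq_len(min(5L, n))] %in% c("K", "R"))) return(NA_integer_)
  kd <- kyte_doolittle()
  h <- unname(kd[lead])
  h[is.na(h)] <- 0
  L <- length(h)
  if (L < 8) return(NA_integer_)
  win <- vapply(seq_len(L - 7L), function(i) mean(h[i:(i + 7L)]), numeric(1))
  wend <- which(win >= 1.6) + 7L       # end positions of qualifying windows
  if (length(wend) == 0) return(NA_integer_)
  small <- c("A", "G", "S", "C", "T")
  for (cpos in 10:min(30L, n - 1L)) {
    if (res[cpos] %in% small && res[cpos - 2L] %in% small &&
        any(wend <= cpos)) {
      return(as.integer(cpos))
    }
  }
  NA_integer_
}

# Identity, deduplication, clustering ---------------------------------------

#' Global-alignment identity between two proteins
#'
#' Identity is the number of identically aligned positions in a global
#' alignment (scoring as in the homology module: BLOSUM62, affine gaps 11/1)
#' divided by the length of the shorter sequence — the CD-HIT convention.
#'
#' @param a,b protein strings (non-empty).
#' @param scheme a [scoring_scheme()].
#' @return Identity fraction in \[0, 1\]; symmetric in its arguments.
#' @examples
#' pairwise_identity("AAAA", "AAAC")
#' @export
pairwise_identity <- function(a, b, scheme = scoring_scheme()) {
  if (is.na(a) || is.na(b) || nchar(a) == 0 || nchar(b) == 0) {
    abort("pairwise_identity requires non-empty sequences",
          class = "toxaudit_input_error")
  }
  r <- nw_align_cpp(encode_protein(a, scheme$matrix),
                    encode_protein(b, scheme$matrix),
                    scheme$matrix, scheme$gap_open, scheme$gap_extend)
  r$matches / min(nchar(a), nchar(b))
}

#' Remove exact duplicate coding sequences
#'
#' Collapses rows with identical `aa_seq`; the survivor of each duplicate
#' group is the row with the lexicographically smallest `id`, and survivors
#' keep their input order.
#'
#' @param cds tibble with columns `id` and `aa_seq`.
#' @return The surviving rows of `cds`.
#' @export
dedupe_identical <- function(cds) {
  stopifnot(all(c("id", "aa_seq") %in% names(cds)))
  if (nrow(cds) == 0) return(cds)
  keep_id <- cds |>
    group_by(.data$aa_seq) |>
    summarise(keep = min(.data$id), .groups = "drop") |>
    pull("keep")
  cds[cds$id %in% keep_id, , drop = FALSE]
}

#' Greedy identity clustering of protein sequences
#'
#' CD-HIT-style greedy incremental clustering: sequences are sorted by
#' decreasing length (ties broken by id), and each sequence joins the first
#' existing cluster whose representative it matches at identity >=
#' `threshold` ([pairwise_identity()]), otherwise it founds a new cluster.
#' Deterministic: shuffling the input does not change the clusters.
#'
#' @param seqs tibble with columns `id` and `seq` (protein).
#' @param threshold identity threshold in (0, 1].
#' @param scheme a [scoring_scheme()].
#' @return Tibble with columns `cluster` (integer), `representative_id`,
#'   `member_id`, `identity` (member vs. representative; 1 for the
#'   representative itself).
#' @export
cluster_by_identity <- function(seqs, threshold, scheme = scoring_scheme()) {
  stopifnot(all(c("id", "seq") %in% names(seqs)))
  if (threshold <= 0 || threshold > 1) {
    abort("threshold must be in (0, 1]", class = "toxaudit_config_error")
  }
  if (nrow(seqs) == 0) {
    return(tibble(cluster = integer(), representative_id = character(),
                  member_id = character(), identity = double()))
  }
  ord <- order(-nchar(seqs$seq), seqs$id)
  s <- seqs[ord, , drop = FALSE]
  enc <- encode_protein_set(s$seq, scheme$matrix)
  rep_idx <- integer(0)              # indices (into s) of representatives
  assign_cl <- integer(nrow(s))
  ident <- numeric(nrow(s))
  for (i in seq_len(nrow(s))) {
    placed <- FALSE
    for (ci in seq_along(rep_idx)) {
      r <- nw_align_cpp(enc[[rep_idx[[ci]]]], enc[[i]], scheme$matrix,
                        scheme$gap_open, scheme$gap_extend)
      idv <- r$matches / min(nchar(s$seq[[rep_idx[[ci]]]]), nchar(s$seq[[i]]))
      if (idv >= threshold) {
        assign_cl[[i]] <- ci; ident[[i]] <- idv; placed <- TRUE
        break
      }
    }
    if (!placed) {
      rep_idx <- c(rep_idx, i)
      assign_cl[[i]] <- length(rep_idx)
      ident[[i]] <- 1
    }
  }
  tibble(
    cluster = assign_cl,
    representative_id = s$id[rep_idx[assign_cl]],
    member_id = s$id,
    identity = ident
  ) |>
    arrange(.data$cluster, .data$member_id)
}
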