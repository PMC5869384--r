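# Independent oracles and fixture builders used across the suite. These
# deliberately re-derive results from first principles (plain R loops, their
# own codon table) so they share no code path with the implementation.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_peptide <- function(n) paste(sample(AA20, n, TRUE), collapse = "")

random_contig <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
}

# Brute-force affine-gap local alignment (score only): three-state DP with
# explicit loops; gap of length g costs open + (g - 1) * extend.
sw_oracle <- function(a, b, mat, open = 11, extend = 1) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  m <- length(x); n <- length(y)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  F <- matrix(-Inf, m + 1, n + 1)
  best <- 0
  for (i in 1:m) {
    for (j in 1:n) {
      E[i + 1, j + 1] <- max(H[i + 1, j] - open, E[i + 1, j] - extend)
      F[i + 1, j + 1] <- max(H[i, j + 1] - open, F[i, j + 1] - extend)
      h <- max(0, H[i, j] + mat[x[i], y[j]],
               E[i + 1, j + 1], F[i + 1, j + 1])
      H[i + 1, j + 1] <- h
      if (h > best) best <- h
    }
  }
  best
}

# Standard genetic code, written out independently of the implementation.
ORACLE_CODONS <- c(
  TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
  ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
  TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
  ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
  TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
  AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
  TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
  AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")

revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# Six-frame translate-and-split ORF oracle; returns a data.frame with the
# same column semantics as extract_orfs().
orf_oracle <- function(contig, min_len_aa = 40) {
  L <- nchar(contig)
  out <- list()
  for (strand in c(1L, -1L)) {
    s <- if (strand == 1L) contig else revcomp_chr(contig)
    for (off in 0:2) {
      nc <- (nchar(s) - off) %/% 3
      if (nc < 1) next
      aa <- character(nc)
      for (k in seq_len(nc)) {
        codon <- substr(s, off + 3 * (k - 1) + 1, off + 3 * k)
        aa[k] <- if (codon %in% names(ORACLE_CODONS))
          ORACLE_CODONS[[codon]] else "X"
      }
      run_start <- NA
      for (k in seq_len(nc + 1)) {
        stop_here <- k > nc || aa[k] == "*"
        if (!stop_here && is.na(run_start)) run_start <- k
        if (stop_here && !is.na(run_start)) {
          run_end <- k - 1
          len <- run_end - run_start + 1
          if (len >= min_len_aa) {
            s_nt <- off + 3 * (run_start - 1)
            e_nt <- off + 3 * run_end
            out[[length(out) + 1]] <- data.frame(
              frame = strand * (off + 1L),
              start = if (strand == 1) s_nt else L - e_nt,
              end = if (strand == 1) e_nt else L - s_nt,
              aa_seq = paste(aa[run_start:run_end], collapse = ""),
              is_complete = run_start > 1 && run_end < nc
            )
          }
          run_start <- NA
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(frame = integer(), start = integer(),
                      end = integer(), aa_seq = character(),
                      is_complete = logical()))
  }
  df <- do.call(rbind, out)
  df[order(df$frame, df$start), ]
}

# Two peptides of length 100 differing at exactly 6 positions (94% identity).
make_94pct_pair <- function() {
  base <- strsplit(strrep("ACDEFGHIKL", 10), "")[[1]]
  other <- base
  other[c(5, 15, 25, 35, 45, 55)] <- c("W", "W", "W", "W", "W", "W")
  c(paste(base, collapse = ""), paste(other, collapse = ""))
}

# Small, fast simulation config for pipeline-level tests.
small_sim <- function(seed = 1, ...) {
  sim_config(seed = seed, n_families = 2L, leaves_per_family = c(8L, 10L),
             ...)
}

quiet_run <- function(rc) suppressMessages(run_pipeline(rc))
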