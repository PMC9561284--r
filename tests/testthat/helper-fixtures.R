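# shared fixtures and independent oracles

# compact reference set: full-size 28S (the 4447 coordinate must exist),
# everything else scaled down
small_layout <- function() {
  ref_layout(len_5ets = 400, len_18s = 300, len_its1 = 120, len_58s = 60,
             len_its2 = 120, len_28s = 4600, len_3ets = 80,
             n_snord = 2, n_snora = 1, len_snorna = 130,
             n_decoy = 1, len_decoy = 300)
}

small_refs <- function(seed = 42) build_reference(seed, small_layout())

# minimal alignment-record tibble for profile-level operations
fake_records <- function(ref, start, aligned_length = 30L,
                         umi = sprintf("U%05d", seq_along(start)),
                         score = 2L * aligned_length,
                         read_id = sprintf("r%05d", seq_along(start))) {
  tibble::tibble(read_id = read_id, umi = umi, ref = ref,
                 start = as.integer(start), strand = "+",
                 aligned_length = as.integer(rep_len(aligned_length,
                                                     length(start))),
                 score = as.integer(rep_len(score, length(start))),
                 cigar = paste0(aligned_length, "M"),
                 query_start = 1L,
                 query_end = as.integer(rep_len(aligned_length,
                                                length(start))),
                 sequence = strrep("A", rep_len(aligned_length,
                                                length(start))))
}

# independent full Smith-Waterman oracle (affine gaps: a gap of length L
# costs gap_open + (L-1) * gap_extend), plain-R dynamic programming
sw_oracle_score <- function(q, t, match = 2, mismatch = -3,
                            gap_open = -5, gap_extend = -2) {
  qv <- strsplit(q, "")[[1]]
  tv <- strsplit(t, "")[[1]]
  m <- length(qv); n <- length(tv)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  F <- matrix(-Inf, m + 1, n + 1)
  best <- 0
  for (i in seq_len(m) + 1) {
    for (j in seq_len(n) + 1) {
      s <- if (qv[i - 1] == tv[j - 1]) match else mismatch
      E[i, j] <- max(H[i, j - 1] + gap_open, E[i, j - 1] + gap_extend)
      F[i, j] <- max(H[i - 1, j] + gap_open, F[i - 1, j] + gap_extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# two-sided Fisher exact p by direct hypergeometric enumeration
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  pobs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# closed-form pooled-variance two-sample t-test
t_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) /
    (n1 + n2 - 2)
  tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df))
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
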