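# Independent brute-force oracles. These deliberately re-derive results from
# first principles (explicit formulas, enumeration) rather than calling the
# package's implementation paths.

# Benjamini-Hochberg step-up, literal formula on the sorted vector
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# hypergeometric upper tail P(X >= a) by explicit binomial-coefficient sums
bf_hyper_tail <- function(a, K, n, N) {
  lo <- max(0, n + K - N)
  hi <- min(K, n)
  if (a > hi) return(0)
  j <- max(a, lo):hi
  sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
}

# evaluator of the eight subregion classes over explicit "winner>loser"
# significance strings; precedence chambers first, then the fixed order
bf_subregion_requirements <- list(
  LV = c("LV>LA", "LV>RA", "LV>RV"),
  RV = c("RV>LA", "RV>RA", "RV>LV"),
  LA = c("LA>LV", "LA>RA", "LA>RV"),
  RA = c("RA>LA", "RA>LV", "RA>RV"),
  Ventricles = c("LV>LA", "RV>LA", "LV>RA", "RV>RA"),
  Atria = c("LA>LV", "RA>LV", "LA>RV", "RA>RV"),
  Left = c("LV>RV", "LV>RA", "LA>RV", "LA>RA"),
  Right = c("RV>LV", "RV>LA", "RA>LV", "RA>LA")
)

bf_classify_one <- function(sig_pairs) {
  qual <- names(Filter(function(req) all(req %in% sig_pairs),
                       bf_subregion_requirements))
  list(primary = if (length(qual)) qual[1] else "none", qualifying = qual)
}

# all 3^6 direction/significance patterns over the six canonical chamber
# pairs, as contrast-style data.frames plus the oracle's significance strings
make_truth_table_grid <- function() {
  pairs <- t(combn(c("LA", "LV", "RA", "RV"), 2))
  states <- as.matrix(expand.grid(rep(list(c(-1L, 0L, 1L)), 6)))
  n <- nrow(states)
  gene_ids <- sprintf("combo_%03d", seq_len(n))
  results <- list()
  for (k in seq_len(6)) {
    s <- states[, k]
    results[[paste(pairs[k, 1], pairs[k, 2], sep = "_vs_")]] <- data.frame(
      gene_id = gene_ids,
      # non-significant state keeps a large fold change so the q-filter,
      # not the FC filter, is what blocks it
      log2FC = ifelse(s == 0L, 2, 2 * s),
      padj = ifelse(s == 0L, 0.5, 0.001),
      stringsAsFactors = FALSE)
  }
  sig_strings <- lapply(seq_len(n), function(i) {
    unlist(lapply(seq_len(6), function(k) {
      if (states[i, k] == 1L) paste0(pairs[k, 1], ">", pairs[k, 2])
      else if (states[i, k] == -1L) paste0(pairs[k, 2], ">", pairs[k, 1])
      else character(0)
    }))
  })
  list(results = results, sig_strings = sig_strings, gene_ids = gene_ids)
}

# small labeled count matrix with named dims, for I/O and filter tests
toy_counts <- function(n_genes = 10, n_samples = 6, seed = 1, mu = 50) {
  set.seed(seed)
  matrix(rnbinom(n_genes * n_samples, mu = mu, size = 5),
         n_genes, n_samples,
         dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                         sprintf("s%02d", seq_len(n_samples))))
}
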