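# Shared fixtures: small configurations and toy containers built in code.

tinyConfig <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_f1 = 12L, n_markers = 4L, n_genes = 60L, n_background_de = 10L,
         n_linked = 3L, lib_size_mean = 5e4, n_proteins = 40L,
         n_da_proteins = 6L, n_absent = 4L, seed = seed),
    list(...))
  do.call(simConfig, args)
}

toyCounts <- function(mat, lengths = NULL, groups = NULL) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat))) rownames(mat) <- paste0("g", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- paste0("s", seq_len(ncol(mat)))
  if (is.null(lengths)) lengths <- rep(1000, nrow(mat))
  if (is.null(groups)) groups <- colnames(mat)
  CountExperiment(mat, lengths, groups)
}

# Independent brute-force conditional test for phi = 0: the two group sums
# conditioned on their total follow Binomial(t, nA / (nA + nB)); two-sided p
# sums the probabilities of all splits no more probable than the observed
# one. Written from first principles (log factorials), separate from the
# package's kernel.
binomConditionalOracle <- function(a, b, nA, nB) {
  t <- a + b
  if (t == 0) return(1)
  p <- nA / (nA + nB)
  k <- 0:t
  w <- exp(lgamma(t + 1) - lgamma(k + 1) - lgamma(t - k + 1) +
             k * log(p) + (t - k) * log(1 - p))
  sum(w[w <= w[a + 1] * (1 + 1e-12)]) / sum(w)
}

# Brute-force hypergeometric upper tail by direct enumeration of overlaps.
hyperOracle <- function(k, K, N, n) {
  kk <- max(0, n - (N - K)):min(n, K)
  pmf <- choose(K, kk) * choose(N - K, n - kk) / choose(N, n)
  sum(pmf[kk >= k])
}
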