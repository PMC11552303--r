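## Count-based differential expression engine: TMM normalisation, TMM-FPKM,
## method-of-moments dispersion with empirical-Bayes-style shrinkage, the
## negative binomial conditional exact test for two groups, BH control and
## threshold calling. Written from the published definitions of each step;
## no external DE library is called.

#' Trimmed mean of M-values normalisation factors
#'
#' Composition-correcting between-sample factors. The reference sample is
#' the one whose 75th-percentile count fraction is closest to the mean of
#' those fractions (unless supplied). For each sample, M (log ratio) and A
#' (log abundance) values are computed over genes expressed in both sample
#' and reference; the 30\% most extreme M and 5\% most extreme A values are
#' discarded two-sided; the factor is 2 to the precision-weighted mean of the
#' retained M values (delta-method binomial weights). Factors are rescaled
#' to geometric mean 1.
#'
#' @param counts genes x samples count matrix or
#'   \linkS4class{CountExperiment}.
#' @param lib_sizes library sizes (default: column sums).
#' @param ref_sample optional reference column index or name.
#' @param logratio_trim,abundance_trim two-sided trim fractions.
#' @return named numeric vector of factors, geometric mean 1.
#' @export
tmmFactors <- function(counts, lib_sizes = NULL, ref_sample = NULL,
                       logratio_trim = 0.3, abundance_trim = 0.05) {
  if (is(counts, "CountExperiment"))
    counts <- SummarizedExperiment::assay(counts, "counts")
  counts <- as.matrix(counts)
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  if (any(lib_sizes == 0)) stop("degenerate library: all-zero sample")
  if (is.null(ref_sample)) {
    f75 <- apply(counts, 2, quantile, probs = 0.75) / lib_sizes
    ref_sample <- which.min(abs(f75 - mean(f75)))
  } else if (is.character(ref_sample)) {
    ref_sample <- match(ref_sample, colnames(counts))
  }
  yr <- counts[, ref_sample]; nr <- lib_sizes[ref_sample]
  one <- function(i) {
    yi <- counts[, i]; ni <- lib_sizes[i]
    keep <- yi > 0 & yr > 0
    if (!any(keep)) return(1)
    M <- log2((yi[keep] / ni) / (yr[keep] / nr))
    A <- 0.5 * log2((yi[keep] / ni) * (yr[keep] / nr))
    v <- (ni - yi[keep]) / (ni * yi[keep]) + (nr - yr[keep]) / (nr * yr[keep])
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * abundance_trim) + 1; hiA <- n + 1 - loA
    kp <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    2^(sum(M[kp] / v[kp], na.rm = TRUE) / sum(1 / v[kp], na.rm = TRUE))
  }
  f <- vapply(seq_len(ncol(counts)), one, numeric(1))
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(counts))
}

#' TMM-normalised FPKM
#'
#' \code{fpkm[g, s] = counts[g, s] * 1e9 / (length[g] * lib[s] * factor[s])}.
#'
#' @param counts count matrix or \linkS4class{CountExperiment}.
#' @param lengths gene lengths in bp (taken from the container if omitted).
#' @param factors TMM factors from \code{\link{tmmFactors}}.
#' @param lib_sizes library sizes (default column sums).
#' @return matrix of FPKM values.
#' @export
tmmFpkm <- function(counts, lengths = NULL, factors = NULL,
                    lib_sizes = NULL) {
  if (is(counts, "CountExperiment")) {
    if (is.null(lengths)) lengths <- geneLengths(counts)
    counts <- SummarizedExperiment::assay(counts, "counts")
  }
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  if (is.null(factors)) factors <- tmmFactors(counts, lib_sizes)
  eff <- lib_sizes * factors
  sweep(counts / lengths, 2, eff, "/") * 1e9
}

#' Per-gene negative binomial dispersion (method of moments, shrunk)
#'
#' Counts are scaled to a common effective library size, within-group
#' residual variance is pooled, and the raw moment estimate
#' \code{max(0, (s^2 - mu) / mu^2)} is shrunk toward the median per-gene
#' value with prior weight \code{prior_df} against the residual degrees of
#' freedom.
#'
#' @param counts count matrix or \linkS4class{CountExperiment}.
#' @param groups group label per sample (taken from the container if
#'   omitted).
#' @param factors TMM factors (computed if omitted).
#' @param prior_df prior weight of the shared (median) dispersion.
#' @return named numeric vector of per-gene dispersions.
#' @export
estimateDispersion <- function(counts, groups = NULL, factors = NULL,
                               prior_df = 10) {
  if (is(counts, "CountExperiment")) {
    if (is.null(groups)) groups <- sampleGroups(counts)
    counts <- SummarizedExperiment::assay(counts, "counts")
  }
  groups <- as.character(groups)
  lib <- colSums(counts)
  if (is.null(factors)) factors <- tmmFactors(counts, lib)
  eff <- lib * factors
  df <- ncol(counts) - length(unique(groups))
  if (df < 1)
    stop("no replication: supply a dispersion explicitly")
  z <- sweep(counts, 2, exp(mean(log(eff))) / eff, "*")
  mu <- rowMeans(z)
  ss <- 0
  for (g in unique(groups)) {
    zi <- z[, groups == g, drop = FALSE]
    if (ncol(zi) > 1) ss <- ss + rowSums((zi - rowMeans(zi))^2)
  }
  s2 <- ss / df
  raw <- pmax(0, (s2 - mu) / mu^2)
  raw[!is.finite(raw)] <- 0
  shared <- median(raw)
  phi <- (prior_df * shared + df * raw) / (prior_df + df)
  setNames(phi, rownames(counts))
}

# Conditional NB log-pmf over all splits (k, t - k) of a fixed total t,
# group sums treated as NB with means proportional to replicate numbers and
# dispersion phi / n. phi = 0 falls back to the Poisson (binomial) kernel.
exactTestPvalue <- function(a, b, nA, nB, phi) {
  t <- a + b
  if (t == 0) return(1)
  k <- 0:t
  pA <- nA / (nA + nB)
  if (phi <= 0) {
    lw <- dbinom(k, t, pA, log = TRUE)
  } else {
    lw <- dnbinom(k, size = nA / phi, mu = t * pA, log = TRUE) +
      dnbinom(t - k, size = nB / phi, mu = t * (1 - pA), log = TRUE)
  }
  lw <- lw - max(lw)
  w <- exp(lw)
  obs <- w[a + 1]
  min(1, sum(w[w <= obs * (1 + 1e-12)]) / sum(w))
}

#' Negative binomial conditional exact test for two groups
#'
#' Counts are scaled to a common effective library size (the geometric mean)
#' and rounded to pseudo-counts; the per-group sums are then compared by a
#' two-sided conditional exact test: over all splits of the total, the
#' probabilities no larger than the observed split's probability are summed
#' and normalised. With dispersion 0 this is exactly the binomial
#' (conditional Poisson) test.
#'
#' @param counts_A,counts_B genes x replicates count matrices.
#' @param phi per-gene dispersion (recycled).
#' @param lib_sizes effective library sizes for the columns of
#'   \code{cbind(counts_A, counts_B)} (default: column sums).
#' @return named vector of two-sided p-values in (0, 1].
#' @export
nbExactTest <- function(counts_A, counts_B, phi, lib_sizes = NULL) {
  counts_A <- as.matrix(counts_A); counts_B <- as.matrix(counts_B)
  stopifnot(nrow(counts_A) == nrow(counts_B))
  if (any(phi < 0)) stop("dispersion must be >= 0")
  nA <- ncol(counts_A); nB <- ncol(counts_B)
  if (nA == 0 || nB == 0) stop("both groups must be nonempty")
  all <- cbind(counts_A, counts_B)
  if (is.null(lib_sizes)) lib_sizes <- colSums(all)
  common <- exp(mean(log(lib_sizes)))
  pseudo <- round(sweep(all, 2, common / lib_sizes, "*"))
  a <- rowSums(pseudo[, seq_len(nA), drop = FALSE])
  b <- rowSums(pseudo[, nA + seq_len(nB), drop = FALSE])
  phi <- rep_len(phi, nrow(all))
  p <- vapply(seq_len(nrow(all)), function(g)
    exactTestPvalue(a[g], b[g], nA, nB, phi[g]), numeric(1))
  setNames(p, rownames(counts_A))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false discovery rate control (monotone q-values).
#'
#' @param p p-values in [0, 1].
#' @return q-values in [0, 1].
#' @export
bhFdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Apply fold-change and FDR call thresholds
#'
#' \code{up_A} iff log2FC > \code{lfc_threshold} and FDR <
#' \code{fdr_threshold}; \code{up_B} symmetric; strict inequalities, so
#' boundary values are not called.
#'
#' @param results data.frame with \code{log2fc} and \code{fdr} columns.
#' @param lfc_threshold,fdr_threshold call cutoffs (defaults 2.0 and 0.05).
#' @return the input with a \code{call} column in {up_A, up_B, ns}.
#' @export
callDE <- function(results, lfc_threshold = 2.0, fdr_threshold = 0.05) {
  call <- rep("ns", nrow(results))
  sig <- results$fdr < fdr_threshold
  call[sig & results$log2fc > lfc_threshold] <- "up_A"
  call[sig & results$log2fc < -lfc_threshold] <- "up_B"
  results$call <- call
  results
}

#' Full two-group differential expression contrast
#'
#' Runs the engine end to end for one contrast: TMM factors on the contrast
#' samples, dispersion estimation (unless supplied), the conditional exact
#' test, log2 fold changes from factor-normalised counts-per-million with a
#' prior count of 0.5 added to both group means, BH control across all
#' tested genes (genes with zero counts in every contrast sample are
#' excluded first), and threshold calling.
#'
#' @param ce a \linkS4class{CountExperiment}.
#' @param group_A,group_B the two group labels to contrast (A over B).
#' @param phi optional fixed per-gene dispersion.
#' @param lfc_threshold,fdr_threshold call cutoffs.
#' @param prior_count prior added to group mean CPM before the log ratio.
#' @param cpm_filter minimum mean CPM to test a gene (0 = no filter).
#' @return data.frame: gene_id, log2fc, p_value, fdr, mean_cpm, call.
#' @export
deTable <- function(ce, group_A, group_B, phi = NULL,
                    lfc_threshold = 2.0, fdr_threshold = 0.05,
                    prior_count = 0.5, cpm_filter = 0) {
  grp <- sampleGroups(ce)
  sel <- grp %in% c(group_A, group_B)
  if (!any(grp == group_A) || !any(grp == group_B))
    stop("both contrast groups must be present")
  cnt <- SummarizedExperiment::assay(ce, "counts")[, sel, drop = FALSE]
  grp <- grp[sel]
  keep <- rowSums(cnt) > 0
  cnt <- cnt[keep, , drop = FALSE]
  lib <- colSums(cnt)
  factors <- tmmFactors(cnt, lib)
  eff <- lib * factors
  if (is.null(phi))
    phi <- estimateDispersion(cnt, grp, factors)
  else phi <- rep_len(phi, nrow(cnt))
  cpm <- sweep(cnt, 2, eff, "/") * 1e6
  mA <- rowMeans(cpm[, grp == group_A, drop = FALSE])
  mB <- rowMeans(cpm[, grp == group_B, drop = FALSE])
  if (cpm_filter > 0) {
    keep2 <- (mA + mB) / 2 >= cpm_filter
    cnt <- cnt[keep2, , drop = FALSE]
    phi <- phi[keep2]; mA <- mA[keep2]; mB <- mB[keep2]
  }
  p <- nbExactTest(cnt[, grp == group_A, drop = FALSE],
                   cnt[, grp == group_B, drop = FALSE],
                   phi, eff)
  res <- data.frame(gene_id = rownames(cnt),
                    log2fc = log2((mA + prior_count) / (mB + prior_count)),
                    p_value = p, fdr = bhFdr(p),
                    mean_cpm = (mA + mB) / 2,
                    row.names = NULL, stringsAsFactors = FALSE)
  callDE(res, lfc_threshold, fdr_threshold)
}

#' PCA of log2 zero-centred expression profiles
#'
#' Features (genes or proteins) are log2-transformed with an offset and
#' gene-wise mean-centred ("log2 zero-centred"), then samples are projected
#' onto principal components.
#'
#' @param mat features x samples matrix of nonnegative values (e.g.
#'   TMM-FPKM), or an already-log2 matrix with \code{log = FALSE}.
#' @param offset added before log2 (default 1).
#' @param log log-transform first (default TRUE).
#' @return list with \code{coords} (samples x PCs) and \code{var_frac}
#'   (nonincreasing, sums to 1).
#' @export
pcaSummary <- function(mat, offset = 1, log = TRUE) {
  x <- if (log) log2(mat + offset) else mat
  x <- x - rowMeans(x)
  if (all(abs(x) < 1e-12)) stop("zero variance: constant matrix")
  pc <- prcomp(t(x), center = FALSE, scale. = FALSE)
  v <- pc$sdev^2
  list(coords = pc$x, var_frac = v / sum(v))
}

#' @importFrom stats dbinom dnbinom
NULL
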