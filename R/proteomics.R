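## Label-free proteomics: flag filtering, log2 transform, downshift
## imputation of missing-not-at-random values, Welch SSDA testing, signed
## relative fold changes, exclusive-detection calls and proteome summaries.

#' Filter flagged proteins and log2-transform intensities
#'
#' Removes reverse-database hits, potential contaminants and
#' identified-by-site entries, then log2-transforms the remaining present
#' values; missingness (NA) is preserved.
#'
#' @param ie an \linkS4class{IntensityExperiment}.
#' @return list: \code{log2} (matrix with NA for missing), \code{groups},
#'   \code{kept} (retained protein ids).
#' @export
filterAndLog <- function(ie) {
  rd <- SummarizedExperiment::rowData(ie)
  keep <- !(rd$reverse | rd$contaminant | rd$identified_by_site)
  x <- SummarizedExperiment::assay(ie, "intensity")[keep, , drop = FALSE]
  list(log2 = log2(x), groups = sampleGroups(ie), kept = rownames(ie)[keep])
}

#' Downshift imputation of missing values
#'
#' Each missing cell is drawn from a narrowed, left-shifted normal
#' distribution that mimics signals of low-abundance proteins:
#' Normal(mu - downshift * sd, (width * sd)^2), where mu and sd are the mean
#' and standard deviation of the measured values in scope ("global", the
#' default, uses all measured values; "per_sample" recomputes per column).
#' Measured cells are never altered.
#'
#' @param log_matrix log2 intensity matrix with NA for missing.
#' @param downshift shift in SD units (default 2.1).
#' @param width SD of the imputation distribution in SD units (default 0.1).
#' @param scope "global" or "per_sample".
#' @param seed optional seed for reproducible draws.
#' @return completed matrix.
#' @examples
#' m <- matrix(c(20, NA, 24, 26), 2, 2)
#' imputeMissing(m, seed = 1)
#' @export
imputeMissing <- function(log_matrix, downshift = 2.1, width = 0.1,
                          scope = c("global", "per_sample"), seed = NULL) {
  scope <- match.arg(scope)
  stopifnot(width > 0, downshift >= 0)
  out <- log_matrix
  withSeed(seed, {
    if (scope == "global") {
      vals <- log_matrix[!is.na(log_matrix)]
      if (length(vals) < 2) stop("no measured values to anchor imputation")
      mu <- mean(vals); s <- sd(vals)
      miss <- is.na(out)
      out[miss] <- rnorm(sum(miss), mu - downshift * s, width * s)
    } else {
      for (j in seq_len(ncol(out))) {
        vals <- log_matrix[!is.na(log_matrix[, j]), j]
        if (length(vals) < 2)
          stop("no measured values in sample ", j, " to anchor imputation")
        mu <- mean(vals); s <- sd(vals)
        miss <- is.na(out[, j])
        out[miss, j] <- rnorm(sum(miss), mu - downshift * s, width * s)
      }
    }
  })
  out
}

#' Welch two-sample test for differential protein abundance
#'
#' Per protein, a Welch (unequal-variance) t-test on imputed log2
#' intensities; proteins with p <= alpha are flagged SSDA (no
#' multiple-testing correction by default, matching the stated cutoff; BH
#' q-values are computed when \code{adjust = TRUE}). Degenerate variances
#' are guarded: equal constant groups give p = 1, unequal constant groups
#' are reported with \code{exactly_separated = TRUE}.
#'
#' @param log_matrix completed log2 matrix (proteins x samples).
#' @param groups two-level group label per sample.
#' @param alpha SSDA cutoff (default 0.05).
#' @param adjust additionally require BH FDR < alpha.
#' @return data.frame: protein_id, log2fc (first group over second), p_value,
#'   neg_log10_p, higher_in, ssda, exactly_separated (+ fdr if adjusted).
#' @export
ssdaTest <- function(log_matrix, groups, alpha = 0.05, adjust = FALSE) {
  lv <- unique(as.character(groups))
  if (length(lv) != 2) stop("exactly two groups required")
  A <- log_matrix[, groups == lv[1], drop = FALSE]
  B <- log_matrix[, groups == lv[2], drop = FALSE]
  nA <- ncol(A); nB <- ncol(B)
  if (nA < 2 || nB < 2) stop("need >= 2 replicates per group")
  mA <- rowMeans(A); mB <- rowMeans(B)
  vA <- apply(A, 1, var); vB <- apply(B, 1, var)
  se2 <- vA / nA + vB / nB
  tstat <- (mA - mB) / sqrt(se2)
  df <- se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
  p <- 2 * pt(-abs(tstat), df)
  sep <- se2 == 0 & mA != mB
  p[se2 == 0 & mA == mB] <- 1
  p[sep] <- 0
  ids <- rownames(log_matrix)
  if (is.null(ids)) ids <- paste0("row", seq_len(nrow(log_matrix)))
  res <- data.frame(protein_id = ids,
                    log2fc = mA - mB, p_value = p,
                    neg_log10_p = -log10(pmax(p, .Machine$double.xmin)),
                    higher_in = ifelse(mA >= mB, lv[1], lv[2]),
                    ssda = p <= alpha, exactly_separated = sep,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (adjust) {
    res$fdr <- bhFdr(res$p_value)
    res$ssda <- res$ssda & res$fdr < alpha
  }
  res
}

#' Signed relative fold change
#'
#' The ratio of raw-scale group-mean LFQ intensities, signed: A/B when
#' A >= B, otherwise -(B/A); magnitude always >= 1.
#'
#' @param mean_A,mean_B positive group means on the raw (un-logged) scale.
#' @return signed fold change (vectorised).
#' @examples
#' rfc(8, 2)  #  4
#' rfc(2, 8)  # -4
#' @export
rfc <- function(mean_A, mean_B) {
  if (any(mean_A <= 0) || any(mean_B <= 0))
    stop("group means must be positive")
  ifelse(mean_A >= mean_B, mean_A / mean_B, -(mean_B / mean_A))
}

#' SSDA results with relative fold changes
#'
#' Convenience wrapper: Welch SSDA testing plus signed RFC computed from the
#' raw-scale (2^log2) group means of the imputed matrix.
#'
#' @inheritParams ssdaTest
#' @return the \code{\link{ssdaTest}} frame with an \code{rfc} column.
#' @export
ssdaWithRfc <- function(log_matrix, groups, alpha = 0.05, adjust = FALSE) {
  res <- ssdaTest(log_matrix, groups, alpha, adjust)
  lv <- unique(as.character(groups))
  mA <- rowMeans(2^log_matrix[, groups == lv[1], drop = FALSE])
  mB <- rowMeans(2^log_matrix[, groups == lv[2], drop = FALSE])
  res$rfc <- rfc(mA, mB)
  res
}

#' Exclusive proteins per genotype
#'
#' A protein is exclusive to a genotype iff it is detected (present before
#' imputation) in all replicates of that genotype and in none of the other.
#'
#' @param ie an \linkS4class{IntensityExperiment} (pre-imputation), or a
#'   raw matrix with NA for missing plus \code{groups}.
#' @param groups group labels when \code{ie} is a plain matrix.
#' @return named list of protein id vectors, one per group (disjoint).
#' @export
exclusiveProteins <- function(ie, groups = NULL) {
  if (is(ie, "IntensityExperiment")) {
    groups <- sampleGroups(ie)
    ie <- SummarizedExperiment::assay(ie, "intensity")
  }
  det <- !is.na(ie)
  lv <- unique(as.character(groups))
  stopifnot(length(lv) == 2)
  out <- list()
  for (i in 1:2) {
    own <- det[, groups == lv[i], drop = FALSE]
    oth <- det[, groups == lv[3 - i], drop = FALSE]
    out[[lv[i]]] <- rownames(ie)[rowSums(own) == ncol(own) &
                                   rowSums(oth) == 0]
  }
  out
}

#' Venn summary of two detected proteomes
#'
#' Counts and integer percentages (half away from zero) of shared and
#' unique proteins; the shared fraction is reported under three
#' denominators (union, |A| and |B|). Optional annotations add secreted and
#' non-annotated percentages per proteome.
#'
#' @param detected_A,detected_B character id sets.
#' @param annotations optional annotation data.frame (see
#'   \code{\link{annotationFractions}}).
#' @param names_AB labels for the two sets.
#' @return list of counts and percentages.
#' @export
proteomeSummary <- function(detected_A, detected_B, annotations = NULL,
                            names_AB = c("A", "B")) {
  detected_A <- unique(detected_A); detected_B <- unique(detected_B)
  shared <- intersect(detected_A, detected_B)
  uA <- setdiff(detected_A, detected_B)
  uB <- setdiff(detected_B, detected_A)
  out <- list(
    n_A = length(detected_A), n_B = length(detected_B),
    n_shared = length(shared),
    n_unique_A = length(uA), n_unique_B = length(uB),
    pct_unique_A = roundHalfUp(100 * length(uA) /
                                 max(1, length(detected_A))),
    pct_unique_B = roundHalfUp(100 * length(uB) /
                                 max(1, length(detected_B))),
    pct_shared_union = roundHalfUp(100 * length(shared) /
                                     max(1, length(union(detected_A,
                                                         detected_B)))),
    pct_shared_of_A = roundHalfUp(100 * length(shared) /
                                    max(1, length(detected_A))),
    pct_shared_of_B = roundHalfUp(100 * length(shared) /
                                    max(1, length(detected_B))))
  names(out) <- sub("_A$", paste0("_", names_AB[1]),
                    sub("_B$", paste0("_", names_AB[2]), names(out)))
  if (!is.null(annotations)) {
    out$annotation_A <- annotationFractions(detected_A, annotations)
    out$annotation_B <- annotationFractions(detected_B, annotations)
  }
  out
}
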