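## Virulence phenotyping: index, classification, confirmation screen,
## cross-host correlation and bulk selection.

#' Virulence index
#'
#' \code{log2(mean_survivors * nymphs + 1)}, where \code{mean_survivors} is
#' the mean number of aphids (out of 5) surviving per plant and
#' \code{nymphs} the mean number of nymphs produced per plant. Zero when
#' nothing survives or nothing reproduces; monotone nondecreasing in both
#' arguments.
#'
#' @param mean_survivors mean survivors per plant, in [0, 5].
#' @param nymphs mean nymphs per plant, >= 0.
#' @return nonnegative virulence index (vectorised).
#' @examples
#' virulenceIndex(5, 10)   # log2(51)
#' virulenceIndex(0, 100)  # 0
#' @export
virulenceIndex <- function(mean_survivors, nymphs) {
  if (any(mean_survivors < 0) || any(nymphs < 0))
    stop("mean_survivors and nymphs must be nonnegative")
  if (any(mean_survivors > 5))
    stop("mean_survivors cannot exceed 5")
  log2(mean_survivors * nymphs + 1)
}

#' Classify a clone as VIR, AVR or unclassified
#'
#' Strict-inequality cutoffs on two resistant hosts: VIR iff index > 4 on
#' A17 and > 5 on RNIL; AVR iff index < 2 on A17 and < 4.5 on RNIL (RNIL
#' resistance is slightly weaker, hence the higher AVR cutoff); anything
#' else, including boundary values, is unclassified.
#'
#' @param vi_A17,vi_RNIL virulence indices on the two hosts (vectorised).
#' @param vir_cut,avr_cut length-2 cutoffs c(A17, RNIL).
#' @return character vector in {"VIR", "AVR", "unclassified"}.
#' @export
classifyClone <- function(vi_A17, vi_RNIL,
                          vir_cut = c(A17 = 4, RNIL = 5),
                          avr_cut = c(A17 = 2, RNIL = 4.5)) {
  stopifnot(all(is.finite(vi_A17)), all(is.finite(vi_RNIL)))
  out <- rep("unclassified", length(vi_A17))
  out[vi_A17 > vir_cut[1] & vi_RNIL > vir_cut[2]] <- "VIR"
  out[vi_A17 < avr_cut[1] & vi_RNIL < avr_cut[2]] <- "AVR"
  out
}

#' Day-5 confirmation screen
#'
#' Virulence is confirmed when survival exceeds 80\% on both resistant
#' hosts; avirulence when survival is below 20\% on A17 and below 70\% on
#' RNIL, or when the override flag marks a weak-growth clone as AVR.
#'
#' @param surv_A17,surv_RNIL survival fractions in [0, 1] (vectorised).
#' @param candidate_class "VIR" or "AVR" per clone.
#' @param override_avr logical; force-confirm an AVR candidate with high
#'   survival but very weak growth.
#' @return logical: confirmed.
#' @export
confirmationScreen <- function(surv_A17, surv_RNIL, candidate_class,
                               override_avr = FALSE) {
  if (any(surv_A17 < 0 | surv_A17 > 1 | surv_RNIL < 0 | surv_RNIL > 1))
    stop("survival fractions must lie in [0, 1]")
  if (any(!candidate_class %in% c("VIR", "AVR")))
    stop("confirmation screen applies only to VIR or AVR candidates")
  n <- max(length(surv_A17), length(candidate_class))
  override_avr <- rep_len(override_avr, n)
  ifelse(candidate_class == "VIR",
         surv_A17 > 0.8 & surv_RNIL > 0.8,
         (surv_A17 < 0.2 & surv_RNIL < 0.7) | override_avr)
}

#' Pearson correlation of virulence indices across hosts
#'
#' @param vi_A17,vi_RNIL paired indices (>= 3 pairs, nonzero variance).
#' @return list with \code{r} and two-sided \code{p} from the t transform
#'   with n - 2 degrees of freedom.
#' @export
hostCorrelation <- function(vi_A17, vi_RNIL) {
  if (length(vi_A17) < 3 || length(vi_A17) != length(vi_RNIL))
    stop("need >= 3 complete pairs")
  if (sd(vi_A17) == 0 || sd(vi_RNIL) == 0)
    stop("zero variance in one coordinate")
  ct <- cor.test(vi_A17, vi_RNIL, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Compute per-clone virulence calls from phenotype records
#'
#' Aggregates plant-level day-10 records per clone x host (mean survivors
#' and mean nymphs per plant, the default; \code{nymphs = "total"} uses the
#' clone total instead), computes indices on A17 and RNIL, classifies, and
#' applies the day-5 confirmation screen if confirmation records are given
#' (survival fraction = total alive / total infested).
#'
#' @param pheno day-10 phenotype data.frame (clone_id, host, plant,
#'   survivors, nymphs).
#' @param confirm optional day-5 data.frame in the same schema.
#' @param n_aphids aphids infested per plant (denominator of survival).
#' @param nymphs "mean" (default) or "total" nymphs per clone.
#' @param override_avr clone ids force-confirmed as AVR (weak growth).
#' @param ... cutoffs passed to \code{\link{classifyClone}}.
#' @return data.frame: clone_id, vi_A17, vi_RNIL, class, confirmed.
#' @export
virulenceCalls <- function(pheno, confirm = NULL, n_aphids = 5,
                           nymphs = c("mean", "total"),
                           override_avr = character(), ...) {
  nymphs <- match.arg(nymphs)
  agg <- aggregate(cbind(survivors, nymphs) ~ clone_id + host, data = pheno,
                   FUN = mean)
  if (nymphs == "total") {
    tot <- aggregate(nymphs ~ clone_id + host, data = pheno, FUN = sum)
    agg$nymphs <- tot$nymphs[match(paste(agg$clone_id, agg$host),
                                   paste(tot$clone_id, tot$host))]
  }
  agg$vi <- virulenceIndex(agg$survivors, agg$nymphs)
  wide <- function(h) {
    i <- agg$host == h
    setNames(agg$vi[i], agg$clone_id[i])
  }
  a17 <- wide("A17"); rnil <- wide("RNIL")
  ids <- intersect(names(a17), names(rnil))
  cls <- classifyClone(a17[ids], rnil[ids], ...)
  confirmed <- rep(NA, length(ids))
  if (!is.null(confirm)) {
    frac <- function(h) {
      i <- confirm$host == h
      tot <- tapply(confirm$survivors[i], confirm$clone_id[i], sum)
      den <- tapply(rep(n_aphids, sum(i)), confirm$clone_id[i], sum)
      (tot / den)[ids]
    }
    fa <- frac("A17"); fr <- frac("RNIL")
    cand <- cls %in% c("VIR", "AVR")
    confirmed <- rep(FALSE, length(ids))
    confirmed[cand] <- confirmationScreen(fa[cand], fr[cand], cls[cand],
                                          ids[cand] %in% override_avr)
  }
  data.frame(clone_id = ids, vi_A17 = unname(a17[ids]),
             vi_RNIL = unname(rnil[ids]), class = cls,
             confirmed = confirmed, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Select the two phenotypic bulks
#'
#' The k confirmed VIR clones with the highest A17 index and the k confirmed
#' AVR clones with the lowest; ties broken by the RNIL index (same
#' direction) and then clone id, so bulks are reproducible.
#'
#' @param calls data.frame from \code{\link{virulenceCalls}} (needs
#'   clone_id, vi_A17, vi_RNIL, class, confirmed).
#' @param k bulk size (22 in the study design).
#' @return list with character vectors \code{vir_bulk} and \code{avr_bulk}.
#' @export
selectBulks <- function(calls, k = 22) {
  conf <- calls[!is.na(calls$confirmed) & calls$confirmed, ]
  pickSide <- function(side, decreasing) {
    cc <- conf[conf$class == side, ]
    if (nrow(cc) < k)
      stop("selection error: only ", nrow(cc), " confirmed ", side,
           " clones for a bulk of ", k, " (shortfall ", k - nrow(cc), ")")
    s <- 1 - 2 * decreasing
    cc <- cc[order(s * cc$vi_A17, s * cc$vi_RNIL, cc$clone_id), ]
    cc$clone_id[seq_len(k)]
  }
  list(vir_bulk = pickSide("VIR", TRUE), avr_bulk = pickSide("AVR", FALSE))
}
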