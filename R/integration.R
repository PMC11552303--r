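## Multi-dataset evidence integration: the gene x dataset evidence matrix,
## the multi-dataset candidate filter, direction conflicts, corroboration
## and annotation statistics, and category enrichment.

DATASETS <- c("saliva", "salivary_gland", "parent_head", "parent_body",
              "F1_body")

mapIds <- function(ids, id_map) {
  if (is.null(id_map)) return(list(mapped = ids, unmapped = character()))
  m <- id_map[ids]
  list(mapped = unname(m[!is.na(m)]), unmapped = ids[is.na(m)])
}

#' Build the gene x dataset evidence matrix
#'
#' Combines directed differential calls (up in VIR or up in AVR) and
#' undirected presence (e.g. detection in saliva without differential
#' abundance) into one matrix over a unified id namespace. Directed calls
#' take precedence over presence; an id listed as up in both directions
#' within one dataset is a data-integrity error; ids with no evidence
#' anywhere are excluded; unmapped ids are reported, never silently dropped.
#'
#' @param directed named list (per dataset) of lists with elements
#'   \code{up_VIR} and \code{up_AVR}, each a character id vector.
#' @param presence named list (per dataset) of character id vectors.
#' @param id_map optional named character vector, raw id -> unified id.
#' @param datasets column order (default: the five study datasets).
#' @return an \linkS4class{EvidenceMatrix}.
#' @export
buildEvidence <- function(directed = list(), presence = list(),
                          id_map = NULL, datasets = DATASETS) {
  unmapped <- character()
  take <- function(ids) {
    r <- mapIds(unique(ids), id_map)
    unmapped <<- union(unmapped, r$unmapped)
    r$mapped
  }
  directed <- lapply(directed, function(d) lapply(d, take))
  presence <- lapply(presence, take)
  all_ids <- sort(unique(c(unlist(directed), unlist(presence))))
  calls <- matrix("absent", length(all_ids), length(datasets),
                  dimnames = list(all_ids, datasets))
  for (ds in names(presence))
    calls[presence[[ds]], ds] <- "present"
  for (ds in names(directed)) {
    up_v <- directed[[ds]]$up_VIR; up_a <- directed[[ds]]$up_AVR
    clash <- intersect(up_v, up_a)
    if (length(clash))
      stop("data-integrity error: contradictory calls in ", ds, " for ",
           paste(clash, collapse = ", "))
    calls[up_v, ds] <- "up_VIR"
    calls[up_a, ds] <- "up_AVR"
  }
  keep <- rowSums(calls != "absent") > 0
  new("EvidenceMatrix", calls = calls[keep, , drop = FALSE],
      unmapped = unmapped)
}

#' Multi-dataset candidate filter
#'
#' A gene/protein is a candidate iff it is represented (non-absent) in at
#' least three datasets, or represented in the F1 whole-body transcriptome
#' plus at least one other dataset. Its side is VIR when every directed cell
#' is up_VIR, AVR when every directed cell is up_AVR, conflict when
#' directions disagree, and undirected when only presence supports it.
#'
#' @param em an \linkS4class{EvidenceMatrix}.
#' @param f1_dataset column holding the F1 contrast (default "F1_body").
#' @param min_datasets representation threshold (default 3).
#' @return data.frame: id, side, n_datasets, rule (three_plus, f1_plus_one
#'   or both), plus one Y/"" column per dataset.
#' @export
table1Filter <- function(em, f1_dataset = "F1_body", min_datasets = 3) {
  calls <- evidenceCalls(em)
  rep_n <- rowSums(calls != "absent")
  in_f1 <- calls[, f1_dataset] != "absent"
  r3 <- rep_n >= min_datasets
  rf1 <- in_f1 & rep_n >= 2
  keep <- r3 | rf1
  side <- apply(calls[keep, , drop = FALSE], 1, function(row) {
    d <- row[row %in% c("up_VIR", "up_AVR")]
    if (!length(d)) "undirected"
    else if (all(d == "up_VIR")) "VIR"
    else if (all(d == "up_AVR")) "AVR"
    else "conflict"
  })
  rule <- ifelse(r3[keep] & rf1[keep], "both",
                 ifelse(r3[keep], "three_plus", "f1_plus_one"))
  out <- data.frame(id = rownames(calls)[keep], side = side,
                    n_datasets = rep_n[keep], rule = rule,
                    row.names = NULL, stringsAsFactors = FALSE)
  ycells <- ifelse(calls[keep, , drop = FALSE] != "absent", "Y", "")
  cbind(out, as.data.frame(ycells, stringsAsFactors = FALSE,
                           row.names = NULL))
}

#' Parent vs F1 direction conflicts
#'
#' Genes whose parent whole-body and F1 whole-body directed calls oppose,
#' labelled by pattern (VIRparent/AVRF1 or AVRparent/VIRF1). Undirected
#' presence never creates a conflict.
#'
#' @param em an \linkS4class{EvidenceMatrix}.
#' @param parent_dataset,f1_dataset the two columns compared.
#' @return data.frame: id, pattern.
#' @export
directionConflicts <- function(em, parent_dataset = "parent_body",
                               f1_dataset = "F1_body") {
  calls <- evidenceCalls(em)
  pb <- calls[, parent_dataset]; f1 <- calls[, f1_dataset]
  c1 <- pb == "up_VIR" & f1 == "up_AVR"
  c2 <- pb == "up_AVR" & f1 == "up_VIR"
  data.frame(id = rownames(calls)[c1 | c2],
             pattern = ifelse(c1[c1 | c2], "VIRparent/AVRF1",
                              "AVRparent/VIRF1"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Corroboration rate of a focal directed set
#'
#' The fraction of a focal set's members that carry a directed call in at
#' least one other dataset.
#'
#' @param focal_set character ids (nonempty).
#' @param other_sets list of directed id vectors from other datasets.
#' @return list: k (corroborated), n, percent (integer, half away from
#'   zero).
#' @examples
#' corroborationRate(letters[1:4], list(letters[1:3]))  # 3/4 = 75%
#' @export
corroborationRate <- function(focal_set, other_sets) {
  focal_set <- unique(focal_set)
  if (!length(focal_set)) stop("focal set is empty")
  other <- unique(unlist(other_sets))
  k <- sum(focal_set %in% other)
  list(k = k, n = length(focal_set),
       percent = roundHalfUp(100 * k / length(focal_set)))
}

# Descriptor rule for "no annotation": hypothetical/uncharacterized
# proteins, NA descriptors, or a bare ACYPIxxxxxx accession with no other
# assigned function.
isNonAnnotated <- function(description) {
  d <- trimws(as.character(description))
  is.na(d) | d == "" | d == "NA" | grepl("^-*NA-*$", d) |
    grepl("hypothetical protein", d, ignore.case = TRUE) |
    grepl("uncharacterized protein", d, ignore.case = TRUE) |
    grepl("^ACYPI[0-9]+$", d)
}

#' Secreted and non-annotated fractions of an id set
#'
#' @param ids character ids; every id must appear in \code{annotations}.
#' @param annotations data.frame with columns \code{id},
#'   \code{description} and logical \code{secreted}.
#' @return list: n, n_secreted, pct_secreted, n_non_annotated,
#'   pct_non_annotated (integer percentages, half away from zero).
#' @export
annotationFractions <- function(ids, annotations) {
  ids <- unique(ids)
  i <- match(ids, annotations$id)
  if (anyNA(i))
    stop("lookup error: unannotated ids: ",
         paste(ids[is.na(i)], collapse = ", "))
  sec <- sum(annotations$secreted[i])
  nan <- sum(isNonAnnotated(annotations$description[i]))
  n <- length(ids)
  list(n = n, n_secreted = sec,
       pct_secreted = roundHalfUp(100 * sec / max(1, n)),
       n_non_annotated = nan,
       pct_non_annotated = roundHalfUp(100 * nan / max(1, n)))
}

# Wallenius noncentral hypergeometric upper tail via the standard integral
# representation of the pmf; odds = 1 reduces to the central case.
walleniusTail <- function(k, K, N, n, odds) {
  kmin <- max(0, n - (N - K)); kmax <- min(n, K)
  pmf <- vapply(kmin:kmax, function(x) {
    d <- odds * (K - x) + (N - K - (n - x))
    if (d <= 0) return(0)
    f <- function(t) (1 - t^(odds / d))^x * (1 - t^(1 / d))^(n - x)
    it <- integrate(f, 0, 1, rel.tol = 1e-8, subdivisions = 500L,
                    stop.on.error = FALSE)
    exp(lchoose(K, x) + lchoose(N - K, n - x)) * it$value
  }, numeric(1))
  pmf <- pmf / sum(pmf)
  sum(pmf[(kmin:kmax) >= k])
}

#' Category (term) over-representation test
#'
#' One-sided hypergeometric over-representation p per term, with an
#' optional Wallenius noncentral variant when per-gene bias weights are
#' supplied (a single odds ratio per term: mean weight inside the term over
#' mean weight outside, approximating length-bias correction). Strict mode
#' keeps terms with BH FDR < 0.05; lenient mode keeps terms with at least
#' two set members and p < 0.05.
#'
#' @param de_set character ids (must be a subset of \code{universe}).
#' @param universe all testable ids.
#' @param categories named list: term -> id vector.
#' @param mode "strict" or "lenient".
#' @param bias_weights optional named numeric per-gene weights.
#' @param alpha significance cutoff (default 0.05).
#' @return data.frame: term, n_term, n_de_in_term, p_value, fdr, enriched.
#' @export
categoryEnrichment <- function(de_set, universe, categories,
                               mode = c("strict", "lenient"),
                               bias_weights = NULL, alpha = 0.05) {
  mode <- match.arg(mode)
  de_set <- unique(de_set); universe <- unique(universe)
  if (!all(de_set %in% universe))
    stop("de_set must be a subset of the universe")
  N <- length(universe); n <- length(de_set)
  rows <- lapply(names(categories), function(term) {
    tg <- intersect(categories[[term]], universe)
    if (!length(tg)) {
      warning("term '", term, "' has no overlap with the universe; skipped")
      return(NULL)
    }
    K <- length(tg); k <- sum(de_set %in% tg)
    p <- if (is.null(bias_weights)) {
      phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    } else {
      w_in <- mean(bias_weights[tg], na.rm = TRUE)
      w_out <- mean(bias_weights[setdiff(universe, tg)], na.rm = TRUE)
      walleniusTail(k, K, N, n, w_in / w_out)
    }
    data.frame(term = term, n_term = K, n_de_in_term = k, p_value = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) return(NULL)
  res$fdr <- bhFdr(res$p_value)
  res$enriched <- if (mode == "strict") res$fdr < alpha
                  else res$n_de_in_term >= 2 & res$p_value < alpha
  res[order(res$p_value), ]
}
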