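toyEvidence <- function() {
  buildEvidence(
    directed = list(
      saliva = list(up_VIR = c("g1"), up_AVR = c("g2")),
      salivary_gland = list(up_VIR = c("g1", "g6"), up_AVR = c("g2")),
      parent_head = list(up_VIR = character(), up_AVR = c("g2")),
      parent_body = list(up_VIR = c("g3", "g6"), up_AVR = c("g4")),
      F1_body = list(up_VIR = c("g4", "g5"), up_AVR = c("g6"))),
    presence = list(saliva = c("g1", "g5", "g7"),
                    salivary_gland = c("g1", "g2", "g7")))
}

test_that("evidence matrix construction: precedence, conflicts, mapping", {
  em <- toyEvidence()
  calls <- evidenceCalls(em)
  # directed calls take precedence over undirected presence
  expect_identical(unname(calls["g1", "saliva"]), "up_VIR")
  expect_identical(unname(calls["g5", "saliva"]), "present")
  expect_identical(unname(calls["g3", "parent_body"]), "up_VIR")
  expect_identical(unname(calls["g3", "saliva"]), "absent")
  # three concordant up_AVR cells on a toy protein
  expect_identical(unname(calls["g2", c("saliva", "salivary_gland",
                                        "parent_head")]),
                   rep("up_AVR", 3))
  # every retained row has evidence somewhere
  expect_true(all(rowSums(calls != "absent") > 0))

  expect_error(buildEvidence(directed = list(
    saliva = list(up_VIR = "a", up_AVR = "a"))), "data-integrity")

  # explicit id map: unmapped ids are reported, mapped ones unified
  em2 <- buildEvidence(
    directed = list(parent_body = list(up_VIR = c("x1", "x9"),
                                       up_AVR = character())),
    id_map = c(x1 = "g1"))
  expect_identical(rownames(evidenceCalls(em2)), "g1")
  expect_identical(unmappedIds(em2), "x9")
})

test_that("candidate filter implements the 3+ and F1+1 rules", {
  em <- toyEvidence()
  cand <- table1Filter(em)
  # g1: saliva + gland directed + presence -> 2 datasets only, no F1: out
  expect_false("g1" %in% cand$id)
  # g2: 3 concordant datasets, no F1 -> in via three_plus, side AVR
  expect_identical(cand$rule[cand$id == "g2"], "three_plus")
  expect_identical(cand$side[cand$id == "g2"], "AVR")
  # g5: F1 + saliva presence (2 datasets) -> f1_plus_one
  expect_identical(cand$rule[cand$id == "g5"], "f1_plus_one")
  expect_identical(cand$side[cand$id == "g5"], "VIR")
  # g3: parent_body only -> excluded
  expect_false("g3" %in% cand$id)
  # g6: gland up_VIR, body up_VIR, F1 up_AVR -> candidate but conflicted
  expect_identical(cand$side[cand$id == "g6"], "conflict")
  # VIR and AVR side tables are disjoint and exclude conflicts
  expect_length(intersect(cand$id[cand$side == "VIR"],
                          cand$id[cand$side == "AVR"]), 0)

  # monotonicity: adding a non-absent cell never removes a candidate
  em2 <- toyEvidence()
  em2@calls["g3", "saliva"] <- "present"
  em2@calls["g3", "F1_body"] <- "up_VIR"
  em2@calls["g1", "F1_body"] <- "up_VIR"
  cand2 <- table1Filter(em2)
  expect_true(all(cand$id %in% cand2$id))
  expect_true(all(c("g1", "g3") %in% cand2$id))
})

test_that("direction conflicts between parent and F1 whole-body calls", {
  em <- toyEvidence()
  cf <- directionConflicts(em)
  expect_setequal(cf$id, c("g4", "g6"))
  expect_identical(cf$pattern[cf$id == "g4"], "AVRparent/VIRF1")
  expect_identical(cf$pattern[cf$id == "g6"], "VIRparent/AVRF1")
  # undirected presence never creates a conflict
  expect_false("g5" %in% cf$id)
})

test_that("corroboration rate counts directed support elsewhere", {
  r <- corroborationRate(paste0("p", 1:24),
                         list(paste0("p", 1:10), paste0("p", 8:18)))
  expect_equal(r$k, 18)
  expect_equal(r$percent, 75)
  expect_equal(corroborationRate(c("a", "b"), list("z"))$percent, 0)
  expect_equal(corroborationRate(c("a", "b", "c", "d"),
                                 list(c("a", "b", "c")))$percent, 75)
  expect_error(corroborationRate(character(), list("a")), "empty")
})

test_that("annotation fractions follow the non-annotated descriptor rule", {
  ann <- data.frame(
    id = paste0("q", 1:136),
    description = c(rep("aminopeptidase N", 109),
                    rep("hypothetical protein X1", 10),
                    rep("uncharacterized protein LOC1", 10),
                    rep("--NA--", 5), "ACYPI007553", "NA"),
    secreted = c(rep(TRUE, 60), rep(FALSE, 76)),
    stringsAsFactors = FALSE)
  f <- annotationFractions(ann$id, ann)
  expect_equal(f$n_secreted, 60)
  expect_equal(f$pct_secreted, 44)     # 60/136
  expect_equal(f$n_non_annotated, 27)
  expect_equal(f$pct_non_annotated, 20)  # 27/136
  expect_equal(annotationFractions("q100", ann)$pct_secreted, 0)
  expect_error(annotationFractions("nope", ann), "lookup")
  # a named accession with a real function is annotated
  expect_false(coseg:::isNonAnnotated("aldo-keto reductase"))
  expect_true(coseg:::isNonAnnotated("ACYPI012345"))
})

test_that("hypergeometric enrichment matches brute-force enumeration", {
  # the fully-overlapping term: p = 1 / C(20, 5)
  uni <- paste0("u", 1:20)
  res <- categoryEnrichment(uni[1:5], uni, list(T1 = uni[1:5]))
  expect_equal(res$p_value, 1 / choose(20, 5), tolerance = 1e-12)

  # random spot grid over small universes against the enumeration oracle
  set.seed(11)
  for (N in c(6, 12, 25)) {
    uni <- paste0("g", 1:N)
    for (rep in 1:10) {
      K <- sample(N, 1); n <- sample(N, 1)
      term <- sample(uni, K); de <- sample(uni, n)
      got <- categoryEnrichment(de, uni, list(t = term))$p_value
      expect_equal(got, hyperOracle(sum(de %in% term), K, N, n),
                   tolerance = 1e-12)
    }
  }

  # chance-level overlap is not significant on average
  set.seed(12)
  uni <- paste0("g", 1:200)
  ps <- replicate(30, categoryEnrichment(
    sample(uni, 40), uni, list(t = sample(uni, 30)))$p_value)
  expect_gt(mean(ps), 0.3)

  # lenient mode requires >= 2 genes regardless of p
  uni <- paste0("g", 1:50)
  one <- categoryEnrichment("g1", uni, list(t = "g1"), mode = "lenient")
  expect_lt(one$p_value, 0.05)
  expect_false(one$enriched)

  # Wallenius with odds 1 reduces to the central distribution
  expect_equal(coseg:::walleniusTail(3, 10, 30, 8, 1),
               hyperOracle(3, 10, 30, 8), tolerance = 1e-6)
  # enrichment weights shift the tail in the expected direction
  w <- setNames(rep(1, 50), uni); w[1:10] <- 3
  biased <- categoryEnrichment(uni[1:8], uni, list(t = uni[1:10]),
                               bias_weights = w)
  plain <- categoryEnrichment(uni[1:8], uni, list(t = uni[1:10]))
  expect_gt(biased$p_value, plain$p_value)

  expect_warning(categoryEnrichment("g1", uni, list(empty = "zzz")),
                 "no overlap")
  expect_error(categoryEnrichment("zz", uni, list(t = uni[1:3])), "subset")
})
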