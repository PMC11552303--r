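test_that("TMM factors: symmetry, depth invariance, edgeR agreement", {
  set.seed(101)
  m <- matrix(rnbinom(1000 * 4, mu = 50, size = 5), 1000, 4)
  colnames(m) <- paste0("s", 1:4)

  # identical samples: all factors 1
  same <- cbind(s1 = m[, 1], s2 = m[, 1], s3 = m[, 1])
  expect_equal(unname(tmmFactors(same)), rep(1, 3))

  # a pure depth difference carries no composition bias
  depth <- cbind(a = m[, 1], b = 2L * m[, 1])
  f <- tmmFactors(depth)
  expect_equal(unname(f), c(1, 1), tolerance = 1e-8)

  # uniform depth rescaling of one library leaves factors (nearly) unchanged
  f0 <- tmmFactors(m)
  m2 <- m; m2[, 2] <- m2[, 2] * 3L
  expect_equal(unname(tmmFactors(m2)), unname(f0), tolerance = 5e-3)

  # independent implementation: edgeR's TMM on the same data
  skip_if_not_installed("edgeR")
  dge <- edgeR::calcNormFactors(edgeR::DGEList(counts = m), method = "TMM")
  expect_equal(unname(tmmFactors(m)),
               unname(dge$samples$norm.factors), tolerance = 1e-6)

  # composition-biased library, brute-force trimmed weighted mean oracle
  set.seed(7)
  b <- matrix(rnbinom(500 * 3, mu = 100, size = 10), 500, 3)
  b[1:50, 3] <- b[1:50, 3] * 20L
  lib <- colSums(b)
  yr <- b[, 1]; yi <- b[, 3]
  keep <- yr > 0 & yi > 0
  M <- log2((yi[keep] / lib[3]) / (yr[keep] / lib[1]))
  A <- 0.5 * log2((yi[keep] / lib[3]) * (yr[keep] / lib[1]))
  v <- (lib[3] - yi[keep]) / (lib[3] * yi[keep]) +
    (lib[1] - yr[keep]) / (lib[1] * yr[keep])
  n <- length(M)
  kp <- rank(M) >= floor(n * .3) + 1 & rank(M) <= n - floor(n * .3) &
    rank(A) >= floor(n * .05) + 1 & rank(A) <= n - floor(n * .05)
  raw3 <- 2^(sum(M[kp] / v[kp]) / sum(1 / v[kp]))
  f3 <- tmmFactors(b, ref_sample = 1)
  # the oracle is the unrescaled factor; compare after the same rescale
  raw1 <- 1
  yi2 <- b[, 2]
  keep2 <- yr > 0 & yi2 > 0
  M2 <- log2((yi2[keep2] / lib[2]) / (yr[keep2] / lib[1]))
  A2 <- 0.5 * log2((yi2[keep2] / lib[2]) * (yr[keep2] / lib[1]))
  v2 <- (lib[2] - yi2[keep2]) / (lib[2] * yi2[keep2]) +
    (lib[1] - yr[keep2]) / (lib[1] * yr[keep2])
  n2 <- length(M2)
  kp2 <- rank(M2) >= floor(n2 * .3) + 1 & rank(M2) <= n2 - floor(n2 * .3) &
    rank(A2) >= floor(n2 * .05) + 1 & rank(A2) <= n2 - floor(n2 * .05)
  raw2 <- 2^(sum(M2[kp2] / v2[kp2]) / sum(1 / v2[kp2]))
  raws <- c(raw1, raw2, raw3)
  expect_equal(unname(f3), raws / exp(mean(log(raws))), tolerance = 1e-10)

  expect_error(tmmFactors(cbind(m[, 1], 0L)), "degenerate")
})

test_that("TMM-FPKM follows the count-length-depth formula", {
  m <- matrix(c(100L, 0L), 2, 1, dimnames = list(c("g1", "g2"), "s"))
  f <- tmmFpkm(m, lengths = c(1000, 1000), factors = c(s = 1),
               lib_sizes = 1e7)
  expect_equal(unname(f["g1", ]), 10)
  expect_equal(unname(f["g2", ]), 0)
  # doubling a gene's length halves its FPKM
  f2 <- tmmFpkm(m, lengths = c(2000, 1000), factors = c(s = 1),
                lib_sizes = 1e7)
  expect_equal(unname(f2["g1", ]), 5)
})

test_that("dispersion estimation: Poisson null, NB recovery, constants", {
  set.seed(21)
  pois <- matrix(rpois(2000 * 5, lambda = 100), 2000, 5)
  phi <- estimateDispersion(pois, groups = rep("a", 5))
  expect_lt(median(phi), 0.02)

  nb <- matrix(rnbinom(2000 * 10, mu = 100, size = 10), 2000, 10)
  phi2 <- estimateDispersion(nb, groups = rep(c("a", "b"), each = 5))
  expect_gt(median(phi2), 0.05)
  expect_lt(median(phi2), 0.2)

  const <- matrix(rep(c(5L, 50L), each = 4), 2, 4, byrow = TRUE)
  phi3 <- estimateDispersion(const, groups = rep("a", 4),
                             factors = rep(1, 4))
  expect_equal(unname(phi3), c(0, 0))

  expect_error(estimateDispersion(nb[, 1:2], groups = c("a", "b")),
               "no replication")
})

test_that("exact test equals the conditional binomial oracle at phi = 0", {
  # every split of every total <= 50, equal and unequal group sizes
  for (sizes in list(c(3, 3), c(2, 3))) {
    nA <- sizes[1]; nB <- sizes[2]
    for (t in c(0:15, 30, 50)) {
      for (a in 0:t) {
        got <- coseg:::exactTestPvalue(a, t - a, nA, nB, 0)
        want <- binomConditionalOracle(a, t - a, nA, nB)
        expect_equal(got, want, tolerance = 1e-10)
      }
    }
  }
})

test_that("exact test symmetry, mode and monotonicity properties", {
  # observed split at the mode gives p = 1
  expect_equal(coseg:::exactTestPvalue(20, 20, 4, 4, 0.1), 1)
  expect_equal(coseg:::exactTestPvalue(0, 0, 3, 3, 0.2), 1)

  # symmetry in the two groups
  for (phi in c(0, 0.1, 0.5)) {
    expect_equal(coseg:::exactTestPvalue(7, 19, 3, 4, phi),
                 coseg:::exactTestPvalue(19, 7, 4, 3, phi))
  }

  # p nonincreasing as the split gets more extreme at fixed total
  t <- 40
  p <- vapply(20:40, function(a)
    coseg:::exactTestPvalue(a, t - a, 5, 5, 0.1), numeric(1))
  expect_true(all(diff(p) <= 1e-12))

  # library-size equalization: scaling one group's depth is corrected
  m <- matrix(rnbinom(200 * 6, mu = 80, size = 10), 200, 6)
  pv1 <- nbExactTest(m[, 1:3], m[, 4:6], phi = 0.1)
  m2 <- m; m2[, 4:6] <- m2[, 4:6] * 4L
  pv2 <- nbExactTest(m2[, 1:3], m2[, 4:6], phi = 0.1,
                     lib_sizes = c(rep(1, 3), rep(4, 3)) * mean(colSums(m)))
  expect_gt(cor(pv1, pv2), 0.95)

  expect_error(nbExactTest(m[, 1:3], m[, 4:6], phi = -1), ">= 0")
})

test_that("BH control and threshold calling", {
  expect_equal(unname(bhFdr(c(0.01, 0.02, 0.03))), c(0.03, 0.03, 0.03))
  expect_equal(bhFdr(0.2), 0.2)
  expect_equal(unname(bhFdr(rep(1, 5))), rep(1, 5))
  expect_error(bhFdr(c(0.5, 1.2)), "\\[0, 1\\]")

  res <- data.frame(log2fc = c(2.5, 2.5, 2.0, -3, -1),
                    fdr = c(0.01, 0.06, 0.01, 0.04, 0.01))
  out <- callDE(res)
  expect_identical(out$call, c("up_A", "ns", "ns", "up_B", "ns"))
})

test_that("deTable recovers simulated effects end to end", {
  cfg <- tinyConfig(seed = 17, n_genes = 500L, n_background_de = 40L,
                    n_linked = 5L, dispersion = 0.05, lib_size_mean = 2e5)
  des <- data.frame(sample_id = paste0("s", 1:10),
                    unit = rep(c("VIRparent", "AVRparent"), each = 5))
  ce <- simulateCounts(des, cfg)
  tab <- deTable(ce, "VIRparent", "AVRparent")
  truth <- groundTruth(ce)
  de_true <- truth$gene_id[truth$class %in% c("background", "linked")]
  hits <- tab$gene_id[tab$call != "ns"]
  expect_gte(length(intersect(hits, de_true)) / length(de_true), 0.8)
  # direction agrees with the simulated allele direction
  up_vir <- truth$gene_id[truth$direction > 0 & truth$class != "null"]
  expect_true(all(tab$log2fc[tab$gene_id %in% up_vir] > 0))
  expect_error(deTable(ce, "VIRparent", "nosuch"), "must be present")
})

test_that("PCA summary: variance conservation and group separation", {
  set.seed(33)
  base <- matrix(rexp(200 * 2, 1 / 50), 200, 2)
  mat <- cbind(base[, 1], base[, 1], base[, 2], base[, 2])
  colnames(mat) <- paste0("s", 1:4)
  pc <- pcaSummary(mat)
  expect_equal(pc$var_frac[1], 1.0, tolerance = 1e-12)
  expect_equal(sum(pc$var_frac), 1.0, tolerance = 1e-9)
  expect_true(all(diff(pc$var_frac) <= 1e-12))

  # simulated parental groups separate on PC1 when the effect dominates
  cfg <- tinyConfig(seed = 19, n_genes = 300L, n_background_de = 60L,
                    n_linked = 5L, dispersion = 0.02)
  des <- data.frame(sample_id = paste0("s", 1:8),
                    unit = rep(c("VIRparent", "AVRparent"), each = 4))
  ce <- simulateCounts(des, cfg)
  fpkm <- tmmFpkm(ce)
  pc2 <- pcaSummary(fpkm)
  side <- pc2$coords[, 1][1:4]; other <- pc2$coords[, 1][5:8]
  expect_true(max(side) < min(other) || min(side) > max(other))

  expect_error(pcaSummary(matrix(1, 3, 3)), "zero variance")
})
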