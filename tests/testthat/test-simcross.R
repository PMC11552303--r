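test_that("cross construction respects Mendelian structure", {
  cfg <- tinyConfig(seed = 11)

  empty <- simulateCross(tinyConfig(n_f1 = 0))
  expect_length(cloneIds(empty), 0)

  pop <- simulateCross(cfg)
  expect_true(all(verifyF1(pop)))
  expect_true(all(cloneGenotypes(pop) %in% c("Vv", "vv")))

  # 1:1 segregation: fraction Vv over 10,000 clones within 3 binomial SEs
  big <- simulateCross(tinyConfig(n_f1 = 10000L, seed = 42))
  frac <- mean(cloneGenotypes(big) == "Vv")
  expect_gt(frac, 0.48)
  expect_lt(frac, 0.52)

  # determinism under a fixed seed
  pop2 <- simulateCross(cfg)
  expect_identical(cloneGenotypes(pop), cloneGenotypes(pop2))
  expect_identical(pop@alleles_a, pop2@alleles_a)
})

test_that("hybrid verification fails selfed or contaminated clones", {
  cfg <- tinyConfig(seed = 3)
  pop <- simulateCross(cfg)

  # selfed VIR parent: both alleles from the VIR parent at every locus
  selfed <- pop
  selfed@alleles_b <- pop@parents$VIR$alleles[
    rep(1, length(cloneIds(pop))), , drop = FALSE]
  expect_false(any(verifyF1(selfed)))

  # a single contaminated locus among several fails the clone
  contam <- pop
  contam@alleles_a[1, 2] <- "alien_allele"
  expect_false(verifyF1(contam)[1])
  expect_true(all(verifyF1(contam)[-1]))
  expect_true(verifyF1(contam, marker_loci = c("M1", "M3", "M4"))[1])

  expect_error(verifyF1(pop, marker_loci = "M99"), "unknown marker")
})

test_that("phenotype simulation obeys dominance and degenerate limits", {
  cfg <- tinyConfig(seed = 5,
                    survival_probs = c(Vv.R = 1, vv.R = 0, Vv.S = 0.9,
                                       vv.S = 0.9),
                    fecundity_mean = c(Vv.R = 10, vv.R = 5, Vv.S = 20,
                                       vv.S = 20))
  pop <- simulateCross(cfg)
  ph <- simulatePhenotypes(pop, cfg, hosts = c(A17 = "R", DZA = "S"))

  gt <- cloneGenotypes(pop)
  vv_R <- ph[ph$host == "A17" & gt[ph$clone_id] == "vv", ]
  expect_true(all(vv_R$survivors == 0))
  expect_true(all(vv_R$nymphs == 0))   # dead clones cannot reproduce

  Vv_R <- ph[ph$host == "A17" & gt[ph$clone_id] == "Vv", ]
  expect_true(all(Vv_R$survivors == 5))  # degenerate binomial p = 1

  # on susceptible hosts every genotype uses the virulent parameters
  onS <- ph[ph$host == "DZA", ]
  agg <- aggregate(cbind(survivors, nymphs) ~ clone_id, onS, mean)
  vi <- virulenceIndex(agg$survivors, agg$nymphs)
  side <- gt[agg$clone_id]
  expect_lt(abs(mean(vi[side == "Vv"]) - mean(vi[side == "vv"])), 1.0)

  bad <- tinyConfig(survival_probs = c(Vv.R = 1, vv.R = 0))
  expect_error(simulatePhenotypes(pop, bad, hosts = c(DZA = "S")),
               "missing survival")
})

test_that("count simulation matches its expectation algebra", {
  # Poisson limit: with phi = 0, per-gene variance ~ mean over replicates
  cfg <- tinyConfig(seed = 9, dispersion = 0, n_genes = 200L,
                    n_background_de = 0L, n_linked = 0L)
  des <- data.frame(sample_id = paste0("r", 1:40),
                    unit = rep("VIRparent", 40))
  ce <- simulateCounts(des, cfg)
  cnt <- SummarizedExperiment::assay(ce, "counts")
  # remove the simulated depth differences before checking the Poisson limit
  lib <- colSums(cnt)
  z <- sweep(cnt, 2, mean(lib) / lib, "*")
  ratio <- apply(z, 1, var) / rowMeans(z)
  expect_lt(abs(median(ratio) - 1), 0.15)

  # pooled contrast: linked genes carry the full effect, background none
  cfg2 <- tinyConfig(seed = 13, n_genes = 400L, n_background_de = 50L,
                     n_linked = 5L, dispersion = 0.05, lib_size_mean = 3e5)
  pop <- simulateCross(tinyConfig(n_f1 = 200L, seed = 13))
  gt <- cloneGenotypes(pop)
  pools <- list(VIRpool = names(gt[gt == "Vv"])[1:22],
                AVRpool = names(gt[gt == "vv"])[1:22])
  des2 <- data.frame(
    sample_id = paste0("p", 1:20),
    unit = rep(c("VIRpool", "AVRpool"), each = 10))
  ce2 <- simulateCounts(des2, cfg2, pop, pools)
  truth <- groundTruth(ce2)
  cnt2 <- SummarizedExperiment::assay(ce2, "counts")
  cpm <- sweep(cnt2, 2, colSums(cnt2), "/") * 1e6
  lfc <- log2((rowMeans(cpm[, 1:10]) + 0.5) / (rowMeans(cpm[, 11:20]) + 0.5))
  linked <- truth$class == "linked"
  expect_true(all(abs(abs(lfc[linked]) - cfg2@effect_log2fc) < 1.5))
  expect_lt(max(abs(lfc[truth$class == "background"])), 1.0)

  # 1-gene, 1-sample degenerate case
  one <- simulateCounts(data.frame(sample_id = "s", unit = "VIRparent"),
                        tinyConfig(n_genes = 1L, n_background_de = 0L,
                                   n_linked = 0L))
  expect_identical(dim(SummarizedExperiment::assay(one)), c(1L, 1L))
  expect_gte(SummarizedExperiment::assay(one)[1, 1], 0)

  expect_error(simulateCounts(des2, cfg2, pop, pools = list(VIRpool = c())),
               "zero members")
})

test_that("intensity simulation: dropout limits, true absence, determinism", {
  # dropout off: steep logistic far below every intensity
  cfg <- tinyConfig(seed = 2, n_absent = 0L,
                    missing_logistic_midpoint = -100,
                    missing_logistic_slope = 50)
  ie <- simulateIntensities(config = cfg)
  expect_false(anyNA(SummarizedExperiment::assay(ie, "intensity")))

  # truly-absent proteins are missing in every replicate of their genotype
  cfg2 <- tinyConfig(seed = 2, n_absent = 6L)
  ie2 <- simulateIntensities(config = cfg2)
  truth <- groundTruth(ie2)
  x <- SummarizedExperiment::assay(ie2, "intensity")
  grp <- sampleGroups(ie2)
  for (side in c("VIR", "AVR")) {
    ab <- truth$protein_id[truth$class == paste0("absent_", side)]
    expect_true(all(is.na(x[ab, grp == side])))
    expect_true(all(rowSums(!is.na(x[ab, grp != side, drop = FALSE])) > 0))
  }

  ie3 <- simulateIntensities(config = cfg2)
  expect_identical(SummarizedExperiment::assay(ie2),
                   SummarizedExperiment::assay(ie3))
})

test_that("count and protein-group tables round-trip through text", {
  cfg <- tinyConfig(seed = 4)
  ce <- simulateCounts(data.frame(sample_id = c("a", "b"),
                                  unit = c("VIRparent", "AVRparent")), cfg)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeCountTable(ce, f)
  back <- readCountTable(f, groups = sampleGroups(ce))
  expect_identical(SummarizedExperiment::assay(back),
                   SummarizedExperiment::assay(ce))
  expect_equal(unname(geneLengths(back)), unname(geneLengths(ce)))

  ie <- simulateIntensities(config = cfg)
  SummarizedExperiment::rowData(ie)$contaminant[3] <- TRUE
  g <- withr::local_tempfile(fileext = ".txt")
  writeProteinGroups(ie, g)
  raw <- readLines(g, n = 1)
  expect_match(raw, "Protein IDs\tLFQ intensity VIR_1")
  back2 <- readProteinGroups(g, groups = sampleGroups(ie))
  expect_equal(SummarizedExperiment::assay(back2),
               SummarizedExperiment::assay(ie))
  expect_true(SummarizedExperiment::rowData(back2)$contaminant[3])
})
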