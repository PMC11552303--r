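## Synthetic F1 cross: genotypes, phenotypes, counts, intensities.
##
## The generator reproduces the statistical structure the downstream analysis
## assumes: a dominant virulence allele V carried heterozygously by the VIR
## parent (so F1 genotypes segregate 1:1), parental expression backgrounds
## divergent at many genes but unlinked to V, a small set of genes cis-linked
## to V, pooled-F1 transcriptomes that average member clones, and label-free
## protein intensities with abundance-dependent dropout.

#' Simulate an F1 population from a VIR x AVR cross
#'
#' Parents carry private heterozygous alleles at every neutral marker locus;
#' each F1 clone inherits one allele from each parent per locus (the hybrid
#' invariant) and draws V or v from the Vv VIR parent with probability 1/2.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return an \linkS4class{F1Population}.
#' @examples
#' pop <- simulateCross(simConfig(n_f1 = 6, seed = 1))
#' cloneGenotypes(pop)
#' @export
simulateCross <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  nm <- config@n_markers
  loci <- paste0("M", seq_len(nm))
  mk <- function(parent) {
    a <- rbind(paste0(loci, "_", parent, "1"), paste0(loci, "_", parent, "2"))
    colnames(a) <- loci
    a
  }
  parents <- list(
    VIR = list(label = "VIR", alleles = mk("V"), virulence_genotype = "Vv"),
    AVR = list(label = "AVR", alleles = mk("A"), virulence_genotype = "vv"))
  n <- config@n_f1
  withSeed(substreamSeed(config@seed, "cross"), {
    pickA <- matrix(sample(c(1L, 2L), n * nm, replace = TRUE), n, nm)
    pickB <- matrix(sample(c(1L, 2L), n * nm, replace = TRUE), n, nm)
    geno <- ifelse(runif(n) < 0.5, "Vv", "vv")
  })
  idx <- function(pick, al) {
    out <- matrix("", n, nm, dimnames = list(NULL, loci))
    for (l in seq_len(nm)) out[, l] <- al[pick[, l], l]
    out
  }
  if (n == 0) {
    e <- matrix(character(), 0, nm, dimnames = list(NULL, loci))
    return(new("F1Population", ids = character(), genotype = character(),
               alleles_a = e, alleles_b = e, parents = parents))
  }
  new("F1Population",
      ids = sprintf("F1_%03d", seq_len(n)), genotype = geno,
      alleles_a = idx(pickA, parents$VIR$alleles),
      alleles_b = idx(pickB, parents$AVR$alleles),
      parents = parents)
}

#' Verify true F1 hybrids at marker loci
#'
#' A clone passes iff at every requested marker locus its unordered allele
#' pair contains exactly one allele attributable to each parent; a single
#' contaminated locus fails the clone.
#'
#' @param pop an \linkS4class{F1Population}.
#' @param marker_loci locus names to check (default: all loci).
#' @return named logical vector, one element per clone.
#' @export
verifyF1 <- function(pop, marker_loci = colnames(pop@alleles_a)) {
  stopifnot(is(pop, "F1Population"))
  bad <- setdiff(marker_loci, colnames(pop@alleles_a))
  if (length(bad))
    stop("unknown marker loci: ", paste(bad, collapse = ", "))
  vir <- pop@parents$VIR$alleles
  avr <- pop@parents$AVR$alleles
  ok <- rep(TRUE, length(pop@ids))
  for (l in marker_loci) {
    a <- pop@alleles_a[, l]; b <- pop@alleles_b[, l]
    ok <- ok & ((a %in% vir[, l] & b %in% avr[, l]) |
                (b %in% vir[, l] & a %in% avr[, l]))
  }
  setNames(ok, pop@ids)
}

# Effective phenotype genotype: the virulence allele is dominant, and every
# genotype behaves as virulent on susceptible hosts.
phenoKey <- function(genotype, host_class) {
  ifelse(host_class == "S", paste0("Vv.", host_class),
         paste0(genotype, ".", host_class))
}

#' Simulate plant-level phenotype records
#'
#' For each clone x host, \code{n_plants} plants each infested with
#' \code{n_aphids} nymphs: survivors ~ Binomial(n_aphids, p) and nymph counts
#' ~ negative binomial with the configured mean, forced to zero on plants
#' with no survivors. Dominance: Vv clones use virulent parameters on
#' resistant hosts, vv clones avirulent ones; all clones are virulent on
#' susceptible hosts.
#'
#' @param pop an \linkS4class{F1Population} (parents may be appended by the
#'   caller as ordinary rows; any vector of ids + genotypes also works via
#'   \code{genotypes}).
#' @param config a \linkS4class{SimConfig} providing \code{survival_probs},
#'   \code{fecundity_mean} and \code{fecundity_size}.
#' @param hosts named character: host name -> host class ("R" or "S").
#' @param n_plants plants per clone x host (10 in the index assay, 4 in the
#'   confirmation screen).
#' @param n_aphids aphids infested per plant (5).
#' @param day assay day recorded in the output (10 or 5).
#' @param genotypes optional named genotype vector overriding \code{pop}.
#' @return data.frame with clone_id, host, plant, survivors, nymphs, day.
#' @export
simulatePhenotypes <- function(pop, config,
                               hosts = c(A17 = "R", RNIL = "R"),
                               n_plants = 10, n_aphids = 5, day = 10,
                               genotypes = NULL) {
  if (is.null(genotypes)) genotypes <- cloneGenotypes(pop)
  keys <- unique(phenoKey(rep(unique(genotypes), each = length(hosts)),
                          rep(hosts, length(unique(genotypes)))))
  miss <- setdiff(keys, intersect(names(config@survival_probs),
                                  names(config@fecundity_mean)))
  if (length(miss))
    stop("missing survival/fecundity parameters for: ",
         paste(miss, collapse = ", "))
  grid <- expand.grid(clone_id = names(genotypes), host = names(hosts),
                      plant = seq_len(n_plants), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$clone_id, grid$host, grid$plant), ]
  key <- phenoKey(genotypes[grid$clone_id], hosts[grid$host])
  withSeed(substreamSeed(config@seed, paste0("phenotypes_day", day)), {
    surv <- rbinom(nrow(grid), n_aphids, config@survival_probs[key])
    nym <- rnbinom(nrow(grid), size = config@fecundity_size,
                   mu = config@fecundity_mean[key])
  })
  nym[surv == 0] <- 0L
  data.frame(clone_id = grid$clone_id, host = grid$host, plant = grid$plant,
             survivors = surv, nymphs = nym, day = day,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Per-unit relative expression given the gene model. Gene effects:
#  - background genes: parents homozygous-divergent; expression of a diploid
#    is the linear-scale mean of its two allele values, so every F1 is the
#    same heterozygote and F1 pools carry no background signal.
#  - linked genes: dominant coding, any V allele shifts the mean by
#    effect_log2fc.
geneModel <- function(config) {
  withSeed(substreamSeed(config@seed, "genemodel"), {
    base <- rnorm(config@n_genes, 0, 1.5)
    cls <- rep("null", config@n_genes)
    pick <- sample(config@n_genes, config@n_linked + config@n_background_de +
                     config@n_host_responsive)
    i_link <- pick[seq_len(config@n_linked)]
    i_bg <- pick[config@n_linked + seq_len(config@n_background_de)]
    i_host <- pick[config@n_linked + config@n_background_de +
                     seq_len(config@n_host_responsive)]
    cls[i_link] <- "linked"; cls[i_bg] <- "background"
    if (config@n_host_responsive > 0) cls[i_host] <- "host_responsive"
    dir_bg <- sample(c(1, -1), length(i_bg), replace = TRUE)
    dir_link <- sample(c(1, -1), length(i_link), replace = TRUE)
    lengths <- sample(200:3000, config@n_genes, replace = TRUE)
  })
  direction <- rep(0, config@n_genes)
  direction[i_bg] <- dir_bg
  direction[i_link] <- dir_link
  list(base = base, class = cls, direction = direction,
       gene_ids = sprintf("G%05d", seq_len(config@n_genes)),
       lengths = lengths)
}

# log2 expression vector for one diploid unit (parent or F1 clone) on a host.
unitExpression <- function(model, config, origin_vir, has_V, host_class = "R") {
  fc <- config@effect_log2fc
  x <- model$base
  bg <- model$class == "background"
  # origin_vir in [0,1]: fraction of alleles from the VIR background.
  hi <- 2^(model$base[bg] + model$direction[bg] * fc / 2)
  lo <- 2^(model$base[bg] - model$direction[bg] * fc / 2)
  xbg <- log2(origin_vir * hi + (1 - origin_vir) * lo)
  lk <- model$class == "linked"
  xlk <- model$base[lk] + ifelse(has_V, model$direction[lk] * fc, 0)
  hr <- model$class == "host_responsive"
  out <- x
  out[bg] <- xbg
  out[lk] <- xlk
  if (any(hr) && host_class == "R") out[hr] <- out[hr] + fc
  out
}

#' Simulate a gene-level count matrix for parents and F1 pools
#'
#' Expected expression per sample follows the configured gene model; pooled
#' samples average the member clones' expected expression (equal-mass
#' pooling) before negative binomial sampling with dispersion
#' \code{config@dispersion} (Poisson when 0). Library sizes vary log-normally
#' (10\% CV) around \code{lib_size_mean}.
#'
#' @param design data.frame with columns \code{sample_id}, \code{unit} and
#'   optionally \code{host} ("R"/"S", default "R"). \code{unit} is
#'   "VIRparent", "AVRparent", or the name of an entry of \code{pools}.
#' @param config a \linkS4class{SimConfig}.
#' @param pop the \linkS4class{F1Population} (needed when pools are used).
#' @param pools named list: pool name -> character vector of member clone ids.
#' @param stage substream label, so heads and body experiments differ.
#' @return a \linkS4class{CountExperiment}; the per-gene ground truth
#'   (class/direction) is attached as \code{metadata(ce)$ground_truth} and the
#'   gene model as \code{metadata(ce)$model}.
#' @export
simulateCounts <- function(design, config, pop = NULL, pools = list(),
                           stage = "counts") {
  stopifnot(all(c("sample_id", "unit") %in% names(design)))
  if (is.null(design$host)) design$host <- "R"
  model <- geneModel(config)
  if (length(pools)) {
    if (any(lengths(pools) == 0)) stop("pool with zero members")
    gt <- cloneGenotypes(pop)
    bad <- setdiff(unlist(pools), names(gt))
    if (length(bad)) stop("pool references unknown clones: ",
                          paste(bad, collapse = ", "))
  }
  unitMean <- function(unit, host) {
    if (unit == "VIRparent")
      return(2^unitExpression(model, config, 1, TRUE, host))
    if (unit == "AVRparent")
      return(2^unitExpression(model, config, 0, FALSE, host))
    if (!unit %in% names(pools)) stop("unknown unit: ", unit)
    members <- pools[[unit]]
    # every F1 is a 50/50 background heterozygote; linked genes depend on V
    ex <- vapply(members, function(cl)
      2^unitExpression(model, config, 0.5, gt[cl] == "Vv", host),
      numeric(config@n_genes))
    rowMeans(ex)
  }
  mus <- matrix(vapply(seq_len(nrow(design)), function(i) {
    m <- unitMean(design$unit[i], design$host[i])
    m / sum(m)
  }, numeric(config@n_genes)), nrow = config@n_genes)
  withSeed(substreamSeed(config@seed, stage), {
    libs <- rlnorm(nrow(design), log(config@lib_size_mean), 0.1)
    mu <- sweep(mus, 2, libs, "*")
    cnt <- if (config@dispersion == 0) {
      matrix(rpois(length(mu), mu), nrow(mu))
    } else {
      matrix(rnbinom(length(mu), size = 1 / config@dispersion, mu = mu),
             nrow(mu))
    }
  })
  dimnames(cnt) <- list(model$gene_ids, design$sample_id)
  ce <- CountExperiment(cnt, model$lengths, design$unit)
  S4Vectors::metadata(ce)$ground_truth <-
    data.frame(gene_id = model$gene_ids, class = model$class,
               direction = model$direction, stringsAsFactors = FALSE)
  S4Vectors::metadata(ce)$model <- model
  ce
}

#' Ground-truth table attached to a simulated experiment
#' @param object a simulated \linkS4class{CountExperiment} or
#'   \linkS4class{IntensityExperiment}.
#' @return the ground-truth data.frame recorded at simulation time.
#' @export
groundTruth <- function(object) S4Vectors::metadata(object)$ground_truth

#' Simulate a label-free protein intensity matrix with MNAR dropout
#'
#' Replicate log2 intensities are Gaussian around protein x genotype means;
#' each observation is dropped with probability
#' \code{plogis((midpoint - x) * slope)}; a configured subset of proteins is
#' truly absent in one genotype (never observed there). Flag columns are
#' present and all FALSE.
#'
#' @param design data.frame with columns \code{sample_id} and \code{group}
#'   ("VIR"/"AVR"); default four replicates per genotype.
#' @param config a \linkS4class{SimConfig}.
#' @param stage substream label (saliva and salivary gland use different
#'   streams).
#' @param ids protein identifiers; defaults to synthetic P-codes, but
#'   passing gene ids couples the proteome to the transcript namespace so
#'   the evidence-integration stage can unify them.
#' @param da optional named character vector (id -> "VIR"/"AVR") forcing
#'   particular proteins to be truly more abundant on a given side, in
#'   addition to the \code{n_da_proteins} random picks.
#' @param absent optional named character vector (id -> genotype the
#'   protein is absent from); default \code{n_absent} random proteins.
#' @return an \linkS4class{IntensityExperiment} with ground truth in
#'   \code{metadata()$ground_truth} (class: null/da_VIR/da_AVR/absent_VIR/
#'   absent_AVR, where absent_VIR means absent from VIR samples).
#' @export
simulateIntensities <- function(design = data.frame(
                                  sample_id = c(paste0("VIR_", 1:4),
                                                paste0("AVR_", 1:4)),
                                  group = rep(c("VIR", "AVR"), each = 4)),
                                config, stage = "intensities",
                                ids = NULL, da = NULL, absent = NULL) {
  np <- config@n_proteins
  if (is.null(ids)) ids <- sprintf("P%05d", seq_len(np))
  stopifnot(length(ids) == np, !anyDuplicated(ids))
  withSeed(substreamSeed(config@seed, paste0(stage, "_model")), {
    mu <- rnorm(np, config@protein_mu, config@protein_sd)
    pick <- sample(np, config@n_da_proteins + config@n_absent)
    i_da <- pick[seq_len(config@n_da_proteins)]
    i_ab <- pick[config@n_da_proteins + seq_len(config@n_absent)]
    da_side <- sample(c("VIR", "AVR"), length(i_da), replace = TRUE)
    ab_side <- sample(c("VIR", "AVR"), length(i_ab), replace = TRUE)
  })
  if (!is.null(da)) {
    stopifnot(all(names(da) %in% ids), all(da %in% c("VIR", "AVR")))
    forced <- match(names(da), ids)
    keepr <- !(i_da %in% forced)
    i_da <- c(forced, i_da[keepr])
    da_side <- c(unname(da), da_side[keepr])
    keepa <- !(i_ab %in% i_da)
    i_ab <- i_ab[keepa]; ab_side <- ab_side[keepa]
  }
  if (!is.null(absent)) {
    stopifnot(all(names(absent) %in% ids),
              all(absent %in% c("VIR", "AVR")))
    i_ab <- match(names(absent), ids); ab_side <- unname(absent)
  }
  cls <- rep("null", np)
  cls[i_da] <- paste0("da_", da_side)
  cls[i_ab] <- paste0("absent_", ab_side)
  shift <- matrix(0, np, 2, dimnames = list(ids, c("VIR", "AVR")))
  shift[i_da, ] <- t(vapply(seq_along(i_da), function(k)
    if (da_side[k] == "VIR") c(config@protein_effect_log2 / 2,
                               -config@protein_effect_log2 / 2)
    else c(-config@protein_effect_log2 / 2, config@protein_effect_log2 / 2),
    numeric(2)))
  withSeed(substreamSeed(config@seed, stage), {
    x <- vapply(seq_len(nrow(design)), function(i) {
      g <- design$group[i]
      rnorm(np, mu + shift[, g], config@protein_rep_sd)
    }, numeric(np))
    pmiss <- plogis((config@missing_logistic_midpoint - x) *
                      config@missing_logistic_slope)
    drop <- matrix(runif(length(x)) < pmiss, nrow(x))
  })
  x[drop] <- NA
  # truly-absent proteins: never observed in the genotype they are absent from
  for (k in seq_along(i_ab))
    x[i_ab[k], design$group == ab_side[k]] <- NA
  raw <- 2^x
  dimnames(raw) <- list(ids, design$sample_id)
  ie <- IntensityExperiment(raw, design$group)
  S4Vectors::metadata(ie)$ground_truth <-
    data.frame(protein_id = ids, class = cls, stringsAsFactors = FALSE)
  ie
}

## ---------------------------------------------------------------------------
## Text interchange (simple TSV count tables, MaxQuant-style protein groups)
## ---------------------------------------------------------------------------

#' Write / read a gene count table
#'
#' Tab-separated: gene_id, length (bp), then one integer column per sample.
#' @param ce a \linkS4class{CountExperiment}.
#' @param path output file.
#' @param groups for \code{readCountTable}: sample group labels (defaults to
#'   the column names).
#' @export
writeCountTable <- function(ce, path) {
  df <- data.frame(gene_id = rownames(ce), length = geneLengths(ce),
                   SummarizedExperiment::assay(ce, "counts"),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCountTable
#' @export
readCountTable <- function(path, groups = NULL) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  cnt <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(cnt) <- df$gene_id
  if (is.null(groups)) groups <- colnames(cnt)
  CountExperiment(cnt, df$length, groups)
}

#' Write / read a MaxQuant-style protein-groups table
#'
#' Tab-separated with columns \code{Protein IDs},
#' \code{LFQ intensity <sample>} (0 = missing), \code{Reverse} and
#' \code{Potential contaminant} ("+" = flagged, empty otherwise).
#' @param ie an \linkS4class{IntensityExperiment}.
#' @param path file path.
#' @param groups for \code{readProteinGroups}: group label per intensity
#'   column (defaults to the sample names).
#' @export
writeProteinGroups <- function(ie, path) {
  x <- SummarizedExperiment::assay(ie, "intensity")
  x[is.na(x)] <- 0
  rd <- SummarizedExperiment::rowData(ie)
  df <- data.frame(`Protein IDs` = rownames(ie), x,
                   Reverse = ifelse(rd$reverse, "+", ""),
                   `Potential contaminant` = ifelse(rd$contaminant, "+", ""),
                   check.names = FALSE)
  names(df)[2:(1 + ncol(x))] <- paste("LFQ intensity", colnames(x))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeProteinGroups
#' @export
readProteinGroups <- function(path, groups = NULL) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  lfq <- grep("^LFQ intensity ", names(df), value = TRUE)
  x <- as.matrix(df[, lfq, drop = FALSE])
  x[x == 0] <- NA
  colnames(x) <- sub("^LFQ intensity ", "", lfq)
  rownames(x) <- df[["Protein IDs"]]
  flag <- function(col) if (col %in% names(df))
    !is.na(df[[col]]) & df[[col]] == "+" else rep(FALSE, nrow(df))
  if (is.null(groups)) groups <- colnames(x)
  IntensityExperiment(x, groups,
                      reverse = flag("Reverse"),
                      contaminant = flag("Potential contaminant"),
                      identified_by_site = flag("Only identified by site"))
}

#' Write a phenotype table (clone, host, plant, survivors, nymphs, day)
#' @param pheno data.frame from \code{\link{simulatePhenotypes}}.
#' @param path file path.
#' @export
writePhenotypeTable <- function(pheno, path) {
  write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
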