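#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames rowData colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats rbinom rnbinom rpois rnorm runif rlnorm plogis quantile
#'   median sd var cor.test pt phyper p.adjust prcomp integrate setNames
#'   aggregate
#' @importFrom utils read.delim write.table
NULL

## ---------------------------------------------------------------------------
## SimConfig
## ---------------------------------------------------------------------------

#' Simulation configuration for the synthetic F1 multi-omics world
#'
#' Holds every parameter of the synthetic cross: the Mendelian dominant
#' virulence locus segregating 1:1 among F1 clones, divergent parental
#' expression backgrounds, negative binomial count sampling, log-normal
#' label-free protein intensities with abundance-dependent (MNAR) dropout,
#' and plant-level phenotype sampling.
#'
#' @slot n_f1 number of F1 clones to simulate.
#' @slot n_markers number of neutral biallelic microsatellite-like marker loci.
#' @slot n_genes total number of genes.
#' @slot n_background_de genes differentially expressed between the parental
#'   backgrounds but unlinked to the virulence locus.
#' @slot n_linked genes cis-linked to the virulence locus (dominant coding).
#' @slot n_host_responsive genes shifted on resistant hosts in all genotypes
#'   (defaults to 0, i.e. no host effect).
#' @slot effect_log2fc log2 effect size for linked and background genes.
#' @slot dispersion negative binomial dispersion phi (>= 0; 0 gives Poisson).
#' @slot lib_size_mean mean sequencing library size (counts per sample).
#' @slot n_proteins number of proteins in the intensity simulation.
#' @slot n_da_proteins proteins with a true abundance difference.
#' @slot protein_effect_log2 log2 shift of differentially abundant proteins.
#' @slot n_absent proteins truly absent in one genotype (candidate exclusives).
#' @slot protein_mu,protein_sd mean and SD of between-protein log2 abundance.
#' @slot protein_rep_sd replicate-level SD on the log2 scale.
#' @slot missing_logistic_midpoint,missing_logistic_slope MNAR dropout model:
#'   an observation at log2 intensity x is missing with probability
#'   plogis((midpoint - x) * slope).
#' @slot survival_probs named numeric, names "<genotype>.<hostclass>"
#'   (e.g. "Vv.R"), per-aphid survival probability.
#' @slot fecundity_mean named numeric, same key scheme, mean nymphs per plant.
#' @slot fecundity_size negative binomial size for nymph counts.
#' @slot seed integer master seed; every stage derives a named substream.
#' @export
setClass("SimConfig", representation(
  n_f1 = "integer", n_markers = "integer", n_genes = "integer",
  n_background_de = "integer", n_linked = "integer",
  n_host_responsive = "integer",
  effect_log2fc = "numeric", dispersion = "numeric", lib_size_mean = "numeric",
  n_proteins = "integer", n_da_proteins = "integer",
  protein_effect_log2 = "numeric", n_absent = "integer",
  protein_mu = "numeric", protein_sd = "numeric", protein_rep_sd = "numeric",
  missing_logistic_midpoint = "numeric", missing_logistic_slope = "numeric",
  survival_probs = "numeric", fecundity_mean = "numeric",
  fecundity_size = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  cnt <- c(n_f1 = object@n_f1, n_markers = object@n_markers,
           n_genes = object@n_genes, n_background_de = object@n_background_de,
           n_linked = object@n_linked, n_proteins = object@n_proteins,
           n_da_proteins = object@n_da_proteins, n_absent = object@n_absent,
           n_host_responsive = object@n_host_responsive)
  if (any(cnt < 0)) msg <- c(msg, "counts must be nonnegative")
  if (object@n_background_de + object@n_linked > object@n_genes)
    msg <- c(msg, "n_background_de + n_linked must not exceed n_genes")
  if (object@dispersion < 0) msg <- c(msg, "dispersion must be >= 0")
  if (any(object@survival_probs < 0 | object@survival_probs > 1))
    msg <- c(msg, "survival probabilities must lie in [0, 1]")
  if (any(object@fecundity_mean < 0))
    msg <- c(msg, "fecundity means must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' Defaults encode the study design the package emulates: 78 F1 clones
#' screened, seven marker loci, bulks of 22, five whole-body and three head
#' replicates, four proteomic replicates per genotype, a dominant virulence
#' locus with 1:1 segregation, and an effect size well above the fold-change
#' call threshold.
#'
#' @param n_f1,n_markers,n_genes,n_background_de,n_linked,n_host_responsive
#'   integer design sizes (see \linkS4class{SimConfig}).
#' @param effect_log2fc,dispersion,lib_size_mean count model parameters.
#' @param n_proteins,n_da_proteins,protein_effect_log2,n_absent,protein_mu,
#'   protein_sd,protein_rep_sd intensity model parameters.
#' @param missing_logistic_midpoint,missing_logistic_slope MNAR dropout model.
#' @param survival_probs,fecundity_mean,fecundity_size phenotype model,
#'   keyed "<genotype>.<hostclass>" with genotype in {Vv, vv} and host class
#'   in {R, S}.
#' @param seed master seed.
#' @return a validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(n_f1 = 10, n_genes = 50, seed = 1)
#' @export
simConfig <- function(n_f1 = 78L, n_markers = 7L, n_genes = 2000L,
                      n_background_de = 200L, n_linked = 10L,
                      n_host_responsive = 0L,
                      effect_log2fc = 4, dispersion = 0.1,
                      lib_size_mean = 2e5,
                      n_proteins = 1000L, n_da_proteins = 100L,
                      protein_effect_log2 = 2, n_absent = 20L,
                      protein_mu = 25, protein_sd = 2, protein_rep_sd = 0.3,
                      missing_logistic_midpoint = 20,
                      missing_logistic_slope = 0.8,
                      survival_probs = c(Vv.R = 0.95, vv.R = 0.05,
                                         Vv.S = 0.95, vv.S = 0.95),
                      fecundity_mean = c(Vv.R = 30, vv.R = 2,
                                         Vv.S = 30, vv.S = 30),
                      fecundity_size = 5, seed = 1L) {
  new("SimConfig",
      n_f1 = as.integer(n_f1), n_markers = as.integer(n_markers),
      n_genes = as.integer(n_genes),
      n_background_de = as.integer(n_background_de),
      n_linked = as.integer(n_linked),
      n_host_responsive = as.integer(n_host_responsive),
      effect_log2fc = effect_log2fc, dispersion = dispersion,
      lib_size_mean = lib_size_mean,
      n_proteins = as.integer(n_proteins),
      n_da_proteins = as.integer(n_da_proteins),
      protein_effect_log2 = protein_effect_log2,
      n_absent = as.integer(n_absent),
      protein_mu = protein_mu, protein_sd = protein_sd,
      protein_rep_sd = protein_rep_sd,
      missing_logistic_midpoint = missing_logistic_midpoint,
      missing_logistic_slope = missing_logistic_slope,
      survival_probs = survival_probs, fecundity_mean = fecundity_mean,
      fecundity_size = fecundity_size, seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@n_f1, "F1 clones,", object@n_genes, "genes (",
      object@n_background_de, "background-DE,", object@n_linked, "linked ),",
      object@n_proteins, "proteins; seed", object@seed, "\n")
})

## ---------------------------------------------------------------------------
## F1Population
## ---------------------------------------------------------------------------

#' A simulated F1 population from a VIR x AVR cross
#'
#' Parents are clonal diploids, heterozygous at every neutral marker locus
#' with private alleles, and the VIR parent is heterozygous (Vv) at the
#' dominant virulence locus while the AVR parent is vv; F1 clones inherit one
#' allele from each parent at every locus, so the virulence genotype
#' segregates 1:1.
#'
#' @slot ids clone identifiers.
#' @slot genotype virulence genotype per clone, "Vv" or "vv".
#' @slot alleles_a,alleles_b clones x loci matrices holding the two allele
#'   symbols carried at each marker locus (unordered pair).
#' @slot parents list with elements VIR and AVR, each a list with an
#'   \code{alleles} 2 x loci matrix and a \code{virulence_genotype}.
#' @export
setClass("F1Population", representation(
  ids = "character", genotype = "character",
  alleles_a = "matrix", alleles_b = "matrix", parents = "list"))

setValidity("F1Population", function(object) {
  n <- length(object@ids)
  if (length(object@genotype) != n ||
      (n > 0 && (nrow(object@alleles_a) != n || nrow(object@alleles_b) != n)))
    return("clone slots have inconsistent lengths")
  if (!all(object@genotype %in% c("Vv", "vv")))
    return("virulence genotypes must be 'Vv' or 'vv'")
  vp <- object@parents$VIR$virulence_genotype
  ap <- object@parents$AVR$virulence_genotype
  if (!identical(vp, "Vv") || !identical(ap, "vv"))
    return("VIR parent must be Vv and AVR parent vv")
  TRUE
})

setMethod("show", "F1Population", function(object) {
  cat("F1Population:", length(object@ids), "clones,",
      ncol(object@alleles_a), "marker loci;",
      sum(object@genotype == "Vv"), "Vv /",
      sum(object@genotype == "vv"), "vv\n")
})

#' @describeIn F1Population-class virulence genotypes ("Vv"/"vv") per clone.
#' @param pop an \linkS4class{F1Population}.
#' @export
cloneGenotypes <- function(pop) setNames(pop@genotype, pop@ids)

#' @describeIn F1Population-class clone identifiers.
#' @export
cloneIds <- function(pop) pop@ids

## ---------------------------------------------------------------------------
## CountExperiment / IntensityExperiment
## ---------------------------------------------------------------------------

#' Gene-level count container
#'
#' A \linkS4class{SummarizedExperiment} with an integer \code{counts} assay,
#' \code{gene_length} (bp) in the rowData and a \code{group} label per sample
#' in the colData.
#'
#' @export
setClass("CountExperiment", contains = "SummarizedExperiment")

setValidity("CountExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  cnt <- SummarizedExperiment::assay(object, "counts")
  if (any(cnt < 0)) msg <- c(msg, "counts must be nonnegative")
  if (!"gene_length" %in% names(SummarizedExperiment::rowData(object)))
    msg <- c(msg, "rowData column 'gene_length' is required")
  else if (any(SummarizedExperiment::rowData(object)$gene_length <= 0))
    msg <- c(msg, "gene lengths must be positive")
  if (!"group" %in% names(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData column 'group' is required")
  if (length(msg)) msg else TRUE
})

#' Construct a CountExperiment
#'
#' @param counts genes x samples matrix of nonnegative integers, with row and
#'   column names.
#' @param gene_lengths positive lengths (bp), one per gene.
#' @param groups sample group label, one per sample.
#' @return a \linkS4class{CountExperiment}.
#' @examples
#' m <- matrix(rpois(12, 10), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' ce <- CountExperiment(m, c(500, 1000, 1500), rep(c("A", "B"), each = 2))
#' @export
CountExperiment <- function(counts, gene_lengths, groups) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(gene_length = as.numeric(gene_lengths),
                                   row.names = rownames(counts)),
    colData = S4Vectors::DataFrame(group = as.character(groups),
                                   row.names = colnames(counts)))
  new("CountExperiment", se)
}

#' Label-free protein intensity container
#'
#' A \linkS4class{SummarizedExperiment} whose \code{intensity} assay holds
#' positive raw-scale label-free intensities with \code{NA} for missing
#' observations; rowData carries the MaxQuant-style \code{reverse},
#' \code{contaminant} and \code{identified_by_site} flags and the colData a
#' \code{group} label per sample.
#'
#' @export
setClass("IntensityExperiment", contains = "SummarizedExperiment")

setValidity("IntensityExperiment", function(object) {
  msg <- character()
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    return("assay 'intensity' is required")
  x <- SummarizedExperiment::assay(object, "intensity")
  if (any(x <= 0, na.rm = TRUE))
    msg <- c(msg, "present intensities must be strictly positive")
  rd <- SummarizedExperiment::rowData(object)
  need <- c("reverse", "contaminant", "identified_by_site")
  if (!all(need %in% names(rd)))
    msg <- c(msg, "rowData must carry reverse/contaminant/identified_by_site")
  if (!"group" %in% names(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData column 'group' is required")
  if (length(msg)) msg else TRUE
})

#' Construct an IntensityExperiment
#'
#' @param intensities proteins x samples matrix, positive or NA (missing).
#' @param groups sample group label per sample.
#' @param reverse,contaminant,identified_by_site logical flags per protein
#'   (default all FALSE).
#' @return an \linkS4class{IntensityExperiment}.
#' @export
IntensityExperiment <- function(intensities, groups,
                                reverse = FALSE, contaminant = FALSE,
                                identified_by_site = FALSE) {
  intensities <- as.matrix(intensities)
  n <- nrow(intensities)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = intensities),
    rowData = S4Vectors::DataFrame(
      reverse = rep_len(reverse, n),
      contaminant = rep_len(contaminant, n),
      identified_by_site = rep_len(identified_by_site, n),
      row.names = rownames(intensities)),
    colData = S4Vectors::DataFrame(group = as.character(groups),
                                   row.names = colnames(intensities)))
  new("IntensityExperiment", se)
}

#' @rdname CountExperiment
#' @param object a CountExperiment.
#' @export
geneLengths <- function(object)
  setNames(SummarizedExperiment::rowData(object)$gene_length, rownames(object))

#' Sample group labels of a count or intensity container
#' @param object a \linkS4class{CountExperiment} or
#'   \linkS4class{IntensityExperiment}.
#' @export
sampleGroups <- function(object)
  setNames(SummarizedExperiment::colData(object)$group, colnames(object))

## ---------------------------------------------------------------------------
## EvidenceMatrix
## ---------------------------------------------------------------------------

#' Gene x dataset evidence matrix
#'
#' Each cell records what one dataset says about one gene/protein:
#' \code{"absent"}, \code{"up_VIR"}, \code{"up_AVR"} or \code{"present"}
#' (detected without direction, as for saliva presence without differential
#' abundance). Rows with no evidence anywhere are excluded at construction.
#'
#' @slot calls character matrix, rows = unified ids, columns = datasets.
#' @slot unmapped input ids that could not be mapped to the unified namespace.
#' @export
setClass("EvidenceMatrix", representation(calls = "matrix",
                                          unmapped = "character"))

setValidity("EvidenceMatrix", function(object) {
  ok <- c("absent", "up_VIR", "up_AVR", "present")
  if (!all(object@calls %in% ok))
    return("cells must be absent/up_VIR/up_AVR/present")
  if (nrow(object@calls) > 0 &&
      any(rowSums(object@calls != "absent") == 0))
    return("every row must have at least one non-absent cell")
  TRUE
})

setMethod("show", "EvidenceMatrix", function(object) {
  cat("EvidenceMatrix:", nrow(object@calls), "ids x",
      ncol(object@calls), "datasets (",
      paste(colnames(object@calls), collapse = ", "), ")\n")
  if (length(object@unmapped))
    cat("  unmapped ids:", length(object@unmapped), "\n")
})

#' @describeIn EvidenceMatrix-class the underlying character matrix of calls.
#' @param object an EvidenceMatrix.
#' @export
evidenceCalls <- function(object) object@calls

#' @describeIn EvidenceMatrix-class ids that failed to map.
#' @export
unmappedIds <- function(object) object@unmapped
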