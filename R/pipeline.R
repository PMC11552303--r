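## End-to-end orchestration: simulate -> phenotype -> bulks -> DE contrasts
## -> proteomics -> integration, with per-stage seed substreams, tab-separated
## artifacts carrying a stage header, and a checksummed run manifest.

defaultRunConfig <- function() {
  list(k = 22L,
       lfc_threshold = 2.0, fdr_threshold = 0.05,
       alpha = 0.05, downshift = 2.1, width = 0.1, scope = "global",
       vir_cut = c(A17 = 4, RNIL = 5), avr_cut = c(A17 = 2, RNIL = 4.5),
       n_body_reps = 5L, n_head_reps = 3L)
}

#' Run the full co-segregation workflow on a synthetic cross
#'
#' Executes every stage of the study design against one
#' \linkS4class{SimConfig}: simulate the F1 population, phenotype and
#' classify clones, select the two bulks, generate and contrast the head
#' (parents on resistant and susceptible hosts) and whole-body (parents and
#' F1 pools) count experiments, run the label-free proteomics workflow for
#' saliva and salivary glands, and integrate all five datasets into the
#' candidate table. Re-running with the same configuration and seed
#' reproduces byte-identical tables.
#'
#' @param sim a \linkS4class{SimConfig} (its seed drives every stage), or a
#'   path to a YAML file whose entries override \code{\link{simConfig}}
#'   arguments (top level) and the run options (under \code{run:}).
#' @param out_dir output directory for tables and the manifest (created;
#'   NULL = no files written).
#' @param options named list overriding the default thresholds
#'   (k, lfc_threshold, fdr_threshold, alpha, downshift, width, scope,
#'   n_body_reps, n_head_reps).
#' @param verbose log stage progress to stderr.
#' @return invisible list with all stage results and the manifest.
#' @export
runAll <- function(sim, out_dir = NULL, options = list(), verbose = TRUE) {
  if (is.character(sim)) {
    cfg <- yaml::read_yaml(sim)
    options <- utils::modifyList(options, cfg$run %||% list())
    cfg$run <- NULL
    sim <- do.call(simConfig, cfg)
  }
  stopifnot(is(sim, "SimConfig"))
  opt <- utils::modifyList(defaultRunConfig(), options)
  say <- function(...) if (verbose) message("[coseg] ", ...)
  emit <- function(df, name, stage, params = NULL) {
    if (!is.null(out_dir))
      writeStageTable(df, file.path(out_dir, name), stage, params)
  }
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  say("simulating cross (", sim@n_f1, " F1 clones)")
  pop <- simulateCross(sim)
  if (!all(verifyF1(pop)))
    stop("stage cross: hybrid verification failed")

  say("phenotyping")
  pheno <- simulatePhenotypes(pop, sim)
  confirm <- simulatePhenotypes(pop, sim, n_plants = 4, day = 5)
  calls <- virulenceCalls(pheno, confirm,
                          vir_cut = opt$vir_cut, avr_cut = opt$avr_cut)
  emit(pheno, "phenotypes_day10.tsv", "phenotype", list(day = 10))
  emit(confirm, "phenotypes_day5.tsv", "phenotype", list(day = 5))
  hc <- hostCorrelation(calls$vi_A17, calls$vi_RNIL)
  say("host correlation r = ", round(hc$r, 3))

  say("selecting bulks of ", opt$k)
  bulks <- tryCatch(selectBulks(calls, opt$k),
                    error = function(e)
                      stop("stage bulk_selection: ", conditionMessage(e)))
  calls$bulk <- ifelse(calls$clone_id %in% bulks$vir_bulk, "VIR",
                       ifelse(calls$clone_id %in% bulks$avr_bulk, "AVR", ""))
  emit(calls, "virulence_calls.tsv", "phenotype",
       list(k = opt$k, r_hosts = round(hc$r, 4)))

  say("simulating counts and testing contrasts")
  nb <- opt$n_body_reps; nh <- opt$n_head_reps
  body_design <- data.frame(
    sample_id = c(paste0("VIRparent_", 1:nb), paste0("AVRparent_", 1:nb),
                  paste0("VIRF1pool_", 1:nb), paste0("AVRF1pool_", 1:nb)),
    unit = rep(c("VIRparent", "AVRparent", "VIRpool", "AVRpool"), each = nb))
  body <- simulateCounts(body_design, sim, pop,
                         pools = list(VIRpool = bulks$vir_bulk,
                                      AVRpool = bulks$avr_bulk),
                         stage = "body_counts")
  head_design <- data.frame(
    sample_id = c(paste0("VIRhead_R_", 1:nh), paste0("AVRhead_R_", 1:nh),
                  paste0("VIRhead_S_", 1:nh), paste0("AVRhead_S_", 1:nh)),
    unit = rep(c("VIRparent", "AVRparent"), each = nh, times = 2),
    host = rep(c("R", "S"), each = 2 * nh))
  heads <- simulateCounts(head_design, sim, stage = "head_counts")
  # per-contrast group labels (heads: genotype x host)
  SummarizedExperiment::colData(heads)$group <-
    paste0(head_design$unit, "_", head_design$host)

  runContrast <- function(ce, gA, gB, name) {
    tab <- deTable(ce, gA, gB, lfc_threshold = opt$lfc_threshold,
                   fdr_threshold = opt$fdr_threshold)
    emit(tab, paste0("de_", name, ".tsv"), "de",
         list(contrast = paste0(gA, "_vs_", gB), lfc = opt$lfc_threshold,
              fdr = opt$fdr_threshold))
    tab
  }
  de <- list(
    parent_body = runContrast(body, "VIRparent", "AVRparent", "parent_body"),
    F1_body = runContrast(body, "VIRpool", "AVRpool", "f1_body"),
    parent_head_R = runContrast(heads, "VIRparent_R", "AVRparent_R",
                                "parent_head_R"),
    parent_head_S = runContrast(heads, "VIRparent_S", "AVRparent_S",
                                "parent_head_S"))
  fpkm <- tmmFpkm(body)
  centred <- log2(fpkm + 1) - rowMeans(log2(fpkm + 1))
  emit(data.frame(gene_id = rownames(centred), centred,
                  check.names = FALSE),
       "body_log2_centred_tmm_fpkm.tsv", "de", list(matrix = "tmm_fpkm"))

  say("proteomics (saliva, salivary gland)")
  # Proteins share the gene namespace: the proteome is a subset of genes,
  # and cis-linked effector genes are truly differential in both tissues
  # (direction following their transcript direction), so saliva and gland
  # evidence can corroborate the F1 transcriptome.
  model <- S4Vectors::metadata(body)$model
  linked <- model$gene_ids[model$class == "linked"]
  prot_ids <- withSeed(substreamSeed(sim@seed, "proteome_universe"), {
    c(linked, sample(setdiff(model$gene_ids, linked),
                     sim@n_proteins - length(linked)))
  })
  linked_side <- ifelse(model$direction[match(linked, model$gene_ids)] > 0,
                        "VIR", "AVR")
  da_fixed <- setNames(linked_side, linked)
  runProteomics <- function(stage) {
    ie <- simulateIntensities(config = sim, stage = stage, ids = prot_ids,
                              da = da_fixed)
    fl <- filterAndLog(ie)
    imp <- imputeMissing(fl$log2, opt$downshift, opt$width, opt$scope,
                         seed = substreamSeed(sim@seed,
                                              paste0(stage, "_impute")))
    ssda <- ssdaWithRfc(imp, fl$groups, opt$alpha)
    excl <- exclusiveProteins(ie)
    det <- lapply(c(VIR = "VIR", AVR = "AVR"), function(g) {
      x <- SummarizedExperiment::assay(ie, "intensity")
      rownames(ie)[rowSums(!is.na(x[, sampleGroups(ie) == g,
                                    drop = FALSE])) > 0]
    })
    emit(ssda, paste0("ssda_", stage, ".tsv"), "proteomics",
         list(alpha = opt$alpha, downshift = opt$downshift,
              width = opt$width))
    list(ie = ie, ssda = ssda, exclusive = excl, detected = det,
         summary = proteomeSummary(det$VIR, det$AVR,
                                   names_AB = c("VIR", "AVR")))
  }
  saliva <- runProteomics("saliva")
  gland <- runProteomics("salivary_gland")

  say("integrating evidence")
  upSets <- function(tab) list(up_VIR = tab$gene_id[tab$call == "up_A"],
                               up_AVR = tab$gene_id[tab$call == "up_B"])
  upProt <- function(px) {
    s <- px$ssda[px$ssda$ssda, ]
    list(up_VIR = s$protein_id[s$higher_in == "VIR"],
         up_AVR = s$protein_id[s$higher_in == "AVR"])
  }
  em <- buildEvidence(
    directed = list(
      saliva = upProt(saliva),
      salivary_gland = upProt(gland),
      parent_head = upSets(de$parent_head_R),
      parent_body = upSets(de$parent_body),
      F1_body = upSets(de$F1_body)),
    presence = list(saliva = unlist(saliva$detected, use.names = FALSE),
                    salivary_gland = unlist(gland$detected,
                                            use.names = FALSE)))
  candidates <- table1Filter(em)
  conflicts <- directionConflicts(em)
  emit(candidates, "candidates.tsv", "integration",
       list(rule = "three_plus|f1_plus_one"))
  emit(conflicts, "direction_conflicts.tsv", "integration")

  manifest <- list(
    seed = sim@seed,
    parameters = opt,
    sim = list(n_f1 = sim@n_f1, n_genes = sim@n_genes,
               n_background_de = sim@n_background_de,
               n_linked = sim@n_linked, effect_log2fc = sim@effect_log2fc,
               dispersion = sim@dispersion,
               n_proteins = sim@n_proteins),
    host_correlation = hc,
    n_de = lapply(de, function(d) sum(d$call != "ns")),
    n_candidates = nrow(candidates))
  if (!is.null(out_dir)) {
    files <- list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE)
    manifest$checksums <- as.list(tools::md5sum(files))
    names(manifest$checksums) <- basename(files)
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  say("done: ", nrow(candidates), " candidates")
  invisible(list(pop = pop, phenotypes = pheno, calls = calls,
                 bulks = bulks, body = body, heads = heads, de = de,
                 saliva = saliva, salivary_gland = gland, evidence = em,
                 candidates = candidates, conflicts = conflicts,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
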