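## End-to-end orchestration: simulate (optional) -> QC -> kinship ->
## heritability -> meQTL classification -> familial correlations ->
## extremes screen -> enrichment.

#' Pipeline configuration with study-default thresholds
#'
#' Every threshold defaults to the value used throughout the analysis:
#' detection p 0.01, sample missingness 1.5%, probe missingness 10%, probe
#' SD 0.02, SNP call rate 0.95, MAF 0.01, per-family MAF rule 10% of
#' families, heritability cutoff 0.4, association alpha 1e-7, region flank
#' 25 kb, 4 methylation PCs.
#'
#' @param sim a [simConfig()] for the synthetic cohort (ignored when input
#'   paths are supplied to [runPipeline()]).
#' @param detection_p,sample_missing,probe_missing,probe_sd,call_rate,maf,perfam_maf,perfam_frac,h2_threshold,alpha,flank,n_pcs thresholds.
#' @param method variance-component estimator, `"REML"` or `"ML"`.
#' @param seed integer seed.
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(sim = simConfig(), detection_p = 0.01,
                           sample_missing = 0.015, probe_missing = 0.10,
                           probe_sd = 0.02, call_rate = 0.95, maf = 0.01,
                           perfam_maf = 0.01, perfam_frac = 0.10,
                           h2_threshold = 0.4, alpha = 1e-7, flank = 25000,
                           n_pcs = 4, method = "REML", seed = 1L) {
  cfg <- list(sim = sim, detection_p = detection_p,
              sample_missing = sample_missing, probe_missing = probe_missing,
              probe_sd = probe_sd, call_rate = call_rate, maf = maf,
              perfam_maf = perfam_maf, perfam_frac = perfam_frac,
              h2_threshold = h2_threshold, alpha = alpha, flank = flank,
              n_pcs = n_pcs, method = method, seed = as.integer(seed))
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read / write a pipeline config as YAML
#'
#' The YAML round-trips losslessly through [pipelineConfig()]; unknown keys
#' are rejected.
#'
#' @param path YAML file path.
#' @return A `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  simArgs <- y$sim
  y$sim <- NULL
  known <- setdiff(names(formals(pipelineConfig)), "sim")
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(simArgs)) {
    badS <- setdiff(names(simArgs), names(formals(simConfig)))
    if (length(badS))
      stop("unknown sim config keys: ", paste(badS, collapse = ", "))
  }
  sim <- do.call(simConfig, if (is.null(simArgs)) list() else simArgs)
  do.call(pipelineConfig, c(list(sim = sim), y))
}

#' @rdname readPipelineConfig
#' @param config a `PipelineConfig`.
#' @export
writePipelineConfig <- function(config, path) {
  y <- unclass(config)
  y$sim <- unclass(y$sim)
  yaml::write_yaml(y, path)
  invisible(path)
}

.stageLog <- function(verbose, stage, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full analysis pipeline
#'
#' Simulates a cohort (unless one is supplied), applies QC (detection mask,
#' sample filter, probe filters, chemistry correction, SNP filters),
#' computes the kinship matrix and methylation PCs, fits the per-CpG
#' variance-component model, classifies highly heritable CpGs by the
#' expanding-window meQTL scan, estimates relative-pair correlations, runs
#' the family-extremes screen on the genotype-independent set, and tests
#' island-relation and gene-region enrichment across classes.
#'
#' @param config a [pipelineConfig()].
#' @param cohort optional precomputed cohort list (as from
#'   [simulateCohort()]: `ped`, `geno`, `methyl`, `truth`); when absent one
#'   is simulated from `config$sim`.
#' @param outdir optional directory; when given, all result tables are
#'   written there as TSV/JSON.
#' @param verbose log stage-by-stage counts (default TRUE).
#' @return list bundle: `ped`, `kinship`, `qc_report`, `methyl`, `geno`,
#'   `pcs`, `h2` (results + residuals), `heritable`, `meqtl`, `famcorr`,
#'   `extremes`, `enrichment`, `truth` (when simulated).
#' @export
runPipeline <- function(config = pipelineConfig(), cohort = NULL,
                        outdir = NULL, verbose = TRUE) {
  if (is.null(cohort)) {
    .stageLog(verbose, "simulate", "families=%d cpgs=%d snps=%d seed=%d",
              config$sim$n_families, config$sim$n_cpgs, config$sim$n_snps,
              config$sim$seed)
    cohort <- simulateCohort(config$sim)
  }
  ped <- cohort$ped
  me <- cohort$methyl
  geno <- cohort$geno
  if (is.null(geno)) stop("configuration error: no genotypes available")
  reports <- list()

  ## QC
  n0 <- dim(me)
  if (!is.null(detP(me))) me <- maskByDetection(me, threshold = config$detection_p)
  fs <- filterSamples(me, config$sample_missing)
  me <- fs$methyl; reports$samples <- fs$report
  .stageLog(verbose, "qc", "samples in=%d out=%d", n0[2], ncol(me))
  fp <- filterProbes(me, config$probe_missing, config$probe_sd)
  me <- fp$methyl; reports$probes <- fp$report
  .stageLog(verbose, "qc", "probes in=%d out=%d", n0[1], nrow(me))
  me <- tryCatch(chemistryCorrect(me), error = function(e) {
    .stageLog(verbose, "qc", "chemistry correction skipped: %s",
              conditionMessage(e))
    me
  })
  keepG <- intersect(colnames(dosages(geno)), colnames(me))
  fsnp <- filterSnps(geno[, keepG], ped, config$call_rate, config$maf,
                     config$perfam_maf, config$perfam_frac)
  geno <- fsnp$geno; reports$snps <- fsnp$report
  .stageLog(verbose, "qc", "snps out=%d", nrow(geno))

  ## kinship + covariates
  pedSub <- Pedigree(
    pedData(ped)$family, pedData(ped)$id, pedData(ped)$father,
    pedData(ped)$mother, pedData(ped)$sex)
  A <- if (!is.null(cohort$kinship)) cohort$kinship else
    kinshipMatrix(pedSub, "relatedness")
  A <- A[colnames(me), colnames(me)]
  pcs <- computePCs(me, config$n_pcs)
  cd <- as.data.frame(SummarizedExperiment::colData(me))
  X <- cbind(intercept = 1, age = cd$age,
             sex = as.integer(cd$sex == "female"), pcs)
  .stageLog(verbose, "model", "n=%d covariates=%d", nrow(X), ncol(X))

  ## heritability scan
  h2 <- runGenomewide(me, X, A, config$method)
  sets <- classifyHeritable(h2$results, config$h2_threshold)
  .stageLog(verbose, "h2", "heritable=%d non-heritable=%d",
            length(sets$heritable), length(sets$non_heritable))

  ## meQTL classification of the heritable set
  pr <- as.data.frame(SummarizedExperiment::rowData(me))
  her <- pr[pr$cpg_id %in% sets$heritable, c("cpg_id", "chrom", "pos")]
  mq <- classifyAll(her, h2$residuals, geno, alpha = config$alpha)
  .stageLog(verbose, "meqtl", "cis=%d trans=%d GIC=%d",
            mq$counts["cis"], mq$counts["trans"], mq$counts["GIC"])

  ## familial correlations + extremes screen on GICs
  pairs <- enumeratePairs(ped)
  fc <- correlationsByRelationship(me, pairs)
  gic <- mq$classification$cpg_id[mq$classification$category %in% "GIC"]
  ext <- if (length(gic)) familyExtremesCheck(me, ped, gic) else NULL

  ## enrichment across classes
  cls <- rbind(
    data.frame(cpg_id = mq$classification$cpg_id,
               class = mq$classification$category,
               stringsAsFactors = FALSE),
    data.frame(cpg_id = sets$non_heritable, class = "non-heritable",
               stringsAsFactors = FALSE))
  enr <- list()
  tabIsl <- try(enrichmentTest(cls, pr, "island_relation"), silent = TRUE)
  if (!inherits(tabIsl, "try-error")) enr$island <- tabIsl
  expd <- expandByGene(cls, pr)
  if (nrow(expd)) {
    tabReg <- try(enrichmentTest(
      data.frame(cpg_id = seq_len(nrow(expd)), class = expd$class),
      expd$region), silent = TRUE)
    if (!inherits(tabReg, "try-error")) enr$region <- tabReg
  }

  bundle <- list(ped = ped, kinship = A, qc_report = reports, methyl = me,
                 geno = geno, pcs = pcs, h2 = h2, heritable = sets,
                 meqtl = mq, famcorr = fc, extremes = ext, enrichment = enr,
                 truth = cohort$truth)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    writePed(ped, file.path(outdir, "pedigree.ped"))
    writeMatrixTsv(A, file.path(outdir, "kinship.tsv"), "id")
    writeMethylTsv(me, file.path(outdir, "methyl"))
    writeDosageTsv(geno, file.path(outdir, "dosage.tsv"))
    data.table::fwrite(h2$results, file.path(outdir, "h2_results.tsv"),
                       sep = "\t", na = "NA", quote = FALSE)
    writeMatrixTsv(h2$residuals, file.path(outdir, "residuals.tsv"), "cpg_id")
    data.table::fwrite(mq$classification,
                       file.path(outdir, "meqtl_classification.tsv"),
                       sep = "\t", na = "NA", quote = FALSE)
    data.table::fwrite(fc, file.path(outdir, "famcorr.tsv"), sep = "\t",
                       na = "NA", quote = FALSE)
    if (!is.null(ext))
      data.table::fwrite(ext, file.path(outdir, "extremes.tsv"), sep = "\t",
                         na = "NA", quote = FALSE)
    jsonlite::write_json(
      list(qc = reports,
           stage_counts = as.list(mq$stage_counts),
           categories = as.list(mq$counts)),
      file.path(outdir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  bundle
}
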