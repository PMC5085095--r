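## Expanding-window SNP association scan on mixed-model residuals.
## Windows grow 5 kb -> 20 kb -> 100 kb -> 1 Mb -> 3 Mb -> chromosome ->
## genome; the scan stops at the first stage containing a SNP with
## p < alpha (default 1e-7). The best SNP of that stage decides the
## category: same chromosome and <= 1 Mb away = cis, otherwise trans; no
## significant SNP anywhere = genotype-independent (GIC).

#' Default window schedule
#'
#' Symmetric +/- windows around the CpG position, then the whole chromosome,
#' then the genome.
#' @return list of stages; numeric entries are half-widths in bp.
#' @export
windowSchedule <- function()
  list(`5kb` = 5e3, `20kb` = 2e4, `100kb` = 1e5, `1Mb` = 1e6, `3Mb` = 3e6,
       chromosome = "chromosome", genome = "genome")

#' Residual-on-dosage association scan
#'
#' Simple linear regression of a residual vector on minor-allele dosage for
#' each SNP, with per-SNP pairwise deletion of missing dosages. Returns the
#' slope and the two-sided t-test p-value on the slope. SNPs with fewer than
#' 10 informative samples are skipped (`p = NA`, reason recorded); SNPs with
#' zero dosage variance in the analysis subset get `p = 1`, flagged.
#'
#' @param resid named residual vector (samples).
#' @param geno genotype `SummarizedExperiment`; samples are intersected with
#'   `names(resid)` by name.
#' @param snpIdx optional integer subset of SNP rows to test.
#' @return data.frame: `snp`, `slope`, `p`, `n`, `flag`.
#' @export
assocScan <- function(resid, geno, snpIdx = NULL) {
  D <- dosages(geno)
  info <- snpInfo(geno)
  if (!is.null(snpIdx)) {
    D <- D[snpIdx, , drop = FALSE]
    info <- info[snpIdx, , drop = FALSE]
  }
  common <- intersect(colnames(D), names(resid))
  D <- D[, common, drop = FALSE]
  r <- resid[common]
  ro <- !is.na(r)
  r0 <- ifelse(ro, r, 0)
  O <- !is.na(D)
  O[, !ro] <- FALSE
  G0 <- D; G0[!O] <- 0
  ns <- rowSums(O)
  Sg <- rowSums(G0)
  Sg2 <- rowSums(G0^2)
  Sr <- as.vector(O %*% r0)
  Sr2 <- as.vector(O %*% r0^2)
  Sgr <- as.vector(G0 %*% r0)
  Sxx <- Sg2 - Sg^2 / ns
  Syy <- Sr2 - Sr^2 / ns
  Sxy <- Sgr - Sg * Sr / ns
  slope <- Sxy / Sxx
  rxy <- Sxy / sqrt(Sxx * Syy)
  rxy <- pmin(pmax(rxy, -1), 1)
  tt <- rxy * sqrt((ns - 2) / pmax(1 - rxy^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tt), ns - 2)
  flag <- rep(NA_character_, nrow(D))
  zerovar <- Sxx <= 1e-12 * pmax(Sg2, 1)
  p[zerovar] <- 1; slope[zerovar] <- NA; flag[zerovar] <- "zero-variance dosage"
  few <- ns < 10
  p[few] <- NA; slope[few] <- NA; flag[few] <- "fewer than 10 informative samples"
  data.frame(snp = info$snp, slope = slope, p = p, n = ns, flag = flag,
             stringsAsFactors = FALSE)
}

## stage SNP index sets for one CpG (indices into snpInfo rows)
.stageSets <- function(info, chrom, pos, schedule) {
  same <- info$chrom == chrom
  dist <- ifelse(same, abs(info$pos - pos), Inf)
  lapply(schedule, function(st) {
    if (identical(st, "genome")) seq_len(nrow(info))
    else if (identical(st, "chromosome")) which(same)
    else which(same & dist <= st)   # inclusive window edge
  })
}

#' Classify one CpG by the expanding-window procedure
#'
#' Stages are evaluated in schedule order; the scan stops at the first stage
#' whose minimum association p-value is below `alpha`. The best SNP at that
#' stage (smallest p; ties broken by smaller distance, then smaller
#' position) determines the category: cis if on the CpG's chromosome within
#' 1 Mb (inclusive), trans otherwise. If no stage is significant the CpG is
#' genotype independent (`"GIC"`).
#'
#' @param cpg list or one-row data.frame with `cpg_id`, `chrom`, `pos`.
#' @param resid named residual vector for this CpG.
#' @param geno genotype `SummarizedExperiment`.
#' @param schedule window schedule, see [windowSchedule()].
#' @param alpha significance threshold (default 1e-7, applied unchanged at
#'   every stage).
#' @param scan optional precomputed full [assocScan()] for this CpG.
#' @return one-row data.frame: `cpg_id`, `category`, `best_snp`, `best_p`,
#'   `best_distance` (NA for other-chromosome hits), `stage_reached`.
#' @export
expandingWindowClassify <- function(cpg, resid, geno,
                                    schedule = windowSchedule(),
                                    alpha = 1e-7, scan = NULL) {
  if (is.null(cpg$chrom) || is.na(cpg$chrom) || is.na(cpg$pos))
    stop("input error: CpG has no annotated chromosome/position")
  info <- snpInfo(geno)
  if (is.null(scan)) scan <- assocScan(resid, geno)
  sets <- .stageSets(info, cpg$chrom, cpg$pos, schedule)
  same <- info$chrom == cpg$chrom
  dist <- ifelse(same, abs(info$pos - cpg$pos), Inf)
  for (k in seq_along(sets)) {
    ix <- sets[[k]]
    if (!length(ix)) next
    pv <- scan$p[ix]
    hit <- !is.na(pv) & pv < alpha
    if (any(hit)) {
      cand <- ix[hit]
      ord <- order(scan$p[cand], dist[cand], info$pos[cand])
      best <- cand[ord[1]]
      iscis <- same[best] && dist[best] <= 1e6
      return(data.frame(cpg_id = cpg$cpg_id,
                        category = if (iscis) "cis" else "trans",
                        best_snp = info$snp[best], best_p = scan$p[best],
                        best_distance = if (same[best]) dist[best] else NA_real_,
                        stage_reached = names(schedule)[k],
                        stringsAsFactors = FALSE))
    }
  }
  data.frame(cpg_id = cpg$cpg_id, category = "GIC", best_snp = NA_character_,
             best_p = NA_real_, best_distance = NA_real_,
             stage_reached = "genome", stringsAsFactors = FALSE)
}

#' Classify every highly heritable CpG
#'
#' Runs [expandingWindowClassify()] for each CpG in `cpgs` using its row of
#' the residual matrix. Per-CpG failures are recorded and the scan
#' continues.
#'
#' @param cpgs data.frame with `cpg_id`, `chrom`, `pos` (the heritable set).
#' @param residMat residual matrix, CpGs x samples (rownames = cpg ids).
#' @param geno genotype `SummarizedExperiment`.
#' @param schedule,alpha see [expandingWindowClassify()].
#' @return list with `classification` (one row per CpG; failed CpGs get
#'   category `NA` and an `error` message) and `counts` (table of categories)
#'   and `stage_counts`.
#' @export
classifyAll <- function(cpgs, residMat, geno, schedule = windowSchedule(),
                        alpha = 1e-7) {
  rows <- vector("list", nrow(cpgs))
  for (i in seq_len(nrow(cpgs))) {
    rows[[i]] <- tryCatch({
      r <- residMat[cpgs$cpg_id[i], ]
      cbind(expandingWindowClassify(cpgs[i, ], r, geno, schedule, alpha),
            error = NA_character_)
    }, error = function(e)
      data.frame(cpg_id = cpgs$cpg_id[i], category = NA_character_,
                 best_snp = NA_character_, best_p = NA_real_,
                 best_distance = NA_real_, stage_reached = NA_character_,
                 error = conditionMessage(e), stringsAsFactors = FALSE))
  }
  cls <- do.call(rbind, rows)
  if (is.null(cls))
    cls <- data.frame(cpg_id = character(), category = character(),
                      best_snp = character(), best_p = numeric(),
                      best_distance = numeric(), stage_reached = character(),
                      error = character(), stringsAsFactors = FALSE)
  list(classification = cls,
       counts = table(factor(cls$category, c("cis", "trans", "GIC"))),
       stage_counts = table(cls$stage_reached))
}
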