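## Array-style quality control: detection-p masking, sample/probe/SNP
## filters, Infinium I/II chemistry correction, methylation principal
## components. Filters follow a fixed order so the bookkeeping is
## deterministic: detection mask -> sample filter -> probe filters.

.qcReport <- function(axis, rule, removed, retained)
  data.frame(axis = axis, rule = rule, removed = removed, retained = retained,
             stringsAsFactors = FALSE)

#' Mask beta values by detection p-value
#'
#' Entries whose detection p-value exceeds `threshold` (default 0.01) are
#' set to missing; nothing else changes.
#'
#' @param m a [MethylExperiment-class].
#' @param detp optional detection p-value matrix; defaults to the `detp`
#'   assay. Must match the beta matrix shape.
#' @param threshold masking cutoff (strict `>`).
#' @return the masked [MethylExperiment-class] (detp assay retained).
#' @export
maskByDetection <- function(m, detp = NULL, threshold = 0.01) {
  if (is.null(detp)) detp <- detP(m)
  if (is.null(detp)) stop("input error: no detection p-value matrix")
  B <- betas(m)
  if (!identical(dim(detp), dim(B)))
    stop("input error: detection p-value matrix shape mismatch")
  B[detp > threshold] <- NA_real_
  MethylExperiment(B, detp = detp,
                   probes = as.data.frame(SummarizedExperiment::rowData(m)),
                   samples = as.data.frame(SummarizedExperiment::colData(m)))
}

#' Remove samples with too much missing data
#'
#' Samples whose missing fraction is strictly above `max_missing` (default
#' 1.5%) are removed.
#'
#' @param m a masked [MethylExperiment-class].
#' @param max_missing maximum tolerated missing fraction.
#' @return list with `methyl` (filtered) and `report`.
#' @export
filterSamples <- function(m, max_missing = 0.015) {
  B <- betas(m)
  frac <- colMeans(is.na(B))
  drop <- frac > max_missing
  if (all(drop)) stop("all samples removed by the missing-data filter")
  rep <- .qcReport("sample", "missing > max_missing", sum(drop), sum(!drop))
  list(methyl = m[, !drop], report = rep,
       removed = colnames(B)[drop])
}

#' Probe filters
#'
#' Applies, in this order: drop non-autosomal probes; drop probes with more
#' than `max_missing` missing entries; drop probes whose SD across observed
#' samples is `<= min_sd` (default 0.02, so constant probes go too); drop
#' probes flagged for a polymorphic SNP in the probe body; drop probes
#' flagged as multimapping. Flags are taken from `rowData` columns
#' `snp_flag` / `multimap_flag` unless supplied. Each rule's removal count
#' refers to the survivors of the previous rules.
#'
#' @param m a [MethylExperiment-class].
#' @param max_missing maximum probe missing fraction (strict `>` removes).
#' @param min_sd minimum SD across observed samples (`<=` removes).
#' @param drop_nonautosomal drop probes on chrX/chrY?
#' @param probe_snp_flags,multimap_flags optional logical vectors per probe.
#' @return list with `methyl` and `report` (one row per rule).
#' @export
filterProbes <- function(m, max_missing = 0.10, min_sd = 0.02,
                         drop_nonautosomal = TRUE, probe_snp_flags = NULL,
                         multimap_flags = NULL) {
  pr <- as.data.frame(SummarizedExperiment::rowData(m))
  if (is.null(probe_snp_flags))
    probe_snp_flags <- if (!is.null(pr$snp_flag)) pr$snp_flag else
      rep(FALSE, nrow(m))
  if (is.null(multimap_flags))
    multimap_flags <- if (!is.null(pr$multimap_flag)) pr$multimap_flag else
      rep(FALSE, nrow(m))
  rpt <- NULL
  keep <- rep(TRUE, nrow(m))
  step <- function(bad, rule) {
    bad <- bad & keep
    rpt <<- rbind(rpt, .qcReport("probe", rule, sum(bad), sum(keep & !bad)))
    keep <<- keep & !bad
  }
  if (drop_nonautosomal)
    step(pr$chrom %in% c("chrX", "chrY", "X", "Y"), "non-autosomal")
  B <- betas(m)
  step(rowMeans(is.na(B)) > max_missing, "missing > max_missing")
  sds <- apply(B, 1, sd, na.rm = TRUE)
  sds[is.na(sds)] <- 0
  step(sds <= min_sd, "sd <= min_sd")
  step(as.logical(probe_snp_flags), "probe SNP")
  step(as.logical(multimap_flags), "multimapping")
  list(methyl = m[keep, ], report = rpt)
}

#' Infinium I/II chemistry correction
#'
#' Finds probe pairs of differing chemistries within `pair_window` bp of
#' each other on the same chromosome, fits a least-squares quadratic mapping
#' from the type-II to the type-I beta over all per-pair per-sample value
#' pairs, and applies the mapping to every type-II probe (clipped to [0,1]).
#' Type-I probes are unchanged. Requires at least 30 such pairs. If the
#' fitted polynomial is non-monotone on [0,1] a warning is recorded.
#'
#' @param m a [MethylExperiment-class] with `chemistry` in `rowData`.
#' @param pair_window maximum pair distance in bp (default 50).
#' @return the corrected [MethylExperiment-class], with the fitted
#'   coefficients in `metadata(m)$chemistry_fit`.
#' @export
chemistryCorrect <- function(m, pair_window = 50) {
  pr <- as.data.frame(SummarizedExperiment::rowData(m))
  if (is.null(pr$chemistry)) stop("input error: no chemistry labels")
  B <- betas(m)
  ordIx <- order(pr$chrom, pr$pos)
  pairs <- list()
  oi <- ordIx
  for (k in seq_len(length(oi) - 1)) {
    a <- oi[k]
    for (l in (k + 1):length(oi)) {
      b <- oi[l]
      if (pr$chrom[b] != pr$chrom[a] || pr$pos[b] - pr$pos[a] > pair_window)
        break
      if (pr$chemistry[a] != pr$chemistry[b]) {
        one <- if (pr$chemistry[a] == "I") a else b
        two <- if (pr$chemistry[a] == "I") b else a
        pairs[[length(pairs) + 1L]] <- c(one, two)
      }
    }
  }
  if (length(pairs) < 30)
    stop("calibration error: only ", length(pairs),
         " type I/II probe pairs within ", pair_window, " bp (need >= 30)")
  P <- do.call(rbind, pairs)
  x <- as.vector(B[P[, 2], ])   # type II
  y <- as.vector(B[P[, 1], ])   # type I (reference)
  ok <- !is.na(x) & !is.na(y)
  fit <- lm(y ~ x + I(x^2), data = data.frame(x = x[ok], y = y[ok]))
  co <- unname(coef(fit))
  ## derivative c1 + 2 c2 t on [0,1]
  if (min(co[2], co[2] + 2 * co[3]) < 0)
    warning("fitted chemistry polynomial is non-monotone on [0, 1]")
  ii <- pr$chemistry == "II"
  B[ii, ] <- pmin(pmax(co[1] + co[2] * B[ii, ] + co[3] * B[ii, ]^2, 0), 1)
  out <- MethylExperiment(B, detp = detP(m), probes = pr,
                          samples = as.data.frame(SummarizedExperiment::colData(m)))
  S4Vectors::metadata(out)$chemistry_fit <- co
  out
}

## minor-allele frequency of a dosage vector (NA-tolerant)
.maf <- function(d) {
  d <- d[!is.na(d)]
  if (!length(d)) return(NA_real_)
  p <- mean(d) / 2
  min(p, 1 - p)
}

#' SNP filters
#'
#' A SNP is retained iff its call rate is at least `min_call`, its overall
#' minor-allele frequency is strictly above `min_maf`, and the fraction of
#' families (from the pedigree) with a within-family MAF above `perfam_maf`
#' is at least `perfam_frac`.
#'
#' @param geno genotype `SummarizedExperiment`.
#' @param ped a [Pedigree-class]; genotyped samples must be pedigree members.
#' @param min_call minimum call rate (default 0.95).
#' @param min_maf overall MAF threshold (default 0.01, strict `>`).
#' @param perfam_maf within-family MAF threshold (default 0.01, strict `>`).
#' @param perfam_frac minimum fraction of families passing (default 0.10).
#' @return list with `geno` (filtered) and `report` (one row per rule).
#' @export
filterSnps <- function(geno, ped, min_call = 0.95, min_maf = 0.01,
                       perfam_maf = 0.01, perfam_frac = 0.10) {
  D <- dosages(geno)
  p <- pedData(ped)
  if (!all(colnames(D) %in% p$id))
    stop("input error: genotyped samples missing from the pedigree")
  fam <- p$family[match(colnames(D), p$id)]
  rpt <- NULL
  keep <- rep(TRUE, nrow(D))
  step <- function(bad, rule) {
    bad <- bad & keep
    rpt <<- rbind(rpt, .qcReport("snp", rule, sum(bad), sum(keep & !bad)))
    keep <<- keep & !bad
  }
  call <- rowMeans(!is.na(D))
  step(call < min_call, "call rate < min_call")
  maf <- apply(D, 1, .maf)
  step(!(maf > min_maf), "MAF <= min_maf")
  famIdx <- split(seq_len(ncol(D)), fam)
  passMat <- matrix(vapply(famIdx, function(ix)
    apply(D[, ix, drop = FALSE], 1, .maf) > perfam_maf, logical(nrow(D))),
    nrow = nrow(D))
  passFrac <- rowMeans(passMat)
  step(passFrac < perfam_frac, "per-family MAF rule")
  list(geno = geno[keep, ], report = rpt)
}

#' Methylation principal components
#'
#' Column-centered SVD scores of the sample x probe matrix (missing entries
#' mean-imputed per probe for the decomposition only), ordered by variance
#' explained, with the sign of each component fixed so that its
#' largest-magnitude probe loading is positive. These serve as
#' cell-composition / technical covariates in the mixed model.
#'
#' @param m a [MethylExperiment-class] or beta matrix (CpGs x samples).
#' @param k number of components (default 4).
#' @return samples x k score matrix (columns `PC1..PCk`).
#' @export
computePCs <- function(m, k = 4) {
  B <- if (is(m, "MethylExperiment")) betas(m) else m
  mu <- rowMeans(B, na.rm = TRUE)
  for (j in which(rowSums(is.na(B)) > 0))
    B[j, is.na(B[j, ])] <- mu[j]
  Xs <- t(B)
  pc <- prcomp(Xs, center = TRUE, scale. = FALSE)
  if (k > ncol(pc$x)) stop("k = ", k, " exceeds the rank of the data")
  sc <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    load <- pc$rotation[, j]
    if (load[which.max(abs(load))] < 0) sc[, j] <- -sc[, j]
  }
  colnames(sc) <- paste0("PC", seq_len(k))
  rownames(sc) <- colnames(B)
  sc
}
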