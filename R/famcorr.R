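## Weighted correlations for typed relative pairs and the rare-variant
## family-extremes screen.

#' Weighted pair correlation
#'
#' Weighted Pearson-type correlation over pairs \eqn{(x_i, y_i)} with
#' weights \eqn{w_i}:
#' \deqn{r = \frac{\sum_i w_i (x_i-\bar x)(y_i-\bar y)}
#'   {\sqrt{\sum_i w_i (x_i-\bar x)^2\; \sum_i w_i (y_i-\bar y)^2}}}
#' where \eqn{\bar x,\bar y} are weighted means with the same weights. With
#' uniform weights this is the ordinary Pearson correlation.
#'
#' @param x,y numeric vectors of equal length (one entry per pair).
#' @param w positive weights (default uniform).
#' @return the correlation, or `NA` if either weighted variance is zero or
#'   fewer than 2 pairs are given.
#' @examples
#' weightedPairCorrelation(c(1, 2, 3), c(2, 4, 6), c(1, 2, 1))  # 1
#' @export
weightedPairCorrelation <- function(x, y, w = rep(1, length(x))) {
  stopifnot(length(x) == length(y), length(w) == length(x))
  if (length(x) < 2) return(NA_real_)
  if (any(w <= 0)) stop("weights must be positive")
  xb <- sum(w * x) / sum(w)
  yb <- sum(w * y) / sum(w)
  num <- sum(w * (x - xb) * (y - yb))
  vx <- sum(w * (x - xb)^2)
  vy <- sum(w * (y - yb)^2)
  if (vx <= 0 || vy <= 0) return(NA_real_)
  num / sqrt(vx * vy)
}

## matrix version: rows = CpGs, columns = pairs; one r per row
.rowWeightedCor <- function(X, Y, w) {
  sw <- sum(w)
  xb <- (X %*% w) / sw
  yb <- (Y %*% w) / sw
  Xc <- X - as.vector(xb)
  Yc <- Y - as.vector(yb)
  num <- (Xc * Yc) %*% w
  vx <- (Xc^2) %*% w
  vy <- (Yc^2) %*% w
  r <- as.vector(num) / sqrt(as.vector(vx) * as.vector(vy))
  r[as.vector(vx) <= 0 | as.vector(vy) <= 0] <- NA_real_
  r
}

#' Per-CpG correlations by relationship type
#'
#' One weighted correlation per CpG per relationship type (and gender
#' subtype). Symmetric types (sibling-sibling, cousin-cousin, mother-father,
#' and the same-sex subtypes) are double-entered — each pair contributes as
#' (a,b) and (b,a) — so the estimate is order-invariant; asymmetric types
#' put the elder member (parent, grandparent, aunt/uncle) in x.
#'
#' @param m a [MethylExperiment-class] or beta matrix.
#' @param pairs relative pairs from [enumeratePairs()].
#' @param cpgs optional subset of CpG ids (default all).
#' @param weights `"uniform"` (default) or `"family-size"`, which weights
#'   each pair by 1 / (number of pairs of the same type in its family) to
#'   downweight large sibships.
#' @param subtypes also compute gender subtypes? (default TRUE)
#' @return data.frame with `cpg_id`, `relationship`, `subtype`, `n_pairs`,
#'   `r`. Relationship/subtype combinations with fewer than 2 pairs get
#'   `r = NA`.
#' @export
correlationsByRelationship <- function(m, pairs, cpgs = NULL,
                                       weights = c("uniform", "family-size"),
                                       subtypes = TRUE) {
  weights <- match.arg(weights)
  B <- if (is(m, "MethylExperiment")) betas(m) else m
  if (!is.null(cpgs)) B <- B[cpgs, , drop = FALSE]
  symTypes <- c("sibling-sibling", "cousin-cousin", "mother-father")
  groups <- split(pairs, pairs$relationship)
  if (subtypes) {
    sub <- pairs[pairs$subtype != "all", ]
    if (nrow(sub))
      groups <- c(groups, split(sub, paste(sub$relationship, sub$subtype,
                                           sep = "\r")))
  }
  out <- list()
  for (g in names(groups)) {
    pp <- groups[[g]]
    nm <- strsplit(g, "\r", fixed = TRUE)[[1]]
    rel <- nm[1]
    sty <- if (length(nm) > 1) nm[2] else "all"
    pp <- pp[pp$id1 %in% colnames(B) & pp$id2 %in% colnames(B), , drop = FALSE]
    npair <- nrow(pp)
    if (npair < 2) {
      out[[g]] <- data.frame(cpg_id = rownames(B), relationship = rel,
                             subtype = sty, n_pairs = npair, r = NA_real_,
                             stringsAsFactors = FALSE)
      next
    }
    w <- if (weights == "uniform") rep(1, npair) else
      1 / as.vector(table(pp$family)[pp$family])
    dbl <- rel %in% symTypes || sty %in%
      c("brother-brother", "sister-sister", "sister-brother")
    i1 <- match(pp$id1, colnames(B)); i2 <- match(pp$id2, colnames(B))
    if (dbl) {
      X <- cbind(B[, i1, drop = FALSE], B[, i2, drop = FALSE])
      Y <- cbind(B[, i2, drop = FALSE], B[, i1, drop = FALSE])
      ww <- c(w, w)
    } else {
      X <- B[, i1, drop = FALSE]
      Y <- B[, i2, drop = FALSE]
      ww <- w
    }
    ## complete pairs only, handled per CpG via NA propagation
    miss <- is.na(X) | is.na(Y)
    if (any(miss)) {
      r <- vapply(seq_len(nrow(X)), function(j) {
        ok <- !miss[j, ]
        if (sum(ok) < 2) return(NA_real_)
        weightedPairCorrelation(X[j, ok], Y[j, ok], ww[ok])
      }, numeric(1))
    } else {
      r <- .rowWeightedCor(X, Y, ww)
    }
    out[[g]] <- data.frame(cpg_id = rownames(B), relationship = rel,
                           subtype = sty, n_pairs = npair, r = r,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize pair correlations by relationship
#'
#' Median and quartiles of the per-CpG correlations for each relationship
#' type / subtype (the numbers behind the density plots).
#'
#' @param tab output of [correlationsByRelationship()].
#' @return data.frame with `relationship`, `subtype`, `n_cpgs`, `median_r`,
#'   `q1`, `q3`, `mean_r`.
#' @export
summarizeCorrelations <- function(tab) {
  sp <- split(tab, paste(tab$relationship, tab$subtype, sep = "\r"))
  res <- lapply(sp, function(d) {
    r <- d$r[!is.na(d$r)]
    data.frame(relationship = d$relationship[1], subtype = d$subtype[1],
               n_cpgs = length(r),
               median_r = if (length(r)) stats::median(r) else NA_real_,
               q1 = if (length(r)) quantile(r, 0.25, names = FALSE) else NA_real_,
               q3 = if (length(r)) quantile(r, 0.75, names = FALSE) else NA_real_,
               mean_r = if (length(r)) mean(r) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Family-extremes screen for private (rare-variant-like) effects
#'
#' For each CpG, takes the `k` largest and `k` smallest observed beta scores
#' (ties broken by sample id for determinism), counts the distinct families
#' represented and the maximum number of individuals any single family
#' contributes in each extreme, and flags CpGs where one family contributes
#' more than 3 individuals to either extreme — the signature expected if a
#' rare variant private to a family drives the methylation.
#'
#' @param m a [MethylExperiment-class] or beta matrix.
#' @param ped a [Pedigree-class].
#' @param cpgs CpG ids to screen (default all).
#' @param k number of extreme values per tail (default 10).
#' @return data.frame with `cpg_id`, `families_max`, `families_min`,
#'   `max_per_family`, `flagged`, `skipped`, `reason`.
#' @export
familyExtremesCheck <- function(m, ped, cpgs = NULL, k = 10) {
  B <- if (is(m, "MethylExperiment")) betas(m) else m
  if (!is.null(cpgs)) B <- B[cpgs, , drop = FALSE]
  p <- pedData(ped)
  fam <- setNames(p$family, p$id)
  out <- vector("list", nrow(B))
  for (j in seq_len(nrow(B))) {
    v <- B[j, ]
    obs <- names(v)[!is.na(v)]
    if (length(obs) < k) {
      out[[j]] <- data.frame(cpg_id = rownames(B)[j], families_max = NA_integer_,
                             families_min = NA_integer_,
                             max_per_family = NA_integer_, flagged = NA,
                             skipped = TRUE,
                             reason = sprintf("only %d non-missing samples (need %d)",
                                              length(obs), k),
                             stringsAsFactors = FALSE)
      next
    }
    vv <- v[obs]
    topIds <- obs[order(-vv, obs)][seq_len(k)]
    botIds <- obs[order(vv, obs)][seq_len(k)]
    fmax <- table(fam[topIds])
    fmin <- table(fam[botIds])
    mpf <- max(max(fmax), max(fmin))
    out[[j]] <- data.frame(cpg_id = rownames(B)[j],
                           families_max = length(fmax),
                           families_min = length(fmin),
                           max_per_family = as.integer(mpf),
                           flagged = mpf > 3, skipped = FALSE,
                           reason = NA_character_, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
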