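## Kinship mixed model per CpG:
##   y = X beta + g + e,   g ~ N(0, sigma2_g A),   e ~ N(0, sigma2_e I)
## Broad-sense heritability H2 = sigma2_g / (sigma2_g + sigma2_e).
##
## Fitting profiles the restricted likelihood over the single ratio
## h = sigma2_g / (sigma2_g + sigma2_e) on [0,1] after rotating into the
## eigenbasis of A: Var(U'y) = sigma2 * diag(h d + (1-h)), so every
## evaluation is O(n p^2). One eigendecomposition per pedigree serves the
## whole genome-wide scan.

.eigenKinship <- function(A) {
  e <- eigen(A, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values)))
    stop("input error: kinship matrix is not positive semidefinite")
  e$values <- pmax(e$values, 0)
  e
}

## restricted (or ML) log-likelihood at ratio h, in the rotated basis
.vcLoglik <- function(h, d, yt, Xt, method = "REML") {
  n <- length(yt); p <- ncol(Xt)
  w <- h * d + (1 - h)
  if (any(w <= 0)) return(-Inf)
  Xw <- Xt / w
  XtWX <- crossprod(Xt, Xw)
  ch <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  beta <- backsolve(ch, forwardsolve(t(ch), crossprod(Xw, yt)))
  r <- yt - Xt %*% beta
  rss <- sum(r^2 / w)
  if (method == "REML") {
    s2 <- rss / (n - p)
    ll <- -0.5 * ((n - p) * log(2 * pi * s2) + sum(log(w)) +
                    2 * sum(log(diag(ch))) + (n - p))
  } else {
    s2 <- rss / n
    ll <- -0.5 * (n * log(2 * pi * s2) + sum(log(w)) + n)
  }
  list(ll = ll, beta = beta, sigma2 = s2)
}

#' Fit the per-CpG kinship variance-component model
#'
#' Estimates \eqn{\sigma^2_g} (family/kinship component) and
#' \eqn{\sigma^2_e} (residual) for a single outcome by bounded scalar
#' optimization (tolerance 1e-8) of the profiled restricted likelihood over
#' \eqn{h = \sigma^2_g/(\sigma^2_g+\sigma^2_e) \in [0,1]}. Both boundary
#' values are evaluated explicitly; a boundary optimum is returned with
#' `boundary = TRUE`, not as an error. With a degenerate kinship matrix
#' proportional to the identity the ratio is not identifiable: a warning is
#' issued and `non_identifiable = TRUE` is set.
#'
#' @param y numeric outcome vector (one CpG's beta scores). `NA` entries are
#'   dropped together with the matching rows of `X` and `A`.
#' @param X fixed-effect design matrix (with intercept); typically age, sex
#'   and the first four methylation principal components.
#' @param A relatedness matrix aligned with `y` (see [kinshipMatrix()]), or a
#'   precomputed `eigen()` of it (complete-case data only).
#' @param method `"REML"` (default) or `"ML"`.
#' @return list with `h2`, `sigma2_g`, `sigma2_e`, `beta` (named fixed-effect
#'   estimates), `residuals` (y - X beta on the original scale, `NA` where y
#'   was missing), `loglik`, `converged`, `boundary`, `non_identifiable`,
#'   `n`.
#' @export
fitVarianceComponents <- function(y, X, A, method = c("REML", "ML")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  obs <- !is.na(y)
  pre <- is.list(A) && !is.null(A$vectors)
  if (!all(obs)) {
    if (pre) stop("precomputed eigendecomposition requires complete y")
    y0 <- y[obs]; X0 <- X[obs, , drop = FALSE]
    e <- .eigenKinship(A[obs, obs, drop = FALSE])
  } else {
    y0 <- y; X0 <- X
    e <- if (pre) A else .eigenKinship(A)
  }
  n <- length(y0)
  ## drop constant non-intercept columns that lost their variance
  keep <- c(TRUE, apply(X0[, -1, drop = FALSE], 2, function(v) sd(v) > 0))
  X0 <- X0[, keep, drop = FALSE]
  p <- ncol(X0)
  if (n <= p + 2) stop("input error: too few observations (", n, ") for ",
                       p, " fixed effects")
  d <- e$values
  yt <- crossprod(e$vectors, y0)
  Xt <- crossprod(e$vectors, X0)
  nonid <- (max(d) - min(d)) < 1e-8 * max(max(d), 1)
  if (nonid)
    warning("kinship matrix is proportional to the identity; ",
            "the variance ratio is not identifiable")
  obj <- function(h) .vcLoglik(h, d, yt, Xt, method)$ll
  opt <- optimize(obj, c(0, 1), maximum = TRUE, tol = 1e-8)
  cand <- c(opt$maximum, 0, 1)
  lls <- c(opt$objective, obj(0), obj(1))
  h <- cand[which.max(lls)]
  fit <- .vcLoglik(h, d, yt, Xt, method)
  beta <- setNames(as.vector(fit$beta), colnames(X0))
  res <- setNames(rep(NA_real_, length(y)), names(y))
  res[obs] <- y0 - as.vector(X0 %*% fit$beta)
  list(h2 = h, sigma2_g = h * fit$sigma2, sigma2_e = (1 - h) * fit$sigma2,
       beta = beta, residuals = res, loglik = fit$ll,
       converged = is.finite(fit$ll), boundary = h %in% c(0, 1),
       non_identifiable = nonid, n = n)
}

#' Genome-wide heritability scan
#'
#' Fits [fitVarianceComponents()] for every probe. The kinship matrix is
#' eigendecomposed once and reused for all complete-case probes; probes with
#' missing entries fall back to a per-missingness-pattern decomposition
#' (patterns are cached). Per-probe failures are flagged, never abort the
#' scan.
#'
#' @param m a [MethylExperiment-class] or beta matrix (CpGs x samples).
#' @param X fixed-effect design matrix (n samples x p, with intercept).
#' @param A relatedness matrix aligned with the samples.
#' @param method `"REML"` or `"ML"`.
#' @return list with `results` (data.frame: `cpg_id`, `h2`, `sigma2_g`,
#'   `sigma2_e`, `loglik`, `converged`, `boundary`, `n`, `error`) and
#'   `residuals` (CpG x sample matrix).
#' @export
runGenomewide <- function(m, X, A, method = "REML") {
  B <- if (is(m, "MethylExperiment")) betas(m) else m
  stopifnot(ncol(B) == nrow(A))
  eFull <- .eigenKinship(A)
  cache <- new.env(parent = emptyenv())
  nC <- nrow(B)
  res <- data.frame(cpg_id = rownames(B), h2 = NA_real_, sigma2_g = NA_real_,
                    sigma2_e = NA_real_, loglik = NA_real_, converged = FALSE,
                    boundary = FALSE, n = NA_integer_, error = NA_character_,
                    stringsAsFactors = FALSE)
  R <- matrix(NA_real_, nC, ncol(B), dimnames = dimnames(B))
  for (j in seq_len(nC)) {
    y <- B[j, ]
    fit <- tryCatch({
      if (anyNA(y)) {
        key <- paste(which(is.na(y)), collapse = ",")
        if (is.null(cache[[key]])) {
          obs <- !is.na(y)
          cache[[key]] <- .eigenKinship(A[obs, obs, drop = FALSE])
        }
        obs <- !is.na(y)
        f <- fitVarianceComponents(y[obs], X[obs, , drop = FALSE],
                                   cache[[key]], method)
        r <- rep(NA_real_, length(y)); r[obs] <- f$residuals
        f$residuals <- r
        f
      } else {
        fitVarianceComponents(y, X, eFull, method)
      }
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      res$error[j] <- conditionMessage(fit)
      next
    }
    res$h2[j] <- fit$h2; res$sigma2_g[j] <- fit$sigma2_g
    res$sigma2_e[j] <- fit$sigma2_e; res$loglik[j] <- fit$loglik
    res$converged[j] <- fit$converged; res$boundary[j] <- fit$boundary
    res$n[j] <- fit$n
    R[j, ] <- fit$residuals
  }
  list(results = res, residuals = R)
}

#' Split probes by the heritability threshold
#'
#' Highly heritable CpGs are those with estimated H2 strictly above
#' `threshold` (default 0.4); the two returned sets are disjoint and
#' exhaustive over probes with a defined estimate.
#'
#' @param results the `results` data.frame from [runGenomewide()].
#' @param threshold heritability cutoff; strict inequality.
#' @return list with character vectors `heritable` and `non_heritable`.
#' @export
classifyHeritable <- function(results, threshold = 0.4) {
  ok <- !is.na(results$h2)
  list(heritable = results$cpg_id[ok & results$h2 > threshold],
       non_heritable = results$cpg_id[ok & results$h2 <= threshold])
}
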