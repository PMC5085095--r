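## Independent oracles and small pedigree fixtures used across the suite.

## --- pedigree builders -----------------------------------------------------

makeTrio <- function(fam = "F1")
  Pedigree(rep(fam, 3), paste0(fam, c("_dad", "_mum", "_kid")),
           c(NA, NA, paste0(fam, "_dad")), c(NA, NA, paste0(fam, "_mum")),
           c("male", "female", "male"))

## three generations, 8 members: grandparents, their two children each
## married with one child
makeThreeGen <- function(fam = "F1") {
  id <- function(x) paste0(fam, "_", x)
  Pedigree(rep(fam, 8),
           id(c("gf", "gm", "s1", "w1", "d2", "h2", "k1", "k2")),
           c(NA, NA, id("gf"), NA, id("gf"), NA, id("s1"), id("h2")),
           c(NA, NA, id("gm"), NA, id("gm"), NA, id("w1"), id("d2")),
           c("male", "female", "male", "female", "female", "male",
             "male", "female"))
}

## random valid pedigree with <= maxn members (for property tests)
randomPedigree <- function(maxn = 12, fam = "R1") {
  n <- sample(3:maxn, 1)
  id <- paste0(fam, "_", seq_len(n))
  sex <- c("male", "female", sample(c("male", "female"), n - 2, replace = TRUE))
  father <- mother <- rep(NA_character_, n)
  for (i in 3:n) {
    males <- which(sex[seq_len(i - 1)] == "male")
    females <- which(sex[seq_len(i - 1)] == "female")
    if (length(males) && length(females) && runif(1) < 0.75) {
      father[i] <- id[males[sample.int(length(males), 1)]]
      mother[i] <- id[females[sample.int(length(females), 1)]]
    }
  }
  Pedigree(rep(fam, n), id, father, mother, sex)
}

## --- path-counting kinship oracle ------------------------------------------

## all ancestral paths from an individual, as id vectors starting at the
## individual; Wright's formula sums (1/2)^(l1+l2+1) over pairs of paths to
## a common ancestor that share no individual except that ancestor
## (non-inbred founders).
.pathsUp <- function(id, fa, mo) {
  out <- list(id)
  for (par in c(fa[id], mo[id])) {
    if (is.na(par)) next
    for (p in .pathsUp(par, fa, mo)) out[[length(out) + 1L]] <- c(id, p)
  }
  out
}

kinshipOracle <- function(ped) {
  p <- pedData(ped)
  fa <- stats::setNames(p$father, p$id)
  mo <- stats::setNames(p$mother, p$id)
  paths <- lapply(p$id, .pathsUp, fa = fa, mo = mo)
  names(paths) <- p$id
  inb <- function(id) {
    if (is.na(fa[id]) || is.na(mo[id])) return(0)
    pairPhi(fa[[id]], mo[[id]])
  }
  pairPhi <- function(u, v) {
    val <- 0
    for (a in paths[[u]]) for (b in paths[[v]]) {
      anc <- a[length(a)]
      if (anc != b[length(b)]) next
      if (length(intersect(a, b)) == 1)
        val <- val + 0.5^(length(a) + length(b) - 1) * (1 + inb(anc))
    }
    val
  }
  n <- nrow(p)
  phi <- matrix(0, n, n, dimnames = list(p$id, p$id))
  for (i in seq_len(n)) for (j in seq_len(i)) {
    if (p$family[i] != p$family[j]) next
    phi[i, j] <- phi[j, i] <- if (i == j) 0.5 * (1 + inb(p$id[i])) else
      pairPhi(p$id[i], p$id[j])
  }
  phi
}

## --- direct (unrotated) restricted likelihood and grid-search oracle -------

remlDirect <- function(y, X, A, h, method = "REML") {
  n <- length(y); p <- ncol(X)
  V <- h * A + (1 - h) * diag(n)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  rss <- drop(t(r) %*% Vi %*% r)
  if (method == "REML") {
    s2 <- rss / (n - p)
    -0.5 * ((n - p) * log(2 * pi * s2) +
              as.numeric(determinant(V)$modulus) +
              as.numeric(determinant(XtViX)$modulus) + (n - p))
  } else {
    s2 <- rss / n
    -0.5 * (n * log(2 * pi * s2) + as.numeric(determinant(V)$modulus) + n)
  }
}

gridSearchH2 <- function(y, X, A, step = 1e-4) {
  ## same restricted likelihood, brute-forced on a grid, but evaluated in
  ## the eigenbasis for speed (one decomposition, direct formula per point)
  e <- eigen(A, symmetric = TRUE)
  d <- pmax(e$values, 0)
  yt <- crossprod(e$vectors, y)
  Xt <- crossprod(e$vectors, X)
  n <- length(y); p <- ncol(X)
  grid <- seq(0, 1, by = step)
  ll <- vapply(grid, function(h) {
    w <- h * d + (1 - h)
    Xw <- Xt / w
    XtWX <- crossprod(Xt, Xw)
    beta <- solve(XtWX, crossprod(Xw, yt))
    rss <- sum((yt - Xt %*% beta)^2 / w)
    s2 <- rss / (n - p)
    -0.5 * ((n - p) * log(2 * pi * s2) + sum(log(w)) +
              as.numeric(determinant(XtWX)$modulus) + (n - p))
  }, numeric(1))
  grid[which.max(ll)]
}

## small simulated variance-component dataset on a given pedigree
simVcData <- function(ped, h2, s = 1, nX = 2) {
  A <- kinshipMatrix(ped, "relatedness")
  n <- nrow(A)
  L <- chol(A + diag(1e-10, n))
  g <- s * sqrt(h2) * drop(crossprod(L, rnorm(n)))
  X <- cbind(1, matrix(rnorm(n * nX), n, nX))
  beta <- rnorm(nX + 1, 0, 0.5)
  y <- drop(X %*% beta) + g + rnorm(n, 0, s * sqrt(1 - h2))
  list(y = y, X = X, A = A)
}

## --- hand-built MethylExperiment for QC filter bookkeeping -----------------

makeQcFixture <- function() {
  set.seed(101)
  nP <- 100; nS <- 50
  B <- matrix(runif(nP * nS, 0.2, 0.8), nP, nS,
              dimnames = list(sprintf("cg%03d", 1:nP), sprintf("s%02d", 1:nS)))
  probes <- data.frame(cpg_id = rownames(B), chrom = "chr1",
                       pos = seq(1e4, by = 1e4, length.out = nP),
                       chemistry = "I", island_relation = "open-sea",
                       gene = NA, region = NA,
                       snp_flag = FALSE, multimap_flag = FALSE,
                       stringsAsFactors = FALSE)
  ## 10 planted violations per rule, in disjoint probe blocks
  probes$chrom[1:10] <- "chrX"                        # non-autosomal
  B[11:20, 1:6] <- NA                                 # 12% missing
  B[21:30, ] <- 0.5                                   # SD 0
  probes$snp_flag[31:40] <- TRUE
  probes$multimap_flag[41:50] <- TRUE
  MethylExperiment(B, probes = probes,
                   samples = data.frame(id = colnames(B)))
}
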