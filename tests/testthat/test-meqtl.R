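## small genotype fixture: n samples, SNPs on two chromosomes
makeGeno <- function(n = 200, m = 60, seed = 1) {
  set.seed(seed)
  ids <- sprintf("s%03d", seq_len(n))
  D <- matrix(rbinom(n * m, 2, 0.3), m, n, dimnames = list(NULL, ids))
  snps <- data.frame(snp = sprintf("snp%03d", seq_len(m)),
                     chrom = rep(c("chr1", "chr2"), each = m / 2),
                     pos = rep(seq(1e5, 4e7, length.out = m / 2), 2),
                     stringsAsFactors = FALSE)
  rownames(D) <- snps$snp
  GenotypeExperiment(D, snps)
}

test_that("association slope and p match the correlation-to-t closed form", {
  g <- makeGeno(300, 40, seed = 2)
  set.seed(3)
  r <- setNames(rnorm(300), colnames(dosages(g)))
  sc <- assocScan(r, g)
  for (i in c(1, 17, 40)) {
    d <- dosages(g)[i, ]
    rxy <- cor(d, r)
    tt <- rxy * sqrt((300 - 2) / (1 - rxy^2))
    expect_equal(sc$p[i], 2 * pt(-abs(tt), 298), tolerance = 1e-10)
    expect_equal(sc$slope[i], cov(d, r) / var(d), tolerance = 1e-10)
  }
})

test_that("a perfect linear signal gives the planted slope and a 0 p-value", {
  g <- makeGeno(700, 10, seed = 4)
  r <- setNames(0.1 * dosages(g)[3, ], colnames(dosages(g)))
  sc <- assocScan(r, g)
  expect_equal(sc$slope[3], 0.1, tolerance = 1e-12)
  expect_lt(sc$p[3], 1e-300)
})

test_that("null SNPs are p-value calibrated and edge cases are flagged", {
  g <- makeGeno(150, 2000, seed = 5)
  set.seed(6)
  r <- setNames(rnorm(150), colnames(dosages(g)))
  sc <- assocScan(r, g)
  frac <- mean(sc$p < 0.01)
  expect_lt(abs(frac - 0.01), 3 * sqrt(0.01 * 0.99 / 2000))

  ## zero-variance dosage -> p = 1, flagged; < 10 informative -> skipped
  D <- dosages(g)[1:3, ]
  D[1, ] <- 1L
  D[2, 10:150] <- NA
  gz <- GenotypeExperiment(D, snpInfo(g)[1:3, ])
  sz <- assocScan(r, gz)
  expect_equal(sz$p[1], 1)
  expect_equal(sz$flag[1], "zero-variance dosage")
  expect_true(is.na(sz$p[2]))
  expect_match(sz$flag[2], "fewer than 10")
})

test_that("missing dosages use pairwise deletion", {
  g <- makeGeno(100, 6, seed = 7)
  D <- dosages(g)
  D[2, 1:20] <- NA
  g2 <- GenotypeExperiment(D, snpInfo(g))
  set.seed(8)
  r <- setNames(rnorm(100), colnames(D))
  sc <- assocScan(r, g2)
  ok <- !is.na(D[2, ])
  ref <- summary(lm(r[ok] ~ D[2, ok]))
  expect_equal(sc$slope[2], unname(coef(ref)[2, 1]), tolerance = 1e-10)
  expect_equal(sc$p[2], unname(coef(ref)[2, 4]), tolerance = 1e-10)
  expect_equal(sc$n[2], sum(ok))
})

test_that("expanding windows stop at the first significant stage", {
  g <- makeGeno(700, 60, seed = 9)
  D <- dosages(g)
  set.seed(10)
  ## causal SNP ~2 kb from the CpG, 30% of residual variance
  causal <- 5
  cpg <- list(cpg_id = "cgA", chrom = snpInfo(g)$chrom[causal],
              pos = snpInfo(g)$pos[causal] + 2000)
  d <- D[causal, ]
  r <- setNames(sqrt(0.3) * (d - mean(d)) / sd(d) + sqrt(0.7) * rnorm(700),
                colnames(D))
  cl <- expandingWindowClassify(cpg, r, g)
  expect_equal(cl$category, "cis")
  expect_equal(cl$stage_reached, "5kb")
  expect_equal(cl$best_snp, snpInfo(g)$snp[causal])
  expect_lte(cl$best_distance, 5000)
})

test_that("a cross-chromosome association classifies as trans at genome stage", {
  g <- makeGeno(700, 60, seed = 11)
  D <- dosages(g)
  set.seed(12)
  causal <- which(snpInfo(g)$chrom == "chr2")[4]
  cpg <- list(cpg_id = "cgB", chrom = "chr1", pos = 1.7e7)
  d <- D[causal, ]
  r <- setNames(sqrt(0.4) * (d - mean(d)) / sd(d) + sqrt(0.6) * rnorm(700),
                colnames(D))
  cl <- expandingWindowClassify(cpg, r, g)
  expect_equal(cl$category, "trans")
  expect_equal(cl$stage_reached, "genome")
  expect_true(is.na(cl$best_distance))
})

test_that("no significant SNP anywhere yields GIC", {
  g <- makeGeno(300, 2000, seed = 13)
  set.seed(14)
  r <- setNames(rnorm(300), colnames(dosages(g)))
  cl <- expandingWindowClassify(list(cpg_id = "cgC", chrom = "chr1",
                                     pos = 2e7), r, g)
  expect_equal(cl$category, "GIC")
  expect_true(is.na(cl$best_snp))
})

test_that("alpha = 1 resolves every CpG at the first stage with SNPs", {
  g <- makeGeno(200, 60, seed = 15)
  set.seed(16)
  r <- setNames(rnorm(200), colnames(dosages(g)))
  cpg <- list(cpg_id = "cgD", chrom = "chr1", pos = snpInfo(g)$pos[3])
  cl <- expandingWindowClassify(cpg, r, g, alpha = 1)
  expect_equal(cl$stage_reached, "5kb")
})

test_that("stage resolution is monotone in alpha and windows nest", {
  g <- makeGeno(400, 80, seed = 17)
  set.seed(18)
  stages <- names(windowSchedule())
  for (k in 1:10) {
    cpg <- list(cpg_id = "cgE", chrom = sample(c("chr1", "chr2"), 1),
                pos = sample.int(4e7, 1))
    d <- dosages(g)[sample.int(80, 1), ]
    r <- setNames(0.3 * d + rnorm(400), colnames(dosages(g)))
    sets <- famMeth:::.stageSets(snpInfo(g), cpg$chrom, cpg$pos,
                                 windowSchedule())
    for (s in 2:6) expect_true(all(sets[[s - 1]] %in% sets[[s]]))
    expect_equal(sets[[7]], seq_len(80))
    sLoose <- match(expandingWindowClassify(cpg, r, g,
                                            alpha = 1e-3)$stage_reached, stages)
    sTight <- match(expandingWindowClassify(cpg, r, g,
                                            alpha = 1e-10)$stage_reached, stages)
    expect_lte(sLoose, sTight)
  }
})

test_that("classification is invariant to SNP input order", {
  g <- makeGeno(500, 60, seed = 19)
  set.seed(20)
  causal <- 12
  d <- dosages(g)[causal, ]
  r <- setNames(sqrt(0.3) * scale(d)[, 1] + sqrt(0.7) * rnorm(500),
                colnames(dosages(g)))
  cpg <- list(cpg_id = "cgF", chrom = snpInfo(g)$chrom[causal],
              pos = snpInfo(g)$pos[causal] + 1000)
  perm <- sample.int(60)
  gp <- GenotypeExperiment(dosages(g)[perm, ], snpInfo(g)[perm, ])
  a <- expandingWindowClassify(cpg, r, g)
  b <- expandingWindowClassify(cpg, r, gp)
  expect_equal(a$category, b$category)
  expect_equal(a$best_snp, b$best_snp)
  expect_equal(a$best_p, b$best_p)
})

test_that("classifyAll recovers a planted cis/trans/none panel", {
  cfg <- simConfig(n_families = 110, family_size_range = c(4, 10),
                   n_cpgs = 60, n_snps = 800,
                   h2_true = 0.3,
                   meqtl_type = rep(c("cis", "trans", "none"), c(42, 6, 12)),
                   meqtl_frac = rep(c(0.3, 0.3, 0), c(42, 6, 12)),
                   covariate_effects = list(age = 0, sex = 0, pc = 0),
                   missing_rate = 0, seed = 23)
  co <- simulateCohort(cfg, artifacts = FALSE)
  X <- matrix(1, ncol(co$methyl), 1)
  h2 <- runGenomewide(co$methyl, X, co$kinship)
  pr <- as.data.frame(SummarizedExperiment::rowData(co$methyl))
  mq <- classifyAll(pr[, c("cpg_id", "chrom", "pos")], h2$residuals, co$geno)
  merged <- merge(mq$classification, co$truth, by = "cpg_id")
  agree <- mean(merged$category == merged$expected_category)
  expect_gt(agree, 0.85)
  expect_equal(nrow(mq$classification), 60)
  ## empty heritable set -> empty table
  empty <- classifyAll(pr[0, c("cpg_id", "chrom", "pos")], h2$residuals,
                       co$geno)
  expect_equal(nrow(empty$classification), 0)
})

test_that("a CpG with no annotation errors but does not abort the scan", {
  g <- makeGeno(100, 10, seed = 25)
  r <- setNames(rnorm(100), colnames(dosages(g)))
  expect_error(expandingWindowClassify(list(cpg_id = "x", chrom = NA,
                                            pos = NA), r, g),
               "input error")
  cpgs <- data.frame(cpg_id = c("ok", "bad"), chrom = c("chr1", NA),
                     pos = c(1e6, NA), stringsAsFactors = FALSE)
  R <- rbind(ok = r, bad = r)
  out <- classifyAll(cpgs, R, g)
  expect_true(is.na(out$classification$category[2]))
  expect_match(out$classification$error[2], "input error")
  expect_false(is.na(out$classification$category[1]))
})
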