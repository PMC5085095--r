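test_that("a (3,3) two-generation family is a trio", {
  cfg <- simConfig(n_families = 1, family_size_range = c(3, 3),
                   n_generations = 2, n_cpgs = 2, n_snps = 2, seed = 1)
  ped <- generatePedigree(cfg)
  p <- pedData(ped)
  expect_equal(nrow(p), 3)
  expect_equal(sum(is.na(p$father) & is.na(p$mother)), 2)
  kid <- p[!is.na(p$father), ]
  expect_equal(nrow(kid), 1)
  expect_equal(sort(c(kid$father, kid$mother)),
               sort(p$id[is.na(p$father)]))
})

test_that("cohort-scale generation respects size bounds and structure", {
  cfg <- simConfig(n_families = 163, family_size_range = c(2, 35),
                   n_generations = 3, n_cpgs = 2, n_snps = 2, seed = 1)
  ped <- generatePedigree(cfg)
  p <- pedData(ped)
  expect_equal(length(unique(p$family)), 163)
  sizes <- table(p$family)
  expect_true(all(sizes >= 2 & sizes <= 35))
  expect_gte(nrow(p), 326); expect_lte(nrow(p), 5705)
  ## every non-founder has both parents; matings male x female enforced by
  ## the Pedigree validity (constructed without error)
  nf <- !is.na(p$father) | !is.na(p$mother)
  expect_true(all(!is.na(p$father[nf]) & !is.na(p$mother[nf])))
  expect_true(any(p$generation == 3))
})

test_that("pedigree generation is seed-deterministic and seed-sensitive", {
  cfg1 <- simConfig(n_families = 10, family_size_range = c(2, 20),
                    n_cpgs = 2, n_snps = 2, seed = 1)
  cfg2 <- simConfig(n_families = 10, family_size_range = c(2, 20),
                    n_cpgs = 2, n_snps = 2, seed = 2)
  expect_identical(pedData(generatePedigree(cfg1)),
                   pedData(generatePedigree(cfg1)))
  expect_false(identical(pedData(generatePedigree(cfg1)),
                         pedData(generatePedigree(cfg2))))
})

test_that("an infeasible size range for the requested depth errors", {
  expect_error(simConfig(n_families = 1, family_size_range = c(2, 4),
                         n_generations = 3, n_cpgs = 2, n_snps = 2),
               "configuration error")
})

test_that("gene dropping is Mendelian-consistent and HWE-calibrated", {
  ## deterministic transmission at homozygous parents + HWE founder check
  founders <- Pedigree(rep("F", 10000), sprintf("i%05d", 1:10000),
                       rep(NA, 10000), rep(NA, 10000),
                       rep(c("male", "female"), 5000))
  cfg <- simConfig(n_families = 1, family_size_range = c(2, 3),
                   n_generations = 1, n_cpgs = 2, n_snps = 4,
                   maf_range = c(0.3, 0.3), seed = 3)
  g <- dropGenotypes(founders, cfg)
  D <- dosages(g)
  frq <- rowMeans(D == 0)
  ## P(dosage 0) = 0.49 at MAF 0.3; 3 SE binomial band, n = 10,000
  se <- sqrt(0.49 * 0.51 / 10000)
  expect_true(all(abs(frq - 0.49) < 3 * se))
  expect_true(all(abs(rowMeans(D == 1) - 0.42) < 3 * sqrt(0.42 * 0.58 / 1e4)))

  ## Mendelian consistency in a real pedigree
  cfg2 <- simConfig(n_families = 30, family_size_range = c(3, 15),
                    n_cpgs = 2, n_snps = 50, seed = 5)
  ped <- generatePedigree(cfg2)
  D2 <- dosages(dropGenotypes(ped, cfg2))
  p <- pedData(ped)
  for (i in which(!is.na(p$father))) {
    df <- D2[, p$father[i]]; dm <- D2[, p$mother[i]]; dk <- D2[, p$id[i]]
    lo <- (df == 2) + (dm == 2)
    hi <- 2 - ((df == 0) + (dm == 0))
    expect_true(all(dk >= lo & dk <= hi))
  }
  ## dosages on two chromosomes
  expect_setequal(unique(snpInfo(dropGenotypes(ped, cfg2))$chrom),
                  c("chr1", "chr2"))
})

test_that("null methylation has uncorrelated relatives; planted h2 shows up", {
  cfg <- simConfig(n_families = 40, family_size_range = c(4, 10),
                   n_cpgs = 300, n_snps = 10, h2_true = 0, c2_true = 0,
                   covariate_effects = list(age = 0, sex = 0, pc = 0),
                   missing_rate = 0, seed = 21)
  co <- simulateCohort(cfg, artifacts = FALSE)
  pairs <- enumeratePairs(co$ped)
  po <- pairs[pairs$relationship == "parent-offspring", ]
  ## center each CpG so pooled pair correlations reflect within-CpG structure
  B <- betas(co$methyl) - rowMeans(betas(co$methyl))
  rNull <- cor(as.vector(B[, po$id1]), as.vector(B[, po$id2]))
  expect_lt(abs(rNull), 0.03)

  cfg8 <- simConfig(n_families = 40, family_size_range = c(4, 10),
                    n_cpgs = 300, n_snps = 10, h2_true = 0.8, c2_true = 0,
                    covariate_effects = list(age = 0, sex = 0, pc = 0),
                    missing_rate = 0, seed = 22)
  co8 <- simulateCohort(cfg8, artifacts = FALSE)
  B8 <- betas(co8$methyl) - rowMeans(betas(co8$methyl))
  pairs8 <- enumeratePairs(co8$ped)
  po8 <- pairs8[pairs8$relationship == "parent-offspring", ]
  ## parent-offspring correlation ~ 0.5 * h2 (relatedness x heritability)
  r8 <- cor(as.vector(B8[, po8$id1]), as.vector(B8[, po8$id2]))
  expect_equal(r8, 0.4, tolerance = 0.15)
})

test_that("a planted cis meQTL explains its variance fraction", {
  cfg <- simConfig(n_families = 60, family_size_range = c(4, 12),
                   n_cpgs = 60, n_snps = 300, h2_true = 0,
                   meqtl_type = "cis", meqtl_frac = 0.3,
                   covariate_effects = list(age = 0, sex = 0, pc = 0),
                   missing_rate = 0, seed = 31)
  co <- simulateCohort(cfg, artifacts = FALSE)
  B <- betas(co$methyl)
  D <- dosages(co$geno)
  r2 <- vapply(seq_len(nrow(B)), function(j) {
    d <- D[co$truth$causal_snp[j], colnames(B)]
    summary(lm(B[j, ] ~ d))$r.squared
  }, numeric(1))
  expect_equal(mean(r2), 0.3, tolerance = 0.05)
  ## cis placement within the configured distance
  sn <- snpInfo(co$geno)
  ix <- match(co$truth$causal_snp, sn$snp)
  expect_true(all(co$truth$chrom == sn$chrom[ix]))
  expect_true(all(abs(co$truth$pos - sn$pos[ix]) <= cfg$cis_distance))
})

test_that("clamping to [0,1] is rare under the default configuration", {
  cfg <- simConfig(n_families = 60, family_size_range = c(3, 12),
                   n_cpgs = 200, n_snps = 10, h2_true = 0.5, seed = 41)
  co <- simulateCohort(cfg, artifacts = FALSE)
  B <- betas(co$methyl)
  expect_lt(mean(B == 0 | B == 1), 0.01)
})

test_that("array artifacts honour the missingness rate and identity distortion", {
  cfg0 <- simConfig(n_families = 20, family_size_range = c(4, 10),
                    n_cpgs = 100, n_snps = 10, missing_rate = 0,
                    chem_distortion = c(0, 1, 0), n_chem_pairs = 0, seed = 51)
  co0 <- simulateCohort(cfg0, artifacts = FALSE)
  me0 <- injectArrayArtifacts(co0$methyl, cfg0)
  expect_true(all(detP(me0) < 0.01))
  expect_equal(betas(me0), betas(co0$methyl))  # identity polynomial, no pairs

  cfg <- simConfig(n_families = 40, family_size_range = c(5, 12),
                   n_cpgs = 400, n_snps = 10, missing_rate = 0.02, seed = 52)
  co <- simulateCohort(cfg)
  dp <- detP(co$methyl)
  N <- length(dp)
  frac <- mean(dp > 0.01)
  expect_lt(abs(frac - 0.02), 3 * sqrt(0.02 * 0.98 / N))
  ## batches of 12 samples
  b <- as.data.frame(SummarizedExperiment::colData(co$methyl))$batch
  expect_true(all(table(b[seq_len(12 * (length(b) %/% 12))]) == 12))
})

test_that("the variance budget is validated", {
  expect_error(simConfig(n_cpgs = 5, h2_true = 0.8, c2_true = 0.3),
               "variance budget")
  expect_error(simConfig(n_cpgs = 5, meqtl_frac = 0.2),
               "meqtl_type")
})

test_that("simulated cohorts are byte-identical under a fixed seed", {
  cfg <- simConfig(n_families = 10, family_size_range = c(3, 8),
                   n_cpgs = 30, n_snps = 40, h2_true = 0.4,
                   meqtl_type = "cis", meqtl_frac = 0.2, seed = 61)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(betas(a$methyl), betas(b$methyl))
  expect_identical(dosages(a$geno), dosages(b$geno))
  expect_identical(a$truth, b$truth)
  expect_identical(detP(a$methyl), detP(b$methyl))
})
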