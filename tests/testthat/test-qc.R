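test_that("detection masking changes exactly the failing entries", {
  set.seed(7)
  B <- matrix(runif(200, 0.2, 0.8), 20, 10,
              dimnames = list(paste0("cg", 1:20), paste0("s", 1:10)))
  dp <- matrix(0.001, 20, 10, dimnames = dimnames(B))
  me <- MethylExperiment(B, detp = dp)
  expect_equal(betas(maskByDetection(me)), B)
  dp2 <- dp; dp2[3, 7] <- 0.02
  me2 <- MethylExperiment(B, detp = dp2)
  out <- betas(maskByDetection(me2))
  expect_true(is.na(out[3, 7]))
  out[3, 7] <- B[3, 7]
  expect_equal(out, B)
  ## threshold 1 masks nothing
  expect_equal(betas(maskByDetection(me2, threshold = 1)), B)
  ## shape mismatch is an input error
  expect_error(maskByDetection(me, detp = dp[1:5, ]), "shape mismatch")
})

test_that("sample filter removes above 1.5% missing, strictly", {
  nP <- 200
  B <- matrix(0.5, nP, 4, dimnames = list(sprintf("cg%03d", 1:nP),
                                          paste0("s", 1:4)))
  B[1:4, 2] <- NA     # 2% -> removed
  B[1:3, 3] <- NA     # exactly 1.5% -> retained
  me <- MethylExperiment(B, samples = data.frame(id = colnames(B)))
  fs <- filterSamples(me)
  expect_equal(fs$removed, "s2")
  expect_equal(ncol(fs$methyl), 3)
  expect_equal(fs$report$removed, 1)
  ## no missing -> nothing removed
  fs0 <- filterSamples(MethylExperiment(B[, 1, drop = FALSE] * 0 + 0.5))
  expect_equal(fs0$report$removed, 0)
  ## everything removed -> hard error
  Ball <- B; Ball[1:10, ] <- NA
  expect_error(filterSamples(MethylExperiment(Ball)), "all samples")
})

test_that("probe filters count planted violations exactly, in order", {
  me <- makeQcFixture()
  fp <- filterProbes(me)
  expect_equal(fp$report$rule,
               c("non-autosomal", "missing > max_missing", "sd <= min_sd",
                 "probe SNP", "multimapping"))
  expect_equal(fp$report$removed, rep(10L, 5))
  expect_equal(nrow(fp$methyl), 50)
  expect_equal(fp$report$retained, seq(90, 50, by = -10))
  ## idempotent: re-applying removes nothing
  fp2 <- filterProbes(fp$methyl)
  expect_equal(sum(fp2$report$removed), 0)
  expect_equal(betas(fp2$methyl), betas(fp$methyl))
})

test_that("boundary probes survive the SD and missingness thresholds", {
  set.seed(11)
  nS <- 1000
  ## SD just above 0.02, 5% missing, autosomal, unflagged -> retained
  v <- rep(c(0.479, 0.521), nS / 2)   # SD ~ 0.021
  B <- rbind(keep = v, drop = rep(0.5, nS))
  colnames(B) <- sprintf("s%04d", 1:nS)
  B[1, 1:50] <- NA
  me <- MethylExperiment(B, probes = data.frame(
    cpg_id = c("keep", "drop"), chrom = "chr1", pos = c(100, 200),
    snp_flag = FALSE, multimap_flag = FALSE))
  fp <- filterProbes(me)
  expect_equal(rownames(betas(fp$methyl)), "keep")
})

test_that("chemistry correction: identity distortion is a near-no-op", {
  cfg <- simConfig(n_families = 30, family_size_range = c(4, 10),
                   n_cpgs = 200, n_snps = 10, missing_rate = 0,
                   chem_distortion = c(0, 1, 0), n_chem_pairs = 40, seed = 61)
  co <- simulateCohort(cfg)
  cc <- chemistryCorrect(co$methyl)
  fitco <- S4Vectors::metadata(cc)$chemistry_fit
  expect_equal(fitco, c(0, 1, 0), tolerance = 0.02)
  expect_lt(max(abs(betas(cc) - betas(co$methyl))), 0.02)
})

test_that("chemistry correction reverses a quadratic distortion", {
  cfg <- simConfig(n_families = 30, family_size_range = c(4, 10),
                   n_cpgs = 200, n_snps = 10, missing_rate = 0,
                   chem_distortion = c(0, 0, 1),  # b_II = b_I^2
                   n_chem_pairs = 40, seed = 62)
  co <- simulateCohort(cfg)
  me <- co$methyl
  pr <- as.data.frame(SummarizedExperiment::rowData(me))
  pairI <- match(pr$chem_pair_anchor[!is.na(pr$chem_pair_anchor)], pr$cpg_id)
  pairII <- which(!is.na(pr$chem_pair_anchor))
  rmsBefore <- sqrt(mean((betas(me)[pairI, ] - betas(me)[pairII, ])^2))
  ## inverting a squaring distortion with a quadratic is slightly
  ## non-monotone at the top of [0,1]; the warning is part of the contract
  cc <- suppressWarnings(chemistryCorrect(me))
  rmsAfter <- sqrt(mean((betas(cc)[pairI, ] - betas(cc)[pairII, ])^2))
  expect_lt(rmsAfter, 0.2 * rmsBefore)
  expect_true(all(betas(cc) >= 0 & betas(cc) <= 1))
  ## type-I probes untouched
  iProbes <- pr$chemistry == "I"
  expect_equal(betas(cc)[iProbes, ], betas(me)[iProbes, ])
})

test_that("chemistry correction needs 30 pairs and respects the 50 bp window", {
  set.seed(13)
  B <- matrix(runif(40, 0.2, 0.8), 4, 10)
  rownames(B) <- paste0("cg", 1:4)
  pr <- data.frame(cpg_id = rownames(B), chrom = "chr1",
                   pos = c(100, 140, 1000, 1060),  # one pair in range
                   chemistry = c("I", "II", "I", "II"))
  me <- MethylExperiment(B, probes = pr)
  expect_error(chemistryCorrect(me), "calibration error")
})

test_that("SNP filters apply call-rate, MAF, and per-family MAF rules", {
  set.seed(17)
  ## 20 families of 5; SNPs crafted per rule
  n <- 100
  fam <- rep(sprintf("F%02d", 1:20), each = 5)
  ids <- sprintf("i%03d", 1:n)
  ped <- Pedigree(fam, ids, rep(NA, n), rep(NA, n),
                  rep(c("male", "female"), 50))
  D <- rbind(
    good = rbinom(n, 2, 0.4),
    lowcall = { v <- rbinom(n, 2, 0.4); v[1:6] <- NA; v },    # 94% call
    mono = rep(0L, n),
    rare = c(1L, rep(0L, n - 1)),                             # MAF 0.005
    onefam = c(rep(1L, 5), rep(0L, n - 5))                    # 1/20 families
  )
  colnames(D) <- ids
  g <- GenotypeExperiment(D, data.frame(snp = rownames(D), chrom = "chr1",
                                        pos = 1:5 * 1000))
  fs <- filterSnps(g, ped)
  expect_equal(rownames(dosages(fs$geno)), "good")
  expect_equal(fs$report$removed, c(1, 2, 1))
  ## idempotence
  fs2 <- filterSnps(fs$geno, ped)
  expect_equal(sum(fs2$report$removed), 0)
})

test_that("principal components: duplication, orthogonality, sign convention", {
  set.seed(19)
  B <- matrix(runif(50 * 40, 0.2, 0.8), 50, 40,
              dimnames = list(sprintf("cg%02d", 1:50), sprintf("s%02d", 1:40)))
  sc <- computePCs(B, 4)
  expect_equal(dim(sc), c(40L, 4L))
  expect_equal(crossprod(sc[, 1], sc[, 2])[1], 0, tolerance = 1e-8)
  ## duplicating every sample duplicates the scores
  B2 <- cbind(B, B)
  colnames(B2) <- make.unique(colnames(B2))
  sc2 <- computePCs(B2, 2)
  expect_equal(abs(sc2[1:40, 1]), abs(sc2[41:80, 1]), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(computePCs(B[1:3, ], 4), "rank")
})

test_that("a dominating cell-mixture gradient lands on PC1", {
  cfg <- simConfig(n_families = 40, family_size_range = c(4, 10),
                   n_cpgs = 150, n_snps = 10, h2_true = 0.2,
                   covariate_effects = list(age = 0, sex = 0, pc = 2.5),
                   missing_rate = 0, seed = 71)
  co <- simulateCohort(cfg, artifacts = FALSE)
  sc <- computePCs(co$methyl, 4)
  grad <- as.data.frame(SummarizedExperiment::colData(co$methyl))$cell_proxy
  expect_gt(abs(cor(sc[, 1], grad)), 0.9)
})
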