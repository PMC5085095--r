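## Synthetic cohort generator: pedigrees, gene-dropped genotypes, and
## beta-distributed methylation with known heritability / meQTL / environment
## structure. The defaults mirror the study cohort shape: 163 extended
## families of 2-35 members spanning up to 3 generations.

#' Simulation configuration
#'
#' Collects every knob of the synthetic cohort in one validated list.
#' Per-CpG truth vectors (`h2_true`, `c2_true`, `meqtl_type`, `meqtl_frac`)
#' are recycled to `n_cpgs`; the variance budget
#' `h2_true + c2_true + meqtl_frac <= 1` is enforced per CpG.
#'
#' @param n_families number of families.
#' @param family_size_range integer (min, max) family size.
#' @param n_generations maximum pedigree depth; families whose sampled size
#'   cannot support this depth (a depth-g chain needs 2g-1 members) are grown
#'   to the deepest feasible depth instead.
#' @param n_cpgs,n_snps panel sizes.
#' @param h2_true additive (kinship-structured) variance fraction per CpG.
#' @param c2_true shared-household variance fraction per CpG.
#' @param meqtl_type `"none"`, `"cis"` or `"trans"` per CpG.
#' @param meqtl_frac variance fraction of the planted SNP effect per CpG.
#' @param cis_distance max distance (bp) of a planted cis SNP from its CpG.
#' @param maf_range founder minor-allele frequency range, in (0, 0.5].
#' @param missing_rate fraction of beta entries given failing detection
#'   p-values (> 0.01); must be < 0.5.
#' @param covariate_effects list with elements `age`, `sex`, `pc`: fixed
#'   effect sizes in units of the latent per-CpG SD.
#' @param baseline_range per-CpG baseline beta range (affine placement of the
#'   latent scale; mid-range baselines keep clamping to [0,1] rare).
#' @param latent_sd latent (pre-clamp) total SD of the random part of each
#'   CpG, on the beta scale.
#' @param n_chem_pairs number of Infinium I/II probe pairs placed within
#'   50 bp of each other for the chemistry-correction round trip.
#' @param chem_distortion quadratic coefficients (c0, c1, c2) applied to
#'   type-II betas: b' = c0 + c1 b + c2 b^2; `c(0, 1, 0)` is the identity.
#' @param seed integer RNG seed; a fixed seed gives byte-identical output.
#' @return A list of class `SimConfig`.
#' @export
simConfig <- function(n_families = 163, family_size_range = c(2L, 35L),
                      n_generations = 3, n_cpgs = 300, n_snps = 4000,
                      h2_true = 0.3, c2_true = 0, meqtl_type = "none",
                      meqtl_frac = 0, cis_distance = 2000,
                      maf_range = c(0.05, 0.5), missing_rate = 0.005,
                      covariate_effects = list(age = 0.2, sex = 0.1, pc = 0.5),
                      baseline_range = c(0.25, 0.75), latent_sd = 0.08,
                      n_chem_pairs = 30, chem_distortion = c(0.02, 0.9, 0.08),
                      seed = 1L) {
  cfg <- list(n_families = as.integer(n_families),
              family_size_range = as.integer(family_size_range),
              n_generations = as.integer(n_generations),
              n_cpgs = as.integer(n_cpgs), n_snps = as.integer(n_snps),
              h2_true = rep_len(h2_true, n_cpgs),
              c2_true = rep_len(c2_true, n_cpgs),
              meqtl_type = rep_len(meqtl_type, n_cpgs),
              meqtl_frac = rep_len(meqtl_frac, n_cpgs),
              cis_distance = cis_distance, maf_range = maf_range,
              missing_rate = missing_rate,
              covariate_effects = covariate_effects,
              baseline_range = baseline_range, latent_sd = latent_sd,
              n_chem_pairs = as.integer(n_chem_pairs),
              chem_distortion = chem_distortion,
              seed = as.integer(seed))
  if (cfg$n_families < 1) stop("configuration error: n_families must be >= 1")
  if (cfg$n_generations < 1)
    stop("configuration error: n_generations must be >= 1")
  if (cfg$family_size_range[1] > cfg$family_size_range[2] ||
      cfg$family_size_range[1] < 1)
    stop("configuration error: bad family_size_range")
  if (cfg$family_size_range[2] < 2 * cfg$n_generations - 1)
    stop("configuration error: family_size_range cannot hold ",
         cfg$n_generations, " generations (a depth-g chain needs 2g-1 members)")
  if (cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5)
    stop("configuration error: maf_range must lie in (0, 0.5]")
  if (cfg$missing_rate >= 0.5)
    stop("configuration error: missing_rate must be < 0.5")
  bad <- cfg$h2_true + cfg$c2_true + cfg$meqtl_frac > 1 + 1e-12
  if (any(bad))
    stop("configuration error: variance budget h2 + c2 + meqtl_frac > 1 for ",
         sum(bad), " CpGs")
  if (any(cfg$meqtl_frac > 0 & cfg$meqtl_type == "none"))
    stop("configuration error: meqtl_frac > 0 with meqtl_type 'none'")
  class(cfg) <- "SimConfig"
  cfg
}

## grow one family to `target` members over at most `gens` generations
.buildFamily <- function(famid, target, gens) {
  gens <- max(1L, min(gens, (target + 1L) %/% 2L))
  id <- function(k) sprintf("%s_%03d", famid, k)
  n <- 0L
  rows <- list()
  add <- function(father, mother, sex, gen) {
    n <<- n + 1L
    rows[[n]] <<- data.frame(id = id(n), father = father, mother = mother,
                             sex = sex, generation = gen,
                             stringsAsFactors = FALSE)
    id(n)
  }
  if (target == 1L) {
    add(NA, NA, sample(c("male", "female"), 1), 1L)
  } else {
    h <- add(NA, NA, "male", 1L)
    w <- add(NA, NA, "female", 1L)
    couples <- data.frame(f = h, m = w, gen = 1L, stringsAsFactors = FALSE)
    singles <- data.frame(id = character(), sex = character(), gen = integer(),
                          stringsAsFactors = FALSE)
    ## mandatory chain guaranteeing the requested depth
    prev <- c(h, w)
    for (g in seq_len(gens - 1L) + 1L) {
      sx <- sample(c("male", "female"), 1)
      kid <- add(prev[1], prev[2], sx, g)
      if (g < gens) {
        sp <- add(NA, NA, if (sx == "male") "female" else "male", g)
        cpl <- if (sx == "male") c(kid, sp) else c(sp, kid)
        couples <- rbind(couples, data.frame(f = cpl[1], m = cpl[2], gen = g,
                                             stringsAsFactors = FALSE))
        prev <- cpl
      } else {
        singles <- rbind(singles, data.frame(id = kid, sex = sx, gen = g,
                                             stringsAsFactors = FALSE))
      }
    }
    ## spend the remaining budget on extra children and marriages
    while (n < target) {
      fertile <- couples[couples$gen < gens, , drop = FALSE]
      marriageable <- singles[singles$gen < gens, , drop = FALSE]
      acts <- c(if (nrow(fertile)) "child",
                if (nrow(marriageable)) "marry")
      if (!length(acts)) {  # single-generation family: unrelated founders
        sx <- sample(c("male", "female"), 1)
        add(NA, NA, sx, 1L)
        next
      }
      act <- if (length(acts) == 1) acts else
        sample(acts, 1, prob = c(0.7, 0.3))
      if (act == "child") {
        k <- sample.int(nrow(fertile), 1)
        sx <- sample(c("male", "female"), 1)
        kid <- add(fertile$f[k], fertile$m[k], sx, fertile$gen[k] + 1L)
        singles <- rbind(singles,
                         data.frame(id = kid, sex = sx,
                                    gen = fertile$gen[k] + 1L,
                                    stringsAsFactors = FALSE))
      } else {
        k <- sample.int(nrow(marriageable), 1)
        s <- marriageable[k, ]
        sp <- add(NA, NA, if (s$sex == "male") "female" else "male", s$gen)
        cpl <- if (s$sex == "male") c(s$id, sp) else c(sp, s$id)
        couples <- rbind(couples, data.frame(f = cpl[1], m = cpl[2],
                                             gen = s$gen,
                                             stringsAsFactors = FALSE))
        singles <- singles[singles$id != s$id, , drop = FALSE]
      }
    }
  }
  out <- do.call(rbind, rows)
  out$family <- famid
  out
}

#' Generate a synthetic pedigree
#'
#' Builds `n_families` independent families. Each family starts from a
#' founding couple; spouses always marry in from outside (founders), so
#' spousal pairs are genetically unrelated. Every non-founder has both
#' parents in the pedigree and every mating is male x female.
#'
#' @param config a [simConfig()] list.
#' @return A [Pedigree-class] with a `generation` column.
#' @export
generatePedigree <- function(config) {
  set.seed(config$seed)
  rng <- seq(config$family_size_range[1], config$family_size_range[2])
  sizes <- rng[sample.int(length(rng), config$n_families, replace = TRUE)]
  fams <- lapply(seq_len(config$n_families), function(i)
    .buildFamily(sprintf("F%03d", i), sizes[i], config$n_generations))
  p <- do.call(rbind, fams)
  Pedigree(p$family, p$id, p$father, p$mother, p$sex, p$generation)
}

#' Gene-drop genotypes through a pedigree
#'
#' Founder genotypes are drawn under Hardy-Weinberg equilibrium at a
#' per-SNP minor-allele frequency sampled uniformly from `maf_range`;
#' offspring receive one allele from each parent, each transmitted with
#' probability dosage/2. SNPs are laid out uniformly on two synthetic 50-Mb
#' chromosomes so that trans (cross-chromosome) placement is possible.
#'
#' @param ped a [Pedigree-class].
#' @param config a [simConfig()] list.
#' @return A genotype `SummarizedExperiment` (assay `dosage`, SNPs x samples).
#' @export
dropGenotypes <- function(ped, config) {
  set.seed(config$seed + 1L)
  p <- pedData(ped)
  n <- nrow(p)
  m <- config$n_snps
  maf <- runif(m, config$maf_range[1], config$maf_range[2])
  chrom <- rep(c("chr1", "chr2"), length.out = m)
  pos <- sample.int(5e7, m, replace = TRUE)
  ord <- order(chrom, pos)
  chrom <- chrom[ord]; pos <- pos[ord]; maf <- maf[ord]
  G <- matrix(NA_integer_, m, n, dimnames = list(NULL, p$id))
  fa <- match(p$father, p$id)
  mo <- match(p$mother, p$id)
  for (i in .topoOrder(p)) {
    if (is.na(fa[i]) && is.na(mo[i])) {
      G[, i] <- rbinom(m, 2L, maf)
    } else {
      G[, i] <- rbinom(m, 1L, G[, fa[i]] / 2) + rbinom(m, 1L, G[, mo[i]] / 2)
    }
  }
  snps <- data.frame(snp = sprintf("snp%05d", seq_len(m)),
                     chrom = chrom, pos = pos, maf = maf,
                     stringsAsFactors = FALSE)
  rownames(G) <- snps$snp
  GenotypeExperiment(G, snps)
}

## single-membership household: parents share with their own children
.householdIds <- function(p) {
  fa <- setNames(p$father, p$id)
  mo <- setNames(p$mother, p$id)
  hasKids <- p$id %in% c(p$father, p$mother)
  spouse <- setNames(rep(NA_character_, nrow(p)), p$id)
  cp <- unique(stats::na.omit(data.frame(f = p$father, m = p$mother,
                                         stringsAsFactors = FALSE)))
  spouse[cp$f] <- cp$m
  spouse[cp$m] <- cp$f
  hh <- character(nrow(p))
  for (i in seq_len(nrow(p))) {
    iid <- p$id[i]
    if (hasKids[i]) {
      hh[i] <- paste(p$family[i], paste(sort(c(iid, spouse[iid])), collapse = "+"))
    } else if (!is.na(fa[iid]) || !is.na(mo[iid])) {
      hh[i] <- paste(p$family[i],
                     paste(sort(stats::na.omit(c(fa[iid], mo[iid]))), collapse = "+"))
    } else {
      hh[i] <- paste(p$family[i], iid)
    }
  }
  hh
}

## per-generation age bands: youngest generation 15-30, +25y per generation up
.simAges <- function(p, gens) {
  g <- if (!is.null(p$generation)) p$generation else rep(1L, nrow(p))
  base <- 15 + 25 * (gens - g)
  round(base + runif(nrow(p), 0, 15), 1)
}

#' Simulate methylation with known truth
#'
#' Per CpG the latent value is baseline + fixed covariate effects (age, sex,
#' and a cell-composition-like sample gradient) + a zero-mean multivariate
#' normal genetic effect with covariance `h2_true * s^2 * A` (drawn per family
#' from the Cholesky factor of the relatedness block) + a shared-household
#' effect (variance `c2_true * s^2`) + an additive effect of the planted
#' causal SNP dosage scaled to `meqtl_frac * s^2` + an independent residual
#' completing the unit budget. Latent values are clamped to [0,1]; with the
#' default mid-range baselines and `latent_sd` 0.08 clamping touches well
#' under 1% of entries.
#'
#' CpGs with a cis meQTL are placed within `cis_distance` bp of their causal
#' SNP; trans CpGs on the other chromosome from theirs.
#'
#' @param ped a [Pedigree-class].
#' @param geno genotype `SummarizedExperiment` from [dropGenotypes()].
#' @param A relatedness matrix from [kinshipMatrix()] (convention
#'   `"relatedness"`), aligned with `ped`.
#' @param config a [simConfig()] list.
#' @return list with elements `methyl` (a [MethylExperiment-class]) and
#'   `truth` (the per-CpG truth table: `cpg_id`, `h2_true`, `c2_true`,
#'   `meqtl_frac`, `causal_snp`, `expected_category`, `chrom`, `pos`).
#' @export
simulateMethylation <- function(ped, geno, A, config) {
  set.seed(config$seed + 2L)
  p <- pedData(ped)
  n <- nrow(p)
  stopifnot(identical(rownames(A), p$id))
  nC <- config$n_cpgs
  s <- config$latent_sd
  snps <- snpInfo(geno)
  D <- dosages(geno)

  ## family-block Cholesky factors, reused across CpGs
  famList <- split(seq_len(n), p$family)
  chols <- lapply(famList, function(ix) chol(A[ix, ix, drop = FALSE]))

  ## covariates
  age <- .simAges(p, config$n_generations)
  sexNum <- as.integer(p$sex == "female")
  cellProxy <- rnorm(n)
  hh <- .householdIds(p)
  hhFac <- factor(hh)
  eff <- config$covariate_effects

  ## CpG placement and causal SNPs
  type <- config$meqtl_type
  causal <- rep(NA_integer_, nC)
  chromC <- character(nC)
  posC <- integer(nC)
  anySnp <- nrow(snps) > 0
  for (j in seq_len(nC)) {
    if (type[j] %in% c("cis", "trans") && anySnp) {
      causal[j] <- sample.int(nrow(snps), 1)
      if (type[j] == "cis") {
        chromC[j] <- snps$chrom[causal[j]]
        off <- sample.int(config$cis_distance, 1) * sample(c(-1L, 1L), 1)
        posC[j] <- min(max(snps$pos[causal[j]] + off, 1L), 5e7)
      } else {
        chromC[j] <- setdiff(c("chr1", "chr2"), snps$chrom[causal[j]])[1]
        posC[j] <- sample.int(5e7, 1)
      }
    } else {
      type[j] <- "none"
      chromC[j] <- sample(c("chr1", "chr2"), 1)
      posC[j] <- sample.int(5e7, 1)
    }
  }

  baseline <- runif(nC, config$baseline_range[1], config$baseline_range[2])
  h2 <- config$h2_true; c2 <- config$c2_true; q <- config$meqtl_frac
  q[type == "none"] <- 0

  ## genetic effects for all CpGs at once, family by family
  Gmat <- matrix(0, n, nC)
  for (f in seq_along(famList)) {
    ix <- famList[[f]]
    Z <- matrix(rnorm(length(ix) * nC), length(ix), nC)
    Gmat[ix, ] <- crossprod(chols[[f]], Z)
  }
  ## household effects
  Hlev <- matrix(rnorm(nlevels(hhFac) * nC), nlevels(hhFac), nC)
  Hmat <- Hlev[as.integer(hhFac), , drop = FALSE]

  B <- matrix(NA_real_, nC, n,
              dimnames = list(sprintf("cg%05d", seq_len(nC)), p$id))
  ageZ <- (age - mean(age)) / sd(age)
  cellZ <- (cellProxy - mean(cellProxy)) / sd(cellProxy)
  for (j in seq_len(nC)) {
    lat <- baseline[j] +
      s * (eff$age * ageZ + eff$sex * sexNum + eff$pc * cellZ) +
      s * sqrt(h2[j]) * Gmat[, j] +
      s * sqrt(c2[j]) * Hmat[, j]
    if (q[j] > 0) {
      d <- D[causal[j], ]
      if (sd(d) < 1e-9) {  # monomorphic draw: fall back to a polymorphic SNP
        causal[j] <- which(apply(D, 1, sd) > 1e-9)[1]
        d <- D[causal[j], ]
      }
      lat <- lat + s * sqrt(q[j]) * (d - mean(d)) / sd(d)
    }
    lat <- lat + rnorm(n, 0, s * sqrt(max(1 - h2[j] - c2[j] - q[j], 0)))
    B[j, ] <- pmin(pmax(lat, 0), 1)
  }

  ## probe annotation: island relation and 0-3 genes per CpG
  islands <- sample(c("island", "shore", "shelf", "open-sea"), nC,
                    replace = TRUE, prob = c(0.3, 0.25, 0.1, 0.35))
  regions <- c("TSS200", "TSS1500", "5'UTR", "1stExon", "Body", "3'UTR")
  nGenes <- sample(0:3, nC, replace = TRUE, prob = c(0.25, 0.5, 0.2, 0.05))
  gene <- vapply(seq_len(nC), function(j) {
    if (nGenes[j] == 0) return(NA_character_)
    paste(sprintf("G%04d", sample.int(500, nGenes[j])), collapse = ";")
  }, character(1))
  region <- vapply(seq_len(nC), function(j) {
    if (nGenes[j] == 0) return(NA_character_)
    paste(sample(regions, nGenes[j], replace = TRUE), collapse = ";")
  }, character(1))

  probes <- data.frame(cpg_id = rownames(B), chrom = chromC, pos = posC,
                       chemistry = sample(c("I", "II"), nC, replace = TRUE),
                       island_relation = islands, gene = gene, region = region,
                       snp_flag = FALSE, multimap_flag = FALSE,
                       stringsAsFactors = FALSE)
  samples <- data.frame(id = p$id, family = p$family, age = age,
                        sex = p$sex, cell_proxy = cellProxy,
                        household = hh, stringsAsFactors = FALSE)
  truth <- data.frame(cpg_id = rownames(B), h2_true = h2, c2_true = c2,
                      meqtl_frac = q,
                      causal_snp = ifelse(is.na(causal), NA_character_,
                                          snps$snp[causal]),
                      expected_category = c(none = "GIC", cis = "cis",
                                            trans = "trans")[type],
                      chrom = chromC, pos = posC, stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  me <- MethylExperiment(B, probes = probes, samples = samples)
  list(methyl = me, truth = truth)
}

#' Inject array artifacts: detection failures, chemistry distortion, batches
#'
#' A `missing_rate` fraction of entries receive failing detection p-values
#' (> 0.01); all other entries get passing p-values (< 0.01).
#' `n_chem_pairs` disjoint probe pairs are rewritten as Infinium I/II pairs
#' within 50 bp of each other on the same chromosome, the type-II partner
#' measuring (almost) the same signal; the configured quadratic distortion is
#' then applied to every type-II probe and clipped to [0,1]. Samples are
#' assigned to batches of 12 (one array per batch).
#'
#' @param sim output of [simulateMethylation()] (list with `methyl`,`truth`),
#'   or a [MethylExperiment-class].
#' @param config a [simConfig()] list.
#' @return A [MethylExperiment-class] with assays `beta` and `detp`, updated
#'   probe chemistry/positions (`chem_pair_anchor` marks rewritten partners)
#'   and a `batch` sample column.
#' @export
injectArrayArtifacts <- function(sim, config) {
  me <- if (is(sim, "MethylExperiment")) sim else sim$methyl
  set.seed(config$seed + 3L)
  B <- betas(me)
  nC <- nrow(B); n <- ncol(B)
  probes <- as.data.frame(SummarizedExperiment::rowData(me))
  samples <- as.data.frame(SummarizedExperiment::colData(me))

  ## chemistry pairs: partner probe moved next to its anchor, same signal
  npair <- min(config$n_chem_pairs, nC %/% 2L)
  probes$chem_pair_anchor <- NA_character_
  if (npair > 0) {
    pick <- sample.int(nC, 2L * npair)
    anchors <- pick[seq_len(npair)]
    partners <- pick[npair + seq_len(npair)]
    probes$chemistry[anchors] <- "I"
    probes$chemistry[partners] <- "II"
    probes$chrom[partners] <- probes$chrom[anchors]
    probes$pos[partners] <- probes$pos[anchors] +
      sample(c(-50:-1, 1:50), npair, replace = TRUE)
    probes$chem_pair_anchor[partners] <- probes$cpg_id[anchors]
    B[partners, ] <- pmin(pmax(B[anchors, ] +
                                 matrix(rnorm(npair * n, 0, 0.005), npair, n),
                               0), 1)
  }
  ## quadratic chemistry distortion of all type-II probes
  co <- config$chem_distortion
  ii <- probes$chemistry == "II"
  B[ii, ] <- pmin(pmax(co[1] + co[2] * B[ii, ] + co[3] * B[ii, ]^2, 0), 1)

  ## detection p-values
  detp <- matrix(runif(nC * n) * 0.0099, nC, n, dimnames = dimnames(B))
  nbad <- rbinom(1, nC * n, config$missing_rate)
  if (nbad > 0) {
    bad <- sample.int(nC * n, nbad)
    detp[bad] <- 0.01 + runif(nbad) * 0.99
  }
  samples$batch <- sprintf("batch%03d", (seq_len(n) - 1L) %/% 12L + 1L)
  MethylExperiment(B, detp = detp, probes = probes, samples = samples)
}

#' Simulate a complete cohort
#'
#' Convenience wrapper running [generatePedigree()], [kinshipMatrix()],
#' [dropGenotypes()], [simulateMethylation()] and [injectArrayArtifacts()].
#'
#' @param config a [simConfig()] list.
#' @param artifacts add array artifacts (detection p-values, chemistry
#'   distortion, batches)? Default TRUE.
#' @return list with `ped`, `kinship`, `geno`, `methyl`, `truth`.
#' @export
simulateCohort <- function(config, artifacts = TRUE) {
  ped <- generatePedigree(config)
  A <- kinshipMatrix(ped, "relatedness")
  geno <- dropGenotypes(ped, config)
  sim <- simulateMethylation(ped, geno, A, config)
  me <- if (artifacts) injectArrayArtifacts(sim, config) else sim$methyl
  list(ped = ped, kinship = A, geno = geno, methyl = me, truth = sim$truth)
}
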