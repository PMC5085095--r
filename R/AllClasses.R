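#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames rowData colData
#' @importFrom stats coef lm optimize pchisq predict pt quantile rbinom rnorm
#'   runif sd var prcomp setNames chisq.test fisher.test r2dtable complete.cases
#' @importFrom utils head read.delim write.table
NULL

#' Pedigree of one or more families
#'
#' Stores family structure as one row per individual with parent links and
#' sex. Founders have `NA` parents. Validity enforces the usual pedigree
#' constraints: parents belong to the same family, fathers are male, mothers
#' female, and the parent relation is acyclic.
#'
#' @slot ped data.frame with columns `family`, `id`, `father`, `mother`,
#'   `sex` (factor, levels `male`/`female`) and optionally `generation`.
#' @export
setClass("Pedigree", representation(ped = "data.frame"))

.validPedigree <- function(object) {
  p <- object@ped
  msgs <- character()
  need <- c("family", "id", "father", "mother", "sex")
  if (!all(need %in% names(p)))
    return(paste("pedigree is missing columns:",
                 paste(setdiff(need, names(p)), collapse = ", ")))
  if (anyDuplicated(p$id))
    msgs <- c(msgs, "duplicate individual ids")
  idx <- match(p$father, p$id)
  midx <- match(p$mother, p$id)
  if (any(!is.na(p$father) & is.na(idx)))
    msgs <- c(msgs, paste("father id not found:",
                          paste(head(p$father[!is.na(p$father) & is.na(idx)], 3), collapse = ", ")))
  if (any(!is.na(p$mother) & is.na(midx)))
    msgs <- c(msgs, paste("mother id not found:",
                          paste(head(p$mother[!is.na(p$mother) & is.na(midx)], 3), collapse = ", ")))
  if (!length(msgs)) {
    ok <- !is.na(idx)
    if (any(p$family[idx[ok]] != p$family[ok]))
      msgs <- c(msgs, "father in a different family")
    ok <- !is.na(midx)
    if (any(p$family[midx[ok]] != p$family[ok]))
      msgs <- c(msgs, "mother in a different family")
    if (any(p$sex[idx[!is.na(idx)]] != "male"))
      msgs <- c(msgs, "a father is not male")
    if (any(p$sex[midx[!is.na(midx)]] != "female"))
      msgs <- c(msgs, "a mother is not female")
    if (is.null(.topoOrder(p)))
      msgs <- c(msgs, "pedigree contains a cycle (individual is its own ancestor)")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
}
setValidity("Pedigree", .validPedigree)

## topological order (parents before children); NULL if cyclic
.topoOrder <- function(p) {
  n <- nrow(p)
  fa <- match(p$father, p$id)
  mo <- match(p$mother, p$id)
  placed <- logical(n)
  ord <- integer(0)
  repeat {
    ## a row is ready when each present parent is already placed
    ready <- !placed &
      (is.na(fa) | placed[ifelse(is.na(fa), 1L, fa)]) &
      (is.na(mo) | placed[ifelse(is.na(mo), 1L, mo)])
    if (!any(ready)) break
    ord <- c(ord, which(ready))
    placed[ready] <- TRUE
  }
  if (all(placed)) ord else NULL
}

#' Construct a Pedigree
#'
#' @param family,id,father,mother character vectors (one entry per
#'   individual); `father`/`mother` use `NA` (or `"0"`) for missing parents.
#' @param sex `"male"`/`"female"`, or PED-style codes 1/2.
#' @param generation optional integer generation index (1 = oldest).
#' @return A [Pedigree-class] object.
#' @examples
#' trio <- Pedigree(family = rep("F1", 3), id = c("dad", "mum", "kid"),
#'                  father = c(NA, NA, "dad"), mother = c(NA, NA, "mum"),
#'                  sex = c("male", "female", "female"))
#' @export
Pedigree <- function(family, id, father, mother, sex, generation = NULL) {
  clean <- function(x) {
    x <- as.character(x)
    x[x %in% c("0", "", "NA")] <- NA_character_
    x
  }
  if (is.numeric(sex)) sex <- c("male", "female")[sex]
  p <- data.frame(family = as.character(family), id = as.character(id),
                  father = clean(father), mother = clean(mother),
                  sex = factor(sex, levels = c("male", "female")),
                  stringsAsFactors = FALSE)
  if (!is.null(generation)) p$generation <- as.integer(generation)
  new("Pedigree", ped = p)
}

#' @describeIn Pedigree underlying data.frame (one row per individual)
#' @param x a `Pedigree`
#' @export
pedData <- function(x) x@ped

#' @export
setMethod("length", "Pedigree", function(x) nrow(x@ped))

#' @describeIn Pedigree number of distinct families
#' @export
nFamilies <- function(x) length(unique(x@ped$family))

setMethod("show", "Pedigree", function(object) {
  p <- object@ped
  cat("Pedigree:", nrow(p), "individuals in", length(unique(p$family)),
      "families\n")
  cat("  founders:", sum(is.na(p$father) & is.na(p$mother)),
      " non-founders:", sum(!is.na(p$father) | !is.na(p$mother)), "\n")
})

#' Methylation experiment container
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] subclass holding a
#' `beta` assay (CpGs x samples, values in [0,1] or `NA`) and optionally a
#' `detp` detection p-value assay. Probe metadata (chromosome, position,
#' chemistry, island relation, gene annotation) lives in `rowData`; sample
#' metadata (family, age, sex, batch) in `colData`.
#'
#' @export
setClass("MethylExperiment", contains = "SummarizedExperiment")

setValidity("MethylExperiment", function(object) {
  if (!"beta" %in% SummarizedExperiment::assayNames(object))
    return("assay 'beta' is required")
  b <- SummarizedExperiment::assay(object, "beta")
  if (any(b < 0 | b > 1, na.rm = TRUE))
    return("beta values must lie in [0, 1]")
  TRUE
})

#' Construct a MethylExperiment
#'
#' @param beta numeric matrix, CpGs x samples, in [0,1] (NA = missing).
#' @param detp optional detection p-value matrix of the same shape.
#' @param probes data.frame of probe metadata (rowData), one row per CpG.
#' @param samples data.frame of sample metadata (colData).
#' @return A [MethylExperiment-class].
#' @export
MethylExperiment <- function(beta, detp = NULL, probes = NULL, samples = NULL) {
  assays <- list(beta = beta)
  if (!is.null(detp)) {
    stopifnot(identical(dim(detp), dim(beta)))
    assays$detp <- detp
  }
  args <- list(assays = assays)
  if (!is.null(probes)) args$rowData <- probes
  if (!is.null(samples)) args$colData <- samples
  se <- do.call(SummarizedExperiment::SummarizedExperiment, args)
  as(se, "MethylExperiment")
}

#' @describeIn MethylExperiment the beta matrix
#' @param x a `MethylExperiment`
#' @export
betas <- function(x) SummarizedExperiment::assay(x, "beta")

#' @describeIn MethylExperiment detection p-value matrix, or NULL
#' @export
detP <- function(x) {
  if ("detp" %in% SummarizedExperiment::assayNames(x))
    SummarizedExperiment::assay(x, "detp") else NULL
}

setMethod("show", "MethylExperiment", function(object) {
  cat("MethylExperiment:", nrow(object), "CpGs x", ncol(object), "samples\n")
  b <- betas(object)
  cat(sprintf("  missing: %.2f%%  assays: %s\n",
              100 * mean(is.na(b)),
              paste(SummarizedExperiment::assayNames(object), collapse = ", ")))
})

#' Genotype dosage container
#'
#' Genotypes are held in a plain [SummarizedExperiment::SummarizedExperiment]
#' with a `dosage` assay (SNPs x samples, minor-allele dosage 0/1/2, `NA` =
#' missing) and `rowData` columns `snp`, `chrom`, `pos`.
#'
#' @param dosage integer/numeric matrix, SNPs x samples.
#' @param snps data.frame with columns `snp`, `chrom`, `pos`.
#' @return A `SummarizedExperiment`.
#' @export
GenotypeExperiment <- function(dosage, snps) {
  stopifnot(all(c("snp", "chrom", "pos") %in% names(snps)),
            nrow(snps) == nrow(dosage))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = dosage), rowData = snps)
}

#' @describeIn GenotypeExperiment dosage matrix accessor
#' @param x a genotype `SummarizedExperiment`
#' @export
dosages <- function(x) SummarizedExperiment::assay(x, "dosage")

#' @describeIn GenotypeExperiment SNP metadata as a data.frame
#' @export
snpInfo <- function(x) as.data.frame(SummarizedExperiment::rowData(x))
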