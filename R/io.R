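## Readers and writers for the interchange formats: 6-column PED/FAM,
## TSV matrices (tab-delimited, header row, NA for missing), minimal VCF
## (GT), probe annotation TSV, BED regions, YAML pipeline config.

#' Read a 6-column PED/FAM pedigree file
#'
#' Columns: family, individual, father, mother, sex (1 = male, 2 = female),
#' phenotype (ignored). `0` marks a missing parent. Malformed parent
#' references are reported with the offending id.
#'
#' @param path file path.
#' @return A [Pedigree-class].
#' @export
readPed <- function(path) {
  d <- read.delim(path, header = FALSE, sep = "", stringsAsFactors = FALSE,
                  colClasses = "character")
  if (ncol(d) < 5) stop("parse error: PED file needs >= 5 columns")
  tryCatch(
    Pedigree(d[[1]], d[[2]], d[[3]], d[[4]], as.integer(d[[5]])),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e)))
}

#' Write a pedigree as 6-column PED/FAM text
#' @param ped a [Pedigree-class].
#' @param path output path.
#' @export
writePed <- function(ped, path) {
  p <- pedData(ped)
  out <- data.frame(p$family, p$id,
                    ifelse(is.na(p$father), "0", p$father),
                    ifelse(is.na(p$mother), "0", p$mother),
                    ifelse(p$sex == "male", 1L, 2L), 0L)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read / write a TSV numeric matrix (rows x header of sample ids)
#'
#' Canonical matrix dialect: tab-delimited, header row of sample ids, first
#' column = row ids, `NA` for missing.
#'
#' @param path file path.
#' @return numeric matrix with dimnames.
#' @export
readMatrixTsv <- function(path) {
  d <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  rn <- d[[1]]
  if (anyDuplicated(rn)) stop("parse error: duplicate row ids in ", path)
  m <- as.matrix(d[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("parse error: non-numeric values in ", path)
  rownames(m) <- rn
  m
}

#' @rdname readMatrixTsv
#' @param m matrix to write.
#' @param idcol name of the first (row id) column.
#' @export
writeMatrixTsv <- function(m, path, idcol = "id") {
  d <- data.table::data.table(rn = rownames(m))
  data.table::setnames(d, "rn", idcol)
  out <- cbind(d, data.table::as.data.table(m))
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a probe annotation TSV
#'
#' Requires columns `cpg_id`, `chrom`, `pos`; recognised extras are
#' `chemistry`, `island_relation`, `gene`, `region`, `snp_flag`,
#' `multimap_flag`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readAnnot <- function(path) {
  d <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  need <- c("cpg_id", "chrom", "pos")
  if (!all(need %in% names(d)))
    stop("parse error: annotation needs columns ",
         paste(need, collapse = ", "))
  if (anyDuplicated(d$cpg_id)) stop("parse error: duplicate cpg ids")
  d
}

#' Read genotype dosages
#'
#' `readDosageTsv` reads a SNPs x samples TSV with columns `snp`, `chrom`,
#' `pos`, then one column per sample. `readVcfDosage` reads a VCF and
#' converts the GT field to minor-allele dosage (`./.` becomes `NA`).
#'
#' @param path file path.
#' @return genotype `SummarizedExperiment` (assay `dosage`).
#' @export
readDosageTsv <- function(path) {
  d <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  need <- c("snp", "chrom", "pos")
  if (!all(need %in% names(d)))
    stop("parse error: dosage TSV needs columns ", paste(need, collapse = ", "))
  D <- as.matrix(d[, setdiff(names(d), need), drop = FALSE])
  rownames(D) <- d$snp
  GenotypeExperiment(D, d[, need])
}

#' @rdname readDosageTsv
#' @param geno genotype `SummarizedExperiment`.
#' @export
writeDosageTsv <- function(geno, path) {
  info <- snpInfo(geno)[, c("snp", "chrom", "pos")]
  out <- cbind(data.table::as.data.table(info),
               data.table::as.data.table(dosages(geno)))
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname readDosageTsv
#' @export
readVcfDosage <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  toDos <- function(g) {
    g[g %in% c("./.", ".|.", ".")] <- NA
    a <- strsplit(g, "[/|]")
    vapply(a, function(x) {
      if (length(x) == 0 || anyNA(x) || any(x == "."))
        return(NA_real_)
      sum(as.numeric(x) > 0)
    }, numeric(1))
  }
  D <- apply(gt, 2, toDos)
  if (is.null(dim(D))) D <- matrix(D, nrow = nrow(gt), dimnames = dimnames(gt))
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  snps <- data.frame(snp = fix$ID, chrom = fix$CHROM, pos = as.integer(fix$POS),
                     stringsAsFactors = FALSE)
  rownames(D) <- snps$snp
  GenotypeExperiment(D, snps)
}

#' @rdname readDosageTsv
#' @details `writeVcf` emits a minimal VCF with a GT field; dosage 0/1/2 maps
#'   to `0/0`, `0/1`, `1/1` and `NA` to `./.`.
#' @export
writeVcf <- function(geno, path) {
  info <- snpInfo(geno)
  D <- dosages(geno)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(D)), collapse = "\t")), con)
  gtmap <- c("0/0", "0/1", "1/1")
  for (i in seq_len(nrow(D))) {
    g <- D[i, ]
    gt <- ifelse(is.na(g), "./.", gtmap[g + 1])
    writeLines(paste(c(info$chrom[i], info$pos[i], info$snp[i], "A", "G",
                       ".", "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read BED regions as 1-based inclusive GRanges
#'
#' BED input is 0-based half-open; the returned `GRanges` is 1-based
#' inclusive, suitable for [intervalOverlap()].
#'
#' @param path BED file path.
#' @return A `GRanges`.
#' @export
readBedRegions <- function(path) rtracklayer::import(path, format = "BED")

#' Write a MethylExperiment to TSV files
#'
#' Emits `<prefix>_beta.tsv`, `<prefix>_detp.tsv` (when present),
#' `<prefix>_probes.tsv` and `<prefix>_samples.tsv`.
#'
#' @param m a [MethylExperiment-class].
#' @param prefix output path prefix.
#' @export
writeMethylTsv <- function(m, prefix) {
  writeMatrixTsv(betas(m), paste0(prefix, "_beta.tsv"), "cpg_id")
  if (!is.null(detP(m)))
    writeMatrixTsv(detP(m), paste0(prefix, "_detp.tsv"), "cpg_id")
  data.table::fwrite(as.data.frame(SummarizedExperiment::rowData(m)),
                     paste0(prefix, "_probes.tsv"), sep = "\t", na = "NA",
                     quote = FALSE)
  data.table::fwrite(as.data.frame(SummarizedExperiment::colData(m)),
                     paste0(prefix, "_samples.tsv"), sep = "\t", na = "NA",
                     quote = FALSE)
  invisible(prefix)
}
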