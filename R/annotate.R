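## Annotation joins and categorical enrichment tests across CpG classes.

#' Expand CpGs to one row per (CpG, gene, region)
#'
#' A CpG annotated to several genes is listed once per gene; a CpG near no
#' gene is dropped. Duplicated (cpg, gene, region) triples are collapsed,
#' which also makes the expansion idempotent.
#'
#' @param cpgs data.frame with at least `cpg_id`; extra columns (e.g. class
#'   labels) are carried along.
#' @param annot probe annotation with `cpg_id` and semicolon-separated
#'   `gene` / `region` columns (as in `rowData` of a simulated cohort).
#' @return data.frame of `cpgs` rows expanded with `gene` and `region`.
#' @export
expandByGene <- function(cpgs, annot) {
  ix <- match(cpgs$cpg_id, annot$cpg_id)
  gn <- as.character(annot$gene[ix])
  rg <- as.character(annot$region[ix])
  gn[is.na(gn)] <- ""
  rg[is.na(rg)] <- ""
  genes <- strsplit(gn, ";")
  regions <- strsplit(rg, ";")
  nrep <- lengths(genes)
  out <- cpgs[rep(seq_len(nrow(cpgs)), nrep), , drop = FALSE]
  out$gene <- unlist(genes)
  out$region <- unlist(regions)
  out <- unique(out)
  rownames(out) <- NULL
  out
}

## multivariate hypergeometric log-probability of a table with fixed margins
.tableLogProb <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(n + 1) -
    sum(lgamma(tab + 1))
}

#' Contingency-table enrichment test
#'
#' Three methods:
#' * `"chi-square"`: Pearson's Chi-squared test without continuity
#'   correction, any r x c table.
#' * `"fisher"`: exact Fisher test (2 x 2; the odds ratio reported is the
#'   sample OR `ad/bc`).
#' * `"fisher-mc"`: Monte Carlo Fisher test for arbitrary tables. `B` tables
#'   are drawn with fixed margins (`r2dtable`); a simulated table counts as
#'   at least as extreme when its conditional probability does not exceed
#'   that of the observed table, and `p = (1 + #extreme) / (1 + B)`.
#'
#' @param tab integer matrix of counts (>= 2 x 2, no zero margins).
#' @param method one of `"chi-square"`, `"fisher"`, `"fisher-mc"`.
#' @param B Monte Carlo replicates (default 1e5).
#' @param seed RNG seed for the Monte Carlo method.
#' @return list with `method`, `statistic`, `p`, `odds_ratio` (2 x 2 only),
#'   `n_montecarlo`.
#' @export
contingencyTest <- function(tab, method = c("chi-square", "fisher",
                                            "fisher-mc"),
                            B = 1e5, seed = NULL) {
  method <- match.arg(method)
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("table must be at least 2 x 2")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin in contingency table")
  or <- if (all(dim(tab) == 2))
    (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1]) else NA_real_
  if (method == "chi-square") {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    return(list(method = method, statistic = unname(ct$statistic),
                p = ct$p.value, odds_ratio = or, n_montecarlo = NA_integer_))
  }
  if (method == "fisher") {
    if (!all(dim(tab) == 2))
      stop("exact fisher here is for 2 x 2 tables; use fisher-mc")
    ft <- fisher.test(tab)
    return(list(method = method, statistic = NA_real_, p = ft$p.value,
                odds_ratio = or, n_montecarlo = NA_integer_))
  }
  if (!is.null(seed)) set.seed(seed)
  lp0 <- .tableLogProb(tab)
  sims <- r2dtable(B, rowSums(tab), colSums(tab))
  lps <- vapply(sims, .tableLogProb, numeric(1))
  extreme <- sum(lps <= lp0 + 1e-9)
  list(method = method, statistic = NA_real_,
       p = (1 + extreme) / (1 + B), odds_ratio = or, n_montecarlo = B)
}

#' Flag CpGs within a flank of annotated regions
#'
#' A CpG overlaps when any region lies within `flank` bp of its position
#' (inclusive: a CpG exactly `flank` bp from a region edge counts).
#' Chromosomes present among the CpGs but absent from the regions produce a
#' warning and no overlap.
#'
#' @param cpgs data.frame with `cpg_id`, `chrom`, `pos`.
#' @param regions a `GRanges` (e.g. from [readBedRegions()]) or data.frame
#'   with `chrom`, `start`, `end` (1-based inclusive).
#' @param flank distance in bp (default 25000).
#' @return `cpgs` with a logical `overlap` column.
#' @export
intervalOverlap <- function(cpgs, regions, flank = 25000) {
  if (is.data.frame(regions))
    regions <- GenomicRanges::GRanges(
      regions$chrom, IRanges::IRanges(regions$start, regions$end))
  missing <- setdiff(unique(cpgs$chrom),
                     as.character(GenomicRanges::seqnames(regions)))
  if (length(missing))
    warning("no regions on chromosome(s): ", paste(missing, collapse = ", "))
  grC <- GenomicRanges::GRanges(cpgs$chrom,
                                IRanges::IRanges(cpgs$pos, cpgs$pos))
  ext <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(regions),
    IRanges::IRanges(pmax(GenomicRanges::start(regions) - flank, 1L),
                     GenomicRanges::end(regions) + flank))
  ## seqlevel mismatches already warned about above
  hits <- suppressWarnings(GenomicRanges::findOverlaps(grC, ext))
  cpgs$overlap <- seq_len(nrow(cpgs)) %in% S4Vectors::queryHits(hits)
  cpgs
}

#' Class-by-annotation enrichment
#'
#' Builds the contingency table of CpG class (e.g. cis / trans / GIC /
#' non-heritable) against an annotation category (e.g. island relation or,
#' after [expandByGene()], gene region) and runs [contingencyTest()].
#'
#' @param classes data.frame with `cpg_id` and `class`.
#' @param annot vector of categories aligned with `classes$cpg_id`, or a
#'   data.frame with `cpg_id` plus one category column named by `column`.
#' @param column category column name when `annot` is a data.frame.
#' @param method,B,seed passed to [contingencyTest()].
#' @return list with `table` and the test result.
#' @export
enrichmentTest <- function(classes, annot, column = NULL,
                           method = "chi-square", B = 1e5, seed = NULL) {
  cat <- if (is.data.frame(annot)) {
    stopifnot(!is.null(column))
    annot[[column]][match(classes$cpg_id, annot$cpg_id)]
  } else annot
  ok <- !is.na(cat) & !is.na(classes$class)
  tab <- table(class = classes$class[ok], category = cat[ok])
  list(table = tab,
       test = contingencyTest(unclass(tab), method = method, B = B,
                              seed = seed))
}
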