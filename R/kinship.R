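## Expected pedigree relatedness and relative-pair enumeration.

#' Expected kinship / relatedness matrix from a pedigree
#'
#' Computes the expected relatedness structure entering the random effect of
#' the methylation mixed model by the tabular recursion: with individuals
#' ordered so parents precede children,
#' \eqn{\Phi_{ii} = \frac{1}{2}(1 + \Phi_{f(i),m(i)})} and
#' \eqn{\Phi_{ij} = \frac{1}{2}(\Phi_{f(i),j} + \Phi_{m(i),j})} for j
#' preceding i, founders being unrelated to everyone already present.
#' Individuals from different families always get 0, so the matrix is block
#' diagonal by family.
#'
#' @param ped a [Pedigree-class].
#' @param convention `"relatedness"` (2Phi, unit diagonal for non-inbred
#'   individuals; the default, so a fully genetic trait has variance ratio
#'   equal to its heritability) or `"kinship"` (Phi, diagonal 1/2).
#' @return symmetric numeric matrix with dimnames = individual ids, in the
#'   pedigree's row order, with attribute `convention`.
#' @examples
#' trio <- Pedigree(rep("F", 3), c("a", "b", "c"), c(NA, NA, "a"),
#'                  c(NA, NA, "b"), c("male", "female", "male"))
#' kinshipMatrix(trio)["a", "c"]   # parent-offspring relatedness 0.5
#' @export
kinshipMatrix <- function(ped, convention = c("relatedness", "kinship")) {
  convention <- match.arg(convention)
  p <- pedData(ped)
  n <- nrow(p)
  K <- matrix(0, n, n, dimnames = list(p$id, p$id))
  for (f in unique(p$family)) {
    rows <- which(p$family == f)
    pf <- p[rows, , drop = FALSE]
    ord <- .topoOrder(pf)
    if (is.null(ord))
      stop("pedigree error: individual listed as own ancestor in family ", f)
    m <- length(rows)
    phi <- matrix(0, m, m)
    fa <- match(pf$father, pf$id)
    mo <- match(pf$mother, pf$id)
    done <- integer(0)
    for (i in ord) {
      if (is.na(fa[i]) && is.na(mo[i])) {
        phi[i, i] <- 0.5
        ## founders unrelated to everyone already placed
      } else {
        pfm <- if (!is.na(fa[i]) && !is.na(mo[i])) phi[fa[i], mo[i]] else 0
        phi[i, i] <- 0.5 * (1 + pfm)
        for (j in done) {
          v <- 0.5 * ((if (!is.na(fa[i])) phi[fa[i], j] else 0) +
                      (if (!is.na(mo[i])) phi[mo[i], j] else 0))
          phi[i, j] <- v
          phi[j, i] <- v
        }
      }
      done <- c(done, i)
    }
    K[rows, rows] <- phi
  }
  if (convention == "relatedness") K <- 2 * K
  attr(K, "convention") <- convention
  K
}

## full siblings: both parents present and identical
.fullSibs <- function(pf) {
  key <- ifelse(is.na(pf$father) | is.na(pf$mother), NA_character_,
                paste(pf$father, pf$mother, sep = "\r"))
  split(pf$id, key)
}

.pairRow <- function(id1, id2, rel, sub, fam)
  data.frame(id1 = id1, id2 = id2, relationship = rel, subtype = sub,
             family = fam, stringsAsFactors = FALSE)

#' Enumerate typed relative pairs
#'
#' Lists every pair of the six familial relationship types used for the
#' pair-correlation analysis: parent-offspring, sibling-sibling (full
#' siblings), grandparent-grandchild, avuncular (a parent's full sibling with
#' the niece/nephew), cousin-cousin (children of full siblings), and
#' mother-father (spouses, defined as co-parents of at least one child).
#' Asymmetric types are ordered elder first (`id1`). Gender subtypes are
#' reported for parent-offspring (father-son, mother-son, father-daughter,
#' mother-daughter) and siblings (brother-brother, sister-brother,
#' sister-sister); other types carry subtype `"all"`. Half relationships are
#' not enumerated.
#'
#' @param ped a [Pedigree-class].
#' @return data.frame with columns `id1`, `id2`, `relationship`, `subtype`,
#'   `family`; each unordered pair appears at most once per relationship type.
#' @export
enumeratePairs <- function(ped) {
  p <- pedData(ped)
  out <- list()
  sexOf <- setNames(as.character(p$sex), p$id)
  for (f in unique(p$family)) {
    pf <- p[p$family == f, , drop = FALSE]
    fa <- setNames(pf$father, pf$id)
    mo <- setNames(pf$mother, pf$id)
    ## parent-offspring
    for (i in seq_len(nrow(pf))) {
      kid <- pf$id[i]
      kidw <- if (sexOf[kid] == "male") "son" else "daughter"
      if (!is.na(fa[kid]))
        out[[length(out) + 1L]] <- .pairRow(fa[kid], kid, "parent-offspring",
                                            paste0("father-", kidw), f)
      if (!is.na(mo[kid]))
        out[[length(out) + 1L]] <- .pairRow(mo[kid], kid, "parent-offspring",
                                            paste0("mother-", kidw), f)
    }
    ## full sibling sets
    sibsets <- .fullSibs(pf)
    for (sibs in sibsets) {
      if (length(sibs) < 2) next
      cmb <- utils::combn(sort(sibs), 2)
      for (k in seq_len(ncol(cmb))) {
        a <- cmb[1, k]; b <- cmb[2, k]
        sx <- sort(c(sexOf[a], sexOf[b]))
        sub <- if (all(sx == "male")) "brother-brother"
               else if (all(sx == "female")) "sister-sister"
               else "sister-brother"
        out[[length(out) + 1L]] <- .pairRow(a, b, "sibling-sibling", sub, f)
      }
    }
    ## grandparent-grandchild
    for (kid in pf$id) {
      for (par in c(fa[kid], mo[kid])) {
        if (is.na(par)) next
        for (gp in c(fa[par], mo[par]))
          if (!is.na(gp))
            out[[length(out) + 1L]] <- .pairRow(gp, kid,
                                                "grandparent-grandchild", "all", f)
      }
    }
    ## avuncular: full sibling of a parent
    sibOf <- list()
    for (sibs in sibsets)
      for (s in sibs) sibOf[[s]] <- setdiff(sibs, s)
    for (kid in pf$id) {
      for (par in c(fa[kid], mo[kid])) {
        if (is.na(par) || is.null(sibOf[[par]])) next
        for (au in sibOf[[par]])
          out[[length(out) + 1L]] <- .pairRow(au, kid, "avuncular", "all", f)
      }
    }
    ## cousins: children of full siblings
    kids <- pf$id[!is.na(fa[pf$id]) | !is.na(mo[pf$id])]
    if (length(kids) >= 2) {
      cous <- character(0)
      for (k in seq_along(kids)) for (l in seq_len(k - 1L)) {
        a <- kids[k]; b <- kids[l]
        pa <- c(fa[a], mo[a]); pb <- c(fa[b], mo[b])
        if (any(stats::na.omit(pa) %in% stats::na.omit(pb))) next  # siblings, not cousins
        isc <- FALSE
        for (x in pa) for (y in pb)
          if (!is.na(x) && !is.na(y) && !is.null(sibOf[[x]]) && y %in% sibOf[[x]])
            isc <- TRUE
        if (isc) {
          pr <- sort(c(a, b))
          key <- paste(pr, collapse = "\r")
          if (!key %in% cous) {
            cous <- c(cous, key)
            out[[length(out) + 1L]] <- .pairRow(pr[1], pr[2], "cousin-cousin",
                                                "all", f)
          }
        }
      }
    }
    ## spouses: co-parents of >= 1 child
    cp <- unique(stats::na.omit(data.frame(fa = pf$father, mo = pf$mother,
                                           stringsAsFactors = FALSE)))
    if (nrow(cp))
      for (k in seq_len(nrow(cp)))
        out[[length(out) + 1L]] <- .pairRow(cp$fa[k], cp$mo[k],
                                            "mother-father", "all", f)
  }
  if (!length(out))
    return(data.frame(id1 = character(), id2 = character(),
                      relationship = character(), subtype = character(),
                      family = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  unique(res)
}
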