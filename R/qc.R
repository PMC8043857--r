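## Sample/variant QC, exact Hardy-Weinberg test, KING-robust kinship,
## relatedness pruning and iterative PCA outlier removal.

## Dosages -> hard calls for HWE/kinship: round when within 0.1 of an
## integer, else treat as missing for those operations.
hardCalls <- function(d, tol = 0.1) {
  h <- round(d)
  h[abs(d - h) > tol] <- NA
  h
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test on the heterozygote count given the allele
#' counts: the P value sums the probabilities of all heterozygote counts
#' no more probable than the observed one under the conditional
#' (hypergeometric-type) distribution. Monomorphic variants return P = 1
#' by convention. An optional mid-P variant halves the probability of the
#' observed configuration.
#'
#' @param nAA,nAa,naa non-negative integer genotype counts.
#' @param midP use the mid-P correction (default FALSE).
#' @return P value in (0, 1].
#' @examples
#' hweExactTest(25, 50, 25)   # perfect HWE proportions
#' hweExactTest(50, 0, 50)    # total heterozygote deficit
#' @export
hweExactTest <- function(nAA, nAa, naa, midP = FALSE) {
  if (any(c(nAA, nAa, naa) < 0) || any(c(nAA, nAa, naa) != round(c(nAA, nAa, naa))))
    stop("genotype counts must be non-negative integers")
  n <- nAA + nAa + naa
  if (n < 1) stop("need at least one genotyped sample")
  nA <- 2L * nAA + nAa
  na <- 2L * naa + nAa
  if (nA == 0L || na == 0L) return(1)
  n1 <- min(nA, na)                     # rare allele count
  hs <- seq(n1 %% 2L, n1, by = 2L)      # feasible het counts share parity
  ## log P(het = h | allele counts), up to the common normalising constant
  lp <- lfactorial(n) - lfactorial((nA - hs) / 2) - lfactorial(hs) -
    lfactorial((na - hs) / 2) + hs * log(2)
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  pObs <- p[hs == nAa]
  tol <- 1 + 1e-12                      # guard against fp ties
  pv <- sum(p[p <= pObs * tol])
  if (midP) pv <- pv - pObs / 2
  min(pv, 1)
}

#' Variant-level quality control
#'
#' Retains variants with folded MAF at or above `mafMin`, per-variant
#' missingness at or below `missMax`, exact Hardy-Weinberg P at or above
#' `hweAlpha` (computed on hard calls; imputed dosages are rounded within
#' 0.1, else treated as missing for the test), and imputation R^2 at or
#' above `rsqMin` when an `rsq` column is present. Defaults mirror the
#' array-genotyping stage (MAF >= 0.1%, missingness <= 2%); for imputed
#' data use `mafMin = 0.02, rsqMin = 0.9`.
#'
#' @param geno a [GenotypeData-class].
#' @param mafMin minimum minor allele frequency (default 0.001).
#' @param missMax maximum per-variant missingness (default 0.02).
#' @param hweAlpha minimum exact HWE P value (default 0, i.e. off).
#' @param rsqMin minimum imputation R^2 (default NULL, off).
#' @return list with `geno` (filtered [GenotypeData-class]) and `report`
#'   (data.frame of per-criterion removal counts).
#' @export
filterVariants <- function(geno, mafMin = 0.001, missMax = 0.02,
                           hweAlpha = 0, rsqMin = NULL) {
  d <- dosages(geno)
  maf <- mafs(geno)
  miss <- colMeans(is.na(d))
  failMaf <- maf < mafMin
  failMiss <- miss > missMax
  failHwe <- rep(FALSE, ncol(d))
  if (hweAlpha > 0) {
    h <- hardCalls(d)
    hweP <- vapply(seq_len(ncol(h)), function(j) {
      x <- h[, j]
      hweExactTest(sum(x == 0, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
                   sum(x == 2, na.rm = TRUE))
    }, 0)
    failHwe <- hweP < hweAlpha
  }
  failRsq <- rep(FALSE, ncol(d))
  vi <- variantInfo(geno)
  if (!is.null(rsqMin) && "rsq" %in% names(vi))
    failRsq <- !is.na(vi$rsq) & vi$rsq < rsqMin
  keep <- !(failMaf | failMiss | failHwe | failRsq)
  if (!any(keep)) stop("all variants removed by QC")
  report <- data.frame(
    criterion = c("maf", "missingness", "hwe", "rsq", "retained"),
    n = c(sum(failMaf), sum(failMiss), sum(failHwe), sum(failRsq), sum(keep)))
  list(geno = new("GenotypeData", dosage = d[, keep, drop = FALSE],
                  variants = vi[keep, , drop = FALSE]),
       report = report)
}

#' Sample-level quality control
#'
#' Drops cases whose genotype missingness exceeds `missMax` (default 2%).
#'
#' @param geno a [GenotypeData-class].
#' @param missMax maximum per-sample missingness.
#' @return list with `geno` (filtered), `report` (per-sample missingness)
#'   and `removed` (case ids).
#' @export
filterSamples <- function(geno, missMax = 0.02) {
  d <- dosages(geno)
  miss <- rowMeans(is.na(d))
  keep <- miss <= missMax
  if (!any(keep)) stop("all samples removed by QC")
  list(geno = new("GenotypeData", dosage = d[keep, , drop = FALSE],
                  variants = variantInfo(geno)),
       report = data.frame(case = rownames(d), missingness = miss,
                           removed = !keep),
       removed = rownames(d)[!keep])
}

#' KING-robust pairwise kinship
#'
#' Moment estimator robust to population structure:
#' \deqn{\hat\phi_{ij} = \frac{N_{Aa,Aa} - 2 N_{AA,aa}}{N_{Aa}(i) + N_{Aa}(j)}}
#' where counts are over sites called in both samples: \eqn{N_{Aa,Aa}}
#' both-heterozygous sites, \eqn{N_{AA,aa}} opposite-homozygous sites, and
#' \eqn{N_{Aa}(\cdot)} each sample's heterozygote count. Duplicates score
#' 0.5, first-degree relatives about 0.25, unrelated pairs about 0.
#' Imputed dosages are rounded to hard calls within 0.1, else treated as
#' missing.
#'
#' @param geno a [GenotypeData-class].
#' @param pairs optional 2-column matrix/data.frame of case-id pairs; all
#'   unordered pairs when omitted.
#' @param variants optional variant ids restricting the computation (e.g.
#'   an LD-pruned set).
#' @return data.frame with `id1`, `id2`, `kinship`, `nSNP`; pairs whose
#'   heterozygote denominator is zero get `NA` kinship and are flagged in
#'   a `flag` column.
#' @export
kingKinship <- function(geno, pairs = NULL, variants = NULL) {
  g <- hardCalls(dosages(geno))
  if (!is.null(variants)) {
    miss <- setdiff(variants, colnames(g))
    if (length(miss)) stop("unknown variants: ", paste(miss, collapse = ", "))
    g <- g[, variants, drop = FALSE]
  }
  ids <- rownames(g)
  M <- !is.na(g)
  H <- (g == 1) & M; H[is.na(H)] <- FALSE
  A0 <- (g == 0) & M; A0[is.na(A0)] <- FALSE
  A2 <- (g == 2) & M; A2[is.na(A2)] <- FALSE
  storage.mode(H) <- storage.mode(A0) <- storage.mode(A2) <-
    storage.mode(M) <- "double"
  hetHet <- tcrossprod(H)
  oppHom <- tcrossprod(A0, A2) + tcrossprod(A2, A0)
  hetShared <- tcrossprod(H, M)          # het in i among sites called in j
  denom <- hetShared + t(hetShared)
  phi <- (hetHet - 2 * oppHom) / denom
  nSNP <- tcrossprod(M)
  if (is.null(pairs)) {
    idx <- which(upper.tri(phi), arr.ind = TRUE)
  } else {
    pairs <- as.matrix(pairs)
    idx <- cbind(match(pairs[, 1], ids), match(pairs[, 2], ids))
    if (anyNA(idx)) stop("unknown case id in pairs")
  }
  out <- data.frame(id1 = ids[idx[, 1]], id2 = ids[idx[, 2]],
                    kinship = phi[idx], nSNP = nSNP[idx])
  out$flag <- ifelse(denom[idx] == 0, "zero-het-denominator", "")
  out
}

#' Prune related samples
#'
#' Builds the relatedness graph over pairs with kinship at or above
#' `threshold` (default 0.0442, the third-degree cutoff
#' \eqn{2^{-9/2}} to 3 significant figures) and, per connected component,
#' retains the sample with the best call rate (ties broken by
#' lexicographically smallest id), removing the rest. Deterministic.
#'
#' @param kin kinship data.frame from [kingKinship()].
#' @param callRates named numeric vector, per-case call rates.
#' @param threshold kinship cutoff (default 0.0442).
#' @return character vector of case ids to remove (possibly empty).
#' @export
pruneRelateds <- function(kin, callRates, threshold = 0.0442) {
  rel <- kin[!is.na(kin$kinship) & kin$kinship >= threshold, , drop = FALSE]
  if (!nrow(rel)) return(character())
  ids <- sort(unique(c(rel$id1, rel$id2)))
  comp <- stats::setNames(seq_along(ids), ids)
  for (r in seq_len(nrow(rel))) {        # union-find (path-free, small n)
    c1 <- comp[rel$id1[r]]; c2 <- comp[rel$id2[r]]
    if (c1 != c2) comp[comp == c2] <- c1
  }
  removed <- character()
  for (cc in unique(comp)) {
    members <- names(comp)[comp == cc]
    cr <- callRates[members]
    if (anyNA(cr)) stop("missing call rate for: ",
                        paste(members[is.na(cr)], collapse = ", "))
    keep <- members[order(-cr, members)][1]
    removed <- c(removed, setdiff(members, keep))
  }
  sort(removed)
}

#' Iterative PCA outlier removal
#'
#' Standardises genotypes against the binomial allele-frequency model
#' (center \eqn{2p}, scale \eqn{\sqrt{2p(1-p)}}), computes the top
#' principal components, removes every sample lying beyond `sdCut`
#' standard deviations on any of the top PCs, and refits -- repeated up
#' to `nIter` times (stopping early when an iteration removes nobody).
#' Defaults (10 PCs, 6 SD, 5 iterations) follow standard
#' population-substructure practice. The final PCs are returned for use
#' as regression covariates.
#'
#' @param geno a [GenotypeData-class].
#' @param nPCs number of components (default 10, capped at n-1).
#' @param sdCut outlier cutoff in SDs (default 6).
#' @param nIter maximum iterations (default 5).
#' @param variants optional variant ids restricting the computation.
#' @return list with `pcs` (matrix, retained cases x PCs) and `removed`
#'   (character vector of case ids, in removal order).
#' @export
pcaOutlierLoop <- function(geno, nPCs = 10L, sdCut = 6, nIter = 5L,
                           variants = NULL) {
  d <- dosages(geno)
  if (!is.null(variants)) {
    miss <- setdiff(variants, colnames(d))
    if (length(miss)) stop("unknown variants: ", paste(miss, collapse = ", "))
    d <- d[, variants, drop = FALSE]
  }
  if (nrow(d) < nPCs + 1L)
    nPCs <- max(1L, nrow(d) - 1L)
  fitPCs <- function(d) {
    p <- colMeans(d, na.rm = TRUE) / 2
    keepVar <- p > 0 & p < 1 & !is.na(p)
    if (!any(keepVar)) stop("no polymorphic variants for PCA")
    z <- sweep(d[, keepVar, drop = FALSE], 2, 2 * p[keepVar])
    z <- sweep(z, 2, sqrt(2 * p[keepVar] * (1 - p[keepVar])), `/`)
    z[is.na(z)] <- 0
    k <- min(nPCs, nrow(z) - 1L, ncol(z))
    sv <- svd(z, nu = k, nv = 0)
    pcs <- sv$u %*% diag(sv$d[seq_len(k)], k)
    dimnames(pcs) <- list(rownames(d), paste0("PC", seq_len(k)))
    pcs
  }
  removed <- character()
  for (it in seq_len(nIter)) {
    pcs <- fitPCs(d)
    zs <- abs(scale(pcs))
    out <- rownames(d)[apply(zs > sdCut, 1, any)]
    if (!length(out)) return(list(pcs = pcs, removed = removed))
    removed <- c(removed, sort(out))
    d <- d[!rownames(d) %in% out, , drop = FALSE]
    if (nrow(d) < 3L) stop("outlier removal exhausted the sample")
  }
  list(pcs = fitPCs(d), removed = removed)
}
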