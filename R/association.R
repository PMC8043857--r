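## Quantitative-trait association: per-variant OLS under the additive
## model, two-stage combined analysis, stage-2 selection with LD pruning,
## Bonferroni thresholding and cis-eQTL with BH q-values.

## Expand a covariate data.frame into a numeric design matrix (categorical
## columns -> indicators), dropping constant columns with a warning.
covariateDesign <- function(cov, cases) {
  if (is.null(cov)) return(NULL)
  cov <- as.data.frame(cov)
  if (!is.null(rownames(cov)) && all(cases %in% rownames(cov)))
    cov <- cov[cases, , drop = FALSE]
  else if (nrow(cov) != length(cases))
    stop("covariate rows do not align with cases")
  X <- stats::model.matrix(~ ., data = cov)[, -1, drop = FALSE]
  keep <- apply(X, 2, function(x) stats::var(x, na.rm = TRUE) > 0)
  if (!all(keep))
    warning("constant covariate columns dropped: ",
            paste(colnames(X)[!keep], collapse = ", "))
  X[, keep, drop = FALSE]
}

## OLS of y on [1, g, X]; returns beta/se/t/p for g, or NA with a reason.
olsVariant <- function(y, g, X) {
  keep <- !is.na(y) & !is.na(g)
  if (!is.null(X)) keep <- keep & stats::complete.cases(X)
  n <- sum(keep)
  p <- 2L + if (is.null(X)) 0L else ncol(X)
  if (n < p + 1L)
    return(list(beta = NA_real_, se = NA_real_, t = NA_real_, p = NA_real_,
                n = n, note = "insufficient-n"))
  gk <- g[keep]
  if (stats::var(gk) == 0)
    return(list(beta = NA_real_, se = NA_real_, t = NA_real_, p = NA_real_,
                n = n, note = "constant-dosage"))
  D <- cbind(1, gk, if (!is.null(X)) X[keep, , drop = FALSE])
  fit <- stats::lm.fit(D, y[keep])
  df <- n - fit$rank
  piv <- fit$qr$pivot[seq_len(fit$rank)]
  k <- match(2L, piv)                    # dosage column within the pivot
  if (df < 1L || is.na(k) || is.na(fit$coefficients[2]))
    return(list(beta = NA_real_, se = NA_real_, t = NA_real_, p = NA_real_,
                n = n, note = "rank-deficient"))
  s2 <- sum(fit$residuals^2) / df
  R <- fit$qr$qr[seq_len(fit$rank), seq_len(fit$rank), drop = FALSE]
  XtXinv <- chol2inv(R)                  # (X'X)^-1 in pivoted order
  se <- sqrt(s2 * XtXinv[k, k])
  tstat <- fit$coefficients[2] / se
  list(beta = unname(fit$coefficients[2]), se = se, t = unname(tstat),
       p = 2 * stats::pt(-abs(tstat), df), n = n, note = "")
}

#' Additive-model quantitative-trait GWAS
#'
#' Per variant, ordinary least squares of the latent-trait phenotype on
#' allele dosage plus covariates (the additive model: one beta in latent
#' units per alternate allele), complete cases per variant, two-sided
#' t-test on residual degrees of freedom. Variants with constant dosage or
#' too few complete cases yield `NA` rows with a reason.
#'
#' @param lt per-case phenotype: named numeric vector or an [eapScores()]
#'   data.frame.
#' @param geno a [GenotypeData-class].
#' @param cov optional covariate data.frame (e.g. age at death in years,
#'   sex, principal components), rownames = case ids.
#' @param trait trait label stamped into the output (default "LT").
#' @param stage stage label (default "stage1").
#' @return data.frame with fixed columns CHR, POS, ID, A1, A2, TRAIT,
#'   BETA, SE, T, P, N, STAGE (plus NOTE for NA rows). A1 is the dosage
#'   (alt) allele, A2 the reference.
#' @export
qtGwas <- function(lt, geno, cov = NULL, trait = "LT", stage = "stage1") {
  if (is.data.frame(lt)) lt <- stats::setNames(lt$eap, lt$case)
  d <- dosages(geno)
  y <- lt[rownames(d)]
  X <- covariateDesign(cov, rownames(d))
  vi <- variantInfo(geno)
  res <- lapply(seq_len(ncol(d)), function(j) olsVariant(y, d[, j], X))
  data.frame(
    CHR = vi$chrom, POS = vi$pos, ID = vi$id, A1 = vi$alt, A2 = vi$ref,
    TRAIT = trait,
    BETA = vapply(res, `[[`, 0, "beta"),
    SE = vapply(res, `[[`, 0, "se"),
    T = vapply(res, `[[`, 0, "t"),
    P = vapply(res, `[[`, 0, "p"),
    N = vapply(res, `[[`, 0L, "n"),
    STAGE = stage,
    NOTE = vapply(res, `[[`, "", "note"))
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param m number of tests.
#' @return alpha / m.
#' @examples
#' bonferroniThreshold(0.05, 559348)   # ~9e-8, genome-wide for ~560k SNPs
#' @export
bonferroniThreshold <- function(alpha = 0.05, m) {
  stopifnot(m >= 1, alpha > 0, alpha < 1)
  alpha / m
}

#' Select stage-2 follow-up variants with LD pruning
#'
#' Takes stage-1 hits below `pCut`, ranks them by P ascending, and
#' greedily keeps a variant unless its squared dosage correlation with an
#' already-kept variant exceeds `ldR2Cut` -- so each LD cluster is
#' represented by its most significant member.
#'
#' @param assoc stage-1 association data.frame from [qtGwas()].
#' @param geno a [GenotypeData-class] carrying the dosages used for LD.
#' @param pCut P-value cutoff (default 1e-5).
#' @param ldR2Cut squared-correlation cutoff (default 0.95).
#' @return character vector of selected variant ids (possibly empty).
#' @export
selectStage2Snps <- function(assoc, geno, pCut = 1e-5, ldR2Cut = 0.95) {
  hits <- assoc[!is.na(assoc$P) & assoc$P < pCut, , drop = FALSE]
  if (!nrow(hits)) return(character())
  hits <- hits[order(hits$P), , drop = FALSE]
  d <- dosages(geno)
  miss <- setdiff(hits$ID, colnames(d))
  if (length(miss)) stop("hit variants missing from genotypes: ",
                         paste(miss, collapse = ", "))
  kept <- character()
  for (id in hits$ID) {
    if (length(kept)) {
      r2 <- vapply(kept, function(k)
        suppressWarnings(stats::cor(d[, id], d[, k],
                                    use = "pairwise.complete.obs"))^2, 0)
      r2[is.na(r2)] <- 0
      if (any(r2 > ldR2Cut)) next
    }
    kept <- c(kept, id)
  }
  kept
}

#' Combine two association stages
#'
#' `method = "ivw"` performs a fixed-effect inverse-variance-weighted
#' meta-analysis per (variant, trait):
#' \eqn{\beta = \sum b_s/se_s^2 / \sum 1/se_s^2},
#' \eqn{se = (\sum 1/se_s^2)^{-1/2}}. `method = "pooled"` re-fits the OLS
#' on the concatenated samples with a stage-indicator covariate and
#' requires the per-stage data via `stageData`. Variants present in only
#' one stage are passed through with a flag.
#'
#' @param stage1,stage2 association data.frames from [qtGwas()].
#' @param method `"pooled"` (default) or `"ivw"`.
#' @param stageData for `"pooled"`: list of two lists, each with elements
#'   `lt`, `geno` and optional `cov`.
#' @return combined association data.frame (STAGE = "combined" or "meta").
#' @export
combineStages <- function(stage1, stage2, method = c("pooled", "ivw"),
                          stageData = NULL) {
  method <- match.arg(method)
  key <- function(x) paste(x$ID, x$TRAIT)
  shared <- intersect(key(stage1), key(stage2))
  only1 <- stage1[!key(stage1) %in% shared, , drop = FALSE]
  only2 <- stage2[!key(stage2) %in% shared, , drop = FALSE]
  if (!length(shared)) {
    out <- stage1[0, , drop = FALSE]
    if (!"NOTE" %in% names(out)) out$NOTE <- character()
  } else if (method == "ivw") {
    s1 <- stage1[match(shared, key(stage1)), , drop = FALSE]
    s2 <- stage2[match(shared, key(stage2)), , drop = FALSE]
    w1 <- 1 / s1$SE^2
    w2 <- 1 / s2$SE^2
    beta <- (s1$BETA * w1 + s2$BETA * w2) / (w1 + w2)
    se <- sqrt(1 / (w1 + w2))
    z <- beta / se
    out <- data.frame(CHR = s1$CHR, POS = s1$POS, ID = s1$ID, A1 = s1$A1,
                      A2 = s1$A2, TRAIT = s1$TRAIT, BETA = beta, SE = se,
                      T = z, P = 2 * stats::pnorm(-abs(z)),
                      N = s1$N + s2$N, STAGE = "meta", NOTE = "")
  } else {
    if (is.null(stageData) || length(stageData) != 2L)
      stop("pooled combination needs stageData = list(stage1 = , stage2 = )")
    g1 <- stageData[[1]]$geno; g2 <- stageData[[2]]$geno
    ids <- unique(stage1$ID[key(stage1) %in% shared])
    lt1 <- stageData[[1]]$lt; lt2 <- stageData[[2]]$lt
    if (is.data.frame(lt1)) lt1 <- stats::setNames(lt1$eap, lt1$case)
    if (is.data.frame(lt2)) lt2 <- stats::setNames(lt2$eap, lt2$case)
    d1 <- dosages(g1); d2 <- dosages(g2)
    cases <- c(rownames(d1), rownames(d2))
    y <- c(lt1[rownames(d1)], lt2[rownames(d2)])
    stageInd <- rep(c(0, 1), c(nrow(d1), nrow(d2)))
    X1 <- covariateDesign(stageData[[1]]$cov, rownames(d1))
    X2 <- covariateDesign(stageData[[2]]$cov, rownames(d2))
    if (xor(is.null(X1), is.null(X2)) ||
        (!is.null(X1) && !identical(colnames(X1), colnames(X2))))
      stop("pooled stages must use the same covariate columns")
    X <- cbind(stage = stageInd, if (!is.null(X1)) rbind(X1, X2))
    trait <- unique(c(stage1$TRAIT, stage2$TRAIT))
    if (length(trait) != 1L) stop("pooled combination expects one trait")
    rows <- lapply(ids, function(id) {
      g <- c(d1[, id], d2[, id])
      r <- olsVariant(y, g, X)
      i <- match(id, stage1$ID)
      data.frame(CHR = stage1$CHR[i], POS = stage1$POS[i], ID = id,
                 A1 = stage1$A1[i], A2 = stage1$A2[i], TRAIT = trait,
                 BETA = r$beta, SE = r$se, T = r$t, P = r$p, N = r$n,
                 STAGE = "combined", NOTE = r$note)
    })
    out <- do.call(rbind, rows)
  }
  if (nrow(only1) || nrow(only2)) {
    pass <- rbind(only1, only2)
    pass$NOTE <- "single-stage"
    out <- rbind(out, pass)
  }
  rownames(out) <- NULL
  out
}

#' cis-eQTL scan with Benjamini-Hochberg q-values
#'
#' For every gene, tests variants whose position lies within `window`
#' base pairs of the gene body (boundary inclusive at exactly the window
#' edge; distance measured from gene start and end, 1-based inclusive
#' coordinates) by a linear model of expression on dosage plus covariates
#' (categorical covariates expanded to indicators). BH q-values are
#' computed over all tested (gene, variant) pairs.
#'
#' @param expr expression matrix, cases x genes (colnames = gene ids).
#' @param geno a [GenotypeData-class].
#' @param genes data.frame with columns `gene`, `chrom`, `start`, `end`
#'   (1-based inclusive; use [readGeneTable()] for BED input).
#' @param cov optional covariate data.frame.
#' @param window cis window in bp (default 1e6).
#' @return data.frame with gene, variant columns, BETA/SE/T/P/N and `q`;
#'   genes with no cis variants are skipped and listed in the
#'   `skippedGenes` attribute.
#' @export
cisEqtl <- function(expr, geno, genes, cov = NULL, window = 1e6) {
  d <- dosages(geno)
  vi <- variantInfo(geno)
  X <- covariateDesign(cov, rownames(d))
  rows <- list()
  skipped <- character()
  for (i in seq_len(nrow(genes))) {
    gn <- genes$gene[i]
    cis <- which(vi$chrom == genes$chrom[i] &
                   vi$pos >= genes$start[i] - window &
                   vi$pos <= genes$end[i] + window)
    if (!length(cis)) { skipped <- c(skipped, gn); next }
    y <- expr[rownames(d), gn]
    for (j in cis) {
      r <- olsVariant(y, d[, j], X)
      rows[[length(rows) + 1L]] <-
        data.frame(gene = gn, CHR = vi$chrom[j], POS = vi$pos[j],
                   ID = vi$id[j], A1 = vi$alt[j], A2 = vi$ref[j],
                   BETA = r$beta, SE = r$se, T = r$t, P = r$p, N = r$n,
                   NOTE = r$note)
    }
  }
  if (!length(rows)) stop("no (gene, variant) pair fell in a cis window")
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$P, method = "BH")
  rownames(out) <- NULL
  attr(out, "skippedGenes") <- skipped
  out
}
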