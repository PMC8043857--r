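## Synthetic cohorts with the statistical structure the pipeline assumes:
## latent severities driving ordinal items, HWE genotypes with planted
## additive effects, related pairs, covariates, cis-regulated expression.

#' Simulate a single-factor graded-response panel
#'
#' Draws latent severities from N(0,1) (or uses supplied values) and item
#' responses from the graded-response category probabilities. The
#' low-level generator behind the cohort simulator; also convenient for
#' parameter-recovery experiments.
#'
#' @param n number of cases (ignored when `theta` supplied).
#' @param a numeric vector of item discriminations.
#' @param b list of increasing threshold vectors, one per item.
#' @param theta optional latent values.
#' @param itemNames optional item labels (`<region>__<lesion>` style).
#' @param missing proportion of responses set missing at random (default 0).
#' @param seed optional RNG seed.
#' @return list with `panel` (a [PathologyPanel-class]), `theta`, `a`, `b`.
#' @export
simulateGRMPanel <- function(n, a, b, theta = NULL, itemNames = NULL,
                             missing = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(theta)) theta <- stats::rnorm(n)
  n <- length(theta)
  nIt <- length(a)
  if (length(b) != nIt) stop("a and b must have the same length")
  if (is.null(itemNames))
    itemNames <- paste0("region", seq_len(nIt), "__sim")
  K <- length(b[[1]]) + 1L
  sc <- matrix(NA_integer_, n, nIt,
               dimnames = list(paste0("case", seq_len(n)), itemNames))
  for (i in seq_len(nIt)) {
    P <- grmCategoryProbs(theta, a[i], b[[i]])
    u <- stats::runif(n)
    cum <- t(apply(P, 1, cumsum))
    sc[, i] <- as.integer(rowSums(u > cum))
  }
  if (missing > 0)
    sc[matrix(stats::runif(length(sc)) < missing, n, nIt)] <- NA_integer_
  list(panel = PathologyPanel(sc, nCat = max(lengths(b)) + 1L),
       theta = theta, a = a, b = b)
}

#' Configuration for a synthetic cohort
#'
#' Bundles and validates every generating parameter. Defaults emulate the
#' study's data structure: a combined-cohort-scale sample, the 18-region
#' x 4-lesion 0-3 panel, discriminations in [0.8, 2.5], lesion-level
#' latent factors with exchangeable correlation 0.6, HWE genotypes, and
#' age/sex covariates with null effects (so covariate adjustment can be
#' exercised both off and on).
#'
#' @param nCases cohort size (default 882, combined-cohort scale).
#' @param schema a [TraitSchema-class] (default [pspSchema()]).
#' @param aRange discrimination range (default c(0.8, 2.5)).
#' @param bCenterRange range of item threshold midpoints (default c(-1, 1)).
#' @param bSpreadRange range of threshold spacings (default c(0.6, 1.2)).
#' @param latentCor exchangeable correlation across lesion factors
#'   (default 0.6).
#' @param nVariants number of variants (default 500).
#' @param mafRange MAF range for simulated variants (default c(0.05, 0.5)).
#' @param plantedEffects data.frame (`variant` index or id, `lesion` label
#'   or "all", `beta` per allele on the latent scale), or NULL.
#' @param ageEffect,sexEffect covariate effects on all latent factors per
#'   unit (default 0).
#' @param lowInfoRegion optional region whose items are made near-constant
#'   (tiny discrimination, high thresholds), emulating a region that
#'   contributes little information.
#' @param missingScores proportion of pathology scores missing (default 0.02).
#' @param seed RNG seed (mandatory).
#' @return validated list of class `cohortConfig`.
#' @export
cohortConfig <- function(nCases = 882L, schema = pspSchema(),
                         aRange = c(0.8, 2.5), bCenterRange = c(-1, 1),
                         bSpreadRange = c(0.6, 1.2), latentCor = 0.6,
                         nVariants = 500L, mafRange = c(0.05, 0.5),
                         plantedEffects = NULL, ageEffect = 0,
                         sexEffect = 0, lowInfoRegion = NULL,
                         missingScores = 0.02, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(nCases >= 2, diff(aRange) >= 0, aRange[1] > 0,
            latentCor >= 0, latentCor < 1, nVariants >= 1,
            mafRange[1] > 0, mafRange[2] <= 0.5,
            missingScores >= 0, missingScores < 1)
  if (!is.null(plantedEffects)) {
    stopifnot(is.data.frame(plantedEffects),
              all(c("variant", "lesion", "beta") %in% names(plantedEffects)))
    num <- suppressWarnings(as.numeric(plantedEffects$variant))
    if (!anyNA(num) && any(num > nVariants))
      stop("planted variant index beyond nVariants")
    bad <- setdiff(plantedEffects$lesion, c(schema@lesions, "all"))
    if (length(bad)) stop("unknown lesion in planted effects: ",
                          paste(bad, collapse = ", "))
  }
  if (!is.null(lowInfoRegion) && !lowInfoRegion %in% schema@regions)
    stop("lowInfoRegion not in schema")
  structure(list(nCases = as.integer(nCases), schema = schema,
                 aRange = aRange, bCenterRange = bCenterRange,
                 bSpreadRange = bSpreadRange, latentCor = latentCor,
                 nVariants = as.integer(nVariants), mafRange = mafRange,
                 plantedEffects = plantedEffects, ageEffect = ageEffect,
                 sexEffect = sexEffect, lowInfoRegion = lowInfoRegion,
                 missingScores = missingScores, seed = as.integer(seed)),
            class = "cohortConfig")
}

#' Simulate a full cohort
#'
#' Lesion-level latent severities are drawn from a multivariate normal
#' with exchangeable correlation; planted genotype and covariate effects
#' shift the targeted lesion factors additively (per allele / per unit);
#' each item's ordinal response is drawn from its graded-response
#' probabilities at the latent value of its lesion's factor; genotypes are
#' drawn under Hardy-Weinberg at the configured MAFs. Byte-identical
#' outputs for identical config (the seed is part of the config).
#'
#' @param cfg a [cohortConfig()] object.
#' @return list with `panel` ([PathologyPanel-class]), `geno`
#'   ([GenotypeData-class]), `covariates` (data.frame: age, sex), and
#'   `truth` (every generating parameter: item parameters, latent factors,
#'   planted effects, variant MAFs, config echo).
#' @export
simulateCohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohortConfig"))
  set.seed(cfg$seed)
  schema <- cfg$schema
  n <- cfg$nCases
  caseIds <- sprintf("case%04d", seq_len(n))

  ## genotypes under HWE
  maf <- stats::runif(cfg$nVariants, cfg$mafRange[1], cfg$mafRange[2])
  G <- vapply(maf, function(p) stats::rbinom(n, 2L, p), integer(n))
  ids <- sprintf("var%04d", seq_len(cfg$nVariants))
  dimnames(G) <- list(caseIds, ids)
  pos <- sort(sample.int(2.4e8, cfg$nVariants))
  variants <- data.frame(id = ids, chrom = "1", pos = pos,
                         ref = "A", alt = "G")
  geno <- GenotypeData(G, variants)

  ## covariates
  age <- stats::rnorm(n, 74.9, 7.8)
  sex <- stats::rbinom(n, 1L, 0.46)
  covariates <- data.frame(age = age, sex = sex, row.names = caseIds)

  ## latent lesion factors: exchangeable MVN + planted shifts
  lesions <- schema@lesions
  L <- length(lesions)
  rho <- cfg$latentCor
  Sigma <- matrix(rho, L, L); diag(Sigma) <- 1
  Z <- matrix(stats::rnorm(n * L), n, L) %*% chol(Sigma)
  dimnames(Z) <- list(caseIds, lesions)
  if (!is.null(cfg$plantedEffects)) {
    pe <- cfg$plantedEffects
    for (r in seq_len(nrow(pe))) {
      v <- pe$variant[r]
      j <- if (v %in% ids) match(v, ids) else as.integer(v)
      target <- if (pe$lesion[r] == "all") lesions else pe$lesion[r]
      Z[, target] <- Z[, target] + pe$beta[r] * G[, j]
    }
  }
  if (cfg$ageEffect != 0) Z <- Z + cfg$ageEffect * (age - mean(age))
  if (cfg$sexEffect != 0) Z <- Z + cfg$sexEffect * sex

  ## item parameters and responses
  items <- as.vector(outer(schema@regions, lesions, paste, sep = "__"))
  nIt <- length(items)
  regOf <- sub("__.*$", "", items)
  lesOf <- sub("^.*__", "", items)
  a <- stats::runif(nIt, cfg$aRange[1], cfg$aRange[2])
  b <- lapply(seq_len(nIt), function(i) {
    ctr <- stats::runif(1, cfg$bCenterRange[1], cfg$bCenterRange[2])
    sp <- stats::runif(1, cfg$bSpreadRange[1], cfg$bSpreadRange[2])
    ctr + c(-1, 0, 1) * sp
  })
  if (!is.null(cfg$lowInfoRegion)) {
    li <- which(regOf == cfg$lowInfoRegion)
    a[li] <- 0.08
    b[li] <- lapply(b[li], function(bk) bk - min(bk) + 3)
  }
  sc <- matrix(NA_integer_, n, nIt, dimnames = list(caseIds, items))
  for (i in seq_len(nIt)) {
    th <- Z[, lesOf[i]]
    P <- grmCategoryProbs(th, a[i], b[[i]])
    u <- stats::runif(n)
    cum <- t(apply(P, 1, cumsum))
    sc[, i] <- as.integer(rowSums(u > cum))
  }
  if (cfg$missingScores > 0)
    sc[matrix(stats::runif(length(sc)) < cfg$missingScores, n, nIt)] <- NA_integer_
  panel <- PathologyPanel(sc, nCat = 4L)

  truth <- list(itemParams = list(items = items, a = a, b = b),
                factors = Z, maf = maf, covariates = covariates,
                plantedEffects = cfg$plantedEffects,
                ageEffect = cfg$ageEffect, sexEffect = cfg$sexEffect,
                config = cfg)
  list(panel = panel, geno = geno, covariates = covariates, truth = truth)
}

#' Simulate related genotype pairs
#'
#' Founders are drawn under HWE at the supplied allele frequencies;
#' offspring receive one gamete from each parent (an allele drawn
#' binomially from the parental dosage); duplicates are exact copies;
#' full sibs share both parents.
#'
#' @param nSNP number of variants (default 10000).
#' @param maf scalar or vector of allele frequencies (default 0.3).
#' @param nDuplicate,nParentOffspring,nFullSib,nUnrelated pair counts.
#' @param seed RNG seed.
#' @return list with `geno` ([GenotypeData-class]; pair members named
#'   `<type><k>_a` / `<type><k>_b`) and `pairs` (data.frame id1, id2,
#'   relationship).
#' @export
simulateRelateds <- function(nSNP = 10000L, maf = 0.3, nDuplicate = 0L,
                             nParentOffspring = 0L, nFullSib = 0L,
                             nUnrelated = 0L, seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  p <- rep_len(maf, nSNP)
  founder <- function() stats::rbinom(nSNP, 2L, p)
  gamete <- function(g) stats::rbinom(nSNP, 1L, g / 2)
  rows <- list(); pairs <- list()
  add <- function(type, k, g1, g2) {
    n1 <- sprintf("%s%d_a", type, k); n2 <- sprintf("%s%d_b", type, k)
    rows[[n1]] <<- g1; rows[[n2]] <<- g2
    pairs[[length(pairs) + 1L]] <<- data.frame(id1 = n1, id2 = n2,
                                               relationship = type)
  }
  for (k in seq_len(nDuplicate)) { g <- founder(); add("dup", k, g, g) }
  for (k in seq_len(nParentOffspring)) {
    p1 <- founder(); p2 <- founder()
    add("po", k, p1, gamete(p1) + gamete(p2))
  }
  for (k in seq_len(nFullSib)) {
    p1 <- founder(); p2 <- founder()
    add("sib", k, gamete(p1) + gamete(p2), gamete(p1) + gamete(p2))
  }
  for (k in seq_len(nUnrelated)) add("unrel", k, founder(), founder())
  G <- do.call(rbind, rows)
  variants <- data.frame(id = sprintf("var%05d", seq_len(nSNP)), chrom = "1",
                         pos = seq_len(nSNP) * 1000L, ref = "A", alt = "G")
  colnames(G) <- variants$id
  list(geno = GenotypeData(G, variants), pairs = do.call(rbind, pairs))
}

#' Simulate cis-regulated expression
#'
#' Per gene: expression = intercept + planted beta x dosage + covariate
#' effects + Gaussian noise. Gene bodies are placed so that each planted
#' variant is within the cis window of its gene while later genes leave
#' some variants trans (outside the window).
#'
#' @param geno a [GenotypeData-class].
#' @param nGenes number of genes (default 10).
#' @param effects data.frame (`gene` index, `variant` id or index, `beta`)
#'   of planted cis effects, or NULL.
#' @param noiseSD residual SD (default 1).
#' @param window cis window the placement respects (default 1e6).
#' @param seed RNG seed.
#' @return list with `expr` (cases x genes matrix), `genes` (data.frame
#'   gene, chrom, start, end; 1-based inclusive), `truth` (planted
#'   effects and noise SD).
#' @export
simulateExpression <- function(geno, nGenes = 10L, effects = NULL,
                               noiseSD = 1, window = 1e6, seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  d <- dosages(geno)
  vi <- variantInfo(geno)
  n <- nrow(d)
  geneIds <- sprintf("gene%03d", seq_len(nGenes))
  ## spread gene bodies across the span of the variant positions
  span <- range(vi$pos)
  starts <- round(seq(span[1], span[2], length.out = nGenes))
  genes <- data.frame(gene = geneIds, chrom = vi$chrom[1],
                      start = starts, end = starts + 49999L)
  expr <- matrix(stats::rnorm(n * nGenes, 0, noiseSD), n, nGenes,
                 dimnames = list(rownames(d), geneIds))
  planted <- NULL
  if (!is.null(effects)) {
    stopifnot(all(c("gene", "variant", "beta") %in% names(effects)))
    for (r in seq_len(nrow(effects))) {
      gi <- as.integer(effects$gene[r])
      v <- effects$variant[r]
      j <- if (v %in% vi$id) match(v, vi$id) else as.integer(v)
      ## move the gene next to its planted variant so the pair is cis
      genes$start[gi] <- max(1L, vi$pos[j] - as.integer(window / 2))
      genes$end[gi] <- genes$start[gi] + 49999L
      expr[, gi] <- expr[, gi] + effects$beta[r] * d[, j]
      planted <- rbind(planted,
                       data.frame(gene = geneIds[gi], variant = vi$id[j],
                                  beta = effects$beta[r]))
    }
  }
  list(expr = expr, genes = genes,
       truth = list(planted = planted, noiseSD = noiseSD))
}
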