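#' @import methods
NULL

#' Case-by-item panel of semi-quantitative pathology scores
#'
#' Holds ordinal lesion-burden ratings (none = 0, mild = 1, moderate = 2,
#' severe = 3) for one or more brain regions and lesion types per case.
#' Rows are cases, columns are items named `<region>__<lesion>`. Missing
#' ratings are `NA`.
#'
#' @slot scores integer matrix, cases x items; non-missing entries are
#'   non-negative ordinal category codes (0-based).
#' @slot items data.frame with columns `item`, `region`, `lesion`, one row
#'   per score column, in column order.
#' @slot nCat integer, number of ordinal categories items are rated on
#'   (4 for the 0-3 scale).
#'
#' @export
setClass("PathologyPanel",
  representation(scores = "matrix", items = "data.frame", nCat = "integer"))

setValidity("PathologyPanel", function(object) {
  sc <- object@scores
  msg <- character()
  if (is.null(rownames(sc))) msg <- c(msg, "scores must have case ids as rownames")
  if (nrow(object@items) != ncol(sc))
    msg <- c(msg, "items metadata must have one row per score column")
  if (!all(c("item", "region", "lesion") %in% names(object@items)))
    msg <- c(msg, "items must have columns item, region, lesion")
  if (anyDuplicated(object@items$item))
    msg <- c(msg, "duplicated (region, lesion) item")
  obs <- sc[!is.na(sc)]
  if (length(obs) && (any(obs < 0) || any(obs >= object@nCat) ||
                      any(obs != round(obs))))
    msg <- c(msg, sprintf("non-missing scores must be integers in 0..%d",
                          object@nCat - 1L))
  if (length(msg)) msg else TRUE
})

#' Construct a PathologyPanel
#'
#' @param scores numeric matrix of ordinal scores (cases x items) with case
#'   ids as rownames and `<region>__<lesion>` column names; `NA` = missing.
#' @param items optional data.frame (`item`, `region`, `lesion`); derived by
#'   splitting column names on `"__"` when omitted.
#' @param nCat number of ordinal categories (default 4, the 0-3 scale).
#' @return A [PathologyPanel-class] object.
#' @examples
#' m <- matrix(c(0, 1, 2, 3, 1, 2), nrow = 3,
#'             dimnames = list(paste0("case", 1:3),
#'                             c("motor_cortex__NFT", "pontine_base__CB")))
#' PathologyPanel(m)
#' @export
PathologyPanel <- function(scores, items = NULL, nCat = 4L) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "integer"
  if (is.null(rownames(scores)))
    rownames(scores) <- paste0("case", seq_len(nrow(scores)))
  if (is.null(items)) {
    parts <- strsplit(colnames(scores), "__", fixed = TRUE)
    if (any(lengths(parts) != 2L))
      stop("column names must look like <region>__<lesion>")
    items <- data.frame(item = colnames(scores),
                        region = vapply(parts, `[`, "", 1L),
                        lesion = vapply(parts, `[`, "", 2L))
  }
  new("PathologyPanel", scores = scores, items = items, nCat = as.integer(nCat))
}

#' Fitted graded response model
#'
#' Item parameters of Samejima's graded response model on the slope /
#' threshold scale: per item a discrimination `a > 0` and strictly
#' increasing thresholds `b_1 < ... < b_{K-1}`, the latent locations where
#' the cumulative probability of scoring at or above each category is 0.5.
#'
#' @slot items character, item labels.
#' @slot a numeric, per-item discriminations.
#' @slot b list of numeric vectors, per-item increasing thresholds.
#' @slot catLabels list of integer vectors: for each item the original
#'   category codes each fitted category maps to (identity unless sparse
#'   middle categories were collapsed during fitting).
#' @slot logLik numeric, final marginal log-likelihood.
#' @slot iterations integer, EM iterations used.
#' @slot converged logical.
#' @slot dropped character, items excluded (fewer than 2 observed categories).
#' @export
setClass("GRMFit",
  representation(items = "character", a = "numeric", b = "list",
                 catLabels = "list", logLik = "numeric",
                 iterations = "integer", converged = "logical",
                 dropped = "character"))

setValidity("GRMFit", function(object) {
  msg <- character()
  n <- length(object@items)
  if (length(object@a) != n || length(object@b) != n)
    msg <- c(msg, "a and b must match items in length")
  if (any(object@a <= 0)) msg <- c(msg, "discriminations must be positive")
  bad <- vapply(object@b, function(b) any(diff(b) <= 0), FALSE)
  if (any(bad)) msg <- c(msg, "thresholds must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' A family of latent-trait phenotypes
#'
#' Per-case expected a posteriori (EAP) severity scores and posterior SDs
#' for a set of named phenotypes, each backed by its own graded-response
#' fit on a defined item subset.
#'
#' @slot scores numeric matrix, cases x phenotypes (EAP, latent scale).
#' @slot psd numeric matrix, same shape, posterior SDs.
#' @slot provenance named list; per phenotype a list with `items` (item
#'   labels used), `hash` (provenance hash of items + data + fit config),
#'   `logLik`, `converged`.
#' @export
setClass("LatentTraitSet",
  representation(scores = "matrix", psd = "matrix", provenance = "list"))

setValidity("LatentTraitSet", function(object) {
  msg <- character()
  if (!identical(dim(object@scores), dim(object@psd)))
    msg <- c(msg, "scores and psd must have the same shape")
  if (!identical(colnames(object@scores), names(object@provenance)))
    msg <- c(msg, "provenance must be named by phenotype")
  if (length(msg)) msg else TRUE
})

#' Case-by-variant genotype dosages with variant metadata
#'
#' Dosages are expected alternate-allele counts in [0, 2]; hard calls are
#' the integers 0/1/2. Variant metadata carries chromosome, 1-based
#' position, ref/alt alleles and (for imputed data) the imputation R^2.
#'
#' @slot dosage numeric matrix, cases x variants, values in [0, 2] or `NA`.
#' @slot variants data.frame with columns `id`, `chrom`, `pos`, `ref`,
#'   `alt` and optionally `rsq`, one row per dosage column.
#' @export
setClass("GenotypeData",
  representation(dosage = "matrix", variants = "data.frame"))

setValidity("GenotypeData", function(object) {
  d <- object@dosage
  msg <- character()
  if (nrow(object@variants) != ncol(d))
    msg <- c(msg, "variants metadata must have one row per dosage column")
  if (!all(c("id", "chrom", "pos", "ref", "alt") %in% names(object@variants)))
    msg <- c(msg, "variants must have columns id, chrom, pos, ref, alt")
  rng <- range(d, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
    msg <- c(msg, "dosages must lie in [0, 2]")
  if (is.null(rownames(d))) msg <- c(msg, "dosage must have case ids as rownames")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeData object
#'
#' @param dosage numeric matrix (cases x variants), values in [0, 2].
#' @param variants data.frame of variant metadata (`id`, `chrom`, `pos`,
#'   `ref`, `alt`, optional `rsq`). A minimal frame is synthesised from
#'   column names when omitted.
#' @return A [GenotypeData-class] object.
#' @export
GenotypeData <- function(dosage, variants = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("case", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage)))
    colnames(dosage) <- paste0("var", seq_len(ncol(dosage)))
  if (is.null(variants))
    variants <- data.frame(id = colnames(dosage), chrom = "1",
                           pos = seq_len(ncol(dosage)), ref = "A", alt = "B")
  new("GenotypeData", dosage = dosage, variants = variants)
}

#' Trait schema: regions, lesions, forebrain/hindbrain partition
#'
#' Defines which regions and lesion types make up the item panel, how the
#' regions split at the mesencephalic/diencephalic junction, and which
#' items are excluded from all latent-trait scoring (e.g. temporal cortex,
#' whose skewed score distribution disqualifies it).
#'
#' @slot regions character, region labels.
#' @slot lesions character, lesion labels (NFT, CB, TA, threads).
#' @slot partition named character, region -> "forebrain"/"hindbrain".
#' @slot exclusions character, item labels never used in scoring.
#' @export
setClass("TraitSchema",
  representation(regions = "character", lesions = "character",
                 partition = "character", exclusions = "character"))

setValidity("TraitSchema", function(object) {
  msg <- character()
  if (!setequal(names(object@partition), object@regions))
    msg <- c(msg, "partition must be total over schema regions")
  if (!all(object@partition %in% c("forebrain", "hindbrain")))
    msg <- c(msg, "partition values must be forebrain/hindbrain")
  if (length(msg)) msg else TRUE
})
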