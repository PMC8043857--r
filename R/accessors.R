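#' Accessors for the core containers
#'
#' Slot access goes through these accessors: `scores()` returns the
#' case-by-item (or case-by-phenotype) matrix, `itemInfo()` the item
#' metadata, `dosages()` the case-by-variant dosage matrix, `mafs()` the
#' folded minor allele frequencies, `callRates()` the per-case genotyping
#' call rates, `discriminations()`/`thresholds()` the graded-response item
#' parameters, `posteriorSD()` the per-case posterior SDs and
#' `provenance()` the per-phenotype fit provenance.
#'
#' @param x a `PathologyPanel`, `GenotypeData`, `GRMFit` or
#'   `LatentTraitSet` object, as appropriate.
#' @param ... unused.
#' @return The corresponding slot content; `mafs()` and `callRates()`
#'   compute their values from the dosage matrix.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("scores", "PathologyPanel", function(x, ...) x@scores)

#' @rdname accessors
#' @export
setMethod("scores", "LatentTraitSet", function(x, ...) x@scores)

#' @rdname accessors
#' @export
setMethod("itemInfo", "PathologyPanel", function(x) x@items)

#' @rdname accessors
#' @export
setMethod("caseIDs", "PathologyPanel", function(x) rownames(x@scores))

#' @rdname accessors
#' @export
setMethod("caseIDs", "GenotypeData", function(x) rownames(x@dosage))

#' @rdname accessors
#' @export
setMethod("dosages", "GenotypeData", function(x) x@dosage)

#' @rdname accessors
#' @export
setMethod("variantInfo", "GenotypeData", function(x) x@variants)

#' @rdname accessors
#' @export
setMethod("mafs", "GenotypeData", function(x) {
  af <- colMeans(x@dosage, na.rm = TRUE) / 2
  pmin(af, 1 - af)
})

#' @rdname accessors
#' @export
setMethod("callRates", "GenotypeData", function(x) {
  1 - rowMeans(is.na(x@dosage))
})

#' @rdname accessors
#' @export
setMethod("discriminations", "GRMFit", function(x) {
  stats::setNames(x@a, x@items)
})

#' @rdname accessors
#' @export
setMethod("thresholds", "GRMFit", function(x) {
  stats::setNames(x@b, x@items)
})

#' @rdname accessors
#' @export
setMethod("posteriorSD", "LatentTraitSet", function(x) x@psd)

#' @rdname accessors
#' @export
setMethod("provenance", "LatentTraitSet", function(x) x@provenance)

setMethod("show", "PathologyPanel", function(object) {
  cat(sprintf("PathologyPanel: %d cases x %d items (%d regions, %d lesions), %d categories\n",
              nrow(object@scores), ncol(object@scores),
              length(unique(object@items$region)),
              length(unique(object@items$lesion)), object@nCat))
  cat(sprintf("  missing scores: %.1f%%\n", 100 * mean(is.na(object@scores))))
})

setMethod("show", "GRMFit", function(object) {
  cat(sprintf("GRMFit: %d items, logLik %.3f, %d EM iterations (%s)\n",
              length(object@items), object@logLik, object@iterations,
              if (object@converged) "converged" else "NOT converged"))
  if (length(object@dropped))
    cat("  dropped items:", paste(object@dropped, collapse = ", "), "\n")
})

setMethod("show", "LatentTraitSet", function(object) {
  cat(sprintf("LatentTraitSet: %d cases x %d phenotypes\n",
              nrow(object@scores), ncol(object@scores)))
  cat("  phenotypes:", paste(colnames(object@scores), collapse = ", "), "\n")
})

setMethod("show", "GenotypeData", function(object) {
  cat(sprintf("GenotypeData: %d cases x %d variants\n",
              nrow(object@dosage), ncol(object@dosage)))
  cat(sprintf("  MAF range: %.3f-%.3f; missing calls: %.2f%%\n",
              min(mafs(object)), max(mafs(object)),
              100 * mean(is.na(object@dosage))))
})

setMethod("show", "TraitSchema", function(object) {
  cat(sprintf("TraitSchema: %d regions x %d lesions (%d forebrain / %d hindbrain)\n",
              length(object@regions), length(object@lesions),
              sum(object@partition == "forebrain"),
              sum(object@partition == "hindbrain")))
  if (length(object@exclusions))
    cat("  excluded items:", paste(object@exclusions, collapse = ", "), "\n")
})
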