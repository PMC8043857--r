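## End-to-end orchestration: QC -> latent traits -> stage-1 GWAS ->
## stage-2 selection -> combined analysis -> optional cis-eQTL.

#' Run the full latent-trait genetics pipeline
#'
#' Stages, in order: sample QC, variant QC, KING-robust relatedness
#' pruning, PCA outlier removal, latent-trait construction, stage-1
#' additive-model GWAS per phenotype, stage-2 SNP selection with LD
#' pruning, and (when expression data are supplied) a cis-eQTL scan.
#' Writes all outputs plus a run manifest (config hash, package version,
#' per-stage counts) into `outDir`. Deterministic for a fixed config.
#'
#' @param config named list (or path to a YAML file) with elements:
#'   \describe{
#'     \item{simulate}{list of [cohortConfig()] arguments (a cohort is
#'       simulated) -- or instead supply `panelFile`, `vcfFile`,
#'       `covariateFile` paths.}
#'     \item{traits}{optional character vector of phenotype names to take
#'       through the GWAS (default "overall").}
#'     \item{qc}{optional list: `sampleMissMax` (0.02), `mafMin` (0.001),
#'       `missMax` (0.02), `hweAlpha` (0), `rsqMin` (NULL),
#'       `kinshipThreshold` (0.0442), `nPCs` (10), `sdCut` (6),
#'       `pcaIter` (5).}
#'     \item{assoc}{optional list: `pCut` (1e-5), `ldR2Cut` (0.95),
#'       `covariates` (character, default c("age", "sex")).}
#'     \item{eqtl}{optional list: `nGenes`, `effects`, `noiseSD`,
#'       `window` (1e6) -- expression is simulated against the cohort's
#'       genotypes.}
#'     \item{seed}{integer, required with `simulate`.}
#'   }
#' @param outDir output directory (created).
#' @return invisibly, a list with the main in-memory artifacts: `geno`,
#'   `lts`, `assoc` (stage-1 tables), `stage2`, `eqtl`, `manifest`.
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logLines <- character()
  note <- function(...) {
    msg <- sprintf(...)
    message(msg)
    logLines <<- c(logLines, msg)
  }

  ## --- inputs ---------------------------------------------------------
  if (!is.null(config$simulate)) {
    cfgArgs <- config$simulate
    if (is.null(cfgArgs$seed)) cfgArgs$seed <- config$seed
    if (is.null(cfgArgs$seed)) stop("simulate requires a seed")
    cfg <- do.call(cohortConfig, cfgArgs)
    sim <- simulateCohort(cfg)
    panel <- sim$panel; geno <- sim$geno; covars <- sim$covariates
    schema <- cfg$schema
  } else {
    for (f in c("panelFile", "vcfFile", "covariateFile"))
      if (is.null(config[[f]])) stop("config misses required path: ", f)
    panel <- readPathologyPanel(config$panelFile)
    geno <- readVCFDosages(config$vcfFile)
    covars <- readCovariates(config$covariateFile)
    schema <- if (!is.null(config$schemaFile)) readSchema(config$schemaFile)
              else pspSchema()
    sim <- NULL
  }
  note("input: %d cases x %d items; %d cases x %d variants",
       nrow(scores(panel)), ncol(scores(panel)),
       nrow(dosages(geno)), ncol(dosages(geno)))

  qcCfg <- utils::modifyList(
    list(sampleMissMax = 0.02, mafMin = 0.001, missMax = 0.02,
         hweAlpha = 0, rsqMin = NULL, kinshipThreshold = 0.0442,
         nPCs = 10L, sdCut = 6, pcaIter = 5L),
    config$qc %||% list())
  asCfg <- utils::modifyList(
    list(pCut = 1e-5, ldR2Cut = 0.95, covariates = c("age", "sex")),
    config$assoc %||% list())
  fitCfg <- utils::modifyList(list(tol = 1e-4, maxIter = 500L),
                              config$fit %||% list())

  missingCov <- setdiff(asCfg$covariates, names(covars))
  if (length(missingCov))
    stop("covariate column(s) not in covariate table: ",
         paste(missingCov, collapse = ", "))

  ## --- QC -------------------------------------------------------------
  fs <- filterSamples(geno, qcCfg$sampleMissMax)
  note("sample QC: removed %d of %d", length(fs$removed), nrow(dosages(geno)))
  fv <- filterVariants(fs$geno, mafMin = qcCfg$mafMin,
                       missMax = qcCfg$missMax, hweAlpha = qcCfg$hweAlpha,
                       rsqMin = qcCfg$rsqMin)
  geno <- fv$geno
  note("variant QC: retained %d variants", ncol(dosages(geno)))
  utils::write.csv(fv$report, file.path(outDir, "qc_variant_report.csv"),
                   row.names = FALSE)

  kin <- kingKinship(geno)
  rel <- pruneRelateds(kin, stats::setNames(callRates(geno), caseIDs(geno)),
                       qcCfg$kinshipThreshold)
  if (length(rel)) {
    geno <- new("GenotypeData",
                dosage = dosages(geno)[!caseIDs(geno) %in% rel, , drop = FALSE],
                variants = variantInfo(geno))
  }
  note("relatedness: removed %d sample(s)", length(rel))
  writeLines(rel, file.path(outDir, "removed_relateds.txt"))

  pca <- pcaOutlierLoop(geno, nPCs = qcCfg$nPCs, sdCut = qcCfg$sdCut,
                        nIter = qcCfg$pcaIter)
  if (length(pca$removed)) {
    geno <- new("GenotypeData",
                dosage = dosages(geno)[!caseIDs(geno) %in% pca$removed, ,
                                       drop = FALSE],
                variants = variantInfo(geno))
  }
  note("PCA outliers: removed %d sample(s)", length(pca$removed))
  writeLines(pca$removed, file.path(outDir, "removed_pca_outliers.txt"))

  ## --- latent traits --------------------------------------------------
  keepCases <- intersect(caseIDs(panel), caseIDs(geno))
  panelQC <- new("PathologyPanel",
                 scores = scores(panel)[keepCases, , drop = FALSE],
                 items = itemInfo(panel), nCat = panel@nCat)
  lts <- buildTraitSet(panelQC, schema, tol = fitCfg$tol,
                       maxIter = fitCfg$maxIter)
  writeLatentTraits(lts, file.path(outDir, "latent_traits.csv"))
  note("latent traits: %d phenotypes x %d cases", ncol(scores(lts)),
       nrow(scores(lts)))

  ## information-curve summary on the overall fit
  overallItems <- provenance(lts)$overall$items
  fitOverall <- fitGRM(panelQC, items = overallItems, tol = fitCfg$tol,
                       maxIter = fitCfg$maxIter)
  grouping <- stats::setNames(sub("__.*$", "", fitOverall@items),
                              fitOverall@items)
  auc <- informationCurveAUC(fitOverall, grouping)
  utils::write.csv(data.frame(region = names(auc), auc = auc),
                   file.path(outDir, "information_auc.csv"),
                   row.names = FALSE)
  grDevices::png(file.path(outDir, "information_curves.png"),
                 width = 900, height = 600)
  plotInformationCurves(fitOverall, grouping)
  grDevices::dev.off()

  ## --- association ----------------------------------------------------
  traits <- config$traits %||% "overall"
  covUse <- covars[keepCases, asCfg$covariates, drop = FALSE]
  genoLT <- new("GenotypeData",
                dosage = dosages(geno)[keepCases, , drop = FALSE],
                variants = variantInfo(geno))
  assocTables <- list()
  stage2 <- list()
  for (tr in traits) {
    lt <- stats::setNames(scores(lts)[, tr], rownames(scores(lts)))
    tab <- qtGwas(lt, genoLT, cov = covUse, trait = tr)
    assocTables[[tr]] <- tab
    stage2[[tr]] <- selectStage2Snps(tab, genoLT, pCut = asCfg$pCut,
                                     ldR2Cut = asCfg$ldR2Cut)
    note("GWAS %s: %d variants tested, %d stage-2 selections", tr,
         sum(!is.na(tab$P)), length(stage2[[tr]]))
  }
  allAssoc <- do.call(rbind, assocTables)
  utils::write.csv(allAssoc, file.path(outDir, "association_stage1.csv"),
                   row.names = FALSE)
  writeLines(unlist(stage2), file.path(outDir, "stage2_selection.txt"))

  ## --- eQTL (optional) ------------------------------------------------
  eq <- NULL
  if (!is.null(config$eqtl)) {
    ec <- config$eqtl
    ex <- simulateExpression(genoLT, nGenes = ec$nGenes %||% 10L,
                             effects = ec$effects,
                             noiseSD = ec$noiseSD %||% 1,
                             window = ec$window %||% 1e6,
                             seed = (config$seed %||% 1L) + 1L)
    eq <- cisEqtl(ex$expr, genoLT, ex$genes, cov = covUse,
                  window = ec$window %||% 1e6)
    utils::write.csv(eq, file.path(outDir, "eqtl.csv"), row.names = FALSE)
    note("eQTL: %d pairs tested, %d with q < 0.05", nrow(eq),
         sum(eq$q < 0.05, na.rm = TRUE))
  }

  ## --- manifest -------------------------------------------------------
  cfgFile <- file.path(outDir, "config_used.yaml")
  yaml::write_yaml(rapply(config, as.vector, how = "replace"), cfgFile)
  manifest <- list(configHash = unname(tools::md5sum(cfgFile)),
                   package = as.character(utils::packageVersion("tauLT")),
                   log = logLines)
  yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
  writeLines(logLines, file.path(outDir, "qc_report.txt"))

  invisible(list(geno = genoLT, lts = lts, assoc = allAssoc,
                 stage2 = stage2, eqtl = eq, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
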