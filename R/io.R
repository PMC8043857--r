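## Readers and writers for the pipeline's plain-text formats: pathology
## CSV, VCF dosages (DS preferred, GT fallback), covariate CSV, gene
## coordinate tables (1-based or BED) and schema sidecars (YAML).

#' Read a pathology panel from a delimited table
#'
#' One row per case, first column the case id, remaining columns named
#' `<region>__<lesion>` with values 0-3 or empty (missing).
#'
#' @param path CSV/TSV file path.
#' @param sep field separator (default ",").
#' @return a [PathologyPanel-class].
#' @export
readPathologyPanel <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(df[[1]])
  PathologyPanel(m)
}

#' Write a pathology panel
#' @param panel a [PathologyPanel-class].
#' @param path output CSV path.
#' @export
writePathologyPanel <- function(panel, path) {
  df <- data.frame(case = caseIDs(panel), scores(panel),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
}

#' Read genotype dosages from a VCF
#'
#' The DS (dosage) FORMAT field is preferred when present; otherwise GT
#' hard calls are converted to alternate-allele counts. Multi-allelic
#' records are skipped with a warning. Returns variants in file order.
#'
#' @param path VCF path (plain or bgzipped).
#' @return a [GenotypeData-class] (cases x variants; `rsq` column filled
#'   from an `R2` or `DR2` INFO key when present).
#' @export
readVCFDosages <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) skipped")
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  fmt <- v@gt[, 1]
  hasDS <- all(grepl("(^|:)DS(:|$)", fmt))
  if (hasDS) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- matrix(vapply(gt, function(x) {
      if (is.na(x) || grepl("\\.", x)) return(NA_real_)
      sum(as.integer(strsplit(x, "[/|]")[[1]]))
    }, 0), nrow = nrow(gt), dimnames = dimnames(gt))
  }
  rsq <- suppressWarnings(as.numeric(sub(".*R2=([0-9.eE+-]+).*", "\\1",
                                         fix$INFO)))
  rsq[!grepl("R2=", fix$INFO)] <- NA_real_
  ids <- fix$ID
  noId <- is.na(ids) | ids == "."
  ids[noId] <- paste0(fix$CHROM[noId], ":", fix$POS[noId])
  variants <- data.frame(id = ids, chrom = fix$CHROM,
                         pos = as.integer(fix$POS), ref = fix$REF,
                         alt = fix$ALT, rsq = rsq)
  d <- t(ds)
  colnames(d) <- ids
  GenotypeData(d, variants)
}

#' Write genotype dosages as a VCF
#'
#' Emits VCF 4.2 with GT (rounded hard call, `./.` when the dosage is not
#' within 0.1 of an integer or is missing) and DS fields; imputation R^2
#' goes into the INFO column as `R2=` when present.
#'
#' @param geno a [GenotypeData-class].
#' @param path output path.
#' @export
writeVCFDosages <- function(geno, path) {
  d <- dosages(geno)
  vi <- variantInfo(geno)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
               "##INFO=<ID=R2,Number=1,Type=Float,Description=\"Imputation R-squared\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(d)), collapse = "\t")), con)
  h <- hardCalls(d)
  gtStr <- matrix("./.", nrow(d), ncol(d))
  gtStr[!is.na(h) & h == 0] <- "0/0"
  gtStr[!is.na(h) & h == 1] <- "0/1"
  gtStr[!is.na(h) & h == 2] <- "1/1"
  for (j in seq_len(ncol(d))) {
    ds <- ifelse(is.na(d[, j]), ".", formatC(d[, j], format = "g", digits = 6))
    info <- if ("rsq" %in% names(vi) && !is.na(vi$rsq[j]))
      paste0("R2=", vi$rsq[j]) else "."
    writeLines(paste(c(vi$chrom[j], vi$pos[j], vi$id[j], vi$ref[j],
                       vi$alt[j], ".", "PASS", info, "GT:DS",
                       paste(gtStr[, j], ds, sep = ":")), collapse = "\t"),
               con)
  }
  invisible(path)
}

#' Read a covariate table
#'
#' First column = case id (used as rownames); remaining columns are
#' covariates. Sex and other categorical covariates are kept as given;
#' encoding is declared by the caller, never inferred from genotypes.
#'
#' @param path CSV path.
#' @return data.frame with case ids as rownames.
#' @export
readCovariates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  rownames(df) <- as.character(df[[1]])
  df[, -1, drop = FALSE]
}

#' Read gene coordinates
#'
#' Either a 1-based inclusive delimited table with columns `gene`,
#' `chrom`, `start`, `end`, or a BED file (0-based half-open, converted
#' to 1-based inclusive on ingest).
#'
#' @param path file path.
#' @param format `"table"` (default) or `"bed"`.
#' @return data.frame `gene`, `chrom`, `start`, `end` (1-based inclusive).
#' @export
readGeneTable <- function(path, format = c("table", "bed")) {
  format <- match.arg(format)
  if (format == "bed") {
    df <- utils::read.table(path, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE)
    data.frame(gene = df[[4]], chrom = as.character(df[[1]]),
               start = df[[2]] + 1L, end = df[[3]])
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    stopifnot(all(c("gene", "chrom", "start", "end") %in% names(df)))
    df$chrom <- as.character(df$chrom)
    df[, c("gene", "chrom", "start", "end")]
  }
}

#' Write latent-trait score and posterior-SD tables
#'
#' @param lts a [LatentTraitSet-class].
#' @param path output CSV for EAP scores; the posterior-SD companion is
#'   written next to it with suffix `_psd.csv`.
#' @export
writeLatentTraits <- function(lts, path) {
  df <- data.frame(case = rownames(scores(lts)), scores(lts),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  psdPath <- sub("\\.csv$", "_psd.csv", path)
  dfp <- data.frame(case = rownames(posteriorSD(lts)), posteriorSD(lts),
                    check.names = FALSE)
  utils::write.csv(dfp, psdPath, row.names = FALSE, quote = FALSE)
  invisible(c(path, psdPath))
}

#' Write / read a trait schema sidecar (YAML)
#'
#' @param schema a [TraitSchema-class].
#' @param path YAML path.
#' @export
writeSchema <- function(schema, path) {
  yaml::write_yaml(list(regions = schema@regions, lesions = schema@lesions,
                        partition = as.list(schema@partition),
                        exclusions = schema@exclusions), path)
  invisible(path)
}

#' @rdname writeSchema
#' @export
readSchema <- function(path) {
  x <- yaml::read_yaml(path)
  TraitSchema(regions = unlist(x$regions), lesions = unlist(x$lesions),
              partition = unlist(x$partition),
              exclusions = as.character(unlist(x$exclusions)))
}
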