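#' Read association inputs from files
#'
#' Ingests a covariate CSV (header; first column the patient id), a
#' phenotype CSV (patient id, 0/1 outcome) and a genotype matrix — either
#' a TSV with one row per patient (first column the patient id, remaining
#' columns 0/1 SNPs) or a VCF (plain or gzipped). The three sources are
#' joined on patient id, never by row order; the intercept column is
#' prepended; all [GwasDataset-class] invariants are validated with
#' row/column context in error messages.
#'
#' VCF genotypes binarize by ALT presence: `0/0 -> 0`; `0/1`, `1/1`,
#' `1|0`, any ALT allele `-> 1`. Missing genotypes (`./.`) are an error
#' unless `imputeMissing` supplies a substitute value.
#'
#' @param covariatesPath path to the covariate CSV.
#' @param phenotypePath path to the phenotype CSV.
#' @param genotypePath path to the genotype TSV or VCF (`.vcf` /
#'   `.vcf.gz`).
#' @param dosage allow 0/1/2 genotype counts in the TSV.
#' @param imputeMissing `NULL` (error on missing genotypes) or a value
#'   (e.g. 0) substituted for them.
#' @return A [GwasDataset-class].
#' @export
readInputs <- function(covariatesPath, phenotypePath, genotypePath,
                       dosage = FALSE, imputeMissing = NULL) {
  for (p in c(covariatesPath, phenotypePath, genotypePath))
    if (!file.exists(p)) stop("input file not found: ", p)
  cov <- utils::read.csv(covariatesPath, check.names = FALSE,
                         stringsAsFactors = FALSE)
  phe <- utils::read.csv(phenotypePath, check.names = FALSE,
                         stringsAsFactors = FALSE)
  ids <- as.character(cov[[1]])
  if (anyDuplicated(ids)) stop("duplicate patient ids in covariate file")
  pheIds <- as.character(phe[[1]])
  missingPhe <- setdiff(ids, pheIds)
  if (length(missingPhe) > 0)
    stop("patients missing from phenotype file: ",
         paste(utils::head(missingPhe, 5), collapse = ", "))
  y <- phe[[2]][match(ids, pheIds)]
  if (anyNA(y) || !all(y %in% c(0, 1)))
    stop("phenotype must be 0/1 with no missing values")
  Xcov <- as.matrix(cov[, -1, drop = FALSE])
  if (anyNA(Xcov)) {
    bad <- which(is.na(Xcov), arr.ind = TRUE)[1, ]
    stop(sprintf("missing covariate value at row %d, column '%s'",
                 bad[1], colnames(Xcov)[bad[2]]))
  }
  if (grepl("\\.vcf(\\.gz)?$", genotypePath, ignore.case = TRUE)) {
    geno <- .readVcfGenotypes(genotypePath, imputeMissing)
  } else {
    gt <- utils::read.delim(genotypePath, check.names = FALSE,
                            stringsAsFactors = FALSE)
    gIds <- as.character(gt[[1]])
    G <- as.matrix(gt[, -1, drop = FALSE])
    storage.mode(G) <- "numeric"
    rownames(G) <- gIds
    geno <- G
  }
  missingGeno <- setdiff(ids, rownames(geno))
  if (length(missingGeno) > 0)
    stop("patients missing from genotype file: ",
         paste(utils::head(missingGeno, 5), collapse = ", "))
  S <- geno[match(ids, rownames(geno)), , drop = FALSE]
  if (anyNA(S)) {
    if (is.null(imputeMissing)) {
      bad <- which(is.na(S), arr.ind = TRUE)[1, ]
      stop(sprintf("missing genotype for patient '%s', SNP '%s' (use imputeMissing to substitute)",
                   rownames(S)[bad[1]], colnames(S)[bad[2]]))
    }
    S[is.na(S)] <- imputeMissing
  }
  if (!dosage && !all(S %in% c(0, 1))) {
    bad <- which(!(S %in% c(0, 1)))[1]
    bc <- arrayInd(bad, dim(S))
    stop(sprintf("non-binary genotype %g for patient '%s', SNP '%s' (use dosage = TRUE)",
                 S[bad], rownames(S)[bc[1]], colnames(S)[bc[2]]))
  }
  X <- cbind(`(Intercept)` = 1, Xcov)
  rownames(X) <- ids
  GwasDataset(X, y, S, snpIds = colnames(S), sampleIds = ids,
              dosage = dosage)
}

#' Parse VCF genotypes into a patient-by-SNP binary matrix
#' @noRd
.readVcfGenotypes <- function(path, imputeMissing = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gtChar <- vcfR::extract.gt(v, element = "GT")
  snp <- rownames(gtChar)
  if (is.null(snp) || anyNA(snp) || anyDuplicated(snp))
    snp <- paste0(v@fix[, "CHROM"], ":", v@fix[, "POS"])
  # any ALT allele present -> 1 (presence coding, phased or unphased)
  hasAlt <- function(g) {
    alleles <- strsplit(g, "[/|]")
    vapply(alleles, function(a) {
      if (any(a == "." | is.na(a))) return(NA_real_)
      as.numeric(any(a != "0"))
    }, numeric(1))
  }
  B <- apply(gtChar, 2, hasAlt)
  B[is.na(gtChar)] <- NA_real_
  B <- matrix(B, nrow = nrow(gtChar), ncol = ncol(gtChar),
              dimnames = list(snp, colnames(gtChar)))
  if (anyNA(B) && is.null(imputeMissing)) {
    bad <- which(is.na(B), arr.ind = TRUE)[1, ]
    stop(sprintf("missing genotype './.' for patient '%s', SNP '%s' (use imputeMissing to substitute)",
                 colnames(B)[bad[2]], rownames(B)[bad[1]]))
  }
  t(B)  # patient-major
}

#' Write per-SNP results to TSV
#'
#' Columns `snp_id`, `numerator`, `denominator`, `tstat`, `pvalue`,
#' `masked` (and `log_stat`, `sign` when present), one row per SNP in
#' input order; masked SNPs carry `masked = 1` and empty
#' `tstat`/`pvalue`. Deterministic formatting, so identical runs produce
#' byte-identical files.
#'
#' @param stats a [SnpStats-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeResults <- function(stats, path) {
  stopifnot(is(stats, "SnpStats"))
  df <- as.data.frame(stats)
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "masked"
  for (j in which(num)) {
    col <- sprintf("%.10g", df[[j]])
    col[!is.finite(df[[j]])] <- ""
    df[[j]] <- col
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a dataset to the on-disk input layout
#'
#' Produces the covariate CSV, phenotype CSV and genotype TSV that
#' [readInputs()] consumes, plus a small JSON-like manifest recording the
#' dimensions. Round-trips through [readInputs()] exactly.
#'
#' @param data a [GwasDataset-class].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Named character vector of the written paths, invisibly.
#' @export
writeFixtures <- function(data, dir, prefix = "gwas") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  X <- covariateMatrix(data)
  y <- phenotype(data)
  S <- genotypeMatrix(data)
  ids <- rownames(X)
  if (is.null(ids)) ids <- paste0("sample", seq_len(nrow(X)))
  covPath <- file.path(dir, paste0(prefix, "_covariates.csv"))
  phePath <- file.path(dir, paste0(prefix, "_phenotype.csv"))
  genPath <- file.path(dir, paste0(prefix, "_genotypes.tsv"))
  manPath <- file.path(dir, paste0(prefix, "_manifest.txt"))
  covDf <- data.frame(patient_id = ids, X[, -1, drop = FALSE],
                      check.names = FALSE)
  utils::write.csv(covDf, covPath, row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(patient_id = ids, y = y), phePath,
                   row.names = FALSE, quote = FALSE)
  genDf <- data.frame(patient_id = ids, S, check.names = FALSE)
  utils::write.table(genDf, genPath, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  writeLines(sprintf("%s\t%d", c("n", "m", "k"),
                     c(nSamples(data), nSnps(data), nCovariates(data))),
             manPath)
  invisible(c(covariates = covPath, phenotype = phePath,
              genotypes = genPath, manifest = manPath))
}
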