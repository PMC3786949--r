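#' Read genotypes from PLINK raw or TSV text
#'
#' PLINK `.raw` additive exports (`FID IID PAT MAT SEX PHENOTYPE SNP...`,
#' phenotype coded 1 = control / 2 = case, mapped to 0/1 internally) or
#' plain TSV (header of SNP ids, optional leading `phenotype` column of
#' 0/1). Missing genotypes (`NA`) are mean-imputed per SNP with the count
#' recorded, and columns are re-oriented to the minor allele.
#'
#' @param path file path.
#' @param format `"plink_raw"` or `"tsv"`.
#' @return list with `genotypes` (a [genotype_matrix()], attribute
#'   `"n_imputed"` giving the imputed-entry count), and `phenotype`
#'   (0/1 vector, or `NULL` when absent).
#' @export
read_genotypes <- function(path, format = c("plink_raw", "tsv")) {
  format <- match.arg(format)
  df <- utils::read.table(path, header = TRUE, sep = if (format == "tsv")
    "\t" else "", na.strings = c("NA", "-9"), check.names = FALSE,
    stringsAsFactors = FALSE)
  if (format == "plink_raw") {
    need <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!all(need %in% names(df)[1:6]))
      stop("malformed PLINK .raw header in ", path)
    pheno <- df$PHENOTYPE
    if (!all(pheno %in% c(1, 2, NA)))
      stop("PLINK phenotype must be coded 1/2 (or missing)")
    pheno <- pheno - 1
    ids <- df$IID
    gcols <- df[-(1:6)]
  } else {
    has_ph <- tolower(names(df)[1]) %in% c("phenotype", "pheno", "y")
    pheno <- if (has_ph) df[[1]] else NULL
    if (!is.null(pheno) && !all(pheno %in% c(0, 1, NA)))
      stop("TSV phenotype must be coded 0/1")
    ids <- rownames(df)
    gcols <- if (has_ph) df[-1] else df
  }
  M <- as.matrix(gcols)
  bad <- which(!(M %in% c(0, 1, 2) | is.na(M)))
  if (length(bad)) {
    ln <- ((bad[1] - 1) %% nrow(M)) + 2L  # +1 header, +1 1-based
    stop(sprintf("non-{0,1,2,NA} genotype in %s (data line %d)", path, ln))
  }
  n_imp <- sum(is.na(M))
  if (n_imp) {
    for (j in which(colSums(is.na(M)) > 0)) {
      mj <- mean(M[, j], na.rm = TRUE)
      M[is.na(M[, j]), j] <- mj
    }
    message(n_imp, " missing genotype(s) mean-imputed")
  }
  G <- orient_minor(genotype_matrix_raw(M, colnames(gcols), ids))
  attr(G, "n_imputed") <- n_imp
  list(genotypes = G, phenotype = pheno)
}

## internal constructor that allows imputed (non-integer) dosages
genotype_matrix_raw <- function(values, snp_ids, sample_ids) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  dimnames(values) <- list(sample_ids, snp_ids)
  class(values) <- c("genotype_matrix", "matrix", "array")
  values
}

#' Write genotypes to PLINK raw or TSV text
#'
#' The PLINK `.raw` layout writes placeholder pedigree columns and maps
#' the 0/1 phenotype to PLINK's 1/2 coding; TSV writes an optional leading
#' `phenotype` column of 0/1.
#'
#' @param G genotype matrix.
#' @param path output path.
#' @param phenotype optional 0/1 vector.
#' @param format `"plink_raw"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(G, path, phenotype = NULL,
                            format = c("plink_raw", "tsv")) {
  format <- match.arg(format)
  G <- as_genotype(G)
  n <- nrow(G)
  if (format == "plink_raw") {
    ph <- if (is.null(phenotype)) rep(NA_integer_, n) else phenotype + 1L
    df <- data.frame(FID = rownames(G), IID = rownames(G), PAT = 0L,
                     MAT = 0L, SEX = 0L, PHENOTYPE = ph,
                     check.names = FALSE)
    df <- cbind(df, as.data.frame(unclass(G)))
    utils::write.table(df, path, sep = " ", quote = FALSE,
                       row.names = FALSE, na = "-9")
  } else {
    df <- as.data.frame(unclass(G))
    if (!is.null(phenotype)) df <- cbind(phenotype = phenotype, df)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
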