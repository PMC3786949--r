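#' Genotype matrix container
#'
#' Wraps an `n x p` matrix of additive minor-allele counts (0, 1, 2) with SNP
#' and sample labels. All set tests in the package consume this container (or
#' a plain numeric matrix, which is coerced on the fly).
#'
#' @param values integer/numeric matrix, `n` individuals by `p` SNPs, entries
#'   in `{0, 1, 2}` (`NA` not allowed; impute before construction, see
#'   [read_genotypes()]).
#' @param snp_ids character vector of `p` SNP labels; defaults to column
#'   names or `snp1..snpP`.
#' @param sample_ids character vector of `n` sample labels; defaults to row
#'   names or `id1..idN`.
#'
#' @return An object of class `genotype_matrix`: the values matrix with
#'   `dimnames` set to `sample_ids` x `snp_ids`.
#' @examples
#' G <- genotype_matrix(rbind(c(0, 1), c(2, 0), c(1, 1)))
#' maf(G)
#' @export
genotype_matrix <- function(values, snp_ids = NULL, sample_ids = NULL) {
  values <- as.matrix(values)
  if (anyNA(values))
    stop("genotype matrix contains NA; impute missing genotypes first")
  if (!all(values %in% c(0, 1, 2)))
    stop("genotype values must be additive minor-allele counts in {0, 1, 2}")
  storage.mode(values) <- "double"
  p <- ncol(values); n <- nrow(values)
  if (is.null(snp_ids)) snp_ids <- colnames(values)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(p))
  if (is.null(sample_ids)) sample_ids <- rownames(values)
  if (is.null(sample_ids)) sample_ids <- paste0("id", seq_len(n))
  stopifnot(length(snp_ids) == p, length(sample_ids) == n)
  dimnames(values) <- list(sample_ids, snp_ids)
  class(values) <- c("genotype_matrix", "matrix", "array")
  values
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs\n", nrow(x), ncol(x)))
  cat("MAF range:", paste(signif(range(maf(x)), 3), collapse = " - "), "\n")
  invisible(x)
}

as_genotype <- function(G) {
  if (inherits(G, "genotype_matrix")) G else genotype_matrix(G)
}

#' Minor allele frequency per SNP
#'
#' @param G a [genotype_matrix()] or plain 0/1/2 matrix.
#' @return numeric vector of per-SNP allele frequencies, `colMeans(G) / 2`.
#' @export
maf <- function(G) {
  colMeans(unclass(as_genotype(G))) / 2
}

#' Orient genotypes to the minor allele
#'
#' Flips any column whose allele frequency exceeds 0.5 (count of the major
#' allele) to `2 - g`, so that every column counts the minor allele and
#' `maf()` lies in `[0, 0.5]`.
#'
#' @param G genotype matrix.
#' @return a `genotype_matrix` with all column means `<= 1`, with attribute
#'   `"flipped"` naming any flipped SNPs.
#' @export
orient_minor <- function(G) {
  G <- as_genotype(G)
  f <- colMeans(unclass(G)) / 2
  flip <- which(f > 0.5)
  if (length(flip)) G[, flip] <- 2 - G[, flip, drop = FALSE]
  attr(G, "flipped") <- colnames(G)[flip]
  G
}
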