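#' Phased haplotype panel container
#'
#' @param alleles binary matrix, `H` haplotypes by `p` SNPs (0 = major,
#'   1 = minor allele).
#' @param snp_ids SNP labels (default from column names or `snp1..snpP`).
#' @param genotyped_mask logical length-`p`: SNPs directly genotyped on the
#'   chip (visible to the tests); default all.
#' @return object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(alleles, snp_ids = NULL, genotyped_mask = NULL) {
  alleles <- as.matrix(alleles)
  if (!all(alleles %in% c(0, 1)))
    stop("haplotype alleles must be 0/1")
  storage.mode(alleles) <- "double"
  p <- ncol(alleles)
  if (is.null(snp_ids)) snp_ids <- colnames(alleles)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(p))
  if (is.null(genotyped_mask)) genotyped_mask <- rep(TRUE, p)
  stopifnot(length(snp_ids) == p, length(genotyped_mask) == p)
  colnames(alleles) <- snp_ids
  structure(list(alleles = alleles, snp_ids = snp_ids,
                 genotyped_mask = genotyped_mask),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype_panel: %d haplotypes x %d SNPs (%d genotyped)\n",
              nrow(x$alleles), ncol(x$alleles), sum(x$genotyped_mask)))
  invisible(x)
}

#' Read a phased haplotype panel from text
#'
#' Whitespace-delimited text, one haplotype per row of 0/1 alleles, with a
#' header row of SNP ids. HapMap-phase-style files carrying leading
#' individual/transmission columns are handled with `skip_cols`. An
#' optional second header line `#genotyped 0 1 0 ...` (written by
#' [write_haplotypes()]) restores the genotyped mask.
#'
#' @param path file path.
#' @param skip_cols number of leading non-allele columns to drop.
#' @return a [haplotype_panel()].
#' @export
read_haplotypes <- function(path, skip_cols = 0) {
  lines <- readLines(path, warn = FALSE)
  mask <- NULL
  gl <- grepl("^#genotyped\\b", lines)
  if (any(gl)) {
    mask <- as.numeric(strsplit(trimws(sub("^#genotyped", "", lines[which(gl)[1]])),
                                "\\s+")[[1]]) > 0
    lines <- lines[!gl]
  }
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "\\s+")
  header <- toks[[1]]
  if (skip_cols > 0) header <- header[-seq_len(skip_cols)]
  rows <- lapply(toks[-1], function(x) {
    if (skip_cols > 0) x <- x[-seq_len(skip_cols)]
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v) || !all(v %in% c(0, 1)))
      stop("non-binary allele entry in haplotype file: ", path)
    v
  })
  alleles <- do.call(rbind, rows)
  if (ncol(alleles) != length(header))
    stop("haplotype file header/row length mismatch: ", path)
  haplotype_panel(alleles, snp_ids = header, genotyped_mask = mask)
}

#' Write a haplotype panel to text
#'
#' @param panel a [haplotype_panel()].
#' @param path output file.
#' @export
write_haplotypes <- function(panel, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(panel$snp_ids, collapse = " "), con)
  writeLines(paste(c("#genotyped", as.integer(panel$genotyped_mask)),
                   collapse = " "), con)
  apply(panel$alleles, 1, function(r)
    writeLines(paste(as.integer(r), collapse = " "), con))
  invisible(path)
}

#' Simulate genotypes by haplotype resampling
#'
#' Each individual is the sum of two haplotypes drawn uniformly with
#' replacement from the panel, so expected MAF and pairwise LD equal the
#' panel's own allele frequencies and LD.
#'
#' @param panel a [haplotype_panel()].
#' @param n number of individuals.
#' @return a [genotype_matrix()] over all panel SNPs (apply the genotyped
#'   mask downstream).
#' @export
simulate_from_panel <- function(panel, n) {
  H <- nrow(panel$alleles)
  if (H < 1) stop("empty haplotype panel")
  i1 <- sample.int(H, n, replace = TRUE)
  i2 <- sample.int(H, n, replace = TRUE)
  genotype_matrix(panel$alleles[i1, , drop = FALSE] +
                  panel$alleles[i2, , drop = FALSE],
                  snp_ids = panel$snp_ids)
}

#' Synthetic 28-SNP gene-region haplotype panel
#'
#' A synthetic stand-in for a phased reference panel of a lung-cancer
#' susceptibility gene region (90 haplotypes x 28 SNPs), built to exercise
#' the tag-SNP simulation designs: four LD blocks of seven SNPs (high
#' within-block latent correlation, weak between-block), allele counts
#' fixed by rank-thresholding the latent draws so the minor allele
#' frequencies at positions 6, 8, 9, 11, 17 and 25 are exactly 0.067,
#' 0.144, 0.189, 0.267, 0.2 and 0.4 (the causal-SNP frequencies of the
#' B-series designs). Eight SNPs (positions 2, 5, 10, 13, 17, 20, 25, 27)
#' form the genotyped mask, including positions 17 and 25 and excluding 6,
#' 8, 9 and 11, so designs with unobserved causal SNPs are expressible.
#' This panel is synthetic: it mimics block LD and the stated frequencies,
#' not any real population's haplotypes.
#'
#' @param n_haplotypes panel depth (default 90).
#' @param seed RNG seed for the latent draws (default 20130930); the
#'   packaged copy in `inst/extdata/chb_clptm1l_synthetic_panel.txt` was
#'   written with the defaults.
#' @return a [haplotype_panel()].
#' @export
synthetic_clptm1l_panel <- function(n_haplotypes = 90, seed = 20130930) {
  p <- 28
  blocks <- rep(1:4, each = 7)
  mafs <- c(0.35, 0.30, 0.30, 0.25, 0.28, 0.067, 0.05,   # block 1 (6 rare)
            0.144, 0.189, 0.12, 0.22, 0.09, 0.16, 0.25,  # block 2 (8, 9 low)
            0.30, 0.25, 0.20, 0.35, 0.28, 0.35, 0.30,    # block 3 (17 = 0.2)
            0.45, 0.38, 0.42, 0.40, 0.35, 0.44, 0.30)    # block 4 (25 = 0.4)
  mafs[11] <- 0.267
  R <- outer(blocks, blocks, function(a, b) ifelse(a == b, 0.85, 0.05))
  diag(R) <- 1
  L <- chol(R)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  Z <- matrix(rnorm(n_haplotypes * p), n_haplotypes, p) %*% L
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  # count-matched thresholding: exactly round(maf * H) minor alleles per SNP,
  # assigned to the lowest-ranked latent values to preserve the LD structure
  A <- matrix(0, n_haplotypes, p)
  for (j in seq_len(p)) {
    k <- round(mafs[j] * n_haplotypes)
    A[order(Z[, j])[seq_len(k)], j] <- 1
  }
  mask <- rep(FALSE, p); mask[c(2, 5, 10, 13, 17, 20, 25, 27)] <- TRUE
  haplotype_panel(A, snp_ids = sprintf("synsnp%02d", seq_len(p)),
                  genotyped_mask = mask)
}
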