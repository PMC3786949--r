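#' Beta-density variant weight
#'
#' Weight for a SNP as the Beta(a1, a2) density evaluated at its minor
#' allele frequency. With the default shapes (1, 25) this is
#' `25 * (1 - maf)^24`, which up-weights rare variants steeply: ~25 as
#' MAF approaches 0, 9.39 at MAF 0.04, and 1.49e-6 at MAF 0.5.
#'
#' @param maf minor allele frequency (vectorised), in `(0, 1)`; the
#'   endpoint 0 is taken as the density limit (monomorphic SNPs should be
#'   filtered upstream).
#' @param a1,a2 Beta shape parameters (defaults 1 and 25).
#' @return positive weight(s).
#' @examples
#' beta_weight(c(0.04, 0.2, 0.5))
#' @export
beta_weight <- function(maf, a1 = 1, a2 = 25) {
  stopifnot(all(maf >= 0), all(maf < 1))
  stats::dbeta(maf, a1, a2)
}

#' Per-SNP weight vector
#'
#' Builds the weight vector used by the weighted-IBS kernel and weighted
#' PCA from the pooled-sample minor allele frequencies.
#'
#' @param G genotype matrix (used to estimate MAF), or pass `mafs` directly.
#' @param scheme `"beta_density"` (default; [beta_weight()]),
#'   `"reciprocal_maf"` (`1 / maf`) or `"uniform"` (all 1).
#' @param beta_params length-2 shapes for the Beta-density scheme.
#' @param mafs optional frequencies overriding estimation from `G`.
#' @return object of class `snp_weights`: numeric weights with attributes
#'   `scheme` and `beta_params`.
#' @export
snp_weights <- function(G = NULL,
                        scheme = c("beta_density", "reciprocal_maf", "uniform"),
                        beta_params = c(1, 25), mafs = NULL) {
  scheme <- match.arg(scheme)
  if (is.null(mafs)) {
    stopifnot(!is.null(G))
    mafs <- maf(G)
  }
  w <- switch(scheme,
    beta_density = beta_weight(mafs, beta_params[1], beta_params[2]),
    reciprocal_maf = 1 / mafs,
    uniform = rep(1, length(mafs)))
  if (any(!is.finite(w)) || any(w <= 0))
    stop("non-positive or non-finite weight; filter monomorphic SNPs first")
  structure(w, scheme = scheme, beta_params = beta_params,
            class = "snp_weights")
}

new_kernel <- function(feature_map, kind) {
  structure(list(feature_map = feature_map, kind = kind),
            class = "snpset_kernel")
}

#' @export
print.snpset_kernel <- function(x, ...) {
  cat(sprintf("%s kernel: %d individuals, feature rank %d\n",
              x$kind, nrow(x$feature_map), ncol(x$feature_map)))
  invisible(x)
}

#' Materialise a kernel as a dense matrix
#'
#' Every kernel is stored through its low-rank feature map `F` with
#' `K = F %*% t(F)`; this reconstructs the full `n x n` matrix (use only
#' for modest `n`).
#'
#' @param x a kernel from [linear_kernel()] or [ibs_kernel()].
#' @param ... unused.
#' @return symmetric positive-semidefinite `n x n` matrix.
#' @export
as.matrix.snpset_kernel <- function(x, ...) {
  tcrossprod(x$feature_map)
}

#' Linear kernel
#'
#' `K = Z Z'` on the raw additive genotype coding (no centering or
#' standardisation); the feature map is `Z` itself.
#'
#' @param G genotype matrix.
#' @return a `snpset_kernel`.
#' @export
linear_kernel <- function(G) {
  new_kernel(unclass(as_genotype(G)), "linear")
}

## 3-feature encoding of a genotype column such that the inner product of
## two encodings equals the IBS sharing count 2 - |g_i - g_j|:
##   f(0) = (sqrt2, 0, 0), f(2) = (0, sqrt2, 0), f(1) = (1/sqrt2, 1/sqrt2, 1)
ibs_features_one <- function(g) {
  s2 <- sqrt(2)
  cbind((g == 0) * s2 + (g == 1) / s2,
        (g == 2) * s2 + (g == 1) / s2,
        (g == 1) * 1)
}

#' IBS and weighted-IBS kernels
#'
#' Average identity-by-state allele sharing,
#' `K_ij = sum_s w_s (2 - |g_is - g_js|) / (2 sum_s w_s)`, with unit
#' weights for the plain IBS kernel. Weighting by the Beta(1,25) density of
#' the MAF up-weights sharing at rare alleles. The kernel is represented by
#' a per-SNP three-feature indicator encoding whose inner products
#' reproduce the IBS counts, so `K = F F'` exactly with `q = 3p` features
#' and downstream eigenvalue work costs `O(n q^2)`, never `O(n^3)`.
#'
#' @param G genotype matrix.
#' @param weights optional [snp_weights()] (or positive numeric vector of
#'   length `p`); `NULL` gives the unweighted IBS kernel.
#' @return a `snpset_kernel` with kind `"ibs"` or `"wibs"`.
#' @export
ibs_kernel <- function(G, weights = NULL) {
  Z <- unclass(as_genotype(G))
  p <- ncol(Z)
  if (is.null(weights)) {
    w <- rep(1, p); kind <- "ibs"
  } else {
    w <- as.numeric(weights); kind <- "wibs"
    stopifnot(length(w) == p)
    if (any(w <= 0)) stop("IBS weights must be positive")
  }
  scale <- sqrt(w / (2 * sum(w)))
  Fm <- matrix(0, nrow(Z), 3L * p)
  for (s in seq_len(p))
    Fm[, (3 * s - 2):(3 * s)] <- ibs_features_one(Z[, s]) * scale[s]
  new_kernel(Fm, kind)
}
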