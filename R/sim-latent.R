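#' Bivariate standard-normal orthant probability
#'
#' `P(X < a, Y < b)` for a standard bivariate normal with correlation `rho`,
#' computed as a one-dimensional integral of the conditional normal CDF.
#' Used by the LD calibration; accuracy ~1e-12.
#'
#' @param a,b upper limits.
#' @param rho correlation in `(-1, 1)`; the limits `rho = +/-1` are handled
#'   in closed form.
#' @return the joint lower-orthant probability.
#' @keywords internal
pnorm2 <- function(a, b, rho) {
  if (abs(rho) >= 1 - 1e-12) {
    if (rho > 0) return(pnorm(min(a, b)))
    return(max(0, pnorm(a) + pnorm(b) - 1))
  }
  if (rho == 0) return(pnorm(a) * pnorm(b))
  s <- sqrt(1 - rho^2)
  stats::integrate(function(x) dnorm(x) * pnorm((b - rho * x) / s),
                   -Inf, a, rel.tol = 1e-12, abs.tol = 1e-14)$value
}

## Allelic (0/1) correlation induced by thresholding a bivariate normal at
## the per-SNP MAF quantiles.
allelic_corr <- function(rho, maf_a, maf_b) {
  ta <- qnorm(maf_a); tb <- qnorm(maf_b)
  p11 <- pnorm2(ta, tb, rho)
  (p11 - maf_a * maf_b) /
    sqrt(maf_a * (1 - maf_a) * maf_b * (1 - maf_b))
}

#' Maximum attainable allelic r-squared for a MAF pair
#'
#' Dichotomised bivariate-normal alleles cannot reach arbitrary r-squared
#' when the two allele frequencies differ: at latent correlation 1 the joint
#' minor-allele probability is `min(maf_a, maf_b)`, which bounds the allelic
#' correlation (r-squared = 1 requires equal MAFs).
#'
#' @param maf_a,maf_b minor allele frequencies in `(0, 0.5]`.
#' @return the supremum of attainable squared allelic correlation.
#' @export
max_attainable_r2 <- function(maf_a, maf_b) {
  num <- min(maf_a, maf_b) - maf_a * maf_b
  (num / sqrt(maf_a * (1 - maf_a) * maf_b * (1 - maf_b)))^2
}

#' Calibrate the latent correlation for a target allelic r-squared
#'
#' Finds the correlation `rho` of the latent bivariate normal such that
#' thresholding at `qnorm(maf_a)`, `qnorm(maf_b)` produces 0/1 alleles whose
#' squared Pearson correlation equals `target_r2`. The map from `rho` to
#' allelic r-squared is strictly increasing on `[0, 1)`, so a monotone root
#' finder applies.
#'
#' @param maf_a,maf_b minor allele frequencies in `(0, 0.5]`.
#' @param target_r2 target squared allelic correlation in `[0, 1)`.
#' @param tol convergence tolerance on r-squared (default `1e-6`).
#' @return latent correlation `rho` in `[0, 1)`.
#' @examples
#' calibrate_latent_corr(0.1, 0.1, 0)    # independence
#' calibrate_latent_corr(0.2, 0.2, 0.5)  # > sqrt(0.5): thresholding attenuates
#' @export
calibrate_latent_corr <- function(maf_a, maf_b, target_r2, tol = 1e-6) {
  stopifnot(maf_a > 0, maf_a <= 0.5, maf_b > 0, maf_b <= 0.5,
            target_r2 >= 0, target_r2 < 1)
  if (target_r2 == 0) return(0)
  r2max <- max_attainable_r2(maf_a, maf_b)
  hi <- 1 - 1e-9
  f <- function(rho) allelic_corr(rho, maf_a, maf_b)^2 - target_r2
  if (target_r2 >= r2max || f(hi) < 0)
    stop(sprintf(
      "infeasible LD: target r2 = %.4g exceeds the maximum attainable %.4g for MAFs (%.3g, %.3g)",
      target_r2, r2max, maf_a, maf_b), call. = FALSE)
  # tol on rho chosen so that |d r2| < tol (slope of r2 in rho is O(1))
  uniroot(f, c(0, hi), tol = min(tol, 1e-8))$root
}

#' Pairwise-calibrated latent correlation matrix
#'
#' Builds the `p x p` latent-normal correlation matrix whose thresholded
#' alleles have pairwise squared correlation `target_r2` (exchangeable
#' across all pairs). Pairs for which the target exceeds the attainable
#' maximum (unequal MAFs) are capped at `cap_frac` times that maximum, with
#' a warning. An indefinite result (possible after capping) is repaired by
#' clipping eigenvalues at a small positive floor and renormalising to unit
#' diagonal, again with a warning.
#'
#' @param mafs vector of minor allele frequencies in `(0, 0.5]`.
#' @param target_r2 exchangeable target allelic r-squared in `[0, 1)`.
#' @param cap_frac fraction of the attainable maximum used for infeasible
#'   pairs (default 0.99).
#' @return list with `latent` (the correlation matrix), `chol` (its upper
#'   Cholesky factor) and `capped` (logical, any pair capped).
#' @export
latent_corr_matrix <- function(mafs, target_r2, cap_frac = 0.99) {
  p <- length(mafs)
  R <- diag(p)
  capped <- FALSE
  if (target_r2 > 0 && p > 1) {
    # calibration depends only on the MAF pair: cache distinct pairs
    cache <- new.env(parent = emptyenv())
    for (i in seq_len(p - 1)) for (j in (i + 1):p) {
      key <- paste(signif(sort(c(mafs[i], mafs[j])), 12), collapse = "|")
      if (is.null(cache[[key]])) {
        r2max <- max_attainable_r2(mafs[i], mafs[j])
        tgt <- target_r2
        if (tgt >= r2max) {
          tgt <- cap_frac * r2max
          capped <- TRUE
        }
        cache[[key]] <- calibrate_latent_corr(mafs[i], mafs[j], tgt)
      }
      R[i, j] <- R[j, i] <- cache[[key]]
    }
    if (capped)
      warning(sprintf(
        "target r2 = %g infeasible for some MAF pairs; capped at %g of the attainable maximum",
        target_r2, cap_frac), call. = FALSE)
  }
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < 1e-8) {
    warning("latent correlation matrix not positive definite; clipping eigenvalues",
            call. = FALSE)
    vals <- pmax(ev$values, 1e-8)
    R <- ev$vectors %*% (vals * t(ev$vectors))
    R <- stats::cov2cor(R)
    if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) <= 0)
      stop("latent correlation matrix remains non-positive-definite after repair")
  }
  list(latent = R, chol = chol(R), capped = capped)
}

#' Simulate genotypes by latent-normal thresholding
#'
#' Each individual is the sum of two independent haplotypes; each haplotype
#' is a draw from a `p`-variate standard normal with the calibrated latent
#' correlation, dichotomised at `qnorm(maf_j)` per SNP (allele = 1 iff the
#' latent variable falls below the threshold). Summing two thresholded
#' haplotypes guarantees Hardy-Weinberg genotype frequencies; empirical MAF
#' converges to `mafs` and pairwise allelic r-squared to `target_r2`.
#'
#' @param n number of individuals.
#' @param mafs per-SNP minor allele frequencies in `(0, 0.5]`.
#' @param target_r2 exchangeable allelic r-squared target (default 0), or
#'   pass a precomputed `latent` object to avoid re-calibration.
#' @param latent optional result of [latent_corr_matrix()] (overrides
#'   `target_r2`).
#' @return a [genotype_matrix()] of dimension `n x p`.
#' @examples
#' G <- simulate_genotypes(500, mafs = rep(0.2, 5), target_r2 = 0.5)
#' round(maf(G), 2)
#' @export
simulate_genotypes <- function(n, mafs, target_r2 = 0, latent = NULL) {
  p <- length(mafs)
  stopifnot(n >= 1, all(mafs > 0), all(mafs <= 0.5))
  if (is.null(latent)) latent <- latent_corr_matrix(mafs, target_r2)
  thr <- qnorm(mafs)
  tmat <- matrix(thr, n, p, byrow = TRUE)
  hap <- function() {
    Z <- matrix(rnorm(n * p), n, p)
    if (p > 1) Z <- Z %*% latent$chol
    (Z < tmat) + 0
  }
  genotype_matrix(hap() + hap())
}
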