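#' (Weighted) principal-component decomposition of a SNP set
#'
#' Mean-centers the genotype columns, optionally post-multiplies by a
#' diagonal weight matrix (the weighted-PCA construction: rare SNPs given
#' large weights contribute more variance and surface in the leading
#' components), eigendecomposes the sample variance-covariance matrix, and
#' selects the smallest number of leading components whose cumulative
#' variance fraction reaches the threshold.
#'
#' @param G genotype matrix; monomorphic columns are dropped with a
#'   warning.
#' @param weights optional [snp_weights()] or positive numeric vector.
#' @param threshold cumulative variance fraction for component selection
#'   (default 0.80); selection uses `>=`.
#' @return object of class `pc_decomposition`: `eigenvalues`
#'   (nonincreasing), `eigenvectors` (orthonormal columns), `k_selected`,
#'   `cumulative_fraction` (at `k_selected`), `scores` (the selected PC
#'   score columns), `weights`, `column_means`.
#' @export
pc_decompose <- function(G, weights = NULL, threshold = 0.80) {
  Z <- unclass(as_genotype(G))
  mono <- apply(Z, 2, function(g) length(unique(g)) == 1)
  if (all(mono)) stop("all SNPs monomorphic; PCA undefined")
  if (any(mono)) {
    warning(sum(mono), " monomorphic SNP(s) dropped before PCA")
    Z <- Z[, !mono, drop = FALSE]
    if (!is.null(weights)) weights <- as.numeric(weights)[!mono]
  }
  p <- ncol(Z)
  mu <- colMeans(Z)
  Zc <- sweep(Z, 2, mu)
  w <- if (is.null(weights)) rep(1, p) else as.numeric(weights)
  stopifnot(length(w) == p, all(w > 0))
  Zw <- sweep(Zc, 2, w, `*`)
  S <- crossprod(Zw) / (nrow(Zw) - 1)
  ev <- eigen(S, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  total <- sum(lam)
  # numerically-zero components are never selectable
  selectable <- lam > 1e-10 * lam[1]
  cumfrac <- cumsum(lam) / total
  k <- which(cumfrac >= threshold & selectable)[1]
  if (is.na(k)) k <- max(which(selectable))
  structure(list(eigenvalues = lam, eigenvectors = ev$vectors,
                 k_selected = k, cumulative_fraction = cumfrac[k],
                 scores = Zw %*% ev$vectors[, seq_len(k), drop = FALSE],
                 weights = w, column_means = mu, threshold = threshold),
            class = "pc_decomposition")
}

#' @export
print.pc_decomposition <- function(x, ...) {
  cat(sprintf("PC decomposition: %d components, %d selected (%.1f%% of variance)\n",
              length(x$eigenvalues), x$k_selected,
              100 * x$cumulative_fraction))
  invisible(x)
}

#' (Weighted) principal-component likelihood-ratio SNP-set test
#'
#' Extracts principal components of the (optionally weighted) SNP set,
#' keeps the leading components explaining at least `threshold` of the
#' variance, and compares logistic models with and without those
#' components by a likelihood-ratio test on `k` degrees of freedom. With
#' Beta(1,25)-density weights this is the weighted-PCA test: inflating the
#' variance of rare SNPs pushes them into the leading components, so fewer
#' components (degrees of freedom) carry the rare-variant signal.
#'
#' @param G genotype matrix.
#' @param y binary phenotype.
#' @param weights optional [snp_weights()]; `NULL` for the unweighted PCA
#'   test, or `weights = "beta"` as shorthand for Beta(1,25) MAF-density
#'   weights estimated from `G`.
#' @param threshold cumulative variance fraction (default 0.80).
#' @param X optional covariates.
#' @return a `snpset_test` with `df = k_selected`.
#' @examples
#' G <- simulate_genotypes(300, c(0.04, rep(0.1, 4)), 0.1)
#' y <- rbinom(300, 1, 0.5)
#' pc_lrt(G, y, weights = "beta")
#' @export
pc_lrt <- function(G, y, weights = NULL, threshold = 0.80, X = NULL) {
  G <- as_genotype(G)
  y <- as.numeric(y)
  if (identical(weights, "beta")) weights <- snp_weights(G)
  dec <- pc_decompose(G, weights = weights, threshold = threshold)
  k <- dec$k_selected
  n <- length(y)
  X0 <- if (is.null(X)) matrix(1, n, 1) else {
    X <- as.matrix(X)
    if (!any(apply(X, 2, function(c) all(c == c[1])))) cbind(1, X) else X
  }
  ctrl <- stats::glm.control(epsilon = 1e-10, maxit = 100)
  fit0 <- stats::glm.fit(X0, y, family = stats::binomial(), control = ctrl)
  fit1 <- stats::glm.fit(cbind(X0, dec$scores), y,
                         family = stats::binomial(), control = ctrl)
  if (!fit0$converged || !fit1$converged)
    stop("logistic fit for the PC likelihood-ratio test did not converge")
  lrt <- max(0, fit0$deviance - fit1$deviance)
  p <- stats::pchisq(lrt, df = k, lower.tail = FALSE)
  test_result(if (is.null(weights)) "pca" else "wpca", lrt, p, df = k,
              details = list(decomposition = dec))
}

#' Single-SNP logistic Wald tests
#'
#' Per-SNP 1-df Wald test of the additive genotype effect in a logistic
#' model, the single-locus comparator to the set tests.
#'
#' @param G genotype matrix.
#' @param y binary phenotype.
#' @param X optional covariates.
#' @return named vector of per-SNP p-values (monomorphic SNPs get 1, with
#'   a warning); attribute `"min_p"` holds the minimum.
#' @export
single_snp_tests <- function(G, y, X = NULL) {
  G <- as_genotype(G)
  y <- as.numeric(y)
  n <- nrow(G)
  X0 <- if (is.null(X)) matrix(1, n, 1) else cbind(1, as.matrix(X))
  ctrl <- stats::glm.control(epsilon = 1e-10, maxit = 100)
  pv <- vapply(seq_len(ncol(G)), function(j) {
    g <- G[, j]
    if (length(unique(g)) == 1) {
      warning("monomorphic SNP ", colnames(G)[j], ": p-value set to 1")
      return(1)
    }
    fit <- stats::glm.fit(cbind(X0, g), y, family = stats::binomial(),
                          control = ctrl)
    co <- ncol(X0) + 1L
    # Wald: beta / se from the weighted cross-product inverse
    XX <- cbind(X0, g)
    W <- fit$fitted.values * (1 - fit$fitted.values)
    V <- solve(crossprod(XX, XX * W))
    z <- fit$coefficients[co] / sqrt(V[co, co])
    2 * stats::pnorm(-abs(z))
  }, numeric(1))
  names(pv) <- colnames(G)
  attr(pv, "min_p") <- min(pv)
  pv
}

#' Effective number of independent tests
#'
#' LD-adjusted count of independent single-SNP tests from the eigenvalues
#' of the SNP correlation matrix, using the composite rule
#' `Meff = sum_i [ 1(lambda_i >= 1) + (lambda_i - floor(lambda_i)) ]`
#' (Li & Ji refinement of Nyholt's spectral approach): `p` independent
#' SNPs give `Meff = p`, perfect correlation collapses pairs to one.
#'
#' @param G genotype matrix with `p >= 2` polymorphic SNPs.
#' @return `Meff`, a real number in `[1, p]`.
#' @export
effective_tests <- function(G) {
  Z <- unclass(as_genotype(G))
  stopifnot(ncol(Z) >= 2)
  C <- stats::cor(Z)
  if (anyNA(C)) stop("correlation undefined (monomorphic SNP?)")
  lam <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  sum((lam >= 1) + (lam - floor(lam)))
}

#' Bonferroni correction by the effective number of tests
#'
#' @param min_p minimum single-SNP p-value in the set.
#' @param meff effective number of tests ([effective_tests()]), or a plain
#'   SNP count for ordinary Bonferroni.
#' @return `min(1, min_p * meff)`.
#' @examples
#' adjust_min_p(2.19e-4, 8)    # 1.752e-3
#' adjust_min_p(5.01e-4, 15)   # 7.515e-3
#' @export
adjust_min_p <- function(min_p, meff) {
  stopifnot(min_p >= 0, min_p <= 1, meff >= 1)
  min(1, min_p * meff)
}
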