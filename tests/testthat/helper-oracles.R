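# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own computational paths.

# Bivariate-normal lower-orthant probability by 2-D grid quadrature
# (midpoint rule on a truncated lattice).
orthant_grid <- function(a, b, rho, lim = 8, n = 2000) {
  x <- seq(-lim, a, length.out = n)
  hx <- x[2] - x[1]
  xm <- x[-1] - hx / 2
  s <- sqrt(1 - rho^2)
  # integrate the conditional CDF over x: exact in y, midpoint in x
  sum(dnorm(xm) * pnorm((b - rho * xm) / s)) * hx
}

# allelic r-squared implied by latent rho, via the grid oracle
allelic_r2_grid <- function(rho, pa, pb) {
  p11 <- orthant_grid(qnorm(pa), qnorm(pb), rho)
  ((p11 - pa * pb) / sqrt(pa * (1 - pa) * pb * (1 - pb)))^2
}

# O(n^2 p) double-loop kernels
linear_kernel_brute <- function(G) {
  n <- nrow(G)
  K <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) K[i, j] <- sum(G[i, ] * G[j, ])
  K
}

ibs_kernel_brute <- function(G, w = rep(1, ncol(G))) {
  n <- nrow(G)
  K <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n)
    K[i, j] <- sum(w * (2 - abs(G[i, ] - G[j, ]))) / (2 * sum(w))
  K
}

# dense-path eigenvalues of (1/2) P0^{1/2} K P0^{1/2}
mixture_eigen_dense <- function(K, mu, X) {
  d <- mu * (1 - mu)
  D <- diag(d)
  P0 <- D - D %*% X %*% solve(t(X) %*% D %*% X) %*% t(X) %*% D
  es <- eigen(P0, symmetric = TRUE)
  P0h <- es$vectors %*% diag(sqrt(pmax(es$values, 0))) %*% t(es$vectors)
  lam <- eigen(0.5 * P0h %*% K %*% P0h, symmetric = TRUE,
               only.values = TRUE)$values
  lam[lam > 1e-10 * max(lam)]
}

# negative log-likelihood for direct ML logistic fits (independent of glm)
logistic_nll <- function(beta, X, y) {
  eta <- drop(X %*% beta)
  sum(log1p(exp(eta))) - sum(y * eta)
}

fit_logistic_direct <- function(X, y) {
  opt <- optim(rep(0, ncol(X)), logistic_nll, X = X, y = y,
               method = "BFGS", control = list(maxit = 1000, reltol = 1e-14))
  opt
}

random_genotypes <- function(n, p, mafs = runif(p, 0.05, 0.5)) {
  G <- sapply(mafs, function(f) rbinom(n, 2, f))
  # guard against monomorphic columns in small draws
  for (j in seq_len(p)) if (length(unique(G[, j])) == 1) G[1, j] <- 1
  genotype_matrix(G)
}
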