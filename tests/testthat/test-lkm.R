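# Logistic kernel machine score test: null fit, statistic, mixture null

test_that("null logistic fit reproduces closed-form proportions", {
  y <- rep(c(1, 0), c(1000, 1000))
  expect_equal(fit_null_logistic(y)$fitted, rep(0.5, 2000), tolerance = 1e-10)

  y2 <- rep(c(1, 0), c(600, 1400))
  expect_equal(fit_null_logistic(y2)$fitted, rep(0.3, 2000), tolerance = 1e-10)

  # saturated binary covariate: fitted values are the cell proportions
  x <- rep(c(0, 1), each = 100)
  y3 <- c(rep(c(1, 0), c(30, 70)), rep(c(1, 0), c(55, 45)))
  mu <- fit_null_logistic(y3, X = cbind(x))$fitted
  expect_equal(unique(round(mu, 10)), c(0.3, 0.55), tolerance = 1e-8)

  expect_error(fit_null_logistic(rep(1, 50)), "both classes")
})

test_that("score statistic equals the double-loop quadratic form", {
  # zero residuals give Q = 0
  n <- 10
  fake_null <- structure(list(fitted = rep(0.5, n),
                              design = matrix(1, n, 1), converged = TRUE),
                         class = "lkm_null")
  K_id <- wsnpset:::new_kernel(diag(n), "linear")
  expect_equal(score_statistic(rep(0.5, n), fake_null, K_id), 0)

  # identity kernel reduces Q to half the residual sum of squares
  y <- rep(c(1, 0), each = 5)
  r <- y - 0.5
  expect_equal(score_statistic(y, fake_null, K_id), 0.5 * sum(r^2))

  # random fixture vs brute-force double sum
  set.seed(12)
  G <- random_genotypes(8, 3)
  y8 <- rbinom(8, 1, 0.5); y8[1:2] <- c(0, 1)
  null <- fit_null_logistic(y8)
  K <- ibs_kernel(G, snp_weights(G))
  Km <- as.matrix(K)
  rr <- y8 - null$fitted
  Q_brute <- 0
  for (i in 1:8) for (j in 1:8) Q_brute <- Q_brute + rr[i] * Km[i, j] * rr[j]
  expect_equal(score_statistic(y8, null, K), Q_brute / 2, tolerance = 1e-10)
})

test_that("low-rank mixture eigenvalues match the dense projection path", {
  set.seed(13)
  y <- rbinom(40, 1, 0.5); y[1:2] <- c(0, 1)
  X <- cbind(1, rnorm(40))
  null <- fit_null_logistic(y, X = X)

  # constant kernel is annihilated by the intercept projection
  K_const <- wsnpset:::new_kernel(matrix(1, 40, 1), "linear")
  null0 <- fit_null_logistic(y)
  expect_error(null_mixture_eigenvalues(K_const, null0), "degenerate")

  # rank-1 feature orthogonal to the design: single closed-form eigenvalue
  f <- rnorm(40)
  d <- null$fitted * (1 - null$fitted)
  Xd <- null$design * d
  f <- f - null$design %*% solve(crossprod(null$design, Xd),
                                 crossprod(Xd, f))  # make DX'f terms vanish
  K1 <- wsnpset:::new_kernel(cbind(as.numeric(f)), "linear")
  lam1 <- null_mixture_eigenvalues(K1, null)
  P0f <- d * f - Xd %*% solve(crossprod(null$design, Xd),
                              crossprod(null$design, d * f))
  expect_equal(lam1, as.numeric(crossprod(f, P0f)) / 2, tolerance = 1e-8)

  # random kernels: low-rank path equals dense n x n eigendecomposition
  for (kind in c("linear", "ibs", "wibs")) {
    G <- random_genotypes(40, 3)
    K <- switch(kind, linear = linear_kernel(G), ibs = ibs_kernel(G),
                wibs = ibs_kernel(G, snp_weights(G)))
    lam <- null_mixture_eigenvalues(K, null)
    lam_dense <- mixture_eigen_dense(as.matrix(K), null$fitted, null$design)
    expect_equal(lam, lam_dense[seq_along(lam)], tolerance = 1e-8)
  }
})

test_that("mixture-of-chi-square p-values match quantiles and Monte Carlo", {
  expect_equal(pvalue_weighted_chisq(qchisq(0.95, 1), 1), 0.05,
               tolerance = 1e-7)
  expect_equal(pvalue_weighted_chisq(qchisq(0.95, 2), c(1, 1)), 0.05,
               tolerance = 1e-7)
  expect_equal(pvalue_weighted_chisq(3.841459, 1), 0.05, tolerance = 1e-6)
  expect_equal(pvalue_weighted_chisq(5.991465, c(1, 1)), 0.05,
               tolerance = 1e-6)

  # Monte-Carlo oracle for an uneven mixture
  lam <- c(2, 1, 0.5)
  p <- pvalue_weighted_chisq(6, lam)
  set.seed(14)
  hits <- 0L
  for (chunk in 1:10) {
    Z <- matrix(rnorm(3 * 1e6), 3)
    hits <- hits + sum(colSums(lam * Z^2) >= 6)
  }
  expect_lt(abs(p - hits / 1e7), 1e-4)

  # moment-matching fallback is close to the inversion
  expect_lt(abs(wsnpset:::liu_tail(6, lam) - p), 5e-3)
})

test_that("kernel scaling leaves the score-test p-value unchanged", {
  set.seed(15)
  G <- random_genotypes(60, 4)
  y <- rbinom(60, 1, 0.5); y[1:2] <- c(0, 1)
  null <- fit_null_logistic(y)
  K <- linear_kernel(G)
  K17 <- wsnpset:::new_kernel(K$feature_map * sqrt(17), "linear")
  p1 <- pvalue_weighted_chisq(score_statistic(y, null, K),
                              null_mixture_eigenvalues(K, null))
  p2 <- pvalue_weighted_chisq(score_statistic(y, null, K17),
                              null_mixture_eigenvalues(K17, null))
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("asymptotic p-value agrees with a permutation oracle at n = 30", {
  set.seed(16)
  G <- random_genotypes(30, 3, mafs = c(0.15, 0.3, 0.4))
  y <- rep(c(1, 0), each = 15)
  res <- lkm_test(G, y, kernel = "ibs")

  # permutation oracle: intercept-only fit is invariant under permutation
  Fm <- ibs_kernel(G)$feature_map
  B <- 1e5
  Y <- replicate(B, sample(y))
  Qs <- 0.5 * colSums(crossprod(Fm, Y - mean(y))^2)
  p_perm <- mean(Qs >= res$statistic)
  expect_lt(abs(res$p_value - p_perm), 0.02)
})

test_that("lkm_test composes and reports a valid result", {
  set.seed(17)
  G <- simulate_genotypes(300, rep(0.2, 6), 0.3)
  y <- rbinom(300, 1, 0.5)
  for (k in c("linear", "ibs", "wibs")) {
    res <- lkm_test(G, y, kernel = k)
    expect_s3_class(res, "snpset_test")
    expect_gte(res$statistic, 0)
    expect_true(res$p_value > 0 && res$p_value <= 1)
    expect_identical(res$method, paste0("lkm-", k))
  }
})
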