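# Latent-normal genotype generator and LD calibration

test_that("latent correlation calibration matches the orthant-grid oracle", {
  expect_identical(calibrate_latent_corr(0.1, 0.1, 0), 0)
  # equal thresholds, target near 1: latent correlation approaches 1
  expect_gt(calibrate_latent_corr(0.2, 0.2, 1 - 1e-4), 0.99)

  # derived case: invert r2(rho) with the independent 2-D quadrature oracle
  rho <- calibrate_latent_corr(0.1, 0.1, 0.5)
  grid <- seq(0.90, 0.96, by = 1e-4)
  r2g <- vapply(grid, allelic_r2_grid, numeric(1), pa = 0.1, pb = 0.1)
  rho_oracle <- grid[which.min(abs(r2g - 0.5))]
  expect_equal(rho, rho_oracle, tolerance = 5e-4)
  # and the calibrated rho reproduces the target r2 through the oracle
  expect_equal(allelic_r2_grid(rho, 0.1, 0.1), 0.5, tolerance = 1e-5)
})

test_that("calibration is monotone in the target and flags infeasible LD", {
  targets <- c(0.05, 0.1, 0.3, 0.5, 0.7)
  rhos <- vapply(targets, function(t2)
    calibrate_latent_corr(0.15, 0.15, t2), numeric(1))
  expect_true(all(diff(rhos) > 0))

  expect_equal(max_attainable_r2(0.04, 0.1), 0.375, tolerance = 1e-12)
  err <- tryCatch(calibrate_latent_corr(0.04, 0.1, 0.8),
                  error = function(e) conditionMessage(e))
  expect_match(err, "infeasible LD")
  expect_match(err, "0.375")
})

test_that("simulated genotypes reproduce target MAF and allelic r2", {
  set.seed(11)
  G <- simulate_genotypes(100000, mafs = 0.5)
  expect_true(all(unclass(G) %in% 0:2))
  se <- sqrt(0.5 * 0.5 / (2 * 1e5))
  expect_lt(abs(mean(G) - 1.0), 3 * 2 * se)

  G0 <- simulate_genotypes(100000, mafs = rep(0.3, 4), target_r2 = 0)
  C0 <- cor(unclass(G0))
  expect_lt(max(C0[upper.tri(C0)]^2), 0.001)

  # exchangeable MAF 0.2 / r2 = 0.5 design: calibration consistency
  G5 <- simulate_genotypes(100000, mafs = rep(0.2, 20), target_r2 = 0.5)
  expect_true(all(abs(maf(G5) - 0.2) < 3 * sqrt(0.2 * 0.8 / 2e5)))
  C5 <- cor(unclass(G5))^2
  expect_lt(abs(mean(C5[upper.tri(C5)]) - 0.5), 0.01)
})

test_that("mixed-MAF scenarios cap unattainable pairwise LD with a warning", {
  mafs <- c(0.04, rep(0.1, 3))
  expect_warning(lt <- latent_corr_matrix(mafs, 0.8), "infeasible")
  expect_true(lt$capped)
  set.seed(4)
  G <- simulate_genotypes(50000, mafs, latent = lt)
  C <- cor(unclass(G))^2
  ut <- which(upper.tri(C), arr.ind = TRUE)
  common <- ut[, 1] > 1                         # pairs among the 0.1-MAF SNPs
  expect_equal(mean(C[upper.tri(C)][common]), 0.8, tolerance = 0.02)
  expect_true(all(C[1, 2:4] < 0.375))                                # capped pairs
})

test_that("disease model matches its closed-form odds ratios", {
  spec0 <- scenario_spec(mafs = rep(0.2, 3), baseline_prevalence = 0.1)
  G <- genotype_matrix(matrix(sample(0:2, 30, TRUE), 10, 3))
  expect_equal(disease_probability(G, spec0), rep(0.1, 10))

  # one causal SNP, OR 1.2: per-allele odds ratio exact
  spec1 <- scenario_spec(mafs = c(0.2, 0.2), causal_indices = 1,
                         odds_ratios = 1.2)
  b0 <- -2
  pr <- disease_probability(genotype_matrix(cbind(0:2, c(0, 0, 0))),
                            spec1, b0 = b0)
  odds <- pr / (1 - pr)
  expect_equal(odds[2] / odds[1], 1.2, tolerance = 1e-12)
  expect_equal(odds[3] / odds[1], 1.2^2, tolerance = 1e-12)

  # two causal SNPs each OR 1.2: (2,2) vs (0,0) gives 1.2^4
  spec2 <- scenario_spec(mafs = c(0.2, 0.2), causal_indices = 1:2,
                         odds_ratios = c(1.2, 1.2))
  pr2 <- disease_probability(genotype_matrix(rbind(c(0, 0), c(2, 2))),
                             spec2, b0 = b0)
  odds2 <- pr2 / (1 - pr2)
  expect_equal(odds2[2] / odds2[1], 1.2^4, tolerance = 1e-12)
})

test_that("solved intercept reproduces the baseline prevalence", {
  spec <- scenario_spec(mafs = c(0.04, rep(0.1, 4)), causal_indices = 1,
                        odds_ratios = 1.2, target_r2 = 0.1,
                        baseline_prevalence = 0.1)
  set.seed(21)
  b0 <- solve_baseline_intercept(spec)
  G <- simulate_genotypes(200000, spec$mafs, spec$target_r2)
  expect_equal(mean(disease_probability(G, spec, b0 = b0)), 0.1,
               tolerance = 0.003)
})

test_that("case-control sampler fills strata exactly and is seed-stable", {
  spec <- virtual_scenario("A1", r2 = 0.1, n_snps = 6,
                           n_cases = 150, n_controls = 250)
  set.seed(31)
  cc <- sample_case_control(spec)
  expect_identical(sum(cc$phenotype), 150L)
  expect_identical(sum(cc$phenotype == 0L), 250L)
  expect_identical(dim(unclass(cc$genotypes)), c(400L, 6L))

  set.seed(31)
  cc2 <- sample_case_control(spec)
  expect_identical(unclass(cc$genotypes), unclass(cc2$genotypes))

  # null model: case and control MAFs agree to Monte-Carlo error
  spec0 <- virtual_scenario("A1", r2 = 0, n_snps = 4,
                            n_cases = 4000, n_controls = 4000)
  set.seed(32)
  cc0 <- sample_case_control(spec0)
  fca <- maf(cc0$genotypes[cc0$phenotype == 1, ])
  fco <- maf(cc0$genotypes[cc0$phenotype == 0, ])
  expect_true(all(abs(fca - fco) < 4 * sqrt(0.2 * 0.8 / 4000)))
})

test_that("case-control sampling preserves the causal log-odds ratio", {
  # pooled logistic regression over a large retrospective sample recovers
  # the per-allele effect (intercept absorbs the ascertainment)
  spec <- scenario_spec(mafs = 0.2, causal_indices = 1, odds_ratios = 1.2,
                        n_cases = 25000, n_controls = 25000,
                        baseline_prevalence = 0.1)
  set.seed(41)
  cc <- sample_case_control(spec)
  fit <- glm(cc$phenotype ~ unclass(cc$genotypes)[, 1], family = binomial)
  bhat <- coef(fit)[2]
  se <- sqrt(diag(vcov(fit)))[2]
  expect_lt(abs(bhat - log(1.2)), 3 * se)
})

test_that("population draw cap triggers a helpful error", {
  spec <- scenario_spec(mafs = 0.2, causal_indices = integer(),
                        n_cases = 100, n_controls = 100,
                        baseline_prevalence = 0.01)
  set.seed(5)
  expect_error(sample_case_control(spec, max_draws = 500),
               "higher baseline prevalence")
})
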