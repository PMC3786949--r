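expit <- function(x) stats::plogis(x)

## Draw a population genotype matrix under the scenario (virtual latent-MVN
## or panel resampling). `latent` is the cached calibration for virtual
## scenarios.
draw_population <- function(spec, n, latent = NULL) {
  if (is.null(spec$panel)) {
    simulate_genotypes(n, spec$mafs, spec$target_r2, latent = latent)
  } else {
    simulate_from_panel(spec$panel, n)
  }
}

#' Solve the disease-model intercept for a target prevalence
#'
#' The disease model is logistic in the causal minor-allele counts,
#' `P(D = 1 | g) = expit(b0 + sum_j log(OR_j) g_j)`. The intercept `b0` is
#' solved by one-dimensional root finding so that the population prevalence
#' (the expectation of the disease probability over the scenario's genotype
#' distribution, estimated by Monte Carlo) equals
#' `spec$baseline_prevalence`. Under no causal SNPs the solution is the
#' logit of the prevalence, returned in closed form.
#'
#' @param spec a [scenario_spec()].
#' @param n_mc Monte-Carlo draws for the genotype expectation (default 1e5).
#' @param latent optional cached [latent_corr_matrix()] result.
#' @return the intercept `b0` (log-odds scale).
#' @export
solve_baseline_intercept <- function(spec, n_mc = 1e5, latent = NULL) {
  if (length(spec$causal_indices) == 0)
    return(stats::qlogis(spec$baseline_prevalence))
  G <- draw_population(spec, n_mc, latent = latent)
  eta <- unclass(G)[, spec$causal_indices, drop = FALSE] %*%
    log(spec$odds_ratios)
  f <- function(b0) mean(expit(b0 + eta)) - spec$baseline_prevalence
  uniroot(f, c(-30, 10), tol = 1e-10)$root
}

#' Per-individual disease probability
#'
#' Evaluates the logistic disease model on a genotype matrix: per-allele
#' log-odds `log(OR_j)` at the causal SNPs over the solved (or supplied)
#' intercept. With no causal SNPs the probability is constant at the
#' baseline prevalence.
#'
#' @param G genotype matrix over the full SNP set (causal columns must be
#'   present, i.e. before any genotyped-mask restriction).
#' @param spec a [scenario_spec()].
#' @param b0 intercept; solved via [solve_baseline_intercept()] when `NULL`.
#' @return numeric vector of `P(D = 1 | g)`.
#' @export
disease_probability <- function(G, spec, b0 = NULL) {
  G <- as_genotype(G)
  if (length(spec$causal_indices) == 0)
    return(rep(spec$baseline_prevalence, nrow(G)))
  stopifnot(max(spec$causal_indices) <= ncol(G))
  if (is.null(b0)) b0 <- solve_baseline_intercept(spec)
  eta <- unclass(G)[, spec$causal_indices, drop = FALSE] %*%
    log(spec$odds_ratios)
  as.vector(expit(b0 + eta))
}

#' Retrospective case-control sample under a scenario
#'
#' Simulates population individuals (genotypes, then Bernoulli disease
#' status from the logistic model) and accumulates them until the case and
#' control strata are filled; excess individuals of a filled stratum are
#' discarded. Only the columns flagged in `spec$genotyped_mask` are
#' returned, reproducing tag-SNP designs where causal SNPs are unobserved.
#'
#' @param spec a [scenario_spec()].
#' @param b0 solved intercept (computed if `NULL`; pass a cached value when
#'   looping over replicates).
#' @param latent cached [latent_corr_matrix()] for virtual scenarios.
#' @param max_draws safety cap on population draws (default 1e7).
#' @return list with `genotypes` (a [genotype_matrix()], cases first),
#'   `phenotype` (1 = affected, 0 = unaffected) and `n_population` (the
#'   number of individuals drawn).
#' @examples
#' sp <- virtual_scenario("A1", r2 = 0, n_snps = 4)
#' cc <- sample_case_control(sp)
#' table(cc$phenotype)
#' @export
sample_case_control <- function(spec, b0 = NULL, latent = NULL,
                                max_draws = 1e7) {
  if (is.null(latent) && is.null(spec$panel))
    latent <- latent_corr_matrix(spec$mafs, spec$target_r2)
  if (is.null(b0)) b0 <- solve_baseline_intercept(spec, latent = latent)
  prev <- spec$baseline_prevalence
  need_ca <- spec$n_cases; need_co <- spec$n_controls
  cases <- controls <- vector("list", 0L)
  drawn <- 0L
  # column permutation relabels which positions host the causal SNPs; fixed
  # for the whole sample so columns keep a single identity across batches
  perm <- if (spec$randomize_causal) sample.int(spec$n_snps) else
    seq_len(spec$n_snps)
  # first batch sized to fill both strata with ~15% headroom
  batch <- ceiling(1.15 * max(need_ca / prev, need_co / (1 - prev)))
  while (need_ca > 0 || need_co > 0) {
    if (drawn + batch > max_draws)
      batch <- max_draws - drawn
    if (batch <= 0)
      stop("population draw cap exceeded before filling case/control strata; ",
           "consider a higher baseline prevalence")
    G <- draw_population(spec, batch, latent = latent)
    pr <- disease_probability(G, spec, b0 = b0)
    d <- rbinom(batch, 1, pr)
    Gp <- unclass(G)[, perm, drop = FALSE]
    if (need_ca > 0) {
      idx <- which(d == 1)
      take <- idx[seq_len(min(length(idx), need_ca))]
      if (length(take)) {
        cases[[length(cases) + 1L]] <- Gp[take, , drop = FALSE]
        need_ca <- need_ca - length(take)
      }
    }
    if (need_co > 0) {
      idx <- which(d == 0)
      take <- idx[seq_len(min(length(idx), need_co))]
      if (length(take)) {
        controls[[length(controls) + 1L]] <- Gp[take, , drop = FALSE]
        need_co <- need_co - length(take)
      }
    }
    drawn <- drawn + batch
    batch <- min(batch, max(2000L,
      ceiling(1.3 * max(need_ca / prev, need_co / (1 - prev)))))
  }
  G <- rbind(do.call(rbind, cases), do.call(rbind, controls))
  y <- rep(c(1L, 0L), c(spec$n_cases, spec$n_controls))
  mask <- spec$genotyped_mask[perm]
  list(genotypes = genotype_matrix(G[, mask, drop = FALSE]),
       phenotype = y, n_population = drawn)
}
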