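## Registry mapping method labels to p-value functions on (G, y).
method_registry <- function(pc_threshold = 0.80, beta_params = c(1, 25)) {
  bw <- function(G) snp_weights(G, beta_params = beta_params)
  list(
    "lkm-linear" = function(G, y) lkm_test(G, y, "linear")$p_value,
    "lkm-ibs"    = function(G, y) lkm_test(G, y, "ibs")$p_value,
    "lkm-wibs"   = function(G, y) lkm_test(G, y, "wibs", weights = bw(G))$p_value,
    "pca"        = function(G, y)
      pc_lrt(G, y, weights = NULL, threshold = pc_threshold)$p_value,
    "wpca"       = function(G, y)
      pc_lrt(G, y, weights = bw(G), threshold = pc_threshold)$p_value,
    "single-snp-meff" = function(G, y) {
      pv <- single_snp_tests(G, y)
      adjust_min_p(attr(pv, "min_p"), effective_tests(G))
    })
}

#' Run a replicated simulation scenario
#'
#' The replicate engine behind the type-I error and power study: for each
#' replicate, draw a case-control sample under the scenario, restrict to
#' the genotyped SNPs, run every requested SNP-set method, and record its
#' p-value; the rejection proportion at `alpha` estimates the type-I error
#' rate (null scenarios) or power (alternative scenarios). The disease
#' intercept and the latent LD calibration are solved once and shared by
#' all replicates. Per-replicate child seeds are drawn up front from the
#' master seed, so results are reproducible and individual replicates can
#' be replayed in isolation.
#'
#' @param spec a [scenario_spec()].
#' @param methods subset of `lkm-linear`, `lkm-ibs`, `lkm-wibs`, `pca`,
#'   `wpca`, `single-snp-meff`.
#' @param alpha rejection level (default 0.05).
#' @param n_replicates override of `spec$n_replicates`.
#' @param seed master RNG seed.
#' @param pc_threshold cumulative-variance threshold for the PC tests.
#' @param beta_params Beta-density weight shapes for the weighted methods.
#' @param keep_pvalues keep the full replicate-by-method p-value matrix.
#' @return object of class `study_result`: data frame with one row per
#'   method (`scenario`, `method`, `power`, `mc_se`, `n_replicates`,
#'   `n_excluded`), with the p-value matrix in `attr(, "pvalues")` when
#'   kept.
#' @examples
#' sp <- virtual_scenario("A1", r2 = 0.1, n_snps = 8,
#'                        n_cases = 200, n_controls = 200)
#' run_scenario(sp, methods = "pca", n_replicates = 20, seed = 1)
#' @export
run_scenario <- function(spec, methods = c("lkm-linear", "lkm-ibs",
                                           "lkm-wibs", "pca", "wpca"),
                         alpha = 0.05, n_replicates = NULL, seed = 1,
                         pc_threshold = 0.80, beta_params = c(1, 25),
                         keep_pvalues = TRUE) {
  reg <- method_registry(pc_threshold, beta_params)
  stopifnot(all(methods %in% names(reg)))
  R <- n_replicates %||% spec$n_replicates
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, R + 1L)
  # shared, replicate-independent pieces
  latent <- if (is.null(spec$panel))
    latent_corr_matrix(spec$mafs, spec$target_r2) else NULL
  set.seed(rep_seeds[R + 1L])
  b0 <- solve_baseline_intercept(spec, latent = latent)
  P <- matrix(NA_real_, R, length(methods),
              dimnames = list(NULL, methods))
  failures <- character(0)
  for (r in seq_len(R)) {
    set.seed(rep_seeds[r])
    ok <- tryCatch({
      cc <- sample_case_control(spec, b0 = b0, latent = latent)
      for (m in methods)
        P[r, m] <- reg[[m]](cc$genotypes, cc$phenotype)
      TRUE
    }, error = function(e) {
      failures <<- c(failures, sprintf("replicate %d: %s", r,
                                       conditionMessage(e)))
      FALSE
    })
    if (!ok) P[r, ] <- NA_real_
  }
  n_excl <- sum(!stats::complete.cases(P))
  if (n_excl > 0.01 * R)
    stop(sprintf("%d/%d replicates failed (> 1%%); first failure: %s",
                 n_excl, R, failures[1]))
  keep <- stats::complete.cases(P)
  pow <- colMeans(P[keep, , drop = FALSE] < alpha)
  res <- data.frame(
    scenario = spec$scenario_id, method = methods,
    power = as.numeric(pow),
    mc_se = sqrt(pow * (1 - pow) / sum(keep)),
    n_replicates = sum(keep), n_excluded = n_excl,
    row.names = NULL)
  class(res) <- c("study_result", "data.frame")
  attr(res, "alpha") <- alpha
  if (keep_pvalues) attr(res, "pvalues") <- P
  if (length(failures)) attr(res, "failures") <- failures
  res
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("scenario %s: rejection proportion at alpha = %g over %d replicates\n",
              x$scenario[1], attr(x, "alpha"), x$n_replicates[1]))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Write a study report
#'
#' Tab-separated table of rejection proportions (scenario x method) with
#' Monte-Carlo standard errors, plus an optional JSON archive of all
#' replicate p-values.
#'
#' @param results a `study_result` or list of them.
#' @param path output TSV path.
#' @param pvalue_json optional path for the replicate p-value archive
#'   (requires the jsonlite package).
#' @return `path`, invisibly.
#' @export
report_study <- function(results, path, pvalue_json = NULL) {
  if (inherits(results, "study_result")) results <- list(results)
  if (!length(results)) stop("no study results to report")
  tab <- do.call(rbind, lapply(results, as.data.frame))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(pvalue_json)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("jsonlite is required for the p-value archive")
    arc <- lapply(results, function(r) {
      P <- attr(r, "pvalues")
      if (is.null(P)) NULL else as.data.frame(P)
    })
    names(arc) <- vapply(results, function(r) r$scenario[1], "")
    jsonlite::write_json(arc, pvalue_json, digits = NA)
  }
  invisible(path)
}
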