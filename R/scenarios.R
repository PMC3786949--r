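#' Simulation scenario specification
#'
#' Describes one case-control simulation scenario: the SNP set (MAFs and
#' exchangeable target LD, or a haplotype panel), the disease model (causal
#' SNPs and per-allele odds ratios over a baseline prevalence), the
#' ascertainment (cases/controls) and the replicate count.
#'
#' @param mafs per-SNP minor allele frequencies (virtual scenarios); ignored
#'   when `panel` is given.
#' @param target_r2 exchangeable pairwise allelic r-squared target in
#'   `[0, 1)` (virtual scenarios).
#' @param panel optional [haplotype_panel()]; when given, genotypes are
#'   simulated by resampling panel haplotypes and `mafs`/`target_r2` are
#'   taken from the panel.
#' @param causal_indices column indices (1-based) of the causal SNPs; empty
#'   under the null.
#' @param odds_ratios per-allele odds ratio for each causal SNP (same
#'   length as `causal_indices`), all `> 0`.
#' @param n_cases,n_controls ascertained stratum sizes.
#' @param n_replicates default replicate count for [run_scenario()].
#' @param genotyped_mask logical length-`p` vector of SNPs visible to the
#'   tests (default all); causal SNPs may be masked (tag-SNP designs).
#' @param baseline_prevalence population disease probability for an
#'   individual carrying no minor alleles at the causal SNPs... more
#'   precisely, the marginal population prevalence that the solved
#'   intercept reproduces. Default 0.10.
#' @param randomize_causal logical; if `TRUE` the SNP columns are permuted
#'   afresh each replicate so any position can host a causal SNP (the set
#'   tests are SNP-order invariant, so this is cosmetic but matches the
#'   study design).
#' @param scenario_id label carried through to reports.
#' @return an object of class `scenario_spec` (a list).
#' @seealso [virtual_scenario()] for the packaged A1-A9 settings,
#'   [panel_scenario()] for the B-series.
#' @export
scenario_spec <- function(mafs = NULL, target_r2 = 0, panel = NULL,
                          causal_indices = integer(), odds_ratios = numeric(),
                          n_cases = 1000, n_controls = 1000,
                          n_replicates = 1000, genotyped_mask = NULL,
                          baseline_prevalence = 0.10,
                          randomize_causal = FALSE,
                          scenario_id = "custom") {
  if (is.null(panel)) {
    stopifnot(!is.null(mafs), all(mafs > 0), all(mafs <= 0.5),
              target_r2 >= 0, target_r2 < 1)
    p <- length(mafs)
  } else {
    p <- ncol(panel$alleles)
    mafs <- colMeans(panel$alleles)
    if (is.null(genotyped_mask)) genotyped_mask <- panel$genotyped_mask
  }
  stopifnot(length(causal_indices) == length(odds_ratios),
            all(odds_ratios > 0),
            all(causal_indices >= 1), all(causal_indices <= p),
            n_cases >= 1, n_controls >= 1,
            baseline_prevalence > 0, baseline_prevalence < 1)
  if (is.null(genotyped_mask)) genotyped_mask <- rep(TRUE, p)
  stopifnot(length(genotyped_mask) == p, any(genotyped_mask))
  structure(list(
    scenario_id = scenario_id, n_snps = p, mafs = mafs,
    target_r2 = target_r2, panel = panel,
    causal_indices = as.integer(causal_indices), odds_ratios = odds_ratios,
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    n_replicates = as.integer(n_replicates),
    genotyped_mask = genotyped_mask,
    baseline_prevalence = baseline_prevalence,
    randomize_causal = randomize_causal
  ), class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("scenario %s: %d SNPs, %d causal, %d cases / %d controls\n",
              x$scenario_id, x$n_snps, length(x$causal_indices),
              x$n_cases, x$n_controls))
  if (is.null(x$panel))
    cat(sprintf("  virtual: MAFs in [%.3g, %.3g], target r2 = %g\n",
                min(x$mafs), max(x$mafs), x$target_r2))
  else cat("  panel-based:", nrow(x$panel$alleles), "haplotypes\n")
  if (length(x$causal_indices))
    cat("  ORs:", paste(x$odds_ratios, collapse = ", "), "\n")
  invisible(x)
}

#' Packaged virtual-dataset scenarios (A series)
#'
#' The nine virtual single-SNP-set settings: null scenarios A1-A3 (odds
#' ratio 1), single-causal-SNP scenarios A4-A6 (per-allele OR 1.2) and
#' two-causal-SNP scenarios A7-A9 (both ORs 1.2), each crossed with an
#' exchangeable pairwise LD target r-squared of 0.1, 0.5 or 0.8. MAF
#' settings: all 0.2 (A1, A5, A8); all 0.1 (A4, A7); one SNP at 0.04 and
#' the rest at 0.1 (A2, A6); two SNPs at 0.04 and the rest at 0.1 (A3,
#' A9). In A6/A9 the low-MAF SNPs are the causal ones. All SNPs are
#' genotyped; 1,000 cases and 1,000 controls per replicate.
#'
#' @param id one of `"A1"`..`"A9"`.
#' @param r2 pairwise LD target: 0.1, 0.5 or 0.8 (any value in `[0,1)`
#'   accepted).
#' @param n_snps SNP-set size, 20 (default) or 100.
#' @param ... overrides passed to [scenario_spec()] (e.g. `n_replicates`,
#'   `baseline_prevalence`).
#' @return a `scenario_spec`.
#' @examples
#' virtual_scenario("A6", r2 = 0.1)
#' @export
virtual_scenario <- function(id, r2 = 0.1, n_snps = 20, ...) {
  id <- toupper(id)
  tab <- list(
    A1 = list(low = 0L, base = 0.2, n_causal = 0L),
    A2 = list(low = 1L, base = 0.1, n_causal = 0L),
    A3 = list(low = 2L, base = 0.1, n_causal = 0L),
    A4 = list(low = 0L, base = 0.1, n_causal = 1L),
    A5 = list(low = 0L, base = 0.2, n_causal = 1L),
    A6 = list(low = 1L, base = 0.1, n_causal = 1L),
    A7 = list(low = 0L, base = 0.1, n_causal = 2L),
    A8 = list(low = 0L, base = 0.2, n_causal = 2L),
    A9 = list(low = 2L, base = 0.1, n_causal = 2L)
  )[[id]]
  if (is.null(tab)) stop("unknown virtual scenario: ", id)
  mafs <- c(rep(0.04, tab$low), rep(tab$base, n_snps - tab$low))
  # causal SNPs: the low-MAF columns where present, else the leading columns
  causal <- seq_len(tab$n_causal)
  scenario_spec(mafs = mafs, target_r2 = r2,
                causal_indices = causal,
                odds_ratios = rep(1.2, tab$n_causal),
                n_replicates = if (tab$n_causal == 0L) 2000 else 1000,
                randomize_causal = TRUE,
                scenario_id = sprintf("%s-r%g", id, r2), ...)
}

#' Packaged haplotype-panel scenarios (B series)
#'
#' Tag-SNP designs on a 28-SNP gene-region panel where only 8 SNPs are
#' directly genotyped: B1 is the null; B2 makes each panel SNP causal in
#' turn (use `b2_causal` to pick one); B3-B8 place two causal SNPs (both
#' ORs 1.2) at fixed panel positions with varying MAF and masking - B3 both
#' genotyped (positions 17, 25), B4 one genotyped (17, 6), B5 none (11, 6),
#' B6 none and both MAFs low (8, 9), B7/B8 one genotyped with one low MAF
#' (17, 8 and 25, 9).
#'
#' @param id one of `"B1"`..`"B8"`.
#' @param panel a [haplotype_panel()] with 28 SNPs and a genotyped mask;
#'   defaults to the packaged synthetic panel ([synthetic_clptm1l_panel()]).
#' @param b2_causal causal position for B2 (default 1).
#' @param ... overrides passed to [scenario_spec()].
#' @return a `scenario_spec`.
#' @export
panel_scenario <- function(id, panel = synthetic_clptm1l_panel(),
                           b2_causal = 1L, ...) {
  id <- toupper(id)
  causal <- switch(id,
    B1 = integer(), B2 = as.integer(b2_causal),
    B3 = c(17L, 25L), B4 = c(17L, 6L), B5 = c(11L, 6L),
    B6 = c(8L, 9L), B7 = c(17L, 8L), B8 = c(25L, 9L),
    stop("unknown panel scenario: ", id))
  scenario_spec(panel = panel, causal_indices = causal,
                odds_ratios = rep(1.2, length(causal)),
                n_replicates = if (id == "B1") 2000 else 1000,
                scenario_id = id, ...)
}

#' Read a scenario configuration file
#'
#' Plain `key = value` text mirroring the [scenario_spec()] fields
#' (`mafs` and `odds_ratios` as comma-separated lists, `genotyped_mask` as
#' comma-separated 0/1). Lines starting with `#` are comments. A `panel`
#' key gives a haplotype panel file path (resolved relative to the config
#' file).
#'
#' @param path config file path.
#' @return a `scenario_spec`.
#' @export
read_scenario <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  names(vals) <- keys
  num <- function(k, default = NULL)
    if (k %in% keys) as.numeric(strsplit(vals[[k]], ",")[[1]]) else default
  args <- list(
    mafs = num("mafs"),
    target_r2 = num("target_r2", 0)[1],
    causal_indices = as.integer(num("causal_indices", integer())),
    odds_ratios = num("odds_ratios", numeric()),
    n_cases = num("n_cases", 1000)[1],
    n_controls = num("n_controls", 1000)[1],
    n_replicates = num("n_replicates", 1000)[1],
    baseline_prevalence = num("baseline_prevalence", 0.10)[1],
    scenario_id = if ("scenario_id" %in% keys) vals[["scenario_id"]] else
      basename(path)
  )
  if ("genotyped_mask" %in% keys)
    args$genotyped_mask <- num("genotyped_mask") > 0
  if ("panel" %in% keys)
    args$panel <- read_haplotypes(file.path(dirname(path), vals[["panel"]]))
  do.call(scenario_spec, args)
}
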