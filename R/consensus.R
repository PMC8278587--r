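#' Consensus count of nominal significance across the 12 combinations
#'
#' For each gene, counts how many of the filter-by-method combinations
#' reached nominal significance (`p < 0.05`, strict inequality; untestable
#' combinations count as non-significant) and flags genes whose
#' FDR-weighted logistic regression under classical filtering is both
#' nominally significant and protective (OR < 1, i.e. more mutation burden
#' in controls).
#'
#' @param results Association results from [run_all_combinations()].
#' @return Data.frame per gene: `n_nominal`, `n_combinations`, `protective`.
#' @export
consensus_count <- function(results) {
  key <- paste(results$gene, results$strategy, results$method)
  if (anyDuplicated(key)) {
    stop("duplicate (gene, strategy, method) rows in results")
  }
  genes <- sort(unique(results$gene))
  sig <- !is.na(results$p_value) & results$p_value < 0.05
  n_nominal <- tapply(sig, factor(results$gene, levels = genes), sum)
  n_comb <- tapply(rep(1, nrow(results)), factor(results$gene, levels = genes),
                   sum)
  wlc <- results$method == "logistic_weighted" &
    results$strategy == "classical"
  prot <- rep(FALSE, length(genes))
  if (any(wlc)) {
    r <- results[wlc, ]
    prot_gene <- r$gene[!is.na(r$p_value) & r$p_value < 0.05 &
                          !is.na(r$odds_ratio) & r$odds_ratio < 1]
    prot <- genes %in% prot_gene
  }
  data.frame(gene = genes, n_nominal = as.integer(n_nominal),
             n_combinations = as.integer(n_comb), protective = prot,
             stringsAsFactors = FALSE)
}

consensus_statistic <- function(results, statistic, n_consensus = 4L) {
  cc <- consensus_count(results)
  switch(statistic,
         s1 = sum(cc$n_nominal >= n_consensus),
         s2 = sum(cc$protective))
}

#' Label-permutation empirical significance of global burden statistics
#'
#' Shuffles the assignment of genomic profiles to (group label, covariates)
#' records — keeping each label bound to its covariates, so the
#' covariate-group relationship is preserved exactly — re-runs the
#' filter/prioritize/test pipeline, and recomputes one of two global
#' statistics:
#' * `s1` — number of genes nominally significant (`p < 0.05`) in at least
#'   `n_consensus` of the 12 combinations (two-sided: doubled smaller tail);
#' * `s2` — number of genes nominally significant with OR < 1 under
#'   FDR-weighted logistic regression with classical filtering (one-sided,
#'   enrichment).
#'
#' `s2` reads only the weighted-logistic classical slice of the pipeline,
#' so its permutation replicates re-run just that combination; `s1`
#' permutations re-run all 12.
#'
#' @param variants Variant table for the analysis samples.
#' @param samples Sample sheet (primary, QC-passing samples).
#' @param statistic `"s1"` or `"s2"`.
#' @param n_perm Number of permutations (default 100).
#' @param seed Integer seed; results are bit-reproducible given it.
#' @param fdr_table [estimate_fdr()] output (needed by weighted methods).
#' @param contrast Contrast to permute (default all cases vs control).
#' @param n_consensus Consensus cutoff for `s1` (default 4).
#' @param plus_one Use the (1 + exceed) / (1 + n_perm) estimator (default);
#'   `FALSE` gives the raw exceed / n_perm estimator.
#' @param rho_grid SKAT-O mixing grid (s1 only).
#' @return List: `statistic_id`, `observed`, `null_values`, `empirical_p`,
#'   `n_perm`, `seed`, plus the observed run's results.
#' @export
permutation_test <- function(variants, samples, statistic = c("s2", "s1"),
                             n_perm = 100L, seed = 1L, fdr_table = NULL,
                             contrast = "all_cases_vs_control",
                             n_consensus = 4L, plus_one = TRUE,
                             rho_grid = c(0, 0.01, 0.04, 0.09, 0.16, 0.25,
                                          0.5, 1)) {
  statistic <- match.arg(statistic)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  methods <- if (statistic == "s2") "logistic_weighted" else ASSOC_METHODS
  strategies <- if (statistic == "s2") "classical" else FILTER_STRATEGIES

  samples <- contrast_subset(samples, contrast)
  y <- as.numeric(samples$group != "control")
  covariates <- covariate_design(samples)
  genes <- sort(unique(variants$gene[!is.na(variants$gene)]))
  mats <- assoc_matrices(variants, samples$sample_id, fdr_table, strategies)
  ctrl <- which(samples$group == "control")

  observed_res <- run_combos_fast(mats, y, covariates, ctrl, genes,
                                  methods = methods, strategies = strategies,
                                  rho_grid = rho_grid)
  observed <- consensus_statistic(observed_res, statistic, n_consensus)

  set.seed(seed)
  n <- nrow(samples)
  null_values <- vapply(seq_len(n_perm), function(b) {
    perm <- sample.int(n)
    res <- run_combos_fast(mats, y, covariates, ctrl, genes,
                           methods = methods, strategies = strategies,
                           rho_grid = rho_grid, perm = perm)
    consensus_statistic(res, statistic, n_consensus)
  }, 0)

  empirical_p <- empirical_pvalue(
    observed, null_values,
    alternative = if (statistic == "s2") "greater" else "two_sided",
    plus_one = plus_one
  )
  list(statistic_id = statistic, observed = observed,
       null_values = null_values, empirical_p = empirical_p,
       n_perm = n_perm, seed = seed, observed_results = observed_res)
}

#' Empirical p-value from a permutation null
#'
#' One-sided (`greater`) p is the plus-one estimator
#' `(1 + #\{null >= observed\}) / (1 + n_perm)`, which cannot return zero at
#' finite `n_perm`; `two_sided` doubles the smaller tail probability, capped
#' at 1 (the null is discrete, so this is the doubled-tail convention).
#' `plus_one = FALSE` gives the raw `count / n_perm` estimator.
#'
#' @param observed Observed statistic.
#' @param null_values Numeric vector of permutation statistics.
#' @param alternative `"greater"` or `"two_sided"`.
#' @param plus_one Use the plus-one correction (default `TRUE`).
#' @return Empirical p-value in \[0, 1\].
#' @export
empirical_pvalue <- function(observed, null_values,
                             alternative = c("greater", "two_sided"),
                             plus_one = TRUE) {
  alternative <- match.arg(alternative)
  n_perm <- length(null_values)
  tail_p <- function(count) {
    if (plus_one) (1 + count) / (1 + n_perm) else count / n_perm
  }
  p_ge <- tail_p(sum(null_values >= observed))
  if (alternative == "greater") return(p_ge)
  p_le <- tail_p(sum(null_values <= observed))
  min(1, 2 * min(p_ge, p_le))
}

#' Bonferroni-corrected significance threshold
#'
#' @param n_genes Number of genes tested.
#' @param alpha Family-wise error target (default 0.05).
#' @return `alpha / n_genes` (0.05 / 93 = 0.000538 for the full panel).
#' @export
bonferroni_threshold <- function(n_genes, alpha = 0.05) {
  stopifnot(n_genes >= 1)
  alpha / n_genes
}
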