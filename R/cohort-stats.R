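#' Published cohort characteristic tables
#'
#' The printed group-by-category count tables of the study cohort
#' (42 cancer-free controls, 36 future ER-negative and 42 future
#' ER-positive cases): age band, histologic impression and lobular atrophy
#' (atrophy counts exclude the 8 subjects with missing atrophy status).
#'
#' @return Named list of 3 x 3 integer matrices (rows = category levels,
#'   columns = control / ER_neg / ER_pos).
#' @export
cohort_characteristic_tables <- function() {
  groups <- c("control", "ER_neg", "ER_pos")
  list(
    age = matrix(c(11, 19, 12, 11, 14, 11, 7, 16, 19), nrow = 3,
                 dimnames = list(c("<45", "45-55", ">55"), groups)),
    histology = matrix(c(25, 16, 1, 14, 19, 3, 19, 14, 9), nrow = 3,
                       dimnames = list(c("non_proliferative",
                                         "proliferative_no_atypia",
                                         "atypical_hyperplasia"), groups)),
    atrophy = matrix(c(9, 16, 15, 13, 13, 7, 6, 23, 10), nrow = 3,
                     dimnames = list(c("none", "partial", "complete"),
                                     groups))
  )
}

#' Pearson chi-square test on a contingency table
#'
#' Classic Pearson statistic \eqn{\sum (O - E)^2 / E} with
#' `(r - 1)(c - 1)` degrees of freedom and no continuity correction.
#' Rows or columns of missing-status counts must be excluded by the caller
#' before testing.
#'
#' @param table r x c matrix of non-negative counts.
#' @return List: `statistic`, `df`, `p_value`, `expected`.
#' @export
pearson_chi_square <- function(table) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("table has an all-zero row or column")
  }
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected <= 0)) stop("all expected counts must be positive")
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value, expected = expected)
}

#' One-way analysis of variance
#'
#' Classic one-way F test of equal group means (equal-variance pooling).
#'
#' @param values Numeric response.
#' @param groups Grouping factor (>= 2 groups, each with >= 2 observations).
#' @return List: `f_statistic`, `df1`, `df2`, `p_value`.
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) {
    stop("each group needs at least 2 observations")
  }
  fit <- stats::anova(stats::lm(values ~ groups))
  list(f_statistic = fit$`F value`[1], df1 = fit$Df[1], df2 = fit$Df[2],
       p_value = fit$`Pr(>F)`[1])
}

#' Per-sample mutational burden under a filtering strategy
#'
#' Number of calls per sample surviving technical filtering, the named AAF
#' strategy, and prioritization against the cohort controls.
#'
#' @param variants Variant table.
#' @param samples Sample sheet (supplies sample universe and which samples
#'   are controls).
#' @param strategy AAF strategy (default `"classical"`, the one the IHC
#'   burden correlations use).
#' @return Named integer vector of counts, one per sample (0 included).
#' @export
sample_mutational_burden <- function(variants, samples,
                                     strategy = "classical") {
  strategy <- match.arg(strategy, FILTER_STRATEGIES)
  v <- filter_technical(variants)
  v <- v[v$sample_id %in% samples$sample_id, ]
  v <- apply_aaf_filter(v, strategy)
  v <- prioritize(v, samples$sample_id[samples$group == "control"])$variants
  counts <- table(factor(v$sample_id, levels = samples$sample_id))
  stats::setNames(as.integer(counts), samples$sample_id)
}

#' Immunohistochemistry associations with group and mutational burden
#'
#' Wilcoxon rank-sum comparison of CD45 H-scores between cases (ER+ and
#' ER- pooled by default) and controls, and Spearman correlation of CD45
#' with per-sample mutational burden overall and within each group. Ties
#' are handled by average ranks with the tie-corrected normal
#' approximation. Ki67 is only summarized.
#'
#' @param samples Sample sheet with `group` and `cd45_hscore` (optionally
#'   `ki67_pct`).
#' @param burdens Named per-sample burden vector (see
#'   [sample_mutational_burden()]).
#' @param pool_cases Pool ER+ and ER- cases for the group comparison
#'   (default `TRUE`); otherwise each case group is compared with controls
#'   separately.
#' @return List: `wilcoxon` (data.frame of comparisons), `spearman`
#'   (data.frame: scope / rho / p / n), `ki67_summary`.
#' @export
ihc_associations <- function(samples, burdens, pool_cases = TRUE) {
  s <- samples[!is.na(samples$cd45_hscore), ]
  b <- burdens[s$sample_id]
  case <- s$group != "control"

  wtest <- function(keep, label) {
    x <- s$cd45_hscore[keep & case]
    y <- s$cd45_hscore[keep & !case]
    if (length(x) < 3L || length(y) < 3L) {
      return(data.frame(comparison = label, p_value = NA_real_,
                        n_cases = length(x), n_controls = length(y)))
    }
    p <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value)
    data.frame(comparison = label, p_value = p, n_cases = length(x),
               n_controls = length(y))
  }
  wilcoxon <- if (pool_cases) {
    wtest(rep(TRUE, nrow(s)), "all_cases_vs_control")
  } else {
    rbind(wtest(s$group %in% c("control", "ER_pos"), "er_pos_vs_control"),
          wtest(s$group %in% c("control", "ER_neg"), "er_neg_vs_control"))
  }

  sp <- function(keep, label) {
    x <- s$cd45_hscore[keep]
    y <- b[keep]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3L || length(unique(x[ok])) < 2L ||
        length(unique(y[ok])) < 2L) {
      return(data.frame(scope = label, rho = NA_real_, p_value = NA_real_,
                        n = sum(ok)))
    }
    ct <- suppressWarnings(stats::cor.test(x[ok], y[ok],
                                           method = "spearman",
                                           exact = FALSE))
    data.frame(scope = label, rho = unname(ct$estimate),
               p_value = ct$p.value, n = sum(ok))
  }
  spearman <- rbind(
    sp(rep(TRUE, nrow(s)), "overall"),
    do.call(rbind, lapply(unique(s$group),
                          function(g) sp(s$group == g, g)))
  )
  ki67 <- if ("ki67_pct" %in% names(samples)) {
    summary(samples$ki67_pct)
  } else NULL
  list(wilcoxon = wilcoxon, spearman = spearman, ki67_summary = ki67)
}
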