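ASSOC_METHODS <- c("skat_o", "skat_o_weighted", "logistic",
                   "logistic_weighted")
FILTER_STRATEGIES <- c("liberal", "classical", "strict")
CONTRASTS <- c("all_cases_vs_control", "er_pos_vs_control",
               "er_neg_vs_control")

#' Build the covariate design matrix for gene-level models
#'
#' Columns: epithelial percentage, histology indicators (baseline
#' non-proliferative), age, centered biopsy year (`year - 1992`), post-1992
#' indicator, their interaction (an FFPE processing protocol changed in
#' 1992), and SNP call rate. Aliased columns are dropped downstream by the
#' model fits.
#'
#' @param samples Sample sheet rows for the analysis samples.
#' @return Numeric matrix with one row per sample.
#' @export
covariate_design <- function(samples) {
  year_c <- samples$biopsy_year - 1992
  post <- as.numeric(samples$biopsy_year > 1992)
  cbind(
    epithelial_pct = samples$epithelial_pct,
    hist_prolif = as.numeric(samples$histology == "proliferative_no_atypia"),
    hist_atypia = as.numeric(samples$histology == "atypical_hyperplasia"),
    age = samples$age,
    year_c = year_c,
    post1992 = post,
    year_x_post1992 = year_c * post,
    snp_call_rate = samples$snp_call_rate
  )
}

#' Per-variant weights for burden and SKAT-O tests
#'
#' Default weights are 1 for the logistic (continuous-burden) test and a
#' Beta(1, 25) density evaluated at the variant's cohort alternate-allele
#' frequency for SKAT-O (the rare-variant convention: rarer variants weigh
#' more). Under the `fdr_downweighted` scheme the base weight is multiplied
#' by `1 - FDR` of the variant's mutation category, so C>T calls — the
#' categories with the highest FFPE artifact FDR — are down-weighted most.
#' Indels (no category) get factor 1.
#'
#' @param variants Variant table.
#' @param fdr_table Output of [estimate_fdr()]; required for
#'   `fdr_downweighted`.
#' @param scheme `"default"` or `"fdr_downweighted"`.
#' @param method `"logistic"` or `"skat"` (selects the base weight).
#' @param n_samples Cohort size used for the mean-AAF frequency (defaults to
#'   the number of distinct samples in `variants`).
#' @return Data.frame with one row per site: `site`, `category`,
#'   `base_weight`, `weight`.
#' @export
compute_weights <- function(variants, fdr_table = NULL,
                            scheme = c("default", "fdr_downweighted"),
                            method = c("logistic", "skat"),
                            n_samples = NULL) {
  scheme <- match.arg(scheme)
  method <- match.arg(method)
  if (is.null(n_samples)) n_samples <- length(unique(variants$sample_id))
  key <- site_key(variants)
  usite <- !duplicated(key)
  ukey <- key[usite]
  freq <- as.vector(tapply(variants$aaf, factor(key, levels = ukey), sum)) /
    n_samples
  base <- if (method == "logistic") rep(1, length(ukey)) else
    stats::dbeta(pmin(freq, 1), 1, 25)
  cat <- variants$category[usite]
  factor_fdr <- rep(1, length(ukey))
  if (scheme == "fdr_downweighted") {
    if (is.null(fdr_table)) stop("fdr_table required for fdr_downweighted")
    idx <- match(cat, fdr_table$category)
    miss <- !is.na(cat) & (is.na(idx) | is.na(fdr_table$fdr[idx]))
    if (any(miss)) {
      stop("no FDR estimate for category: ",
           paste(unique(cat[miss]), collapse = ", "))
    }
    factor_fdr[!is.na(cat)] <- 1 - fdr_table$fdr[idx[!is.na(cat)]]
  }
  data.frame(site = ukey, category = cat, base_weight = base,
             weight = base * factor_fdr, stringsAsFactors = FALSE)
}

#' Per-sample gene burden and presence matrix
#'
#' The continuous burden is the weighted sum of a sample's alternate allele
#' fractions over the gene's retained variants,
#' \eqn{B_i = \sum_v w_v \mathrm{AAF}_{iv}}; the presence matrix records
#' which samples carry which variant.
#'
#' @param variants Filtered, prioritized variant table.
#' @param sample_ids Samples defining the rows (absent call = 0).
#' @param gene Gene symbol.
#' @param weights Named weight vector by site key, or a [compute_weights()]
#'   data.frame; default all 1.
#' @return List with `burden` (named vector), `presence` (samples x sites
#'   0/1 matrix) and `aaf` (samples x sites AAF matrix).
#' @export
gene_burden <- function(variants, sample_ids, gene, weights = NULL) {
  v <- variants[!is.na(variants$gene) & variants$gene == gene, ]
  key <- site_key(v)
  usites <- unique(key)
  aaf <- matrix(0, length(sample_ids), length(usites),
                dimnames = list(sample_ids, usites))
  if (nrow(v)) {
    aaf[cbind(match(v$sample_id, sample_ids), match(key, usites))] <- v$aaf
  }
  w <- rep(1, length(usites))
  if (!is.null(weights)) {
    if (is.data.frame(weights)) {
      w <- weights$weight[match(usites, weights$site)]
    } else {
      w <- weights[usites]
    }
    if (anyNA(w)) stop("missing weight for some sites")
  }
  list(burden = as.vector(aaf %*% w), presence = (aaf > 0) * 1L, aaf = aaf)
}

## logistic fit via IRLS with Wald inference on the last column of X.
fast_logistic_wald <- function(Xfull, y) {
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(Xfull, y, family = stats::binomial())),
    error = function(e) NULL
  )
  if (is.null(fit)) return(NULL)
  d <- fit$fitted.values * (1 - fit$fitted.values)
  info <- crossprod(Xfull, Xfull * d)
  vc <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(vc)) return(NULL)
  k <- ncol(Xfull)
  beta <- unname(fit$coefficients[k])
  se <- sqrt(vc[k, k])
  list(beta = beta, se = se, deviance = fit$deviance,
       converged = fit$converged && is.finite(se) &&
         se < 1e3 && abs(beta) < 1e3)
}

#' Logistic regression test of continuous gene burden
#'
#' Maximum-likelihood logistic regression of case status on the gene's
#' continuous burden plus covariates. The p-value is the likelihood-ratio
#' (drop-in-deviance) test of the burden term — better calibrated than Wald
#' when most samples carry zero burden — and the odds ratio, reported per
#' unit of summed weighted AAF, carries a Wald 95% interval.
#'
#' @param burden Per-sample burden vector.
#' @param case_indicator Binary 0/1 vector.
#' @param covariates Covariate matrix or `NULL`.
#' @param null_deviance Optional precomputed deviance of the
#'   covariates-only fit (for repeated calls on the same design).
#' @return List: `p_value`, `odds_ratio`, `ci_lower`, `ci_upper`,
#'   `converged`, `testable`.
#' @export
logistic_burden_test <- function(burden, case_indicator, covariates = NULL,
                                 null_deviance = NULL) {
  out <- list(p_value = NA_real_, odds_ratio = NA_real_,
              ci_lower = NA_real_, ci_upper = NA_real_,
              converged = FALSE, testable = FALSE)
  if (length(unique(case_indicator)) < 2L) return(out)
  if (length(unique(burden)) < 2L) return(out)
  X <- if (is.null(covariates)) {
    matrix(1, length(burden), 1)
  } else {
    cbind(1, covariates)
  }
  qr_x <- qr(X)
  X <- X[, qr_x$pivot[seq_len(qr_x$rank)], drop = FALSE]
  fit <- fast_logistic_wald(cbind(X, burden = burden), case_indicator)
  if (is.null(fit)) return(out)
  out$testable <- TRUE
  out$converged <- fit$converged
  if (!fit$converged) return(out)
  if (is.null(null_deviance)) {
    fit0 <- tryCatch(
      suppressWarnings(stats::glm.fit(X, case_indicator,
                                      family = stats::binomial())),
      error = function(e) NULL
    )
    if (is.null(fit0)) return(out)
    null_deviance <- fit0$deviance
  }
  z <- stats::qnorm(0.975)
  lr <- max(null_deviance - fit$deviance, 0)
  out$p_value <- stats::pchisq(lr, df = 1, lower.tail = FALSE)
  out$odds_ratio <- exp(fit$beta)
  out$ci_lower <- exp(fit$beta - z * fit$se)
  out$ci_upper <- exp(fit$beta + z * fit$se)
  out
}

## ---- fast matrix path shared by run_all_combinations and permutations ----

## Per strategy: dense sample x site AAF matrix plus label-independent site
## metadata. Prioritization rule (b) (control-common) depends on which rows
## are controls and is applied at test time.
assoc_matrices <- function(variants, sample_ids, fdr_table = NULL,
                           strategies = FILTER_STRATEGIES) {
  variants <- filter_technical(variants)
  variants <- variants[variants$sample_id %in% sample_ids, ]
  out <- lapply(strategies, function(strategy) {
    v <- apply_aaf_filter(variants, strategy)
    key <- site_key(v)
    usite <- !duplicated(key)
    ukey <- key[usite]
    aaf <- matrix(0, length(sample_ids), length(ukey),
                  dimnames = list(sample_ids, ukey))
    aaf[cbind(match(v$sample_id, sample_ids), match(key, ukey))] <- v$aaf
    w_log <- compute_weights(v, method = "logistic",
                             n_samples = length(sample_ids))
    w_skat <- compute_weights(v, method = "skat",
                              n_samples = length(sample_ids))
    fdr_factor <- rep(1, length(ukey))
    if (!is.null(fdr_table)) {
      wf <- compute_weights(v, fdr_table, scheme = "fdr_downweighted",
                            method = "logistic",
                            n_samples = length(sample_ids))
      fdr_factor <- wf$weight[match(ukey, wf$site)]
    }
    list(
      aaf = aaf,
      sites = data.frame(
        site = ukey,
        gene = v$gene[usite],
        removed_fixed = (!is.na(v$population_af[usite]) &
                           v$population_af[usite] > 0.005) |
          (!is.na(v$impact[usite]) & v$impact[usite] == "low_impact"),
        w_logistic = w_log$weight[match(ukey, w_log$site)],
        w_skat = w_skat$weight[match(ukey, w_skat$site)],
        fdr_factor = fdr_factor,
        stringsAsFactors = FALSE
      )
    )
  })
  names(out) <- strategies
  out
}

## Run the 12 (or a subset of) combinations given a label assignment.
## `perm` permutes which sample row of the AAF matrices belongs to which
## (group, covariates) record.
run_combos_fast <- function(mats, y, covariates, control_rows,
                            genes, methods = ASSOC_METHODS,
                            strategies = names(mats),
                            rho_grid = c(0, 0.01, 0.04, 0.09, 0.16, 0.25,
                                         0.5, 1),
                            control_vmf_cut = 0.05, perm = NULL) {
  need_skat <- any(c("skat_o", "skat_o_weighted") %in% methods)
  null <- if (need_skat) {
    suppressWarnings(skat_null_model(y, covariates))
  } else NULL
  X <- cbind(1, covariates)
  qr_x <- qr(X)
  X <- X[, qr_x$pivot[seq_len(qr_x$rank)], drop = FALSE]
  nd0 <- if (any(c("logistic", "logistic_weighted") %in% methods)) {
    suppressWarnings(stats::glm.fit(X, y,
                                    family = stats::binomial()))$deviance
  } else NULL

  n_rows <- length(strategies) * length(genes) * length(methods)
  out <- data.frame(
    gene = character(n_rows), strategy = character(n_rows),
    method = character(n_rows), p_value = NA_real_,
    odds_ratio = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
    n_variants = 0L, testable = FALSE, converged = NA,
    stringsAsFactors = FALSE
  )
  i <- 0L
  for (strategy in strategies) {
    m <- mats[[strategy]]
    A <- m$aaf
    if (!is.null(perm)) A <- A[perm, , drop = FALSE]
    ctrl_mean <- colMeans(A[control_rows, , drop = FALSE])
    retained <- !m$sites$removed_fixed & ctrl_mean <= control_vmf_cut
    gene_idx <- split(which(retained),
                      factor(m$sites$gene[retained], levels = genes))
    for (gene in genes) {
      idx <- gene_idx[[gene]]
      Asub <- A[, idx, drop = FALSE]
      for (method in methods) {
        i <- i + 1L
        out$gene[i] <- gene
        out$strategy[i] <- strategy
        out$method[i] <- method
        out$n_variants[i] <- length(idx)
        if (!length(idx)) next
        if (method %in% c("logistic", "logistic_weighted")) {
          w <- m$sites$w_logistic[idx]
          if (method == "logistic_weighted") w <- w * m$sites$fdr_factor[idx]
          lt <- logistic_burden_test(as.vector(Asub %*% w), y,
                                     covariates, null_deviance = nd0)
          out$p_value[i] <- lt$p_value
          out$odds_ratio[i] <- lt$odds_ratio
          out$ci_lower[i] <- lt$ci_lower
          out$ci_upper[i] <- lt$ci_upper
          out$testable[i] <- lt$testable
          out$converged[i] <- lt$converged
        } else {
          w <- m$sites$w_skat[idx]
          if (method == "skat_o_weighted") w <- w * m$sites$fdr_factor[idx]
          st <- skat_o_test((Asub > 0) * 1L, weights = w,
                            rho_grid = rho_grid, null = null)
          out$p_value[i] <- st$p_value
          out$testable[i] <- st$testable
          out$converged[i] <- st$testable
        }
      }
    }
  }
  out
}

contrast_subset <- function(samples, contrast) {
  contrast <- match.arg(contrast, CONTRASTS)
  keep_groups <- switch(contrast,
    all_cases_vs_control = c("control", "ER_pos", "ER_neg"),
    er_pos_vs_control = c("control", "ER_pos"),
    er_neg_vs_control = c("control", "ER_neg")
  )
  samples[samples$group %in% keep_groups, , drop = FALSE]
}

#' Run all twelve filter-by-method association combinations
#'
#' For each of \{liberal, classical, strict\} x \{SKAT-O, FDR-weighted
#' SKAT-O, logistic burden, FDR-weighted logistic burden\}, runs the full
#' technical-filter, AAF-filter, prioritize, test chain for every gene and
#' returns one result row per gene x strategy x method. Models adjust for
#' the covariates of [covariate_design()]. Untestable gene/combination cells
#' (no retained variants, constant burden, non-convergence) are flagged, not
#' dropped.
#'
#' @param variants Variant table for the analysis samples.
#' @param samples Sample sheet (primary, QC-passing samples; needs `group`
#'   plus the covariate columns).
#' @param contrast One of `"all_cases_vs_control"`, `"er_pos_vs_control"`,
#'   `"er_neg_vs_control"`.
#' @param fdr_table [estimate_fdr()] output for the weighted methods.
#' @param genes Genes to test (default: all genes observed in `variants`).
#' @param rho_grid SKAT-O mixing grid.
#' @param methods,strategies Subsets of methods / strategies to run
#'   (defaults: all four and all three).
#' @return Data.frame of association results with a `contrast` column.
#' @export
run_all_combinations <- function(variants, samples,
                                 contrast = "all_cases_vs_control",
                                 fdr_table = NULL, genes = NULL,
                                 rho_grid = c(0, 0.01, 0.04, 0.09, 0.16,
                                              0.25, 0.5, 1),
                                 methods = ASSOC_METHODS,
                                 strategies = FILTER_STRATEGIES) {
  if (any(c("skat_o_weighted", "logistic_weighted") %in% methods) &&
      is.null(fdr_table)) {
    stop("fdr_table required for the FDR-weighted methods")
  }
  samples <- contrast_subset(samples, contrast)
  y <- as.numeric(samples$group != "control")
  covariates <- covariate_design(samples)
  if (is.null(genes)) {
    genes <- sort(unique(variants$gene[!is.na(variants$gene)]))
  }
  mats <- assoc_matrices(variants, samples$sample_id, fdr_table, strategies)
  out <- run_combos_fast(mats, y, covariates,
                         control_rows = which(samples$group == "control"),
                         genes = genes, methods = methods,
                         strategies = strategies, rho_grid = rho_grid)
  out$contrast <- contrast
  out
}
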