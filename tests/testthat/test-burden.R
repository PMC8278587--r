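test_that("compute_weights down-weights by category FDR on top of the base weight", {
  vt <- vtable(
    vrow(pos = 1L, ref = "C", alt = "T", context = "ACA", aaf = 0.2),
    vrow(pos = 2L, ref = "T", alt = "A", context = "ATA", aaf = 0.2)
  )
  fdr <- data.frame(category = c("C>T", "T>A"), fdr = c(0.6, 0.1))
  w0 <- compute_weights(vt, method = "logistic")
  expect_equal(w0$weight, c(1, 1))
  w <- compute_weights(vt, fdr, scheme = "fdr_downweighted",
                       method = "logistic")
  expect_equal(w$weight[w$category == "C>T"], 0.4)
  expect_equal(w$weight[w$category == "T>A"], 0.9)
  expect_lt(w$weight[w$category == "C>T"], w$weight[w$category == "T>A"])
  ## FDR 0 leaves the weight unchanged
  w_id <- compute_weights(vt, data.frame(category = c("C>T", "T>A"),
                                         fdr = c(0, 0)),
                          scheme = "fdr_downweighted", method = "logistic")
  expect_equal(w_id$weight, w0$weight)
  ## missing category FDR errors by name
  expect_error(compute_weights(vt, fdr[1, ], scheme = "fdr_downweighted"),
               "T>A")
  ## SKAT base weight: Beta(1,25) density at the cohort mean AAF
  ws <- compute_weights(vt, method = "skat", n_samples = 4)
  expect_equal(ws$base_weight, rep(stats::dbeta(0.2 / 4, 1, 25), 2),
               tolerance = 1e-12)
})

test_that("gene_burden sums weighted AAFs with zeros for non-carriers", {
  vt <- vtable(
    vrow(sample_id = "A", pos = 1L, aaf = 0.1),
    vrow(sample_id = "A", pos = 2L, ref = "T", alt = "C", context = "ATA",
         aaf = 0.2),
    vrow(sample_id = "B", pos = 1L, aaf = 0.3)
  )
  gb <- gene_burden(vt, c("A", "B", "C"), "GENE001")
  expect_equal(gb$burden, c(0.3, 0.3, 0))
  w <- stats::setNames(c(0.5, 1), unique(site_key(vt)))
  gb2 <- gene_burden(vt, c("A", "B", "C"), "GENE001", w)
  expect_equal(gb2$burden, c(0.05 + 0.2, 0.15, 0))
  expect_equal(unname(gb$presence[, 1]), c(1, 1, 0))
})

test_that("logistic burden OR matches the 2x2 cross-product ratio", {
  ## cases: 8 exposed / 12 unexposed; controls: 3 exposed / 17 unexposed
  burden <- c(rep(1, 8), rep(0, 12), rep(1, 3), rep(0, 17))
  y <- c(rep(1, 20), rep(0, 20))
  res <- logistic_burden_test(burden, y)
  expect_true(res$converged)
  expect_equal(res$odds_ratio, 8 * 17 / (12 * 3), tolerance = 1e-6)
  expect_true(res$ci_lower < res$odds_ratio && res$odds_ratio < res$ci_upper)
  ## constant burden is untestable
  expect_false(logistic_burden_test(rep(1, 40), y)$testable)
})

test_that("logistic burden recovers a planted coefficient", {
  set.seed(99)
  hits <- 0L
  for (r in 1:60) {
    n <- 500
    burden <- stats::rexp(n)
    eta <- -0.2 + -0.5 * burden
    y <- stats::rbinom(n, 1, stats::plogis(eta))
    res <- logistic_burden_test(burden, y)
    beta <- log(res$odds_ratio)
    se <- (log(res$ci_upper) - log(res$ci_lower)) / (2 * stats::qnorm(0.975))
    if (abs(beta - (-0.5)) <= 2 * se) hits <- hits + 1L
  }
  expect_gte(hits / 60, 0.9)
})

test_that("SKAT-O single-variant input reproduces the closed-form score test", {
  set.seed(4)
  for (r in 1:5) {
    n <- 80
    X <- cbind(stats::rnorm(n), stats::rbinom(n, 1, 0.5))
    y <- stats::rbinom(n, 1, 0.45)
    g <- stats::rbinom(n, 1, 0.2)
    if (sum(g) == 0) next
    st <- skat_o_test(matrix(g), y, X)
    ## closed-form covariate-adjusted score test
    fit <- stats::glm(y ~ X, family = stats::binomial())
    mu <- fit$fitted.values
    d <- mu * (1 - mu)
    X1 <- cbind(1, X)
    s <- sum(g * (y - mu))
    v <- sum(d * g^2) -
      (t(g * d) %*% X1) %*% solve(t(X1) %*% (X1 * d)) %*% t(X1) %*% (g * d)
    p_ref <- stats::pchisq(s^2 / as.numeric(v), 1, lower.tail = FALSE)
    expect_equal(st$p_value, p_ref, tolerance = 1e-6)
    expect_true(all(abs(st$p_rho - p_ref) < 1e-12))
  }
})

test_that("SKAT-O with rho = 1 collapses to the weighted burden score test", {
  set.seed(12)
  n <- 100; p <- 4
  G <- matrix(stats::rbinom(n * p, 1, 0.15), n, p)
  y <- stats::rbinom(n, 1, 0.5)
  w <- c(1, 0.5, 2, 1)
  st <- skat_o_test(G, y, weights = w, rho_grid = 1)
  ## burden score test on the weighted collapse
  b <- as.vector(G %*% w)
  mu <- mean(y)
  s <- sum(b * (y - mu))
  v <- mu * (1 - mu) * sum((b - mean(b))^2)
  p_ref <- stats::pchisq(s^2 / v, 1, lower.tail = FALSE)
  expect_equal(st$p_value, p_ref, tolerance = 1e-8)
})

test_that("SKAT-O omnibus p is calibrated under its own null (normal scores)", {
  ## draw score vectors from N(0, M) directly: agreement here isolates the
  ## mixture inversion + omnibus integration from finite-sample effects
  set.seed(6)
  n <- 60; p <- 6
  G <- matrix(stats::rbinom(n * p, 1, 0.25), n, p)
  y <- stats::rbinom(n, 1, 0.5)
  null <- skat_null_model(y)
  A <- bbdburden:::skat_adjust(null, G)
  M <- crossprod(A)
  L <- t(chol(M + diag(1e-12, p)))
  B <- 40000
  S <- L %*% matrix(stats::rnorm(p * B), p)
  qs <- colSums(S^2); qb <- colSums(S)^2
  rho <- c(0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1)
  pmat <- vapply(rho, function(r) {
    Q <- (1 - r) * qs + r * qb
    (B + 1 - rank(Q, ties.method = "min")) / B
  }, numeric(B))
  Tb <- apply(pmat, 1, min)
  st <- skat_o_test(G, y)
  T_obs <- min(st$p_rho)
  p_mc <- mean(Tb <= T_obs)
  se <- sqrt(p_mc * (1 - p_mc) / B)
  ## within MC error plus the min-p combination approximation's own
  ## accuracy (the one-dimensional integration treats the shared and
  ## residual score components as independent; worst-case ~2% here)
  expect_lt(abs(st$p_value - p_mc), 3 * se + 0.025)
})

test_that("down-weighting a variant to zero equals removing it, for both tests", {
  set.seed(33)
  n <- 90; p <- 5
  G <- matrix(stats::rbinom(n * p, 1, 0.2), n, p)
  y <- stats::rbinom(n, 1, 0.5)
  w <- c(1, 1, 0, 1, 1)
  st_w <- skat_o_test(G, y, weights = w)
  st_rm <- skat_o_test(G[, -3], y, weights = w[-3])
  expect_equal(st_w$p_rho, st_rm$p_rho, tolerance = 1e-10)
  expect_equal(st_w$p_value, st_rm$p_value, tolerance = 1e-10)
  A <- matrix(stats::runif(n * p, 0, 0.4), n, p) * G
  b_w <- as.vector(A %*% w)
  b_rm <- as.vector(A[, -3] %*% w[-3])
  expect_equal(logistic_burden_test(b_w, y)$p_value,
               logistic_burden_test(b_rm, y)$p_value, tolerance = 1e-10)
})

test_that("run_all_combinations yields 12 rows per gene and is invariant to sample order", {
  coh <- small_cohort()
  prim <- coh$samples[coh$samples$is_primary, ]
  fdr <- small_fdr_table()
  res <- run_all_combinations(coh$variants, prim, fdr_table = fdr,
                              genes = panel_genes(3))
  expect_identical(nrow(res), 36L)
  expect_identical(as.integer(table(res$gene)), rep(12L, 3))
  ## permuting sample order leaves all p-values unchanged
  ord <- sample.int(nrow(prim))
  res2 <- run_all_combinations(coh$variants, prim[ord, ], fdr_table = fdr,
                               genes = panel_genes(3))
  key <- function(x) x[order(x$gene, x$strategy, x$method), "p_value"]
  expect_equal(key(res2), key(res), tolerance = 1e-10)
})

test_that("fast matrix path agrees with the explicit filter/prioritize/test chain", {
  coh <- small_cohort(seed = 23)
  prim <- coh$samples[coh$samples$is_primary, ]
  fdr <- small_fdr_table()
  res <- run_all_combinations(coh$variants, prim, fdr_table = fdr)
  ## recompute one cell by explicit steps: classical x logistic for a gene
  v <- filter_technical(coh$variants)
  v <- v[v$sample_id %in% prim$sample_id, ]
  v <- apply_aaf_filter(v, "classical")
  pri <- prioritize(v, prim$sample_id[prim$group == "control"])
  genes <- unique(res$gene[res$testable & res$strategy == "classical" &
                             res$method == "logistic"])
  g <- genes[1]
  gb <- gene_burden(pri$variants, prim$sample_id, g)
  ref <- logistic_burden_test(gb$burden,
                              as.numeric(prim$group != "control"),
                              covariate_design(prim))
  got <- res[res$gene == g & res$strategy == "classical" &
               res$method == "logistic", ]
  expect_equal(got$p_value, ref$p_value, tolerance = 1e-10)
  expect_equal(got$odds_ratio, ref$odds_ratio, tolerance = 1e-10)
})
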