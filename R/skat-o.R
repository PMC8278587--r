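## Survival function of a positive linear combination of 1-df chi-squares,
## by Imhof's characteristic-function inversion, with a Liu moment-matching
## fallback. The workhorse behind all SKAT-O p-values.

## Vectorized over q with a shared lambda set: the integrand's
## u-independent pieces (theta offset, envelope) are computed once, so
## evaluating the survival at many quantiles (as the omnibus integration
## does) costs little more than at one.
imhof_sf_multi <- function(qs, lambda, tol = 2e-6) {
  lambda <- lambda[lambda > 1e-10 * max(lambda)]
  m <- length(lambda)
  if (m == 0L) return(rep(NA_real_, length(qs)))
  if (m == 1L) {
    return(stats::pchisq(qs / lambda, df = 1, lower.tail = FALSE))
  }
  if (max(lambda) / min(lambda) < 1 + 1e-10) {
    return(stats::pchisq(qs / mean(lambda), df = m, lower.tail = FALSE))
  }
  ## truncation point: envelope 1/(u rho(u)) ~ c u^(-m/2 - 1) beyond
  ## u0 = 1/min(lambda). Two tail bounds — the raw envelope integral and
  ## the van der Corput cancellation bound 4 env(U) / q — take the smaller U
  gm <- exp(mean(log(lambda)))
  u0 <- 1 / min(lambda)
  c_env <- gm^(-m / 2)
  q_lo <- max(min(qs), sum(lambda) * 1e-3)
  U_env <- (2 * c_env / (m * tol))^(2 / m)
  U_osc <- (8 * c_env / (tol * q_lo))^(1 / (m / 2 + 1))
  ## the cancellation bound needs the phase derivative ~ -q/2 past U:
  ## sum(lambda) / (1 + lambda_min^2 U^2) <= q/4
  u_star <- sqrt(max(4 * sum(lambda) / q_lo - 1, 0)) / min(lambda)
  U <- max(u0 * 2, min(U_env, max(U_osc, 1.5 * u_star)))
  ## resolve the oscillation sin(theta(u)); |theta'| <= (sum(lambda) + q)/2
  freq <- (sum(lambda) + max(abs(qs))) / 2
  n_per <- U * freq / (2 * pi)
  N <- ceiling(n_per * 24)
  N <- min(max(N, 1024L), 131072L)
  if (n_per * 12 > 131072) {
    ## grid cannot resolve the oscillation; fall back per q
    return(vapply(qs, function(q) imhof_sf_adaptive(q, lambda), 0))
  }
  N <- 2L * as.integer(ceiling(N / 2))  # composite Simpson needs even N
  u <- seq(0, U, length.out = N + 1L)[-1L]
  atan_part <- 0.5 * colSums(atan(lambda %o% u))
  env <- 1 / (u * exp(0.25 * colSums(log1p((lambda %o% u)^2))))
  h <- u[2L] - u[1L]
  w <- rep(c(4, 2), length.out = N)
  w[N] <- 1
  theta <- matrix(atan_part, N, length(qs)) - outer(u, qs) * 0.5
  integral <- colSums(sin(theta) * (env * w)) * h / 3
  ## endpoint at u=0 contributes f(0)*h/3 with f(0) finite
  integral <- integral + 0.5 * (sum(lambda) - qs) * h / 3
  p <- 0.5 + integral / pi
  bad <- p < 1e-8 | p > 1 | !is.finite(p)
  if (any(bad)) {
    p[bad] <- vapply(qs[bad], function(q) liu_pvalue(q, lambda), 0)
  }
  pmin(pmax(p, 0), 1)
}

## adaptive scalar fallback for pathological lambda/q scales
imhof_sf_adaptive <- function(q, lambda) {
  integrand <- function(u) {
    theta <- 0.5 * colSums(atan(lambda %o% u)) - 0.5 * q * u
    rho <- exp(0.25 * colSums(log1p((lambda %o% u)^2)))
    val <- sin(theta) / (u * rho)
    val[u == 0] <- 0.5 * (sum(lambda) - q)
    val
  }
  res <- tryCatch(
    stats::integrate(integrand, 0, Inf, abs.tol = 1e-9,
                     subdivisions = 500L),
    error = function(e) NULL
  )
  if (is.null(res) || !is.finite(res$value)) return(liu_pvalue(q, lambda))
  p <- 0.5 + res$value / pi
  if (p < 1e-8 || p > 1) return(liu_pvalue(q, lambda))
  min(max(p, 0), 1)
}

imhof_sf <- function(q, lambda) imhof_sf_multi(q, lambda)[1L]

.gl_cache <- new.env(parent = emptyenv())
gauss_legendre <- function(n) {
  key <- as.character(n)
  if (is.null(.gl_cache[[key]])) {
    g <- pracma::gaussLegendre(n, -1, 1)
    .gl_cache[[key]] <- list(nodes = g$x, weights = g$w)
  }
  .gl_cache[[key]]
}

liu_moments <- function(lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    d <- s1 * a^3 - a^2
    l <- a^2 - 2 * d
  } else {
    l <- 1 / s2
    a <- sqrt(l)
    d <- 0
  }
  list(muQ = c1, sigmaQ = sqrt(2 * c2), l = l, d = d,
       muX = l + d, sigmaX = sqrt(2) * sqrt(l + 2 * d))
}

liu_pvalue <- function(q, lambda) {
  m <- liu_moments(lambda)
  tstar <- (q - m$muQ) / m$sigmaQ
  stats::pchisq(tstar * m$sigmaX + m$muX, df = m$l, ncp = m$d,
                lower.tail = FALSE)
}

liu_qvalue <- function(p, lambda) {
  m <- liu_moments(lambda)
  qx <- stats::qchisq(p, df = m$l, ncp = m$d, lower.tail = FALSE)
  (qx - m$muX) / m$sigmaX * m$sigmaQ + m$muQ
}

#' Fit the logistic null model used by score-based gene tests
#'
#' Fits `case ~ covariates` by maximum likelihood and precomputes the pieces
#' of the efficient score projection shared by every gene's test. Aliased
#' covariate columns are dropped with a warning.
#'
#' @param y Binary 0/1 outcome vector.
#' @param X Covariate matrix (without intercept) or `NULL`.
#' @return An object of class `skat_null` with fitted means, residuals and
#'   projection components.
#' @export
skat_null_model <- function(y, X = NULL) {
  n <- length(y)
  X1 <- if (is.null(X)) matrix(1, n, 1) else cbind(1, as.matrix(X))
  qr_x <- qr(X1)
  if (qr_x$rank < ncol(X1)) {
    drop <- setdiff(seq_len(ncol(X1)), qr_x$pivot[seq_len(qr_x$rank)])
    warning("dropping ", length(drop), " aliased covariate column(s)")
    X1 <- X1[, -drop, drop = FALSE]
  }
  fit <- stats::glm.fit(X1, y, family = stats::binomial())
  mu <- fit$fitted.values
  d <- mu * (1 - mu)
  XtDX <- crossprod(X1, X1 * d)
  structure(list(y = y, X1 = X1, mu = mu, res = y - mu, d = d,
                 XtDX_inv = solve(XtDX), converged = fit$converged),
            class = "skat_null")
}

## A = D^{1/2} (I - X(X'DX)^{-1}X'D) Z : half-projection of weighted
## genotypes; Cov(score) = A'A.
skat_adjust <- function(null, Z) {
  XtDZ <- crossprod(null$X1, Z * null$d)
  sqrt(null$d) * (Z - null$X1 %*% (null$XtDX_inv %*% XtDZ))
}

#' SKAT-O: optimal unified burden / variance-component gene test
#'
#' Score-based omnibus test of association between a gene's binary
#' presence/absence variant matrix and a binary outcome, adjusting for
#' covariates through a logistic null model. The statistic
#' \eqn{Q_\rho = (1-\rho) Q_{SKAT} + \rho Q_{burden}} is evaluated over a
#' grid of mixing parameters; each \eqn{Q_\rho} is referred to its
#' mixture-of-chi-squares null (Imhof characteristic-function inversion,
#' Liu moment-matching fallback) and the omnibus p-value of the minimum
#' per-rho p is obtained by one-dimensional integration over the shared
#' chi-square(1) component. A single-variant input collapses to the
#' covariate-adjusted score test.
#'
#' @param G Matrix n x p of 0/1 variant presence indicators.
#' @param y Binary outcome, or a prefit [skat_null_model()] in `null`.
#' @param X Covariate matrix (ignored when `null` given).
#' @param weights Per-variant non-negative weights (default all 1).
#' @param rho_grid Mixing grid (default `c(0, 0.1^2, 0.2^2, 0.3^2, 0.4^2,
#'   0.5^2, 0.5, 1)`).
#' @param null Optional prefit null model for repeated calls.
#' @return List with `p_value`, `p_rho` (per-rho p-values), `rho_grid`,
#'   `n_variants`, and `testable`.
#' @export
skat_o_test <- function(G, y = NULL, X = NULL, weights = NULL,
                        rho_grid = c(0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1),
                        null = NULL) {
  if (is.null(null)) null <- skat_null_model(y, X)
  G <- as.matrix(G)
  if (is.null(weights)) weights <- rep(1, ncol(G))
  if (any(weights < 0)) stop("weights must be non-negative")
  keep <- weights > 0 & apply(G != 0, 2, any)
  G <- G[, keep, drop = FALSE]
  weights <- weights[keep]
  p <- ncol(G)
  untestable <- list(p_value = NA_real_, p_rho = NULL, rho_grid = rho_grid,
                     n_variants = p, testable = FALSE)
  if (p == 0L) return(untestable)

  Z <- sweep(G, 2, weights, "*")
  s <- as.vector(crossprod(Z, null$res))
  A <- skat_adjust(null, Z)
  M <- crossprod(A)

  if (p == 1L) {
    v <- M[1, 1]
    if (v <= 1e-12) return(untestable)
    pv <- stats::pchisq(s[1]^2 / v, df = 1, lower.tail = FALSE)
    return(list(p_value = pv, p_rho = rep(pv, length(rho_grid)),
                rho_grid = rho_grid, n_variants = 1L, testable = TRUE))
  }

  q_skat <- sum(s^2)
  q_burden <- sum(s)^2
  q_rho <- (1 - rho_grid) * q_skat + rho_grid * q_burden

  lambdas <- lapply(rho_grid, function(rho) {
    a <- sqrt(1 - rho)
    b <- (sqrt(1 - rho + p * rho) - a) / p
    Rh <- diag(a, p) + matrix(b, p, p)
    ev <- eigen(Rh %*% M %*% Rh, symmetric = TRUE, only.values = TRUE)$values
    ev[ev > 1e-10 * max(ev, 1e-300)]
  })
  if (any(!vapply(lambdas, length, 1L))) return(untestable)
  p_rho <- vapply(seq_along(rho_grid),
                  function(i) imhof_sf(q_rho[i], lambdas[[i]]), 0)
  p_min <- min(p_rho)
  if (length(rho_grid) == 1L) {
    return(list(p_value = p_rho, p_rho = p_rho, rho_grid = rho_grid,
                n_variants = p, testable = TRUE))
  }

  ## omnibus: integrate over the shared chi-square(1) direction
  qmin <- vapply(seq_along(rho_grid),
                 function(i) liu_qvalue(p_min, lambdas[[i]]), 0)
  z_mean <- rowMeans(A)
  zz <- sum(z_mean^2)
  if (zz < 1e-12) {
    ## weighted genotypes average out: per-rho statistics coincide
    pv <- p_min
    return(list(p_value = pv, p_rho = p_rho, rho_grid = rho_grid,
                n_variants = p, testable = TRUE))
  }
  cof <- as.vector(crossprod(z_mean, A)) / zz
  A1 <- outer(z_mean, cof)
  A2 <- A - A1
  K2 <- crossprod(A2)
  lam <- eigen(K2, symmetric = TRUE, only.values = TRUE)$values
  lam <- lam[lam > 1e-10 * max(lam, 1e-300)]
  mu_q <- sum(lam)
  var_remain <- 4 * sum(crossprod(A1) * K2)
  var_q <- 2 * sum(lam^2) + var_remain
  tau <- rho_grid * p^2 * zz + (1 - rho_grid) * zz * sum(cof^2)
  rho_adj <- pmin(rho_grid, 0.999)

  sd_ratio <- if (var_q > 0) sqrt(max(var_q - var_remain, 0) / var_q) else 1
  ## integrate P(kappa <= q(x)) over the shared chi-square(1) direction;
  ## substituting x = t^2 removes the x^(-1/2) density singularity, after
  ## which fixed Gauss-Legendre quadrature suffices
  gl <- gauss_legendre(64L)
  tmax <- sqrt(60)
  tt <- 0.5 * tmax * (gl$nodes + 1)
  wt <- 0.5 * tmax * gl$weights * sqrt(2 / pi) * exp(-tt^2 / 2)
  qx <- vapply(tt^2, function(xi) min((qmin - tau * xi) / (1 - rho_adj)), 0)
  q_adj <- (qx - mu_q) * sd_ratio + mu_q
  sf <- rep(1, length(q_adj))
  pos <- q_adj > 0
  if (any(pos)) sf[pos] <- imhof_sf_multi(q_adj[pos], lam)
  pv <- 1 - sum((1 - sf) * wt)
  ## the omnibus p is bounded by the min p and its Bonferroni bound
  if (!is.finite(pv)) pv <- min(p_min * length(rho_grid), 1)
  pv <- min(max(pv, p_min), min(p_min * length(rho_grid), 1))
  list(p_value = pv, p_rho = p_rho, rho_grid = rho_grid, n_variants = p,
       testable = TRUE)
}
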