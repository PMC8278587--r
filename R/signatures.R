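#' Per-sample mutation spectrum
#'
#' Counts each sample's classified SNVs per mutation category, under either
#' the seven-category scheme (`C>A`, ..., `T>G` with `C>T_at_CpG` separate)
#' or the standard 96 trinucleotide-context classes
#' (`A[C>A]A`, ..., pyrimidine-strand normalized).
#'
#' @param variants Variant table (SNVs are used; indels ignored).
#' @param scheme `"seven_category"` or `"trinucleotide_96"`.
#' @param sample_ids Row universe (default: samples observed in `variants`);
#'   samples without SNVs get a zero row.
#' @return Integer count matrix samples x categories.
#' @export
spectrum_table <- function(variants,
                           scheme = c("seven_category", "trinucleotide_96"),
                           sample_ids = NULL) {
  scheme <- match.arg(scheme)
  if (is.null(sample_ids)) sample_ids <- sort(unique(variants$sample_id))
  v <- variants[is_snv(variants$ref, variants$alt), ]
  if (scheme == "seven_category") {
    cats <- mutation_categories()
    lab <- v$category
    if (anyNA(lab)) {
      miss <- is.na(lab)
      if (any(is.na(v$context[miss]))) {
        stop("SNVs without context cannot be classified: ",
             paste(utils::head(site_key(v[miss, ]), 5), collapse = ", "))
      }
      lab[miss] <- classify_mutation(v$ref[miss], v$alt[miss],
                                     v$context[miss])
    }
  } else {
    if (anyNA(v$context)) {
      stop("missing trinucleotide context for: ",
           paste(utils::head(site_key(v[is.na(v$context), ]), 5),
                 collapse = ", "))
    }
    subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
    bases <- c("A", "C", "G", "T")
    cats <- as.vector(vapply(subs, function(s) {
      as.vector(outer(bases, bases, function(f, t)
        paste0(f, "[", s, "]", t)))
    }, character(16)))
    ref <- toupper(v$ref); alt <- toupper(v$alt); ctx <- toupper(v$context)
    flip <- ref %in% c("A", "G")
    ref[flip] <- chartr("AG", "TC", ref[flip])
    alt[flip] <- chartr("ACGT", "TGCA", alt[flip])
    ctx[flip] <- revcomp(ctx[flip])
    lab <- paste0(substr(ctx, 1, 1), "[", ref, ">", alt, "]",
                  substr(ctx, 3, 3))
  }
  tab <- table(factor(v$sample_id, levels = sample_ids),
               factor(lab, levels = cats))
  m <- matrix(as.integer(tab), nrow = length(sample_ids),
              dimnames = list(sample_ids, cats))
  m
}

#' Cosine similarity of two non-negative vectors
#'
#' @param a,b Numeric vectors of equal length.
#' @return `a . b / (|a| |b|)`; `NA` when either vector is all zero.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}

#' Column-wise cosine similarity between two matrices
#'
#' @param A,B Matrices with the same number of rows.
#' @return Matrix `ncol(A)` x `ncol(B)` of cosine similarities.
#' @export
cosine_matrix <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  num <- crossprod(A, B)
  den <- sqrt(colSums(A^2)) %o% sqrt(colSums(B^2))
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

kl_divergence <- function(V, WH) {
  eps <- 1e-12
  sum(ifelse(V > 0, V * log(V / pmax(WH, eps)), 0) - V + WH)
}

nmf_single <- function(V, k, max_iter, tol, objective) {
  m <- nrow(V); n <- ncol(V)
  eps <- 1e-12
  W <- matrix(stats::runif(m * k, 0.1, 1), m, k)
  H <- matrix(stats::runif(k * n, 0.1, 1), k, n)
  obj <- Inf
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    WH <- pmax(W %*% H, eps)
    if (objective == "kl") {
      W <- W * ((V / WH) %*% t(H)) / pmax(matrix(rowSums(H), m, k,
                                                 byrow = TRUE), eps)
      WH <- pmax(W %*% H, eps)
      H <- H * (t(W) %*% (V / WH)) / pmax(matrix(colSums(W), k, n), eps)
      WH <- pmax(W %*% H, eps)
      new_obj <- kl_divergence(V, WH)
    } else {
      W <- W * (V %*% t(H)) / pmax(W %*% (H %*% t(H)), eps)
      H <- H * (t(W) %*% V) / pmax((t(W) %*% W) %*% H, eps)
      WH <- W %*% H
      new_obj <- sum((V - WH)^2)
    }
    trace <- c(trace, new_obj)
    if (is.finite(obj) && (obj - new_obj) < tol * max(obj, 1)) {
      obj <- new_obj
      break
    }
    obj <- new_obj
  }
  scale <- colSums(W)
  scale[scale == 0] <- 1
  list(W = sweep(W, 2, scale, "/"), H = H * scale, objective = obj,
       trace = trace)
}

#' De-novo mutational signature extraction by NMF with consensus clustering
#'
#' Factorizes the spectrum (samples x categories) into `k` non-negative,
#' column-stochastic signature profiles and per-sample exposures. Multiple
#' random restarts of multiplicative-update NMF (generalized
#' Kullback-Leibler objective by default) are pooled; the `k * n_restarts`
#' candidate signatures are clustered by cosine similarity (average-linkage
#' hierarchical clustering cut at `k`), each consensus signature is the
#' renormalized cluster centroid, and its stability is the mean cosine
#' similarity of cluster members to the centroid. Exposures are refit
#' against the consensus signatures by non-negative least squares.
#'
#' @param spectrum Count matrix samples x categories (see
#'   [spectrum_table()]).
#' @param k Number of signatures; must not exceed either spectrum dimension.
#' @param n_restarts Random restarts (default 30).
#' @param max_iter,tol Update iterations cap and relative-improvement
#'   stopping tolerance.
#' @param seed Integer seed.
#' @param objective `"kl"` (default) or `"frobenius"`.
#' @param reference_catalog Optional categories x profiles matrix (see
#'   [read_signature_catalog()]) for cosine comparison.
#' @return List of class `signature_set`: `signatures` (categories x k,
#'   columns sum to 1), `exposures` (samples x k), `stability` (per
#'   signature), `similarity` (k x reference profiles, when a catalog is
#'   given), `objective` (best restart), `objective_trace` (best restart's
#'   per-iteration objective), `recon_error` (relative Frobenius residual of
#'   the consensus refit) and `restart_recon_error` (same for the best
#'   single restart).
#' @export
nmf_extract <- function(spectrum, k, n_restarts = 30L, max_iter = 1000L,
                        tol = 1e-6, seed = 1L,
                        objective = c("kl", "frobenius"),
                        reference_catalog = NULL) {
  objective <- match.arg(objective)
  V <- t(as.matrix(spectrum))  # categories x samples
  if (all(V == 0)) stop("spectrum is all zero")
  nonzero_rows <- sum(rowSums(t(V)) > 0)
  if (k < 1L || k > min(dim(V))) stop("k must be in 1..min(dim(spectrum))")
  if (nonzero_rows < k) stop("spectrum needs at least k non-zero rows")
  set.seed(seed)
  runs <- lapply(seq_len(n_restarts), function(r) {
    nmf_single(V, k, max_iter, tol, objective)
  })
  best <- runs[[which.min(vapply(runs, `[[`, 0, "objective"))]]

  pool <- do.call(cbind, lapply(runs, `[[`, "W"))  # categories x (k*restarts)
  if (k == 1L) {
    member <- rep(1L, ncol(pool))
  } else {
    cs <- cosine_matrix(pool, pool)
    cs[is.na(cs)] <- 0
    member <- stats::cutree(stats::hclust(stats::as.dist(pmax(1 - cs, 0)),
                                          method = "average"), k = k)
  }
  sigs <- vapply(seq_len(k), function(cl) {
    cen <- rowMeans(pool[, member == cl, drop = FALSE])
    cen / sum(cen)
  }, numeric(nrow(V)))
  stability <- vapply(seq_len(k), function(cl) {
    mem <- pool[, member == cl, drop = FALSE]
    mean(vapply(seq_len(ncol(mem)),
                function(j) cosine_similarity(mem[, j], sigs[, cl]), 0))
  }, 0)
  ord <- order(stability, decreasing = TRUE)
  sigs <- sigs[, ord, drop = FALSE]
  stability <- stability[ord]
  rownames(sigs) <- rownames(V)
  colnames(sigs) <- paste0("signature_", LETTERS[seq_len(k)])

  expo <- vapply(seq_len(ncol(V)), function(i) {
    pracma::lsqnonneg(sigs, V[, i])$x
  }, numeric(k))
  expo <- if (k == 1L) matrix(expo, ncol = 1L) else t(expo)
  dimnames(expo) <- list(colnames(V), colnames(sigs))

  rel_err <- function(W, H) {
    sqrt(sum((V - W %*% H)^2)) / sqrt(sum(V^2))
  }
  out <- list(
    signatures = sigs, exposures = expo, stability = stability,
    objective = best$objective, objective_trace = best$trace,
    recon_error = rel_err(sigs, t(expo)),
    restart_recon_error = rel_err(best$W, best$H)
  )
  if (!is.null(reference_catalog)) {
    out$similarity <- cosine_matrix(sigs, as.matrix(reference_catalog))
  }
  class(out) <- "signature_set"
  out
}

#' Stability-vs-rank report for signature extraction
#'
#' Runs [nmf_extract()] over a range of ranks and reports mean consensus
#' stability and reconstruction error per rank, to support choosing `k`.
#'
#' @param spectrum Count matrix samples x categories.
#' @param ks Candidate ranks.
#' @param ... Passed to [nmf_extract()].
#' @return Data.frame: `k`, `mean_stability`, `min_stability`,
#'   `recon_error`.
#' @export
nmf_rank_report <- function(spectrum, ks = 2:6, ...) {
  do.call(rbind, lapply(ks, function(k) {
    fit <- nmf_extract(spectrum, k, ...)
    data.frame(k = k, mean_stability = mean(fit$stability),
               min_stability = min(fit$stability),
               recon_error = fit$recon_error)
  }))
}

#' Rank-based association of signature exposures with a sample attribute
#'
#' Wilcoxon rank-sum for a binary attribute (e.g. biopsy before/after 1992)
#' or Kruskal-Wallis for a multi-level attribute (e.g. the three study
#' groups).
#'
#' @param exposures Numeric vector (one signature's exposures) or matrix
#'   samples x signatures.
#' @param sample_attribute Factor-like attribute, one value per sample.
#' @param test `"wilcoxon_rank_sum"` or `"kruskal_wallis"`.
#' @return Named numeric p-value(s), one per signature column; `NA` with a
#'   warning when an attribute level has fewer than 2 samples.
#' @export
associate_exposures <- function(exposures, sample_attribute,
                                test = c("wilcoxon_rank_sum",
                                         "kruskal_wallis")) {
  test <- match.arg(test)
  x <- as.matrix(exposures)
  f <- factor(sample_attribute)
  if (any(table(f) < 2L)) {
    warning("attribute level with fewer than 2 samples; p-value undefined")
    return(stats::setNames(rep(NA_real_, ncol(x)), colnames(x)))
  }
  if (test == "wilcoxon_rank_sum" && nlevels(f) != 2L) {
    stop("wilcoxon_rank_sum needs a binary attribute")
  }
  p <- apply(x, 2, function(v) {
    if (test == "wilcoxon_rank_sum") {
      suppressWarnings(stats::wilcox.test(v ~ f, exact = FALSE)$p.value)
    } else {
      stats::kruskal.test(v ~ f)$p.value
    }
  })
  stats::setNames(p, colnames(x))
}
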