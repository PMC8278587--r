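#' Remove calls flagged by upstream technical filters
#'
#' Drops every call carrying at least one technical failure flag
#' (strand bias, low-complexity region, low base quality, shallow
#' molecular-tag coverage) as reported by the upstream caller.
#'
#' @param variants Variant table with a `technical_flags` column
#'   (comma-separated string, `""` when clean).
#' @return The variant table restricted to unflagged calls.
#' @export
filter_technical <- function(variants) {
  flags <- variants$technical_flags
  flags[is.na(flags)] <- ""
  variants[flags == "", , drop = FALSE]
}

#' Call a genotype from an alternate allele fraction
#'
#' AAF bins, endpoints inclusive: \[0, 0.2\] hom-ref (rare homozygote),
#' \[0.4, 0.6\] heterozygote, \[0.8, 1.0\] hom-alt (common homozygote);
#' anything between bins is a no-call.
#'
#' @param aaf Numeric vector of AAFs in \[0, 1\].
#' @return Character vector: `hom_ref`, `het`, `hom_alt` or `no_call`.
#' @export
call_genotype <- function(aaf) {
  if (any(aaf < 0 | aaf > 1, na.rm = TRUE)) stop("aaf must lie in [0, 1]")
  out <- rep(NA_character_, length(aaf))
  out[aaf >= 0 & aaf <= 0.2] <- "hom_ref"
  out[aaf >= 0.4 & aaf <= 0.6] <- "het"
  out[aaf >= 0.8 & aaf <= 1.0] <- "hom_alt"
  out[is.na(out) & !is.na(aaf)] <- "no_call"
  out
}

#' Sample-level QC
#'
#' A sample fails if its mean unique-molecular-tag coverage is below 20x or
#' its SNP genotyping call rate is below 80%. The call rate is the fraction
#' of known SNP positions with a binnable genotype (see [call_genotype()]);
#' a known SNP with no call record counts as hom-ref, i.e. genotyped.
#'
#' @param samples Sample sheet with `sample_id` and `mean_umt_coverage`.
#' @param known_snps Data.frame of assayed SNP sites
#'   (`chrom`, `pos`, `ref`, `alt`).
#' @param variants Variant table for the same samples.
#' @param min_umt,min_call_rate QC thresholds (defaults 20 and 0.80).
#' @return The sample sheet with `snp_call_rate`, `qc_pass` and
#'   `qc_fail_reason` columns.
#' @export
sample_qc <- function(samples, known_snps, variants,
                      min_umt = 20, min_call_rate = 0.80) {
  if (nrow(known_snps) == 0L) {
    samples$snp_call_rate <- NA_real_
  } else {
    samples$snp_call_rate <- snp_call_rate(samples$sample_id, known_snps,
                                           variants)
  }
  fail_cov <- is.na(samples$mean_umt_coverage) |
    samples$mean_umt_coverage < min_umt
  fail_cr <- is.na(samples$snp_call_rate) |
    samples$snp_call_rate < min_call_rate
  samples$qc_pass <- !(fail_cov | fail_cr)
  reason <- character(nrow(samples))
  reason[fail_cov] <- "low_umt_coverage"
  reason[fail_cr] <- trimws(paste(reason[fail_cr], "low_snp_call_rate"))
  samples$qc_fail_reason <- reason
  samples
}

#' Replicate-identity check via rank correlation of SNP allele fractions
#'
#' Computes the pairwise Spearman correlation matrix of per-sample AAF
#' vectors over a shared set of known SNPs (absent call = AAF 0) and calls a
#' pair same-source when the correlation exceeds the threshold. Technical
#' replicates of one tissue source correlate near 1; unrelated samples,
#' sharing only population structure, sit well below.
#'
#' @param aaf_matrix Numeric matrix samples x SNPs (rownames = sample ids).
#' @param threshold Same-source threshold (default 0.85).
#' @return List with `correlation` (samples x samples Spearman matrix) and
#'   `same_source` (logical matrix, `NA` where correlation is undefined).
#' @export
replicate_identity <- function(aaf_matrix, threshold = 0.85) {
  aaf_matrix <- as.matrix(aaf_matrix)
  if (nrow(aaf_matrix) < 2L) stop("need at least 2 samples")
  if (ncol(aaf_matrix) < 1L) stop("shared SNP set is empty")
  constant <- apply(aaf_matrix, 1, function(x) length(unique(x)) == 1L)
  if (any(constant)) {
    warning("constant AAF vector(s): ",
            paste(rownames(aaf_matrix)[constant], collapse = ", "),
            "; correlations undefined")
  }
  cc <- suppressWarnings(stats::cor(t(aaf_matrix), method = "spearman"))
  same <- cc > threshold
  diag(same) <- NA
  list(correlation = cc, same_source = same)
}

#' Build the AAF matrix over known SNPs used for identity checks
#'
#' @param samples Sample sheet (or character vector of sample ids).
#' @param known_snps Known SNP sites.
#' @param variants Variant table.
#' @return Matrix samples x SNPs of AAFs, 0 where no call exists.
#' @export
snp_aaf_matrix <- function(samples, known_snps, variants) {
  ids <- if (is.data.frame(samples)) samples$sample_id else samples
  kkey <- paste(known_snps$chrom, known_snps$pos, known_snps$ref,
                known_snps$alt, sep = ":")
  m <- matrix(0, length(ids), length(kkey),
              dimnames = list(ids, kkey))
  hit <- variants[site_key(variants) %in% kkey &
                    variants$sample_id %in% ids, ]
  m[cbind(match(hit$sample_id, ids), match(site_key(hit), kkey))] <- hit$aaf
  m
}

#' Estimate per-category FFPE false discovery rates from paired tissue
#'
#' For each mutation category (optionally further split by AAF bin), the FDR
#' is the fraction of FFPE SNV calls absent from the paired fresh-frozen
#' sample, matching calls on (pair, chrom, pos, ref, alt). Formalin-induced
#' cytosine deamination makes C>T categories carry most of the artifact
#' load.
#'
#' @param ffpe,frozen Variant tables for the FFPE and frozen members.
#' @param pairs Data.frame with `pair_id`, `ffpe_sample`, `frozen_sample`.
#' @param aaf_bins Optional numeric vector of AAF bin edges; when given the
#'   table is additionally stratified by the FFPE call's AAF bin.
#' @return Data.frame (`fdr_table`) with `category`, optional `aaf_bin`,
#'   `n_ffpe_calls`, `n_ffpe_only`, `fdr` (`NA` where no FFPE calls).
#' @export
estimate_fdr <- function(ffpe, frozen, pairs, aaf_bins = NULL) {
  ffpe <- ffpe[is_snv(ffpe$ref, ffpe$alt), ]
  frozen <- frozen[is_snv(frozen$ref, frozen$alt), ]
  fp <- pairs$pair_id[match(ffpe$sample_id, pairs$ffpe_sample)]
  zp <- pairs$pair_id[match(frozen$sample_id, pairs$frozen_sample)]
  if (anyNA(fp)) stop("FFPE samples missing from the pairing key")
  ffpe_key <- paste(fp, site_key(ffpe), sep = "|")
  frozen_key <- paste(zp, site_key(frozen), sep = "|")
  ffpe_only <- !(ffpe_key %in% frozen_key)

  cats <- mutation_categories()
  cell <- function(keep, label, bin = NA_character_) {
    n <- sum(keep)
    n_only <- sum(ffpe_only[keep])
    data.frame(category = label, aaf_bin = bin, n_ffpe_calls = n,
               n_ffpe_only = n_only,
               fdr = if (n > 0) n_only / n else NA_real_,
               stringsAsFactors = FALSE)
  }
  if (is.null(aaf_bins)) {
    out <- do.call(rbind, lapply(cats, function(cat) {
      cell(ffpe$category == cat, cat)
    }))
    out$aaf_bin <- NULL
  } else {
    bins <- cut(ffpe$aaf, aaf_bins, include.lowest = TRUE)
    out <- do.call(rbind, lapply(cats, function(cat) {
      do.call(rbind, lapply(levels(bins), function(b) {
        cell(ffpe$category == cat & !is.na(bins) & bins == b, cat, b)
      }))
    }))
  }
  rownames(out) <- NULL
  out
}

#' Apply an AAF filtering strategy
#'
#' The three nested strategies address low-AAF FFPE artifacts:
#' * `liberal`  — remove calls with AAF < 0.05;
#' * `classical` — remove C>T calls (both plain and at-CpG) without an rsID
#'   when AAF < 0.1, and all other calls when AAF < 0.05;
#' * `strict`   — remove all calls with AAF < 0.1.
#'
#' Thresholds are exclusive (`<`), so survivors satisfy
#' strict \eqn{\subseteq} classical \eqn{\subseteq} liberal.
#'
#' @param variants Variant table (`category` populated for SNVs).
#' @param strategy One of `"liberal"`, `"classical"`, `"strict"`.
#' @return The filtered variant table.
#' @export
apply_aaf_filter <- function(variants,
                             strategy = c("liberal", "classical", "strict")) {
  strategy <- match.arg(strategy)
  aaf <- variants$aaf
  keep <- switch(strategy,
    liberal = aaf >= 0.05,
    strict = aaf >= 0.1,
    classical = {
      ct <- !is.na(variants$category) &
        variants$category %in% c("C>T", "C>T_at_CpG") &
        is.na(variants$rsid)
      ifelse(ct, aaf >= 0.1, aaf >= 0.05)
    }
  )
  variants[keep, , drop = FALSE]
}

#' Concordance of cohort allele frequencies with population frequencies
#'
#' For each rsID-annotated site, the cohort alternate-allele frequency is
#' computed from genotype calls across samples
#' (`(het + 2 * hom_alt) / (2 * called)`, with absent calls counted as
#' hom-ref and no-calls excluded) and correlated with the annotated
#' population AF. High concordance indicates the AAF filtering did not skew
#' the germline allele distribution.
#'
#' @param variants Variant table (rsID sites are used).
#' @param sample_ids Character vector of samples defining the cohort
#'   denominator.
#' @param by_category Also return one correlation per mutation category.
#' @param method Correlation method (default `"spearman"`).
#' @return List with `overall` (correlation, n sites) and, when requested,
#'   `by_category` (data.frame category / correlation / n). `NA` when fewer
#'   than 3 shared sites.
#' @export
population_af_concordance <- function(variants, sample_ids,
                                      by_category = FALSE,
                                      method = "spearman") {
  v <- variants[!is.na(variants$rsid) & !is.na(variants$population_af) &
                  variants$sample_id %in% sample_ids, ]
  n_samp <- length(unique(sample_ids))
  if (nrow(v) == 0L) {
    return(list(overall = c(correlation = NA_real_, n = 0)))
  }
  v$genotype <- call_genotype(v$aaf)
  key <- site_key(v)
  sites <- v[!duplicated(key), c("chrom", "pos", "ref", "alt",
                                 "population_af", "category")]
  skey <- site_key(sites)
  alt_dose <- c(hom_ref = 0, het = 1, hom_alt = 2)[v$genotype]
  dose <- tapply(alt_dose, factor(key, levels = skey), sum, na.rm = TRUE)
  n_nocall <- tapply(v$genotype == "no_call", factor(key, levels = skey), sum)
  called <- n_samp - ifelse(is.na(n_nocall), 0, n_nocall)
  sites$cohort_af <- as.vector(ifelse(called > 0,
                                      ifelse(is.na(dose), 0, dose) /
                                        (2 * called), NA_real_))
  corr <- function(idx) {
    x <- sites$population_af[idx]
    y <- sites$cohort_af[idx]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3L) return(c(correlation = NA_real_, n = sum(ok)))
    c(correlation = suppressWarnings(stats::cor(x[ok], y[ok],
                                                method = method)),
      n = sum(ok))
  }
  out <- list(overall = corr(seq_len(nrow(sites))), sites = sites)
  if (by_category) {
    cats <- sort(unique(sites$category[!is.na(sites$category)]))
    out$by_category <- do.call(rbind, lapply(cats, function(cat) {
      cc <- corr(which(!is.na(sites$category) & sites$category == cat))
      data.frame(category = cat, correlation = cc[["correlation"]],
                 n = cc[["n"]], stringsAsFactors = FALSE)
    }))
  }
  out
}
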