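#' Simulation configuration for synthetic BBD cohorts
#'
#' Builds the configuration object consumed by [generate_cohort()] and
#' [generate_paired_ffpe_frozen()]. Defaults emulate the targeted-panel FFPE
#' study design the pipeline is built for: 42 cancer-free controls, 42 future
#' ER-positive and 36 future ER-negative cases, a 93-gene panel, germline
#' SNPs drawn from population allele frequencies under Hardy-Weinberg with
#' genotype-consistent AAF noise, C>T-dominated FFPE artifact calls at low
#' AAF (below 0.2), and true somatic calls planted per gene at group-dependent
#' rates.
#'
#' @param n_control,n_er_pos,n_er_neg Group sizes (defaults 42 / 42 / 36).
#' @param n_genes Number of panel genes (default 93).
#' @param n_germline_snps Number of known germline SNP positions assayed.
#' @param germline_af_distribution List with `p_common` and the uniform
#'   `common_range` / `rare_range` the population AF is drawn from; the rare
#'   component sits below the 0.005 prioritization cut so the common/rare
#'   split gives the prioritization filter real work.
#' @param germline_aaf_noise SD of the truncated-normal AAF noise around the
#'   genotype means (het 0.5, hom-alt 0.95).
#' @param nocall_rate Per sample x SNP probability that a heterozygous or
#'   hom-alt genotype is observed at an out-of-bin AAF (allelic imbalance in
#'   degraded loci), yielding a genotype no-call.
#' @param artifact_rate_by_category Named mean artifact calls per sample per
#'   mutation category (C>T-dominated by default).
#' @param artifact_aaf Parameters of the artifact AAF law: Beta(shape1,
#'   shape2) rescaled to (0, max); max defaults to 0.2 so liberal / classical
#'   / strict filters bite differently.
#' @param somatic_rate Baseline true-somatic calls per gene per sample.
#' @param somatic_aaf_range Uniform range of true somatic AAF.
#' @param effect_genes Data.frame with columns `gene`, `group`,
#'   `log_multiplier`: per-group log multiplier on the somatic rate in that
#'   gene (empty by default, i.e. a null cohort).
#' @param n_replicate_sets,replicates_per_set Technical replicate structure:
#'   the first `n_replicate_sets` control subjects are profiled
#'   `replicates_per_set` times (shared germline genotypes and somatic
#'   variants, redrawn artifacts and AAF noise).
#' @param frac_flagged Fraction of calls carrying an upstream technical
#'   failure flag.
#' @param cd45_slope,cd45_noise_sd CD45 H-score model: baseline 20 plus
#'   `cd45_slope` per true somatic/artifact call above AAF 0.1, plus normal
#'   noise.
#' @param n_pairs,pair_calls_per_category,artifact_fraction_by_category
#'   Paired FFPE/frozen truth-set design: number of pairs, total FFPE calls
#'   per mutation category, and the fraction of those that are FFPE-only
#'   artifacts (defaults 0.6 for C>T, 0.25 for C>T at CpG, 0.1 elsewhere).
#' @param seed Integer seed; every generator draw derives from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_control = 42L, n_er_pos = 42L, n_er_neg = 36L,
                       n_genes = 93L,
                       n_germline_snps = 350L,
                       germline_af_distribution = list(
                         p_common = 0.7,
                         common_range = c(0.05, 0.5),
                         rare_range = c(1e-4, 0.004)
                       ),
                       germline_aaf_noise = 0.03,
                       nocall_rate = 0.04,
                       artifact_rate_by_category = c(
                         "C>A" = 1, "C>G" = 1, "C>T" = 10, "C>T_at_CpG" = 4,
                         "T>A" = 0.7, "T>C" = 2, "T>G" = 0.7
                       ),
                       artifact_aaf = list(shape1 = 1.2, shape2 = 6,
                                           max = 0.2),
                       somatic_rate = 0.05,
                       somatic_aaf_range = c(0.1, 0.4),
                       effect_genes = NULL,
                       n_replicate_sets = 3L, replicates_per_set = 2L,
                       frac_flagged = 0.02,
                       cd45_slope = 4, cd45_noise_sd = 15,
                       n_pairs = 4L,
                       pair_calls_per_category = 600L,
                       artifact_fraction_by_category = c(
                         "C>A" = 0.1, "C>G" = 0.1, "C>T" = 0.6,
                         "C>T_at_CpG" = 0.25, "T>A" = 0.1, "T>C" = 0.1,
                         "T>G" = 0.1
                       ),
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_control >= 1L, cfg$n_er_pos >= 1L, cfg$n_er_neg >= 1L,
            cfg$n_genes >= 1L, all(artifact_rate_by_category >= 0),
            somatic_rate >= 0, germline_aaf_noise >= 0,
            artifact_aaf$max > 0, artifact_aaf$max <= 1)
  if (!is.null(effect_genes)) {
    stopifnot(is.data.frame(effect_genes),
              all(c("gene", "group", "log_multiplier") %in%
                    names(effect_genes)))
    if (!all(effect_genes$gene %in% panel_genes(cfg$n_genes))) {
      stop("effect gene not in the gene panel")
    }
    if (!all(effect_genes$group %in% c("control", "ER_pos", "ER_neg"))) {
      stop("effect group must be control / ER_pos / ER_neg")
    }
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Default planted protective-effect design
#'
#' Ten panel genes with an elevated somatic mutation rate in the cancer-free
#' control group — the "higher burden in controls" pattern the association
#' pipeline is built to detect. The default rate ratio of 10 is chosen so a
#' single filter-method combination detects a planted gene with probability
#' about 0.85-0.9 at the default group sizes (a priori normal-approximation
#' power calculation on the continuous burden contrast), making recovery
#' experiments informative about the machinery rather than about borderline
#' power.
#'
#' @param genes Genes to plant effects in (default: 10 spread across the
#'   93-gene panel).
#' @param rate_ratio Control-to-case somatic rate ratio (default 10).
#' @return Data.frame suitable for `sim_config(effect_genes = ...)`.
#' @export
protective_effect_genes <- function(genes = panel_genes(93)[c(3, 11, 20, 28,
                                                              35, 47, 52,
                                                              64, 71, 88)],
                                    rate_ratio = 10) {
  data.frame(gene = genes, group = "control",
             log_multiplier = log(rate_ratio), stringsAsFactors = FALSE)
}

#' Panel gene names
#' @param n_genes Number of genes.
#' @return Character vector `GENE001` ... .
#' @export
panel_genes <- function(n_genes) sprintf("GENE%03d", seq_len(n_genes))

GENE_SPAN <- 10000L

gene_of_pos <- function(pos, n_genes) {
  panel_genes(n_genes)[pmin((pos - 1L) %/% GENE_SPAN + 1L, n_genes)]
}

rand_base <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

## ref/alt/context for n draws of a given pyrimidine-strand category,
## placed on a random strand.
category_snv <- function(category, n) {
  pyr_ref <- substr(category, 1, 1)
  pyr_alt <- substr(category, 3, 3)
  five <- rand_base(n)
  three <- rand_base(n)
  if (category == "C>T_at_CpG") {
    three <- rep("G", n)
  } else if (category == "C>T") {
    three[three == "G"] <- sample(c("A", "C", "T"), sum(three == "G"),
                                  replace = TRUE)
  }
  ctx <- paste0(five, pyr_ref, three)
  ref <- rep(pyr_ref, n)
  alt <- rep(pyr_alt, n)
  flip <- stats::runif(n) < 0.5
  if (any(flip)) {
    ref[flip] <- chartr("ACGT", "TGCA", ref[flip])
    alt[flip] <- chartr("ACGT", "TGCA", alt[flip])
    ctx[flip] <- revcomp(ctx[flip])
  }
  list(ref = ref, alt = alt, context = ctx)
}

trunc_norm <- function(n, mean, sd, lo, hi) {
  pmin(hi, pmax(lo, stats::rnorm(n, mean, sd)))
}

## Table 1 margins used by the covariate model.
AGE_PROPS <- list(control = c(11, 19, 12) / 42,
                  ER_neg = c(11, 14, 11) / 36,
                  ER_pos = c(7, 16, 19) / 42)
HIST_PROPS <- list(control = c(25, 16, 1) / 42,
                   ER_neg = c(14, 19, 3) / 36,
                   ER_pos = c(19, 14, 9) / 42)
ATRO_PROPS <- list(control = c(9, 16, 15) / 40,
                   ER_neg = c(13, 13, 7) / 33,
                   ER_pos = c(6, 23, 10) / 39)
YEAR_MEAN <- c(control = 1986, ER_neg = 1987, ER_pos = 1988)

#' Generate a synthetic BBD cohort with ground truth
#'
#' Draws a sample sheet, a variant table and per-variant ground-truth origin
#' labels (`germline`, `somatic_true`, `ffpe_artifact`) under the model in
#' [sim_config()]. Germline calls follow Hardy-Weinberg genotypes at each
#' SNP's population AF with AAF near \{0.5, 1\}; FFPE artifacts concentrate
#' in C>T categories at AAF below 0.2; true somatic calls land in each gene
#' at a group-dependent Poisson rate scaled by any planted `effect_genes`.
#' Technical replicates share germline and somatic calls but redraw
#' artifacts and measurement noise. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @param seed Optional override of `config$seed`.
#' @return List with `samples` (sheet incl. `subject_id`, `is_primary`),
#'   `variants` (variant table), `known_snps` (assayed SNP sites with
#'   population AF), and `truth` (per-call origin labels + planted effects).
#' @export
generate_cohort <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(if (is.null(seed)) config$seed else seed)
  genes <- panel_genes(config$n_genes)
  groups <- rep(c("control", "ER_pos", "ER_neg"),
                c(config$n_control, config$n_er_pos, config$n_er_neg))
  n_subj <- length(groups)
  subject_id <- sprintf("S%03d", seq_len(n_subj))

  ## replicate structure: extra profiles of the first control subjects
  rep_sets <- min(config$n_replicate_sets, config$n_control)
  prof_subject <- c(seq_len(n_subj),
                    rep(seq_len(rep_sets),
                        each = max(config$replicates_per_set - 1L, 0L)))
  prof_index <- c(rep(1L, n_subj),
                  rep(seq_len(max(config$replicates_per_set - 1L, 0L)) + 1L,
                      times = rep_sets))
  n_prof <- length(prof_subject)
  sample_id <- ifelse(prof_index == 1L, subject_id[prof_subject],
                      sprintf("%s_R%d", subject_id[prof_subject], prof_index))

  ## --- covariates (per subject, shared by replicates) ---
  age_breaks <- list(c(30, 44), c(45, 55), c(56, 70))
  age <- histology <- atrophy <- numeric(n_subj)
  histology <- atrophy <- character(n_subj)
  hist_levels <- c("non_proliferative", "proliferative_no_atypia",
                   "atypical_hyperplasia")
  atro_levels <- c("none", "partial", "complete")
  for (i in seq_len(n_subj)) {
    g <- groups[i]
    band <- sample.int(3L, 1L, prob = AGE_PROPS[[g]])
    age[i] <- round(stats::runif(1, age_breaks[[band]][1],
                                 age_breaks[[band]][2]))
    histology[i] <- sample(hist_levels, 1L, prob = HIST_PROPS[[g]])
    atrophy[i] <- if (stats::runif(1) < 0.03) NA_character_ else
      sample(atro_levels, 1L, prob = ATRO_PROPS[[g]])
  }
  biopsy_year <- pmin(2001, pmax(1969, round(stats::rnorm(
    n_subj, YEAR_MEAN[groups], 8))))
  epithelial_pct <- round(stats::runif(n_subj, 5, 60), 1)

  mean_umt <- trunc_norm(n_prof, 595, 120, 30, 1200)
  mean_raw <- mean_umt / stats::runif(n_prof, 0.04, 0.09)

  ## --- known germline SNP sites ---
  afd <- config$germline_af_distribution
  n_snp <- config$n_germline_snps
  common <- stats::runif(n_snp) < afd$p_common
  pop_af <- ifelse(common,
                   stats::runif(n_snp, afd$common_range[1], afd$common_range[2]),
                   stats::runif(n_snp, afd$rare_range[1], afd$rare_range[2]))
  snp_pos <- sample.int(config$n_genes * GENE_SPAN, n_snp)
  snp_mut <- category_snv(sample(mutation_categories(), 1L), n_snp)
  ## draw each SNP's substitution independently for spectral variety
  snp_cat <- sample(mutation_categories(), n_snp, replace = TRUE,
                    prob = c(2, 2, 3, 1, 2, 3, 2))
  for (cat in unique(snp_cat)) {
    idx <- which(snp_cat == cat)
    m <- category_snv(cat, length(idx))
    snp_mut$ref[idx] <- m$ref
    snp_mut$alt[idx] <- m$alt
    snp_mut$context[idx] <- m$context
  }
  known_snps <- data.frame(
    chrom = "panel", pos = snp_pos, ref = snp_mut$ref, alt = snp_mut$alt,
    rsid = sprintf("rs%06d", 100000L + seq_len(n_snp)),
    gene = gene_of_pos(snp_pos, config$n_genes),
    impact = sample(c("low_impact", "nonsynonymous"), n_snp, replace = TRUE,
                    prob = c(0.8, 0.2)),
    population_af = pop_af, context = snp_mut$context,
    stringsAsFactors = FALSE
  )

  ## --- germline genotypes per subject (HWE), AAF per profile ---
  p <- matrix(pop_af, n_subj, n_snp, byrow = TRUE)
  geno <- matrix(stats::rbinom(n_subj * n_snp, 2L, p), n_subj, n_snp)
  rows <- list()
  g_prof <- geno[prof_subject, , drop = FALSE]
  carrier <- which(g_prof > 0L, arr.ind = TRUE)
  if (nrow(carrier)) {
    gt <- g_prof[carrier]
    mu <- ifelse(gt == 2L, 0.95, 0.5)
    aaf <- trunc_norm(nrow(carrier), mu, config$germline_aaf_noise, 0.01, 1)
    nocall <- stats::runif(nrow(carrier)) < config$nocall_rate
    if (any(nocall)) {
      lo <- stats::runif(sum(nocall)) < 0.5
      aaf[nocall] <- ifelse(lo, stats::runif(sum(nocall), 0.21, 0.39),
                            stats::runif(sum(nocall), 0.61, 0.79))
    }
    j <- carrier[, 2]
    rows$germline <- data.frame(
      sample_id = sample_id[carrier[, 1]],
      chrom = "panel", pos = known_snps$pos[j], ref = known_snps$ref[j],
      alt = known_snps$alt[j], aaf = aaf,
      umt_depth = stats::rpois(nrow(carrier), mean_umt[carrier[, 1]]),
      rsid = known_snps$rsid[j], gene = known_snps$gene[j],
      impact = known_snps$impact[j],
      population_af = known_snps$population_af[j],
      context = known_snps$context[j],
      origin = "germline", stringsAsFactors = FALSE
    )
  }

  ## --- true somatic calls (per subject, shared by replicates) ---
  rate <- matrix(config$somatic_rate, n_subj, config$n_genes,
                 dimnames = list(NULL, genes))
  if (!is.null(config$effect_genes)) {
    for (k in seq_len(nrow(config$effect_genes))) {
      e <- config$effect_genes[k, ]
      rate[groups == e$group, e$gene] <-
        rate[groups == e$group, e$gene] * exp(e$log_multiplier)
    }
  }
  counts <- matrix(stats::rpois(length(rate), rate), n_subj, config$n_genes)
  tot <- sum(counts)
  if (tot) {
    subj <- rep(rep(seq_len(n_subj), config$n_genes), as.vector(counts))
    gidx <- rep(rep(seq_len(config$n_genes), each = n_subj),
                as.vector(counts))
    pos <- (gidx - 1L) * GENE_SPAN + sample.int(GENE_SPAN, tot, replace = TRUE)
    cat_draw <- sample(mutation_categories(), tot, replace = TRUE)
    mut <- list(ref = character(tot), alt = character(tot),
                context = character(tot))
    for (cat in unique(cat_draw)) {
      idx <- which(cat_draw == cat)
      m <- category_snv(cat, length(idx))
      mut$ref[idx] <- m$ref
      mut$alt[idx] <- m$alt
      mut$context[idx] <- m$context
    }
    som <- data.frame(
      subject = subj, pos = pos, ref = mut$ref, alt = mut$alt,
      context = mut$context,
      aaf0 = stats::runif(tot, config$somatic_aaf_range[1],
                          config$somatic_aaf_range[2]),
      impact = sample(setdiff(impact_classes(), "low_impact"), tot,
                      replace = TRUE),
      stringsAsFactors = FALSE
    )
    som$impact[stats::runif(tot) < 0.15] <- "low_impact"
    ## expand to profiles of each subject, with per-profile AAF noise
    for_prof <- split(seq_len(n_prof), prof_subject)
    reps <- lengths(for_prof)[as.character(som$subject)]
    idx <- rep(seq_len(tot), reps)
    prof <- unlist(for_prof[as.character(som$subject)], use.names = FALSE)
    rows$somatic <- data.frame(
      sample_id = sample_id[prof], chrom = "panel", pos = som$pos[idx],
      ref = som$ref[idx], alt = som$alt[idx],
      aaf = pmin(0.98, pmax(0.02, som$aaf0[idx] +
                              stats::rnorm(length(idx), 0, 0.01))),
      umt_depth = stats::rpois(length(idx), mean_umt[prof]),
      rsid = NA_character_,
      gene = gene_of_pos(som$pos[idx], config$n_genes),
      impact = som$impact[idx], population_af = NA_real_,
      context = som$context[idx], origin = "somatic_true",
      stringsAsFactors = FALSE
    )
  }

  ## --- FFPE artifacts (redrawn per profile) ---
  art_rows <- list()
  for (cat in names(config$artifact_rate_by_category)) {
    n_art <- stats::rpois(n_prof, config$artifact_rate_by_category[[cat]])
    tot <- sum(n_art)
    if (!tot) next
    prof <- rep(seq_len(n_prof), n_art)
    m <- category_snv(cat, tot)
    aaf <- stats::rbeta(tot, config$artifact_aaf$shape1,
                        config$artifact_aaf$shape2) * config$artifact_aaf$max
    pos <- sample.int(config$n_genes * GENE_SPAN, tot, replace = TRUE)
    art_rows[[cat]] <- data.frame(
      sample_id = sample_id[prof], chrom = "panel", pos = pos,
      ref = m$ref, alt = m$alt, aaf = pmax(aaf, 0.005),
      umt_depth = stats::rpois(tot, mean_umt[prof]), rsid = NA_character_,
      gene = gene_of_pos(pos, config$n_genes),
      impact = sample(impact_classes(), tot, replace = TRUE,
                      prob = c(rep(1, 8), 3)),
      population_af = NA_real_, context = m$context,
      origin = "ffpe_artifact", stringsAsFactors = FALSE
    )
  }
  rows$artifact <- do.call(rbind, art_rows)

  variants <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(variants) <- NULL
  variants$technical_flags <- ""
  flagged <- stats::runif(nrow(variants)) < config$frac_flagged
  variants$technical_flags[flagged] <- sample(
    c("strand_bias", "low_complexity", "low_base_quality",
      "shallow_mt_coverage"), sum(flagged), replace = TRUE)
  origin <- variants$origin
  variants$origin <- NULL
  variants$category <- NA_character_
  variants <- as_variant_table(variants)

  ## --- sample sheet ---
  s_age <- age[prof_subject]
  call_rate <- snp_call_rate(sample_id, known_snps, variants)
  n_som_art <- tabulate(match(
    variants$sample_id[origin != "germline" & variants$aaf >= 0.1],
    sample_id), n_prof)
  cd45 <- pmax(0, 20 + config$cd45_slope * n_som_art +
                 stats::rnorm(n_prof, 0, config$cd45_noise_sd))
  samples <- data.frame(
    sample_id = sample_id, subject_id = subject_id[prof_subject],
    is_primary = prof_index == 1L,
    group = groups[prof_subject], age = s_age,
    histology = histology[prof_subject], atrophy = atrophy[prof_subject],
    epithelial_pct = epithelial_pct[prof_subject],
    biopsy_year = biopsy_year[prof_subject],
    mean_umt_coverage = round(mean_umt, 1),
    mean_raw_coverage = round(mean_raw, 1),
    molecular_diversity = round(molecular_diversity(mean_umt, mean_raw), 2),
    snp_call_rate = call_rate,
    replicate_set = ifelse(prof_subject <= rep_sets &
                             config$replicates_per_set > 1L,
                           subject_id[prof_subject], NA_character_),
    cd45_hscore = round(pmin(300, cd45), 1),
    ki67_pct = round(pmin(100, abs(stats::rnorm(n_prof, 0.5, 0.6))), 2),
    stringsAsFactors = FALSE
  )

  truth <- list(
    origin = data.frame(sample_id = variants$sample_id,
                        site = site_key(variants), origin = origin,
                        stringsAsFactors = FALSE),
    effect_genes = config$effect_genes,
    artifact_rate_by_category = config$artifact_rate_by_category
  )
  list(samples = samples, variants = variants, known_snps = known_snps,
       truth = truth)
}

## call-rate helper shared with sample_qc(): fraction of known SNP positions
## with a binnable genotype; absent call = hom-ref (a valid call).
snp_call_rate <- function(sample_ids, known_snps, variants) {
  kkey <- paste(known_snps$chrom, known_snps$pos, known_snps$ref,
                known_snps$alt, sep = ":")
  at_snp <- variants[site_key(variants) %in% kkey, ]
  nocall <- at_snp[call_genotype(at_snp$aaf) == "no_call", ]
  n_nc <- tabulate(match(nocall$sample_id, sample_ids), length(sample_ids))
  1 - n_nc / length(kkey)
}

#' Generate paired FFPE / fresh-frozen truth sets
#'
#' Simulates the paired-tissue experiment used to estimate per-category FFPE
#' false discovery rates: each FFPE call in each mutation category is an
#' FFPE-only artifact with the category's configured probability
#' (`artifact_fraction_by_category`), otherwise a genuine call also present
#' in the paired frozen sample (up to AAF measurement noise).
#'
#' @param config A [sim_config()]; uses `n_pairs`,
#'   `pair_calls_per_category`, `artifact_fraction_by_category` and
#'   `artifact_aaf`.
#' @param seed Optional override of `config$seed`.
#' @return List with `ffpe` and `frozen` variant tables, `pairs`
#'   (pair_id / ffpe_sample / frozen_sample), and `truth` (per-FFPE-call
#'   origin + the planted artifact fractions).
#' @export
generate_paired_ffpe_frozen <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(if (is.null(seed)) config$seed else seed + 1L)
  cats <- mutation_categories()
  frac <- config$artifact_fraction_by_category[cats]
  if (any(is.na(frac))) stop("artifact_fraction_by_category must cover all 7 categories")
  n_pairs <- config$n_pairs
  per_cat <- config$pair_calls_per_category
  ffpe_rows <- frozen_rows <- list()
  for (ci in seq_along(cats)) {
    n <- per_cat
    pair <- sample.int(n_pairs, n, replace = TRUE)
    m <- category_snv(cats[ci], n)
    pos <- sample.int(config$n_genes * GENE_SPAN, n)
    is_art <- stats::runif(n) < frac[ci]
    aaf <- ifelse(is_art,
                  pmax(stats::rbeta(n, config$artifact_aaf$shape1,
                                    config$artifact_aaf$shape2) *
                         config$artifact_aaf$max, 0.005),
                  stats::runif(n, 0.1, 0.9))
    base <- data.frame(
      chrom = "panel", pos = pos, ref = m$ref, alt = m$alt, aaf = aaf,
      umt_depth = stats::rpois(n, 600), rsid = NA_character_,
      gene = gene_of_pos(pos, config$n_genes),
      impact = "nonsynonymous", population_af = NA_real_,
      context = m$context, technical_flags = "",
      origin = ifelse(is_art, "ffpe_artifact", "somatic_true"),
      pair = pair, stringsAsFactors = FALSE
    )
    ffpe <- base
    ffpe$sample_id <- sprintf("pair%02d_FFPE", pair)
    frozen <- base[!is_art, ]
    frozen$sample_id <- sprintf("pair%02d_frozen", frozen$pair)
    frozen$aaf <- pmin(0.99, pmax(0.01, frozen$aaf +
                                    stats::rnorm(nrow(frozen), 0, 0.02)))
    ffpe_rows[[ci]] <- ffpe
    frozen_rows[[ci]] <- frozen
  }
  ffpe <- do.call(rbind, ffpe_rows)
  frozen <- do.call(rbind, frozen_rows)
  truth <- list(
    origin = data.frame(sample_id = ffpe$sample_id,
                        site = paste(ffpe$chrom, ffpe$pos, ffpe$ref,
                                     ffpe$alt, sep = ":"),
                        origin = ffpe$origin, stringsAsFactors = FALSE),
    artifact_fraction_by_category = frac
  )
  drop_cols <- function(x) {
    x$origin <- NULL
    x$pair <- NULL
    x$category <- NA_character_
    as_variant_table(x)
  }
  pairs <- data.frame(
    pair_id = sprintf("pair%02d", seq_len(n_pairs)),
    ffpe_sample = sprintf("pair%02d_FFPE", seq_len(n_pairs)),
    frozen_sample = sprintf("pair%02d_frozen", seq_len(n_pairs)),
    stringsAsFactors = FALSE
  )
  list(ffpe = drop_cols(ffpe), frozen = drop_cols(frozen), pairs = pairs,
       truth = truth)
}

#' Generate per-sample mutation spectra from known signature mixtures
#'
#' Each sample's category counts are drawn from a multinomial whose
#' probability vector is the exposure-weighted mixture of the given
#' signature profiles — the ground-truth model that signature extraction by
#' NMF is expected to invert.
#'
#' @param signature_profiles Matrix categories x K, columns summing to 1.
#' @param exposures Matrix samples x K of non-negative mixing weights.
#' @param n_mutations_per_sample Integer scalar or per-sample vector.
#' @param seed Integer seed.
#' @return List with `spectrum` (samples x categories count matrix) and
#'   `truth` (profiles + row-normalized exposures).
#' @export
generate_signature_cohort <- function(signature_profiles, exposures,
                                      n_mutations_per_sample, seed = 1L) {
  signature_profiles <- as.matrix(signature_profiles)
  exposures <- as.matrix(exposures)
  if (ncol(signature_profiles) != ncol(exposures)) {
    stop("signature_profiles and exposures disagree on K")
  }
  if (any(signature_profiles < 0) || any(exposures < 0)) {
    stop("profiles and exposures must be non-negative")
  }
  if (any(abs(colSums(signature_profiles) - 1) > 1e-8)) {
    stop("signature profiles must be column-stochastic")
  }
  set.seed(seed)
  n <- nrow(exposures)
  sizes <- rep_len(n_mutations_per_sample, n)
  spectrum <- matrix(0L, n, nrow(signature_profiles),
                     dimnames = list(rownames(exposures),
                                     rownames(signature_profiles)))
  for (i in seq_len(n)) {
    if (sizes[i] == 0L) next
    w <- exposures[i, ]
    mix <- as.vector(signature_profiles %*% (w / sum(w)))
    spectrum[i, ] <- stats::rmultinom(1L, sizes[i], mix)[, 1]
  }
  expo_norm <- exposures / rowSums(exposures)
  list(spectrum = spectrum,
       truth = list(profiles = signature_profiles, exposures = expo_norm))
}
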