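## In-code fixtures shared across test files.

## One variant-table row with sensible defaults, overridable per field.
vrow <- function(sample_id = "S1", chrom = "panel", pos = 100L, ref = "C",
                 alt = "T", aaf = 0.5, umt_depth = 100L,
                 rsid = NA_character_, gene = "GENE001",
                 impact = "nonsynonymous", population_af = NA_real_,
                 context = NULL, technical_flags = "",
                 category = NA_character_) {
  if (is.null(context)) {
    context <- if (nchar(ref) == 1 && nchar(alt) == 1) {
      paste0("A", ref, "A")
    } else NA_character_
  }
  data.frame(sample_id = sample_id, chrom = chrom, pos = pos, ref = ref,
             alt = alt, aaf = aaf, umt_depth = umt_depth, rsid = rsid,
             gene = gene, impact = impact, population_af = population_af,
             context = context, technical_flags = technical_flags,
             category = category, stringsAsFactors = FALSE)
}

vtable <- function(...) as_variant_table(do.call(rbind, list(...)))

## The 12-variant table covering every (category family x rsID x AAF band)
## cell relevant to the three filter strategies, with hand-derived survivor
## sets per strategy.
toy_filter_table <- function() {
  vt <- vtable(
    # C>T family, no rsID: below 0.05 / in [0.05, 0.1) / at or above 0.1
    vrow(pos = 1L, ref = "C", alt = "T", context = "ACA", aaf = 0.04),
    vrow(pos = 2L, ref = "C", alt = "T", context = "ACA", aaf = 0.07),
    vrow(pos = 3L, ref = "C", alt = "T", context = "ACA", aaf = 0.20),
    # C>T at CpG, no rsID
    vrow(pos = 4L, ref = "C", alt = "T", context = "ACG", aaf = 0.04),
    vrow(pos = 5L, ref = "C", alt = "T", context = "ACG", aaf = 0.07),
    vrow(pos = 6L, ref = "C", alt = "T", context = "ACG", aaf = 0.20),
    # C>T with rsID (classical exception)
    vrow(pos = 7L, ref = "C", alt = "T", context = "ACA", aaf = 0.04,
         rsid = "rs1"),
    vrow(pos = 8L, ref = "C", alt = "T", context = "ACA", aaf = 0.07,
         rsid = "rs2"),
    vrow(pos = 9L, ref = "C", alt = "T", context = "ACA", aaf = 0.20,
         rsid = "rs3"),
    # non-C>T
    vrow(pos = 10L, ref = "T", alt = "A", context = "ATA", aaf = 0.04),
    vrow(pos = 11L, ref = "T", alt = "A", context = "ATA", aaf = 0.07),
    vrow(pos = 12L, ref = "T", alt = "A", context = "ATA", aaf = 0.20)
  )
  survivors <- list(
    liberal = c(2, 3, 5, 6, 8, 9, 11, 12),
    classical = c(3, 6, 8, 9, 11, 12),
    strict = c(3, 6, 9, 12)
  )
  list(variants = vt, survivors = survivors)
}

## random variant table exercising all categories, rsIDs, and AAF bands
random_variant_table <- function(n = 40) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  rsid <- ifelse(stats::runif(n) < 0.3, paste0("rs", seq_len(n)),
                 NA_character_)
  as_variant_table(data.frame(
    sample_id = sample(c("S1", "S2", "S3"), n, replace = TRUE),
    chrom = "panel", pos = seq_len(n), ref = ref, alt = alt,
    aaf = round(stats::runif(n), 3), umt_depth = 100L, rsid = rsid,
    gene = "GENE001", impact = "nonsynonymous", population_af = NA_real_,
    context = paste0(sample(bases, n, TRUE), ref, sample(bases, n, TRUE)),
    technical_flags = "", category = NA_character_,
    stringsAsFactors = FALSE
  ))
}

## small cohort for pipeline-level tests (fast default scales)
small_cohort <- function(seed = 11, ...) {
  generate_cohort(sim_config(n_control = 15L, n_er_pos = 12L, n_er_neg = 12L,
                             n_genes = 10L, n_germline_snps = 60L,
                             seed = seed, ...))
}

small_fdr_table <- function(seed = 5) {
  pf <- generate_paired_ffpe_frozen(sim_config(pair_calls_per_category = 300L,
                                               seed = seed))
  estimate_fdr(pf$ffpe, pf$frozen, pf$pairs)
}
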