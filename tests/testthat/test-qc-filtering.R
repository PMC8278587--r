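test_that("filter_technical removes exactly the flagged calls", {
  vt <- do.call(vtable, c(
    lapply(1:7, function(i) vrow(pos = i)),
    lapply(8:10, function(i) vrow(pos = i, technical_flags = "strand_bias"))
  ))
  out <- filter_technical(vt)
  expect_identical(nrow(out), 7L)
  expect_true(all(out$technical_flags == ""))
})

test_that("call_genotype bins AAF with inclusive endpoints", {
  expect_identical(call_genotype(c(0, 0.2, 0.5, 0.4, 0.6, 0.8, 1.0, 0.3,
                                   0.7, 0.79)),
                   c("hom_ref", "hom_ref", "het", "het", "het", "hom_alt",
                     "hom_alt", "no_call", "no_call", "no_call"))
  expect_error(call_genotype(1.2))
  expect_error(call_genotype(-0.1))
})

test_that("sample_qc fails on low UMT coverage or low SNP call rate", {
  snps <- data.frame(chrom = "panel", pos = 1:20, ref = "C", alt = "T",
                     stringsAsFactors = FALSE)
  ## sample B has 5 of 20 SNPs observed at a no-call AAF -> rate 0.75
  variants <- do.call(vtable, c(
    lapply(1:5, function(i) vrow(sample_id = "B", pos = i, aaf = 0.3)),
    list(vrow(sample_id = "A", pos = 1L, aaf = 0.5),
         vrow(sample_id = "C", pos = 1L, aaf = 0.5))
  ))
  samples <- data.frame(
    sample_id = c("A", "B", "C"),
    mean_umt_coverage = c(19.5, 100, 100),
    stringsAsFactors = FALSE
  )
  out <- sample_qc(samples, snps, variants)
  expect_identical(out$qc_pass, c(FALSE, FALSE, TRUE))
  expect_match(out$qc_fail_reason[1], "low_umt_coverage")
  expect_match(out$qc_fail_reason[2], "low_snp_call_rate")
  expect_equal(out$snp_call_rate, c(1, 0.75, 1))
})

test_that("replicate_identity separates identical, reversed, and constant profiles", {
  m <- rbind(a = c(0.1, 0.5, 0.9, 0.3, 0.7),
             b = c(0.1, 0.5, 0.9, 0.3, 0.7),
             c = c(0.9, 0.3, 0.1, 0.7, 0.2),
             d = rep(0.5, 5))
  expect_warning(out <- replicate_identity(m), "constant")
  expect_equal(out$correlation["a", "b"], 1)
  expect_true(out$same_source["a", "b"])
  expect_equal(out$correlation["c", "a"],
               stats::cor(m["c", ], m["a", ], method = "spearman"))
  ## a vector against its reverse-ranked counterpart correlates at -1
  rev_pair <- rbind(x = c(0.1, 0.3, 0.5, 0.7, 0.9),
                    y = c(0.9, 0.7, 0.5, 0.3, 0.1))
  out_rev <- replicate_identity(rev_pair)
  expect_equal(out_rev$correlation["x", "y"], -1)
  expect_false(out_rev$same_source["x", "y"])
  expect_true(is.na(out$correlation["d", "a"]) ||
                !isTRUE(out$same_source["d", "a"]))
  expect_error(replicate_identity(m[1, , drop = FALSE]))
})

test_that("estimate_fdr computes the FFPE-only fraction per category", {
  ## 10 FFPE C>A calls, 3 absent from the frozen pair -> FDR 0.30
  mk <- function(sample, pos) {
    vrow(sample_id = sample, pos = pos, ref = "C", alt = "A",
         context = "TCT", aaf = 0.3)
  }
  ffpe <- do.call(vtable, lapply(1:10, function(i) mk("p1_F", i)))
  frozen <- do.call(vtable, lapply(1:7, function(i) mk("p1_Z", i)))
  pairs <- data.frame(pair_id = "p1", ffpe_sample = "p1_F",
                      frozen_sample = "p1_Z", stringsAsFactors = FALSE)
  fdr <- estimate_fdr(ffpe, frozen, pairs)
  expect_equal(fdr$fdr[fdr$category == "C>A"], 0.3)
  expect_identical(fdr$n_ffpe_calls[fdr$category == "C>A"], 10L)
  ## categories absent from FFPE are missing
  expect_true(is.na(fdr$fdr[fdr$category == "T>G"]))
  ## invariant to pair labels and row order
  fdr2 <- estimate_fdr(ffpe[sample.int(10), ], frozen[sample.int(7), ],
                       pairs)
  expect_equal(fdr2, fdr)
})

test_that("estimate_fdr recovers planted artifact fractions within binomial CIs", {
  cfg <- sim_config(seed = 31, pair_calls_per_category = 600L)
  pf <- generate_paired_ffpe_frozen(cfg)
  fdr <- estimate_fdr(pf$ffpe, pf$frozen, pf$pairs)
  truth <- pf$truth$artifact_fraction_by_category
  z <- vapply(names(truth), function(cat) {
    row <- fdr[fdr$category == cat, ]
    (row$fdr - truth[[cat]]) /
      sqrt(truth[[cat]] * (1 - truth[[cat]]) / row$n_ffpe_calls)
  }, 0)
  ## joint check over 7 binomial cells: family-wise bound plus no gross miss
  expect_gte(sum(abs(z) <= 2.58), 6L)
  expect_true(all(abs(z) <= 4))
})

test_that("AAF filters match hand-derived survivor sets and the classical rsID exception", {
  toy <- toy_filter_table()
  for (strategy in names(toy$survivors)) {
    got <- apply_aaf_filter(toy$variants, strategy)
    expect_identical(sort(got$pos), sort(toy$variants$pos[toy$survivors[[strategy]]]),
                     info = strategy)
  }
  ## spec'd single-variant cases
  ct <- vtable(vrow(ref = "C", alt = "T", context = "ACA", aaf = 0.07))
  expect_identical(nrow(apply_aaf_filter(ct, "classical")), 0L)
  ct_rs <- vtable(vrow(ref = "C", alt = "T", context = "ACA", aaf = 0.07,
                       rsid = "rs123"))
  expect_identical(nrow(apply_aaf_filter(ct_rs, "classical")), 1L)
  ta <- vtable(vrow(ref = "T", alt = "A", context = "ATA", aaf = 0.07))
  expect_identical(nrow(apply_aaf_filter(ta, "classical")), 1L)
  expect_identical(nrow(apply_aaf_filter(ta, "strict")), 0L)
  any04 <- vtable(vrow(ref = "T", alt = "C", context = "ATA", aaf = 0.04))
  expect_identical(nrow(apply_aaf_filter(any04, "liberal")), 0L)
})

test_that("strategies are nested and idempotent on randomized tables", {
  set.seed(42)
  for (i in 1:200) {
    vt <- random_variant_table(25)
    lib <- apply_aaf_filter(vt, "liberal")
    cla <- apply_aaf_filter(vt, "classical")
    str <- apply_aaf_filter(vt, "strict")
    lib_k <- paste(lib$sample_id, site_key(lib))
    cla_k <- paste(cla$sample_id, site_key(cla))
    str_k <- paste(str$sample_id, site_key(str))
    expect_true(all(str_k %in% cla_k))
    expect_true(all(cla_k %in% lib_k))
    expect_identical(apply_aaf_filter(cla, "classical"), cla)
  }
})

test_that("population AF concordance is exact on noiseless genotypes and splits by category", {
  ## cohort of 10 samples; construct calls so cohort AF == population AF
  n <- 10
  rows <- list()
  for (s in 1:4) {  # 4 sites: pop AF 0.2, 0.35, 0.05, 0.45
    af <- c(0.2, 0.35, 0.05, 0.45)[s]
    n_het <- round(2 * n * af)  # put all alt dosage into hets
    refalt <- list(c("C", "T"), c("T", "G"), c("C", "A"), c("T", "C"))[[s]]
    for (i in seq_len(n_het)) {
      rows[[length(rows) + 1L]] <- vrow(
        sample_id = paste0("S", i), pos = s * 10L, ref = refalt[1],
        alt = refalt[2], context = paste0("A", refalt[1], "A"), aaf = 0.5,
        rsid = paste0("rs", s), population_af = af)
    }
  }
  vt <- as_variant_table(do.call(rbind, rows))
  conc <- population_af_concordance(vt, paste0("S", 1:n),
                                    by_category = TRUE)
  expect_equal(unname(conc$overall["correlation"]), 1)
  expect_equal(conc$sites$cohort_af, conc$sites$population_af)
  expect_identical(nrow(conc$by_category),
                   length(unique(conc$sites$category)))
  ## fewer than 3 shared sites -> missing
  few <- population_af_concordance(vt[vt$pos == 10, ], paste0("S", 1:n))
  expect_true(is.na(few$overall["correlation"]))
})

test_that("synthetic germline cohort concordance with population AFs is high", {
  coh <- generate_cohort(sim_config(seed = 17))
  germ_sites <- coh$truth$origin$origin == "germline"
  v <- coh$variants[germ_sites, ]
  prim <- coh$samples$sample_id[coh$samples$is_primary]
  conc <- population_af_concordance(v[v$sample_id %in% prim, ], prim)
  expect_gt(conc$overall[["correlation"]], 0.95)
})
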