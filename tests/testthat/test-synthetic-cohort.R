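test_that("generate_cohort is deterministic given the seed and matches the study group sizes", {
  a <- generate_cohort(sim_config(seed = 7))
  b <- generate_cohort(sim_config(seed = 7))
  expect_identical(a, b)
  prim <- a$samples[a$samples$is_primary, ]
  expect_equal(as.vector(table(prim$group)[c("control", "ER_pos", "ER_neg")]),
               c(42L, 42L, 36L))
  expect_identical(nrow(a$truth$origin), nrow(a$variants))
  expect_true(all(a$truth$origin$origin %in%
                    c("germline", "somatic_true", "ffpe_artifact")))
  c <- generate_cohort(sim_config(seed = 8))
  expect_false(identical(a$variants, c$variants))
})

test_that("germline AAFs land in the intended genotype bin almost always", {
  coh <- generate_cohort(sim_config(seed = 3))
  germ <- coh$variants[coh$truth$origin$origin == "germline", ]
  gt <- call_genotype(germ$aaf)
  ## non-dropout draws follow truncated normals around 0.5 / 0.95; the
  ## injected no-call fraction is the config's nocall_rate (0.04)
  expect_gt(mean(gt %in% c("het", "hom_alt")), 0.94)
  in_bin <- mean(gt[gt != "no_call"] %in% c("het", "hom_alt"))
  expect_gte(in_bin, 0.99)
  expect_true(all(coh$variants$aaf >= 0 & coh$variants$aaf <= 1))
})

test_that("artifact calls are C>T-dominated, low-AAF, and match configured rates", {
  cfg <- sim_config(seed = 21)
  coh <- generate_cohort(cfg)
  art <- coh$variants[coh$truth$origin$origin == "ffpe_artifact", ]
  expect_true(all(art$aaf < 0.2))
  n_prof <- nrow(coh$samples)
  rate_hat <- table(factor(art$category, levels = mutation_categories())) /
    n_prof
  rate_cfg <- cfg$artifact_rate_by_category[mutation_categories()]
  ## Poisson marginal rates within ~4 MC standard errors
  se <- sqrt(rate_cfg / n_prof)
  expect_true(all(abs(rate_hat - rate_cfg) < 4 * se + 1e-9))
  expect_gt(sum(art$category %in% c("C>T", "C>T_at_CpG")) / nrow(art), 0.5)
})

test_that("technical replicates share germline and somatic calls but not artifacts", {
  coh <- generate_cohort(sim_config(seed = 5))
  reps <- coh$samples[!coh$samples$is_primary, ]
  expect_gt(nrow(reps), 0)
  origin <- coh$truth$origin
  for (i in seq_len(nrow(reps))) {
    rep_id <- reps$sample_id[i]
    prim_id <- reps$subject_id[i]
    for (org in c("germline", "somatic_true")) {
      s_rep <- origin$site[origin$sample_id == rep_id & origin$origin == org]
      s_prim <- origin$site[origin$sample_id == prim_id &
                              origin$origin == org]
      expect_setequal(s_rep, s_prim)
    }
    a_rep <- origin$site[origin$sample_id == rep_id &
                           origin$origin == "ffpe_artifact"]
    a_prim <- origin$site[origin$sample_id == prim_id &
                            origin$origin == "ffpe_artifact"]
    expect_lt(length(intersect(a_rep, a_prim)),
              max(1, 0.2 * length(a_rep)))
  }
})

test_that("paired FFPE/frozen sets carry the planted artifact structure", {
  cfg <- sim_config(seed = 13, pair_calls_per_category = 400L)
  pf <- generate_paired_ffpe_frozen(cfg)
  expect_true(all(site_key(pf$frozen) %in% site_key(pf$ffpe)))
  ## artifact rates all zero: FFPE and frozen identical up to AAF noise
  cfg0 <- sim_config(seed = 13, artifact_fraction_by_category =
                       stats::setNames(rep(0, 7), mutation_categories()))
  pf0 <- generate_paired_ffpe_frozen(cfg0)
  expect_identical(nrow(pf0$ffpe), nrow(pf0$frozen))
  expect_setequal(site_key(pf0$ffpe), site_key(pf0$frozen))
  ## seed change: different placements, same marginal artifact fractions
  pf2 <- generate_paired_ffpe_frozen(cfg, seed = 99)
  expect_false(identical(site_key(pf2$ffpe), site_key(pf$ffpe)))
  f1 <- estimate_fdr(pf$ffpe, pf$frozen, pf$pairs)
  f2 <- estimate_fdr(pf2$ffpe, pf2$frozen, pf2$pairs)
  expect_true(all(abs(f1$fdr - f2$fdr) < 4 * sqrt(0.6 * 0.4 / 400) + 1e-9))
})

test_that("signature cohorts draw from the exposure-weighted mixture", {
  profiles <- cbind(sigA = c(0.7, 0.2, 0.1, 0, 0, 0, 0),
                    sigB = c(0, 0, 0, 0, 0.1, 0.2, 0.7))
  rownames(profiles) <- mutation_categories()
  expo <- rbind(c(1, 0), c(0, 1), c(0.5, 0.5), c(1, 0))
  ## single signature, large n: empirical spectrum converges to the profile
  sc <- generate_signature_cohort(profiles[, 1, drop = FALSE],
                                  matrix(1, 4, 1), 50000L, seed = 2)
  emp <- sc$spectrum[1, ] / sum(sc$spectrum[1, ])
  expect_lt(max(abs(emp - profiles[, 1])), 0.01)
  ## zero mutations: zero row
  sc0 <- generate_signature_cohort(profiles, expo, c(100L, 0L, 100L, 100L),
                                   seed = 2)
  expect_true(all(sc0$spectrum[2, ] == 0))
  expect_equal(rowSums(sc0$spectrum), c(100, 0, 100, 100),
               ignore_attr = TRUE)
  expect_error(generate_signature_cohort(profiles, expo[, 1, drop = FALSE],
                                         100L), "disagree")
})
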