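#!/usr/bin/env Rscript
## Label-permutation empirical significance of the two global statistics:
## S1 (number of genes nominally significant in >= 4 of 12 combinations,
## two-sided) and S2 (number of protective genes under weighted logistic x
## classical, one-sided). S1 re-runs all 12 combinations per permutation and
## dominates the runtime.

suppressMessages(library(bbdburden))

n_perm <- 100L
seed <- 20260920L

samples <- read_sample_sheet("results/sample_sheet.tsv")
variants <- read_variants("results/cohort_variants.vcf",
                          "results/cohort_annotation.tsv")
known_snps <- utils::read.delim("results/known_snps.tsv")
fdr <- utils::read.delim("results/fdr_by_category.tsv")
qc <- sample_qc(samples, known_snps, variants)
prim <- qc[qc$is_primary & qc$qc_pass, ]

pt2 <- permutation_test(variants, prim, "s2", n_perm = n_perm, seed = seed,
                        fdr_table = fdr)
cat(sprintf("S2 (protective genes): observed %d, empirical p = %.4f (%d perms)\n",
            pt2$observed, pt2$empirical_p, pt2$n_perm))

pt1 <- permutation_test(variants, prim, "s1", n_perm = n_perm, seed = seed,
                        fdr_table = fdr)
cat(sprintf("S1 (consensus genes >= 4/12): observed %d, empirical p = %.4f\n",
            pt1$observed, pt1$empirical_p))

write_results_tsv(
  data.frame(statistic = c("s1", "s2"),
             observed = c(pt1$observed, pt2$observed),
             empirical_p = c(pt1$empirical_p, pt2$empirical_p),
             n_perm = n_perm, seed = seed),
  "results/permutation_summary.tsv"
)
write_results_tsv(data.frame(perm = seq_len(n_perm), s1 = pt1$null_values,
                             s2 = pt2$null_values),
                  "results/permutation_null_values.tsv")
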