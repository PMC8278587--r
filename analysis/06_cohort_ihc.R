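#!/usr/bin/env Rscript
## Descriptive statistics: the published cohort-characteristic tables (the
## exact in-paper inputs) and, for the simulated cohort, the group
## comparisons, per-sample mutational burden and CD45/Ki67 IHC associations.

suppressMessages(library(bbdburden))

## published tables: Pearson chi-square without continuity correction
tabs <- cohort_characteristic_tables()
tab_stats <- do.call(rbind, lapply(names(tabs), function(nm) {
  r <- pearson_chi_square(tabs[[nm]])
  data.frame(variable = nm, statistic = r$statistic, df = r$df,
             p_value = r$p_value)
}))
write_results_tsv(tab_stats, "results/published_table_stats.tsv")
cat("published cohort tables:\n"); print(tab_stats, digits = 3)

## simulated cohort
samples <- read_sample_sheet("results/sample_sheet.tsv")
variants <- read_variants("results/cohort_variants.vcf",
                          "results/cohort_annotation.tsv")
known_snps <- utils::read.delim("results/known_snps.tsv")
qc <- sample_qc(samples, known_snps, variants)
prim <- qc[qc$is_primary & qc$qc_pass, ]

sim_hist <- table(prim$histology, prim$group)
cat(sprintf("simulated histology-by-group chi-square p = %.3f\n",
            pearson_chi_square(sim_hist)$p_value))
aov_year <- one_way_anova(prim$biopsy_year, prim$group)
cat(sprintf("simulated biopsy-year ANOVA: F = %.2f, p = %.3f\n",
            aov_year$f_statistic, aov_year$p_value))

burdens <- sample_mutational_burden(variants, prim, "classical")
write_results_tsv(data.frame(sample_id = names(burdens), burden = burdens),
                  "results/sample_burden_classical.tsv")
cat(sprintf("burden (classical): median %d, range %d-%d\n",
            as.integer(median(burdens)), min(burdens), max(burdens)))
grp_burden <- tapply(burdens, prim$group, mean)
cat("mean burden by group:", paste(names(grp_burden),
                                   round(grp_burden, 1), sep = "=",
                                   collapse = ", "), "\n")

ihc <- ihc_associations(prim, burdens)
write_results_tsv(ihc$wilcoxon, "results/ihc_wilcoxon.tsv")
write_results_tsv(ihc$spearman, "results/ihc_spearman.tsv")
cat(sprintf("CD45 cases vs controls (Wilcoxon): p = %.3f\n",
            ihc$wilcoxon$p_value[1]))
ov <- ihc$spearman[ihc$spearman$scope == "overall", ]
cat(sprintf("CD45 vs burden (Spearman): rho = %.2f, p = %.2g (n = %d)\n",
            ov$rho, ov$p_value, ov$n))
cat("Ki67 summary (percent positive nuclei):\n")
print(ihc$ki67_summary)
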