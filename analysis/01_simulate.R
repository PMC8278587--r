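#!/usr/bin/env Rscript
## Simulate the study cohort: 42 cancer-free controls, 42 future ER+ and 36
## future ER- cases over a 93-gene panel, with germline SNPs, C>T-dominated
## FFPE artifacts, planted protective burden effects in 10 genes, technical
## replicates, and a paired FFPE/frozen truth set for FDR estimation.
## Writes VCF + annotation + sample sheet + ground truth under results/.

suppressMessages(library(bbdburden))

seed <- 20260920L
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(effect_genes = protective_effect_genes(), seed = seed)
coh <- generate_cohort(cfg)

write_variants(coh$variants, "results/cohort_variants.vcf",
               "results/cohort_annotation.tsv")
write_sample_sheet(coh$samples, "results/sample_sheet.tsv")
write_results_tsv(coh$known_snps, "results/known_snps.tsv")
jsonlite::write_json(coh$truth$origin, "results/ground_truth_origins.json")
jsonlite::write_json(cfg[!vapply(cfg, is.data.frame, TRUE)],
                     "results/simulation_config.json", auto_unbox = TRUE)
write_results_tsv(cfg$effect_genes, "results/planted_effects.tsv")

pf <- generate_paired_ffpe_frozen(cfg)
write_variants(pf$ffpe, "results/paired_ffpe.vcf",
               "results/paired_ffpe_annotation.tsv")
write_variants(pf$frozen, "results/paired_frozen.vcf",
               "results/paired_frozen_annotation.tsv")
write_results_tsv(pf$pairs, "results/paired_key.tsv")

origin <- coh$truth$origin$origin
cat(sprintf(
  "cohort: %d profiles (%d primary), %d variant calls (%d germline, %d somatic, %d artifact)\n",
  nrow(coh$samples), sum(coh$samples$is_primary), nrow(coh$variants),
  sum(origin == "germline"), sum(origin == "somatic_true"),
  sum(origin == "ffpe_artifact")))
cat(sprintf("paired truth set: %d FFPE calls across %d pairs\n",
            nrow(pf$ffpe), nrow(pf$pairs)))
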