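---
title: "Methods: FFPE-aware somatic burden analysis for benign breast disease"
author: "bbdburden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FFPE-aware somatic burden analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(bbdburden)
```

## The scientific problem

Benign breast disease (BBD) biopsies elevate future breast-cancer risk, and
archival formalin-fixed paraffin-embedded (FFPE) blocks are often the only
tissue available decades later. Targeted panel sequencing of such tissue can
ask whether somatic mutation burden in BBD predicts which women later
develop estrogen-receptor-positive (ER+) or -negative (ER−) cancer. The
catch is that formalin fixation deaminates cytosines, producing artifactual
C>T calls at low alternate allele fraction (AAF) that can swamp genuine
somatic variation. This package implements the full analysis chain for that
setting — FFPE-aware variant QC, nested AAF filters, gene-level burden
association under twelve filter-by-method combinations, permutation-based
global significance, mutational-signature extraction, and cohort/IHC
statistics — together with a synthetic cohort generator carrying ground
truth, so every stage is testable without access to protected sequencing
data.

## Data model

The atom is a *variant call*: one sample × site × ALT observation with AAF,
unique-molecular-tag (UMT) depth, optional rsID, gene, functional impact,
population allele frequency, trinucleotide context, and upstream technical
flags. SNVs are classified into seven categories after normalization to the
pyrimidine strand: C>A, C>G, C>T, C>T at CpG, T>A, T>C, T>G; the CpG
subtype is split out because both endogenous deamination at methylated CpGs
and formalin artifacts concentrate there. Indels are carried through
filtering and prioritization (their impact classes include frameshift and
in-frame indels) but have no category: they are excluded from spectra and
take an FDR down-weighting factor of 1. Coordinates are 1-based as in VCF;
multi-allelic records are split per ALT; AAF is read from a configurable
FORMAT key (default `VAF`) or derived from `AD`.

## Quality control and filtering

* **Sample QC.** A sample fails below 20× mean UMT coverage or below an 80%
  SNP genotyping call rate. Genotypes are called from AAF bins with
  inclusive endpoints — [0, 0.2] hom-ref, [0.4, 0.6] het, [0.8, 1.0]
  hom-alt — and anything between bins is a no-call. A known SNP position
  with no call record counts as hom-ref (genotyped): missingness is
  expressed as out-of-bin AAF, which is how degraded loci actually present.
* **Replicate identity.** Spearman correlation of per-sample AAF vectors
  over the known SNPs (absent call = 0); pairs above 0.85 are called
  same-source. In the synthetic cohort, replicates land near 0.97 and
  unrelated pairs near 0.2–0.5; the real-data analogue concentrates
  unrelated pairs around 0.6, still clearly below the threshold. The
  generator was not tuned to reproduce 0.6 exactly — only the separation
  matters for the check.
* **FFPE FDR.** From paired FFPE/fresh-frozen samples, the per-category FDR
  is the fraction of FFPE SNV calls absent from the paired frozen tissue,
  matched on (pair, chrom, pos, ref, alt). An AAF-binned variant is
  available behind `aaf_bins` since only the empirical AAF–FDR relationship
  is specified, not its binning.
* **AAF strategies.** Liberal removes AAF < 0.05; classical removes C>T
  (including the CpG subtype, which inherits the C>T rule) without an rsID
  at AAF < 0.1 and everything else at AAF < 0.05; strict removes AAF < 0.1.
  Thresholds are exclusive; bin endpoints above are inclusive. The rsID
  exception applies only in the classical strategy. Survivors are nested:
  strict ⊆ classical ⊆ liberal.
* **Prioritization.** Sites are removed if population AF > 0.005, if the
  mean AAF over cancer-free controls (0 imputed where a control lacks the
  call, denominator = all controls) exceeds 0.05, or if the impact is
  low. Missing impact retains the site with a warning. The pipeline order
  is technical filter → AAF strategy → prioritization.

## Gene-level association

Each gene is tested per contrast (all cases vs control; ER+ vs control; ER−
vs control) under 3 strategies × 4 methods = 12 combinations:

* **Continuous burden, logistic regression.** The burden is the weighted
  sum of a sample's AAFs over the gene's retained variants; the odds ratio
  is per unit of summed (weighted) AAF, unstandardized — the natural scale
  of the statistic, since no external convention is available for it. The
  p-value is the likelihood-ratio (drop-in-deviance) test of the burden
  term: with most samples at zero burden the Wald statistic suffers the
  Hauck–Donner effect (inflating its own standard error as the estimate
  grows) and rejects far below nominal rate, while the LRT stays close to
  its chi-square reference. The OR keeps a Wald 95% interval. Separation
  or non-convergence flags the cell rather than triggering a silent
  penalized refit, keeping results auditable.
* **Binary presence, SKAT-O.** A logistic null model of case status on the
  covariates is fit once per contrast; the statistic
  $Q_\rho = (1-\rho)\,Q_{\mathrm{SKAT}} + \rho\,Q_{\mathrm{burden}}$ runs
  over $\rho \in \{0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1\}$. Each
  $Q_\rho$ is referred to its mixture-of-$\chi^2_1$ null via Imhof
  characteristic-function inversion (vectorized fixed-grid quadrature with
  truncation set by an envelope bound and a stationary-phase-aware
  cancellation bound; a Liu moment-matching fallback catches pathological
  scales), and the omnibus p of the minimum per-$\rho$ p comes from the
  standard one-dimensional integration over the shared $\chi^2_1$
  direction. A single-variant gene collapses exactly to the
  covariate-adjusted score test. Default SKAT weights are the Beta(1, 25)
  density at the variant's cohort mean AAF (computed over all samples with
  0 for non-carriers) — cohort rather than population frequency, since the
  panel's artifact and somatic sites have no population frequency at all.
* **FDR down-weighting.** The weighted variants of both methods multiply
  each variant's base weight by $1 - \mathrm{FDR}$ of its category. The
  linear factor is chosen for boundedness ([0, w]) and the identity at FDR
  0; only the direction (C>T down-weighted hardest) is externally
  specified.
* **Covariates.** Epithelial percentage, histology indicators, age, biopsy
  year centered at 1992, a post-1992 indicator (an FFPE processing change),
  their interaction, and SNP call rate. Centering at 1992 keeps the
  interaction column numerically tame; aliased columns are dropped with a
  warning.

Untestable cells (gene emptied by a filter, constant burden,
non-convergence) are flagged and count as non-significant downstream.

## Consensus and permutation significance

Per gene, `n_nominal` counts combinations with p < 0.05 (strict); the
protective flag marks p < 0.05 with OR < 1 under weighted logistic ×
classical. Two global statistics get label-permutation empirical p-values:
S1 = number of genes with `n_nominal` ≥ 4 (two-sided, doubled smaller
tail — the two-sided construction on a discrete null is not externally
pinned down, so the doubled-tail convention is used and the raw estimator
is available by flag), and S2 = number of protective genes (one-sided
enrichment). Permutation shuffles the assignment of genomic profiles to
(group label, covariate) records, which preserves the covariate–group
relationship exactly — the only reading that does. The plus-one estimator
$(1 + \#\{null \ge obs\})/(1 + n_{perm})$ avoids zero p at finite
$n_{perm}$. S2 depends only on the weighted-logistic classical slice, so
its permutation replicates recompute just that slice — identical results,
an order of magnitude faster; S1 replicates re-run all 12 combinations.

## Mutational signatures

Per-sample spectra are counted under the seven-category scheme (default;
the 96 trinucleotide-context scheme is available when contexts are
complete). De-novo extraction is multiplicative-update NMF under the
generalized Kullback–Leibler objective (the convention of
mutational-signature tools; Frobenius available by flag), with random
restarts pooled by average-linkage clustering on cosine distance, consensus
signatures as renormalized centroids, stability as mean within-cluster
cosine, and exposures refit by non-negative least squares. The objective is
non-increasing per iteration by construction and asserted numerically in
the tests. Rank selection is by a stability-vs-k report; the bundled
reference catalog under `inst/extdata/` is synthetic (five labelled
profiles for tests and examples) — the 30-profile COSMIC v2 catalog is not
redistributed but can be supplied as a TSV to `read_signature_catalog()`.

## The synthetic cohort generator

Defaults are the study conditions: 42 controls / 42 ER+ / 36 ER− primary
samples, 93 panel genes, 350 known germline SNPs with population AFs from a
common/rare mixture (30% below the 0.005 prioritization cut, so the filter
has real work), Hardy–Weinberg genotypes with truncated-normal AAF noise
(SD 0.03) around 0.5/0.95, a 4% per-observation rate of out-of-bin AAFs
emulating degraded loci, FFPE artifacts at C>T-dominated Poisson rates
(~19 calls/sample, 72% C>T or C>T-at-CpG) with Beta(1.2, 6)-distributed
AAF rescaled to (0, 0.2) — a generative law chosen so the three filter
strategies bite differently, since no empirical law is specified — true
somatic calls at 0.05 per gene per sample with AAF uniform on [0.1, 0.4],
technical replicates of the first three control subjects, and CD45
H-scores generated as 20 + 4 × (somatic + artifact calls at AAF ≥ 0.1)
plus noise, giving a Spearman correlation with burden around 0.5.
Covariate margins (age bands, histology, atrophy, biopsy year) follow the
published cohort table. Planted effects act multiplicatively on the somatic
rate per gene per group; `protective_effect_genes()` plants a
control-to-case rate ratio of 10 in ten genes, set by an a priori power
calculation so that a single combination detects a planted gene with
probability ≈ 0.85–0.9 at these group sizes — recovery experiments then
test the machinery, not borderline power.

What the generator does *not* emulate: read-level errors, mapping
artifacts, copy number, contamination, population structure beyond
independent HWE sites, and linkage between sites. Passing recovery tests
therefore demonstrates correctness of the statistical machinery under the
stated model, not robustness to everything real FFPE data can do.

## Numerical choices and validation design

* Imhof inversion: absolute tolerance ~2 × 10⁻⁶; grid truncation uses the
  smaller of an envelope-integral bound and a van der Corput cancellation
  bound pushed past the phase's stationary point; 24 grid points per
  oscillation period, capped at 2¹⁷ points with an adaptive scalar
  fallback. Values below 10⁻⁸ or above 1 defer to the Liu approximation.
* The SKAT-O omnibus integration is the standard approximation that treats
  the shared-burden and residual score components as independent after a
  variance correction; validated against Monte-Carlo sampling of its own
  multivariate-normal null, it is accurate to about 0.005–0.02 depending
  on geometry. At n = 60 with sparse binary genotype columns the *exact*
  permutation null differs from any continuous asymptotic approximation by
  up to several hundredths in p (discreteness plus CLT error at ~15
  carriers per variant); the acceptance suite measures this gap against a
  100,000-draw permutation oracle, and the unit suite separately verifies
  the implementation under its own asymptotic null, where agreement is
  within Monte-Carlo error of the approximation's accuracy.
* The permutation oracle permutes outcomes directly when no covariates are
  present and permutes null-model residuals (Freedman–Lane under the
  reduced model) otherwise; oracle covariates are simulated independent of
  the outcome, making either scheme a valid null draw.
* Problem sizes in the test suite: type-I calibration pools 50 seeded null
  cohorts at the default design; effect recovery uses 10 seeded cohorts
  with 100 permutations each; the SKAT-O oracle uses 20 instances at
  n = 60 with 100,000 draws; NMF recovery uses 100 samples × 2,000
  mutations.

## Type-I calibration at the study's sparsity

Pooling 50 seeded null cohorts (93 genes each), the logistic LRT rejects
at 0.027–0.062 across the three filter strategies and asymptotic SKAT-O at
0.031–0.035, against a nominal 0.05. The driver is sparsity: a typical
gene retains about six variant sites, most carried by a single sample, and
no continuous asymptotic null is exact there — SKAT-O's mixture null is
mildly conservative for near-singleton presence matrices (the situation
the rare-variant literature's small-sample corrections address; a
variance-only moment correction was evaluated and rejected here because it
overcorrects the tail without joint kurtosis matching). This is the same
finite-sample phenomenon the permutation oracle comparison quantifies, and
it is why the study design bases its global conclusions on
label-permutation empirical p-values, which are exact by construction,
rather than on per-gene asymptotic p-values.

## Known limitations

* The OR scale for continuous burden is per unit summed AAF; magnitudes
  are not comparable across genes with different variant counts.
* The analytic SKAT-O p is asymptotic; at these sample sizes its exact
  permutation calibration is approximate (see above), which is precisely
  why the study's global inference rests on label permutation rather than
  on the per-gene asymptotic p-values.
* Signature extraction on seven categories has limited resolution; the
  96-context scheme is available but the synthetic generator plants
  category-level, not context-level, structure.
* The in-paper gene-specific results (per-gene p-values and ORs) require
  the original sequencing data and are out of scope; the package
  reproduces the published cohort-table statistics exactly and validates
  everything else by property-based recovery on synthetic ground truth.
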