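#' Prioritize variants for gene-level association
#'
#' Removes sites, with a removal ledger, that are unlikely to be informative
#' somatic events:
#' (a) common in reference populations — population AF > `pop_maf_cut`;
#' (b) common among the cohort's cancer-free controls — mean AAF across
#'     control samples (0 imputed where the control lacks the call)
#'     > `control_vmf_cut`;
#' (c) annotated as low functional impact.
#' Rules act on sites (`chrom:pos:ref:alt`); all sample-level calls at a
#' removed site are dropped. Sites with missing impact are retained with a
#' warning.
#'
#' @param variants Variant table (post technical / AAF filtering).
#' @param control_sample_ids Character vector of control sample ids (the
#'   denominator of the control mean AAF).
#' @param pop_maf_cut Population-frequency cut (default 0.005, i.e. 0.5%).
#' @param control_vmf_cut Control mean-AAF cut (default 0.05).
#' @return List with `variants` (retained calls) and `ledger` (one row per
#'   removed site with logical columns `rule_population_af`,
#'   `rule_control_common`, `rule_low_impact`).
#' @export
prioritize <- function(variants, control_sample_ids,
                       pop_maf_cut = 0.005, control_vmf_cut = 0.05) {
  if (length(control_sample_ids) == 0L) stop("control set must be nonempty")
  key <- site_key(variants)
  usites <- !duplicated(key)
  ukey <- key[usites]

  pop_af <- variants$population_af[usites]
  rule_a <- !is.na(pop_af) & pop_af > pop_maf_cut

  in_ctrl <- variants$sample_id %in% control_sample_ids
  ctrl_sum <- tapply(variants$aaf[in_ctrl],
                     factor(key[in_ctrl], levels = ukey), sum)
  ctrl_mean <- ifelse(is.na(ctrl_sum), 0, ctrl_sum) /
    length(unique(control_sample_ids))
  rule_b <- ctrl_mean > control_vmf_cut

  impact <- variants$impact[usites]
  if (anyNA(impact)) {
    warning(sum(is.na(impact)), " site(s) with missing impact retained")
  }
  rule_c <- !is.na(impact) & impact == "low_impact"

  removed <- rule_a | rule_b | rule_c
  ledger <- data.frame(
    site = ukey[removed],
    rule_population_af = rule_a[removed],
    rule_control_common = rule_b[removed],
    rule_low_impact = rule_c[removed],
    stringsAsFactors = FALSE
  )
  keep <- !(key %in% ukey[removed])
  list(variants = variants[keep, , drop = FALSE], ledger = ledger)
}
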