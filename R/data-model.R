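#' @keywords internal
"_PACKAGE"

## Column layout of a variant table: one row per sample x site x ALT call.
VARIANT_COLUMNS <- c(
  "sample_id", "chrom", "pos", "ref", "alt", "aaf", "umt_depth", "rsid",
  "gene", "impact", "population_af", "context", "technical_flags", "category"
)

#' The seven single-nucleotide mutation categories
#'
#' Pyrimidine-strand substitution labels used throughout the pipeline:
#' `C>A`, `C>G`, `C>T`, `C>T_at_CpG`, `T>A`, `T>C`, `T>G`. `C>T` calls whose
#' (strand-normalized) 3' neighbour is G form the separate CpG category,
#' reflecting both spontaneous deamination at methylated CpG sites and the
#' formalin-induced deamination artifacts that dominate FFPE variant calls.
#'
#' @return Character vector of the seven category labels.
#' @export
mutation_categories <- function() {
  c("C>A", "C>G", "C>T", "C>T_at_CpG", "T>A", "T>C", "T>G")
}

#' Controlled vocabulary of functional-impact labels
#'
#' Medium/high-impact labels plus `low_impact`; everything except
#' `low_impact` is retained by [prioritize()].
#'
#' @return Character vector of impact labels.
#' @export
impact_classes <- function() {
  c("essential_splice", "stop_gain", "frameshift", "nonsynonymous",
    "inframe_indel", "start_codon", "stop_loss", "exon_end", "low_impact")
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of A/C/G/T strings.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACG")  # "CGT"
revcomp <- function(x) {
  comp <- chartr("ACGTacgt", "TGCAtgca", x)
  vapply(strsplit(comp, ""), function(s) paste(rev(s), collapse = ""), "")
}

is_snv <- function(ref, alt) {
  nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
}

#' Classify an SNV into one of the seven mutation categories
#'
#' Substitutions with a purine reference (A or G) are reverse-complemented to
#' the pyrimidine strand before labelling, so e.g. G>A in context `CGT`
#' becomes C>T in context `ACG` and is labelled `C>T_at_CpG`. The context is
#' the trinucleotide centred on the variant position; its middle base must
#' equal the reference allele.
#'
#' @param ref,alt Single-base reference and alternate alleles (vectorized).
#' @param context Trinucleotide reference context centred on the position.
#' @return Character vector of category labels (see [mutation_categories()]).
#' @export
#' @examples
#' classify_mutation("C", "T", "ACG")  # "C>T_at_CpG"
#' classify_mutation("G", "A", "CGT")  # "C>T_at_CpG" (reverse complement)
classify_mutation <- function(ref, alt, context) {
  n <- max(length(ref), length(alt), length(context))
  ref <- rep_len(toupper(ref), n)
  alt <- rep_len(toupper(alt), n)
  context <- rep_len(toupper(context), n)
  if (!all(is_snv(ref, alt))) {
    stop("classify_mutation() requires single-base A/C/G/T ref and alt")
  }
  if (any(ref == alt)) stop("ref and alt must differ")
  if (any(nchar(context) != 3L)) stop("context must be a trinucleotide")
  if (any(substr(context, 2L, 2L) != ref)) {
    stop("context middle base must equal ref")
  }
  flip <- ref %in% c("A", "G")
  ref[flip] <- chartr("AG", "TC", ref[flip])
  alt[flip] <- chartr("ACGT", "TGCA", alt[flip])
  context[flip] <- revcomp(context[flip])
  out <- paste0(ref, ">", alt)
  out[out == "C>T" & substr(context, 3L, 3L) == "G"] <- "C>T_at_CpG"
  out
}

#' Molecular diversity score
#'
#' The proportion of unique-molecular-tag (consensus) coverage relative to
#' raw read coverage, on a 0-100 scale: `100 * mt / raw`. Low values indicate
#' heavy PCR duplication, typical of degraded FFPE input.
#'
#' @param mt_coverage Mean molecular-tag (UMT) coverage.
#' @param raw_coverage Mean raw read coverage; must be positive for a
#'   defined score.
#' @return Numeric score in \[0, 100\]; `NA` where `raw_coverage` is 0.
#' @export
molecular_diversity <- function(mt_coverage, raw_coverage) {
  if (any(mt_coverage < 0, na.rm = TRUE)) stop("mt_coverage must be >= 0")
  if (any(mt_coverage > raw_coverage, na.rm = TRUE)) {
    stop("mt_coverage cannot exceed raw_coverage")
  }
  out <- 100 * mt_coverage / raw_coverage
  out[raw_coverage == 0] <- NA_real_
  out
}

#' Validate (and complete) a variant table
#'
#' Checks the column layout and invariants of a variant table and derives the
#' `category` column for SNVs where missing. Indels get `category = NA` and
#' are excluded from spectra and category-specific FDR weighting downstream.
#'
#' @param variants A data.frame with the variant-table columns (see Details).
#' @return The validated data.frame with `category` populated for SNVs.
#' @details Required columns: `sample_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `aaf`, `umt_depth`, `rsid`, `gene`, `impact`, `population_af`,
#'   `context`, `technical_flags`, `category`. `technical_flags` is a
#'   comma-separated string, `""` when clean.
#' @export
as_variant_table <- function(variants) {
  stopifnot(is.data.frame(variants))
  for (col in setdiff(VARIANT_COLUMNS, names(variants))) {
    variants[[col]] <- if (col %in% c("aaf", "population_af")) {
      NA_real_
    } else if (col %in% c("pos", "umt_depth")) {
      NA_integer_
    } else if (col == "technical_flags") "" else NA_character_
  }
  variants <- variants[, VARIANT_COLUMNS]
  if (any(variants$aaf < 0 | variants$aaf > 1, na.rm = TRUE)) {
    stop("aaf must lie in [0, 1]")
  }
  if (any(variants$umt_depth < 0, na.rm = TRUE)) stop("umt_depth must be >= 0")
  snv <- is_snv(variants$ref, variants$alt)
  need <- snv & is.na(variants$category) & !is.na(variants$context)
  if (any(need)) {
    variants$category[need] <- classify_mutation(
      variants$ref[need], variants$alt[need], variants$context[need]
    )
  }
  variants$category[!snv] <- NA_character_
  variants
}

#' Site keys for a variant table
#'
#' @param variants Variant table.
#' @return Character vector `chrom:pos:ref:alt`, one per row.
#' @export
site_key <- function(variants) {
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
}
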