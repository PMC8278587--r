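#' Read variant calls from VCF plus an annotation table
#'
#' Reads a VCF (v4.2) and a tab-separated annotation table keyed by
#' `(chrom, pos, ref, alt)` that supplies `gene`, `impact`, `population_af`
#' and `context`, and returns one variant-table row per sample x ALT call.
#' A call exists for a sample at a site when its alternate-allele-fraction
#' FORMAT value is non-missing. Multi-allelic records are split into one row
#' per ALT allele. Records with `ALT = "."` carry no variant and are skipped
#' with a warning.
#'
#' @param vcf_path Path to a VCF file (plain text or bgzipped).
#' @param annotation_path Path to the annotation TSV; `NULL` to skip
#'   annotation (gene/impact/population_af/context left `NA`).
#' @param aaf_field FORMAT key holding the alternate allele fraction
#'   (default `"VAF"`). If the key is absent the AAF is computed from the
#'   `AD` field as `alt / (ref + alt)`.
#' @param depth_field FORMAT key holding the unique-molecular-tag depth
#'   (default `"DP"`).
#' @param flags_field FORMAT key holding comma-separated technical failure
#'   flags (default `"TF"`); absent key means no flags.
#' @return A variant table (see [as_variant_table()]).
#' @export
read_variants <- function(vcf_path, annotation_path = NULL,
                          aaf_field = "VAF", depth_field = "DP",
                          flags_field = "TF") {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("VCF contains no records: ", vcf_path)
  samples <- colnames(vcf@gt)[-1]

  no_alt <- is.na(fix$ALT) | fix$ALT == "."
  if (any(no_alt)) {
    warning(sum(no_alt), " record(s) with ALT='.' skipped")
  }

  meta_ids <- tryCatch(vcfR::vcf_field_names(vcf, tag = "FORMAT")$ID,
                       error = function(e) character(0))
  gt_field <- function(key) {
    if (key %in% meta_ids ||
        any(grepl(paste0("(^|:)", key, "(:|$)"), vcf@gt[, "FORMAT"]))) {
      vcfR::extract.gt(vcf, element = key, as.numeric = FALSE)
    } else {
      NULL
    }
  }
  aaf_raw <- gt_field(aaf_field)
  ad_raw <- if (is.null(aaf_raw)) gt_field("AD") else NULL
  if (is.null(aaf_raw) && is.null(ad_raw)) {
    stop("neither FORMAT/", aaf_field, " nor FORMAT/AD present in ", vcf_path)
  }
  dp_raw <- gt_field(depth_field)
  tf_raw <- gt_field(flags_field)

  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    if (no_alt[i]) next
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    for (a in seq_along(alts)) {
      pick <- function(m) {
        if (is.null(m)) return(rep(NA_character_, length(samples)))
        v <- m[i, ]
        # per-ALT comma lists are indexed by allele
        vapply(strsplit(ifelse(is.na(v), "", v), ",", fixed = TRUE),
               function(p) if (length(p) >= a) p[a] else
                 if (length(p) >= 1L) p[1L] else NA_character_,
               NA_character_)
      }
      if (!is.null(aaf_raw)) {
        aaf <- suppressWarnings(as.numeric(pick(aaf_raw)))
      } else {
        ad <- m_ad <- ad_raw[i, ]
        aaf <- vapply(strsplit(ifelse(is.na(m_ad), "", m_ad), ",",
                               fixed = TRUE), function(p) {
          if (length(p) < a + 1L) return(NA_real_)
          cnt <- suppressWarnings(as.numeric(p))
          tot <- cnt[1L] + cnt[a + 1L]
          if (is.na(tot) || tot == 0) NA_real_ else cnt[a + 1L] / tot
        }, NA_real_)
      }
      present <- !is.na(aaf)
      if (!any(present)) next
      dp <- suppressWarnings(as.integer(pick(dp_raw)))
      tf <- pick(tf_raw)
      tf[is.na(tf) | tf == "."] <- ""
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = samples[present],
        chrom = fix$CHROM[i],
        pos = as.integer(fix$POS[i]),
        ref = fix$REF[i],
        alt = alts[a],
        aaf = aaf[present],
        umt_depth = dp[present],
        rsid = if (is.na(fix$ID[i]) || fix$ID[i] == ".") NA_character_ else fix$ID[i],
        technical_flags = tf[present],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) stop("no variant calls found in ", vcf_path)

  out$gene <- NA_character_
  out$impact <- NA_character_
  out$population_af <- NA_real_
  out$context <- NA_character_
  if (!is.null(annotation_path)) {
    ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE,
                             colClasses = "character")
    needed <- c("chrom", "pos", "ref", "alt")
    if (!all(needed %in% names(ann))) {
      stop("annotation table must have columns chrom, pos, ref, alt")
    }
    akey <- paste(ann$chrom, ann$pos, ann$ref, ann$alt, sep = ":")
    if (anyDuplicated(akey)) {
      stop("annotation key collision at ",
           paste(unique(akey[duplicated(akey)]), collapse = ", "))
    }
    idx <- match(paste(out$chrom, out$pos, out$ref, out$alt, sep = ":"), akey)
    hit <- !is.na(idx)
    if ("gene" %in% names(ann)) out$gene[hit] <- ann$gene[idx[hit]]
    if ("impact" %in% names(ann)) out$impact[hit] <- ann$impact[idx[hit]]
    if ("population_af" %in% names(ann)) {
      out$population_af[hit] <- as.numeric(ann$population_af[idx[hit]])
    }
    if ("context" %in% names(ann)) out$context[hit] <- ann$context[idx[hit]]
    out$population_af[out$population_af %in% ""] <- NA_real_
    for (col in c("gene", "impact", "context")) {
      out[[col]][out[[col]] %in% ""] <- NA_character_
    }
  }
  out$category <- NA_character_
  as_variant_table(out)
}

#' Write a variant table as VCF plus an annotation table
#'
#' Serializes a variant table to a VCF v4.2 file (one record per site, one
#' column per sample; FORMAT fields `VAF` = alternate allele fraction,
#' `DP` = UMT depth, `TF` = technical flags) and a companion annotation TSV
#' holding the site-level gene / impact / population AF / context columns.
#' [read_variants()] on the two files reproduces the table.
#'
#' @param variants Variant table.
#' @param vcf_path Output VCF path.
#' @param annotation_path Output annotation TSV path.
#' @return Invisibly, the two paths.
#' @export
write_variants <- function(variants, vcf_path, annotation_path) {
  variants <- as_variant_table(variants)
  samples <- sort(unique(variants$sample_id))
  key <- site_key(variants)
  sites <- variants[!duplicated(key), c("chrom", "pos", "ref", "alt", "rsid",
                                        "gene", "impact", "population_af",
                                        "context")]
  skey <- site_key(sites)
  ord <- order(sites$chrom, sites$pos, sites$ref, sites$alt)
  sites <- sites[ord, ]
  skey <- skey[ord]

  fmt_num <- function(x) ifelse(is.na(x), ".", format(x, digits = 15,
                                                      trim = TRUE,
                                                      scientific = FALSE))
  gt <- matrix(".:.:.", nrow = nrow(sites), ncol = length(samples),
               dimnames = list(NULL, samples))
  ri <- match(key, skey)
  ci <- match(variants$sample_id, samples)
  gt[cbind(ri, ci)] <- paste(
    fmt_num(variants$aaf),
    ifelse(is.na(variants$umt_depth), ".", variants$umt_depth),
    ifelse(variants$technical_flags == "", ".", variants$technical_flags),
    sep = ":"
  )

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=bbdburden",
    "##FORMAT=<ID=VAF,Number=1,Type=Float,Description=\"Alternate allele fraction\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Unique molecular tag depth\">",
    "##FORMAT=<ID=TF,Number=1,Type=String,Description=\"Technical failure flags, comma separated\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- paste(sites$chrom, sites$pos,
                ifelse(is.na(sites$rsid), ".", sites$rsid),
                sites$ref, sites$alt, ".", "PASS", ".", "VAF:DP:TF",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), vcf_path)

  ann <- sites[, c("chrom", "pos", "ref", "alt", "gene", "impact",
                   "population_af", "context")]
  ann$population_af <- fmt_num(ann$population_af)
  ann$population_af[ann$population_af == "."] <- ""
  utils::write.table(ann, annotation_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(c(vcf_path, annotation_path))
}

#' Read or write a sample sheet
#'
#' The sample sheet is a TSV with one row per sequenced sample: `sample_id`,
#' `group` (control / ER_pos / ER_neg), covariates (`age`, `histology`,
#' `atrophy`, `epithelial_pct`, `biopsy_year`), coverage QC metrics
#' (`mean_umt_coverage`, `mean_raw_coverage`, `molecular_diversity`,
#' `snp_call_rate`), optional `replicate_set`, and optional IHC scores
#' (`cd45_hscore`, `ki67_pct`).
#'
#' @param path File path.
#' @return A data.frame of sample records.
#' @export
read_sample_sheet <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_sample_sheet
#' @param samples Sample-record data.frame to write.
#' @export
write_sample_sheet <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Write a results table as TSV
#'
#' @param x Data.frame of results.
#' @param path Output path.
#' @export
write_results_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a signature reference catalog
#'
#' A reference catalog is a TSV with a `category` column followed by one
#' column per reference profile; profiles are renormalized to sum to one.
#'
#' @param path Path to the catalog TSV.
#' @return Matrix categories x profiles, columns summing to 1.
#' @export
read_signature_catalog <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"category" %in% names(tab)) stop("catalog needs a 'category' column")
  m <- as.matrix(tab[, setdiff(names(tab), "category"), drop = FALSE])
  rownames(m) <- tab$category
  if (any(m < 0)) stop("catalog profiles must be non-negative")
  sweep(m, 2, colSums(m), "/")
}
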