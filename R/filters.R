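#' Somatic filter for a tumor with matched normal
#'
#' A candidate passes when every clause holds: tumor depth >= `min_depth`,
#' normal depth >= `min_depth`, tumor VAF strictly > `tumor_vaf_min`,
#' normal VAF strictly < `normal_vaf_max`, and tumor VAF minus normal VAF
#' strictly > `vaf_diff_min`. Every failed clause is reported as a
#' machine-readable reason code.
#'
#' @param v Variant record with populated normal fields
#'   (see [mt_variant_record()]).
#' @param p [analysis_params()].
#' @return A `filter_decision`: list with `passed` (logical) and `reasons`
#'   (character vector of failure codes, empty iff passed).
#' @examples
#' p <- analysis_params()
#' v <- mt_variant_record("T1", 3745, "G", "A", 0.5, 20,
#'                        normal_vaf = 0, normal_depth = 20)
#' filter_matched(v, p)$passed
#' @export
filter_matched <- function(v, p = analysis_params()) {
  v <- as_record(v)
  p <- as_analysis_params(p)
  if (!has_matched_normal(v))
    stop_input("record has no matched normal; use filter_unmatched()")
  reasons <- character(0)
  if (!(v$tumor_depth >= p$min_depth))  reasons <- c(reasons, "LOW_DEPTH_TUMOR")
  if (!(v$normal_depth >= p$min_depth)) reasons <- c(reasons, "LOW_DEPTH_NORMAL")
  if (!(v$tumor_vaf > p$tumor_vaf_min)) reasons <- c(reasons, "LOW_TUMOR_VAF")
  if (!(v$normal_vaf < p$normal_vaf_max)) reasons <- c(reasons, "HIGH_NORMAL_VAF")
  if (!(v$tumor_vaf - v$normal_vaf > p$vaf_diff_min))
    reasons <- c(reasons, "LOW_VAF_DIFF")
  filter_decision(reasons)
}

#' Somatic filter for a tumor without matched normal
#'
#' Without a normal to subtract, only clearly pathogenic calls are
#' reported: the candidate passes when tumor depth >= `min_depth` and it
#' is either a loss-of-function (disruptive) variant or on the whitelist
#' of known pathogenic alleles. The default whitelist holds the MELAS
#' tRNA variant m.3244G>A only; study-specific additions are supplied by
#' the caller.
#'
#' @param v Variant record with `has_matched_normal(v)` false and effect
#'   fields populated (see [annotate_variants()]).
#' @param whitelist Data frame with columns `position`, `ref`, `alt`.
#' @param p [analysis_params()].
#' @return A `filter_decision` (see [filter_matched()]); failure codes are
#'   `LOW_DEPTH_TUMOR` and `NOT_LOF_UNMATCHED`.
#' @export
filter_unmatched <- function(v, whitelist = default_whitelist(),
                             p = analysis_params()) {
  v <- as_record(v)
  p <- as_analysis_params(p)
  if (has_matched_normal(v))
    stop_input("record has a matched normal; use filter_matched()")
  if (is.null(v$is_disruptive) || is.na(v$is_disruptive))
    stop_input("effect classification required before unmatched filtering; ",
               "run annotate_variants() first")
  reasons <- character(0)
  if (!(v$tumor_depth >= p$min_depth)) reasons <- c(reasons, "LOW_DEPTH_TUMOR")
  whitelisted <- any(whitelist$position == v$position &
                       whitelist$ref == v$ref & whitelist$alt == v$alt)
  if (!(isTRUE(v$is_disruptive) || whitelisted))
    reasons <- c(reasons, "NOT_LOF_UNMATCHED")
  filter_decision(reasons)
}

#' @rdname filter_unmatched
#' @export
default_whitelist <- function() {
  data.frame(position = 3244L, ref = "G", alt = "A", stringsAsFactors = FALSE)
}

#' @noRd
filter_decision <- function(reasons) {
  structure(list(passed = length(reasons) == 0L, reasons = reasons),
            class = "filter_decision")
}

#' @export
print.filter_decision <- function(x, ...) {
  if (x$passed) cat("PASS\n")
  else cat("FAIL:", paste(x$reasons, collapse = ", "), "\n")
  invisible(x)
}

#' Apply the somatic filters to a variant table
#'
#' Dispatches each record to [filter_matched()] or [filter_unmatched()]
#' depending on whether its normal fields are populated, and returns the
#' table with `passed` and `filter_reasons` columns appended. Records
#' without a matched normal must be annotated first.
#'
#' @param variants Variant data frame.
#' @param whitelist Whitelist for the unmatched rule.
#' @param p [analysis_params()].
#' @param verbose Log each decision (one line per variant) to `message()`.
#' @return The data frame with `passed` (logical) and `filter_reasons`
#'   (comma-separated codes) columns.
#' @export
apply_somatic_filters <- function(variants, whitelist = default_whitelist(),
                                  p = analysis_params(), verbose = FALSE) {
  p <- as_analysis_params(p)
  decisions <- lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, , drop = FALSE]
    if (has_matched_normal(v)) filter_matched(v, p)
    else filter_unmatched(v, whitelist, p)
  })
  variants$passed <- vapply(decisions, `[[`, logical(1), "passed")
  variants$filter_reasons <- vapply(decisions, function(d)
    paste(d$reasons, collapse = ","), character(1))
  if (verbose && nrow(variants))
    for (i in seq_len(nrow(variants)))
      message(sprintf("[filter] %s m.%d %s>%s: %s%s",
                      variants$sample_id[i], variants$position[i],
                      variants$ref[i], variants$alt[i],
                      if (variants$passed[i]) "PASS" else "FAIL",
                      if (nzchar(variants$filter_reasons[i]))
                        paste0(" (", variants$filter_reasons[i], ")") else ""))
  variants
}

#' Validate a variant call against an RNA-seq pileup
#'
#' A DNA call is validated when the RNA-seq heteroplasmy at the position
#' is strictly greater than `rna_validation_min` (default 10%). With zero
#' RNA depth the call is not assessable, which is distinct from failing.
#'
#' @param v Variant record.
#' @param rna_col [pileup_column()] from RNA-seq at the same position.
#' @param p [analysis_params()].
#' @return `"validated"`, `"failed"`, or `"not_assessable"`.
#' @examples
#' v <- mt_variant_record("T1", 3745, "G", "A", 0.6, 1000)
#' validate_rna(v, pileup_column(3745, "G", c(G = 88, A = 12)))  # validated
#' @export
validate_rna <- function(v, rna_col, p = analysis_params()) {
  v <- as_record(v)
  p <- as_analysis_params(p)
  stopifnot(inherits(rna_col, "pileup_column"))
  if (rna_col$position != v$position)
    stop_input("pileup position ", rna_col$position,
               " does not match variant position ", v$position)
  if (sum(rna_col$counts) == 0) return("not_assessable")
  vaf <- vaf_from_pileup(rna_col, allele_key(v$ref, v$alt))
  if (vaf > p$rna_validation_min) "validated" else "failed"
}

#' Cell-line pathogenicity rule
#'
#' For cell lines (no matched normal tissue exists), variants are kept as
#' candidate pathogenic when they are nonsynonymous, have VAF strictly
#' above `cellline_vaf_min` (default 0.1), and are not known haplogroup
#' markers. "Nonsynonymous" here means any non-synonymous, non-intergenic
#' effect (missense, nonsense, frameshift, in-frame indel, tRNA, rRNA);
#' set `protein_only = TRUE` to restrict to protein-altering classes.
#'
#' @param variants Annotated variant data frame ([annotate_variants()]).
#' @param haplogroup_blacklist Data frame with columns `position`, `ref`,
#'   `alt` of haplogroup-defining alleles to exclude; default empty.
#' @param p [analysis_params()].
#' @param protein_only Restrict to missense/nonsense/frameshift/
#'   inframe_indel.
#' @return The rows that pass the rule.
#' @export
call_cellline <- function(variants,
                          haplogroup_blacklist = empty_blacklist(),
                          p = analysis_params(),
                          protein_only = FALSE) {
  p <- as_analysis_params(p)
  if (nrow(variants) == 0L) return(variants)
  if (is.null(variants$effect) || any(is.na(variants$effect)))
    stop_input("effects must be populated; run annotate_variants() first")
  nonsyn <- if (protein_only)
    variants$effect %in% c("missense", "nonsense", "frameshift", "inframe_indel")
  else variants$is_nonsynonymous
  blacklisted <- vapply(seq_len(nrow(variants)), function(i)
    any(haplogroup_blacklist$position == variants$position[i] &
          haplogroup_blacklist$ref == variants$ref[i] &
          haplogroup_blacklist$alt == variants$alt[i]), logical(1))
  keep <- nonsyn & variants$tumor_vaf > p$cellline_vaf_min & !blacklisted
  variants[keep, , drop = FALSE]
}

#' @rdname call_cellline
#' @export
empty_blacklist <- function() {
  data.frame(position = integer(0), ref = character(0), alt = character(0),
             stringsAsFactors = FALSE)
}
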