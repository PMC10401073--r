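#' Analysis thresholds
#'
#' Every numeric threshold used by the somatic filters, RNA validation,
#' cell-line pathogenicity rule, cohort summary, and screen hit calling,
#' collected in one object. All VAF thresholds are compared strictly
#' (`>` / `<`) exactly as stated; read depth is compared inclusively
#' (`>= min_depth`).
#'
#' @param min_depth Minimum read depth in tumor and (when present) matched
#'   normal, inclusive. Default 15 reads.
#' @param tumor_vaf_min Tumor VAF must exceed this (strict). Default 0.3.
#' @param normal_vaf_max Matched-normal VAF must be below this (strict).
#'   Default 0.05.
#' @param vaf_diff_min Tumor VAF minus normal VAF must exceed this (strict).
#'   Default 0.4.
#' @param cohort_vaf_min Cohort summaries count a tumor as altered when it
#'   carries a variant above this VAF (strict). Default 0.20.
#' @param rna_validation_min RNA-seq heteroplasmy must exceed this for a
#'   call to validate (strict). Default 0.10.
#' @param cellline_vaf_min Cell-line pathogenicity rule keeps variants above
#'   this VAF (strict). Default 0.1.
#' @param hit_threshold Screen hits have delta-Z strictly below this.
#'   Default -2.
#' @param reference_day Screen log2 fold-changes are taken relative to this
#'   day post infection. Default 5.
#'
#' @return A list of class `analysis_params`.
#' @examples
#' p <- analysis_params()
#' p$tumor_vaf_min
#' analysis_params(hit_threshold = -1.5)$hit_threshold
#' @export
analysis_params <- function(min_depth = 15,
                            tumor_vaf_min = 0.3,
                            normal_vaf_max = 0.05,
                            vaf_diff_min = 0.4,
                            cohort_vaf_min = 0.20,
                            rna_validation_min = 0.10,
                            cellline_vaf_min = 0.1,
                            hit_threshold = -2,
                            reference_day = 5) {
  if (!is_count(min_depth)) stop_input("min_depth must be a non-negative integer")
  check_fraction(tumor_vaf_min, "tumor_vaf_min")
  check_fraction(normal_vaf_max, "normal_vaf_max")
  check_fraction(vaf_diff_min, "vaf_diff_min")
  check_fraction(cohort_vaf_min, "cohort_vaf_min")
  check_fraction(rna_validation_min, "rna_validation_min")
  check_fraction(cellline_vaf_min, "cellline_vaf_min")
  if (!is.numeric(hit_threshold) || length(hit_threshold) != 1L || is.na(hit_threshold))
    stop_input("hit_threshold must be a single number")
  if (!is_count(reference_day)) stop_input("reference_day must be a non-negative integer")
  structure(list(min_depth = as.integer(min_depth),
                 tumor_vaf_min = tumor_vaf_min,
                 normal_vaf_max = normal_vaf_max,
                 vaf_diff_min = vaf_diff_min,
                 cohort_vaf_min = cohort_vaf_min,
                 rna_validation_min = rna_validation_min,
                 cellline_vaf_min = cellline_vaf_min,
                 hit_threshold = hit_threshold,
                 reference_day = as.integer(reference_day)),
            class = "analysis_params")
}

#' @export
print.analysis_params <- function(x, ...) {
  cat("Analysis parameters:\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# Coerce a plain list (e.g. parsed from a config file) into analysis_params,
# overriding defaults only for keys that are present.
#' @noRd
as_analysis_params <- function(x) {
  if (inherits(x, "analysis_params")) return(x)
  if (is.null(x)) return(analysis_params())
  known <- names(formals(analysis_params))
  bad <- setdiff(names(x), known)
  if (length(bad))
    stop_input("unknown analysis parameter(s): ", paste(bad, collapse = ", "))
  do.call(analysis_params, x)
}
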