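#' Summarize filtered mtDNA calls over a tumor cohort
#'
#' Counts, over tumors (not variants): how many tumors carry any mtDNA
#' alteration above the cohort VAF threshold (strict `> cohort_vaf_min`,
#' default 0.20); how many carry a disruptive (nonsense/frameshift)
#' variant per OXPHOS complex (a tumor with disruptive variants in two
#' complexes counts once in each); how many carry a tRNA-gene variant; and
#' RNA-seq validation tallies when an `rna_status` column is present
#' (`"validated"` / `"failed"` / `"not_assessable"`, see [validate_rna()]).
#'
#' @param variants Annotated, already-filtered variant data frame (the
#'   passed calls). May include an `rna_status` column.
#' @param samples Character vector of all tumor identifiers in the cohort,
#'   including tumors with no passing variant. Defaults to the samples
#'   present in `variants`.
#' @param p [analysis_params()].
#' @param model [mt_gene_model][load_gene_model] (used only to validate
#'   complex labels).
#' @return A list of class `cohort_summary` with `n_tumors`,
#'   `n_with_alteration`, `per_complex` (named integer vector),
#'   `n_with_trna_variant`, `n_rna_validated`, `n_rna_assessed`.
#' @export
summarize_cohort <- function(variants, samples = NULL,
                             p = analysis_params(), model = NULL) {
  p <- as_analysis_params(p)
  if (is.null(samples)) samples <- unique(variants$sample_id)
  samples <- unique(as.character(samples))
  if (nrow(variants)) {
    key <- paste(variants$sample_id, variants$position, variants$ref,
                 variants$alt, sep = "|")
    if (anyDuplicated(key)) {
      dup <- unique(key[duplicated(key)])
      for (k in dup) {
        rows <- variants[key == k, , drop = FALSE]
        if (length(unique(rows$tumor_vaf)) > 1L)
          stop_input("conflicting duplicate records for ", k)
      }
      variants <- variants[!duplicated(key), , drop = FALSE]
    }
    extra <- setdiff(unique(variants$sample_id), samples)
    if (length(extra))
      stop_input("variants reference sample(s) not in cohort: ",
                 paste(extra, collapse = ", "))
  }

  altered <- variants$sample_id[variants$tumor_vaf > p$cohort_vaf_min]
  complexes <- c("CI", "CIII", "CIV", "CV", "tRNA", "rRNA")
  per_complex <- setNames(integer(length(complexes)), complexes)
  if (nrow(variants)) {
    disr <- variants[isTRUE_vec(variants$is_disruptive), , drop = FALSE]
    for (cx in complexes)
      per_complex[cx] <- length(unique(disr$sample_id[!is.na(disr$complex) &
                                                        disr$complex == cx]))
  }
  trna_tumors <- if (nrow(variants))
    unique(variants$sample_id[!is.na(variants$effect) &
                                variants$effect == "tRNA"]) else character(0)

  n_validated <- n_assessed <- 0L
  if (!is.null(variants$rna_status) && nrow(variants)) {
    by_sample <- split(variants$rna_status, variants$sample_id)
    n_assessed <- sum(vapply(by_sample, function(s)
      any(s %in% c("validated", "failed")), logical(1)))
    n_validated <- sum(vapply(by_sample, function(s)
      any(s == "validated"), logical(1)))
  }

  structure(list(n_tumors = length(samples),
                 n_with_alteration = length(unique(altered)),
                 per_complex = per_complex,
                 n_with_trna_variant = length(trna_tumors),
                 n_rna_validated = n_validated,
                 n_rna_assessed = n_assessed),
            class = "cohort_summary")
}

#' @noRd
isTRUE_vec <- function(x) !is.na(x) & x

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d tumors: %d with an mtDNA alteration (%.0f%%)\n",
              x$n_tumors, x$n_with_alteration,
              if (x$n_tumors) 100 * x$n_with_alteration / x$n_tumors else 0))
  cat("tumors with a disruptive variant, by OXPHOS complex:\n")
  for (cx in names(x$per_complex))
    if (x$per_complex[cx] > 0) cat(sprintf("  %-5s %d\n", cx, x$per_complex[cx]))
  cat(sprintf("tumors with a tRNA-gene variant: %d\n", x$n_with_trna_variant))
  if (x$n_rna_assessed > 0)
    cat(sprintf("RNA-seq: %d of %d assessable tumors validated\n",
                x$n_rna_validated, x$n_rna_assessed))
  invisible(x)
}
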