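# Candidate variant records are plain data frames, one row per variant,
# with the documented column schema (see read_variant_table). A "record"
# argument below is a one-row data frame or a named list with the same
# fields.

VARIANT_REQUIRED_COLS <- c("sample_id", "position", "ref", "alt",
                           "tumor_vaf", "tumor_depth")
VARIANT_OPTIONAL_COLS <- c("normal_vaf", "normal_depth", "gene", "effect",
                           "is_disruptive", "is_nonsynonymous")

#' Construct a candidate mtDNA variant record
#'
#' @param sample_id Tumor or cell-line identifier.
#' @param position 1-based rCRS position.
#' @param ref,alt Allele strings over A/C/G/T.
#' @param tumor_vaf Tumor variant allele fraction in \[0, 1\].
#' @param tumor_depth Tumor read depth at the position.
#' @param normal_vaf,normal_depth Matched-normal VAF and depth, or `NA`
#'   when no matched normal exists. Both must be present or both absent.
#' @return A one-row data frame; `has_matched_normal(v)` is `TRUE` when
#'   the normal fields are populated.
#' @examples
#' v <- mt_variant_record("HC024", 3745, "G", "A",
#'                        tumor_vaf = 0.602, tumor_depth = 1000,
#'                        normal_vaf = 0.001, normal_depth = 800)
#' has_matched_normal(v)
#' @export
mt_variant_record <- function(sample_id, position, ref, alt,
                              tumor_vaf, tumor_depth,
                              normal_vaf = NA_real_, normal_depth = NA_real_) {
  check_allele(ref, "ref")
  check_allele(alt, "alt")
  if (!is_count(position) || position < 1 || position > MT_GENOME_LENGTH)
    stop_input("position must be in [1, ", MT_GENOME_LENGTH, "]")
  check_fraction(tumor_vaf, "tumor_vaf")
  if (!is_count(tumor_depth)) stop_input("tumor_depth must be a non-negative integer")
  if (is.na(normal_vaf) != is.na(normal_depth))
    stop_input("normal_vaf and normal_depth must be both present or both absent")
  if (!is.na(normal_vaf)) {
    check_fraction(normal_vaf, "normal_vaf")
    if (!is_count(normal_depth)) stop_input("normal_depth must be a non-negative integer")
  }
  data.frame(sample_id = sample_id, position = as.integer(position),
             ref = ref, alt = alt,
             tumor_vaf = tumor_vaf, tumor_depth = as.integer(tumor_depth),
             normal_vaf = as.numeric(normal_vaf),
             normal_depth = as.integer(normal_depth),
             stringsAsFactors = FALSE)
}

#' @rdname mt_variant_record
#' @param v A variant record.
#' @export
has_matched_normal <- function(v) {
  v <- as_record(v)
  !is.null(v$normal_vaf) && !is.na(v$normal_vaf) &&
    !is.null(v$normal_depth) && !is.na(v$normal_depth)
}

#' @noRd
as_record <- function(v) {
  if (is.data.frame(v)) {
    if (nrow(v) != 1L) stop_input("expected a single variant record")
    v <- as.list(v)
  }
  missing <- setdiff(VARIANT_REQUIRED_COLS, names(v))
  if (length(missing))
    stop_input("variant record missing field(s): ", paste(missing, collapse = ", "))
  v
}

#' Annotate variants with effect, gene and OXPHOS complex
#'
#' Runs [classify_effect()] on every row and appends `gene`, `effect`,
#' `is_disruptive`, `is_nonsynonymous` and `complex` columns.
#'
#' @param variants Variant data frame (see [read_variant_table()]).
#' @param model An [mt_gene_model][load_gene_model].
#' @return The annotated data frame.
#' @export
annotate_variants <- function(variants, model) {
  if (nrow(variants) == 0L) {
    variants[c("gene", "effect")] <- character(0)
    variants[c("is_disruptive", "is_nonsynonymous")] <- logical(0)
    variants$complex <- character(0)
    return(variants)
  }
  effs <- lapply(seq_len(nrow(variants)), function(i)
    classify_effect(variants$position[i], variants$ref[i], variants$alt[i], model))
  variants$gene <- vapply(effs, function(e) e$gene, character(1))
  variants$effect <- vapply(effs, function(e) e$effect, character(1))
  variants$is_disruptive <- vapply(effs, function(e) e$is_disruptive, logical(1))
  variants$is_nonsynonymous <- vapply(effs, function(e) e$is_nonsynonymous, logical(1))
  variants$complex <- vapply(seq_len(nrow(variants)), function(i) {
    g <- variants$gene[i]
    if (is.na(g)) NA_character_ else assign_complex(g, model)
  }, character(1))
  variants
}
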