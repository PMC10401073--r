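#' Construct a pileup column
#'
#' One position of an mpileup-style allele-count table. Allele keys are
#' SNV bases (`"A"`, `"C"`, `"G"`, `"T"`), deletions (`"del:<seq>"`) and
#' insertions (`"ins:<seq>"`) anchored at this base.
#'
#' @param position 1-based position on the mitochondrial genome.
#' @param ref_base Reference base, one of A/C/G/T.
#' @param counts Named non-negative integer vector of per-allele read
#'   counts; total depth is their sum.
#' @return An object of class `pileup_column`.
#' @examples
#' pileup_column(3745, "G", c(G = 398, A = 602))
#' @export
pileup_column <- function(position, ref_base, counts) {
  if (!is_count(position) || position < 1 || position > MT_GENOME_LENGTH)
    stop_input("position must be in [1, ", MT_GENOME_LENGTH, "]")
  if (!ref_base %in% c("A", "C", "G", "T"))
    stop_input("ref_base must be one of A/C/G/T")
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop_input("counts must be a named vector of allele counts")
  if (any(is.na(counts)) || any(counts < 0) || any(counts != trunc(counts)))
    stop_input("counts must be non-negative integers")
  bad <- names(counts)[!grepl("^([ACGT]|del:[ACGT]+|ins:[ACGT]+)$", names(counts))]
  if (length(bad))
    stop_input("invalid allele key(s): ", paste(bad, collapse = ", "))
  structure(list(position = as.integer(position),
                 ref_base = ref_base,
                 counts = counts),
            class = "pileup_column")
}

#' @export
print.pileup_column <- function(x, ...) {
  cat(sprintf("pileup m.%d ref=%s depth=%d: %s\n", x$position, x$ref_base,
              sum(x$counts),
              paste(names(x$counts), x$counts, sep = "=", collapse = " ")))
  invisible(x)
}

#' Variant allele fraction from a pileup column
#'
#' The proportion of reads supporting an alternate allele at one position:
#' `count(alt) / total depth`. An allele key absent from the column counts
#' as zero. This is the heteroplasmy estimate used throughout.
#'
#' @param col A [pileup_column()].
#' @param alt Allele key (`"A"`..`"T"`, `"del:<seq>"`, `"ins:<seq>"`).
#' @return The fraction in \[0, 1\].
#' @examples
#' vaf_from_pileup(pileup_column(3745, "G", c(G = 398, A = 602)), "A") # 0.602
#' @export
vaf_from_pileup <- function(col, alt) {
  stopifnot(inherits(col, "pileup_column"))
  total <- sum(col$counts)
  if (total <= 0)
    stop_input("zero total depth at position ", col$position,
               ": VAF is undefined")
  n_alt <- if (alt %in% names(col$counts)) col$counts[[alt]] else 0
  n_alt / total
}

# Map a variant's ref/alt allele pair onto the pileup allele key for the
# anchor base: SNV -> alt base; VCF-style deletion CA>C -> "del:A";
# insertion C>CA -> "ins:A".
#' @noRd
allele_key <- function(ref, alt) {
  if (nchar(ref) == 1L && nchar(alt) == 1L) return(alt)
  if (nchar(ref) > nchar(alt)) {
    if (substr(ref, 1L, nchar(alt)) != alt)
      stop_input("unsupported allele pair ", ref, ">", alt)
    return(paste0("del:", substr(ref, nchar(alt) + 1L, nchar(ref))))
  }
  if (substr(alt, 1L, nchar(ref)) != ref)
    stop_input("unsupported allele pair ", ref, ">", alt)
  paste0("ins:", substr(alt, nchar(ref) + 1L, nchar(alt)))
}
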