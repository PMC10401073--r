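#' Classify the functional effect of a mitochondrial variant
#'
#' SNVs inside a protein-coding gene are classified by translating the
#' affected codon under the vertebrate mitochondrial code (synonymous,
#' missense, or nonsense for stop-gain; stop-loss is reported as missense).
#' Length-changing variants in protein genes are `frameshift` when the
#' length difference is not a multiple of three, else `inframe_indel`.
#' Positions in tRNA/rRNA genes classify as `tRNA`/`rRNA`; intergenic
#' positions as `noncoding`. Light-strand genes are translated from the
#' reverse complement; incomplete terminal stop codons are A-completed
#' (polyadenylation). Indels use VCF-style anchored alleles, so the bases
#' of `ref` after the first are the deleted ones.
#'
#' A variant overlapping several genes (the mitochondrial genome has
#' overlapping gene pairs, e.g. MT-ATP8/MT-ATP6) is classified against each
#' of them; the reported `effect`/`gene` is the most severe, with severity
#' order nonsense = frameshift > missense > inframe_indel > tRNA = rRNA >
#' synonymous > noncoding. All per-gene classifications are kept in
#' `$details`.
#'
#' @param position 1-based rCRS position of the first `ref` base.
#' @param ref,alt Non-empty allele strings over A/C/G/T; must differ.
#'   Flanking codon bases are taken from the model's reference sequence;
#'   at `position` itself the supplied `ref` base is used.
#' @param model An [mt_gene_model][load_gene_model].
#' @return An object of class `mt_effect`: list with `effect`, `gene`,
#'   `is_disruptive`, `is_nonsynonymous`, and `details` (one row per
#'   overlapped feature, plus a `noncoding` row when nothing overlaps).
#' @examples
#' model <- load_gene_model()
#' classify_effect(3745, "G", "A", model)$effect   # missense in MT-ND1
#' classify_effect(3244, "G", "A", model)$effect   # tRNA (MT-TL1)
#' classify_effect(12417, "CA", "C", model)$effect # frameshift in MT-ND5
#' @export
classify_effect <- function(position, ref, alt, model) {
  stopifnot(inherits(model, "mt_gene_model"))
  check_allele(ref, "ref")
  check_allele(alt, "alt")
  if (identical(ref, alt)) stop_input("ref and alt alleles are identical")
  if (!is_count(position) || position < 1 || position > model$genome_length)
    stop_input("position must be in [1, ", model$genome_length, "]")
  position <- as.integer(position)

  span_end <- wrap_pos(position + nchar(ref) - 1L, model$genome_length)
  f <- model$features
  hit <- vapply(seq_len(nrow(f)), function(i)
    interval_overlaps(position, span_end, f$start[i], f$end[i],
                      model$genome_length), logical(1))
  feats <- f[hit, , drop = FALSE]

  if (nrow(feats) == 0L) {
    details <- data.frame(gene = NA_character_, feature_type = "noncoding",
                          effect = "noncoding", stringsAsFactors = FALSE)
  } else {
    details <- do.call(rbind, lapply(seq_len(nrow(feats)), function(i) {
      feat <- feats[i, ]
      eff <- classify_in_feature(position, ref, alt, feat, model)
      data.frame(gene = feat$name, feature_type = feat$type, effect = eff,
                 stringsAsFactors = FALSE)
    }))
  }
  sev <- effect_severity(details$effect)
  top <- which.max(sev)
  effect <- details$effect[top]
  structure(list(position = position, ref = ref, alt = alt,
                 effect = effect,
                 gene = details$gene[top],
                 is_disruptive = effect %in% c("nonsense", "frameshift"),
                 is_nonsynonymous = !effect %in% c("synonymous", "noncoding"),
                 details = details),
            class = "mt_effect")
}

#' @export
print.mt_effect <- function(x, ...) {
  cat(sprintf("m.%d %s>%s: %s%s%s\n", x$position, x$ref, x$alt, x$effect,
              if (is.na(x$gene)) "" else paste0(" in ", x$gene),
              if (x$is_disruptive) " (disruptive)" else ""))
  if (nrow(x$details) > 1L) {
    cat("overlapping features:\n")
    print(x$details, row.names = FALSE)
  }
  invisible(x)
}

#' Severity rank of effect classes
#'
#' Order used to pick the reported effect for variants overlapping several
#' genes: nonsense = frameshift > missense > inframe_indel > tRNA = rRNA >
#' synonymous > noncoding.
#'
#' @param effect Character vector of effect class names.
#' @return Integer severity ranks (higher is more severe).
#' @export
effect_severity <- function(effect) {
  ranks <- c(noncoding = 0L, synonymous = 1L, tRNA = 2L, rRNA = 2L,
             inframe_indel = 3L, missense = 4L, nonsense = 5L, frameshift = 5L)
  unknown <- setdiff(effect, names(ranks))
  if (length(unknown))
    stop_input("unknown effect class: ", paste(unknown, collapse = ", "))
  unname(ranks[effect])
}

#' @noRd
check_allele <- function(x, name) {
  if (!is.character(x) || length(x) != 1L || is.na(x) ||
      !grepl("^[ACGT]+$", x))
    stop_input(name, " must be a non-empty string over A/C/G/T")
}

# Classification of one variant against one overlapping feature.
#' @noRd
classify_in_feature <- function(position, ref, alt, feat, model) {
  if (feat$type == "tRNA") return("tRNA")
  if (feat$type == "rRNA") return("rRNA")
  if (feat$type == "noncoding") return("noncoding")
  d <- nchar(ref) - nchar(alt)
  if (d != 0L)
    return(if (abs(d) %% 3L != 0L) "frameshift" else "inframe_indel")
  if (nchar(ref) == 1L)
    return(classify_snv(position, ref, alt, feat, model))
  # equal-length multi-base substitution: classify per base, keep worst
  refs <- strsplit(ref, "")[[1]]
  alts <- strsplit(alt, "")[[1]]
  effs <- character(0)
  for (k in seq_along(refs)) {
    if (refs[k] == alts[k]) next
    p <- wrap_pos(position + k - 1L, model$genome_length)
    if (p >= feat$start && p <= feat$end)
      effs <- c(effs, classify_snv(p, refs[k], alts[k], feat, model))
  }
  if (!length(effs)) return("synonymous")
  effs[which.max(effect_severity(effs))]
}

#' @noRd
classify_snv <- function(position, ref, alt, feat, model) {
  code <- mt_genetic_code()
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  if (feat$strand == "heavy") {
    off <- position - feat$start
    cpos <- off %% 3L
    codon_pos <- position - cpos + 0:2
    # incomplete terminal stop codon: complete with polyadenylated A's
    bases <- ifelse(codon_pos > feat$end, "A", model$sequence[codon_pos])
    ref_b <- ref; alt_b <- alt
  } else {
    off <- feat$end - position
    cpos <- off %% 3L
    codon_pos <- position + cpos - 0:2
    bases <- ifelse(codon_pos < feat$start, "T", model$sequence[codon_pos])
    bases <- comp[bases]
    ref_b <- comp[[ref]]; alt_b <- comp[[alt]]
  }
  ref_codon <- bases; ref_codon[cpos + 1L] <- ref_b
  alt_codon <- bases; alt_codon[cpos + 1L] <- alt_b
  aa_ref <- code[[paste(ref_codon, collapse = "")]]
  aa_alt <- code[[paste(alt_codon, collapse = "")]]
  if (aa_ref == aa_alt) "synonymous"
  else if (aa_alt == "*") "nonsense"
  else "missense"
}
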