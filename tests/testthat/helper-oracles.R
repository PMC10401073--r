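# Independent oracles, coded without touching the implementation's
# helpers: a hand-built vertebrate mitochondrial codon table and a
# brute-force somatic filter.

# Standard genetic code in canonical TCAG order, then the four vertebrate
# mitochondrial differences (AGA/AGG -> stop, ATA -> Met, TGA -> Trp).
oracle_mito_code <- local({
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  b <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(
    as.vector(t(outer(b, b, paste0))), b, paste0)))
  code <- setNames(aas, codons)
  code[c("AGA", "AGG")] <- "*"
  code["ATA"] <- "M"
  code["TGA"] <- "W"
  code
})

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# Brute-force SNV classification at one position of one protein gene,
# written as a direct transcription of the codon rules.
oracle_classify_snv <- function(seq, feat, pos, ref, alt) {
  if (feat$strand == "heavy") {
    idx <- pos - feat$start
    codon_start <- feat$start + (idx %/% 3) * 3
    codon <- seq[codon_start + 0:2]
    codon[codon_start + 0:2 > feat$end] <- "A"  # poly-A completion
    within <- pos - codon_start + 1
    ref_codon <- codon; ref_codon[within] <- ref
    alt_codon <- codon; alt_codon[within] <- alt
    aa_r <- oracle_mito_code[[paste(ref_codon, collapse = "")]]
    aa_a <- oracle_mito_code[[paste(alt_codon, collapse = "")]]
  } else {
    idx <- feat$end - pos
    codon_top <- feat$end - (idx %/% 3) * 3 - 2:0  # genome order
    codon <- seq[pmax(codon_top, 1)]
    codon[codon_top < feat$start] <- "T"
    within <- pos - codon_top[1] + 1
    ref_codon <- codon; ref_codon[within] <- ref
    alt_codon <- codon; alt_codon[within] <- alt
    aa_r <- oracle_mito_code[[oracle_revcomp(paste(ref_codon, collapse = ""))]]
    aa_a <- oracle_mito_code[[oracle_revcomp(paste(alt_codon, collapse = ""))]]
  }
  if (aa_r == aa_a) "synonymous" else if (aa_a == "*") "nonsense" else "missense"
}

# Direct transcription of the printed matched-normal filter clauses.
oracle_filter_matched <- function(tv, nv, td, nd,
                                  min_depth = 15, tmin = 0.3, nmax = 0.05,
                                  dmin = 0.4) {
  td >= min_depth && nd >= min_depth && tv > tmin && nv < nmax &&
    (tv - nv) > dmin
}

# Straight-line recomputation of the screen formulas with explicit loops.
oracle_score_screen <- function(counts_a, counts_b, library, days,
                                reference_day = 5) {
  score_line <- function(counts) {
    norm <- counts
    for (j in seq_len(ncol(counts))) {
      tot <- sum(counts[, j])
      for (i in seq_len(nrow(counts)))
        norm[i, j] <- log2(counts[i, j] / tot * 1e6 + 1)
    }
    ref <- norm[, paste0("D", reference_day)]
    sapply(days, function(d) {
      lfc <- norm[, paste0("D", d)] - ref
      (lfc - mean(lfc)) / sd(lfc)
    })
  }
  za <- score_line(counts_a); zb <- score_line(counts_b)
  group <- ifelse(is.na(library$gene), library$category, library$gene)
  out <- NULL
  for (k in seq_along(days)) {
    ga <- tapply(za[library$guide_id, k], group, mean)
    gb <- tapply(zb[library$guide_id, k], group, mean)
    dz <- (ga - gb[names(ga)]) / 2
    out <- rbind(out, data.frame(gene = names(ga), day = days[k],
                                 z_a = as.numeric(ga),
                                 z_b = as.numeric(gb[names(ga)]),
                                 delta_z = as.numeric(dz),
                                 stringsAsFactors = FALSE))
  }
  out$hit <- out$delta_z < -2
  out
}

# Jaccard index of two (non-wrapping or wrapping) circular intervals.
oracle_jaccard <- function(s1, e1, s2, e2, L = 16569) {
  pos <- function(s, e) if (s <= e) s:e else c(s:L, 1:e)
  a <- pos(s1, e1); b <- pos(s2, e2)
  length(intersect(a, b)) / length(union(a, b))
}
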