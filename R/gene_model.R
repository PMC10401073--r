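#' Load the mitochondrial gene model
#'
#' Builds the annotation object used for effect classification and
#' OXPHOS-complex assignment: the 37-gene coordinate table of the revised
#' Cambridge Reference Sequence (rCRS, NC_012920; 16,569 bp, circular),
#' the vertebrate mitochondrial genetic code, and a reference base at every
#' position.
#'
#' The packaged coordinate table is the standard rCRS annotation
#' (13 protein-coding genes, 22 tRNAs, 2 rRNAs; 1-based inclusive
#' coordinates; `heavy`/`light` strand). Protein genes whose length is not
#' divisible by three end in an incomplete stop codon completed by
#' polyadenylation; these are flagged (`incomplete_stop`) and their terminal
#' codon is A-completed during classification.
#'
#' If no FASTA is supplied, the model carries a deterministic
#' **synthetic** reference sequence: codon-structure-aware (no premature
#' in-frame stop codons in any protein gene's own reading frame) with the
#' handful of positions exercised by the packaged examples pinned to their
#' real rCRS bases. It supports testing the classification machinery
#' end-to-end, but it is not NC_012920; supply the real sequence via
#' `fasta` for analyses of real variants.
#'
#' @param path Optional path to a gene table TSV with columns
#'   `name`, `start`, `end`, `strand`, `type`. Defaults to the packaged
#'   rCRS table.
#' @param fasta Optional path to a single-sequence FASTA whose length
#'   matches the genome; used as the reference sequence.
#' @return An object of class `mt_gene_model`: a list with `features`
#'   (data frame), `genome_length`, `genetic_code` (NCBI translation table
#'   id, `"2"`), `sequence` (character vector of bases), and
#'   `sequence_source`.
#' @examples
#' model <- load_gene_model()
#' subset(model$features, name == "MT-ND1")
#' genes_at(model, 3745)$name
#' @export
load_gene_model <- function(path = NULL, fasta = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "rcrs_genes.tsv", package = "mitoscreen",
                        mustWork = TRUE)
  feats <- read_gene_table(path)
  genome_length <- MT_GENOME_LENGTH
  if (!is.null(fasta)) {
    ss <- Biostrings::readDNAStringSet(fasta)
    if (length(ss) != 1L)
      stop_input("fasta must contain exactly one sequence")
    if (Biostrings::nchar(ss)[1] != genome_length)
      stop_input("fasta sequence length ", Biostrings::nchar(ss)[1],
                 " does not match genome length ", genome_length)
    sequence <- strsplit(toupper(as.character(ss[[1]])), "")[[1]]
    sequence_source <- fasta
  } else {
    sequence <- synthetic_mt_sequence(feats, genome_length)
    sequence_source <- "synthetic"
  }
  structure(list(features = feats,
                 genome_length = genome_length,
                 genetic_code = "2",
                 sequence = sequence,
                 sequence_source = sequence_source),
            class = "mt_gene_model")
}

# Parse and validate the gene table TSV.
#' @noRd
read_gene_table <- function(path) {
  if (!file.exists(path)) stop_input("gene table not found: ", path)
  feats <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("name", "start", "end", "strand", "type")
  missing <- setdiff(required, names(feats))
  if (length(missing))
    stop_input("gene table missing column(s): ", paste(missing, collapse = ", "))
  for (i in seq_len(nrow(feats))) {
    row <- feats[i, ]
    line <- i + 1L  # header is line 1
    if (is.na(row$start) || is.na(row$end) ||
        row$start != trunc(row$start) || row$end != trunc(row$end))
      stop_input("gene table line ", line, ": start/end must be integers")
    if (row$start < 1 || row$end > MT_GENOME_LENGTH || row$start > row$end)
      stop_input("gene table line ", line,
                 ": need 1 <= start <= end <= ", MT_GENOME_LENGTH)
    if (!row$strand %in% c("heavy", "light"))
      stop_input("gene table line ", line, ": strand must be heavy or light")
    if (!row$type %in% c("protein", "tRNA", "rRNA", "noncoding"))
      stop_input("gene table line ", line, ": unknown feature type '", row$type, "'")
  }
  dup <- feats$name[duplicated(feats$name)]
  if (length(dup))
    stop_input("duplicated gene name(s): ", paste(unique(dup), collapse = ", "))
  n_type <- table(factor(feats$type, levels = c("protein", "tRNA", "rRNA")))
  if (n_type[["protein"]] != 13L || n_type[["tRNA"]] != 22L || n_type[["rRNA"]] != 2L)
    stop_input("gene model must contain 13 protein, 22 tRNA and 2 rRNA genes; got ",
               n_type[["protein"]], "/", n_type[["tRNA"]], "/", n_type[["rRNA"]])
  feats$start <- as.integer(feats$start)
  feats$end <- as.integer(feats$end)
  len <- feats$end - feats$start + 1L
  feats$incomplete_stop <- feats$type == "protein" & (len %% 3L) != 0L
  feats
}

#' @export
print.mt_gene_model <- function(x, ...) {
  n <- table(x$features$type)
  cat(sprintf("mt_gene_model: %d features (%s) on a circular %d bp genome\n",
              nrow(x$features),
              paste(names(n), n, sep = "=", collapse = ", "),
              x$genome_length))
  cat("reference sequence:", x$sequence_source, "\n")
  invisible(x)
}

#' Features overlapping a position
#'
#' @param model An `mt_gene_model`.
#' @param position 1-based position on the circular genome.
#' @return The rows of `model$features` overlapping `position` (possibly
#'   none: intergenic).
#' @export
genes_at <- function(model, position) {
  stopifnot(inherits(model, "mt_gene_model"))
  if (!is_count(position) || position < 1 || position > model$genome_length)
    stop_input("position must be in [1, ", model$genome_length, "]")
  f <- model$features
  f[f$start <= position & f$end >= position, , drop = FALSE]
}

#' Assign a mitochondrial gene to its OXPHOS complex
#'
#' The 13 mtDNA-encoded OXPHOS subunits map to complex I (MT-ND1..6,
#' MT-ND4L), complex III (MT-CYB), complex IV (MT-CO1..3) and complex V
#' (MT-ATP6, MT-ATP8); tRNA and rRNA genes map to their own categories.
#'
#' @param gene Gene symbol present in the model.
#' @param model An `mt_gene_model`.
#' @return One of `"CI"`, `"CIII"`, `"CIV"`, `"CV"`, `"tRNA"`, `"rRNA"`,
#'   `"other"`.
#' @examples
#' model <- load_gene_model()
#' assign_complex("MT-ND5", model)
#' assign_complex("MT-TL1", model)
#' @export
assign_complex <- function(gene, model) {
  stopifnot(inherits(model, "mt_gene_model"))
  f <- model$features
  if (!gene %in% f$name)
    stop_input("unknown gene symbol '", gene, "'; valid symbols: ",
               paste(sort(f$name), collapse = ", "))
  type <- f$type[f$name == gene]
  if (type == "tRNA") return("tRNA")
  if (type == "rRNA") return("rRNA")
  if (type == "protein") {
    if (grepl("^MT-ND", gene)) return("CI")
    if (gene == "MT-CYB") return("CIII")
    if (grepl("^MT-CO", gene)) return("CIV")
    if (grepl("^MT-ATP", gene)) return("CV")
  }
  "other"
}

# ---- synthetic reference sequence ------------------------------------------

# Deterministic Lehmer generator so building the model never touches R's
# global RNG stream.
#' @noRd
lehmer_stream <- function(n, seed = 20260926) {
  out <- integer(n)
  x <- seed
  for (i in seq_len(n)) {
    x <- (48271 * x) %% 2147483647
    out[i] <- x %% 4L
  }
  out
}

# Build a synthetic stand-in for the rCRS base sequence: random bases,
# then every protein gene's own reading frame is scrubbed of premature
# stop codons (vertebrate mitochondrial stops TAA/TAG/AGA/AGG), then the
# few positions used by packaged examples are pinned to their real rCRS
# bases so the documented variants classify as in the field's reports.
#' @noRd
synthetic_mt_sequence <- function(feats, genome_length) {
  bases <- c("A", "C", "G", "T")
  seq <- bases[lehmer_stream(genome_length) + 1L]
  code <- mt_genetic_code()
  stop_fix <- c(TAA = "TCA", TAG = "TCG", AGA = "ACA", AGG = "ACG")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  prot <- feats[feats$type == "protein", , drop = FALSE]
  # Overlapping protein genes share bases, so a fix in one frame can
  # create a stop in the other: iterate to a fixpoint.
  for (pass in 1:20) {
    fixed_any <- FALSE
    for (i in seq_len(nrow(prot))) {
      s <- prot$start[i]; e <- prot$end[i]
      n_codon <- (e - s + 1L) %/% 3L
      for (k in seq_len(n_codon) - 1L) {
        if (prot$strand[i] == "heavy") {
          idx <- s + 3L * k + 0:2
          codon <- paste(seq[idx], collapse = "")
          if (code[[codon]] == "*") {
            seq[idx] <- strsplit(stop_fix[[codon]], "")[[1]]
            fixed_any <- TRUE
          }
        } else {
          idx <- e - 3L * k - 0:2
          codon <- paste(comp[seq[idx]], collapse = "")
          if (code[[codon]] == "*") {
            seq[idx] <- comp[strsplit(stop_fix[[codon]], "")[[1]]]
            fixed_any <- TRUE
          }
        }
      }
    }
    if (!fixed_any) break
  }
  # Pinned rCRS bases: m.3244 (MT-TL1); codon GAA at 3745-3747 so that
  # m.3745G>A is the known MT-ND1 missense; codon GGA at 3916-3918 so that
  # m.3916G>A is stop-gain; CA at 12417-12418 (MT-ND5 m.CA12417C context).
  seq[3244L] <- "G"
  seq[3745:3747] <- c("G", "A", "A")
  seq[3916:3918] <- c("G", "G", "A")
  seq[12417:12419] <- c("C", "A", "T")
  seq
}

# Vertebrate mitochondrial codon table (NCBI translation table 2).
#' @noRd
mt_genetic_code <- local({
  code <- NULL
  function() {
    if (is.null(code)) code <<- Biostrings::getGeneticCode("2")
    code
  }
})
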