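# Readers and writers for the plain-text formats the pipeline touches.
# Internal coordinates are 1-based inclusive everywhere; BED export is
# 0-based half-open, converted in exactly one place (to_bed_intervals).

#' Read a variant table
#'
#' Two dialects:
#'
#' * `tsv` — columns `sample_id`, `position`, `ref`, `alt`, `tumor_vaf`,
#'   `tumor_depth`, and optionally `normal_vaf`/`normal_depth` (`NA` or
#'   absent for tumors without a matched normal).
#' * `vcf` — a minimal VCF v4.2 subset. `CHROM` must be a mitochondrial
#'   contig (`MT`, `chrM`, `chrMT`, or `NC_012920*`). Per sample, VAF is
#'   taken from the `AF` FORMAT field when present, else computed from
#'   `AD` (alt / (ref + alt)); depth from `DP`, else the `AD` sum. With
#'   two samples the tumor is the one named `TUMOR`/`*tumor*` (the other
#'   is the normal), falling back to first = tumor, second = normal; with
#'   one sample the record is unmatched.
#'
#' @param path Input file.
#' @param dialect `"tsv"` or `"vcf"`.
#' @return Variant data frame (see [mt_variant_record()]).
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_input("input file not found: ", path)
  if (dialect == "vcf") return(read_variant_vcf(path))
  # an all-"T" allele column must not parse as logical
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(sample_id = "character", ref = "character",
                                  alt = "character"))
  missing <- setdiff(VARIANT_REQUIRED_COLS, names(df))
  if (length(missing))
    stop_input("variant table missing column(s): ", paste(missing, collapse = ", "))
  if (!"normal_vaf" %in% names(df)) df$normal_vaf <- NA_real_
  if (!"normal_depth" %in% names(df)) df$normal_depth <- NA_integer_
  for (col in c("tumor_vaf", "normal_vaf")) {
    bad <- which(!is.na(df[[col]]) & (df[[col]] < 0 | df[[col]] > 1))
    if (length(bad))
      stop_input(col, " outside [0, 1] at line ", bad[1] + 1L)
  }
  bad_pos <- which(df$position < 1 | df$position > MT_GENOME_LENGTH)
  if (length(bad_pos))
    stop_input("position outside [1, ", MT_GENOME_LENGTH, "] at line ",
               bad_pos[1] + 1L)
  if (any(is.na(df$normal_vaf) != is.na(df$normal_depth)))
    stop_input("normal_vaf and normal_depth must be both present or both NA")
  df$position <- as.integer(df$position)
  df$tumor_vaf <- as.numeric(df$tumor_vaf)
  df$normal_vaf <- as.numeric(df$normal_vaf)
  df$tumor_depth <- as.integer(df$tumor_depth)
  df$normal_depth <- as.integer(df$normal_depth)
  df
}

#' @noRd
read_variant_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop_input("reading VCF requires the vcfR package")
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))  # single-record VCF
  if (nrow(fix) == 0L) return(read_variant_table_empty())
  ok_chrom <- grepl("^(MT|chrM|chrMT|NC_012920)", fix[, "CHROM"])
  if (!all(ok_chrom))
    stop_input("non-mitochondrial contig in VCF: ",
               paste(unique(fix[!ok_chrom, "CHROM"]), collapse = ", "))
  samples <- colnames(v@gt)[-1]
  if (length(samples) < 1L || length(samples) > 2L)
    stop_input("VCF must have one (tumor) or two (tumor, normal) samples")
  tumor <- if (length(samples) == 1L) samples else {
    hit <- grepl("tumor", samples, ignore.case = TRUE)
    if (sum(hit) == 1L) samples[hit] else samples[1]
  }
  normal <- setdiff(samples, tumor)
  sample_stats <- function(who) {
    af <- tryCatch(vcfR::extract.gt(v, "AF", as.numeric = TRUE)[, who],
                   error = function(e) rep(NA_real_, nrow(fix)))
    ad <- tryCatch(vcfR::extract.gt(v, "AD")[, who],
                   error = function(e) rep(NA_character_, nrow(fix)))
    dp <- tryCatch(vcfR::extract.gt(v, "DP", as.numeric = TRUE)[, who],
                   error = function(e) rep(NA_real_, nrow(fix)))
    ad_mat <- t(vapply(strsplit(ifelse(is.na(ad), "NA,NA", ad), ","),
                       function(x) suppressWarnings(as.numeric(x[1:2])),
                       numeric(2)))
    vaf <- ifelse(!is.na(af), af,
                  ad_mat[, 2] / (ad_mat[, 1] + ad_mat[, 2]))
    depth <- ifelse(!is.na(dp), dp, ad_mat[, 1] + ad_mat[, 2])
    list(vaf = vaf, depth = depth)
  }
  t_st <- sample_stats(tumor)
  if (any(is.na(t_st$vaf)))
    stop_input("cannot derive tumor VAF (need AF or AD) at VCF record ",
               which(is.na(t_st$vaf))[1])
  n_st <- if (length(normal)) sample_stats(normal) else
    list(vaf = rep(NA_real_, nrow(fix)), depth = rep(NA_real_, nrow(fix)))
  data.frame(sample_id = tumor,
             position = as.integer(fix[, "POS"]),
             ref = fix[, "REF"], alt = fix[, "ALT"],
             tumor_vaf = t_st$vaf, tumor_depth = as.integer(t_st$depth),
             normal_vaf = n_st$vaf,
             normal_depth = as.integer(round(n_st$depth)),
             stringsAsFactors = FALSE)
}

#' @noRd
read_variant_table_empty <- function() {
  data.frame(sample_id = character(0), position = integer(0),
             ref = character(0), alt = character(0),
             tumor_vaf = numeric(0), tumor_depth = integer(0),
             normal_vaf = numeric(0), normal_depth = integer(0),
             stringsAsFactors = FALSE)
}

#' @rdname read_variant_table
#' @param variants Variant data frame to write.
#' @export
write_variant_table <- function(variants, path) {
  write.table(variants, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write pileup tables
#'
#' TSV with columns `position`, `ref`, `counts`, where `counts` holds
#' semicolon-separated `allele=count` pairs (allele keys as in
#' [pileup_column()], e.g. `G=398;A=602;del:A=3`).
#'
#' @param path File path.
#' @return `read_pileup_table()`: a list of [pileup_column()]s.
#' @export
read_pileup_table <- function(path) {
  if (!file.exists(path)) stop_input("input file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("position", "ref", "counts"), names(df))
  if (length(missing))
    stop_input("pileup table missing column(s): ", paste(missing, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i) {
    pairs <- strsplit(strsplit(df$counts[i], ";")[[1]], "=")
    bad <- which(vapply(pairs, length, integer(1)) != 2L)
    if (length(bad))
      stop_input("malformed counts field at line ", i + 1L)
    counts <- setNames(as.numeric(vapply(pairs, `[`, character(1), 2L)),
                       vapply(pairs, `[`, character(1), 1L))
    pileup_column(df$position[i], df$ref[i], counts)
  })
}

#' @rdname read_pileup_table
#' @param cols List of [pileup_column()]s.
#' @export
write_pileup_table <- function(cols, path) {
  df <- data.frame(
    position = vapply(cols, `[[`, integer(1), "position"),
    ref = vapply(cols, `[[`, character(1), "ref_base"),
    counts = vapply(cols, function(x)
      paste(names(x$counts), x$counts, sep = "=", collapse = ";"),
      character(1)),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write deletion calls as BED6
#'
#' Converts the 1-based inclusive internal intervals to BED's 0-based
#' half-open convention. A call wrapping the origin is emitted as two
#' lines sharing a name. The score column is `round(1000 * del_fraction)`.
#'
#' @param calls Deletion-call data frame from [scan_deletions()].
#' @param path Output file.
#' @param chrom Contig name to write. Default `"chrM"`.
#' @return `path`, invisibly.
#' @export
write_deletion_bed <- function(calls, path, chrom = "chrM") {
  lines <- "# mtDNA deletion calls; score = round(1000 * del_fraction)"
  for (i in seq_len(nrow(calls))) {
    name <- sprintf("%s_del%d", calls$sample_id[i], i)
    iv <- to_bed_intervals(calls$start[i], calls$end[i])
    for (j in seq_len(nrow(iv)))
      lines <- c(lines, paste(chrom, iv[j, 1], iv[j, 2], name,
                              round(1000 * calls$del_fraction[i]), "+",
                              sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a fitness table
#'
#' @param fitness Fitness table from [score_screen()].
#' @param path Output TSV (`gene`, `day`, `z_a`, `z_b`, `delta_z`, `hit`).
#' @export
write_fitness_table <- function(fitness, path) {
  write.table(as.data.frame(fitness), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a two-line screen counts TSV
#'
#' First column `guide_id`; remaining columns named `<cellline>_D<day>`.
#'
#' @param path Counts TSV.
#' @param library A [screen_library()].
#' @return Named list of [count_matrix()], one per cell line.
#' @export
read_count_table <- function(path, library) {
  if (!file.exists(path)) stop_input("input file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "guide_id")
    stop_input("first column must be guide_id")
  sample_cols <- names(df)[-1]
  m <- regmatches(sample_cols, regexec("^(.+)_D([0-9]+)$", sample_cols))
  bad <- sample_cols[vapply(m, length, integer(1)) != 3L]
  if (length(bad))
    stop_input("sample column(s) not of the form <cellline>_D<day>: ",
               paste(bad, collapse = ", "))
  lines <- vapply(m, `[`, character(1), 2L)
  days <- vapply(m, `[`, character(1), 3L)
  out <- lapply(unique(lines), function(ln) {
    cols <- which(lines == ln)
    mat <- as.matrix(df[, sample_cols[cols], drop = FALSE])
    rownames(mat) <- df$guide_id
    colnames(mat) <- paste0("D", days[cols])
    count_matrix(mat, library, ln)
  })
  setNames(out, unique(lines))
}

#' @rdname read_count_table
#' @param counts_list Named list of [count_matrix()] sharing a library.
#' @export
write_count_table <- function(counts_list, path) {
  mats <- lapply(counts_list, function(cm) {
    m <- cm$counts
    colnames(m) <- paste0(cm$cell_line, "_", colnames(m))
    m
  })
  all <- do.call(cbind, mats)
  df <- data.frame(guide_id = rownames(all), all, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write the screen library manifest TSV
#'
#' Columns `guide_id`, `gene` (empty for controls), `category`.
#'
#' @param path File path.
#' @export
read_library_manifest <- function(path) {
  if (!file.exists(path)) stop_input("input file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$gene[!is.na(df$gene) & df$gene == ""] <- NA_character_
  screen_library(df)
}

#' @rdname read_library_manifest
#' @param library A [screen_library()].
#' @export
write_library_manifest <- function(library, path) {
  write.table(as.data.frame(library), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' A JSON sidecar recording the tool version, subcommand, effective
#' parameters, input checksums (MD5), seeds and a timestamp, so that any
#' output can be traced to the exact inputs and settings that produced it.
#'
#' @param path Output JSON path.
#' @param subcommand Name of the operation run.
#' @param params [analysis_params()] or any parameter list.
#' @param inputs Character vector of input file paths (checksummed).
#' @param seed Seed(s) used, if any.
#' @return The manifest list, invisibly.
#' @export
write_run_manifest <- function(path, subcommand, params = analysis_params(),
                               inputs = character(0), seed = NULL) {
  manifest <- list(
    tool = "mitoscreen",
    version = as.character(utils::packageVersion("mitoscreen")),
    subcommand = subcommand,
    params = unclass(params),
    inputs = if (length(inputs))
      lapply(inputs, function(p)
        list(path = p, md5 = unname(tools::md5sum(p)))) else list(),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}

#' Read a flat key=value config file
#'
#' Blank lines and `#` comments are ignored; values are parsed as numbers
#' when possible, else kept as strings.
#'
#' @param path Config file.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_input("config file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  bad <- which(!grepl("=", lines, fixed = TRUE))
  if (length(bad))
    stop_input("config line not of the form key=value: '", lines[bad[1]], "'")
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1L))
  vals <- trimws(vapply(kv, `[`, character(1), 2L))
  parsed <- lapply(vals, function(v) {
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) n else v
  })
  setNames(parsed, keys)
}
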