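#' Construct a screen library manifest
#'
#' @param guides Data frame with columns `guide_id`, `gene`, `category`.
#'   Categories are `gene_of_interest`, `control_gene`, `essential`
#'   (targeting categories; `gene` required) and `cutting_control`,
#'   `noncutting_control` (`gene` must be `NA`).
#' @param guides_per_gene Expected guides per targeted gene (informational).
#' @return A data frame of class `screen_library`.
#' @export
screen_library <- function(guides, guides_per_gene = 5L) {
  required <- c("guide_id", "gene", "category")
  missing <- setdiff(required, names(guides))
  if (length(missing))
    stop_input("library missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(guides$guide_id))
    stop_input("duplicated guide_id(s): ",
               paste(unique(guides$guide_id[duplicated(guides$guide_id)]),
                     collapse = ", "))
  targeting <- c("gene_of_interest", "control_gene", "essential")
  controls <- c("cutting_control", "noncutting_control")
  bad_cat <- setdiff(unique(guides$category), c(targeting, controls))
  if (length(bad_cat))
    stop_input("unknown guide category: ", paste(bad_cat, collapse = ", "))
  if (any(guides$category %in% targeting & is.na(guides$gene)))
    stop_input("targeting guides must name a gene")
  if (any(guides$category %in% controls & !is.na(guides$gene)))
    stop_input("control guides must not name a gene")
  attr(guides, "guides_per_gene") <- as.integer(guides_per_gene)
  class(guides) <- c("screen_library", "data.frame")
  guides
}

#' Construct an sgRNA count matrix for one cell line
#'
#' @param counts Integer matrix, guides in rows (rownames = guide ids),
#'   one column per timepoint named `D<day>` (e.g. `D5`, `D16`).
#' @param library A [screen_library()] whose every guide has a row.
#' @param cell_line Cell-line identifier.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, library, cell_line) {
  stopifnot(inherits(library, "screen_library"))
  if (is.null(rownames(counts)))
    stop_input("counts must have guide ids as rownames")
  if (!all(grepl("^D[0-9]+$", colnames(counts))))
    stop_input("count columns must be named D<day>")
  missing <- setdiff(library$guide_id, rownames(counts))
  if (length(missing))
    stop_input("counts missing library guide(s): ",
               paste(utils::head(missing, 5), collapse = ", "),
               if (length(missing) > 5) ", ..." else "")
  if (any(counts < 0) || any(counts != trunc(counts)))
    stop_input("counts must be non-negative integers")
  counts <- counts[library$guide_id, , drop = FALSE]
  structure(list(counts = counts, library = library, cell_line = cell_line,
                 days = as.integer(sub("^D", "", colnames(counts)))),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix %s: %d guides x days {%s}\n", x$cell_line,
              nrow(x$counts), paste(x$days, collapse = ", ")))
  invisible(x)
}

#' Log2 counts-per-million normalization
#'
#' Per sample: `log2(reads of a guide / total reads in the sample * 1e6 + 1)`.
#' By construction, for every sample the sum over guides of
#' `2^value - 1` equals one million (to floating tolerance).
#'
#' @param m A [count_matrix()], or a plain numeric matrix of counts with
#'   samples in columns.
#' @return Matrix of log2-normalized values, same shape as the counts.
#' @examples
#' normalize_counts(matrix(c(100, 999900), 2, 1,
#'                  dimnames = list(c("g1", "g2"), "D5")))[1, 1] # log2(101)
#' @export
normalize_counts <- function(m) {
  counts <- if (inherits(m, "count_matrix")) m$counts else m
  totals <- colSums(counts)
  zero <- colnames(counts)[totals == 0]
  if (length(zero))
    stop_input("sample(s) with zero total reads: ", paste(zero, collapse = ", "))
  log2(sweep(counts, 2, totals, "/") * 1e6 + 1)
}

#' Log2 fold-change against the reference day
#'
#' @param norm Matrix of log2-normalized values ([normalize_counts()]),
#'   columns named `D<day>`.
#' @param day Day to compare.
#' @param reference_day Reference day (default 5).
#' @return Named per-guide vector `norm[, day] - norm[, reference_day]`.
#' @export
log2fc_vs_reference <- function(norm, day, reference_day = 5) {
  dcol <- paste0("D", day); rcol <- paste0("D", reference_day)
  if (!rcol %in% colnames(norm))
    stop_input("reference sample ", rcol, " missing")
  if (!dcol %in% colnames(norm))
    stop_input("sample ", dcol, " missing")
  norm[, dcol] - norm[, rcol]
}

#' Z-score guide-level log2 fold-changes
#'
#' Standardizes each guide's log2 fold-change against the mean and sample
#' standard deviation (n - 1 denominator) of a standardization population:
#' all guides in the sample by default, or only the non-cutting controls
#' (`z_ref = "noncutting"`), a common choice when the library is expected
#' to contain many true dropouts.
#'
#' @param lfc Named per-guide log2 fold-change vector for one sample.
#' @param library Optional [screen_library()]; required for
#'   `z_ref = "noncutting"`.
#' @param z_ref `"all"` or `"noncutting"`.
#' @return Named per-guide Z vector.
#' @export
zscore_guides <- function(lfc, library = NULL, z_ref = c("all", "noncutting")) {
  z_ref <- match.arg(z_ref)
  if (length(lfc) < 2L) stop_input("need at least 2 guides to standardize")
  pop <- if (z_ref == "all") lfc else {
    if (is.null(library)) stop_input("library required for z_ref = 'noncutting'")
    ids <- library$guide_id[library$category == "noncutting_control"]
    if (length(ids) < 2L) stop_input("need >= 2 non-cutting controls")
    lfc[ids]
  }
  s <- stats::sd(pop)
  if (!is.finite(s) || s == 0)
    stop_input("zero dispersion in the standardization population")
  (lfc - mean(pop)) / s
}

#' Aggregate guide Z-scores to gene level
#'
#' @param z Named per-guide Z vector.
#' @param library A [screen_library()].
#' @param agg `"mean"` (default) or `"median"`.
#' @return Named per-gene Z vector; control categories are aggregated
#'   under their category label.
#' @export
gene_zscore <- function(z, library, agg = c("mean", "median")) {
  agg <- match.arg(agg)
  fun <- if (agg == "mean") mean else stats::median
  stopifnot(inherits(library, "screen_library"))
  missing <- setdiff(library$guide_id, names(z))
  if (length(missing))
    stop_input("guide(s) without a Z value: ",
               paste(utils::head(missing, 5), collapse = ", "))
  group <- ifelse(is.na(library$gene), library$category, library$gene)
  vapply(split(z[library$guide_id], group), fun, numeric(1))
}

#' Differential fitness between two cell lines
#'
#' `delta_z = (z_a - z_b) / 2`: half the difference between a gene's
#' Z-scored dropout in the tumor line (a) and the control line (b).
#' Strongly negative values mean the knockout is selectively depleted in
#' the tumor line.
#'
#' @param z_a,z_b Named per-gene Z vectors for the same day from the two
#'   cell lines; names must agree.
#' @return Named per-gene delta-Z vector.
#' @examples
#' delta_fitness(c(GPX4 = -3), c(GPX4 = 1))  # -2
#' @export
delta_fitness <- function(z_a, z_b) {
  if (!setequal(names(z_a), names(z_b)))
    stop_input("gene sets differ between cell lines: ",
               paste(utils::head(c(setdiff(names(z_a), names(z_b)),
                                   setdiff(names(z_b), names(z_a))), 5),
                     collapse = ", "))
  (z_a - z_b[names(z_a)]) / 2
}

#' Call screen hits
#'
#' Hits are genes whose delta-Z is strictly below `p$hit_threshold`
#' (default -2) at the queried day, sorted ascending by delta-Z.
#'
#' @param fitness A fitness table from [score_screen()].
#' @param day Day to query; default all days in the table.
#' @param p [analysis_params()].
#' @return The hit rows of the fitness table, sorted by `delta_z`.
#' @export
call_hits <- function(fitness, day = NULL, p = analysis_params()) {
  p <- as_analysis_params(p)
  rows <- if (is.null(day)) fitness else fitness[fitness$day %in% day, , drop = FALSE]
  hits <- rows[rows$delta_z < p$hit_threshold, , drop = FALSE]
  hits[order(hits$delta_z), , drop = FALSE]
}

#' Score a pooled CRISPR knockout screen
#'
#' Composes the full scoring chain for every day other than the reference
#' day: log2 CPM normalization, per-guide log2 fold-change versus day 5,
#' per-guide Z within each sample, gene-level aggregation, and
#' differential fitness `delta_z = (Z_a - Z_b) / 2` with strict-threshold
#' hit calls. Deterministic given its inputs.
#'
#' @param counts_a,counts_b [count_matrix()] objects for the tumor (a) and
#'   control (b) cell line; identical libraries, both containing the
#'   reference day.
#' @param p [analysis_params()].
#' @param z_ref,agg Passed to [zscore_guides()] and [gene_zscore()].
#' @return A data frame of class `fitness_table`: `gene`, `day`, `z_a`,
#'   `z_b`, `delta_z`, `hit`, with attributes `guide_z` (per-line guide
#'   Z matrices) and `cell_lines`.
#' @export
score_screen <- function(counts_a, counts_b, p = analysis_params(),
                         z_ref = c("all", "noncutting"),
                         agg = c("mean", "median")) {
  z_ref <- match.arg(z_ref); agg <- match.arg(agg)
  p <- as_analysis_params(p)
  stopifnot(inherits(counts_a, "count_matrix"), inherits(counts_b, "count_matrix"))
  if (!setequal(counts_a$library$guide_id, counts_b$library$guide_id))
    stop_input("libraries differ between cell lines: ",
               paste(utils::head(c(setdiff(counts_a$library$guide_id,
                                           counts_b$library$guide_id),
                                   setdiff(counts_b$library$guide_id,
                                           counts_a$library$guide_id)), 10),
                     collapse = ", "))
  days <- sort(intersect(counts_a$days, counts_b$days))
  days <- setdiff(days, p$reference_day)
  if (!length(days)) stop_input("no non-reference days shared by both lines")

  line_scores <- function(cm) {
    norm <- normalize_counts(cm)
    sapply(days, function(d) {
      lfc <- log2fc_vs_reference(norm, d, p$reference_day)
      zscore_guides(lfc, cm$library, z_ref)
    })
  }
  gz_a <- apply(line_scores(counts_a), 2, gene_zscore,
                library = counts_a$library, agg = agg)
  gz_b <- apply(line_scores(counts_b), 2, gene_zscore,
                library = counts_b$library, agg = agg)
  colnames(gz_a) <- colnames(gz_b) <- paste0("D", days)

  out <- do.call(rbind, lapply(seq_along(days), function(i) {
    dz <- delta_fitness(gz_a[, i], gz_b[, i])
    data.frame(gene = rownames(gz_a), day = days[i],
               z_a = gz_a[, i], z_b = gz_b[rownames(gz_a), i],
               delta_z = dz[rownames(gz_a)],
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  out$hit <- out$delta_z < p$hit_threshold
  attr(out, "cell_lines") <- c(a = counts_a$cell_line, b = counts_b$cell_line)
  class(out) <- c("fitness_table", "data.frame")
  out
}
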