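#' Construct a per-base coverage profile
#'
#' @param sample_id Sample identifier.
#' @param depth Non-negative per-base read-depth vector covering the whole
#'   circular genome.
#' @param genome_length Genome length; `depth` must have exactly this many
#'   elements.
#' @return An object of class `coverage_profile`.
#' @export
coverage_profile <- function(sample_id, depth,
                             genome_length = MT_GENOME_LENGTH) {
  if (length(depth) != genome_length)
    stop_input("depth vector has length ", length(depth),
               " but genome length is ", genome_length)
  if (any(is.na(depth)) || any(depth < 0))
    stop_input("depths must be non-negative")
  structure(list(sample_id = sample_id,
                 genome_length = as.integer(genome_length),
                 depth = as.numeric(depth)),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("coverage_profile %s: %d bp, median depth %.0fx\n",
              x$sample_id, x$genome_length, stats::median(x$depth)))
  invisible(x)
}

#' Scan a coverage profile for large heteroplasmic deletions
#'
#' Detects large mtDNA deletions from non-uniformity of sequencing
#' coverage. Per-base depth is normalized by the sample's genome-wide
#' median, computed in two passes so a large deletion does not bias its
#' own baseline: candidate low windows are flagged against the naive
#' median, then the median is recomputed excluding them. Maximal circular
#' runs of windows whose median normalized depth falls below `drop_ratio`
#' become candidate deletions; runs separated by less than `window_bp` are
#' merged, breakpoints are refined to the steepest depth change within the
#' flanking window, and runs shorter than `min_len_bp` are dropped.
#'
#' The deleted-molecule fraction is estimated as
#' `1 - mean(depth inside) / mean(depth outside)`, clamped to \[0, 1\]
#' (assumes a single heteroplasmic deletion species; overlapping
#' deletions come out merged).
#'
#' @param cov A [coverage_profile()].
#' @param window_bp Window size in bp (>= 50). Default 300.
#' @param drop_ratio Windows below this fraction of the genome-wide median
#'   are candidate deleted windows. Default 0.7.
#' @param min_len_bp Minimum reported deletion length. Default 500.
#' @param model Optional [mt_gene_model][load_gene_model] used to list the
#'   genes lost.
#' @return A data frame with one row per call: `sample_id`, `start`,
#'   `end` (1-based inclusive; `start > end` means the call wraps the
#'   origin), `length`, `del_fraction`, `genes_lost` (comma-separated).
#' @examples
#' set.seed(1)
#' depth <- rpois(16569, 1000)
#' depth[3000:6709] <- rpois(3710, 400)
#' scan_deletions(coverage_profile("T1", depth), model = load_gene_model())
#' @export
scan_deletions <- function(cov, window_bp = 300, drop_ratio = 0.7,
                           min_len_bp = 500, model = NULL) {
  stopifnot(inherits(cov, "coverage_profile"))
  if (!is_count(window_bp) || window_bp < 50)
    stop_input("window_bp must be an integer >= 50")
  check_fraction(drop_ratio, "drop_ratio")
  if (!is_count(min_len_bp)) stop_input("min_len_bp must be a non-negative integer")
  depth <- cov$depth
  L <- cov$genome_length
  if (all(depth == 0)) stop_input("all-zero coverage profile")

  w <- as.integer(window_bp)
  win_start <- seq.int(1L, L, by = w)
  win_end <- pmin(win_start + w - 1L, L)
  n_win <- length(win_start)
  win_med <- vapply(seq_len(n_win), function(i)
    stats::median(depth[win_start[i]:win_end[i]]), numeric(1))

  # two-pass median normalization
  med1 <- stats::median(depth)
  cand <- win_med < drop_ratio * med1
  keep_bases <- unlist(lapply(which(!cand), function(i) win_start[i]:win_end[i]))
  med <- if (length(keep_bases)) stats::median(depth[keep_bases]) else med1
  flagged <- win_med < drop_ratio * med
  if (!any(flagged)) return(empty_deletion_calls(cov$sample_id))
  if (all(flagged)) stop_input("all windows flagged: coverage profile degenerate")

  runs <- circular_runs(flagged)
  # merge runs whose circular gap is shorter than one window
  runs <- merge_runs(runs, win_start, win_end, w, L)

  calls <- lapply(runs, function(r) {
    coarse_start <- win_start[r[1]]
    coarse_end <- win_end[r[2]]
    s <- refine_breakpoint(depth, coarse_start, w, L, side = "start")
    e <- refine_breakpoint(depth, coarse_end, w, L, side = "end")
    len <- interval_length(s, e, L)
    if (len < min_len_bp || len >= L) return(NULL)
    inside <- interval_positions(s, e, L)
    outside <- setdiff(seq_len(L), inside)
    dfrac <- 1 - mean(depth[inside]) / mean(depth[outside])
    dfrac <- min(max(dfrac, 0), 1)
    genes <- if (is.null(model)) NA_character_ else {
      f <- model$features
      hit <- vapply(seq_len(nrow(f)), function(i)
        interval_overlaps(s, e, f$start[i], f$end[i], L), logical(1))
      paste(f$name[hit], collapse = ",")
    }
    data.frame(sample_id = cov$sample_id, start = s, end = e,
               length = len, del_fraction = dfrac, genes_lost = genes,
               stringsAsFactors = FALSE)
  })
  calls <- calls[!vapply(calls, is.null, logical(1))]
  if (!length(calls)) return(empty_deletion_calls(cov$sample_id))
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' @noRd
empty_deletion_calls <- function(sample_id) {
  data.frame(sample_id = character(0), start = integer(0), end = integer(0),
             length = integer(0), del_fraction = numeric(0),
             genes_lost = character(0), stringsAsFactors = FALSE)
}

# Maximal runs of TRUE in a circular logical vector; returns a list of
# c(first, last) window indices (first > last when the run wraps).
#' @noRd
circular_runs <- function(flag) {
  n <- length(flag)
  if (all(flag)) return(list(c(1L, n)))
  anchor <- which(!flag)[1]
  rot <- flag[c(seq.int(anchor, n), seq_len(anchor - 1L))]
  r <- rle(rot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  lapply(idx, function(i) {
    s <- ((starts[i] + anchor - 2L) %% n) + 1L
    e <- ((ends[i] + anchor - 2L) %% n) + 1L
    c(s, e)
  })
}

# Merge circular runs of windows separated by a bp gap < window_bp.
#' @noRd
merge_runs <- function(runs, win_start, win_end, w, L) {
  if (length(runs) <= 1L) return(runs)
  n_win <- length(win_start)
  # order runs by start window, then merge neighbours (circularly)
  runs <- runs[order(vapply(runs, `[`, integer(1), 1L))]
  repeat {
    merged <- FALSE
    k <- length(runs)
    if (k <= 1L) break
    for (i in seq_len(k)) {
      j <- if (i == k) 1L else i + 1L
      gap_first <- runs[[i]][2] %% n_win + 1L      # window after run i
      gap_last <- (runs[[j]][1] - 2L) %% n_win + 1L # window before run j
      gap_bp <- if (gap_first == runs[[j]][1]) 0L else
        interval_length(win_start[gap_first], win_end[gap_last], L)
      if (gap_bp < w) {
        runs[[i]] <- c(runs[[i]][1], runs[[j]][2])
        runs[[j]] <- NULL
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  runs
}

# Steepest-depth-change breakpoint within +/- window_bp of a coarse
# boundary. For "start" the depth falls at the breakpoint base; for "end"
# it rises just after it.
#' @noRd
refine_breakpoint <- function(depth, approx, w, L, side) {
  flank <- min(w, 150L)
  cands <- wrap_pos(approx + seq.int(-w, w), L)
  score <- vapply(cands, function(b) {
    right <- mean(depth[wrap_pos(b + 0:(flank - 1L), L)])
    left <- mean(depth[wrap_pos(b - seq_len(flank), L)])
    right - left
  }, numeric(1))
  if (side == "start") cands[which.min(score)]
  else wrap_pos(cands[which.max(score)] - 1L, L)
}
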