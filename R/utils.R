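# Shared helpers: circular-genome arithmetic, coordinate conversion,
# input checks. Internal, position arguments are 1-based inclusive.

MT_GENOME_LENGTH <- 16569L

#' @noRd
stop_input <- function(...) {
  stop(structure(class = c("mitoscreen_input_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' @noRd
wrap_pos <- function(pos, genome_length = MT_GENOME_LENGTH) {
  ((pos - 1L) %% genome_length) + 1L
}

# Expand a possibly origin-wrapping interval to the ordered vector of
# positions it covers. start > end means the interval crosses 16569/1.
#' @noRd
interval_positions <- function(start, end, genome_length = MT_GENOME_LENGTH) {
  if (start <= end) seq.int(start, end)
  else c(seq.int(start, genome_length), seq.int(1L, end))
}

#' @noRd
interval_length <- function(start, end, genome_length = MT_GENOME_LENGTH) {
  if (start <= end) end - start + 1L
  else (genome_length - start + 1L) + end
}

# Does the (possibly wrapping) query interval overlap a non-wrapping
# feature [fstart, fend]?
#' @noRd
interval_overlaps <- function(qstart, qend, fstart, fend,
                              genome_length = MT_GENOME_LENGTH) {
  if (qstart <= qend) {
    qstart <= fend && qend >= fstart
  } else {
    # wraps: [qstart, L] U [1, qend]
    (qstart <= fend) || (qend >= fstart)
  }
}

# 1-based inclusive -> BED 0-based half-open; returns one or two rows
# (chromStart, chromEnd) when the interval wraps the origin.
#' @noRd
to_bed_intervals <- function(start, end, genome_length = MT_GENOME_LENGTH) {
  if (start <= end) {
    cbind(start - 1L, end)
  } else {
    rbind(cbind(start - 1L, genome_length), cbind(0L, end))
  }
}

#' @noRd
is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x == trunc(x) && x >= 0

#' @noRd
check_fraction <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1))
    stop_input(name, " must be in [0, 1]")
  invisible(x)
}

# Deterministic sub-seed derivation so per-sample draws are stable when
# other samples are added or reordered. Kept below 2^31 - 1.
#' @noRd
derive_seed <- function(master, ...) {
  parts <- unlist(lapply(list(...), function(p) utf8ToInt(paste0(p))))
  h <- as.double(master %% 2147483647L)
  for (p in parts) h <- (h * 131 + p) %% 2147483629
  as.integer(h %% 2147483647)
}

# Run an expression with a local RNG seed, restoring global state after.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
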