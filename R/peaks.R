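#' Coverage-threshold peak calling with summit-centered intervals
#'
#' Maximal runs of positions whose coverage is at least `min_coverage` become
#' raw regions. Each raw region's summit is its coverage maximum (leftmost on
#' ties) and the emitted peak is the `width`-bp interval centered at the
#' summit, regardless of the raw region's extent. Intervals are clipped at
#' position 0 (clipped peaks are flagged).
#'
#' @param track A `coverage_track` (see [coverage_track()]).
#' @param min_coverage Minimum per-base coverage defining a region (default
#'   10).
#' @param width Emitted interval width in bp (default 500; use 200 for
#'   motif-overlap style peak sets).
#' @param sample_id Label recorded on each peak.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `summit`,
#'   `max_coverage`, `sample_id`, `clipped`, sorted by `start`.
#' @export
call_peaks <- function(track, min_coverage = 10L, width = 500L,
                       sample_id = "sample") {
  stopifnot(min_coverage >= 1, width >= 1)
  v <- track$values
  above <- v >= min_coverage
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  n <- length(runs)
  summit <- integer(n); maxcov <- numeric(n)
  for (k in seq_len(n)) {
    i0 <- starts[runs[k]]; i1 <- ends[runs[k]]
    seg <- v[i0:i1]
    j <- which.max(seg)                      # leftmost maximum
    summit[k] <- track$origin + i0 - 1L + (j - 1L)
    maxcov[k] <- seg[j]
  }
  half <- width %/% 2L
  start <- summit - half
  clipped <- start < 0L
  start <- pmax(0L, start)
  out <- data.frame(
    chrom = rep(track$chrom, n),
    start = as.integer(start),
    end = as.integer(summit - half + width),
    summit = summit,
    max_coverage = maxcov,
    sample_id = rep(sample_id, n),
    clipped = clipped,
    stringsAsFactors = FALSE
  )
  out[order(out$start), , drop = FALSE]
}

#' Merge peak sets into a union of disjoint intervals
#'
#' Overlapping and bookended intervals across all input sets are merged into
#' maximal disjoint intervals, sorted by chromosome and start.
#'
#' @param peak_sets A list of peak or interval `data.frame`s (each with
#'   `chrom`, `start`, `end`), or a single such `data.frame`.
#' @return Interval `data.frame` of disjoint merged intervals.
#' @export
union_intervals <- function(peak_sets) {
  if (is.data.frame(peak_sets)) peak_sets <- list(peak_sets)
  all <- do.call(rbind, lapply(peak_sets, function(p)
    p[, c("chrom", "start", "end"), drop = FALSE]))
  if (is.null(all) || nrow(all) == 0)
    return(genomic_intervals(character(), integer(), integer()))
  merged <- GenomicRanges::reduce(as_granges(all))  # merges bookended too
  out <- from_granges(GenomicRanges::sort(merged))
  rownames(out) <- NULL
  out
}

#' Read a conservation score table
#'
#' Tab-delimited, no header: chrom, start, end, mean_score (0-based half-open
#' intervals; scores in \[0, 1\], e.g. interval-averaged phastCons).
#'
#' @param path Path to the table.
#' @return `data.frame` with columns `chrom`, `start`, `end`, `mean_score`.
#' @export
read_conservation <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "mean_score"))
  out <- as.data.frame(dt)
  if (any(out$mean_score < 0 | out$mean_score > 1))
    stop("conservation scores must lie in [0, 1]", call. = FALSE)
  out
}

#' Filter intervals by mean conservation score
#'
#' Keeps intervals whose mean score is strictly greater than `min_score`.
#' Every interval must have a matching score record (same chrom/start/end).
#'
#' @param intervals Interval `data.frame`.
#' @param scores Conservation `data.frame` (see [read_conservation()]).
#' @param min_score Strict lower bound (default 0.8).
#' @return The conserved subset of `intervals`.
#' @export
filter_conserved <- function(intervals, scores, min_score = 0.8) {
  key_i <- paste(intervals$chrom, intervals$start, intervals$end)
  key_s <- paste(scores$chrom, scores$start, scores$end)
  idx <- match(key_i, key_s)
  if (anyNA(idx)) {
    miss <- which(is.na(idx))[1]
    stop("no conservation score for interval ", key_i[miss], call. = FALSE)
  }
  keep <- scores$mean_score[idx] > min_score
  out <- intervals[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
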