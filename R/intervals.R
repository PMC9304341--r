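#' Construct a table of genomic intervals
#'
#' Intervals are 0-based half-open (BED convention): `start` is the first base
#' included, `end` the first base excluded. One-based inclusive genome-browser
#' spans can be converted with `from_browser = TRUE`.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors of coordinates (recycled against `chrom`).
#' @param strand Strand, one of `"+"`, `"-"`, `"."` (default `"."`).
#' @param from_browser If `TRUE`, `start`/`end` are interpreted as 1-based
#'   inclusive and converted to 0-based half-open (`start - 1`, `end`).
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `strand`.
#' @examples
#' genomic_intervals("chr5", 29314590, 29316266)
#' genomic_intervals("chr5", 29314591, 29316266, from_browser = TRUE)
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".",
                              from_browser = FALSE) {
  if (from_browser) start <- start - 1L
  out <- data.frame(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    strand = as.character(strand),
    stringsAsFactors = FALSE
  )
  validate_intervals(out)
  out
}

validate_intervals <- function(x, what = "interval") {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$start)) || any(is.na(x$end)))
    stop(what, ": start/end must be non-missing integers", call. = FALSE)
  if (any(x$start < 0))
    stop(what, ": start must be >= 0", call. = FALSE)
  bad <- which(x$end <= x$start)
  if (length(bad))
    stop(what, ": end must be > start (first violation at row ", bad[1], ")",
         call. = FALSE)
  if (any(!nzchar(x$chrom)))
    stop(what, ": chrom must be non-empty", call. = FALSE)
  invisible(x)
}

# internal: data.frame intervals -> GRanges (still 0-based stored as 1-based
# IRanges internally; converted back on the way out)
as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

from_granges <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = ".",
    stringsAsFactors = FALSE
  )
}

#' Central sub-window of each interval
#'
#' @param intervals Interval `data.frame`.
#' @param width Width in bp of the centered sub-window.
#' @return Interval `data.frame` of the same length.
#' @export
central_window <- function(intervals, width) {
  validate_intervals(intervals)
  mid <- (intervals$start + intervals$end) %/% 2L
  out <- intervals
  out$start <- pmax(0L, as.integer(mid - width %/% 2L))
  out$end <- as.integer(out$start + width)
  out
}

# internal: logical, does each query interval overlap >= 1 bp of any subject
overlaps_any <- function(query, subject) {
  if (nrow(subject) == 0) return(rep(FALSE, nrow(query)))
  IRanges::overlapsAny(as_granges(query), as_granges(subject))
}
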