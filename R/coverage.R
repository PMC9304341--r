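#' Per-base fragment coverage over a window
#'
#' `values[i]` counts the fragments whose interval overlaps position
#' `origin + i - 1` (0-based). Fragments on other chromosomes are ignored;
#' fragments partially outside the window contribute their clipped overlap.
#'
#' @param fragments Fragment `data.frame`.
#' @param chrom Chromosome of the window.
#' @param window Single-row interval `data.frame` (see [genomic_intervals()]),
#'   or `NULL` to span the full fragment extent on `chrom`.
#' @return A `coverage_track`: list with `chrom`, `origin` (0-based start of
#'   the window) and integer `values`.
#' @export
coverage_track <- function(fragments, chrom, window = NULL) {
  if (is.null(window)) {
    on_chrom <- fragments[fragments$chrom == chrom, , drop = FALSE]
    if (nrow(on_chrom) == 0)
      stop("no fragments on ", chrom, " and no window given", call. = FALSE)
    window <- genomic_intervals(chrom, min(on_chrom$start), max(on_chrom$end))
  }
  validate_intervals(window, "window")
  origin <- window$start[1]
  width <- window$end[1] - origin
  f <- fragments[fragments$chrom == chrom, , drop = FALSE]
  s <- pmax(f$start, origin) - origin
  e <- pmin(f$end, window$end[1]) - origin
  keep <- e > s
  s <- s[keep]; e <- e[keep]
  # difference array: +1 at each clipped start, -1 at each clipped end
  delta <- integer(width + 1L)
  if (length(s)) {
    ts <- tabulate(s + 1L, nbins = width + 1L)
    te <- tabulate(e + 1L, nbins = width + 1L)
    delta <- ts - te
  }
  new_track(chrom, origin, cumsum(delta[seq_len(width)]))
}

new_track <- function(chrom, origin, values) {
  structure(
    list(chrom = chrom, origin = as.integer(origin), values = as.numeric(values)),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %s:%d-%d  (%d bp, max %g)\n",
              x$chrom, x$origin, x$origin + length(x$values),
              length(x$values), if (length(x$values)) max(x$values) else 0))
  invisible(x)
}

#' Write a coverage track as bedGraph
#'
#' Runs of equal value are merged into single records; zero-valued runs are
#' omitted (the reader treats absent positions as zero).
#'
#' @param track A `coverage_track`.
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  r <- rle(track$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != 0
  dt <- data.table::data.table(
    chrom = track$chrom,
    start = track$origin + starts[keep],
    end = track$origin + ends[keep],
    value = r$values[keep]
  )
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a bedGraph file back into a coverage track
#'
#' @param path bedGraph path.
#' @param chrom Chromosome to extract.
#' @param window Single-row interval `data.frame`, or `NULL` to span the
#'   records on `chrom`. Positions without a record are zero.
#' @return A `coverage_track`.
#' @export
read_bedgraph <- function(path, chrom, window = NULL) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "value"))
  dt <- dt[dt$chrom == chrom, ]
  if (is.null(window)) {
    if (nrow(dt) == 0) stop("no records on ", chrom, call. = FALSE)
    window <- genomic_intervals(chrom, min(dt$start), max(dt$end))
  }
  origin <- window$start[1]
  width <- window$end[1] - origin
  values <- numeric(width)
  if (nrow(dt)) {
    s <- pmax(dt$start, origin) - origin
    e <- pmin(dt$end, window$end[1]) - origin
    for (i in which(e > s)) {
      values[(s[i] + 1L):e[i]] <- dt$value[i]
    }
  }
  new_track(chrom, origin, values)
}
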