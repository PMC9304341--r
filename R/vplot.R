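#' Define a V-plot binning grid
#'
#' A V-plot is a 2-D histogram of fragments around a genomic anchor: columns
#' bin the fragment midpoint position across a `window_width`-bp window, rows
#' bin the fragment length over `[size_min, size_max)`. Defaults (640-bp
#' window, 10-bp bins, sizes 50-370) give a 32 x 64 grid that resolves the
#' sub-nucleosomal (< ~150 bp) and mono-nucleosomal (~180-250 bp) bands.
#'
#' @param window_width Window width in bp; must be divisible by
#'   `position_bin`.
#' @param position_bin Position bin width in bp.
#' @param size_min,size_max Fragment-size range, half-open
#'   `[size_min, size_max)`; the span must be divisible by `size_bin`.
#' @param size_bin Fragment-size bin width in bp.
#' @return A `vplot_grid` object.
#' @export
vplot_grid <- function(window_width = 640L, position_bin = 10L,
                       size_min = 50L, size_max = 370L, size_bin = 10L) {
  stopifnot(window_width > 0, position_bin > 0, size_bin > 0,
            size_max > size_min,
            window_width %% position_bin == 0,
            (size_max - size_min) %% size_bin == 0)
  structure(
    list(window_width = as.integer(window_width),
         position_bin = as.integer(position_bin),
         size_min = as.integer(size_min), size_max = as.integer(size_max),
         size_bin = as.integer(size_bin),
         n_pos = as.integer(window_width %/% position_bin),
         n_size = as.integer((size_max - size_min) %/% size_bin)),
    class = "vplot_grid"
  )
}

same_grid <- function(a, b) {
  identical(unclass(a)[c("window_width", "position_bin", "size_min",
                         "size_max", "size_bin")],
            unclass(b)[c("window_width", "position_bin", "size_min",
                         "size_max", "size_bin")])
}

#' Build the V-plot of one region
#'
#' A fragment contributes one count to the cell indexed by the size bin of
#' its length and the position bin of its midpoint, iff its midpoint lies in
#' the region and `size_min <= length < size_max`. Total mass equals the
#' number of qualifying fragments.
#'
#' @param fragments Fragment `data.frame`.
#' @param region Single-row interval `data.frame`; its width must equal
#'   `grid$window_width` (clipped windows are rejected).
#' @param grid A [vplot_grid()].
#' @return A `vplot` object: list with `region`, `grid`, `counts`
#'   (size bins x position bins) and `total`.
#' @export
build_vplot <- function(fragments, region, grid = vplot_grid()) {
  validate_intervals(region, "region")
  if ((region$end[1] - region$start[1]) != grid$window_width)
    stop("region width ", region$end[1] - region$start[1],
         " != grid window width ", grid$window_width, call. = FALSE)
  f <- fragments[fragments$chrom == region$chrom[1], , drop = FALSE]
  mid <- (f$start + f$end) %/% 2L
  keep <- mid >= region$start[1] & mid < region$end[1] &
    f$length >= grid$size_min & f$length < grid$size_max
  mid <- mid[keep]
  len <- f$length[keep]
  row <- (len - grid$size_min) %/% grid$size_bin + 1L
  col <- (mid - region$start[1]) %/% grid$position_bin + 1L
  counts <- matrix(0L, grid$n_size, grid$n_pos)
  if (length(row)) {
    tab <- tabulate((col - 1L) * grid$n_size + row,
                    nbins = grid$n_size * grid$n_pos)
    counts <- matrix(tab, grid$n_size, grid$n_pos)
  }
  structure(
    list(region = region[1, c("chrom", "start", "end"), drop = FALSE],
         grid = grid, counts = counts, total = sum(counts)),
    class = "vplot"
  )
}

#' Build V-plots for many regions at once
#'
#' @param fragments Fragment `data.frame`.
#' @param regions Interval `data.frame`, one V-plot per row.
#' @param grid A [vplot_grid()].
#' @return List of `vplot` objects.
#' @export
build_vplots <- function(fragments, regions, grid = vplot_grid()) {
  lapply(seq_len(nrow(regions)), function(i)
    build_vplot(fragments, regions[i, , drop = FALSE], grid))
}

#' Aggregate V-plots over a region set
#'
#' Each V-plot is normalized to a density (counts / total); regions with zero
#' total carry no density information and are excluded (counted in
#' `n_skipped`). Densities are averaged element-wise and renormalized to
#' sum 1.
#'
#' @param vplots List of `vplot` objects sharing one grid.
#' @return An `aggregated_vplot`: list with `grid`, `density`, `n_regions`,
#'   `n_skipped`.
#' @export
aggregate_vplots <- function(vplots) {
  if (length(vplots) == 0)
    stop("cannot aggregate an empty set of V-plots", call. = FALSE)
  grid <- vplots[[1]]$grid
  for (v in vplots)
    if (!same_grid(v$grid, grid))
      stop("all V-plots must share one grid", call. = FALSE)
  nz <- Filter(function(v) v$total > 0, vplots)
  if (length(nz) == 0)
    stop("cannot aggregate: all V-plots have zero total", call. = FALSE)
  acc <- Reduce(`+`, lapply(nz, function(v) v$counts / v$total))
  dens <- acc / length(nz)
  dens <- dens / sum(dens)
  structure(
    list(grid = grid, density = dens, n_regions = length(nz),
         n_skipped = length(vplots) - length(nz)),
    class = "aggregated_vplot"
  )
}

#' Coverage restricted to one fragment-size class
#'
#' @param fragments Fragment `data.frame`.
#' @param window Single-row interval `data.frame`.
#' @param keep Which class to keep: `"NFR"` or `"NUCLEOSOMAL"`.
#' @param threshold Size cutoff in bp (default 150; nucleosomal is strictly
#'   `> threshold`).
#' @return A `coverage_track` over `window`.
#' @export
size_partitioned_track <- function(fragments, window, keep = "NUCLEOSOMAL",
                                   threshold = 150L) {
  keep <- match.arg(keep, c("NFR", "NUCLEOSOMAL"))
  f <- fragments[classify_size(fragments, threshold) == keep, , drop = FALSE]
  coverage_track(f, window$chrom[1], window)
}

#' Depth-normalized ratio of two coverage tracks
#'
#' Both tracks are scaled to a common total mass within the window (their
#' mean total), then the per-base ratio
#' `(num + pseudocount) / (den + pseudocount)` is returned. Doubling one
#' track uniformly therefore leaves the ratio at 1.
#'
#' @param numerator,denominator `coverage_track`s over the same window.
#' @param pseudocount Added to both sides after depth normalization
#'   (default 1).
#' @return A `coverage_track` with real-valued `values` (the ratios).
#' @export
accessibility_ratio_track <- function(numerator, denominator,
                                      pseudocount = 1.0) {
  if (numerator$chrom != denominator$chrom ||
      numerator$origin != denominator$origin ||
      length(numerator$values) != length(denominator$values))
    stop("ratio track requires two tracks over the same window", call. = FALSE)
  sn <- sum(numerator$values); sd_ <- sum(denominator$values)
  target <- mean(c(sn, sd_))
  nv <- if (sn > 0) numerator$values * (target / sn) else numerator$values
  dv <- if (sd_ > 0) denominator$values * (target / sd_) else denominator$values
  new_track(numerator$chrom, numerator$origin,
            (nv + pseudocount) / (dv + pseudocount))
}

#' Smoothed nucleosome-occupancy proxy
#'
#' Gaussian-kernel-smoothed density of the midpoints of nucleosome-sized
#' fragments (length strictly greater than `threshold`). The track sums to
#' the number of such midpoints in the window, up to kernel mass lost at the
#' window edges. This is a deliberately simple stand-in for model-based
#' nucleosome callers: high values mark where nucleosome-protected fragments
#' are centered.
#'
#' @param fragments Fragment `data.frame`.
#' @param window Single-row interval `data.frame`.
#' @param threshold Nucleosomal size cutoff in bp (default 150).
#' @param kernel_sd Gaussian kernel standard deviation in bp (default 20).
#' @return A `coverage_track` with real-valued `values`.
#' @export
occupancy_proxy <- function(fragments, window, threshold = 150L,
                            kernel_sd = 20) {
  stopifnot(kernel_sd > 0)
  f <- fragments[fragments$chrom == window$chrom[1] &
                   fragments$length > threshold, , drop = FALSE]
  mid <- (f$start + f$end) %/% 2L
  mid <- mid[mid >= window$start[1] & mid < window$end[1]]
  origin <- window$start[1]
  width <- window$end[1] - origin
  pos <- origin + seq_len(width) - 1L
  values <- numeric(width)
  for (m in mid) values <- values + stats::dnorm(pos, mean = m, sd = kernel_sd)
  new_track(window$chrom[1], origin, values)
}
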