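#' Four-way open/closed grouping of motif-centric regions
#'
#' A region is "open" in a sample iff the central `center_width`-bp window
#' of the region overlaps at least 1 bp of any called peak in that sample.
#' The code concatenates the state in reference sample A then B
#' (`1` = open): `"00"` closed in both, `"01"` open in B only, `"10"` open
#' in A only, `"11"` open in both.
#'
#' @param regions Interval `data.frame` of motif-centric windows.
#' @param peaks_a,peaks_b Peak `data.frame`s (see [call_peaks()]) for the
#'   two reference samples.
#' @param center_width Central window in bp (default 200).
#' @return `data.frame`: `chrom`, `start`, `end`, `code`.
#' @export
assign_groups <- function(regions, peaks_a, peaks_b, center_width = 200L) {
  validate_intervals(regions, "regions")
  centers <- central_window(regions, center_width)
  open_a <- overlaps_any(centers, peaks_a)
  open_b <- overlaps_any(centers, peaks_b)
  data.frame(
    chrom = regions$chrom, start = regions$start, end = regions$end,
    code = paste0(as.integer(open_a), as.integer(open_b)),
    stringsAsFactors = FALSE
  )
}

#' Annotation-overlap proportion per accessibility group
#'
#' For each of the four codes, counts how many regions overlap at least one
#' annotation interval (e.g. known enhancers, ChIP-seq peaks) and the
#' proportion among the group's regions. Codes with zero regions are
#' reported with proportion `NA`.
#'
#' @param groups Output of [assign_groups()].
#' @param annotation Interval `data.frame` of annotated elements.
#' @return `data.frame` with one row per code: `code`, `n_regions`,
#'   `n_annotated`, `proportion`.
#' @export
group_enrichment <- function(groups, annotation) {
  hit <- overlaps_any(groups, annotation)
  codes <- c("00", "01", "10", "11")
  out <- data.frame(code = codes, n_regions = 0L, n_annotated = 0L,
                    proportion = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_along(codes)) {
    sel <- groups$code == codes[k]
    out$n_regions[k] <- sum(sel)
    out$n_annotated[k] <- sum(hit & sel)
    if (out$n_regions[k] > 0)
      out$proportion[k] <- out$n_annotated[k] / out$n_regions[k]
  }
  out
}
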