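#' Read ATAC fragments from a BED3+ file
#'
#' Reads tab-separated BED records (no header; gzip-transparent) into a
#' fragment table. Each record is one sequenced fragment, i.e. the span
#' between two Tn5 insertion events.
#'
#' @param path Path to a BED3+ file (`chrom`, `start`, `end`, further columns
#'   ignored). May be gzip-compressed.
#' @param sample_id,replicate_id Identity attached to every record.
#' @param permissive If `FALSE` (default) malformed lines abort with an error
#'   naming the line; if `TRUE` they are skipped and counted in the
#'   `"n_skipped"` attribute.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `sample_id`,
#'   `replicate_id`, `length`, in file order.
#' @export
read_fragment_bed <- function(path, sample_id = "sample", replicate_id = "rep1",
                              permissive = FALSE) {
  if (!file.exists(path)) stop("fragment file not found: ", path, call. = FALSE)
  if (file.size(path) == 0)
    return(fragment_table(character(), integer(), integer(),
                          sample_id, replicate_id))
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                          colClasses = list(character = 1))
  if (nrow(dt) == 0) {
    return(fragment_table(character(), integer(), integer(),
                          sample_id, replicate_id))
  }
  if (ncol(dt) < 3)
    stop("BED file must have >= 3 tab-separated columns: ", path, call. = FALSE)
  chrom <- as.character(dt[[1]])
  start <- suppressWarnings(as.integer(dt[[2]]))
  end <- suppressWarnings(as.integer(dt[[3]]))
  bad <- is.na(start) | is.na(end) | start < 0 | end <= start | !nzchar(chrom)
  if (any(bad)) {
    if (!permissive)
      stop("malformed BED record at line ", which(bad)[1], " of ", path,
           call. = FALSE)
    n_skipped <- sum(bad)
    chrom <- chrom[!bad]; start <- start[!bad]; end <- end[!bad]
  } else n_skipped <- 0L
  out <- fragment_table(chrom, start, end, sample_id, replicate_id)
  attr(out, "n_skipped") <- n_skipped
  out
}

fragment_table <- function(chrom, start, end, sample_id, replicate_id) {
  data.frame(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    sample_id = rep_len(as.character(sample_id), length(chrom)),
    replicate_id = rep_len(as.character(replicate_id), length(chrom)),
    length = as.integer(end) - as.integer(start),
    stringsAsFactors = FALSE
  )
}

#' Write fragments as BED
#'
#' Columns: chrom, start, end, sample_id, replicate_id. Round-trips through
#' [read_fragment_bed()].
#'
#' @param fragments Fragment `data.frame`.
#' @param path Output path (`.gz` suffix compresses).
#' @export
write_fragment_bed <- function(fragments, path) {
  data.table::fwrite(
    fragments[, c("chrom", "start", "end", "sample_id", "replicate_id")],
    path, sep = "\t", col.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Tn5 insertion-offset correction
#'
#' Moves each fragment's left coordinate (the plus-strand read start) +4 bp
#' and its right coordinate (the minus-strand read start) -5 bp, so that both
#' ends mark the center of the Tn5 transposition event. Every corrected
#' fragment is exactly 9 bp shorter. Fragments of length <= 9 bp would invert
#' and are dropped; their count is recorded in the `"n_dropped"` attribute.
#'
#' @param fragments Fragment `data.frame`.
#' @return Corrected fragment `data.frame` (possibly fewer rows), with
#'   attribute `"n_dropped"`.
#' @export
tn5_shift <- function(fragments) {
  drop <- fragments$length <= 9L
  out <- fragments[!drop, , drop = FALSE]
  out$start <- out$start + 4L
  out$end <- out$end - 5L
  out$length <- out$end - out$start
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(drop)
  out
}

#' Classify fragments as sub-nucleosomal or nucleosomal
#'
#' Fragments longer than `threshold` bp are nucleosome-protected
#' (`"NUCLEOSOMAL"`); fragments of `threshold` bp or shorter come from
#' nucleosome-free DNA (`"NFR"`). The tie at exactly `threshold` is NFR
#' (the nucleosomal class is strictly `> threshold`).
#'
#' @param lengths Integer vector of fragment lengths, or a fragment
#'   `data.frame` with a `length` column.
#' @param threshold Size cutoff in bp (default 150).
#' @return Character vector of `"NFR"` / `"NUCLEOSOMAL"`.
#' @export
classify_size <- function(lengths, threshold = 150L) {
  stopifnot(threshold > 0)
  if (is.data.frame(lengths)) lengths <- lengths$length
  ifelse(lengths > threshold, "NUCLEOSOMAL", "NFR")
}
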