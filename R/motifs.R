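#' Parse a degenerate consensus pattern
#'
#' Patterns are written as a run of bases where a parenthesized alternative
#' group `(A/C/G)` allows any of the listed bases at that position, e.g. the
#' ETS-family binding consensus `"(A/C/G)AGGAA(G/A)T"`. Only A, C, G, T are
#' allowed inside groups; `N` never matches.
#'
#' @param consensus Pattern string.
#' @return A list of per-position allowed-base character vectors.
#' @export
parse_consensus <- function(consensus) {
  chars <- strsplit(consensus, "")[[1]]
  allowed <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "(") {
      j <- i
      while (j <= length(chars) && chars[j] != ")") j <- j + 1L
      if (j > length(chars)) stop("unclosed '(' in consensus", call. = FALSE)
      grp <- strsplit(paste(chars[(i + 1L):(j - 1L)], collapse = ""), "/")[[1]]
      if (!all(grp %in% c("A", "C", "G", "T")) || length(grp) == 0)
        stop("invalid alternative group in consensus: ",
             paste(grp, collapse = "/"), call. = FALSE)
      allowed[[length(allowed) + 1L]] <- grp
      i <- j + 1L
    } else if (ch %in% c("A", "C", "G", "T")) {
      allowed[[length(allowed) + 1L]] <- ch
      i <- i + 1L
    } else {
      stop("invalid consensus character: '", ch, "'", call. = FALSE)
    }
  }
  if (length(allowed) == 0) stop("empty consensus pattern", call. = FALSE)
  allowed
}

revcomp_chars <- function(chars) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rev(unname(map[chars]))
}

#' Reverse-complement a DNA string
#' @param x DNA string over A/C/G/T/N.
#' @return Reverse complement string.
#' @export
reverse_complement <- function(x) {
  paste(revcomp_chars(strsplit(toupper(x), "")[[1]]), collapse = "")
}

scan_one_strand <- function(chars, allowed) {
  m <- length(allowed)
  L <- length(chars)
  if (L < m) return(integer())
  npos <- L - m + 1L
  ok <- rep(TRUE, npos)
  for (j in seq_len(m)) {
    ok <- ok & chars[seq_len(npos) + (j - 1L)] %in% allowed[[j]]
  }
  which(ok)
}

#' Scan a sequence for a degenerate consensus on both strands
#'
#' Minus-strand matches are found by scanning with the reverse-complemented
#' pattern; their coordinates and `matched_sequence` are reported on the
#' forward strand. `N` bases never match.
#'
#' @param sequence DNA string over A/C/G/T/N (case-insensitive).
#' @param consensus Degenerate pattern (see [parse_consensus()]).
#' @param offset 0-based genomic coordinate of the first sequence base.
#' @param chrom Chromosome name recorded on each site.
#' @param motif_name Name recorded on each site.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `strand`,
#'   `motif_name`, `matched_sequence`, sorted by `start`.
#' @export
scan_consensus <- function(sequence, consensus = "(A/C/G)AGGAA(G/A)T",
                           offset = 0L, chrom = "chr", motif_name = "motif") {
  allowed <- parse_consensus(consensus)
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (length(bad <- setdiff(unique(chars), c("A", "C", "G", "T", "N"))))
    stop("invalid sequence character(s): ", paste(bad, collapse = ","),
         call. = FALSE)
  m <- length(allowed)
  fwd <- scan_one_strand(chars, allowed)
  rc_allowed <- rev(lapply(allowed, revcomp_chars))
  rev_ <- scan_one_strand(chars, rc_allowed)
  pos <- c(fwd, rev_)
  strand <- rep(c("+", "-"), c(length(fwd), length(rev_)))
  o <- order(pos, strand)
  pos <- pos[o]; strand <- strand[o]
  matched <- vapply(pos, function(p)
    paste(chars[p:(p + m - 1L)], collapse = ""), character(1))
  data.frame(
    chrom = rep(chrom, length(pos)),
    start = as.integer(offset + pos - 1L),
    end = as.integer(offset + pos - 1L + m),
    strand = strand,
    motif_name = rep(motif_name, length(pos)),
    matched_sequence = matched,
    stringsAsFactors = FALSE
  )
}

#' Scan a FASTA file for a degenerate consensus
#'
#' Applies [scan_consensus()] to each sequence; the sequence name is used as
#' the chromosome.
#'
#' @param path FASTA path.
#' @param consensus Degenerate pattern.
#' @param motif_name Name recorded on each site.
#' @return Combined site `data.frame` across all sequences.
#' @export
scan_fasta <- function(path, consensus = "(A/C/G)AGGAA(G/A)T",
                       motif_name = "motif") {
  seqs <- Biostrings::readDNAStringSet(path)
  hits <- lapply(seq_along(seqs), function(i) {
    scan_consensus(as.character(seqs[[i]]), consensus,
                   chrom = sub("\\s.*$", "", names(seqs)[i]),
                   motif_name = motif_name)
  })
  do.call(rbind, hits)
}

#' Fixed-width windows centered on motif midpoints
#'
#' Each window is centered at the midpoint of its motif site and has total
#' width `width`. Windows extending below position 0 are clipped and flagged.
#'
#' @param sites Motif-site `data.frame` (needs `chrom`, `start`, `end`).
#' @param width Even window width in bp (default 640).
#' @return Interval `data.frame` with a logical `clipped` column.
#' @export
motif_centric_windows <- function(sites, width = 640L) {
  stopifnot(width %% 2L == 0L)
  mid <- (sites$start + sites$end) %/% 2L
  start <- mid - width %/% 2L
  clipped <- start < 0L
  out <- data.frame(
    chrom = sites$chrom,
    start = as.integer(pmax(0L, start)),
    end = as.integer(start + width),
    strand = ".",
    clipped = clipped,
    stringsAsFactors = FALSE
  )
  out
}
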