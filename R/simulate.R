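#' Configuration for the nucleosome-aware fragment simulator
#'
#' The generator emulates the fragment-level structure of paired-end ATAC
#' data around motif-centric windows: a mixture of sub-nucleosomal fragments
#' (midpoints uniform in a central nucleosome-free sub-interval) and
#' mono-nucleosomal fragments (midpoints at positioned dyads with jitter),
#' a two-condition design with replicates, condition-specific nucleosome
#' displacement at designated regions (the sub-nucleosomal mixture weight
#' rises from `pi_nfr_base` to `pi_nfr_displaced`), and an optional
#' per-sample fragment-length shift emulating a batch effect.
#'
#' @param n_regions Number of 640-bp regions (default 200).
#' @param n_displaced Number of regions displaced in condition B (default
#'   40); always the first `n_displaced` regions.
#' @param fragments_per_region Fragments per region per sample (default
#'   300).
#' @param replicates_per_condition Replicates for each of the two
#'   conditions (default 2).
#' @param pi_nfr_base,pi_nfr_displaced Sub-nucleosomal mixture weight in
#'   baseline and displaced states (defaults 0.2 and 0.7).
#' @param nfr_len_mean,nfr_len_sd Sub-nucleosomal fragment length
#'   distribution, truncated to \[30, 150\] bp (defaults 75, 15).
#' @param nuc_len_mean,nuc_len_sd Mono-nucleosomal fragment length
#'   distribution, truncated to \[151, 330\] bp (defaults 200, 25).
#' @param dyad_jitter_sd Nucleosome positioning jitter in bp (default 10).
#' @param dyads Dyad offsets from region start (default 135, 320, 505:
#'   a nucleosome over the central motif flanked at ~185-bp spacing).
#' @param nfr_offsets Start/end offsets of the nucleosome-free sub-interval
#'   (default central 150 bp: 245-395).
#' @param batch_len_shift Named numeric vector of per-sample length shifts
#'   in bp (names = sample ids, e.g. `c(B_rep1 = 15)`); unnamed scalar
#'   applies to all samples. Default 0.
#' @param region_width,region_spacing,chrom Region geometry.
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_regions = 200L, n_displaced = 40L,
                       fragments_per_region = 300L,
                       replicates_per_condition = 2L,
                       pi_nfr_base = 0.2, pi_nfr_displaced = 0.7,
                       nfr_len_mean = 75, nfr_len_sd = 15,
                       nuc_len_mean = 200, nuc_len_sd = 25,
                       dyad_jitter_sd = 10,
                       dyads = c(135L, 320L, 505L),
                       nfr_offsets = c(245L, 395L),
                       batch_len_shift = 0,
                       region_width = 640L, region_spacing = 2000L,
                       chrom = "chrS", seed = 1L) {
  stopifnot(n_displaced <= n_regions, n_regions >= 1,
            pi_nfr_base >= 0, pi_nfr_base <= 1,
            pi_nfr_displaced >= 0, pi_nfr_displaced <= 1,
            nfr_len_sd > 0, nuc_len_sd > 0, dyad_jitter_sd > 0,
            all(dyads >= 0), all(dyads < region_width),
            nfr_offsets[1] >= 0, nfr_offsets[2] <= region_width,
            nfr_offsets[2] > nfr_offsets[1])
  structure(as.list(environment()), class = "sim_config")
}

# truncated normal via inverse-CDF; errors on impossible bounds
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd); phi <- stats::pnorm(hi, mean, sd)
  if (any(phi <= plo))
    stop("impossible truncation bounds [", lo, ", ", hi, "] for Normal(",
         mean, ", ", sd, ")", call. = FALSE)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Simulate two-condition ATAC fragment data with ground truth
#'
#' For every region and sample, `fragments_per_region` fragments are drawn:
#' with probability pi (the displaced value in displaced regions of
#' condition B, the base value otherwise) a sub-nucleosomal fragment with
#' midpoint uniform in the region's nucleosome-free sub-interval, otherwise
#' a mono-nucleosomal fragment whose midpoint is the dyad nearest a uniform
#' draw plus Gaussian jitter. Per-sample batch shifts move both length
#' means. Output is deterministic for a given seed.
#'
#' @param config A [sim_config()].
#' @param dir Optional directory: writes one fragment BED per sample and a
#'   `truth.tsv` table.
#' @return List with `fragments` (all samples), `samples`
#'   (`sample_id`, `condition`, `replicate`), `regions` (truth table with
#'   `region_id`, coordinates, `displaced`, motif coordinates) and
#'   `config`.
#' @export
simulate_fragments <- function(config = sim_config(), dir = NULL) {
  set.seed(config$seed)
  nr <- config$n_regions
  region_start <- 1000L + (seq_len(nr) - 1L) * config$region_spacing
  regions <- data.frame(
    region_id = sprintf("region_%03d", seq_len(nr)),
    chrom = config$chrom,
    start = region_start,
    end = region_start + config$region_width,
    displaced = seq_len(nr) <= config$n_displaced,
    stringsAsFactors = FALSE
  )
  mid <- (regions$start + regions$end) %/% 2L
  regions$motif_start <- mid - 4L   # 8-bp motif centered in the window
  regions$motif_end <- mid + 4L

  conds <- c("A", "B")
  samples <- expand.grid(replicate = seq_len(config$replicates_per_condition),
                         condition = conds, stringsAsFactors = FALSE)
  samples$sample_id <- paste0(samples$condition, "_rep", samples$replicate)
  samples <- samples[, c("sample_id", "condition", "replicate")]
  shift <- config$batch_len_shift
  shift_of <- function(id) {
    if (is.null(names(shift))) shift[1]
    else if (id %in% names(shift)) shift[[id]] else 0
  }

  frags <- vector("list", nrow(samples) * nr)
  k <- 0L
  for (s in seq_len(nrow(samples))) {
    id <- samples$sample_id[s]
    sh <- shift_of(id)
    for (i in seq_len(nr)) {
      pi_nfr <- if (regions$displaced[i] && samples$condition[s] == "B")
        config$pi_nfr_displaced else config$pi_nfr_base
      nf <- config$fragments_per_region
      is_nfr <- stats::runif(nf) < pi_nfr
      n1 <- sum(is_nfr); n2 <- nf - n1
      len <- integer(nf)
      midp <- integer(nf)
      if (n1 > 0) {
        len[is_nfr] <- pmin(150L, pmax(30L, as.integer(round(
          rtrunc_norm(n1, config$nfr_len_mean + sh, config$nfr_len_sd,
                      30, 150)))))
        midp[is_nfr] <- regions$start[i] + as.integer(
          config$nfr_offsets[1] +
            floor(stats::runif(n1) *
                    (config$nfr_offsets[2] - config$nfr_offsets[1])))
      }
      if (n2 > 0) {
        len[!is_nfr] <- pmin(330L, pmax(151L, as.integer(round(
          rtrunc_norm(n2, config$nuc_len_mean + sh, config$nuc_len_sd,
                      151, 330)))))
        u <- stats::runif(n2) * config$region_width
        nearest <- vapply(u, function(x)
          config$dyads[which.min(abs(config$dyads - x))], numeric(1))
        midp[!is_nfr] <- regions$start[i] + as.integer(round(
          nearest + stats::rnorm(n2, 0, config$dyad_jitter_sd)))
      }
      start <- midp - len %/% 2L
      k <- k + 1L
      frags[[k]] <- fragment_table(rep(config$chrom, nf), start, start + len,
                                   id, paste0("rep", samples$replicate[s]))
    }
  }
  fragments <- do.call(rbind, frags)
  rownames(fragments) <- NULL
  out <- list(fragments = fragments, samples = samples, regions = regions,
              config = config)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (id in samples$sample_id)
      write_fragment_bed(fragments[fragments$sample_id == id, , drop = FALSE],
                         file.path(dir, paste0(id, ".bed")))
    data.table::fwrite(regions, file.path(dir, "truth.tsv"), sep = "\t")
  }
  out
}

#' Fixture with known open/closed codes for grouping tests
#'
#' Builds regions whose ground-truth accessibility code (`00`, `01`, `10`,
#' `11`) is recovered exactly by [call_peaks()] at default parameters:
#' "open" regions receive `depth` fragments concentrated in their central
#' window (central coverage well above the caller's threshold), "closed"
#' regions receive 2 stray fragments.
#'
#' @param n_per_code Regions per code (default 50).
#' @param depth Fragments per open region per sample (default 60).
#' @param seed Integer seed.
#' @return List with `fragments_a`, `fragments_b` (one reference sample
#'   each), `regions` (with truth `code`), and `chrom`.
#' @export
generate_grouping_fixture <- function(n_per_code = 50L, depth = 60L,
                                      seed = 1L) {
  stopifnot(n_per_code >= 1)
  set.seed(seed)
  codes <- rep(c("00", "01", "10", "11"), each = n_per_code)
  nr <- length(codes)
  width <- 640L; spacing <- 2000L; chrom <- "chrG"
  start <- 1000L + (seq_len(nr) - 1L) * spacing
  regions <- data.frame(
    region_id = sprintf("region_%03d", seq_len(nr)),
    chrom = chrom, start = start, end = start + width, code = codes,
    stringsAsFactors = FALSE
  )
  one_sample <- function(open, id) {
    frags <- vector("list", nr)
    for (i in seq_len(nr)) {
      center <- (regions$start[i] + regions$end[i]) %/% 2L
      if (open[i]) {
        midp <- center + as.integer(floor(stats::runif(depth, -50, 50)))
        len <- rep(100L, depth)
      } else {
        midp <- regions$start[i] +
          as.integer(floor(stats::runif(2, 0, width)))
        len <- rep(100L, 2L)
      }
      s <- midp - len %/% 2L
      frags[[i]] <- fragment_table(rep(chrom, length(s)), s, s + len,
                                   id, "rep1")
    }
    out <- do.call(rbind, frags); rownames(out) <- NULL; out
  }
  list(
    fragments_a = one_sample(substr(codes, 1, 1) == "1", "refA"),
    fragments_b = one_sample(substr(codes, 2, 2) == "1", "refB"),
    regions = regions, chrom = chrom
  )
}

#' FASTA stub with planted consensus motif instances
#'
#' A random background sequence with non-overlapping instances of a
#' degenerate consensus planted at known positions (each instance sampled
#' from the pattern's allowed bases; roughly half are planted as reverse
#' complements). Useful as a scanner fixture: every planted site must be
#' found, though the random background may contribute extra matches.
#'
#' @param n_sites Number of planted instances (default 10).
#' @param length Sequence length in bp (default 5000).
#' @param consensus Degenerate pattern (see [parse_consensus()]).
#' @param seed Integer seed.
#' @param path Optional path: writes a single-record FASTA.
#' @return List with `sequence`, `sites` (`start`, `end`, `strand`,
#'   0-based) and `consensus`.
#' @export
simulate_motif_fasta <- function(n_sites = 10L, length = 5000L,
                                 consensus = "(A/C/G)AGGAA(G/A)T",
                                 seed = 1L, path = NULL) {
  set.seed(seed)
  allowed <- parse_consensus(consensus)
  m <- base::length(allowed)
  chars <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
  slots <- seq(51L, length - m - 50L, by = max(4L * m, 50L))
  stopifnot(base::length(slots) >= n_sites)
  pos <- sort(sample(slots, n_sites))
  strand <- sample(c("+", "-"), n_sites, replace = TRUE)
  sites <- data.frame(start = pos - 1L, end = pos - 1L + m, strand = strand,
                      stringsAsFactors = FALSE)
  for (i in seq_len(n_sites)) {
    inst <- vapply(allowed, function(a) sample(a, 1)[1], character(1))
    if (strand[i] == "-") inst <- revcomp_chars(inst)
    chars[pos[i]:(pos[i] + m - 1L)] <- inst
  }
  sequence <- paste(chars, collapse = "")
  if (!is.null(path))
    writeLines(c(">synthetic_motif_stub", sequence), path)
  list(sequence = sequence, sites = sites, consensus = consensus)
}
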