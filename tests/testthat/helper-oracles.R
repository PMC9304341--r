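# Independent brute-force oracles used across the suite. These deliberately
# recompute results the slow, obvious way and must stay free of package
# internals beyond plain accessors.

# per-position membership count: loop positions x fragments
oracle_coverage <- function(fragments, chrom, window) {
  width <- window$end[1] - window$start[1]
  vals <- numeric(width)
  for (i in seq_len(width)) {
    pos <- window$start[1] + i - 1L
    vals[i] <- sum(fragments$chrom == chrom &
                     fragments$start <= pos & fragments$end > pos)
  }
  vals
}

# position-by-position run scanner for the peak caller
oracle_peaks <- function(values, origin, chrom, min_coverage, width) {
  above <- values >= min_coverage
  out <- list()
  i <- 1L
  while (i <= length(values)) {
    if (above[i]) {
      j <- i
      while (j < length(values) && above[j + 1L]) j <- j + 1L
      seg <- values[i:j]
      best <- i - 1L + which(seg == max(seg))[1]     # leftmost max
      summit <- origin + best - 1L
      st <- summit - width %/% 2L
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = max(0L, st), end = st + width,
        summit = summit, max_coverage = max(seg), stringsAsFactors = FALSE)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), summit = integer(),
                      max_coverage = numeric()))
  df <- do.call(rbind, out)
  df[order(df$start), , drop = FALSE]
}

# double loop over fragments: the V-plot binning oracle
oracle_vplot <- function(fragments, region, grid) {
  counts <- matrix(0L, grid$n_size, grid$n_pos)
  for (i in seq_len(nrow(fragments))) {
    if (fragments$chrom[i] != region$chrom[1]) next
    mid <- (fragments$start[i] + fragments$end[i]) %/% 2L
    len <- fragments$length[i]
    if (mid < region$start[1] || mid >= region$end[1]) next
    if (len < grid$size_min || len >= grid$size_max) next
    r <- (len - grid$size_min) %/% grid$size_bin + 1L
    c <- (mid - region$start[1]) %/% grid$position_bin + 1L
    counts[r, c] <- counts[r, c] + 1L
  }
  counts
}

# boolean per-bp mask union of interval sets on one chromosome
oracle_union_mask <- function(interval_sets, limit) {
  mask <- logical(limit)
  for (s in interval_sets)
    for (i in seq_len(nrow(s)))
      if (s$end[i] > 0)
        mask[(s$start[i] + 1L):min(s$end[i], limit)] <- TRUE
  mask
}

interval_mask <- function(intervals, limit) {
  oracle_union_mask(list(intervals), limit)
}

# rank-sum AUROC of scores (higher score = predicted positive)
auroc <- function(scores, truth) {
  r <- rank(scores, ties.method = "average")
  n1 <- sum(truth); n0 <- sum(!truth)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

random_fragments <- function(n, chrom = "chr1", lo = 0L, hi = 2000L,
                             max_len = 400L) {
  start <- sample(lo:hi, n, replace = TRUE)
  len <- sample(20:max_len, n, replace = TRUE)
  data.frame(chrom = chrom, start = start, end = start + len,
             sample_id = "s", replicate_id = "r", length = len,
             stringsAsFactors = FALSE)
}

# deterministic tiny training set for VAE contract tests
tiny_vae_fixture <- function(n_regions = 20L, steps = 200L, seed = 7L) {
  cfg <- sim_config(n_regions = n_regions, n_displaced = n_regions %/% 4L,
                    fragments_per_region = 150L,
                    replicates_per_condition = 1L, seed = seed)
  sim <- simulate_fragments(cfg)
  grid <- vplot_grid()
  vplots <- list(); ids <- character(0)
  for (id in sim$samples$sample_id) {
    vp <- build_vplots(sim$fragments[sim$fragments$sample_id == id, ,
                                     drop = FALSE], sim$regions, grid)
    vplots <- c(vplots, vp)
    ids <- c(ids, rep(id, nrow(sim$regions)))
  }
  list(sim = sim, vplots = vplots, ids = ids, grid = grid,
       config = vae_config(total_steps = steps, warmup_steps = 20L,
                           hidden = 32L, batch_size = 32L, seed = seed))
}
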