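#' Fragment counts per interval per sample
#'
#' `counts[i, n]` is the number of sample-`n` fragments overlapping interval
#' `i` by at least 1 bp.
#'
#' @param fragments Fragment `data.frame` (with `sample_id`).
#' @param intervals Interval `data.frame` (e.g. the union peak set).
#' @return Integer matrix intervals x samples with sample ids as column
#'   names.
#' @export
count_fragments <- function(fragments, intervals) {
  validate_intervals(intervals)
  ids <- sort(unique(fragments$sample_id))
  gr_i <- as_granges(intervals)
  out <- matrix(0L, nrow(intervals), length(ids),
                dimnames = list(NULL, ids))
  for (id in ids) {
    f <- fragments[fragments$sample_id == id, , drop = FALSE]
    out[, id] <- GenomicRanges::countOverlaps(gr_i, as_granges(f))
  }
  out
}

#' Motif membership of intervals
#'
#' `membership[i, j]` is `TRUE` iff interval `i` overlaps at least one site
#' of motif `j`.
#'
#' @param intervals Interval `data.frame`.
#' @param sites Motif-site `data.frame` with a `motif_name` column.
#' @return Logical matrix intervals x motifs.
#' @export
motif_membership <- function(intervals, sites) {
  motifs <- sort(unique(sites$motif_name))
  out <- matrix(FALSE, nrow(intervals), length(motifs),
                dimnames = list(NULL, motifs))
  for (mj in motifs)
    out[, mj] <- overlaps_any(intervals,
                              sites[sites$motif_name == mj, , drop = FALSE])
  out
}

#' Expected motif-associated counts under uniform accessibility
#'
#' With `w_i` the fraction of all reads falling in interval `i` (pooled over
#' samples), the expected count of motif `j` in sample `n` is
#' `E[j, n] = (sum of w_i over member intervals) * (total reads in sample
#' n)`.
#'
#' @param counts Intervals x samples count matrix.
#' @param membership Intervals x motifs logical matrix.
#' @return Motifs x samples matrix of expected counts. Motifs without
#'   member intervals are recorded in the `"empty_motifs"` attribute.
#' @export
expected_counts <- function(counts, membership) {
  totals <- colSums(counts)
  if (any(totals == 0))
    stop("sample(s) with zero reads: ",
         paste(colnames(counts)[totals == 0], collapse = ", "), call. = FALSE)
  w <- rowSums(counts) / sum(counts)
  E <- (t(membership) %*% w) %*% t(totals)
  dimnames(E) <- list(colnames(membership), colnames(counts))
  attr(E, "empty_motifs") <- colnames(membership)[colSums(membership) == 0]
  E
}

# decile strata of intervals by pooled read fraction; returns index list
accessibility_strata <- function(w, n_strata = 10L) {
  rk <- rank(w, ties.method = "first")
  stratum <- ceiling(rk / (length(w) / n_strata))
  split(seq_along(w), stratum)
}

#' Bias-corrected motif deviation scores
#'
#' The raw deviation of motif `j` in sample `n` is
#' `(observed - expected) / expected` with expectations from
#' [expected_counts()]. Each motif is then standardized against
#' `n_background` random interval sets of the same size, drawn to match the
#' motif's member intervals on mean-accessibility decile: the reported
#' deviation is `(raw - mean_bg) / sd_bg`. Per-motif variability is the
#' standard deviation of the deviations across samples, with an upper-tail
#' empirical p-value from the background variability distribution
#' (add-one smoothed, so never exactly 0).
#'
#' @param counts Intervals x samples count matrix.
#' @param membership Intervals x motifs logical matrix.
#' @param n_background Number of background draws (default 50).
#' @param seed Integer seed for the background sampling.
#' @return List with `deviations` (motifs x samples), `variability`,
#'   `variability_p` (named per motif), and `excluded` (motifs with no
#'   member intervals).
#' @export
deviation_scores <- function(counts, membership, n_background = 50L,
                             seed = 1L) {
  stopifnot(n_background >= 2)
  empty <- colnames(membership)[colSums(membership) == 0]
  if (length(empty)) {
    warning("excluding motif(s) with no member intervals: ",
            paste(empty, collapse = ", "))
    membership <- membership[, colSums(membership) > 0, drop = FALSE]
  }
  E <- expected_counts(counts, membership)
  obs <- t(membership) %*% counts
  raw <- (obs - E) / E
  w <- rowSums(counts) / sum(counts)
  totals <- colSums(counts)
  strata <- accessibility_strata(w)
  stratum_of <- integer(length(w))
  for (s in seq_along(strata)) stratum_of[strata[[s]]] <- s

  set.seed(seed)
  n_motif <- ncol(membership); n_samp <- ncol(counts)
  bg_raw <- array(NA_real_, c(n_motif, n_samp, n_background))
  for (j in seq_len(n_motif)) {
    members <- which(membership[, j])
    tab <- table(stratum_of[members])
    for (b in seq_len(n_background)) {
      bg <- unlist(lapply(names(tab), function(s) {
        pool <- strata[[as.integer(s)]]
        sample(pool, tab[[s]], replace = tab[[s]] > length(pool))
      }), use.names = FALSE)
      ob <- colSums(counts[bg, , drop = FALSE])
      eb <- sum(w[bg]) * totals
      bg_raw[j, , b] <- (ob - eb) / eb
    }
  }
  mean_bg <- apply(bg_raw, c(1, 2), mean)
  sd_bg <- apply(bg_raw, c(1, 2), stats::sd)
  sd_bg[sd_bg == 0] <- 1e-12
  dev <- (raw - mean_bg) / sd_bg
  variability <- apply(dev, 1, stats::sd)
  bg_var <- matrix(NA_real_, n_motif, n_background)
  for (b in seq_len(n_background)) {
    dev_b <- (bg_raw[, , b] - mean_bg) / sd_bg
    if (is.null(dim(dev_b))) dev_b <- matrix(dev_b, n_motif, n_samp)
    bg_var[, b] <- apply(dev_b, 1, stats::sd)
  }
  variability_p <- (1 + rowSums(bg_var >= variability)) / (n_background + 1)
  names(variability) <- names(variability_p) <- rownames(raw)
  list(deviations = dev, variability = variability,
       variability_p = variability_p, excluded = empty)
}

#' PCA of motif deviation scores
#'
#' Samples are observations and motifs variables: the motifs x samples
#' deviation matrix is transposed, column-centered and decomposed by SVD.
#' Explained-variance fractions sum to 1; each component's sign is fixed by
#' making its largest-magnitude motif loading positive.
#'
#' @param deviations Motifs x samples matrix (e.g.
#'   `deviation_scores()$deviations`).
#' @return List with `scores` (samples x components),
#'   `loadings` (motifs x components), `explained_variance` (fractions).
#' @export
pca_deviations <- function(deviations) {
  if (ncol(deviations) < 2)
    stop("PCA needs at least 2 samples", call. = FALSE)
  X <- t(deviations)
  X <- sweep(X, 2, colMeans(X))
  sv <- svd(X)
  flip <- vapply(seq_along(sv$d), function(k) {
    l <- sv$v[, k]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(sv$u %*% diag(sv$d, length(sv$d)), 2, flip, `*`)
  loadings <- sweep(sv$v, 2, flip, `*`)
  rownames(scores) <- colnames(deviations)
  rownames(loadings) <- rownames(deviations)
  list(scores = scores, loadings = loadings,
       explained_variance = sv$d^2 / sum(sv$d^2))
}

#' Hierarchical clustering orders for a deviation heatmap
#'
#' Euclidean distance, average linkage; returns leaf orders for motifs
#' (rows) and samples (columns). Deterministic for a given matrix.
#'
#' @param deviations Motifs x samples matrix.
#' @return List with `row_order` and `column_order` (integer permutations).
#' @export
cluster_deviations <- function(deviations) {
  row_order <- if (nrow(deviations) > 1)
    stats::hclust(stats::dist(deviations), method = "average")$order
  else 1L
  column_order <- if (ncol(deviations) > 1)
    stats::hclust(stats::dist(t(deviations)), method = "average")$order
  else 1L
  list(row_order = row_order, column_order = column_order)
}
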