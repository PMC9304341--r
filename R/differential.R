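#' Chi-squared test between two pooled latent posteriors
#'
#' Replicate posteriors within each condition are pooled: the pooled mean is
#' the average of the replicate means and the pooled variance is the average
#' of the replicate variances divided by the replicate count (the variance
#' of the mean). The statistic is the standardized squared distance of the
#' pooled means,
#' `T = sum_k (muA_k - muB_k)^2 / (sdA_k^2 + sdB_k^2)`,
#' referred to the upper tail of a chi-squared distribution with K degrees
#' of freedom.
#'
#' @param mean_a,sd_a Replicates x K matrices (or K-vectors) of posterior
#'   means / standard deviations for condition A.
#' @param mean_b,sd_b Same for condition B.
#' @return List with `chi2_stat`, `df`, `p_value`.
#' @export
chi2_test <- function(mean_a, sd_a, mean_b, sd_b) {
  as_mat <- function(x) if (is.null(dim(x))) matrix(x, 1) else x
  mean_a <- as_mat(mean_a); sd_a <- as_mat(sd_a)
  mean_b <- as_mat(mean_b); sd_b <- as_mat(sd_b)
  if (ncol(mean_a) != ncol(mean_b))
    stop("latent dimensionality mismatch between conditions", call. = FALSE)
  stopifnot(nrow(mean_a) >= 1, nrow(mean_b) >= 1)
  K <- ncol(mean_a)
  mu_a <- colMeans(mean_a); va <- colMeans(sd_a^2) / nrow(mean_a)
  mu_b <- colMeans(mean_b); vb <- colMeans(sd_b^2) / nrow(mean_b)
  stat <- sum((mu_a - mu_b)^2 / (va + vb))
  list(chi2_stat = stat, df = K,
       p_value = stats::pchisq(stat, df = K, lower.tail = FALSE))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up adjusted p-values (`p * n / rank`, running minimum from
#' the largest p downward, capped at 1), returned in input order.
#'
#' @param p_values Numeric vector with entries in (0, 1].
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values <= 0 | p_values > 1 | !is.finite(p_values)))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  n <- length(p_values)
  if (n <= 1) return(p_values)
  o <- order(p_values, decreasing = TRUE)
  adj <- pmin(1, cummin(p_values[o] * n / seq(n, 1)))
  adj[order(o)]
}

# central nucleosomal density of a V-plot: fraction of total mass in
# size bins with lower edge >= threshold and position bins within
# center_width of the window center, with a count pseudocount
central_nuc_density <- function(vplot, center_width, threshold, pseudocount) {
  g <- vplot$grid
  size_lo <- g$size_min + (seq_len(g$n_size) - 1L) * g$size_bin
  rows <- which(size_lo >= threshold)
  center <- g$window_width / 2
  pos_lo <- (seq_len(g$n_pos) - 1L) * g$position_bin
  pos_hi <- pos_lo + g$position_bin
  cols <- which(pos_hi > center - center_width / 2 &
                  pos_lo < center + center_width / 2)
  cc <- sum(vplot$counts[rows, cols])
  (cc + pseudocount) / (vplot$total + pseudocount)
}

#' Log ratio of central nucleosomal density between two V-plots
#'
#' For each V-plot, the fraction of its mass that is nucleosome-sized
#' (fragment length strictly above `threshold`) and centered (position
#' within the central `center_width` bp of the window) is computed with a
#' count pseudocount; the natural log of the A/B ratio of these fractions
#' is returned. Negative values mean condition A has proportionally fewer
#' central nucleosomal fragments than B, i.e. the nucleosome over the
#' window center has been depleted in A.
#'
#' @param vplot_a,vplot_b `vplot` objects sharing one grid (replicates may
#'   be pooled by summing counts beforehand; see [pool_vplots()]).
#' @param center_width Central window in bp (default 200).
#' @param threshold Nucleosomal size cutoff in bp (default 150).
#' @param pseudocount Added to the central count and total (default 1).
#' @return Scalar log ratio.
#' @export
log_ratio <- function(vplot_a, vplot_b, center_width = 200L, threshold = 150L,
                      pseudocount = 1) {
  if (!same_grid(vplot_a$grid, vplot_b$grid))
    stop("V-plots have different grids", call. = FALSE)
  log(central_nuc_density(vplot_a, center_width, threshold, pseudocount) /
        central_nuc_density(vplot_b, center_width, threshold, pseudocount))
}

#' Pool replicate V-plots by summing counts
#'
#' @param vplots List of `vplot` objects over the same region and grid.
#' @return A single `vplot` with summed counts.
#' @export
pool_vplots <- function(vplots) {
  stopifnot(length(vplots) >= 1)
  out <- vplots[[1]]
  for (v in vplots[-1]) {
    if (!same_grid(v$grid, out$grid))
      stop("V-plots have different grids", call. = FALSE)
    out$counts <- out$counts + v$counts
  }
  out$total <- sum(out$counts)
  out
}

#' Differential V-plot test across a region set
#'
#' For every region, replicate V-plots are built per sample, encoded with
#' the trained VAE, pooled per condition, and compared with [chi2_test()];
#' p-values are BH-adjusted and the central-nucleosomal [log_ratio()]
#' (condition A over condition B) is attached.
#'
#' @param model A trained `vplot_vae`.
#' @param fragments Fragment `data.frame` covering all samples.
#' @param regions Interval `data.frame` of V-plot windows (width equal to
#'   the model grid's `window_width`).
#' @param samples `data.frame` with columns `sample_id`, `condition`.
#' @param condition_a,condition_b The two condition labels to compare
#'   (negative log ratio = central nucleosomal depletion in `condition_a`).
#' @return `data.frame` with one row per region: `chrom`, `start`, `end`,
#'   `chi2_stat`, `df`, `p_value`, `p_adjusted`, `log_ratio`, `rank`.
#' @export
test_differential <- function(model, fragments, regions, samples,
                              condition_a, condition_b) {
  grid <- model$config$grid
  ids_a <- samples$sample_id[samples$condition == condition_a]
  ids_b <- samples$sample_id[samples$condition == condition_b]
  if (length(ids_a) == 0 || length(ids_b) == 0)
    stop("both conditions need at least one sample", call. = FALSE)
  by_sample <- lapply(c(ids_a, ids_b), function(id)
    build_vplots(fragments[fragments$sample_id == id, , drop = FALSE],
                 regions, grid))
  names(by_sample) <- c(ids_a, ids_b)
  n <- nrow(regions)
  enc <- lapply(names(by_sample), function(id)
    encode_vplots(model, by_sample[[id]], rep(id, n)))
  names(enc) <- names(by_sample)
  stat <- p <- lr <- numeric(n)
  for (i in seq_len(n)) {
    ma <- do.call(rbind, lapply(ids_a, function(id) enc[[id]]$mean[i, ]))
    sa <- do.call(rbind, lapply(ids_a, function(id) enc[[id]]$sd[i, ]))
    mb <- do.call(rbind, lapply(ids_b, function(id) enc[[id]]$mean[i, ]))
    sb <- do.call(rbind, lapply(ids_b, function(id) enc[[id]]$sd[i, ]))
    ct <- chi2_test(ma, sa, mb, sb)
    stat[i] <- ct$chi2_stat; p[i] <- ct$p_value
    va <- pool_vplots(lapply(ids_a, function(id) by_sample[[id]][[i]]))
    vb <- pool_vplots(lapply(ids_b, function(id) by_sample[[id]][[i]]))
    lr[i] <- log_ratio(va, vb)
  }
  out <- data.frame(
    chrom = regions$chrom, start = regions$start, end = regions$end,
    chi2_stat = stat, df = model$config$K, p_value = p,
    p_adjusted = bh_adjust(p), log_ratio = lr,
    stringsAsFactors = FALSE
  )
  out$rank <- rank_regions(out)$results$rank
  out
}

#' Select and rank differential regions
#'
#' Selection keeps regions with `p_adjusted < p_cut` and
#' `log_ratio < lr_cut`. All regions are ranked by ascending adjusted
#' p-value with ascending log ratio as tie-breaker; a region's percentile
#' is `rank / n`.
#'
#' @param results Differential-result `data.frame`
#'   (see [test_differential()]).
#' @param p_cut Adjusted p-value cutoff (default 0.05).
#' @param lr_cut Log-ratio cutoff (default -0.2).
#' @param region_index Optional row index of a region of interest.
#' @return List with `results` (ranked), `selected` (the selected subset)
#'   and, when `region_index` is given, `percentile` of that region.
#' @export
rank_regions <- function(results, p_cut = 0.05, lr_cut = -0.2,
                         region_index = NULL) {
  o <- order(results$p_adjusted, results$log_ratio)
  rk <- integer(nrow(results)); rk[o] <- seq_len(nrow(results))
  results$rank <- rk
  sel <- results$p_adjusted < p_cut & results$log_ratio < lr_cut
  out <- list(results = results,
              selected = results[sel, , drop = FALSE])
  if (!is.null(region_index))
    out$percentile <- rk[region_index] / nrow(results)
  out
}
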