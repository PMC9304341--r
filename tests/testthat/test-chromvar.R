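# deterministic planted-motif fixture: n_intervals x 4 samples (2 per
# condition), motif_1's member intervals 3x accessible in condition A.
# Baseline accessibility is heterogeneous (gamma-distributed interval
# means), as in real peak sets, so decile-matched backgrounds are
# informative rather than collapsing onto the planted intervals.
planted_counts <- function(n_intervals = 400, n_motifs = 10, seed = 81,
                           effect = 3) {
  set.seed(seed)
  lambda <- rgamma(n_intervals, shape = 2, scale = 30)
  counts <- matrix(rpois(n_intervals * 4, lambda), n_intervals, 4,
                   dimnames = list(NULL, c("A1", "A2", "B1", "B2")))
  membership <- matrix(FALSE, n_intervals, n_motifs,
                       dimnames = list(NULL, paste0("motif_", 1:n_motifs)))
  for (j in 1:n_motifs)
    membership[sample(n_intervals, 40), j] <- TRUE
  members <- which(membership[, 1])
  counts[members, c("A1", "A2")] <- counts[members, c("A1", "A2")] * effect
  list(counts = counts, membership = membership)
}

test_that("expected_counts follows the read-fraction formula", {
  # uniform counts, motif owning half the intervals -> half of each total
  counts <- matrix(10, 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  membership <- matrix(c(rep(TRUE, 50), rep(FALSE, 50)), 100, 1,
                       dimnames = list(NULL, "m"))
  E <- expected_counts(counts, membership)
  expect_equal(as.numeric(E), rep(500, 3))

  zero <- counts; zero[, 2] <- 0
  expect_error(expected_counts(zero, membership), "zero reads")

  none <- cbind(membership, none = rep(FALSE, 100))
  expect_equal(attr(expected_counts(counts, none), "empty_motifs"), "none")
})

test_that("expected_counts matches the direct formula on random input", {
  set.seed(82)
  counts <- matrix(rpois(200 * 3, 20), 200, 3,
                   dimnames = list(NULL, c("x", "y", "z")))
  membership <- matrix(runif(200 * 4) < 0.3, 200, 4,
                       dimnames = list(NULL, paste0("m", 1:4)))
  E <- expected_counts(counts, membership)
  w <- rowSums(counts) / sum(counts)
  for (j in 1:4) for (n in 1:3)
    expect_equal(E[j, n], sum(w[membership[, j]]) * sum(counts[, n]))
})

test_that("a planted differential motif attains rank-1 variability", {
  fx <- planted_counts()
  dev <- deviation_scores(fx$counts, fx$membership, seed = 5)
  expect_equal(names(which.max(dev$variability)), "motif_1")
  expect_true(all(dev$variability_p["motif_1"] <=
                    dev$variability_p[-1]))
  expect_true(all(dev$variability_p > 0))
})

test_that("deviations are invariant to uniform count scaling", {
  fx <- planted_counts(n_intervals = 200, n_motifs = 5, seed = 83)
  d1 <- deviation_scores(fx$counts, fx$membership, seed = 9)
  d2 <- deviation_scores(fx$counts * 2L, fx$membership, seed = 9)
  expect_equal(d1$deviations, d2$deviations, tolerance = 1e-10)
  expect_equal(d1$variability, d2$variability, tolerance = 1e-10)
})

test_that("motifs with no member intervals are excluded with a warning", {
  fx <- planted_counts(n_intervals = 100, n_motifs = 3, seed = 84)
  fx$membership[, 2] <- FALSE
  expect_warning(dev <- deviation_scores(fx$counts, fx$membership, seed = 2),
                 "no member intervals")
  expect_equal(dev$excluded, "motif_2")
  expect_equal(nrow(dev$deviations), 2)
})

test_that("pca_deviations: rank-1 duplicated groups give PC1 fraction 1", {
  profile1 <- rnorm(20); profile2 <- rnorm(20)
  dev <- cbind(s1 = profile1, s2 = profile1, s3 = profile2, s4 = profile2)
  out <- pca_deviations(dev)
  expect_equal(out$explained_variance[1], 1, tolerance = 1e-10)
  expect_equal(sum(out$explained_variance), 1, tolerance = 1e-10)
  expect_error(pca_deviations(dev[, 1, drop = FALSE]), "2 samples")
})

test_that("pca_deviations explained fractions match eigenvalues", {
  set.seed(85)
  X <- matrix(rnorm(30 * 6), 30, 6, dimnames = list(NULL, paste0("s", 1:6)))
  out <- pca_deviations(X)
  C <- t(X) - colMeans(t(X))  # center samples-x-motifs matrix by motif
  C <- sweep(t(X), 2, colMeans(t(X)))
  ev <- eigen(crossprod(C), symmetric = TRUE)$values
  expect_equal(out$explained_variance, ev[seq_along(out$explained_variance)] /
                 sum(ev), tolerance = 1e-10)
  expect_true(all(diff(out$explained_variance) <= 1e-12))
  # permuting samples permutes scores identically
  perm <- sample(6)
  out2 <- pca_deviations(X[, perm])
  expect_equal(abs(out2$scores), abs(out$scores[perm, , drop = FALSE]),
               tolerance = 1e-8)
})

test_that("cluster_deviations orders are deterministic and block-aware", {
  set.seed(86)
  # two motif blocks with distinct sample profiles
  block <- rbind(matrix(rnorm(10 * 4, mean = 3), 10, 4),
                 matrix(rnorm(10 * 4, mean = -3), 10, 4))
  rownames(block) <- paste0("m", 1:20)
  colnames(block) <- paste0("s", 1:4)
  ord <- cluster_deviations(block)
  expect_identical(ord, cluster_deviations(block))
  groups <- rep(1:2, each = 10)[ord$row_order]
  expect_equal(length(rle(groups)$lengths), 2)  # blocks contiguous
  # identical columns end up adjacent
  dup <- cbind(block, s5 = block[, 1])
  co <- cluster_deviations(dup)$column_order
  expect_equal(abs(which(co == 1) - which(co == 5)), 1)
})

test_that("count_fragments counts overlaps per sample", {
  iv <- genomic_intervals("chr1", c(0, 100), c(50, 200))
  f <- rbind(
    fragment_table("chr1", c(10L, 45L, 150L), c(40L, 120L, 260L), "s1", "r"),
    fragment_table("chr1", 110L, 130L, "s2", "r")
  )
  cm <- count_fragments(f, iv)
  expect_equal(cm[, "s1"], c(2L, 2L))
  expect_equal(cm[, "s2"], c(0L, 1L))
})
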