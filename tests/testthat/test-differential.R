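test_that("chi2_test: identical posteriors give T = 0, p = 1", {
  m <- matrix(rnorm(10), 2, 5)
  s <- matrix(runif(10, 0.5, 2), 2, 5)
  out <- chi2_test(m, s, m, s)
  expect_equal(out$chi2_stat, 0)
  expect_equal(out$p_value, 1)
  expect_equal(out$df, 5)
})

test_that("chi2_test K=1 spot value matches numeric integration", {
  out <- chi2_test(2, 1, 0, 1)          # mean diff 2, pooled variances 1+1
  expect_equal(out$chi2_stat, 2)
  oracle <- integrate(function(x) dchisq(x, df = 1), 2, Inf,
                      rel.tol = 1e-10)$value
  expect_equal(out$p_value, oracle, tolerance = 1e-8)
  expect_equal(out$p_value, 0.1572992, tolerance = 1e-6)
})

test_that("chi2_test pools replicates as mean of means / scaled variance", {
  ma <- rbind(c(1, 0), c(3, 0)); sa <- rbind(c(1, 1), c(1, 1))
  mb <- rbind(c(0, 0), c(0, 0)); sb <- rbind(c(2, 2), c(2, 2))
  # pooled: muA = (2,0), vA = 1/2; muB = 0, vB = 4/2 = 2
  out <- chi2_test(ma, sa, mb, sb)
  expect_equal(out$chi2_stat, 4 / (0.5 + 2))
  expect_error(chi2_test(ma, sa, mb[, 1, drop = FALSE],
                         sb[, 1, drop = FALSE]), "mismatch")
})

test_that("bh_adjust applies the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.42), 0.42)
  expect_equal(bh_adjust(rep(0.2, 7)), rep(0.2, 7))
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("bh_adjust agrees with an independent step-up implementation", {
  set.seed(71)
  for (rep in 1:1000) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), p.adjust(p, method = "BH"))
  }
})

test_that("log_ratio: zero for identical V-plots, negative under depletion", {
  g <- vplot_grid()
  region <- genomic_intervals("chr1", 0, 640)
  set.seed(72)
  f <- random_fragments(400, lo = 0L, hi = 600L, max_len = 320L)
  vp <- build_vplot(f, region, g)
  expect_equal(log_ratio(vp, vp), 0)

  # remove central nucleosomal mass from A
  a <- vp
  rows <- which(seq(g$size_min, g$size_max - g$size_bin,
                    g$size_bin) >= 150)
  cols <- which(abs(seq(5, 635, 10) - 320) < 100)
  a$counts[rows, cols] <- 0L
  a$total <- sum(a$counts)
  expect_lt(log_ratio(a, vp), 0)
})

test_that("log_ratio matches a hand calculation on a 2-region toy", {
  g <- vplot_grid()
  region <- genomic_intervals("chr1", 0, 640)
  # A: 10 nucleosomal fragments (length 200) at the center, 10 NFR at edge
  # B: 30 nucleosomal at center, 10 NFR at edge
  mk <- function(n_center) {
    center <- fragment_table("chr1", rep(220L, n_center),
                             rep(420L, n_center), "s", "r")
    edge <- fragment_table("chr1", rep(10L, 10), rep(110L, 10), "s", "r")
    build_vplot(rbind(center, edge), region, g)
  }
  a <- mk(10); b <- mk(30)
  want <- log(((10 + 1) / (20 + 1)) / ((30 + 1) / (40 + 1)))
  expect_equal(log_ratio(a, b), want, tolerance = 1e-12)
})

test_that("pool_vplots sums counts and rejects grid mismatches", {
  g <- vplot_grid()
  region <- genomic_intervals("chr1", 0, 640)
  set.seed(73)
  v1 <- build_vplot(random_fragments(100, hi = 600L), region, g)
  v2 <- build_vplot(random_fragments(100, hi = 600L), region, g)
  pooled <- pool_vplots(list(v1, v2))
  expect_equal(pooled$counts, v1$counts + v2$counts)
  expect_equal(pooled$total, v1$total + v2$total)
  v3 <- build_vplot(random_fragments(10),
                    genomic_intervals("chr1", 0, 320),
                    vplot_grid(window_width = 320))
  expect_error(pool_vplots(list(v1, v3)), "grids")
})

test_that("rank_regions selects and ranks per the cutoffs", {
  res <- data.frame(chrom = "c", start = 1:4, end = 2:5,
                    chi2_stat = 1, df = 5,
                    p_value = c(0.5, 0.01, 0.8, 0.01),
                    p_adjusted = c(1, 0.01, 1, 0.04),
                    log_ratio = c(0, -0.5, 0, -0.1))
  out <- rank_regions(res)
  expect_equal(out$selected$start, 2L)       # p_adj and lr both pass
  expect_equal(out$results$rank[2], 1L)
  # all null: empty selection
  null <- res; null$p_adjusted <- 1
  expect_equal(nrow(rank_regions(null)$selected), 0)
  # percentile of a named region
  expect_equal(rank_regions(res, region_index = 2)$percentile, 1 / 4)
})

test_that("rank_regions matches a filter-and-sort oracle on random tables", {
  set.seed(74)
  for (rep in 1:20) {
    n <- 50
    res <- data.frame(chrom = "c", start = 1:n, end = 2:(n + 1),
                      chi2_stat = rchisq(n, 5), df = 5,
                      p_value = runif(n),
                      p_adjusted = runif(n),
                      log_ratio = rnorm(n, 0, 0.4))
    out <- rank_regions(res)
    want_sel <- which(res$p_adjusted < 0.05 & res$log_ratio < -0.2)
    expect_equal(out$selected$start, res$start[want_sel])
    o <- order(res$p_adjusted, res$log_ratio)
    expect_equal(out$results$rank[o], seq_len(n))
  }
})
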