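test_that("vplot_grid validates its geometry", {
  g <- vplot_grid()
  expect_equal(g$n_pos, 64L)
  expect_equal(g$n_size, 32L)
  expect_error(vplot_grid(window_width = 641), "divisible|== 0")
  expect_error(vplot_grid(size_min = 50, size_max = 375), "divisible|== 0")
})

test_that("build_vplot places single fragments in the right cell", {
  g <- vplot_grid()
  region <- genomic_intervals("chr1", 10000, 10640)
  # length 200, midpoint at the region center
  f <- fragment_table("chr1", 10220L, 10420L, "s", "r")
  vp <- build_vplot(f, region, g)
  expect_equal(vp$total, 1L)
  expect_equal(sum(vp$counts), 1L)
  expect_equal(vp$counts[(200 - 50) %/% 10 + 1, (320 %/% 10) + 1], 1L)

  # midpoint 1 bp outside the region contributes nothing
  f2 <- fragment_table("chr1", 10540L, 10742L, "s", "r")  # midpoint 10641
  expect_equal(build_vplot(f2, region, g)$total, 0L)

  # out-of-range sizes excluded (half-open [size_min, size_max))
  f3 <- fragment_table("chr1", c(10300L, 10135L), c(10349L, 10505L),
                       "s", "r")  # lengths 49 and 370
  expect_equal(build_vplot(f3, region, g)$total, 0L)

  wrong <- genomic_intervals("chr1", 0, 500)
  expect_error(build_vplot(f, wrong, g), "window width")
})

test_that("build_vplot equals the double-loop oracle on random fragments", {
  g <- vplot_grid()
  set.seed(61)
  for (rep in 1:10) {
    region <- genomic_intervals("chr1", 5000, 5640)
    f <- random_fragments(500, lo = 4700L, hi = 5800L, max_len = 420L)
    vp <- build_vplot(f, region, g)
    expect_equal(vp$counts, oracle_vplot(f, region, g), ignore_attr = TRUE)
    expect_equal(vp$total, sum(vp$counts))
  }
})

test_that("build_vplot is translation invariant", {
  g <- vplot_grid()
  set.seed(62)
  f <- random_fragments(300, lo = 1000L, hi = 2000L)
  region <- genomic_intervals("chr1", 1200, 1840)
  base <- build_vplot(f, region, g)
  sh <- f; sh$start <- sh$start + 7777L; sh$end <- sh$end + 7777L
  region2 <- genomic_intervals("chr1", 1200 + 7777, 1840 + 7777)
  expect_equal(build_vplot(sh, region2, g)$counts, base$counts)
})

test_that("aggregate_vplots averages densities and skips empty regions", {
  g <- vplot_grid()
  region <- genomic_intervals("chr1", 0, 640)
  set.seed(63)
  f <- random_fragments(200, lo = 0L, hi = 600L)
  vp <- build_vplot(f, region, g)
  agg <- aggregate_vplots(list(vp, vp))
  expect_equal(agg$density, vp$counts / vp$total)
  expect_equal(agg$n_regions, 2)

  empty <- build_vplot(f[0, ], region, g)
  agg2 <- aggregate_vplots(list(vp, vp, empty))
  expect_equal(agg2$n_regions, 2)
  expect_equal(agg2$n_skipped, 1)
  expect_error(aggregate_vplots(list()), "empty")
  expect_error(aggregate_vplots(list(empty)), "zero total")
})

test_that("aggregate_vplots matches direct recomputation, any order", {
  g <- vplot_grid()
  region <- genomic_intervals("chr1", 0, 640)
  set.seed(64)
  vps <- lapply(1:8, function(i)
    build_vplot(random_fragments(80, lo = 0L, hi = 600L), region, g))
  agg <- aggregate_vplots(vps)
  dens <- Reduce(`+`, lapply(vps, function(v) v$counts / v$total)) /
    length(vps)
  dens <- dens / sum(dens)
  expect_equal(agg$density, dens, tolerance = 1e-12)
  perm <- aggregate_vplots(vps[sample(length(vps))])
  expect_equal(perm$density, agg$density, tolerance = 1e-12)
  expect_equal(sum(agg$density), 1, tolerance = 1e-12)
})

test_that("size_partitioned_track filters by class and partitions coverage", {
  w <- genomic_intervals("chr1", 0, 1000)
  set.seed(65)
  f <- random_fragments(150, hi = 800L)
  nfr <- size_partitioned_track(f, w, "NFR")
  nuc <- size_partitioned_track(f, w, "NUCLEOSOMAL")
  full <- coverage_track(f, "chr1", w)
  expect_equal(nfr$values + nuc$values, full$values)
  # filter-then-coverage oracle
  expect_equal(nuc$values,
               oracle_coverage(f[f$length > 150, ], "chr1", w))
  short <- f; short$length <- 100L; short$end <- short$start + 100L
  expect_equal(sum(size_partitioned_track(short, w, "NUCLEOSOMAL")$values), 0)
})

test_that("accessibility_ratio_track depth-normalizes", {
  w <- genomic_intervals("chr1", 0, 5)
  a <- vplotdiff:::new_track("chr1", 0L, c(2, 4, 6, 0, 2))
  expect_equal(accessibility_ratio_track(a, a)$values, rep(1, 5))
  doubled <- vplotdiff:::new_track("chr1", 0L, 2 * a$values)
  expect_equal(accessibility_ratio_track(doubled, a)$values, rep(1, 5))
  # hand-computed 5-bp example: num (1,1,1,1,1) den (2,0,0,0,3),
  # totals 5 each so no rescaling; ratio = (v+1)/(d+1)
  num <- vplotdiff:::new_track("chr1", 0L, rep(1, 5))
  den <- vplotdiff:::new_track("chr1", 0L, c(2, 0, 0, 0, 3))
  expect_equal(accessibility_ratio_track(num, den)$values,
               c(2 / 3, 2, 2, 2, 2 / 4))
  other <- vplotdiff:::new_track("chr1", 10L, rep(1, 5))
  expect_error(accessibility_ratio_track(num, other), "same window")
})

test_that("occupancy_proxy matches the kernel-sum oracle and edge cases", {
  w <- genomic_intervals("chr1", 0, 800)
  f <- fragment_table("chr1", 300L, 500L, "s", "r")   # midpoint 400
  tr <- occupancy_proxy(f, w)
  expect_equal(which.max(tr$values) - 1L, 400L)
  expect_equal(sum(tr$values), 1, tolerance = 1e-6)   # kernel fits window

  none <- f; none$length <- 100L; none$end <- none$start + 100L
  expect_equal(sum(occupancy_proxy(none, w)$values), 0)

  set.seed(66)
  f2 <- random_fragments(200, lo = 100L, hi = 600L, max_len = 330L)
  tr2 <- occupancy_proxy(f2, w, kernel_sd = 15)
  mids <- (f2$start + f2$end) %/% 2L
  mids <- mids[f2$length > 150 & mids >= 0 & mids < 800]
  want <- sapply(0:799, function(p) sum(dnorm(p, mids, 15)))
  expect_lt(max(abs(tr2$values - want)), 1e-9)
})
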