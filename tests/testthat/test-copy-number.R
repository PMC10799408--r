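region_df <- function(len, gc, counts) {
  start <- cumsum(c(0, head(len, -1)))
  data.frame(chrom = "chr1", start = start, end = start + len,
             gc_fraction = gc, read_count = counts)
}

test_that("uniform regions correct to constant coverage", {
  df <- region_df(rep(100, 30), rep(0.5, 30), rep(200, 30))
  corr <- gc_length_correct(df)
  expect_true(all(abs(corr - corr[1]) < 1e-12))
  expect_error(gc_length_correct(region_df(rep(100, 30), rep(0.5, 30),
                                           rep(0, 30))), "zero")
})

test_that("length doubling leaves the corrected/median structure unchanged", {
  set.seed(51)
  len <- sample(100:300, 40, replace = TRUE)
  gc <- runif(40, 0.3, 0.7)
  counts <- rpois(40, 200)
  a <- gc_length_correct(region_df(len, gc, counts))
  b <- gc_length_correct(region_df(2 * len, gc, counts))
  expect_equal(b / median(b), a / median(a), tolerance = 1e-12)
})

test_that("a quadratic GC bias is flattened by the correction", {
  set.seed(52)
  n <- 500
  gc <- runif(n, 0.3, 0.7)
  len <- sample(120:400, n, replace = TRUE)
  bias <- exp(-6 * (gc - 0.40)^2)
  counts <- rpois(n, 200 * (len / 260) * bias)
  df <- region_df(len, gc, counts)
  rate <- counts / len
  expect_gt(abs(cor(rate, gc)), 0.3)          # bias present before
  corr <- gc_length_correct(df)
  expect_lt(abs(cor(corr, gc)), 0.1)          # flat after
})

test_that("log2 ratios are exact for exact relationships", {
  panel <- matrix(rep(c(10, 20, 40), 3), ncol = 3)
  tumor <- rowMeans(panel)
  expect_equal(compute_log2_ratios(tumor, panel), c(0, 0, 0))
  tumor2 <- tumor
  tumor2[2] <- 2 * tumor[2]
  expect_equal(compute_log2_ratios(tumor2, panel)[2], 1)
  expect_error(compute_log2_ratios(tumor[1:2], panel), "different region")
  expect_error(compute_log2_ratios(tumor, panel[, 1, drop = FALSE]),
               ">= 2")
})

test_that("null tumors drawn from the panel model centre near zero", {
  set.seed(53)
  n <- 500
  mu <- runif(n, 50, 400)
  panel <- matrix(rpois(n * 20, mu), nrow = n)
  tumor <- rpois(n, mu)
  lr <- compute_log2_ratios(tumor, panel, eps = 0.5)
  expect_lt(abs(mean(lr)), 0.05)
})

test_that("z-scores standardise against the panel with P95 + 2 SD thresholds", {
  set.seed(54)
  panel <- matrix(rnorm(20 * 30), nrow = 20)
  tumor <- rowMeans(panel)
  z <- compute_z_scores(tumor, panel)
  expect_equal(z$z, rep(0, 20), tolerance = 1e-12)
  # with approximately standard-normal panel z, thresholds sit near 3.6
  expect_lt(abs(mean(z$threshold) - 3.6), 0.5)
  expect_error(compute_z_scores(tumor, panel[, 1, drop = FALSE]), ">= 2")
})

test_that("constant panel regions are floored and flagged", {
  panel <- matrix(1, nrow = 3, ncol = 5)
  expect_message(z <- compute_z_scores(c(1, 1.1, 1), panel), "floored")
  expect_gt(abs(z$z[2]), 1e4)
})

test_that("CNI sums retained z one-sidedly", {
  z <- c(0.2, -5, 10, 1)
  thr <- rep(3.6, 4)
  res <- cni_score(z, thr)
  expect_equal(res$cni, 10)
  expect_equal(which(res$retained), 3L)
  # deletions never contribute one-sidedly, but do two-sidedly
  expect_equal(cni_score(c(-10, -8), thr[1:2])$cni, 0)
  expect_equal(cni_score(c(-10, -8), thr[1:2], two_sided = TRUE)$cni, 18)
  expect_equal(cni_score(numeric(), numeric())$cni, 0)
})

test_that("CNV calls use strict gain/loss thresholds", {
  calls <- call_cnv(c(5, 1.0, 4.0, 1.2, 2.0))
  expect_identical(calls$call,
                   c("gain", "loss", "neutral", "neutral", "neutral"))
  expect_equal(calls$n_gain, 1)
  expect_equal(calls$n_loss, 1)
  expect_equal(calls$burden, 2 / 5)
  expect_error(call_cnv(c(-1, 2)), "non-negative")
  # derived from log2 when cn is absent: log2 = 1 -> CN 4 -> neutral
  expect_identical(call_cnv(log2_ratio = c(1, 1.59))$call,
                   c("neutral", "gain"))
})

test_that("pipeline recovers engineered amplifications and stays null otherwise", {
  sim <- simulate_region_counts(n_regions = 200, panel_n = 20,
                                tumor_ids = c("FLAT", "AMP"),
                                cn_truth = list(
                                  FLAT = rep(2L, 200),
                                  AMP = c(rep(6L, 20), rep(2L, 180))),
                                seed = 55)
  flat <- cni_pipeline(sim$tumors$FLAT, sim$panel)
  amp <- cni_pipeline(sim$tumors$AMP, sim$panel)
  expect_lt(flat$cni$cni, 5)
  expect_equal(flat$cnv$burden, 0)
  expect_gt(amp$cni$cni, flat$cni$cni)
  expect_gte(amp$cnv$n_gain, 18)  # CN 6 regions called gain
  expect_equal(amp$cnv$n_loss, 0)
})

test_that("amplifying a single region never decreases the CNI score", {
  sim <- simulate_region_counts(n_regions = 100, panel_n = 15,
                                tumor_ids = "T", seed = 56)
  base <- cni_pipeline(sim$tumors$T, sim$panel)$cni$cni
  for (mult in c(2, 5, 10)) {
    boosted <- sim$tumors$T
    boosted$read_count[7] <- boosted$read_count[7] * mult
    expect_gte(cni_pipeline(boosted, sim$panel)$cni$cni, base)
  }
})
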