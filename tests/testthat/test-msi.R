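hist_of <- function(counts, sample_id = "T", locus_id = "L1") {
  str_histogram(sample_id, locus_id, counts)
}

# a histogram whose QC'd allele count is exactly n
hist_n_alleles <- function(n, sample_id = "N", locus_id = "L1",
                           depth = 200) {
  counts <- rep(round(depth / n), n)
  names(counts) <- 15 + seq_len(n) - 1
  str_histogram(sample_id, locus_id, counts)
}

test_that("allele QC enforces depth and per-allele read rules", {
  expect_null(filter_alleles(hist_of(c(`15` = 90))))
  # 17 fails the 2-read minimum; 16 fails 5%-of-top (9 < 0.05 * 200)
  expect_equal(filter_alleles(hist_of(c(`15` = 200, `16` = 9, `17` = 1))),
               15L)
  expect_equal(filter_alleles(hist_of(c(`15` = 200, `16` = 10, `17` = 1))),
               c(15L, 16L))
  expect_equal(filter_alleles(hist_of(c(`15` = 1000, `16` = 40))), 15L)
  # 5%-of-top boundary is inclusive
  expect_equal(filter_alleles(hist_of(c(`15` = 1000, `16` = 50))),
               c(15L, 16L))
})

test_that("depth cutoff is strict at 100", {
  h100 <- hist_of(c(`15` = 60, `16` = 40))   # total exactly 100
  h101 <- hist_of(c(`15` = 60, `16` = 41))
  expect_null(filter_alleles(h100))
  expect_equal(filter_alleles(h101), c(15L, 16L))
})

test_that("baseline stores per-locus mean and sample SD of allele counts", {
  panel <- list(
    N1 = list(L1 = hist_n_alleles(2, "N1")),
    N2 = list(L1 = hist_n_alleles(3, "N2")),
    N3 = list(L1 = hist_n_alleles(4, "N3")))
  b <- build_msi_baseline(panel)
  expect_equal(b$mean_allele_count, 3)
  expect_equal(b$sd_allele_count, 1)  # sample SD of {2,3,4}
  expect_equal(b$n_panel, 3)

  const <- lapply(stats::setNames(1:30, sprintf("N%02d", 1:30)),
                  function(i) list(L1 = hist_n_alleles(3)))
  bc <- build_msi_baseline(const)
  expect_equal(bc$mean_allele_count, 3)
  expect_equal(bc$sd_allele_count, 0)
})

test_that("loci evaluable in fewer than two panel samples are dropped", {
  panel <- list(
    N1 = list(L1 = hist_n_alleles(3, "N1"),
              L2 = hist_of(c(`20` = 50), "N1", "L2")),   # fails depth QC
    N2 = list(L1 = hist_n_alleles(3, "N2"),
              L2 = hist_of(c(`20` = 60), "N2", "L2")))
  expect_warning(b <- build_msi_baseline(panel), "L2")
  expect_identical(b$locus_id, "L1")
  expect_error(build_msi_baseline(list()), "empty")
})

test_that("locus instability is strict above mean + 4 SD", {
  b <- structure(data.frame(locus_id = "L1", mean_allele_count = 3,
                            sd_allele_count = 0.5, n_panel = 10),
                 class = c("msi_baseline", "data.frame"))
  expect_identical(call_msi_locus(hist_n_alleles(6), b)$status, "unstable")
  expect_identical(call_msi_locus(hist_n_alleles(5), b)$status, "stable")
  low <- hist_of(c(`15` = 40, `16` = 40))  # depth 80
  expect_identical(call_msi_locus(low, b)$status, "not_evaluable")
  expect_warning(
    call <- call_msi_locus(hist_of(c(`15` = 200), locus_id = "L9"), b),
    "absent from baseline")
  expect_identical(call$status, "not_evaluable")
  expect_true(is.na(call$allele_count))
})

test_that("sample classification follows the 2-unstable/4-stable rule", {
  calls <- function(u, s, ne = 0) data.frame(
    locus_id = sprintf("L%d", seq_len(u + s + ne)),
    allele_count = c(rep(8L, u + s), rep(NA_integer_, ne)),
    status = c(rep("unstable", u), rep("stable", s),
               rep("not_evaluable", ne)))
  expect_identical(classify_msi_sample(calls(2, 5))$status, "MSI-H")
  expect_identical(classify_msi_sample(calls(0, 4))$status, "MSS")
  expect_identical(classify_msi_sample(calls(1, 3, 3))$status, "QNS")
  # MSI-H precedence when both thresholds are met
  expect_identical(classify_msi_sample(calls(2, 4))$status, "MSI-H")
})

test_that("increasing baseline SD never flips stable to unstable", {
  h <- hist_n_alleles(6)
  for (sd in c(0, 0.5, 1, 2)) {
    b <- structure(data.frame(locus_id = "L1", mean_allele_count = 3,
                              sd_allele_count = sd, n_panel = 10),
                   class = c("msi_baseline", "data.frame"))
    call <- call_msi_locus(h, b)
    if (sd >= 0.75) expect_identical(call$status, "stable")
  }
  # adding a QC-passing allele never decreases the allele count
  h5 <- hist_n_alleles(5)
  counts6 <- c(h5$counts, `30` = 40)
  h6 <- str_histogram("N", "L1", counts6)
  expect_gt(length(filter_alleles(h6)), length(filter_alleles(h5)))
})

test_that("baseline round-trips through JSON", {
  panel <- list(
    N1 = list(L1 = hist_n_alleles(2, "N1")),
    N2 = list(L1 = hist_n_alleles(3, "N2")),
    N3 = list(L1 = hist_n_alleles(4, "N3")))
  b <- build_msi_baseline(panel)
  path <- withr::local_tempfile(fileext = ".json")
  write_msi_baseline(b, path)
  expect_equal(read_msi_baseline(path), b)
})

test_that("end-to-end recovery on simulated panels", {
  sim_h <- simulate_str_panel(tumor_ids = "T1", msi_truth = "MSI-H",
                              seed = 41)
  b <- build_msi_baseline(sim_h$panel)
  expect_identical(call_msi_sample(sim_h$tumors$T1, b)$status, "MSI-H")

  sim_s <- simulate_str_panel(tumor_ids = "T2", msi_truth = "MSS",
                              seed = 42)
  b2 <- build_msi_baseline(sim_s$panel)
  expect_identical(call_msi_sample(sim_s$tumors$T2, b2)$status, "MSS")

  sim_q <- simulate_str_panel(tumor_ids = "T3", msi_truth = "MSS",
                              tumor_depth = 50, seed = 43)
  b3 <- build_msi_baseline(sim_q$panel)
  expect_identical(call_msi_sample(sim_q$tumors$T3, b3)$status, "QNS")
})

test_that("panel self-consistency: leave-one-out calls are overwhelmingly stable", {
  sim <- simulate_str_panel(n_normals = 20, tumor_ids = character(),
                            seed = 44)
  n_stable <- 0
  n_called <- 0
  for (sid in names(sim$panel)) {
    b <- build_msi_baseline(sim$panel[setdiff(names(sim$panel), sid)])
    call <- call_msi_sample(sim$panel[[sid]], b)
    n_stable <- n_stable + call$n_stable
    n_called <- n_called + nrow(call$locus_calls)
  }
  expect_gte(n_stable / n_called, 0.95)
})
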