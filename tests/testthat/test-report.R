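# exact two-sided rank-sum p by enumeration of all group assignments
enumerate_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  obs <- sum(r[seq_along(a)])
  combs <- utils::combn(length(pooled), length(a))
  dist <- apply(combs, 2, function(idx) sum(r[idx]))
  min(1, 2 * min(mean(dist <= obs), mean(dist >= obs)))
}

test_that("metrics are complete on a full synthetic cohort", {
  fix <- cohort_fixture()
  m <- fix$res$metrics
  expect_equal(nrow(m), 12)
  expect_false(anyNA(m$tmb))
  expect_false(anyNA(m$math))
  expect_false(anyNA(m$msi_status))
  expect_false(anyNA(m$cni))
  expect_false(anyNA(m$cnv_burden))
  expect_true(all(m$cnv_burden >= 0 & m$cnv_burden <= 1))
})

test_that("samples lacking a data type get missing fields with warnings", {
  fix <- cohort_fixture()
  kept <- kept_variants(fix$res$outcome)
  one <- kept[kept$sample_id == "S01", ]
  expect_warning(
    expect_warning(
      m <- collect_metrics(one, tmb = tmb_config(3.4e7)),
      "STR"),
    "region")
  expect_true(is.na(m$msi_status))
  expect_true(is.na(m$cni))
  expect_false(is.na(m$tmb))
  expect_error(suppressWarnings(
    collect_metrics(one[0, ], tmb = tmb_config(3.4e7))), "no samples")
})

test_that("recomputing metrics on fixed inputs is deterministic", {
  fix <- cohort_fixture()
  res2 <- suppressWarnings(run_cohort_analysis(fix$dir))
  expect_equal(res2$metrics, fix$res$metrics)
})

test_that("identical groups compare at p = 1", {
  m <- data.frame(sample_id = c("A1", "A2", "A3", "B1", "B2", "B3"),
                  tmb = c(4, 5, 6, 4, 5, 6), math = 1, cni = 1,
                  cnv_burden = 0, n_gain = 0L, n_loss = 0L,
                  msi_status = "MSS", stringsAsFactors = FALSE)
  g <- data.frame(sample_id = m$sample_id,
                  group_label = rep(c("X", "Y"), each = 3))
  cmp <- compare_groups(m, g, "tmb")
  expect_equal(cmp$p_value, 1)
})

test_that("rank-sum p-values agree with exact enumeration", {
  m <- data.frame(sample_id = sprintf("S%d", 1:6),
                  tmb = c(10, 11, 12, 1, 2, 3), math = 1, cni = 1,
                  cnv_burden = 0, n_gain = 0L, n_loss = 0L,
                  msi_status = "MSS", stringsAsFactors = FALSE)
  g <- data.frame(sample_id = m$sample_id,
                  group_label = rep(c("HE", "HI"), each = 3))
  cmp <- compare_groups(m, g, "tmb")
  expect_equal(cmp$p_value, 0.1)  # 2 / choose(6, 3)
  expect_equal(cmp$p_value, enumerate_ranksum_p(c(10, 11, 12), c(1, 2, 3)))

  set.seed(61)
  for (i in 1:10) {
    na <- sample(2:4, 1)
    nb <- sample(2:4, 1)
    a <- round(runif(na), 3)
    b <- round(runif(nb), 3)
    if (anyDuplicated(c(a, b))) next
    m2 <- data.frame(sample_id = sprintf("S%d", seq_len(na + nb)),
                     tmb = c(a, b), math = 1, cni = 1, cnv_burden = 0,
                     n_gain = 0L, n_loss = 0L, msi_status = "MSS",
                     stringsAsFactors = FALSE)
    g2 <- data.frame(sample_id = m2$sample_id,
                     group_label = rep(c("P", "Q"), c(na, nb)))
    expect_equal(compare_groups(m2, g2, "tmb")$p_value,
                 enumerate_ranksum_p(a, b), tolerance = 1e-12)
  }
})

test_that("MSI status compares by Fisher's exact test", {
  m <- data.frame(sample_id = sprintf("S%02d", 1:12),
                  tmb = 1, math = 1, cni = 1, cnv_burden = 0,
                  n_gain = 0L, n_loss = 0L,
                  msi_status = c(rep("MSS", 6), "MSI-H", rep("MSS", 5)),
                  stringsAsFactors = FALSE)
  g <- data.frame(sample_id = m$sample_id,
                  group_label = rep(c("HE", "HI"), each = 6))
  cmp <- compare_groups(m, g, "msi_status")
  expect_equal(cmp$p_value, 1)  # hypergeometric: 0/6 vs 1/6
  expect_equal(unname(cmp$summary_a["msi_h"]), 0)
  expect_equal(unname(cmp$summary_b["msi_h"]), 1)
})

test_that("missing metric values are dropped with a warning", {
  m <- data.frame(sample_id = sprintf("S%d", 1:6),
                  tmb = c(1, 2, NA, 4, 5, 6), math = 1, cni = 1,
                  cnv_burden = 0, n_gain = 0L, n_loss = 0L,
                  msi_status = "MSS", stringsAsFactors = FALSE)
  g <- data.frame(sample_id = m$sample_id,
                  group_label = rep(c("A", "B"), each = 3))
  expect_warning(cmp <- compare_groups(m, g, "tmb"), "missing")
  expect_equal(unname(cmp$summary_a["n"]), 2)
})

test_that("the rendered report is valid and mirrors the groups file", {
  fix <- cohort_fixture()
  report_dir <- file.path(fix$dir, "report")
  expect_true(file.exists(file.path(report_dir, "report.json")))
  expect_true(validate_report(file.path(report_dir, "report.json")))
  rep <- jsonlite::read_json(file.path(report_dir, "report.json"),
                             simplifyVector = FALSE)
  groups <- fix$sim$groups
  for (lab in unique(groups$group_label)) {
    expect_setequal(unlist(rep$groups[[lab]]),
                    groups$sample_id[groups$group_label == lab])
  }
  expect_equal(length(rep$samples), nrow(groups))
  # truth propagation: the HI-like group is C>T dominant with one MSI-H
  sp <- rep$spectrum[[1]]
  expect_identical(sp$dominant_class_a, "C>A")
  expect_identical(sp$dominant_class_b, "C>T")
  expect_equal(rep$msi_h_counts$HE, 0)
  expect_equal(rep$msi_h_counts$HI, 1)
})

test_that("a report without comparisons still renders and validates", {
  fix <- cohort_fixture()
  d <- withr::local_tempdir()
  rep <- render_report(fix$res$metrics, fix$sim$groups, out_dir = d)
  expect_true(validate_report(file.path(d, "report.json")))
  expect_length(rep$comparisons, 0)
  expect_true(file.exists(file.path(d, "summary.txt")))
  # invalid reports are rejected
  expect_error(validate_report(list(tool = "wescohort")), "lacks key")
})
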