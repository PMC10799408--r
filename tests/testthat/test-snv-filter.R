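reasons_of <- function(outcome, i) {
  r <- outcome$reasons[i]
  if (r == "") character() else strsplit(r, ";", fixed = TRUE)[[1]]
}

test_that("depth below threshold removes an otherwise clean variant", {
  v <- make_variant(depth = 20L, alt_fwd = 3L, alt_rev = 3L,
                    tumor_vaf = 6 / 20)
  out <- apply_snv_filters(v)
  expect_false(out$kept)
  expect_identical(reasons_of(out, 1), "low_depth")
})

test_that("a clean missense SNV is kept with empty reasons", {
  out <- apply_snv_filters(make_variant())
  expect_true(out$kept)
  expect_identical(out$reasons, "")
})

test_that("hotspot rescue keeps low-VAF hotspot variants meeting the hotspot thresholds", {
  hot <- make_variant(is_hotspot = TRUE, depth = 150L, alt_fwd = 3L,
                      alt_rev = 3L, tumor_vaf = 0.06, control_vaf = 0.02)
  out <- apply_snv_filters(hot)
  expect_true(out$kept)
  # same evidence without the hotspot flag fails only on support reads
  nohot <- make_variant(depth = 150L, alt_fwd = 2L, alt_rev = 2L,
                        tumor_vaf = 4 / 150)
  out2 <- apply_snv_filters(nohot)
  expect_identical(reasons_of(out2, 1), "vaf_support")
  # hotspot below a hotspot threshold (plasma frequency) is removed
  hot2 <- make_variant(is_hotspot = TRUE, depth = 150L, alt_fwd = 3L,
                       alt_rev = 3L, tumor_vaf = 0.06, control_vaf = 0)
  expect_identical(reasons_of(apply_snv_filters(hot2), 1), "vaf_support")
})

test_that("single-strand support triggers strand_support", {
  v <- make_variant(alt_fwd = 0L, alt_rev = 12L, tumor_vaf = 12 / 200)
  out <- apply_snv_filters(v)
  expect_true("strand_support" %in% reasons_of(out, 1))
})

test_that("audit fixture: each engineered variant fails exactly its criterion", {
  aud <- make_filter_audit_table()
  out <- apply_snv_filters(aud$variants)
  expect_identical(out$reasons, aud$expected_reasons)
  expect_identical(which(out$kept), which(aud$expected_reasons == ""))
})

test_that("all triggered criteria are listed, not just the first", {
  v <- make_variant(depth = 20L, alt_fwd = 3L, alt_rev = 3L,
                    tumor_vaf = 6 / 20, in_blacklist = TRUE,
                    region_class = "intronic")
  out <- apply_snv_filters(v)
  expect_setequal(reasons_of(out, 1),
                  c("low_depth", "blacklist", "intronic"))
})

test_that("PolyPhen, database and population criteria skip indels", {
  indel <- make_variant(ref_allele = "AT", alt_allele = "-",
                        variant_type = "DEL",
                        variant_class = "frameshift",
                        in_cosmic = FALSE, in_snp138 = FALSE,
                        polyphen_div = "B", polyphen_var = "B",
                        popmax_af = 0.05)
  out <- apply_snv_filters(indel)
  expect_true(out$kept)
})

test_that("missing PolyPhen codes never trigger the benign criterion", {
  v <- make_variant(polyphen_div = "B", polyphen_var = "missing")
  expect_true(apply_snv_filters(v)$kept)
})

test_that("filtering partitions the input and is idempotent", {
  sim <- simulate_variants("S1", n_variants = 400,
                           violation_rates = stats::setNames(
                             rep(0.04, length(filter_reasons)),
                             filter_reasons),
                           seed = 11)
  out <- apply_snv_filters(sim$variants)
  expect_equal(sum(out$kept) + sum(!out$kept), nrow(sim$variants))
  again <- apply_snv_filters(kept_variants(out))
  expect_true(all(again$kept))
})

test_that("raising min_depth never enlarges the kept set", {
  sim <- simulate_variants("S1", n_variants = 400, seed = 12)
  kept30 <- apply_snv_filters(sim$variants, filter_config(min_depth = 30))$kept
  kept90 <- apply_snv_filters(sim$variants, filter_config(min_depth = 90))$kept
  expect_true(all(kept90 <= kept30))
  expect_lt(sum(kept90), sum(kept30))
})

test_that("config switches flip the debatable criteria", {
  absent <- make_variant(in_cosmic = FALSE, in_snp138 = FALSE)
  expect_false(apply_snv_filters(absent)$kept)
  expect_true(apply_snv_filters(
    absent, filter_config(db_absence_excludes = FALSE))$kept)
  nons <- make_variant(variant_class = "nonsense")
  expect_false(apply_snv_filters(nons)$kept)
  expect_true(apply_snv_filters(
    nons, filter_config(exclude_nonsense = FALSE))$kept)
})

test_that("filter config validates and loads from JSON", {
  expect_error(filter_config(min_depth = -1), "non-negative")
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"min_depth": 40, "exclude_nonsense": false}', path)
  cfg <- read_filter_config(path)
  expect_equal(cfg$min_depth, 40)
  expect_false(cfg$exclude_nonsense)
  writeLines('{"bogus_key": 1}', path)
  expect_error(read_filter_config(path), "bogus_key")
})
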