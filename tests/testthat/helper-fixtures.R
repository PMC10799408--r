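# Shared fixture builders.  A "clean" variant passes every filter
# criterion under the default config; overrides patch single fields.

make_variant <- function(..., sample_id = "S1") {
  v <- data.frame(
    sample_id = sample_id, chrom = "chr1", pos = 100L,
    ref_allele = "C", alt_allele = "T",
    variant_type = "SNP", variant_class = "missense",
    region_class = "exonic", gene = "GENE001",
    depth = 200L, alt_fwd = 30L, alt_rev = 28L,
    tumor_vaf = 58 / 200, control_vaf = 0,
    in_cosmic = TRUE, in_snp138 = FALSE,
    polyphen_div = "D", polyphen_var = "D",
    popmax_af = 0, is_hotspot = FALSE, in_blacklist = FALSE,
    stringsAsFactors = FALSE
  )
  args <- list(...)
  for (nm in names(args)) v[[nm]] <- args[[nm]]
  v
}

variants_table <- function(...) {
  out <- do.call(rbind, list(...))
  rownames(out) <- NULL
  out
}

# a variant table of n SNVs drawn on the pyrimidine strand from the
# given class probabilities (no strand flip; used where the spectrum is
# the object under test)
spectrum_variants <- function(n, probs, sample_id = "S1") {
  cls <- sample(substitution_classes, n, replace = TRUE, prob = probs)
  make_variant(sample_id = sample_id)[rep(1, n), ] |>
    transform(pos = seq_len(n),
              ref_allele = substr(cls, 1, 1),
              alt_allele = substr(cls, 3, 3))
}

# one small simulated cohort + its full analysis, computed once per run
cohort_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "wescohort-fixture")
      sim <- simulate_cohort(seed = 101, out_dir = dir,
                             n_regions = 150, str_panel_n = 15,
                             region_panel_n = 15, n_variants = 200)
      res <- suppressWarnings(
        run_cohort_analysis(dir, out_dir = file.path(dir, "report")))
      cache <<- list(dir = dir, sim = sim, res = res)
    }
    cache
  }
})

# brute-force median via explicit sorting (independent of stats::median)
sort_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}
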