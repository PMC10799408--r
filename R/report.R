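# Cohort assembly and reporting: per-sample metrics, between-group
# contrasts, and the machine/human-readable report.
#
# Group tests are deliberately assumption-light for tiny cohorts:
# Wilcoxon rank-sum for continuous metrics, Fisher's exact test for
# MSI-H counts.  No multiple-testing correction is applied; the report
# says so and prints raw p-values alongside medians.

.metric_columns <- c("tmb", "math", "cni", "cnv_burden", "n_gain", "n_loss")

#' Assemble per-sample metrics
#'
#' Computes, for every sample, TMB and MATH from its kept variants, MSI
#' status from its STR histograms against the baseline, and CNV
#' calls/burden plus the CNI score from its region counts against the
#' normal panel.  A sample lacking one data type gets `NA` in the
#' corresponding fields with a warning -- never a silent zero.
#'
#' @param variants Kept (filtered) variant data frame, all samples.
#' @param tmb A [tmb_config()].
#' @param math A [math_config()] (default defaults).
#' @param str_tumors Nested histogram list (sample -> locus), or `NULL`.
#' @param msi_baseline An `msi_baseline`, or `NULL`.
#' @param tumor_regions Named list of region data frames, or `NULL`.
#' @param panel_regions Named list of region data frames (the normal
#'   panel), or `NULL`.
#' @param sample_ids Samples to report; defaults to the union of sample
#'   ids seen in the inputs.
#' @param ... Passed to [cni_pipeline()] (`two_sided`,
#'   `global_threshold`, gain/loss thresholds).
#' @return Data frame with columns `sample_id`, `tmb`, `math`,
#'   `msi_status`, `n_gain`, `n_loss`, `cnv_burden`, `cni`.
#' @export
collect_metrics <- function(variants, tmb, math = math_config(),
                            str_tumors = NULL, msi_baseline = NULL,
                            tumor_regions = NULL, panel_regions = NULL,
                            sample_ids = NULL, ...) {
  stopifnot(inherits(tmb, "tmb_config"), inherits(math, "math_config"))
  if (is.null(sample_ids)) {
    sample_ids <- sort(unique(c(variants$sample_id, names(str_tumors),
                                names(tumor_regions))))
  }
  if (!length(sample_ids)) stop("no samples to report", call. = FALSE)
  rows <- lapply(sample_ids, function(sid) {
    sub <- variants[variants$sample_id == sid, ]
    row <- data.frame(sample_id = sid,
                      tmb = compute_tmb(sub, tmb),
                      math = compute_math(select_math_vafs(sub, math),
                                          math$style),
                      msi_status = NA_character_,
                      n_gain = NA_integer_, n_loss = NA_integer_,
                      cnv_burden = NA_real_, cni = NA_real_,
                      stringsAsFactors = FALSE)
    if (!is.null(str_tumors) && !is.null(msi_baseline) &&
        !is.null(str_tumors[[sid]])) {
      row$msi_status <- call_msi_sample(str_tumors[[sid]],
                                        msi_baseline)$status
    } else {
      warning(sprintf("sample '%s': no STR data/baseline; MSI status missing",
                      sid), call. = FALSE)
    }
    if (!is.null(tumor_regions) && !is.null(panel_regions) &&
        !is.null(tumor_regions[[sid]])) {
      cn <- cni_pipeline(tumor_regions[[sid]], panel_regions, ...)
      row$n_gain <- cn$cnv$n_gain
      row$n_loss <- cn$cnv$n_loss
      row$cnv_burden <- cn$cnv$burden
      row$cni <- cn$cni$cni
    } else {
      warning(sprintf("sample '%s': no region counts/panel; CNV and CNI missing",
                      sid), call. = FALSE)
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Contrast one metric between two groups
#'
#' Continuous metrics (`tmb`, `math`, `cni`, `cnv_burden`, `n_gain`,
#' `n_loss`): two-sided Wilcoxon rank-sum on per-sample values, with
#' missing values dropped (warned) and medians/IQRs as summaries.
#' `msi_status`: 2x2 table of MSI-H versus not (MSS and QNS both count
#' as not MSI-H) with Fisher's exact p-value and MSI-H counts as
#' summaries.  A group left with no usable values yields a missing
#' p-value with a warning.
#'
#' @param metrics Data frame from [collect_metrics()].
#' @param groups Data frame from [read_group_file()].
#' @param metric One of the metric column names or `"msi_status"`.
#' @param group_a,group_b Group labels; default the first two labels in
#'   `groups`.
#' @return An object of class `group_comparison`: `metric`, `group_a`,
#'   `group_b`, `summary_a`, `summary_b`, `statistic`, `p_value`.
#' @export
compare_groups <- function(metrics, groups, metric,
                           group_a = NULL, group_b = NULL) {
  labels <- unique(groups$group_label)
  if (is.null(group_a)) group_a <- labels[1]
  if (is.null(group_b)) group_b <- labels[2]
  stopifnot(metric %in% c(.metric_columns, "msi_status"))
  pick <- function(label) {
    ids <- groups$sample_id[groups$group_label == label]
    metrics[metrics$sample_id %in% ids, ]
  }
  ma <- pick(group_a)
  mb <- pick(group_b)
  if (!nrow(ma) || !nrow(mb)) {
    stop("both groups need at least one sample", call. = FALSE)
  }
  if (metric == "msi_status") {
    count_h <- function(m) sum(m$msi_status == "MSI-H", na.rm = TRUE)
    tab <- matrix(c(count_h(ma), sum(!is.na(ma$msi_status)) - count_h(ma),
                    count_h(mb), sum(!is.na(mb$msi_status)) - count_h(mb)),
                  nrow = 2,
                  dimnames = list(c("MSI-H", "not"), c(group_a, group_b)))
    ft <- stats::fisher.test(tab)
    return(structure(
      list(metric = metric, group_a = group_a, group_b = group_b,
           summary_a = c(msi_h = tab[1, 1], n = sum(tab[, 1])),
           summary_b = c(msi_h = tab[1, 2], n = sum(tab[, 2])),
           statistic = unname(ft$estimate), p_value = ft$p.value),
      class = "group_comparison"))
  }
  va <- ma[[metric]]
  vb <- mb[[metric]]
  if (anyNA(va) || anyNA(vb)) {
    warning(sprintf("metric '%s': dropped %d sample(s) with missing values",
                    metric, sum(is.na(va)) + sum(is.na(vb))),
            call. = FALSE)
    va <- va[!is.na(va)]
    vb <- vb[!is.na(vb)]
  }
  summarize <- function(v) {
    if (!length(v)) return(c(median = NA_real_, iqr = NA_real_, n = 0))
    c(median = stats::median(v), iqr = stats::IQR(v), n = length(v))
  }
  if (!length(va) || !length(vb)) {
    warning(sprintf("metric '%s': a group has no usable values; p missing",
                    metric), call. = FALSE)
    stat <- NA_real_
    p <- NA_real_
  } else {
    wt <- suppressWarnings(stats::wilcox.test(va, vb))
    stat <- unname(wt$statistic)
    p <- wt$p.value
  }
  structure(
    list(metric = metric, group_a = group_a, group_b = group_b,
         summary_a = summarize(va), summary_b = summarize(vb),
         statistic = stat, p_value = p),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: %s vs %s, p = %s\n", x$metric,
              x$group_a, x$group_b, format(x$p_value, digits = 3)))
  invisible(x)
}

.comparison_row <- function(cmp) {
  data.frame(metric = cmp$metric, group_a = cmp$group_a,
             group_b = cmp$group_b,
             summary_a = paste(names(cmp$summary_a),
                               signif(cmp$summary_a, 6),
                               sep = "=", collapse = ";"),
             summary_b = paste(names(cmp$summary_b),
                               signif(cmp$summary_b, 6),
                               sep = "=", collapse = ";"),
             statistic = cmp$statistic, p_value = cmp$p_value,
             stringsAsFactors = FALSE)
}

#' Render the cohort report
#'
#' Writes `metrics.tsv`, `comparisons.tsv`, a machine-readable
#' `report.json` and a human-readable `summary.txt` naming, per
#' contrast, the dominant substitution class of each group, the
#' transition/transversion test result, MSI-H counts and metric medians.
#'
#' @param metrics Data frame from [collect_metrics()].
#' @param groups Data frame from [read_group_file()].
#' @param comparisons List of `group_comparison` objects.
#' @param spectrum_comparisons List of `spectrum_comparison` objects.
#' @param out_dir Output directory (created if needed).
#' @return (Invisibly) the report structure written to `report.json`.
#' @export
render_report <- function(metrics, groups, comparisons = list(),
                          spectrum_comparisons = list(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(metrics, file.path(out_dir, "metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cmp_df <- if (length(comparisons)) {
    do.call(rbind, lapply(comparisons, .comparison_row))
  } else {
    data.frame(metric = character(), group_a = character(),
               group_b = character(), summary_a = character(),
               summary_b = character(), statistic = numeric(),
               p_value = numeric(), stringsAsFactors = FALSE)
  }
  utils::write.table(cmp_df, file.path(out_dir, "comparisons.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  group_samples <- split(groups$sample_id, groups$group_label)
  msi_h_counts <- vapply(group_samples, function(ids)
    sum(metrics$msi_status[metrics$sample_id %in% ids] == "MSI-H",
        na.rm = TRUE), numeric(1))
  report <- list(
    tool = "wescohort",
    note = "raw p-values; no multiple-testing correction applied",
    groups = lapply(group_samples, as.list),
    msi_h_counts = as.list(msi_h_counts),
    samples = metrics,
    comparisons = lapply(comparisons, function(cmp)
      list(metric = cmp$metric, group_a = cmp$group_a,
           group_b = cmp$group_b,
           summary_a = as.list(cmp$summary_a),
           summary_b = as.list(cmp$summary_b),
           statistic = cmp$statistic, p_value = cmp$p_value)),
    spectrum = lapply(spectrum_comparisons, function(sc)
      list(group_a = sc$group_a, group_b = sc$group_b,
           dominant_class_a = dominant_class(sc, "a"),
           dominant_class_b = dominant_class(sc, "b"),
           titv_p = sc$titv_p,
           per_class = sc$per_class))
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "rows")

  lines <- c("Cohort report", "=============", "",
             sprintf("Samples: %d in %d group(s) [%s]", nrow(metrics),
                     length(group_samples),
                     paste(names(group_samples), collapse = ", ")),
             "")
  for (g in names(group_samples)) {
    lines <- c(lines, sprintf("Group %s: %d samples, %d MSI-H", g,
                              length(group_samples[[g]]),
                              msi_h_counts[[g]]))
  }
  for (sc in spectrum_comparisons) {
    lines <- c(lines, "", sprintf(
      "Spectrum %s vs %s: dominant class %s vs %s; TiTv rank-sum p = %s",
      sc$group_a, sc$group_b, dominant_class(sc, "a"),
      dominant_class(sc, "b"), format(sc$titv_p, digits = 3)))
  }
  for (cmp in comparisons) {
    lines <- c(lines, sprintf(
      "%s: %s [%s] vs %s [%s], p = %s (raw)", cmp$metric, cmp$group_a,
      paste(signif(cmp$summary_a, 4), collapse = "/"), cmp$group_b,
      paste(signif(cmp$summary_b, 4), collapse = "/"),
      format(cmp$p_value, digits = 3)))
  }
  writeLines(lines, file.path(out_dir, "summary.txt"))
  invisible(report)
}

#' Structurally validate a cohort report
#'
#' Checks the report written by [render_report()] against the shipped
#' schema (`inst/extdata/report_schema.json`): required top-level keys,
#' per-comparison fields, and p-value ranges.
#'
#' @param report A report list or a path to a `report.json`.
#' @return `TRUE` invisibly if valid; errors otherwise.
#' @export
validate_report <- function(report) {
  if (is.character(report)) {
    report <- jsonlite::read_json(report, simplifyVector = FALSE)
  }
  need <- c("tool", "note", "groups", "msi_h_counts", "samples",
            "comparisons", "spectrum")
  missing_keys <- setdiff(need, names(report))
  if (length(missing_keys)) {
    stop(sprintf("report lacks key '%s'", missing_keys[1]), call. = FALSE)
  }
  for (cmp in report$comparisons) {
    for (k in c("metric", "group_a", "group_b", "p_value")) {
      if (!k %in% names(cmp)) {
        stop(sprintf("comparison lacks field '%s'", k), call. = FALSE)
      }
    }
    p <- cmp$p_value
    if (!is.null(p) && !is.na(p) && (p < 0 || p > 1)) {
      stop("comparison p-value outside [0, 1]", call. = FALSE)
    }
  }
  for (sc in report$spectrum) {
    for (k in c("group_a", "group_b", "dominant_class_a",
                "dominant_class_b", "titv_p")) {
      if (!k %in% names(sc)) {
        stop(sprintf("spectrum entry lacks field '%s'", k), call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' Run the whole cohort analysis from files on disk
#'
#' Reads the inputs that [simulate_cohort()] writes (or equivalently
#' formatted real inputs), filters variants, summarises spectra and
#' compares them between the first two group labels, builds the MSI
#' baseline and calls MSI per sample, runs the copy-number pipeline per
#' sample (region-count samples not listed in the groups file form the
#' normal panel), assembles the metrics, contrasts every metric between
#' the groups, and optionally renders the report.
#'
#' @param input_dir Directory holding `variants.tsv`, `str_panel.tsv`,
#'   `str_tumors.tsv`, `region_counts.tsv`, `groups.tsv`.
#' @param exon_bases TMB denominator in bases (default 3.4e7, a typical
#'   whole-exome target size).
#' @param filter A [filter_config()].
#' @param math A [math_config()].
#' @param out_dir Optional report directory for [render_report()].
#' @param ... Passed to [collect_metrics()] / [cni_pipeline()].
#' @return List with `outcome` (filter outcomes), `summaries`
#'   (per-sample `spectrum_summary`), `spectrum_comparison`, `metrics`,
#'   `comparisons` (named list), and `report` (when `out_dir` given).
#' @export
run_cohort_analysis <- function(input_dir, exon_bases = 3.4e7,
                                filter = filter_config(),
                                math = math_config(), out_dir = NULL,
                                ...) {
  path <- function(f) file.path(input_dir, f)
  variants <- read_variant_table(path("variants.tsv"))
  groups <- read_group_file(path("groups.tsv"))
  str_panel <- read_str_histograms(path("str_panel.tsv"))
  str_tumors <- read_str_histograms(path("str_tumors.tsv"))
  region_all <- read_region_counts(path("region_counts.tsv"))

  outcome <- apply_snv_filters(variants, filter)
  kept <- kept_variants(outcome)

  labels <- unique(groups$group_label)
  summaries <- lapply(stats::setNames(groups$sample_id, groups$sample_id),
                      function(sid)
    summarize_spectrum(kept[kept$sample_id == sid, ], sample_id = sid))
  spectrum_cmp <- NULL
  if (length(labels) >= 2) {
    ids_a <- groups$sample_id[groups$group_label == labels[1]]
    ids_b <- groups$sample_id[groups$group_label == labels[2]]
    spectrum_cmp <- compare_group_spectra(summaries[ids_a],
                                          summaries[ids_b],
                                          labels[1], labels[2])
  }

  baseline <- build_msi_baseline(str_panel)
  tumor_ids <- groups$sample_id
  tumor_regions <- region_all[intersect(names(region_all), tumor_ids)]
  panel_regions <- region_all[setdiff(names(region_all), tumor_ids)]

  metrics <- collect_metrics(
    kept, tmb = tmb_config(exon_bases), math = math,
    str_tumors = str_tumors, msi_baseline = baseline,
    tumor_regions = tumor_regions, panel_regions = panel_regions,
    sample_ids = tumor_ids, ...)

  comparisons <- list()
  if (length(labels) >= 2) {
    for (metric in c("tmb", "math", "cnv_burden", "cni", "msi_status")) {
      comparisons[[metric]] <- compare_groups(metrics, groups, metric,
                                              labels[1], labels[2])
    }
  }
  report <- NULL
  if (!is.null(out_dir)) {
    report <- render_report(metrics, groups, comparisons,
                            if (is.null(spectrum_cmp)) list()
                            else list(spectrum_cmp),
                            out_dir)
  }
  list(outcome = outcome, summaries = summaries,
       spectrum_comparison = spectrum_cmp, metrics = metrics,
       comparisons = comparisons, report = report)
}
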