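# Region-level copy-number analysis: GC/length-corrected coverage, log2
# ratios against a normal panel, per-region Z-scores with a
# P95 + 2*SD retention threshold, the summed CNI score, and gain/loss
# calling on copy-number estimates.

#' GC- and length-correct per-region coverage
#'
#' Read counts are converted to rates (reads per base), each rate is
#' divided by the median rate of its GC bin (bins of `gc_bin_width` in GC
#' fraction) and rescaled by the sample's global median rate, removing
#' the coverage trend along GC while preserving the overall scale.  Bins
#' holding fewer than `min_bin_regions` regions borrow the global median
#' (no GC correction there).
#'
#' @param regions Per-sample region data frame (`chrom`, `start`, `end`,
#'   `gc_fraction`, `read_count`), see [read_region_counts()].
#' @param gc_bin_width GC bin width as a fraction (default 0.02).
#' @param min_bin_regions Minimum regions per bin for a bin-specific
#'   median (default 5).
#' @return Numeric vector of corrected coverage rates, strictly positive
#'   wherever the input count is positive.
#' @export
gc_length_correct <- function(regions, gc_bin_width = 0.02,
                              min_bin_regions = 5) {
  len <- regions$end - regions$start
  if (any(len <= 0)) stop("region end must exceed start", call. = FALSE)
  if (all(regions$read_count == 0)) {
    stop("all read counts are zero; nothing to correct", call. = FALSE)
  }
  rate <- regions$read_count / len
  global_med <- stats::median(rate)
  bin <- floor(regions$gc_fraction / gc_bin_width)
  bin_med <- tapply(rate, bin, stats::median)
  bin_n <- tapply(rate, bin, length)
  factor_by_bin <- ifelse(bin_n >= min_bin_regions & bin_med > 0,
                          bin_med, global_med)
  corr <- rate / factor_by_bin[as.character(bin)] * global_med
  as.numeric(corr)
}

#' Log2 coverage ratios of a tumor against a normal panel
#'
#' Per region, `log2((tumor + eps) / (panel mean + eps))` where the panel
#' mean is taken across panel samples.  `eps` guards zero coverage; pass
#' the rate-scale equivalent of half a read (e.g. `0.5 / region length`)
#' when working with corrected rates, as [cni_pipeline()] does.  The
#' default `eps = 0` makes exact relationships exact (a region at twice
#' the panel mean has ratio 1).
#'
#' @param tumor Numeric vector of corrected coverage.
#' @param panel Numeric matrix, regions x panel samples, of corrected
#'   coverage on the identical region set.
#' @param eps Zero-guard, scalar or per-region vector (default 0).
#' @return Numeric vector of per-region log2 ratios.
#' @export
compute_log2_ratios <- function(tumor, panel, eps = 0) {
  panel <- as.matrix(panel)
  if (length(tumor) != nrow(panel)) {
    stop("tumor and panel cover different region sets", call. = FALSE)
  }
  if (ncol(panel) < 2) stop("panel must hold >= 2 samples", call. = FALSE)
  log2((tumor + eps) / (rowMeans(panel) + eps))
}

#' Per-region Z-scores and retention thresholds
#'
#' Standardises the tumor log2 ratio per region against the panel's log2
#' ratios (mean and sample SD across panel members, SD floored at
#' `sd_floor`), and derives a per-region retention threshold as the 95th
#' percentile of the panel's own standardised values plus two times their
#' SD.  With `global_threshold = TRUE` the percentile and SD are taken
#' over the pooled panel Z-values of all regions instead, giving one
#' threshold for the whole sample.
#'
#' Panel log2 ratios should be computed leave-one-out (each panel member
#' against the mean of the others) so the null distribution matches what
#' a normal tumor would produce; [cni_pipeline()] does this.
#'
#' @param tumor_log2 Numeric vector of tumor log2 ratios.
#' @param panel_log2 Numeric matrix, regions x panel samples, of panel
#'   log2 ratios.
#' @param quantile_prob Percentile for the threshold (default 0.95).
#' @param sd_multiplier SD multiplier added to the percentile (default
#'   2).
#' @param sd_floor Floor on the per-region panel SD (default 1e-6);
#'   floored regions are reported in a message.
#' @param global_threshold Pool panel Z-values across regions for a
#'   single threshold (default `FALSE`).
#' @return List with `z` (tumor Z-scores), `threshold` (per-region),
#'   `panel_mean`, `panel_sd`.
#' @export
compute_z_scores <- function(tumor_log2, panel_log2, quantile_prob = 0.95,
                             sd_multiplier = 2, sd_floor = 1e-6,
                             global_threshold = FALSE) {
  panel_log2 <- as.matrix(panel_log2)
  if (length(tumor_log2) != nrow(panel_log2)) {
    stop("tumor and panel cover different region sets", call. = FALSE)
  }
  if (ncol(panel_log2) < 2) {
    stop("panel must hold >= 2 samples", call. = FALSE)
  }
  m <- rowMeans(panel_log2)
  s <- apply(panel_log2, 1, stats::sd)
  floored <- s < sd_floor
  if (any(floored)) {
    message(sprintf("%d region(s) with near-constant panel coverage; SD floored",
                    sum(floored)))
    s[floored] <- sd_floor
  }
  z <- (tumor_log2 - m) / s
  panel_z <- sweep(sweep(panel_log2, 1, m, "-"), 1, s, "/")
  if (global_threshold) {
    pooled <- as.numeric(panel_z)
    thr <- stats::quantile(pooled, quantile_prob, names = FALSE, type = 7) +
      sd_multiplier * stats::sd(pooled)
    threshold <- rep(thr, length(z))
  } else {
    threshold <- apply(panel_z, 1, function(v)
      stats::quantile(v, quantile_prob, names = FALSE, type = 7) +
        sd_multiplier * stats::sd(v))
  }
  list(z = as.numeric(z), threshold = as.numeric(threshold),
       panel_mean = as.numeric(m), panel_sd = as.numeric(s))
}

#' Copy-number instability (CNI) score
#'
#' Retains the regions whose Z-score strictly exceeds the retention
#' threshold and sums their Z-scores.  The default is one-sided (only
#' positive excursions contribute, so the score is positive by
#' construction and an unaltered genome scores ~0); `two_sided = TRUE`
#' retains regions with `|z|` above threshold and sums `|z|`, letting
#' deletions contribute too.
#'
#' @param z Numeric vector of per-region Z-scores.
#' @param threshold Per-region retention threshold (vector or scalar).
#' @param two_sided Retain on `|z|` instead of `z` (default `FALSE`).
#' @return An object of class `cni_result`: `z`, `threshold`, `retained`
#'   (logical), `cni` (the summed score; 0 when nothing is retained).
#' @export
cni_score <- function(z, threshold, two_sided = FALSE) {
  threshold <- rep_len(threshold, length(z))
  score_base <- if (two_sided) abs(z) else z
  retained <- score_base > threshold
  structure(list(z = z, threshold = threshold, retained = retained,
                 cni = sum(score_base[retained])),
            class = "cni_result")
}

#' @export
print.cni_result <- function(x, ...) {
  cat(sprintf("<cni_result> CNI = %.3f (%d of %d regions retained)\n",
              x$cni, sum(x$retained), length(x$z)))
  invisible(x)
}

#' Call copy-number gain/loss per region
#'
#' Strict thresholds: `gain` when CN > `gain_threshold`, `loss` when
#' CN < `loss_threshold`, `neutral` otherwise (boundary values are
#' neutral).  When absolute copy number is not supplied it is estimated
#' from the log2 ratio as `2 * 2^log2_ratio` (diploid autosome
#' assumption).  The burden is the fraction of regions called gain or
#' loss.
#'
#' @param cn_estimate Numeric vector of copy-number estimates, or `NULL`
#'   to derive from `log2_ratio`.
#' @param log2_ratio Numeric vector of log2 ratios (used when
#'   `cn_estimate` is `NULL`).
#' @param gain_threshold CN above which a region is a gain (default 4).
#' @param loss_threshold CN below which a region is a loss (default
#'   1.2).
#' @return An object of class `cnv_calls`: `cn_estimate`, `call`
#'   (character vector over gain/loss/neutral), `n_gain`, `n_loss`,
#'   `burden`.
#' @export
call_cnv <- function(cn_estimate = NULL, log2_ratio = NULL,
                     gain_threshold = 4, loss_threshold = 1.2) {
  if (is.null(cn_estimate)) {
    if (is.null(log2_ratio)) {
      stop("supply cn_estimate or log2_ratio", call. = FALSE)
    }
    cn_estimate <- 2 * 2^log2_ratio
  }
  if (any(cn_estimate < 0, na.rm = TRUE)) {
    stop("copy-number estimates must be non-negative", call. = FALSE)
  }
  call <- rep("neutral", length(cn_estimate))
  call[cn_estimate > gain_threshold] <- "gain"
  call[cn_estimate < loss_threshold] <- "loss"
  n_gain <- sum(call == "gain")
  n_loss <- sum(call == "loss")
  structure(list(cn_estimate = cn_estimate, call = call,
                 n_gain = n_gain, n_loss = n_loss,
                 burden = (n_gain + n_loss) / length(call)),
            class = "cnv_calls")
}

#' @export
print.cnv_calls <- function(x, ...) {
  cat(sprintf("<cnv_calls> %d gain, %d loss of %d regions (burden %.3f)\n",
              x$n_gain, x$n_loss, length(x$call), x$burden))
  invisible(x)
}

#' Run the full region-level copy-number pipeline for one tumor
#'
#' Chains GC/length correction (tumor and each panel sample
#' independently), log2 ratios of the tumor against the panel mean,
#' leave-one-out panel log2 ratios, Z-scores with per-region (or global)
#' retention thresholds, the CNI score, and gain/loss calls on
#' `2 * 2^log2` copy-number estimates.  The zero-guard passed to
#' [compute_log2_ratios()] is half a read per region on the rate scale
#' (`0.5 / length`).
#'
#' @param tumor_regions Region data frame of the tumor sample.
#' @param panel_regions Named list of region data frames of the normal
#'   panel (identical region set).
#' @param two_sided,global_threshold See [cni_score()] and
#'   [compute_z_scores()].
#' @param gain_threshold,loss_threshold See [call_cnv()].
#' @param gc_bin_width,min_bin_regions See [gc_length_correct()].
#' @return List with `log2_ratio`, `z` (from [compute_z_scores()]),
#'   `cni` (a `cni_result`) and `cnv` (a `cnv_calls`).
#' @export
cni_pipeline <- function(tumor_regions, panel_regions,
                         two_sided = FALSE, global_threshold = FALSE,
                         gain_threshold = 4, loss_threshold = 1.2,
                         gc_bin_width = 0.02, min_bin_regions = 5) {
  if (length(panel_regions) < 2) {
    stop("panel must hold >= 2 samples", call. = FALSE)
  }
  key <- .region_key(tumor_regions)
  for (sid in names(panel_regions)) {
    if (!identical(.region_key(panel_regions[[sid]]), key)) {
      stop(sprintf("panel sample '%s' covers a different region set", sid),
           call. = FALSE)
    }
  }
  tumor_cov <- gc_length_correct(tumor_regions, gc_bin_width,
                                 min_bin_regions)
  panel_cov <- vapply(panel_regions, gc_length_correct,
                      numeric(nrow(tumor_regions)),
                      gc_bin_width = gc_bin_width,
                      min_bin_regions = min_bin_regions)
  eps <- 0.5 / (tumor_regions$end - tumor_regions$start)
  tumor_log2 <- compute_log2_ratios(tumor_cov, panel_cov, eps = eps)
  n_panel <- ncol(panel_cov)
  panel_log2 <- vapply(seq_len(n_panel), function(j) {
    compute_log2_ratios(panel_cov[, j], panel_cov[, -j, drop = FALSE],
                        eps = eps)
  }, numeric(nrow(panel_cov)))
  zres <- compute_z_scores(tumor_log2, panel_log2,
                           global_threshold = global_threshold)
  cni <- cni_score(zres$z, zres$threshold, two_sided = two_sided)
  cnv <- call_cnv(log2_ratio = tumor_log2,
                  gain_threshold = gain_threshold,
                  loss_threshold = loss_threshold)
  list(log2_ratio = tumor_log2, z = zres, cni = cni, cnv = cnv)
}
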