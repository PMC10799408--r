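# Microsatellite instability (MSI) calling from STR allele-length
# histograms against a normal-panel baseline.
#
# The caller never touches reads: its unit is the per-locus histogram of
# read counts by allele length.  A locus's "allele count" is the number
# of distinct allele lengths surviving QC; instability at a locus means
# the tumor shows more alleles than the panel mean plus four panel SDs.

#' Allele-level QC for one STR locus
#'
#' A locus is evaluable only when its total depth strictly exceeds
#' `min_depth`.  Among evaluable loci, an allele length is retained when
#' its read count is at least `min_allele_reads` and at least
#' `min_top_fraction` of the most-supported allele's count.
#'
#' @param hist An [str_histogram()].
#' @param min_depth Minimum total read depth, exclusive (default 100).
#' @param min_allele_reads Minimum reads per allele (default 2).
#' @param min_top_fraction Minimum fraction of the top allele's reads
#'   (default 0.05).
#' @return Integer vector of retained allele lengths, or `NULL` when the
#'   locus is not evaluable.
#' @export
filter_alleles <- function(hist, min_depth = 100, min_allele_reads = 2,
                           min_top_fraction = 0.05) {
  stopifnot(inherits(hist, "str_histogram"))
  total <- sum(hist$counts)
  if (total <= min_depth) return(NULL)
  top <- max(hist$counts)
  keep <- hist$counts >= min_allele_reads &
    hist$counts >= min_top_fraction * top
  as.integer(names(hist$counts)[keep])
}

#' Build an MSI baseline from a normal panel
#'
#' For every locus, runs [filter_alleles()] on each panel sample and
#' records the mean and sample (n-1) standard deviation of the allele
#' counts, together with the number of evaluable panel samples.  Loci
#' evaluable in fewer than two panel samples are dropped with a warning.
#'
#' @param panel Nested list, sample -> locus -> [str_histogram()], as
#'   returned by [read_str_histograms()].
#' @param min_depth,min_allele_reads,min_top_fraction QC thresholds, see
#'   [filter_alleles()].
#' @return An object of class `msi_baseline`: a data frame with columns
#'   `locus_id`, `mean_allele_count`, `sd_allele_count`, `n_panel`.
#' @export
build_msi_baseline <- function(panel, min_depth = 100,
                               min_allele_reads = 2,
                               min_top_fraction = 0.05) {
  if (!length(panel)) stop("empty normal panel", call. = FALSE)
  loci <- unique(unlist(lapply(panel, names)))
  rows <- list()
  dropped <- character()
  for (locus in loci) {
    counts <- numeric()
    for (sid in names(panel)) {
      h <- panel[[sid]][[locus]]
      if (is.null(h)) next
      alleles <- filter_alleles(h, min_depth, min_allele_reads,
                                min_top_fraction)
      if (!is.null(alleles)) counts <- c(counts, length(alleles))
    }
    if (length(counts) < 2) {
      dropped <- c(dropped, locus)
      next
    }
    rows[[locus]] <- data.frame(
      locus_id = locus,
      mean_allele_count = mean(counts),
      sd_allele_count = stats::sd(counts),
      n_panel = length(counts),
      stringsAsFactors = FALSE)
  }
  if (length(dropped)) {
    warning(sprintf("dropped %d locus/loci evaluable in <2 panel samples: %s",
                    length(dropped), paste(dropped, collapse = ", ")),
            call. = FALSE)
  }
  if (!length(rows)) stop("no locus evaluable in >=2 panel samples",
                          call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("msi_baseline", "data.frame"))
}

#' Serialise an MSI baseline to JSON
#'
#' The baseline is written as a JSON object keyed by locus id, each
#' entry carrying `mean_allele_count`, `sd_allele_count` and `n_panel`.
#'
#' @param baseline An `msi_baseline`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msi_baseline <- function(baseline, path) {
  entries <- lapply(seq_len(nrow(baseline)), function(i) {
    list(mean_allele_count = baseline$mean_allele_count[i],
         sd_allele_count = baseline$sd_allele_count[i],
         n_panel = baseline$n_panel[i])
  })
  names(entries) <- baseline$locus_id
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_msi_baseline
#' @export
read_msi_baseline <- function(path) {
  entries <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- do.call(rbind, lapply(names(entries), function(locus) {
    e <- entries[[locus]]
    data.frame(locus_id = locus,
               mean_allele_count = as.numeric(e$mean_allele_count),
               sd_allele_count = as.numeric(e$sd_allele_count),
               n_panel = as.integer(e$n_panel),
               stringsAsFactors = FALSE)
  }))
  structure(out, class = c("msi_baseline", "data.frame"))
}

#' Call stability of one STR locus in a tumor sample
#'
#' The tumor allele count comes from [filter_alleles()]; the locus is
#' `unstable` when the count strictly exceeds the baseline mean plus four
#' baseline SDs, `stable` otherwise, and `not_evaluable` when the tumor
#' fails depth QC or the locus is absent from the baseline (warned).
#'
#' @param hist An [str_histogram()] of the tumor locus.
#' @param baseline An `msi_baseline`.
#' @param sd_multiplier Instability threshold multiplier (default 4).
#' @param min_depth,min_allele_reads,min_top_fraction QC thresholds.
#' @return One-row data frame: `locus_id`, `allele_count`, `status`.
#' @export
call_msi_locus <- function(hist, baseline, sd_multiplier = 4,
                           min_depth = 100, min_allele_reads = 2,
                           min_top_fraction = 0.05) {
  row <- baseline[baseline$locus_id == hist$locus_id, ]
  if (nrow(row) == 0) {
    warning(sprintf("locus '%s' absent from baseline; not evaluable",
                    hist$locus_id), call. = FALSE)
    return(data.frame(locus_id = hist$locus_id,
                      allele_count = NA_integer_,
                      status = "not_evaluable",
                      stringsAsFactors = FALSE))
  }
  alleles <- filter_alleles(hist, min_depth, min_allele_reads,
                            min_top_fraction)
  if (is.null(alleles)) {
    status <- "not_evaluable"
    count <- NA_integer_
  } else {
    count <- length(alleles)
    threshold <- row$mean_allele_count +
      sd_multiplier * row$sd_allele_count
    status <- if (count > threshold) "unstable" else "stable"
  }
  data.frame(locus_id = hist$locus_id, allele_count = count,
             status = status, stringsAsFactors = FALSE)
}

#' Classify a sample's MSI status from its locus calls
#'
#' `MSI-H` when at least two loci are unstable; otherwise `MSS` when at
#' least four loci are stable; otherwise `QNS` (quantity not
#' sufficient).  MSI-H takes precedence when both thresholds are met.
#'
#' @param locus_calls Data frame of locus calls (rows from
#'   [call_msi_locus()]).
#' @param min_unstable MSI-H threshold on unstable loci (default 2).
#' @param min_stable MSS threshold on stable loci (default 4).
#' @return An object of class `msi_sample_call`: `locus_calls`,
#'   `n_unstable`, `n_stable`, `status`.
#' @export
classify_msi_sample <- function(locus_calls, min_unstable = 2,
                                min_stable = 4) {
  if (!nrow(locus_calls)) stop("no locus calls", call. = FALSE)
  n_unstable <- sum(locus_calls$status == "unstable")
  n_stable <- sum(locus_calls$status == "stable")
  status <- if (n_unstable >= min_unstable) "MSI-H"
    else if (n_stable >= min_stable) "MSS" else "QNS"
  structure(list(locus_calls = locus_calls,
                 n_unstable = n_unstable, n_stable = n_stable,
                 status = status),
            class = "msi_sample_call")
}

#' @export
print.msi_sample_call <- function(x, ...) {
  cat(sprintf("<msi_sample_call> %s (%d unstable, %d stable, %d loci)\n",
              x$status, x$n_unstable, x$n_stable, nrow(x$locus_calls)))
  invisible(x)
}

#' Call MSI status of one tumor sample
#'
#' Convenience wrapper: calls every locus of the tumor against the
#' baseline and classifies the sample.
#'
#' @param tumor_hists Named list (by locus) of [str_histogram()] objects
#'   for one sample, e.g. one element of [read_str_histograms()].
#' @param baseline An `msi_baseline`.
#' @param ... Passed to [call_msi_locus()] and [classify_msi_sample()]
#'   (`sd_multiplier`, QC thresholds, `min_unstable`, `min_stable`).
#' @return An `msi_sample_call`.
#' @export
call_msi_sample <- function(tumor_hists, baseline, sd_multiplier = 4,
                            min_depth = 100, min_allele_reads = 2,
                            min_top_fraction = 0.05, min_unstable = 2,
                            min_stable = 4) {
  calls <- do.call(rbind, lapply(tumor_hists, call_msi_locus,
                                 baseline = baseline,
                                 sd_multiplier = sd_multiplier,
                                 min_depth = min_depth,
                                 min_allele_reads = min_allele_reads,
                                 min_top_fraction = min_top_fraction))
  rownames(calls) <- NULL
  classify_msi_sample(calls, min_unstable, min_stable)
}
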