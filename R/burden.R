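# Tumor mutational burden (TMB) and mutant-allele tumor heterogeneity
# (MATH) from a sample's filtered variant table.

#' TMB configuration
#'
#' @param exon_bases Total number of targeted exonic bases (the TMB
#'   denominator); must be positive.
#' @param min_depth Minimum depth for a candidate mutation (default 30).
#' @param min_vaf_pct Minimum tumor VAF in percent (default 5).
#' @param count_indels Whether insertions/deletions count as candidates
#'   alongside SNVs (default `TRUE`).
#' @return An object of class `tmb_config`.
#' @export
tmb_config <- function(exon_bases, min_depth = 30, min_vaf_pct = 5,
                       count_indels = TRUE) {
  if (!is.numeric(exon_bases) || length(exon_bases) != 1 || exon_bases <= 0) {
    stop("exon_bases must be a positive number", call. = FALSE)
  }
  structure(list(exon_bases = exon_bases, min_depth = min_depth,
                 min_vaf_pct = min_vaf_pct,
                 count_indels = isTRUE(count_indels)),
            class = "tmb_config")
}

#' Compute tumor mutational burden
#'
#' Candidate mutations are non-synonymous coding variants (exonic,
#' `variant_class != "synonymous"`) -- SNVs, plus indels when
#' `count_indels` -- passing the depth and VAF thresholds.  TMB is
#' `candidates * 1e6 / exon_bases`, i.e. mutations per megabase of
#' targeted exonic sequence.
#'
#' @param variants Filtered variant data frame of one sample.
#' @param config A [tmb_config()].
#' @return TMB in mutations per megabase (non-negative number).
#' @export
compute_tmb <- function(variants, config) {
  stopifnot(inherits(config, "tmb_config"))
  cand <- variants$region_class == "exonic" &
    variants$variant_class != "synonymous" &
    variants$depth >= config$min_depth &
    variants$tumor_vaf * 100 >= config$min_vaf_pct &
    (variants$variant_type == "SNP" | config$count_indels)
  sum(cand) * 1e6 / config$exon_bases
}

#' MATH configuration
#'
#' Selection rules applied to a sample's SNVs before the MATH statistic:
#' tumor VAF >= `min_vaf_pct`, depth >= `min_depth`, exonic only
#' (`exonic_only`), non-synonymous only (`drop_synonymous`).  Variants at
#' tumor VAF >= `tumor_high_vaf_pct` are kept unconditionally; variants
#' below it are kept only when the tumor VAF is at least
#' `low_vaf_ratio` times the matched-control VAF (guarding low-frequency
#' calls against germline/contamination leakage).
#'
#' @param min_vaf_pct Minimum tumor VAF in percent (default 5).
#' @param min_depth Minimum depth (default 50).
#' @param exonic_only Restrict to exonic variants (default `TRUE`).
#' @param drop_synonymous Drop synonymous variants (default `TRUE`).
#' @param tumor_high_vaf_pct VAF (%) above which a variant is kept
#'   unconditionally (default 10).
#' @param low_vaf_ratio Required tumor/control VAF ratio below
#'   `tumor_high_vaf_pct` (default 10).
#' @param style `"canonical"` (default) or `"literal"`; see
#'   [compute_math()].
#' @return An object of class `math_config`.
#' @export
math_config <- function(min_vaf_pct = 5, min_depth = 50,
                        exonic_only = TRUE, drop_synonymous = TRUE,
                        tumor_high_vaf_pct = 10, low_vaf_ratio = 10,
                        style = c("canonical", "literal")) {
  structure(list(min_vaf_pct = min_vaf_pct, min_depth = min_depth,
                 exonic_only = isTRUE(exonic_only),
                 drop_synonymous = isTRUE(drop_synonymous),
                 tumor_high_vaf_pct = tumor_high_vaf_pct,
                 low_vaf_ratio = low_vaf_ratio,
                 style = match.arg(style)),
            class = "math_config")
}

#' Select the VAFs entering the MATH statistic
#'
#' Applies the [math_config()] selection rules to one sample's variant
#' table and returns the tumor VAFs of the surviving SNVs.
#'
#' @param variants Variant data frame of one sample.
#' @param config A [math_config()].
#' @return Numeric vector of tumor VAFs (fractions).
#' @export
select_math_vafs <- function(variants, config = math_config()) {
  stopifnot(inherits(config, "math_config"))
  keep <- variants$variant_type == "SNP" &
    variants$tumor_vaf * 100 >= config$min_vaf_pct &
    variants$depth >= config$min_depth
  if (config$exonic_only) keep <- keep & variants$region_class == "exonic"
  if (config$drop_synonymous) {
    keep <- keep & variants$variant_class != "synonymous"
  }
  high <- variants$tumor_vaf * 100 >= config$tumor_high_vaf_pct
  ratio_ok <- variants$tumor_vaf >=
    config$low_vaf_ratio * variants$control_vaf
  keep <- keep & (high | ratio_ok)
  variants$tumor_vaf[keep]
}

#' Compute the MATH statistic
#'
#' MATH summarises intra-tumor heterogeneity as the spread of the VAF
#' distribution relative to its centre.  `style = "canonical"` is the
#' literature convention, `100 * 1.4826 * MAD / median(VAF)` where MAD is
#' the median absolute deviation from the median and 1.4826 the Gaussian
#' consistency constant; `style = "literal"` is the bare ratio
#' `MAD / median(VAF)` without the constant or the x100 scaling.  The two
#' differ only by the fixed factor 148.26.
#'
#' @param vafs Numeric vector of tumor VAFs (fractions), typically from
#'   [select_math_vafs()].
#' @param style `"canonical"` (default) or `"literal"`.
#' @return The MATH value, or `NA` when fewer than two VAFs are supplied
#'   or the median VAF is zero (with a warning in the latter case).
#' @export
compute_math <- function(vafs, style = c("canonical", "literal")) {
  style <- match.arg(style)
  vafs <- vafs[!is.na(vafs)]
  if (length(vafs) < 2) return(NA_real_)
  med <- stats::median(vafs)
  if (med == 0) {
    warning("median VAF is zero; MATH undefined", call. = FALSE)
    return(NA_real_)
  }
  mad_raw <- stats::median(abs(vafs - med))
  if (style == "literal") mad_raw / med else 100 * 1.4826 * mad_raw / med
}
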