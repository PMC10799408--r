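# Multi-criteria somatic SNV filter with hotspot rescue.
#
# Each criterion is an exclusion: a variant is removed iff it triggers at
# least one, and every triggered criterion is recorded so rejects are
# auditable.  Thresholds expressed in percent (matching how allele
# frequencies are usually quoted clinically) are converted to fractions
# internally; VAF columns are fractions in [0, 1].

#' Removal reasons recognised by the somatic filter
#' @format Character vector, in evaluation order.
#' @export
filter_reasons <- c(
  "low_depth", "blacklist", "intronic", "nonsense", "db_absent",
  "hla_or_none_gene", "polyphen_benign", "population_af",
  "strand_support", "vaf_support"
)

#' Configuration of the somatic SNV filter
#'
#' Thresholds named `*_pct` are percentages (e.g. `min_tumor_vaf_pct = 5`
#' means tumor VAF >= 5%).  Hotspot variants (`is_hotspot = TRUE`) bypass
#' the ordinary frequency/support rule and must instead satisfy the three
#' hotspot thresholds: alternate reads >= `min_hotspot_support`, control
#' (plasma) VAF >= `min_hotspot_control_vaf_pct` and tumor VAF >=
#' `min_hotspot_tumor_vaf_pct`.
#'
#' @param min_depth Minimum sequencing depth at the site (default 30).
#' @param min_hotspot_support Minimum alternate reads at hotspot sites.
#' @param min_hotspot_control_vaf_pct Minimum control/plasma VAF (%) at
#'   hotspot sites.
#' @param min_hotspot_tumor_vaf_pct Minimum tumor VAF (%) at hotspot
#'   sites.
#' @param min_tumor_vaf_pct Minimum tumor VAF (%) for non-hotspot
#'   variants.
#' @param min_support_reads Minimum alternate reads for non-hotspot
#'   variants.
#' @param max_popmax_af Maximum population allele frequency (fraction)
#'   from ExAC/gnomAD before a variant is treated as common germline.
#' @param db_absence_excludes If `TRUE` (default), an SNV recorded in
#'   neither COSMIC nor snp138 is removed.  The intended direction of
#'   this criterion is debatable, hence the switch.
#' @param exclude_nonsense If `TRUE` (default), nonsense variants are
#'   removed.  Unusual for somatic analyses but kept as the default rule;
#'   set `FALSE` to retain them.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_depth = 30,
                          min_hotspot_support = 5,
                          min_hotspot_control_vaf_pct = 1,
                          min_hotspot_tumor_vaf_pct = 5,
                          min_tumor_vaf_pct = 5,
                          min_support_reads = 5,
                          max_popmax_af = 0.001,
                          db_absence_excludes = TRUE,
                          exclude_nonsense = TRUE) {
  cfg <- list(min_depth = min_depth,
              min_hotspot_support = min_hotspot_support,
              min_hotspot_control_vaf_pct = min_hotspot_control_vaf_pct,
              min_hotspot_tumor_vaf_pct = min_hotspot_tumor_vaf_pct,
              min_tumor_vaf_pct = min_tumor_vaf_pct,
              min_support_reads = min_support_reads,
              max_popmax_af = max_popmax_af,
              db_absence_excludes = isTRUE(db_absence_excludes),
              exclude_nonsense = isTRUE(exclude_nonsense))
  num <- vapply(cfg[1:7], is.numeric, logical(1))
  if (!all(num) || any(unlist(cfg[1:7]) < 0)) {
    stop("filter thresholds must be non-negative numbers", call. = FALSE)
  }
  structure(cfg, class = "filter_config")
}

#' Read a JSON filter configuration
#'
#' Unknown keys raise an error; absent keys take the [filter_config()]
#' defaults.
#'
#' @param path Path to a JSON file.
#' @return A `filter_config` object.
#' @export
read_filter_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(filter_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop(sprintf("unknown filter config key '%s'", unknown[1]), call. = FALSE)
  }
  do.call(filter_config, vals)
}

#' Apply the somatic SNV filter
#'
#' Evaluates every exclusion criterion on every variant (no
#' short-circuiting) and returns the input rows, in order, with two added
#' columns: `kept` (logical) and `reasons` (semicolon-joined subset of
#' [filter_reasons], empty iff kept).
#'
#' Criteria:
#' \describe{
#'   \item{low_depth}{depth below `min_depth`.}
#'   \item{blacklist}{site on the blacklist.}
#'   \item{intronic}{intronic region.}
#'   \item{nonsense}{nonsense variant (when `exclude_nonsense`).}
#'   \item{db_absent}{SNV in neither COSMIC nor snp138 (when
#'     `db_absence_excludes`).}
#'   \item{hla_or_none_gene}{gene annotated `HLA*` or `NONE`.}
#'   \item{polyphen_benign}{both PolyPhen-2 (HDIV and HVAR) codes are
#'     `B`; a missing code never triggers this.}
#'   \item{population_af}{population allele frequency above
#'     `max_popmax_af` (common germline).}
#'   \item{strand_support}{no alternate read on one of the two strands.}
#'   \item{vaf_support}{frequency/support rule: non-hotspot variants need
#'     alternate reads >= `min_support_reads` and tumor VAF >=
#'     `min_tumor_vaf_pct`; hotspot variants instead need the three
#'     hotspot thresholds (the hotspot rescue).}
#' }
#'
#' PolyPhen, database and population-frequency criteria apply only to
#' SNP records; indels pass through the criteria that are well defined
#' for them.  When per-strand counts are absent the strand criterion is
#' not evaluated and support is approximated by `round(tumor_vaf * depth)`.
#'
#' @param variants Variant data frame (see [read_variant_table()]).
#' @param config A [filter_config()].
#' @return The variant data frame with `kept` and `reasons` columns.
#' @seealso [kept_variants()], [rejected_variants()]
#' @export
apply_snv_filters <- function(variants, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  validate_variant_table(variants)
  n <- nrow(variants)
  is_snp <- variants$variant_type == "SNP"

  trig <- matrix(FALSE, nrow = n, ncol = length(filter_reasons),
                 dimnames = list(NULL, filter_reasons))
  trig[, "low_depth"] <- variants$depth < config$min_depth
  trig[, "blacklist"] <- variants$in_blacklist
  trig[, "intronic"] <- variants$region_class == "intronic"
  trig[, "nonsense"] <- config$exclude_nonsense &
    variants$variant_class == "nonsense"
  trig[, "db_absent"] <- config$db_absence_excludes & is_snp &
    !(variants$in_cosmic | variants$in_snp138)
  gene <- variants$gene
  trig[, "hla_or_none_gene"] <- !is.na(gene) &
    (startsWith(gene, "HLA") | gene == "NONE")
  trig[, "polyphen_benign"] <- is_snp &
    variants$polyphen_div == "B" & variants$polyphen_var == "B"
  trig[, "population_af"] <- is_snp & !is.na(variants$popmax_af) &
    variants$popmax_af > config$max_popmax_af

  strands_known <- !is.na(variants$alt_fwd) & !is.na(variants$alt_rev)
  trig[, "strand_support"] <- strands_known &
    (variants$alt_fwd < 1 | variants$alt_rev < 1)

  support <- ifelse(strands_known, variants$alt_fwd + variants$alt_rev,
                    round(variants$tumor_vaf * variants$depth))
  tumor_pct <- variants$tumor_vaf * 100
  control_pct <- variants$control_vaf * 100
  ok_standard <- support >= config$min_support_reads &
    tumor_pct >= config$min_tumor_vaf_pct
  ok_hotspot <- support >= config$min_hotspot_support &
    control_pct >= config$min_hotspot_control_vaf_pct &
    tumor_pct >= config$min_hotspot_tumor_vaf_pct
  trig[, "vaf_support"] <- ifelse(variants$is_hotspot,
                                  !ok_hotspot, !ok_standard)

  out <- variants
  out$kept <- rowSums(trig) == 0
  out$reasons <- apply(trig, 1, function(r)
    paste(filter_reasons[r], collapse = ";"))
  out
}

#' Extract kept / rejected variants from a filter outcome
#'
#' @param outcome Result of [apply_snv_filters()].
#' @return The corresponding variant rows without the `kept`/`reasons`
#'   columns (`kept_variants`), or with the `reasons` column retained
#'   (`rejected_variants`).
#' @export
kept_variants <- function(outcome) {
  stopifnot(all(c("kept", "reasons") %in% names(outcome)))
  out <- outcome[outcome$kept, variant_columns]
  rownames(out) <- NULL
  out
}

#' @rdname kept_variants
#' @export
rejected_variants <- function(outcome) {
  stopifnot(all(c("kept", "reasons") %in% names(outcome)))
  out <- outcome[!outcome$kept, c(variant_columns, "reasons")]
  rownames(out) <- NULL
  out
}
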