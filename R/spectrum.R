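# Six-class mutation spectrum, transition/transversion analysis and
# between-group spectrum comparison.
#
# Every SNV is represented on the pyrimidine strand (the COSMIC /
# maftools convention): a substitution whose reference base is a purine
# is complemented, merging complementary pairs (G>A == C>T), which yields
# six classes.  C>T and T>C are the transitions.

#' The six pyrimidine-collapsed substitution classes
#' @format Character vector.
#' @export
substitution_classes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

.transition_classes <- c("C>T", "T>C")

.complement <- c(A = "T", C = "G", G = "C", T = "A")

#' Classify a single-base substitution
#'
#' Collapses the substitution onto the pyrimidine strand and returns one
#' of the six classes in [substitution_classes].  Vectorised.
#'
#' @param ref_allele,alt_allele Single bases in `A`, `C`, `G`, `T`;
#'   `ref_allele != alt_allele` element-wise.
#' @return Character vector of substitution classes.
#' @examples
#' classify_substitution("G", "A")  # "C>T"
#' @export
classify_substitution <- function(ref_allele, alt_allele) {
  ref <- toupper(ref_allele)
  alt <- toupper(alt_allele)
  if (any(!ref %in% names(.complement)) || any(!alt %in% names(.complement))) {
    stop("alleles must be single bases A, C, G or T", call. = FALSE)
  }
  if (any(ref == alt)) {
    stop("ref and alt alleles must differ", call. = FALSE)
  }
  purine <- ref %in% c("A", "G")
  ref[purine] <- .complement[ref_allele[purine]]
  alt[purine] <- .complement[alt_allele[purine]]
  paste0(ref, ">", alt)
}

#' Summarise the mutation spectrum of one sample
#'
#' Tallies the kept variants of a single sample: six-class substitution
#' counts (SNP records only), transition/transversion counts, and
#' variant-classification and variant-type tallies (all records).
#'
#' @param variants Variant data frame of one sample (typically the kept
#'   set from [apply_snv_filters()]).
#' @param sample_id Optional; inferred from the table when omitted.
#' @return An object of class `spectrum_summary` with elements
#'   `sample_id`, `class_counts` (named over [substitution_classes]),
#'   `ti_count`, `tv_count`, `classification_counts`, `type_counts`.
#' @export
summarize_spectrum <- function(variants, sample_id = NULL) {
  ids <- unique(variants$sample_id)
  if (length(ids) > 1) {
    stop("summarize_spectrum expects variants of a single sample; got ",
         length(ids), call. = FALSE)
  }
  if (is.null(sample_id)) {
    sample_id <- if (length(ids)) ids else NA_character_
  }
  snp <- variants[variants$variant_type == "SNP", ]
  cls <- if (nrow(snp)) {
    classify_substitution(snp$ref_allele, snp$alt_allele)
  } else character()
  class_counts <- table(factor(cls, levels = substitution_classes))
  class_counts <- stats::setNames(as.integer(class_counts),
                                  substitution_classes)
  classification_counts <- table(factor(variants$variant_class,
                                        levels = .variant_class_levels))
  type_counts <- table(factor(variants$variant_type,
                              levels = .variant_type_levels))
  structure(
    list(sample_id = sample_id,
         class_counts = class_counts,
         ti_count = sum(class_counts[.transition_classes]),
         tv_count = sum(class_counts[setdiff(substitution_classes,
                                             .transition_classes)]),
         classification_counts =
           stats::setNames(as.integer(classification_counts),
                           .variant_class_levels),
         type_counts = stats::setNames(as.integer(type_counts),
                                       .variant_type_levels)),
    class = "spectrum_summary"
  )
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat(sprintf("<spectrum_summary> sample %s: %d SNVs (Ti %d / Tv %d)\n",
              x$sample_id, sum(x$class_counts), x$ti_count, x$tv_count))
  print(x$class_counts)
  invisible(x)
}

#' Within-sample transition/transversion imbalance test
#'
#' Exact two-sided binomial test of the transition count among all
#' substitutions against the null proportion 1/3 -- two of the six
#' collapsed classes are transitions, so a spectrum that is uniform over
#' classes has Ti fraction 1/3.  A small p-value indicates a spectrum
#' skewed towards (or away from) transitions, typically driven by C>T.
#'
#' @param summary A `spectrum_summary`, or a list with `ti_count` and
#'   `tv_count`.
#' @param null_prop Null transition proportion (default `1/3`).
#' @return Two-sided p-value, or `NA` when the sample has no SNVs.
#' @export
titv_imbalance_test <- function(summary, null_prop = 1/3) {
  n <- summary$ti_count + summary$tv_count
  if (n < 1) return(NA_real_)
  stats::binom.test(summary$ti_count, n, p = null_prop)$p.value
}

.class_proportions <- function(summary) {
  total <- sum(summary$class_counts)
  if (total == 0) return(rep(NA_real_, length(substitution_classes)))
  summary$class_counts / total
}

#' Compare the mutation spectra of two sample groups
#'
#' Group-level proportions are pooled counts over pooled totals (the
#' quantity a stacked-bar figure displays); significance is assessed at
#' sample level: per class, a two-sided Wilcoxon rank-sum test on the
#' per-sample class proportions, and a rank-sum test on the per-sample
#' transition fractions (`titv_p`).  Samples with zero SNVs are dropped
#' from the tests with a warning; when either group has fewer than two
#' usable samples the p-values are `NA`.
#'
#' @param summaries_a,summaries_b Non-empty lists of `spectrum_summary`
#'   objects.
#' @param label_a,label_b Group labels for the report.
#' @return An object of class `spectrum_comparison`: `group_a`,
#'   `group_b`, `per_class` (data frame with `class`, `proportion_a`,
#'   `proportion_b`, `p_value`), and `titv_p`.
#' @export
compare_group_spectra <- function(summaries_a, summaries_b,
                                  label_a = "A", label_b = "B") {
  if (!length(summaries_a) || !length(summaries_b)) {
    stop("both groups need at least one spectrum summary", call. = FALSE)
  }
  pooled <- function(summaries) {
    counts <- Reduce(`+`, lapply(summaries, `[[`, "class_counts"))
    total <- sum(counts)
    if (total == 0) rep(NA_real_, length(counts)) else counts / total
  }
  usable <- function(summaries, label) {
    nz <- vapply(summaries, function(s) sum(s$class_counts) > 0, logical(1))
    if (any(!nz)) {
      warning(sprintf("group %s: dropped %d sample(s) with zero SNVs from tests",
                      label, sum(!nz)), call. = FALSE)
    }
    summaries[nz]
  }
  use_a <- usable(summaries_a, label_a)
  use_b <- usable(summaries_b, label_b)
  testable <- length(use_a) >= 2 && length(use_b) >= 2

  prop_a <- vapply(use_a, .class_proportions,
                   numeric(length(substitution_classes)))
  prop_b <- vapply(use_b, .class_proportions,
                   numeric(length(substitution_classes)))
  p_class <- rep(NA_real_, length(substitution_classes))
  if (testable) {
    for (i in seq_along(substitution_classes)) {
      p_class[i] <- suppressWarnings(
        stats::wilcox.test(prop_a[i, ], prop_b[i, ])$p.value)
    }
  }
  ti_frac <- function(summaries) vapply(summaries, function(s)
    s$ti_count / (s$ti_count + s$tv_count), numeric(1))
  titv_p <- if (testable) {
    suppressWarnings(
      stats::wilcox.test(ti_frac(use_a), ti_frac(use_b))$p.value)
  } else NA_real_

  structure(
    list(group_a = label_a, group_b = label_b,
         per_class = data.frame(
           class = substitution_classes,
           proportion_a = as.numeric(pooled(summaries_a)),
           proportion_b = as.numeric(pooled(summaries_b)),
           p_value = p_class,
           stringsAsFactors = FALSE),
         titv_p = titv_p),
    class = "spectrum_comparison"
  )
}

#' @export
print.spectrum_comparison <- function(x, ...) {
  cat(sprintf("<spectrum_comparison> %s vs %s (TiTv rank-sum p = %s)\n",
              x$group_a, x$group_b, format(x$titv_p, digits = 3)))
  print(x$per_class)
  invisible(x)
}

#' Dominant substitution class of a group
#'
#' The class with the largest pooled proportion.
#'
#' @param comparison A `spectrum_comparison`.
#' @param side `"a"` or `"b"`.
#' @return A class name from [substitution_classes].
#' @export
dominant_class <- function(comparison, side = c("a", "b")) {
  side <- match.arg(side)
  col <- paste0("proportion_", side)
  comparison$per_class$class[which.max(comparison$per_class[[col]])]
}
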