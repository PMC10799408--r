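# Seeded synthetic-cohort generator: variant tables, STR histogram
# panels, and region read-count panels, each with a truth manifest.
# Stands in for the controlled-access patient data the analysis was
# designed around; it emulates the statistical structure the downstream
# modules assume (six-class spectra, beta-distributed VAFs, negative
# binomial depths, Poisson region counts with a smooth GC bias), not
# read-level sequencing artefacts.
#
# All randomness flows from a single integer seed; cohort-level
# generation derives one child seed per sample (documented linear
# scheme), so any single sample can be regenerated in isolation.

.child_seed <- function(seed, index) {
  # keep well inside 32-bit integer range
  as.integer((as.numeric(seed) * 1009 + index * 9973) %% 2147483629 + 1)
}

.pyrimidine_pair <- function(class) {
  cbind(ref = substr(class, 1, 1), alt = substr(class, 3, 3))
}

#' Simulate an annotated somatic variant table for one sample
#'
#' Draws `n_variants` variants: substitution classes multinomially from
#' `class_probs` (rendered on a random strand so downstream
#' pyrimidine-collapse is exercised), depths from a negative binomial,
#' VAFs from a beta distribution, alternate reads binomially from depth
#' and VAF with a binomial strand split, and annotation flags set so a
#' baseline variant passes every filter criterion.  A configurable
#' fraction of variants is then altered to violate one named criterion
#' each; which rows were altered is recorded in the returned truth
#' table.
#'
#' @param sample_id Sample identifier.
#' @param n_variants Number of variants (default 300).
#' @param class_probs Named probabilities over [substitution_classes]
#'   (default uniform); must sum to 1.
#' @param indel_rate Fraction of variants rendered as indels (default
#'   0.05).
#' @param depth_mean,depth_size Negative binomial depth parameters
#'   (defaults 200 and 10); depths are floored at 60 so baseline
#'   variants clear the depth filters.
#' @param vaf_shape1,vaf_shape2 Beta parameters of the VAF distribution
#'   (defaults 2 and 6, mean 0.25); VAFs are clamped to `[0.08, 0.95]`
#'   so baseline variants clear the frequency filters.
#' @param hotspot_rate Fraction of clean SNVs flagged as hotspots with a
#'   low-positive control VAF (default 0).
#' @param violation_rates Named numeric vector/list over
#'   [filter_reasons]; each entry is the fraction of variants engineered
#'   to violate that criterion (default none).
#' @param seed Optional integer seed.
#' @return List with `variants` (a variant data frame) and `truth`
#'   (data frame `sample_id`, `row`, `reason`; one row per engineered
#'   violation).
#' @export
simulate_variants <- function(sample_id, n_variants = 300,
                              class_probs = NULL, indel_rate = 0.05,
                              depth_mean = 200, depth_size = 10,
                              vaf_shape1 = 2, vaf_shape2 = 6,
                              hotspot_rate = 0,
                              violation_rates = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(class_probs)) {
    class_probs <- stats::setNames(rep(1/6, 6), substitution_classes)
  }
  if (!all(substitution_classes %in% names(class_probs)) ||
      abs(sum(unlist(class_probs)) - 1) > 1e-8 ||
      any(unlist(class_probs) < 0)) {
    stop("class_probs must be non-negative over the six classes and sum to 1",
         call. = FALSE)
  }
  n <- n_variants
  is_indel <- stats::runif(n) < indel_rate
  class <- sample(substitution_classes, n, replace = TRUE,
                  prob = unlist(class_probs)[substitution_classes])
  pair <- .pyrimidine_pair(class)
  flip <- stats::runif(n) < 0.5
  ref <- ifelse(flip, unname(.complement[pair[, "ref"]]), pair[, "ref"])
  alt <- ifelse(flip, unname(.complement[pair[, "alt"]]), pair[, "alt"])

  bases <- c("A", "C", "G", "T")
  ins <- is_indel & stats::runif(n) < 0.5
  del <- is_indel & !ins
  ref[ins] <- "-"
  alt[ins] <- vapply(which(ins), function(i)
    paste(sample(bases, sample(1:3, 1), replace = TRUE), collapse = ""),
    character(1))
  ref[del] <- vapply(which(del), function(i)
    paste(sample(bases, sample(2:4, 1), replace = TRUE), collapse = ""),
    character(1))
  alt[del] <- "-"

  variant_type <- ifelse(ins, "INS", ifelse(del, "DEL", "SNP"))
  variant_class <- ifelse(
    is_indel,
    sample(c("frameshift", "inframe_indel"), n, replace = TRUE,
           prob = c(0.6, 0.4)),
    sample(c("missense", "synonymous", "splice", "other"), n,
           replace = TRUE, prob = c(0.75, 0.15, 0.05, 0.05)))

  depth <- pmax(60L, stats::rnbinom(n, mu = depth_mean, size = depth_size))
  vaf <- pmin(pmax(stats::rbeta(n, vaf_shape1, vaf_shape2), 0.08), 0.95)
  alt_reads <- pmin(depth, pmax(5L, stats::rbinom(n, depth, vaf)))
  alt_fwd <- 1L + stats::rbinom(n, alt_reads - 2L, 0.5)
  alt_rev <- alt_reads - alt_fwd
  tumor_vaf <- alt_reads / depth
  control_vaf <- rep(0, n)

  in_cosmic <- stats::runif(n) < 0.7
  in_snp138 <- stats::runif(n) < 0.2
  neither <- !in_cosmic & !in_snp138
  in_cosmic[neither] <- TRUE
  pp_codes <- c("D", "P", "missing")
  polyphen_div <- sample(pp_codes, n, replace = TRUE, prob = c(.5, .3, .2))
  polyphen_var <- sample(pp_codes, n, replace = TRUE, prob = c(.5, .3, .2))
  gene <- sprintf("GENE%03d", sample.int(80, n, replace = TRUE))
  is_hotspot <- rep(FALSE, n)
  if (hotspot_rate > 0) {
    hot <- stats::runif(n) < hotspot_rate & !is_indel
    is_hotspot[hot] <- TRUE
    control_vaf[hot] <- 0.02
  }

  df <- data.frame(
    sample_id = sample_id,
    chrom = sample(paste0("chr", 1:22), n, replace = TRUE),
    pos = sample.int(2e8, n, replace = TRUE),
    ref_allele = ref, alt_allele = alt,
    variant_type = variant_type, variant_class = variant_class,
    region_class = "exonic", gene = gene,
    depth = as.integer(depth), alt_fwd = as.integer(alt_fwd),
    alt_rev = as.integer(alt_rev),
    tumor_vaf = tumor_vaf, control_vaf = control_vaf,
    in_cosmic = in_cosmic, in_snp138 = in_snp138,
    polyphen_div = polyphen_div, polyphen_var = polyphen_var,
    popmax_af = 0, is_hotspot = is_hotspot, in_blacklist = FALSE,
    stringsAsFactors = FALSE
  )

  truth <- data.frame(sample_id = character(), row = integer(),
                      reason = character(), stringsAsFactors = FALSE)
  if (!is.null(violation_rates) && length(violation_rates)) {
    rates <- unlist(violation_rates)
    unknown <- setdiff(names(rates), filter_reasons)
    if (length(unknown)) {
      stop(sprintf("unknown violation reason '%s'", unknown[1]),
           call. = FALSE)
    }
    # violations are injected into SNV rows only, disjointly per reason
    pool <- sample(which(!is_indel))
    taken <- 0L
    for (reason in names(rates)) {
      k <- round(rates[[reason]] * n)
      if (k == 0) next
      if (taken + k > length(pool)) {
        stop("violation rates exceed available SNV rows", call. = FALSE)
      }
      idx <- pool[(taken + 1L):(taken + k)]
      taken <- taken + k
      df <- .inject_violation(df, idx, reason)
      truth <- rbind(truth, data.frame(sample_id = sample_id, row = idx,
                                       reason = reason,
                                       stringsAsFactors = FALSE))
    }
  }
  list(variants = df, truth = truth[order(truth$row), ])
}

# Rewrite rows `idx` of a clean table so each triggers `reason` (and, by
# construction, only that criterion under the default filter config).
.inject_violation <- function(df, idx, reason) {
  m <- length(idx)
  resupport <- function(df, idx, depth, alt) {
    df$depth[idx] <- depth
    df$alt_fwd[idx] <- pmax(1L, as.integer(floor(alt / 2)))
    df$alt_rev[idx] <- as.integer(alt) - df$alt_fwd[idx]
    df$tumor_vaf[idx] <- alt / depth
    df
  }
  switch(reason,
    low_depth = {
      d <- sample(10:29, m, replace = TRUE)
      resupport(df, idx, as.integer(d), pmax(5L, as.integer(round(0.3 * d))))
    },
    blacklist = { df$in_blacklist[idx] <- TRUE; df },
    intronic = { df$region_class[idx] <- "intronic"; df },
    nonsense = { df$variant_class[idx] <- "nonsense"; df },
    db_absent = {
      df$in_cosmic[idx] <- FALSE; df$in_snp138[idx] <- FALSE; df
    },
    hla_or_none_gene = {
      df$gene[idx] <- sample(c("HLA-A", "HLA-B", "NONE"), m, replace = TRUE)
      df
    },
    polyphen_benign = {
      df$polyphen_div[idx] <- "B"; df$polyphen_var[idx] <- "B"; df
    },
    population_af = { df$popmax_af[idx] <- 0.01; df },
    strand_support = {
      alt <- df$alt_fwd[idx] + df$alt_rev[idx]
      df$alt_fwd[idx] <- as.integer(alt); df$alt_rev[idx] <- 0L; df
    },
    vaf_support = resupport(df, idx, 200L, 4L),
    stop(sprintf("unknown reason '%s'", reason), call. = FALSE)
  )
}

#' Deterministic filter-audit fixture
#'
#' Builds an 11-variant table: one clean variant that satisfies every
#' filter criterion, plus one variant per removal reason engineered to
#' violate exactly that criterion and no other.  Used to audit the
#' filter's reason reporting.
#'
#' @param sample_id Sample identifier (default `"AUDIT"`).
#' @return List with `variants` and `expected_reasons` (character
#'   vector, `""` for the clean row, aligned with the rows).
#' @export
make_filter_audit_table <- function(sample_id = "AUDIT") {
  clean <- data.frame(
    sample_id = sample_id, chrom = "chr1", pos = 0L,
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
  rows <- c("", filter_reasons)
  df <- clean[rep(1, length(rows)), ]
  df$pos <- seq_along(rows) * 1000L
  rownames(df) <- NULL
  for (i in seq_along(rows)) {
    r <- rows[i]
    if (r == "") next
    df[i, ] <- switch(r,
      low_depth = { x <- df[i, ]; x$depth <- 20L; x$alt_fwd <- 3L
        x$alt_rev <- 3L; x$tumor_vaf <- 6 / 20; x },
      blacklist = { x <- df[i, ]; x$in_blacklist <- TRUE; x },
      intronic = { x <- df[i, ]; x$region_class <- "intronic"; x },
      nonsense = { x <- df[i, ]; x$variant_class <- "nonsense"; x },
      db_absent = { x <- df[i, ]; x$in_cosmic <- FALSE; x },
      hla_or_none_gene = { x <- df[i, ]; x$gene <- "HLA-A"; x },
      polyphen_benign = { x <- df[i, ]; x$polyphen_div <- "B"
        x$polyphen_var <- "B"; x },
      population_af = { x <- df[i, ]; x$popmax_af <- 0.01; x },
      strand_support = { x <- df[i, ]; x$alt_fwd <- 58L; x$alt_rev <- 0L; x },
      vaf_support = { x <- df[i, ]; x$alt_fwd <- 2L; x$alt_rev <- 2L
        x$tumor_vaf <- 4 / 200; x }
    )
  }
  list(variants = df, expected_reasons = rows)
}

.str_table_from_hists <- function(hists) {
  rows <- list()
  for (sid in names(hists)) {
    for (lid in names(hists[[sid]])) {
      h <- hists[[sid]][[lid]]
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, locus_id = lid,
        allele_length = as.integer(names(h$counts)),
        read_count = as.numeric(h$counts), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

.render_str_histogram <- function(sample_id, locus_id, base_length,
                                  n_alleles, depth) {
  w <- stats::runif(n_alleles, 0.8, 1.2)
  counts <- pmax(2, round(depth * w / sum(w)))
  lengths <- base_length + seq_len(n_alleles) - 1L
  str_histogram(sample_id, locus_id, stats::setNames(counts, lengths))
}

#' Simulate an STR panel and tumor histograms
#'
#' Normal-panel samples draw per-locus allele counts from a rounded
#' normal distribution (`mean_alleles`, `sd_alleles`, floored at 1) and
#' render them as read-count histograms with total depth above the QC
#' cutoff.  Tumors labelled `MSI-H` have their allele counts inflated at
#' the first `n_unstable_loci` loci to
#' `ceiling(mean + 4 * sd) + 3`, clearly beyond the instability
#' threshold; `MSS` tumors draw from the normal model.  Forcing
#' `tumor_depth` to 100 or less renders every tumor locus not evaluable
#' (a QNS sample).
#'
#' @param loci Character vector of locus ids, or a count (default 10).
#' @param n_normals Panel size (default 30).
#' @param tumor_ids Character vector of tumor sample ids.
#' @param msi_truth `"MSS"` or `"MSI-H"`, recycled over `tumor_ids`.
#' @param n_unstable_loci Loci inflated in MSI-H tumors (default 3).
#' @param mean_alleles,sd_alleles Normal model of the per-locus allele
#'   count (defaults 3 and 0.5).
#' @param depth_range Range of per-locus total depths (default 150-300).
#' @param tumor_depth Optional fixed tumor depth overriding
#'   `depth_range`.
#' @param seed Optional integer seed.
#' @return List with `panel` and `tumors` (nested histogram lists as in
#'   [read_str_histograms()]), `panel_table` and `tumor_table` (long
#'   data frames), and `truth` (data frame `sample_id`, `msi_truth`).
#' @export
simulate_str_panel <- function(loci = 10, n_normals = 30,
                               tumor_ids = "TUMOR", msi_truth = "MSS",
                               n_unstable_loci = 3, mean_alleles = 3,
                               sd_alleles = 0.5,
                               depth_range = c(150, 300),
                               tumor_depth = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_normals < 2) stop("need at least 2 panel samples", call. = FALSE)
  if (is.numeric(loci)) loci <- sprintf("MSI%02d", seq_len(loci))
  base_length <- stats::setNames(14L + 2L * seq_along(loci), loci)
  msi_truth <- rep_len(msi_truth, length(tumor_ids))
  if (!all(msi_truth %in% c("MSS", "MSI-H"))) {
    stop("msi_truth must be 'MSS' or 'MSI-H'", call. = FALSE)
  }

  draw_count <- function() max(1L, round(stats::rnorm(1, mean_alleles,
                                                      sd_alleles)))
  draw_depth <- function() sample(depth_range[1]:depth_range[2], 1)

  panel <- list()
  for (i in seq_len(n_normals)) {
    sid <- sprintf("NORM%02d", i)
    panel[[sid]] <- lapply(stats::setNames(loci, loci), function(l)
      .render_str_histogram(sid, l, base_length[[l]], draw_count(),
                            draw_depth()))
  }
  inflated_count <- as.integer(ceiling(mean_alleles + 4 * sd_alleles) + 3)
  tumors <- list()
  for (i in seq_along(tumor_ids)) {
    sid <- tumor_ids[i]
    unstable <- if (msi_truth[i] == "MSI-H") loci[seq_len(n_unstable_loci)]
      else character()
    tumors[[sid]] <- lapply(stats::setNames(loci, loci), function(l) {
      k <- if (l %in% unstable) inflated_count else draw_count()
      d <- if (is.null(tumor_depth)) draw_depth() else tumor_depth
      .render_str_histogram(sid, l, base_length[[l]], k, d)
    })
  }
  list(panel = panel, tumors = tumors,
       panel_table = .str_table_from_hists(panel),
       tumor_table = .str_table_from_hists(tumors),
       truth = data.frame(sample_id = tumor_ids, msi_truth = msi_truth,
                          stringsAsFactors = FALSE))
}

#' Simulate region read counts for tumors and a normal panel
#'
#' Lays out a shared region grid (lengths uniform over `length_range`,
#' GC fraction uniform on 0.3-0.7), and draws Poisson read counts with
#' expectation `mean_depth * (length / median length) * gc_bias(gc) *
#' CN / 2`.  Panel samples sit at copy number 2 throughout; tumor copy
#' number comes from `cn_truth`.
#'
#' @param n_regions Number of regions (default 300, minimum 20).
#' @param panel_n Normal-panel size (default 30).
#' @param tumor_ids Character vector of tumor sample ids.
#' @param cn_truth Named list (by tumor id) of integer copy-number
#'   vectors of length `n_regions`; default copy number 2 everywhere.
#' @param mean_depth Expected count of a median-length CN-2 region with
#'   unit GC bias (default 200).
#' @param gc_bias Function of GC fraction giving the relative coverage
#'   bias (default a smooth bump peaked at GC 0.42).
#' @param length_range Region length range in bp (default 120-400).
#' @param seed Optional integer seed.
#' @return List with `tumors` (named list of region data frames),
#'   `panel` (named list, ids `RPANEL*`), and `truth` (the `cn_truth`
#'   used).
#' @export
simulate_region_counts <- function(n_regions = 300, panel_n = 30,
                                   tumor_ids = "TUMOR", cn_truth = NULL,
                                   mean_depth = 200,
                                   gc_bias = function(gc)
                                     exp(-4 * (gc - 0.42)^2),
                                   length_range = c(120, 400),
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_regions < 20) stop("need at least 20 regions", call. = FALSE)
  len <- sample(length_range[1]:length_range[2], n_regions, replace = TRUE)
  gap <- 1000L
  start <- cumsum(c(0L, utils::head(len, -1) + gap))
  grid <- data.frame(chrom = "chr1", start = start, end = start + len,
                     gc_fraction = round(stats::runif(n_regions, 0.3, 0.7), 4),
                     stringsAsFactors = FALSE)
  if (is.null(cn_truth)) {
    cn_truth <- stats::setNames(
      rep(list(rep(2L, n_regions)), length(tumor_ids)), tumor_ids)
  }
  if (!all(tumor_ids %in% names(cn_truth))) {
    stop("cn_truth must name every tumor sample", call. = FALSE)
  }
  base_mu <- mean_depth * (len / stats::median(len)) *
    gc_bias(grid$gc_fraction)
  draw <- function(cn) {
    out <- grid
    out$read_count <- stats::rpois(n_regions, base_mu * cn / 2)
    out
  }
  panel <- lapply(stats::setNames(seq_len(panel_n),
                                  sprintf("RPANEL%02d", seq_len(panel_n))),
                  function(i) draw(2))
  tumors <- lapply(stats::setNames(tumor_ids, tumor_ids), function(sid) {
    cn <- cn_truth[[sid]]
    if (length(cn) != n_regions) {
      stop(sprintf("cn_truth for '%s' must have %d entries", sid,
                   n_regions), call. = FALSE)
    }
    draw(cn)
  })
  list(tumors = tumors, panel = panel, truth = cn_truth)
}

#' Simulate a complete two-group cohort
#'
#' Generates everything the pipeline consumes for a cohort of
#' `n_per_group` samples per group: per-sample variant tables (group A
#' with a C>A-dominant spectrum, group B C>T-dominant, by default),
#' STR histograms for all tumors plus a shared normal panel, region read
#' counts for all tumors plus a shared normal panel, a groups file, and
#' a truth manifest.  By default one designated group-B sample is
#' simulated MSI-H and every group-B sample carries copy-number 6 in a
#' fraction `cn6_region_fraction` of regions.
#'
#' Per-sample child seeds are derived from `seed` by a fixed linear
#' scheme, so individual samples are reproducible in isolation, and a
#' fixed seed yields byte-identical output files.
#'
#' @param seed Integer seed (mandatory: the cohort is defined by it).
#' @param out_dir Optional directory; when given, writes
#'   `variants.tsv`, `str_panel.tsv`, `str_tumors.tsv`,
#'   `region_counts.tsv`, `groups.tsv` and `truth.json` there.
#' @param n_per_group Samples per group (default 6).
#' @param group_labels Two labels (default `c("HE", "HI")`).
#' @param dominant_fraction Weight of the dominant class in each group's
#'   spectrum (default 0.7, remainder spread evenly).
#' @param dominant_classes Dominant class per group (default C>A for
#'   group A, C>T for group B).
#' @param n_variants Variants per sample (default 300).
#' @param violation_rates Per-criterion violation fractions passed to
#'   [simulate_variants()] (default 0.02 for each criterion).
#' @param n_msi_h Number of MSI-H samples in group B (default 1).
#' @param cn6_region_fraction Fraction of regions at copy number 6 in
#'   group-B samples (default 0.1).
#' @param n_loci STR loci (default 10).
#' @param str_panel_n,region_panel_n Normal panel sizes (default 30).
#' @param n_regions Regions (default 300).
#' @return (Invisibly) a list with `variants`, `variant_truth`, `str`
#'   (from [simulate_str_panel()]), `regions` (from
#'   [simulate_region_counts()]), `groups` (data frame), and `truth`
#'   (manifest list).
#' @export
simulate_cohort <- function(seed, out_dir = NULL, n_per_group = 6,
                            group_labels = c("HE", "HI"),
                            dominant_fraction = 0.7,
                            dominant_classes = c("C>A", "C>T"),
                            n_variants = 300,
                            violation_rates = NULL,
                            n_msi_h = 1, cn6_region_fraction = 0.1,
                            n_loci = 10, str_panel_n = 30,
                            region_panel_n = 30, n_regions = 300) {
  stopifnot(length(group_labels) == 2, length(dominant_classes) == 2)
  if (is.null(violation_rates)) {
    violation_rates <- stats::setNames(rep(0.02, length(filter_reasons)),
                                       filter_reasons)
  }
  spectrum_for <- function(dom) {
    p <- stats::setNames(rep((1 - dominant_fraction) / 5, 6),
                         substitution_classes)
    p[dom] <- dominant_fraction
    p
  }
  n_total <- 2 * n_per_group
  sample_ids <- sprintf("S%02d", seq_len(n_total))
  group <- rep(group_labels, each = n_per_group)
  groups <- data.frame(sample_id = sample_ids, group_label = group,
                       stringsAsFactors = FALSE)
  in_b <- group == group_labels[2]
  msi_truth <- ifelse(in_b & seq_len(n_total) <=
                        n_per_group + n_msi_h, "MSI-H", "MSS")
  msi_truth[!in_b] <- "MSS"

  variants <- list()
  vtruth <- list()
  for (i in seq_len(n_total)) {
    dom <- if (in_b[i]) dominant_classes[2] else dominant_classes[1]
    sim <- simulate_variants(sample_ids[i], n_variants = n_variants,
                             class_probs = spectrum_for(dom),
                             violation_rates = violation_rates,
                             seed = .child_seed(seed, i))
    variants[[i]] <- sim$variants
    vtruth[[i]] <- sim$truth
  }
  variants <- do.call(rbind, variants)
  vtruth <- do.call(rbind, vtruth)

  str_sim <- simulate_str_panel(loci = n_loci, n_normals = str_panel_n,
                                tumor_ids = sample_ids,
                                msi_truth = msi_truth,
                                seed = .child_seed(seed, n_total + 1L))

  n_cn6 <- round(cn6_region_fraction * n_regions)
  cn_truth <- lapply(stats::setNames(seq_len(n_total), sample_ids),
                     function(i) {
    cn <- rep(2L, n_regions)
    if (in_b[i] && n_cn6 > 0) cn[seq_len(n_cn6)] <- 6L
    cn
  })
  region_sim <- simulate_region_counts(
    n_regions = n_regions, panel_n = region_panel_n,
    tumor_ids = sample_ids, cn_truth = cn_truth,
    seed = .child_seed(seed, n_total + 2L))

  truth <- list(
    seed = seed,
    samples = lapply(stats::setNames(seq_len(n_total), sample_ids),
                     function(i) {
      list(group = group[i],
           dominant_class = if (in_b[i]) dominant_classes[2]
             else dominant_classes[1],
           spectrum = as.list(spectrum_for(
             if (in_b[i]) dominant_classes[2] else dominant_classes[1])),
           n_variants = n_variants,
           msi_truth = msi_truth[i],
           cn6_regions = if (in_b[i]) n_cn6 else 0L,
           child_seed = .child_seed(seed, i))
    })
  )

  result <- list(variants = variants, variant_truth = vtruth,
                 str = str_sim, regions = region_sim, groups = groups,
                 truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_variant_table(variants, file.path(out_dir, "variants.tsv"))
    utils::write.table(str_sim$panel_table,
                       file.path(out_dir, "str_panel.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(str_sim$tumor_table,
                       file.path(out_dir, "str_tumors.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_region_counts(c(region_sim$tumors, region_sim$panel),
                        file.path(out_dir, "region_counts.tsv"))
    utils::write.table(groups, file.path(out_dir, "groups.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(result)
}
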