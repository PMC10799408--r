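# Tabular input/output for the three data formats the pipeline consumes:
# annotated variant tables (MAF-like TSV, 1-based), STR allele-length
# histograms (TSV), and per-region read counts (BED-like TSV, 0-based
# half-open), plus the groups file and the JSON filter config.

#' Column order of the variant table
#'
#' The documented header of the tab-separated variant table, one row per
#' somatic variant per sample.  `"."` denotes a missing value.
#'
#' @format Character vector of column names.
#' @export
variant_columns <- c(
  "sample_id", "chrom", "pos", "ref_allele", "alt_allele",
  "variant_type", "variant_class", "region_class", "gene",
  "depth", "alt_fwd", "alt_rev", "tumor_vaf", "control_vaf",
  "in_cosmic", "in_snp138", "polyphen_div", "polyphen_var",
  "popmax_af", "is_hotspot", "in_blacklist"
)

.mandatory_variant_columns <- c(
  "sample_id", "chrom", "pos", "ref_allele", "alt_allele",
  "depth", "tumor_vaf"
)

.variant_type_levels <- c("SNP", "INS", "DEL")
.variant_class_levels <- c(
  "missense", "nonsense", "synonymous", "splice",
  "frameshift", "inframe_indel", "other"
)
.region_class_levels <- c("exonic", "intronic", "UTR", "intergenic", "splicing")
.polyphen_levels <- c("B", "P", "D", "missing")

.parse_numeric <- function(x, col) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad)) {
    stop(sprintf("unparsable numeric value '%s' in column '%s', row %d",
                 x[bad[1]], col, bad[1]), call. = FALSE)
  }
  out
}

.parse_logical <- function(x) {
  out <- rep(NA, length(x))
  out[toupper(x) %in% c("TRUE", "T", "1", "YES")] <- TRUE
  out[toupper(x) %in% c("FALSE", "F", "0", "NO")] <- FALSE
  out
}

.check_enum <- function(x, levels, col) {
  bad <- which(!is.na(x) & !(x %in% levels))
  if (length(bad)) {
    stop(sprintf("invalid value '%s' in column '%s', row %d (allowed: %s)",
                 x[bad[1]], col, bad[1], paste(levels, collapse = ", ")),
         call. = FALSE)
  }
  x
}

# Infer SNP/INS/DEL from the allele pair when the column is absent.
.infer_variant_type <- function(ref, alt) {
  type <- rep("SNP", length(ref))
  type[ref == "-" | nchar(alt) > nchar(ref)] <- "INS"
  type[alt == "-" | nchar(ref) > nchar(alt)] <- "DEL"
  type
}

#' Read an annotated somatic variant table
#'
#' Reads a tab-separated variant table (one row per variant per sample,
#' 1-based coordinates) into a data frame with one column per field of
#' [variant_columns].  Mandatory columns are `sample_id`, `chrom`, `pos`,
#' `ref_allele`, `alt_allele`, `depth` and `tumor_vaf`; any other column
#' that is absent is filled with its documented default (`FALSE` for
#' database/blacklist/hotspot flags, `"missing"` for PolyPhen-2 codes,
#' `NA` for `popmax_af` and the strand counts, `0` for `control_vaf`,
#' inferred from the alleles for `variant_type`, `"other"`/`"exonic"` for
#' the functional classes) and a warning is issued.  VAFs are fractions
#' in `[0, 1]`.
#'
#' Rows violating a record invariant (strand support exceeding depth,
#' VAF outside `[0, 1]`, an SNP whose ref and alt are not distinct single
#' bases) raise an error rather than being dropped.
#'
#' @param path Path to a tab-separated file with a header line.
#' @return A data frame with the columns of [variant_columns].
#' @seealso [write_variant_table()]
#' @export
read_variant_table <- function(path) {
  raw <- utils::read.delim(path, colClasses = "character",
                           na.strings = ".", check.names = FALSE)
  missing_mand <- setdiff(.mandatory_variant_columns, names(raw))
  if (length(missing_mand)) {
    stop(sprintf("variant table '%s' lacks mandatory column '%s'",
                 path, missing_mand[1]), call. = FALSE)
  }
  n <- nrow(raw)
  absent <- setdiff(variant_columns, names(raw))
  if (length(absent)) {
    warning(sprintf("variant table '%s': optional column(s) %s absent; using defaults",
                    path, paste(sQuote(absent), collapse = ", ")),
            call. = FALSE)
  }
  get <- function(col, default) if (col %in% names(raw)) raw[[col]] else rep(default, n)

  df <- data.frame(
    sample_id   = raw$sample_id,
    chrom       = raw$chrom,
    pos         = .parse_numeric(raw$pos, "pos"),
    ref_allele  = raw$ref_allele,
    alt_allele  = raw$alt_allele,
    variant_type  = get("variant_type", NA_character_),
    variant_class = get("variant_class", "other"),
    region_class  = get("region_class", "exonic"),
    gene        = get("gene", NA_character_),
    depth       = .parse_numeric(raw$depth, "depth"),
    alt_fwd     = .parse_numeric(get("alt_fwd", NA_character_), "alt_fwd"),
    alt_rev     = .parse_numeric(get("alt_rev", NA_character_), "alt_rev"),
    tumor_vaf   = .parse_numeric(raw$tumor_vaf, "tumor_vaf"),
    control_vaf = .parse_numeric(get("control_vaf", "0"), "control_vaf"),
    in_cosmic   = .parse_logical(get("in_cosmic", "FALSE")),
    in_snp138   = .parse_logical(get("in_snp138", "FALSE")),
    polyphen_div = get("polyphen_div", "missing"),
    polyphen_var = get("polyphen_var", "missing"),
    popmax_af   = .parse_numeric(get("popmax_af", NA_character_), "popmax_af"),
    is_hotspot  = .parse_logical(get("is_hotspot", "FALSE")),
    in_blacklist = .parse_logical(get("in_blacklist", "FALSE")),
    stringsAsFactors = FALSE
  )
  df$variant_class[is.na(df$variant_class)] <- "other"
  df$region_class[is.na(df$region_class)] <- "exonic"
  df$polyphen_div[is.na(df$polyphen_div)] <- "missing"
  df$polyphen_var[is.na(df$polyphen_var)] <- "missing"
  df$variant_type[is.na(df$variant_type)] <-
    .infer_variant_type(df$ref_allele, df$alt_allele)[is.na(df$variant_type)]
  for (flag in c("in_cosmic", "in_snp138", "is_hotspot", "in_blacklist")) {
    df[[flag]][is.na(df[[flag]])] <- FALSE
  }
  df$control_vaf[is.na(df$control_vaf)] <- 0
  validate_variant_table(df)
}

#' Validate a variant data frame against the record invariants
#'
#' Checks column presence, enum values, coordinate and VAF ranges, that
#' per-strand alternate read support does not exceed depth, and that SNP
#' records carry distinct single-base alleles.  Called by
#' [read_variant_table()]; exported so programmatically built tables can
#' be checked too.
#'
#' @param df A data frame with the columns of [variant_columns].
#' @return `df`, invisibly unchanged, if valid.  Errors otherwise.
#' @export
validate_variant_table <- function(df) {
  missing_cols <- setdiff(variant_columns, names(df))
  if (length(missing_cols)) {
    stop(sprintf("variant table lacks column '%s'", missing_cols[1]),
         call. = FALSE)
  }
  .check_enum(df$variant_type, .variant_type_levels, "variant_type")
  .check_enum(df$variant_class, .variant_class_levels, "variant_class")
  .check_enum(df$region_class, .region_class_levels, "region_class")
  .check_enum(df$polyphen_div, .polyphen_levels, "polyphen_div")
  .check_enum(df$polyphen_var, .polyphen_levels, "polyphen_var")
  if (any(df$pos < 1, na.rm = TRUE)) {
    stop("variant positions are 1-based and must be >= 1", call. = FALSE)
  }
  if (any(df$depth < 0, na.rm = TRUE)) {
    stop("depth must be non-negative", call. = FALSE)
  }
  for (col in c("tumor_vaf", "control_vaf", "popmax_af")) {
    if (any(df[[col]] < 0 | df[[col]] > 1, na.rm = TRUE)) {
      stop(sprintf("%s must lie in [0, 1]", col), call. = FALSE)
    }
  }
  support <- df$alt_fwd + df$alt_rev
  bad <- which(!is.na(support) & support > df$depth)
  if (length(bad)) {
    stop(sprintf(
      "row %d violates alt_fwd + alt_rev <= depth (%d + %d > %d)",
      bad[1], df$alt_fwd[bad[1]], df$alt_rev[bad[1]], df$depth[bad[1]]),
      call. = FALSE)
  }
  snp <- which(df$variant_type == "SNP")
  bad <- snp[nchar(df$ref_allele[snp]) != 1 | nchar(df$alt_allele[snp]) != 1 |
               df$ref_allele[snp] == df$alt_allele[snp]]
  if (length(bad)) {
    stop(sprintf("row %d: SNP records need distinct single-base ref and alt",
                 bad[1]), call. = FALSE)
  }
  df
}

#' Write a variant table
#'
#' Inverse of [read_variant_table()]: writes the documented tab-separated
#' format with `"."` for missing values, so that read-write-read is the
#' identity at field level.
#'
#' @param df Variant data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(df, path) {
  out <- df[, variant_columns]
  for (col in names(out)) {
    v <- out[[col]]
    s <- as.character(v)
    s[is.na(v)] <- "."
    out[[col]] <- s
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

#' Construct an STR locus allele-length histogram
#'
#' A histogram of read counts by allele length (in bp) at one short
#' tandem repeat locus of one sample -- the unit of the MSI caller.
#'
#' @param sample_id,locus_id Identifiers.
#' @param counts Named non-negative numeric vector; names are positive
#'   integer allele lengths in bp.
#' @return An object of class `str_histogram`.
#' @export
str_histogram <- function(sample_id, locus_id, counts) {
  lengths <- as.integer(names(counts))
  if (anyNA(lengths) || any(lengths <= 0)) {
    stop("allele lengths must be positive integers", call. = FALSE)
  }
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("read counts must be non-negative", call. = FALSE)
  structure(
    list(sample_id = sample_id, locus_id = locus_id,
         counts = stats::setNames(counts, lengths)),
    class = "str_histogram"
  )
}

#' @export
print.str_histogram <- function(x, ...) {
  cat(sprintf("<str_histogram> sample %s, locus %s, depth %d, %d lengths\n",
              x$sample_id, x$locus_id, sum(x$counts), length(x$counts)))
  invisible(x)
}

#' Read STR allele-length histograms
#'
#' Reads a TSV with columns `sample_id`, `locus_id`, `allele_length`,
#' `read_count` and groups rows into [str_histogram()] objects per sample.
#' Rows sharing `(sample, locus, length)` are summed.  A locus present in
#' a tumor file but absent from a baseline panel is accepted here; the
#' MSI caller marks it not evaluable downstream.
#'
#' @param path Path to the TSV.
#' @return Named list (by `sample_id`) of named lists (by `locus_id`) of
#'   `str_histogram` objects.
#' @export
read_str_histograms <- function(path) {
  raw <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  need <- c("sample_id", "locus_id", "allele_length", "read_count")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop(sprintf("STR histogram file lacks column '%s'", missing_cols[1]),
         call. = FALSE)
  }
  if (nrow(raw) == 0) return(stats::setNames(list(), character()))
  raw$allele_length <- .parse_numeric(raw$allele_length, "allele_length")
  raw$read_count <- .parse_numeric(raw$read_count, "read_count")
  if (any(raw$read_count < 0)) {
    stop("negative read_count in STR histogram file", call. = FALSE)
  }
  if (any(raw$allele_length <= 0)) {
    stop("allele_length must be positive", call. = FALSE)
  }
  agg <- stats::aggregate(read_count ~ sample_id + locus_id + allele_length,
                          data = raw, FUN = sum)
  out <- list()
  for (sid in unique(agg$sample_id)) {
    sub <- agg[agg$sample_id == sid, ]
    hists <- list()
    for (lid in unique(sub$locus_id)) {
      loc <- sub[sub$locus_id == lid, ]
      loc <- loc[order(loc$allele_length), ]
      hists[[lid]] <- str_histogram(
        sid, lid, stats::setNames(loc$read_count, loc$allele_length))
    }
    out[[sid]] <- hists
  }
  out
}

#' Write STR allele-length histograms
#'
#' @param hists Nested list as returned by [read_str_histograms()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_str_histograms <- function(hists, path) {
  rows <- list()
  for (sid in names(hists)) {
    for (lid in names(hists[[sid]])) {
      h <- hists[[sid]][[lid]]
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, locus_id = lid,
        allele_length = as.integer(names(h$counts)),
        read_count = h$counts, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(), locus_id = character(),
               allele_length = integer(), read_count = numeric())
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.region_key <- function(df) paste(df$chrom, df$start, df$end, sep = ":")

#' Read per-region read counts
#'
#' Reads a BED-like TSV (`chrom`, `start`, `end`, `gc_fraction`,
#' `read_count`, `sample_id`; 0-based half-open coordinates) and splits
#' it per sample, sorting regions by `(chrom, start)`.  All samples must
#' share an identical region set -- the tumor/panel comparisons are
#' region-wise -- otherwise an error names the first discrepancy.
#'
#' @param path Path to the TSV.
#' @return Named list (by `sample_id`) of data frames with columns
#'   `chrom`, `start`, `end`, `gc_fraction`, `read_count`.
#' @export
read_region_counts <- function(path) {
  raw <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  need <- c("chrom", "start", "end", "gc_fraction", "read_count", "sample_id")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop(sprintf("region count file lacks column '%s'", missing_cols[1]),
         call. = FALSE)
  }
  raw$start <- .parse_numeric(raw$start, "start")
  raw$end <- .parse_numeric(raw$end, "end")
  raw$gc_fraction <- .parse_numeric(raw$gc_fraction, "gc_fraction")
  raw$read_count <- .parse_numeric(raw$read_count, "read_count")
  if (any(raw$end <= raw$start)) {
    stop("region end must exceed start (0-based half-open)", call. = FALSE)
  }
  if (any(raw$gc_fraction < 0 | raw$gc_fraction > 1)) {
    stop("gc_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (any(raw$read_count < 0)) {
    stop("read_count must be non-negative", call. = FALSE)
  }
  out <- list()
  for (sid in unique(raw$sample_id)) {
    sub <- raw[raw$sample_id == sid,
               c("chrom", "start", "end", "gc_fraction", "read_count")]
    sub <- sub[order(sub$chrom, sub$start), ]
    rownames(sub) <- NULL
    out[[sid]] <- sub
  }
  if (length(out) > 1) {
    ref_key <- .region_key(out[[1]])
    for (sid in names(out)[-1]) {
      key <- .region_key(out[[sid]])
      if (length(key) != length(ref_key) || any(key != ref_key)) {
        mism <- if (length(key) != length(ref_key)) {
          sprintf("sample '%s' has %d regions, sample '%s' has %d",
                  names(out)[1], length(ref_key), sid, length(key))
        } else {
          i <- which(key != ref_key)[1]
          sprintf("region %d differs: '%s' (%s) vs '%s' (%s)",
                  i, ref_key[i], names(out)[1], key[i], sid)
        }
        stop(sprintf("region sets differ across samples: %s", mism),
             call. = FALSE)
      }
    }
  }
  out
}

#' Write per-region read counts
#'
#' @param counts Named list of per-sample region data frames, as returned
#'   by [read_region_counts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_region_counts <- function(counts, path) {
  rows <- lapply(names(counts), function(sid) {
    df <- counts[[sid]]
    data.frame(chrom = df$chrom, start = df$start, end = df$end,
               gc_fraction = df$gc_fraction, read_count = df$read_count,
               sample_id = sid, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-group membership file
#'
#' TSV with columns `sample_id` and `group_label`.  Sample ids must be
#' unique within a group.
#'
#' @param path Path to the TSV.
#' @return Data frame with columns `sample_id`, `group_label`.
#' @export
read_group_file <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  need <- c("sample_id", "group_label")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(sprintf("groups file lacks column '%s'", missing_cols[1]),
         call. = FALSE)
  }
  if (anyDuplicated(df[, need])) {
    stop("duplicate sample within a group", call. = FALSE)
  }
  df[, need]
}
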