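---
title: "Methods: somatic filtering and instability metrics in wescohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic filtering and instability metrics in wescohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wescohort)
```

`wescohort` implements the downstream, post-alignment half of a
tumor/normal whole-exome study: it starts from annotated variant
tables, STR allele-length histograms and per-region read counts, and
produces filtered somatic SNV sets, mutation spectra, TMB, MATH, MSI
calls, copy-number gain/loss calls, the CNI score and cohort-level
group contrasts. Variant calling, annotation and segmentation are
upstream of this package and are consumed as input columns. This
vignette describes the models and decision rules, the parameters that
matter, what the synthetic-data generator does and does not emulate,
and the numerical choices made where the design was genuinely open.

## Somatic SNV filter

The filter is a conjunction of exclusion criteria: a variant is
removed if it triggers at least one, and *all* triggered criteria are
reported per variant (`apply_snv_filters()` never short-circuits), so
a rejects file is a complete audit trail. The criteria, with defaults
in `filter_config()`:

| criterion | rule (default) |
|---|---|
| `low_depth` | depth < 30 |
| `blacklist` | site blacklisted (input flag) |
| `intronic` | intronic region |
| `nonsense` | nonsense variant (switchable) |
| `db_absent` | SNV in neither COSMIC nor snp138 (switchable) |
| `hla_or_none_gene` | gene `HLA*` or `NONE` |
| `polyphen_benign` | PolyPhen-2 HDIV **and** HVAR both `B` |
| `population_af` | ExAC/gnomAD popmax AF > 0.001 |
| `strand_support` | no alternate read on one strand |
| `vaf_support` | < 5 alternate reads or tumor VAF < 5% |

Hotspot variants bypass only the `vaf_support` rule and must instead
meet three hotspot thresholds: ≥ 5 alternate reads, control (plasma)
VAF ≥ 1% and tumor VAF ≥ 5%. Three rules deserve comment because the
underlying convention is genuinely ambiguous, and each is exposed as a
switch rather than hard-coded:

* **Database direction.** `db_absence_excludes = TRUE` removes SNVs
  recorded in *neither* COSMIC nor snp138. Somatic pipelines more
  commonly remove variants present in germline databases only; both
  behaviours are one flag apart.
* **Nonsense exclusion.** Excluding nonsense variants is unusual for
  somatic analyses (they are typically of high interest);
  `exclude_nonsense = FALSE` retains them.
* **PolyPhen benign.** Removal requires both codes to be `B`; a
  missing code never triggers the rule (least-destructive reading).

Indels pass through the criteria that are well defined for them
(depth, blacklist, region, gene, strand, frequency/support); the
PolyPhen, database and population-frequency rules apply to SNVs only.
VAF columns are fractions in `[0, 1]`; config thresholds are expressed
in percent, matching how allele frequencies are quoted clinically, and
are converted internally.

## Mutation spectrum and TiTv

SNVs are collapsed onto the pyrimidine strand (the COSMIC/maftools
convention), giving six substitution classes; C>T and T>C are the
transitions. Under a spectrum uniform over the six classes the
transition fraction is 1/3, so the within-sample imbalance test
(`titv_imbalance_test()`) is an exact two-sided binomial test of the
transition count against 1/3. Between groups,
`compare_group_spectra()` reports pooled-count proportions (what a
stacked-bar figure shows) but tests at sample level: a two-sided
Wilcoxon rank-sum on per-sample class proportions per class, and on
per-sample transition fractions for the TiTv contrast. No published
convention fixes the TiTv test in this setting; the exact
binomial/rank-sum pair was chosen as the assumption-light option and
should be read as one reasonable interpretation. Samples with zero
SNVs carry no proportion information and are dropped from the tests
with a warning; groups with fewer than two usable samples yield
missing p-values rather than degenerate ones.

## TMB

TMB counts non-synonymous coding mutations (exonic, not synonymous;
SNVs and, by default, indels) with depth ≥ 30 and tumor VAF ≥ 5%, and
scales by the targeted exome size:
`TMB = candidates × 1e6 / exon_bases`, in mutations per megabase. The
depth/VAF thresholds for candidacy are not fixed by any universal
standard; the defaults reuse the filter's own thresholds and are
config-exposed. `exon_bases` has no universal value either — it is the
capture design's targeted exonic footprint; the pipeline default of
3.4 × 10^7 bp is a typical whole-exome target and should be replaced
by the actual panel size when known.

## MATH

MATH summarises intra-tumor heterogeneity as the relative spread of
the VAF distribution. Variants enter the statistic when they are SNVs
with tumor VAF ≥ 5%, depth ≥ 50, exonic and non-synonymous; variants
below 10% tumor VAF must additionally show a tumor/control VAF ratio
≥ 10, which guards low-frequency calls against germline or
contamination leakage. The statistic itself is

\[ \mathrm{MATH} = 100 \times 1.4826 \times
   \frac{\mathrm{median}(|v - \mathrm{median}(v)|)}{\mathrm{median}(v)} \]

in the default `canonical` style — the literature convention, with the
Gaussian consistency constant and ×100 scaling, so values are
comparable to published MATH scores (typically tens). The `literal`
style omits both factors and returns the bare MAD/median ratio; the
two differ only by the constant 148.26, so orderings and group
contrasts are identical. MAD always uses the median (not the mean) of
absolute deviations. Fewer than two VAFs, or a zero median, yield a
missing value.

## MSI caller

The caller consumes per-locus histograms of read counts by STR allele
length; read-level STR extraction is upstream. Three QC rules make a
locus evaluable and define its allele count: total depth strictly
greater than 100; at least 2 reads per allele; and alleles below 5% of
the top allele's read count are dropped (the 5% comparison is
inclusive at the boundary, all three comparisons are unit-tested at
their edges). A baseline panel of normals (`build_msi_baseline()`)
stores, per locus, the mean and sample (n−1) SD of the allele counts
over evaluable panel members; loci evaluable in fewer than two
normals are dropped. A tumor locus is **unstable** when its allele
count strictly exceeds `mean + 4 × SD`, **stable** otherwise, and
**not evaluable** when QC fails or the locus is missing from the
baseline. A sample is **MSI-H** with ≥ 2 unstable loci, otherwise
**MSS** with ≥ 4 stable loci, otherwise **QNS**. When both thresholds
are met, instability evidence dominates (MSI-H precedence) — an
interpretation, flagged as such. The unstable/stable thresholds are
absolute counts, as printed, not fractions of the locus panel.

## Copy number: gain/loss calls and the CNI score

Per-region read counts are first corrected for region length and GC
content: counts become rates (reads per base), each rate is divided by
the median rate of its 2%-wide GC bin and rescaled by the global
median rate. Bins with fewer than 5 regions borrow the global median
(no correction). This median-ratio binning is the simplest standard
de-biasing scheme; the bin width is config-exposed.

The tumor's corrected coverage is compared region-wise to the mean of
a normal panel as `log2((t + ε)/(p̄ + ε))`. In `cni_pipeline()` the
zero-guard ε is half a read on the rate scale (`0.5 / region length`);
the standalone `compute_log2_ratios()` defaults to ε = 0 so that exact
relationships stay exact (a region at twice the panel mean has ratio
exactly 1). Panel members' own log2 ratios are computed leave-one-out
(each against the mean of the others), so the panel's null
distribution matches what an unremarkable tumor would produce.

Z-scores standardise the tumor's log2 ratio per region by the panel's
mean and sample SD (SD floored at 10⁻⁶; floored regions are flagged,
since any deviation there produces an arbitrarily large score). The
retention threshold is the 95th percentile of the panel's own
standardised values plus twice their SD — computed per region by
default, or pooled across regions with `global_threshold = TRUE`. With
a panel of 30 the per-region threshold sits near 1.645 + 2 ≈ 3.6.
Quantiles use linear interpolation between order statistics (R type
7), fixed so the P95 is bit-reproducible. The **CNI score** is the sum
of Z-scores strictly above threshold. Summation is one-sided as
printed — deletions never contribute — so a quiet genome scores ≈ 0
and the score is positive by construction; `two_sided = TRUE` retains
and sums `|z|` exceedances for analyses where losses should count.

Gain/loss calls use strict thresholds on the copy-number estimate:
gain when CN > 4, loss when CN < 1.2, boundary values neutral. When no
absolute CN is supplied it is estimated as `2 × 2^log2` (diploid
autosome assumption; sex chromosomes are out of scope). The CNV
burden is the fraction of regions called gain or loss.

## Group comparison and reporting

Continuous metrics are contrasted by two-sided Wilcoxon rank-sum on
per-sample values; MSI status by Fisher's exact test on the 2×2 table
of MSI-H versus not (QNS counts as not MSI-H). With exact group sizes
of 6 vs 6 the rank-sum test's discreteness caps its smallest
achievable p at 2/924 ≈ 0.0022 and its true type-I rate near 4% at
nominal 5% — adequate for cohorts this size, which is why no
parametric model is layered on top. **No multiple-testing correction
is applied**; the report prints raw p-values with an explicit note, and
medians/IQRs are reported alongside so the tests read as descriptive.

## The synthetic cohort generator

`simulate_cohort()` replaces controlled-access patient data with a
seeded, fully specified cohort. Its defaults *are* the study
conditions the rest of the package is tested under: two groups of 6
samples; 300 variants per sample with a 70%-dominant substitution
class per group (C>A for the first group, C>T for the second) and the
remaining classes even; negative binomial depths (mean 200, size 10);
Beta(2, 6) VAFs clamped to [0.08, 0.95]; binomial strand splits; a 2%
per-criterion rate of engineered filter violations; 10 STR loci with a
30-normal panel, per-locus allele counts from a rounded Normal(3,
0.5), one designated MSI-H sample whose allele counts are inflated
beyond `mean + 4·SD`; and 300 regions with a 30-normal panel, Poisson
counts with a smooth GC bias bump, and copy number 6 in 10% of regions
of the second group's samples. The panel sizes of 30 match the normal
control group the CNI method assumes; sample sizes match the 6-vs-6
group design; the remaining distributional choices are minimal
standard models for WES data, set once and documented here.

All randomness flows from one integer seed; per-sample child seeds are
derived by a fixed linear scheme (`seed × 1009 + index × 9973`, modulo
a 31-bit prime), so any single sample can be regenerated in isolation
and a fixed seed yields byte-identical files.

What the generator deliberately does **not** emulate: read-level
artefacts (mapping error, FFPE damage, oxidative artefacts),
trinucleotide-context signatures, subclonal structure beyond a
unimodal VAF distribution, locus-specific STR stutter, segmentation
effects, purity/ploidy shifts, and germline contamination beyond a
constant control VAF. Passing tests on synthetic cohorts therefore
demonstrate that the decision rules and statistics recover the
structure they are defined on — not that the pipeline is robust to
every artefact of real sequencing data.

## Problem sizes used by the test suite

The shipped tests run the end-to-end recovery check on 20 replicate
cohorts at the generator defaults above; the calibration checks use
400 replicates of 12 samples × 100 SNVs for the TiTv null and 200
replicates of null tumors against panels of 15 over 100 regions (and
15-normal STR panels) for the CNI/MSS null. These sizes were chosen as
the smallest at which the binomial tolerances of the calibration
claims are meaningful.

## Known limitations

* The filter's database and nonsense rules encode one reading of an
  ambiguous convention; both are switches, and analyses should state
  which setting they used.
* MATH's low-VAF ratio rule takes the matched control as the
  comparator; with no control (control VAF 0) every low-VAF variant
  passes the ratio rule.
* The CNI score is one-sided by default: homozygous deletions do not
  raise it. Use `two_sided = TRUE` when losses matter.
* Region-level CN estimates ignore tumor purity; in impure tumors the
  strict CN > 4 / CN < 1.2 thresholds under-call.
* Rank-sum and Fisher tests at n = 6 per group have limited power;
  absence of significance is not evidence of absence.

## A worked example

```{r example, eval = FALSE}
dir <- tempfile("cohort")
simulate_cohort(seed = 1, out_dir = dir)
res <- run_cohort_analysis(dir, out_dir = file.path(dir, "report"))
res$metrics
res$spectrum_comparison
res$comparisons$cni
```
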