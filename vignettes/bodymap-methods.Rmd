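---
title: "Methods: multi-tissue expression atlas analysis with bodymapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-tissue expression atlas analysis with bodymapr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bodymapr)
```

# The problem

A multi-tissue RNA-seq "body map" measures one FPKM value per gene per
sample across a panel of tissues from a handful of individuals of both
sexes. The questions such data answer are always the same: which genes are
expressed where; which are restricted to one tissue; which differ between
the sexes; which are stable enough across tissues to serve as normalization
controls; and whether any sample or spike-in control misbehaved. bodymapr
packages those analyses behind a single set of conventions, with a
synthetic-data generator that plants known gene classes so every stage can
be verified without any external download.

# Conventions and thresholds

All stages share one `analysis_config()`:

| parameter | default | units | role |
|---|---|---|---|
| `expressed_threshold` | 0.1 | FPKM | a gene is expressed in a sample at or above this |
| `log_pseudocount` | 1 | FPKM | added before `log2`; keeps transformed values ≥ 0 |
| `fc_pseudocount` | 0.01 | FPKM | added to linear group means before fold ratios |
| `deg_alpha` | 0.05 | FDR | BH level for differential calls |
| `deg_fc` | 2 | ratio | minimum linear fold change for a call |
| `ts_fc_grid` | 2,4,8,16,32 | ratio | tissue-specific fold ladder (default call at 4) |
| `sex_fc` | 2 | ratio | sex-dominated fold cutoff |
| `hk_min_fpkm`, `hk_max_sd_log2`, `hk_max_dev_log2` | 1, 1, 2 | FPKM, log2, log2 | housekeeping tier |
| `ref_min_fpkm`, `ref_max_sd_log2`, `ref_max_dev_log2` | 50, 0.5, 1 | FPKM, log2, log2 | reference tier |

Boundary conventions worth stating explicitly:

* **Expressed at `>=`.** Published descriptions of the 0.1 FPKM rule mix
  strict and non-strict inequalities. bodymapr applies `FPKM >= threshold`
  everywhere; one consistent convention matters more than which one, and the
  threshold is configurable.
* **Housekeeping criteria are strict (`>`, `<`) exactly as conventionally
  printed**; genes sitting exactly on a boundary are excluded.
* **Two pseudocounts, two jobs.** The log transform uses +1 so that zero
  FPKM maps to 0; fold changes use a much smaller +0.01 on linear means so
  that ratios at low expression stay informative instead of being crushed
  toward 1 by the transform pseudocount.
* **Missing cells are illegal.** An absent FPKM is indistinguishable from
  zero, so loaders demand a complete matrix and reject negatives and
  non-numbers with coordinates.

# Stage-by-stage model

## Landscape

`flag_expressed()` computes per-gene expressed/ubiquitous flags;
`biotype_summary()` partitions them over the four-way biotype grouping
(protein-coding, ncRNA, pseudogene, other). Finer annotation labels
(`lincRNA`, `processed_pseudogene`, ...) are accepted only through a shipped
mapping table; an unmapped label is an error rather than a silent "other",
because mis-binned biotypes silently distort the landscape percentages.
`expressed_per_tissue()` reports the mean of per-sample expressed counts
within each tissue (the convention used by published per-tissue bar plots);
a union-over-samples mode exists for comparison.

## Log matrix and clustering QC

`make_log_matrix()` removes genes that are zero in every sample (they carry
no information on the log scale) and transforms the rest to
`log2(FPKM + 1)`. `cluster_samples()` uses `1 − Pearson r` between samples
over all retained genes with average-linkage agglomeration. Published
dendrograms rarely state their metric and linkage; both are configurable
(Spearman/Euclidean; complete/Ward) and the default was chosen because
correlation distance is insensitive to library-size scaling and average
linkage is the common default in expression atlas work. A zero-variance
sample has no defined correlation and is reported by name as an error.

`flag_outliers()` operationalizes the visual "one sample does not cluster
with its tissue mates" check: a sample is flagged when its nearest
neighbour (smallest clustering distance) belongs to a different tissue,
provided its own tissue has at least two samples. This is deterministic and
testable, unlike dendrogram inspection. The pipeline's exclusion mode
(`exclude_outliers`) drops *all* samples of any affected tissue, mirroring
the conservative practice of removing a whole tissue when one of its
samples is unexplainable; the default is flag-only.

## Differential expression

`pairwise_deg()` runs a two-sided **Welch** t-test per gene on the log2
values. The unequal-variance test was chosen because tissue groups have
2–8 samples and no reason to share variances; a pooled-variance option is
retained. BH adjustment is applied **per tissue pair**, matching how
per-pair DEG counts are conventionally reported; calls additionally require
a ≥ 2-fold change of linear-scale tissue means. Degenerate genes (zero
variance in both groups, equal means) get p = 1. The up/down count matrix
is antisymmetric by construction (`up[A,B] == down[B,A]`), which the tests
assert exactly.

## Tissue-specific and sex-dominated calling

A gene's candidate tissue is its highest-mean tissue; the achieved fold is
the minimum ratio against every other tissue (with `fc_pseudocount`), so
calls at a higher threshold are automatically nested within calls at a
lower one. Calls also require the candidate-tissue mean to reach the
expressed threshold — without this, ratios among near-silent genes produce
meaningless "specific" calls. Tissue means pool both sexes (sexual tissues
are necessarily single-sex).

Sex-dominated calling is fold-only by default (> 2-fold between sex means
within one non-sexual tissue): with two replicates per sex a t-test has
essentially no power, and the fold criterion is the one conventionally
used. An optional Welch+BH gate exists behind a flag. Requesting a sexual
tissue is an error, not an empty result.

## Housekeeping and reference genes

`stability_stats()` works on `log2(FPKM)` **without** pseudocount: the
selection criteria guarantee candidates are above 1 FPKM, and a gene with
any zero auto-fails criterion (i) instead of being rescued by a
pseudocount. Spread is computed across **per-tissue means** rather than raw
samples, because the criteria speak of tissues ("no exceptional expression
in any single tissue") and replicate counts differ per tissue; a per-sample
mode exists behind a flag. The SD across tissues is the **population** SD
(divide by n): the tissue panel is the entire frame of reference, not a
sample from a larger population; n−1 is available. The two tiers are
monotone by construction: with the default thresholds the reference set is
provably a subset of the housekeeping set, and relaxing any single
threshold can only grow a tier.

`gene_variability_report()` reproduces the classic diagnostic that
widely-used controls (Gapdh-, Actb-, B2m-like genes) can vary tens of fold
across tissues and fail the criteria, while `homology_overlap()` reports
cross-species agreement of a housekeeping list in both directions
(overlap / mapped-foreign and overlap / own), to one decimal.

## ERCC spike-in QC

Spike rows are identified by the `ERCC-` prefix. Per sample, measured FPKM
(+ `fc_pseudocount`) is regressed in log-log space on the assigned mix's
concentration over detected spikes; undetected spikes are excluded from the
fit but count toward the detection minimum. Flags have a fixed precedence:
`missing_spike_in` (< 8 detected spikes or spike fraction < 0.1% of summed
FPKM), `excess_spike_in` (> 3%, the degradation signature),
`poor_linearity` (R² < 0.8), else `ok`. Published anomaly reports quote
fractions of *mapped reads*; bodymapr operates on fractions of *summed
FPKM*, which is an analogue rather than an equivalence — hence the
re-tuned default band (0.1%–3% around the nominal ~1% spike-in) rather than
read-scale numbers.

# The synthetic world

`generate_dataset()` emulates the canonical body-map design: 17 tissues
(13 non-sexual; ovary and uterus female-only, testis and vesicular gland
male-only), four individuals (two per sex), 68 samples — eight brain and
liver, four kidney, two testis, four of each remaining non-sexual tissue
split evenly between the sexes, two of each single-sex tissue. A uniform or
named per-tissue design can be substituted.

Expression follows `FPKM = 2^(μ_g + τ_{g,t} + σ_{g,sex} + ε)` with
`ε ~ N(0, 0.25)` on the log2 scale — lognormal noise keeps values positive
and matches the heavy-tailed FPKM distributions the analyses assume. The
planted classes, all protein-coding:

* **housekeeping** (200 of 2,000 by default): μ ~ U(2.5, 7) log2 FPKM,
  per-tissue effects SD 0.3;
* **reference** (30): μ ~ U(7, 9) (comfortably above 50 FPKM), per-tissue
  SD 0.15;
* **tissue-specific** (20 per tissue): flat baseline μ ~ U(2, 5) plus
  `log2(16)` in the target tissue, so the planted fold is realized exactly
  in expectation;
* **sex-dominated** (6 per non-sexual tissue): an ordinary background-style
  tissue profile plus `log2(4)` in one sex of one tissue;
* **silent**: exact zeros (not tiny values), so the zero-row-removal rule
  has unambiguous planted truth. Silent fractions are biotype-structured
  (8% of protein-coding, 66% of ncRNA, 47% of pseudogenes, 14% of other),
  reproducing the complementary coding/non-coding landscape pattern;
* **background** (everything else): μ ~ N(2, 2), per-tissue effects
  SD 2.0 — *with the largest effect tied to the runner-up*.

That last clause is the generator's key structural choice. Real
transcriptomes contain genes that genuinely satisfy the housekeeping or
tissue-specific definitions without being "planted"; a simulator with free
iid tissue effects would create such genes at random, and planted-truth
precision would then measure an arbitrary mixture of signal and
coincidence. Tying each background gene's top tissue effect to its second
largest guarantees that no background gene is single-tissue specific, and
an SD of 2.0 (typical genes vary ~16-fold across tissues, consistent with
only a minority of genes passing stability criteria in real atlases) keeps
background genes out of the housekeeping set. The planted classes are
therefore the *only* genes that can meet the definitions, and
precision/recall against truth labels is meaningful. The flip side, stated
plainly: a green recovery test establishes that the implementation computes
the definitions correctly on data where the classes are well separated; it
does not establish performance on real data, where class boundaries are
genuinely ambiguous.

Spike-ins mirror the real ERCC design *shape* — 92 spikes, four Mix1:Mix2
ratio groups (4:1, 1:1, 2:3, 1:2) of 23 each, ≥ 2^18 concentration range —
but the concentrations are generated, not copied from the vendor table
(synthetic by construction and labeled as such). `spike_dataset()` scales
spike rows so they are exactly the configured fraction (default 1%) of each
sample's total signal, with per-sample overrides for missing or degraded
spike-ins. `generate_homology()` builds a synthetic foreign housekeeping
list sharing an exact, configurable fraction of its mapped genes with the
planted set.

Everything is deterministic: the same `(config, seed)` yields bit-identical
matrices (seeds are applied via `withr::with_seed`, leaving the caller's
RNG untouched), and the TSV writers emit 17 significant digits so a
write/read round trip reproduces doubles bit-exactly.

What the generator deliberately does **not** model: read-level sampling or
count (negative-binomial) noise, GC/length bias, batch effects, correlated
gene modules beyond tissue structure, or isoforms. It is an FPKM-level
world for validating FPKM-level logic.

# Numerical choices and degenerate inputs

* BH step-up is implemented directly (sort, `p·m/i`, running minimum from
  the largest p, cap at 1) and is tested against an independent loop oracle
  and `stats::p.adjust`.
* Welch degrees of freedom use Welch–Satterthwaite; groups with zero
  variance contribute zero to the df denominator, and genes with zero
  variance in both groups get p = 1 (equal means) or p = 0 (different
  means).
* Correlation distances are clamped so the diagonal is exactly zero before
  `hclust`.
* R² in the ERCC fit is the squared Pearson correlation computed in closed
  form; a constant response with varying predictor is R² = 1 only in the
  degenerate noiseless-slope sense and otherwise 0/0 cases never arise
  because the fit requires ≥ 2 detected spikes.
* `tissue_specific` breaks exact mean ties by taking the first tissue in
  metadata order as candidate; a tie at the top yields achieved fold ≈ 1
  and therefore no call at any threshold ≥ 2.

# Known limitations

* The pipeline assumes FPKM-normalized input; it performs no
  quantification, no GTF parsing beyond a flat annotation table, and no
  count modeling (no limma/DESeq-style moderation — with 2–8 replicates the
  Welch test is honest but not powerful).
* Headline gene counts from any specific published atlas (e.g. exact
  housekeeping-list sizes) are functions of the underlying accession data
  and are not reproduced by the synthetic world; the test suite instead
  verifies the arithmetic identities those publications print and the
  method's behaviour on planted truth.
* The outlier rule is intentionally simple (nearest-neighbour tissue
  mismatch); subtler batch or degradation effects that leave a sample
  nearest its tissue mates pass undetected and belong to the ERCC QC layer.
* Enrichment analysis of resulting gene lists is out of scope.
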