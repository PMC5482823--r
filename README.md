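# bodymapr

Analysis toolkit for multi-tissue RNA-seq "body map" experiments: gene ×
sample FPKM matrices spanning many tissues, both sexes and a few individuals.
It is aimed at researchers who need the standard battery of atlas-level
analyses — which genes are expressed where, which are tissue-specific, which
are stable enough to normalize against — without re-deriving the thresholds
and conventions each time.

## What it computes

Given an FPKM matrix `X` (genes × samples), gene annotation (biotype,
chromosome) and sample metadata (tissue, sex, individual):

- **Expression landscape** — a gene is *expressed* in a sample when
  `FPKM ≥ 0.1`, *expressed overall* when that holds in ≥ 1 sample, and
  *ubiquitous* when it holds in all samples; summaries per biotype group
  (protein-coding / ncRNA / pseudogene / other) and mean expressed-gene
  counts per tissue.
- **Log matrix & clustering QC** — all-zero rows removed, values transformed
  to `log2(FPKM + 1)`; samples clustered on `1 − Pearson r` with average
  linkage; a sample is flagged as an outlier when its nearest neighbour
  belongs to a different tissue (the operational form of "this sample does
  not sit with its tissue mates in the dendrogram").
- **Differential expression** — per tissue pair, a two-sided Welch t-test on
  log2 values with Benjamini–Hochberg FDR per pair; a gene is called at
  `q < 0.05` and linear fold change ≥ 2 (or ≤ 0.5), yielding the classic
  tissue × tissue up/down count matrix.
- **Tissue-specific genes** — gene g is specific to tissue t when
  `min_{o≠t} (mean_t + c)/(mean_o + c) > f` over a fold grid
  `f ∈ {2,4,8,16,32}` (default call at 4), with `c = 0.01` and the extra
  requirement `mean_t ≥ 0.1`.
- **Sex-dominated genes** — within each non-sexual tissue, > 2-fold higher
  mean expression in one sex.
- **Housekeeping / reference genes** — two-tier stability selection:
  housekeeping requires `FPKM > 1` in every sample, population SD of
  per-tissue mean `log2(FPKM)` < 1, and no tissue deviating ≥ 2 log2 units
  (four-fold) from the cross-tissue mean; the reference tier tightens this to
  `FPKM > 50`, SD < 0.5 and deviation < 1. Includes fold-variability
  diagnostics, chromosome distribution, and cross-species homology overlap.
- **ERCC spike-in QC** — per sample, `log2(measured)` vs
  `log2(concentration)` linearity (R², slope) for the assigned mix, spike
  fraction of total signal, and flags
  `missing_spike_in > excess_spike_in > poor_linearity > ok`.
- **Synthetic data generator** — a 17-tissue, two-sex, 68-sample FPKM world
  with planted housekeeping / reference / tissue-specific / sex-dominated /
  silent gene classes of known effect size, lognormal replicate noise, a
  92-spike ERCC-style reference, and ground-truth labels, so every stage is
  testable without downloads.

## Worked example

```r
library(bodymapr)

sim <- generate_dataset(simulation_config(n_genes = 2000, seed = 42))
validate_partition(sim$annotation)
#> protein_coding          ncRNA     pseudogene          other
#>           1020            400            360            220

fl <- flag_expressed(sim$matrix, 0.1)
sum(fl$expressed); sum(fl$ubiquitous)
#> [1] 1454
#> [1] 1214

biotype_summary(fl, sim$annotation)
#>    biotype_group total expressed not_expressed pct_expressed
#> 1 protein_coding  1020       938            82          92.0
#> 2          ncRNA   400       136           264          34.0
#> 3     pseudogene   360       191           169          53.1
#> 4          other   220       189            31          85.9

st <- stability_stats(sim$matrix, sim$metadata)
length(identify_housekeeping(st)$genes)   # 232 of 230 planted stable genes
#> [1] 232
length(select_reference_genes(st)$genes)  # high-expression reference tier
#> [1] 50

nrow(tissue_specific(sim$matrix, sim$metadata)$calls[["4"]])
#> [1] 340   # exactly the 20 planted per tissue x 17 tissues
```

The biotype table reproduces the expected atlas pattern: most protein-coding
genes are expressed somewhere (92%), most ncRNA genes are not (34%
expressed), pseudogenes sit near even, and the "other" group behaves like
protein-coding genes. The housekeeping call recovers the 230 planted stable
genes with precision 0.991 and recall 1 on this seed.

## Command line

```sh
exec/bodymap simulate --seed 11 --n-genes 2000 --spike --out data/
exec/bodymap landscape --matrix data/sim_fpkm.tsv \
    --annotation data/sim_annotation.tsv --meta data/sim_metadata.tsv --out out/
exec/bodymap run-all --config config.json --out out/
```

`run-all` takes a JSON config (`inputs`, `analysis` threshold overrides,
`stages` toggles, `exclude_outliers`) and writes TSV artifacts plus a
`manifest.json` with input digests and per-stage counts; re-running with the
same config is byte-identical.

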