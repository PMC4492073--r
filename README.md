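# msatlas

Post-assembly analytics for a two-genotype alfalfa RNA-seq expression
atlas.

Alfalfa (*Medicago sativa*) cultivars derive from two hybridizing
subspecies with distinct phenotypes. An expression atlas built from de
novo-assembled transcriptomes of one clone of each subspecies — sampled in
leaf, flower, elongating stem internode (ES), post-elongation stem
internode (PES), root and nitrogen-fixing nodule, with three biological
replicates — supports a family of downstream analyses that this package
implements as tested, reusable functions:

- **Expression**: RPKM normalization
  (`RPKM = 10^9 · C / (N · L)` for count `C`, mapped-library size `N`,
  transcript length `L` bp), a read-retention filter (≥ 10 reads in ≥ 2 of
  3 replicates of some tissue), classification of transcripts as
  expressed / tissue-specific / genotype-specific at an RPKM ≥ 1 presence
  threshold, top-N expression rankings, and a coefficient-of-variation
  screen for housekeeping candidates (RPKM > 2 everywhere, COV < 0.13).
- **Differential expression**: a deterministic nonparametric caller in the
  M–D family. Per transcript, `M = log2` ratio and `D` = absolute
  difference of condition means; the probability of signal
  `q = 1 − P(noise ≥ (|M|, D))` is estimated from the pooled
  within-condition replicate-pair noise cloud; a call requires fold change
  ≥ 2 and `q ≥ 0.95`.
- **SNPs**: per-replicate variant evidence filtered at ≥ 10 alt-supporting
  reads, retained only when concordant across all three replicates of a
  (genotype, tissue), then classified genotype-specific vs shared, with
  tissue-specificity flags.
- **Gene families**: single-linkage clustering of an all-vs-all homology
  hit table (connected components at E = 0), and a ploidy-aware 1-df
  chi-square goodness-of-fit expansion test against an expected 2:1
  (tetraploid : diploid) member ratio with Bonferroni correction; plus
  best-hit annotation with unique-target counting.
- **NCR motifs**: six-frame translation and a greedy scanner for
  cysteine-spacing patterns (`C-X(a..b)-C-...`) characteristic of
  nodule-specific cysteine-rich peptides, joined with nodule-specificity
  calls.
- **Enrichment**: one-sided Fisher (hypergeometric tail) GO
  over-representation with Bonferroni correction, and 150-kb windowed
  feature-density profiles.
- **Synthetic data**: a seeded generator that emulates the full
  2 genotypes × 6 tissues × 3 replicates design with negative-binomial
  counts and planted truth for every pipeline stage.
- **Pipeline**: `run_pipeline()` orchestrates the stages and writes
  TSV/JSON reports shaped like the published summary tables.

## Worked example

```r
library(msatlas)

cfg   <- simulation_config(seed = 1, n_transcripts = 600)
atlas <- simulate_atlas(cfg)
rpkm  <- rpkm_normalize(atlas$counts$counts, atlas$counts$lengths)
cls   <- classify_expression(rpkm, atlas$counts$design)
cls
#> expression_classification: 600 transcripts, 2 genotypes, 6 tissues
#>   presence threshold RPKM >= 1 | absence threshold RPKM < 1
#>   B47: expressed 540, tissue-specific 204
#>   F56: expressed 540, tissue-specific 204

s <- expression_summary(cls)
sum(unlist(s$totals$tissue_specific)) - s$totals$common  # union identity
#> [1] 228
```

204 tissue-specific calls per genotype are the 180 planted common
tissue-specific transcripts plus 24 genotype-specific transcripts
restricted to a single tissue; the union identity
`|specific(B47)| + |specific(F56)| − |common| = |union|` gives 228.

```r
d   <- atlas$counts$design
de  <- call_de(rpkm, d$library[d$genotype == "B47" & d$tissue == "Leaf"],
                     d$library[d$genotype == "F56" & d$tissue == "Leaf"])
sum(de$called)
#> [1] 100
```

100 = 20 planted leaf fold-changes plus 80 genotype-specific transcripts
(which are extreme between-genotype differences by construction).

```r
snp <- classify_snps(consolidate_snps(
  call_replicate_snps(atlas$variants$evidence), 3))
snp$summary
#>                       B47 F56 shared
#> total_snps             10  10     10
#> tissue_specific_snps    5   5     10
#> transcripts_with_snps  10  10     10
```

The published summary tables ship with the package for arithmetic
verification:

```r
tabs <- msgi_tables()
de_total_from_table3(tabs$table3)                          # 26053
tissue_specific_union_from_table6(tabs$table6, "Nodule")   # 9360
```

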