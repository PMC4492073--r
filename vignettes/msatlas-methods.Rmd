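---
title: "Methods and design notes for the msatlas pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for the msatlas pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msatlas)
```

msatlas implements the downstream analytics of a two-genotype alfalfa
expression atlas: two subspecies clones (labeled B47 and F56 throughout),
six tissues (leaf, flower, elongating and post-elongation stem internodes,
root, nodule), three biological replicates, and a de novo transcript
catalog against which reads were counted. This vignette records the models,
the parameters that matter, and the design decisions taken where the
procedure was genuinely open.

## Expression model

Counts are normalized to reads per kilobase per million mapped reads,
`RPKM[t, l] = 1e9 * C[t, l] / (N[l] * L[t])`. Two choices are worth
stating:

* **Library size `N`** defaults to the column sum of the supplied count
  matrix, which makes the normalization self-contained. When counts cover
  only part of the mapped reference (as in the original atlas, which mapped
  to the full assembly), the true mapped-read totals can be passed via
  `lib_sizes`; the round-trip `C = RPKM * N * L / 1e9` then still recovers
  counts exactly (verified to 1e-9 relative tolerance in the tests).
* **Tissue-level expression** is the arithmetic mean of the replicate
  RPKMs. Aggregation across replicates is not dictated by the atlas
  methodology; the mean is the simplest estimator and keeps the presence
  calls linear in the data.

The retention filter (defaults: 10 reads in at least 2 of 3 replicates of
at least one genotype–tissue group) is monotone in the counts; it guards
classification and DE from transcripts supported only by stray reads.

Classification thresholds: a tissue counts as expressed at tissue-mean
RPKM >= `presence` (default 1, the atlas convention). A tissue-specific
call requires exactly one tissue at/above `presence` and every other
tissue below `absence`. The atlas description of the absence side ("RPKM
< 0 in all other tissues") is unsatisfiable as written — RPKM is
non-negative — and is read here as a typo for "< 1", consistent with the
"not detected (RPKM >= 1)" convention used elsewhere for the same data;
`absence` is configurable and must not exceed `presence`.

The top-expressed ranking metric is not pinned down by the atlas. The
default here is the maximum tissue-mean within the genotype (a transcript
enormous in one tissue ranks high even if silent elsewhere, which matches
the prominence of nodule-specific transcripts in such lists); a
genotype-wide mean is available via `metric = "mean"`. Ties break
lexicographically by id so rankings are total and reproducible.

The stability (housekeeping) screen requires RPKM strictly above
`min_rpkm = 2` in *every* in-scope sample, scores candidates by
COV = sd/mean with the sample (n−1) standard deviation, keeps COV < 0.13
and reports the 50 most stable. COV ties also break by id.

## Differential expression

The caller is a deterministic variant of the nonparametric M–D family of
tests. For a contrast of two replicate groups it computes, per transcript,
`M = log2((meanA + pseudo) / (meanB + pseudo))` and
`D = |meanA − meanB|`, and compares the signal `(|M|, D)` against a noise
cloud holding one point per within-condition replicate pair per
transcript, pooled over both conditions. The probability of signal is

```
q = 1 − #{noise points with Mn >= |M| and Dn >= D} / #noise
```

A transcript is called when its pseudo-counted fold change is >= `fc_min`
(default 2) and `q >= q_min` (default 0.95, the conventional analog of an
FDR of 0.05 for this family; no additional multiple-testing layer is
applied). Numerical choices, all configurable: pseudo-count 0.5 before
logs; strict `>=` dominance comparisons, which makes the all-replicates-
equal noise point (0, 0) dominate any zero-signal transcript and drive its
q to 0; transcripts at zero in every library of both groups are reported
with q = 0 and never called. The caller takes normalized RPKM as input —
the atlas does not state whether its tool consumed counts or RPKM, and
RPKM keeps the fold-change scale consistent with the classification
thresholds. Under a null self-comparison of 2,000 transcripts drawn from
one distribution the measured q >= 0.95 rate is well under the 8% bound
asserted in the acceptance tests.

Directional summaries follow the published convention: in the
within-genotype tissue-pair matrix, cell (row, column) counts transcripts
up-regulated in the column tissue relative to the row tissue.

## SNP filtering and classes

"At least 10 reads" per replicate is interpreted as reads supporting the
variant allele, the standard pileup-filter reading; an optional minimum
alt-fraction exists but is off by default. A variant passes for a
(genotype, tissue) only when all three replicates carry it. Classes
partition the retained SNPs by genotype overlap: all occurrences in one
genotype means genotype-specific, otherwise shared. The stricter reading
of shared — co-occurrence in the *same* tissue of both genotypes, the
signature of allelic variation collapsed into one contig — is recorded per
SNP in a `same_tissue` flag and can drive the summary's shared column via
`shared_mode = "same_tissue"`; it is not the default because a variant
seen in, say, B47 leaf and F56 root would then belong to no class and the
partition identity (B47 + F56 + shared = total) would fail. Multi-allelic
positions are independent (transcript, pos, alt) records.

## Gene families and the expansion test

Families are connected components of the graph whose edges are hits at or
below `family_evalue` in an all-vs-all homology table. The default cutoff
is 0 — only hits reported with E = 0 form edges — mirroring a two-stage
procedure in which the search ran at E <= 1e-20 and family assignment used
the stricter cutoff. Components are renumbered by their lexicographically
smallest member, so output is independent of hit order.

The expansion test is a 1-df chi-square goodness of fit of a family's
(focal, reference) member counts against expected proportions
`(r/(r+1), 1/(r+1))`. The default `expected_ratio = 2` encodes the focal
species' tetraploidy against a diploid reference. Families need
`min_total >= 5` members to be tested (keeping expected cells above ~1.7);
Bonferroni correction runs over the families tested; no Yates correction
by default (flag available). Two genuinely open points, and how they were
resolved:

* The expected ratio could alternatively be the genome-wide
  transcript-count ratio of the two catalogs (~2.21:1); both are
  supported, the ploidy ratio is the default because it is the stated
  biological rationale.
* Under this formulation a 16:2 or 19:3 family is *not* significant at
  alpha 0.01 (16:2 gives chi2 = 4.0, raw p = 0.0455 before any
  correction), although families of exactly these sizes are reported as
  significantly expanded in the atlas literature. The published test
  formulation is therefore not recoverable from its description; this
  package keeps the stated goodness-of-fit definition rather than
  reverse-engineering a formulation that reproduces the published calls,
  and the acceptance suite records the resulting recall honestly.

Best-hit annotation keeps hits at E <= 1e-10 and selects per query by
lowest E-value, then highest bit score, then lexicographic subject id.
Restricting a reference set to primary transcripts is the caller's
responsibility.

## NCR motif scanning

Transcripts are translated in all six frames (standard code, trailing
partial codons dropped, ambiguous codons as X, stops retained as `*`).
A motif is an ordered cysteine-spacing pattern `C-X(a1..b1)-C-...`; the
scanner is greedy and deterministic: leftmost feasible start, shortest
admissible gaps with backtracking (equivalently, the lexicographically
first chain, which is exactly what a lazy regular expression finds),
non-overlapping by default, and never spanning a stop codon. The exact
cysteine spacing of the nodule-specific cysteine-rich (NCR) peptide family
is not published with the atlas, so the package default
`C-X(4..20)-C-X(4..30)-C-X(4..20)-C` is an explicit stand-in; all
synthetic-data validation uses planted patterns rather than asserting the
default as biological fact, and absolute NCR counts from the atlas are
accordingly not treated as reproduction targets.

## Enrichment and densities

GO over-representation is the one-sided hypergeometric tail (Fisher's
exact test, alternative "greater"; under-representation by flag), with
Bonferroni correction over the terms annotated to at least one background
transcript — the multiplier's scope is not dictated, and restricting it to
testable terms avoids paying for terms that cannot reject. Annotations are
used as given, without propagation up the GO graph. Feature densities use
0-based half-open windows `[i*w, (i+1)*w)` (default 150 kb); a position at
an exact window boundary belongs to the higher window.

## The synthetic generator

`simulation_config()` fixes the study design the generator emulates: 2
genotypes × 6 tissues × 3 replicates of negative-binomial counts (NB is
the standard overdispersed RNA-seq count model; the atlas asserts none).
Planted classes — housekeeping (50, tight dispersion), common
tissue-specific (30 per tissue), genotype-specific (60 per genotype, 40%
of them single-tissue), per-tissue fold changes (20 per tissue at 4-fold),
background — are assigned in deterministic id blocks so every generator
agrees on the truth without sharing RNG state; each generator seeds its
own stream from the config seed, making outputs byte-identical per seed.
The default catalog holds 2,000 transcripts, which keeps every stage
comfortably within interactive runtimes while leaving hundreds of
background transcripts per planted class; unit tests use 120–600.

In noiseless mode (default) absent cells are exactly 0 and present cells
are floored at 20 reads, so classification truth is recoverable with zero
errors — the point of that mode is to make classification tests exact,
not realistic. What the generator does *not* emulate: sequencing-error
and mapping ambiguity (counts are drawn, not aligned), assembly chimeras
and collapsed paralogs, correlated library-size or batch effects, GC and
length biases, and realistic motif sequence context (planted ORFs are
random DNA around a reverse-translated peptide). Passing planted-truth
tests therefore demonstrates the correctness of the decision rules, not
robustness to those real-data pathologies.

Planted SNPs have alt-read support >= 10 in all three replicates of their
occurrence cells; near-misses violate exactly one rule (one replicate at
9). Planted families are E = 0 cliques: background families at 4:2
(matching the 2:1 expectation), expanded families at 16:2, the sizes the
family-expansion discussion above refers to. The planted motif pattern is
a strict six-cysteine chain with exact gaps, chosen so that a random
600-transcript catalog matches it nowhere outside the plants.

## Published-table arithmetic

The published per-tissue expression summary, SNP summary and DE summary
tables ship in `inst/extdata` and load through `msgi_tables()`. The
report helpers recompute their derived quantities — summing the six
per-tissue DE cells, summing the SNP class totals, and the union identity
`|specific(B47)| + |specific(F56)| − |common| = |union|` overall and for
the nodule row — and the acceptance suite asserts the published values
(26,053; 110,241; 23,725; 9,360) exactly. Published percentages are
whole numbers, so recomputed percentages are asserted to within one
point. Where the surrounding literature prints a conflicting total for
the same quantity (an abstract-level 20,447 against the table sum
26,053), the table-derived figure is the one verified.

## Known limitations

* The DE caller is intentionally a simplified deterministic relative of
  the published nonparametric tool, not a re-implementation; exact call
  counts from the atlas are out of reach (and depend on the raw data
  anyway).
* The noise-dominance count is quadratic in transcripts × replicate
  pairs; at the package's desk scales (≤ a few thousand transcripts) a
  contrast runs in well under a second, but very large catalogs would
  want a sorted dominance counter.
* The expansion test inherits the chi-square approximation; families near
  `min_total` have expected cells below 5, where exactness degrades —
  the binomial test would be the exact alternative.
* GO annotations are tested as given; no ancestor propagation.
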