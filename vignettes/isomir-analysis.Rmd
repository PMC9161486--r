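---
title: "Methods: 5'isomiR quantification, shifted-seed targeting and gene-set activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 5'isomiR quantification, shifted-seed targeting and gene-set activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A mature miRNA is not a single sequence. Imprecise and alternative
Drosha/Dicer processing produces isomiRs, and the subset with a
shifted 5' end is special: shifting the 5' end shifts the seed
(nucleotides 2–8), which redirects the target spectrum. Two molecules
from the same hairpin, one base apart at the 5' end, can regulate
substantially different gene sets. This package implements the
computational arc needed to study that phenomenon end to end:
quantify 5'isomiRs from reads, test their differential expression in
a tumor/normal cohort, predict their shifted-seed targets over
expressed 3'UTRs, score the downstream activity of a transcription
factor program per patient, and connect miRNA expression to pathway
activity by rank-correlation GSEA — plus simulators that generate
every input with known truth.

# Read classification and 5'-end aggregation

A read is assigned to a 5'isomiR when it is an exact substring of the
precursor hairpin, its start lies on the annotated mature arm, and
its 3' end is within `tol3 = 3` nt of the canonical arm end. The
signed start difference is the 5' offset (`miR-183-5p|+2` starts two
bases downstream of canonical); the 3' difference is recorded but
deliberately aggregated away — counts are summed over all 3' ends
sharing a 5' start (`collapse_5p()`), because the seed, and hence
targeting, depends only on the 5' end.

Decisions made where the convention was genuinely open:

* **Templated 3' ends only, by default.** A read whose 3' tail is not
  precursor sequence is unassigned. Non-templated mono/di-additions
  (typically A/U tailing) can be admitted with
  `trim_nontemplated = 1` or `2`, which trims terminal bases and
  retries; the default stays strict so that the assigned set is
  exactly the templated set.
* **Multi-mapping within the hairpin** resolves to the occurrence
  minimizing `|offset5|`, ties to the smaller signed offset —
  deterministic and favoring the canonical annotation.
* Offsets beyond ±5 are assigned but flagged `implausible`;
  processing heterogeneity is local, and such calls usually indicate
  an annotation problem.
* A key must leave at least 8 nt of mature sequence (a seed must
  exist), otherwise the read is unassigned.

RPM normalization is `count / library_size * 1e6`. The expressed
universe is defined by a strictly-greater median filter, default
15 RPM across all samples (`filter_expressed()`); the mean is
available as an alternative summary because cohort figures are
sometimes described per group rather than per cohort, but the median
is the default and what the acceptance checks use.

# Differential expression

Per feature: log2 fold change as the ratio of group means,
`log2((mean(tumor) + c) / (mean(normal) + c))` with pseudocount
`c = 0.5` RPM (configurable; it bounds fold changes of
zero-expression groups), an unpaired two-sided t-test, BH adjustment,
and volcano classification with strict cuts — significant iff
`|log2FC| > 2` **and** adjusted p `< 0.05`. Points exactly on a cut
are not significant.

* **Welch by default.** Equal variances are not assumed; the pooled
  (Student) variant is available. Since the design is explicitly
  unpaired, the fold change defaults to ratio-of-means; a
  mean-of-paired-ratios variant (`paired_ratio = TRUE`) exists for
  matched designs.
* Degenerate variances are defined, not accidental: identical
  constant groups give t = 0, p = 1; separated constant groups give
  the smallest representable p.
* P-values are reported at full double precision.

Protein regulation calls (proteome arm) use raw p `< 0.05` with any
non-zero signed log2 fold change, on non-imputed data; enrichment of
a set among regulated proteins is a one-sided hypergeometric
(Fisher) test with all detected proteins as the universe. The odds
ratio reported is the sample odds ratio `ad/bc` (infinite when
`bc = 0`), not the conditional MLE.

# Downshifted-Gaussian imputation

Label-free proteomics misses values preferentially at low abundance.
Missing cells are imputed per sample from
`Normal(mean_s − 1.8·sd_s, (0.3·sd_s)^2)`, where mean/sd are the
sample's observed statistics — the conventional width-0.3 /
shift-1.8 defaults of this imputation family. Observed cells are
returned bit-identical; draws are deterministic under a seed.
Imputation feeds only the ranked-list/GSEA arm; regulation calls and
Fisher tests run on non-imputed data.

# Shifted-seed target prediction

Prediction is restricted to *expressed* 3'UTR sequence: read
alignments are intersected with annotated UTRs and merged
(book-ended runs merge; separate runs within one UTR stay separate
regions). Two independent predictors must then agree
(`consensus_targets()`):

1. **Seed scanner** (`seed_site_scan()`): every occurrence of the
   four canonical site types for the offset-applied seed — 8mer
   (pairing 2–8 + A opposite position 1), 7mer-m8 (2–8), 7mer-A1
   (2–7 + A), 6mer (2–7) — each seed-core position reported once
   with its highest-priority type. Coordinates are 0-based half-open
   on the mRNA 5'→3'; the base opposite miRNA position 1 is the
   3'-most base of a site. The minimum qualifying type defaults to
   7mer (7mer-A1 or better), TargetScan's conserved-site convention,
   configurable down to 6mer.
2. **Duplex scorer** (`duplex_score()`): a deliberately simple
   miRanda-style local alignment of the miRNA against the reversed
   (antiparallel) UTR window: Watson–Crick +5, G:U wobble +1,
   mismatch −3, gap open −8, extend −2 (a length-L gap costs
   open + (L−1)·extend), pair scores at miRNA positions 2–8 doubled,
   Smith–Waterman floor at zero. A pair qualifies when the best
   score over 30-nt windows centred on any seed site reaches 80 —
   roughly "perfect seed plus appreciable 3' pairing", since a
   perfect 7-pair seed alone contributes 70. Free-energy filtering
   is not emulated; the score threshold plays that role. All
   parameters live in `duplex_params()`.

The *logic* faithfully reproduced here is the consensus idea —
intersecting transcript/miRNA pairs from two independent predictors
over expressed UTRs to trade sensitivity for precision. The scorer
itself is this package's own simplified stand-in, with every
parameter exposed, not a re-implementation of miRanda 3.3a or
TargetScan 7.1; absolute consensus-set sizes from those tools are
therefore not comparable, only the structure of the analysis.

A biological subtlety the workflow illustrates: neighboring
5'isomiRs share 6 of 7 seed bases, so their site sets nest
asymmetrically. For miR-183-5p specifically, position 3 of the
canonical sequence is U, whose complement A doubles as the 7mer-A1
anchor — every 7mer/8mer site of |+1 therefore embeds a ≥7mer site
of |+2, while |+2 can hold truly private sites. Venn partitions of
per-isomiR target sets are computed by `target_overlap()`.

# Activity score and GSEA

The single-sample activity score of a gene set is the per-patient
median of gene-wise z-scores (`zscale_genes()` then
`activity_score()`; sample sd, n−1). Z-scaling makes the score
exactly invariant under per-gene affine transforms of the raw
matrix, so platform scale and gene-specific offsets cannot move it;
zero-variance genes are emitted as all-missing with a warning and
skipped in the median.

The GSEA engine is self-contained:

* **Statistic**: the weighted KS running sum — hits add
  `|score|^p / Σ_hits |score|^p`, misses subtract `1/(N − N_h)`;
  ES is the signed extremum. `p = 1` (the standard weighted form) is
  the default; `p = 0` recovers the unweighted KS statistic. When
  the positive and negative extrema tie in magnitude (within 1e-9,
  i.e. numerically indistinguishable), the positive one is reported;
  a fixed convention keeps results platform-stable.
* **Null distributions**: preranked mode draws random gene sets of
  matching size; phenotype mode permutes the phenotype vector and
  recomputes the full Spearman correlation ranking per permutation,
  which preserves gene–gene correlation. Because Spearman is itself
  rank-based, permuting the phenotype before or after converting
  expression to ranks yields identical correlations, so no separate
  switch is needed for that ordering.
* **Normalization**: sign-stratified, NES = ES / mean(|null ES| of
  the same sign); permutation p uses the +1 correction
  (`p ≥ 1/(n_perm+1)`, never exactly zero) against same-sign nulls;
  FDR q follows the pooled-NES estimate (fraction of pooled null NES
  at least as extreme over fraction of observed NES at least as
  extreme, capped at 1). A set with no same-sign permutation ES gets
  missing p/q with a warning.
* Sets are intersected with the measured universe first; sets
  reduced below 5 members (configurable) are skipped with a warning.
  Rankings break ties lexicographically by feature id, so every
  ordering is deterministic. Default 1000 permutations.

Single-set GSEA runs make the pooled FDR denominator degenerate
(every observed NES is "as extreme as itself"), so q collapses
toward p; meaningful q values need a collection of sets, which is
how the validation runs are built (one planted set among random
ones).

# What the simulators emulate — and what they do not

* `simulate_reads()`: error-free reads over one hairpin with i.i.d.
  (5' offset, 3' offset) draws. No sequencing error, no adapters, no
  quality model — classification is exact-substring, so error reads
  would only inflate the unassigned count.
* `simulate_cohort()`: negative-binomial counts (dispersion 0.2,
  `1/size` parameterization; 0 gives Poisson) around log-normal
  baselines (meanlog 4, sdlog 1.5 on the RPM scale — median ≈ 55 RPM
  with a long tail, the shape of small-RNA libraries), library size
  1e6, default 20 vs 20 samples. Planted features scale the tumor
  mean by `2^log2fc`. No batch effects, no correlation between
  features.
* `simulate_activity_cohort()`: latent activity A ~ N(0,1) drives
  the designated set (`loading·A + noise`, loading 1, noise sd 1,
  100 set genes among 1000, 300 patients); the miRNA couples to A
  through a Gaussian copula with the Pearson parameter
  `2·sin(π·ρ_S/6)` so the *population* Spearman equals the target
  exactly. Real cohorts have correlated backgrounds and non-Gaussian
  tails; passing recovery checks here shows estimator correctness,
  not robustness to those.
* `simulate_proteome()`: Gaussian log2 intensities (baseline
  N(25, 2), replicate sd 0.25, 4 vs 4), one set shifted down in the
  treatment group, and logistic left-censoring centred 3 baseline sd
  below the mean (≈ 1% missing cells at defaults). Real LFQ data add
  peptide-level effects and heavier missingness.
* `simulate_utrs()`: random-background UTRs with exact site strings
  planted at recorded positions; backgrounds are rejection-sampled
  (bounded at 1e4 attempts) to carry no accidental site of the
  queried isomiRs, and plants are re-scanned so junction artifacts
  are rejected — the truth table is exhaustive by construction.

Every generator is deterministic under its seed and emits truth
alongside data.

# Validation problem sizes

The package validates itself at these scales: 1e4 simulated reads
for offset recovery; 200 null cohorts (500 features, 20 vs 20) for
DE calibration and 10 cohorts with 20 planted log2FC = 3 features
for power; exhaustive BH/Fisher oracle comparisons on universes up
to 50; exhaustive ES oracle comparison over all subsets of ranked
lists up to length 12; planted-depletion GSEA at 1000 permutations
with 50 null replicates; 100 activity-cohort replicates at n = 300;
and 1000 random UTRs against an exhaustive seed-scan enumeration.

# Known limitations

* The duplex scorer is a transparent surrogate; it ranks
  complementarity sensibly but its absolute scores have no
  free-energy interpretation.
* Conservation, context features (local AU content, position within
  the UTR), CDS/5'UTR sites and non-canonical pairing are out of
  scope.
* The DE layer is a t-test on (normalized) expression, not a count
  model; for small cohorts or very low counts a negative-binomial
  framework would be preferable.
* The packaged precursor reference is a constructed hairpin around
  the canonical mature miR-183-5p sequence (labelled synthetic); for
  real libraries supply the genuine precursor FASTA and arm
  coordinates.
* Phenotype-permutation GSEA recomputes genome-wide Spearman
  correlations per permutation; at very large gene counts the
  preranked mode is the pragmatic default.
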