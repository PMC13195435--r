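---
title: "Methods: diversity, inbreeding, load and genomic-offset scans in fragmented cohorts"
author: "skypurge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity, inbreeding, load and genomic-offset scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`skypurge` is a population-genomic analysis pipeline for small, fragmented
("sky-island") cohorts genotyped by whole-genome resequencing: seven
montane populations in three lineages, roughly twenty diploids each, is
the design the defaults assume. The pipeline runs from a multi-sample VCF
to (i) windowed diversity and differentiation scans, (ii) run-of-homozygosity
(ROH) based inbreeding, (iii) polarized genetic-load quantification,
(iv) joint-outlier selective-sweep detection, (v) genotype–environment
association (GEA), and (vi) gradient-forest genomic-offset projection
under future climate grids. A seeded synthetic-cohort generator with full
truth tables drives all statistical testing.

# Site filtering and LD pruning

Filtering mirrors a standard VCFtools refinement of a raw GATK call set:
genotypes with GQ < 10 are masked first, then sites are dropped in a
fixed rule order — multiallelic, indel, QUAL < 30, mean depth over called
genotypes < 3, call rate < 0.8, minor-allele frequency < 0.05 — with each
site attributed to the first rule it fails, so the per-rule removal
counts in the filter log always sum to the total. MAF is computed on
called alleles only; a site left monomorphic by GQ masking therefore
falls to the MAF rule. The GQ-mask → call-rate → MAF order is a
documented choice; the three rules do not commute on masked genotypes.

LD pruning uses the composite (dosage) r², not haplotype LD, because
genotypes are treated as unphased throughout. Within sliding windows of
100 SNPs the later-positioned SNP of any pair with r² > 0.5 is removed —
a deterministic keep-earlier rule. The implementation processes windows
over the *retained* SNP sequence, which for step sizes larger than one is
slightly stronger than the literal windowing (it never leaves a linked
pair closer than 100 retained SNPs apart); the post-condition is verified
exhaustively in the tests.

# Windowed statistics

All window statistics share one frame: 100-kb windows advanced by 10 kb,
anchored at position 1 of each chromosome, with terminal windows keeping
their true span as the per-bp denominator.

* **π** — per site, the unbiased estimator `n/(n−1) · 2p(1−p)` with `n`
  the called allele count; summed over variant sites and divided by the
  window span. This equals pairwise-mismatch counting over called
  alleles, which is how the test oracle computes it.
* **Tajima's D** — the classical constants evaluated at the harmonic mean
  of per-site called allele counts across the window's segregating
  sites; the harmonic-number sums are linearly interpolated for
  fractional `n` (a choice forced by missing data; with complete data it
  reduces to the textbook integer formula). Windows with no segregating
  site are reported as undefined, never zero.
* **F_ST** — the Weir–Cockerham (1984) θ with per-site variance
  components a, b, c; a window's value is Σa / Σ(a+b+c). Negative values
  are retained. Genome-wide values are reported both as the
  ratio-of-sums over all sites (primary, less biased for small windows)
  and as the mean of per-window values (secondary).
* **Private alleles** count either allele (REF or ALT) observed in
  exactly one population.
* **LD decay** averages pair r² within 300 kb in distance bins; the
  "decay distance" is the first bin midpoint where a 3-bin running mean
  falls below the query level (0.2 by default).
* **Mantel tests** (999 permutations, explicit seed) use the one-sided
  permutation p `(1 + #{r* ≥ r}) / (n_perm + 1)`. Isolation-by-distance
  uses great-circle distance vs linearized F_ST `Fst/(1−Fst)`;
  isolation-by-environment uses Euclidean distance on z-scored
  variables. The metrics are package choices; only the test design is
  fixed.

# Inbreeding

Expected homozygosity for F_IS uses sample-wide allele frequencies
without small-sample correction — a deliberate simplification whose
difference from the VCFtools `--het` estimator is O(1/2n) per site.

ROH are maximal runs of consecutive homozygous calls, truncated at every
heterozygous call; a run is kept when it spans more than 1 kb (strict)
and contains at least 50 homozygous SNPs. Missing calls neither break a
run nor count toward the SNP minimum (PLINK-like tolerance). Segment
coordinates are the first and last homozygous SNP positions. The 1-kb /
50-SNP combination implies very dense SNPs at the minimum length; both
knobs are exposed, and the synthetic genomes are dense enough (one SNP
per ~0.5–1 kb) for the defaults to bite. Segments of 1–100 kb are
"short" (boundary inclusive), longer ones "long"; F_ROH divides total
ROH length by the genome length (default 786,920,000 bp, the assembly
size of the shrub genome the design emulates). ROH run on the full
filtered SNP set, not the LD-pruned one.

# Genetic load

Polarization to derived alleles uses the majority-homozygote rule: the
allele for which more than 50% of called individuals are homozygous is
ancestral; sites without such a class are excluded as ties, and — as a
reference-bias guard, on by default — sites whose inferred ancestral
allele differs from the reference are excluded too. When the ALT allele
is ancestral (guard off), dosages are recoded `d′ = 2 − d` and REF/ALT
swapped, making the operation an involution. One consequence worth
noting: under this strict rule the derived-allele frequency at a
polarized site is always below 0.5; the rule still differs from a
frequency rule, because the decision tracks zygosity (an all-het site is
a tie at frequency 0.5 while a hom-rich site at frequency 0.4
polarizes).

Effect classes come from translating reference vs alternate codons in
annotated CDS (reverse-complemented on minus strands, phase-aware):
synonymous (SYN), missense (MIS), and loss-of-function (LoF = stop gain,
stop loss, start loss, or a hit in a canonical 2-bp splice
dinucleotide). Missense calls are split by an externally supplied
deleteriousness score in [0, 1]: DEL below 0.5, TOL at or above, with
missing or low-confidence scores excluded from tallies. The package does
not recompute such scores (that requires a protein database); the
synthetic generator fabricates them with known truth.

Load ratios are zygosity-matched by default — hom DEL / hom SYN and het
DEL / het SYN — because heterozygous and homozygous tracts answer
different questions about masked vs expressed load; a total-SYN
denominator is available behind a flag. π0/π4 averages per-site π over
*all* annotated 0-fold and 4-fold degenerate positions (monomorphic
positions contribute zero but stay in the denominator), so the ratio is
comparable across populations.

# Selective sweeps

For a focal/contrast population pair the scan intersects the upper 5%
empirical tails of windowed F_ST and ln(π_contrast/π_focal); the ratio is
oriented so its upper tail means diversity loss in the focal population.
Thresholds are order statistics with inclusive ties (the k-th largest
value with k = ⌈(1−q)·n⌉; an epsilon guards the ceiling against binary
floating-point excess). Windows with undefined F_ST or an undefined
ratio (either π zero) are excluded before quantile estimation.
Overlapping or bookended candidate windows merge into regions; genes
overlap regions at 1 bp.

# Genotype–environment association

GEA runs on the near-complete subset (call rate ≥ 0.99 after GQ
masking). Environmental variables are selected greedily by descending
importance under a |r| < 0.8 Pearson filter.

The latent-factor scan is a deterministic ridge/least-squares variant of
the LFMM: for each variable, the variable's projection is removed from
the centered genotype matrix, the top-K left singular vectors of the
residual become latent factors (estimated via the n×n cross-product,
since samples ≪ SNPs), and each SNP is regressed on variable plus
factors. This replaces the Bayesian MCMC formulation with a reproducible
closed-form one — the trade-off is a point estimate of the factors
instead of posterior averaging. K defaults to 7, the number of ancestral
populations in the design. t-statistics are converted to p-values and
recalibrated by the genomic inflation factor λ = median(t²)/qchisq(0.5, 1)
(the familiar 0.456); significance is a fixed p ≤ 1e−5 for at least one
variable, with no additional FDR step. With population-level predictors
and only seven populations, drift aligned with the tested variable is
not absorbable by factors orthogonal to it, so raw λ well above 1 is
expected and the calibration is essential. The calibration is exact when
the confounding is Gaussian and rank-K — which is what the matched-K
null in the tests simulates (rank-7 Gaussian logit shifts in population
space); under Balding–Nichols beta drift the extreme tail is slightly
heavier than χ², visibly so for rare alleles, which is one reason the
GEA stage runs after MAF filtering.

RDA regresses the mean-imputed, centered genotype matrix on the
standardized variables and takes the SVD of the fitted values; SNP
loadings are the right singular vectors, axis variance fractions are
d²/total variance (non-increasing by construction). Outliers deviate
from an axis's mean loading by more than 3.5 SD on at least one of the
first three axes (three retained variables in the emulated design).
Individual-level genotypes are used; population allele frequencies are
available behind a flag. Core SNPs are the intersection of
LFMM-significant and RDA-outlier sets, with per-method provenance.

# Gradient forest and genomic offset

No gradient-forest implementation is available as a dependency, so the
package includes its own: per SNP, an ensemble of CART regression trees
(bootstrap resampling, random predictor subsets, exhaustive split
search) predicts population allele frequency from the environmental
predictors; every split's SSE reduction is attributed to its predictor
at the split value; per-SNP importances are averaged over trees,
weighted by out-of-bag R² truncated at zero, and binned (200 bins per
predictor) into nondecreasing cumulative-importance step functions. The
units are populations, so trees are tiny; defaults are 500 trees per
SNP, leaf size 2, depth 3, mtry ⌈p/3⌉, all under one seed with
bit-for-bit reproducibility. A `bootstrap = FALSE` mode fits every tree
on the full data, which makes single-tree behaviour deterministic — the
configuration used by the step-recovery check.

Offset transforms current and future climate vectors through the
cumulative-importance functions (values below the first step map to 0,
above the last to the function maximum) and takes the per-cell Euclidean
distance. Grids are plain CSV rasters sharing a cell registry; offsets
are computed per climate model and scenario independently and then
averaged cellwise across models. All 19 variables enter the offset by
default, with the GEA-selected subset available as an option. By
default the forest is fit on the GEA core SNPs.

# The synthetic cohort generator

The generator is the package's study-design stand-in, not a fixture: it
produces a genotype matrix, environment table, climate grids, toy genome
annotation and complete truth tables from one seed.

* **Structure** — ancestral derived-allele frequencies ~ Uniform(0.05,
  0.95); lineage then population frequencies follow nested
  Balding–Nichols Beta draws (F_lineage = F_pop = 0.08), giving
  genome-wide pairwise F_ST near 0.15 — the level reported for the
  emulated system. Genotypes are Hardy–Weinberg within populations.
* **Autozygosity** — per individual, non-overlapping tracts with
  exponential lengths (mean 500 kb) are placed until the target genome
  fraction is covered (defaults 0.08–0.24, peaking in JK); within
  tracts, heterozygous calls are resolved by copying one allele at
  random. Literal tracts give ROH detection positional ground truth.
* **Load classes** — SNPs are assigned SYN/TOL/DEL/LoF (20/4/10/3% of
  sites; the rest noncoding) with class-specific frequency suppression
  (×1/0.9/0.5/0.3) as a purifying-selection surrogate. The coding
  fraction is deliberately dense for a toy genome: load ratios are
  ratios of modest counts, and their between-population drift noise
  scales as the inverse square root of the class site count.
* **Purging** — in designated populations (JK, δ = 0.3) a fraction δ of
  realized homozygous-DEL genotypes is converted to heterozygous,
  directly imposing the hom-DEL deficit that genetic purging produces,
  after tract placement so the statistic sees it.
* **Adaptive loci** — 50 noncoding SNPs get population frequencies
  logit-shifted by slope × z(bio18), a latitudinal precipitation-like
  gradient. Adaptive loci are re-anchored at intermediate ancestral
  frequencies (0.35–0.65) so clines have room to express; with the
  default slope 5 the realized standardized effects on dosage
  concentrate around 0.8–0.9 — strong, detectable clines.
* **Annotation** — every coding SNP receives its own 30-codon
  single-exon gene (alternating strands) built from template codons
  (GGA third position for 4-fold SYN, GCA second position for 0-fold
  missense, TGG→TAG for stop gain), written into the genome sequence so
  sequence-based classification recovers the truth classes exactly.
  Deleteriousness scores are drawn below 0.5 for DEL, at or above for
  TOL, with ~8% set missing.
* **Climate** — 19 bioclim-style variables are smooth deterministic
  functions of lon/lat (bio18 is the pure latitudinal gradient; bio19 is
  nearly collinear with it to exercise the correlation filter). Future
  grids displace each variable along a fixed direction scaled by
  scenario (0.5–2 spatial SD for ssp126–ssp585) with small per-model
  perturbations, so offset must rank scenarios correctly.
* **Filter fodder** — a few deliberately failing records (indels,
  multiallelics, low QUAL, high missingness) plus 0.5% random
  missingness and 1% low-GQ genotypes keep the filtering stage honest.

What the generator does **not** emulate: linkage disequilibrium between
neighbouring SNPs (sites are conditionally independent given population
frequencies — LD-decay and pruning behaviour on real data is richer),
demographic history (no bottlenecks, migration or coalescent
genealogies), recombination-rate or mutation-rate heterogeneity,
sequencing error structure beyond GQ masking, and realized fitness
effects of load. Passing tests therefore certify the estimators and
their error control under the assumed statistical structure, not the
biology of any particular data set.

# Problem sizes and numerical choices

The test-suite and acceptance computations use desk-scale cohorts chosen
to keep each statistical check sharp: 20,000 SNPs on two 6-Mb
chromosomes for the purging signature (100 cohorts), 4,000 SNPs on two
2-Mb chromosomes for GEA power (100 cohorts) and the end-to-end run,
25,000 × 5 tests for the matched-K null, 10,000 SNPs for RDA null
calibration, and 20 × 200 panels against brute-force oracles. Seeds are
fixed in tests and exposed as parameters everywhere else. Undefined
statistics are `NA`, never 0; tie rules (quantile inclusion, ROH
boundary at exactly 100 kb = short, score exactly 0.5 = TOL) follow the
printed conventions of the emulated protocol.

# Known limitations

* The ridge LFMM gives point-estimate factors; its p-values differ from
  the Bayesian MCMC variant, especially at small K.
* With seven populations, population-level predictors have seven
  effective observations; GIF calibration handles scale but cannot
  manufacture degrees of freedom — interpret per-variable λ.
* The gradient-forest importance attribution spreads across correlated
  predictors (as any tree ensemble does); offsets are comparable across
  cells and scenarios, not across refits with different SNP sets.
* F_ROH slightly underestimates tract fractions because segment
  coordinates stop at observed SNPs and sub-threshold tracts escape
  detection; at the default SNP densities the bias is well under 0.05.
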