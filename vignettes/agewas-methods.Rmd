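---
title: "Methods: age effects on DNA methylation with agewas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: age effects on DNA methylation with agewas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agewas)
```

# The problem

Chronological age reshapes the blood DNA methylome. On Illumina
450K-style arrays each CpG site is summarised by a beta value — the
fraction of methylated signal, in [0, 1] — and an epigenome-wide
association study (EWAS) of age asks, site by site, whether that
fraction drifts upward (hypermethylation) or downward
(hypomethylation) across the lifespan, and where in the genome each
kind of drift concentrates. `agewas` implements that analysis as a
tested pipeline: per-site linear models, modality profiling of the
beta distributions, PCA-based variance attribution, genomic-context
enrichment, CpG-island (CGI) ranking, and integration with age trends
in gene expression — together with a synthetic-cohort generator that
provides ground truth for every step.

# Per-site association model

For each site, beta is regressed by ordinary least squares on
chronological age, sex (0 = female, 1 = male) and BMI, using complete
cases per site. Significance of the age effect is the two-sided
t-test of the age coefficient in this adjusted model. Alongside it we
report the *marginal* Pearson correlation of beta with age: the
adjusted model decides significance, the marginal correlation carries
the sign and is the ordering variable for all binned-context figures.
The per-site correlation could also have been defined as a partial
correlation given sex and BMI; we chose the marginal form because it
matches the selection language used for island ranking ("correlation
coefficient > 0") and, in cohorts where age is essentially
uncorrelated with sex and BMI, the two are nearly identical. This
choice is flagged here because it is a genuine interpretation
decision.

Sites are classified by a Bonferroni rule with denominator equal to
the number of probes actually tested after QC:

* **hyper** — age p below `alpha / n_tests` and positive correlation;
* **hypo** — below threshold and negative correlation;
* **uncorrelated** — nominal p > 0.05 (or no valid p: constant beta
  rows and rank-deficient per-site designs are flagged with a missing
  p and fall here);
* **suggestive** — nominally but not Bonferroni significant.

The four classes partition the tested sites. A sex-by-age interaction
scan refits every site with an additional `sex:age` term under the
same Bonferroni rule. Two-sided tests are used throughout, and no
batch or kinship terms are included: the model is deliberately plain
OLS.

Cohort-level drift is summarised by correlating each sample's mean,
Q1, median and Q3 of autosomal beta with age. A methylome drifting
toward hemimethylation shows a rising Q1 (unmethylated sites gaining)
and a falling median/Q3 (methylated sites losing); the per-sample
median is also compared between sexes by a Wilcoxon rank-sum test.

# Modality of beta distributions

Some sites are not unimodal across a cohort: an X-linked site is
bimodal across sexes, and a SNP inside the CpG dinucleotide produces
two or three genotype-driven modes. Mode counting here is fixed-
bandwidth Gaussian kernel density estimation: bandwidth 0.05 on the
beta scale (the analysis-defining smoothing factor), evaluated on a
fixed 512-point grid over [0, 1], with no assumption on the number of
modes. Modes are strict local maxima after merging flat plateaus;
peaks below 0.5% of the global maximum are discarded as numerical
ripple (the floor is exposed as a parameter). No boundary reflection
is applied; betas are clipped to [0, 1] first. Constant inputs are
one mode at the constant. This deterministic estimator replaces a
hierarchical mode-association clustering procedure with the same
observable (the mode count): it is order-invariant, duplication-
invariant, and its mode count is non-increasing in the bandwidth —
all asserted as properties in the test suite.

SNP proximity uses the convention that the interrogated CpG occupies
positions `pos` and `pos + 1`; the distance to a SNP is the minimum
over both, so a SNP anywhere in the dinucleotide is at distance 0 and
one at `pos + 2` is at distance 1. The default search window is 50 bp
(the probe footprint); the "more than 10 bp away" class in the
modality-by-SNP table is bounded by this window, since no outer bound
is inherent in the definition. Modality and distance class are
cross-tabulated and tested by chi-square without continuity
correction.

# Variance attributed to age

PCA treats samples as observations and sites as variables, after
per-site mean imputation of the sparse post-QC missingness and
site-wise mean centering. No variable scaling is applied: betas share
a natural [0, 1] scale, and unit-variance scaling would inflate
low-variance probes. Variance proportions come from squared singular
values. For each leading component (default 10) the Spearman rank
correlation rho of its scores with age is computed, and the variance
attributed to age is `rho^2 * prop_var`, accumulated over components.
This estimator deliberately mixes a rank-based association with a
linear variance decomposition; it is reported exactly in that form
rather than replaced by a purely linear R^2, because the quantity is
defined that way. It is invariant to PC sign flips and bounded by the
variance proportion per component.

The recovery test for this module uses a purpose-built construction:
site loadings times centered age plus isotropic Gaussian noise whose
SD is solved so that a chosen fraction `f` of the total site-centered
variance is age-driven in expectation (`generate_age_variance_dataset`).
The matrix is mapped affinely into [0.01, 0.99] — which changes
neither variance proportions nor rank correlations — so it is a valid
beta matrix. At 400 samples x 5,000 sites the cumulative attribution
over 10 components recovers `f` well within ±0.05.

# Genomic context and binned enrichment

Island geometry follows the standard annotation: shores are 1–2,000
bp from an island edge, shelves 2,001–4,000 bp, N upstream (lower
coordinates) and S downstream; anything farther is open sea; the
nearest island wins and an exact distance tie resolves to the
upstream island. Manifest positions are 1-based (array convention),
BED chromatin segments 0-based half-open; all conversion happens at
read time. The CGI predicate is conjunctive Gardiner–Garden — length
> 200 bp AND GC >= 50% AND observed/expected CpG > 0.6 — with a
disjunctive mode behind a flag for sensitivity analysis, since the
three conditions are occasionally quoted with "or".

Enrichment curves order sites by the marginal correlation and split
them into 100 contiguous equal-count bins (sizes differ by at most 1;
earlier bins absorb the remainder — a fixed, documented choice).
Per-bin category fractions are computed over any closed partition:
island relation, gene feature group, or chromatin state 1–15 plus an
explicit "none" for uncovered sites. Per-bin island statistics (mean
length, CpG percentage, observed/expected ratio) are averaged over
island-linked sites, with site-to-island linkage preferring the
manifest's island id and falling back to coordinates.

# Island ranking and expression integration

Autosomal islands with strictly more than three measured sites are
scored by the fraction of member sites classified hyper (and,
separately, hypo); the top-k (default 500) per direction are ranked
descending by fraction, ties broken by significant-site count then
island id, so the ranking is total and reproducible. For gene lists,
one gene per island is drawn uniformly at random under a seed — the
standard guard against clusters of co-located, functionally similar
genes — and the list is de-duplicated keeping first occurrences.

Expression probes are fitted by OLS on age and sex; a probe decreases
(increases) with age if its age p-value is below 0.05 with a negative
(positive) slope, else it is flat. Genes take the direction of their
most significant probe (an aggregation the source analysis leaves
open; most-significant-probe is the common array-era convention).
Direction enrichment in the hyper/hypo gene lists is a 2x2 chi-square
without Yates correction; gene-set overlaps use the one-tailed Fisher
exact test.

# The synthetic-data generator

The generator defines the study conditions for every recovery test.
A cohort draws ages from a mixture with extra mass near 17, 45 and 67
years over a uniform background, truncated to 14–94 — emulating a
multigeneration population sample — with a configurable sex ratio and
truncated-normal BMI. Sites belong to seven classes with default
proportions calibrated to the headline prevalence structure the
analysis expects: 29% age-affected, split 60.5% hypomethylating /
39.5% hypermethylating; the rest is 28% stable-unmethylated, 28%
stable-methylated, 10% conserved promoter, 3% SNP-modal and 2%
X-linked.

Effects live on the logit scale, so betas stay in (0, 1) without
truncation artifacts (a final clip at 0.001/0.999 guards numerics):
`beta = plogis(baseline + slope * age + noise)`. Hypermethylating
sites start low (beta 0.15–0.45 at mid-age) and rise at 0.008–0.035
logit/year; hypomethylating sites start high (0.55–0.85) and fall at
the same magnitudes — so both drift toward hemimethylation, the slope
range brackets an exemplar site spanning roughly 0.35 to 0.89 over 80
years, and per-site age correlations spread across the binning range.
Stable classes have slope exactly zero. SNP-modal sites draw a
Hardy–Weinberg genotype per sample (MAF 0.1–0.5) and emit ordered
genotype means near 0.1/0.5/0.9 with small beta-scale noise. X-linked
sites are hemimethylated in females with a female-specific drift of
0.01 logit/year and extreme (low) in males — which both reproduces
the sex-dimorphic X pattern and plants the sex-by-age interactions
that the interaction scan should concentrate on chrX. Sex effects are
zero for autosomal classes.

Spatially, hypermethylating sites are grouped into long (800–3,000
bp), CpG-rich islands overlaid with state-4 (strong enhancer)
chromatin at 85% fidelity; conserved promoter sites sit in promoter
islands under state 1; hypomethylating sites sit in open sea under
state 5; stable sites populate background islands, shore/shelf flanks
at their defining distances, and open sea (with a share of state-15
repetitive chromatin). SNP-modal sites carry a common SNP at distance
0; a small background of SNPs at distances 1–39 bp and at-site SNPs
on 0.5% of stable sites populates the remaining distance classes.
A detection-p layer is attached with ~0.5% degraded probes so the QC
filter has work to do. Everything is deterministic under a seed.

What the generator does **not** emulate: type I/II probe chemistry,
batch effects, cell-composition mixtures, genetic relatedness, and
nonlinear age trajectories. Recovery tests passing on this generator
therefore demonstrate correctness of the statistical machinery under
the stated model, not robustness to those real-data complications.
Because the X-linked class is genuinely age-dependent in females by
design, sensitivity and false-discovery metrics are computed over
autosomal sites, mirroring the autosomal scope of the dataset-level
analyses.

# Quality control

A call is detected iff its detection p-value is <= 0.01; a probe is
kept iff its detected fraction is strictly greater than 0.98 (the
strict/non-strict directions follow the thresholds' conventional
wording). Undetected calls in surviving probes are set missing, which
is what makes filtering idempotent. Per-sample call rates are
reported but never used to exclude samples. Whether the quoted call
rate is per-probe or per-sample is ambiguous in common usage; both
are computed, and the probe-level rate drives filtering.

# Problem sizes and numerical choices

The default recovery dataset is 400 samples x 10,000 sites (29%
affected), the attribution recovery 400 x 5,000, and the oracle
checks run on toy matrices — sizes chosen so the whole suite
completes in well under a minute while leaving the planted effects
overwhelmingly detectable (the weakest planted slope gives an age
t-statistic around 6 at n = 400, far beyond the Bonferroni
threshold). Other numerical conventions: OLS via QR decomposition
with a vectorised path for complete matrices and a per-site
complete-case fallback; Spearman p-values via the t approximation
(ties are ubiquitous in beta data); KDE grid 512 points; float I/O at
17 significant digits so write/read round-trips are bit-exact; all
RNG use goes through a seed-scoped helper that restores the caller's
RNG state.

# Limitations

* Plain OLS ignores relatedness and cell-type composition; on real
  cohorts with strong family structure a mixed model would be the
  conservative choice.
* The attribution estimator (rho^2 x variance proportion) is an
  extrapolation, not a variance-components fit; it inherits the
  instability of rank correlations on low-variance components.
* Mode counting at bandwidth 0.05 cannot separate genotype means
  closer than about one bandwidth, and very rare genotype classes
  (below the peak floor at small n) are merged.
* The CGI predicate operates on provided island tables; the package
  does not call islands from genome sequence.
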