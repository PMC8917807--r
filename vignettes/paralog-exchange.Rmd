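---
title: "Models and methods for paralog co-expression divergence and exchange"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for paralog co-expression divergence and exchange}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paraflux)
```

This vignette documents the statistical models behind each analysis in
`paraflux`, the parameters that matter and their defaults, what the
synthetic-data generators emulate (and do not), and the numerical and
design choices made where more than one reasonable option existed.

## 1. Pair co-expression and the divergence rule

The unit of analysis is the unordered paralog pair, canonically oriented
with the lexicographically smaller gene identifier first
(`canonicalize_pairs()`). Orientation-specific percent identities travel
with the pair and the mean reciprocal identity is their average.
Lexicographic ordering is identifier-scheme-agnostic and makes
canonicalization idempotent; for families with more than two members,
every unordered pair is a separate record.

Co-expression is the Pearson correlation of the two members' abundance
profiles across conditions or tissues, computed on the dataset's native
scale as loaded (TPM for development-style transcriptomes, log2
quantities for proteomes) over pairwise-complete observations. Two
guards apply:

- `min_obs = 5`: a correlation is reported only when at least five
  complete observation pairs exist. Five points is the floor below which
  a sample correlation is mostly noise for profiles of this length.
- Constant series give a *missing* correlation, not zero. Pearson's R is
  undefined at zero variance, and mapping it to 0 would silently inflate
  the divergent class, whose rule is R ≤ 0.

A pair is **divergent** iff R ≤ 0 and **co-regulated** iff R > 0. The
boundary is included in the divergent class; classification of a missing
R is missing. The divergent fraction is taken over pairs with defined R.

The per-gene coefficient of variation (sample sd / mean, `min_obs = 5`)
is computed on the linear scale only; sd throughout the package is the
sample sd (denominator n − 1), a documented choice where the convention
is not dictated.

The random-pair null (`random_pair_null()`) samples pairs of distinct
genes uniformly, with 10,000 draws by default — the reference
distribution against which paralog pairs are judged. The draw count is
exposed because no canonical value exists.

Identity-binned comparisons use left-closed bins `[edge, next)`; the top
bin also includes its right edge so an identity of exactly 100 is not
dropped. Within each bin, same-complex pairs are compared with all other
pairs by a two-sided Wilcoxon rank-sum test; bins with fewer than two
observations on either side are reported untestable (`NA`).

## 2. Complex variability and stability classes

A complex is scored when at least `min_members = 5` members are
quantified. All pairwise member correlations are computed as above, the
median is taken, and variability is defined as 1 − median R (range
[0, 2]). Two robustness rules: a pairwise R enters the median only if it
is itself defined under `min_obs`, and the complex is scored only when
at least `ceiling(choose(5, 2) / 2) = 5` pairwise correlations are
defined, so a median is never taken over a handful of surviving pairs.

Stability classes come from the quartiles of the observed median-R
distribution: strictly above the 75th percentile is *stable*, strictly
below the 25th is *variable*, the rest *intermediate*. Strict
inequalities send boundary ties to intermediate, which keeps the extreme
classes conservative and makes the degenerate all-equal distribution
entirely intermediate. Genes in several complexes contribute to each
independently.

Paralog content is the fraction of members having at least one paralog,
either anywhere in the genome (precomputed flags) or within the same
complex (requiring the pair table) — the stricter variant. The
content–variability relation is a Pearson correlation with two-sided p,
with optional exclusion of heterodimers and all-paralog complexes. The
per-subunit view (`subunit_median_correlation()`) reports each member's
median correlation with its co-members; a flag exists to exclude a
subunit's own paralog partner from "co-members", since it is unknowable
whether the original analyses did (we include partners by default).

The random-complex null reassembles the catalog's exact size spectrum
from randomly drawn quantified genes and scores it identically, giving
the reference distribution for "are real complexes more co-expressed
than chance".

## 3. Stoichiometric stability against a permutation null

For each condition comparison, per-gene log2 fold changes are taken
relative to the dataset's first condition, averaging replicates. Each
subunit's statistic is the median Euclidean distance between its
fold-change vector and each co-member's (the absolute difference when a
single comparison is analyzed). The null reassembles complexes of the
same size from all quantified genes and recomputes the same statistic;
the default draw count is 2,500. The empirical probability uses add-one
smoothing:

p = (#{null < observed} + 1) / (n_null + 1)

so p is never 0 and its floor 1/(n_null + 1) is guaranteed only for
zero-distance subunits. The comparison is strict (`<`), matching the
definition as the probability of observing *lower* distances; a `<=`
variant is available. By default one null is shared per complex-size
class within a comparison, which keeps the cost linear; per-subunit
nulls (`per_subunit_null = TRUE`) are used where independent p-values
are needed, e.g. when testing the uniformity of the null p distribution,
because 500 p-values ranked against one shared null are dependent and a
Kolmogorov–Smirnov test against Uniform(0, 1] is then unreliable. The
complex-level score is 1 − median of member p-values; the median (rather
than mean) was chosen as the more robust summary, another place where
the convention is not dictated.

## 4. Differential abundance, concordance, degradation classes, PSMs

The internal differential test is Welch's t on log2 values with BH
adjustment; significance requires |log2 FC| strictly greater than 0.58
(~1.5-fold) *and* adjusted p < 0.05. The strict inequality at the fold
threshold is deliberate and configurable. Precomputed DE tables from any
upstream pipeline are accepted wherever a `de` argument appears, so
dataset-specific machinery (moderated models, empirical-null FDR) can be
honoured without re-implementation.

Pair concordance considers pairs whose two members are both significant:
same fold-change sign is *concordant*, different *opposite*; exact-zero
fold changes are excluded with a warning rather than arbitrarily signed.

The degradation-class analysis couples two tests: a Fisher exact test on
the 2×2 of NED status × complex membership, and a Wilcoxon rank-sum
comparison of Δ = R_protein − R_rna between pairs with at least one NED
member and pairs of two ED proteins. Lower Δ for NED-containing pairs
indicates divergence arising post-transcriptionally.

PSM processing applies the filters in order — reverse/contaminant flags,
search score ≥ 15, reporter intensity ≥ 10³ in at least one of the 10
channels — then log2-transforms, subtracts each channel's median
(location normalization; "normalized" is otherwise underdetermined),
drops peptides with any missing channel, requires ≥ 2 unique peptides
per protein group, and summarizes by the channel-wise median. The
all-channels reading of the intensity floor (discard only when *every*
channel is below it) is the documented resolution of an ambiguous rule;
per-channel masking would be the alternative.

## 5. The conserved paralog-substitution signature

Ratios are formed per sample as log2(a) − log2(b) wherever both genes
are quantified; working in ratio space removes global per-sample
abundance shifts, which is also why no cross-species normalization is
attempted. Ratio changes are tested against the reference (first)
condition with a moderated t:

- per pair, the pooled two-group variance s² with d = n1 + n2 − 2;
- across the ensemble of pairs within a comparison, a scaled inverse
  chi-square prior (d0, s0²) is fitted by the method of moments on the
  variances, using Var(F)/E(F)² = 2(d + d0 − 2)/(d(d0 − 4)) for
  s²/s0² ~ F(d, d0). When the observed variances are no more dispersed
  than sampling alone explains (r·d ≤ 2), d0 = ∞ and the pooled mean
  variance is used; a numerical guard keeps estimated d0 ≥ 2.5 so the
  prior mean exists;
- the posterior variance is s²_post = (d0·s0² + d·s²)/(d0 + d) and the
  moderated t has d0 + d degrees of freedom. Setting d0 = 0 recovers the
  ordinary pooled t exactly — the sensitivity-analysis escape hatch.

This captures empirical-Bayes variance shrinkage with a closed,
verifiable formula instead of a full empirical-Bayes fit. An unpaired
design is the default; a paired mode (one-sample t on per-replicate
ratio differences, matched by replicate label) exists because the
original designs are ambiguous about replicate blocking.

Gene pairs are mapped to orthogroup pairs per species; pairs with an
unmapped member are dropped, orthogroup pairs are canonically oriented
(deltas negated on flips), and when several gene pairs collapse onto one
orthogroup pair in a comparison, both deltas and p-values are averaged
arithmetically — averaging happens within comparison, *before* p-value
combination.

Per orthogroup pair, the per-comparison p-values are combined with
Fisher's method (X² = −2 Σ log p against χ² with 2k df), BH-adjusted
across pairs, and the three-way rule applied: present in all species,
sign-consistent in at least `min_consistent = 5` comparisons, adjusted
combined p ≤ 0.05. Orientation for sign counting flips each pair so its
summed delta is positive (positive ratios prioritized); the consistency
count is therefore orientation-invariant, exact zeros count as
inconsistent, and for pairs quantified in only five or six comparisons
the ≥ 5 rule applies to the quantified ones.

Fisher's method assumes the combined p-values are independent.
Comparisons that share reference samples (two time points of one time
course both tested against the first) violate this and make the
combination anti-conservative; the synthetic panel therefore generates
every comparison as an independent batch with its own reference
replicates, and the calibration results reported by the test suite hold
under that independence. On real shared-baseline time courses the
combined p-values should be read as enrichment scores rather than
calibrated probabilities — a known limitation of the method.

## 6. Promoter motif scanning

Position frequency matrices (JASPAR text format, hand-parsed) become
probability matrices after adding a pseudocount of 0.8 distributed by
the background composition (uniform by default; both configurable). The
score of a window is the log2 odds versus background, min–max rescaled
by the motif's achievable extremes, so 1 is the consensus and 0 the
anti-consensus. Scanning slides over all positions of the promoter and
its reverse complement; windows containing ambiguous bases are skipped;
the reported value is the maximum relative score if it reaches the 0.8
threshold and 0 otherwise — absent motifs are zeros, not missing, so
downstream set arithmetic is well-defined. The promoter window is
2,000 bp upstream of the transcription start site by convention; the
"80%" threshold is interpreted as the conventional relative-score scale
of motif toolkits. Shared-TF fractions are defined over the union of the
two members' repertoires, so shared + exclusive = 1. Per-TF difference
distributions require the TF in at least 10 pairs and fix pair
orientation upstream.

## 7. Enrichment

Overrepresentation is the one-sided Fisher exact test (hypergeometric
upper tail) per term on flat gene sets; graph-aware decorrelation of GO
annotations is deliberately out of scope, so results on hierarchical
vocabularies are those of the classic test. Ranked enrichment is the
two-sample KS test between in-set and out-of-set scores, exact p for
small samples and asymptotic otherwise (the `stats::ks.test()` rule).
Adjustments are BH and Hommel, validated in the test suite against a
literal step-up loop and an exhaustive closed-testing oracle
respectively.

## 8. What the generators emulate — and what they do not

`simulate_expression_study()` draws one latent trajectory per pair — a
standard-normal random walk over conditions, standardized to unit sd, so
`noise_sd` reads directly as a fraction of the latent sd — and gives
both members the latent plus independent Gaussian noise; divergent pairs
(planted fraction exact up to rounding) use opposite signs of the
latent, which hits the R ≤ 0 rule sharply at low noise while noise moves
realized R continuously. Complexes are built around their own latent
trajectories from co-regulated pairs and singletons with a per-complex
target paralog content drawn from U(0.1, 0.9); with
`content_coupling > 0`, paralog-bearing members get noise inflated by
(1 + coupling), which plants the positive content–variability relation;
at coupling 0 paralog and singleton members are exchangeable, so the
relation test is calibrated. Paralog-gene profiles are amplitude-scaled
by `paralog_var_boost = 1.5` (correlation-invariant), planting the
higher CV of paralog genes. The protein layer adds independent noise
(sd 0.3) and extra noise (sd 0.5) for pairs containing a NED-labelled
gene; NED labels are drawn with probability 0.45 inside complexes and
0.2 outside, planting the NED–complex enrichment. Defaults — 2,000
pairs, 500 singletons, 10 conditions, divergent fraction 0.35, noise sd
0.3, 60 complexes of 5–12 members — are the study conditions exercised
by the test suite, chosen as a realistic mid-size developmental design.

`simulate_multispecies_proteomes()` emits a four-species panel covering
seven comparisons (2+2+2+1), three replicates, each comparison an
independent batch with its own reference replicates (see §5 for why).
Planted conserved pairs (default 50 of 1,000) shift the log2 ratio by
`effect_size` (default 1) with one sign across all their comparisons,
split half onto each gene; nulls have zero shift; replicate noise is
Gaussian (sd 0.25 in log2 units).

`simulate_promoters()` plants motif consensus sequences at
non-overlapping random positions in i.i.d. background;
`simulate_psm_table()` converts violation rates to exact planted counts
on disjoint PSMs and appends a clean single-peptide protein, so survivor
counts are hand-checkable.

All generators are driven by one study seed expanded into fixed
per-generator offsets (expression +0, multispecies +1, promoters +2,
PSM +3), so adding one generator to a workflow never perturbs another's
draws, and everything is bitwise reproducible for a fixed seed.

What passing tests on these generators shows is that the *pipeline*
recovers planted structure at realistic noise levels and stays
calibrated under its own null assumptions. What they do not show:
robustness to multi-mapping reads in transcript quantification, to
missing-not-at-random proteomic missingness (only flat missingness is
representable), to instrument-level intensity noise, to incomplete or
wrong complex catalogs, or to correlated comparisons in real
time-course designs.

## 9. Problem sizes in the test suite

The shipped tests run the divergence recovery at 2,000 pairs × 10
conditions, the stoichiometric calibration at 500 null subunits × 2,500
draws each, the conservation recovery at 1,000 orthogroup pairs × 7
comparisons × 3 replicates (plus twenty null-panel replicates), and the
remaining checks on small enumerable fixtures. These sizes give the
recovery statistics comfortable operating margins (e.g. per-comparison
signal-to-noise ≈ 1/0.25 per replicate for planted conserved pairs)
while keeping a full run of the suite to a few minutes on one core.
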