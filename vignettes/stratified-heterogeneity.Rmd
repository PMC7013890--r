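---
title: "Detecting stratified heterogeneity in accident severity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting stratified heterogeneity in accident severity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qdetect)
```

## The question and the statistic

Road-accident severity is a geographical outcome: accidents with many
casualties are not scattered uniformly but concentrate in strata defined by
where, when and how the accident happened.  *Spatial stratified
heterogeneity* means exactly this: within a stratum the outcome varies
little, between strata it varies a lot.  The q statistic measures how much
of the outcome's variation a candidate stratification explains:

$$q = 1 - \frac{\sum_{h=1}^{H} N_h \sigma_h^2}{N \sigma^2}
    = 1 - \frac{\mathrm{SSW}}{\mathrm{SST}},$$

where $h$ indexes the $H$ strata, $N_h$ and $\sigma_h^2$ are the size and
variance of stratum $h$, and $N$, $\sigma^2$ describe the pooled data.
$q \in [0, 1]$: 0 means the stratification explains nothing, 1 means it
determines the outcome completely, and $100\,q$ is read as the percentage
of heterogeneity explained.

Four detectors build on this:

* **Factor detector** — `compute_q()` / `qdetect()`: q of each candidate
  factor's stratification, with significance.
* **Influence (risk) detector** — `risk_detector()`: which strata have
  significantly higher mean severity, via pairwise Welch comparisons.
* **Ecological detector** — `ecological_detector()`: which of two factors
  explains more, via the F ratio of their within-strata variance sums.
* **Interaction detector** — `interaction_detector()`: q of the overlay
  (superposition) of two stratifications, classified against the individual
  q values and their sum.

A global Moran's I check (`moran_test()`) answers the prior question of
whether the outcome is spatially dependent at all, which matters for model
selection in follow-up regression work.

## Numerical conventions

**Variance divisor.** All variances in the q decomposition are population
variances (divisor $N_h$, $N$).  This makes the two forms of the definition
coincide exactly: $\mathrm{SST} = N\sigma^2$ is the total sum of squared
deviations and $\mathrm{SSW} = \sum_h N_h \sigma_h^2$ the within-strata sum
of squares, so `q` equals the between/total share of a one-way ANOVA
decomposition ($R^2$ of the group-means model).  The test suite asserts
agreement with `lm()`'s $R^2$ to $10^{-10}$ on a thousand random instances.
Singleton strata contribute $\sigma_h^2 = 0$ to SSW and are therefore
retained in q (they are excluded from pairwise mean comparisons, which need
at least two observations per stratum).

**Degenerate input.** If $\mathrm{SST} = 0$ (constant outcome) q is defined
as 0 and flagged; its p-value is 1.

**Significance of q.** The default is a permutation test: stratum labels
are randomly reassigned `n_perm = 999` times and
$p = (1 + \#\{q^{perm} \ge q^{obs}\})/(1 + n_\mathrm{perm})$.  This is
exact-level by construction and makes no distributional assumption; its
empirical type-I error at $\alpha = 0.05$ is checked to lie in
$[0.03, 0.07]$ over 500 null replicates.  An analytic alternative
(`method = "noncentral_f"`) refers $F = \frac{N-H}{H-1}\,\frac{q}{1-q}$ to
a noncentral F distribution with noncentrality estimated from the stratum
means; it is offered as a cross-check because analyses in this literature
report q p-values computed that way.

**Welch form of the risk detector.**  The pairwise statistic is
$t = (\bar Y_a - \bar Y_b)\,/\,\sqrt{s_a^2/n_a + s_b^2/n_b}$ with
Satterthwaite degrees of freedom — the standard unequal-variance form, in
which the two variance-over-n terms *add* (a difference there can produce a
negative radicand and is not a valid standard error).  Sample variances
(divisor $n_h - 1$) are used here, as in any two-sample t machinery.  No
multiple-testing adjustment is applied by default, matching the per-pair
95%-confidence reading of this kind of analysis; `p_adjust = "BH"` is
available.

**Ecological detector.**  $F = \frac{N_a (N_b - 1)\,\mathrm{SSW}_a}
{N_b (N_a - 1)\,\mathrm{SSW}_b}$ with $(N_a - 1, N_b - 1)$ degrees of
freedom.  The p-value is two-sided (twice the smaller tail), so comparing a
stratification with itself gives $F = 1$, $p = 1$; when significant, the
factor with the smaller within-strata variance sum is reported as dominant.
A zero denominator SSW yields an infinite F with a flag.

**Interaction classification.**  With $q_a$, $q_b$, $q_{ab}$ (the overlay):
Independent when $|q_{ab} - (q_a + q_b)| \le$ `tolerance` (default
$10^{-9}$); Enhance-nonlinear when $q_{ab}$ exceeds the sum; Weaken-
nonlinear below the minimum; Enhance-bi at or above the maximum; Weaken-
single between minimum and maximum.  The published rule uses strict
inequalities and leaves boundaries undefined; checking Independence first
and resolving ties with the min/max to the adjacent category nearer
Independence makes the classification total and deterministic on
$[0,1]^3$, which the tests assert.  Because the overlay is a common
refinement of both parents, $q_{ab} \ge \max(q_a, q_b)$ up to rounding, so
Weaken labels cannot arise from a genuine overlay — they are reachable only
when classifying externally supplied q triples.

**Missing factor codes.**  A missing code is a first-class sentinel (`NA`):
the record is dropped from any detector run involving that factor and kept
everywhere else, so q values stay comparable across factors with different
missingness.  Inside `interaction_detector()` all three q values are
evaluated on the records usable in the overlay, preserving the refinement
inequality under factor-specific missingness.

**Spatial weights.**  Moran's I depends on the weight choice, and point
data come with no canonical one.  The default is k-nearest-neighbour
(k = 8) row-standardized weights on great-circle (haversine) distances —
a robust, density-adaptive choice for irregular urban point patterns.
Inference uses the analytic randomization (permutation-moment) variance,
cross-checked in the tests against an independent reference implementation
(`ape::Moran.I`) to $10^{-8}$; a Monte-Carlo permutation p-value is
optional.

## The synthetic generator

Real crash-record microdata of the kind this package targets are not
publicly deposited, so the generator is a first-class module: every
detector is validated end-to-end on data whose ground truth is known.

Each record draws a zone (giving spatially clustered coordinates), integer
category codes for each factor — zone-tilted where a factor's prevalence
should vary over space — and an outcome around the latent mean
$\beta_0 + \sum_h a_h + \sum_{hk} c_{hk}$, where the $a_h$ are per-category
effects centered under the category probabilities
($\sum_h p_h a_h = 0$) and the $c_{hk}$ are doubly centered interaction
cross terms.  Centering guarantees effects change stratification, not the
overall level, and makes the planted q analytic under Gaussian noise:

$$q^* = \frac{\sum_h p_h a_h^2}{\sum_h p_h a_h^2 + \sigma^2}$$

(`expected_q()`).  Parameter recovery — $|\hat q - q^*| \le 0.03$ in at
least 90% of seeds at $n = 5000$ for $q^* \in \{0.1, 0.3, 0.5\}$ — is part
of the acceptance suite.

Real accident records carry integer casualty counts, but the table
validator deliberately enforces only non-negative finite outcomes: the
Gaussian noise model produces continuous severity values, and detectors are
agnostic to integrality, so synthetic Gaussian tables round-trip through
the same I/O as real data.

Three noise models are available: Gaussian (truncated at zero), Poisson,
and a moment-matched discrete model for small counts.  The discrete model
fits the maximum-entropy distribution on a small integer support with a
requested mean and SD (`fit_discrete_moments()`, an exponential family in
$k$ and $k^2$ solved by convex optimisation) and injects planted effects by
exponentially tilting that baseline so each record's mean shifts by exactly
its latent effect, clamped just inside the support range.  Infeasible
moment requests (mean outside the support, variance outside the two-point
bounds) raise an error naming the violated constraint.

### The Shenzhen-like calibration preset

`make_preset("shenzhen_like")` emulates the published study conditions:
3250 records over five zone clusters with the full 17-factor coding
inventory, split into a fatal-accident subpopulation and an injuries-only
subpopulation, a planted cause-by-responsible-party interaction, and three
deliberately null factors (day of week, traffic sign, weather) so that
significance masking has something to mask.

One published pair of numbers deserves care: the fatality-group severity
summary is printed as mean 0.48, SD 0.301.  Those two values cannot be the
conditional moments of a per-accident fatality *count* in a group defined
by having at least one fatality — any such count has mean at least 1, and
an integer-valued variable with mean 0.48 has SD at least 0.4996.  The
printed mean is, however, exactly what one gets by averaging the fatality
column over *all* records (zeros included), and the printed SD is
attainable as the conditional SD of a count on $\{1, 2\}$.  The preset
therefore pins what is attainable: the conditional fatality distribution is
$\{1, 2\}$ with $P(2) \approx 0.1008$ (conditional SD exactly 0.301,
conditional mean 1.1007), and the fatal-accident share is
$0.48 / 1.1007 \approx 0.436$ so that the table-wide fatality mean is the
printed 0.48.  The injuries-only group's moments are attainable as printed
and are matched exactly: support $\{1,\dots,6\}$ with mean 1.41, SD 1.055.
This is an emulation choice about internally inconsistent summary
statistics, not a claim about the real records; the conditional group-1
mean of the preset (≈ 1.10) intentionally differs from the printed 0.48,
and the acceptance report shows the honestly computed value.

The preset's spatial structure is deliberately mild: zone effects are sized
to the small published zone-level q (~0.01–0.02), which induces clustered
coordinates but only weak global autocorrelation of the outcome.  The
`spatial_demo` preset provides the strong-dependence condition (five tight
clusters whose zone effects dominate the outcome) used for the Moran
acceptance check.  `null` and `interaction_demo` provide the no-structure
and strong-interaction conditions.

What passing tests on these presets do **not** show: the generator draws
factors independently across records (no road-network geometry, no
spatio-temporal accident process), injects interactions only through
specified cross terms, and knows nothing about reporting or geocoding
artefacts in real crash records.  Recovery of planted structure validates
the estimators, not any claim that real Shenzhen q values would be
reproduced.

## Problem sizes used in validation

The test and acceptance suites run at sizes chosen to make Monte-Carlo
bands comfortably narrow while staying desk-scale: 1000 random instances
for the ANOVA-oracle equivalence, 500 randomized tables for refinement
monotonicity, 500 null replicates with 999 permutations ($n = 200$) for
the type-I calibration, 100 seeds at $n = 5000$ per planted q level for
recovery, 100 seeds at $n = 2000$ for interaction labelling, and the full
$n = 3250$ for the calibration preset.

## Known limitations

* Detector inputs are categorical codings; no discretisation optimisation
  for continuous covariates is offered.
* No spatially explicit q variants (zoning or scale search) and no local
  spatial statistics (LISA, Getis–Ord).
* Interactions are pairwise; three-factor overlays are easy to form with
  `overlay()` but not classified.
* The permutation p-value's resolution is $1/(n_\mathrm{perm}+1)$; with
  999 permutations the smallest reportable p is 0.001.
* The ecological detector follows the classical F-ratio form, whose
  sampling theory treats the within-strata variance sums as if they came
  from independent samples; its p-values are best read comparatively.
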