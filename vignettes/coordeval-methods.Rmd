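---
title: "Methods: construction and application of the coordination-ability evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: construction and application of the coordination-ability evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coordeval)
```

## The instrument

`coordeval` implements a norm-referenced evaluation of coordination ability
for children aged 4.0–5.9 years. The construct is measured through 20 field
test indicators (`x1`–`x20`) organised in six dimensions: balance, rhythm,
spatial orientation, limb range of motion, body coordination and perceptual
judgment. Children are evaluated in two discrete age groups — 4.0–4.9 years
(`group4`) and 5.0–5.9 years (`group5`) — because motor performance at this
age changes quickly; age is computed in completed calendar months divided by
12, truncated to one decimal, so that group membership never depends on
fractional days. Six-year-olds and under-fours are excluded.

The pipeline has four layers, each exposed as ordinary functions:

1. **Dimension weights** from expert judgment via the analytic hierarchy
   process (AHP).
2. **Within-dimension indicator weights** from data: correlation-matrix
   principal components for dimensions with 3–4 indicators, and
   coefficient-of-variation (CV) weighting for the two-indicator dimensions
   (body coordination, perceptual judgment), where a component analysis is
   degenerate.
3. **Five-level percentile norms** per indicator and age group with a P3
   no-score floor, and a weighted composite score
   $\mathrm{total} = \sum_x P_x W_x$ on a 0–100 scale.
4. **Four-band classification** (Excellent/Good/Qualified/Unqualified) cut
   at the P90/P65/P15 percentiles of a modeling sample, validated by an
   80/20 back-test.

The published artifacts of the instrument — judgment matrix, weight system,
norm tables, composite band tables — are shipped verbatim as plain-text
JSON/CSV under `inst/extdata` and loaded with `coordination_judgment_matrix()`,
`load_weight_table()`, `load_norm_tables()` and `load_composite_bands()`.

## AHP dimension weighting

The judgment matrix $C$ is a positive reciprocal pairwise-comparison matrix
over the six dimensions. Weights use the *sum method*: column-normalize
($D_{ij} = C_{ij} / \sum_i C_{ij}$), sum rows, renormalize. The consistency
chain is

$$\lambda_{\max} = \frac{1}{n}\sum_i \frac{(CW)_i}{W_i},\qquad
  C.I. = \frac{\lambda_{\max} - n}{n - 1},\qquad
  C.R. = \frac{C.I.}{R.I.},$$

with the Saaty random-index table ($R.I. = 1.24$ at $n = 6$) and acceptance
at $C.R. < 0.1$. Two numerical choices matter:

* **Rounded entries.** Published matrices carry two-decimal entries (0.33
  for 1/3, 0.14 for 1/7), so exact reciprocity fails by design. The
  validator accepts $|a_{ij}a_{ji} - 1| \le 0.02$ by default
  (`reciprocity_tolerance`); strict mode (`0`) is available. The shipped
  matrix is stored with its printed decimals — reproducing the published
  chain requires analysing the matrix *as printed*, not an idealised one.
* **Sum method, not eigenvector.** The exact principal eigenvector is used
  only as a test oracle. For consistent matrices the two coincide; the
  estimate $\lambda_{\max}$ is bounded below by $n$ for any reciprocal
  matrix, which the tests verify against `eigen()`.

## Data-driven indicator weighting

For a dimension's indicator block the chain is: KMO sampling adequacy (from
the anti-image/inverse correlation matrix), eigen-decomposition of the
sample correlation matrix, retention of components with eigenvalue $> 1$
extended minimally to reach 80% cumulative variance, coefficients
$a_{ij} = \ell_{ij}/\sqrt{\lambda_j}$, variance-weighted composite
coefficients $b_i = \sum_j a_{ij} v_j / \sum_j v_j$, and normalization
$w_i = b_i / \sum b_i$. Components are unrotated; each component is
oriented so its largest-magnitude loading is positive, which fixes the
eigenvector sign ambiguity and reproduces the published sign pattern for
the balance block. Negative composite coefficients abort normalization by
default (a negative weight is uninterpretable); an absolute-value fallback
exists behind a warning.

CV weighting is $w_i = (s_i/\bar x_i) / \sum_k (s_k/\bar x_k)$ with sample
(n−1) standard deviations — indicators that spread children more get more
weight. Final weights multiply the AHP dimension weight by the
within-dimension weight; with both layers normalized they total exactly 1
(the published rounded tables total 1.001 for the 4-year group, which the
loaders accept within 0.002).

The EFA retention screen (`efa_screen()`) drops indicators whose maximum
absolute loading is below 0.5 (low convergence) and flags items whose top
two loadings differ by less than 0.2 (cross-loading); this mirrors how the
original 28-item battery was reduced to the final 20 indicators.

## Norms, scoring and classification

Each indicator's five levels (scores 20/40/60/80/100) are cut at empirical
percentiles along the direction-adjusted axis (so "better" is always one
direction; nine of the 20 indicators are timed tasks where lower is
better). Percentiles use linear interpolation between closest ranks
(`quantile(type = 7)`, configurable). The published tables print only the
P3 floor and the composite P90/P65/P15 anchors, not the interior five-level
anchors; `build_indicator_norms()` therefore takes the anchors as an
explicit parameter with default $\{P3, P25, P50, P75, P90\}$ — a choice,
made once, that yields theoretical level shares of 3% (no score), 22%, 25%,
25%, 15% and 10%, consistent with a 10%-share top level matching the
composite's Excellent share. Scoring against the published tables never
depends on this default because those tables are shipped verbatim.

Values on the worse side of the P3 floor receive **no score** (0 points,
flagged in the report, the record is not invalidated) — the floor exists to
direct attention to children far behind the norm rather than to grade them.
Interval closure: bands are half-open toward the worse direction, so a
value exactly on a cut takes the better band; published bands printed with
strict inequalities (`>`, `<`) keep their strict closure. Composite
classification uses the same better-band-at-the-edge rule.

Obvious misprints in the published tables are handled conservatively and
documented in the artifact files: the 5-year x13/x14 fourth band's printed
lower edge "−1.50" overlaps the fifth band (a dropped sign; the adjacent
band ends at 1.49/1.50) and is transcribed as 1.50; the x19/x20 rows print
auxiliary per-second figures beside the centimeter bands — the centimeter
bands are canonical and the seconds figures are not transcribed.

## Back-testing

`split_cohort()` partitions the valid records 80/20, stratified by age
group × sex with largest-remainder rounding, under a mandatory seed.
`run_backtest()` rebuilds the *entire* standard on the modeling set only —
norms at the configured anchors, composite cutoffs at P90/P65/P15 rounded
to two decimals as published tables are — then scores and classifies the
held-out set. Two error notions are reported because they answer different
questions:

* **Signed band errors** (observed − theoretical percentage per band, per
  age group) show where the classification drifts;
* an **overall per-record misclassification rate**: a test record's
  *theoretical* band is where its composite falls in the modeling set's
  empirical CDF against the 10/25/50/15 shares, and the record is
  misclassified when the rounded published-style cut table assigns a
  different band. Disagreements arise from quantile interpolation, the
  two-decimal rounding of cutoffs, and ties in the discrete composite
  distribution — all properties of the published standard itself. The rate
  is reported with its Wilson score interval and a pass flag at the 5%
  threshold.

## Reliability and consensus statistics

The psychometric layer implements the statistics used to validate such
instruments: Pearson test-retest correlation; ICC(2,1) — two-way random
effects, single measure, absolute agreement — from the ANOVA mean squares
with Satterthwaite/F-based confidence bounds; Cronbach's α; McDonald's ω
from loadings and uniquenesses, $\omega = (\sum\ell)^2 / ((\sum\ell)^2 +
\sum u)$; Kendall's W with tie correction and its $\chi^2 = m(n-1)W$ test;
Delphi consensus CV per item (sample SD, consensus at CV < 0.25); the
expert authority coefficient $C_r = (\text{judgment basis} +
\text{familiarity})/2$ (the conventional composition — the threshold 0.80
is standard, the formula itself is a documented convention); and the Wilson
score interval. Tests verify shift/scale invariances, the α = ω identity
under tau-equivalence, agreement of Kendall's W with `friedman.test()`, and
agreement of ICC(2,1) with an `lme4` variance-component fit on balanced
tables.

The original rater and expert tables are unpublished, so the package makes
no claim to reproduce the instrument's specific reliability values; the
statistics carry the thresholds as semantics (flags), not as targets.

## Group comparisons

`comparison_table()` reproduces the published sex-difference layout for one
age group: 20 indicator rows on unweighted level scores, six dimension rows
on weighted subtotals, one composite row; each with group summaries, a
pooled-variance t test (Welch behind a flag; the workflow gates on Levene's
test first — `levene_test()`, classical mean-centering by default,
Brown–Forsythe by option), and Cohen's d with pooled SD (no small-sample
correction — this is the form that reproduces the published effect sizes
from the reported summaries). Magnitudes band at $|d| \ge 0.8$ (large) and
$\ge 0.5$ (medium); the conventional anchors leave (0.2, 0.5) verbally
unassigned and it is banded as small. No multiplicity correction is applied
across the 27 rows, matching the source workflow; this is a known
limitation of the layout.

## The synthetic cohort generator

Because the original cohort is not deposited, `generate_cohort()` draws
populations with the statistical structure the instrument assumes, so that
every downstream operation is testable:

* **Cell sizes** default to the reported valid cohort: 266/264
  girls/boys in the 4-year group and 270/268 in the 5-year group (1,068
  records).
* **Correlation structure**: one latent factor per dimension with loading
  $\sqrt\rho$ on each of its indicators; $\rho = 0.4$ by default. The true
  within-dimension correlations are unpublished; 0.4 gives pairwise raw
  correlations around 0.3–0.4, the range typical of motor test batteries
  that still yields a dominant first component, and was fixed once.
  Cross-dimension correlation is 0 by default (also unpublished) and
  configurable only through `rho` within blocks.
* **Marginals**: band-anchored to the published norm tables for x1–x16
  (draw a band by the theoretical shares 3/22/25/25/15/10, then uniformly
  within the band's raw interval), and normal with the published means/SDs
  for x17–x20. Open outer bands extend by half the adjacent band's width
  (`tail_factor = 0.5`); printed single-value bands (the 1–5 rating rows)
  are point bands and return their value exactly — for those rows the
  below-floor share folds into level 5, since a bounded rating scale has no
  beyond-floor region. Count indicators sample integers within bands.
* **Sex effects**: the published per-indicator d values are planted as
  latent mean shifts of $\pm d/2$ along the better direction, so the
  female−male latent difference is $d$ SD. Recovering d from five-level
  scores attenuates it slightly (the step function loses a little
  variance), which the recovery tests absorb inside their ±0.1 band.
* **Truncation**: times are clipped at 0.01 s, counts rounded to
  non-negative integers, ratings clipped to [1, 5] — after the shifts.
  For strongly truncated settings (e.g. a normal count marginal with mass
  near zero) the realized mean is biased upward relative to the configured
  one; the moment-recovery test therefore targets x17, whose truncation
  mass is negligible.

What passing tests on this generator do **not** show: real cohorts have
skewed, heteroscedastic marginals, cross-dimension correlations, rater
effects and cluster (kindergarten) structure that the generator does not
model. The generator validates the *pipeline's arithmetic and statistical
behaviour*, not the field instrument's norms.

## Problem sizes and runtime choices

The test suite exercises the worked printed examples exactly (they are
desk-scale); the stochastic properties use: band-anchored round-trips at
n = 10,000 (averaged over a few replicates so the check targets the
estimator's center rather than one draw), a 1,000-record cohort for the
back-test distribution check, 10,000 replicates for the t-test type-I
rate, and 500 records per sex (averaged over four cohorts) for
planted-effect recovery. These sizes put every Monte-Carlo tolerance at
3–4 standard errors while keeping the full suite under a minute on one
core.

## Known limitations

* The five-level interior anchors are a package default, not a published
  fact; users reproducing the published tables should score against the
  shipped artifacts (the default).
* Eight of the 20 indicator names are only partially documented in the
  source instrument; the catalogue marks them `provisional`. Ids are
  authoritative everywhere.
* Confirmatory factor analysis / SEM fit assessment of the construct model
  is out of scope, as are Delphi round administration and sampling design.
* The back-test implements a single split by design; k-fold
  cross-validation is an extension point, not implemented behaviour.
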