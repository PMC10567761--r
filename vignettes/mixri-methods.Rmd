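---
title: "Indirect reference intervals by Gaussian mixture decomposition: models, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Indirect reference intervals by Gaussian mixture decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixri)
```

## The problem

A reference interval (RI) is the central range — conventionally 95% — of an
analyte's values in a healthy population; laboratory reports flag results
outside it. Establishing RIs directly requires sampling at least 120 vetted
healthy volunteers per population segment and analyte, which is why the
intervals used in practice are often old, unverified, and one-size-fits-all
even though analyte distributions depend strongly on sex and age.

Routine clinical laboratory databases contain millions of results, but they
mix healthy and pathological readings without diagnostic labels. `mixri`
implements an *indirect* estimation method for such data, applied here to
the renal-panel analytes serum creatinine (LOINC 2160-0) and blood urea
nitrogen (LOINC 3094-0), both in mg/dl: within each (gender, age) segment a
two-component Gaussian mixture separates the dominant healthy subpopulation
from the pathological tail, and the reference limits are read off the
healthy component.

## The model

Within one segment the value distribution is modeled as

$$p(x) = \sum_{k=1}^{K} a_k\, N(x \mid \mu_k, \Sigma_k), \qquad K = 2,$$

with mixing weights $a_k$, means $\mu_k$ and covariances $\Sigma_k$
estimated by maximum-likelihood EM (canonical) or variational Bayes
(`method = "variational"`). The *principal* component — by default the one
with the largest weight — is interpreted as the healthy subpopulation: the
underlying assumption is that normal organ function produces a narrow,
approximately Gaussian spread of values, while chronic conditions overlay a
thick tail on top of it. The complement of the principal weight,
`outlier_fraction()`, estimates the pathological share of results in the
segment.

The 1D reference interval is then the central `coverage` mass of the
principal Gaussian, $\mu \pm z\,\sigma$ with
$z = \Phi^{-1}((1+\text{coverage})/2)$; at the default coverage 0.95 these
are the 2.5th and 97.5th percentiles. Limits are computed analytically from
$(\mu, \sigma)$, not empirically from points assigned to the component, so
they inherit the estimator's robustness to contamination.

### Bivariate generalization

Creatinine and urea are physiologically coupled (both are renally cleared),
so their joint distribution carries more diagnostic information than the
marginals. The same decomposition applies in two dimensions; the RI
generalizes to the highest-density region of the principal binormal: the
ellipse $\{x : (x-\mu)^\top \Sigma^{-1} (x-\mu) \le r^2\}$ with
$r^2 = \chi^2_2(\text{mass}) = -2\ln(1-\text{mass})$. This is exactly the
contour obtained by integrating the density outward from the mean, computed
in closed form. Slicing the ellipse at a fixed value of one analyte gives
the *chord interval* for the other — a conditional acceptable range that
narrows as the fixed reading moves off-center and vanishes when the fixed
reading alone falls outside the joint region. The alternative semantic, the
central interval of the exact conditional Gaussian $c \mid u$ (which never
vanishes), is provided separately as `conditional_interval()`; the chord is
the primary semantic because the vanishing behavior is what distinguishes a
joint assessment from a marginal one.

### Continuous abnormal flags

The binary in/out-of-RI flag generalizes to the highest-density-region
percentile of a reading: $P(f(X) \ge f(x))$ for $X \sim N(\mu, \Sigma)$,
i.e. the chi-square($d$) CDF of the squared Mahalanobis distance. It is 0 at
the segment mean, 0.95 exactly at the RI limit (1D) or on the 95% ellipse
(2D), and measures how unusual a reading is *for its own gender/age
segment*, in any dimension. The two-sided density-ranking definition (rather
than a one-sided CDF) is used because a low reading far below the mean is as
unusual as a high one far above — for waste products only high values are
pathological, but distance from the population center is what the flag
quantifies. `build_population_model()` persists the fitted principal
Gaussians keyed by (analyte set, gender, age); `predict()` scores readings
against them. Ages are exact-match keys: a missing segment is an error, not
an extrapolation, because segments are estimated independently.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `K` | 2 | — | one healthy + one pathological component; configurable |
| `coverage` | 0.95 | mass | the conventional central-95% RI |
| `min_n` | 120 | results | the direct-method minimum sample size, reused as a reliability floor |
| `bin_width` | 1 | years | large routine datasets support single-year bins |
| `tol` | 1e-6 | mean log-lik. | see "Numerical choices" |
| `max_iter` | 500 | iterations | ample for these fits (typically < 100) |
| `reg` | 1e-6 × mean sample variance | (mg/dl)² | covariance diagonal floor added each M-step |
| `n_init` | 5 | restarts | deterministic splits + random restarts against local optima |
| `B`, `frac` | 100, 0.5 | — | bootstrap convention: 100 samples of half the dataset size |
| `threshold` | 0.95 | percentile | binary flag cut, consistent with the RI mass |

Thresholds for implausible readings default to 25 mg/dl (creatinine) and
150 mg/dl (urea); values above them are treated as entry or unit errors.
The boundary is inclusive (a value exactly at the threshold is kept), and
non-positive values are always removed because concentrations are strictly
positive.

## Numerical choices

**Initialization.** For 1D fits with $K=2$ the first three restarts are
deterministic equal-rank splits at the 50th, 90th and 97.5th percentile;
remaining restarts assign points to random centers. The tail-oriented splits
matter: on segments with little contamination (a few percent), EM started
from a median split converges to a local optimum that halves the healthy
bulk into two overlapping Gaussians — at visibly lower log-likelihood than
the healthy + tail solution, which the 90th/97.5th-percentile splits reach
reliably. In 2D the first restart uses k-means++ center seeding. The best
restart by final log-likelihood wins.

**Convergence.** EM stops when the mean per-point log-likelihood changes by
less than `tol`. The default is 1e-6: at segment sizes around $10^4$ a
looser 1e-4 halts after a handful of iterations while the mixing weight is
still drifting by whole percentage points, because near-converged EM moves
mass between overlapping components with tiny likelihood gains.

**Regularization and degeneracies.** Each M-step adds `reg` to every
covariance diagonal, keeping components positive definite on
near-degenerate segments; on exactly constant input a tiny absolute floor
is substituted so the degenerate case (every value identical) yields a
zero-width interval rather than an error. If a component's responsibility
mass empties out mid-run — the data do not support $K$ components — the run
returns its last valid iterate as a non-converged fit with the outlier
weight near zero, and restart selection proceeds normally.

**Ties.** An exact tie in principal-component weights is broken toward the
smaller generalized variance $\det \Sigma$ (the tighter component is the
healthier candidate); an alternative rule selecting the component nearest a
supplied center is available.

**Variational variant.** `method = "variational"` implements a standard
conjugate variational-Bayes mixture with Dirichlet weight concentration
$1/K$ and normal-Wishart priors centered on the data moments
($\nu_0 = d$, expected precision matched to the inverse data covariance).
Its practical property is weight shrinkage: spurious components on
well-separated data collapse to near-zero weight instead of splitting a
cluster. EM remains the canonical method; the variational path shares the
same output contract.

## Trends, rates, and uncertainty

Per-segment limits form limit-versus-age series. Over adulthood the high
limits are close to linear (`fit_linear_trend`, default ranges 20–60 for
creatinine and 20–50 for urea, per-analyte configurable); beyond age 60 the
widening accelerates and a cubic (`fit_cubic_trend`) captures it. Both are
ordinary least squares via `stats::lm` with standard t-test p-values.

`annual_deterioration_rate()` converts a linear high-limit slope into a
relative annual change, $100\,s/(b + 20 s)$ percent per year — anchored at
the predicted limit at age 20, i.e. the fraction of young-adult capacity
lost per year. The anchor convention is configurable; anchoring at age 20
is the documented default because the rate then reads as loss relative to
the fully developed, pre-deterioration organ.

`bootstrap_ri()` quantifies estimation error: `B = 100` subsamples of
`frac = 0.5` of the data, drawn with replacement, each re-estimated with the
full pipeline; the interval is reported as the replicate mean and its error
as the replicate standard deviation. Note the replicate spread contains an
EM-refit component on top of pure sampling variability, so it shrinks
somewhat more slowly than $1/\sqrt{m}$ in the subsample size $m$.

## The synthetic cohort generator

The study data this method targets are licensed and unavailable, so the
package ships a generator (`default_spec()`, `generate_cohort()`) encoding
the reported structure of the real cohort, and every estimation stage is
validated against the generator's hidden truth labels:

* **Healthy component.** Parameterized per analyte and gender by a stable
  low limit and a linear-in-age high limit — creatinine male
  $0.00387\,\text{age} + 1.108239$, female $0.00298\,\text{age} + 0.83276$;
  urea male $0.13385\,\text{age} + 17.18661$, female
  $0.10959\,\text{age} + 14.8156$ (mg/dl) — from which the Gaussian mean
  and SD follow. Low limits are fixed at 0.55/0.45 (creatinine male/female)
  and 7.0/6.0 (urea) mg/dl, inside the reported 0.4–0.6 and 5.0–9.0 bands.
* **Old-age acceleration.** Above age 60 an additive cubic term
  $c\,(\text{age}-60)^3$ steepens the high limit, with
  $c = 2\times10^{-5}$ (creatinine) and $4\times10^{-4}$ (urea) — chosen
  once as plausible accelerations; the real cubic coefficients are not
  published in the main text and their numeric reproduction is out of
  scope.
* **Pathological component.** The healthy Gaussian shifted by +3 healthy
  SDs and widened ×2.5, with weight ramping linearly from 1% at age 20 to
  11% (creatinine) / 16% (urea) at age 90. Within a visit the component
  indicators are nested (one latent uniform), so each analyte carries its
  exact marginal ramp.
* **Joint structure.** Correlation 0.5 between analytes within a component
  — a plausible positive renal coupling, synthetic rather than estimated.
* **Visits.** Counts per person follow a shifted geometric distribution
  with mean 3.2 and median 2, matching annual-screening behavior with a
  long tail of frequently tested persons.
* **Entry errors.** At rate 0.002 per reading the value is multiplied by
  100 (a decimal-shift/unit error), guaranteeing it exceeds its
  plausibility threshold.
* **Positivity.** Rare non-positive Gaussian draws (order $10^{-3}$ in the
  widest old-age urea segments) are redrawn from the component's positive
  tail, since concentrations are strictly positive.

What the generator does **not** emulate: the real cohort's age pyramid
(ages are covered uniformly), body-size and ethnicity covariates,
longitudinal disease progression within a person, skewed or non-Gaussian
healthy physiology, and laboratory batch effects. Passing recovery tests
therefore demonstrates that the pipeline correctly inverts its own
generative assumptions at realistic sample sizes — not that real lab data
satisfy those assumptions.

## Validation design and known limitations

The test suite validates each stage at deliberately chosen problem sizes:
parameter recovery and interval coverage on contaminated segments of
$n = 20{,}000$; end-to-end cohort recovery on the ramp-endpoint ages
(20, 90) and a four-age spread (25, 50, 75, 90) at $n = 10{,}000$ per
segment and both genders, rather than all 71 ages of the default
specification; Monte-Carlo oracles use $10^5$–$10^6$ draws.

Known limitations, all visible in the validation results:

* **Interval limits are the robust deliverable; mixture weights are not.**
  Recovered limits stay within a tenth of the healthy SD of their true
  values across segments, but the estimated outlier fraction is biased
  where the components overlap heavily. Small true weights (~1%) are
  over-estimated by up to a few percentage points because the tail
  component also absorbs the extreme quantiles of the healthy Gaussian —
  a $K=2$ fit on *pure* Gaussian data already reports an apparent outlier
  share of 1–2%. Conversely, in the widest old-age urea segments the weight
  is under-estimated by a couple of percentage points: the generating Gaussians
  there place ~1% of pathological mass below zero, positivity truncates
  it, and the untruncated-Gaussian likelihood attributes part of the
  overlap back to the healthy component (on untruncated draws from the same
  configuration the estimated weight recovers the encoded value — the bias
  comes from the truncation, not the fitting).
* **No smoothing across ages.** Segments are estimated independently;
  interpolation (the trend fits) is presentational. Consequently the
  population model refuses to score ages it has no segment for.
* **Same-day repeats and frequent testers are not reweighted.** All results
  enter estimation, matching how the method is described on the real
  cohort; per-person deduplication is available as a sensitivity switch in
  `segment_by_gender_age()`-based workflows by pre-filtering the table.
* **Chord intervals assume the fitted binormal is trustworthy** out to the
  95% contour; with near-singular correlation (|ρ| > 0.999) the ellipse
  construction errs out rather than silently inflating.

## Reproducibility

Every stochastic step takes an explicit seed: the generator, each mixture
fit (restart initializations), and the bootstrap resampler. Identical seeds
yield byte-identical cohorts, tables, and persisted models; the
command-line pipeline (`exec/mixri`) logs its seeds and writes the resolved
configuration next to each output.
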