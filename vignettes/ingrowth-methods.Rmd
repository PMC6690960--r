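---
title: "Ingrowth back-extrapolation and the free-daughter ratio: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ingrowth back-extrapolation and the free-daughter ratio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recoilfit)
```

## The measurement problem

Alpha emission imparts a 100–200 keV recoil to the daughter nucleus, which
breaks any chemical bond to a carrier. For Ac-225-based therapy this means
the daughters Fr-221, At-217 and Bi-213 escape the carrier in proportion
to the carrier geometry, and free Bi-213 (t½ = 45.6 min) accumulates
preferentially in the kidneys or is excreted in urine. The experimental
question is: at the moment an animal is sacrificed — when blood flow, and
with it inter-organ transport, stops — how much Bi-213 is in each organ,
and how much of that is carrier-bound versus redistributed?

A single gamma count cannot answer this, because a Bi-213 measurement made
minutes after excision already mixes the decaying sacrifice-time activity
with freshly ingrown daughter from the carrier-bound parent. The solution
is kinetic: count each organ repeatedly for many daughter half-lives and
decompose the curve.

## The two-amplitude ingrowth model

With the parent activity effectively constant over the counting session,
the daughter activity in an excised organ follows

$$A_2(t) = A_{eq}\,(1 - e^{-\lambda_2 t}) + A_0\, e^{-\lambda_2 t},$$

where $t$ is time since sacrifice, $\lambda_2 = \ln 2 / 45.6$ min$^{-1}$
is the Bi-213 decay constant, $A_0$ is the total Bi-213 activity at
sacrifice and $A_{eq}$ the equilibrium activity sustained by carrier-bound
Ac-225. Both amplitudes share whatever unit the counter reports (cpm or
efficiency-corrected activity); the analysis never needs the absolute
efficiency because its headline statistic,

$$\mathrm{ratio} = A_0 / A_{eq},$$

is scale-invariant. A ratio below 1 marks an organ releasing recoiled
daughters; above 1, one accumulating free Bi-213 delivered by the blood.
For organs with essentially no carrier signal ($A_{eq} \approx 0$, e.g.
blood or kidney after intratumoural injection) the ratio diverges and
`free_ratio()` refuses to report it; the back-extrapolated $A_0$ itself is
then the meaningful indicator.

### Fitting

Because $\lambda_2$ is a physical constant, the model is *linear* in
$(A_{eq}, A_0)$: `fit_ingrowth()` solves the normal equations exactly
rather than running an iterative optimiser, and the reported standard
errors and covariance come from the usual linear-model covariance scaled
by the residual variance. Consequences worth knowing:

* noise-free model-generated data are recovered to machine precision, and
  extrapolation to $t = 0$ is exact even when counting starts late;
* with unweighted least squares and Poisson counting noise the estimator
  is exactly unbiased (the noise is mean-zero in the linear model);
  optional `weighting = "poisson"` applies one inverse-expected-count
  reweighting pass for near-efficient errors at low counts;
* identifiability requires the design to separate the two basis functions
  $1 - e^{-\lambda_2 t}$ and $e^{-\lambda_2 t}$: a series confined to
  $t \gg 1/\lambda_2$ (or entirely at $t \approx 0$) triggers a
  conditioning error, and a span shorter than $2/\lambda_2$ a warning.

Under noise the fitted intercept can be negative; it is reported with a
warning rather than clipped, so that group averages stay unbiased.

### Parent constancy, and the exact chain solution

Holding $A_{eq}$ constant ignores the ~0.4% decay of Ac-225 over an 18 h
count. The package fits the constant-parent model by default — it is the
model under which the published ratios are defined — and exposes the exact
branched Bateman solution (`bateman_activities()`) as ground truth: the
two-member chain with the true Ac-225 decay constant converges to the
two-amplitude curve linearly in $\lambda_1$, with sub-percent discrepancy
at the real half-lives (the secular-equilibrium activity ratio is
$\lambda_2 / (\lambda_2 - \lambda_1) = 1.0032$, not exactly 1). Chains
with (near-)equal decay constants are handled by a 1-part-in-$10^9$
perturbation of the clashing constants instead of the confluent closed
form; the induced error is orders of magnitude below counting noise.
The default chain treats At-217 (sub-second) as instantaneous and omits
everything below Bi-213, which is the last measured member; explicit
members can be configured via the YAML nuclide table.

## Aggregation across animals

Published group ratios can be formed two ways that disagree under skewed
per-animal variation: the mean of per-animal ratios, or the ratio of
group-mean amplitudes (e.g. amplitudes 1.1 and 8.8 give 0.125 pooled
versus 0.14 as a per-animal mean). The package's default is the mean of
per-animal ratios — group uncertainties are defined as standard deviations
over mice, which only makes sense per-animal — while
`group_ratio_of_means()` provides the pooled alternative; the retention
pipeline reports both. Group contrasts use the closed-form t statistic
(`compare_groups()`): Welch by default, since the treatment groups are
independent animals, with `"student"` and `"paired"` modes available to
reproduce the published convention on equal-length groups.

## %ID/g and efficacy endpoints

Percent injected dose per gram is computed against an explicit counted
dose standard (a known fraction of the injected dose), with both counts
decay-correctable to a common reference using the parent decay constant —
equilibrium windows track Ac-225. Blood is treated as an organ sample by
mass, with no total-blood-volume extrapolation.

Tumour volumes use the ellipsoid formula $V = \pi W L H / 6$; relative
growth is normalised at a configurable baseline day; the doubling event is
the *first* measured day at which relative growth reaches 2, kept even if
the tumour later regresses. Time-to-event analysis uses the humane
endpoint (volume > 2000 mm³) at measurement-day granularity — no
interpolation between twice-weekly calipers — with other removals
censored. Kaplan–Meier curves and Mantel–Cox log-rank tests are delegated
to the `survival` package behind the package's interface, with all
pairwise group comparisons judged against a Bonferroni threshold
$\alpha/m$ over the $m = \binom{k}{2}$ comparisons.

## What the synthetic generator does and does not emulate

`simulate_cohort()` generates everything the pipelines consume. Its
defaults are the study conditions: three organs (blood ~1.5 g sample,
spleen 0.1 g, kidneys 0.4 g), 10-min counting cycles over 18 h, five
animals per intravenous group, carrier biodistributions matching the
published group means of the two formulations, and release fractions
chosen so the generated blood and spleen ratios equal the published ones
(blood 0.06/0.14, spleen 0.67/0.64). Free daughter is pooled and split
40% to kidneys, 30% to urine, 30% to the remaining carcass — the accepted
disposition of free Bi-213 — in a *single instantaneous* redistribution
step: no kinetic rates for free-daughter transport are available, so a
two-compartment kinetic model is deliberately out of scope. The urine and
carcass pools are tracked for exact activity conservation but emit no
counting series. Between-animal variation is lognormal (activities are
positive and right-skewed) with CV 0.2, the magnitude of the published
group standard deviations. Counting noise is Poisson on expected counts;
`counts_per_unit = Inf` is the exact noise-free mode used by the recovery
tests.

The tumour generator draws per-animal doubling times lognormally around
18 d (CV 0.5, matching the untreated 18 ± 9 d), grows volumes
exponentially from ~100 mm³ at treatment, lets a configurable fraction of
tumours switch to regression at a random time (spontaneous regression was
observed even untreated), measures calipers twice a week with 3% per-axis
noise, and censors at day 115.

What passing tests on these cohorts shows: the estimator chain — fit,
back-extrapolation, ratio, aggregation, survival machinery — is correct
and calibrated under the stated noise model. What it does not show:
biological fidelity of organ uptake beyond the emulated means, detector
dead-time or background drift, Fr-221 kinetics (too short-lived to have
been measured), or free-daughter transport kinetics.

## Problem sizes and numerical tolerances

Test and validation runs use the sizes a desk reproduction warrants:
exact-recovery checks on 100 random amplitude pairs (tolerance $10^{-9}$
relative), optimiser-oracle agreement on 20 noisy series ($10^{-6}$),
ODE-oracle agreement on random 2–5-member chains ($10^{-6}$ relative),
500 Poisson replicates at $\ge 10^4$ counts per point for the bias check
(<1%), 100 random redistribution configurations for conservation
($10^{-9}$), and 1000 null replicates of two 8-animal cohorts for log-rank
calibration (binomial 95% band around 0.05). The acceptance script runs
the noise-free blood-series reproduction, which is deterministic.

## Known limitations

* Absolute activities (Bq) require a detector efficiency the analysis
  never needs for ratios; %ID/g normalisation therefore goes through an
  explicit dose standard.
* The ratio's delta-method standard error is first-order; at very low
  equilibrium amplitudes the ratio distribution is heavy-tailed and the
  error estimate optimistic — the undefined-ratio guard exists for the
  limiting case.
* Per-organ fits are independent; no hierarchical sharing of information
  across organs or animals is attempted.
* Log-rank calibration at $n = 8$ per arm is adequate but not exact; the
  chi-square reference slightly overstates evidence in tiny samples, which
  the null-calibration test bounds empirically.
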