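# recoilfit

Quantifying the in-vivo redistribution of recoiling alpha-decay daughters
from serial gamma-counting data.

## The problem

In targeted alpha therapy with Ac-225 (t½ = 10 d), every alpha emission
ejects the daughter nuclide from its carrier with a recoil energy of
100–200 keV — far more than any chemical bond. The freed daughters
(Fr-221, At-217, Bi-213) redistribute through the body; free Bi-213
(t½ = 45.6 min) is kidney-avid, so daughter escape converts a tumour dose
into a renal one. Assessing carrier designs (vesicles, nanoparticles,
antibodies) therefore requires measuring *where the daughters are* at the
moment blood flow stops, separately from where the carrier is.

`recoilfit` implements the counting-based solution for preclinical
biodistribution studies. After an organ is excised, Bi-213 grows back into
secular equilibrium with its carrier-bound parent. Counting the organ
repeatedly for ~18 h and fitting

  A₂(t) = A_eq (1 − e^(−λ₂ t)) + A₀ e^(−λ₂ t)

(λ₂ fixed at ln 2 / 45.6 min⁻¹) separates two amplitudes:

* **A₀** — the back-extrapolated Bi-213 activity at sacrifice (t = 0):
  carrier-bound plus redistributed free daughter;
* **A_eq** — the asymptote: Bi-213 fed only by carrier-bound Ac-225, i.e.
  the carrier's own biodistribution.

The **free-daughter ratio** A₀/A_eq is the headline statistic: below 1 the
organ is releasing recoiled daughters (blood, carrier-rich spleen or
tumour); above 1 it is accumulating free Bi-213 (kidney). With λ₂ fixed
the model is linear in the amplitudes, so the fit is an exact weighted
linear least-squares solution with analytic standard errors, and the ratio
gets a delta-method uncertainty from the fit covariance.

Around this core the package provides a general Bateman decay-chain solver
(the simulation ground truth), %ID/g biodistribution tables and dose
standards, tumour-growth and Kaplan–Meier efficacy endpoints with
Bonferroni-corrected log-rank tests, a synthetic cohort generator
emulating the whole counting experiment, and two end-to-end pipelines
(`run_retention_pipeline()`, `run_efficacy_pipeline()`) plus a thin CLI
(`inst/cli/recoilfit.R`).

## Worked example

```r
library(recoilfit)

lam <- decay_constant(45.6)              # Bi-213, min^-1
t   <- seq(0, 1080, by = 10)             # 18 h of 10-min counting cycles

# a spleen-like organ: carrier-rich, releasing a third of its daughters
series <- simulate_counting_series(A_eq_true = 86, A0_true = 58,
                                   lambda2 = lam, schedule = t,
                                   counts_per_unit = 2000, seed = 1)
fit <- fit_ingrowth(series, lambda2 = lam)
summary(fit)
```

```
Daughter ingrowth fit (two-amplitude model)
  lambda2 = 0.0152006 (t1/2 = 45.6), n = 109, weighting = none
  A_eq (equilibrium) = 86.01 +/- 0.01793
  A0   (at t = 0)    = 58.04 +/- 0.09115
  residual RMS = 0.1739
  free-daughter ratio A0/A_eq = 0.6748 +/- 0.001092  [releasing]
```

The fit recovers the simulated truth (A_eq = 86, A₀ = 58): the organ holds
58 activity units of Bi-213 at sacrifice against 86 at equilibrium — a
ratio of 0.67, i.e. about a third of the locally produced daughter has
been released and carried away by the blood.

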