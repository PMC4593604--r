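---
title: "Statistical models for visual motor response assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical models for visual motor response assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vmrstats)
```

## The data and its structure

The visual motor response (VMR) of larval zebrafish is a startle-like burst
of locomotion triggered by an abrupt light onset (Light-On) or offset
(Light-Off). In a plate-based assay, up to 96 larvae are recorded at 30
frames/s while a light source below the plate switches On and Off in three
consecutive 30-minute trials after a long dark adaptation. Each animal's
movement is reduced to one number per second, the *Burst Duration*: the
fraction of that second's frames in which the animal was detected moving.
Values lie in [0, 1]; second $s$ covers the half-open frame interval
$[s-1, s)$, so the value at second 1 summarizes activity between the light
change (time 0) and one second later. A trailing second with fewer than
`fps` frames is dropped rather than rescaled, since a partial denominator
would change the statistic's support.

For analysis, a fixed window is cut around every light change: 30 seconds
before (relative seconds $-29 \dots 0$; 0 is the last pre-change second)
and 30 after (relative seconds $1 \dots 30$). Each retained (animal,
event) pair contributes one 30- or 60-dimensional activity vector. Animals
missing any second of a window are excluded from that event only
(complete-case per window); exclusion counts are reported. Light changes
are abrupt in this assay, so events must fall on integer second
boundaries; sub-second event times are rejected rather than interpolated.

## Two-sample profile comparison

Activity profiles are compared with the two-sample Hotelling $T^2$ test,

$$T^2 = \frac{n_1 n_2}{n_1+n_2}\,
 (\bar X^{(1)} - \bar X^{(2)})' S^{-1} (\bar X^{(1)} - \bar X^{(2)}),$$

with $S$ the pooled (df-weighted) sample covariance. Under the null,
$F = \frac{n_1+n_2-p-1}{p(n_1+n_2-2)} T^2 \sim F_{p,\,n_1+n_2-p-1}$. Unlike
a per-second $t$ test, this respects the strong temporal correlation of
Burst Duration and gives one familywise-coherent answer per window. For
$p=1$ the statistic is exactly the squared pooled-variance two-sample $t$.

Design choices worth knowing:

* **Pooled covariance only.** The model assumes a common covariance; no
  Behrens–Fisher variant is offered.
* **Singular $S$ is a hard error** naming zero-variance or collinear
  columns. An opt-in ridge ($S + \varepsilon I$) exists for exploration
  only — it changes the null distribution, so it is never applied
  silently.
* **FDR family = one battery invocation.** `pairwise_battery()` adjusts
  all its tests with Benjamini–Hochberg in a single family and reports raw
  p-values alongside; the choice is echoed in the output metadata.
* **Observation unit = (animal, event) vector.** Pooling biological and
  technical repeats raises effective $n$ but risks pseudoreplication
  (repeated measures of the same animals); the battery warns whenever
  several trials are pooled.

## Power and sample size

Power uses the noncentral-$F$ tail at the central-$F$ critical value with
noncentrality
$\tau^2 = \frac{n_1 n_2}{n_1+n_2} (\mu^{(1)}-\mu^{(2)})' \Sigma^{-1} (\mu^{(1)}-\mu^{(2)})$.
The noncentral-$F$ distribution function itself is evaluated with R's
`pf(..., ncp = )`; the test suite cross-checks it against an independent
Poisson-mixture-of-central-$F$-tails series on a grid, and the null case
(`ncp = 0`) is returned as `alpha` identically rather than through the
noncentral code path.

**Effect-size parametrization.** The effect size $\Delta$ of a power
request can be read two ways: as the Mahalanobis *distance*
$\sqrt{\delta'\Sigma^{-1}\delta}$ (so $\tau^2 = (n/2)\Delta^2$ for equal
groups) or as the *quadratic form* itself ($\tau^2 = (n/2)\Delta$). For a
2-second window at $\alpha = 0.05$ and target power 0.8, the distance
reading yields minimal group sizes 32, 41, 56 and 79 for
$\Delta = 0.8, 0.7, 0.6, 0.5$ — a mutually consistent grid that the
quadratic reading cannot produce; `vmrstats` therefore defaults to
`parametrization = "distance"`, keeps `"quadratic"` selectable, and pins
the four integers with a standing regression test against the independent
series oracle.

```{r power}
vapply(c(0.8, 0.7, 0.6, 0.5), min_sample_size, integer(1), p_dim = 2)
```

**Search strategy.** `min_sample_size()` scans integers upward from
$p+2$; each power evaluation is cheap, and a scan cannot skip the minimal
$n$ the way a bisection on a nearly flat power curve might.

**Scenario simulation.** `simulate_power_scenarios()` draws population
mean profiles elementwise from stated uniform bounds and needs an explicit
population covariance. In the motivating use that covariance was estimated
from experimental data; as a self-contained default the package ships
`ar1_covariance()` (AR(1), $\rho = 0.5$), clearly documented as a
synthetic stand-in, not an estimate from any dataset — scenario powers are
therefore reproducible only qualitatively, and the covariance is exposed
as configuration rather than guessed.

## MANOVA and effect-size dynamics

`manova_fit()` decomposes the model SSCP *sequentially* (Type I): the
hypothesis SSCP $H_k$ of term $k$ is the increment in fitted SSCP when the
term enters after terms $1 \dots k-1$, so $\sum_k H_k + E$ equals the
total centered SSCP exactly and term order is part of the model (it is
recorded in the output). Sequential SS keeps unbalanced data well-defined
without assuming balance, and makes the per-term shares interpretable as a
true variance partition. Each term is tested with the Pillai–Bartlett
trace $V = \mathrm{tr}[H(H+E)^{-1}]$ and its standard approximate $F$.
Numerically, the increments come from a single orthogonal (QR)
decomposition of the design matrix — not normal equations — which stays
stable with a 96-level well-location factor in the design; error df below
the response dimension is refused with advice to shorten the window or
reduce terms.

The default term order (`default_vmr_terms()`) is: well location,
biological repeat, strain, stage, technical repeat, light stimulus, then
interactions among the biological/treatment factors. Location and
biological repeat enter as main effects only: plate-position effects
(illumination non-uniformity across the plate) and collection-day effects
are taken as invariant across strains, stages, trials and stimuli. Users
can override the list; interactions must follow their main effects.

`dynamic_effect_timecourse()` runs the univariate analogue of the same
ordered model at every relative second and reports
$\eta^2 = SS_{\mathrm{effect}}/SS_{\mathrm{total}}$ per term — a
time-resolved picture of when each factor explains activity variance. On
and Off responses are never mixed in one fit. Because the same sequential
convention is used, the per-second $\eta^2$ values plus the residual share
sum to 1 exactly; a constant second (zero total SS) yields all-zero
$\eta^2$ with a warning rather than NaN.

## The synthetic generator

`generate_plate_experiment()` emulates the assay's statistical structure:
per animal and second a latent rate
$r = \mathrm{clamp}_{[0,1]}(b_{strain} m_{stage} + loc(well) + \beta_{bio}
+ \gamma_{trial} + u_a + kernel(t) + \epsilon_t)$, with $u_a$ an animal
random intercept and $\epsilon_t$ stationary AR(1). The stimulus response
is an exponential-decay-to-plateau kernel
($A e^{-k(t-1)} + s$ above baseline from relative second 1), separately
parameterized for On and Off; real response shapes are not published in
parametric form, so the kernel is a documented modeling choice with every
constant in the config. The default schedule is the real assay's (30 min
recorded dark, then 3 × 30 min On + 30 min Off at 30 fps); default effect
magnitudes are plausible for Burst-Duration-scale data (baselines
0.10–0.14, strong Off response peaking ~0.45 above baseline, weak repeat
effects) but are synthetic choices, not estimates. The location gradient
defaults to 0, with a radial center-bright option.

Two modes exist deliberately: **frame mode** draws per-frame Bernoulli
indicators (Burst Duration becomes Binomial(fps, r)/fps) and exercises the
summarization path end to end; **second mode** emits the latent rate
directly, giving exactly known $(\mu, \Sigma)$ for power validation —
there, clamping should be disabled (a warning reports the out-of-range
fraction) because truncation would distort the nominal moments. One root
seed with per-animal counter substreams makes output bitwise reproducible
and invariant to adding animals.

What passing tests on this generator do **not** show: real recordings have
habituation across trials, circadian drift, non-Gaussian burst/quiescence
dynamics, and boundary inflation at 0 — none of which are modeled. Results
on synthetic data validate the *statistical machinery* (calibration,
power, partitions), not biological conclusions.

## Numerical and testing choices

* Near-singular pooled covariances are detected via the symmetric
  eigenvalue condition number (threshold $100 \cdot$ machine epsilon).
* CSV writers emit doubles at 17 significant digits so write→read round
  trips are bit-exact; one dialect (comma, UTF-8, `.` decimal, header)
  with no sniffing.
* The optional frame-level burst-threshold filter common in acquisition
  systems is not applied by this package (its typical use leaves it off);
  inputs are taken as per-frame moved/not-moved calls.
* Test problem sizes: calibration studies use 2000 null replicates
  (p = 30, 50 animals per group) and 1000 replicates per power setting
  across $p \in \{2, 10, 30\}$, with agreement judged at 3 binomial
  standard errors; structural identities (partitions, reductions,
  oracles) are checked at $10^{-8}$–$10^{-10}$. The demo pipeline uses a
  reduced plate (4×6 wells, 2 stages, 40-s phases) — chosen sizes for a
  fast, reproducible example with the full factor structure.

## Known limitations

* No nonparametric or permutation profile tests; non-Gaussian activity
  distributions affect small-sample p-values.
* No mixed-effects / repeated-measures modeling: animals contributing
  several (animal, event) vectors are treated as independent, with a
  pseudoreplication warning rather than a correction.
* Power analysis assumes equal group sizes and a known covariance.
* Exact reproduction of any published MANOVA table depends on its term
  order and sums-of-squares type; this package fixes sequential (Type I)
  SS in the printed order and echoes that assumption in its output.
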