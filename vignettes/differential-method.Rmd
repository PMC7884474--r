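---
title: "Locating key points of hydraulic vulnerability curves with the differential method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating key points of hydraulic vulnerability curves with the differential method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hvcdm)
```

## The model

A hydraulic vulnerability curve (HVC) relates the fractional loss of xylem
hydraulic conductivity (LC) to the water-potential tension $\Psi$ a stem
experiences.  `hvcdm` models the HVC with the Weibull cumulative
distribution function

$$LC(\Psi) = 1 - \exp\!\left[-\left(\frac{\Psi}{a}\right)^{b}\right],$$

with scale $a > 0$ (MPa) and dimensionless shape $b > 0$.  One convention
is stated once and enforced everywhere: **water potentials are positive
tension magnitudes in MPa**.  Field instruments report negative potentials;
users take the absolute value before entry, and negative inputs are
rejected rather than silently negated.

Three biologically meaningful key points sit on this curve:

* the **air-entry point** $\Psi_e$, where cavitation begins and LC starts
  rising appreciably;
* the **fastest-drop point** $\Psi_m$, the steepest part of the curve,
  commonly used as an index of embolism resistance;
* the **lethal point** $\Psi_l$, beyond which a plant cannot recover after
  rewatering.

The *differential method* (DM) defines these geometrically: $\Psi_m$ is the
inflection of the curve (root of $y''$), and $\Psi_e$, $\Psi_l$ are the
lower and upper turning points (roots of $y'''$).  For the Weibull CDF all
three have closed forms.  Writing $u = (\Psi/a)^b$, the third derivative is
proportional to a quadratic in $u$, so

$$\Psi_m = a\left(\frac{b-1}{b}\right)^{1/b},\qquad
  \Psi_{e,l} = a\left(\frac{3(b-1) \mp \sqrt{(b-1)(5b-1)}}{2b}\right)^{1/b}.$$

The *traditional method* (TM) instead reads tensions at fixed loss
quantiles, $\Psi_p = a(-\ln(1-p))^{1/b}$ at $p = 0.12, 0.50, 0.88$.

```{r}
p <- weibull_params(a = 2.23, b = 2.50)
dm_key_points(p)
tm_points(p)
```

At these parameters every TM reading exceeds its DM counterpart, the
quantitative form of the claim that quantile readings overestimate the true
geometric key points.  This ordering is asserted **only at these
parameters**: it is not universal in $b$ (for large shapes the LC at the
lower turning point exceeds 0.12 and the comparison reverses), so the
package makes no global claim.

### Domain of validity

The closed forms impose conditions the model statement leaves implicit:

* $b \le 1$: the curve has no interior inflection; `dm_key_points()`
  errors.
* $1 < b \le 2$: the lower root of the quadratic in $u$ is non-positive,
  so no air-entry point exists; `psi_e`/`lc_e` are returned as an explicit
  `NA`, never a silent zero or NaN.
* $b > 2$: all three points exist and satisfy
  $0 < \Psi_e < \Psi_m < \Psi_l$.

The four-period classification (stationary, accelerated decline,
decelerated decline, platform) partitions $\Psi \ge 0$ by half-open
intervals $[0,\Psi_e)$, $[\Psi_e,\Psi_m)$, $[\Psi_m,\Psi_l)$,
$[\Psi_l,\infty)$; a tension equal to a key point belongs to the higher
period.  It therefore requires $b > 2$.

The model's tension axis is unbounded; the experimental air-injection
schedule spans 0–6 MPa, but that range is treated as a property of the
measurement design, not a hard model domain.

### The numeric cross-check

`numeric_key_points()` recomputes all three points by bracketed
root-finding (`uniroot`) on the analytic second and third derivatives,
scanning a 4096-point log-spaced grid over $(0, \Psi_{\max}]$ with
$\Psi_{\max} = 2\,\Psi_{0.9999}$ — an upper bracket adapted to the
parameters rather than a fixed window, since all derivative roots lie well
inside it.  The test suite demands agreement with the closed forms below
$10^{-8}$ MPa over a 20-point $(a, b)$ grid; disagreement, or a missing
sign change where one is expected, signals a derivative bug and is raised
as an internal error rather than patched over.

## Fitting

`fit_weibull()` estimates $(a, b)$ by unweighted nonlinear least squares on
LC, using the Levenberg–Marquardt implementation in `minpack.lm` under
positivity bounds, with relative tolerance $10^{-10}$ and at most 200
iterations — a cheap, smooth 2-parameter problem.  Starting values come
from the exact linearisation $\log(-\log(1-LC)) = b\log\Psi - b\log a$
fitted by ordinary least squares; observations at $LC \in \{0, 1\}$ or
$\Psi = 0$ are singular under the transform and are excluded from the
*guess* while remaining in the nonlinear objective (a fully embolised
point is informative).

Observations are pooled across samples by default, matching a curve built
from several stems measured on a shared pressure schedule;
`by_sample = TRUE` fits each stem separately and summarises the parameter
spread (mean, SE).  No weighting is applied because the LC error model is
unknown.

`bootstrap_ci()` attaches percentile confidence intervals by
case-resampling — chosen over residual resampling because LC noise is
heteroscedastic near the 0 and 1 boundaries.  Resamples that cannot
support a 2-parameter fit (fewer than 3 usable points, fewer than 2
distinct tensions, or optimiser failure) are redrawn and counted.  Every
stochastic routine in the package takes a single integer seed and is
bit-reproducible from it.

The model's coefficient of determination is reported as
$R^2 = 1 - SS_{res}/SS_{tot}$ on LC.  No p-value is attached to it: the
test behind such a value is not well defined for this fit and is not
reproduced.

## Raw-measurement computations

Stem-specific conductivity is $K_s = L(m/t)/(Ap)$
(kg m⁻¹ s⁻¹ MPa⁻¹), and loss of conductivity is
$LC = (K_m - K_s)/K_m$ against the flushed maximum $K_m$.  When geometry
and driving head are constant across an injection series this reduces to
the time ratio $LC_i = 1 - T/t_i$, an algebraic identity the test suite
verifies exactly.  Negative LC values (conductance above the flushed
maximum) are *flagged, never clamped*: they indicate a measurement anomaly
and quality control belongs to the user.

The water balance couples the curve to whole-plant state:
$WG = K_m\,\Delta\Psi\,A\,(1-LC)/L$ and $WL = E \times LA$.  As printed,
the loss formula multiplies a molar flux (mol m⁻² s⁻¹) by an area and is
labelled in kg s⁻¹; the package's default resolves the unit mismatch by
multiplying by the molar mass of water, 0.018015 kg mol⁻¹, and
`convert_to_kg = FALSE` preserves the literal product.  The net balance is
$WG - WL$.  A 30 cm hydraulic head corresponds to
`head_to_pressure(0.30)` = `r head_to_pressure(0.30)` MPa
($\rho = 1000$ kg m⁻³, $g = 9.81$ m s⁻²).

## Validation statistics

Whether a *calculated* key point represents an *experimental* group is
tested with a one-sample t test; equality claims default to two-sided
because the original comparisons do not state a direction.  A
zero-variance sample equal to the point is reported as $p = 1$ by
convention.  The bracketing ("squeeze") argument — a key point lies
strictly between a group below it and a group above it — is formalised as
two one-sided one-sample tests, both required significant at
$\alpha = 0.05$ (the package-wide default level):

```{r}
kp <- dm_key_points(p)
lower <- generate_group_samples(2.73, sd = 0.03, n = 10, seed = 1)
upper <- generate_group_samples(2.93, sd = 0.03, n = 10, seed = 2)
bracket_test(lower, upper, kp$psi_l)
```

`method_comparison_report()` runs the same test for DM and TM points
against matched groups and labels each method consistent,
overestimating, or underestimating.  Routine multi-group machinery
(ANOVA, post-hoc multiple comparisons, the auxiliary linear regressions)
is deliberately out of scope — base R provides it directly.

## What the synthetic generators emulate

The generators produce every input the pipeline needs, with no downloads:

* `default_pressure_schedule()` — the 24-level air-injection design
  (0–4 MPa in 0.2 MPa steps, then 4.5, 5, 6 MPa) on which vulnerability
  curves are built;
* `generate_vc_observations()` — per-stem LC readings on that schedule
  with additive Gaussian noise censored to $[0, 1]$;
* `generate_injection_series()` — raw conductance-time series obtained by
  inverting the time-ratio identity, with LC capped at $1 - 10^{-4}$ so
  times stay finite (capping is reported);
* `generate_group_samples()` — Gaussian groups of $n = 10$ measurements
  around a centre, emulating the per-treatment mean ± SE data used for
  validation; defaults in examples use 2.73 and 2.93 MPa, the observed
  range bracketing the lethal point.

Defaults are the study conditions: 10 samples per curve, LC noise SD 0.02
(a visually tight curve with $R^2 \approx 0.997$, consistent with the
near-perfect fits such schedules produce), group SD 0.03 MPa.  The noise
model is a deliberate simplification: real LC errors are heteroscedastic,
autocorrelated along a pressure series, and bounded by construction rather
than by censoring, and between-stem variation is not separately modelled.
Passing tests therefore demonstrate correctness of the *computations*
and estimator behaviour under a clean error model — not robustness to
every pathology of field data.

## Numerical choices and degenerate inputs

* Root-finding tolerance $10^{-12}$ on tension; closed-form/oracle
  agreement required below $10^{-8}$ MPa.
* Quantile inversion uses `log1p`/`expm1` to stay accurate near both LC
  boundaries; the round trip holds to $10^{-10}$.
* Degenerate fits fail loudly: all-zero LC ("curve degenerate"), fewer
  than 3 observations, fewer than 2 distinct tensions, non-increasing
  linearised data.
* Human-readable printing rounds to 2 decimals, matching how such key
  points are conventionally reported; all machine output (JSON reports)
  carries full precision.
* Report JSON carries a versioned schema; readers reject other major
  versions.  Timestamps are excluded from determinism guarantees.

Test problem sizes are the package's own choices balancing statistical
power against a fast default run: 100–500 replicate fits for parameter
recovery (median relative error below 2% at noise SD 0.02), 300–1000
seeded replicates for bracketing power (above 99%), and 40 outer
replicates × 200 resamples for bootstrap coverage (observed coverage above
0.8 at nominal 0.95).

## Known limitations

* Only the Weibull CDF is implemented; alternative sigmoidal/exponential
  vulnerability models are out of scope, as is plotting.
* The DM/TM ordering shown above is parameter-specific; no universal
  ordering exists across shapes.
* Published summary figures that depend on unpublished raw measurements
  (the original fit's $R^2$, its conductivity range, and the absolute
  water-balance values) cannot be recomputed from first principles; the
  suite instead verifies the algebraic identities and stochastic contracts
  underlying them.
* Foliar water uptake and stem evaporation are neglected in the water
  balance, and the generators do not simulate soil drying or recovery
  dynamics.
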