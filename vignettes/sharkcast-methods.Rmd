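---
title: "Methods: projecting shark-bite incidence and bites averted by electronic deterrents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: projecting shark-bite incidence and bites averted by electronic deterrents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sharkcast)
```

## The problem

Shark bites on people are rare events — in Australia the long-run average is
on the order of ten recorded incidents per year against a population in the
tens of millions — yet each event carries large personal, social and economic
costs. Personal electronic deterrents, which emit an electric field around
the wearer, are the one class of personal mitigation with field evidence of a
substantial reduction (roughly 60%) in the probability of a bite. `sharkcast`
asks the resulting planning question: *if some proportion of water users wore
such a device over the coming half-century, how many people would avoid being
bitten?*

Answering it requires four pieces, each a module of this package:

1. **Rate construction** (`read_incidents()` through `rms_scale()`): convert
   registry-style incident records and yearly population series into
   dimensionless, per-capita bite-rate series.
2. **Trend characterization** (`rank_models()`, `acf_pacf()`,
   `smoothed_periodogram()`): establish that the century-scale series carries
   structure beyond a flat or monotone trend.
3. **Projection** (`fit_sinusoid()`, `build_residual_sampler()`,
   `project_ensemble()`): fit a multidecadal sinusoid and propagate the
   empirical residual distribution forward to 2066.
4. **Intervention scenarios** (`averted_matrix()`, `reporting_proportion()`,
   `adjust_series_for_abundance()`): convert projected bites into bites
   averted under deterrent uptake, and stress the answer against
   under-reporting and shark-abundance assumptions.

Because the national shark-attack registry is not publicly deposited, the
package ships a synthetic-data generator whose defaults emulate that
registry's published summary composition; every stage is validated against
the generator's known ground truth.

## Rate construction

Incident records carry `year`, `region` (NSW, QLD, WA, SA, VIC, TAS, NT, or
`UNK` for unknown state), `species` (`white`, `tiger`, `bull`, `whaler`,
`other`, `unknown`), and logical `fatal` / `provoked` flags. Records are
subset by the five presets of `filter_presets()`: all incidents, fatalities
only, unprovoked only, white sharks only, or the three species responsible
for most bites (white, tiger, bull). Free-text species labels are mapped
through a small alias table (bronze whaler and dusky sharks are recorded as
`whaler`); bull and whaler are merged only inside the abundance scenarios,
never in the core filters.

The fitting window defaults to **1900–2019 inclusive** (n = 120 years):
the record is too sparse before 1900 for credible model fits, 2019 is the
last complete year before the projection window opens in 2020, and
population projections extend to 2066, which fixes the projection horizon.
The national series (`AUS`) is always computed by aggregating incidents —
never by summing state-level rates — and records with unknown state count
toward the national series only.

Counts become rates by elementwise division by the region-year population
(bites person⁻¹ year⁻¹), and rates are made dimensionless by dividing by
their root mean square with the n−1 denominator,

$$s = \sqrt{\frac{\sum_t r_t^2}{n-1}},$$

the divisor used by `scale(x, center = FALSE)`. The divisor is stored on the
series so `unscale()` inverts the transform exactly (round-trip error below
10⁻¹² relative); the same stored factor converts projected scaled rates back
into people bitten. The denominator is configurable (`"n"` available) but
the n−1 convention is the default throughout.

## Trend models and diagnostics

Four nested polynomial trend models — intercept-only, linear, quadratic,
cubic — are fitted to the scaled series by Gamma maximum likelihood with an
**identity** link, and ranked by the sample-size-corrected Akaike
information criterion,

$$\mathrm{AICc} = -2\,\mathrm{LL} + 2k + \frac{2k(k+1)}{n-k-1},$$

with Akaike weights computed through the shifted exponential form for
numerical stability. Goodness of fit is the percentage of deviance explained,
$\%\mathrm{DE} = 100\,(D_0 - D)/D_0$, defined as 0 for the null model.

Numerical choices that matter here:

* **Zero handling.** The Gamma likelihood needs a strictly positive
  response; years with zero bites are replaced by half the smallest positive
  scaled value in the series (default), which preserves n and the series
  shape. Dropping zeros is available (`zero_policy = "drop"`).
* **Covariate conditioning.** The year covariate is centred and scaled to
  unit variance before polynomial expansion — raw calendar years cubed are
  of order 10¹⁰ and destroy the conditioning of the fit. Coefficients are
  reported in both the transformed and the raw calendar-year basis.
* **Likelihood convention.** The Gamma shape parameter is profiled out
  numerically (maximized given the fitted means) and is *not* counted in
  `k`; `k = degree + 1` counts regression coefficients only. Published
  model-ranking tables for such fits depend on how the source software
  counts the dispersion parameter, so cross-software agreement of absolute
  AICc values is not expected — rankings and weights are.
* **Identity-link feasibility.** Iteratively reweighted least squares can
  step outside the positive-mean region; the fitter falls back to direct
  deviance minimization with a feasibility barrier, and reports a classed
  fit error if no positive-mean solution exists. The degree-0 fit returns
  the sample mean exactly (the identity-link null-model property), which the
  tests assert.

Supporting diagnostics mirror standard time-series practice: demeaned
autocorrelations, partial autocorrelations via the Durbin–Levinson recursion
(`stats::pacf`), an FFT periodogram smoothed with modified Daniell kernels
(default spans `c(3, 3)`), and a centred 5-year running mean (odd window,
shrinking endpoints) for climate-index comparators such as the Southern
Oscillation Index. Periodogram ordinates follow the classical convention
$I(f_j) = |\mathrm{DFT}|^2/n$; the reported `density` column is $2I(f_j)$,
whose Riemann sum over the frequency grid recovers the series' mean square
about its mean (exactly so for odd n, up to the Nyquist-term convention for
even n). Wavelet coherence against climate indices is outside this package's
scope; the periodogram/ACF suite is the periodicity diagnostic provided.

## The sinusoid and stochastic projection

Extending the quadratic or cubic trends forward would send projected rates
upward without bound, so the projection model is the bounded periodic form

$$y = \alpha + \beta\cos(\gamma x + \delta),$$

with $x$ the years since the series origin, $\alpha$ the level, $\beta \ge 0$
the amplitude, $\gamma > 0$ the angular frequency (radians year⁻¹) and
$\delta \in [0, 2\pi)$ the phase. For fixed $\gamma$ the model is linear in
$(\alpha, \beta\cos\delta, -\beta\sin\delta)$, so the fitter profiles the
linear parameters over a dense log-spaced frequency grid (240 candidate
periods between 4 years and five series lengths, augmented with the three
dominant raw-periodogram frequencies), then polishes the best six candidates
with Levenberg–Marquardt. This initialization matters: with only ~1.2 cycles
of a centennial oscillation observed in 120 years, naive single-start
optimization routinely locks onto harmonics. Negative-amplitude and
negative-frequency solutions are normalized by the identities
$-\beta\cos(\theta) = \beta\cos(\theta + \pi)$ and
$\cos(-\gamma x + \delta) = \cos(\gamma x - \delta)$. Five observations is
the hard minimum (four parameters); a perfect fit (all residuals zero) is
reported as a degenerate input rather than silently building an empty
residual model.

Uncertainty is propagated by resampling the fit's own residuals:

* Residuals are split into **positive and negative pools** (each must hold
  at least 2 members); exact zeros alternate between the pools in year
  order.
* Each pool gets a Gaussian KDE with **Sheather–Jones** bandwidth
  (`bw.SJ`; Silverman's rule is the fallback for pools too sparse for the
  solve-the-equation estimate), and each observed residual receives a
  resampling weight proportional to the KDE density evaluated at itself.
  Resampling therefore draws the *observed* residuals, concentrated where
  the estimated density is high; the smoothed-bootstrap alternative
  (jittering each draw with the pool's kernel, i.e. sampling the KDE
  itself) is available via `resample = "kde_smooth"`.
* Residual **magnitude varies over the cycle**: in the observed series the
  spread is smaller in bite-rate troughs and larger near peaks. This is
  encoded by regressing |residual| on the sinusoid level at the residual's
  year (one regression per pool) and scaling each projected draw by
  `max(0.1, predicted |r| / mean predicted |r|)`. The 0.1 floor prevents
  degenerate or sign-flipping multipliers when the regression extrapolates
  below zero. The linear-in-level form is one defensible reading of a
  "linear relationship with the period of the sinusoid"; the coefficients
  are stored so alternatives can be swapped in.
* Each projected iteration-year draws a pool by a fair coin
  (`sign_prob = 0.5`), a residual from that pool by its weights, scales it,
  adds it to the sinusoid median, and **floors the sum at zero** — a
  per-capita rate cannot be negative. Draws are independent across years
  within an iteration.

The default ensemble is 10 000 iterations over 2020–2066, fully determined
by an integer seed (R's Mersenne–Twister via `set.seed()`; every stage seed
is recorded in the run manifest). Back-transforming multiplies by the stored
RMS factor and the projected population; counts stay continuous until public
summaries, which round half away from zero (so an interval computed as
92.5–1060.5 people is reported as 93–1061).

## Deterrent scenarios

Deterrent effectiveness is a Beta-distributed reduction in bite probability
centred on 0.60 with standard deviation 0.05, moment-matched to shapes

$$\nu = \frac{\mu(1-\mu)}{\sigma^2} - 1,\quad a = \mu\nu,\ b = (1-\mu)\nu
\;\Rightarrow\; (a, b) = (57, 38).$$

An independent effectiveness is drawn per iteration-year (per-iteration
draws are available as an option). The averted-bite array is

$$\mathrm{averted}_{i,t,p} = \mathrm{bites}_{i,t} \times
\mathrm{effectiveness}_{i,t} \times p$$

over the uptake grid $p \in \{0.1, \dots, 0.9, 1.0\}$ — full uptake is
included because headline summaries quote the all-users case. Within an
iteration the averted count is exactly linear in $p$, which is why halving a
full-uptake interval reproduces the 50%-uptake interval. Cumulative totals
over 2020–2066 are computed **per iteration first** (sum over years, then
quantiles across iterations): the quantity of interest is the uncertainty of
the *total*, and quantiles of sums are not sums of quantiles — the tests
demonstrate the difference on a 3 × 3 toy ensemble.

## Under-reporting sensitivity

Early-twentieth-century incidents were plausibly under-recorded. Two
hypothetical reporting curves express this: scenario A (about 60% of
incidents recorded in 1900, rising through the 1950s television era,
asymptoting to full reporting by the 1990s; γ = 0.602, α = −1601.064,
β = 211.348) and scenario B (40% floor, asymptoting during the 2000s;
γ = 0.394, α = −1381.997, β = 182.430).

The orientation of the sigmoid deserves a note. Written literally as
$y = 1 - \gamma/(1 + e^{-\alpha - \beta\log x})$ with the parameter values
above, the curve *decreases* from ≈1.0 in 1900 to ≈1−γ, contradicting every
described property of the scenarios. The adopted form,

$$\mathrm{reporting}(x) = \gamma + (1-\gamma)\,
\sigma(\alpha + \beta\ln x),$$

with $\sigma$ the standard logistic and the natural log of the calendar
year, reproduces all of them with the same parameter values: scenario A
gives 0.604 at 1900, its midpoint at $x = e^{-\alpha/\beta} \approx 1950$,
and 0.995 by 1990; scenario B gives 0.399 at 1900 and exceeds 0.99 during
the 2000s. The natural log is pinned by the midpoint: $\alpha/\beta =
-7.5755 = -\ln 1949.6$ only under base e. Both forms are available
(`form = "adopted"` / `"literal"`); the adopted orientation is the default
and the package's own interpretation, not an assertion about any other
implementation. Correction divides observed values by the reporting
proportion at their year, after which the corrected series re-enters the
standard scaling/fit/projection path; thinning synthetic data by a curve and
correcting by the same curve recovers expected counts within Monte-Carlo
error (an inverse-pair property the tests check).

## Relative-abundance scenarios

Where relative shark abundance $N_{\mathrm{rel}}$ (scaled to a maximum of 1)
changes over time, the bite rate responds as the power law

$$r_b = N_{\mathrm{rel}}^{0.4307},$$

the exponent being $\ln 2/\ln 5$ to four decimals — a fivefold change in
abundance doubles (or halves) the bite rate. For species-resolved scenarios
(white, tiger, bull/whaler — the latter merged because many bites attributed
to whalers are likely bull sharks), each species' scaled bite-rate series is
regressed on its $N_{\mathrm{rel}}$ trajectory with a Gamma log-link GLM and
rescaled **multiplicatively** by the fitted abundance response
$e^{b_1 N_{\mathrm{rel}}}$, normalized to a maximum of 1. The rescaled
species series are summed, the sum is expressed as a proportion of its own
maximum, and that proportional series multiplies the region's total scaled
series before refitting and reprojection. Additive adjustment was the
alternative reading; multiplicative was chosen because the downstream series
must stay non-negative and the species series are themselves ratio-scaled.
A constant trajectory carries no abundance signal, so its slope is pinned to
zero rather than left unidentifiable. Autocorrelation in these short species
series biases the GLM standard errors; the coefficients are used only as a
rescaling device, never for inference.

## The synthetic-data generator

`synthetic_region_config()` defines a region's ground truth: a non-negative
sinusoidal scaled rate ($\alpha \ge \beta \ge 0$), a `rate_scale` factor
playing the role of the stored RMS divisor, a deterministic
compound-growth population trajectory, and the categorical composition of
records. Defaults mirror the published summary of the century-scale
Australian record: 20% of incidents fatal, 65% unprovoked, species shares
31% white / 21% tiger / 14% bull / 6% whaler, remainder split between other
identified species (19%) and unattributed records (9%). Counts are Poisson
around the truth (`mode = "poisson"`) — the natural rare-event model, since
the procedure being emulated works purely with residuals and is silent on a
generative law — or deterministic rounded expectations
(`mode = "expected"`) for exact-recovery tests.

`default_synthetic_country()` is the bundled four-region world: three
data-rich states (NSW, QLD, WA) plus one sparse state (SA, ~70 incidents in
120 years, deliberately below the 100-incident projection threshold so the
skip path is exercised), all sharing a 100-year period with distinct phases
and amplitudes. Base populations (1.4 M / 0.5 M / 0.19 M / 0.36 M in 1900)
and growth rates (1.3–2.2% year⁻¹) give a 2019 national population around
25 M, and the rate scales are set so the national record holds roughly 985
incidents over 1900–2019 — the density of the registry being emulated.

What the generator does *not* emulate — and therefore what passing tests do
not establish about real data: reporting effort that drifts with media
technology (available only as an explicit thinning scenario, never implicit);
dependence between species and severity (a white-shark bite is more likely
fatal in reality; flags are independent by default and the dependence switch
is off); within-year timing, location, and victim activity; species
misattribution; and any climate forcing beyond the deterministic sinusoid
itself. Recovery of the sinusoid from synthetic data shows the estimator is
consistent under the model's own assumptions, not that the Australian series
is truly periodic.

## Problem sizes and reproducibility

The test suite and the acceptance script use the study-scale configuration
throughout: 120-year fitting windows, 47-year projections, 10 000-iteration
ensembles for headline runs, 2 000 iterations for the 20-replicate coverage
study, 100 replicates for period-recovery statistics and 200 for
model-ranking recovery — sizes at which every Monte-Carlo tolerance asserted
is justified by its standard error. All stochastic stages require an explicit
seed; run manifests record the master seed, per-stage seeds, and MD5
checksums of every numeric artifact, and identical configurations reproduce
byte-identical artifacts.

## Known limitations

* The projection assumes the fitted sinusoid's period, phase and amplitude
  persist to 2066; with only ~1.2 observed cycles this is a hypothesis, not
  an estimate with meaningful period uncertainty.
* Residual resampling treats iteration-years as independent given the pools;
  serially correlated shocks (bite clusters) widen true uncertainty beyond
  the ensemble band.
* Deterrent effectiveness is treated as exchangeable across species, years
  and wearers; field estimates come from baited trials on motivated sharks.
* The averted calculation scales linearly in uptake, ignoring possible
  group-protection effects among water users.
* Economic costs, geocoding and wavelet-coherence climate attribution are
  out of scope.
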