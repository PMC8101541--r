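# sharkcast

Modelling long-term per-capita shark-bite incidence and projecting how many
people could avoid being bitten if water users wore personal electronic
deterrents.

Shark bites are rare — of the order of ten recorded incidents per year in
Australia against a population of tens of millions — but each carries severe
personal and economic costs, and electronic deterrents are the one class of
personal mitigation with field evidence of a substantial (~60%) reduction in
bite probability. `sharkcast` turns a century-scale incident registry and
population projections into an answer to the planning question: *how many
bites would be averted, by when, at what deterrent uptake?*

The pipeline, stage by stage:

1. **Per-capita scaled rates.** Incident records (year, region, species,
   fatal/provoked flags) are filtered (all / fatal-only / unprovoked-only /
   white-only / white+tiger+bull), tallied into yearly counts, divided by the
   region's population, and made dimensionless by dividing by the series'
   root mean square *s* = √(Σr²/(n−1)); the stored divisor makes the
   transform exactly invertible.
2. **Trend ranking.** Four nested polynomial models (intercept, linear,
   quadratic, cubic) are fitted by Gamma maximum likelihood with an identity
   link and ranked by AICc = −2LL + 2k + 2k(k+1)/(n−k−1), with Akaike
   weights and percentage of deviance explained; ACF/PACF and a smoothed FFT
   periodogram provide periodicity diagnostics.
3. **Sinusoidal projection.** Because polynomial trends explode when
   extrapolated, the projection model is *y* = α + βcos(γx + δ). Residuals
   from the fit are split into positive/negative pools, each pool gets a
   Sheather–Jones-bandwidth KDE, and 10 000 future trajectories to 2066 are
   generated by coin-flipping a pool, drawing observed residuals with
   KDE-density weights, scaling their magnitude with the sinusoid's cycle,
   and adding them to the median prediction. Back-transforming by the stored
   RMS factor and projected population yields people bitten per year.
4. **Averted bites.** Effectiveness is Beta(57, 38) (mean 0.60, sd 0.05,
   moment-matched); averted_{i,t,p} = bites_{i,t} × effectiveness_{i,t} × p
   over an uptake grid p = 0.1 … 1.0. Cumulative 2020–2066 totals are
   summed per iteration before taking quantiles. Sensitivity analyses cover
   historical under-reporting (sigmoidal reporting curves rising from 60% or
   40% in 1900 to full reporting) and changing relative shark abundance
   (bite rate ∝ N_rel^0.4307, so fivefold abundance change doubles or halves
   the rate).

The national registry this is designed for is not publicly deposited, so the
package includes a first-class synthetic-data generator
(`default_synthetic_country()`) whose defaults emulate the registry's
published composition (≈985 incidents 1900–2019; 20% fatal, 65% unprovoked;
31/21/14/6% white/tiger/bull/whaler) around a known 100-year sinusoidal
truth, giving every stage a ground truth to validate against.

## Worked example

```r
library(sharkcast)

cfgs <- default_synthetic_country()
sim  <- generate_country(cfgs, 1900:2019, seed = 42, pop_years = 1900:2066)
cfg  <- pipeline_config(incidents = sim$records, population = sim$populations,
                        out_dir = "run", n_iter = 10000, seed = 42)
run  <- run_pipeline(cfg)

print(run$results$AUS$ranking)
print(run$results$AUS$sinusoid)
cum <- run$results$AUS$averted$cumulative
print(round(cum[cum$uptake %in% c(0.5, 1.0), ], 1), row.names = FALSE)
```

```
Gamma identity-link trend-model ranking
        model degree      LL k    AICc  dAICc    wAICc pctDE
1 ~yr+yr2+yr3      3 -37.761 4  83.870  0.000 1.00e+00  29.2
2     ~yr+yr2      2 -51.488 3 109.183 25.314 3.19e-06  11.6
3         ~yr      1 -56.099 2 116.300 32.431 9.07e-08   4.8
4          ~1      0 -59.163 1 120.361 36.491 1.19e-08   0.0
sinusoid fit: alpha=0.8848 beta=0.3410 period=101.3 yr delta=4.478 rad (SSE 15.46, n=120)
 uptake   mean median  lo95   hi95
    0.5  502.6  502.5 458.6  546.4
    1.0 1005.1 1004.9 917.1 1092.8
```

Reading the output: on this synthetic country (998 incidents, seed 42) the
cubic trend dominates the AICc ranking (wAICc ≈ 1, 29.2% of deviance
explained) — the short-term signature of an underlying oscillation — and the
fitted sinusoid recovers the generator's 100-year period (101.3 years). If
every water user wore an electronic deterrent, a mean of about 1005 bites
(95% interval 917–1093) would be averted nationally over 2020–2066; at 50%
uptake the numbers halve exactly, reflecting the linear uptake model. Per
region and per year, `run$results[[region]]$averted$summary` holds the
median and 95% band, and `write_report(run)` renders the projection band,
averted-by-uptake and year × uptake surface figures with seed-bearing
captions.

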