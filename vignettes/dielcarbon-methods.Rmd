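---
title: "Stream metabolism and CO2 evasion from diel sensor series: models and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stream metabolism and CO2 evasion from diel sensor series: models and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dielcarbon)
```

`dielcarbon` implements the inference chain that links continuous dissolved
O2 and CO2 records in running waters to daily metabolic rates and CO2
evasion: gas-exchange physics, night-time regression estimation of the gas
exchange coefficient, a Bayesian diel oxygen model, day-level quality
control, CO2 flux and diel metrics, and reach-scale mass balance. This
vignette is the package's own account of the models, their assumptions, and
the conventions we adopted where the methodology left choices open.

## The diel oxygen model

Dissolved O2 in a well-mixed stream reach integrates three processes:
photosynthetic production, respiratory consumption, and exchange with the
atmosphere. The model steps the concentration (g O2 m^-3) forward in time:

$$
O_{2,t} = O_{2,t-1}
 + \frac{\mathrm{GPP}}{z}\,\frac{\mathrm{PAR}_{t-1}}{\sum_t \mathrm{PAR}_t}
 + \frac{\mathrm{ER}\,\Delta t}{z}
 + K_{O_2}\,(O_{2,\mathrm{sat},t-1} - O_{2,t-1})\,\Delta t
$$

with daily gross primary production GPP (distributed over time steps in
proportion to PAR), daily ecosystem respiration ER (uniform in time, stored
negative), gas exchange coefficient $K_{O_2}$ (day^-1), mean depth $z$ (m)
and time step $\Delta t$ (days; 10-minute data give $\Delta t = 1/144$).
The first observation anchors the trajectory; because the recursion is
linear in O2 it is evaluated with a recursive filter, which makes the
sampler fast in plain R. The model assumes rates and depth constant within
a day, a well-mixed channel, and negligible groundwater O2 input -- the
same assumptions that motivate the quality filters below.

Saturation O2 comes from the Garcia-Gordon polynomial fit to the
Benson-Krause solubility data (the convention of the open-channel
metabolism literature; the methodology we follow names no formula),
pressure-corrected with the site's barometric pressure, which in turn is
transferred from a reference station through the isothermal barometric
formula with scale height 8434 m. Dissolved CO2 concentrations use the
Weiss freshwater solubility function of temperature. Since the published
workflow states only "Henry's law" and no O2-saturation formula, values
that depend on these formulations should be compared across
implementations only at the percent level.

## Priors, sampler and numerical choices

Each day is fitted by component-wise Gaussian random-walk Metropolis over
four parameters: GPP, ER, $K_{O_2}$ and the observation-error SD
$\sigma$. Priors:

* GPP $\sim N(1, 2)$ and ER $\sim N(-5, 2)$ g O2 m^-2 day^-1 -- weakly
  informative values appropriate for oligotrophic high-latitude streams;
* $K_{O_2}$ $\sim N(\mu_K, \sigma_K)$ with $\mu_K, \sigma_K$ taken from
  the site's fitted K600-discharge relation at the day's discharge
  (Schmidt-scaled to O2 at the day's mean temperature). This informed
  prior is the guard against *equifinality* -- distinct (GPP, ER, K)
  triplets reproducing the same O2 curve. Setting $\sigma_K = 0$ fixes K.
* $\sigma \sim$ half-Normal(1). The source methodology is silent on the
  observation error; estimating it avoids an arbitrary fixed value and
  follows common practice in this model family. A floor of $10^{-6}$
  g m^-3 keeps the likelihood finite on noise-free synthetic data.

Default run length is 150000 iterations per day keeping the last 100000,
matching the published configuration. The discarded warm-up doubles as an
adaptation phase: every 50 iterations each proposal scale is multiplied by
`exp(rate - 0.44)` (clamped), targeting the standard componentwise
acceptance rate; scales are frozen when the kept phase begins, so kept
draws come from a fixed kernel. Chains start at the prior means, with
$\sigma$ initialized at the residual SD of the prior-mean trajectory --
this "annealed" start lets poorly guessed rate parameters travel before
the error term tightens. The acceptance rate over the kept phase is
reported and flagged when outside [0.1, 0.6]. Fits are bit-reproducible
given a seed. Test and acceptance runs use 30000 iterations with 10000
warm-up, which these single-day, three-to-four-parameter posteriors mix
through comfortably; parameter-recovery results are indistinguishable from
long runs at the problem sizes we use.

GPP and ER are converted to carbon units by the 1:1 molar O2:CO2
assumption (multiply by 12/32); NEP = GPP + ER throughout (ER signed
negative; summaries that print ER as a magnitude handle the sign at the
reporting layer).

## Night-time regression and the K600-discharge relation

After sunset GPP vanishes and the model reduces to
$\mathrm{d}O_2/\mathrm{d}t = \mathrm{ER}/z + K_{O_2} D$ with saturation
deficit $D = O_{2,\mathrm{sat}} - O_2$: a straight line in $D$ with slope
$K_{O_2}$. Two conventions needed fixing:

* **Differencing.** We estimate the rate as a lagged forward difference
  $(O_{2,t+m} - O_{2,t}) / (m \Delta t)$ regressed on the *mean* deficit
  over the same span. For the Euler recursion above this pairing is exact
  at any lag $m$ (the lagged difference telescopes into the span-mean
  deficit), so noise-free simulated nights recover $K_{O_2}$ to machine
  precision -- and an $m$ of about an hour divides the sensor-noise
  amplification of 10-minute point-to-point differencing by $m$. A
  central-difference scheme, by contrast, is biased by a factor
  $\approx 1 + K \Delta t / 2$ against data generated by the recursion
  itself, which is why we did not adopt it.
* **Windows.** Because high-latitude nights shrink to nothing in
  midsummer, six equal-length overlapping windows of half the night each,
  with starts evenly spaced from sunset, tile every night regardless of
  its duration (their union is exactly sunset-to-sunrise). Windows with
  regression $R^2 \le 0.7$ or a non-positive slope are dropped; nights
  shorter than 2 h (including polar days) yield no estimate, which is an
  expected outcome, not an error. Among retained windows the highest
  $R^2$ wins.

Retained nightly K600 values are regressed on daily discharge; the fitted
line and its residual SD become the daily K prior. In turbulent streams
(K600 above roughly 20 day^-1) the post-sunset transient decays within
minutes, the regression signal is weak, and nightly estimates scatter
widely -- the relation then constrains the model only loosely and the
posterior leans on the O2 data. This is a known limitation of night-time
regression, not of its implementation here.

## Quality control

Two quantitative day-level filters follow the published thresholds: a day
is discarded when the mean absolute error between observed O2 and the
posterior-mean trajectory exceeds 0.2 g m^-3, or when depth (the proxy
for K600, assumed constant within a day) varies by more than 10% within
the day. Both thresholds are strict ("more than"), so boundary days are
kept. The relative depth range uses the daily mean as denominator (the
source says only "changed more than 10%"; range/mean is our documented,
configurable reading). The published workflow added a manual visual
inspection of each day's fit; we replace it with the model's quantitative
diagnostics (MAE, acceptance-rate flag), an automation, not a
reproduction.

## CO2 evasion and diel metrics

Evasion follows $E = K_{CO_2}\, z\, ([CO_2]_w - [CO_2]_a)$, converted to
g C m^-2 day^-1; $[CO_2]_a$ is the Henry's-law concentration in
equilibrium with 380 ppm (a field-measured air value; overridable). The
pipeline evaluates $K_{CO_2}$ per time step by Schmidt-scaling each fitted
day's posterior-mean K600 at the in-situ temperature, so metabolism and
evasion share one gas exchange estimate and any K600 bias moves both in
the same direction. Diel metrics per day:

* $\Delta CO_2$: the within-day range (max - min) of pCO2;
* diel evasion contrast: (mean daytime rate - mean night rate) x daytime
  duration. "Cumulative daytime evasion minus evasion before sunrise" is
  duration-ambiguous at high latitudes, where the night can be a tenth of
  the day; normalizing both to the daytime duration keeps the metric well
  defined for any photoperiod, at the cost of making its regression
  slopes against GPP comparable across studies only qualitatively.
  Undefined (flagged `NA`) on polar days;
* noon/midnight evasion: means over 1-h bins centred on *solar* noon and
  midnight -- at these longitudes clock noon is almost an hour off solar
  noon in summer.

## Reach mass balance

For a stream segment with measured discharge and CO2 concentration at
both ends, in-stream net CO2 production is
$P = Q_{out} C_{out} - Q_{in} C_{in} - Q_{GW} C_{GW} + E A$ with
$Q_{GW} = Q_{out} - Q_{in}$. In a *losing* segment ($Q_{out} < Q_{in}$)
no net groundwater CO2 enters and the groundwater term books the CO2
carried out with infiltrating water at the mean of the segment's two
stream concentrations (segment mean, not reach mean -- the source is
ambiguous; this is the local reading). Gaining segments require the user
to supply a groundwater concentration, which is not derivable from stream
data. Reach summaries report P/A per segment and the area-weighted mean.

## The synthetic deployment generator

Field deployments are replaced by seeded virtual ones with known truth,
so every stage has a recoverable target. The generator emulates:
high-latitude photoperiods (clear-sky PAR proportional to the sine of
solar elevation, positive all day above the Arctic circle in midsummer);
diel O2 from the same forward recursion the model fits (one code path, so
noise-free refits are exact); a CO2 series mirroring O2 mole-for-mole
through NEP, relaxed towards 380 ppm by Schmidt-scaled exchange, plus an
optional constant groundwater CO2 flux uncoupled from O2; day-to-day
lognormal AR(1) discharge with optional within-day spates (to exercise
the depth filter); K600 linear in discharge with Normal scatter; and a
sinusoidal diel temperature cycle (the monitored streams span roughly
4-10 degC with modest diel amplitude).

Defaults describe a small subarctic tundra stream in midsummer: latitude
68.35 N, 10-minute sampling, GPP 0.6 and ER -4.8 g O2 m^-2 day^-1 on
average (about 0.22 and -1.8 g C -- strongly heterotrophic, |ER| roughly
eight times GPP), base flow 0.1 m^3/s, K600 near 15 day^-1, persistent
CO2 supersaturation supported by a 0.5 g C m^-2 day^-1 groundwater input.
O2 noise defaults to 0.005 g m^-3, the point-to-point precision of
optical O2 loggers (their 0.01 mg/L resolution implies ~0.003 rms); the
larger figures quoted as sensor *accuracy* are calibration bias, which
within-day inference does not see (the night-regression estimate is
invariant to a joint offset of O2 and its saturation value). pCO2 carries
2% multiplicative lognormal noise. Parameter-recovery experiments in the
acceptance suite use a heavier 0.05 g m^-3 O2 noise.

What the generator does *not* emulate -- and hence what passing tests do
not demonstrate about field data: sensor drift and fouling, within-day
variation in ER or K600, hyporheic storage, non-Gaussian disturbance
events, and model misspecification generally. Recovery results here show
the chain is correct and well calibrated *under its own assumptions*; on
real streams the dominant errors are the assumptions themselves, which is
exactly why the day-level quality filters and the informed K priors
matter.

## Problem sizes and reproducibility

The bundled experiments use: 12-to-20-day deployments for pipeline runs;
20 simulated site-days (GPP in [0.5, 3], ER in [-8, -1], K600 in [5, 60],
10-minute steps) for credible-interval calibration; 40 simulated nights
for the K600-discharge recovery; and 30000-iteration sampler runs
(10000 warm-up) against 150000/100000 defaults. All randomness flows from
explicit seeds; identical seeds give bit-identical deployments, fits and
pipeline tables. The day-weighted cross-site arithmetic is checked
against a bundled published six-site summary table (`site_summary_table()`),
whose NEP column equals GPP + ER at printed precision for five of the six
sites -- the remaining site (M9) appears to carry a typographical
inconsistency in the source table, and is excluded from that check.
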