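---
title: "Compositional analysis of 24-hour time use: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional analysis of 24-hour time use: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timeuse24)
```

## Why compositions

Daily time use in five behaviours — sitting, standing, light physical
activity (LPA), moderate-to-vigorous physical activity (MVPA) and sleeping —
is constrained to 1440 minutes. Only relative information is meaningful:
adding 30 minutes of MVPA necessarily removes 30 minutes from something
else. `timeuse24` therefore works in the Aitchison geometry of the
4-simplex. All internal durations are minutes/day closed to 1440; h:mm
strings appear only in reports.

Compositions are mapped to real space with isometric log-ratio *pivot
coordinates*. For the part order $(x_1,\dots,x_5)$,

$$\mathrm{ilr}_j=\sqrt{\frac{D-j}{D-j+1}}\;
\ln\!\frac{x_j}{\Big(\prod_{k=j+1}^{D}x_k\Big)^{1/(D-j)}},\qquad
j=1,\dots,4,\; D=5,$$

so the first coordinate contrasts the lead behaviour against the geometric
mean of the rest, with coefficient $\sqrt{4/5}$. Reordering the parts
(`reorder_basis()`) changes coordinates 2–4 by a rotation but leaves fitted
values, $R^2$ and predictions of any linear model unchanged — the
permutation principle, asserted to $10^{-10}$ in the test suite. A
consequence we rely on: the order of the four non-lead parts is
statistically irrelevant, so the package fixes the canonical relative order
(sitting, standing, lpa, mvpa, sleeping) and reports coordinate-1 effects
for each lead in turn.

Zero durations are a hard error throughout. Log-ratios are undefined at
zero, and silent zero-replacement changes estimates; upstream aggregation
and the synthetic generator guarantee positivity, and a participant whose
average for any behaviour is zero is excluded with an explicit reason.

## From monitor days to compositions

Day-level records enter with a day index, recorded hours, waking minutes,
sitting/standing minutes and stepping epochs `(duration, cadence)`.
Validity rules (`filter_valid_days()`): the first measured day is always
dropped (clinic-visit day); the final day is dropped when it holds ≤ 14 h
of recorded information; every remaining day must have ≥ 14 h (840 min) of
waking time. Stepping is classified by cadence — LPA below 100 steps/min,
MVPA at or above. Behaviours are averaged arithmetically over valid days,
and sleeping is 24 h minus average waking time.

Monitors typically leave a small unclassified waking remainder. The default
(`residual = "proportional"`) rescales the four waking behaviours to
exactly partition waking time, preserving their ratios; `residual =
"error"` fails instead when the discrepancy exceeds one minute. We chose
proportional redistribution as the default because it keeps the 24-h
identity without inventing a sixth "unclassified" part; the alternative is
one switch away. Sub-day non-wear inside otherwise valid days is not
modelled.

## Outcomes

Six outcomes are analysed as z-scores: waist circumference, fasting plasma
glucose (FPG), 2-h post-load glucose (2hPLG), HbA1c, the Matsuda index

$$\mathrm{ISI\text{-}M}=\frac{10{,}000}
{\sqrt{(\mathrm{FPG}\cdot\mathrm{FPI})\cdot
(\bar G_{\mathrm{OGTT}}\cdot\bar I_{\mathrm{OGTT}})}},$$

and the clustered cardiometabolic risk score

$$\mathrm{CMR}=\tfrac15\big(z(\text{waist})+z(\ln\mathrm{FPG})+
z(\ln\mathrm{TG})-z(\ln\mathrm{HDL})+z(\text{mean BP})\big),$$

with mean BP = (SBP + DBP)/2. FPG, 2hPLG and HbA1c are z-scored on the
natural-log scale (right-skewed residuals); waist and ISI-M on the identity
scale. Design choices worth stating:

- Sample SDs use the $n-1$ denominator.
- ISI-M levels depend on the insulin concentration unit; z-scores are
  invariant to multiplicative unit changes, so the package computes on
  supplied units. HbA1c is handled in mmol/mol; percent values convert via
  the affine NGSP/IFCC relation (`hba1c_percent_to_mmol()`) *before*
  logging, because the two unit scales are affine rather than proportional
  and log-z-scores would otherwise differ.
- CMR is already a standardised score; by default it is re-z-scored so all
  six effect sizes are strictly per-SD comparable (`rescale_cmr = FALSE`
  disables this).
- ISI-M is z-scored untransformed by default; `log_isim = TRUE` is a
  sensitivity option.

Glycaemic status follows WHO 2006 bands: IGT is FPG < 7.0 with
7.8 ≤ 2hPLG < 11.1 mmol/l, IFG is 6.1 ≤ FPG < 7.0 with 2hPLG < 7.8, either
gives IGM. The type-2-diabetes glucose rule defaults to the WHO reading
(FPG ≥ 7.0 **or** 2hPLG ≥ 11.1); a strict conjunction reading (**and**) is
available via `conjunction = "and"`. Under the conjunction reading a point
such as (FPG 8.0, 2hPLG 5.0) falls outside every band and is labelled NGM —
a property of the literal band definitions, verified by a lattice scan in
the tests. Glucose-lowering medication always classifies as T2D.

## Regression, interactions, substitution

`fit_compositional_model()` is ordinary least squares of an outcome z-score
on the four ilr coordinates plus covariates: age and diet score
(continuous, centred — centring cannot alter composition effects and
improves intercept interpretability), sex, education, smoking and, for
overall-sample analyses, diabetes status (treatment contrasts, first level
alphabetically as reference; the reference cannot change composition
effects and is recorded in the fit). Analyses are complete-case. Inference
uses the t distribution on residual df; no robust errors. A
waist-circumference sensitivity adjustment is a config flag that is
automatically suppressed when the outcome is waist or CMR.

Composition-by-stratum interaction (`test_interaction()`) compares the
common-slope model against stratum-specific slopes for all four
coordinates with an F-test (numerator df = 4 × (levels − 1)); per-stratum
lead-coordinate slopes are read from the nested parameterisation.

Isotemporal substitution (`substitute_time()`) moves Δ minutes (default
30) from one behaviour to another, starting from the sample's
compositional geometric mean (per-stratum means for stratified analyses),
and evaluates $d'\hat\beta$ with $d=\mathrm{ilr}(x_{new})-
\mathrm{ilr}(x_{base})$, variance $d'\hat V d$, and a 95% t CI. Because
the model has no composition-by-covariate interaction, the estimate is
exactly the prediction difference at any covariate values — the test suite
asserts equality with that brute-force oracle to $10^{-10}$. Note that the
ilr map is non-linear: reverse substitutions are only approximately
antisymmetric, and for behaviours whose base time is small relative to Δ
(e.g. 30 min against a 50-min MVPA average) the asymmetry is large. This
is a property of the geometry, not an artefact.

## The optimal-zone grid search

The footprint is the per-behaviour 1st–99th percentile band
(linear-interpolation quantiles, rounded to the nearest 10-min step).
`enumerate_grid()` lists every 5-tuple on the lattice, inclusive bounds,
summing exactly to 1440 — implemented by enumerating four behaviours and
solving for the fifth, and verified against a naive five-loop oracle on
random footprints. With externally published bounds of 5:40–13:20
(sitting), 1:40–7:50 (standing), 0:30–2:20 (LPA), 0:10–2:20 (MVPA) and
6:20–10:40 (sleeping), the enumeration yields exactly 142,938
compositions, which validates the inclusive-bounds reading of the lattice.

Each grid composition is scored by the compositional part of the linear
predictor only; covariate terms are constant across the grid and cancel in
ranking (for this reason the engine refuses models with
composition-by-stratum interactions — those must be ranked per stratum).
The best `ceiling(fraction * N)` compositions are kept — `ceiling` because
a "best 5%" of a non-divisible count must round somehow and `ceiling`
guarantees non-emptiness — with deterministic tie-breaking by predicted
value, then lexicographic composition. Direction is per outcome: lower is
better for all risk markers, higher for ISI-M.

Zone summaries report the compositional centre (part-wise geometric mean
closed to 1440, then each part rounded to the nearest 10 min — the rounded
parts may therefore not sum exactly to 24 h) and per-behaviour min–max
ranges. The cross-outcome overlap intersects the per-outcome selections at
a common fraction, escalating 5% → 10% in 1% steps until non-empty; the
escalation grid is a declared convention (only the two endpoints are
canonical). An empty overlap at 10% is a reported result with pairwise
diagnostics, not an error. For visualisation, grid points at a fixed sleep
level (default 8 h) have their four waking shares mapped as barycentric
weights onto a regular tetrahedron; a vertex is 100% of waking time in one
behaviour, the centroid equal 25% shares.

## The synthetic cohort

Real cohorts of this kind are not redistributable, so validation runs on a
generator with known truth. Compositions are logistic-normal: ilr
coordinates drawn from a stratum-specific multivariate normal and
inverted. The three strata (NGM/IGM/T2D, default n = 1341/363/684)
have centres at sitting 9.1/9.6/10.2 h, standing 4.4/4.2/3.7 h, LPA
1.1/1.1/0.9 h, MVPA 1.0/0.8/0.6 h and sleeping 8.2/8.2/8.3 h. Dispersion
and correlation are not published for such cohorts, so we fixed plausible
values once: log-scale SDs (0.18, 0.30, 0.36, 0.51, 0.11) chosen so
marginal IQR/median ratios are realistic, mild negative sitting–activity
correlations (−0.4 to −0.15) and a small positive standing–LPA
correlation. Outcome z-scores follow
$z = \mathrm{ilr}(x)\beta + w'\gamma + \varepsilon$, $\varepsilon\sim
N(0,1)$; the true $\beta$ are specified as sum-zero log-contrast vectors
(sitting adverse, activity protective, reversed for ISI-M) and mapped to
ilr space.

Raw markers are back-generated from the latent z-scores on their natural
scales, with stratum centres and small log-scale slopes chosen so WHO
classification of the generated glucose values recovers the intended
stratum for ≥ 95% of rows (≈ 99.8% in practice). OGTT insulin values are
solved so the computed Matsuda index hits its generating target exactly.
Two things follow that a user should know. First, the latent `z_*` columns
— not re-z-scored raw markers — are the ground truth for
coefficient-recovery checks, because re-standardising a generated outcome
rescales its coefficients by the realised sample SD. Second, because the
stratum separation of the glycaemic markers is large relative to their
within-stratum spread, regressions of the *raw-marker* z-scores show
unrealistically high $R^2$ (the diabetes-status covariate absorbs the
separation); the generator prioritises classification fidelity over
marginal realism here. The generator also does not emulate outcome-level
skewness beyond log-normality, missing data (beyond optional complete-case
paths), or accelerometer-level measurement error; passing tests show the
*methods* are correct and calibrated, not that real-data effect sizes are
reproduced.

Day-level records emulate an 8-day continuous-wear protocol: day 1
flagged, a final removal day with uniformly drawn recorded hours
(sometimes ≤ 14 h), per-day behaviours jittered multiplicatively (log-SD
0.08) around the participant's composition, ≈ 1.5% of waking time left
unclassified, and stepping epochs with cadences straddling 100 steps/min.
One global seed governs all draws; the day-record generator uses a
deterministic sub-stream so adding stages does not perturb earlier draws.

## Numerical conventions and problem sizes

- Closure tolerance $10^{-6}$ min; ilr round-trip is exact to
  $\sim10^{-13}$.
- Percentile footprints use type-7 (linear interpolation) quantiles.
- Grid enumeration is integer arithmetic throughout; ranking ties are
  broken deterministically.
- Calibration checks in the tests use 200 replicates at the default
  n = 2388 for coefficient recovery and CI coverage (pooled over the four
  coordinates), 1000 replicates at n = 240 for interaction-test type-I
  error, 1000 replicates at n = 250 for substitution CI coverage, and 50
  random footprints for enumeration and optimum-recovery properties —
  sizes at which Monte-Carlo error is small relative to the asserted
  bands while the whole suite stays quick.

## Limitations

Cross-sectional associations only; no causal or longitudinal claims. The
grid search ranks by the fitted linear predictor, so "optimal"
compositions inherit all model misspecification. Raw activPAL event
processing and sleep/wake detection are upstream of this package. The
public contract is fixed at five parts; the internals generalise to other
D but that surface is deliberately not exported.
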