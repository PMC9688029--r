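---
title: "Length-based stock assessment with lenstock: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Length-based stock assessment with lenstock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lenstock)
```

`lenstock` implements a complete length-based assessment for a data-limited
demersal stock, built around the Azorean silver scabbardfish
(*Lepidopus caudatus*) as the worked case: growth from monthly length
frequencies, total/natural/fishing mortality and exploitation rate, a
two-part spatial distribution model for zero-inflated survey catch rates,
and standardization and trend comparison of fishery-dependent abundance
indices. Because the real survey, landings and inquiry data for such stocks
are typically confidential, the package ships a seeded synthetic-data
generator that reproduces the statistical structure those analyses assume;
every stage is validated against it.

This vignette records the models, every tunable that matters, the design
choices made where the design was genuinely open, and what the validation
does and does not demonstrate.

## The growth model and its ELEFAN estimator

Mean length at age follows the von Bertalanffy growth function in its
t0-free form,

$$L(t) = L_\infty\,(1 - e^{-kt}),$$

with $L_\infty$ the asymptotic length (cm) and $k$ (year⁻¹) the rate at
which it is approached. Because this form carries no theoretical age at
length zero, cohorts are aligned with the calendar through a third
parameter, `t_anchor` ∈ [0, 1): the fraction of the year at which a cohort
is born. The growth performance index
$\Phi' = 2\log_{10}L_\infty + \log_{10}k$ makes fits comparable across
stocks; note that a bootstrap central value of $\Phi'$ need not equal
$\Phi'$ evaluated at the point estimates, so both conventions can
legitimately appear for the same fit.

`fit_growth_ga()` estimates $(L_\infty, k, t_{anchor})$ by electronic
length-frequency analysis (ELEFAN):

1. **Restructuring** (`restructure_lfq()`). Within each monthly sample,
   each bin's count is divided by the centred moving average over `ma = 5`
   bins (windows truncate at the table edges) minus one, so local peaks
   score positive and troughs negative; isolated peaks (positive bins whose
   window neighbours are empty) are deflated by $2^{n_z}$; positives are
   then rescaled so they balance the negatives within the sample. The sum
   of all positive scores is the *available sum of peaks* (ASP).
2. **Scoring** (`elefan_score()`). For a candidate parameter set, one
   growth curve per annual cohort is traced across the sampling dates;
   every (bin, date) cell crossed by any curve is collected — each cell at
   most once overall, which keeps the score bounded — and the crossed
   scores sum to the *explained sum of peaks* (ESP). The goodness score is
   $R_n = 10^{ESP/ASP}/10 \in (0, 1]$. Cohorts are traced to the
   approximate maximum age $3/k$, the same convention the
   natural-mortality battery uses for $t_{max}$; beyond it the curve is
   flat against the asymptote and cohorts are effectively extinct.
3. **Search.** A real-coded genetic algorithm (population 50, 100
   generations, tournament selection of size 2, arithmetic crossover,
   Gaussian mutation whose step decays linearly, elitism 2 — all
   overridable through `ga_settings()`) maximizes $R_n$ over the box
   $L_\infty \in [0.8, 1.3]\,L_{max}$ ($L_{max}$ = largest occupied bin
   midpoint), $k \in [0.01, 1]$, $t_{anchor} \in [0, 1)$. Fitness ties are
   broken toward smaller $L_\infty$ for determinism.
4. **Uncertainty.** A non-parametric bootstrap resamples each date's
   counts multinomially (preserving per-date sample sizes), refits, and
   reports 0.95 percentile intervals for $L_\infty$, $k$ and $\Phi'$. The
   conventional 1000 resamples is the pipeline default
   (`run_config()`); each refit costs a full GA run (a few seconds at the
   default budget), so reduced counts are used in the test suite, which
   checks the bootstrap's structure and determinism rather than its
   coverage.

### When growth is identifiable — and when it is not

ELEFAN reads growth off the *modal progression* of cohorts. Two
consequences shape both the generator defaults and the validation design:

* **Individual variability.** The generator places growth variability on
  $L_\infty$ alone (shared $k$, curves non-crossing in expectation), with
  CV 2.5% by default. For a slow grower ($k = 0.12$) on 5 cm bins the
  cohort modes are 8–15 cm apart over the informative size range; CVs much
  above 4% erase them, and with them any length-based growth signal. The
  generator must emulate data to which the method is applicable.
* **Exploitation.** Under the fishery's total mortality ($Z = 0.47$)
  survival to age 12 is under half a percent, the length structure above
  ~130 cm is empty, and after restructuring, the steep exponential tail
  scores negative in every bin it occupies. The ELEFAN surface then
  rewards curve sets that stop short of the true asymptote, and
  $L_\infty$ is genuinely unidentifiable — a property of such data, not of
  the implementation. The package's parameter-recovery experiment
  therefore simulates a lightly exploited population ($Z = M = 0.22$,
  24 monthly samples of ≥3000 fish), where recovery lands within a few
  percent of the truth. Passing that experiment demonstrates the
  estimator is correct; it does not promise tight asymptotic-length
  estimates from a heavily fished stock's landings.

## Mortality

`length_converted_catch_curve()` pools the length-frequency table over
dates, converts bin midpoints to relative ages through the inverse VBGF
($t = -\ln(1-L/L_\infty)/k$), and regresses $\ln(N/\Delta t)$ on relative
age; $Z$ is the negative slope, with its OLS standard error. The
descending limb is chosen automatically — the points after the maximum of
$\ln(N/\Delta t)$ through the last non-empty bin with midpoint below
$0.9\,L_\infty$ — and can be overridden, because $Z$ depends on this
choice; the selection is stored in the fitted object. Pooling across
several monthly samples is recommended with pulsed recruitment: a single
date leaves the age axis discretized at cohort spacing, and the
binning artefacts bias the slope by several percent.

`natural_mortality_battery()` evaluates fourteen empirical estimators of
natural mortality from $L_\infty$, $k$, $t_{max}$ (default $3/k$, carried
at full precision) and water temperature (default 18 °C), and returns
their arithmetic mean, which downstream code uses as $M$. The formulas are
implemented exactly as printed in the battery the package reproduces; two
of them deserve a note. The Pauly (1980) row applies `exp()` to a linear
combination of base-10 logarithms — the canonical form of that
relationship applies $10^x$ instead and gives about 0.24 rather than 0.53
for this stock; the canonical version is available via
`pauly = "log10"`. The Alverson–Carney row uses the denominator
$\exp(0.38\,t_{max}k - 1)$. With those readings and $k = 0.13$
(equivalently $t_{max} = 3/k \approx 23.1$ years) every printed row of the
reference battery reproduces to two decimals, including the mean of 0.22;
the headline growth estimate $k = 0.12$ does not reproduce the individual
rows, so the battery-consistent $k$ is used when that table is being
reproduced. Mean $M$ is rounded only for display; full precision
propagates into $F = Z - M$ (negative values are flagged implausible, not
clipped) and the exploitation rate $E = F/(F+M)$, for which $E = 0.5$ is
the conventional optimal-exploitation benchmark.

## Spatial distribution: the two-part (hurdle) GAM

Longline survey catch rates (RPN, individuals per 10³ hooks) are about 90%
zeros. `fit_hurdle_sdm()` models presence/absence of all records with a
binomial GAM (logit link) and the natural log of the positive catch rates
with a Gaussian GAM, both with the additive structure

$$g(\eta) = s(\text{longitude}, \text{latitude}) + s(\text{depth}) +
\text{substrate},$$

using thin-plate regression splines (depth basis dimension 4 by default;
the bivariate smooth's basis shrinks automatically when the positive
subset is small). Zero records contribute only to the binomial part — the
defining hurdle property, which also makes the binomial part invariant to
any rescaling of positive magnitudes. Smoothness is selected by REML
(default, more stable than GCV on zero-heavy data; GCV available). The
reference substrate level is coarse sediment (`C.Sed`, first
alphabetically of the seven categories). Back-transformed abundance
predictions use a plain `exp()` with no lognormal bias correction, so
predicted conditional abundances are medians rather than means;
`predict()` can combine the parts as
$p(\text{presence}) \times E[\text{abundance}\mid\text{positive}]$.
Separation or non-convergence in the binomial part surfaces through the
stored mgcv diagnostics rather than an error.

## Size structure and sex ratio

`ks_two_sample()` computes the two-sample Kolmogorov–Smirnov $D$ by
evaluating both ECDFs at every observed point (deterministic under ties)
with the asymptotic Kolmogorov p-value (exact available for small,
tie-free samples). `welch_anova()` is the heteroscedastic one-way F test
with Satterthwaite-type denominator degrees of freedom; note it equals the
classical ANOVA F only asymptotically even under equal variances.
`games_howell()` performs all pairwise comparisons with Welch standard
errors and degrees of freedom against the studentized range distribution
(`ptukey`, computed numerically — no Monte Carlo), reducing to the
unadjusted Welch test when only two groups exist. `sex_ratio_test()` is
the chi-square goodness-of-fit test against 1:1; strata with fewer than 10
fish are flagged `low_n` but never suppressed, and single-sex strata
report an infinite (or zero) ratio with the test still computed.

## Abundance standardization and trend comparison

`standardize_cpue_hurdle()` removes fleet effects from trip-level catch
rates with a hurdle–lognormal GLM: a binomial part on whether the trip
caught anything and a Gaussian part on $\log(\text{catch}/\text{effort})$
of the positive trips, both with the same categorical factors (year,
quarter, vessel class, gear by default; a continuous target share is
binned to quartiles when requested). The annual index is the
least-squares mean of the year factor — all other factors balanced at
equal level weights — and the parts combine as
$\exp(\text{LSM}_{pos}) \times \text{logit}^{-1}(\text{LSM}_{bin})$,
standard delta-lognormal practice; the positive part alone is available
because the combination rule is a modelling choice, not a given. Standard
errors come from the delta method under independence of the parts. On a
balanced noiseless design the index equals the injected year effects up to
one global scale; on a confounded design (vessel power drifting across
years) the standardized index stays flat where the nominal mean trends —
both are exercised in the test suite. Effort is whatever the effort column
contains: days at sea gives CPUE, landing events gives LPUE; the code
treats them identically.

Indices are min–max normalized (`minmax_normalize()`); a constant series
maps to 0.5 with a warning rather than an error so degenerate simulations
do not kill a pipeline. `compare_trends_ancova()` stacks two or more
normalized series and fits `value ~ year * index`; the interaction term
tests parallelism (type-II table via car). Only when the slopes are
parallel at the configured α (default 0.05) does it refit without the
interaction and run single-step Tukey contrasts (multcomp) on the index
intercepts — the sequential parallelism-then-intercepts logic of
abundance-trend comparison.

## The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions for the worked stock.

* `simulate_population()`: annual recruitment pulses (default month 1),
  individual $L_\infty \sim$ lognormal(mean 171.62 cm, CV 2.5%), shared
  $k = 0.12$, age at death Exponential($Z = 0.47$), 68.5% female (the
  0.46:1 male:female ratio). Gear selectivity is logistic with
  $L_{50} = 85$ cm by default — the fishery lands essentially no fish
  below ~84 cm, and no fleet selectivity has been published for this
  stock, so this is a free parameter; validation experiments that need
  juvenile modes use lower values explicitly.
* `simulate_survey_records()`: stations on a stratified design (50 m depth
  strata to 600 m), presence with a Gaussian-in-depth logit (optimum
  300 m, SD 75 m) plus a substrate effect (only `Sand` non-zero by
  default), lognormal positive catch rates on the same surface.
  `zero_inflation = 0.75` is the zero fraction *at the optimum*; under the
  uniform-depth design this yields ≈90% zeros overall, the zero-heaviness
  such surveys report.
* `simulate_trip_records()`: catch = effort × baseline × year × quarter ×
  vessel × gear multipliers × lognormal noise, zeroed with probability
  `p_zero`; `confound_vessel_year` deliberately drifts powerful vessels
  into late years to generate the bias standardization must remove.

What the generator does **not** emulate: continuous or multi-pulse
recruitment, time-varying growth or selectivity, spatial movement,
environmental covariates beyond depth and substrate, and correlated
vessel-level random effects. Passing tests therefore demonstrate
correctness of the estimators under their own assumptions, not robustness
to every violation real data can present.

## Numerical conventions and degenerate inputs

* Length bins are left-closed, right-open `[lower, lower + width)`,
  labelled by lower edge; months are the time unit, finer dates truncate
  with a warning.
* All-zero samples restructure to all-zero scores (defined, not NaN); an
  LFQ with no peaks at all (ASP = 0) is a scoring error, since there is
  nothing for curves to explain.
* GA fitness ties break toward smaller $L_\infty$; every random routine
  takes an explicit seed and is a pure function of (parameters, seed).
* Catch-curve bins with zero counts inside the selected limb are excluded
  with a warning; fewer than three usable points is an error.
* The VBGF/inverse-VBGF round trip is exact to better than 1e-9 relative
  over $L/L_\infty \in [0, 0.99]$.

## Problem sizes used in validation

The test suite simulates ~200 k individuals for parameter-recovery
(24 monthly samples of 3–8 k fish), 125 k+ individuals for catch-curve
recovery (12 pooled monthly samples), 2000 survey stations for the
distribution model, 4–5 k trips for standardization, and 1000 replicate
null datasets for the Welch type-I-error calibration — sizes at which the
Monte-Carlo error is comfortably inside the asserted tolerances while the
whole suite runs in well under a minute, with the GA experiments adding a
few seconds each.
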