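---
title: "Validating dietary assessment tools against doubly labelled water"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating dietary assessment tools against doubly labelled water}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutrivalid)
```

## The problem

Self-reported dietary intake — whether captured by an AI-powered
photo-logging app or by an interviewer-administered 24-hour recall — is
systematically biased, and the bias is largest in populations with obesity.
The only practical physiological criterion for free-living energy intake in
weight-stable adults is total daily energy expenditure (TDEE) measured by
doubly labelled water (DLW): the differential elimination of two stable
tracers, ²H and ¹⁸O, from body water isolates CO₂ production, and CO₂
production converts to energy expenditure.

`nutrivalid` implements that entire validation pipeline as reusable,
individually tested components: the DLW engine, energy-requirement and
physical-activity-level (PAL) prediction, Goldberg misreporting
classification, method-comparison statistics, and a nine-facet validity
scorecard. Because individual-level data from validation studies are rarely
machine-readable, the package also ships a seeded synthetic-cohort generator
that emulates the data structure of such a study, so every downstream stage
can be exercised, tested, and power-analysed without any external data.

## The DLW model

For each participant the two-point protocol yields, per tracer, a post-dose
plateau enrichment and a final enrichment about a week later. We work
throughout in *excess* enrichment above the participant's pre-dose baseline,
in ppm atom fraction. Three quantities follow:

* **Elimination rates** \(k_O, k_d\) (per day) — the log-linear slope between
  the plateau and the final sample:
  \(k = (\ln E_{\mathrm{plateau}} - \ln E_{\mathrm{final}})/\Delta t\).
* **Dilution spaces** \(N_O, N_d\) (mol) — dose bookkeeping:
  \(N = n_{\mathrm{excess}}/E_{\mathrm{plateau}}\), where
  \(n_{\mathrm{excess}}\) is the moles of excess tracer administered. For
  deuterium the two hydrogen sites per molecule cancel against the per-site
  definition of enrichment, so both tracers share one formula.
* **CO₂ production and energy**:
  \(r\mathrm{CO}_2 = 0.4664\,N\,(1.007\,k_O - 1.043\,k_d)\times 22.26\)
  L/day, and by the Weir equation
  \(\mathrm{TDEE} = r\mathrm{CO}_2\,(1.106 + 3.94/\mathrm{RQ})\) kcal/day,
  with a respiratory quotient of 0.85 assumed for mixed diets.

Three conventions in this chain are genuinely underdetermined in the applied
literature, so the package fixes defaults and exposes them as arguments:

* **Plateau pooling.** When both a 4 h and a 5 h post-dose sample exist, the
  plateau enrichment is their arithmetic mean, and the elimination interval
  runs from the plateau midpoint (4.5 h) to the final sample.
* **Pool-size convention.** The body-water pool entering the rCO₂ equation is
  \(N = (N_O + N_d/1.041)/2\) — each dilution space corrected to a common
  scale by the reference dilution-space ratio 1.041 before averaging
  (`nd_no_ref` argument). This is standard two-point practice; other
  conventions differ by well under 1% for physiologic ratios.
* **Quality control.** The observed ratio \(N_d/N_O\) is checked against a
  configurable band (default 1.00–1.07); violations, negative elimination
  rates, and negative rCO₂ attach flags to the result rather than erroring,
  because a QC failure is a finding, not a software fault.

Physiologically \(k_O > k_d\) always (oxygen exchanges with both water and
CO₂), so the rate-ratio QC metric is reported as \(k_O/k_d\), near 1.32 in
adults.

## Energy requirements and PAL

Predicting resting requirements from actual body weight overestimates BMR in
obesity, so the Mifflin–St Jeor and Harris–Benedict equations are evaluated
by default on **adjusted body weight**, `ABW = IBW + 0.3 (W − IBW)`, with
ideal body weight from the Devine formula. The working `abmr` column uses
Mifflin–St Jeor, which at the default cohort's mean anthropometrics
reproduces typical published cohort BMR values to a few kcal/day;
Harris–Benedict (revised classic female coefficients, configurable) is
computed alongside. PAL comes in three variants: TDEE/aBMR, TDEE/device-REE,
and a self-reported lifestyle value passed through untouched — a missing REE
or lifestyle column yields `NA`, never a default.

## Goldberg classification

A participant's mean reported intake divided by the BMR/REE denominator is
compared against log-scale bounds
\(\mathrm{PAL}_{\mathrm{ref}} \exp(\pm z\,S/100/\sqrt{n})\). The composite
variability factor \(S = \sqrt{CV_{wTDEI}^2/d + CV_{wB}^2 + CV_{tP}^2}\)
pools within-person intake variability over \(d\) reporting days, the
denominator's uncertainty (8.5% by Black's literature value; the component
is rarely printed in applied papers), and between-person PAL variability.
`classification_grid()` runs the full grid — both denominators, three PAL
variants, study-specific and Black's default \(S\) — because the choice of
cell moves individuals across the plausibility boundary far more than their
data do; the cell maximising plausible reporters is flagged, mirroring how
such grids are reported. Ties at a bound count as plausible (conservative
toward the null of accurate reporting). The number of participants entering
the bounds defaults to \(n\), with an `"n-1"` option, since published
intervals reconstruct under either convention depending on the study.

## Agreement statistics

`bland_altman()` keeps the divisor convention explicit: published
method-comparison tables mix `SE = SD/√n` with `SD/√(n−1)` — sometimes
within one table — so the divisor \(m\) (and the \(t\) degrees of freedom
\(m-1\) for the bias CI) is a per-call argument carried in the result, and
the limits of agreement are always exactly `bias ± 1.96 SD`. `SE(LoA)` uses
the standard large-sample approximation `SD·√(3/m)`. Paired tests are gated
on Shapiro–Wilk normality of the differences (t-test vs Wilcoxon) with a
Bonferroni cap, as is conventional in this literature. Day-to-day reporting
stability uses ICC(2,1) — two-way random effects, single measure, absolute
agreement — computed from the ANOVA mean squares with the
Satterthwaite-based F confidence interval; the implementation is verified in
the test suite against an independent `aov()`-based oracle and a frozen
external reference computation.

The scorecard's association facets report a *signed* \(R^2\),
\(\mathrm{sign}(r)\,r^2\): in a validity context a negative relationship
between reported intake and fat-free mass is qualitatively different from a
weak positive one, and an unsigned \(R^2\) would hide that.

## The synthetic cohort

`cohort_params()` defaults describe the study conditions the package is
built around: 20 adult females with obesity (weight 108.4 ± 16.3 kg, height
1.66 ± 0.06 m, age 37.9 ± 13.4 y), TDEE 3004.2 ± 480.5 kcal/day, a 7-day
reporting window, an app-like tool underreporting by 25% on average with
large within-person variability (CV 88.36%, the measured value for
photo-based logging in this population), and a recall-like tool
underreporting by 50%. Values the literature does not pin down were chosen
once as field-realistic and are not tuned: between-person reporting CVs (35%
app, 25% recall), the recall tool's within-person CV (26%, Black's adult
default), eating-occasion Poisson means (5.5 and 3.4/day), a fixed
macronutrient energy split (45/35/20), body-fat fraction 48 ± 4% of weight,
and device-REE noise of 5% CV.

The generator works backwards from each participant's true TDEE: it draws
the dilution-space ratio (1.0398 ± 0.0067) and rate ratio (1.3207 ± 0.0598)
from their physiologic distributions, fixes the body-water pool from
TBW = 0.732·FFM, and solves the rCO₂ equation for the elimination rates.
Plateau samples are laid on the decay curve rescaled so their arithmetic
mean equals the exact plateau enrichment — which makes the noise-free
forward–inverse round trip exact to machine precision, a property the test
suite asserts at 10⁻⁶ relative and observes at ~10⁻¹⁴. Isotope measurement
noise is additive Gaussian on the post-dose excesses, default 0.25 ppm:
optical-spectrometer analytic precision, which after propagation through the
two-point rate difference yields the ~4–6% TDEE repeatability DLW is known
for. Intake noise is multiplicative lognormal (mean-1 factors at the
configured within- and between-person CVs), which keeps intake positive and
reproduces the right-skew of app-reported energy.

What the generator does **not** emulate: food-recognition errors as a
mechanism (bias and variance are phenomenological), day-of-week or
within-week trends, correlated macronutrient-specific errors, dropout or
missing days, and isotope baseline drift. Passing recovery tests therefore
demonstrates that the *statistical machinery* is correct under the assumed
error structure, not that any particular app behaves lognormally.

## Worked example

```{r example}
params <- cohort_params(n = 20, seed = 1)
sim <- simulate_cohort(params)
dlw <- run_dlw_cohort(sim$isotope$samples, sim$isotope$doses)
bundle <- assemble_validation(sim$participants, sim$intake, dlw)
build_scorecard(bundle, tool = "app")
```

The bias and limits of agreement describe group- and individual-level
agreement in kcal/day; facet 3's percentage difference is the mean of
per-participant percentage errors (mean of ratios — deliberately not the
ratio of means, which differs whenever error tracks expenditure); facet 5
reports the best-performing Goldberg cell; facets 6–8 are signed-\(R^2\)
plausibility regressions (energy-storage change is weight change × 7700
kcal/kg, the conventional energy density of mixed tissue); facet 9 is the
day-to-day ICC, which is near zero by construction here because daily
reporting noise dwarfs the between-person signal — the situation real app
validations report.

## Numerical and degenerate-input choices

* All SDs may be zero: truncated-normal draws degenerate to the mean, and
  lognormal factors to 1, so fully deterministic cohorts are available for
  identity tests.
* Anthropometric draws truncate at 2 SD below the mean (and physiologic
  floors); no upper truncation, preserving right tails.
* `run_dlw()` errors on structurally missing data (absent tracer, plateau,
  dose) naming what is absent, but never on QC failures.
* Bound ties in the Goldberg classifier are plausible; `NA` ratios are
  `"unclassifiable"` and never silently dropped from grid counts.
* Problem sizes in the test suite — recovery at n = 200 participants and
  ICC recovery on 500 × 7 matrices — were chosen so that three-standard-error
  Monte-Carlo bands are a few percentage points wide, tight enough to catch
  sign and scale errors while keeping the suite quick to run.

## Known limitations

The engine implements the two-point plateau method only — no multi-point
regression variant, no intercept-method selection, no spectrometer
drift/memory correction (assumed handled upstream by the isotope lab). The
Goldberg grid reports counts, not per-participant labels matched to any
specific published cohort, since that requires individual-level data.
Proportional-bias assessment in Bland–Altman plots is visual; a slope
diagnostic is deliberately not fitted by default, matching descriptive
practice in validation studies.
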