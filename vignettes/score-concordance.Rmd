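---
title: "Methods: concordance of cardiovascular risk scores in survey data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: concordance of cardiovascular risk scores in survey data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskconcord)
```

## The problem

Clinical guidelines stratify people without established cardiovascular
disease by their predicted 10-year risk of a cardiovascular event, and
different guidelines recommend different prognostic equations. When two
equations are applied to the same population, both the continuous risks and
the resulting strata can disagree, which matters directly for who is offered
treatment. This package implements a reproducible pipeline for measuring
that disagreement on national-health-survey style data: harmonize raw survey
records into risk-factor profiles, score everyone with three equations, and
quantify between-score agreement.

## Risk equations as data

Each equation is a declarative JSON "coefficient set": a link function, the
profile fields that select a stratum (sex for all shipped models), linear
predictor terms (variable, identity or natural-log transform, optional
interaction partner, optional boolean conditions such as treatment status or
race), per-stratum baseline quantities, per-variable validity bounds and
declared units. A md5 checksum over the file's substance is verified on
load, so a silently edited coefficient is a hard error. The evaluator is
generic; the three shipped files are:

* `framingham_gcvd` — sex-specific Cox model on log age, log total and HDL
  cholesterol, log SBP (separate coefficients for treated and untreated
  blood pressure), smoking and diabetes; risk is
  $1 - S_0^{\exp(L - \bar L)}$ with the published 10-year baseline survival
  and mean linear predictor. This file is a transcription of the published
  equation and reproduces its published worked example (a 61-year-old
  smoking woman, SBP 124 untreated, TC 180, HDL 47: risk 10.48%).
* `pce2018` — a sex-stratified logistic model with black race, treatment and
  interaction terms, mirroring the 2018 logistic re-derivation of the pooled
  cohort equations. The numerical content is a *reconstruction* (the file is
  suffixed `_synthetic`): it reproduces the published model's structure and
  realistic behaviour, but the original coefficient table must be
  re-transcribed before real-data use.
* `globorisk_lac` — a laboratory (cholesterol-based) recalibrated equation
  of Globorisk form for fatal plus non-fatal events. Relative risks use
  age-attenuated log hazard ratios for SBP, TC, diabetes and smoking
  ($\beta_j(a) = \beta_j(60) + s_j (a - 60)$); the absolute scale comes from
  a country calibration table of sex × 5-year age-band baseline annual event
  rates and mean risk-factor levels. Risk accumulates year by year while the
  person ages through the bands:
  $1 - \exp\{-\sum_{t=0}^{9} \lambda(s, a{+}t) \, e^{\beta(a+t)'(x - \bar
  x(s, a+t))}\}$. The exponential-survival form keeps every annual hazard,
  and hence the 10-year risk, inside (0,1) even for extreme profiles. The
  whole file is synthetic: the published recalibration inputs are
  distributed in supplementary material and are represented here by
  epidemiologically plausible stand-ins for Brazil (male rates roughly
  double female rates, rising ~1.45× per band from 0.2%/yr at 40–44;
  mean SBP rising 126→148 mmHg across bands). Its TC block is declared in
  mmol/L, exercising the load-time unit conversion (×38.67 to mg/dL).

Canonical internal units are mg/dL, mmHg and years, matching the survey's
variables. Out-of-range inputs are rejected with the variable and bounds
named, never clamped: silent clamping would distort the agreement statistics
that are the point of the analysis, and filtering is the eligibility stage's
job.

## Cohort preparation

Harmonization mirrors the survey's structure. The two-week antihypertensive
question is only asked of people reporting a hypertension diagnosis, so a
missing answer with no diagnosis (outside pregnancy) or never-measured blood
pressure is a structural "no". Diabetes is derived in a fixed order: people
never tested are first taken as non-diabetic, then HbA1c ≥ 6.5% (inclusive)
overrides any prior answer. Smoking covers daily and less-than-daily
smokers; "black" maps self-reported parda or preta skin color; history is an
OR of heart-disease and stroke diagnoses.

Eligibility applies four rules in a fixed order, each with its own tally
count: age 40–74 inclusive; *joint* completeness (a person missing HDL is
excluded even though the recalibrated equation ignores HDL — comparisons are
only valid on a common cohort); no cardiovascular history; SBP/TC inside
atypical-value bounds. The bounds default to SBP 70–270 mmHg and TC 2.6–13
mmol/L — the exclusions used in the recalibrated equation's development, as
best we could establish them — and are configurable. The tally always
conserves counts (`n_in = n_eligible + Σ exclusions`). Survey weights are
carried unmodified; absolute frequencies are reported unweighted and every
other statistic weighted, the convention of the source survey's analyses.

## Agreement

Two risks are **concordant** when the larger is strictly less than 1.25× the
smaller. On the log scale this is the Bland-Altman window (0.8, 1.25); the
25% margin is a common default for the smallest clinically relevant effect.
The strictness at exactly 1.25 is deliberate ("less than 25% higher"), and
the classification depends only on the ratio, so fractions and percentages
give identical results.

For stratified agreement, risks are cut into ordinal categories with
lower-bound-inclusive intervals (exactly 10% is intermediate, exactly 20% is
high under the main 10/20 scheme). Adjacent strata count as fully
discordant — no ordinal weighting — and agreement is summarized by the
weighted observed agreement $P_a$ (diagonal mass of the weighted
contingency table) and Gwet's first-order coefficient

$$AC_1 = \frac{P_a - P_e}{1 - P_e}, \qquad
P_e = \frac{1}{q-1} \sum_k \pi_k (1 - \pi_k), \qquad
\pi_k = \frac{p_{k\cdot} + p_{\cdot k}}{2}.$$

AC1 is chosen over Cohen's κ because κ collapses when one category is rare
(high-risk strata are rare in a general population); the suite asserts
AC1 ≥ κ on skewed tables and verifies the weighted implementation against
the classical count-based formula on an exhaustive enumeration of small
tables. With all weights equal the weighted statistic reduces exactly to the
classical one; multiplying all weights by any constant changes nothing.

Weighted quantiles use the left-continuous inverse CDF (the lowest value
whose cumulative normalized weight reaches p) by default; an interpolating
rule is available via `type = "interpolate"`. The non-interpolating default
was chosen for determinism and exact reducibility to order statistics; with
thousands of distinct values the two rules differ at most in the last
printed decimal.

Point estimates only: the intended survey's public laboratory file lacks
the cluster variable, so no design-based variance, confidence interval or
p-value is computable, and the package does not pretend otherwise.

## The synthetic population

`generate_population()` emulates the analysis population's published
marginals: female 52.3%, black 48.8%, smokers 17.7%, antihypertensive use
23.4%, diabetes 13.9%; age normal (mean 53.4, SD 9.4) truncated to 40–74;
TC median 191 (IQR 169–216) mg/dL, HDL 44 (37–53) mg/dL, SBP 128
(116–140.5) mmHg. Continuous marginals are **shifted log-normals** solved to
match the three printed quantiles exactly; a plain two-parameter log-normal
cannot match both quartiles when the log-scale quartiles are asymmetric (as
for HDL and SBP), and the mismatch would exceed sampling error at the
n = 100,000 used in the marginal-recovery test. SBP and TC are truncated to
the atypical-value bounds, so the generator never produces an atypical
exclusion — mirroring the analysis this package emulates, which found none.

Dependence is a Gaussian copula with a sparse, configurable correlation
matrix (age–SBP 0.3, TC–HDL 0.1, age–diabetes 0.2, all else 0): enough
joint structure to make the agreement statistics non-degenerate, without
asserting a joint distribution no source reports. HbA1c is generated
consistently with the diabetes share under the 6.5% rule (diabetics draw
6.5 + Exp(mean 1.2)%, others a normal around 5.4% capped below 6.5%), and
the diagnosis categories exercise both imputation rules. Survey weights are
log-normal (meanlog log 1000, sdlog 0.5); every statistic downstream is
weight-scale invariant, so only their relative spread matters.

Contamination defaults — 3% of records missing one of SBP/TC/HDL, 5.5%/3%
heart-disease/stroke history, 10% of ages resampled outside 40–74 — are
there so every eligibility filter fires on default settings; they are not a
model of the survey's sampling frame or response process. What passing tests
on this population show is that the *pipeline machinery* is correct
(conservation, invariances, boundary semantics, marginal recovery); they say
nothing about how the three equations rank a real population, which depends
on the transcribed coefficient content discussed above.

Ages are kept continuous rather than rounded to survey-style integer years;
the scoring equations are continuous in age, and rounding is a data-ingestion
concern, not a generator one.

## Numerical and design choices

* Stratum boundary values sit exactly on cut points (10% → intermediate), and
  the fold criterion is strict at 1.25; both are asserted at the boundary.
* The AC1 denominator `1 − Pe` cannot vanish for a proper table
  (`Pe ≤ 1/q`), but a degenerate-table error is raised defensively.
* Coefficient checksums make the data files tamper-evident; files whose
  numerical content is reconstructed rather than transcribed are suffixed
  `_synthetic` and say so in their `source` field.
* Problem sizes used by the checks: exhaustive AC1 enumeration over all
  2×2 and 3×3 integer tables with n ≤ 12; monotonicity grids over ages
  40–74 and SBP 90–200 mmHg (the range over which the published equations
  were derived and are used); pipeline properties at n = 2,000; marginal
  recovery at n = 100,000 with bootstrap (B = 200) standard errors; the
  acceptance script simulates n = 20,000. These sizes make every check's
  sampling error small relative to its tolerance while keeping the whole
  suite quick on a laptop.

## Known limitations

* Two of the three coefficient files are synthetic stand-ins (see above);
  shipped results characterize the pipeline and the models' forms, not the
  exact published equations.
* No design-based inference (by construction of the intended data source).
* The generator draws one SBP per person; if a survey provides repeated
  measurements, averaging them is the ingesting user's responsibility.
* Reading fixed-width national microdata dialects is out of scope; ingest
  via CSV plus a column mapping (`read_survey_csv()`).
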