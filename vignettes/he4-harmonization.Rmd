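---
title: "Harmonizing HE4 across immunoassay platforms and evaluating marker accuracy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing HE4 across immunoassay platforms and evaluating marker accuracy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(he4align)
```

## The problem

HE4 is measured on several automated immunoassay families (competitive
chemiluminescent enzyme immunoassays, electrochemiluminescence, and
chemiluminescent microparticle assays) that use different antibody pairs and
detection chemistries. The same serum yields systematically different
concentrations on different platforms, so a cut-off derived on one
instrument does not transfer to another. `he4align` implements a two-part
workflow: detect and correct inter-laboratory bias using a shared
calibration curve, then evaluate the harmonized marker's diagnostic
accuracy with a covariate-adjusted ROC regression.

## Ordinary least product regression

Each laboratory measures the same ten-sample dilution series (bundled as
`he4_calibration_curve()`, spanning roughly 30 to 1074 pmol/L). Because both
the reference and the test instrument carry measurement error, ordinary
least squares of one on the other is attenuated; the package instead fits
the **ordinary least product** (geometric-mean) line, which minimizes the
sum of products of vertical and horizontal deviations and is symmetric in
the two axes:

$$\hat\beta = \operatorname{sign}(S_{xy})\sqrt{S_{yy}/S_{xx}}, \qquad
  \hat\alpha = \bar y - \hat\beta \bar x,$$

with $x$ the test-lab and $y$ the reference-lab readings. The model
direction `reference = α + β · test` is chosen so that the correction
`adjusted = α + β · raw` maps a biased laboratory's raw values onto the
reference scale; labs that read *low* therefore get β > 1.

**Confidence intervals.** The default analytic intervals follow Ludbrook's
construction: with $B = t^2(1-r^2)/(n-2)$ and $t$ the two-sided critical
value on $n-2$ df, the slope limits are $\hat\beta(\sqrt{B+1} \mp \sqrt B)$
and each slope limit, paired with the centroid, gives an intercept limit. A
fixed bias is declared when the intercept CI excludes 0 and a proportional
bias when the slope CI excludes 1; only flagged laboratories are corrected
under the default `biased_only` policy (`always` and `never` are
available — pooled summaries of adjusted values are often wanted for all
labs).

The analytic interval assumes homoscedastic errors. Immunoassay noise is
closer to *multiplicative* (a roughly constant coefficient of variation),
and on a dilution design dominated by its top concentration this makes the
analytic slope interval anti-conservative: in our simulations its coverage
of a true slope fell well below nominal while the pairs-bootstrap interval
(`ci_method = "bootstrap"`, 2000 resamples) stayed at the nominal rate. The
analytic method remains the default because it is deterministic and is the
one whose significance pattern anchors the bundled calibration table; the
bootstrap is the recommended robustness check, and the coverage property is
asserted for it in the test suite.

**Numerical edge cases.** Series must have at least 3 strictly positive,
finite concentrations and non-zero variance; replicate readings are averaged
per sample before fitting; negatively correlated series fit with a warning
(they indicate data corruption, not a meaningful bias); adjusted
concentrations below zero — possible for small raw values under a negative
fitted intercept — are clamped to 0 with a warning.

## Two-stage ROC regression

Factors can shift a marker's *level* without changing its *accuracy*, and
vice versa; the two-stage formulation separates them.

1. **Control model.** Ordinary least squares of the marker on covariates
   among disease-free subjects (benign plus healthy). The default
   covariates are creatinine and menopausal status; age is deliberately
   excluded by default because it is nearly collinear with menopausal
   status, and the fit refuses designs whose condition number exceeds 1e8.

2. **Placement values and ROC-GLM.** Each case's placement value is the
   fraction of control-model residuals strictly above the case's residual —
   the covariate-adjusted fraction of controls exceeding it. For a grid of
   false-positive rates $u$ (default 30 interior points $k/31$; endpoints
   excluded because the probit diverges), the indicators
   $U_{iu} = 1\{PV_i \le u\}$ follow a probit-link GLM
   $P(U_{iu}=1) = \Phi(\gamma_0 + \gamma_1\Phi^{-1}(u) + \beta'X_i)$, so a
   positive covariate coefficient means the covariate *increases*
   discriminatory accuracy at every operating point. The implied AUC at
   covariates $X$ has the closed binormal form
   $\Phi\big((\gamma_0+\beta'X)/\sqrt{1+\gamma_1^2}\big)$. Placement values
   of exactly 0 or 1 are moved to $1/(2n_0)$ from the boundary inside the
   indicator construction only, keeping grid-end indicators informative;
   fully separated samples are rejected with advice rather than fitted.

3. **Cluster bootstrap.** Hospitals are resampled with replacement (the
   same number per replicate) and the *entire* two-stage procedure is
   refitted per replicate; 50 replicates by default, each seeded
   deterministically as `seed + replicate`, so results are exactly
   reproducible and extendable. Replicates whose resample lacks a class are
   discarded (more than 20% discarded is an error). Intervals are
   normal-approximation (estimate ± z · bootstrap SD) by default: with ~50
   replicates a percentile interval's 2.5% tail rests on roughly one order
   statistic and runs short — we measured clearly sub-nominal null coverage
   for percentile intervals at this replicate count, while normal intervals
   were near nominal. Percentile intervals remain available
   (`ci_type = "percentile"`). With very few clusters (the motivating
   setting has six hospitals) any cluster bootstrap is anti-conservative;
   the coverage property in the test suite therefore uses 30 clusters,
   where bootstrap asymptotics are meaningful, and the six-cluster setting
   should be read with that caveat.

## Cut-offs, dichotomization and AUC comparison

The HE4 cut-off in each analysis stratum maximizes the Youden index
$J = Se + Sp - 1$ over every observed value used as a strict `>` threshold;
ties are broken toward the smallest threshold (maximizing sensitivity at
equal $J$) and the winner is rounded to the nearest integer pmol/L by
default (`rounding = "none"` disables this). Ca125 uses the conventional
fixed cut-off of > 35 IU/mL, strict inequality throughout. Dichotomous
markers are compared on the same subjects with DeLong's paired test; its
variance is validated in the tests against a leave-one-out jackknife and
against `pROC`. For a dichotomized marker the empirical AUC reduces to
$(Se+Sp)/2$, which is asserted as an invariant.

## Study pipeline

`run_study()` chains: OLP bias fitting → harmonization → eligibility →
full-cohort ROC regression → four strata × two contrasts → the sensitivity
analysis. Eligibility excludes, in order (first matching rule logged):
missing age; age outside 18–70; creatinine ≤ 0.3 or > 3 mg/dL (renal
function alters HE4); premenopausal status recorded with age > 55
(inconsistent records); missing or unrecognized diagnosis group. Strata are
pre-menopausal ≤ 40 / > 40 years and post-menopausal ≤ 60 / > 60 years. The
two contrasts are malignant vs everyone else and malignant vs benign only;
the sensitivity analysis restricts benign diagnoses to ovarian, annexal and
peritoneal lesions and endometriosis. The sample-size calculator uses
$n_{cases} = \lceil z^2 Se(1-Se)/d^2\rceil$ cases and
$\lceil n_{cases}/\text{prevalence}\rceil$ total subjects, with the CI
*half*-width $d$; at prevalence 0.20, Se 0.85, 95% confidence and $d=0.05$
this gives 980, the planning figure the defaults reproduce. The full-width
reading of "CI width 0.05" would quadruple the case count and is
incompatible with that figure, which settled the ambiguity.

## The synthetic-data generator

No patient-level data ship with the package; the generator produces cohorts
with the structure the analysis assumes.

* **Calibration experiments** invert the harmonization map: a lab with true
  bias $(\alpha^*, \beta^*)$ reads $(\text{true}-\alpha^*)/\beta^*$, times
  multiplicative noise at the platform's coefficient of variation, floored
  at 3.5 pmol/L (instruments do not report below their limit of
  quantitation). Duplicate readings are averaged, as calibration samples
  are conventionally run in duplicate. Default lab parameters are the
  biases estimated from the bundled curve with CVs at the manufacturers'
  declared totals (3.2% CLEIA, 10% ECLIA and CMIA-Architect, 4.9%
  CMIA-Alinity).
* **Cohorts** default to 627 malignant / 583 benign / 299 healthy women.
  HE4 and Ca125 are lognormal per group with parameters moment-matched to
  the target arithmetic means and SDs (e.g. malignant HE4 474.1/1207
  pmol/L — an SD far above the mean forces a heavy-tailed family, which is
  why lognormal was chosen). The malignant-group Ca125 dispersion is set to
  twice its mean: the small printed SD that would otherwise be implied is
  implausible for this marker and is treated as unreliable. Age is
  truncated normal on 18–70 per group; menopausal status is Bernoulli per
  group but forced consistent with age (never post-menopausal under 40,
  always over 55) so generated cohorts do not trip the eligibility filter
  by accident — an optional contamination count injects rule-violating
  records for testing the filter. Post-menopausal cases get an extra
  separation shift of 0.5 on the probit scale by default, reproducing the
  qualitative finding that accuracy is higher after menopause. Each subject
  is assigned a hospital whose platform bias is inverted (plus assay noise,
  LoQ-floored) to produce the raw HE4 reading, so harmonization should
  recover the latent reference-scale value.

**What the generator does not emulate:** assay-specific epitope or splice
variant effects, within-subject longitudinal variation, informative
hospital case-mix differences, or missing-data mechanisms. Passing tests
demonstrate that the machinery recovers known structure under this model,
not that any particular clinical conclusion holds in real cohorts.

## Problem sizes and test design

The validation suite uses sizes chosen to make sampling error small
relative to the asserted tolerances while keeping the suite quick:
binormal ROC-GLM recovery at 2000 cases/2000 controls; two-stage vs
Mann–Whitney AUC agreement at 1500/1500; OLP CI coverage over 250
simulated calibration experiments with 1000-resample bootstrap intervals;
null-marker bootstrap coverage over 100 replicates of a 150/150 cohort
with 30 clusters and 50 bootstrap replicates each.

The end-to-end bias-recovery check regresses harmonized HE4 on the latent
true HE4 per laboratory and asserts slope within 1 ± 0.05 and intercept
within ±5 pmol/L. Its calibration experiment uses a 2% CV and ten
replicate readings: with duplicate readings at a 10% CV the calibration
slope itself carries sampling error of about 5%, so recovery at the
asserted precision would measure assay noise rather than pipeline
correctness (that noise propagation is covered instead by the coverage
property). The regression is weighted by $1/\text{true}^2$, matching the
multiplicative error model, and restricted to raw readings ≥ 20 pmol/L,
inside the platforms' declared linearity range, where the LoQ floor cannot
distort the line.

## Known limitations

* The affine bias model cannot represent a laboratory whose fixed bias
  exceeds the lowest calibration concentration without leaving the
  instrument's reportable range; harmonization below ~20 pmol/L (well
  under any clinically used HE4 cut-off) should not be trusted.
* Analytic OLP intervals are anti-conservative under multiplicative noise
  (use the bootstrap when that matters).
* Cluster-bootstrap intervals with six clusters are anti-conservative;
  interpret borderline covariate effects cautiously.
* Ca125 passes through unharmonized: the calibration exercise concerns HE4
  only, and no shared Ca125 curve exists to fit.

## A minimal session

```{r example}
fits <- fit_all_labs(he4_calibration_curve(), reference_lab = "lab1")
classify_biases(fits, reference_lab = "lab1")
```
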