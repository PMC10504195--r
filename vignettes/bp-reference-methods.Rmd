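---
title: "Constructing pediatric blood-pressure reference tables: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing pediatric blood-pressure reference tables: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bpcentile)
```

## The problem

Clinical assessment of a young child's blood pressure (BP) requires
reference values: the BP below which a stated proportion of healthy
children of the same sex and body size falls. Because BP in toddlers
varies with stature much more than with anything else measurable at the
bedside, reference tables are indexed by sex, height percentile and BP
percentile. `bpcentile` implements the full construction pipeline for a
single-age (2-year-old) cohort measured in triplicate by auscultation:

1. triplicate measurement selection (the `<` 5 mmHg consecutive-pair rule);
2. height Z-scoring (`Zht`) against a pluggable LMS growth standard;
3. a six-criterion exclusion cascade with participant-flow accounting;
4. sex-stratified centile estimation over `Zht`, by the LMS (BCCG)
   method and by a quartic-polynomial comparison model;
5. height-percentile x BP-percentile reference tables in integer mmHg;
6. fit diagnostics (observed-vs-fitted curves, residual density, normal
   Q-Q), emitted as data.

Cohorts of this kind are typically access-restricted, so the package also
ships a synthetic-cohort generator whose truth surfaces are calibrated to
a published reference table; every stage of the pipeline is testable
against a known ground truth.

## The LMS (BCCG) model

At a fixed height Z-score `z`, BP is modelled as Box-Cox-Cole-Green
(BCCG) distributed: a power transform of a log-normal-like family with
three parameters, the Box-Cox power `L(z)` (skewness), the median `M(z)`
(mmHg) and the coefficient of variation `S(z)`. The transform to a
standard-normal score is

    zscore(y) = ((y/M)^L - 1) / (L*S)      (L != 0)
    zscore(y) = log(y/M) / S               (L  = 0)

and any centile is closed-form: `C(p; z) = M * (1 + L*S*qnorm(p))^(1/L)`.
`fit_lms()` estimates the three curves by penalized maximum likelihood in
the Cole-Green backfitting scheme: each curve in turn receives a
Fisher-scoring update that is then smoothed over `z` by a cubic smoothing
spline at a fixed equivalent degrees of freedom (edf). The
expected-information weights are `(1 + 2 L^2 S^2)/S^2` for `log M`, `2`
for `log S` and `7 S^2 / 4` for `L`. A likelihood decrease triggers
step-halving toward the previous iterate; convergence is declared when
the relative log-likelihood change falls below `1e-6` (cap 200
iterations), and a model that cannot converge is reported as an error
naming the edf triple, never silently returned.

Smoothness is selected by BIC, `-2*loglik + log(n) * (edf_L + edf_M +
edf_S)`, over a grid of edf triples. The default grid
(`default_edf_grid()`) allows `edf_M` in 2-5, `edf_S` in 1-3 and `edf_L`
in 1-2, where 1 means a constant and 2 a straight line: in a single-age
cohort the median needs the most flexibility, the spread less, and the
skewness is at most linear in `z`. The BIC uses the unpenalized
log-likelihood at the fitted curves with the summed edf as the parameter
count — the conventional accounting for smoothers; a penalized variant
would only shift all grid points by similar amounts.

Fitted curves are stored as values on a dense `Zht` grid (201 points plus
the seven tabulated height-percentile knots) and interpolated linearly;
at that spacing the interpolation error is orders of magnitude below
sampling error, and the representation serializes losslessly
(`write_lms_model()` exports `%.17g` CSV, and a re-imported model
reproduces its reference table bit for bit). Centile evaluation outside
the fitted `Zht` range is refused unless `allow_extrapolation = TRUE`
(flat extension), because a spline has no information there.

## The polynomial comparison model

`fit_bp_polynomial()` is ordinary least squares of BP on `(1, z, z^2,
z^3, z^4)` per sex and outcome, following the established US
reference-table methodology with age terms dropped for a single-age
cohort. The source methodology does not state how percentiles are formed
from the fit; we use the normal residual model `mean(z) +
qnorm(p) * resid_sd` (residual SD on `n - 5` degrees of freedom), which
is the standard reading and reduces to the LMS model when `L = 1` and `S`
is constant. Sex is handled by stratification (separate fits); a
pooled-with-indicator variant is available via `pooled_sex = TRUE`
because the methodology's wording admits either reading.

## Measurement selection and exclusions

`select_bp_value()` adopts the mean of two consecutive readings differing
by less than 5 mmHg, preferring the second/third pair, falling back to
the first/second, and — only when the second reading is missing — to the
first/third. A difference of exactly 5 mmHg disqualifies a pair
("unstable BP" is defined as >= 5 mmHg between consecutive readings). The
rule runs separately per channel, so a child can enter the systolic
analysis and not the diastolic one. Two readings missing rejects the
triplet. Two boundary interpretations are deliberately conservative and
isolated in one function: (a) when only the first pair qualifies it is
used, since later readings are preferred by all major guidelines but the
rule's wording covers any consecutive pair; (b) when the second reading
is present but both consecutive pairs fail, the first/third pair is never
consulted. A diastolic reading of 0 mmHg (unreadable Korotkoff phase V)
rejects the channel whenever the adopted pair contains the zero or no
pair can be adopted at all; an accepted pair of non-zero readings stands.

`apply_exclusions()` applies, in order: (1) chronic disease; (2)+(3)
missing readings / zero diastolic / unstable measurement condition (one
grouped flowchart box, with sub-reasons logged); (4) unstable BP by the
5 mmHg rule; (5) missing covariates or height beyond 5 SD of the growth
standard; (6) age under 24 months. Each child lands in exactly one bucket
per channel — the first applicable — so bucket counts depend on the
order, but membership of the analyzed set does not: a child is analyzed
exactly when no criterion applies (a tested property). Selected values
are kept at one decimal (means of integers); rounding happens only in
table output, half away from zero, since published tables print integers
and R's default round-half-even would bias cells at `.5` downward.

## Height Z-scores

`height_zscore()` applies the LMS transform using a growth-standard
table's `(L, M, S)` at the child's sex and age, interpolating the three
parameters linearly between tabulated months (months are the finest age
resolution collected in such surveys). A mean/SD standard is the `L = 1`
special case. The bundled `synthetic_growth_standard()` is a documented
stand-in — anchored at 84.0 cm around 27 months with a 0.2 cm/month
slope, CV 0.0345, L = 1 — not a national reference; any standard CSV
with columns `sex, age_months, L, M, S` can be supplied instead.

## The synthetic cohort and its calibration

The generator (`generate_cohort()`) defines the study conditions under
which the pipeline is validated:

* **Truth surfaces.** `jecs_presets()` inverts each height-percentile
  column of the published 2-year-old auscultatory reference table (four
  BP centiles per column) into a BCCG knot via
  `calibrate_bccg_from_quantiles()`: `M` is pinned to the printed median
  (the 50th centile of a BCCG is its median), and `(L, S)` are fitted by
  least squares **bounded** so that every printed cell is reproduced
  within 0.5 mmHg — the rounding half-width of an integer table, hence
  the tightest claim the printed evidence supports. Plain least squares
  can exceed that bound (by 0.003 mmHg at one cell of one column) because
  the integers are themselves rounded; the bound restores consistency
  with rounding. Between knots the three parameters are interpolated by a
  monotone (Fritsch-Carlson) cubic and held flat beyond the outermost
  knots, where the table carries no information. Because integer rounding
  leaves `(L, S)` only weakly identified per column, the calibrated knot
  sequences wobble column to column; the wobble is within what the
  printed integers cannot distinguish, and the anchor cells used for
  validation sit exactly on knots.

* **Cohort structure.** Defaults: height normal with mean 84.0 cm, SD
  2.9 cm (truncated at 5 SD of the bundled standard), 49.7% boys, ages
  uniform over 24-30 months, matching the published cohort's
  descriptives. True SBP and DBP are drawn from the sex-specific truth
  surfaces at the child's realized `Zht`, coupled by a Gaussian copula
  with correlation 0.5 (a typical SBP-DBP correlation; the source does
  not report one).

* **Readings.** Each of the three readings adds independent Gaussian
  within-child noise (SD 2 mmHg by default) and is rounded to 2 mmHg,
  the auscultatory reading convention. The within-child SD is a **free
  parameter** of the generator, not an estimate from the source cohort,
  which reports no repeat-measurement variance; 2 mmHg is at the low end
  of reported auscultatory repeatability and keeps the selected value
  (mean of two readings) within ~1.4 mmHg of the child's true BP.

* **Nuisance categories.** Chronic disease, unstable conditions
  (crying/sleeping/fever), planted unstable triplets, a zero diastolic,
  missing second readings, underage children and deliberate height
  outliers are planted mutually exclusively at configured rates and
  recorded in `planted_category`, so flow accounting can be checked
  against the generator's own bookkeeping (`planted_flow()`, exact under
  zero reading noise). The plain `sim_config()` defaults set all nuisance
  rates to zero — a pure-sampling cohort in which the analyzed size
  equals the simulated size, which is what parameter-recovery experiments
  need; `jecs_rates()` documents a rate set whose magnitudes emulate the
  published participant flowchart for exercising the exclusion machinery.

What the generator does **not** emulate: regional-center effects,
seasonal BP variation, gestational-age effects, any age trend in BP
within the 24-30-month window, and examiner or device biases. Passing
recovery tests therefore demonstrates that the estimation machinery
inverts its own generating process at realistic sample sizes — not that
the pipeline would reproduce a real cohort's tables from real data.

## Reference tables

`build_reference_table()` evaluates a fitted model at the `Zht` values
`qnorm(height percentile)` for height percentiles {5, 10, 25, 50, 75,
90, 95} and BP percentiles {50, 90, 95, 99} (both configurable), checks
that unrounded cells increase strictly down each column, and rounds half
away from zero to integer mmHg. Normal quantiles are used at full double
precision, not 4-decimal textbook constants. `compare_tables()` reports
cellwise differences between the LMS and polynomial tables.

## Validation design and problem sizes

The test suite checks, among others: exhaustive agreement of the
selection rule with a brute-force oracle over all integer triplets in
[60, 140]^3 including missing-slot variants; BCCG identities (median,
normal case, round trip to 1e-10, L -> 0 continuity); recovery of a
constant truth (L = 1, M = 90, S = 0.09) at n = 5000 over 20 seeds to
within 0.5 mmHg in M and 0.01 in S across `Zht` in [-2, 2]; agreement of
LMS and polynomial tables within 1 mmHg on homoskedastic normal data
(n = 5000); end-to-end recovery of the published anchor cells from
preset-calibrated cohorts at the published analysis sizes (n = 3139
systolic, 3042 diastolic; exact at the package's default seed 1 and
within 1 mmHg in at least 18 of 20 seeds); and exact equality of flow
accounting with planted counts on a noise-free cohort of 4988 children.
Distributional screens (Kolmogorov-Smirnov on z-residuals, Q-Q
tracking) run at n = 2000-10000 with 10-12 replicates — sizes chosen to
make Monte-Carlo error small relative to the asserted tolerances while
keeping the default test run fast.

## Known limitations

* Single-age design: no age-surface smoothing; applying the fits outside
  roughly 24-30 months is unsupported.
* The BCCG family models skewness only; kurtosis extensions (BCT/BCPE)
  are out of scope.
* Truth-surface calibration inherits the granularity of a printed integer
  table: distinct `(L, S)` within rounding distance are indistinguishable,
  so tail behavior beyond the 99th centile is not pinned down.
* The bundled growth standard is synthetic; real Z-scores require the
  user's national reference table.
* `fit_lms()` refuses to extrapolate; tables at the 5th/95th height
  percentile require the data's `Zht` range to cover ±1.645 (at the
  default cohort sizes it always does) or an explicit
  `allow_extrapolation` flag.

## A minimal worked run

```{r example, eval = FALSE}
cfg <- run_config(simulate = list(n_children = 3361),
                  out_dir = "run1", seed = 1)
res <- run_pipeline(cfg)
res$flow
res$tables$lms_boy_SBP
```
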