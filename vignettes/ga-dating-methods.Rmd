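---
title: "Gestational age dating, agreement evaluation and cohort simulation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gestational age dating, agreement evaluation and cohort simulation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gestage)
```

## The problem

Every routinely available estimate of gestational age (GA) at birth is
imperfect in its own way.  Menstrual dating (birth date minus the first day
of the last menstrual period, LMP) is universally collectable but relies on
recall of an event months in the past; ultrasound dating degrades as
pregnancy advances because fetal size becomes more variable; and neonatal
maturity exams such as the Capurro score compress the extremes of the GA
distribution toward term.  Where early ultrasound coverage is incomplete,
an analysis must combine these sources explicitly rather than pretend one
of them is truth.  `gestage` implements that combination as a transparent,
testable pipeline: per-source dating, biological plausibility screening via
birthweight, hierarchical selection, and a full agreement battery.

## Dating conventions

All GA arithmetic is in integer days; completed weeks are `floor(days/7)`.
Both dating formulas are pure calendar arithmetic, so no fractional weeks
ever arise:

* LMP: `GA = birth_date − lmp_date` (exact day count);
* ultrasound: `GA = (birth_date − exam_date) + clinician GA at exam`.

Ultrasound windows use completed-week semantics: "7–20 weeks" means 7w0d
through 20w6d, i.e. 49–146 days; 21–28 weeks is 147–202; 29+ weeks is
≥ 203.  Exams before 49 days belong to no window.  Within a window the exam
performed *earliest in gestation* is used, with ties broken by record order
so results never depend on incidental sort order.  Maturity cut-offs follow
the standard completed-week convention: preterm < 259 days (37 weeks),
post-term ≥ 294 days (42 weeks).

An alternative reading would truncate the first window at 20w0d; we adopt
the inclusive completed-week reading throughout because window labels
elsewhere in the pipeline ("21–28") unambiguously denote completed weeks,
and a mixed convention would create a 6-day gap between windows.

## Birthweight-for-GA screening

A grossly wrong GA usually makes the observed birthweight implausible for
that GA.  We score `z = (weight − μ(sex, week)) / σ(sex, week)` against a
sex × completed-week growth reference and flag |z| ≥ 3.  Two boundary
conventions circulate ("beyond 3 SD" vs "at or beyond 3 SD"); the package
defaults to the inclusive rule, with `strict = TRUE` available, because the
inclusive form is the one used when analyses exclude outliers.  GA weeks
outside the reference range (22–44) are clamped to the nearest covered week
with a warning: a candidate GA of, say, 18 weeks for a 3 kg newborn should
be *flagged*, not error out, and clamping achieves exactly that.

The bundled reference is deliberately synthetic: a per-sex logistic median
curve (asymptote ≈ 4.2–4.3 kg, midpoint ≈ 31.6 weeks, steepness 0.205/week)
with SD equal to 12% of the mean.  It has realistic magnitudes and the
right monotone shape, and because the simulator draws birthweights from the
same table, the Z-score machinery is exactly self-consistent: weights drawn
from the reference show the two-sided normal tail rate beyond 3 SD
(≈ 0.27%), which the test suite verifies.  It is *not* a published growth
standard; `read_growth_reference()` accepts any `sex,week,mean_g,sd_g`
table for real analyses.

## The assignment algorithm

`assign_ga()` walks a priority list — by default US 7–20 w, US 21–28 w,
US 29+ w, LMP — and assigns the first available estimate that does not make
the birthweight an outlier.  Two design points deserve emphasis:

* **The outlier rule is re-evaluated per candidate.**  The Z-score depends
  on the candidate GA, so a record can be outlying under its early
  ultrasound but plausible under its mid-pregnancy one; the algorithm then
  falls through rather than discarding the newborn.  The alternative
  (excluding the newborn whenever its top source is an outlier) would leave
  the lower entrance criteria nearly empty, which is inconsistent with how
  such algorithms populate their second tier in practice.
* **The Capurro exam is excluded from the default priority** because its
  chance-corrected agreement with early ultrasound on prematurity is poor —
  its shrinkage toward term reclassifies moderately preterm newborns as
  term.  It can be appended via `priority = c(..., "CAPURRO")` for
  sensitivity analyses, and an `lmp_certain_only` flag restricts the LMP
  tier to women sure of their date.

Unclassified is a valid outcome, not an error; every skipped source is
recorded in an exclusion trail (`missing`, `outlier`, or `invalid` for
undatable intervals), and the entrance tally always conserves the cohort
size.

## Agreement battery

Comparisons are pairwise-complete: each method-vs-reference analysis is
restricted to records carrying both estimates.  For each dichotomy
(preterm vs not, post-term vs not) we report unweighted Cohen's kappa with
Landis–Koch bands, sensitivity, specificity, PPV and NPV (reference taken
as truth), and a Pearson chi-square (1 df, no continuity correction)
comparing the two methods' rates.  The chi-square deliberately treats the
two methods as independent samples — this mirrors the classical
presentation of such tables — but ignores the pairing; a McNemar variant on
the discordant cells is available (`paired = TRUE`) for methodologically
stricter use.  Zero-denominator metrics return an explicit `NA` marker
(rendered "—"), never 0, so "no positive calls" is distinguishable from
"all positive calls wrong".

Day differences (comparator − reference; positive = comparator dates the
pregnancy further along) are summarised in five bands — < −14, −14…−8, ±7,
+8…+14, > +14 days — the clinical thresholds at which an LMP date would be
replaced by a first- or second-trimester ultrasound date.  Percentages in
all report tables are rounded half-up to one decimal, matching how such
tables are conventionally printed (base R's round-half-even would disagree
at .x5 boundaries).

## What the simulator emulates

`simulate_cohort()` generates records under a versioned YAML config
(`inst/extdata/sim-config-default.yaml`).  The default availability rates
describe a public-sector antenatal cohort: LMP reported by 97.4% of women,
76.9% of those certain of the date; at least one ultrasound at 7–20 w for
78.6%, 21–28 w for 59.8%, 29+ w for 61.7%; a Capurro exam for 87.5%.  The
true-GA distribution is a three-component truncated-normal mixture with
12.5% preterm and 2% post-term mass; component means/SDs live in the config
file, not in code.

Error mechanisms, per source:

* **LMP.**  Certain dates get small symmetric error (SD 8 d); uncertain
  dates get wider error (SD 16 d) plus, with probability 0.25, a
  one-calendar-month slip using the actual length of the slipped month
  (recall is calendar-based, so a February slip moves 28 or 29 days, not a
  fixed 30).  Slips go toward a *later* reported date with probability 0.8,
  emulating women reporting the first missed period — which underestimates
  GA and inflates apparent prematurity.  No quantitative LMP error
  distribution is available to calibrate against, so these magnitudes are
  order-of-magnitude choices, fully exposed in the config and chosen once.
* **Ultrasound.**  One exam per available window, scheduled uniformly over
  the window's feasible days (a window is infeasible when birth occurs
  before it opens — why third-trimester dating cannot overestimate very
  preterm births).  The clinician GA at exam is truth plus window-specific
  error, SD 4 / 8 / 14 days for the three windows, reflecting the growth in
  biometric dating error with advancing gestation.  Downstream window
  grouping uses the *observed* GA, so noisy exams can migrate across window
  boundaries, slightly censoring the extremes of each window's error
  distribution — visible as a recovered SD a little below 14 for the third
  window.
* **Capurro.**  `GA_est = GA + 0.15 × (273 − GA) + noise (SD 5 d)`: a pull
  toward a term target that overestimates GA for preterm and underestimates
  it for post-term newborns, reproducing the sign pattern such exams show.
* **Birthweight.**  Drawn from the scoring growth reference at the *true*
  GA (multiplier × reference SD), plus gross transcription errors with
  probability 0.01 (uniform 500–6000 g) to exercise the outlier machinery.

Reproducibility: every record's draws come from a substream seeded
deterministically from `(master seed, record index)`, so a cohort of 15 is
a prefix of the cohort of 40 under the same seed and insertion order can
never change a record's values.

What the simulator does **not** emulate: correlation between covariates and
error magnitude (real recall error worsens with lower schooling and extreme
ages), digit preference in reported dates, multiple gestation, pregnancy
loss, or any calibration to a specific study's printed tables — the
marginals published in such studies do not identify the underlying error
distributions, and fitting them would be circular.  Passing tests therefore
demonstrate the pipeline's correctness and the *direction* of the classical
biases, not quantitative agreement with any particular population.

## Numerical and testing choices

Degenerate inputs are handled explicitly: kappa is `NA` with a warning when
expected agreement is 1; chi-square is `NA` when a class is empty; empty
comparisons error; an empty cohort flows through every stage as empty
output.  Dates are ISO-8601 only — in a package whose subject is date
misreporting, silently guessing day/month order would be absurd.

The test suite checks the statistics against brute-force oracles
(label-expansion kappa, textbook Pearson formula, an independent library
implementation), verifies the noiseless simulator limit in closed form
(every kappa exactly 1, all differences 0), and recovers configured error
SDs within ±15% at n = 5000.  Directional bias checks run at the default
cohort size of n = 1483; structural tests use cohorts of 50–600, sizes at
which every maturity class is reliably populated while the full suite stays
fast.

## Limitations

The bundled growth reference is a stand-in; results that depend on absolute
Z-values should use a published standard.  The unpaired chi-square
understates evidence relative to a paired test.  The algorithm selects a
single source per newborn; it never blends estimates, and it does not
impute GA for unclassified records.  Simulator parameters are plausible
defaults, not estimates.
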