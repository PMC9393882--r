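---
title: "Methods: the bidirectional spatial lag-grid case-crossover design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the bidirectional spatial lag-grid case-crossover design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splagcc)
```

# The design

A temporal case-crossover study compares a patient's exposure at the event
time with exposures at referent times, so each case is its own control and
all time-invariant confounders cancel. The spatial lag-grid variant keeps
the temporal referents but moves the *exposure location*: every analysis is
repeated with the exposure read not in the patient's grid of residence (the
index grid, lag 0) but in the grids 1–4 positions before it in a canonical
walk over the study lattice, plus three summary labels (01, 24, 04) that
average member exposures over lags {0,1}, {2,3,4} and {0,...,4}. If an
experimental exposure surface carries the same health signal as the baseline
surface out to lag k, the association is spatially homogeneous over k+1
adjacent grids — a homogeneous spatial area (HOSA) of width 12(k+1) km and
area 144(k+1) km² on the 12-km lattice.

## The lattice and the canonical ordering

`baltimore_lattice()` ships the 11 × 9 study lattice (99 cells, rows south
to north, columns west to east) with its 15 monitor cells (17 monitors; the
Baltimore-city cell at row 6, column 6 holds three). Lag grids are assigned
within a *monitor condition subset* — cells without monitors ("No"), with
monitors ("Yes"), or all cells ("Both") — by walking the subset's canonical
ordering: **row descending, then column ascending**, treated as a ring.

This ordering is a design decision. The source material's prose footnote
("column first, row second") contradicts all three of its own worked
examples; (row descending, column ascending) is the unique simple sort that
reproduces every example, including the monitor-only sequence
(6,7) → (6,6) → (7,7) → (7,6) → (7,5) and the rule that an index grid in
column 4 takes its fourth lag from column 9 one row above. The golden tests
pin all three sequences. Two further conventions close gaps the examples do
not reach:

* **Ring wrap.** Nothing specifies what happens when the walk runs off the
  start of the ordering (e.g. an index grid at (11, 2)). The ordering is
  treated as a ring — the predecessor of the first cell is the last cell —
  which keeps lag assignment a total function; such sequences are flagged
  `wrapped_around_lattice` so analysts can exclude them.
* **Half-open cells.** Centroid-to-grid assignment treats each cell square
  as half-open (west and south edges inclusive), so every point maps to
  exactly one cell, including points on shared edges.

Lag cells in the index row *precede* the index grid in the walk; lag cells
pushed into the row above *follow* it, which is what makes the spatial
design bidirectional. `precede_follow_table()` reports both unweighted and
observation-weighted percentages; the printed percentages in the source
material could not be reproduced by unweighted tallies under any tested
definition (they likely weight by per-grid record counts from the
confidential data), so no numerical target is asserted on them.

## Strata and referents

One stratum per event: the case takes the mean exposure of its calendar
quarter (Q1 = Jan–Mar, ..., fixed by the printed case mean monthly ranks
2.0/5.0/8.0/11.0); controls 1–3 take referent means over the month sets
{1,4,7,10}, {2,5,8,11}, {3,6,9,12} (mean ranks 5.5/6.5/7.5). All four
members share the matching key (5-year age band, gender, race, insurance,
ZIP, year, day of week; the 5-year band width is a configurable default —
the matching variable list is fixed but the band width was never stated).
Everything is computed from **monthly grid means**: the stratum construction
is defined entirely on monthly means, so the package stores monthly values
and derives quarterly/referent means from them. Missing months (possible for
the non-gap-filled surfaces) are skipped with a completeness flag; a member
whose month set is entirely missing drops its event with a logged reason —
silent dropping would hide data loss.

Warm season defaults to April–September (configurable). The source
material never defines its warm/cold boundary (it inherits one from an
earlier companion study); a symmetric 6-month split consistent with the
quarterly structure is the package default.

# Conditional logistic regression

For stratum *s* with case *i(s)*, the conditional likelihood contribution is
`exp(x_i' beta) / sum_{j in s} exp(x_j' beta)`; `fit_clr()` maximizes the
log-likelihood by Newton–Raphson with analytic score and Hessian,
per-stratum log-sum-exp stabilization and step halving. Standard errors come
from the inverse observed information; ORs, 95% CIs and p-values are Wald
(matching the OR (95% CI) presentation convention; a likelihood-ratio test
is reported alongside). Convergence requires a relative log-likelihood
change below 1e-10 and maximum absolute score below 1e-6 — chosen, not
inherited.

**Matched covariates.** Covariates constant within every stratum cancel from
the conditional likelihood; they are detected by within-stratum centering
and dropped with a message rather than an error.

**Separation.** A diverging coefficient is flagged when it exceeds 10 on the
within-stratum standardized scale *and* its Wald z is below 3. The second
condition matters: under genuine (quasi-)complete separation the observed
information collapses, so z → 0 while beta diverges; whereas strongly
identified but collinear pairs — apparent temperature and its square, whose
individual standardized coefficients legitimately reach ~50 with z ≈ 6.5 —
must not be misflagged. (A plain |standardized beta| threshold, the obvious
first choice, fails exactly there.)

**Effect-modifier screening.** Candidate modifiers are screened in four
separate grouped runs (comorbidities; gender/age/race;
insurance/poverty/log-density; season); a modifier enters the final model
when its term's two-sided Wald p ≤ 0.09. Whether "its term" means the
modifier's own coefficient or an exposure-by-modifier interaction is
ambiguous in the source; the default screens the modifier's own term, with
`mode = "interaction"` as a switch. Under the null this retains a pure-noise
modifier ~9% of the time, which the acceptance suite verifies over 500
replicates.

## Two referent-design artefacts at monthly aggregation

Both surfaced during implementation and are properties of the referent
scheme itself, not of the fitter:

1. **The squared-AT term.** Each referent month set averages one month per
   season, so every control sits near the annual apparent-temperature mean
   while extreme-quarter cases sit at parabola extremes: a convex AT term
   can discriminate case status almost perfectly and the likelihood
   quasi-separates (an independent implementation, `survival::clogit`, also
   fails to converge there). In the original daily-resolution setting,
   day-to-day weather variation blurs this. `run_config(include_at_sq=)`
   therefore defaults the term off while `build_strata()` still supplies it.
2. **Season-specific slopes.** Stratifying by season (or, equivalently, a
   season × exposure interaction on raw exposures — season is constant
   within a stratum) leaves the within-season exposure contrast dominated by
   the deterministic annual cycle, driving season-specific slopes to absurd
   values. The pipeline computes warm/cold ORs on **seasonally adjusted
   exposures**: each member's exposure minus the cross-grid mean for its
   month set and year (a seasonal climatology), leaving the
   spatial/meteorological anomaly, whose season-specific slopes are
   identified. This is the package's construction; the source describes its
   seasonal computation only as "season interactions".

# HOSA delineation

Two ORs are compared with the point-outside-reference-CI rule: `or_a` is
significantly higher/lower than `or_b` when it falls strictly outside
`or_b`'s 95% CI (a point exactly on a bound is not significant). The rule is
anti-conservative relative to a two-sample z-test on the log-OR difference —
the test suite *measures* its type-I level (~17% for equal-width CIs) rather
than assuming it — and a `mode = "ztest"` alternative is provided. The lag
labels where an experimental surface's OR is higher than the baseline's form
the significant-lag set; summary labels imply their individual lags
(04 → {0,...,4}); and the HOSA is the maximal contiguous run of implied lags
containing lag 0 (width 0 if lag 0 is absent — a configuration never
observed in practice, flagged `contiguous = FALSE` when implied lags remain
outside the run). ΔOR% contrasts are `100·(OR_A − OR_B)/OR_B` (A =
no-monitor or warm); the formula is never printed in the source, but this
definition reproduces every qualitative sign statement there.

# Spatial diagnostics

Moran's I uses binary contiguity weights — rook by default, the simplest
scheme consistent with "adjacent and distant observation pairs"; queen and
distance-band are selectable — with expectation −1/(n−1) and variance under
the randomization assumption (normality selectable). The randomization
variance is validated in the tests against a 4000-draw permutation
distribution on a skewed field, and the statistic itself against a
brute-force double sum (1e-12) and the ±1 checkerboard identity (I = −1
exactly under rook weights). Categorical tables classify per-grid multi-year
means as Below/Within/Above the all-grids mean's 95% CI (strict
inequalities) and test category × condition tables with Pearson chi-square
(`stats::chisq.test`, no continuity correction); tables with an empty margin
are flagged degenerate instead of tested. Reported percents round half-up to
one decimal, matching printed-table conventions.

# The synthetic study generator

`simulate_study()` emulates the structure of the confidential study — never
its confidential values:

* monthly grid values = baseline (14 µg/m³) + seasonal cosine peaking in
  July (amplitude 2.5 µg/m³, giving the warm > cold pattern) + a
  moving-average-smoothed shared spatial field (a formal Gaussian process
  would buy nothing here: only the autocorrelation sign and range matter for
  testing Moran's I and HOSA recovery) + monitor-condition offsets
  (all surfaces except PMCK average higher in monitor grids; PMCK slightly
  higher in no-monitor grids) + surface-specific noise, truncated at zero;
* the noise standard deviations (PMCQ 0.5 < PMCKQ 1.0 < PMC 1.6 < PMCK 2.3)
  induce the observed cross-correlation ordering with the baseline,
  r(PMCQ) > r(PMCKQ) > r(PMC) > r(PMCK), asserted in the tests as an
  ordering, never as exact values;
* PMC and PMCQ are masked at a 20% missingness rate; PMCK and PMCKQ are
  their gap-filled (neighbourhood-mean) copies and are never missing;
* apparent temperature, pollen, holiday and snowstorm columns carry
  year-month anomalies and grid-level noise. This is deliberate: at monthly
  aggregation, deterministic calendar covariates would let the month-set
  fingerprint identify the case slot exactly and quasi-separate every fit;
  real data's daily and spatial variability prevents that, and the generator
  emulates it;
* events are drawn from candidate person-days with probability proportional
  to `exp(log(true OR per 10)/10 · PM(index grid, month))`, the effect
  confined to grids within a configurable Chebyshev range of source grids;
  demographics follow a configured mix; person-time is simulated directly as
  candidate events because the case-crossover design needs only cases and
  their referent exposures. The default true OR is 1.5 per 10 µg/m³ — the
  upper end of plausible short-term PM2.5 effects, chosen so that
  moderate-size simulations carry a detectable signal.

What the generator does **not** emulate: satellite retrieval and cloud
masks, real fusion-model posterior draws, daily (sub-monthly) variation,
real ZIP/ZCTA polygon geometry, health-care access patterns, and the
confidential OR magnitudes. Passing tests therefore demonstrate that the
machinery is correct and calibrated under the stated generating model, not
that the epidemiologic findings generalize.

## Calibration generators

Two stratum-level generators bypass the study machinery for statistical
calibration, sampling the case slot within each stratum with probability
proportional to `exp(score)` — exactly the model CLR fits:

* `simulate_clr_strata()` (score = β · exposure) drives the coverage and
  parameter-recovery experiments: over 500 replicates of 500 strata the 95%
  CI covers a true OR of 1.0 between 93% and 97% of the time, and over 200
  replicates of 2000 strata the mean fitted OR per 10 units lands within
  ±0.03 of a true 1.5.
* `simulate_lag_strata()` plants a known HOSA. Members carry exposures at
  lags 0–4 on a baseline surface `b` and an experimental surface
  `e = b + u`; the selection score is
  `β0 · mean_k b_k + βx · Σ_{k≤r} u_k`, so the shared component elevates the
  baseline ORs at every lag (as real baselines are) while the extra
  component acts only within the planted range r.

**Why the planted design needs the shared component.** Against a *null*
baseline, the summary label 04 always absorbs the lag-0 signal: the
projection of a lag-0 effect onto the 5-lag mean covariate has the same
per-unit coefficient, so 04 would be "significant" — and the recovered width
5 — for every planted range. With the shared component, writing ρ = βx/β0
and R = {0..r}, the experimental-minus-baseline log-OR contrast at label S
is proportional to

    ρ·|S ∩ R|  −  |S|/5,

negative at excluded labels (the experimental surface pays an attenuation
penalty of |S|/5 on the shared effect because var(e) > var(b)) and positive
at exactly the labels spanning R whenever ρ ∈ (0.2, 0.4); ρ = 0.3 maximizes
the margin (0.1·β0 at the weakest label) simultaneously for r ∈ {0, 1, 4}.

**Power.** The significance rule compares the experimental point estimate
with the *baseline's* CI, so the baseline's standard error — which scales
with 1/sd(b) — sets the threshold; sd(b) must not be small. With
sd(b) = sd(u) = 10 (abstract units), β0 = 0.25 per unit and 2000 strata, the
weakest-label margin is ≈ 4 combined standard errors (per-label detection
probability ≈ 0.99) and every excluded label sits ≥ 2.8 combined standard
errors below its threshold, so the median recovered width over 100
replicates equals r + 1 exactly for r ∈ {0, 1, 4}. These planted effects are
deliberately strong: the experiment tests the delineation logic, not
statistical power. (Marginal per-lag ORs are attenuated below the β0/5
projection by the unobserved-heterogeneity effect familiar from non-linear
models; the contrast algebra above is unaffected because both surfaces are
attenuated at the same label.)

# Problem sizes and numerical conventions

The test suite runs, on one CPU in a few minutes: 500 coverage replicates at
500 strata; 200 recovery replicates at 2000 strata; 100 HOSA-recovery
replicates per planted range at 2000 strata; 1000 white-noise Moran
replicates on the 99-cell lattice; 500 screening replicates at 300 strata;
4000 Moran permutations on a 6 × 6 field. All are seeded. Output formatting:
ORs to 3 decimals, percents to 1 decimal (half-up), fixed row ordering —
re-running a pipeline on the same inputs reproduces byte-identical CSVs.

# Known limitations

* Monthly aggregation is coarser than the daily satellite inputs of the
  original setting; the two referent-design artefacts above are the price,
  and the seasonal-anomaly construction is this package's own remedy.
* No robust/sandwich variance, no exact conditional inference for sparse
  strata, no multiple-testing correction across the surface × outcome × lag
  grid of OR comparisons (none is applied in the source either; the report
  logs the number of comparisons instead).
* The interval comparison rule is anti-conservative; use `mode = "ztest"`
  when a calibrated pairwise test matters.
* HOSA widths are sizes only: the design cannot say *which* grids form a
  HOSA, only how many adjacent lag grids behave homogeneously.
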