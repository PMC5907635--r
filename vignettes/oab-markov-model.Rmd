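---
title: "A Markov cost-utility model of oral antimuscarinic therapy for overactive bladder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cost-utility model of oral antimuscarinic therapy for overactive bladder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and model structure

`oabcea` implements a cohort state-transition model for the cost-utility
analysis of oral antimuscarinic agents in overactive bladder (OAB) from
a UK NHS perspective: monthly cycles over a five-year horizon, costs and
QALYs discounted at 3.5% per year, solifenacin 5 mg/day as the reference
strategy and eight oral comparators.

A model state is the product of a *symptom state* and a *pathway state*.
Symptoms are two dimensions — daily micturition frequency and daily
incontinence episodes — each with five ordered severity levels (level 1
best, level 5 worst). The pathway state records the treatment phase
(first-line drug, next-line A, next-line B, off-treatment, BTX-A success,
BTX-A failed), a months-on-current-treatment counter, the number of
failed oral lines (capped at 2+), and whether an adverse event (dry
mouth or constipation) is currently active. Two pieces of bookkeeping
extend the published state description because the pathway rules need
them: off-treatment states remember which line was last used (restarts
return to "the previous treatment"), and BTX-A success states carry a
months-since-injection counter so reinjection can occur 6-monthly. The
months-on-treatment counter runs 1, 2, 3, 4+ rather than capping at 3+:
the adverse-event window covers months 1–3 and must be distinguishable
from "month 4 and later", where the month-3 symptom matrix is reused.

The cohort distribution is stored as a (pathway state × symptom cell)
mass matrix; the symptom transition of a joint cell is the Kronecker
product of the two marginal 5×5 matrices, i.e. the two dimensions evolve
independently given the drug and month. Whether the original analysis
coupled them is not stated; independence is the natural reading of
per-dimension monthly matrices and is used throughout, including in the
calibration (each dimension is calibrated to its own NMA effect).

### Within-cycle event order

The published description does not fix an ordering, so the package
defines one and uses it everywhere (engine, microsimulation oracle,
documentation):

1. **Adverse-event onset.** Monthly probability converted from the
   3-month probability by the constant-hazard formula
   `1 − (1 − p3m)^(1/3)`; applied only in months 1–3 on the current drug
   and only if no AE is already active. Dry mouth and constipation act
   as independent risks; a single "AE active" flag carries the utility
   decrement.
2. **Discontinuation.** 90% per cycle if an AE is active *or onset this
   cycle* (this makes AE-driven discontinuation act in the AE's own
   cycle, which is how a "90% given adverse events" probability listed
   beside monthly probabilities is read here); otherwise the drug's
   monthly no-AE probability (6.8% base case).
3. **Switch or stop.** A discontinuing patient switches immediately to
   the next oral line with probability 26.1% (symptoms carried, AE flag
   cleared, month counter reset) or goes off-treatment (symptom
   distribution reset to baseline). Every discontinuation increments the
   failed-lines count, switch or not: BTX-A eligibility is "failed ≥ 2
   antimuscarinics", and a failed line is a discontinued line however it
   ended. From next-line B there is no further oral line, so all
   discontinuations go off-treatment.
4. **Restart / BTX-A.** Off-treatment patients with fewer than two
   failed lines restart at 5.6%/month, one-third each to the previous
   drug and the two configured next-line agents (tolterodine ER 4 mg and
   oxybutynin IR 10 mg by default; the source names neither). With two
   or more failed lines the only exit is BTX-A at 0.1%/month; all
   injected patients count as successes until each 6-month point, where
   70% are reinjected and 30% move to "BTX-A failed" and receive no
   further treatment.
5. **Symptom transition.** Patients remaining on a drug transition by
   that drug's month-indexed matrix (month-3 matrix from month 3 on);
   next-line phases use the tolterodine ER model, per the published
   assumption. New entrants to a line (switchers, restarters) hold their
   symptom distribution in the entry cycle and start month-1 dynamics
   the following cycle, so "k cycles on a drug" always means k matrix
   applications. Off-treatment and BTX-A phases hold the baseline
   distribution (whether BTX-A improves symptoms is not stated; a
   config-overridable BTX-A symptom distribution is provided, defaulting
   to baseline).

Costs and QALYs are computed on the **end-of-cycle** distribution: a
patient who develops an AE and stays on treatment bears the utility
decrement in the onset cycle ("applied for the duration of a cycle"),
and a switcher pays the new drug from the switch cycle. Visits are
event-driven: model entry costs one first GP visit (£65) plus specialist
visits; each later initiation (switch, restart, first BTX-A injection)
costs one follow-up GP visit (£27) plus specialist visits. The
resource-use table and the costing text disagree on specialist visits
per initiation (1 vs 1.5); the package defaults to 1 with
`specialist_visits_at_initiation` exposed. BTX-A reinjections cost the
injection price only (the £1,151.98 bundle already includes procedure
and nurse review; whether extra consultations apply is ambiguous, and
none are added). Pads follow incontinence-level occupancy in *all*
phases — pads track symptoms, not therapy.

No half-cycle correction is applied in the base case (the source is
silent); `settings$half_cycle_correction` averages occupancy-driven
quantities over cycle boundaries when enabled, leaving event-driven
tallies untouched. Discounting uses `(1 + r)^(−(t − 1)/12)` so cycle 1
is undiscounted.

## Estimation stages

**Transition regression.** `fit_transition_regression()` estimates, for
each of months 1–3, `P(level_m = j | level_{m−1} = i)`. The default
specification is saturated per origin level, whose maximum-likelihood
estimates are the observed destination frequencies — computed in closed
form, which doubles as the independent oracle in the tests. A smoothed
multinomial logit (linear in origin level, via `nnet::multinom`) is
available for sparse data. Origin levels with no observations get an
identity row and are flagged rather than silently imputed.

**Utility regression.** `fit_utility_regression()` is OLS of the EQ-5D
index on severity-level indicators (level 5 reference in each dimension)
plus sex, age and country, mirroring the published utility model. The
intercept estimates the utility of the worst state at reference
covariate values. Constant covariates are dropped; an inestimable
severity term (single observed level) is a hard error naming the term.

**Calibration.** Comparator transition matrices are derived from the
reference drug's by a one-parameter monotone family: each row's
cumulative destination probabilities are shifted by δ on the logit scale
(a proportional-odds shift over the ordered destinations) and
differenced back. The published calibration is under-specified; this
family was chosen because it is monotone in δ, row-stochastic by
construction, exactly the identity at δ = 0, and makes the minimization
well-posed with a closed-form-checkable round trip. δ is applied
uniformly to the month 1–3 matrices (whether the original varied it by
month is not stated) and fitted per (drug, dimension) by bounded scalar
minimization (`stats::optimize` on [−8, 8], deterministic) of the
squared gap between the model-predicted month-3 change in daily episode
count and the target "reference change + NMA mean difference". The
severity-level ↔ daily-count bridge uses configurable midpoints
(defaults: micturition {6, 9, 11, 13, 16} voids/day, incontinence
{0, 0.5, 1.5, 3, 6} episodes/day); the source prints no level
boundaries, so these are package stand-ins chosen once on clinical
plausibility. An unreachable target (e.g. identity reference dynamics)
yields a warning carrying the achieved value, not silent clipping.

## The synthetic-data module

The trial-level and supplementary inputs behind the original analysis
(patient-level 12-week trial data, pooled baseline severity strata, NMA
effect tables, observational discontinuation rates) are not deposited.
The generator reproduces their *statistical structure* so every
downstream stage runs and can be tested for parameter recovery:

* **Baseline strata** (stand-in): independent truncated-geometric
  marginals over levels 1–5, decay 0.7 per level in both dimensions —
  monotonically decreasing occupancy with severity, which is the
  clinically plausible shape for a treated OAB trial population, and
  fully documented/configurable.
* **Reference transition matrices** (stand-in): tridiagonal monthly
  matrices with improvement strongest in month 1 (move-down probability
  0.30 → 0.22 → 0.18 across months; move-up 0.15 → 0.15 → 0.12), so the
  reused month-3 matrix is mildly improving and the long-run on-treatment
  distribution stays near baseline — the sustained-effect assumption.
* **EQ-5D observations**: linear predictor from the utility
  specification plus small covariate effects (sex −0.013, age
  −0.0006/year centered at 55, country offsets ±0.01) and Gaussian noise
  (SD 0.1), truncated to the UK tariff range [−0.594, 1]. Simple and
  recoverable by OLS, which the tests verify.
* **NMA summaries**: point estimates equal the generating effects (the
  Bayesian NMA itself is out of scope — only its outputs are consumed);
  odds ratios are those implied by the printed per-drug 3-month AE
  probabilities; interval half-widths are configurable.
* **NMA mean differences** (stand-in): per-comparator values of 0.05–0.25
  micturitions/day and 0.02–0.12 incontinence episodes/day worse than
  the reference, with solifenacin 10 mg slightly better on symptoms
  (−0.10/−0.05) but penalized by its higher AE rates — magnitudes in the
  range antimuscarinic NMAs report. These determine which comparators
  the synthetic base case dominates; they are inputs, not targets.

What the generator does **not** emulate: dropout/missingness,
within-patient correlation beyond the Markov structure, urgency and
nocturia (excluded symptoms), mortality, adherence/wastage. Passing
recovery tests therefore show the estimation machinery is correct under
the assumed data-generating process, not that the stand-ins equal the
unavailable originals — the published per-arm totals are not
reproducible from scratch, and the package does not claim them.

## Parameter choices that needed a decision

* **Level-4 utility coefficients.** The printed base-case values are
  illegible in the source table (only the sensitivity ranges
  0.0104–0.0316 and 0.0128–0.0369 are readable). Defaults interpolate
  between the level-3 coefficient and 0 (level 5), clipped into the
  printed range: micturition 0.0104, incontinence 0.0157. Both keep the
  coefficient sequence monotone and are user-overridable.
* **Base utility of the worst state.** Not printed (it lives in an
  unavailable supplementary regression table); default 0.76, a synthetic
  stand-in giving 5-year QALY totals in the published ballpark (~3.7–3.9
  per arm).
* **BTX-A monthly probability range.** The printed sensitivity range
  (0–0.05%) does not bracket the 0.1% base case — an apparent typo — so
  the packaged DSA range is 0–0.5%.
* **Restart after repeated failure.** Whether re-failed restarters
  qualify differently for BTX-A is not stated; the failed-lines count
  simply accumulates.

## Sensitivity analyses

The one-way analysis perturbs one parameter to each bound, recalibrates
the affected transition models, reruns both arms and records (ΔC, ΔQ);
a degenerate range reproduces the base case to 1e−9 (tested). The PSA
draws all parameters independently per iteration — probabilities from
beta (method-of-moments on the point estimate with SE = range/3.92,
falling back to uniform on the interval when the variance is infeasible,
with the fallback counted and reported), utility coefficients and NMA
mean differences from normal, resource counts from gamma, odds ratios
from lognormal. The distribution families are package choices (the
source says "data not shown"); no correlation structure is reported, so
draws are independent. All randomness flows through a single seed
(`withr::with_seed`), making every PSA bit-reproducible. The scenario
analysis replaces both discontinuation channels with a single per-drug
observational rate.

## Numerical conventions and problem sizes

Row-stochasticity is enforced at 1e−9 throughout; cohort mass is checked
every cycle at 1e−9; currency is read at 2 dp, computed in floating
point, and rounded to £1 only in report tables; calibration uses a
deterministic bounded scalar search with the identity snapped exactly at
a zero target. The test suite exercises the full 60-cycle model for the
economics and conservation checks and a reduced model (two severity
levels per dimension, 12 cycles) for the cohort-vs-microsimulation
comparison (10,000 walkers, agreement within 3 binomial SE per cycle and
phase) and the 1,000-iteration PSA reproducibility checks; parameter
recovery uses 2,000 patients × 10 seeds with 3-SE coverage ≥ 95%. These
sizes give stable Monte-Carlo comparisons at interactive runtimes.

## Known limitations

Comparator dynamics inherit the reference drug's matrix structure
through a single latent shift — a strong but transparent assumption
forced by calibrating to one scalar effect per dimension. The symptom
dimensions are independent given drug and month. The pathway has no
mortality and no heterogeneity beyond the state space. And all
supplementary-input stand-ins are exactly that: the package reproduces
the model's *machinery* faithfully; its shipped numbers describe the
synthetic base case, not the original study data.
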