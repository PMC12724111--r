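---
title: "Methods: within-trial cost-effectiveness analysis with trialcea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: within-trial cost-effectiveness analysis with trialcea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialcea)
```

## What the package computes

`trialcea` implements the analysis pipeline of a within-trial economic
evaluation of a two-arm randomised controlled trial, taking a health and
social care perspective over a one-year horizon (no discounting is applied,
since no cost or outcome falls beyond one year). The motivating setting is a
trial of a modular psychological therapy delivered within paediatric
epilepsy services to children and young people with epilepsy and a comorbid
common mental health disorder (anxiety, depression or disruptive
behaviour), with assessment-enhanced usual care as the comparator — but
every stage is driven by user-supplied tables and configuration and carries
no trial-specific constants.

The pipeline has five analytic stages:

1. **Costing.** Service-use records (contacts, nights, prescription
   item-months per participant and period) are priced against a unit-cost
   table. The intervention itself is micro-costed from staff time: the
   delivery band's cost per working hour times face-to-face hours per
   session, inflated by an indirect-to-face activity ratio (preparation,
   administration, supervision attendance), plus per-session shares of
   supervision time and of a training cost amortised equally over a cohort
   of participants. A substitution scenario scales the intervention
   component only (e.g. 75% of full cost, reflecting delivery partly by
   existing staff in place of standard activity).
2. **Outcomes.** The clinical endpoint is the parent-reported SDQ total
   difficulties score (0–40, lower is better) at 6 or 12 months.
   Quality-adjusted life years are computed from utility scores at 0, 6 and
   12 months by trapezoidal area under the curve, assuming linear change
   between measurements: over two half-year intervals,
   $\mathrm{QALY} = \tfrac{1}{2}\cdot\tfrac{u_0+u_6}{2} +
   \tfrac{1}{2}\cdot\tfrac{u_6+u_{12}}{2}$. Child utilities derive from
   CHU9D and caregiver utilities from EQ-5D-5L value sets upstream of this
   package; the pipeline consumes the scores. Dyad-level QALYs are the
   arithmetic sum of child and caregiver QALYs — no aggregation convention
   is standard for combining QALYs measured on different instruments, and
   the sum ("total QALY gain") is the transparent default, isolated in
   `combine_qalys()` so it can be swapped.
3. **Adjusted estimation.** Each between-arm difference is the arm
   coefficient of a linear mixed model of the outcome on arm, baseline
   covariates (baseline cost and SDQ for every outcome, plus the relevant
   baseline utility for QALY outcomes) and the four categorical
   minimisation factors (primary disorder, age band, autism, intellectual
   disability), with a random intercept for recruiting site. Analyses are
   complete-case per outcome: each model uses the rows complete for *its*
   columns, since completeness differs by measure.
4. **Decision analysis.** Incremental cost-effectiveness ratios with
   quadrant labels; net monetary benefit $\lambda E - C$; a non-parametric
   bootstrap (participants resampled with replacement, stratified by arm,
   both adjusted models refit per resample) of the *joint* incremental
   cost–effect distribution; and cost-effectiveness acceptability curves —
   at each willingness-to-pay $\lambda$, the fraction of replicates with
   positive incremental net benefit, ties at exactly zero counted as one
   half.
5. **Missing data.** Chained-equation multiple imputation with predictive
   mean matching over the outcome set (period costs, QALYs, SDQ per
   timepoint), pooled by Rubin's rules, and an MI-aware CEAC.

## Key parameters and defaults

| Parameter | Default | Units / rationale |
|---|---|---|
| Allocation | 167 / 167 of 334, 13 sites | 1:1 permuted allocation; minimisation itself is a trial-conduct detail irrelevant to the estimators and is not re-implemented |
| WTP grid, SDQ | £0–£1000 step £1 | no accepted threshold exists for an SDQ point, so a fine wide grid is scanned |
| WTP grid, QALY | £0–£50 000 step £500 | spans the NICE £20 000–£30 000 band |
| Bootstrap `B` | 5000 | inference-grade; examples and tests use smaller `B`, stated where used |
| Imputations `m` | 31 | convention of matching the percentage of incomplete cases |
| PMM donors `k` | 5 | standard donor-pool size |
| Chain iterations | 10 | chains over six outcome variables converge quickly |
| Substitution factor | 1.0 (full cost) | 0.75 for the substitution sensitivity scenario |

Currency arithmetic is double precision throughout, with half-even rounding
to £0.01 applied only when report tables are written.

## The synthetic-trial generator

Participant-level data from trials of this kind are rarely public, so the
package ships a generator, `generate_trial()`, whose defaults emulate the
statistical structure the analysis assumes. It is first-class, tested code:
every configured treatment effect is a *conditional* effect given baseline
covariates, so the adjusted estimators are, by construction, calibrated to
recover it — this is what the calibration-recovery tests verify at 500
simulated trials.

* **Costs** are gamma distributed (non-negative, right-skewed; shape 1.2 by
  default). Baseline 3-month costs have arm-specific means (£1602
  intervention, £2076 control), a deliberate baseline imbalance that
  exercises the adjustment machinery. Follow-up cost (two 6-month periods)
  has a conditional mean linear in the *realised* baseline cost (slope 0.8)
  plus an arm effect of −£796 excluding the intervention.
* **Service use is generated cost-first**: a target cost per
  participant-period is decomposed into per-category quantities
  (Dirichlet-perturbed expected shares divided by unit costs, rounded to
  integer counts), and the stored cost is the re-priced quantity total.
  Pricing the emitted records therefore reproduces the stored costs
  exactly, and the integer-rounding perturbation is identical in
  distribution across arms, so arm contrasts are unaffected.
* **Utilities** are simulated on a latent normal scale (participant random
  intercept 0.07, occasion noise 0.07, site 0.02) and clipped to [0, 1].
  Control-arm means default to 0.70 at every occasion for both roles —
  plausibly low for a clinical paediatric population and their caregivers,
  and deliberately far enough from 1 that clipping affects under ~2% of
  draws even in the shifted arm, keeping the configured QALY effects
  essentially unattenuated. The treatment effect is placed equally on the
  6- and 12-month occasions, scaled by $1/0.75$ so the trapezoid contrast
  equals the configured QALY effect (0.023 child; 0.070 caregiver, chosen
  so the combined effect is 0.093).
* **SDQ** is a latent normal (participant SD 4, occasion SD 4, site SD 1)
  rounded to integers and clamped to [0, 40]; with an occasion SD of 4
  points the rounding is self-dithering and the clamp binds almost never,
  so the configured effects (−2.0 at 6 months, −2.021 at 12) survive both.
* **Sessions attended** (intervention arm only) follow a discrete
  distribution on 2–23 with geometric decay away from the maximum — most
  participants complete most sessions, a long left tail of early dropout —
  whose decay rate is solved numerically so the exact mean equals 18.23.
* **Missingness** is monotone within measure (missing at 6 months implies
  missing at 12) at default rates of 16%/22% for SDQ and period costs and
  20%/35% for utilities, so that roughly 78% of 12-month SDQ and 65% of
  QALY trajectories are complete. Under MAR the masking probability is
  logistic in standardised baseline SDQ (slope 0.5) and standardised
  log-baseline-cost (slope 0.3), with the intercept solved so the average
  probability equals the configured rate; MCAR is available for
  unbiasedness testing. Whether real follow-up losses are MAR cannot be
  established from data; MAR is the working assumption that gives multiple
  imputation its validity, and it is never asserted as fact.

What the generator does *not* emulate: instrument-level item responses and
tariff scoring, informative (MNAR) dropout, within-family correlation
between child and caregiver utilities beyond the site effect, seasonal or
pandemic-era disruption of service use, and zero-inflation structure beyond
what integer rounding of small category shares produces. Passing tests on
generated data therefore demonstrate that the *estimators and decision
machinery* behave as designed under the assumed structure — not that any
particular real-world dataset satisfies that structure.

## Numerical and design choices

* **Estimator.** "Mixed effects" admits many structures; the package uses
  the simplest defensible one, a random intercept for recruiting site, with
  an automatic OLS fallback (and a warning) when only one site level is
  present. Wald intervals from the asymptotic covariance are reported;
  with n ≈ 334 and 13 sites the small-sample correction would be
  immaterial and symmetric intervals match how such results are reported.
  Continuous covariates are standardised inside the fitter (the arm
  coefficient is invariant) to keep the optimiser well conditioned.
* **Singularities.** A rank-deficient fixed design is an error naming the
  collinear columns. Inside the bootstrap, degenerate resamples are redrawn
  and counted; more than 10% redraws aborts the run.
* **Effect direction.** For SDQ scenarios the incremental effect is defined
  as the *reduction* in score (control minus intervention), so
  acceptability curves always read "per unit improvement".
* **Ties.** Replicates with incremental net benefit exactly zero count as
  one half — measure-zero on real data, but it fixes deterministic
  behaviour on toy examples.
* **Bootstrap × imputation ordering.** The default MI-aware CEAC nests the
  arm-stratified bootstrap *within* each completed dataset (roughly `B/m`
  replicates each, seeds derived from the master seed) and pools the
  replicate clouds before computing one curve: this preserves the joint
  (ΔC, ΔE) dependence while propagating imputation uncertainty. The
  alternative — Rubin-pooling an adjusted net-benefit regression at every
  willingness-to-pay value and converting the pooled z-score to a
  probability — is available via `method = "rubin_nmb"`; for linear models
  the two agree closely.
* **Training amortisation.** Total training cost is divided equally over a
  configurable participant cohort (default: the intervention-arm size);
  per-participant overheads (supervision, training) become per-session
  shares through a reference session count, so the per-session price is a
  stable unit cost rather than varying with each participant's attendance.
* **Reproducibility.** Every stochastic stage (generation, masking,
  bootstrap, imputation) is deterministic given its seed; the analysis
  runner shares one master seed across scenarios so curves are comparable
  replicate by replicate, and writes a config hash and seed into its run
  log.

## Worked example

```{r example}
cfg <- trial_config(seed = 1)
ds <- generate_trial(cfg) |> cost_trial() |> add_qalys()
adjusted_difference(ds, default_adjustment_spec("sdq_12"))
res <- run_scenarios(ds, scenario_grid(outcome = "sdq_12m",
                                       costing = c("full", "s75")),
                     B = 300, seed = 5)
res[c("outcome", "costing", "delta_cost", "delta_effect", "icer",
      "crossing_lambda")]
```

On this calibrated dataset the intervention costs more and improves SDQ, so
the acceptability curve rises with willingness-to-pay and crosses 50%
probability at a few hundred pounds per SDQ point; under 75% intervention
costing the crossing moves left. (Exact values depend on the seed; the
numbers shown are computed when the vignette is built.)

## Known limitations

* **PMM attenuation.** Predictive mean matching imputes only observed
  values, and donor pools mix arms when the arm effect is small relative to
  the prediction spread; the pooled arm coefficient therefore shrinks
  slightly toward zero (on the default calibration, a relative bias of
  roughly 8% of the SDQ effect at the default missingness intensity — an
  independent reference implementation of chained-equation PMM shows larger shrinkage
  on the same design, so this is a property of the method, not of this
  implementation). Coverage of the pooled intervals remains near nominal.
  Sensitivity analyses on imputed data should be read with this in mind.
* The trapezoid QALY assumes linear utility change between sparse
  measurement occasions; rapid fluctuation between visits is invisible.
* Worse-than-dead utilities are excluded by the default [0, 1] domain;
  widen to [−0.594, 1] where EQ-5D-5L tariffs can produce them.
* The mixed model treats costs as Gaussian conditional on covariates;
  with heavily skewed costs the arithmetic-mean contrast remains the
  decision-relevant estimand, but small-sample intervals can be optimistic.
  The bootstrap-based decision analysis does not rely on that normality.
* Combining child and caregiver QALYs by summation weights both lives
  equally and ignores within-dyad correlation in the point estimate (the
  bootstrap propagates it into uncertainty).

## Problem sizes used in validation

The calibration-recovery study simulates 500 trials of n = 334 in the test
suite (1000 in the standalone reproduction script) and fits the full mixed
models; bootstrap properties are checked at B between 60 and
4000 (with exhaustive enumeration on a 4-participant toy set as the exact
reference); imputation Monte-Carlo studies use m = 5 with 5 chain
iterations over 200 replicates, since the properties under test do not
depend on m. These sizes are the package's validation design choices and
are stated here so they can be scaled up by anyone wishing to tighten the
Monte-Carlo resolution.
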