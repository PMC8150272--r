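---
title: "Estimating ventilator settings by inverting a neural surrogate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating ventilator settings by inverting a neural surrogate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventinvert)
```

## The problem

A clinician setting up pressure-controlled mechanical ventilation chooses a
handful of machine parameters — set inspiratory pressure (SetP), peak
inspiratory pressure (PIP), PEEP, pressure-support level (PSV), respiratory
rate (RR) and inspired oxygen fraction (FiO2) — and watches the patient's
response: tidal volume (Vti), dynamic compliance (Cdyn), end-tidal CO2,
oxygen saturation, heart rate, blood pressure and temperature.  `ventinvert`
addresses the inverse question: *given the response we want, which settings
produce it?*

A network trained directly in the inverse direction (observations →
settings) would return a single answer, but the inverse problem — like
inverse kinematics — typically has many solutions.  The package instead
trains the *forward* map with a feed-forward network and searches its input
space with a stochastic optimizer, so that repeated trials chart the set of
setting combinations consistent with the target, and their spread is itself
clinically informative.

## The optimizer

The Graded Particle Swarm Optimizer (GPSO) extends classic momentum PSO.
The swarm is partitioned into equal-sized groups; each group's best-so-far
member is its leader (`gbest`), and the best of the leaders is the universal
leader (`ubest`).  Each particle `i` feels three attractions:

$$v_{t+1}(i) = \omega v_t(i) + r_1 c_1\,(pbest_t(i) - x_t(i))
             + r_2 c_2\,(gbest_t(j) - x_t(i)) + r_3 c_3\,(ubest_t - x_t(i))$$
$$x_{t+1}(i) = x_t(i) + v_{t+1}(i)$$

with fresh uniform(0,1) draws $r_1,r_2,r_3$ and influence constants
$c_1,c_2,c_3$.  When a group stalls at a local optimum, better-performing
groups pull it out through the universal term.  Defaults follow the
full-scale published protocol: population 2000 in 50 groups, $\omega=0.8$,
$c_1=c_2=c_3=1.2$.

Design choices the update rule leaves open, and how this package resolves
them:

* **Leader memory.** `pbest`, `gbest` and `ubest` are best-*so-far* values
  (the standard PSO convention), not current-iteration bests.
* **Group membership** is static: a contiguous equal partition of particle
  indices fixed at initialization (the method is explicitly contrasted with
  dynamic-membership club-style swarms).
* **Random draws** default to one scalar per term per particle per
  iteration, matching the scalar notation of the update rule; a
  per-dimension mode is available (`r_mode = "per_dimension"`).
* **Velocity** starts at zero and is not clamped; only positions are
  truncated to the search box, after every move.
* **Ties** among equal-fitness leaders break toward the lowest particle
  index, keeping runs deterministic given a seed.
* **Non-finite objective values** are treated as $+\infty$ (counted in the
  trace, never promoted to a leader).
* **Termination** is an iteration cap or a fitness tolerance.  The source
  protocol states two inconsistent pairs, so both ship as named profiles:
  `"table2"` (100 iterations, tolerance 0.01) and `"text"` (1000
  iterations, tolerance $10^{-4}$); the choice is always explicit in the
  config.

Two degenerate readings of the grouping deserve a note.  With a single
group, the group and universal leaders coincide and the two leader terms
merge: GPSO reduces *exactly* to classic PSO with $c_2' = c_2 + c_3$.  The
implementation preserves this bit-for-bit (with `tie_leader_draws = TRUE`
the two leader terms share one draw, and the summation order makes the
collapse exact in floating point); `pso_optimize()` is an independently
written classic-PSO oracle, and the equivalence is asserted over full
position histories in the test suite.  With one member per group the source
describes the group term as vanishing; strictly, a singleton's group best
*is* its personal best, which duplicates the personal term rather than
vanishing.  The package implements the update rule literally and documents
the discrepancy here rather than resolving it.

## The forward surrogate

`train_network()` fits an 8-input, 7-output regression network with hidden
widths 8–16–14–7 (tanh) and a linear output layer.  Inputs and outputs are
min-max normalized to the cohort's observed bounds — the same bounds later
used for truncation and for the inversion fitness.  The original work used
a proprietary toolbox's defaults; the trainer here is full-batch Adam
(learning rate 0.01, up to 2000 epochs) with early stopping on a validation
partition, which fits these sub-thousand-record cohorts in seconds and is
fully seeded.  The exact trainer is not load-bearing for any contract in
the package, and the topology and epochs are arguments.

A model's `total_error` is the **sum** of squared errors on the normalized
scale over the train, validation and test partitions together (the
published totals are on the order of $10^3$, consistent with sums rather
than means).  Split fractions are 70/15/15, matching the published
473/101/101 segregation of 675 modelling records; each candidate re-draws
its split.  `train_ensemble()` trains `n_candidates` such networks
(published scale: 200) and keeps the `k` (10) with the smallest total
error; every selection test asserts the dominance property rather than any
particular error value.

## The inversion engine

The fitness of a candidate settings vector is half the sum of squared
normalized residuals between the surrogate's prediction and the target:

$$MSE_n = \tfrac12 \sum_i (OutputN_i - TargetN_i)^2 .$$

The definition is kept exactly as published — note it is half a *sum*, not
a mean, despite its name.  Age and weight are known per patient and frozen
during the search (zero velocity, pinned position); all remaining
dimensions are clamped to the observed cohort bounds every iteration.  A
campaign runs `n_trials` trials (published: 100) on each ensemble member
(10), derives per-trial seeds as `seed + 1000*network + trial`, and pools
per-parameter min/max/mean/sd across all trials and networks — the pooled
reading of the published statistics; a per-network breakdown is retained so
the per-network reading stays available.  Each trial contributes the
swarm's universal best.

One physical identity needs a decision: PIP = SetP + PEEP holds on the
ventilator, but the published search treats PIP as a free 8th dimension, so
free search is the default here too.  `project_pip = TRUE` projects the
identity after every clamping step for users who want physically consistent
candidates; the package's own recovery experiments enable it, because in
the synthetic world only the difference PIP − PEEP enters the response, so
without the constraint SetP lies on a known one-dimensional degeneracy and
its "recovery" would measure nothing.

## The synthetic world

Clinical records cannot ship with the package, so `generate_cohort()`
produces cohorts from an explicit ground-truth model.  Its scale mirrors
the cohort the pipeline was designed around: 24 patients (about a sixth
feline, six with healthy lungs), ~30 timestamped records each, so ~720
rows.  The response map is *not* a mechanistic lung simulator; its forms
are invented, smooth, monotone where physiology dictates, and chosen so
that every free setting is identifiable from the outputs — the property
that makes recovery tests meaningful.  All coefficients sit in one
documented parameter block (`ground_truth_model()$params`):

* `Cdyn` is allometric in weight, mildly decreasing in age, and multiplied
  by 0.45 for unhealthy lungs; it never depends on the settings.
* `Vti = Cdyn · (PIP − PEEP)` exactly (the compliance identity, verified to
  $10^{-9}$ cohort-wide).
* `EtCO2` decays exponentially with specific minute ventilation
  `RR·Vti/weight`, between hypo- and hyper-ventilation asymptotes (80 and
  10 mmHg), strictly monotone — no hard clipping.
* `SpO2` = 100·(1 − shunt·exp(−(FiO2−21)/60 − PEEP/6)): rising and
  saturating in FiO2 and PEEP, shunt 0.035 healthy / 0.18 unhealthy.
* `BP` falls with PEEP (and weakly SetP); `HR` rises with EtCO2 and falls
  2 bpm per cmH2O of pressure support; `Temp` is nearly constant per
  patient.

Observation noise is multiplicative, `obs·(1 + σ·ε)`, default σ = 0.02.
Missingness is masked completely at random over the *observation* columns
only — settings are machine-logged and demographics known, which is also
why age and weight can be frozen during inversion — at a default 15% of
cells.  Sampling uses physiologic boxes (SetP 5–30, PEEP 0–12, PSV 0–15
cmH2O, RR 8–40/min, FiO2 21–100%, ages 0.5–15 y, weights 2–60 kg with cats
2.5–6 kg) and enforces PIP = SetP + PEEP.

What the generator does **not** emulate: temporal correlation within a
patient (records are exchangeable rows), species physiology beyond a size
effect, informative missingness, measurement drift, and any dependence of
clinician-chosen settings on the patient's state.  A green recovery test
therefore establishes that the pipeline inverts a smooth identifiable
forward map under modest noise — not that it would do so on real intensive
care data.

Two conditioning choices matter when interpreting results:

* **Lung status is not a surrogate input.**  Five of the seven outputs
  depend on it, so on a mixed cohort the 8→7 map is a mixture and no
  network can fit it well (this mirrors the original study's situation on
  real data).  The quantitative recovery experiments therefore generate
  their cohort from the unhealthy stratum alone — by far the dominant
  class clinically, since patients with healthy lungs rarely need
  ventilation.  The default mixed cohort remains for imputation and
  pipeline tests, where the other observed fields carry the status
  information.
* **Inversion fixtures** sample settings from the central 70% of each
  bound range.  At the extreme edges the response saturates (most visibly
  SpO2 at very high FiO2), and no method could identify a setting the
  outputs no longer reflect.

## Data pruning and imputation

`prune_cohort()` mirrors the clinical pre-processing: per-field observed
bounds are computed from the initial data *before* any imputation and every
imputed value is truncated to them; a missing Cdyn is derived from the
compliance identity when Vti, PIP and PEEP are present (a recorded Cdyn
always wins over the identity — observational data are authoritative — but
disagreements beyond 5% are counted); each remaining incomplete field is
filled by its own small regression network, most-complete field first;
rows missing more than half their fields are dropped and counted, and the
report reconciles every row (`original = final + dropped`).

One deliberate deviation from the simplest per-field scheme: imputers train
on rows where the *target* is observed, with missing predictor cells filled
by column means at train and predict time, rather than on fully complete
rows only.  With cells missing completely at random, complete rows vanish
geometrically as missingness grows (at 30% masking of seven fields, ~8% of
rows survive), so the complete-case scheme collapses exactly where
imputation matters most; mean-filled predictors degrade gracefully instead,
and the mask-and-recover suite measures the degradation directly.  The
masked-cell benchmark is scored against the noiseless ground truth — an
imputed cell should be at least as close to the truth as a 2%-noise
measurement would be — and the measured pooled median relative error is
about 1%, roughly half the noise scale.

## Numerical and reproducibility notes

* Every public entry point that consumes randomness takes a seed and
  restores the caller's RNG state (`withr::with_seed`); campaigns derive
  per-trial seeds arithmetically, so any single trial can be reproduced in
  isolation.  Identical seed and config produce byte-identical written
  reports (asserted in the tests).
* Normalization maps a degenerate feature (observed min = max) to 0.5, so
  constant columns carry neither gradient nor fitness weight.
* Normalized targets outside [0,1] (a target beyond the training cohort's
  range) are permitted but warned about once per trial.
* The desk-scale profile (population 200 in 10 groups, 20 candidates / top
  3, 20 trials) is a deliberate ~10× reduction of the published scale so
  the full pipeline runs in minutes on one CPU; the full-scale profiles are
  one argument away (`profile = "table2"` / `"text"`).

## Known limitations

* The surrogate carries no lung-status input, so mixed-status cohorts
  bound its accuracy (see above); adding status as a ninth input would be
  a natural extension but departs from the 8-input protocol.
* FiO2 is the least identifiable setting in the synthetic world: near the
  top of its range the saturating SpO2 response moves by fractions of a
  unit against a 2-unit noise floor.  Across seeds, typically 5–9 of 10
  fixture patients recover every free setting within 10% of its bound
  range; the misses are marginal (11–15% of range, occasionally worse for
  FiO2 near saturation) and are a noise-information limit of the world, not
  an optimizer defect: a surrogate trained on ~700 records with 2%
  observation noise carries about 2% of range in irreducible prediction
  error per output, and dividing by a weak output sensitivity (SpO2 vs
  FiO2, HR vs PSV) can exceed the 10% bar.  Longer or slower training does
  not move this floor (measured).
* Eq-style fitness weighs all seven outputs equally on the normalized
  scale; outputs whose observed range is noise-dominated (temperature
  here) contribute noise to the objective, which the ensemble averaging,
  not the fitness, absorbs.
* The optimizer assumes a box; it cannot express joint constraints beyond
  the optional PIP projection.
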