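---
title: "Learning Alzheimer's treatment regimens from longitudinal visit data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning Alzheimer's treatment regimens from longitudinal visit data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Alzheimer's disease (AD) has no curative medication; clinicians manage
symptoms and comorbidities (most often hypertension and depression) by
trialing regimens of cholinesterase inhibitors (ChEIs), memantine, their
combination, antihypertensives and supplements. `regimenrl` treats regimen
selection as an offline reinforcement-learning problem over longitudinal
clinic-visit tables: each visit is abstracted into a discrete disease
state, the prescribed medication class is the action, and the change in
the Mini-Mental State Exam (MMSE, 0--30, higher is better) between
consecutive visits is the reward. Because real AD registries are
access-controlled, the package ships a synthetic cohort generator with a
known ground-truth Markov decision process (MDP), so that every stage of
the pipeline is testable and the true optimal policy is known by
construction.

## The decision process

A visit in state $s$ under medication class $a$ receives reward
$R = \mathrm{MMSE}_{t+1} - \mathrm{MMSE}_t$, and the return from step $t$
is the discounted sum

$$G_t = R_{t+1} + \gamma R_{t+2} + \gamma^2 R_{t+3} + \cdots,$$

with discount $\gamma = 0.3$ throughout: treatment decisions in this
setting are dominated by their next-visit effect, with a modest tail.
Rewards are computed on forward-filled MMSE values; inter-visit gaps are
not time-normalized (consecutive visits are differenced as logged).
An open question in the data model is whether a visit's recorded
medications label the interval before or after it; we take the visit's
medications to govern the interval that follows it, so the action at
visit $t$ is paired with the MMSE change over $(t, t+1]$.

**Actions.** Six classes, in fixed index order: `NO_DRUGS`, `CHEI`,
`MEMANTINE`, `CHEI_MEMANTINE`, `ANTIHTN`, `SUPPLEMENT`. Free-text
medication entries are mapped by a user-overridable dictionary; when
classes co-occur at one visit the precedence is ChEI+memantine (if both),
then ChEI > memantine > antihypertensive > supplement -- AD-specific drugs
dominate because the reward measures cognition. Unrecognized entries fall
through to `SUPPLEMENT`; an empty list is `NO_DRUGS`.

**States.** Ordinary least squares regresses MMSE on the candidate
features (ADAS13, RAVLT immediate and learning, CDRSB, MoCA, FDG, age);
features with coefficient $p < 0.05$ enter a CART regression tree
(squared-error splits, via `rpart`) predicting MMSE. The tree's leaves are
the discrete states, numbered depth-first. Minimum leaf occupancy is 50
visits (states with fewer occurrences are not retained; visits falling in
pruned regions are "unassigned" and transitions touching them are
dropped). Depth is capped at 6 -- published rule paths of this kind use at
most four predicates -- and the complexity parameter keeps `rpart`'s
standard 0.01 default, so a split must explain at least 1% of remaining
variance; this stops the tree at the genuinely distinct severity strata
instead of chasing noise into many small leaves whose empirical rewards
would be unstable. Refits on identical data are bit-identical.

The package also ships a published 42-row decision-tree ruleset (13
whole-data states S0--S12, 9 AD states, 12 AD-hypertension rows, 9
AD-depression rows) as a plain-text fixture, loadable with
`load_published_rules()`. Intervals follow the printed left-open,
right-closed convention `(a, b]` -- a boundary value belongs to the lower
leaf -- while fitted trees follow `rpart`'s native `x < c` / `x >= c`
split semantics; both are encoded with explicit open/closed flags and
`assign_state()` honours whichever the model carries. Two defects of the
printed table are encoded verbatim and flagged rather than silently
repaired: the AD-depression list labels two distinct rule paths "S41", and
AD-hypertension row S33 overlaps the S27/S28 region (ambiguous visits
resolve to the lowest state index, with the multiplicity reported).

## Policies and solvers

All policies are tabular: a states-by-6 row-stochastic matrix,
deterministic policies one-hot.

* **Policy iteration** alternates exact policy evaluation -- the linear
  solve $v = r_\pi + \gamma P_\pi v$, exact at these state counts (a
  direct solve is used up to a few hundred states) -- with greedy
  improvement, until the policy stops changing.
* **Q-learning** replays the logged transitions in randomized seeded
  sweeps of the off-policy temporal-difference update
  $Q(s,a) \leftarrow Q(s,a) + \alpha\,(r + \gamma \max_{a'} Q(s',a') - Q(s,a))$,
  with $\alpha = 0.05$, $Q$ initialized at 0, and the bootstrap max taken
  over actions actually observed at $s'$. Terminal transitions use the
  target $r$. Replaying the log is the default; nothing is simulated from
  the fitted model.
* **Clinician policy**: one policy-evaluation + policy-improvement cycle
  applied to the empirical behavior policy (per-state observed action
  frequencies) on the empirical transition model -- a decision rule
  derived entirely from the clinicians' own logged prescribing.
* **Zero** (always `NO_DRUGS`) and **random** (uniform over six actions)
  references.

Two conventions apply to every solver. First, *support restriction*: the
argmax runs only over actions observed at a state -- the log carries no
information about unobserved pairs and no dynamics are fabricated for
them; a state with no observed action falls back to `NO_DRUGS` with a
warning. Second, determinism: ties break to the lowest action index, and
every source of randomness takes an explicit seed (hierarchical seeds are
derived with `derive_seed()` so that, e.g., patient $i$'s record stream
does not depend on the cohort size).

### Constant-step-size noise and the consensus ensemble

With a constant learning rate, a converged tabular Q-entry is an
exponentially weighted average of its recent targets and therefore
fluctuates around its fixed point with standard deviation of order
$\sqrt{\alpha/(2-\alpha)}\,\mathrm{sd}(\text{target})$. With MMSE-change
rewards (between-state jumps of 3--9 points plus measurement noise) this
is roughly 0.5 MMSE points at $\alpha = 0.05$ -- comparable to the action
gaps at some states -- so the greedy action of a single run can flip at
marginal states. `q_learning_ensemble()` trains repeatedly (50 seeded
repetitions by default) and takes the per-state majority action, which
averages the fluctuation away; it is the recommended way to extract a
single stable regimen plan, and the one the recovery analysis
(`analysis/06_recovery.R`) uses. The experiment harness instead keeps the
repetition whose greedy policy scores best on the validation split, which
preserves the "train repeatedly, keep the best" protocol but, we note, is
measurably less stable than the consensus (validation-set value estimates
are noisy, so selection suffers a winner's curse).

## Off-policy evaluation: step-WIS

Policies are valued from logged trajectories by stepwise (per-decision)
weighted importance sampling. For trajectory $i$ at step $t$, with target
$\pi$ and behavior $\pi_b$,

$$w_{i,t} = \prod_{u \le t} \frac{\pi(a_u \mid s_u)}{\pi_b(a_u \mid s_u)},
\qquad
\hat{V} = \sum_t \gamma^{t-1} \frac{\sum_i w_{i,t}\, r_{i,t}}{\sum_i w_{i,t}},$$

where a trajectory that has ended keeps its final cumulative weight in
the normalizer with zero reward (the consistent step-WIS convention).
That convention is what makes two exact identities hold, both asserted in
the tests: evaluating the behavior policy against its own log returns
exactly the empirical mean discounted return, and a two-trajectory
worked example with one surviving weight returns that trajectory's
reward. A step whose normalizer is zero contributes 0 and is flagged; a
target with no support anywhere returns a flagged 0. The behavior policy
used for evaluation is the empirical policy of the same log, which
guarantees positive probability on every logged action. Trajectory-wise
WIS and plain (unnormalized) per-decision IS are available behind a
`method` flag for comparison, and an optional `clip` bounds the
cumulative ratios; clipping is off by default.

Step-WIS point estimates for *deterministic* targets deserve a caution:
only log segments that match the target's actions carry weight, so the
effective sample size shrinks geometrically with depth and the estimate's
sign under small held-out sets is noisy. Comparisons between two good
policies on a few hundred logged transitions should be read with that
variance in mind; the experiment harness therefore reports full bootstrap
distributions rather than single points.

## The experiment harness

`run_policy_comparison()` is the shared stage: patient-level 60/20/20
train/validation/test split (never visit-level), state tree fit on the
training split, five policies trained as above, then all five scored by
step-WIS on 100 bootstrap resamples of the *test trajectories* -- the same
resample for every policy, so comparisons are paired. Pairwise policy
differences use Welch's unequal-variance $t$-test by default (a flag
restores the pooled form). The five harnesses:

1. **Data-size sweep**: 100/80/50/30% of the training patients. The state
   tree is fit once on the full training split and shared across
   fractions -- the experiment varies the solvers' data, not the state
   abstraction, and rewards on a common abstraction are directly
   comparable (refitting per fraction at 30% can collapse to a one-state
   model whose rewards live on a different scale).
2. **Comorbidity cohorts**: AD, AD-hypertension, AD-depression,
   AD-depression-hypertension, built by patient-level predicates
   (diagnosed AD/MCI at any visit, or prescribed an AD-specific drug, or
   carrying the comorbidity flag -- cognitively normal comorbid patients
   are deliberately included), with the containment lattice asserted in
   tests.
3. **JR/SR strata**: patients below/above the grand mean of per-patient
   mean MMSE, a proxy for harder/easier caseloads.
4. **Learning-rate sweep**: $\alpha = 0.1, \ldots, 0.9$ on a fixed split.
5. **State-count sweep**: occupancy thresholds 50/100/200, refitting the
   tree per threshold and reporting the state count alongside rewards.

The training-side bootstrap that a strict reading of the protocol might
add is off by default (the source description is ambiguous); the
bootstrap is over test patients.

## The synthetic cohort generator

The generator emulates the *shape* of a longitudinal AD registry, not any
real cohort's distributions (no public estimates exist for the latter;
every default below is a design choice):

* **Latent dynamics.** Four severity states -- CN, MCI, mild AD,
  moderate-severe AD -- with MMSE emission means 29/26/21/12. Each action
  sets per-state probabilities of improving/worsening one state; no-drugs
  worsens expected MMSE fastest in every non-floor state, ChEIs are most
  protective early, the combination in mild AD, memantine late, so the
  optimal policy is state-dependent and the per-state best-action value
  gap is at least 0.5 MMSE points (asserted in tests). At the floor state
  nothing can decline further -- a bounded chain necessarily has such a
  state -- so there the no-drugs action is value-dominated rather than
  strictly worsening.
* **Emissions.** Seven assessments drawn around the latent state's means
  (ADAS13, RAVLT immediate/learning, CDRSB, MoCA, FDG alongside MMSE),
  truncated to instrument ranges and rounded to instrument granularity
  (integers for MMSE/MoCA, half-point steps for CDRSB). Noise SDs are
  well below the between-state separations, so the tree can recover the
  latent strata.
* **Structure.** 2--15 visits per patient, uniform (no informative
  dropout), at 6-month spacing; baseline age truncated-normal in
  [55, 95] with a severity-linked offset at baseline only, so patients
  age monotonically; hypertension and depression as patient-level
  Bernoulli flags (defaults 0.40 and 0.25); diagnosis labels follow the
  latent state.
* **Behavior policy.** Softmax over per-(state, action) clinician logits
  (temperature 1), favouring clinically typical prescribing while keeping
  full support -- weighted importance sampling needs a non-degenerate,
  state-dependent behavior policy.
* **Missingness.** Each score cell is blanked independently at rate 0.10,
  except MMSE at the first visit; downstream code forward-fills and then
  requires complete records, which drops a realistic fraction of
  patients, mimicking registry attrition.
* **Determinism.** One global seed feeds a derived stream per patient, so
  the same patient index reproduces the same record regardless of cohort
  size, and identical config + seed reproduces the CSV byte-for-byte.

What the generator does *not* emulate -- and hence what passing tests do
not establish about real registries: informative dropout, practice and
learning effects on repeated testing, co-prescription across classes
within one visit beyond the ChEI+memantine combination, site effects,
diagnosis error, or any real registry's score distributions. Conclusions
about solver behaviour transfer; numeric reward levels do not.

## Problem sizes and reproducibility

The package's own analyses run at desk scale, chosen to keep a full run
in minutes while leaving each claim statistically comfortable: recovery
uses ten cohorts of 2000 patients (about 8000 logged transitions each),
where both solvers recover the known optimal policy on essentially all
states; the data-volume comparison uses 300-patient cohorts, where the
30% training arm (about 20 patients) is genuinely data-poor and the
effect on held-out step-WIS value is around +1.5 discounted MMSE points;
oracle checks (exhaustive policy enumeration, replayed deterministic
MDPs) use 2--4 states and 2--3 actions where brute force is exact.
`scripts/acceptance.R` re-runs all of it from scratch under a caller
seed. Numerical tolerances: transition rows sum to 1 within 1e-12,
policy-iteration values match enumeration within 1e-8, Q-learning Bellman
residuals on deterministic replays converge below 1e-3 at 600 sweeps.

## Known limitations

* Everything is tabular; no function approximation, and no
  conservative/regularized offline-RL variants.
* Step-WIS sign comparisons between near-equal deterministic policies at
  small held-out sizes are noise-dominated (see the caution above);
  bootstrap distributions, not point signs, are the reliable output.
* The reward ignores inter-visit gap length; a 6-month and an 18-month
  interval count equally.
* The published ruleset is reproduced verbatim, including its two printed
  anomalies; it cannot be re-derived without the access-controlled
  registry data.
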