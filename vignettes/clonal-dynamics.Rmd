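---
title: "Clonal dynamics of hippocampal neural stem cells: models and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clonal dynamics of hippocampal neural stem cells: models and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonedyn)
```

## The analysis problem

Chronic intravital two-photon imaging can follow a single labelled radial
glia-like neural stem cell (an *R cell*) of the dentate gyrus, and all of
its progeny, over weeks to months. Each imaging field is revisited daily;
annotators code every visible cell at every timepoint with its identity,
type (`R`, nonradial progenitor `NR`, or neuron `N`), mother and sister
links, uncertainty flags, and death events. `clonedyn` starts exactly
there: it consumes those coding tables, reconstructs the clone as a rooted
binary-division lineage tree, and derives the quantities used to compare
young and middle-aged cohorts — clone sizes and compositions, division
counts and intervals, activity and self-renewal durations, two-wave death
statistics, long-term quiescence and resting R cells, and newborn-neuron
morphometrics. A stochastic clone simulator generates synthetic cohorts
with the same statistical structure, so every pipeline stage can be
exercised and validated without access to imaging data.

## The lineage model and its conventions

A clone is a tree rooted in one R cell. A division *replaces* the mother
cell by exactly two daughter cells with fresh identities — even when one
daughter is biologically "the same" stem cell — so every internal node has
exactly two children. Cell types may only progress `R -> NR -> N`, both
along a cell's own history and across divisions; neurons never divide.

Several conventions are not dictated by the data and had to be fixed:

* **Division time.** The coding convention records daughters from their
  first appearance; we define a mother's division time as its daughters'
  first observed timepoint. This makes every interval computable from
  observations alone.
* **Timepoints** are real-valued days post induction (tamoxifen day 0).
  Tables using integer session indices are converted through
  `timepoint_units = "session"` with a configurable cadence and
  first-session day (default day 2, the usual first imaging session).
* **Clones seen with two cells at the first session** are assembled with
  the root's division at the first imaging day, and their time to first
  division is reported as 1 day, following the coding convention for
  divisions that predate the first session.
* **Certainty.** Any uncertainty flag (type, mother or sister) excludes a
  cell from all metric computations — a conservative reading of the rule
  that only unambiguously coded cells are analysed. Uncertain cells stay
  in the tree so that links remain intact.
* **The continuing R cell.** Self-renewal duration and quiescence
  classification follow "the" R cell through successive divisions: at
  each division the R-typed daughter continues the lineage; if both
  daughters are R-typed, the one whose own R lineage is observed longest
  continues (ties break on cell id).

## Metric definitions

With divisions attributed to the mother's type:

* `final_cell_number` / `final_composition`: cells neither divided nor
  dead at the end of observation, by type.
* `activity_duration`: first R division to the last division of any
  progenitor; 0 for a single division.
* `r_self_renewal_duration`: first R division to the last timepoint the
  continuing R cell is observed as type R; 0 if the R lineage vanishes at
  the first division.
* `division_intervals`: gaps between successive divisions of one type.
  For R cells the root's waiting time is excluded, and "rank 1" labels
  the gap between the first and second R division. For NR cells the gap
  from the NR cell's birth (the division that created it) to its own
  division counts, with rank equal to the NR generation — this makes the
  number of NR intervals equal the number of NR divisions, matching how
  the per-rank interval counts are reported in the source cohorts. A
  `rank_offset` argument shifts the labelling if a different convention
  is wanted.
* `time_to_first_division`: from induction (day 0) to the root's observed
  division. The origin is configurable because "time from induction"
  could defensibly be measured from the first imaging day instead.
* Cell death: a death is a disappearance/debris event recorded by the
  annotator. Ages at death split deaths into an **early** wave (<= 7 days
  after birth, inclusive — the boundary is a parameter because "within 7
  days" does not resolve the boundary) and a **late** wave (> 7 days).
  Death *rates* are deaths per division, in percent.
* Long-term (LT) self-renewal: the continuing R cell shows a
  division-free observed span strictly longer than 30 days after some
  division. **Resting** R cells are LT cells whose long span is final;
  their `persisting_time` runs from the last division to the last
  observation. Note that on censored data a cell pausing beyond the end
  of observation is indistinguishable from a resting cell; the
  classifier reports what is observable.
* `subtree_death_asymmetry`: death frequencies (dead terminal cells over
  terminal cells) of the two subtrees created by the root's division.
  Terminal cells are leaves whether surviving or dead — the eligibility
  rule ("at least four terminal cells") counts outputs, not survivors.
* Division modes: the nine labels reachable under the allowed type
  transitions, grouped as symmetric self-renewing, asymmetric, and
  symmetric differentiating. The taxonomy lives in data
  (`division_mode_table()`) so it can be re-mapped. Divisions with any
  uncertain participant are excluded from tallies, not errors.

## The statistics kernel

Cohort comparisons in this literature use four tests, provided here in
the exact conventions needed to re-derive published legend values:

* `welch_t()` works from per-group summaries (mean, per-group SD, n).
  Published legends label the spread "s.e.m.", but the printed t and df
  values are reproducible only when the value is treated as a per-group
  standard deviation with n = 3 — verified analytically for the
  NSC-count comparisons — so that is the convention `group_summary()`
  documents and uses.
* `mann_whitney_u()` reports `U = min(U1, U2)` with midrank ties; p is
  exact by full enumeration of group assignments for small samples
  (valid under ties) and a tie-corrected normal approximation with
  continuity correction otherwise.
* `fisher_exact_2x2()` defaults to the probability-mass ("minlike")
  two-sided rule used by the common analysis software; the doubling rule
  is available by flag. On the activation/dormancy table (56/80 vs
  47/161) both conventions give p = 0.0003 to printed precision.
* `ks_two_sample()` returns the ECDF supremum D with the asymptotic
  Kolmogorov p at the effective sample size.

Under a simulated null, all four hold empirical type-I error near the
nominal 5% at the sample sizes the test suite uses (the exact Fisher and
asymptotic KS tests are conservative at small n, which is a property of
the tests, not an implementation artefact).

## The clone simulator

`simulate_clone()` draws one clone forward:

1. **Activation**: Bernoulli with the cohort activation probability
   (0.412 young, 0.226 middle-aged). Active clones draw a time to first
   division from a log-normal distribution truncated at the horizon, so
   "active" always means "divided during observation". Dormant cells die
   with the observed dormant-death probability (0 young, 1/161
   middle-aged).
2. **R lineage**: the clone draws whether its R cell will return to
   long-term quiescence (0.1964/0.4255); LT clones draw how many
   divisions precede the rest (young: always one; middle-aged:
   53.8/30.8/15.4% for 1–3) and whether the rest is final (resting;
   5/11 and 14/20 of LT cells). Regular division gaps are log-normal,
   moment-matched to the published interval means and SDs, *truncated at
   the 30-day quiescence threshold*; rest gaps are 30 days plus a
   log-normal excess. This truncation is what makes the >30-day
   classifier recover the LT probability exactly in expectation — an
   untruncated gap distribution would occasionally produce "accidental"
   long pauses that are operationally indistinguishable from long-term
   quiescence. Division modes are drawn per division; the R lineage ends
   when a mode without an R daughter is drawn. Symmetric `R->R+R`
   expansion is kept in the taxonomy but set to probability zero in both
   presets, consistent with its rarity in adult dentate gyrus imaging
   and keeping the LT probability identifiable.
3. **NR cascade**: each surviving NR divides after a log-normal gap
   (1.38 ± 1.83 d young, 2.33 ± 2.82 d middle-aged), to a maximum
   generation of 5, at which the division is forced symmetric
   differentiating.
4. **Death**: every non-R daughter independently dies early or late at
   birth, with per-daughter probability equal to half the published
   per-division death rate (each division contributes two daughters).
   Early ages are log-normal on (0, 7]; late ages are 7 days plus an
   exponential excess, truncated to the observable window. Assigning
   death at birth reproduces the two-wave age-at-death histogram without
   modelling mechanism.
5. **Observation**: event times are discretized to a daily imaging grid
   from day 2 to day 115 (both configurable); `imaging_interval = 0`
   records exact event times. Daily rounding biases interval estimates
   upward by about half a day, so distribution-recovery checks run in
   the exact-time mode while round-trip and qualitative checks use the
   daily grid. Death and division gaps are bounded below by the imaging
   interval so that recorded intervals are strictly positive, as they
   are in session-coded data.

Values the source cohorts do not pin down were chosen once as
field-plausible defaults and are not tuned: the time to first division
(log-normal, mean 25 ± 18 d, shared by both presets, matching the
observation that it does not differ substantially with age), the division
mode probabilities, the within-wave death-age shapes, and all morphometry
parameters. `age_params()` exposes every parameter for override.

What the generator does *not* emulate: niche or spatial interactions,
type transitions within a single cell's history (an NR maturing into an N
under the same id — the assembler supports them, the generator does not
emit them), annotator disagreement structure beyond independent per-cell
uncertainty flags, and irregular imaging gaps. Tests passing on
simulated cohorts therefore validate the bookkeeping and estimators, not
the biological realism of any particular parameter value.

## Parameter recovery

`recover_parameters()` re-estimates generator parameters by running the
complete pipeline (trees -> metrics) on a simulated cohort and reports
`z = (estimate - target) / se` per quantity. Estimator design notes:

* death rates use the per-daughter estimator `2 * deaths / non-R
  daughters`, whose expectation is the per-division rate, with a
  cluster-robust standard error (daughter counts and deaths cluster
  within clones);
* the late-wave estimator conditions on daughters born at least 7 days
  before the end of observation, for whom a late death always falls
  inside the window — removing right-censoring bias;
* interval means condition on gaps that start early enough to complete
  before the horizon and are compared against the analytic truncated
  log-normal mean (`truncated_lnorm_mean()`).

At 2000 clones per preset all six quantities sit within 3 standard errors
of their generator values; this is asserted in the test suite.

## Morphometrics

Migration uses consecutive recorded positions: accumulative distance is
the sum of step lengths, displacement the first-to-last distance, and
migration is considered over after the last step exceeding a 1 µm motion
threshold (the data do not define when migration "stops"; the threshold
is a parameter). Soma growth is normalized by an anchor granule cell
measured in the same field — a stable, reporter-leaky mature cell — which
cancels session-to-session acquisition scaling; `time_to_max_soma()`
resolves ties to the earliest day. Dendrite skeletons are read from SWC
files, with node chains collapsed to unbranched segments between the
soma, branch points and tips; the branch count is the number of terminal
tips (an unbranched neurite counts one; an internal-branch-point count
can be derived from the same structure). Positions are treated as 2-D
projections, with a z column used when present.

## Problem sizes and numerical choices

The test suite simulates cohorts of 20–400 clones for structural and
qualitative checks and 2000 clones per preset for parameter recovery; the
acceptance script uses 2000 (recovery) and 500 (cohort summaries) clones.
These sizes give standard errors comfortably below the effect sizes being
checked while keeping a full run in minutes on one core. Ties in soma
maxima resolve to the earliest timepoint; the Fisher "minlike" rule
includes tables whose probability is within a relative 1e-7 of the
observed table's, the standard guard against floating-point
near-equality; tree assembly tolerates equality of a mother's last
observation with its daughters' first.

## Known limitations

* Quantities that depend on the deposited imaging data (cohort means of
  the real young and middle-aged clones) can be recomputed by pointing
  `read_cohort_dir()` + `cohort_regression_summary()` at a local copy of
  the published lineage archive; the package itself ships no imaging
  data.
* The simulator's clone-level LT draw makes lineage fates exchangeable
  within a preset; real clones are nested within animals, so
  animal-level variance components are not represented.
* Censoring at the horizon means "resting" is always a statement about
  the observed window; the simulator's ground truth distinguishes a
  resting cell from a pausing one, the classifier cannot.
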