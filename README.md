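# clonedyn

Clonal lineage dynamics of hippocampal neural stem cells from chronic
intravital imaging.

## What this is for

Adult neurogenesis in the mouse dentate gyrus declines sharply with age.
Chronic intravital two-photon imaging makes it possible to follow a
single labelled radial glia-like stem cell (**R** cell) and all of its
progeny — nonradial progenitors (**NR**) and newborn neurons (**N**) —
daily, for up to 115 days, inside the living hippocampus. The raw output
of such an experiment, after manual annotation, is an *ROI coding table*:
one row per cell per timepoint with columns `CellID`, `CellType`,
`UncertaintyCellType`, `Timepoint`, `MotherID`, `UncertaintyMotherCell`,
`SisterID`, `UncertaintySisterCell`, `CellDeath`.

`clonedyn` is an R package for everything downstream of that table:

* **Lineage assembly** — parse coding tables, build validated
  binary-division lineage trees (every division replaces a mother by two
  daughters; types progress `R -> NR -> N`), apply the
  certainty rules, export JSON/Newick.
* **Clonal metrics** — final clone size and composition, division counts
  and maximum successive divisions, activity duration, R self-renewal
  duration, division intervals by rank, time to first division.
* **Fate and death** — early (≤ 7 d after birth) versus late (> 7 d)
  death waves, death rates per division, long-term (> 30 d) return to
  quiescence, resting R cells and their persisting times, the
  nine-label division-mode taxonomy, subtree death asymmetry.
* **Morphometrics** — newborn-neuron migration (accumulative distance,
  displacement, speed, duration), anchor-normalized soma growth, and
  dendrite metrics (total/primary/longest-branch length, branch count)
  from SWC skeletons, with weekly growth curves.
* **Statistics kernel** — Welch's t test computable from printed
  per-group summaries (mean, SD, n), Mann–Whitney U (min(U1,U2), exact
  enumeration for small samples), two-sided Fisher's exact test
  (probability-mass and doubling conventions), and the two-sample
  Kolmogorov–Smirnov test. For example, Welch's t from two summary
  triples:

  t = (m₁ − m₂) / √(s₁²/n₁ + s₂²/n₂),  df by Welch–Satterthwaite.

* **Clone simulator** — an event-driven branching-process generator with
  `young` and `middle_aged` presets (activation 41.2% vs 22.6%, R
  intervals 10.48 ± 13.43 vs 25.68 ± 30.21 d, NR intervals 1.38 ± 1.83
  vs 2.33 ± 2.82 d, long-term quiescence 19.64% vs 42.55%, early/late
  death 36.55%/20.48% vs 53.92%/17.48% of divisions), a daily
  observation/censoring model, and emission of schema-complete coding
  tables, so the whole pipeline runs with no external data.

## Worked example

```r
library(clonedyn)

# simulate a middle-aged cohort of 150 tracked R cells
sim <- simulate_cohort(150, "middle_aged", seed = 42)
sim$cohort
#> <clone_cohort> middle_aged
#>   clones: 150 | active: 43 | dormant R cells: 107

activation_summary(sim$cohort)$fraction_active   # 0.287

m <- cohort_metrics(sim$cohort)                  # one row per active clone
mean(m$final_cell_number)                        # 3.4 cells
mean(m$lt_self_renewing); mean(m$resting_R)      # 0.49, 0.40

ev <- do.call(rbind, lapply(active_clones(sim$cohort), classify_deaths))
death_wave_fractions(ev)$early_pct               # 82.4 (% of deaths early)

tree <- active_clones(sim$cohort)[[1]]
tree
#> <lineage_tree> clone clone_0013 [middle_aged]
#>   cells: 13 | active: TRUE | window: 2 - 115 days
#>   final types: R=4 NR=4 N=5
clone_metrics(tree)[, c("final_cell_number", "n_divisions_total",
                        "activity_duration", "time_to_first_division")]
#>   final_cell_number n_divisions_total activity_duration time_to_first_division
#> 1                 6                 6                28                     21
```

The 43/150 active clones (28.7%) reflect the preset's 22.6% activation
probability at this cohort size; the mean final clone size of 3.4 cells,
the ~49% long-term self-renewal and the early-dominated death wave are
the middle-aged clonal signature the simulator encodes. The same
functions run unchanged on real coding tables:

```r
cohort <- read_cohort_dir("path/to/coding_csvs", label = "young")
cohort_regression_summary(cohort)   # mean clone size, LT %, resting %, ...
```

Published legend statistics re-derive from printed summaries alone:

```r
welch_t(group_summary(5435, 707, 3), group_summary(980, 265, 3))
#> $t 10.22, $df 2.551, $p_two_sided 0.0039
fisher_exact_2x2(matrix(c(56, 47, 80, 161), 2, 2))$p_two_sided
#> 0.0003
```

A thin CLI wrapper lives at `inst/cli/clonedyn.R`
(`validate`, `tree`, `metrics`, `simulate`).

## Documentation

The methods vignette (`vignettes/clonal-dynamics.Rmd`) documents the
lineage model and every convention choice (division timing, rank
labelling, certainty handling, death-wave boundary, the continuing-R-cell
rule), the generative model behind the simulator presets, the estimator
design used for parameter recovery, and known limitations.
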