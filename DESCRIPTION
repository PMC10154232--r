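Package: clonedyn
Title: Clonal Lineage Dynamics of Hippocampal Neural Stem Cells from
    Chronic Intravital Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the clonal analysis of radial glia-like neural stem
    cells (R cells) and their progeny followed by chronic intravital
    two-photon imaging in the mouse dentate gyrus. Parses per-cell ROI
    coding tables (CellID, CellType, Timepoint, MotherID, SisterID,
    uncertainty and death flags), assembles and validates binary-division
    lineage trees, and computes per-clone dynamics: final clone size and
    composition, division counts and successive-division depth, activity
    and self-renewal durations, division intervals by rank, time to first
    division, early/late (7-day threshold) cell-death classification and
    rates, long-term (>30 day) return to quiescence, resting R cells and
    their persisting times, division-mode taxonomy, and subtree death
    asymmetry. Includes newborn-neuron morphometrics (migration distance,
    displacement and speed; anchor-normalized soma growth; dendrite length
    and branching from SWC skeletons), the summary-statistic tests used for
    cohort comparisons (Welch t from summaries, Mann-Whitney U, two-sided
    Fisher exact, two-sample Kolmogorov-Smirnov), and a stochastic
    branching-process clone simulator with young and middle-aged parameter
    presets that emits schema-complete coding tables for end-to-end runs
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
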