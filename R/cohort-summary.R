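## Cohort-level summaries matching the figures reported for the young and
## middle-aged imaging cohorts, so a locally downloaded copy of the
## deposited lineage data (a directory of ROI coding CSVs) can be
## re-analysed end to end.

#' Assemble a cohort from a directory of coding CSVs
#'
#' Reads every `*.csv` file under `dir` with [read_coding_table()] and
#' assembles all clones found (one clone per file, or several via a
#' `CloneID` column).
#'
#' @param dir Directory containing coding CSV files.
#' @param label Cohort label.
#' @param n_dormant Optional dormant-cell count when dormant R cells were
#'   tallied outside the coding tables.
#' @param ... Passed to [read_coding_table()] (e.g. `timepoint_units`).
#' @return A `clone_cohort`.
#' @export
read_cohort_dir <- function(dir, label = NULL, n_dormant = NULL, ...) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  if (length(files) == 0) {
    stop("no .csv coding tables found under ", dir, call. = FALSE)
  }
  assemble_cohort(as.list(files), label = label, n_dormant = n_dormant, ...)
}

#' Cohort regression summary
#'
#' The headline cohort statistics: mean final size of active clones, the
#' percentage of active clones whose R cell shows long-term (>30 d) return
#' to quiescence, the percentage classified as resting R cells, and the
#' mean persisting time of resting R cells.
#'
#' @param cohort A `clone_cohort`.
#' @param quiescence_threshold Long-term quiescence threshold in days.
#' @return List with `n_active`, `mean_final_cell_number`,
#'   `sd_final_cell_number`, `lt_self_renewal_pct`, `resting_r_pct` and
#'   `mean_persisting_time`.
#' @export
cohort_regression_summary <- function(cohort, quiescence_threshold = 30) {
  stopifnot(inherits(cohort, "clone_cohort"))
  act <- active_clones(cohort)
  if (length(act) == 0) {
    stop("cohort has no active clones", call. = FALSE)
  }
  sizes <- vapply(act, final_cell_number, numeric(1))
  fate <- lapply(act, classify_lt_self_renewal,
                 quiescence_threshold = quiescence_threshold)
  lt <- vapply(fate, `[[`, logical(1), "lt_self_renewing")
  resting <- vapply(fate, `[[`, logical(1), "resting_R")
  persist <- vapply(fate, `[[`, numeric(1), "persisting_time")
  list(n_active = length(act),
       mean_final_cell_number = mean(sizes),
       sd_final_cell_number = stats::sd(sizes),
       lt_self_renewal_pct = 100 * mean(lt),
       resting_r_pct = 100 * mean(resting),
       mean_persisting_time = if (any(resting))
         mean(persist[resting]) else NA_real_)
}
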