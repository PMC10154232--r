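## Per-clone dynamic metrics.
##
## Conventions: a division is attributed to the mother's type at the time
## of division; only fully certain cells contribute (see filter_certain);
## a division's time is its daughters' first observed timepoint; intervals
## are computed from recorded timepoints, not session indices.

.not_active <- function(tree) {
  stop(structure(class = c("clonedyn_not_active", "error", "condition"),
                 list(message = paste0("clone ", tree$clone_id,
                                       " is quiescent (root never divided)"),
                      call = sys.call(-1))))
}

#' Division events of a clone
#'
#' One row per division: mother id and type, division time, overall rank
#' (1 = the root's division), same-type rank (`type_rank`, counting
#' divisions by mothers of the same type along the ancestral path,
#' inclusive), the gap since the division that produced the mother
#' (`interval`, `NA` for the root), daughters and their birth types, and
#' certainty flags.
#'
#' @param tree A `lineage_tree`.
#' @param certain_only Restrict to divisions by fully certain mothers
#'   (default, matching the coding convention that only CERTAIN cells are
#'   analysed).
#' @return Data frame of division events, ordered by time.
#' @export
divisions <- function(tree, certain_only = TRUE) {
  stopifnot(inherits(tree, "lineage_tree"))
  cells <- tree$cells
  mothers <- cells$cell_id[!is.na(cells$division_time)]
  out <- data.frame(mother_id = character(0), mother_type = character(0),
                    time = numeric(0), rank = integer(0),
                    type_rank = integer(0), interval = numeric(0),
                    d1 = character(0), d2 = character(0),
                    d1_type = character(0), d2_type = character(0),
                    certain = logical(0), daughters_certain = logical(0),
                    stringsAsFactors = FALSE)
  if (length(mothers) == 0) return(out)

  ## per-cell counts of R/NR divisions along the ancestral path (at birth)
  counts <- matrix(0L, nrow = nrow(cells), ncol = 2,
                   dimnames = list(cells$cell_id, c("R", "NR")))
  ord <- cells$cell_id[order(cells$generation)]
  for (id in ord) {
    m <- cells[id, "mother_id"]
    if (!is.na(m)) {
      counts[id, ] <- counts[m, ]
      mt <- cells[m, "final_type"]
      if (mt %in% c("R", "NR")) counts[id, mt] <- counts[id, mt] + 1L
    }
  }
  rows <- lapply(mothers, function(m) {
    d <- .daughters_of(tree, m)
    mt <- cells[m, "final_type"]
    data.frame(
      mother_id = m, mother_type = mt,
      time = cells[m, "division_time"],
      rank = cells[m, "generation"] + 1L,
      type_rank = counts[m, mt] + 1L,
      interval = if (m == tree$root_id) NA_real_ else
        cells[m, "division_time"] - cells[m, "birth_time"],
      d1 = d[1], d2 = d[2],
      d1_type = cells[d[1], "first_type"], d2_type = cells[d[2], "first_type"],
      certain = cells[m, "certain"],
      daughters_certain = all(cells[d, "certain"]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$time, out$mother_id), , drop = FALSE]
  if (certain_only) out <- out[out$certain, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Final clone size
#'
#' Number of (certain) cells alive — neither divided nor dead — at the end
#' of observation.
#'
#' @param tree A `lineage_tree`.
#' @return Integer count (0 for a fully extinct clone).
#' @export
final_cell_number <- function(tree) {
  cells <- .metric_cells(tree)
  sum(is.na(cells$division_time) & is.na(cells$death_time))
}

#' Final clone composition by cell type
#'
#' @param tree A `lineage_tree`.
#' @return Named integer vector with counts of surviving `R`, `NR` and `N`
#'   cells; sums to [final_cell_number()].
#' @export
final_composition <- function(tree) {
  cells <- .metric_cells(tree)
  alive <- cells[is.na(cells$division_time) & is.na(cells$death_time), ]
  tab <- table(factor(alive$final_type, levels = .cell_types))
  stats::setNames(as.integer(tab), .cell_types)
}

#' Division counts
#'
#' Total number of divisions in the clone, split by the mother's type at
#' division.
#'
#' @param tree A `lineage_tree`.
#' @return List with `total`, `R` and `NR` counts
#'   (`total = R + NR`; neurons never divide).
#' @export
count_divisions <- function(tree) {
  div <- divisions(tree)
  list(total = nrow(div),
       R = sum(div$mother_type == "R"),
       NR = sum(div$mother_type == "NR"))
}

#' Maximum rounds of successive divisions
#'
#' The largest number of division events encountered along any single
#' root-to-leaf path, optionally restricted to divisions by mothers of one
#' type.
#'
#' @param tree A `lineage_tree`.
#' @param type `"any"`, `"R"` or `"NR"`.
#' @return Integer count (0 for a quiescent clone).
#' @export
max_successive_divisions <- function(tree, type = c("any", "R", "NR")) {
  type <- match.arg(type)
  cells <- tree$cells
  rec <- function(id) {
    d <- .daughters_of(tree, id)
    if (length(d) == 0) return(0L)
    here <- as.integer(cells[id, "certain"] &&
                         (type == "any" || cells[id, "final_type"] == type))
    here + max(vapply(d, rec, integer(1)))
  }
  rec(tree$root_id)
}

## Latest timepoint at which type R is observed anywhere along the R-typed
## descendant chain starting from `id` (used to decide which of two R
## daughters continues "the R cell")
.r_reach <- function(tree, id) {
  cells <- tree$cells
  own <- tree$history$timepoint[tree$history$cell_id == id &
                                  tree$history$type == "R"]
  reach <- if (length(own)) max(own) else -Inf
  if (!is.na(cells[id, "division_time"]) && cells[id, "final_type"] == "R") {
    d <- .daughters_of(tree, id)
    dR <- d[cells[d, "first_type"] == "R"]
    for (x in dR) reach <- max(reach, .r_reach(tree, x))
  }
  reach
}

## The R-cell continuation chain: the root, then at each division the R
## daughter (when both daughters are R, the one whose own R lineage is
## observed longest; ties break lexicographically on cell id). Stops when
## the lineage loses type R, becomes uncertain, dies or stops dividing.
.r_chain <- function(tree) {
  cells <- tree$cells
  chain <- character(0)
  division_times <- numeric(0)
  cur <- tree$root_id
  repeat {
    chain <- c(chain, cur)
    if (!cells[cur, "certain"]) break
    if (is.na(cells[cur, "division_time"]) ||
        cells[cur, "final_type"] != "R") break
    division_times <- c(division_times, cells[cur, "division_time"])
    d <- .daughters_of(tree, cur)
    dR <- d[cells[d, "first_type"] == "R"]
    if (length(dR) == 0) break
    if (length(dR) == 2) {
      reach <- vapply(dR, function(x) .r_reach(tree, x), numeric(1))
      dR <- dR[order(-reach, dR)][1]
    }
    cur <- dR
  }
  last_r_obs <- max(c(-Inf, tree$history$timepoint[
    tree$history$cell_id %in% chain & tree$history$type == "R"]))
  list(cells = chain, division_times = division_times,
       last_r_obs = last_r_obs,
       last_cell = chain[length(chain)])
}

#' Activity duration of a clone
#'
#' Days from the first R division to the last division of any progenitor
#' (R or NR) in the clone; 0 when the clone divided only once.
#'
#' @param tree An active `lineage_tree`.
#' @return Duration in days (`NA` if no certain R division is recorded).
#' @export
activity_duration <- function(tree) {
  if (!tree$active) .not_active(tree)
  div <- divisions(tree)
  r_times <- div$time[div$mother_type == "R"]
  if (length(r_times) == 0) return(NA_real_)
  max(div$time) - min(r_times)
}

#' R self-renewal duration
#'
#' Days from the first R division until the last timepoint at which the
#' continuing R cell (the R daughter retained across successive divisions)
#' was observed with type R; 0 when the R lineage disappeared after the
#' first division.
#'
#' @param tree An active `lineage_tree`.
#' @return Duration in days.
#' @export
r_self_renewal_duration <- function(tree) {
  if (!tree$active) .not_active(tree)
  ch <- .r_chain(tree)
  if (length(ch$division_times) == 0) return(NA_real_)
  max(0, ch$last_r_obs - ch$division_times[1])
}

#' Division intervals by rank
#'
#' Gaps between successive divisions of cells of one type. For R cells the
#' root's time to first division is excluded, and rank 1 labels the gap
#' between the first and second R division along a lineage. For NR cells
#' the gap from an NR cell's birth (the division that created it) to its
#' own division is included, with rank equal to the NR division generation.
#'
#' @param tree A `lineage_tree`.
#' @param type `"R"` or `"NR"`.
#' @param rank_offset Added to the reported ranks, should a different rank
#'   labelling convention be required.
#' @return Data frame with columns `rank`, `interval` (days) and `time`
#'   (the day of the later division); zero rows when no interval is
#'   measurable.
#' @export
division_intervals <- function(tree, type = c("R", "NR"), rank_offset = 0L) {
  type <- match.arg(type)
  div <- divisions(tree)
  div <- div[div$mother_type == type & !is.na(div$interval), , drop = FALSE]
  if (nrow(div) == 0) {
    return(data.frame(rank = integer(0), interval = numeric(0),
                      time = numeric(0)))
  }
  rank <- if (type == "R") div$type_rank - 1L else div$type_rank
  out <- data.frame(rank = rank + as.integer(rank_offset),
                    interval = div$interval, time = div$time)
  out[order(out$rank, out$interval), , drop = FALSE]
}

#' Time to first R division
#'
#' Days from induction (day 0) to the first observed division of the root
#' R cell. Clones already consisting of two cells at the first imaging
#' session are assigned `first_session_value` (default 1 day).
#'
#' @param tree An active `lineage_tree`.
#' @param origin Reference time in days (0 = induction; set to the first
#'   imaging day to measure from the start of observation instead).
#' @param first_session_value Value assigned when the root had already
#'   divided by the first imaging session.
#' @return Time in days.
#' @export
time_to_first_division <- function(tree, origin = 0, first_session_value = 1) {
  if (!tree$active) .not_active(tree)
  t1 <- tree$cells[tree$root_id, "division_time"]
  if (t1 <= tree$observation_start) return(first_session_value)
  t1 - origin
}

#' All per-clone metrics as a one-row data frame
#'
#' Convenience wrapper collecting sizes, composition, division counts and
#' depths, durations, interval summaries, time to first division, death
#' rates and fate labels for one clone.
#'
#' @param tree A `lineage_tree`.
#' @param early_threshold Early/late death boundary in days.
#' @param quiescence_threshold Long-term quiescence threshold in days.
#' @return One-row data frame.
#' @export
clone_metrics <- function(tree, early_threshold = 7,
                          quiescence_threshold = 30) {
  comp <- final_composition(tree)
  ndiv <- count_divisions(tree)
  ri <- division_intervals(tree, "R")
  ni <- division_intervals(tree, "NR")
  act <- tree$active
  rates <- if (act && ndiv$total > 0) {
    death_rates(tree, early_threshold = early_threshold)
  } else {
    list(total_rate = NA_real_, early_rate = NA_real_, late_rate = NA_real_)
  }
  fate <- if (act) {
    classify_lt_self_renewal(tree, quiescence_threshold = quiescence_threshold)
  } else {
    list(lt_self_renewing = FALSE, resting_R = FALSE,
         n_R_divisions_before_rest = NA_integer_, persisting_time = NA_real_)
  }
  data.frame(
    clone_id = tree$clone_id,
    label = if (is.null(tree$label)) NA_character_ else tree$label,
    active = act,
    final_cell_number = final_cell_number(tree),
    final_R = comp[["R"]], final_NR = comp[["NR"]], final_N = comp[["N"]],
    n_divisions_total = ndiv$total, n_divisions_R = ndiv$R,
    n_divisions_NR = ndiv$NR,
    max_successive_total = max_successive_divisions(tree, "any"),
    max_successive_R = max_successive_divisions(tree, "R"),
    max_successive_NR = max_successive_divisions(tree, "NR"),
    activity_duration = if (act) activity_duration(tree) else NA_real_,
    r_self_renewal_duration = if (act) r_self_renewal_duration(tree)
                              else NA_real_,
    time_to_first_division = if (act) time_to_first_division(tree)
                             else NA_real_,
    mean_r_interval = if (nrow(ri)) mean(ri$interval) else NA_real_,
    n_r_intervals = nrow(ri),
    mean_nr_interval = if (nrow(ni)) mean(ni$interval) else NA_real_,
    n_nr_intervals = nrow(ni),
    total_death_rate = rates$total_rate,
    early_death_rate = rates$early_rate,
    late_death_rate = rates$late_rate,
    lt_self_renewing = fate$lt_self_renewing,
    resting_R = fate$resting_R,
    n_R_divisions_before_rest = fate$n_R_divisions_before_rest,
    persisting_time = fate$persisting_time,
    stringsAsFactors = FALSE
  )
}

#' Per-clone metrics for a cohort
#'
#' @param cohort A `clone_cohort`.
#' @param active_only Restrict to active clones (default; dormant R cells
#'   contribute to [activation_summary()] instead).
#' @param ... Passed to [clone_metrics()].
#' @return Data frame with one row per clone.
#' @export
cohort_metrics <- function(cohort, active_only = TRUE, ...) {
  stopifnot(inherits(cohort, "clone_cohort"))
  clones <- if (active_only) active_clones(cohort) else cohort$clones
  do.call(rbind, lapply(clones, clone_metrics, ...))
}

#' Pooled division intervals for a cohort
#'
#' @param cohort A `clone_cohort`.
#' @param type `"R"` or `"NR"`.
#' @return Data frame with `clone_id`, `rank` and `interval` over all
#'   active clones (the per-division pooling used for cohort interval
#'   means).
#' @export
cohort_division_intervals <- function(cohort, type = c("R", "NR")) {
  type <- match.arg(type)
  rows <- lapply(active_clones(cohort), function(tr) {
    iv <- division_intervals(tr, type)
    if (nrow(iv) == 0) return(NULL)
    cbind(clone_id = tr$clone_id, iv, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(clone_id = character(0), rank = integer(0),
                      interval = numeric(0))
  }
  rownames(out) <- NULL
  out
}
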