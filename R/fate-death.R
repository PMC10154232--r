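## Cell-death waves, long-term self-renewal and division-mode taxonomy.
##
## Two death waves are distinguished by age at death: "early" within the
## first 7 days after birth (inclusive boundary), "late" beyond. Death
## rates are expressed relative to the number of divisions in the clone.

#' Classify death events into early and late waves
#'
#' @param tree A `lineage_tree`.
#' @param early_threshold Age at death (days) up to and including which a
#'   death counts as early.
#' @param certain_only Restrict to fully certain cells.
#' @return Data frame with one row per dead cell: `cell_id`, `birth_time`,
#'   `death_time`, `age_at_death`, `wave` (`"early"`/`"late"`) and
#'   `division_rank_of_mother` (the rank of the division that produced the
#'   cell; 0 for a dormant root).
#' @export
classify_deaths <- function(tree, early_threshold = 7, certain_only = TRUE) {
  stopifnot(inherits(tree, "lineage_tree"))
  cells <- .metric_cells(tree, certain_only = certain_only)
  dead <- cells[!is.na(cells$death_time), , drop = FALSE]
  age <- dead$death_time - dead$birth_time
  data.frame(
    cell_id = dead$cell_id,
    birth_time = dead$birth_time,
    death_time = dead$death_time,
    age_at_death = age,
    wave = ifelse(age <= early_threshold, "early", "late"),
    division_rank_of_mother = dead$generation,
    stringsAsFactors = FALSE
  )
}

#' Early/late composition of a set of death events
#'
#' @param ages Numeric vector of ages at death (days), or a data frame from
#'   [classify_deaths()].
#' @param early_threshold Early/late boundary in days.
#' @return List with `n_early`, `n_late`, `early_pct` and `late_pct`
#'   (percentages of all deaths).
#' @examples
#' # 256 early and 200 late events -> early 56.14%
#' death_wave_fractions(c(rep(1, 256), rep(14, 200)))
#' @export
death_wave_fractions <- function(ages, early_threshold = 7) {
  if (is.data.frame(ages)) ages <- ages$age_at_death
  stopifnot(is.numeric(ages))
  if (length(ages) == 0) {
    return(list(n_early = 0L, n_late = 0L,
                early_pct = NA_real_, late_pct = NA_real_))
  }
  n_early <- sum(ages <= early_threshold)
  n_late <- length(ages) - n_early
  list(n_early = n_early, n_late = n_late,
       early_pct = 100 * n_early / length(ages),
       late_pct = 100 * n_late / length(ages))
}

#' Per-clone death rates
#'
#' The death rate is the number of dying cells divided by the total number
#' of divisions in the clone, in percent; early and late rates split the
#' numerator by death wave.
#'
#' @param tree An active `lineage_tree` with at least one division.
#' @param early_threshold Early/late boundary in days.
#' @return List with `total_rate`, `early_rate` and `late_rate`
#'   (percentages).
#' @export
death_rates <- function(tree, early_threshold = 7) {
  n_div <- count_divisions(tree)$total
  if (n_div == 0) {
    stop("clone ", tree$clone_id,
         " has no divisions: death rate is undefined", call. = FALSE)
  }
  ev <- classify_deaths(tree, early_threshold = early_threshold)
  list(total_rate = 100 * nrow(ev) / n_div,
       early_rate = 100 * sum(ev$wave == "early") / n_div,
       late_rate = 100 * sum(ev$wave == "late") / n_div)
}

#' Long-term self-renewal and resting-R classification
#'
#' An activated R cell shows long-term (LT) self-renewal when, after some
#' division, its continuing R lineage is observed division-free for
#' strictly more than `quiescence_threshold` days. It is a resting R cell
#' when that quiescent span is final, i.e. no further division occurs
#' through the end of observation.
#'
#' @param tree An active `lineage_tree`.
#' @param quiescence_threshold Quiescent-span threshold in days (>30 d
#'   defines long-term quiescence).
#' @return List with `clone_id`, `lt_self_renewing`, `resting_R`,
#'   `n_R_divisions_before_rest` (R divisions up to and including the one
#'   preceding the first long quiescent span; `NA` when not LT) and
#'   `persisting_time` (days; `NA` unless resting).
#' @export
classify_lt_self_renewal <- function(tree, quiescence_threshold = 30) {
  if (!tree$active) .not_active(tree)
  ch <- .r_chain(tree)
  k <- length(ch$division_times)
  out <- list(clone_id = tree$clone_id, lt_self_renewing = FALSE,
              resting_R = FALSE, n_R_divisions_before_rest = NA_integer_,
              persisting_time = NA_real_)
  if (k == 0) return(out)
  ## division-free spans of the continuing R cell: between successive
  ## chain divisions, then from the last division to the last R observation
  spans <- c(diff(ch$division_times),
             ch$last_r_obs - ch$division_times[k])
  long <- which(spans > quiescence_threshold)
  if (length(long) == 0) return(out)
  out$lt_self_renewing <- TRUE
  out$n_R_divisions_before_rest <- long[1]
  if (long[1] == k) {
    out$resting_R <- TRUE
    out$persisting_time <- min(tree$observation_end, ch$last_r_obs) -
      ch$division_times[k]
  }
  out
}

#' Persisting time of a resting R cell
#'
#' Days from the resting R cell's last division to the end of observation
#' (or its last observation, if earlier).
#'
#' @inheritParams classify_lt_self_renewal
#' @return Time in days.
#' @export
persisting_time <- function(tree, quiescence_threshold = 30) {
  lab <- classify_lt_self_renewal(tree,
                                  quiescence_threshold = quiescence_threshold)
  if (!lab$resting_R) {
    stop("clone ", tree$clone_id,
         " is not a resting-R clone; persisting time is undefined",
         call. = FALSE)
  }
  lab$persisting_time
}

#' Division-mode taxonomy
#'
#' The nine modes a binary division can take under the allowed type
#' transitions (R daughters only from R mothers, N cells never divide),
#' grouped into the classic categories: symmetric self-renewing (both
#' daughters retain the mother's type), asymmetric (one does), and
#' symmetric differentiating (neither does).
#'
#' @return Data frame with columns `label`, `mother`, `d1`, `d2` and
#'   `class`.
#' @export
division_mode_table <- function() {
  tab <- data.frame(
    mother = c("R", "R", "R", "R", "R", "R", "NR", "NR", "NR"),
    d1 = c("R", "R", "R", "NR", "NR", "N", "NR", "NR", "N"),
    d2 = c("R", "NR", "N", "NR", "N", "N", "NR", "N", "N"),
    class = c("symmetric self-renewing", "asymmetric", "asymmetric",
              "symmetric differentiating", "symmetric differentiating",
              "symmetric differentiating", "symmetric self-renewing",
              "asymmetric", "symmetric differentiating"),
    stringsAsFactors = FALSE
  )
  tab$label <- paste0(tab$mother, "->", tab$d1, "+", tab$d2)
  tab[, c("label", "mother", "d1", "d2", "class")]
}

#' Classify the mode of one division
#'
#' @param mother_type Mother's type at division (`"R"` or `"NR"`).
#' @param daughter_types Character vector of the two daughters' birth
#'   types.
#' @return List with `label` (e.g. `"R->R+NR"`) and `class`.
#' @export
division_mode <- function(mother_type, daughter_types) {
  stopifnot(length(daughter_types) == 2)
  d <- daughter_types[order(.type_rank[daughter_types])]
  tab <- division_mode_table()
  hit <- tab[tab$mother == mother_type & tab$d1 == d[1] & tab$d2 == d[2], ]
  if (nrow(hit) != 1) {
    stop("division ", mother_type, " -> ", paste(d, collapse = "+"),
         " violates the allowed type transitions", call. = FALSE)
  }
  list(label = hit$label, class = hit$class)
}

#' Division modes of a clone
#'
#' Classifies every division in which the mother and both daughters are
#' fully certain; divisions with an uncertain participant are excluded
#' (filtered, not an error).
#'
#' @param tree A `lineage_tree`.
#' @return Data frame with `mother_id`, `time`, `rank`, `label` and
#'   `class`; zero rows for quiescent clones.
#' @export
division_modes <- function(tree) {
  div <- divisions(tree)
  div <- div[div$daughters_certain, , drop = FALSE]
  if (nrow(div) == 0) {
    return(data.frame(mother_id = character(0), time = numeric(0),
                      rank = integer(0), label = character(0),
                      class = character(0), stringsAsFactors = FALSE))
  }
  modes <- lapply(seq_len(nrow(div)), function(i) {
    division_mode(div$mother_type[i], c(div$d1_type[i], div$d2_type[i]))
  })
  data.frame(mother_id = div$mother_id, time = div$time, rank = div$rank,
             label = vapply(modes, `[[`, character(1), "label"),
             class = vapply(modes, `[[`, character(1), "class"),
             stringsAsFactors = FALSE)
}

#' Death asymmetry between the two first-division subtrees
#'
#' Splits the clone at the root's division and compares death frequencies
#' (dead terminal cells over all terminal cells, in percent) between the
#' two subtrees. Only clones whose main tree generated at least
#' `min_terminal_cells` terminal cells are eligible.
#'
#' @param tree An active `lineage_tree`.
#' @param min_terminal_cells Minimum number of terminal cells (leaves,
#'   surviving or dead) across both subtrees.
#' @param certain_only Restrict to fully certain cells.
#' @return List with `freq_subtree1`, `freq_subtree2` (percent),
#'   `abs_difference`, and per-subtree `n_terminal`/`n_dead` counts.
#'   Ineligible clones raise a condition of class
#'   `"clonedyn_ineligible_clone"`.
#' @export
subtree_death_asymmetry <- function(tree, min_terminal_cells = 4,
                                    certain_only = TRUE) {
  if (!tree$active) .not_active(tree)
  cells <- tree$cells
  d <- .daughters_of(tree, tree$root_id)
  subtree_ids <- function(id) {
    out <- id
    frontier <- id
    while (length(frontier) > 0) {
      nxt <- cells$cell_id[!is.na(cells$mother_id) &
                             cells$mother_id %in% frontier]
      out <- c(out, nxt)
      frontier <- nxt
    }
    out
  }
  stats_of <- function(ids) {
    sub <- cells[cells$cell_id %in% ids, , drop = FALSE]
    if (certain_only) sub <- sub[sub$certain, , drop = FALSE]
    leaves <- sub[is.na(sub$division_time), , drop = FALSE]
    c(n_terminal = nrow(leaves), n_dead = sum(!is.na(leaves$death_time)))
  }
  s1 <- stats_of(subtree_ids(d[1]))
  s2 <- stats_of(subtree_ids(d[2]))
  n_term <- s1[["n_terminal"]] + s2[["n_terminal"]]
  if (n_term < min_terminal_cells) {
    stop(structure(
      class = c("clonedyn_ineligible_clone", "error", "condition"),
      list(message = paste0("clone ", tree$clone_id, " generated ", n_term,
                            " terminal cells (< ", min_terminal_cells, ")"),
           call = sys.call(-1))))
  }
  f1 <- if (s1[["n_terminal"]] > 0) 100 * s1[["n_dead"]] / s1[["n_terminal"]]
        else NA_real_
  f2 <- if (s2[["n_terminal"]] > 0) 100 * s2[["n_dead"]] / s2[["n_terminal"]]
        else NA_real_
  list(freq_subtree1 = f1, freq_subtree2 = f2,
       abs_difference = abs(f1 - f2),
       n_terminal = c(subtree1 = s1[["n_terminal"]],
                      subtree2 = s2[["n_terminal"]]),
       n_dead = c(subtree1 = s1[["n_dead"]], subtree2 = s2[["n_dead"]]))
}

#' Distribution of early deaths over division rank
#'
#' Histogram of the division rank of the mothers of cells that died in the
#' early wave, pooled over a cohort.
#'
#' @param x A `clone_cohort`, a list of `lineage_tree`s, or a data frame of
#'   classified deaths.
#' @param early_threshold Early/late boundary in days.
#' @param normalize Return proportions instead of counts.
#' @return Named numeric vector indexed by division rank (empty when there
#'   are no early deaths).
#' @export
early_death_by_rank <- function(x, early_threshold = 7, normalize = FALSE) {
  events <- if (is.data.frame(x)) {
    x
  } else {
    trees <- if (inherits(x, "clone_cohort")) x$clones else x
    do.call(rbind, lapply(trees, classify_deaths,
                          early_threshold = early_threshold))
  }
  early <- events[events$wave == "early", , drop = FALSE]
  if (nrow(early) == 0) return(stats::setNames(numeric(0), character(0)))
  tab <- table(early$division_rank_of_mother)
  out <- as.numeric(tab)
  if (normalize) out <- out / sum(out)
  stats::setNames(out, names(tab))
}
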