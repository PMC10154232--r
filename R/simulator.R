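## Stochastic branching-process simulator of NSC clones.
##
## Forward model: Bernoulli activation of the labelled R cell; a waiting
## time to the first division; binary divisions whose modes set daughter
## types; per-daughter two-wave death (early <= 7 d, late > 7 d after
## birth); return of the R cell to long-term (>30 d) quiescence with an
## age-dependent probability; and censoring by a finite observation
## horizon with daily (or continuous) imaging. Waiting times are
## log-normal, moment-matched to cohort means and standard deviations.

`%||%` <- function(a, b) if (is.null(a)) b else a

.lnorm_pars <- function(mean, sd) {
  stopifnot(mean > 0, sd >= 0)
  if (sd == 0) return(c(meanlog = log(mean), sdlog = 0))
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  c(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

.rlnorm_ms <- function(n, mean, sd) {
  p <- .lnorm_pars(mean, sd)
  if (p[["sdlog"]] == 0) return(rep(mean, n))
  stats::rlnorm(n, p[["meanlog"]], p[["sdlog"]])
}

.rlnorm_trunc <- function(n, mean, sd, lower = 0, upper = Inf) {
  p <- .lnorm_pars(mean, sd)
  if (p[["sdlog"]] == 0) return(rep(min(max(mean, lower), upper), n))
  lo <- stats::plnorm(lower, p[["meanlog"]], p[["sdlog"]])
  hi <- stats::plnorm(upper, p[["meanlog"]], p[["sdlog"]])
  if (hi <= lo) return(rep(lower, n))
  stats::qlnorm(stats::runif(n, lo, hi), p[["meanlog"]], p[["sdlog"]])
}

#' Mean of a truncated log-normal distribution
#'
#' Expected value of a log-normal variable, moment-matched to the given
#' mean and standard deviation, conditioned on lying in `(lower, upper]`.
#' Used as the analytic target when checking that pipeline-extracted
#' waiting times recover the generative distribution.
#'
#' @param mean,sd Mean and standard deviation of the untruncated
#'   distribution.
#' @param lower,upper Truncation bounds.
#' @return The truncated mean.
#' @export
truncated_lnorm_mean <- function(mean, sd, lower = 0, upper = Inf) {
  if (sd == 0) return(min(max(mean, lower), upper))
  p <- .lnorm_pars(mean, sd)
  mu <- p[["meanlog"]]
  s <- p[["sdlog"]]
  lo <- if (lower <= 0) -Inf else log(lower)
  up <- if (is.infinite(upper)) Inf else log(upper)
  num <- stats::pnorm((up - mu - s^2) / s) - stats::pnorm((lo - mu - s^2) / s)
  den <- stats::pnorm((up - mu) / s) - stats::pnorm((lo - mu) / s)
  exp(mu + s^2 / 2) * num / den
}

.r_modes_with_r <- c("R+R", "R+NR", "R+N")

#' Age-preset generative parameters
#'
#' Parameter set of the clone simulator for one age group. The young and
#' middle-aged presets transcribe published cohort statistics where
#' available: activation fractions 41.2% vs 22.6%; R division intervals
#' 10.48 +/- 13.43 vs 25.68 +/- 30.21 d; NR intervals 1.38 +/- 1.83 vs
#' 2.33 +/- 2.82 d; long-term quiescence 19.64% vs 42.55% of active
#' clones (resting thereafter in 5/11 vs 14/20); rounds of division before
#' rest (young always one; middle-aged 53.8/30.8/15.4% for 1/2/3); early
#' and late death rates 36.55%/20.48% vs 53.92%/17.48% of divisions; and
#' dormant-cell death 0/80 vs 1/161. Division-mode probabilities and the
#' time to first division are not printed as cohort statistics and carry
#' field-typical defaults (see the package vignette).
#'
#' @param preset `"young"` or `"middle_aged"`.
#' @param ... Named overrides of individual parameters.
#' @return An `age_params` list. Death rates are per division (the unit in
#'   which death percentages are reported); each non-R daughter dies with
#'   probability `rate / 2`.
#' @export
age_params <- function(preset = c("young", "middle_aged"), ...) {
  preset <- match.arg(preset)
  young <- preset == "young"
  p <- list(
    label = preset,
    activation_prob = if (young) 0.412 else 0.226,
    t_first_div = c(mean = 25, sd = 18),
    r_interval = if (young) c(mean = 10.48, sd = 13.43)
                 else c(mean = 25.68, sd = 30.21),
    nr_interval = if (young) c(mean = 1.38, sd = 1.83)
                  else c(mean = 2.33, sd = 2.82),
    quiescence_threshold = 30,
    lt_quiescence_prob = if (young) 0.1964 else 0.4255,
    resting_prob_given_lt = if (young) 5 / 11 else 14 / 20,
    rest_division_dist = if (young) 1 else c(0.538, 0.308, 0.154),
    rest_gap_excess = c(mean = 20, sd = 15),
    mode_probs = list(
      R = c("R+R" = 0, "R+NR" = 0.57, "R+N" = 0.03,
            "NR+NR" = 0.16, "NR+N" = 0.10, "N+N" = 0.14),
      NR = c("NR+NR" = 0.42, "NR+N" = 0.22, "N+N" = 0.36)
    ),
    nr_max_divisions = 5,
    early_death_rate = if (young) 0.3655 else 0.5392,
    late_death_rate = if (young) 0.2048 else 0.1748,
    early_threshold = 7,
    early_death_age = c(mean = 2.5, sd = 1.5),
    late_death_age_mean = 8,
    dormant_death_prob = if (young) 0 else 1 / 161,
    morpho = list(
      motion_threshold = 1,
      step_mean = if (young) 4.23 else 4.56,
      migration_duration = if (young) c(mean = 9.68, sd = 5.66)
                           else c(mean = 8.86, sd = 5.08),
      soma = list(base = 50, amp = 0.8, anchor = 120,
                  t_max = if (young) c(mean = 27.69, sd = 12.48)
                          else c(mean = 31.36, sd = 13.52),
                  session_sd = 0.05, noise_sd = 0),
      dendrite = list(l_max = if (young) 250 else 200,
                      tau = if (young) 10 else 14,
                      b_max = if (young) 8 else 6,
                      tau_b = if (young) 12 else 16)
    )
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown) > 0) {
    stop("unknown age_params field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  p[names(dots)] <- dots
  stopifnot(p$activation_prob >= 0, p$activation_prob <= 1,
            p$lt_quiescence_prob >= 0, p$lt_quiescence_prob <= 1,
            p$early_death_rate + p$late_death_rate <= 2,
            p$r_interval[["mean"]] > 0, p$nr_interval[["mean"]] > 0,
            abs(sum(p$mode_probs$R) - 1) < 1e-8,
            abs(sum(p$mode_probs$NR) - 1) < 1e-8)
  structure(p, class = "age_params")
}

## observed-timepoint map: smallest imaging day >= t (NA beyond the last
## session); imaging_interval = 0 means continuous observation
.make_obs_map <- function(start, horizon, imaging_interval) {
  if (imaging_interval > 0) {
    obs_end <- start + floor((horizon - start) / imaging_interval +
                               1e-9) * imaging_interval
    ot <- function(t) {
      if (t > obs_end + 1e-9) return(NA_real_)
      start + imaging_interval * max(0, ceiling((t - start) /
                                                  imaging_interval - 1e-9))
    }
  } else {
    obs_end <- horizon
    ot <- function(t) if (t > obs_end + 1e-9) NA_real_ else max(t, start)
  }
  list(ot = ot, obs_end = obs_end)
}

#' Simulate one clone
#'
#' Draws one clone forward from a labelled R cell under an [age_params()]
#' parameter set, then discretizes all event times to the imaging grid and
#' assembles the observed lineage tree. Uses the current RNG state; call
#' [set.seed()] or use [simulate_cohort()] for reproducibility.
#'
#' @param params An [age_params()] object.
#' @param horizon Last day of observation (days post induction).
#' @param start First imaging day (days post induction).
#' @param imaging_interval Days between imaging sessions; 0 records exact
#'   event times (continuous observation).
#' @param clone_id Identifier for the clone.
#' @param label Cohort label stored on the tree.
#' @return List with `tree` (a `lineage_tree`; `attr(tree,
#'   "imaging_interval")` records the grid) and `truth` (generator ground
#'   truth: activation, LT/resting draws, realized division gaps, division
#'   modes and assigned deaths).
#' @export
simulate_clone <- function(params, horizon = 115, start = 2,
                           imaging_interval = 1, clone_id = "clone",
                           label = params$label) {
  stopifnot(inherits(params, "age_params"))
  omap <- .make_obs_map(start, horizon, imaging_interval)
  ot <- omap$ot
  obs_end <- omap$obs_end
  gap_lower <- if (imaging_interval > 0) imaging_interval else 0

  ids <- character(0); type <- character(0); birth <- numeric(0)
  mother <- character(0); sister <- character(0); death <- numeric(0)
  divide <- numeric(0); gen_nr <- integer(0)
  new_cell <- function(ty, b, mo, g) {
    n <- length(ids) + 1L
    id <- as.character(n)
    ids[n] <<- id; type[n] <<- ty; birth[n] <<- b; mother[n] <<- mo
    sister[n] <<- NA_character_; death[n] <<- NA_real_
    divide[n] <<- NA_real_; gen_nr[n] <<- g
    id
  }
  q_early <- params$early_death_rate / 2
  q_late <- params$late_death_rate / 2
  deaths_truth <- list()
  assign_death <- function(id) {
    i <- match(id, ids)
    u <- stats::runif(1)
    max_age <- obs_end - birth[i]
    thr <- params$early_threshold
    if (u < q_early) {
      if (max_age <= 0) return(FALSE)
      age <- .rlnorm_trunc(1, params$early_death_age[["mean"]],
                           params$early_death_age[["sd"]],
                           upper = min(thr, max_age))
      death[i] <<- birth[i] + age
      deaths_truth[[length(deaths_truth) + 1]] <<-
        data.frame(cell = id, wave = "early", age = age)
      return(TRUE)
    }
    if (u < q_early + q_late) {
      if (max_age <= thr) return(FALSE)   # late death not observable
      excess <- stats::qexp(stats::runif(1) *
                              stats::pexp(max_age - thr,
                                          1 / params$late_death_age_mean),
                            1 / params$late_death_age_mean)
      death[i] <<- birth[i] + thr + excess
      deaths_truth[[length(deaths_truth) + 1]] <<-
        data.frame(cell = id, wave = "late", age = thr + excess)
      return(TRUE)
    }
    FALSE
  }

  root <- new_cell("R", start, NA_character_, 0L)
  active <- stats::runif(1) < params$activation_prob
  lt <- FALSE; resting <- FALSE; n_rest <- NA_integer_
  t1 <- NA_real_
  r_gaps <- numeric(0); rest_gap <- NA_real_; nr_gaps <- numeric(0)
  modes_truth <- list()
  nr_queue <- character(0)

  spawn <- function(mother_id, t_div, mode, mother_is_r, forced = FALSE) {
    dt <- strsplit(mode, "+", fixed = TRUE)[[1]]
    d <- vapply(dt, function(ty) {
      g <- if (ty == "NR") {
        if (mother_is_r) 1L else gen_nr[match(mother_id, ids)] + 1L
      } else 0L
      new_cell(ty, t_div, mother_id, g)
    }, character(1))
    sister[match(d[1], ids)] <<- d[2]
    sister[match(d[2], ids)] <<- d[1]
    modes_truth[[length(modes_truth) + 1]] <<-
      data.frame(mother = mother_id,
                 mother_type = if (mother_is_r) "R" else "NR",
                 label = paste0(if (mother_is_r) "R" else "NR", "->", mode),
                 time = t_div, forced = forced)
    for (j in seq_along(d)) {
      if (dt[j] != "R") {
        dead <- assign_death(d[j])
        if (dt[j] == "NR" && !dead) nr_queue <<- c(nr_queue, d[j])
      }
    }
    d[dt == "R"]
  }

  if (!active) {
    if (stats::runif(1) < params$dormant_death_prob) {
      death[1] <- stats::runif(1, start, obs_end)
    }
  } else {
    t1 <- .rlnorm_trunc(1, params$t_first_div[["mean"]],
                        params$t_first_div[["sd"]], upper = obs_end)
    lt <- stats::runif(1) < params$lt_quiescence_prob
    if (lt) {
      dist <- params$rest_division_dist
      n_rest <- sample.int(length(dist), 1, prob = dist)
      resting <- stats::runif(1) < params$resting_prob_given_lt
    }
    cur <- root
    t_div <- t1
    k <- 0L
    rest_done <- FALSE
    pending_gap <- NA_real_
    repeat {
      if (is.na(ot(t_div))) break        # division censored by the horizon
      if (!is.na(pending_gap)) {
        r_gaps <- c(r_gaps, pending_gap)
        pending_gap <- NA_real_
      }
      k <- k + 1L
      mp <- params$mode_probs$R
      if (lt && !rest_done && k <= n_rest) {
        mp <- mp[names(mp) %in% .r_modes_with_r]
        mp <- mp / sum(mp)
      }
      mode <- sample(names(mp), 1, prob = mp)
      divide[match(cur, ids)] <- t_div
      d_r <- spawn(cur, t_div, mode, mother_is_r = TRUE)
      if (length(d_r) == 0) break        # R lineage exhausted
      cur <- d_r[1]                      # continuation; a second R daughter
                                         # (R+R) stays quiescent
      if (lt && !rest_done && k == n_rest) {
        if (resting) break
        rest_gap <- params$quiescence_threshold +
          .rlnorm_ms(1, params$rest_gap_excess[["mean"]],
                     params$rest_gap_excess[["sd"]])
        rest_done <- TRUE
        t_div <- t_div + rest_gap
      } else {
        g <- .rlnorm_trunc(1, params$r_interval[["mean"]],
                           params$r_interval[["sd"]], lower = gap_lower,
                           upper = params$quiescence_threshold)
        pending_gap <- g
        t_div <- t_div + g
      }
    }
    ## NR cascade
    while (length(nr_queue) > 0) {
      id <- nr_queue[1]
      nr_queue <- nr_queue[-1]
      i <- match(id, ids)
      if (gen_nr[i] > params$nr_max_divisions) next
      g <- .rlnorm_trunc(1, params$nr_interval[["mean"]],
                         params$nr_interval[["sd"]], lower = gap_lower)
      t_div_nr <- birth[i] + g
      if (is.na(ot(t_div_nr))) next
      at_cap <- gen_nr[i] == params$nr_max_divisions
      mode <- if (at_cap) "N+N" else
        sample(names(params$mode_probs$NR), 1, prob = params$mode_probs$NR)
      divide[i] <- t_div_nr
      nr_gaps <- c(nr_gaps, g)
      spawn(id, t_div_nr, mode, mother_is_r = FALSE, forced = at_cap)
    }
  }

  ## discretize to the imaging grid and emit sparse coding rows
  rows <- list()
  step <- if (imaging_interval > 0) imaging_interval else 0
  for (i in seq_along(ids)) {
    b <- ot(birth[i])
    tps <- b
    if (!is.na(divide[i])) {
      dv <- ot(divide[i])
      if (step > 0 && dv - step > b + 1e-9) tps <- c(tps, dv - step)
    } else if (!is.na(death[i])) {
      de <- ot(death[i])
      if (de > b + 1e-9) tps <- c(tps, de)
    } else {
      if (obs_end > b + 1e-9) tps <- c(tps, obs_end)
    }
    dies_at <- if (is.na(death[i])) NA_real_ else ot(death[i])
    rows[[i]] <- data.frame(
      cell_id = ids[i], cell_type = type[i], cell_type_uncertain = FALSE,
      timepoint = tps, mother_id = mother[i], mother_uncertain = FALSE,
      sister_id = sister[i], sister_uncertain = FALSE,
      death_flag = !is.na(dies_at) & abs(tps - dies_at) < 1e-9,
      stringsAsFactors = FALSE)
  }
  obs <- do.call(rbind, rows)
  obs$clone_id <- clone_id
  class(obs) <- c("coding_table", "data.frame")
  tree <- assemble_lineage(obs, clone_id = clone_id,
                           observation_start = start,
                           observation_end = obs_end, label = label)
  attr(tree, "imaging_interval") <- imaging_interval
  truth <- list(
    clone_id = clone_id, active = active, lt = lt, resting = resting,
    n_rest_divisions = n_rest, t_first_division = t1,
    r_gaps = r_gaps, rest_gap = rest_gap, nr_gaps = nr_gaps,
    modes = if (length(modes_truth)) do.call(rbind, modes_truth) else NULL,
    deaths = if (length(deaths_truth)) do.call(rbind, deaths_truth) else NULL,
    n_non_r_daughters = sum(!is.na(mother) & type != "R")
  )
  list(tree = tree, truth = truth)
}

#' Simulate a cohort of clones
#'
#' @param n_clones Number of labelled R cells to follow.
#' @param params An [age_params()] object, or a preset name passed to
#'   [age_params()].
#' @param horizon,start,imaging_interval See [simulate_clone()].
#' @param seed Integer seed; identical configurations with the same seed
#'   yield identical cohorts.
#' @param label Cohort label; defaults to the preset label.
#' @return List with `cohort` (a `clone_cohort` containing every tracked
#'   clone, active and dormant), `truth` (per-clone generator ground
#'   truth) and `params`.
#' @export
simulate_cohort <- function(n_clones, params = "young", horizon = 115,
                            start = 2, imaging_interval = 1, seed = NULL,
                            label = NULL) {
  if (is.character(params)) params <- age_params(params)
  stopifnot(inherits(params, "age_params"), n_clones >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(label)) label <- params$label
  sims <- lapply(seq_len(n_clones), function(i) {
    simulate_clone(params, horizon = horizon, start = start,
                   imaging_interval = imaging_interval,
                   clone_id = sprintf("clone_%04d", i), label = label)
  })
  trees <- lapply(sims, `[[`, "tree")
  list(cohort = clone_cohort(trees, label = label),
       truth = lapply(sims, `[[`, "truth"),
       params = params)
}

#' Emit coding-table rows for simulated clones
#'
#' Expands a lineage tree (or every clone of a cohort) into the ROI coding
#' schema, one row per cell per imaged timepoint, so the full reading and
#' assembly pipeline can run on simulated data. Inverse of
#' [assemble_lineage()] up to the set of emitted timepoints.
#'
#' @param x A `lineage_tree` or `clone_cohort`.
#' @param path Optional CSV output path (written with
#'   [write_coding_table()]).
#' @param imaging_interval Grid spacing for emitted rows; defaults to the
#'   interval recorded on the tree, falling back to one row per recorded
#'   timepoint.
#' @return A `coding_table` (invisibly when `path` is given).
#' @export
emit_coding_table <- function(x, path = NULL, imaging_interval = NULL) {
  trees <- if (inherits(x, "clone_cohort")) x$clones else list(x)
  stopifnot(all(vapply(trees, inherits, logical(1), "lineage_tree")))
  tabs <- lapply(trees, function(tree) {
    iv <- imaging_interval %||% attr(tree, "imaging_interval") %||% 0
    cells <- tree$cells
    rows <- lapply(seq_len(nrow(cells)), function(i) {
      last <- if (!is.na(cells$death_time[i])) cells$death_time[i] else
        cells$last_seen[i]
      tps <- if (iv > 0) {
        seq(cells$birth_time[i], last, by = iv)
      } else {
        h <- tree$history
        sort(unique(h$timepoint[h$cell_id == cells$cell_id[i]]))
      }
      if (!last %in% tps) tps <- c(tps, last)
      h <- tree$history
      h <- h[h$cell_id == cells$cell_id[i], , drop = FALSE]
      h <- h[order(h$timepoint), , drop = FALSE]
      ty <- vapply(tps, function(t) {
        known <- h$type[h$timepoint <= t + 1e-9]
        if (length(known)) known[length(known)] else h$type[1]
      }, character(1))
      data.frame(
        cell_id = cells$cell_id[i], cell_type = ty,
        cell_type_uncertain = !cells$certain[i], timepoint = tps,
        mother_id = cells$mother_id[i], mother_uncertain = FALSE,
        sister_id = cells$sister_id[i], sister_uncertain = FALSE,
        death_flag = !is.na(cells$death_time[i]) &
          abs(tps - cells$death_time[i]) < 1e-9,
        clone_id = tree$clone_id,
        stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  class(out) <- c("coding_table", "data.frame")
  if (!is.null(path)) {
    write_coding_table(out, path)
    return(invisible(out))
  }
  out
}

#' Flag random cells as uncertain
#'
#' Marks each cell's type annotation uncertain with probability `rate`
#' (all rows of the cell), emulating ambiguous manual coding.
#'
#' @param table A `coding_table`.
#' @param rate Per-cell probability of an uncertain type call.
#' @param seed Optional seed.
#' @return The modified `coding_table`.
#' @export
inject_uncertainty <- function(table, rate, seed = NULL) {
  table <- as_coding_table(table)
  if (!is.null(seed)) set.seed(seed)
  key <- if (is.null(table$clone_id)) table$cell_id else
    paste(table$clone_id, table$cell_id)
  cells <- unique(key)
  flagged <- cells[stats::runif(length(cells)) < rate]
  table$cell_type_uncertain[key %in% flagged] <- TRUE
  table
}

#' Pipeline parameter recovery on a simulated cohort
#'
#' Re-estimates the generative parameters by running the full analysis
#' pipeline on the simulated trees and compares each estimate with its
#' generator value: the activation fraction, early and late death rates
#' (via the per-daughter estimator `2 * deaths / non-R daughters`, whose
#' expectation is the per-division death rate), the long-term quiescence
#' proportion, and the mean R (regular, i.e. below the quiescence
#' threshold) and NR division intervals against their truncated
#' log-normal means.
#'
#' @param sim Result of [simulate_cohort()].
#' @return Data frame with one row per quantity: `estimate`, `target`,
#'   `se` (standard error of the estimate) and `z = (estimate - target) /
#'   se`.
#' @export
recover_parameters <- function(sim) {
  cohort <- sim$cohort
  params <- sim$params
  act <- active_clones(cohort)
  n <- length(cohort$clones)
  iv <- attr(cohort$clones[[1]], "imaging_interval") %||% 0
  gap_lower <- if (iv > 0) iv else 0

  rows <- list()
  add <- function(quantity, estimate, target, se, n_used) {
    rows[[length(rows) + 1]] <<- data.frame(
      quantity = quantity, estimate = estimate, target = target, se = se,
      z = (estimate - target) / se, n = n_used, stringsAsFactors = FALSE)
  }

  p_act <- length(act) / n
  add("activation_fraction", p_act, params$activation_prob,
      sqrt(params$activation_prob * (1 - params$activation_prob) / n), n)

  ## ratio estimator over clones; clone totals are the sampling unit
  ## (death feeds back on how many daughters are born, so per-daughter
  ## outcomes cluster within clones), hence a cluster-robust se. The late
  ## wave conditions on daughters born at least `early_threshold` days
  ## before the end of observation: only for those can a late death fall
  ## inside the window, so the conditional count is censoring-free.
  thr_d <- params$early_threshold
  per_clone <- lapply(act, function(tr) {
    ev <- classify_deaths(tr, early_threshold = thr_d)
    is_d <- !is.na(tr$cells$mother_id) & tr$cells$first_type != "R"
    late_ok <- tr$cells$birth_time <= tr$observation_end - thr_d
    late_cells <- tr$cells$cell_id[is_d & late_ok]
    c(m = sum(is_d), m_late = length(late_cells),
      early = sum(ev$wave == "early"),
      late = sum(ev$wave == "late" & ev$cell_id %in% late_cells))
  })
  pc <- do.call(rbind, per_clone)
  for (wave in c("early", "late")) {
    rate <- if (wave == "early") params$early_death_rate else
      params$late_death_rate
    m_i <- pc[, if (wave == "early") "m" else "m_late"]
    d_i <- pc[, wave]
    q_hat <- sum(d_i) / sum(m_i)
    se <- 2 * sqrt(sum((d_i - q_hat * m_i)^2)) / sum(m_i)
    add(paste0(wave, "_death_rate"), 2 * q_hat, rate, se, sum(m_i))
  }

  lt <- vapply(act, function(tr) {
    classify_lt_self_renewal(
      tr, quiescence_threshold = params$quiescence_threshold)$lt_self_renewing
  }, logical(1))
  p_lt <- params$lt_quiescence_prob
  add("lt_quiescence_prob", mean(lt), p_lt,
      sqrt(p_lt * (1 - p_lt) / length(act)), length(act))

  ## Interval estimators condition on the interval starting early enough
  ## for any gap below the comparison bound to complete before the end of
  ## observation; this removes right-censoring bias at the horizon.
  obs_end <- max(vapply(act, `[[`, numeric(1), "observation_end"))
  thr <- params$quiescence_threshold
  r_iv <- cohort_division_intervals(cohort, "R")
  r_reg <- r_iv$interval[r_iv$interval <= thr &
                           (r_iv$time - r_iv$interval) <= obs_end - thr]
  add("mean_r_interval", mean(r_reg),
      truncated_lnorm_mean(params$r_interval[["mean"]],
                           params$r_interval[["sd"]], lower = gap_lower,
                           upper = thr),
      stats::sd(r_reg) / sqrt(length(r_reg)), length(r_reg))

  nr_bound <- 60
  nr_iv <- cohort_division_intervals(cohort, "NR")
  nr_reg <- nr_iv$interval[nr_iv$interval <= nr_bound &
                             (nr_iv$time - nr_iv$interval) <=
                               obs_end - nr_bound]
  add("mean_nr_interval", mean(nr_reg),
      truncated_lnorm_mean(params$nr_interval[["mean"]],
                           params$nr_interval[["sd"]], lower = gap_lower,
                           upper = nr_bound),
      stats::sd(nr_reg) / sqrt(length(nr_reg)), length(nr_reg))

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Truncate a tree's observation window
#'
#' Restricts a lineage tree to events observed up to `end`: cells born
#' later are dropped, divisions and deaths beyond `end` are censored and
#' last observations clipped.
#'
#' @param tree A `lineage_tree`.
#' @param end New observation end (days).
#' @return A `lineage_tree`.
#' @export
truncate_observation <- function(tree, end) {
  stopifnot(inherits(tree, "lineage_tree"), end >= tree$observation_start)
  h <- tree$history[tree$history$timepoint <= end + 1e-9, , drop = FALSE]
  keep <- tree$cells$cell_id[tree$cells$birth_time <= end + 1e-9]
  cells <- tree$cells[tree$cells$cell_id %in% keep, , drop = FALSE]
  obs <- do.call(rbind, lapply(cells$cell_id, function(id) {
    tps <- h$timepoint[h$cell_id == id]
    if (length(tps) == 0) tps <- cells[id, "birth_time"]
    data.frame(cell_id = id,
               cell_type = vapply(tps, function(t) {
                 hh <- tree$history
                 ty <- hh$type[hh$cell_id == id & hh$timepoint <= t + 1e-9]
                 ty[length(ty)]
               }, character(1)),
               cell_type_uncertain = !cells[id, "certain"],
               timepoint = tps,
               mother_id = cells[id, "mother_id"],
               mother_uncertain = FALSE,
               sister_id = cells[id, "sister_id"],
               sister_uncertain = FALSE,
               death_flag = !is.na(cells[id, "death_time"]) &
                 abs(tps - cells[id, "death_time"]) < 1e-9,
               stringsAsFactors = FALSE)
  }))
  ## a daughter pair straddling the cut would leave a single daughter;
  ## both daughters share birth_time, so pairs are kept or dropped whole
  out <- assemble_lineage(structure(obs,
                                    class = c("coding_table", "data.frame")),
                          clone_id = tree$clone_id,
                          observation_start = tree$observation_start,
                          observation_end = min(end, tree$observation_end),
                          label = tree$label)
  attr(out, "imaging_interval") <- attr(tree, "imaging_interval")
  out
}

#' Simulate newborn-neuron morphometry series
#'
#' Generates per-neuron migration trajectories (a persistent random walk
#' that halts after a log-normally distributed migration phase), soma-size
#' series with a shared anchor cell and multiplicative session scaling
#' (peaking at a planted day), and weekly dendrite traces growing along a
#' saturating-exponential length/branching curve (slower in the
#' middle-aged preset).
#'
#' @param params An [age_params()] object.
#' @param n_neurons Number of neurons.
#' @param duration Days of daily follow-up per neuron.
#' @param trace_days Ages (days) at which dendrite traces are taken.
#' @param seed Optional seed.
#' @return List with `trajectories` (list of [trajectory()]), `soma`
#'   (list of [soma_series()]), `dendrites` (list of [dendrite_trace()])
#'   and `truth` (per-neuron migration durations, step means, planted
#'   soma-peak days and the dendrite growth-curve function).
#' @export
simulate_morphometry <- function(params, n_neurons, duration = 45,
                                 trace_days = c(7, 14, 21, 28),
                                 seed = NULL) {
  stopifnot(inherits(params, "age_params"), n_neurons >= 1)
  if (!is.null(seed)) set.seed(seed)
  mo <- params$morpho
  trajectories <- vector("list", n_neurons)
  soma <- vector("list", n_neurons)
  dendrites <- list()
  mig_dur <- integer(n_neurons)
  t_peak <- numeric(n_neurons)
  l_curve <- function(t) mo$dendrite$l_max * (1 - exp(-t / mo$dendrite$tau))
  b_curve <- function(t) {
    1 + floor((mo$dendrite$b_max - 1) * (1 - exp(-t / mo$dendrite$tau_b)))
  }
  for (i in seq_len(n_neurons)) {
    id <- sprintf("neuron_%03d", i)
    days <- 0:duration
    ## migration: daily steps above the motion threshold while migrating,
    ## stationary afterwards
    dur <- max(1L, min(length(days) - 1L,
                       round(.rlnorm_ms(1, mo$migration_duration[["mean"]],
                                        mo$migration_duration[["sd"]]))))
    mig_dur[i] <- dur
    moving <- if (mo$step_mean > mo$motion_threshold) {
      mo$motion_threshold +
        stats::rexp(dur, 1 / (mo$step_mean - mo$motion_threshold))
    } else {
      rep(0, dur)                       # degenerate: the cell never moves
    }
    step_len <- c(moving, rep(0, length(days) - 1 - dur))
    theta <- stats::runif(length(step_len), 0, 2 * pi)
    xy <- apply(rbind(c(0, 0),
                      cbind(step_len * cos(theta), step_len * sin(theta))),
                2, cumsum)
    trajectories[[i]] <- trajectory(days, xy[, 1], xy[, 2], cell_id = id)
    ## soma: smooth rise to a planted peak, shared session scaling
    tm <- max(3, round(.rlnorm_ms(1, mo$soma$t_max[["mean"]],
                                  mo$soma$t_max[["sd"]])))
    t_peak[i] <- min(tm, duration)
    shape <- 1 + mo$soma$amp * (days / tm) * exp(1 - days / tm)
    session <- exp(stats::rnorm(length(days), 0, mo$soma$session_sd))
    noise <- if (mo$soma$noise_sd > 0)
      exp(stats::rnorm(length(days), 0, mo$soma$noise_sd)) else 1
    soma[[i]] <- soma_series(days, mo$soma$base * shape * session * noise,
                             mo$soma$anchor * session, cell_id = id)
    ## dendrites: one trace per requested age
    for (d in trace_days) {
      if (d > duration) next
      n_tips <- b_curve(d)
      parent <- NA_integer_
      leaves <- 1L
      n_seg <- 1L
      while (leaves < n_tips) {
        leaf_idx <- setdiff(seq_len(n_seg), parent[!is.na(parent)])
        at <- if (length(leaf_idx) == 1) leaf_idx else sample(leaf_idx, 1)
        parent <- c(parent, at, at)
        n_seg <- n_seg + 2L
        leaves <- leaves + 1L
      }
      w <- stats::runif(n_seg, 0.5, 1.5)
      lens <- w / sum(w) * l_curve(d)
      dendrites[[length(dendrites) + 1]] <-
        dendrite_trace(lens, parent, cell_id = id, timepoint = d)
    }
  }
  list(trajectories = trajectories, soma = soma, dendrites = dendrites,
       truth = list(migration_duration = mig_dur, step_mean = mo$step_mean,
                    soma_peak_day = t_peak, dendrite_length_curve = l_curve,
                    dendrite_branch_curve = b_curve))
}

#' Write a dendrite trace as an SWC file
#'
#' Each segment becomes one SWC node placed at its parent's position plus
#' a random direction scaled to the segment length, so segment lengths
#' survive an SWC round trip through [read_swc()].
#'
#' @param trace A [dendrite_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(trace, path) {
  stopifnot(inherits(trace, "dendrite_trace"))
  n <- length(trace$length)
  pos <- matrix(0, nrow = n + 1, ncol = 3)  # row 1 = soma
  lines <- "1 1 0 0 0 1 -1"
  for (i in seq_len(n)) {
    par_node <- if (is.na(trace$parent[i])) 1L else trace$parent[i] + 1L
    v <- stats::rnorm(3)
    v <- v / sqrt(sum(v^2)) * trace$length[i]
    pos[i + 1, ] <- pos[par_node, ] + v
    lines <- c(lines, paste(i + 1, 3, pos[i + 1, 1], pos[i + 1, 2],
                            pos[i + 1, 3], 0.5, par_node))
  }
  writeLines(c("# generated by clonedyn", lines), path)
  invisible(path)
}
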