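## Newborn-neuron morphometrics: migration, soma growth, dendrite
## maturation. Positions are micrometres in the imaging plane (2-D
## projection-based tracking); a z column is used when present.

#' Construct a migration trajectory
#'
#' @param timepoint Strictly increasing observation days.
#' @param x,y,z Positions in micrometres (`z` optional).
#' @param cell_id Optional identifier.
#' @return A `trajectory` data frame.
#' @export
trajectory <- function(timepoint, x, y, z = NULL, cell_id = "neuron") {
  stopifnot(is.numeric(timepoint), is.numeric(x), is.numeric(y),
            length(x) == length(timepoint), length(y) == length(timepoint))
  if (is.unsorted(timepoint, strictly = TRUE)) {
    stop("trajectory timepoints must be strictly increasing", call. = FALSE)
  }
  out <- data.frame(cell_id = cell_id, timepoint = timepoint, x = x, y = y,
                    stringsAsFactors = FALSE)
  if (!is.null(z)) out$z <- z
  class(out) <- c("trajectory", "data.frame")
  out
}

.step_lengths <- function(traj) {
  cols <- intersect(c("x", "y", "z"), names(traj))
  pos <- as.matrix(traj[, cols, drop = FALSE])
  if (nrow(pos) < 2) return(numeric(0))
  sqrt(rowSums((pos[-1, , drop = FALSE] - pos[-nrow(pos), , drop = FALSE])^2))
}

#' Migration metrics of a newborn neuron
#'
#' The accumulative distance is the sum of step lengths between
#' consecutive recorded positions; the direct displacement is the distance
#' from the first to the last position. Migration is considered over after
#' the last step exceeding `motion_threshold`; the mean speed is the
#' accumulative distance divided by the migration duration.
#'
#' @param traj A [trajectory()] with at least two samples.
#' @param motion_threshold Minimum step length (micrometres) counting as
#'   movement.
#' @return List with `accumulative_distance` (um), `direct_displacement`
#'   (um), `migration_duration` (days) and `mean_speed` (um/day; 0 when
#'   the cell never moved).
#' @export
migration_metrics <- function(traj, motion_threshold = 1) {
  stopifnot(inherits(traj, "trajectory"))
  if (nrow(traj) < 2) {
    stop("at least two samples are required for migration metrics",
         call. = FALSE)
  }
  steps <- .step_lengths(traj)
  cols <- intersect(c("x", "y", "z"), names(traj))
  pos <- as.matrix(traj[, cols, drop = FALSE])
  disp <- sqrt(sum((pos[nrow(pos), ] - pos[1, ])^2))
  moving <- which(steps > motion_threshold)
  duration <- if (length(moving) == 0) 0 else
    traj$timepoint[moving[length(moving)] + 1] - traj$timepoint[1]
  list(accumulative_distance = sum(steps),
       direct_displacement = disp,
       migration_duration = duration,
       mean_speed = if (duration > 0) sum(steps) / duration else 0)
}

#' Construct a soma-size series
#'
#' Each sample pairs the newborn cell's soma area with the area of a
#' stable anchor granule cell measured in the same field at the same
#' session, used to normalise out acquisition variability.
#'
#' @param timepoint Strictly increasing observation days (first sample at
#'   birth).
#' @param area,anchor_area Soma areas in square micrometres (positive).
#' @param cell_id Optional identifier.
#' @return A `soma_series` data frame.
#' @export
soma_series <- function(timepoint, area, anchor_area, cell_id = "neuron") {
  stopifnot(length(area) == length(timepoint),
            length(anchor_area) == length(timepoint))
  if (is.unsorted(timepoint, strictly = TRUE)) {
    stop("soma series timepoints must be strictly increasing", call. = FALSE)
  }
  if (any(area <= 0) || any(anchor_area <= 0)) {
    stop("soma and anchor areas must be positive", call. = FALSE)
  }
  structure(data.frame(cell_id = cell_id, timepoint = timepoint,
                       area = area, anchor_area = anchor_area,
                       stringsAsFactors = FALSE),
            class = c("soma_series", "data.frame"))
}

#' Time to maximum soma size
#'
#' Days from birth (the first sample) to the sample at which the —
#' optionally anchor-normalised — soma area is largest; ties resolve to
#' the earliest timepoint.
#'
#' @param series A [soma_series()] with at least three samples.
#' @param normalize Divide by the anchor area before locating the maximum
#'   (default).
#' @return Time in days.
#' @export
time_to_max_soma <- function(series, normalize = TRUE) {
  stopifnot(inherits(series, "soma_series"))
  if (nrow(series) < 3) {
    stop("at least three samples are required to locate the soma-size peak",
         call. = FALSE)
  }
  val <- if (normalize) series$area / series$anchor_area else series$area
  series$timepoint[which.max(val)] - series$timepoint[1]
}

#' Construct a dendrite trace
#'
#' A dendritic arbour as a tree of unbranched segments rooted at the soma.
#' The segment with no parent is the primary dendrite (the segment leaving
#' the soma); exactly one such segment is required.
#'
#' @param length Segment lengths in micrometres (positive).
#' @param parent Integer index of each segment's parent segment (`NA` or 0
#'   for the primary segment).
#' @param cell_id Optional identifier.
#' @param timepoint Days since birth of the trace (optional, used by
#'   [growth_curve()]).
#' @return A `dendrite_trace` object.
#' @export
dendrite_trace <- function(length, parent, cell_id = "neuron",
                           timepoint = NA_real_) {
  stopifnot(is.numeric(length), base::length(parent) == base::length(length))
  parent <- as.integer(ifelse(is.na(parent) | parent == 0, NA, parent))
  n <- base::length(length)
  if (any(length <= 0)) stop("segment lengths must be positive",
                             call. = FALSE)
  if (sum(is.na(parent)) != 1) {
    stop("exactly one primary segment (parent = NA) is required",
         call. = FALSE)
  }
  if (any(stats::na.omit(parent) < 1 | stats::na.omit(parent) > n)) {
    stop("parent indices out of range", call. = FALSE)
  }
  ## cycle check by walking each segment to the root
  for (i in seq_len(n)) {
    seen <- integer(0)
    j <- i
    while (!is.na(j)) {
      if (j %in% seen) {
        stop("segment graph contains a cycle at segment ", i, call. = FALSE)
      }
      seen <- c(seen, j)
      j <- parent[j]
    }
  }
  structure(list(cell_id = cell_id, timepoint = timepoint,
                 length = as.numeric(length), parent = parent,
                 primary = which(is.na(parent))),
            class = "dendrite_trace")
}

#' Dendrite morphometrics
#'
#' @param trace A [dendrite_trace()] (or a path to an SWC file).
#' @return List with `total_length` (sum of all segments, um),
#'   `primary_length` (the soma-leaving segment, um), `longest_branch`
#'   (maximal soma-to-tip path length, um) and `n_branches` (number of
#'   terminal tips; an unbranched neurite counts 1).
#' @export
dendrite_metrics <- function(trace) {
  if (is.character(trace)) trace <- read_swc(trace)
  stopifnot(inherits(trace, "dendrite_trace"))
  n <- length(trace$length)
  children <- lapply(seq_len(n), function(i) which(!is.na(trace$parent) &
                                                     trace$parent == i))
  depth <- function(i) {
    kids <- children[[i]]
    trace$length[i] + if (length(kids) == 0) 0 else
      max(vapply(kids, depth, numeric(1)))
  }
  leaves <- which(vapply(children, length, integer(1)) == 0)
  list(total_length = sum(trace$length),
       primary_length = trace$length[trace$primary],
       longest_branch = depth(trace$primary),
       n_branches = length(leaves))
}

#' Read an SWC neuron skeleton
#'
#' Reads the standard whitespace-separated SWC format (`id type x y z
#' radius parent`, `parent = -1` at the root) and collapses chains of
#' nodes into unbranched segments between the soma, branch points and
#' tips.
#'
#' @param path Path to an SWC file (lines starting with `#` are comments).
#' @param cell_id,timepoint Passed to [dendrite_trace()].
#' @return A `dendrite_trace`.
#' @export
read_swc <- function(path, cell_id = NULL, timepoint = NA_real_) {
  if (is.null(cell_id)) cell_id <- sub("\\.swc$", "", basename(path))
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("id", "type", "x", "y", "z",
                                         "radius", "parent"))
  if (nrow(tab) < 2) stop("SWC file has no dendrite nodes", call. = FALSE)
  root <- tab$id[tab$parent == -1]
  if (length(root) != 1) {
    stop("SWC file must contain exactly one root node", call. = FALSE)
  }
  idx <- match(tab$parent, tab$id)
  if (any(is.na(idx) & tab$parent != -1)) {
    stop("SWC parent ids refer to missing nodes", call. = FALSE)
  }
  pos <- as.matrix(tab[, c("x", "y", "z")])
  edge_len <- rep(NA_real_, nrow(tab))
  has_parent <- tab$parent != -1
  edge_len[has_parent] <- sqrt(rowSums(
    (pos[has_parent, , drop = FALSE] - pos[idx[has_parent], , drop = FALSE])^2))
  n_children <- tabulate(idx[has_parent], nbins = nrow(tab))

  ## collapse node chains into segments; a segment ends at a branch point
  ## (>1 child) or a tip
  root_row <- which(tab$parent == -1)
  seg_len <- numeric(0)
  seg_par <- integer(0)
  walk <- function(start_row, parent_seg) {
    row <- start_row
    acc <- edge_len[row]
    while (n_children[row] == 1) {
      row <- which(has_parent & idx == row)
      acc <- acc + edge_len[row]
    }
    seg_len <<- c(seg_len, acc)
    seg_par <<- c(seg_par, parent_seg)
    this_seg <- length(seg_len)
    for (child_row in which(has_parent & idx == row)) {
      walk(child_row, this_seg)
    }
  }
  first_rows <- which(has_parent & idx == root_row)
  if (length(first_rows) != 1) {
    stop("SWC root must issue exactly one primary neurite", call. = FALSE)
  }
  walk(first_rows, NA_integer_)
  dendrite_trace(seg_len, seg_par, cell_id = cell_id, timepoint = timepoint)
}

#' Dendrite growth curve over the first weeks after birth
#'
#' For each neuron and each requested day, picks the trace closest in age
#' (within `tolerance` days) and tabulates its dendrite metrics; days
#' without a trace yield missing values.
#'
#' @param traces List of [dendrite_trace()] objects with their `timepoint`
#'   set to days since the neuron's birth.
#' @param days Days after birth at which to sample the curve.
#' @param tolerance Maximum age difference (days) between a requested day
#'   and the trace used for it.
#' @return Data frame with `cell_id`, `day`, `trace_age`, `total_length`,
#'   `primary_length`, `longest_branch` and `n_branches`.
#' @export
growth_curve <- function(traces, days = c(7, 14, 21, 28), tolerance = 3) {
  stopifnot(is.list(traces), length(traces) > 0)
  ids <- vapply(traces, `[[`, character(1), "cell_id")
  ages <- vapply(traces, `[[`, numeric(1), "timepoint")
  if (anyNA(ages)) {
    stop("every trace needs a timepoint (days since birth)", call. = FALSE)
  }
  rows <- list()
  for (id in unique(ids)) {
    sel <- which(ids == id)
    for (d in days) {
      gap <- abs(ages[sel] - d)
      best <- sel[which.min(gap)]
      if (min(gap) <= tolerance) {
        m <- dendrite_metrics(traces[[best]])
        rows[[length(rows) + 1]] <- data.frame(
          cell_id = id, day = d, trace_age = ages[best],
          total_length = m$total_length, primary_length = m$primary_length,
          longest_branch = m$longest_branch, n_branches = m$n_branches,
          stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1]] <- data.frame(
          cell_id = id, day = d, trace_age = NA_real_,
          total_length = NA_real_, primary_length = NA_real_,
          longest_branch = NA_real_, n_branches = NA_integer_,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Cohort summary of a growth curve
#'
#' @param curve Output of [growth_curve()].
#' @param metric Column to summarise.
#' @return Data frame with per-day `n`, `mean` and `sd` over neurons with
#'   a measurement.
#' @export
growth_curve_summary <- function(curve, metric = "total_length") {
  stopifnot(metric %in% names(curve))
  out <- lapply(split(curve, curve$day), function(g) {
    v <- g[[metric]][!is.na(g[[metric]])]
    data.frame(day = g$day[1], n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else NA_real_)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
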