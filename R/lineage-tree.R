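## Lineage tree assembly and validation.
##
## A lineage_tree is a rooted binary-division clone: the root is the
## labelled R cell, every division replaces the mother cell by exactly two
## daughter cells with fresh ids, and each cell carries its observed type
## history, certainty and death status.

.type_rank <- c(R = 1L, NR = 2L, N = 3L)

#' Assemble a lineage tree from coding-table rows
#'
#' Aggregates one coded clone (one row per cell per timepoint) into a
#' validated lineage tree. The mother/daughter links must describe a binary
#' tree: every cell has 0 or 2 daughters, daughters share their first
#' observed timepoint (the mother's division time), and recorded sister
#' links must be mutually consistent. Cell types may only progress
#' R -> NR -> N along a cell's own history and across divisions.
#'
#' @param obs A `coding_table` (see [read_coding_table()]) holding a single
#'   clone, or a table with a `clone_id` column from which one clone is
#'   selected via `clone_id`.
#' @param clone_id Clone identifier; required when `obs` spans several
#'   clones, otherwise defaults to the table's clone id or `"clone"`.
#' @param observation_start,observation_end Observation window in days post
#'   induction; default to the first and last recorded timepoint.
#' @param label Optional cohort label (e.g. `"young"`).
#' @return A `lineage_tree` object: a list with elements `clone_id`,
#'   `cells` (one row per cell: `cell_id`, `birth_time`, `last_seen`,
#'   `death_time`, `final_type`, `first_type`, `mother_id`, `sister_id`,
#'   `certain`, `division_time`, `generation`), `history` (long table of
#'   `(cell_id, timepoint, type)`), `root_id`, `observation_start`,
#'   `observation_end`, `active` and `label`.
#' @examples
#' obs <- data.frame(
#'   CellID = c("a", "a", "b", "c"), CellType = c("R", "R", "R", "NR"),
#'   UncertaintyCellType = FALSE, Timepoint = c(2, 5, 5, 5),
#'   MotherID = c(NA, NA, "a", "a"), UncertaintyMotherCell = FALSE,
#'   SisterID = c(NA, NA, "c", "b"), UncertaintySisterCell = FALSE,
#'   CellDeath = FALSE)
#' tree <- assemble_lineage(as_coding_table(obs))
#' tree$active
#' @export
assemble_lineage <- function(obs, clone_id = NULL, observation_start = NULL,
                             observation_end = NULL, label = NULL) {
  obs <- as_coding_table(obs)
  if (!is.null(obs$clone_id)) {
    ids <- unique(obs$clone_id)
    if (is.null(clone_id)) {
      if (length(ids) > 1) {
        stop("table holds ", length(ids),
             " clones; supply `clone_id` (or use assemble_cohort())",
             call. = FALSE)
      }
      clone_id <- ids
    }
    obs <- obs[obs$clone_id == clone_id, , drop = FALSE]
    if (nrow(obs) == 0) stop("no rows for clone ", clone_id, call. = FALSE)
  }
  if (is.null(clone_id)) clone_id <- "clone"
  obs <- obs[order(obs$timepoint, obs$cell_id), , drop = FALSE]

  ids <- unique(obs$cell_id)
  per <- split(seq_len(nrow(obs)), factor(obs$cell_id, levels = ids))
  first_of <- function(x) x[!is.na(x)][1]
  cells <- do.call(rbind, lapply(ids, function(id) {
    rows <- obs[per[[id]], , drop = FALSE]
    ## type must be monotone along the cell's own history
    rk <- .type_rank[rows$cell_type]
    if (is.unsorted(rk)) {
      stop("cell ", id, ": cell type regresses over time (",
           paste(rows$cell_type, collapse = " -> "), ")", call. = FALSE)
    }
    death <- if (any(rows$death_flag))
      rows$timepoint[rows$death_flag][1] else NA_real_
    if (!is.na(death) && any(rows$timepoint > death)) {
      stop("cell ", id, " observed after its recorded death", call. = FALSE)
    }
    data.frame(
      cell_id = id,
      birth_time = rows$timepoint[1],
      last_seen = rows$timepoint[nrow(rows)],
      death_time = death,
      first_type = rows$cell_type[1],
      final_type = rows$cell_type[nrow(rows)],
      mother_id = first_of(rows$mother_id),
      sister_id = first_of(rows$sister_id),
      certain = !any(rows$cell_type_uncertain | rows$mother_uncertain |
                       rows$sister_uncertain),
      stringsAsFactors = FALSE
    )
  }))
  rownames(cells) <- cells$cell_id

  roots <- cells$cell_id[is.na(cells$mother_id)]
  if (length(roots) == 0) {
    stop("no root cell: every cell has a mother", call. = FALSE)
  }
  if (length(roots) > 1) {
    stop("ambiguous root: cells ", paste(roots, collapse = ", "),
         " all lack a mother", call. = FALSE)
  }
  root_id <- roots
  if (cells[root_id, "first_type"] != "R") {
    stop("root cell ", root_id, " is of type ",
         cells[root_id, "first_type"],
         "; clones must start from an R cell", call. = FALSE)
  }
  missing_mother <- setdiff(stats::na.omit(cells$mother_id), cells$cell_id)
  if (length(missing_mother) > 0) {
    stop("mother cell(s) not present in table: ",
         paste(missing_mother, collapse = ", "), call. = FALSE)
  }

  ## daughters: binary divisions only, synchronous birth, sister symmetry
  kids <- split(cells$cell_id, cells$mother_id)
  cells$division_time <- NA_real_
  for (m in names(kids)) {
    d <- kids[[m]]
    if (length(d) != 2) {
      stop("cell ", m, " has ", length(d),
           " daughter(s); divisions must produce exactly 2", call. = FALSE)
    }
    bt <- cells[d, "birth_time"]
    if (bt[1] != bt[2]) {
      stop("daughters of cell ", m,
           " first appear at different timepoints (", bt[1], " vs ", bt[2],
           ")", call. = FALSE)
    }
    sis <- cells[d, "sister_id"]
    ok <- (is.na(sis[1]) || sis[1] == d[2]) && (is.na(sis[2]) || sis[2] == d[1])
    if (!ok) {
      stop("sister links of daughters of cell ", m,
           " are not mutually consistent", call. = FALSE)
    }
    if (bt[1] < cells[m, "last_seen"]) {
      stop("cell ", m, " observed after its division at day ", bt[1],
           call. = FALSE)
    }
    if (!is.na(cells[m, "death_time"])) {
      stop("cell ", m, " both divides and dies", call. = FALSE)
    }
    if (cells[m, "final_type"] == "N") {
      stop("neuron ", m, " cannot divide", call. = FALSE)
    }
    bad <- .type_rank[cells[d, "first_type"]] < .type_rank[cells[m, "final_type"]]
    if (any(bad)) {
      stop("daughter of ", cells[m, "final_type"], " cell ", m,
           " has earlier type ", cells[d, "first_type"][bad][1], call. = FALSE)
    }
    cells[m, "division_time"] <- bt[1]
  }

  ## generation = number of divisions separating a cell from the root
  cells$generation <- NA_integer_
  cells[root_id, "generation"] <- 0L
  pending <- root_id
  while (length(pending) > 0) {
    m <- pending[1]
    pending <- pending[-1]
    d <- kids[[m]]
    if (!is.null(d)) {
      cells[d, "generation"] <- cells[m, "generation"] + 1L
      pending <- c(pending, d)
    }
  }
  if (anyNA(cells$generation)) {
    stop("unreachable cell(s): ",
         paste(cells$cell_id[is.na(cells$generation)], collapse = ", "),
         call. = FALSE)
  }

  if (is.null(observation_start)) observation_start <- min(obs$timepoint)
  if (is.null(observation_end)) observation_end <- max(obs$timepoint)
  if (observation_end < observation_start) {
    stop("observation_end precedes observation_start", call. = FALSE)
  }
  if (min(obs$timepoint) < observation_start ||
      max(obs$timepoint) > observation_end) {
    stop("recorded timepoints fall outside the observation window",
         call. = FALSE)
  }

  structure(
    list(clone_id = clone_id,
         cells = cells,
         history = data.frame(cell_id = obs$cell_id,
                              timepoint = obs$timepoint,
                              type = obs$cell_type,
                              stringsAsFactors = FALSE),
         root_id = root_id,
         observation_start = observation_start,
         observation_end = observation_end,
         active = !is.na(cells[root_id, "division_time"]),
         label = label),
    class = "lineage_tree"
  )
}

#' Assemble a cohort of clones from a multi-clone coding table
#'
#' @param obs A `coding_table` with a `clone_id` column, a path to such a
#'   CSV file, or a list of per-clone tables/paths.
#' @param label Cohort label attached to every clone.
#' @param n_dormant Number of tracked never-dividing R cells in the cohort.
#'   Defaults to the number of assembled quiescent (single-cell, undivided)
#'   clones; supply explicitly when dormant cells were tallied separately
#'   from the coding tables.
#' @param ... Passed to [read_coding_table()] for path inputs.
#' @return A `clone_cohort`; see [clone_cohort()].
#' @export
assemble_cohort <- function(obs, label = NULL, n_dormant = NULL, ...) {
  tables <- if (is.list(obs) && !is.data.frame(obs)) obs else list(obs)
  clones <- list()
  for (tab in tables) {
    if (is.character(tab)) tab <- read_coding_table(tab, ...)
    tab <- as_coding_table(tab)
    ids <- if (is.null(tab$clone_id)) "clone" else unique(tab$clone_id)
    for (id in ids) {
      sub <- if (is.null(tab$clone_id)) tab else
        tab[tab$clone_id == id, , drop = FALSE]
      clones[[length(clones) + 1]] <-
        assemble_lineage(sub, clone_id = id, label = label)
    }
  }
  clone_cohort(clones, label = label, n_dormant = n_dormant)
}

#' Construct a cohort of lineage trees
#'
#' @param clones List of `lineage_tree` objects (active and/or dormant).
#' @param label Cohort label, e.g. `"young"` or `"middle_aged"`.
#' @param n_dormant Total number of tracked never-dividing R cells,
#'   including any dormant single-cell trees present in `clones`. Defaults
#'   to the number of inactive trees in `clones`.
#' @return A `clone_cohort` object.
#' @export
clone_cohort <- function(clones, label = NULL, n_dormant = NULL) {
  stopifnot(is.list(clones),
            all(vapply(clones, inherits, logical(1), "lineage_tree")))
  inactive <- sum(!vapply(clones, `[[`, logical(1), "active"))
  if (is.null(n_dormant)) {
    n_dormant <- inactive
  } else if (n_dormant < inactive) {
    stop("n_dormant (", n_dormant, ") is smaller than the number of ",
         "dormant trees in `clones` (", inactive, ")", call. = FALSE)
  }
  names(clones) <- vapply(clones, `[[`, character(1), "clone_id")
  structure(list(label = label, clones = clones,
                 n_dormant = as.integer(n_dormant)),
            class = "clone_cohort")
}

#' Active clones of a cohort
#' @param cohort A `clone_cohort`.
#' @return List of active `lineage_tree` objects.
#' @export
active_clones <- function(cohort) {
  stopifnot(inherits(cohort, "clone_cohort"))
  Filter(function(tr) tr$active, cohort$clones)
}

#' Restrict a tree to fully certain cells
#'
#' Returns a view of the tree in which only cells whose type, mother and
#' sister annotations were all coded unambiguously contribute to metrics.
#' Uncertain cells remain present (links are not rewired) but carry
#' `included = FALSE`; all metric functions in the package respect this
#' flag.
#'
#' @param tree A `lineage_tree`.
#' @return The tree with an `included` column on `cells`.
#' @export
filter_certain <- function(tree) {
  stopifnot(inherits(tree, "lineage_tree"))
  tree$cells$included <- tree$cells$certain
  tree
}

## cells contributing to metrics: certainty-filtered unless the tree
## carries an explicit `included` column
.metric_cells <- function(tree, certain_only = TRUE) {
  cells <- tree$cells
  keep <- if (!is.null(cells$included)) cells$included
          else if (certain_only) cells$certain
          else rep(TRUE, nrow(cells))
  cells[keep, , drop = FALSE]
}

.daughters_of <- function(tree, id) {
  tree$cells$cell_id[!is.na(tree$cells$mother_id) &
                       tree$cells$mother_id == id]
}

#' Cohort activation summary
#'
#' Fraction of tracked labelled R cells whose clone divided at least once
#' during observation.
#'
#' @param x A `clone_cohort`, or the number of active clones.
#' @param n_dormant Number of dormant (never-dividing) R cells when `x` is
#'   a count.
#' @return List with `n_active`, `n_dormant` and `fraction_active`
#'   (in `[0, 1]`).
#' @examples
#' activation_summary(56, 80)$fraction_active  # 0.412
#' @export
activation_summary <- function(x, n_dormant = NULL) {
  if (inherits(x, "clone_cohort")) {
    n_active <- length(active_clones(x))
    n_dormant <- x$n_dormant
  } else {
    stopifnot(is.numeric(x), length(x) == 1, !is.null(n_dormant))
    n_active <- as.integer(x)
    n_dormant <- as.integer(n_dormant)
  }
  total <- n_active + n_dormant
  if (total == 0) {
    stop("empty cohort: activation fraction is undefined", call. = FALSE)
  }
  list(n_active = n_active, n_dormant = n_dormant,
       fraction_active = n_active / total)
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat("<lineage_tree> clone", x$clone_id,
      if (!is.null(x$label)) paste0("[", x$label, "]"), "\n")
  cat("  cells:", nrow(x$cells),
      "| active:", x$active,
      "| window:", x$observation_start, "-", x$observation_end, "days\n")
  comp <- table(factor(x$cells$final_type, levels = .cell_types))
  cat("  final types:", paste(names(comp), comp, sep = "=", collapse = " "),
      "\n")
  invisible(x)
}

#' @export
print.clone_cohort <- function(x, ...) {
  n_act <- length(active_clones(x))
  cat("<clone_cohort>", if (!is.null(x$label)) x$label, "\n")
  cat("  clones:", length(x$clones), "| active:", n_act,
      "| dormant R cells:", x$n_dormant, "\n")
  invisible(x)
}

#' Serialize a lineage tree to JSON
#'
#' @param tree A `lineage_tree`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
tree_to_json <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "lineage_tree"))
  payload <- list(
    clone_id = tree$clone_id,
    label = tree$label,
    observation_start = tree$observation_start,
    observation_end = tree$observation_end,
    active = tree$active,
    root = tree$root_id,
    cells = tree$cells[, c("cell_id", "birth_time", "last_seen",
                           "death_time", "first_type", "final_type",
                           "mother_id", "certain", "division_time",
                           "generation")],
    history = tree$history
  )
  js <- jsonlite::toJSON(payload, dataframe = "rows", auto_unbox = TRUE,
                         na = "null", pretty = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Export a lineage tree as annotated Newick
#'
#' Branch lengths are cell lifetimes in days (division, death or last
#' observation minus birth); node labels combine the cell type and id.
#'
#' @param tree A `lineage_tree`.
#' @return A Newick string terminated by `";"`.
#' @export
tree_to_newick <- function(tree) {
  stopifnot(inherits(tree, "lineage_tree"))
  cells <- tree$cells
  lab <- function(id) {
    paste0(gsub("[,:;()\\s]", "_", cells[id, "final_type"]), "_",
           gsub("[,:;() \t]", "_", id))
  }
  rec <- function(id) {
    end <- if (!is.na(cells[id, "division_time"])) cells[id, "division_time"]
           else if (!is.na(cells[id, "death_time"])) cells[id, "death_time"]
           else cells[id, "last_seen"]
    len <- end - cells[id, "birth_time"]
    d <- .daughters_of(tree, id)
    if (length(d) == 0) {
      paste0(lab(id), ":", format(len, trim = TRUE))
    } else {
      paste0("(", rec(d[1]), ",", rec(d[2]), ")", lab(id), ":",
             format(len, trim = TRUE))
    }
  }
  paste0(rec(tree$root_id), ";")
}
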