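# In-code fixtures used across the suite.

# One coding row with schema defaults.
row <- function(id, type, tp, mother = NA, sister = NA, death = FALSE,
                type_unc = FALSE, mother_unc = FALSE, sister_unc = FALSE) {
  data.frame(CellID = id, CellType = type, UncertaintyCellType = type_unc,
             Timepoint = tp, MotherID = mother,
             UncertaintyMotherCell = mother_unc, SisterID = sister,
             UncertaintySisterCell = sister_unc, CellDeath = death,
             stringsAsFactors = FALSE)
}

obs_table <- function(...) as_coding_table(do.call(rbind, list(...)))

# Quiescent single R cell observed over [2, end].
quiescent_tree <- function(end = 60) {
  assemble_lineage(obs_table(row("r", "R", 2), row("r", "R", end)))
}

# R divides at day `t1` into (R, NR); the NR divides at `t2` into (N, N);
# optionally one N dies at day `death_day`.
two_division_tree <- function(t1 = 5, t2 = 9, death_day = NA, end = 60) {
  rows <- list(
    row("r", "R", 2),
    row("r2", "R", t1, mother = "r", sister = "nr"),
    row("r2", "R", end),
    row("nr", "NR", t1, mother = "r", sister = "r2"),
    row("n1", "N", t2, mother = "nr", sister = "n2"),
    row("n1", "N", end),
    row("n2", "N", t2, mother = "nr", sister = "n1"))
  if (is.na(death_day)) {
    rows <- c(rows, list(row("n2", "N", end)))
  } else {
    rows <- c(rows, list(row("n2", "N", death_day, death = TRUE)))
  }
  assemble_lineage(do.call(obs_table, rows))
}

# An R cell dividing repeatedly along its continuation chain at the given
# days; non-R daughters are terminal neurons.
r_chain_tree <- function(div_days, end = 115) {
  rows <- list(row("r1", "R", 2))
  prev <- "r1"
  for (i in seq_along(div_days)) {
    t <- div_days[i]
    rn <- paste0("r", i + 1)
    nn <- paste0("n", i)
    rows <- c(rows, list(
      row(rn, "R", t, mother = prev, sister = nn),
      row(nn, "N", t, mother = prev, sister = rn),
      row(nn, "N", end)))
    prev <- rn
  }
  rows <- c(rows, list(row(prev, "R", end)))
  assemble_lineage(do.call(obs_table, rows), observation_end = end)
}

# Independent brute-force oracle: maximum number of divisions (optionally
# by mother type) along any root-to-leaf path, via explicit path
# enumeration over the cells table.
oracle_max_successive <- function(tree, type = "any") {
  cells <- tree$cells
  kids <- function(id) cells$cell_id[!is.na(cells$mother_id) &
                                       cells$mother_id == id]
  paths <- list()
  grow <- function(path) {
    k <- kids(path[length(path)])
    if (length(k) == 0) {
      paths[[length(paths) + 1]] <<- path
    } else {
      for (d in k) grow(c(path, d))
    }
  }
  grow(tree$root_id)
  max(vapply(paths, function(p) {
    divs <- p[!is.na(cells[p, "division_time"])]
    divs <- divs[cells[divs, "certain"]]
    if (type != "any") divs <- divs[cells[divs, "final_type"] == type]
    length(divs)
  }, numeric(1)))
}

# Small simulated clones for property tests.
sim_trees <- function(n, preset = "young", seed = 1, ...) {
  sim <- simulate_cohort(n, preset, seed = seed, ...)
  sim$cohort$clones
}
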