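test_that("death events classify into waves with an inclusive boundary", {
  mk <- function(death_day) {
    assemble_lineage(obs_table(
      row("r", "R", 2),
      row("a", "R", 5, mother = "r", sister = "b"), row("a", "R", 60),
      row("b", "NR", 5, mother = "r", sister = "a"),
      row("b", "NR", death_day, death = TRUE)))
  }
  ev <- classify_deaths(mk(6))          # one day after birth
  expect_equal(ev$age_at_death, 1)
  expect_equal(ev$wave, "early")
  expect_equal(ev$division_rank_of_mother, 1L)
  expect_equal(classify_deaths(mk(19))$wave, "late")   # 14 d after birth
  expect_equal(classify_deaths(mk(12))$wave, "early")  # exactly 7 d
  expect_equal(classify_deaths(mk(12), early_threshold = 5)$wave, "late")
})

test_that("wave fractions reproduce the printed event-count percentages", {
  f <- death_wave_fractions(c(rep(1, 256), rep(14, 200)))
  expect_equal(round(f$early_pct, 2), 56.14)
  f2 <- death_wave_fractions(c(rep(3, 264), rep(20, 96)))
  expect_equal(round(f2$early_pct, 2), 73.33)
  expect_equal(death_wave_fractions(numeric(0))$n_early, 0L)
})

test_that("death rates are deaths per division, in percent", {
  expect_equal(death_rates(two_division_tree())$total_rate, 0)
  early <- death_rates(two_division_tree(death_day = 12))  # dies at age 3
  expect_equal(early$total_rate, 50)  # 1 death / 2 divisions
  expect_equal(early$early_rate, 50)
  expect_equal(early$late_rate, 0)
  late <- death_rates(two_division_tree(death_day = 25))   # dies at age 16
  expect_equal(late$early_rate, 0)
  expect_equal(late$late_rate, 50)
  expect_error(death_rates(quiescent_tree()), "undefined")
})

test_that("early + late deaths partition the total at any threshold", {
  trees <- sim_trees(40, "middle_aged", seed = 19)
  for (tree in trees) {
    ev <- classify_deaths(tree)
    for (thr in c(3, 7, 12)) {
      f <- death_wave_fractions(ev, early_threshold = thr)
      expect_equal(f$n_early + f$n_late, nrow(ev))
    }
    # raising the threshold never decreases the early count
    counts <- vapply(c(2, 5, 7, 10, 20),
                     function(thr) death_wave_fractions(ev, thr)$n_early,
                     numeric(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("death rates are invariant to id relabeling and time shifts", {
  tree <- NULL
  for (tr in sim_trees(30, "middle_aged", seed = 57)) {
    if (tr$active && nrow(classify_deaths(tr)) > 0) { tree <- tr; break }
  }
  expect_false(is.null(tree))
  tab <- emit_coding_table(tree)
  shifted <- tab
  shifted$timepoint <- shifted$timepoint + 10
  shifted$cell_id <- paste0("x", shifted$cell_id)
  shifted$mother_id <- ifelse(is.na(shifted$mother_id), NA,
                              paste0("x", shifted$mother_id))
  shifted$sister_id <- ifelse(is.na(shifted$sister_id), NA,
                              paste0("x", shifted$sister_id))
  tree2 <- assemble_lineage(as_coding_table(shifted))
  expect_equal(death_rates(tree2), death_rates(tree))
})

test_that("long-term self-renewal requires a >30 d quiescent span", {
  # one division at day 10, quiescent to day 70: LT and resting
  lab <- classify_lt_self_renewal(r_chain_tree(10, end = 70))
  expect_true(lab$lt_self_renewing)
  expect_true(lab$resting_R)
  expect_equal(lab$n_R_divisions_before_rest, 1L)
  expect_equal(lab$persisting_time, 60)

  # two divisions then 40 d of quiescence: resting after two rounds
  lab2 <- classify_lt_self_renewal(r_chain_tree(c(10, 25), end = 65))
  expect_true(lab2$resting_R)
  expect_equal(lab2$n_R_divisions_before_rest, 2L)

  # observed only 25 d beyond the division: not LT
  lab3 <- classify_lt_self_renewal(r_chain_tree(10, end = 35))
  expect_false(lab3$lt_self_renewing)

  # a long mid-chain gap with a later division: LT but not resting
  lab4 <- classify_lt_self_renewal(r_chain_tree(c(10, 45), end = 60))
  expect_true(lab4$lt_self_renewing)
  expect_false(lab4$resting_R)
  expect_true(is.na(lab4$persisting_time))
})

test_that("resting implies long-term self-renewal across cohorts", {
  for (tree in sim_trees(60, "middle_aged", seed = 71)) {
    if (!tree$active) next
    lab <- classify_lt_self_renewal(tree)
    if (lab$resting_R) expect_true(lab$lt_self_renewing)
  }
})

test_that("persisting time runs from the last division to last observation", {
  expect_equal(persisting_time(r_chain_tree(10, end = 70)), 60)
  expect_error(persisting_time(r_chain_tree(c(10, 45), end = 60)),
               "not a resting-R clone")
  # persisting time exceeds every R division interval for resting clones
  for (tree in sim_trees(80, "middle_aged", seed = 83)) {
    if (!tree$active) next
    lab <- classify_lt_self_renewal(tree)
    if (!lab$resting_R) next
    iv <- division_intervals(tree, "R")
    if (nrow(iv) > 0) expect_gt(lab$persisting_time, max(iv$interval))
  }
})

test_that("division modes follow the classic taxonomy", {
  expect_equal(division_mode("R", c("R", "NR")),
               list(label = "R->R+NR", class = "asymmetric"))
  expect_equal(division_mode("NR", c("N", "N"))$class,
               "symmetric differentiating")
  expect_equal(division_mode("R", c("R", "R"))$class,
               "symmetric self-renewing")
  expect_error(division_mode("NR", c("R", "NR")), "violates")
  tab <- division_mode_table()
  expect_equal(nrow(tab), 9)
  expect_setequal(unique(tab$class),
                  c("symmetric self-renewing", "asymmetric",
                    "symmetric differentiating"))
})

test_that("cohort mode tallies match the generator frequencies", {
  sim <- simulate_cohort(400, "young", seed = 29)
  modes <- do.call(rbind, lapply(active_clones(sim$cohort), division_modes))
  truth_modes <- do.call(rbind, lapply(sim$truth, `[[`, "modes"))
  # pipeline labels agree with the generator's event log
  expect_equal(sort(table(modes$label)), sort(table(truth_modes$label)))
  # freely drawn NR modes are i.i.d.: tallies within multinomial error
  # (depth-cap divisions are forced to N+N and excluded)
  nr <- truth_modes[truth_modes$mother_type == "NR" & !truth_modes$forced, ]
  p <- age_params("young")$mode_probs$NR
  for (lab in names(p)) {
    obs <- mean(nr$label == paste0("NR->", lab))
    se <- sqrt(p[[lab]] * (1 - p[[lab]]) / nrow(nr))
    expect_lt(abs(obs - p[[lab]]), 4 * se)
  }
})

test_that("uncertain participants are excluded from mode tallies", {
  tab <- emit_coding_table(two_division_tree())
  tab$cell_type_uncertain[tab$cell_id == "n1"] <- TRUE
  tree <- assemble_lineage(tab)
  m <- division_modes(tree)
  expect_equal(m$label, "R->R+NR")  # the NR->N+N division is excluded
})

test_that("subtree death asymmetry compares the two first-division subtrees", {
  # 6 terminal cells; subtree under a: 3 dead of 3; under b: 1 dead of 3
  rows <- list(
    row("r", "R", 2),
    row("a", "NR", 5, mother = "r", sister = "b"),
    row("b", "NR", 5, mother = "r", sister = "a"),
    row("a1", "N", 8, mother = "a", sister = "a2"),
    row("a1", "N", 10, death = TRUE),
    row("a2", "NR", 8, mother = "a", sister = "a1"),
    row("a3", "N", 11, mother = "a2", sister = "a4"),
    row("a3", "N", 13, death = TRUE),
    row("a4", "N", 11, mother = "a2", sister = "a3"),
    row("a4", "N", 14, death = TRUE),
    row("b1", "N", 9, mother = "b", sister = "b2"),
    row("b1", "N", 12, death = TRUE),
    row("b2", "NR", 9, mother = "b", sister = "b1"),
    row("b3", "N", 12, mother = "b2", sister = "b4"),
    row("b3", "N", 60),
    row("b4", "N", 12, mother = "b2", sister = "b3"),
    row("b4", "N", 60))
  tree <- assemble_lineage(do.call(obs_table, rows))
  a <- subtree_death_asymmetry(tree)
  expect_equal(a$freq_subtree1, 100)
  expect_equal(round(a$freq_subtree2, 1), 33.3)
  expect_equal(round(a$abs_difference, 1), 66.7)
  expect_equal(unname(a$n_terminal), c(3, 3))

  # symmetric deaths: zero difference
  sym <- assemble_lineage(obs_table(
    row("r", "R", 2),
    row("a", "NR", 5, mother = "r", sister = "b"),
    row("a1", "N", 8, mother = "a", sister = "a2"),
    row("a1", "N", 9, death = TRUE),
    row("a2", "N", 8, mother = "a", sister = "a1"), row("a2", "N", 60),
    row("b", "NR", 5, mother = "r", sister = "a"),
    row("b1", "N", 8, mother = "b", sister = "b2"),
    row("b1", "N", 9, death = TRUE),
    row("b2", "N", 8, mother = "b", sister = "b1"), row("b2", "N", 60)))
  expect_equal(subtree_death_asymmetry(sym)$abs_difference, 0)

  # too few terminal cells: ineligible signal
  expect_error(subtree_death_asymmetry(two_division_tree()),
               class = "clonedyn_ineligible_clone")
})

test_that("early deaths tabulate by the mother's division rank", {
  tree <- two_division_tree(death_day = 11)  # N dies 2 d after birth, rank 2
  h <- early_death_by_rank(list(tree))
  expect_equal(names(h), "2")
  expect_equal(unname(h), 1)
  expect_equal(length(early_death_by_rank(list(quiescent_tree()))), 0)
  hn <- early_death_by_rank(list(tree), normalize = TRUE)
  expect_equal(sum(hn), 1)
  # pooled over a simulated cohort the histogram matches the event log
  sim <- simulate_cohort(150, "young", seed = 37)
  h2 <- early_death_by_rank(sim$cohort)
  ev <- do.call(rbind, lapply(sim$cohort$clones, classify_deaths))
  expect_equal(sum(h2), sum(ev$wave == "early"))
})
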