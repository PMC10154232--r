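test_that("final size and composition count survivors by type", {
  expect_equal(final_cell_number(quiescent_tree()), 1)
  expect_equal(final_composition(quiescent_tree()),
               c(R = 1L, NR = 0L, N = 0L))

  # R->(R,NR); NR->(N,N); one N dies: survivors r2, n1
  tree <- two_division_tree(death_day = 12)
  expect_equal(final_cell_number(tree), 2)
  expect_equal(final_composition(tree), c(R = 1L, NR = 0L, N = 1L))

  # without the death, three survivors
  tree2 <- two_division_tree()
  expect_equal(final_cell_number(tree2), 3)
  expect_equal(sum(final_composition(tree2)), final_cell_number(tree2))
})

test_that("division counts split by mother type and sum to the total", {
  expect_equal(count_divisions(quiescent_tree()),
               list(total = 0L, R = 0L, NR = 0L))
  d <- count_divisions(two_division_tree())
  expect_equal(d$total, 2L)
  expect_equal(d$R, 1L)
  expect_equal(d$NR, 1L)
})

test_that("composition sums equal final sizes on simulated cohorts", {
  for (tree in sim_trees(30, "middle_aged", seed = 9)) {
    expect_equal(sum(final_composition(tree)), final_cell_number(tree))
    d <- count_divisions(tree)
    expect_equal(d$total, d$R + d$NR)
  }
})

test_that("successive-division depth matches exhaustive path enumeration", {
  expect_equal(max_successive_divisions(quiescent_tree()), 0L)
  # chain of three successive divisions
  ch <- r_chain_tree(c(5, 15, 22))
  expect_equal(max_successive_divisions(ch, "R"), 3L)
  expect_equal(max_successive_divisions(ch, "NR"), 0L)
  for (tree in sim_trees(40, "young", seed = 23)) {
    for (ty in c("any", "R", "NR")) {
      expect_equal(max_successive_divisions(tree, ty),
                   oracle_max_successive(tree, ty))
    }
  }
})

test_that("activity duration spans first R to last division", {
  tree <- r_chain_tree(c(5, 20))
  expect_equal(activity_duration(tree), 15)
  # a single division has zero activity duration
  single <- r_chain_tree(5)
  expect_equal(activity_duration(single), 0)
  expect_error(activity_duration(quiescent_tree()),
               class = "clonedyn_not_active")
})

test_that("R self-renewal follows the continuing R daughter", {
  # R divides day 10, R daughter observed to day 40
  tree <- r_chain_tree(10, end = 40)
  expect_equal(r_self_renewal_duration(tree), 30)

  # the R lineage vanishes at the first division (no R daughter)
  tab <- obs_table(row("r", "R", 2),
                   row("a", "NR", 10, mother = "r", sister = "b"),
                   row("a", "NR", 30),
                   row("b", "NR", 10, mother = "r", sister = "a"),
                   row("b", "NR", 30))
  expect_equal(r_self_renewal_duration(assemble_lineage(tab)), 0)
})

test_that("division intervals report rank and gap per the Div. convention", {
  # R divides at days 5, 15, 22 -> intervals (1,10), (2,7)
  iv <- division_intervals(r_chain_tree(c(5, 15, 22)), "R")
  expect_equal(iv$rank, c(1L, 2L))
  expect_equal(iv$interval, c(10, 7))
  # a single division yields no interval
  expect_equal(nrow(division_intervals(r_chain_tree(5), "R")), 0)
  # NR intervals include the birth-to-division gap at rank 1
  tree <- two_division_tree(t1 = 5, t2 = 9)
  nv <- division_intervals(tree, "NR")
  expect_equal(nv$rank, 1L)
  expect_equal(nv$interval, 4)
  # the rank labelling can be shifted
  expect_equal(division_intervals(r_chain_tree(c(5, 15, 22)), "R",
                                  rank_offset = 1L)$rank, c(2L, 3L))
})

test_that("interval counts equal divisions minus excluded first divisions", {
  for (tree in sim_trees(30, "young", seed = 77)) {
    d <- count_divisions(tree)
    iv_r <- division_intervals(tree, "R")
    # every R division except chain-starting ones (roots of R lineages)
    div <- divisions(tree)
    n_first_r <- sum(div$mother_type == "R" & is.na(div$interval))
    expect_equal(nrow(iv_r), d$R - n_first_r)
    iv_nr <- division_intervals(tree, "NR")
    expect_equal(nrow(iv_nr), d$NR)
  }
})

test_that("time to first division measures from induction", {
  tree <- r_chain_tree(12)
  expect_equal(time_to_first_division(tree), 12)
  # two cells at the first imaging session are assigned one day
  tab <- obs_table(row("r", "R", 2),
                   row("a", "R", 2, mother = "r", sister = "b"),
                   row("a", "R", 30),
                   row("b", "NR", 2, mother = "r", sister = "a"),
                   row("b", "NR", 30))
  expect_equal(time_to_first_division(assemble_lineage(tab)), 1)
  expect_error(time_to_first_division(quiescent_tree()),
               class = "clonedyn_not_active")
})

test_that("durations never exceed the observation window", {
  for (tree in sim_trees(40, "middle_aged", seed = 13)) {
    if (!tree$active) next
    win <- tree$observation_end - tree$observation_start
    expect_lte(activity_duration(tree), win)
    expect_lte(r_self_renewal_duration(tree), win)
  }
})

test_that("truncating observation never increases size- or duration-derived metrics", {
  for (tree in sim_trees(25, "young", seed = 31)) {
    if (!tree$active) next
    short <- truncate_observation(tree, 50)
    expect_lte(count_divisions(short)$total, count_divisions(tree)$total)
    if (short$active) {
      expect_lte(activity_duration(short), activity_duration(tree))
      expect_lte(r_self_renewal_duration(short),
                 r_self_renewal_duration(tree))
    }
  }
})

test_that("clone_metrics collects one consistent row per clone", {
  m <- clone_metrics(two_division_tree(death_day = 12))
  expect_equal(nrow(m), 1)
  expect_equal(m$final_cell_number, 2)
  expect_equal(m$n_divisions_total, 2)
  expect_equal(m$total_death_rate, 50)  # 1 death / 2 divisions
  co <- simulate_cohort(20, "young", seed = 3)$cohort
  cm <- cohort_metrics(co)
  expect_equal(nrow(cm), length(active_clones(co)))
})
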