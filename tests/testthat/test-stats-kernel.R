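test_that("welch_t reproduces the published NSC-count statistics", {
  # R-cell counts, young vs middle-aged (n = 3 mice each)
  r <- welch_t(group_summary(5435, 707, 3), group_summary(980, 265, 3))
  expect_equal(round(r$t, 2), 10.22)
  expect_equal(round(r$df, 3), 2.551)
  # DCX+ newborn-neuron counts
  d <- welch_t(group_summary(7685, 1189, 3), group_summary(163, 55, 3))
  expect_equal(round(d$t, 2), 10.95)
  expect_equal(round(d$df, 3), 2.009)
})

test_that("welch_t is antisymmetric and degenerate inputs are handled", {
  a <- group_summary(10, 2, 5)
  b <- group_summary(12, 3, 7)
  r1 <- welch_t(a, b)
  r2 <- welch_t(b, a)
  expect_equal(r1$t, -r2$t)
  expect_equal(r1$df, r2$df)
  expect_equal(r1$p_two_sided, r2$p_two_sided)
  same <- welch_t(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p_two_sided, 1)
  expect_error(welch_t(group_summary(5, 0, 3), group_summary(5, 0, 3)),
               "degenerate")
})

test_that("welch_t from summaries equals t.test on matching raw data", {
  set.seed(91)
  for (i in 1:10) {
    x <- rnorm(sample(4:12, 1), mean = runif(1, -2, 2), sd = runif(1, .5, 3))
    y <- rnorm(sample(4:12, 1), mean = runif(1, -2, 2), sd = runif(1, .5, 3))
    mine <- welch_t(x, y)
    ref <- stats::t.test(x, y)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(mine$p_two_sided, ref$p.value, tolerance = 1e-10)
  }
})

test_that("mann_whitney_u statistics match hand values and identities", {
  expect_equal(mann_whitney_u(c(1, 2, 3), c(10, 11, 12))$U, 0)
  ident <- mann_whitney_u(1:4, 1:4)
  expect_equal(ident$U, 8)  # n1 n2 / 2 under full symmetry
  set.seed(92)
  for (i in 1:25) {
    x <- sample(1:10, sample(2:8, 1), replace = TRUE)
    y <- sample(1:10, sample(2:8, 1), replace = TRUE)
    r <- mann_whitney_u(x, y)
    expect_equal(r$U1 + r$U2, length(x) * length(y))
    # all-pairs brute force for U1
    wins <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    expect_equal(r$U1, wins)
  }
})

test_that("exact Mann-Whitney p agrees with wilcox.test when tie-free", {
  set.seed(93)
  for (i in 1:15) {
    x <- rnorm(sample(3:7, 1))
    y <- rnorm(sample(3:7, 1))
    mine <- mann_whitney_u(x, y, method = "exact")
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(mine$p_two_sided, ref$p.value, tolerance = 1e-10)
  }
  # normal approximation path tracks wilcox.test's corrected z
  x <- rnorm(30); y <- rnorm(35, 0.5)
  mine <- mann_whitney_u(x, y, method = "normal")
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(mine$p_two_sided, ref$p.value, tolerance = 1e-8)
  expect_error(mann_whitney_u(numeric(0), 1:3), "nonempty")
})

test_that("fisher_exact_2x2 reproduces the activation-table p value", {
  r <- fisher_exact_2x2(matrix(c(56, 47, 80, 161), nrow = 2))
  expect_equal(round(r$p_two_sided, 4), 3e-04)
  expect_equal(fisher_exact_2x2(matrix(5, 2, 2))$p_two_sided, 1)
})

test_that("fisher p agrees with full hypergeometric enumeration", {
  # independent oracle: direct binomial-coefficient enumeration over all
  # tables with the observed margins
  oracle <- function(tab) {
    r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
    amin <- max(0, r1 + c1 - n); amax <- min(r1, c1)
    prob <- function(a) {
      choose(c1, a) * choose(n - c1, r1 - a) / choose(n, r1)
    }
    ps <- vapply(amin:amax, prob, numeric(1))
    sum(ps[ps <= prob(tab[1, 1]) * (1 + 1e-07)])
  }
  set.seed(94)
  for (i in 1:40) {
    tab <- matrix(sample(0:15, 4, replace = TRUE), 2, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    mine <- fisher_exact_2x2(tab)
    expect_equal(mine$p_two_sided, oracle(tab), tolerance = 1e-10)
    expect_equal(mine$p_two_sided, stats::fisher.test(tab)$p.value,
                 tolerance = 1e-8)
    # invariances of the two-sided p
    expect_equal(fisher_exact_2x2(t(tab))$p_two_sided, mine$p_two_sided,
                 tolerance = 1e-10)
    expect_equal(fisher_exact_2x2(tab[2:1, 2:1])$p_two_sided,
                 mine$p_two_sided, tolerance = 1e-10)
  }
  expect_error(fisher_exact_2x2(matrix(c(0, 0, 1, 2), 2, 2)), "margins")
})

test_that("the doubling convention equals twice the smaller exact tail", {
  set.seed(95)
  for (i in 1:20) {
    tab <- matrix(sample(1:12, 4, replace = TRUE), 2, 2)
    pd <- fisher_exact_2x2(tab, method = "doubling")$p_two_sided
    r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
    pr <- function(a) choose(c1, a) * choose(n - c1, r1 - a) / choose(n, r1)
    supp <- max(0, r1 + c1 - n):min(r1, c1)
    lower <- sum(vapply(supp[supp <= tab[1, 1]], pr, numeric(1)))
    upper <- sum(vapply(supp[supp >= tab[1, 1]], pr, numeric(1)))
    expect_equal(pd, min(1, 2 * min(lower, upper)), tolerance = 1e-10)
  }
})

test_that("ks_two_sample matches ks.test and its boundary cases", {
  x <- c(1, 2, 3, 4)
  expect_equal(ks_two_sample(x, x)$D, 0)
  expect_equal(ks_two_sample(1:5, 11:15)$D, 1)
  set.seed(96)
  for (i in 1:15) {
    a <- rnorm(sample(10:40, 1))
    b <- rnorm(sample(10:40, 1), mean = runif(1, 0, 1))
    mine <- ks_two_sample(a, b)
    ref <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
    expect_equal(mine$D, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-7)
  }
  expect_error(ks_two_sample(numeric(0), 1:3), "nonempty")
})

test_that("all four tests hold their size under the null", {
  set.seed(2026)
  reps <- 1000
  hits <- matrix(FALSE, reps, 4,
                 dimnames = list(NULL, c("welch", "mw", "ks", "fisher")))
  for (i in seq_len(reps)) {
    hits[i, "welch"] <- welch_t(rnorm(30), rnorm(30))$p_two_sided < 0.05
    hits[i, "mw"] <- mann_whitney_u(rnorm(25), rnorm(25))$p_two_sided < 0.05
    hits[i, "ks"] <- ks_two_sample(rnorm(200), rnorm(200))$p < 0.05
    a <- rbinom(1, 500, 0.3)
    b <- rbinom(1, 500, 0.3)
    hits[i, "fisher"] <- fisher_exact_2x2(
      matrix(c(a, b, 500 - a, 500 - b), 2, 2))$p_two_sided < 0.05
  }
  rates <- colMeans(hits)
  expect_true(all(rates >= 0.03 & rates <= 0.07),
              info = paste(names(rates), round(rates, 3), collapse = " "))
})
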