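## The statistical procedures used for cohort comparisons, in the exact
## conventions needed to reproduce published legend values: Welch's t
## computable from per-group summary statistics, Mann-Whitney U reported
## as min(U1, U2), Fisher's exact two-sided p by the probability-mass rule
## (with the doubling rule as an alternative), and the two-sample
## Kolmogorov-Smirnov D with its asymptotic p.

#' Per-group summary statistics
#'
#' @param mean Group mean.
#' @param sd Per-group standard deviation (not the standard error).
#' @param n Group size (>= 2).
#' @return A `group_summary` object.
#' @export
group_summary <- function(mean, sd, n) {
  stopifnot(is.numeric(mean), is.numeric(sd), sd >= 0, n >= 2)
  structure(list(mean = mean, sd = sd, n = as.integer(n)),
            class = "group_summary")
}

.as_summary <- function(x) {
  if (inherits(x, "group_summary")) return(x)
  stopifnot(is.numeric(x), length(x) >= 2)
  group_summary(mean(x), stats::sd(x), length(x))
}

#' Welch's unpaired two-sample t test
#'
#' Computes t, the Welch–Satterthwaite degrees of freedom and the
#' two-sided p value from per-group summary statistics (mean, per-group
#' standard deviation, n) or from raw samples, so published group
#' summaries can be re-tested without raw data.
#'
#' @param x,y [group_summary()] objects or raw numeric vectors.
#' @return List with `t`, `df` and `p_two_sided`.
#' @examples
#' welch_t(group_summary(5435, 707, 3), group_summary(980, 265, 3))
#' @export
welch_t <- function(x, y) {
  g1 <- .as_summary(x)
  g2 <- .as_summary(y)
  v1 <- g1$sd^2 / g1$n
  v2 <- g2$sd^2 / g2$n
  se2 <- v1 + v2
  if (se2 == 0) {
    if (g1$mean == g2$mean) {
      stop("degenerate comparison: zero variance and equal means",
           call. = FALSE)
    }
    return(list(t = sign(g1$mean - g2$mean) * Inf, df = NA_real_,
                p_two_sided = 0))
  }
  t_stat <- (g1$mean - g2$mean) / sqrt(se2)
  df <- se2^2 / (v1^2 / (g1$n - 1) + v2^2 / (g2$n - 1))
  list(t = t_stat, df = df,
       p_two_sided = 2 * stats::pt(-abs(t_stat), df))
}

## U1 (x wins over y) with midrank ties, by the rank-sum identity
.u_stat <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Mann-Whitney U test
#'
#' Reports `U = min(U1, U2)` with midrank handling of ties. The p value is
#' exact (full enumeration of group assignments, valid under ties) for
#' small samples and a tie-corrected normal approximation with continuity
#' correction otherwise.
#'
#' @param x,y Nonempty numeric samples.
#' @param method `"auto"` (exact when both groups have at most
#'   `exact_limit` observations), `"exact"` or `"normal"`.
#' @param exact_limit Largest per-group size for the automatic exact path.
#' @param correct Apply the continuity correction in the normal
#'   approximation.
#' @return List with `U`, `U1`, `U2` and `p_two_sided`.
#' @export
mann_whitney_u <- function(x, y, method = c("auto", "exact", "normal"),
                           exact_limit = 8, correct = TRUE) {
  method <- match.arg(method)
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  n1 <- length(x)
  n2 <- length(y)
  u1 <- .u_stat(x, y)
  u2 <- n1 * n2 - u1
  u <- min(u1, u2)
  if (method == "auto") {
    method <- if (max(n1, n2) <= exact_limit) "exact" else "normal"
  }
  if (method == "exact") {
    pooled <- c(x, y)
    combos <- utils::combn(n1 + n2, n1)
    u_null <- apply(combos, 2, function(sel) {
      .u_stat(pooled[sel], pooled[-sel])
    })
    lo <- min(u1, u2)
    hi <- max(u1, u2)
    p <- (sum(u_null <= lo) + sum(u_null >= hi)) / ncol(combos)
  } else {
    n <- n1 + n2
    ties <- table(c(x, y))
    sigma2 <- n1 * n2 / 12 * (n + 1 - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 == 0) {
      p <- 1
    } else {
      z <- u1 - n1 * n2 / 2
      if (correct) z <- z - sign(z) * 0.5
      p <- 2 * stats::pnorm(-abs(z) / sqrt(sigma2))
    }
  }
  list(U = u, U1 = u1, U2 = u2, p_two_sided = min(1, p))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p value from the hypergeometric distribution with fixed
#' margins. The default (`"minlike"`) convention sums the probabilities of
#' all tables no more probable than the observed one; the `"doubling"`
#' convention doubles the smaller tail.
#'
#' @param table 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @param method `"minlike"` or `"doubling"`.
#' @return List with `p_two_sided` and `odds_ratio` (the sample odds
#'   ratio `ad/bc`).
#' @examples
#' fisher_exact_2x2(matrix(c(56, 47, 80, 161), nrow = 2))
#' @export
fisher_exact_2x2 <- function(table, method = c("minlike", "doubling")) {
  method <- match.arg(method)
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0),
            all(table == round(table)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("all margins of the 2x2 table must be positive", call. = FALSE)
  }
  a <- table[1, 1]
  m <- sum(table[, 1])          # first-column margin
  n <- sum(table[, 2])
  k <- sum(table[1, ])          # first-row margin
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- if (method == "minlike") {
    sum(probs[probs <= p_obs * (1 + 1e-07)])
  } else {
    lower <- sum(probs[support <= a])
    upper <- sum(probs[support >= a])
    min(1, 2 * min(lower, upper))
  }
  or <- (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])
  list(p_two_sided = min(1, p), odds_ratio = or)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum distance between the two empirical distribution
#' functions; the p value uses the asymptotic Kolmogorov distribution at
#' the effective sample size `n1 n2 / (n1 + n2)`.
#'
#' @param x,y Nonempty numeric samples.
#' @return List with `D` and `p` (asymptotic, two-sided).
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  n1 <- length(x)
  n2 <- length(y)
  pts <- sort(unique(c(x, y)))
  ecdf1 <- vapply(pts, function(t) sum(x <= t) / n1, numeric(1))
  ecdf2 <- vapply(pts, function(t) sum(y <= t) / n2, numeric(1))
  d <- max(abs(ecdf1 - ecdf2))
  lambda <- sqrt(n1 * n2 / (n1 + n2)) * d
  if (lambda < 1e-10) {
    p <- 1
  } else {
    j <- 1:100
    p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
    p <- min(1, max(0, p))
  }
  list(D = d, p = p)
}
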