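# Power analysis for paired t-tests: Monte-Carlo simulation with a
# noncentral-t analytic companion.

#' Analytic power of a paired (one-sample) t-test
#'
#' Closed form via the noncentral t distribution with `df = n - 1` and
#' noncentrality `d * sqrt(n)`:
#' one-sided, `P(T > t_{1-alpha})`; two-sided, both tails at
#' `t_{1-alpha/2}`.
#'
#' @param n number of paired observations, `>= 2`.
#' @param d paired Cohen's d (mean difference in SD units).
#' @param alpha test level.
#' @param sided `"one"` or `"two"`.
#' @return power in `[0, 1]`.
#' @export
analytic_power_paired_t <- function(n, d, alpha = 0.05,
                                    sided = c("one", "two")) {
  sided <- match.arg(sided)
  stopifnot(n >= 2)
  df <- n - 1
  ncp <- d * sqrt(n)
  if (sided == "one") {
    stats::pt(stats::qt(1 - alpha, df), df, ncp = ncp, lower.tail = FALSE)
  } else {
    crit <- stats::qt(1 - alpha / 2, df)
    stats::pt(crit, df, ncp = ncp, lower.tail = FALSE) +
      stats::pt(-crit, df, ncp = ncp)
  }
}

#' Simulated power of a paired t-test
#'
#' Draws `reps` replicates of `n` paired differences from `Normal(d, 1)` (so
#' `d` is exactly the paired Cohen's d), applies the one-sample t-test at
#' `alpha` with the stated sidedness, and returns the rejection fraction
#' with its Monte-Carlo standard error and the noncentral-t analytic value
#' as a cross-check.
#'
#' @param n paired observations per replicate.
#' @param d paired Cohen's d.
#' @param alpha test level.
#' @param sided `"one"` or `"two"`.
#' @param reps Monte-Carlo replicates, `>= 1000`.
#' @param seed RNG seed (mandatory).
#' @return object of class `cb_power`: `power`, `mc_se`, `analytic_power`,
#'   plus the design fields (`n`, `d`, `alpha`, `sided`, `reps`, `seed`).
#' @export
simulate_power <- function(n, d, alpha = 0.05, sided = c("one", "two"),
                           reps = 20000, seed) {
  sided <- match.arg(sided)
  stopifnot(reps >= 1000, n >= 2)
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  x <- matrix(stats::rnorm(reps * n, mean = d, sd = 1), nrow = reps)
  m <- rowMeans(x)
  s <- sqrt((rowSums(x^2) - n * m^2) / (n - 1))
  tt <- m / (s / sqrt(n))
  df <- n - 1
  reject <- if (sided == "one") tt > stats::qt(1 - alpha, df)
            else abs(tt) > stats::qt(1 - alpha / 2, df)
  p <- mean(reject)
  structure(list(n = n, d = d, alpha = alpha, sided = sided, reps = reps,
                 seed = seed, power = p,
                 mc_se = sqrt(p * (1 - p) / reps),
                 analytic_power = analytic_power_paired_t(n, d, alpha, sided)),
            class = "cb_power")
}

#' @export
print.cb_power <- function(x, ...) {
  cat(sprintf("<cb_power> n=%d d=%.2f %s-sided alpha=%.3g: power %.3f (MC SE %.4f; analytic %.3f)\n",
              x$n, x$d, x$sided, x$alpha, x$power, x$mc_se, x$analytic_power))
  invisible(x)
}

#' Power curve over a grid of sample sizes
#'
#' @param n_grid integer vector of sample sizes.
#' @param d paired Cohen's d.
#' @param alpha test level.
#' @param sided `"one"` or `"two"`.
#' @param reps Monte-Carlo replicates per cell.
#' @param seed base seed; cell `i` uses `seed + i`.
#' @return data.frame: `n`, `power`, `mc_se`, `analytic_power`.
#' @export
power_curve <- function(n_grid, d = 0.6, alpha = 0.05,
                        sided = c("one", "two"), reps = 20000, seed) {
  sided <- match.arg(sided)
  rows <- lapply(seq_along(n_grid), function(i) {
    r <- simulate_power(n_grid[i], d, alpha, sided, reps, seed + i)
    data.frame(n = r$n, power = r$power, mc_se = r$mc_se,
               analytic_power = r$analytic_power)
  })
  do.call(rbind, rows)
}
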