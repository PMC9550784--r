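test_that("compute_st matches term-by-term summation and its conventions", {
  # independent oracle: literal sum of X_j * log(X_j / X_j_st)
  X <- c(60, 40); Xst <- c(50, 50)
  expect_equal(compute_st(X, Xst), 60 * log(60 / 50) + 40 * log(40 / 50))
  expect_equal(compute_st(c(3, 7), c(3, 7)), 0)
  # zero amount contributes nothing (0 log 0 = 0)
  expect_equal(compute_st(c(0, 40), c(50, 50)), 40 * log(40 / 50))
  expect_error(compute_st(c(1, 1), c(0, 1)), "baseline")
})

test_that("ST is nonnegative at matched totals (Gibbs inequality)", {
  withr::with_seed(99, {
    for (i in 1:200) {
      n <- sample(2:6, 1)
      Xst <- runif(n, 0.1, 10)
      X <- runif(n, 0.1, 10)
      X <- X * sum(Xst) / sum(X)    # match the total amount
      expect_gte(compute_st(X, Xst), 0)
    }
  })
})

test_that("total_duration is the amount-weighted sum of durations", {
  expect_equal(total_duration(10, 30), 300)
  expect_equal(total_duration(c(1, 1), c(10, 20)), 30)
  # amount form equals the proportion form times the total
  X <- c(2, 3, 5); tau <- c(10, 20, 40)
  expect_equal(total_duration(X, tau), sum(X) * sum((X / sum(X)) * tau))
  expect_error(total_duration(c(1, 2), 3), "length")
})

test_that("compute_str is the log fold-change per minute", {
  expect_equal(compute_str(1, 30), 0)
  expect_equal(compute_str(exp(3), 30), 0.1)
  expect_error(compute_str(0, 30), "integral_ratio")
  expect_error(compute_str(2, -1), "tau")
})

test_that("tilt_distribution imposes an exactly uniform STR", {
  p_st <- c(0.5, 0.5); tau <- c(10, 20)
  p <- tilt_distribution(p_st, tau, 0.05)
  expect_equal(p, c(0.5 * exp(-0.5), 0.5 * exp(-1)), tolerance = 1e-10)
  expect_equal(log(p / p_st) / tau, rep(-0.05, 2), tolerance = 1e-14)
  # zero multiplier is the identity tilt
  expect_equal(tilt_distribution(p_st, tau, 0), p_st)
  # equal durations scale all proportions by a common factor
  p2 <- tilt_distribution(c(0.2, 0.3, 0.5), c(30, 30, 30), 0.01)
  expect_equal(p2 / c(0.2, 0.3, 0.5), rep(exp(-0.3), 3))
})

test_that("solve_beta meets its constraint to high precision", {
  p_st <- c(0.5, 0.5); tau <- c(10, 20)
  # already-satisfied constraints give a zero multiplier
  expect_equal(solve_beta(p_st, tau, 1, "normalization")$beta, 0,
               tolerance = 1e-10)
  expect_equal(solve_beta(p_st, tau, sum(p_st * tau), "duration")$beta, 0,
               tolerance = 1e-10)
  # duration constraint: check against a plain bisection oracle
  sol <- solve_beta(p_st, tau, 12, "duration")
  expect_lt(abs(sol$residual), 1e-10)
  g <- function(b) sum(p_st * tau * exp(-b * tau)) - 12
  lo <- -1; hi <- 1
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  expect_equal(sol$beta, (lo + hi) / 2, tolerance = 1e-10)
  expect_error(solve_beta(p_st, tau, -1, "duration"), "target")
})

test_that("solve_beta round-trips a known multiplier", {
  withr::with_seed(7, {
    for (i in 1:20) {
      n <- sample(2:6, 1)
      p_st <- runif(n); p_st <- p_st / sum(p_st)
      tau <- runif(n, 5, 120)
      beta <- runif(1, -0.1, 0.1)
      p <- tilt_distribution(p_st, tau, beta)
      for (kind in c("normalization", "duration")) {
        target <- if (kind == "duration") sum(p * tau) else sum(p)
        expect_equal(solve_beta(p_st, tau, target, kind)$beta, beta,
                     tolerance = 1e-8)
      }
    }
  })
})

test_that("verify_uniform_str detects uniform and perturbed allocations", {
  p_st <- c(0.3, 0.3, 0.4); tau <- c(15, 30, 60)
  p <- tilt_distribution(p_st, tau, 0.02)
  v <- verify_uniform_str(p, p_st, tau)
  expect_true(v$is_uniform)
  expect_equal(v$per_step_beta, rep(-0.02, 3), tolerance = 1e-12)
  # unchanged proportions are uniform at rate zero even with unequal tau
  v0 <- verify_uniform_str(p_st, p_st, tau)
  expect_true(v0$is_uniform)
  expect_equal(v0$per_step_beta, rep(0, 3))
  # a 10% bump on one molecule breaks uniformity at tol 1e-6
  p[2] <- p[2] * 1.1
  expect_false(verify_uniform_str(p, p_st, tau, tol = 1e-6)$is_uniform)
})

test_that("the tilted allocation is a strict one-sided extremum of ST", {
  chk <- st_projection_check(c(0.2, 0.3, 0.5), c(15, 30, 60), beta = -0.02,
                             n_perturb = 50, seed = 123)
  expect_true(chk$one_sided)
  # convexity: every feasible perturbation carries strictly more ST
  expect_true(all(chk$delta_st > 0))
  # and perturbed allocations exactly preserve the matched constraints
  # (checked indirectly: the check itself constructs them in the null space)
  expect_length(chk$delta_st, 50)
})
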