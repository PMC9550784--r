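test_that("trim_outliers applies the median/IQR rule with a floor of five", {
  clean <- c(2.0, 2.1, 1.9, 2.05, 1.95, 2.0)
  expect_equal(trim_outliers(clean), clean)
  # hand check: median 2.025, IQR 0.125 -> band [1.8375, 2.2125]; 9 is out
  spiked <- c(2.0, 2.1, 1.9, 2.05, 1.95, 9.0)
  expect_equal(trim_outliers(spiked), spiked[-6])
  # the minimum-five floor readmits flagged values
  five <- c(2.0, 2.1, 1.9, 2.05, 9.0)
  expect_equal(sort(trim_outliers(five)), sort(five))
  expect_error(trim_outliers(c(1, 2, 3, 4)), "five")
})

test_that("fit_posterior agrees with the analytic normal-model posterior", {
  y <- withr::with_seed(21, rnorm(6, 2.0, 0.2))
  fit <- fit_posterior(y, fast_mcmc(seed = 31), molecule_id = "m")
  # with a nearly flat prior the EAP is the sample mean
  expect_lt(abs(fit$eap_mu - mean(y)), 0.05)
  expect_lte(fit$r_hat, 1.1)
  expect_true(fit$converged)
  # posterior SD of the mean is near the conjugate-approximation scale
  expect_equal(fit$post_sd, sd(y) / sqrt(6), tolerance = 0.5)
  expect_equal(fit$n_used, 6L)
})

test_that("fit_posterior is bit-reproducible and guards its preconditions", {
  y <- c(1.9, 2.0, 2.05, 2.1, 2.2, 1.95)
  f1 <- fit_posterior(y, fast_mcmc(seed = 5))
  f2 <- fit_posterior(y, fast_mcmc(seed = 5))
  expect_identical(f1$mu_draws, f2$mu_draws)
  expect_identical(f1$sigma_draws, f2$sigma_draws)
  expect_error(fit_posterior(c(1, 2, 3, 4), fast_mcmc()), "five")
  # near-degenerate replicates: posterior concentrates at their value
  z <- fit_posterior(rep(0.5, 6) + c(-1, 1, -1, 1, -1, 1) * 1e-4,
                     fast_mcmc(seed = 6))
  expect_lt(abs(z$eap_mu - 0.5), 0.01)
})

test_that("effect_size uses the upstream posterior SD and is asymmetric", {
  A <- make_posterior(rep(2.0, 10), rep(0.5, 10), "A"); A$post_sd <- 1.0
  B <- make_posterior(rep(2.3, 10), rep(0.5, 10), "B"); B$post_sd <- 0.1
  expect_equal(effect_size(A, B), 0.3)
  expect_equal(effect_size(B, A), 3.0)
  expect_equal(effect_size(A, A), 0)
  # pooled alternative is symmetric
  expect_equal(effect_size(A, B, "pooled"), effect_size(B, A, "pooled"))
})

test_that("prob_dominance matches the closed-form normal difference", {
  K <- 40000
  # degenerate posteriors make the predictive exactly Normal
  A <- make_posterior(rep(2.0, K), rep(0.2, K), "A")
  B <- make_posterior(rep(2.2, K), rep(0.2, K), "B")
  pd <- prob_dominance(A, B, seed = 1)
  expect_equal(pd, pnorm(-0.2 / sqrt(0.08)), tolerance = 0.02)
  # identical posteriors: one half by symmetry
  expect_equal(prob_dominance(A, A, seed = 2), 0.5, tolerance = 0.02)
  # separation drives dominance to certainty
  Bfar <- make_posterior(rep(10, K), rep(0.2, K), "B")
  expect_gt(prob_dominance(Bfar, A, seed = 3), 0.999)
  # complementarity within Monte-Carlo error
  expect_equal(prob_dominance(A, B, seed = 4) + prob_dominance(B, A, seed = 5),
               1, tolerance = 0.02)
})

test_that("prob_direction matches the closed-form and is swap-invariant", {
  K <- 40000
  mA <- withr::with_seed(8, rnorm(K, 2.00, 0.1))
  mB <- withr::with_seed(9, rnorm(K, 2.05, 0.1))
  A <- make_posterior(mA, rep(0.1, K), "A")
  B <- make_posterior(mB, rep(0.1, K), "B")
  dp <- prob_direction(A, B)
  expect_equal(dp, max(pnorm(-0.05 / sqrt(0.02)),
                       1 - pnorm(-0.05 / sqrt(0.02))), tolerance = 0.02)
  expect_identical(prob_direction(A, B), prob_direction(B, A))
  expect_gte(dp, 0.5)
  # identical draws: exactly at the similarity midpoint... up to ties
  expect_equal(prob_direction(A, A), 0.5, tolerance = 1e-12)
  # fully separated posteriors
  Bfar <- make_posterior(mA + 10, rep(0.1, K), "B")
  expect_equal(prob_direction(A, Bfar), 1.0)
})

test_that("similarity_verdict applies the rounded two-of-three rule", {
  # three criteria met
  v1 <- similarity_verdict(0.1, 0.5, 0.6)
  expect_true(v1$similar); expect_equal(sum(v1$c1, v1$c2, v1$c3), 3)
  # none met
  v0 <- similarity_verdict(0.6, 0.3, 0.9)
  expect_false(v0$similar); expect_equal(sum(v0$c1, v0$c2, v0$c3), 0)
  # exactly two met (effect size too large)
  v2 <- similarity_verdict(0.5, 0.6, 0.6)
  expect_true(v2$similar)
  expect_false(v2$c1); expect_true(v2$c2); expect_true(v2$c3)
  # bounds are inclusive after rounding to one decimal
  expect_true(similarity_verdict(0.3, 0.4, 0.6)$similar)
  expect_true(similarity_verdict(0.34, 0.44, 0.559)$similar)  # rounds inside
  expect_false(similarity_verdict(0.36, 0.35, 0.65)$similar)  # rounds outside
})

test_that("posterior-based verdicts behave sensibly end to end", {
  y <- c(1.9, 2.0, 2.05, 2.1, 2.2, 1.95)
  A <- fit_posterior(y, fast_mcmc(seed = 41), "A")
  B <- fit_posterior(y + 5, fast_mcmc(seed = 42), "B")   # far apart
  pair <- assess_pair(A, B, seed = 43)
  expect_false(pair$similar)
  expect_equal(pair$d_mu, 5, tolerance = 0.2)
  # a molecule against itself is always similar
  self <- assess_pair(A, fit_posterior(y, fast_mcmc(seed = 44), "A2"),
                      seed = 45)
  expect_true(self$similar)
})
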