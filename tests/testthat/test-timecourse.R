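make_flat_dataset <- function(phospho = 100, total = 200, nc = 50,
                              times = c(0, 15, 30), reps = 1:5) {
  grid <- tidyr::expand_grid(time_min = times, replicate = reps)
  dplyr::bind_rows(
    tibble::tibble(molecule_id = "m", channel = "phospho",
                   time_min = grid$time_min, replicate = grid$replicate,
                   intensity = phospho, condition = "c"),
    tibble::tibble(molecule_id = "m", channel = "total",
                   time_min = grid$time_min, replicate = grid$replicate,
                   intensity = total, condition = "c"),
    tibble::tibble(molecule_id = "negative_control",
                   channel = "negative_control",
                   time_min = grid$time_min, replicate = grid$replicate,
                   intensity = nc, condition = "c")
  )
}

test_that("normalization yields unit ratios for constant channels", {
  r <- normalize_ratios(make_flat_dataset())
  expect_true(all(r$ratio == 1))
})

test_that("normalization is ratio arithmetic with r(0) = 1 exactly", {
  ds <- make_flat_dataset()
  ds$intensity[ds$channel == "phospho" & ds$time_min == 15] <- 200  # doubles
  r <- normalize_ratios(ds)
  expect_equal(r$ratio[r$time_min == 15], rep(2, 5))
  expect_identical(r$ratio[r$time_min == 0], rep(1, 5))
})

test_that("normalization cancels a common per-array gain", {
  spec <- recovery_spec(seed = 5)
  ds <- generate_dataset(spec)
  r0 <- normalize_ratios(ds)
  ds2 <- ds
  scale_up <- ds2$replicate == 3      # rescale one replicate's whole array
  ds2$intensity[scale_up] <- ds2$intensity[scale_up] * 7.3
  r2 <- normalize_ratios(ds2)
  expect_equal(r2$ratio, r0$ratio, tolerance = 1e-12)
})

test_that("normalization reproduces the noiseless pulse fold-change", {
  spec <- noiseless_spec(beta = 0.02, tau = 45, baseline = 800)
  m <- spec$molecules[1, ]
  r <- normalize_ratios(generate_dataset(spec))
  r1 <- r[r$replicate == 1, ]
  expect_equal(r1$ratio,
               1 + pulse_value(m, r1$time_min) / m$baseline_intensity,
               tolerance = 1e-12)
})

test_that("normalization reports structural gaps and bad intensities", {
  ds <- make_flat_dataset()
  expect_error(normalize_ratios(ds[!(ds$channel == "negative_control" &
                                       ds$time_min == 15), ]),
               "negative_control missing at time 15")
  ds_bad <- make_flat_dataset()
  ds_bad$intensity[4] <- -1
  expect_error(normalize_ratios(ds_bad), "nonpositive intensity")
})

test_that("estimate_tau finds the zero crossing of the decline", {
  # line through (15, 1.5) and (45, 0.5) crosses zero at 60 min
  est <- estimate_tau(c(0, 15, 45), c(1, 2.5, 1.5), signal_threshold = 0.6)
  expect_equal(est$tau, 60)
  expect_equal(est$status, "estimated")
  expect_equal(c(est$t1, est$t2, est$dX1, est$dX2), c(15, 45, 1.5, 0.5))
  # dX(t2) = 0 collapses the estimator to t2
  est2 <- estimate_tau(c(0, 15, 45), c(1, 2.5, 1.0))
  expect_equal(est2$tau, 45)
  # nothing above baseline: no signal to time
  est3 <- estimate_tau(c(0, 15, 45), c(1, 0.9, 0.8))
  expect_equal(est3$status, "no_signal")
  # still above threshold at the end of the grid: censored
  est4 <- estimate_tau(c(0, 15, 45), c(1, 2, 1.5))
  expect_equal(est4$status, "censored_at_grid_end")
  expect_equal(est4$tau, 45)
  # the probe points always straddle the threshold, so dX1 > dX2 and the
  # crossing lies beyond t1
  expect_gt(est$dX1, est$dX2)
  expect_gt(est$tau, est$t1)
})

test_that("estimate_tau is exact on noiseless declines spanning two grid points", {
  # tau_true off-grid: both probe points sit on the linear decline when a
  # positive threshold admits a small residual excess at t2
  m <- molecule_spec("m", 1, pulse_amplitude = 2, t_peak = 15, tau_true = 50)
  tt <- c(0, 15, 30, 45, 60)
  r <- 1 + pulse_value(m, tt)
  est <- estimate_tau(tt, r, signal_threshold = 0.3)
  expect_equal(est$tau, 50, tolerance = 1e-12)
  # tau_true on the grid, threshold zero
  m2 <- molecule_spec("m", 1, pulse_amplitude = 2, t_peak = 15, tau_true = 45)
  est2 <- estimate_tau(tt, 1 + pulse_value(m2, tt))
  expect_equal(est2$tau, 45, tolerance = 1e-12)
})

test_that("integrate_ratio applies the trapezoid rule with analytic endpoint", {
  # flat baseline integrates to its own level
  est <- list(tau = 30, status = "estimated")
  expect_equal(integrate_ratio(c(0, 15, 30), rep(1, 3), est), 1)
  expect_equal(integrate_ratio(c(0, 15, 30), rep(2.5, 3), est), 2.5)
  # hand trapezoid: (0,1) (15,3) then back to (30,1)
  expect_equal(integrate_ratio(c(0, 15, 30), c(1, 3, 1), est), 2.0)
  # off-grid tau appends (tau, 1): hand value
  est2 <- list(tau = 20, status = "estimated")
  # pieces: [0,15] mean 2 -> 30; [15,20] mean 2 -> 10; total 40 / 20
  expect_equal(integrate_ratio(c(0, 15, 30), c(1, 3, 1), est2), 2.0)
  expect_error(integrate_ratio(c(0, 15), c(1, 1),
                               list(tau = NA, status = "no_signal")),
               "no_signal")
})

test_that("full noiseless pipeline recovers tau and beta exactly", {
  spec <- noiseless_spec(beta = 0.03, tau = 45, baseline = 1000)
  strs <- str_table(normalize_ratios(generate_dataset(spec)))
  expect_equal(strs$tau, rep(45, nrow(strs)), tolerance = 1e-12)
  expect_equal(strs$beta, rep(0.03, nrow(strs)), tolerance = 1e-12)
  expect_true(all(strs$status == "estimated"))
})

test_that("str_table flags signal-free series with zero rate", {
  spec <- noiseless_spec(beta = 0)
  strs <- str_table(normalize_ratios(generate_dataset(spec)))
  expect_true(all(strs$status == "no_signal"))
  expect_true(all(strs$beta == 0))
  expect_true(all(strs$integral_ratio == 1))
})
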