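#' Normalize raw array intensities to phosphorylation ratios
#'
#' Applies the array normalization chain: each phospho and total intensity is
#' divided by the negative-control intensity of the same array (time,
#' replicate); the phospho signal is divided by the total-protein signal of
#' the same molecule; and the resulting series is divided by its value at
#' t = 0. The result is the phosphorylation ratio
#' `r(t) = p_j(t) / p_j^st`, with `r(0) = 1` exactly for every
#' molecule/replicate. Because the negative-control division cancels, the
#' ratio is invariant to rescaling all intensities of one array by a common
#' gain factor.
#'
#' @param dataset Long-format dataset as produced by [generate_dataset()] or
#'   [read_phospho_dataset()].
#' @return Tibble with columns `molecule_id`, `replicate`, `time_min`,
#'   `ratio`, `condition`, one row per molecule/replicate/time.
#' @export
normalize_ratios <- function(dataset) {
  validate_phospho_dataset(dataset)
  nc <- dataset[dataset$channel == "negative_control",
                c("time_min", "replicate", "intensity")]
  names(nc)[3] <- "negctrl"
  mol <- dataset[dataset$channel %in% c("phospho", "total"), ]
  wide <- tidyr::pivot_wider(mol, names_from = "channel",
                             values_from = "intensity")
  wide <- dplyr::left_join(wide, nc, by = c("time_min", "replicate"))
  if (anyNA(wide$negctrl)) {
    gap <- wide[is.na(wide$negctrl), c("time_min", "replicate")][1, ]
    stop(sprintf("no negative_control record at time %g, replicate %d",
                 gap$time_min, gap$replicate), call. = FALSE)
  }
  wide$s <- (wide$phospho / wide$negctrl) / (wide$total / wide$negctrl)
  wide <- dplyr::arrange(wide, .data$molecule_id, .data$replicate, .data$time_min)
  out <- dplyr::group_by(wide, .data$molecule_id, .data$replicate)
  out <- dplyr::mutate(out, ratio = .data$s / .data$s[.data$time_min == 0])
  out <- dplyr::ungroup(out)
  out[, c("molecule_id", "replicate", "time_min", "ratio", "condition")]
}

#' Phosphorylation-style ratio series of the negative-control spot
#'
#' The negative control has no total-protein channel; its pseudo-ratio is
#' the spot intensity divided by its value at t = 0. Feeding these series
#' through the same duration/STR estimators as real molecules yields the
#' noise STRs used for the activation floor (see [noise_floor()]).
#'
#' @inheritParams normalize_ratios
#' @return Tibble like [normalize_ratios()], with
#'   `molecule_id = "negative_control"`.
#' @export
negative_control_ratios <- function(dataset) {
  validate_phospho_dataset(dataset)
  nc <- dataset[dataset$channel == "negative_control", ]
  nc <- dplyr::arrange(nc, .data$replicate, .data$time_min)
  out <- dplyr::group_by(nc, .data$replicate)
  out <- dplyr::mutate(out, ratio = .data$intensity / .data$intensity[.data$time_min == 0])
  out <- dplyr::ungroup(out)
  out$molecule_id <- "negative_control"
  out[, c("molecule_id", "replicate", "time_min", "ratio", "condition")]
}

#' Estimate the signal duration of one time course
#'
#' The signal duration tau is the time at which phosphorylation returns to
#' its pre-stimulation level. With `dX(t) = r(t) - 1`, the estimator locates
#' the decline: `t1` is the last grid time with `dX > signal_threshold` and
#' `t2` the following grid time, and tau is the zero crossing of the line
#' through the two points,
#' `tau = (t2 * dX(t1) - t1 * dX(t2)) / (dX(t1) - dX(t2))`.
#' When `dX(t2) > 0` (possible with a positive threshold) tau extrapolates
#' beyond `t2`; when `dX(t2) = 0`, tau equals `t2`. If the signal never
#' exceeds the threshold the series is classified `no_signal`; if it is
#' still above threshold at the last grid time the estimate is censored at
#' the grid end.
#'
#' @param times Numeric vector of grid times (min), starting at 0,
#'   increasing.
#' @param ratio Phosphorylation ratios `r(t)` at `times` (`r[1] = 1`).
#' @param signal_threshold Nonnegative detection threshold on `dX`; 0 means
#'   any positive excursion counts as signal. A positive threshold (the
#'   pipeline default is 0.3) suppresses noise-driven duration estimates on
#'   real data.
#' @return A one-row tibble: `tau`, `t1`, `t2`, `dX1`, `dX2`, `status`
#'   (`"estimated"`, `"censored_at_grid_end"` or `"no_signal"`).
#' @export
estimate_tau <- function(times, ratio, signal_threshold = 0) {
  stopifnot(length(times) == length(ratio), length(times) >= 2,
            times[1] == 0, !is.unsorted(times, strictly = TRUE),
            signal_threshold >= 0)
  dX <- ratio - 1
  res <- function(tau, t1, t2, dX1, dX2, status) {
    tibble::tibble(tau = tau, t1 = t1, t2 = t2, dX1 = dX1, dX2 = dX2,
                   status = status)
  }
  above <- which(dX > signal_threshold & times > 0)
  if (length(above) == 0) {
    return(res(NA_real_, NA_real_, NA_real_, NA_real_, NA_real_, "no_signal"))
  }
  i1 <- max(above)
  if (i1 == length(times)) {
    return(res(times[i1], times[i1], NA_real_, dX[i1], NA_real_,
               "censored_at_grid_end"))
  }
  i2 <- i1 + 1L
  dX1 <- dX[i1]; dX2 <- dX[i2]
  if (dX1 == dX2) {
    stop("degenerate slope: dX(t1) == dX(t2), zero-crossing undefined",
         call. = FALSE)
  }
  tau <- (times[i2] * dX1 - times[i1] * dX2) / (dX1 - dX2)
  res(tau, times[i1], times[i2], dX1, dX2, "estimated")
}

#' Integrate the phosphorylation ratio over the signal duration
#'
#' Computes the integrated fold-change
#' `int_0^tau (X^st + dX) dt / int_0^tau X^st dt`, which in normalized units
#' is `int_0^tau r(t) dt / tau`, by the trapezoid rule over the grid points
#' inside `[0, tau]`. When tau is not itself a grid point, the analytic
#' endpoint `(tau, 1)` is appended — the ratio is back at baseline at tau by
#' definition of the duration. For a censored estimate the integral runs to
#' the grid end. For a nonnegative pulse the result is >= 1.
#'
#' @inheritParams estimate_tau
#' @param est Duration estimate from [estimate_tau()] (status must not be
#'   `no_signal`).
#' @return Dimensionless integral ratio (scalar).
#' @export
integrate_ratio <- function(times, ratio, est) {
  stopifnot(length(times) == length(ratio))
  if (est$status == "no_signal") {
    stop("cannot integrate a series with status 'no_signal'", call. = FALSE)
  }
  tau <- est$tau
  keep <- times <= tau
  tt <- times[keep]; rr <- ratio[keep]
  if (tail(tt, 1) < tau) {
    tt <- c(tt, tau)
    rr <- c(rr, 1)
  }
  trapz(tt, rr) / tau
}

## plain trapezoid rule
trapz <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

#' Per-replicate signal transduction rates for a whole dataset
#'
#' Runs [estimate_tau()], [integrate_ratio()] and [compute_str()] on every
#' molecule/replicate ratio series. Series with no detectable signal get
#' `beta = 0` (integral ratio 1, no information gain); censored series are
#' computed to the grid end and flagged in `status`.
#'
#' @param ratios Output of [normalize_ratios()] (or
#'   [negative_control_ratios()]).
#' @param signal_threshold Detection threshold passed to [estimate_tau()].
#' @return Tibble with one row per molecule/replicate: `molecule_id`,
#'   `replicate`, `tau`, `integral_ratio`, `beta`, `status`, `condition`.
#' @export
str_table <- function(ratios, signal_threshold = 0) {
  grp <- dplyr::group_split(ratios, ratios$molecule_id, ratios$replicate,
                            .keep = TRUE)
  rows <- purrr::map(grp, function(g) {
    g <- dplyr::arrange(g, .data$time_min)
    est <- estimate_tau(g$time_min, g$ratio, signal_threshold)
    if (est$status == "no_signal") {
      ir <- 1
      beta <- 0
      tau <- NA_real_
    } else {
      ir <- integrate_ratio(g$time_min, g$ratio, est)
      tau <- est$tau
      beta <- if (ir > 0) compute_str(ir, tau) else NA_real_
    }
    tibble::tibble(molecule_id = g$molecule_id[1], replicate = g$replicate[1],
                   tau = tau, integral_ratio = ir, beta = beta,
                   status = est$status, condition = g$condition[1])
  })
  dplyr::bind_rows(rows)
}
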