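#' @keywords internal
#' @importFrom rlang .data
#' @importFrom utils tail head
"_PACKAGE"

## Evaluate code under a given RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Describe one signaling molecule for simulation
#'
#' A molecule is simulated as a constant baseline phospho-intensity plus, if
#' active, a single transient phosphorylation pulse: a linear rise from 0 at
#' the moment of stimulation to `pulse_amplitude` at `t_peak`, then a linear
#' decline back to baseline at `tau_true`. The triangular shape is a
#' deliberate choice: the zero-crossing duration estimator and trapezoidal
#' integration are exact on piecewise-linear signals, so every simulated
#' molecule has a closed-form ground-truth signal duration and signal
#' transduction rate (see [ground_truth()]).
#'
#' @param molecule_id Character scalar naming the molecule.
#' @param baseline_intensity Pre-stimulation phospho-channel fluorescence
#'   (arbitrary units, > 0).
#' @param pulse_amplitude Peak increment above baseline (a.u., >= 0). Zero
#'   means the molecule is inactive (no pulse).
#' @param t_peak Time of the pulse apex in minutes (> 0).
#' @param tau_true True signal duration in minutes (> `t_peak`): the time at
#'   which phosphorylation returns to baseline.
#' @param total_level Intensity of the total-protein (unphosphorylated)
#'   channel, held constant over time. Defaults to `baseline_intensity`.
#' @return A one-row tibble with the molecule parameters and a derived
#'   `active` flag (`pulse_amplitude > 0`).
#' @seealso [dataset_spec()], [pulse_value()], [amplitude_for_str()]
#' @export
molecule_spec <- function(molecule_id, baseline_intensity, pulse_amplitude = 0,
                          t_peak = 15, tau_true = 45,
                          total_level = baseline_intensity) {
  stopifnot(is.character(molecule_id), length(molecule_id) == 1L)
  if (!is.finite(baseline_intensity) || baseline_intensity <= 0) {
    stop("`baseline_intensity` must be > 0", call. = FALSE)
  }
  if (!is.finite(pulse_amplitude) || pulse_amplitude < 0) {
    stop("`pulse_amplitude` must be >= 0", call. = FALSE)
  }
  if (pulse_amplitude > 0 && !(tau_true > t_peak && t_peak > 0)) {
    stop("need tau_true > t_peak > 0 for an active molecule", call. = FALSE)
  }
  if (total_level <= 0) stop("`total_level` must be > 0", call. = FALSE)
  tibble::tibble(
    molecule_id = molecule_id,
    baseline_intensity = baseline_intensity,
    pulse_amplitude = pulse_amplitude,
    t_peak = t_peak,
    tau_true = tau_true,
    total_level = total_level,
    active = pulse_amplitude > 0
  )
}

#' Pulse amplitude required for a target signal transduction rate
#'
#' Inverts the closed-form STR of the triangular pulse,
#' `beta = log(1 + A / (2 * baseline)) / tau`, for the amplitude `A`.
#'
#' @param beta Target STR in 1/min.
#' @param tau_true Signal duration in minutes.
#' @param baseline_intensity Baseline phospho intensity (a.u.).
#' @return Pulse amplitude in a.u.
#' @export
amplitude_for_str <- function(beta, tau_true, baseline_intensity) {
  stopifnot(beta >= 0, tau_true > 0, baseline_intensity > 0)
  2 * baseline_intensity * expm1(beta * tau_true)
}

#' Specify a synthetic phospho-array experiment
#'
#' Bundles a panel of [molecule_spec()] rows with the measurement design:
#' the sampling grid, the number of replicate assays, the multiplicative
#' noise level and the negative-control spot intensity. The defaults mirror
#' a standard EGF-stimulation array experiment: samples at 0, 15, 30, 45,
#' 60, 120 and 180 min, six replicates, and a replicate coefficient of
#' variation just under 0.1.
#'
#' @param molecules Tibble of molecule parameters, typically `dplyr::bind_rows()`
#'   of [molecule_spec()] calls.
#' @param time_grid Strictly increasing measurement times in minutes,
#'   starting at 0.
#' @param n_replicates Number of independent replicate assays (>= 5).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   measurement noise (0 <= cv < 1).
#' @param negctrl_level Mean intensity of the antibody-free negative-control
#'   spot (a.u.).
#' @param condition Condition label carried through all outputs (e.g.
#'   `"non_stressed"`, `"stressed"`).
#' @param seed Integer seed making the generated dataset reproducible.
#' @return An object of class `"dataset_spec"`.
#' @export
dataset_spec <- function(molecules,
                         time_grid = c(0, 15, 30, 45, 60, 120, 180),
                         n_replicates = 6, noise_cv = 0.08,
                         negctrl_level = 150,
                         condition = "non_stressed", seed = 1L) {
  molecules <- tibble::as_tibble(molecules)
  need <- c("molecule_id", "baseline_intensity", "pulse_amplitude",
            "t_peak", "tau_true", "total_level", "active")
  if (!all(need %in% names(molecules))) {
    stop("`molecules` must be built with molecule_spec()", call. = FALSE)
  }
  if (anyDuplicated(molecules$molecule_id)) {
    stop("duplicate molecule_id in panel", call. = FALSE)
  }
  if (length(time_grid) < 2 || time_grid[1] != 0 || any(diff(time_grid) <= 0)) {
    stop("`time_grid` must start at 0 and be strictly increasing", call. = FALSE)
  }
  if (n_replicates < 5) {
    stop("`n_replicates` must be >= 5 (outlier trimming keeps a minimum of five)",
         call. = FALSE)
  }
  if (noise_cv < 0 || noise_cv >= 1) stop("`noise_cv` must be in [0, 1)", call. = FALSE)
  if (negctrl_level <= 0) stop("`negctrl_level` must be > 0", call. = FALSE)
  structure(
    list(molecules = molecules, time_grid = as.numeric(time_grid),
         n_replicates = as.integer(n_replicates), noise_cv = noise_cv,
         negctrl_level = negctrl_level, condition = condition,
         seed = as.integer(seed)),
    class = "dataset_spec"
  )
}

#' @export
print.dataset_spec <- function(x, ...) {
  cat("<dataset_spec> ", nrow(x$molecules), " molecules (",
      sum(x$molecules$active), " active), grid ",
      paste(x$time_grid, collapse = "/"), " min, ",
      x$n_replicates, " replicates, noise CV ", x$noise_cv,
      ", condition '", x$condition, "'\n", sep = "")
  invisible(x)
}

#' Noise-free phosphorylation pulse of a molecule
#'
#' The increment of phospho intensity above baseline at time `t` for the
#' triangular pulse of a [molecule_spec()]: `A * t / t_peak` on the rise,
#' `A * (tau_true - t) / (tau_true - t_peak)` on the decline, and 0 after
#' `tau_true`. Continuous and nonnegative.
#'
#' @param spec A one-row molecule tibble (or list) with fields
#'   `pulse_amplitude`, `t_peak`, `tau_true`.
#' @param t Time(s) in minutes, >= 0. Vectorized.
#' @return Intensity increment(s) in a.u.
#' @export
pulse_value <- function(spec, t) {
  stopifnot(all(t >= 0))
  A <- spec$pulse_amplitude
  if (A == 0) return(rep(0, length(t)))
  tp <- spec$t_peak
  tau <- spec$tau_true
  out <- numeric(length(t))
  rise <- t <= tp
  out[rise] <- A * t[rise] / tp
  fall <- t > tp & t <= tau
  out[fall] <- A * (tau - t[fall]) / (tau - tp)
  out
}

## One multiplicative lognormal noise factor per record: unit mean,
## coefficient of variation exactly `cv`.
lognormal_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic phospho-array dataset
#'
#' Simulates the long-format record table of a phospho-antibody array time
#' course. Each molecule contributes a `phospho` channel — baseline plus
#' triangular pulse, times a multiplicative lognormal noise factor of
#' coefficient of variation `noise_cv` — and a time-constant `total`
#' (unphosphorylated protein) channel with the same noise law. A shared
#' `negative_control` channel (one antibody-free spot per time and
#' replicate) is generated at `negctrl_level`. Identical seeds give
#' identical datasets.
#'
#' @param spec A [dataset_spec()].
#' @return A tibble with columns `molecule_id`, `channel`
#'   (`phospho`/`total`/`negative_control`), `time_min`, `replicate`,
#'   `intensity`, `condition`. Negative-control rows carry
#'   `molecule_id = "negative_control"`.
#' @export
generate_dataset <- function(spec) {
  if (!inherits(spec, "dataset_spec")) stop("`spec` must be a dataset_spec", call. = FALSE)
  tg <- spec$time_grid
  reps <- seq_len(spec$n_replicates)
  with_seed(spec$seed, {
    per_mol <- purrr::map(seq_len(nrow(spec$molecules)), function(i) {
      m <- spec$molecules[i, ]
      grid <- tidyr::expand_grid(time_min = tg, replicate = reps)
      mean_phospho <- m$baseline_intensity + pulse_value(m, grid$time_min)
      tibble::tibble(
        molecule_id = m$molecule_id,
        channel = rep(c("phospho", "total"), each = nrow(grid)),
        time_min = rep(grid$time_min, 2),
        replicate = rep(grid$replicate, 2),
        intensity = c(mean_phospho * lognormal_factor(nrow(grid), spec$noise_cv),
                      m$total_level * lognormal_factor(nrow(grid), spec$noise_cv))
      )
    })
    nc_grid <- tidyr::expand_grid(time_min = tg, replicate = reps)
    nc <- tibble::tibble(
      molecule_id = "negative_control",
      channel = "negative_control",
      time_min = nc_grid$time_min,
      replicate = nc_grid$replicate,
      intensity = spec$negctrl_level * lognormal_factor(nrow(nc_grid), spec$noise_cv)
    )
    out <- dplyr::bind_rows(per_mol, list(nc))
    out$condition <- spec$condition
    out
  })
}

#' Closed-form ground truth of a simulated panel
#'
#' For the triangular pulse the integrated fold-change over `[0, tau_true]`
#' is `1 + A / (2 * baseline)` (triangle area over baseline area), so the
#' true signal transduction rate is
#' `beta_true = log(1 + A / (2 * baseline)) / tau_true`. Inactive molecules
#' have `beta_true = 0` and an undefined (`NA`) duration.
#'
#' @param spec A [dataset_spec()].
#' @return Tibble with `molecule_id`, `tau_true` (min; `NA` when inactive)
#'   and `beta_true` (1/min).
#' @export
ground_truth <- function(spec) {
  if (!inherits(spec, "dataset_spec")) stop("`spec` must be a dataset_spec", call. = FALSE)
  m <- spec$molecules
  tibble::tibble(
    molecule_id = m$molecule_id,
    tau_true = ifelse(m$active, m$tau_true, NA_real_),
    beta_true = ifelse(
      m$active,
      log1p(m$pulse_amplitude / (2 * m$baseline_intensity)) / m$tau_true,
      0
    )
  )
}

#' Default 19-molecule EGF-stimulation panel
#'
#' A ready-made simulation panel emulating an EGF-stimulated A431-style
#' experiment. The proliferative Src-Raf1-MEK1-ERK1 (SRME) cascade is active
#' in both conditions with a common STR; the stress-responsive
#' ASK1-MKK4/MKK3-JNK (AMMJ) cascade and its downstream targets (HSF1, Tau,
#' HSP27, ATF2, c-Jun) become active with a common STR only under
#' starvation stress, where only the upstream kinases ASK1/MKK3/MKK4 carry a
#' weak signal without stress. Active STRs are 0.008-0.03 per min, giving
#' peak phosphorylation fold-changes of roughly 2-5 over baseline.
#'
#' @param condition `"non_stressed"` or `"stressed"`.
#' @param seed Integer seed for [generate_dataset()].
#' @param noise_cv Replicate noise level, default 0.08.
#' @param n_replicates Number of replicates, default 6.
#' @return A [dataset_spec()].
#' @export
default_panel <- function(condition = c("non_stressed", "stressed"), seed = 1L,
                          noise_cv = 0.08, n_replicates = 6) {
  condition <- match.arg(condition)
  stressed <- condition == "stressed"
  base <- c(
    Src = 1200, Raf1 = 900, MEK1 = 1500, ERK1 = 1100, p53 = 800,
    ASK1 = 1000, MKK3 = 950, MKK4 = 1050, JNK = 1300, HSF1 = 700,
    Tau = 600, HSP27 = 850, ATF2 = 750, cJun = 900, EGFR = 1400,
    Akt = 1250, p38 = 1000, STAT3 = 1100, GSK3B = 950
  )
  beta <- stats::setNames(rep(0, length(base)), names(base))
  beta[c("Src", "Raf1", "MEK1", "ERK1")] <- 0.025
  beta["EGFR"] <- 0.03
  beta["p53"] <- 0.01
  if (stressed) {
    beta[c("ASK1", "MKK3", "MKK4", "JNK", "HSF1", "Tau")] <- 0.02
    beta[c("HSP27", "ATF2", "cJun")] <- 0.015
  } else {
    beta[c("ASK1", "MKK3", "MKK4")] <- 0.008
  }
  tau <- stats::setNames(rep(45, length(base)), names(base))
  tau[c("p53", "HSF1", "Tau")] <- 60
  mols <- dplyr::bind_rows(purrr::map(names(base), function(id) {
    A <- if (beta[[id]] > 0) amplitude_for_str(beta[[id]], tau[[id]], base[[id]]) else 0
    molecule_spec(id, baseline_intensity = base[[id]], pulse_amplitude = A,
                  t_peak = 15, tau_true = tau[[id]],
                  total_level = 2 * base[[id]])
  }))
  dataset_spec(mols, noise_cv = noise_cv, n_replicates = n_replicates,
               condition = condition, seed = seed)
}
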