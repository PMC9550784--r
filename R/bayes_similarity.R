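#' MCMC configuration for STR posterior estimation
#'
#' @param n_chains Number of chains (>= 2; the convergence diagnostic needs
#'   several).
#' @param n_draws Iterations per chain, including warmup.
#' @param n_warmup Warmup iterations discarded from each chain.
#' @param seed Integer seed; fits are bit-reproducible for a fixed seed and
#'   configuration.
#' @param prior_mu_sd Prior SD of the mean STR, `mu ~ Normal(0, prior_mu_sd^2)`
#'   (1/min). Weakly informative: measured STRs are well below 10/min.
#' @param prior_sigma_scale Scale of the half-Normal prior on the replicate
#'   SD (1/min).
#' @return A list of class `"mcmc_config"`.
#' @export
mcmc_config <- function(n_chains = 4, n_draws = 2000, n_warmup = 1000,
                        seed = 1L, prior_mu_sd = 10, prior_sigma_scale = 5) {
  stopifnot(n_chains >= 2, n_draws > n_warmup, n_warmup >= 0,
            prior_mu_sd > 0, prior_sigma_scale > 0)
  structure(list(n_chains = as.integer(n_chains), n_draws = as.integer(n_draws),
                 n_warmup = as.integer(n_warmup), seed = as.integer(seed),
                 prior_mu_sd = prior_mu_sd,
                 prior_sigma_scale = prior_sigma_scale),
            class = "mcmc_config")
}

#' Exclude outlying replicate STR values
#'
#' Removes values outside `median +/- 1.5 * IQR`, but never trims below five
#' kept values: if the rule would leave fewer than five, the least extreme
#' of the flagged values are readmitted until five remain.
#'
#' @param x Numeric vector of replicate STRs (length >= 5).
#' @return The kept values, in their original order.
#' @export
trim_outliers <- function(x) {
  if (length(x) < 5) {
    stop("at least five replicate values are required", call. = FALSE)
  }
  med <- stats::median(x)
  iqr <- stats::IQR(x)
  dev <- abs(x - med)
  out <- dev > 1.5 * iqr
  if (sum(!out) < 5) {
    ## readmit flagged values closest to the median until five are kept
    flagged <- which(out)
    readmit <- flagged[order(dev[flagged])]
    need <- 5 - sum(!out)
    out[readmit[seq_len(need)]] <- FALSE
  }
  x[!out]
}

## Split-chain Gelman-Rubin diagnostic. `draws` is an iterations x chains
## matrix of retained draws; each chain is split in half.
split_rhat <- function(draws) {
  n <- nrow(draws)
  half <- floor(n / 2)
  halves <- cbind(draws[seq_len(half), , drop = FALSE],
                  draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(halves)
  L <- nrow(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, stats::var)
  W <- mean(vars)
  B <- L * stats::var(means)
  var_plus <- (L - 1) / L * W + B / L
  sqrt(var_plus / W)
}

#' Posterior of a molecule's mean STR from replicate measurements
#'
#' Fits `y_i ~ Normal(mu, sigma)` with weakly informative priors
#' (`mu ~ Normal(0, prior_mu_sd^2)`, `sigma ~ half-Normal(prior_sigma_scale)`)
#' by Markov chain Monte Carlo: a Gibbs update for `mu` (conditionally
#' conjugate) and a random-walk Metropolis update on `log sigma`. Chains are
#' initialized overdispersed around the sample moments. Returns the expected
#' a posteriori (EAP) mean — the Bayesian analogue of the classical mean —
#' the posterior SD of `mu`, the split-chain Gelman-Rubin diagnostic, and
#' the retained draws. A fit with `r_hat > 1.1` is not converged; it is
#' returned but flagged with a warning.
#'
#' @param y Replicate STR values (5 or more, typically after
#'   [trim_outliers()]).
#' @param cfg An [mcmc_config()].
#' @param molecule_id Optional label stored in the result.
#' @return A list of class `"posterior_summary"`: `molecule_id`, `eap_mu`,
#'   `post_sd`, `r_hat`, `mu_draws`, `sigma_draws`, `n_used`, `converged`.
#' @export
fit_posterior <- function(y, cfg = mcmc_config(), molecule_id = NA_character_) {
  if (length(y) < 5) {
    stop("at least five replicate values are required", call. = FALSE)
  }
  stopifnot(inherits(cfg, "mcmc_config"))
  n <- length(y)
  ybar <- mean(y)
  s_y <- max(stats::sd(y), 1e-9)
  keep <- cfg$n_draws - cfg$n_warmup
  prior_prec <- 1 / cfg$prior_mu_sd^2
  sig_scale2 <- cfg$prior_sigma_scale^2
  offsets <- rep(c(-2, -1, 1, 2), length.out = cfg$n_chains)
  with_seed(cfg$seed, {
    mu_mat <- matrix(NA_real_, keep, cfg$n_chains)
    sig_mat <- matrix(NA_real_, keep, cfg$n_chains)
    for (ch in seq_len(cfg$n_chains)) {
      mu <- ybar + offsets[ch] * s_y
      lsig <- log(s_y) + 0.5 * offsets[ch]
      lp_sig <- function(ls, mu) {
        sig2 <- exp(2 * ls)
        -n * ls - sum((y - mu)^2) / (2 * sig2) - sig2 / (2 * sig_scale2) + ls
      }
      for (it in seq_len(cfg$n_draws)) {
        sig2 <- exp(2 * lsig)
        prec <- prior_prec + n / sig2
        mu <- stats::rnorm(1, (sum(y) / sig2) / prec, sqrt(1 / prec))
        prop <- lsig + stats::rnorm(1, 0, 0.5)
        if (log(stats::runif(1)) < lp_sig(prop, mu) - lp_sig(lsig, mu)) {
          lsig <- prop
        }
        if (it > cfg$n_warmup) {
          mu_mat[it - cfg$n_warmup, ch] <- mu
          sig_mat[it - cfg$n_warmup, ch] <- exp(lsig)
        }
      }
    }
    rhat <- split_rhat(mu_mat)
    if (is.finite(rhat) && rhat > 1.1) {
      warning(sprintf("R_hat = %.3f > 1.1 for '%s': chains not converged",
                      rhat, molecule_id), call. = FALSE)
    }
    structure(
      list(molecule_id = molecule_id, eap_mu = mean(mu_mat),
           post_sd = stats::sd(as.numeric(mu_mat)), r_hat = rhat,
           mu_draws = as.numeric(mu_mat), sigma_draws = as.numeric(sig_mat),
           n_used = n, converged = is.finite(rhat) && rhat <= 1.1),
      class = "posterior_summary"
    )
  })
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("<posterior_summary> %s: EAP %.4g, post SD %.3g, R_hat %.3f (n = %d)\n",
              x$molecule_id, x$eap_mu, x$post_sd, x$r_hat, x$n_used))
  invisible(x)
}

#' Effect size of an STR difference
#'
#' `|delta| = |EAP_A - EAP_B| / sd`, where the denominator is by default the
#' posterior standard deviation of the first (upstream) molecule's mean STR.
#' The statistic is therefore asymmetric in its arguments; a pooled
#' denominator `sqrt((sd_A^2 + sd_B^2)/2)` is available as an alternative.
#' Values at or below 0.3 are "small" on Cohen's scale and count toward
#' similarity.
#'
#' @param A,B `posterior_summary` objects (A upstream).
#' @param denominator `"first"` (default) or `"pooled"`.
#' @return Nonnegative scalar.
#' @export
effect_size <- function(A, B, denominator = c("first", "pooled")) {
  denominator <- match.arg(denominator)
  sd_ref <- switch(denominator,
                   first = A$post_sd,
                   pooled = sqrt((A$post_sd^2 + B$post_sd^2) / 2))
  if (sd_ref <= 0) stop("degenerate posterior: zero posterior SD", call. = FALSE)
  abs(A$eap_mu - B$eap_mu) / sd_ref
}

#' Probability of dominance between two molecules' STRs
#'
#' Posterior-predictive dominance at the observation level: for each
#' retained draw `k`, hypothetical replicate measurements are simulated,
#' `y_A ~ Normal(mu_A_k, sigma_A_k)` and likewise for B, and `pi_d` is the
#' fraction with `y_A > y_B`. Identical posteriors give 0.5; values near
#' 0.5 indicate similar STR distributions. Satisfies
#' `pi_d(A, B) + pi_d(B, A) = 1` up to Monte-Carlo error.
#'
#' @inheritParams effect_size
#' @param seed Optional seed for the predictive draws.
#' @return Probability in `[0, 1]`.
#' @export
prob_dominance <- function(A, B, seed = NULL) {
  k <- min(length(A$mu_draws), length(B$mu_draws))
  run <- function() {
    ya <- stats::rnorm(k, A$mu_draws[seq_len(k)], A$sigma_draws[seq_len(k)])
    yb <- stats::rnorm(k, B$mu_draws[seq_len(k)], B$sigma_draws[seq_len(k)])
    mean(ya > yb)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Direction probability of an STR difference
#'
#' The larger of the two posterior probabilities that one mean STR exceeds
#' the other: with `p = Pr(mu_A > mu_B)` estimated over paired retained
#' draws, returns `max(p, 1 - p)`. Always in `[0.5, 1]` and invariant to
#' swapping the molecules; the closer to 0.5, the more similar the two mean
#' STRs.
#'
#' @inheritParams effect_size
#' @return Probability in `[0.5, 1]`.
#' @export
prob_direction <- function(A, B) {
  k <- min(length(A$mu_draws), length(B$mu_draws))
  a <- A$mu_draws[seq_len(k)]
  b <- B$mu_draws[seq_len(k)]
  p <- mean(a > b) + 0.5 * mean(a == b)   # exact ties split evenly
  max(p, 1 - p)
}

## round half away from zero, matching how the reported statistics are
## printed to one decimal
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Two-of-three STR similarity verdict
#'
#' Applies the similarity decision rule to the three statistics of a cascade
#' step: (1) effect size `|delta| <= 0.3` (Cohen-small); (2) probability of
#' dominance `pi_d` in `[0.4, 0.6]`; (3) direction probability `d_pi` in
#' `[0.4, 0.6]`. The statistics are rounded (half-up) to one decimal before
#' comparison, matching the precision at which such statistics are
#' reported, and the bounds are inclusive. The STRs are declared similar
#' when at least two of the three criteria hold.
#'
#' @param effect_size Nonnegative effect size `|delta|`.
#' @param pi_d Probability of dominance.
#' @param d_pi Direction probability (in `[0.5, 1]`).
#' @param delta_max Effect-size bound, default 0.3.
#' @param band Two-sided probability window, default `c(0.4, 0.6)`.
#' @param digits Decimal places used for the rounded comparison, default 1.
#' @return One-row tibble with the rounded statistics, criterion flags
#'   `c1`, `c2`, `c3`, and the `similar` verdict.
#' @export
similarity_verdict <- function(effect_size, pi_d, d_pi, delta_max = 0.3,
                               band = c(0.4, 0.6), digits = 1) {
  es <- round_half_up(effect_size, digits)
  pd <- round_half_up(pi_d, digits)
  dp <- round_half_up(d_pi, digits)
  eps <- 1e-9
  c1 <- es <= delta_max + eps
  c2 <- pd >= band[1] - eps && pd <= band[2] + eps
  c3 <- dp >= band[1] - eps && dp <= band[2] + eps
  tibble::tibble(effect_size = es, pi_d = pd, d_pi = dp,
                 c1 = c1, c2 = c2, c3 = c3,
                 similar = (c1 + c2 + c3) >= 2)
}

#' Assess the STR similarity of one cascade step
#'
#' Computes the STR difference, effect size, probability of dominance and
#' direction probability for an ordered molecule pair and applies
#' [similarity_verdict()].
#'
#' @inheritParams effect_size
#' @param seed Optional seed for the posterior-predictive dominance draws.
#' @param ... Passed to [similarity_verdict()] (thresholds, rounding).
#' @return One-row tibble: `molecule_a`, `molecule_b`, `d_mu`, raw and
#'   rounded statistics, criterion flags and verdict.
#' @export
assess_pair <- function(A, B, seed = NULL, ...) {
  if (!isTRUE(A$converged) || !isTRUE(B$converged)) {
    warning(sprintf("assessing pair %s-%s with a non-converged posterior",
                    A$molecule_id, B$molecule_id), call. = FALSE)
  }
  es <- effect_size(A, B)
  pd <- prob_dominance(A, B, seed = seed)
  dp <- prob_direction(A, B)
  v <- similarity_verdict(es, pd, dp, ...)
  tibble::tibble(molecule_a = A$molecule_id, molecule_b = B$molecule_id,
                 d_mu = abs(A$eap_mu - B$eap_mu),
                 effect_size_raw = es, pi_d_raw = pd, d_pi_raw = dp,
                 effect_size = v$effect_size, pi_d = v$pi_d, d_pi = v$d_pi,
                 c1 = v$c1, c2 = v$c2, c3 = v$c3, similar = v$similar)
}
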