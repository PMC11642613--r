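#' Ensemble moments of the melanoma population
#'
#' Per-time mean, standard deviation and coefficient of variation of the
#' melanoma count across the stochastic samples of an ensemble. Moments use
#' the population convention (divisor N, not N - 1), matching the
#' definition the autocorrelation coefficient is built on.
#'
#' @param traj Ensemble trajectory tibble ([simulate_ensemble()]).
#' @param variable Count column to summarize (default `"n_melanoma"`).
#' @return Tibble with columns `time_h`, `n_samples`, `mean`, `sd`, `cv`
#'   (`NA` where the mean is zero).
#' @export
ensemble_stats <- function(traj, variable = "n_melanoma") {
  if (!variable %in% names(traj)) abort(sprintf("no column '%s'", variable))
  traj |>
    dplyr::group_by(.data$time_h) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      mean = mean(.data[[variable]]),
      sd = sqrt(mean((.data[[variable]] - mean(.data[[variable]]))^2)),
      .groups = "drop"
    ) |>
    dplyr::mutate(cv = ifelse(.data$mean > 0, .data$sd / .data$mean, NA_real_))
}

#' Ensemble autocorrelation coefficient
#'
#' Correlation between the melanoma populations of the same stochastic
#' samples at a reference time `ti` and a later time `t`:
#' `A(t, ti) = (1/N) * sum_a (C_a(ti) - mu(ti)) (C_a(t) - mu(t)) /
#' (sigma(ti) sigma(t))` with population (divisor-N) moments. `A` near 1
#' means trajectories keep their ordering from `ti` (little mixing); fast
#' decay toward 0 means stochastic mixing erases the earlier state.
#'
#' @param traj Ensemble trajectory tibble.
#' @param ti Reference time (must be on the recording grid).
#' @param t Evaluation time on the grid. Both times need strictly positive
#'   ensemble standard deviation, otherwise the coefficient is undefined
#'   and an error is raised.
#' @param variable Count column (default `"n_melanoma"`).
#' @return A single number in `[-1, 1]`.
#' @seealso [autocorrelation_curve()] for the whole `A(t, ti)` curve.
#' @export
autocorrelation <- function(traj, ti, t, variable = "n_melanoma") {
  ci <- counts_at(traj, ti, variable)
  ct <- counts_at(traj, t, variable)
  n <- length(ci)
  si <- sqrt(mean((ci - mean(ci))^2))
  st <- sqrt(mean((ct - mean(ct))^2))
  if (si == 0 || st == 0) {
    abort("autocorrelation undefined: zero ensemble standard deviation")
  }
  mean((ci - mean(ci)) * (ct - mean(ct))) / (si * st)
}

#' @rdname autocorrelation
#' @export
autocorrelation_curve <- function(traj, ti, variable = "n_melanoma") {
  times <- sort(unique(traj$time_h))
  vals <- vapply(times, function(t) {
    tryCatch(autocorrelation(traj, ti, t, variable), error = function(e) NA_real_)
  }, numeric(1))
  tibble::tibble(time_h = times, ti = ti, autocorrelation = vals)
}

counts_at <- function(traj, t, variable) {
  sub <- traj[abs(traj$time_h - t) < 1e-9, ]
  if (nrow(sub) == 0) abort(sprintf("time %g is not on the recording grid", t))
  sub <- sub[order(sub$sample_id), ]
  sub[[variable]]
}

#' Coefficient of variation at one time
#'
#' @inheritParams autocorrelation
#' @param t Time on the recording grid; the ensemble mean must be > 0.
#' @return `sigma(t) / mu(t)` with population moments.
#' @export
coefficient_of_variation <- function(traj, t, variable = "n_melanoma") {
  ct <- counts_at(traj, t, variable)
  if (mean(ct) <= 0) abort("coefficient of variation undefined: mean is zero")
  sqrt(mean((ct - mean(ct))^2)) / mean(ct)
}

#' Transition time of an ensemble
#'
#' Estimates the time at which the dynamics switch from the early, mixing
#' stage to the late, dispersed growth stage: the recording-grid time at
#' which the ensemble-mean melanoma population attains its minimum (first
#' minimum on ties). When the mean is monotone the estimate sits on an
#' endpoint of the grid and is flagged.
#'
#' @inheritParams ensemble_stats
#' @return One-row tibble: `tau_star` (hours), `at_boundary`, `estimator`.
#' @export
transition_time <- function(traj, variable = "n_melanoma") {
  st <- ensemble_stats(traj, variable)
  if (nrow(st) < 3) abort("need at least 3 time points")
  k <- which.min(st$mean)
  tibble::tibble(
    tau_star = st$time_h[k],
    at_boundary = k == 1 || k == nrow(st),
    estimator = "argmin_mean"
  )
}

#' Fit a Yule (linear pure-birth) process to ensemble growth
#'
#' Least-squares fit of a line to `log(mu(t))` over a time window; the
#' slope is the Yule birth rate and the fitted value at the window start,
#' exponentiated, is the effective initial population. The fit uses the
#' log of the ensemble mean (exactly exponential for a Yule process)
#' rather than the mean of log counts, which is biased for branching
#' processes.
#'
#' @inheritParams ensemble_stats
#' @param window Length-2 numeric, `[t_start, t_end]` in hours; the
#'   ensemble mean must be positive throughout.
#' @return An `ics_yule_fit`: list with `lambda` (per hour), `n0`,
#'   `window`, `n_points`.
#' @export
fit_yule <- function(traj, window, variable = "n_melanoma") {
  st <- ensemble_stats(traj, variable)
  st <- st[st$time_h >= window[1] & st$time_h <= window[2], ]
  if (nrow(st) < 2) abort("window must contain at least 2 time points")
  if (any(st$mean <= 0)) abort("ensemble mean must be > 0 throughout the window")
  fit <- lm(log(mean) ~ time_h, data = st)
  lambda <- unname(coef(fit)[2])
  n0 <- exp(unname(predict(fit, tibble::tibble(time_h = window[1]))))
  structure(
    list(lambda = lambda, n0 = n0, window = window, n_points = nrow(st)),
    class = "ics_yule_fit"
  )
}

#' @export
print.ics_yule_fit <- function(x, ...) {
  cat(sprintf(
    "<ics_yule_fit> lambda = %.4g / h, n0 = %.4g over [%g, %g] h (%d points)\n",
    x$lambda, x$n0, x$window[1], x$window[2], x$n_points
  ))
  invisible(x)
}

#' Closed-form moments of the Yule process
#'
#' Mean and variance of a linear pure-birth process started from `n0`
#' cells with per-cell birth rate `lambda`: `mean = n0 exp(lambda t)`,
#' `variance = n0 exp(lambda t) (exp(lambda t) - 1)`.
#'
#' @param n0 Initial population (>= 1).
#' @param lambda Birth rate per cell per hour (>= 0).
#' @param t Time(s) in hours.
#' @return A list with numeric vectors `mean` and `variance`.
#' @export
yule_moments <- function(n0, lambda, t) {
  if (n0 < 1) abort("n0 must be >= 1")
  if (lambda < 0 || any(t < 0)) abort("lambda and t must be >= 0")
  g <- exp(lambda * t)
  list(mean = n0 * g, variance = n0 * g * (g - 1))
}

#' Closed-form autocorrelation of the Yule process
#'
#' Correlation of the population at times `ti` and `t >= ti` for a Yule
#' process. By the branching property, `E[N(t) | N(ti)] = N(ti)
#' exp(lambda (t - ti))`, so `Cov(N(ti), N(t)) = exp(lambda (t - ti))
#' Var(N(ti))` and
#' `A(t, ti) = exp(lambda (t - ti) / 2) * sqrt((exp(lambda ti) - 1) /
#' (exp(lambda t) - 1))`.
#' The initial count cancels. As `t` grows the coefficient approaches the
#' positive constant `sqrt(1 - exp(-lambda ti))`: pure-birth trajectories
#' barely mix after an early ordering is established.
#'
#' @param n0 Initial population (unused by the formula, kept so calls
#'   mirror [yule_moments()]).
#' @param lambda Birth rate (> 0).
#' @param ti Reference time (> 0; the variance at time 0 vanishes and the
#'   coefficient is undefined there).
#' @param t Evaluation time(s), `>= ti`.
#' @return Numeric vector of correlations in `(0, 1]`.
#' @export
yule_autocorrelation <- function(n0, lambda, ti, t) {
  if (lambda <= 0) abort("lambda must be > 0")
  if (ti <= 0) abort("ti must be > 0 (zero variance at t = 0)")
  if (any(t < ti)) abort("t must be >= ti")
  exp(lambda * (t - ti) / 2) * sqrt((exp(lambda * ti) - 1) / (exp(lambda * t) - 1))
}
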