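#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the score surface of a calibration fit
#'
#' @param x An `ics_fit` from [fit_exhaustion_rates()].
#' @param ... Unused.
#' @return Tibble with one row per grid point: `bC`, `bM`, `score`,
#'   `log_score`.
#' @export
tidy.ics_fit <- function(x, ...) {
  x$surface
}

#' One-row summary of a calibration fit
#'
#' @param x An `ics_fit`.
#' @param ... Unused.
#' @return Tibble with `bC`, `bM`, `score`, `neg_log_score`, `n_grid`,
#'   `n_sims`, `b`.
#' @export
glance.ics_fit <- function(x, ...) {
  tibble::tibble(
    bC = x$estimate$bC, bM = x$estimate$bM, score = x$estimate$score,
    neg_log_score = -log(x$estimate$score),
    n_grid = nrow(x$surface), n_sims = x$n_sims, b = x$b
  )
}

#' Tidy the bootstrap DSS replicates
#'
#' @param x An `ics_dss` from [bootstrap_dss()].
#' @param ... Unused.
#' @return Tibble with one row per bootstrap replicate (`replicate`,
#'   `dss`).
#' @export
tidy.ics_dss <- function(x, ...) {
  tibble::tibble(replicate = seq_along(x$dss), dss = x$dss)
}

#' One-row summary of a bootstrap model comparison
#'
#' @param x An `ics_dss`.
#' @param ... Unused.
#' @return Tibble with `p_value`, `ci_upper`, `reject`, `alpha`, `n_boot`,
#'   `n_slides`, `b`.
#' @export
glance.ics_dss <- function(x, ...) {
  tibble::tibble(
    p_value = x$p_value, ci_upper = x$ci_upper, reject = x$reject,
    alpha = x$alpha, n_boot = x$n_boot, n_slides = x$n_slides, b = x$b
  )
}

#' Tidy a Yule fit
#'
#' @param x An `ics_yule_fit` from [fit_yule()].
#' @param ... Unused.
#' @return Tibble with `term` / `estimate` rows for the birth rate and the
#'   effective initial population.
#' @export
tidy.ics_yule_fit <- function(x, ...) {
  tibble::tibble(
    term = c("lambda", "n0"),
    estimate = c(x$lambda, x$n0)
  )
}

#' @export
glance.ics_yule_fit <- function(x, ...) {
  tibble::tibble(
    lambda = x$lambda, n0 = x$n0,
    window_start = x$window[1], window_end = x$window[2],
    n_points = x$n_points
  )
}

#' Tidy a fencing permutation null
#'
#' @param x An `ics_fencing_null` from [fencing_null()].
#' @param ... Unused.
#' @return Tibble with one row per permutation (`permutation`,
#'   `fraction`).
#' @export
tidy.ics_fencing_null <- function(x, ...) {
  tibble::tibble(permutation = seq_along(x$null_fractions), fraction = x$null_fractions)
}

#' @export
glance.ics_fencing_null <- function(x, ...) {
  tibble::tibble(
    observed = x$observed,
    null_mean = mean(x$null_fractions),
    null_q95 = unname(quantile(x$null_fractions, 0.95)),
    n_perm = x$n_perm, pool = x$pool, min_size = x$min_size, mode = x$mode
  )
}
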