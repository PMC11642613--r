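#' Bootstrap comparison of two models via the DSS statistic
#'
#' Compares a base and an alternate model using their cached per-slide
#' prediction success frequencies. For each bootstrap replicate, N slides
#' are drawn with replacement from the N cohort slides (the same resampled
#' multiset for both models), the prediction success score of each model is
#' computed on the resample, and the difference in log scores
#' `DSS = ln(score_alt) - ln(score_base)` is recorded. No re-simulation
#' happens inside the loop, which is what makes 100,000 replicates cheap.
#'
#' The reported p-value is the fraction of replicates with `DSS >= 0` (the
#' alternate at least as good as the base); equality of the models is
#' rejected at level `alpha` when the one-sided `(1 - alpha)` upper
#' confidence bound for DSS lies below zero, equivalently `p <= alpha`.
#'
#' @param f_base,f_alt Per-slide frequencies for the two models: numeric
#'   vectors over the same slides in the same order, or tibbles with
#'   columns `slide_id` and `f` (matched by `slide_id`).
#' @param b Dataset-limitation constant of the score.
#' @param n_boot Number of bootstrap replicates (default 100,000).
#' @param alpha Test level.
#' @param seed Optional integer seed.
#' @return An `ics_dss`: list with `dss` (replicate values), `p_value`,
#'   `ci_upper`, `reject`, `alpha`, `n_boot`, `b`, `n_slides`.
#' @export
bootstrap_dss <- function(f_base, f_alt, b = 0.1, n_boot = 1e5,
                          alpha = 0.05, seed = NULL) {
  if (is.data.frame(f_base) && is.data.frame(f_alt)) {
    if (!setequal(f_base$slide_id, f_alt$slide_id) ||
      nrow(f_base) != nrow(f_alt)) {
      abort("f_base and f_alt must cover the same slides")
    }
    f_alt <- f_alt[match(f_base$slide_id, f_alt$slide_id), ]
    f_base <- f_base$f
    f_alt <- f_alt$f
  }
  if (length(f_base) != length(f_alt)) {
    abort("f_base and f_alt must have the same length")
  }
  n <- length(f_base)
  if (n == 0) abort("empty frequency vectors")
  # per-slide log-score contributions; DSS of a resample is the sum of the
  # per-slide differences over the sampled multiset
  d <- log((1 - b) * f_alt + b / 2) - log((1 - b) * f_base + b / 2)
  dss <- with_seed_if(seed, {
    idx <- sample.int(n, n * n_boot, replace = TRUE)
    colSums(matrix(d[idx], nrow = n))
  })
  p <- mean(dss >= 0)
  ci_upper <- unname(quantile(dss, 1 - alpha))
  structure(
    list(
      dss = dss, p_value = p, ci_upper = ci_upper,
      reject = p <= alpha, alpha = alpha, n_boot = n_boot,
      b = b, n_slides = n
    ),
    class = "ics_dss"
  )
}

#' @export
print.ics_dss <- function(x, ...) {
  cat(sprintf(
    "<ics_dss> %d bootstrap replicates over %d slides\n  p = %.4g (one-sided %.0f%% upper CI bound %.4g) -> %s equality\n",
    x$n_boot, x$n_slides, x$p_value, 100 * (1 - x$alpha), x$ci_upper,
    if (x$reject) "reject" else "do not reject"
  ))
  invisible(x)
}

#' Bonferroni adjustment
#'
#' Multiplies each p-value by the number of tests performed, capping at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param m Number of simultaneous tests (default `length(p)`).
#' @return Adjusted p-values.
#' @export
#' @examples
#' bonferroni_adjust(c(0.07, 0.09)) # 0.14, 0.18
bonferroni_adjust <- function(p, m = length(p)) {
  if (any(!is.finite(p) | p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  if (m < 1) abort("m must be >= 1")
  pmin(1, m * p)
}

#' Construct an alternate (null-mechanism) parameter set
#'
#' Sets one of the fitted exhaustion rates to zero, encoding hypotheses
#' such as "TAMs do not exhaust activated CD8+ T cells" (`which = "bM"`) or
#' "melanoma cells do not exhaust activated CD8+ T cells" (`which =
#' "bC"`). The caller should then re-estimate the remaining exhaustion rate
#' with [fit_exhaustion_rates()] (single-value grid for the zeroed rate)
#' before comparing models with [bootstrap_dss()].
#'
#' @param params `ics_rate_params`.
#' @param which `"bC"` or `"bM"`.
#' @return The modified `ics_rate_params`.
#' @export
make_alternate <- function(params, which = c("bC", "bM")) {
  if (!is.character(which) || length(which) != 1) {
    abort("which must be 'bC' or 'bM'")
  }
  which <- match.arg(which)
  args <- list()
  args[[which]] <- 0
  do.call(rate_params_update, c(list(params), args))
}
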