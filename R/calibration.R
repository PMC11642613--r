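#' Melanoma fold change of a trajectory
#'
#' Ratio of the melanoma population at the final recorded time to the
#' initial population, per stochastic sample.
#'
#' @param traj Trajectory tibble ([simulate_ics()] / [simulate_ensemble()]).
#' @return Tibble with columns `sample_id` and `fold_change`.
#' @export
fold_change <- function(traj) {
  out <- traj |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      n0 = .data$n_melanoma[which.min(.data$time_h)],
      nT = .data$n_melanoma[which.max(.data$time_h)],
      .groups = "drop"
    )
  if (any(out$n0 <= 0)) {
    abort("fold change undefined: zero melanoma cells at t = 0")
  }
  dplyr::transmute(out, sample_id = .data$sample_id, fold_change = .data$nT / .data$n0)
}

#' Classify response from a melanoma fold change
#'
#' A fold change below 1 over the treatment window designates the slide's
#' patient a responder, above 1 a nonresponder. A fold change of exactly 1
#' is classified nonresponder: no net shrinkage is read conservatively as
#' no response (flip with `tie`).
#'
#' @param fc Numeric vector of fold changes (>= 0).
#' @param tie Label assigned at fold change exactly 1.
#' @return Character vector of `"responder"` / `"nonresponder"`.
#' @export
#' @examples
#' predict_response(c(0.5, 3, 1))
predict_response <- function(fc, tie = c("nonresponder", "responder")) {
  tie <- match.arg(tie)
  if (any(!is.finite(fc) | fc < 0)) abort("fold changes must be finite and >= 0")
  out <- ifelse(fc < 1, "responder", "nonresponder")
  if (tie == "responder") out[fc == 1] <- "responder"
  out
}

#' Prediction success frequency for one slide
#'
#' Fraction of `n_sims` independent stochastic simulations, started from
#' the slide's rasterized initial condition, whose predicted response
#' (melanoma fold change direction at `t_end`) agrees with the recorded
#' clinical label.
#'
#' @param lattice Initial `ics_lattice` for the slide.
#' @param response Clinical label, `"responder"` or `"nonresponder"`.
#' @param params,config Simulation settings.
#' @param n_sims Number of simulations.
#' @param seed Optional integer seed.
#' @return A single frequency in `[0, 1]`.
#' @export
prediction_frequency <- function(lattice, response, params = rate_params(),
                                 config = sim_config(), n_sims = 100,
                                 seed = NULL) {
  if (is.null(response) || is.na(response) ||
    !response %in% c("responder", "nonresponder")) {
    abort("slide must carry a response label")
  }
  if (sum(lattice$counts[, , "melanoma"]) == 0) {
    abort("slide has zero melanoma cells; fold change undefined")
  }
  traj <- simulate_ensemble(lattice, n_sims, params = params, config = config, seed = seed)
  fc <- fold_change(traj)$fold_change
  mean(predict_response(fc) == response)
}

#' Prediction success frequencies for every slide of a cohort
#'
#' Rasterizes each labeled slide and computes its prediction success
#' frequency. Per-slide seeds are derived as `seed + slide index`, so
#' calling this with the same `seed` but different rate parameters reuses
#' common random numbers across parameter sets.
#'
#' @param cohort An `ics_cohort`.
#' @param params,config Simulation settings.
#' @param n_sims Simulations per slide.
#' @param l0,cap,type_map Rasterization settings (see [slide_to_lattice()]).
#' @param seed Optional integer base seed.
#' @return Tibble with columns `slide_id`, `response`, `f`, `n_sims`.
#' @export
cohort_frequencies <- function(cohort, params = rate_params(),
                               config = sim_config(), n_sims = 100,
                               l0 = 10, cap = 4, type_map = NULL,
                               seed = NULL) {
  lattices <- cohort_lattices(cohort, l0 = l0, cap = cap, type_map = type_map)
  freqs <- purrr::imap_dbl(lattices, function(lat, i) {
    idx <- match(i, cohort$manifest$slide_id)
    prediction_frequency(
      lat, cohort$manifest$response[idx],
      params = params, config = config, n_sims = n_sims,
      seed = if (is.null(seed)) NULL else seed + idx
    )
  })
  tibble::tibble(
    slide_id = cohort$manifest$slide_id,
    response = cohort$manifest$response,
    f = unname(freqs[cohort$manifest$slide_id]),
    n_sims = n_sims
  )
}

cohort_lattices <- function(cohort, l0 = 10, cap = 4, type_map = NULL) {
  ids <- cohort$manifest$slide_id
  lats <- lapply(ids, function(sid) {
    slide_to_lattice(
      dplyr::filter(cohort$cells, .data$slide_id == sid),
      l0 = l0, cap = cap, width = cohort$width, height = cohort$height,
      type_map = type_map, quiet = TRUE
    )
  })
  names(lats) <- ids
  lats
}

#' Prediction success score
#'
#' The cohort-level calibration objective: the product over slides of
#' `(1 - b) * f_i + b / 2`, where `f_i` is slide i's prediction success
#' frequency and `b` captures intrinsic dataset limitations (a 1 x 1 mm
#' core may not represent the tumor at large, so even a perfect model is
#' credited at most `1 - b/2` per slide, and a hopeless one no less than
#' `b/2` since random chance agrees with a binary outcome half the time).
#'
#' @param f Numeric vector of per-slide frequencies in `[0, 1]`, or the
#'   tibble returned by [cohort_frequencies()].
#' @param b Dataset-limitation constant in `[0, 1)`; default 0.1.
#' @return The score, a single number in `((b/2)^N, (1 - b/2)^N)`.
#' @export
#' @examples
#' score_frequencies(rep(1, 30)) # 0.95^30
score_frequencies <- function(f, b = 0.1) {
  if (is.data.frame(f)) f <- f$f
  if (length(f) == 0) abort("empty frequency vector")
  if (any(!is.finite(f) | f < 0 | f > 1)) abort("frequencies must lie in [0, 1]")
  if (b < 0 || b >= 1) abort("b must lie in [0, 1)")
  prod((1 - b) * f + b / 2)
}

#' Calibrate the exhaustion rates against clinical response
#'
#' Evaluates the prediction success score on a grid of `(bC, bM)` values
#' and returns the maximizing pair. The objective is stochastic, so the
#' grid is evaluated with common random numbers (identical per-slide seed
#' streams at every grid point), which makes the surface reproducible and
#' comparable across points; ties are broken toward smaller `(bC, bM)`
#' lexicographically. Use a grid of length 1 in one coordinate to re-fit a
#' single-rate alternate model (see [make_alternate()]).
#'
#' @param cohort A labeled `ics_cohort`; every slide needs at least one
#'   melanoma cell.
#' @param base_params `ics_rate_params` supplying all non-fitted rates.
#' @param bC_grid,bM_grid Numeric vectors of candidate rates (typically
#'   log-spaced).
#' @param config Simulation configuration.
#' @param n_sims Simulations per slide per grid point.
#' @param b Dataset-limitation constant of the score (see
#'   [score_frequencies()]).
#' @param l0,cap,type_map Rasterization settings.
#' @param seed Integer base seed for the common-random-number streams.
#' @return An `ics_fit`: list with `estimate` (one-row tibble `bC`, `bM`,
#'   `score`), `surface` (tibble over the grid with `log_score`),
#'   `frequencies` (per-slide f at the optimum), `n_sims`, `b`, `seed`.
#' @export
fit_exhaustion_rates <- function(cohort, base_params = rate_params(),
                                 bC_grid, bM_grid, config = sim_config(),
                                 n_sims = 100, b = 0.1, l0 = 10, cap = 4,
                                 type_map = NULL, seed = NULL) {
  if (length(bC_grid) == 0 || length(bM_grid) == 0) abort("empty parameter grid")
  miss <- is.na(cohort$manifest$response)
  if (any(miss)) abort("every slide must carry a response label")
  lattices <- cohort_lattices(cohort, l0 = l0, cap = cap, type_map = type_map)
  zero_mel <- names(lattices)[vapply(
    lattices, function(l) sum(l$counts[, , "melanoma"]) == 0, logical(1)
  )]
  if (length(zero_mel) > 0) {
    abort(paste0("slide(s) with zero melanoma cells: ", paste(zero_mel, collapse = ", ")))
  }
  grid <- tidyr::expand_grid(bC = sort(bC_grid), bM = sort(bM_grid))
  responses <- cohort$manifest$response
  eval_point <- function(bC, bM) {
    params <- rate_params_update(base_params, bC = bC, bM = bM)
    f <- vapply(seq_along(lattices), function(i) {
      prediction_frequency(
        lattices[[i]], responses[i],
        params = params, config = config, n_sims = n_sims,
        seed = if (is.null(seed)) NULL else seed + i
      )
    }, numeric(1))
    f
  }
  fmat <- mapply(eval_point, grid$bC, grid$bM) # n_slides x n_points
  fmat <- matrix(fmat, nrow = length(lattices))
  grid$score <- apply(fmat, 2, score_frequencies, b = b)
  grid$log_score <- log(grid$score)
  # maximal score; ties toward smaller (bC, bM) lexicographically -- grid
  # is already sorted that way
  best <- which(grid$score >= max(grid$score) - 0)[1]
  structure(
    list(
      estimate = grid[best, c("bC", "bM", "score")],
      surface = grid,
      frequencies = tibble::tibble(
        slide_id = cohort$manifest$slide_id,
        response = responses,
        f = fmat[, best]
      ),
      n_sims = n_sims, b = b, seed = seed,
      crn = TRUE
    ),
    class = "ics_fit"
  )
}

rate_params_update <- function(params, ...) {
  upd <- list(...)
  for (nm in names(upd)) params[[nm]] <- upd[[nm]]
  do.call(rate_params, unclass(params))
}

#' @export
print.ics_fit <- function(x, ...) {
  cat(sprintf(
    "<ics_fit> %d-point grid, n_sims = %d per slide per point\n  bC = %g, bM = %g (score %.4g, -log score %.4g)\n",
    nrow(x$surface), x$n_sims, x$estimate$bC, x$estimate$bM,
    x$estimate$score, -log(x$estimate$score)
  ))
  invisible(x)
}
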