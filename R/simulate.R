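#' Kinetic rates of the interacting-cell-system model
#'
#' All rates are per hour. Interaction rates apply per contact pair; the
#' two exhaustion rates `bC` (activated T exhausted by contacting melanoma)
#' and `bM` (activated T exhausted by a same-chamber TAM) are the
#' parameters calibrated against clinical response in
#' [fit_exhaustion_rates()]. Activated-T proliferation and recruitment
#' respond to recent tumor killing: their rates are
#' `r_prolif_T0 + k_prolif * L` (per cell) and `r_recruit0 + k_recruit * L`
#' (slide-wide), where `L` is the number of melanoma cells lysed in the
#' previous completed feedback window of length `dt_feedback`.
#'
#' The defaults are the package's documented placeholder parameterization,
#' chosen to put each process on a biologically plausible scale (melanoma
#' doubling on the order of days, T-cell motility of tens of micrometers
#' per hour); they are not a fit to any dataset.
#'
#' @param r_prolif_mel Melanoma proliferation rate per cell.
#' @param l Lysis rate per (activated T, melanoma) contact pair.
#' @param bC Exhaustion rate per (activated T, melanoma) contact pair.
#' @param bM Exhaustion rate per (activated T, TAM) same-chamber pair.
#' @param r_death_ex Death rate per exhausted T cell.
#' @param r_hop_T,r_hop_M Total hop rate per CD8+ T cell (activated or
#'   exhausted) and per TAM.
#' @param r_prolif_T0,k_prolif Baseline activated-T proliferation rate and
#'   its gain per lysed melanoma cell.
#' @param r_recruit0,k_recruit Baseline slide-wide activated-T recruitment
#'   rate and its gain per lysed melanoma cell.
#' @param dt_feedback Feedback window length (hours).
#' @return An `ics_rate_params` list.
#' @export
#' @examples
#' rate_params(bC = 0.02, bM = 0)
rate_params <- function(r_prolif_mel = 0.02, l = 0.1, bC = 0.05, bM = 0.05,
                        r_death_ex = 0.01, r_hop_T = 1.2, r_hop_M = 1.2,
                        r_prolif_T0 = 0.005, k_prolif = 1e-4,
                        r_recruit0 = 0.5, k_recruit = 1e-2,
                        dt_feedback = 24) {
  p <- list(
    r_prolif_mel = r_prolif_mel, l = l, bC = bC, bM = bM,
    r_death_ex = r_death_ex, r_hop_T = r_hop_T, r_hop_M = r_hop_M,
    r_prolif_T0 = r_prolif_T0, k_prolif = k_prolif,
    r_recruit0 = r_recruit0, k_recruit = k_recruit,
    dt_feedback = dt_feedback
  )
  for (nm in names(p)) assert_number(p[[nm]], nm, lower = 0)
  if (dt_feedback <= 0) abort("dt_feedback must be > 0")
  structure(p, class = c("ics_rate_params", "list"))
}

#' Simulation configuration
#'
#' @param t_end End time in hours. The default 333 h (about two weeks)
#'   spans a cycle of checkpoint-inhibitor therapy.
#' @param record_every Recording interval (hours) for population counts.
#' @param contact Neighborhood defining cell-cell contact across chambers
#'   for lysis and melanoma-induced exhaustion: `"moore8"` (default;
#'   diagonal chamber centers are ~14 um apart, about one cell diameter) or
#'   `"vonneumann4"`.
#' @param hop Neighborhood for diffusive hops: `"vonneumann4"` (default,
#'   standard lattice diffusion) or `"moore8"`.
#' @param cap Chamber capacity override; `NULL` uses the lattice's own cap.
#' @return An `ics_sim_config` list.
#' @export
sim_config <- function(t_end = 333, record_every = 1,
                       contact = c("moore8", "vonneumann4"),
                       hop = c("vonneumann4", "moore8"), cap = NULL) {
  contact <- match.arg(contact)
  hop <- match.arg(hop)
  assert_number(t_end, "t_end")
  if (t_end <= 0) abort("t_end must be > 0")
  assert_number(record_every, "record_every")
  if (record_every <= 0) abort("record_every must be > 0")
  structure(
    list(
      t_end = t_end, record_every = record_every,
      contact = contact, hop = hop, cap = cap
    ),
    class = c("ics_sim_config", "list")
  )
}

#' Simulate the interacting-cell-system model
#'
#' Evolves a lattice initial condition by kinetic Monte Carlo: every
#' enabled event (melanoma proliferation, lysis, exhaustion by melanoma and
#' by TAMs, activated-T proliferation and recruitment with lysis feedback,
#' exhausted-T death, diffusive hops) carries an exponential clock, event
#' waiting times are exponential in the total rate, and blocked
#' proliferation/hop/recruitment attempts are null events. Boundaries are
#' reflecting. Population counts are recorded on the regular grid
#' `0, record_every, ..., t_end` by carrying the last state forward.
#'
#' @param lattice Initial `ics_lattice` (see [slide_to_lattice()] or
#'   [lattice_from_counts()]).
#' @param params `ics_rate_params`.
#' @param config `ics_sim_config`.
#' @param seed Optional integer seed (fixed seed implies an identical
#'   trajectory).
#' @param sample_id Integer identifier stored in the output.
#' @param snapshot_times Numeric vector of times (hours) at which to store
#'   full per-chamber snapshots; retrieve them with `attr(x, "snapshots")`.
#' @return A trajectory tibble (`sample_id`, `time_h`, `n_melanoma`,
#'   `n_t_active`, `n_t_exhausted`, `n_tam`) of class `ics_trajectory`,
#'   with attributes `snapshots`, `n_events` and `total_lysed`.
#' @export
simulate_ics <- function(lattice, params = rate_params(),
                         config = sim_config(), seed = NULL,
                         sample_id = 1L, snapshot_times = numeric(0)) {
  stopifnot(inherits(lattice, "ics_lattice"))
  cap <- config$cap %||% lattice$cap
  occ <- apply(lattice$counts, c(1, 2), sum)
  if (any(occ > cap)) {
    abort("initial state violates chamber capacity")
  }
  res <- with_seed_if(seed, kmc_run(
    lattice$counts[, , "melanoma"], lattice$counts[, , "t_active"],
    lattice$counts[, , "t_exhausted"], lattice$counts[, , "tam"],
    as.integer(cap), unclass(params), config$t_end, config$record_every,
    config$contact == "moore8", config$hop == "moore8",
    as.numeric(snapshot_times)
  ))
  out <- tibble::tibble(
    sample_id = as.integer(sample_id),
    time_h = res$time_h,
    n_melanoma = res$n_melanoma,
    n_t_active = res$n_t_active,
    n_t_exhausted = res$n_t_exhausted,
    n_tam = res$n_tam
  )
  out <- new_trajectory(out)
  attr(out, "snapshots") <- lapply(res$snapshots, function(s) {
    s[c("time_h", ics_cell_types())]
  })
  attr(out, "n_events") <- res$n_events
  attr(out, "total_lysed") <- res$total_lysed
  out
}

#' Simulate an ensemble of independent trajectories
#'
#' Runs `n_sims` stochastic replicates of the same initial condition and
#' stacks them into one long trajectory tibble, the input expected by the
#' ensemble statistics ([ensemble_stats()], [autocorrelation()],
#' [fit_yule()]).
#'
#' @inheritParams simulate_ics
#' @param n_sims Number of replicates.
#' @return An `ics_trajectory` tibble with `sample_id` 1..`n_sims`.
#' @export
simulate_ensemble <- function(lattice, n_sims, params = rate_params(),
                              config = sim_config(), seed = NULL) {
  runs <- with_seed_if(seed, lapply(seq_len(n_sims), function(k) {
    simulate_ics(lattice, params = params, config = config, sample_id = k)
  }))
  new_trajectory(dplyr::bind_rows(runs))
}
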