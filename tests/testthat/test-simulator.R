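zero_rates <- function(...) {
  base <- list(
    r_prolif_mel = 0, l = 0, bC = 0, bM = 0, r_death_ex = 0,
    r_hop_T = 0, r_hop_M = 0, r_prolif_T0 = 0, k_prolif = 0,
    r_recruit0 = 0, k_recruit = 0
  )
  ov <- list(...)
  base[names(ov)] <- ov
  do.call(rate_params, base)
}

test_that("all-zero rates freeze the state", {
  lat <- lattice_from_counts(
    melanoma = matrix(2L, 3, 3), t_active = matrix(1L, 3, 3), cap = 5
  )
  traj <- simulate_ics(lat, zero_rates(), sim_config(t_end = 50, record_every = 10), seed = 1)
  expect_equal(unique(traj$n_melanoma), 18L)
  expect_equal(unique(traj$n_t_active), 9L)
  expect_equal(traj$time_h, seq(0, 50, by = 10))
})

test_that("fixed seed gives a bit-identical trajectory, snapshots conserve capacity", {
  withr::with_seed(5, {
    cells <- csr_slide(
      list(melanoma = 150, t_active = 80, tam = 40),
      width = 300, height = 300
    )
  })
  lat <- slide_to_lattice(cells, width = 300, height = 300, quiet = TRUE)
  cfg <- sim_config(t_end = 60, record_every = 10)
  t1 <- simulate_ics(lat, rate_params(), cfg, seed = 42, snapshot_times = c(30, 60))
  t2 <- simulate_ics(lat, rate_params(), cfg, seed = 42, snapshot_times = c(30, 60))
  expect_equal(as.data.frame(t1), as.data.frame(t2))

  for (snap in attr(t1, "snapshots")) {
    occ <- snap$melanoma + snap$t_active + snap$t_exhausted + snap$tam
    expect_true(all(occ <= lat$cap))
    expect_true(all(occ >= 0))
    # snapshot totals agree with the recorded counts at that time
    k <- which(t1$time_h == snap$time_h)
    expect_equal(sum(snap$melanoma), t1$n_melanoma[k])
    expect_equal(sum(snap$t_exhausted), t1$n_t_exhausted[k])
  }
})

test_that("population counts match the initial slide after rasterization", {
  withr::with_seed(6, {
    cells <- csr_slide(list(melanoma = 90, t_active = 30), width = 200, height = 200)
  })
  lat <- slide_to_lattice(cells, width = 200, height = 200, quiet = TRUE)
  traj <- simulate_ics(lat, zero_rates(), sim_config(t_end = 5), seed = 1)
  expect_equal(traj$n_melanoma[1], 90L)
  expect_equal(traj$n_t_active[1], 30L)
})

test_that("pure lysis decays melanoma as exponential per contact pair", {
  # one activated T pinned next to a chamber of 30 melanoma cells; only l > 0
  m <- matrix(0L, 3, 3)
  m[2, 3] <- 30L
  tt <- matrix(0L, 3, 3)
  tt[2, 2] <- 1L
  lat <- lattice_from_counts(melanoma = m, t_active = tt, cap = 40)
  l <- 0.05
  t_end <- 20
  cfg <- sim_config(t_end = t_end, record_every = t_end)
  withr::with_seed(9, {
    finals <- replicate(500, {
      tr <- simulate_ics(lat, zero_rates(l = l), cfg)
      tr$n_melanoma[2]
    })
  })
  # each melanoma dies independently at rate l: Binomial(30, e^{-l t})
  p_surv <- exp(-l * t_end)
  expect_equal(mean(finals), 30 * p_surv,
    tolerance = 3 * sqrt(30 * p_surv * (1 - p_surv) / 500) / (30 * p_surv)
  )
})

test_that("exhaustion only converts activated T and never helps the tumor die", {
  m <- matrix(0L, 5, 5)
  m[, 1:2] <- 3L
  tt <- matrix(0L, 5, 5)
  tt[, 4] <- 2L
  lat <- lattice_from_counts(melanoma = m, t_active = tt, cap = 6)
  cfg <- sim_config(t_end = 120, record_every = 120)
  p_noex <- zero_rates(l = 0.05, r_hop_T = 0.5)
  p_ex <- zero_rates(l = 0.05, r_hop_T = 0.5, bC = 0.3)
  withr::with_seed(17, {
    pairs <- t(replicate(200, {
      s <- sample.int(1e6, 1)
      a <- simulate_ics(lat, p_ex, cfg, seed = s)
      b <- simulate_ics(lat, p_noex, cfg, seed = s)
      c(with_ex = a$n_melanoma[2], without_ex = b$n_melanoma[2])
    }))
  })
  # strong exhaustion shields the tumor: stochastically more melanoma left
  expect_gt(mean(pairs[, "with_ex"]), mean(pairs[, "without_ex"]))

  # conservation of T lineage when only exhaustion acts: T + E constant
  p_onlyex <- zero_rates(bC = 0.5)
  tr <- simulate_ics(lat, p_onlyex, sim_config(t_end = 50, record_every = 10), seed = 3)
  expect_equal(unique(tr$n_t_active + tr$n_t_exhausted), 10L)
  expect_equal(unique(tr$n_melanoma), 30L)
  # exhausted T only ever increases via exhaustion, monotonically here
  expect_true(all(diff(tr$n_t_exhausted) >= 0))
})

test_that("hops conserve counts and diffuse like a lattice random walk", {
  tt <- matrix(0L, 21, 21)
  tt[11, 11] <- 1L
  lat <- lattice_from_counts(t_active = tt, cap = 4)
  h <- 1.2
  t_end <- 5
  cfg <- sim_config(t_end = t_end, record_every = t_end)
  withr::with_seed(23, {
    d2 <- replicate(400, {
      tr <- simulate_ics(lat, zero_rates(r_hop_T = h), cfg, snapshot_times = t_end)
      pos <- which(attr(tr, "snapshots")[[1]]$t_active > 0, arr.ind = TRUE)
      (pos[1] - 11)^2 + (pos[2] - 11)^2
    })
  })
  # vonneumann4 walk: MSD (chamber^2) = h * t; equivalently 4 D t with
  # D = h l0^2 / 4 in physical units
  expect_equal(mean(d2), h * t_end, tolerance = 4 * sd(d2) / sqrt(400) / (h * t_end))
})

test_that("the incremental engine matches naive full re-enumeration in distribution", {
  counts <- array(0L, c(3, 3, 4))
  counts[, , 1] <- matrix(c(2, 0, 0, 1, 0, 0, 0, 0, 1), 3, 3)
  counts[, , 2] <- matrix(c(0, 1, 0, 0, 1, 0, 0, 0, 0), 3, 3)
  counts[, , 3] <- matrix(c(0, 0, 1, 0, 0, 0, 0, 0, 0), 3, 3)
  counts[, , 4] <- matrix(c(0, 0, 0, 0, 1, 0, 1, 0, 0), 3, 3)
  p <- rate_params(
    r_prolif_mel = 0.03, l = 0.08, bC = 0.06, bM = 0.05, r_death_ex = 0.02,
    r_hop_T = 0.6, r_hop_M = 0.4, r_prolif_T0 = 0.01, k_prolif = 0,
    r_recruit0 = 0.05, k_recruit = 0, dt_feedback = 1e6
  )
  t_end <- 40
  cap <- 4
  n <- 400
  lat <- lattice_from_counts(
    melanoma = counts[, , 1], t_active = counts[, , 2],
    t_exhausted = counts[, , 3], tam = counts[, , 4], cap = cap
  )
  cfg <- sim_config(t_end = t_end, record_every = t_end, cap = cap)
  withr::with_seed(31, {
    fast <- t(replicate(n, {
      tr <- simulate_ics(lat, p, cfg)
      c(tr$n_melanoma[2], tr$n_t_active[2], tr$n_t_exhausted[2], tr$n_tam[2])
    }))
    slow <- t(replicate(n, oracle_kmc_final(counts, p, t_end, cap)))
  })
  for (k in 1:4) {
    se <- sqrt(var(fast[, k]) / n + var(slow[, k]) / n)
    expect_lt(abs(mean(fast[, k]) - mean(slow[, k])), 4 * max(se, 1e-9) + 1e-9)
  }
})

test_that("degenerate inputs are rejected", {
  lat <- lattice_from_counts(melanoma = matrix(3L, 2, 2), cap = 4)
  expect_error(
    simulate_ics(lat, rate_params(), sim_config(t_end = 10, cap = 2)),
    "capacity"
  )
  expect_error(rate_params(l = -1), "l")
  expect_error(sim_config(t_end = 0), "t_end")
  expect_error(lattice_from_counts(melanoma = matrix(9L, 2, 2), cap = 4), "cap")
})
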