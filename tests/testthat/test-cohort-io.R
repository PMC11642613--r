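write_tmp_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  readr::write_csv(df, path)
  path
}

test_that("read_cell_table maps rows to slides and preserves unknown phenotypes", {
  tab <- tibble::tibble(
    slide_id = c("a", "a", "a"), x = c(1, 2, 3), y = c(4, 5, 6),
    cell_type = c("melanoma", "t_active", "B cell")
  )
  cells <- read_cell_table(write_tmp_csv(tab))
  expect_equal(nrow(cells), 3)
  expect_equal(unique(cells$slide_id), "a")
  expect_equal(cells$cell_type[3], "other:B cell")

  # empty table -> zero rows
  empty <- read_cell_table(write_tmp_csv(tab[0, ]))
  expect_equal(nrow(empty), 0)

  # two slides with 5 + 7 rows keep their row counts
  tab2 <- tibble::tibble(
    slide_id = rep(c("s1", "s2"), c(5, 7)),
    x = runif(12, 0, 1000), y = runif(12, 0, 1000), cell_type = "melanoma"
  )
  cells2 <- read_cell_table(write_tmp_csv(tab2))
  expect_equal(as.vector(table(cells2$slide_id)), c(5, 7))
})

test_that("read_cell_table supports column dialects and rejects bad input", {
  tab <- tibble::tibble(
    Image = "a", Xpos = 10, Ypos = 20, phenotype = "melanoma"
  )
  cells <- read_cell_table(
    write_tmp_csv(tab),
    dialect = c(slide_id = "Image", x = "Xpos", y = "Ypos", cell_type = "phenotype")
  )
  expect_equal(cells$x, 10)

  # missing required column
  expect_error(
    read_cell_table(write_tmp_csv(tab[, -2])),
    "missing required column"
  )
  # out-of-bounds coordinate names the row
  bad <- tibble::tibble(slide_id = "a", x = 1200, y = 5, cell_type = "melanoma")
  expect_error(read_cell_table(write_tmp_csv(bad)), "row")
})

test_that("read_cohort attaches labels and reports missing slides", {
  cells <- tibble::tibble(
    slide_id = rep(c("s1", "s2"), each = 3),
    x = runif(6, 0, 1000), y = runif(6, 0, 1000), cell_type = "melanoma"
  )
  man <- tibble::tibble(slide_id = c("s1", "s2"), response = c("responder", "nonresponder"))
  coh <- read_cohort(write_tmp_csv(cells), write_tmp_csv(man))
  expect_s3_class(coh, "ics_cohort")
  expect_equal(coh$n_slides, 2)
  expect_equal(coh$manifest$response, c("responder", "nonresponder"))

  man_bad <- tibble::tibble(slide_id = c("s1", "s3"), response = c("responder", "responder"))
  expect_error(read_cohort(write_tmp_csv(cells), write_tmp_csv(man_bad)), "s3")
})

test_that("trajectory files round-trip losslessly and reject degenerate input", {
  lat <- lattice_from_counts(melanoma = matrix(5L, 2, 2), cap = 10)
  traj <- simulate_ensemble(
    lat, 2,
    params = rate_params(
      r_prolif_mel = 0.01, l = 0, bC = 0, bM = 0, r_death_ex = 0,
      r_hop_T = 0, r_hop_M = 0, r_prolif_T0 = 0, k_prolif = 0,
      r_recruit0 = 0, k_recruit = 0
    ),
    config = sim_config(t_end = 10, record_every = 5, cap = 10), seed = 1
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, path)
  back <- read_trajectory(path)
  cols <- c("sample_id", "time_h", "n_melanoma", "n_t_active", "n_t_exhausted", "n_tam")
  expect_equal(as.data.frame(back), as.data.frame(traj[cols]), ignore_attr = TRUE)
  # 3 time points per sample
  expect_equal(sum(back$sample_id == 1), 3)

  expect_error(write_trajectory(traj[0, ], path), "empty")
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("sample_id,oops\n1,2", bad)
  expect_error(suppressWarnings(read_trajectory(bad)), "malformed")
})

test_that("rasterization follows the half-open floor rule", {
  mk <- function(x, y) {
    tibble::tibble(slide_id = "s", x = x, y = y, cell_type = "melanoma")
  }
  lat <- slide_to_lattice(mk(5, 5), l0 = 10, quiet = TRUE)
  expect_equal(unname(lat$counts[1, 1, "melanoma"]), 1L)

  # x = 10 lies in column 2 (0-based chamber 1), not column 1
  lat2 <- slide_to_lattice(mk(10, 0), l0 = 10, quiet = TRUE)
  expect_equal(unname(lat2$counts[1, 2, "melanoma"]), 1L)
  expect_equal(unname(lat2$counts[1, 1, "melanoma"]), 0L)

  expect_error(slide_to_lattice(mk(5, 5), l0 = 7), "does not divide")
})

test_that("capacity overflow relocates to the nearest free chamber and conserves totals", {
  cells <- tibble::tibble(
    slide_id = "s", x = rep(5, 3), y = rep(5, 3), cell_type = "melanoma"
  )
  expect_message(
    lat <- slide_to_lattice(cells, l0 = 10, cap = 2),
    "relocated 1"
  )
  expect_equal(unname(lat$counts[1, 1, "melanoma"]), 2L)
  # the third cell went to an adjacent chamber; totals conserved
  expect_equal(sum(lat$counts[, , "melanoma"]), 3L)
  moved <- which(lat$counts[, , "melanoma"] > 0, arr.ind = TRUE)
  expect_true(all(abs(moved - 1) <= 1))
  expect_equal(lat$n_relocated, 1L)
})

test_that("rasterization conserves per-type totals for arbitrary slides", {
  withr::with_seed(11, {
    cells <- csr_slide(list(
      melanoma = 120, t_active = 60, t_exhausted = 15, tam = 40,
      `other:stroma` = 25
    ))
  })
  expect_message(lat <- slide_to_lattice(cells, cap = 4), "dropped 25")
  pc <- population_counts(lat)
  expect_equal(pc$n, c(120L, 60L, 15L, 40L))
})

test_that("contact_pairs counts occupancy products over the neighborhood", {
  m <- matrix(0L, 3, 3)
  tt <- matrix(0L, 3, 3)
  tt[1, 1] <- 1L
  m[1, 2] <- 1L
  lat <- lattice_from_counts(melanoma = m, t_active = tt, cap = 4)
  expect_equal(contact_pairs(lat, "t_active", "melanoma", "moore8"), 1)
  expect_equal(contact_pairs(lat, "t_active", "melanoma", "vonneumann4"), 1)

  # product rule in one chamber: 2 T x 3 melanoma = 6 ordered pairs
  m2 <- matrix(0L, 3, 3)
  t2 <- matrix(0L, 3, 3)
  m2[2, 2] <- 3L
  t2[2, 2] <- 2L
  lat2 <- lattice_from_counts(melanoma = m2, t_active = t2, cap = 5)
  expect_equal(contact_pairs(lat2, "t_active", "melanoma", "moore8"), 6)
  expect_equal(contact_pairs(lat2, "t_active", "melanoma", "same"), 6)

  # diagonal contact exists under moore8 only
  m3 <- matrix(0L, 3, 3)
  t3 <- matrix(0L, 3, 3)
  t3[1, 1] <- 1L
  m3[2, 2] <- 1L
  lat3 <- lattice_from_counts(melanoma = m3, t_active = t3, cap = 4)
  expect_equal(contact_pairs(lat3, "t_active", "melanoma", "moore8"), 1)
  expect_equal(contact_pairs(lat3, "t_active", "melanoma", "vonneumann4"), 0)
})
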