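test_that("a hand-traced lattice chain forms one melanoma-touching cluster", {
  m <- matrix(0L, 10, 10)
  e <- matrix(0L, 10, 10)
  m[5, 5] <- 1L
  e[5, 6] <- 1L
  e[5, 7] <- 1L
  e[5, 8] <- 1L
  lat <- lattice_from_counts(melanoma = m, t_exhausted = e, cap = 4)
  cl <- fencing_clusters(lat, mode = "lattice")
  expect_equal(nrow(cl), 1)
  expect_equal(cl$size, 3L)
  expect_true(cl$touches_melanoma)
  expect_equal(fencing_fraction(cl, 3, min_size = 3), 1)
  expect_equal(fencing_fraction(cl, 3, min_size = 4), 0)
})

test_that("isolated point-cloud cells are non-touching singletons", {
  cells <- tibble::tibble(
    slide_id = "s",
    x = c(100, 200, 300, 700), y = c(100, 300, 500, 700),
    cell_type = c(rep("t_exhausted", 3), "melanoma")
  )
  cl <- fencing_clusters(cells, mode = "points", radius = 15)
  expect_equal(cl$size, rep(1L, 3))
  expect_false(any(cl$touches_melanoma))

  # without melanoma, clusters exist but never touch
  chain <- tibble::tibble(
    slide_id = "s", x = c(0, 10, 20, 30), y = 0, cell_type = "t_exhausted"
  )
  cl2 <- fencing_clusters(chain, mode = "points", radius = 15)
  expect_equal(cl2$size, 4L)
  expect_false(any(cl2$touches_melanoma))
  expect_equal(fencing_fraction(cl2, 4), 0)

  # empty input
  expect_equal(nrow(fencing_clusters(chain[0, ], mode = "points")), 0)
  expect_equal(fencing_fraction(fencing_clusters(chain[0, ], mode = "points"), 0), 0)
})

test_that("fraction arithmetic over qualifying clusters", {
  cl <- tibble::tibble(
    cluster_id = 1:3, size = c(3L, 5L, 12L),
    touches_melanoma = c(TRUE, TRUE, FALSE)
  )
  expect_equal(fencing_fraction(cl, 20), 0.4)
})

test_that("cluster decomposition matches union-find brute force in both modes", {
  # point-cloud mode on a 500-cell input
  withr::with_seed(61, {
    cells <- csr_slide(
      list(melanoma = 150, t_exhausted = 250, t_active = 100),
      width = 600, height = 600
    )
  })
  for (radius in c(15, 30)) {
    got <- fencing_clusters(cells, mode = "points", radius = radius)
    ex <- cells[cells$cell_type == "t_exhausted", ]
    mel <- cells[cells$cell_type == "melanoma", ]
    d <- as.matrix(dist(cbind(ex$x, ex$y)))
    comp <- oracle_components(d <= radius)
    dm <- outer(ex$x, mel$x, "-")^2 + outer(ex$y, mel$y, "-")^2
    touch <- apply(dm <= radius^2, 1, any)
    want_sizes <- as.integer(table(comp))
    want_touch <- as.logical(tapply(touch, comp, any))
    expect_equal(
      cluster_signature(got$size, got$touches_melanoma),
      cluster_signature(want_sizes, want_touch)
    )
  }

  # lattice mode: random occupancy, both neighborhoods
  withr::with_seed(62, {
    e <- matrix(rbinom(400, 2, 0.12), 20, 20)
    m <- matrix(rbinom(400, 2, 0.08), 20, 20)
  })
  lat <- lattice_from_counts(melanoma = m, t_exhausted = e, cap = 10)
  for (nb in c("moore8", "vonneumann4")) {
    got <- fencing_clusters(lat, mode = "lattice", neighborhood = nb)
    occ <- which(e > 0, arr.ind = TRUE)
    adj <- if (nb == "moore8") {
      abs(outer(occ[, 1], occ[, 1], "-")) <= 1 &
        abs(outer(occ[, 2], occ[, 2], "-")) <= 1
    } else {
      abs(outer(occ[, 1], occ[, 1], "-")) +
        abs(outer(occ[, 2], occ[, 2], "-")) <= 1
    }
    comp <- oracle_components(adj)
    sizes <- as.integer(tapply(e[occ], comp, sum))
    # brute-force melanoma contact per occupied chamber
    touch_ch <- vapply(seq_len(nrow(occ)), function(i) {
      r <- occ[i, 1]
      cc <- occ[i, 2]
      any(vapply(seq_len(nrow(which(m > 0, arr.ind = TRUE))), function(j) {
        mm <- which(m > 0, arr.ind = TRUE)[j, , drop = FALSE]
        if (nb == "moore8") {
          max(abs(mm[1] - r), abs(mm[2] - cc)) <= 1
        } else {
          abs(mm[1] - r) + abs(mm[2] - cc) <= 1
        }
      }, logical(1)))
    }, logical(1))
    want_touch <- as.logical(tapply(touch_ch, comp, any))
    expect_equal(
      cluster_signature(got$size, got$touches_melanoma),
      cluster_signature(sizes, want_touch)
    )
    expect_equal(sum(got$size), sum(e))
  }
})

test_that("fencing fraction is monotone in min_size and point-cloud radius", {
  withr::with_seed(63, {
    cells <- csr_slide(
      list(melanoma = 100, t_exhausted = 200),
      width = 500, height = 500
    )
  })
  total <- 200
  cl15 <- fencing_clusters(cells, mode = "points", radius = 15)
  fr_by_minsize <- vapply(1:6, function(ms) {
    fencing_fraction(cl15, total, min_size = ms)
  }, numeric(1))
  expect_true(all(diff(fr_by_minsize) <= 0))

  fr_by_radius <- vapply(c(5, 10, 15, 25, 40), function(r) {
    fencing_fraction(fencing_clusters(cells, mode = "points", radius = r), total)
  }, numeric(1))
  expect_true(all(diff(fr_by_radius) >= 0))
  expect_true(all(fr_by_radius >= 0 & fr_by_radius <= 1))
})

test_that("permutations preserve type counts and expose genuine fencing", {
  # exhausted T packed against a melanoma block; the rest of the immune
  # pool spread far away -> observed fraction beats the null
  mel <- tibble::tibble(
    slide_id = "s", x = rep(seq(200, 260, by = 15), each = 5),
    y = rep(seq(200, 260, by = 15), 5), cell_type = "melanoma"
  )
  ex <- tibble::tibble(
    slide_id = "s", x = seq(180, 280, length.out = 12), y = 190,
    cell_type = "t_exhausted"
  )
  withr::with_seed(64, {
    rest <- csr_slide(list(t_active = 120, tam = 60), width = 1000, height = 1000)
  })
  cells <- rbind(mel, ex, rest)
  nul <- fencing_null(cells,
    mode = "points", pool = "immune", n_perm = 200, seed = 65
  )
  expect_gt(nul$observed, mean(nul$null_fractions))
  expect_gt(nul$observed, 0.9)

  # label shuffles conserve every type count: the null fractions are valid
  # fractions and the degenerate pool has zero variance
  expect_true(all(nul$null_fractions >= 0 & nul$null_fractions <= 1))
  only_ex <- rbind(mel, ex)
  nul2 <- fencing_null(only_ex,
    mode = "points", pool = "immune", n_perm = 20, seed = 66
  )
  expect_equal(var(nul2$null_fractions), 0)
  expect_equal(nul2$null_fractions[1], nul2$observed)

  expect_error(fencing_null(mel, mode = "points", pool = "immune"), "empty")
})

test_that("lattice-mode permutation null preserves per-type totals", {
  withr::with_seed(67, {
    e <- matrix(rbinom(100, 1, 0.2), 10, 10)
    a <- matrix(rbinom(100, 1, 0.3), 10, 10)
    m <- matrix(rbinom(100, 1, 0.2), 10, 10)
  })
  lat <- lattice_from_counts(melanoma = m, t_exhausted = e, t_active = a, cap = 5)
  nul <- fencing_null(lat, mode = "lattice", pool = "immune", n_perm = 50, seed = 68)
  expect_length(nul$null_fractions, 50)
  expect_true(all(is.finite(nul$null_fractions)))
  g <- glance(nul)
  expect_equal(g$n_perm, 50)
})
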