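#' Fencing clusters of exhausted CD8+ T cells
#'
#' Decomposes the exhausted CD8+ T cells of a configuration into connected
#' clusters and flags the clusters in contact with melanoma. Two adjacency
#' modes are supported: `"lattice"` for simulator snapshots (cells are
#' adjacent when their chambers are identical or neighbors under
#' `neighborhood`) and `"points"` for imaging-style coordinate tables
#' (cells are adjacent when their centers are within `radius` micrometers).
#' A cluster "touches melanoma" when any member is adjacent, under the same
#' rule, to a melanoma cell. Clusters in contact with melanoma and holding
#' at least `min_size` exhausted T cells are the fencing clusters: walls of
#' spent T cells along tumor boundaries that shield melanoma from active
#' T cells.
#'
#' @param x For `mode = "lattice"`: an `ics_lattice` or one snapshot from
#'   `attr(simulate_ics(...), "snapshots")`. For `mode = "points"`: a cell
#'   tibble for a single slide.
#' @param mode `"lattice"` or `"points"`.
#' @param neighborhood Lattice adjacency, `"moore8"` (default, consistent
#'   with the simulator's contact rule) or `"vonneumann4"`.
#' @param radius Point-cloud adjacency radius in micrometers (default
#'   15, about one nucleus-to-nucleus contact distance).
#' @return Tibble with one row per cluster: `cluster_id`, `size`,
#'   `touches_melanoma`. For point mode an attribute `"members"` holds the
#'   row indices (into the exhausted-T subset) of each cluster.
#' @export
fencing_clusters <- function(x, mode = c("lattice", "points"),
                             neighborhood = c("moore8", "vonneumann4"),
                             radius = 15) {
  mode <- match.arg(mode)
  neighborhood <- match.arg(neighborhood)
  if (mode == "lattice") {
    fencing_clusters_lattice(x, neighborhood)
  } else {
    fencing_clusters_points(x, radius)
  }
}

snapshot_matrices <- function(x) {
  if (inherits(x, "ics_lattice")) {
    list(
      melanoma = x$counts[, , "melanoma"],
      t_exhausted = x$counts[, , "t_exhausted"]
    )
  } else if (is.list(x) && all(c("melanoma", "t_exhausted") %in% names(x))) {
    list(melanoma = x$melanoma, t_exhausted = x$t_exhausted)
  } else {
    abort("lattice mode expects an ics_lattice or a simulator snapshot")
  }
}

fencing_clusters_lattice <- function(x, neighborhood) {
  m <- snapshot_matrices(x)
  E <- m$t_exhausted
  M <- m$melanoma
  occ <- which(E > 0, arr.ind = TRUE)
  if (nrow(occ) == 0) {
    return(empty_cluster_table())
  }
  # chambers holding exhausted T are the nodes; all cells within one
  # chamber are mutually in contact, so cluster size is the summed count
  adj <- chamber_adjacency(occ, neighborhood)
  g <- igraph::make_empty_graph(nrow(occ), directed = FALSE)
  if (nrow(adj) > 0) g <- igraph::add_edges(g, t(adj))
  comp <- igraph::components(g)$membership
  Mnb <- neighborhood_sum(M, neighborhood)
  touch_chamber <- Mnb[occ] > 0
  sizes <- tapply(E[occ], comp, sum)
  touches <- tapply(touch_chamber, comp, any)
  tibble::tibble(
    cluster_id = as.integer(names(sizes)),
    size = as.integer(sizes),
    touches_melanoma = as.logical(touches)
  )
}

# edge list (possibly empty) linking occupied chambers that are lattice
# neighbors; vertices indexed by row of `occ`
chamber_adjacency <- function(occ, neighborhood) {
  n <- nrow(occ)
  if (n == 1) {
    return(matrix(integer(0), ncol = 2))
  }
  dr <- outer(occ[, 1], occ[, 1], "-")
  dc <- outer(occ[, 2], occ[, 2], "-")
  near <- if (neighborhood == "moore8") {
    abs(dr) <= 1 & abs(dc) <= 1
  } else {
    abs(dr) + abs(dc) <= 1
  }
  near[lower.tri(near, diag = TRUE)] <- FALSE
  which(near, arr.ind = TRUE)
}

fencing_clusters_points <- function(cells, radius) {
  ex <- dplyr::filter(cells, .data$cell_type == "t_exhausted")
  mel <- dplyr::filter(cells, .data$cell_type == "melanoma")
  n <- nrow(ex)
  if (n == 0) {
    return(empty_cluster_table())
  }
  d2 <- outer(ex$x, ex$x, "-")^2 + outer(ex$y, ex$y, "-")^2
  near <- d2 <= radius^2
  near[lower.tri(near, diag = TRUE)] <- FALSE
  edges <- which(near, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges) > 0) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  touches_cell <- if (nrow(mel) > 0) {
    dm2 <- outer(ex$x, mel$x, "-")^2 + outer(ex$y, mel$y, "-")^2
    apply(dm2 <= radius^2, 1, any)
  } else {
    rep(FALSE, n)
  }
  sizes <- tapply(rep(1L, n), comp, sum)
  touches <- tapply(touches_cell, comp, any)
  out <- tibble::tibble(
    cluster_id = as.integer(names(sizes)),
    size = as.integer(sizes),
    touches_melanoma = as.logical(touches)
  )
  attr(out, "members") <- split(seq_len(n), comp)
  out
}

empty_cluster_table <- function() {
  tibble::tibble(
    cluster_id = integer(0), size = integer(0), touches_melanoma = logical(0)
  )
}

#' Fencing fraction
#'
#' Fraction of all exhausted CD8+ T cells that sit in melanoma-contacting
#' clusters of at least `min_size` members. Defined as 0 when the
#' configuration holds no exhausted T cells, so the metric can be traced
#' from time zero.
#'
#' @param clusters Cluster table from [fencing_clusters()].
#' @param total_exhausted Total number of exhausted T cells in the
#'   configuration (the clusters partition them).
#' @param min_size Minimum cluster size (default 3).
#' @return A fraction in `[0, 1]`.
#' @export
fencing_fraction <- function(clusters, total_exhausted, min_size = 3) {
  if (total_exhausted == 0) {
    return(0)
  }
  qual <- clusters$touches_melanoma & clusters$size >= min_size
  sum(clusters$size[qual]) / total_exhausted
}

#' Permutation null of the fencing fraction
#'
#' Shuffles the type labels of a pool of cells while keeping every position
#' (and all melanoma cells) fixed, recomputing the fencing fraction for
#' each permutation. The pool is `"immune"` (activated T, exhausted T and
#' TAMs; the natural null for simulator snapshots) or
#' `"all_but_melanoma"` (every non-melanoma cell; the natural null for
#' imaging cell tables). Each permutation preserves the total count of
#' every cell type exactly.
#'
#' @param x Configuration as in [fencing_clusters()].
#' @param mode,neighborhood,radius Adjacency settings, as in
#'   [fencing_clusters()].
#' @param pool `"immune"` or `"all_but_melanoma"`.
#' @param n_perm Number of permutations.
#' @param min_size Minimum fencing cluster size.
#' @param seed Optional integer seed.
#' @return An `ics_fencing_null`: list with `observed`, `null_fractions`,
#'   `n_perm`, `pool`, `min_size`.
#' @export
fencing_null <- function(x, mode = c("lattice", "points"),
                         pool = c("immune", "all_but_melanoma"),
                         n_perm = 200, min_size = 3,
                         neighborhood = c("moore8", "vonneumann4"),
                         radius = 15, seed = NULL) {
  mode <- match.arg(mode)
  pool <- match.arg(pool)
  neighborhood <- match.arg(neighborhood)
  if (mode == "lattice") {
    cells <- lattice_to_cells(x)
  } else {
    cells <- x
  }
  pool_types <- if (pool == "immune") {
    c("t_active", "t_exhausted", "tam")
  } else {
    setdiff(unique(cells$cell_type), "melanoma")
  }
  in_pool <- cells$cell_type %in% pool_types
  if (sum(in_pool) == 0) abort("empty permutation pool")
  n_ex <- sum(cells$cell_type == "t_exhausted")
  observed <- fencing_fraction(
    fencing_clusters(x, mode = mode, neighborhood = neighborhood, radius = radius),
    n_ex, min_size
  )
  nulls <- with_seed_if(seed, vapply(seq_len(n_perm), function(i) {
    perm <- cells
    perm$cell_type[in_pool] <- sample(cells$cell_type[in_pool])
    y <- if (mode == "lattice") cells_to_snapshot(perm, attr(cells, "grid")) else perm
    fencing_fraction(
      fencing_clusters(y, mode = mode, neighborhood = neighborhood, radius = radius),
      n_ex, min_size
    )
  }, numeric(1)))
  structure(
    list(
      observed = observed, null_fractions = nulls, n_perm = n_perm,
      pool = pool, min_size = min_size, mode = mode
    ),
    class = "ics_fencing_null"
  )
}

#' @export
print.ics_fencing_null <- function(x, ...) {
  cat(sprintf(
    "<ics_fencing_null> observed fencing fraction %.3f vs null mean %.3f (%d permutations, pool = %s)\n",
    x$observed, mean(x$null_fractions), x$n_perm, x$pool
  ))
  invisible(x)
}

# expand a lattice/snapshot into one pseudo-cell per individual with its
# chamber coordinates, so label shuffles act on cell slots
lattice_to_cells <- function(x) {
  mats <- if (inherits(x, "ics_lattice")) {
    setNames(lapply(ics_cell_types(), function(tp) x$counts[, , tp]), ics_cell_types())
  } else {
    x[ics_cell_types()]
  }
  rows <- lapply(ics_cell_types(), function(tp) {
    m <- mats[[tp]]
    occ <- which(m > 0, arr.ind = TRUE)
    if (nrow(occ) == 0) {
      return(NULL)
    }
    reps <- m[occ]
    tibble::tibble(
      row = rep(occ[, 1], reps), col = rep(occ[, 2], reps), cell_type = tp
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "grid") <- dim(mats[["melanoma"]])
  out
}

cells_to_snapshot <- function(cells, grid_dim) {
  mats <- lapply(ics_cell_types(), function(tp) {
    m <- matrix(0L, grid_dim[1], grid_dim[2])
    sel <- cells$cell_type == tp
    if (any(sel)) {
      tab <- table(factor(
        (cells$col[sel] - 1) * grid_dim[1] + cells$row[sel],
        levels = seq_len(prod(grid_dim))
      ))
      m[] <- as.integer(tab)
    }
    m
  })
  setNames(mats, ics_cell_types())
}
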