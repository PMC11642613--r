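#' Rasterize a slide onto the chamber grid
#'
#' Maps a point-cloud slide onto the lattice used by the simulator: the
#' slide is divided into `l0` x `l0` micrometer chambers and each cell is
#' assigned to chamber `(floor(y / l0), floor(x / l0))` (half-open
#' convention, so a cell at `x = k * l0` belongs to column `k`). Chambers
#' hold at most `cap` cells in total, reflecting the physical size of the
#' cells relative to a 10-micrometer chamber; cells landing in a full
#' chamber are relocated to the nearest chamber (by center-to-center
#' distance, ties broken in row-major order) with spare capacity, so
#' per-type totals are conserved.
#'
#' @param cells Cell tibble for a single slide.
#' @param l0 Chamber side length (micrometers); must divide both slide
#'   dimensions.
#' @param cap Maximum number of cells per chamber.
#' @param width,height Slide dimensions (micrometers).
#' @param type_map Named character vector mapping observed `cell_type`
#'   labels to the four model types; defaults to the identity on
#'   [ics_cell_types()]. Cells whose label is not mapped are dropped (with
#'   a message reporting how many).
#' @param quiet Suppress messages about dropped and relocated cells.
#' @return An `ics_lattice`: list with `counts` (integer array
#'   `n_rows x n_cols x 4`, third dimension named by cell type), `l0`,
#'   `cap`, `width`, `height`, `n_relocated`, `n_dropped`.
#' @export
slide_to_lattice <- function(cells, l0 = 10, cap = 4, width = 1000,
                             height = 1000, type_map = NULL, quiet = FALSE) {
  if (length(unique(cells$slide_id)) > 1) {
    abort("slide_to_lattice() expects cells from a single slide")
  }
  if (abs(width / l0 - round(width / l0)) > 1e-9 ||
    abs(height / l0 - round(height / l0)) > 1e-9) {
    abort(sprintf("l0 = %g does not divide slide dimensions %g x %g", l0, width, height))
  }
  validate_cells(cells, width = width, height = height)
  types <- ics_cell_types()
  if (is.null(type_map)) {
    type_map <- setNames(types, types)
  }
  mapped <- unname(type_map[cells$cell_type])
  keep <- !is.na(mapped) & mapped %in% types
  n_dropped <- sum(!keep)
  if (n_dropped > 0 && !quiet) {
    inform(sprintf("dropped %d cell(s) with phenotypes outside the model vocabulary", n_dropped))
  }
  n_rows <- as.integer(round(height / l0))
  n_cols <- as.integer(round(width / l0))
  counts <- array(0L, dim = c(n_rows, n_cols, 4), dimnames = list(NULL, NULL, types))
  occ <- matrix(0L, n_rows, n_cols)
  n_reloc <- 0L

  if (any(keep)) {
    rows <- pmin(floor(cells$y[keep] / l0), n_rows - 1L) + 1L
    cols <- pmin(floor(cells$x[keep] / l0), n_cols - 1L) + 1L
    tps <- match(mapped[keep], types)
    for (i in seq_along(rows)) {
      r <- rows[i]
      cc <- cols[i]
      if (occ[r, cc] >= cap) {
        free <- which(occ < cap, arr.ind = TRUE)
        if (nrow(free) == 0) {
          abort("slide has more model cells than total lattice capacity")
        }
        d2 <- (free[, 1] - r)^2 + (free[, 2] - cc)^2
        # ties resolved row-major: which() already enumerates column-major,
        # so order on (distance, row, col) explicitly
        ord <- order(d2, free[, 1], free[, 2])
        r <- free[ord[1], 1]
        cc <- free[ord[1], 2]
        n_reloc <- n_reloc + 1L
      }
      counts[r, cc, tps[i]] <- counts[r, cc, tps[i]] + 1L
      occ[r, cc] <- occ[r, cc] + 1L
    }
  }
  if (n_reloc > 0 && !quiet) {
    inform(sprintf("relocated %d cell(s) from chambers at capacity", n_reloc))
  }
  structure(
    list(
      counts = counts, l0 = l0, cap = as.integer(cap),
      width = width, height = height,
      n_relocated = n_reloc, n_dropped = n_dropped
    ),
    class = "ics_lattice"
  )
}

#' @export
print.ics_lattice <- function(x, ...) {
  n <- population_counts(x)
  cat(sprintf(
    "<ics_lattice> %d x %d chambers (l0 = %g um, cap = %d): %s\n",
    dim(x$counts)[1], dim(x$counts)[2], x$l0, x$cap,
    paste(sprintf("%s=%d", n$cell_type, n$n), collapse = ", ")
  ))
  invisible(x)
}

#' Total population counts on a lattice
#'
#' @param lattice An `ics_lattice`.
#' @return Tibble with columns `cell_type` and `n`.
#' @export
population_counts <- function(lattice) {
  tibble::tibble(
    cell_type = ics_cell_types(),
    n = as.integer(apply(lattice$counts, 3, sum))
  )
}

#' Count contact pairs between two cell types on the lattice
#'
#' Counts ordered pairs (cell of `type_a`, cell of `type_b`) whose chambers
#' are identical or adjacent under the requested neighborhood; the count is
#' the occupancy product summed over chamber pairs, the quantity that
#' multiplies per-pair interaction rates (lysis, exhaustion) in the
#' simulator.
#'
#' @param lattice An `ics_lattice`.
#' @param type_a,type_b Model cell types.
#' @param neighborhood `"moore8"` (default; 8 surrounding chambers plus the
#'   chamber itself), `"vonneumann4"`, or `"same"` (same chamber only).
#' @return Number of ordered pairs.
#' @export
contact_pairs <- function(lattice, type_a, type_b,
                          neighborhood = c("moore8", "vonneumann4", "same")) {
  neighborhood <- match.arg(neighborhood)
  types <- ics_cell_types()
  if (!type_a %in% types || !type_b %in% types) {
    abort("type_a and type_b must be model cell types")
  }
  a <- lattice$counts[, , type_a]
  b <- lattice$counts[, , type_b]
  sum(a * neighborhood_sum(b, neighborhood))
}

# sum of a count matrix over each chamber's neighborhood (self included for
# moore8/vonneumann4; self only for "same"), with reflecting borders simply
# truncated
neighborhood_sum <- function(m, neighborhood) {
  if (neighborhood == "same") {
    return(m)
  }
  offs <- neighborhood_offsets(neighborhood)
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (k in seq_len(nrow(offs))) {
    dr <- offs[k, 1]
    dc <- offs[k, 2]
    src_r <- seq_len(nr) + dr
    src_c <- seq_len(nc) + dc
    ok_r <- src_r >= 1 & src_r <= nr
    ok_c <- src_c >= 1 & src_c <= nc
    out[which(ok_r), which(ok_c)] <- out[which(ok_r), which(ok_c)] +
      m[src_r[ok_r], src_c[ok_c], drop = FALSE]
  }
  out
}

neighborhood_offsets <- function(neighborhood) {
  if (neighborhood == "moore8") {
    as.matrix(expand.grid(dr = -1:1, dc = -1:1))
  } else {
    rbind(c(0, 0), c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  }
}

#' Build a lattice directly from per-chamber count matrices
#'
#' Mostly useful for constructing controlled initial conditions in tests
#' and examples.
#'
#' @param melanoma,t_active,t_exhausted,tam Integer matrices of identical
#'   dimensions (rows = chamber rows). Missing types default to zero.
#' @param l0 Chamber side (micrometers).
#' @param cap Chamber capacity.
#' @return An `ics_lattice`.
#' @export
lattice_from_counts <- function(melanoma = NULL, t_active = NULL,
                                t_exhausted = NULL, tam = NULL,
                                l0 = 10, cap = 4) {
  mats <- list(melanoma, t_active, t_exhausted, tam)
  ref <- Filter(Negate(is.null), mats)
  if (length(ref) == 0) {
    abort("at least one count matrix must be supplied")
  }
  nr <- nrow(ref[[1]])
  nc <- ncol(ref[[1]])
  counts <- array(0L, dim = c(nr, nc, 4), dimnames = list(NULL, NULL, ics_cell_types()))
  for (i in seq_along(mats)) {
    if (is.null(mats[[i]])) next
    m <- mats[[i]]
    if (nrow(m) != nr || ncol(m) != nc) abort("count matrices must share dimensions")
    if (any(m < 0)) abort("counts must be non-negative")
    counts[, , i] <- as.integer(m)
  }
  occ <- apply(counts, c(1, 2), sum)
  if (any(occ > cap)) abort("per-chamber occupancy exceeds cap")
  structure(
    list(
      counts = counts, l0 = l0, cap = as.integer(cap),
      width = nc * l0, height = nr * l0, n_relocated = 0L, n_dropped = 0L
    ),
    class = "ics_lattice"
  )
}
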