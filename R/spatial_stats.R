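#' Per-slide cell-type densities
#'
#' @param cells Cell tibble (one or several slides).
#' @param cell_type Optional character vector of types to report; defaults
#'   to every type observed. Requested types absent from a slide are
#'   reported with density 0.
#' @param width,height Slide dimensions (micrometers).
#' @return Tibble with columns `slide_id`, `cell_type`, `n`,
#'   `density_mm2` (cells per square millimeter).
#' @export
cell_density <- function(cells, cell_type = NULL, width = 1000, height = 1000) {
  if (width <= 0 || height <= 0) abort("slide must have positive area")
  area_mm2 <- width * height / 1e6
  types <- cell_type %||% sort(unique(cells$cell_type))
  slides <- unique(cells$slide_id)
  grid <- tidyr::expand_grid(slide_id = slides, cell_type = types)
  counts <- cells |>
    dplyr::filter(.data$cell_type %in% types) |>
    dplyr::count(.data$slide_id, .data$cell_type)
  grid |>
    dplyr::left_join(counts, by = c("slide_id", "cell_type")) |>
    dplyr::mutate(
      n = dplyr::coalesce(.data$n, 0L),
      density_mm2 = .data$n / area_mm2
    )
}

#' Annulus pair-correlation statistic
#'
#' For each reference cell, target cells whose center-to-center distance
#' falls in the annulus `[R - delta/2, R + delta/2)` are counted and
#' divided by the in-bounds annulus area; the per-reference-cell local
#' densities are averaged, the slide-wide target density is subtracted, and
#' the result is divided by a normalization constant (by convention the
#' mean target-cell count across the cohort's slides). Positive values at a
#' radius mean targets are enriched around references relative to a
#' homogeneous random arrangement, negative values mean avoidance. When
#' reference and target types coincide, each cell is excluded from its own
#' annulus counts.
#'
#' @param cells Cell tibble (one or several slides; the curve is computed
#'   per slide).
#' @param ref_type,target_type Phenotype labels.
#' @param radii Annulus center radii (micrometers), strictly increasing.
#'   The default single radius 10.5 um is about one nearest-neighbor
#'   distance.
#' @param delta Annulus thickness (micrometers, > 0).
#' @param norm_constant Normalization; defaults to the mean target-cell
#'   count across the slides present in `cells`.
#' @param edge_correction If `TRUE` (default) the annulus area is its
#'   geometric intersection with the slide rectangle; otherwise the full
#'   annulus area is used.
#' @param width,height Slide dimensions (micrometers).
#' @return Tibble with columns `slide_id`, `ref_type`, `target_type`, `r`,
#'   `value`.
#' @export
pair_correlation <- function(cells, ref_type, target_type,
                             radii = 10.5, delta = 3, norm_constant = NULL,
                             edge_correction = TRUE, width = 1000,
                             height = 1000) {
  if (delta <= 0) abort("delta must be > 0")
  if (length(radii) == 0 || any(diff(radii) <= 0)) {
    abort("radii must be non-empty and strictly increasing")
  }
  slides <- unique(cells$slide_id)
  if (is.null(norm_constant)) {
    norm_constant <- cells |>
      dplyr::filter(.data$cell_type == target_type) |>
      dplyr::count(.data$slide_id) |>
      dplyr::pull(.data$n) |>
      (\(n) sum(n) / length(slides))()
  }
  if (!is.finite(norm_constant) || norm_constant <= 0) {
    abort("norm_constant must be > 0 (no target cells in the cohort?)")
  }
  purrr::map(slides, function(sid) {
    sl <- dplyr::filter(cells, .data$slide_id == sid)
    refs <- dplyr::filter(sl, .data$cell_type == ref_type)
    tars <- dplyr::filter(sl, .data$cell_type == target_type)
    if (nrow(refs) == 0) {
      abort(sprintf("slide %s has no reference cells of type '%s'", sid, ref_type))
    }
    slide_density <- nrow(tars) / (width * height)
    # n_ref x n_target squared distances
    d2 <- outer(refs$x, tars$x, "-")^2 + outer(refs$y, tars$y, "-")^2
    self_pair <- ref_type == target_type
    vals <- vapply(radii, function(r) {
      r_lo <- max(r - delta / 2, 0)
      r_hi <- r + delta / 2
      counts <- rowSums(d2 >= r_lo^2 & d2 < r_hi^2)
      if (self_pair) {
        # remove each reference cell from its own annulus count when the
        # annulus includes distance zero
        if (r_lo <= 0) counts <- counts - 1
      }
      if (edge_correction) {
        areas <- annulus_area_in_rect(refs$x, refs$y, r_lo, r_hi, width, height)
      } else {
        areas <- rep(pi * (r_hi^2 - r_lo^2), nrow(refs))
      }
      (mean(counts / areas) - slide_density) / norm_constant
    }, numeric(1))
    tibble::tibble(
      slide_id = sid, ref_type = ref_type, target_type = target_type,
      r = radii, value = vals
    )
  }) |>
    dplyr::bind_rows()
}

#' Area of an annulus clipped to the slide rectangle
#'
#' Geometric intersection area of the annulus `[r_lo, r_hi)` centered at
#' `(x, y)` with the rectangle `[0, width] x [0, height]`, vectorized over
#' centers. Used for edge correction of the pair-correlation statistic.
#'
#' @param x,y Annulus centers (micrometers).
#' @param r_lo,r_hi Inner and outer radii.
#' @param width,height Rectangle dimensions.
#' @return Numeric vector of areas (square micrometers).
#' @export
annulus_area_in_rect <- function(x, y, r_lo, r_hi, width, height) {
  disk_area_in_rect(x, y, r_hi, width, height) -
    disk_area_in_rect(x, y, max(r_lo, 0), width, height)
}

disk_area_in_rect <- function(x, y, r, width, height) {
  if (r <= 0) {
    return(rep(0, length(x)))
  }
  # inclusion-exclusion over the four signed quadrant areas relative to the
  # disk center
  F <- function(a, b) sign(a) * sign(b) * quadrant_disk_area(abs(a), abs(b), r)
  F(width - x, height - y) - F(-x, height - y) - F(width - x, -y) + F(-x, -y)
}

# area of the disk of radius r centered at the origin intersected with the
# quadrant rectangle [0, a] x [0, b], a, b >= 0 (vectorized)
quadrant_disk_area <- function(a, b, r) {
  G <- function(x) 0.5 * (x * sqrt(pmax(r^2 - x^2, 0)) + r^2 * asin(pmin(x / r, 1)))
  xa <- pmin(a, r)
  x0 <- ifelse(b >= r, 0, sqrt(pmax(r^2 - b^2, 0)))
  ifelse(
    x0 >= xa,
    pmin(b, r) * xa,
    pmin(b, r) * x0 + G(xa) - G(x0)
  )
}

#' Compare a spatial summary between responders and nonresponders
#'
#' Two-sided test for a difference in means between two groups of per-slide
#' values (densities or pair-correlation values at a chosen radius). The
#' default is Welch's t-test; `"permutation"` uses random label shuffles
#' with the observed absolute mean difference as statistic and add-one
#' smoothing, so identical groups give p = 1.
#'
#' @param values_a,values_b Numeric vectors of per-slide values.
#' @param method `"welch_t"` or `"permutation"`.
#' @param n_perm Number of label shuffles for the permutation test.
#' @param seed Optional integer seed (permutation only).
#' @return One-row tibble: `method`, `statistic`, `p_value`, `mean_a`,
#'   `mean_b`, `n_a`, `n_b`.
#' @export
compare_groups <- function(values_a, values_b,
                           method = c("welch_t", "permutation"),
                           n_perm = 10000, seed = NULL) {
  method <- match.arg(method)
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  n_a <- length(values_a)
  n_b <- length(values_b)
  if (method == "welch_t") {
    if (n_a < 2 || n_b < 2) abort("welch_t needs >= 2 finite values per group")
    tt <- t.test(values_a, values_b)
    stat <- unname(tt$statistic)
    p <- tt$p.value
  } else {
    if (n_a < 1 || n_b < 1) abort("permutation needs >= 1 value per group")
    obs <- abs(mean(values_a) - mean(values_b))
    pooled <- c(values_a, values_b)
    perm <- with_seed_if(seed, vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n_a + n_b, n_a)
      abs(mean(pooled[idx]) - mean(pooled[-idx]))
    }, numeric(1)))
    stat <- obs
    p <- (1 + sum(perm >= obs - 1e-12)) / (n_perm + 1)
  }
  tibble::tibble(
    method = method, statistic = stat, p_value = p,
    mean_a = mean(values_a), mean_b = mean(values_b),
    n_a = n_a, n_b = n_b
  )
}
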