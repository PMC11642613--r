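#' Spatial pattern specifications for synthetic slides
#'
#' Constructors for the three spatial point patterns the generator can
#' emulate, mirroring the motifs seen across patient tissue microarrays:
#' `pattern_uniform()` is complete spatial randomness;
#' `pattern_clustered()` is a Thomas-like parent/offspring process
#' (`n_parents` uniformly placed parents, isotropic Gaussian offspring with
#' standard deviation `offspring_sd` micrometers, out-of-bounds offspring
#' re-drawn so requested counts are exact); `pattern_segregated()` confines
#' a cell type to an axis-aligned rectangular region of the slide.
#'
#' @param n_parents Number of cluster centers.
#' @param offspring_sd Gaussian spread of offspring around their parent
#'   (micrometers, > 0).
#' @param xlim,ylim Region bounds (micrometers); `NULL` means the full
#'   extent of the slide in that axis.
#' @return An `ics_pattern` object.
#' @export
pattern_uniform <- function() {
  structure(list(kind = "uniform"), class = "ics_pattern")
}

#' @rdname pattern_uniform
#' @export
pattern_clustered <- function(n_parents = 5, offspring_sd = 20) {
  if (n_parents < 1) abort("n_parents must be >= 1")
  if (offspring_sd <= 0) abort("offspring_sd must be > 0")
  structure(
    list(kind = "clustered", n_parents = n_parents, offspring_sd = offspring_sd),
    class = "ics_pattern"
  )
}

#' @rdname pattern_uniform
#' @export
pattern_segregated <- function(xlim = NULL, ylim = NULL) {
  structure(
    list(kind = "segregated", xlim = xlim, ylim = ylim),
    class = "ics_pattern"
  )
}

#' Specification of one synthetic slide
#'
#' @param n_melanoma,n_t_active,n_t_exhausted,n_tam Exact per-type cell
#'   counts.
#' @param patterns Named list of [pattern_uniform()]-style objects keyed by
#'   cell type; types without an entry default to uniform.
#' @param width,height Slide dimensions in micrometers (defaults emulate a
#'   1 x 1 mm tissue microarray core).
#' @return An `ics_slide_spec`.
#' @export
slide_spec <- function(n_melanoma = 0, n_t_active = 0, n_t_exhausted = 0,
                       n_tam = 0, patterns = list(), width = 1000,
                       height = 1000) {
  counts <- c(
    melanoma = n_melanoma, t_active = n_t_active,
    t_exhausted = n_t_exhausted, tam = n_tam
  )
  if (any(counts < 0)) abort("cell counts must be >= 0")
  bad <- setdiff(names(patterns), ics_cell_types())
  if (length(bad) > 0) {
    abort(paste0("patterns for unknown cell types: ", paste(bad, collapse = ", ")))
  }
  structure(
    list(counts = counts, patterns = patterns, width = width, height = height),
    class = "ics_slide_spec"
  )
}

#' Generate a synthetic slide
#'
#' Draws cell positions according to the slide specification; the output is
#' a tidy cell table interchangeable with one read from real imaging data.
#' Generation is deterministic under a fixed seed.
#'
#' @param spec An [slide_spec()].
#' @param slide_id Identifier for the generated slide.
#' @param seed Optional integer seed.
#' @return Cell tibble (`slide_id`, `x`, `y`, `cell_type`).
#' @export
#' @examples
#' s <- generate_slide(slide_spec(n_melanoma = 100), seed = 1)
#' nrow(s)
generate_slide <- function(spec, slide_id = "synthetic-1", seed = NULL) {
  stopifnot(inherits(spec, "ics_slide_spec"))
  with_seed_if(seed, {
    parts <- lapply(ics_cell_types(), function(tp) {
      n <- spec$counts[[tp]]
      if (n == 0) {
        return(NULL)
      }
      pat <- spec$patterns[[tp]] %||% pattern_uniform()
      xy <- draw_pattern(pat, n, spec$width, spec$height)
      tibble::tibble(
        slide_id = slide_id, x = xy$x, y = xy$y, cell_type = tp
      )
    })
    dplyr::bind_rows(parts)
  })
}

draw_pattern <- function(pat, n, width, height) {
  switch(pat$kind,
    uniform = list(
      x = runif(n, 0, width) %% width,
      y = runif(n, 0, height) %% height
    ),
    clustered = {
      px <- runif(pat$n_parents, 0, width)
      py <- runif(pat$n_parents, 0, height)
      x <- numeric(n)
      y <- numeric(n)
      need <- seq_len(n)
      while (length(need) > 0) {
        pid <- sample.int(pat$n_parents, length(need), replace = TRUE)
        xx <- rnorm(length(need), px[pid], pat$offspring_sd)
        yy <- rnorm(length(need), py[pid], pat$offspring_sd)
        ok <- xx >= 0 & xx < width & yy >= 0 & yy < height
        x[need[ok]] <- xx[ok]
        y[need[ok]] <- yy[ok]
        need <- need[!ok]
      }
      list(x = x, y = y)
    },
    segregated = {
      xl <- pat$xlim %||% c(0, width)
      yl <- pat$ylim %||% c(0, height)
      if (xl[1] < 0 || xl[2] > width || yl[1] < 0 || yl[2] > height ||
        xl[1] >= xl[2] || yl[1] >= yl[2]) {
        abort("segregated region must be a non-empty rectangle inside the slide")
      }
      list(
        x = pmin(runif(n, xl[1], xl[2]), xl[2] - 1e-9),
        y = pmin(runif(n, yl[1], yl[2]), yl[2] - 1e-9)
      )
    },
    abort("unknown pattern kind")
  )
}

#' Generate a synthetic cohort with response labels
#'
#' Builds `n_slides` synthetic slides and attaches binary clinical response
#' labels, either fixed (`labels` a character vector) or forward-simulated:
#' each slide is rasterized and evolved `n_sims` times under `params`, and
#' the label is the majority fold-change direction (melanoma fold change
#' < 1 in most runs labels the slide `"responder"`). Forward-simulated
#' labeling is a coarse, fast stand-in for the per-slide prediction success
#' frequency used in calibration.
#'
#' @param specs A single [slide_spec()] (recycled) or a list of length
#'   `n_slides`.
#' @param n_slides Number of slides.
#' @param labels Character vector of length `n_slides` with values
#'   `"responder"`/`"nonresponder"`, or `"simulate"` for forward-simulated
#'   labels.
#' @param params,config Simulation settings used when `labels =
#'   "simulate"`.
#' @param n_sims Simulations per slide for forward labeling.
#' @param l0,cap Rasterization settings for forward labeling.
#' @param seed Optional integer seed.
#' @return An `ics_cohort`.
#' @export
generate_cohort <- function(specs, n_slides = NULL, labels = "simulate",
                            params = NULL, config = sim_config(),
                            n_sims = 20, l0 = 10, cap = 4, seed = NULL) {
  if (inherits(specs, "ics_slide_spec")) {
    if (is.null(n_slides)) abort("n_slides is required when a single spec is recycled")
    specs <- rep(list(specs), n_slides)
  }
  n_slides <- length(specs)
  if (n_slides < 1) abort("cohort must contain at least one slide")
  fixed_labels <- !(length(labels) == 1 && identical(labels, "simulate"))
  if (fixed_labels && length(labels) != n_slides) {
    abort("labels must be 'simulate' or one label per slide")
  }
  if (!fixed_labels && is.null(params)) {
    abort("forward-simulated labeling requires rate params")
  }
  with_seed_if(seed, {
    ids <- sprintf("synthetic-%02d", seq_len(n_slides))
    cells <- dplyr::bind_rows(purrr::map2(specs, ids, function(sp, id) {
      generate_slide(sp, slide_id = id)
    }))
    width <- specs[[1]]$width
    height <- specs[[1]]$height
    if (fixed_labels) {
      resp <- labels
    } else {
      resp <- purrr::map2_chr(specs, ids, function(sp, id) {
        if (sp$counts[["melanoma"]] == 0) {
          abort(sprintf("slide %s has zero melanoma cells; fold change undefined", id))
        }
        lat <- slide_to_lattice(
          dplyr::filter(cells, .data$slide_id == id),
          l0 = l0, cap = cap, width = sp$width, height = sp$height, quiet = TRUE
        )
        traj <- simulate_ensemble(lat, n_sims, params = params, config = config)
        fc <- fold_change(traj)$fold_change
        if (mean(fc < 1) > 0.5) "responder" else "nonresponder"
      })
    }
    new_cohort(
      cells, tibble::tibble(slide_id = ids, response = resp),
      width = width, height = height
    )
  })
}

#' Re-seed one cell type's positions uniformly at random
#'
#' Implements the position-randomization perturbation: all cells of
#' `cell_type` are re-placed uniformly at random over the slide while every
#' other cell stays put, so per-type counts are conserved exactly. Applied
#' per slide when `cells` spans several slides.
#'
#' @param cells Cell tibble.
#' @param cell_type Type whose positions are randomized; must be a model
#'   type or a phenotype present in the slide (randomizing a model type
#'   with zero cells is a no-op).
#' @param width,height Slide dimensions (micrometers).
#' @param seed Optional integer seed.
#' @return Cell tibble with the same rows, and new coordinates for the
#'   chosen type.
#' @export
randomize_positions <- function(cells, cell_type, width = 1000, height = 1000,
                                seed = NULL) {
  known <- cell_type %in% ics_cell_types() || cell_type %in% cells$cell_type
  if (!known) {
    abort(sprintf("unknown cell type '%s'", cell_type))
  }
  with_seed_if(seed, {
    idx <- which(cells$cell_type == cell_type)
    cells$x[idx] <- runif(length(idx), 0, width) %% width
    cells$y[idx] <- runif(length(idx), 0, height) %% height
    cells
  })
}
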