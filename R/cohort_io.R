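#' Read a per-cell coordinate table
#'
#' Reads a delimited text file with one row per segmented cell (as exported
#' from IMC/CyCIF-style multiplexed imaging pipelines) into the tidy cell
#' table used throughout the package: one row per cell with columns
#' `slide_id`, `x`, `y` (micrometers, origin at the slide's lower-left
#' corner) and `cell_type`.
#'
#' Phenotype labels outside the model vocabulary ([ics_cell_types()]) are
#' preserved with an `"other:"` prefix so that no cells are silently lost;
#' [slide_to_lattice()] decides later which phenotypes enter the model.
#'
#' @param path Path to a CSV file.
#' @param dialect Optional named character vector mapping the standard
#'   column names to the file's column names, e.g.
#'   `c(x = "X_position", y = "Y_position")`. Unmentioned columns are
#'   assumed to already carry the standard names.
#' @param width,height Slide dimensions in micrometers; coordinates must lie
#'   in `[0, width)` x `[0, height)`.
#' @return A tibble with columns `slide_id`, `x`, `y`, `cell_type`.
#' @seealso [read_cohort()] to attach clinical response labels.
#' @export
read_cell_table <- function(path, dialect = NULL, width = 1000, height = 1000) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  std <- c("slide_id", "x", "y", "cell_type")
  nm <- setNames(std, std)
  if (!is.null(dialect)) {
    bad <- setdiff(names(dialect), std)
    if (length(bad) > 0) {
      abort(paste0("unknown dialect keys: ", paste(bad, collapse = ", ")))
    }
    nm[names(dialect)] <- dialect
  }
  missing <- setdiff(unname(nm), names(raw))
  if (length(missing) > 0) {
    abort(paste0(
      "cell table is missing required column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  cells <- tibble::tibble(
    slide_id = as.character(raw[[nm[["slide_id"]]]]),
    x = as.numeric(raw[[nm[["x"]]]]),
    y = as.numeric(raw[[nm[["y"]]]]),
    cell_type = as.character(raw[[nm[["cell_type"]]]])
  )
  validate_cells(cells, width = width, height = height)
  known <- cells$cell_type %in% ics_cell_types() |
    startsWith(cells$cell_type, "other:")
  cells$cell_type[!known] <- paste0("other:", cells$cell_type[!known])
  cells
}

validate_cells <- function(cells, width, height) {
  if (nrow(cells) == 0) {
    return(invisible(cells))
  }
  if (any(is.na(cells$slide_id)) || any(!nzchar(cells$cell_type)) ||
    any(is.na(cells$cell_type))) {
    abort("cell table has missing slide_id or empty cell_type values")
  }
  bad <- which(!is.finite(cells$x) | !is.finite(cells$y) |
    cells$x < 0 | cells$x >= width | cells$y < 0 | cells$y >= height)
  if (length(bad) > 0) {
    abort(sprintf(
      "cell coordinates out of bounds [0, %g) x [0, %g) at row(s): %s",
      width, height, paste(head(bad, 5), collapse = ", ")
    ))
  }
  invisible(cells)
}

#' Read a cohort: cell table plus clinical response manifest
#'
#' Combines a per-cell coordinate table with a manifest mapping each slide
#' to the patient's binary clinical response under immune checkpoint
#' inhibitor therapy (`"responder"` or `"nonresponder"`, as scored by
#' immune-related response criteria).
#'
#' @param cells_path Path to the cell table CSV (see [read_cell_table()]).
#' @param manifest_path Path to a CSV with columns `slide_id` and
#'   `response`.
#' @param dialect,width,height Passed to [read_cell_table()].
#' @return An `ics_cohort` object: a list with elements `cells` (tibble,
#'   restricted to manifest slides), `manifest` (tibble), `n_slides`,
#'   `width`, `height`.
#' @export
read_cohort <- function(cells_path, manifest_path, dialect = NULL,
                        width = 1000, height = 1000) {
  cells <- read_cell_table(cells_path, dialect = dialect, width = width, height = height)
  manifest <- readr::read_csv(manifest_path, show_col_types = FALSE, progress = FALSE)
  new_cohort(cells, manifest, width = width, height = height)
}

#' Assemble a cohort from in-memory tables
#'
#' @param cells Cell tibble (`slide_id`, `x`, `y`, `cell_type`).
#' @param manifest Tibble with columns `slide_id`, `response`.
#' @param width,height Slide dimensions (micrometers).
#' @return An `ics_cohort` object.
#' @export
new_cohort <- function(cells, manifest, width = 1000, height = 1000) {
  need <- setdiff(c("slide_id", "response"), names(manifest))
  if (length(need) > 0) {
    abort(paste0("manifest is missing column(s): ", paste(need, collapse = ", ")))
  }
  manifest <- tibble::as_tibble(manifest)
  manifest$slide_id <- as.character(manifest$slide_id)
  bad_resp <- setdiff(unique(manifest$response), c("responder", "nonresponder"))
  if (length(bad_resp) > 0) {
    abort(paste0(
      "manifest responses must be 'responder' or 'nonresponder'; got: ",
      paste(bad_resp, collapse = ", ")
    ))
  }
  if (anyDuplicated(manifest$slide_id)) {
    abort("manifest has duplicated slide_id values")
  }
  absent <- setdiff(manifest$slide_id, unique(cells$slide_id))
  if (length(absent) > 0) {
    abort(paste0(
      "manifest slide(s) absent from cell table: ",
      paste(absent, collapse = ", ")
    ))
  }
  cells <- dplyr::filter(cells, .data$slide_id %in% manifest$slide_id)
  structure(
    list(
      cells = cells, manifest = manifest, n_slides = nrow(manifest),
      width = width, height = height
    ),
    class = "ics_cohort"
  )
}

#' @export
print.ics_cohort <- function(x, ...) {
  cat(sprintf(
    "<ics_cohort> %d slides (%d responder, %d nonresponder), %d cells, %g x %g um\n",
    x$n_slides, sum(x$manifest$response == "responder"),
    sum(x$manifest$response == "nonresponder"),
    nrow(x$cells), x$width, x$height
  ))
  invisible(x)
}

#' Write / read a simulated trajectory
#'
#' Trajectories are stored as plain CSV with columns `sample_id`, `time_h`,
#' `n_melanoma`, `n_t_active`, `n_t_exhausted`, `n_tam`; the round trip is
#' lossless.
#'
#' @param traj Trajectory tibble as returned by [simulate_ics()] or
#'   [simulate_ensemble()].
#' @param path Output file path.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns the trajectory tibble.
#' @export
write_trajectory <- function(traj, path) {
  cols <- trajectory_columns()
  if (!all(cols %in% names(traj))) {
    abort(paste0("trajectory must have columns: ", paste(cols, collapse = ", ")))
  }
  if (nrow(traj) == 0) {
    abort("refusing to write an empty trajectory")
  }
  readr::write_csv(traj[cols], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  out <- readr::read_csv(
    path,
    col_types = readr::cols(
      sample_id = readr::col_integer(),
      time_h = readr::col_double(),
      n_melanoma = readr::col_integer(),
      n_t_active = readr::col_integer(),
      n_t_exhausted = readr::col_integer(),
      n_tam = readr::col_integer()
    ),
    progress = FALSE
  )
  missing <- setdiff(trajectory_columns(), names(out))
  if (length(missing) > 0) {
    abort(paste0("malformed trajectory file; missing: ", paste(missing, collapse = ", ")))
  }
  new_trajectory(tibble::as_tibble(out))
}

trajectory_columns <- function() {
  c("sample_id", "time_h", "n_melanoma", "n_t_active", "n_t_exhausted", "n_tam")
}

new_trajectory <- function(df) {
  class(df) <- unique(c("ics_trajectory", class(df)))
  df
}
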