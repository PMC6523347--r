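# Data model and tabular I/O for grid-based TMS motor maps.
#
# A map is a rectangular grid of square cells; each cell holds an ordered
# sample of MEP peak-to-peak amplitudes (microvolt). Responses below the
# detection threshold theta (default 50 uV) are unrecordable: they are stored
# as left-censored observations whose true amplitude lies in [0, theta).

#' Stimulation grid geometry
#'
#' Describes a rectangular grid of square stimulation cells. Cell indices are
#' 0-based `(row, col)`; the centre of cell `(r, c)` is
#' `origin_xy_mm + cell_side_mm * (c, r)`, i.e. x grows with column and y with
#' row. The default geometry is the 7 x 7 grid of 7.63 mm cells used with the
#' Nexstim grid tool (53 mm side at 20 mm peeling depth).
#'
#' @param n_rows,n_cols grid dimensions (counts, >= 1).
#' @param cell_side_mm side of a square cell in mm (> 0).
#' @param origin_xy_mm numeric length-2: centre of cell (0, 0) in mm. The
#'   default centres the whole grid on the origin (the hotspot).
#' @param peeling_depth_mm informational metadata: depth (mm) at which targets
#'   are projected onto the cortex by the navigation system.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec()
#' g$cell_side_mm^2 # cell area in mm^2
#' @export
grid_spec <- function(n_rows = 7L, n_cols = 7L, cell_side_mm = 7.63,
                      origin_xy_mm = NULL, peeling_depth_mm = 20) {
  if (!is_count(n_rows) || !is_count(n_cols))
    stop_usage("n_rows and n_cols must be integers >= 1")
  if (!is_scalar_num(cell_side_mm) || cell_side_mm <= 0)
    stop_usage("cell_side_mm must be a positive length in mm")
  if (is.null(origin_xy_mm)) {
    origin_xy_mm <- -cell_side_mm * c((n_cols - 1) / 2, (n_rows - 1) / 2)
  }
  if (length(origin_xy_mm) != 2L || !all(is.finite(origin_xy_mm)))
    stop_usage("origin_xy_mm must be a finite length-2 coordinate")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 cell_side_mm = as.numeric(cell_side_mm),
                 origin_xy_mm = as.numeric(origin_xy_mm),
                 peeling_depth_mm = as.numeric(peeling_depth_mm)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells, side %.4g mm (area %.4g mm^2)\n",
              x$n_rows, x$n_cols, x$cell_side_mm, x$cell_side_mm^2))
  invisible(x)
}

n_cells <- function(grid) grid$n_rows * grid$n_cols

cell_area <- function(grid) grid$cell_side_mm^2

# Row-major linear index of 0-based (row, col).
cell_index <- function(grid, row, col) row * grid$n_cols + col + 1L

#' Cell-centre coordinates of a grid
#'
#' @param grid a [grid_spec()].
#' @return A matrix with one row per cell in row-major order and columns
#'   `row`, `col` (0-based indices), `x_mm`, `y_mm`.
#' @export
cell_centers <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  row <- rep(seq_len(grid$n_rows) - 1L, each = grid$n_cols)
  col <- rep(seq_len(grid$n_cols) - 1L, times = grid$n_rows)
  cbind(row = row, col = col,
        x_mm = grid$origin_xy_mm[1] + col * grid$cell_side_mm,
        y_mm = grid$origin_xy_mm[2] + row * grid$cell_side_mm)
}

# ---- maps -------------------------------------------------------------------

new_cell <- function(amplitude_uV, censored) {
  list(amplitude_uV = as.numeric(amplitude_uV), censored = as.logical(censored))
}

validate_cell <- function(cell, threshold_uV, where = "cell") {
  amp <- cell$amplitude_uV; cen <- cell$censored
  if (length(amp) != length(cen))
    stop_usage("%s: amplitude and censored flags differ in length", where)
  if (any(!cen & (!is.finite(amp) | amp < threshold_uV)))
    stop_usage(paste0(
      "%s: uncensored amplitude below the detection threshold (%g uV); ",
      "responses below threshold must be recorded as censored"),
      where, threshold_uV)
  invisible(cell)
}

#' Construct a grid-based TMS map
#'
#' @param grid a [grid_spec()].
#' @param cells list of length `n_rows * n_cols` in row-major cell order; each
#'   element a list with numeric `amplitude_uV` (NA where censored) and
#'   logical `censored` of equal length, in stimulation order.
#' @param subject_id,session_id labels.
#' @param intensity_meta free-text stimulation-intensity metadata.
#' @param threshold_uV detection threshold used to validate uncensored
#'   amplitudes (default 50).
#' @return An object of class `tms_map`.
#' @export
tms_map <- function(grid, cells, subject_id = "S1", session_id = "1",
                    intensity_meta = "", threshold_uV = 50) {
  stopifnot(inherits(grid, "grid_spec"))
  if (length(cells) != n_cells(grid))
    stop_usage("expected %d cells, got %d", n_cells(grid), length(cells))
  cc <- cell_centers(grid)
  for (i in seq_along(cells)) {
    validate_cell(cells[[i]], threshold_uV,
                  sprintf("cell (%d,%d)", cc[i, "row"], cc[i, "col"]))
  }
  structure(list(grid = grid, cells = cells,
                 subject_id = as.character(subject_id),
                 session_id = as.character(session_id),
                 intensity_meta = as.character(intensity_meta)),
            class = "tms_map")
}

#' @export
print.tms_map <- function(x, ...) {
  ns <- vapply(x$cells, function(ce) length(ce$censored), integer(1))
  cat(sprintf("<tms_map> subject %s session %s: %d x %d grid, %d stimuli (%s per cell)\n",
              x$subject_id, x$session_id, x$grid$n_rows, x$grid$n_cols,
              sum(ns), if (length(unique(ns)) == 1L) ns[1] else
                paste0(min(ns), "-", max(ns))))
  invisible(x)
}

map_is_complete <- function(map) {
  all(vapply(map$cells, function(ce) length(ce$censored), integer(1)) >= 1L)
}

assert_complete <- function(map) {
  ns <- vapply(map$cells, function(ce) length(ce$censored), integer(1))
  if (any(ns == 0L)) {
    cc <- cell_centers(map$grid)
    i <- which(ns == 0L)[1]
    stop_usage("map %s/%s is incomplete: cell (%d,%d) has no samples",
               map$subject_id, map$session_id, cc[i, "row"], cc[i, "col"])
  }
  invisible(map)
}

#' Point-cloud (gridless) TMS map
#'
#' Stimulation points placed adaptively without a grid; each point carries one
#' stimulus outcome. The hotspot is the point with the maximal uncensored
#' amplitude (ties broken by lowest index).
#'
#' @param x_mm,y_mm point coordinates (mm).
#' @param amplitude_uV MEP amplitudes (NA where censored).
#' @param censored logical censoring flags.
#' @param subject_id,muscle labels.
#' @param threshold_uV detection threshold for validation.
#' @return An object of class `point_map`.
#' @export
point_map <- function(x_mm, y_mm, amplitude_uV, censored,
                      subject_id = "S1", muscle = "APB", threshold_uV = 50) {
  n <- length(x_mm)
  if (length(y_mm) != n || length(amplitude_uV) != n || length(censored) != n)
    stop_usage("point_map: coordinate/amplitude/censored lengths differ")
  pm <- structure(list(x_mm = as.numeric(x_mm), y_mm = as.numeric(y_mm),
                       amplitude_uV = as.numeric(amplitude_uV),
                       censored = as.logical(censored),
                       subject_id = as.character(subject_id),
                       muscle = as.character(muscle)),
                  class = "point_map")
  validate_cell(list(amplitude_uV = pm$amplitude_uV, censored = pm$censored),
                threshold_uV, sprintf("point_map %s/%s", subject_id, muscle))
  pm
}

#' @export
print.point_map <- function(x, ...) {
  cat(sprintf("<point_map> subject %s muscle %s: %d points (%d suprathreshold)\n",
              x$subject_id, x$muscle, length(x$x_mm), sum(!x$censored)))
  invisible(x)
}

#' Collection of maps keyed by (subject, session)
#'
#' @param maps list of [tms_map()] objects. Keys `subject|session` must be
#'   unique and all maps of one subject must share a grid geometry.
#' @return An object of class `session_set` (a named list of maps).
#' @export
session_set <- function(maps = list()) {
  keys <- vapply(maps, function(m) paste(m$subject_id, m$session_id, sep = "|"),
                 character(1))
  if (anyDuplicated(keys))
    stop_usage("duplicate (subject, session) keys: %s",
               paste(unique(keys[duplicated(keys)]), collapse = ", "))
  subj <- vapply(maps, function(m) m$subject_id, character(1))
  for (s in unique(subj)) {
    gs <- lapply(maps[subj == s], function(m) m$grid)
    if (length(unique(vapply(gs, function(g) paste(unlist(g), collapse = ","),
                             character(1)))) > 1L)
      stop_usage("subject %s: sessions use different grid geometries", s)
  }
  names(maps) <- keys
  structure(maps, class = "session_set")
}

#' @export
print.session_set <- function(x, ...) {
  cat(sprintf("<session_set> %d map(s): %s\n", length(x),
              paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Subset the maps of one subject, ordered by session label
#' @param set a [session_set()].
#' @param subject_id subject label.
#' @return A list of `tms_map` in session order.
#' @export
subject_maps <- function(set, subject_id) {
  stopifnot(inherits(set, "session_set"))
  m <- Filter(function(x) x$subject_id == subject_id, unclass(set))
  m[order(vapply(m, function(x) x$session_id, character(1)))]
}

#' Analysis configuration
#'
#' Bundles the tunable constants of the pipeline: detection threshold
#' `theta` (50 uV), bootstrap replicate count `B` (1000), significance level
#' (0.05, uncorrected), histogram bin count for overlaps, master seed, and the
#' simulated stimuli-per-cell range (1..10).
#'
#' @param threshold_uV detection threshold in uV (> 0).
#' @param n_boot bootstrap replicates B (>= 1).
#' @param alpha significance level in (0, 1).
#' @param n_bins histogram bins for distribution overlap (>= 2).
#' @param seed master RNG seed or NULL.
#' @param k_range integer vector of stimuli-per-cell values.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(threshold_uV = 50, n_boot = 1000, alpha = 0.05,
                            n_bins = 30, seed = NULL, k_range = 1:10) {
  if (!is_scalar_num(threshold_uV) || threshold_uV <= 0)
    stop_usage("threshold_uV must be > 0")
  if (!is_count(n_boot)) stop_usage("n_boot must be an integer >= 1")
  if (!is_scalar_num(alpha) || alpha <= 0 || alpha >= 1)
    stop_usage("alpha must be in (0, 1)")
  if (!is_count(n_bins, min = 2L)) stop_usage("n_bins must be >= 2")
  if (!all(vapply(k_range, is_count, logical(1))))
    stop_usage("k_range must contain integers >= 1")
  structure(list(threshold_uV = threshold_uV, n_boot = as.integer(n_boot),
                 alpha = alpha, n_bins = as.integer(n_bins),
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 k_range = as.integer(k_range)),
            class = "analysis_config")
}

# ---- tabular I/O ------------------------------------------------------------

map_table_cols <- c("subject", "session", "row", "col", "stim_index",
                    "amplitude_uV", "censored")

#' Read a session set from a delimited map table
#'
#' The table is comma-separated with a header row and columns `subject`,
#' `session`, `row`, `col`, `stim_index`, `amplitude_uV`, `censored` (0/1);
#' optional `x_mm`/`y_mm` columns are ignored on input (the grid geometry is
#' authoritative). Samples are ordered by `stim_index` within each cell.
#'
#' @param path file path.
#' @param grid a [grid_spec()] shared by all maps in the table.
#' @param threshold_uV detection threshold used for validation (default 50).
#' @return A [session_set()].
#' @export
read_map_table <- function(path, grid, threshold_uV = 50) {
  stopifnot(inherits(grid, "grid_spec"))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(map_table_cols, names(tab))
  if (length(missing_cols))
    stop_usage("map table %s lacks required column(s): %s", path,
               paste(missing_cols, collapse = ", "))
  if (nrow(tab) == 0L) return(session_set(list()))
  tab$censored <- as.logical(tab$censored)
  bad <- which(!tab$censored &
                 (!is.finite(tab$amplitude_uV) | tab$amplitude_uV < threshold_uV))
  if (length(bad))
    stop_usage("uncensored amplitude below threshold %g uV in row(s): %s",
               threshold_uV, paste(utils::head(bad, 20), collapse = ", "))
  if (any(tab$row < 0 | tab$row >= grid$n_rows |
          tab$col < 0 | tab$col >= grid$n_cols))
    stop_usage("cell indices outside the %d x %d grid", grid$n_rows, grid$n_cols)
  maps <- list()
  for (key in unique(paste(tab$subject, tab$session, sep = "|"))) {
    sub <- tab[paste(tab$subject, tab$session, sep = "|") == key, , drop = FALSE]
    sub <- sub[order(sub$row, sub$col, sub$stim_index), , drop = FALSE]
    cells <- rep(list(new_cell(numeric(0), logical(0))), n_cells(grid))
    idx <- cell_index(grid, sub$row, sub$col)
    for (i in unique(idx)) {
      rows <- sub[idx == i, , drop = FALSE]
      amp <- rows$amplitude_uV
      amp[rows$censored] <- NA_real_
      cells[[i]] <- new_cell(amp, rows$censored)
    }
    maps[[key]] <- tms_map(grid, cells, subject_id = sub$subject[1],
                           session_id = as.character(sub$session[1]),
                           threshold_uV = threshold_uV)
  }
  session_set(maps)
}

#' Write a session set to a map table
#'
#' Inverse of [read_map_table()]: amplitudes are written with 17 significant
#' digits so the round-trip reproduces the set exactly. Censored samples are
#' written with an empty amplitude and `censored = 1`.
#'
#' @param set a [session_set()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_map_table <- function(set, path) {
  stopifnot(inherits(set, "session_set"))
  rows <- list()
  for (m in set) {
    cc <- cell_centers(m$grid)
    for (i in seq_along(m$cells)) {
      ce <- m$cells[[i]]
      n <- length(ce$censored)
      if (n == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        subject = m$subject_id, session = m$session_id,
        row = unname(cc[i, "row"]), col = unname(cc[i, "col"]),
        x_mm = unname(cc[i, "x_mm"]), y_mm = unname(cc[i, "y_mm"]),
        stim_index = seq_len(n),
        amplitude_uV = ifelse(ce$censored, "",
                              sprintf("%.17g", ce$amplitude_uV)),
        censored = as.integer(ce$censored),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(data.frame(matrix(nrow = 0, ncol = 9)),
                    c("subject", "session", "row", "col", "x_mm", "y_mm",
                      "stim_index", "amplitude_uV", "censored"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read gridless point maps from a table
#'
#' Columns: `subject`, `muscle`, `x_mm`, `y_mm`, `amplitude_uV`, `censored`.
#'
#' @param path file path.
#' @param threshold_uV detection threshold used for validation.
#' @return A list of [point_map()] objects, one per (subject, muscle).
#' @export
read_point_table <- function(path, threshold_uV = 50) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "muscle", "x_mm", "y_mm", "amplitude_uV", "censored")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop_usage("point table %s lacks required column(s): %s", path,
               paste(missing_cols, collapse = ", "))
  keys <- paste(tab$subject, tab$muscle, sep = "|")
  lapply(stats::setNames(unique(keys), unique(keys)), function(key) {
    sub <- tab[keys == key, , drop = FALSE]
    amp <- sub$amplitude_uV
    amp[as.logical(sub$censored)] <- NA_real_
    point_map(sub$x_mm, sub$y_mm, amp, as.logical(sub$censored),
              subject_id = sub$subject[1], muscle = sub$muscle[1],
              threshold_uV = threshold_uV)
  })
}

#' Write point maps to a table
#' @param point_maps list of [point_map()] objects.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_point_table <- function(point_maps, path) {
  rows <- lapply(point_maps, function(pm) {
    data.frame(subject = pm$subject_id, muscle = pm$muscle,
               x_mm = sprintf("%.17g", pm$x_mm),
               y_mm = sprintf("%.17g", pm$y_mm),
               amplitude_uV = ifelse(pm$censored, "",
                                     sprintf("%.17g", pm$amplitude_uV)),
               censored = as.integer(pm$censored),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- summaries --------------------------------------------------------------

#' Per-cell summary statistics of a map
#'
#' For each grid cell returns the sample count `n`, the suprathreshold count
#' `n_supra` (uncensored and amplitude >= threshold), the suprathreshold
#' probability estimate `p_supra = n_supra / n`, the mean amplitude `mean_uV`
#' (censored samples contribute 0, the conservative convention for
#' left-censored responses), and the maximum `max_uV` (0 when all censored).
#'
#' @param map a complete [tms_map()].
#' @param threshold_uV detection threshold theta (> 0), default 50.
#' @return A data.frame with one row per cell in row-major order and columns
#'   `row`, `col`, `x_mm`, `y_mm`, `n`, `n_supra`, `p_supra`, `mean_uV`,
#'   `max_uV`.
#' @examples
#' m <- simulate_session(excitability_surface(), grid_spec(), seed = 1)
#' head(cell_summaries(m))
#' @export
cell_summaries <- function(map, threshold_uV = 50) {
  stopifnot(inherits(map, "tms_map"))
  if (!is_scalar_num(threshold_uV) || threshold_uV <= 0)
    stop_usage("threshold_uV must be > 0")
  assert_complete(map)
  cc <- cell_centers(map$grid)
  stats_per_cell <- t(vapply(map$cells, function(ce) {
    amp0 <- ifelse(ce$censored, 0, ce$amplitude_uV)
    supra <- !ce$censored & ce$amplitude_uV >= threshold_uV
    c(n = length(amp0), n_supra = sum(supra), mean_uV = mean(amp0),
      max_uV = max(amp0))
  }, numeric(4)))
  data.frame(cc, n = as.integer(stats_per_cell[, "n"]),
             n_supra = as.integer(stats_per_cell[, "n_supra"]),
             p_supra = stats_per_cell[, "n_supra"] / stats_per_cell[, "n"],
             mean_uV = stats_per_cell[, "mean_uV"],
             max_uV = stats_per_cell[, "max_uV"])
}
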