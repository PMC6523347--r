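# Coverage of gridless muscle representations by candidate square grids.
#
# Gridless maps place each stimulation point adaptively, so representation
# extent is unconstrained and the point clouds sample the population size
# distribution. A square grid centered on the hotspot is guaranteed to cover
# a point under any grid orientation only if the point lies within the circle
# inscribed in the square (radius = half the grid side): coverage estimates
# below use that conservative rule.

#' Fraction of a representation covered by a square grid
#'
#' The grid is centered on the hotspot (the point with maximal uncensored
#' amplitude; ties broken by lowest index). A suprathreshold point counts as
#' covered when its distance to the hotspot is at most half the grid side.
#'
#' @param pm a [point_map()] with at least one suprathreshold point.
#' @param grid_side_mm side length of the candidate square grid (mm).
#' @param threshold_uV detection threshold (default 50).
#' @return Fraction in `[0, 1]` of suprathreshold points covered.
#' @export
coverage_fraction <- function(pm, grid_side_mm, threshold_uV = 50) {
  stopifnot(inherits(pm, "point_map"))
  if (!is_scalar_num(grid_side_mm) || grid_side_mm <= 0)
    stop_usage("grid_side_mm must be > 0")
  supra <- !pm$censored & pm$amplitude_uV >= threshold_uV
  supra[is.na(supra)] <- FALSE
  if (!any(supra))
    stop_usage("coverage undefined: map %s/%s has no suprathreshold points",
               pm$subject_id, pm$muscle)
  amp <- ifelse(supra, pm$amplitude_uV, -Inf)
  hot <- which.max(amp) # ties -> lowest index
  d <- sqrt((pm$x_mm - pm$x_mm[hot])^2 + (pm$y_mm - pm$y_mm[hot])^2)
  mean(d[supra] <= grid_side_mm / 2)
}

#' Coverage curve across maps for one grid size
#'
#' For each percentage `X`, the fraction of maps in which at least `X` per
#' cent of the representation is covered by a grid of the given size.
#'
#' @param point_maps list of [point_map()] objects.
#' @param grid_side_mm grid side (mm).
#' @param x_grid_percent percentages at which to evaluate (default 0..100).
#' @param threshold_uV detection threshold.
#' @return An object of class `coverage_curve`: data.frame with columns
#'   `X_percent` and `fraction_of_maps`, plus attribute `grid_side_mm`.
#' @export
coverage_curve <- function(point_maps, grid_side_mm,
                           x_grid_percent = 0:100, threshold_uV = 50) {
  if (!length(point_maps)) stop_usage("need >= 1 point map")
  cov <- vapply(point_maps, coverage_fraction, numeric(1),
                grid_side_mm = grid_side_mm, threshold_uV = threshold_uV)
  frac <- vapply(x_grid_percent, function(X) mean(cov >= X / 100), numeric(1))
  structure(data.frame(X_percent = x_grid_percent, fraction_of_maps = frac),
            grid_side_mm = grid_side_mm, class = c("coverage_curve",
                                                   "data.frame"))
}

#' Mean representation coverage for a set of grid sizes
#'
#' @param point_maps list of [point_map()] objects.
#' @param grid_sides_mm candidate grid sides; the default
#'   `c(38, 46, 53, 61, 69)` mm corresponds to 10-18 cells in the Nexstim
#'   grid tool.
#' @param threshold_uV detection threshold.
#' @return A data.frame with columns `grid_side_mm`, `mean_coverage`
#'   (fraction) and `mean_bias` (`-(1 - mean_coverage)`, the mean relative
#'   area bias due to incomplete coverage).
#' @export
mean_coverage <- function(point_maps, grid_sides_mm = c(38, 46, 53, 61, 69),
                          threshold_uV = 50) {
  if (!length(point_maps)) stop_usage("need >= 1 point map")
  rows <- lapply(grid_sides_mm, function(side) {
    cov <- vapply(point_maps, coverage_fraction, numeric(1),
                  grid_side_mm = side, threshold_uV = threshold_uV)
    data.frame(grid_side_mm = side, mean_coverage = mean(cov),
               mean_bias = -(1 - mean(cov)))
  })
  do.call(rbind, rows)
}
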