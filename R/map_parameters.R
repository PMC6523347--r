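# The eight muscle-representation parameters of a grid-based motor map:
# three thresholded areas, two weighted areas, and three centres of gravity.

area_variants <- c("mean_above", "any_supra", "majority_supra")
weighted_variants <- c("amplitude", "probability")
cog_variants <- c("mean_amplitude", "max_amplitude", "probability")

#' Specify one representation parameter
#'
#' @param family one of `"area"` (thresholded cell-count area),
#'   `"weighted_area"`, `"cog"` (centre of gravity).
#' @param variant for `area`: `"mean_above"` (cells whose mean MEP, censored
#'   counted as 0, is >= threshold), `"any_supra"` (cells with at least one
#'   suprathreshold MEP, equivalently maximum >= threshold),
#'   `"majority_supra"` (cells with more than half suprathreshold MEPs).
#'   For `weighted_area`: `"amplitude"` (map volume) or `"probability"`.
#'   For `cog`: `"mean_amplitude"`, `"max_amplitude"` or `"probability"`.
#' @param threshold_uV detection/qualification threshold theta (default 50).
#' @return An object of class `parameter_spec`.
#' @export
parameter_spec <- function(family = c("area", "weighted_area", "cog"),
                           variant, threshold_uV = 50) {
  family <- match.arg(family)
  valid <- switch(family, area = area_variants,
                  weighted_area = weighted_variants, cog = cog_variants)
  if (missing(variant) || !(variant %in% valid))
    stop_usage("variant for family '%s' must be one of: %s", family,
               paste(valid, collapse = ", "))
  if (!is_scalar_num(threshold_uV) || threshold_uV <= 0)
    stop_usage("threshold_uV must be > 0")
  structure(list(family = family, variant = variant,
                 threshold_uV = threshold_uV),
            class = "parameter_spec")
}

#' @export
print.parameter_spec <- function(x, ...) {
  cat(sprintf("<parameter_spec> %s/%s (threshold %g uV)\n",
              x$family, x$variant, x$threshold_uV))
  invisible(x)
}

spec_label <- function(spec) paste(spec$family, spec$variant, sep = "/")

#' The eight default parameter specifications
#'
#' @param threshold_uV detection threshold (default 50).
#' @return Named list of eight [parameter_spec()] objects.
#' @export
default_parameter_specs <- function(threshold_uV = 50) {
  specs <- c(lapply(area_variants, function(v)
               parameter_spec("area", v, threshold_uV)),
             lapply(weighted_variants, function(v)
               parameter_spec("weighted_area", v, threshold_uV)),
             lapply(cog_variants, function(v)
               parameter_spec("cog", v, threshold_uV)))
  stats::setNames(specs, vapply(specs, spec_label, character(1)))
}

# ---- parameter evaluation from per-cell summaries ---------------------------
# All parameters are functions of the per-cell (n, n_supra, mean, max) only,
# which is what makes the vectorized bootstrap path possible.

area_qualifies <- function(variant, n, n_supra, mean_uV, max_uV, threshold) {
  switch(variant,
         mean_above = mean_uV >= threshold,
         any_supra = n_supra >= 1L,
         majority_supra = n_supra > n / 2,
         stop_usage("unknown area variant '%s'", variant))
}

cog_weights <- function(variant, n, n_supra, mean_uV, max_uV) {
  switch(variant,
         mean_amplitude = mean_uV,
         max_amplitude = max_uV,
         probability = n_supra / n,
         stop_usage("unknown cog variant '%s'", variant))
}

#' Thresholded representation area
#'
#' Cell area times the number of qualifying cells. Qualification per variant:
#' `mean_above` uses the censored-as-zero cell mean >= threshold; `any_supra`
#' needs at least one suprathreshold MEP; `majority_supra` needs strictly more
#' than half of the cell's stimuli suprathreshold (>= 6 of 10; >= 5 of 9),
#' which produces the characteristic even/odd pattern in the stimulus count.
#'
#' @param map a complete [tms_map()].
#' @param variant one of `"mean_above"`, `"any_supra"`, `"majority_supra"`.
#' @param threshold_uV threshold theta in uV.
#' @return Area in mm^2.
#' @export
representation_area <- function(map, variant = "any_supra", threshold_uV = 50) {
  s <- cell_summaries(map, threshold_uV)
  q <- area_qualifies(variant, s$n, s$n_supra, s$mean_uV, s$max_uV, threshold_uV)
  cell_area(map$grid) * sum(q)
}

#' Weighted representation area
#'
#' `amplitude`: sum over all cells of cell area times mean MEP amplitude
#' (map volume, mm^2 uV). `probability`: sum of cell area times the
#' suprathreshold probability estimate (mm^2). No additional thresholding is
#' applied: non-responding cells contribute zero weight anyway.
#'
#' @inheritParams representation_area
#' @param variant `"amplitude"` or `"probability"`.
#' @return Weighted area (mm^2 uV for amplitude, mm^2 for probability).
#' @export
weighted_area <- function(map, variant = "probability", threshold_uV = 50) {
  s <- cell_summaries(map, threshold_uV)
  w <- switch(variant,
              amplitude = s$mean_uV,
              probability = s$p_supra,
              stop_usage("unknown weighted_area variant '%s'", variant))
  cell_area(map$grid) * sum(w)
}

#' Centre of gravity of a map
#'
#' Weighted mean of the cell-centre coordinates, with weights given by the
#' per-cell mean amplitude, maximum amplitude, or suprathreshold probability.
#'
#' @inheritParams representation_area
#' @param weighting `"mean_amplitude"`, `"max_amplitude"` or `"probability"`.
#' @return Named numeric length-2 `c(x_mm, y_mm)`.
#' @export
center_of_gravity <- function(map, weighting = "probability",
                              threshold_uV = 50) {
  s <- cell_summaries(map, threshold_uV)
  w <- cog_weights(weighting, s$n, s$n_supra, s$mean_uV, s$max_uV)
  if (sum(w) == 0)
    stop_usage("COG undefined: all %s weights are zero (fully censored map)",
               weighting)
  c(x_mm = sum(w * s$x_mm) / sum(w), y_mm = sum(w * s$y_mm) / sum(w))
}

#' Evaluate a parameter specification on a map
#'
#' @param map a complete [tms_map()].
#' @param spec a [parameter_spec()].
#' @return A scalar for areas; `c(x_mm, y_mm)` for COGs.
#' @export
map_parameter <- function(map, spec) {
  stopifnot(inherits(spec, "parameter_spec"))
  switch(spec$family,
         area = representation_area(map, spec$variant, spec$threshold_uV),
         weighted_area = weighted_area(map, spec$variant, spec$threshold_uV),
         cog = center_of_gravity(map, spec$variant, spec$threshold_uV))
}

#' All eight representation parameters of a map
#'
#' @param map a complete [tms_map()].
#' @param threshold_uV threshold theta in uV.
#' @return A data.frame with columns `subject`, `session`, `parameter`,
#'   `value`, `unit` (COGs contribute two rows, `cog_*_x_mm` / `cog_*_y_mm`).
#' @export
all_parameters <- function(map, threshold_uV = 50) {
  specs <- default_parameter_specs(threshold_uV)
  rows <- lapply(specs, function(sp) {
    if (sp$family == "cog") {
      cog <- tryCatch(map_parameter(map, sp), error = function(e) c(NA, NA))
      data.frame(parameter = paste0(spec_label(sp), c("_x", "_y")),
                 value = as.numeric(cog), unit = "mm")
    } else {
      unit <- if (sp$family == "weighted_area" && sp$variant == "amplitude")
        "mm^2.uV" else "mm^2"
      data.frame(parameter = spec_label(sp),
                 value = map_parameter(map, sp), unit = unit)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  cbind(subject = map$subject_id, session = map$session_id, out)
}
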