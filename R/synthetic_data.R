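# Synthetic motor-map generator.
#
# Real grid maps show a compact core of cells with near-certain
# suprathreshold responses (probability >= 0.9) surrounded by a fringe of
# intermediate probability, with heavy-tailed (lognormal) MEP amplitudes
# left-censored below the 50 uV detection threshold. The generator emulates
# exactly this: a radially decaying log-median amplitude surface
#   mu(d) = log_mu_peak - d^2 / (2 sigma_mm^2)
# with lognormal trial-to-trial spread log_sigma, which yields the implied
# suprathreshold probability p(d) = 1 - Phi((ln theta - mu(d)) / log_sigma).

#' Generative excitability surface
#'
#' @param center_xy_mm hotspot location (mm), default the origin.
#' @param sigma_mm spatial scale of the excitability decay (> 0). Default
#'   10 mm, giving a high-probability core of roughly 1-2 cell widths and an
#'   intermediate fringe within the default 53 mm grid.
#' @param log_mu_peak natural-log median amplitude at the hotspot. Default
#'   `log(300)`: a median hotspot MEP of 300 uV at 110% RMT, implying
#'   p_supra ~ 0.96 at the centre.
#' @param log_sigma log-scale amplitude spread (> 0). Default 1.0: amplitudes
#'   spanning about two orders of magnitude across trials.
#' @param threshold_uV detection threshold theta (default 50).
#' @return An object of class `excitability_surface`.
#' @export
excitability_surface <- function(center_xy_mm = c(0, 0), sigma_mm = 10,
                                 log_mu_peak = log(300), log_sigma = 1,
                                 threshold_uV = 50) {
  if (length(center_xy_mm) != 2L || !all(is.finite(center_xy_mm)))
    stop_usage("center_xy_mm must be a finite length-2 coordinate")
  if (!is_scalar_num(sigma_mm) || sigma_mm <= 0)
    stop_usage("sigma_mm must be > 0")
  if (!is_scalar_num(log_sigma) || log_sigma <= 0)
    stop_usage("log_sigma must be > 0")
  structure(list(center_xy_mm = as.numeric(center_xy_mm),
                 sigma_mm = sigma_mm, log_mu_peak = log_mu_peak,
                 log_sigma = log_sigma, threshold_uV = threshold_uV),
            class = "excitability_surface")
}

#' @export
print.excitability_surface <- function(x, ...) {
  cat(sprintf(
    "<excitability_surface> centre (%.3g, %.3g) mm, sigma %.3g mm, median peak %.3g uV, p_supra(centre) = %.3f\n",
    x$center_xy_mm[1], x$center_xy_mm[2], x$sigma_mm, exp(x$log_mu_peak),
    surface_probability(x, matrix(x$center_xy_mm, 1))))
  invisible(x)
}

surface_logmu <- function(surface, xy) {
  xy <- matrix(xy, ncol = 2)
  d2 <- (xy[, 1] - surface$center_xy_mm[1])^2 +
    (xy[, 2] - surface$center_xy_mm[2])^2
  surface$log_mu_peak - d2 / (2 * surface$sigma_mm^2)
}

#' Suprathreshold probability of a surface at given locations
#'
#' @param surface an [excitability_surface()].
#' @param xy_mm numeric length-2 coordinate or a 2-column matrix (mm).
#' @return Probability (vector) in (0, 1) that a single stimulus at each
#'   location yields an amplitude >= threshold.
#' @export
surface_probability <- function(surface, xy_mm) {
  stopifnot(inherits(surface, "excitability_surface"))
  mu <- surface_logmu(surface, xy_mm)
  1 - stats::pnorm((log(surface$threshold_uV) - mu) / surface$log_sigma)
}

#' Simulate one grid-mapping session
#'
#' Draws `n_stimuli_per_cell` lognormal amplitudes per cell from the surface
#' evaluated at the cell centre; draws below the threshold are recorded as
#' censored. A 7 x 7 grid with 10 stimuli per cell yields 490 samples, the
#' standard protocol load.
#'
#' @param surface an [excitability_surface()].
#' @param grid a [grid_spec()] (default: 7 x 7, 7.63 mm cells, centred on the
#'   origin).
#' @param n_stimuli_per_cell stimuli per cell (default 10).
#' @param subject_id,session_id labels for the generated map.
#' @param seed optional RNG seed.
#' @return A complete [tms_map()].
#' @export
simulate_session <- function(surface, grid = grid_spec(),
                             n_stimuli_per_cell = 10, subject_id = "S1",
                             session_id = "1", seed = NULL) {
  stopifnot(inherits(surface, "excitability_surface"))
  if (!is_count(n_stimuli_per_cell))
    stop_usage("n_stimuli_per_cell must be an integer >= 1")
  cc <- cell_centers(grid)
  mu <- surface_logmu(surface, cc[, c("x_mm", "y_mm")])
  with_seed_or_not(seed, {
    cells <- lapply(seq_len(nrow(cc)), function(i) {
      amp <- stats::rlnorm(n_stimuli_per_cell, meanlog = mu[i],
                           sdlog = surface$log_sigma)
      cen <- amp < surface$threshold_uV
      amp[cen] <- NA_real_
      new_cell(amp, cen)
    })
    tms_map(grid, cells, subject_id = subject_id, session_id = session_id,
            intensity_meta = "simulated 110% RMT",
            threshold_uV = surface$threshold_uV)
  })
}

#' Between-session drift specification
#'
#' @param mode `"null"` (all sessions share the surface exactly; any
#'   between-session difference is pure sampling noise) or `"drift"`.
#' @param center_shift_mm SD (mm) of the per-session random hotspot
#'   displacement (each coordinate Gaussian).
#' @param gain_shift_log SD of the per-session random shift of the log-median
#'   peak amplitude (excitability gain drift).
#' @return An object of class `drift_spec`.
#' @export
drift_spec <- function(mode = c("null", "drift"), center_shift_mm = 0,
                       gain_shift_log = 0) {
  mode <- match.arg(mode)
  if (mode == "null" && (center_shift_mm != 0 || gain_shift_log != 0))
    stop_usage("mode 'null' requires zero drift scales")
  structure(list(mode = mode, center_shift_mm = center_shift_mm,
                 gain_shift_log = gain_shift_log), class = "drift_spec")
}

#' Simulate a multi-session mapping of one subject
#'
#' Under `mode = "null"` every session is an independent draw from the same
#' surface. Under `mode = "drift"` each session uses a perturbed surface:
#' hotspot translated by a Gaussian vector of SD `center_shift_mm` per
#' coordinate and `log_mu_peak` shifted by a Gaussian draw of SD
#' `gain_shift_log`.
#'
#' @param surface base [excitability_surface()].
#' @param drift a [drift_spec()] (default null).
#' @param n_sessions number of sessions (default 3, consecutive days).
#' @param grid a [grid_spec()].
#' @param n_stimuli_per_cell stimuli per cell (default 10).
#' @param subject_id subject label.
#' @param seed optional RNG seed.
#' @return A [session_set()] with sessions labelled `"1" ... "n"`.
#' @export
simulate_multisession <- function(surface, drift = drift_spec(),
                                  n_sessions = 3, grid = grid_spec(),
                                  n_stimuli_per_cell = 10,
                                  subject_id = "S1", seed = NULL) {
  stopifnot(inherits(surface, "excitability_surface"),
            inherits(drift, "drift_spec"))
  if (!is_count(n_sessions)) stop_usage("n_sessions must be >= 1")
  with_seed_or_not(seed, {
    maps <- lapply(seq_len(n_sessions), function(s) {
      surf_s <- surface
      if (drift$mode == "drift") {
        surf_s$center_xy_mm <- surface$center_xy_mm +
          stats::rnorm(2, 0, drift$center_shift_mm)
        surf_s$log_mu_peak <- surface$log_mu_peak +
          stats::rnorm(1, 0, drift$gain_shift_log)
      }
      simulate_session(surf_s, grid, n_stimuli_per_cell,
                       subject_id = subject_id, session_id = as.character(s))
    })
    session_set(maps)
  })
}

#' Simulate a cohort of subjects
#'
#' Convenience wrapper producing one [session_set()] with `n_sessions`
#' sessions for each of `n_subjects` subjects, all drawn from the same base
#' surface (each subject gets an independent realization).
#'
#' @param n_subjects number of subjects (default 8).
#' @param surface base [excitability_surface()].
#' @param drift a [drift_spec()].
#' @param n_sessions sessions per subject (default 1).
#' @param grid a [grid_spec()].
#' @param n_stimuli_per_cell stimuli per cell (default 10).
#' @param seed optional master seed; subject `i` uses a derived stream.
#' @return A [session_set()] with subjects labelled `"S1" ... "Sn"`.
#' @export
simulate_cohort <- function(n_subjects = 8, surface = excitability_surface(),
                            drift = drift_spec(), n_sessions = 1,
                            grid = grid_spec(), n_stimuli_per_cell = 10,
                            seed = NULL) {
  if (!is_count(n_subjects)) stop_usage("n_subjects must be >= 1")
  maps <- list()
  for (i in seq_len(n_subjects)) {
    sset <- simulate_multisession(surface, drift, n_sessions, grid,
                                  n_stimuli_per_cell,
                                  subject_id = sprintf("S%d", i),
                                  seed = derive_seed(seed, i))
    maps <- c(maps, unclass(sset))
  }
  session_set(maps)
}

#' Simulate gridless adaptive point mapping
#'
#' Emulates the grid-free protocol: the hotspot is stimulated first, then the
#' mapping walks outward along `n_rays` radial directions at `spacing_mm`
#' steps, one stimulus per point, terminating a ray after two consecutive
#' points without a suprathreshold response.
#'
#' @param surface an [excitability_surface()].
#' @param spacing_mm radial step between consecutive points (> 0, default 5).
#' @param n_rays number of equally spaced directions (default 8).
#' @param max_steps safety cap on steps per ray (default 100).
#' @param subject_id,muscle labels.
#' @param seed optional RNG seed.
#' @return A [point_map()].
#' @export
simulate_point_mapping <- function(surface, spacing_mm = 5, n_rays = 8,
                                   max_steps = 100, subject_id = "S1",
                                   muscle = "APB", seed = NULL) {
  stopifnot(inherits(surface, "excitability_surface"))
  if (!is_scalar_num(spacing_mm) || spacing_mm <= 0)
    stop_usage("spacing_mm must be > 0")
  th <- surface$threshold_uV
  draw <- function(xy) stats::rlnorm(1, surface_logmu(surface, xy),
                                     surface$log_sigma)
  with_seed_or_not(seed, {
    xs <- surface$center_xy_mm[1]
    ys <- surface$center_xy_mm[2]
    amps <- draw(surface$center_xy_mm)
    for (r in seq_len(n_rays)) {
      ang <- 2 * pi * (r - 1) / n_rays
      misses <- 0L
      for (step in seq_len(max_steps)) {
        xy <- surface$center_xy_mm + step * spacing_mm * c(cos(ang), sin(ang))
        a <- draw(xy)
        xs <- c(xs, xy[1]); ys <- c(ys, xy[2]); amps <- c(amps, a)
        misses <- if (a < th) misses + 1L else 0L
        if (misses >= 2L) break
      }
    }
    cen <- amps < th
    amps[cen] <- NA_real_
    point_map(xs, ys, amps, cen, subject_id = subject_id, muscle = muscle,
              threshold_uV = th)
  })
}
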