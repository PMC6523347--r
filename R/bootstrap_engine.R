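# Bootstrap simulation of mapping with k stimuli per cell.
#
# Resampling the measured amplitudes with replacement simulates maps that
# would have been obtained with any number of stimuli per cell (not
# necessarily smaller than the measured ten). The spread and mean of a
# representation parameter over B such maps yield its normalized bias
#   Bnorm(P) = (mean(P) - P0) / P0,
# coefficient of variation CV(P) = std(P) / mean(P), the between-session
# variability index V(P) = (Pmax - Pmin) / (Pmax + Pmin) averaged over
# bootstrap triples, and the mean COG displacement in mm.

# Uniform-n matrix representation of a map, or NULL when cells have ragged
# sample counts (then the per-cell fallback path is used).
map_matrices <- function(map, threshold_uV) {
  ns <- lengths(lapply(map$cells, `[[`, "censored"))
  if (length(unique(ns)) != 1L || ns[1] == 0L) return(NULL)
  n <- ns[1]
  amp <- vapply(map$cells, function(ce)
    ifelse(ce$censored, 0, ce$amplitude_uV), numeric(n))
  supra <- vapply(map$cells, function(ce)
    !ce$censored & ce$amplitude_uV >= threshold_uV, logical(n))
  supra[is.na(supra)] <- FALSE
  dim(amp) <- c(n, length(map$cells))
  dim(supra) <- c(n, length(map$cells))
  list(amp0 = amp, supra = supra, n = n)
}

# Per-cell summary stats (mean, max, n_supra) for B bootstrap replicates at k
# stimuli per cell. Returns C x B matrices. Consumes the ambient RNG stream.
boot_cell_stats <- function(map, k, B, threshold_uV) {
  C <- n_cells(map$grid)
  mm <- map_matrices(map, threshold_uV)
  if (!is.null(mm)) {
    idx <- sample.int(mm$n, k * C * B, replace = TRUE)
    offset <- rep((rep(seq_len(C), times = B) - 1L) * mm$n, each = k)
    vals <- mm$amp0[idx + offset]
    sup <- mm$supra[idx + offset]
    dim(vals) <- c(k, C * B)
    meanv <- .colMeans(vals, k, C * B)
    pv <- .colMeans(matrix(sup, k, C * B), k, C * B)
    maxv <- if (k == 1L) vals[1L, ] else
      do.call(pmax, lapply(seq_len(k), function(i) vals[i, ]))
  } else {
    # ragged cell counts: resample cell by cell (rare; operator-error maps)
    meanv <- pv <- maxv <- matrix(0, C, B)
    for (ci in seq_len(C)) {
      ce <- map$cells[[ci]]
      n <- length(ce$censored)
      if (n == 0L) stop_usage("cell %d has no samples", ci)
      amp0 <- ifelse(ce$censored, 0, ce$amplitude_uV)
      sup <- !ce$censored & ce$amplitude_uV >= threshold_uV
      sup[is.na(sup)] <- FALSE
      idx <- matrix(sample.int(n, k * B, replace = TRUE), k, B)
      meanv[ci, ] <- .colMeans(matrix(amp0[idx], k, B), k, B)
      pv[ci, ] <- .colMeans(matrix(sup[idx], k, B), k, B)
      maxv[ci, ] <- apply(matrix(amp0[idx], k, B), 2, max)
    }
    return(list(mean = meanv, p = pv, max = maxv, k = k))
  }
  list(mean = matrix(meanv, C, B), p = matrix(pv, C, B),
       max = matrix(maxv, C, B), k = k)
}

# Parameter values for all B replicates from bootstrap cell stats.
# Scalar families give a length-B vector; cog gives a B x 2 matrix with NA
# rows where all weights vanished.
param_from_stats <- function(stats, spec, grid) {
  ca <- cell_area(grid)
  th <- spec$threshold_uV
  k <- stats$k
  if (spec$family == "area") {
    q <- switch(spec$variant,
                mean_above = stats$mean >= th,
                any_supra = stats$p > 0,
                majority_supra = stats$p > 0.5)
    return(ca * .colSums(q, nrow(q), ncol(q)))
  }
  if (spec$family == "weighted_area") {
    w <- switch(spec$variant, amplitude = stats$mean, probability = stats$p)
    return(ca * .colSums(w, nrow(w), ncol(w)))
  }
  # cog
  cc <- cell_centers(grid)
  w <- switch(spec$variant, mean_amplitude = stats$mean,
              max_amplitude = stats$max, probability = stats$p)
  sw <- .colSums(w, nrow(w), ncol(w))
  out <- cbind(x_mm = .colSums(w * cc[, "x_mm"], nrow(w), ncol(w)) / sw,
               y_mm = .colSums(w * cc[, "y_mm"], nrow(w), ncol(w)) / sw)
  out[sw == 0, ] <- NA_real_
  out
}

#' Resample a map with k stimuli per cell
#'
#' Draws, independently in every cell, `k` samples with replacement from that
#' cell's measured samples (amplitude and censoring flag travel together).
#' The source map is not modified.
#'
#' @param map a complete [tms_map()].
#' @param k stimuli per cell in the simulated map (>= 1; may exceed the
#'   measured count).
#' @param seed optional RNG seed.
#' @return A new [tms_map()] with exactly `k` samples in every cell.
#' @export
resample_map <- function(map, k, seed = NULL) {
  stopifnot(inherits(map, "tms_map"))
  if (!is_count(k)) stop_usage("k must be an integer >= 1")
  assert_complete(map)
  with_seed_or_not(seed, {
    cells <- lapply(map$cells, function(ce) {
      idx <- sample.int(length(ce$censored), k, replace = TRUE)
      new_cell(ce$amplitude_uV[idx], ce$censored[idx])
    })
    out <- map
    out$cells <- cells
    out
  })
}

#' Bootstrap distribution of a representation parameter
#'
#' Generates `B` maps by [resample_map()] at `k` stimuli per cell and
#' evaluates `spec` on each.
#'
#' @param map a complete [tms_map()].
#' @param spec a [parameter_spec()].
#' @param k stimuli per cell (>= 1).
#' @param B number of bootstrap replicates (default 1000).
#' @param seed optional RNG seed; the same seed reproduces the values exactly.
#' @return An object of class `bootstrap_sample`: list with `values` (length-B
#'   vector, or B x 2 matrix for COGs with NA rows where the COG was undefined
#'   in a replicate), `k`, `B`, `seed`, `source` (subject, session), `spec`,
#'   and `n_undefined`.
#' @export
bootstrap_distribution <- function(map, spec, k, B = 1000, seed = NULL) {
  stopifnot(inherits(map, "tms_map"), inherits(spec, "parameter_spec"))
  if (!is_count(k)) stop_usage("k must be an integer >= 1")
  if (!is_count(B)) stop_usage("B must be an integer >= 1")
  assert_complete(map)
  stats <- with_seed_or_not(seed,
    boot_cell_stats(map, as.integer(k), as.integer(B), spec$threshold_uV))
  values <- param_from_stats(stats, spec, map$grid)
  n_undef <- if (is.matrix(values)) sum(is.na(values[, 1])) else 0L
  structure(list(values = values, k = as.integer(k), B = as.integer(B),
                 seed = seed, source = c(subject_id = map$subject_id,
                                         session_id = map$session_id),
                 spec = spec, n_undefined = n_undef),
            class = "bootstrap_sample")
}

#' @export
print.bootstrap_sample <- function(x, ...) {
  cat(sprintf("<bootstrap_sample> %s, k = %d, B = %d (%d undefined)\n",
              spec_label(x$spec), x$k, x$B, x$n_undefined))
  invisible(x)
}

#' Normalized bootstrap bias of a scalar parameter
#'
#' `(mean of bootstrap values - P0) / P0` where `P0` is the value measured on
#' the experimental map.
#'
#' @param boot_sample a [bootstrap_distribution()] result for a scalar
#'   parameter (areas / weighted areas).
#' @param P0 the parameter value of the source map (non-zero).
#' @return Dimensionless normalized bias.
#' @export
normalized_bias <- function(boot_sample, P0) {
  stopifnot(inherits(boot_sample, "bootstrap_sample"))
  if (is.matrix(boot_sample$values))
    stop_usage("normalized bias is defined for scalar parameters, not COGs")
  if (!is_scalar_num(P0) || P0 == 0)
    stop_usage("normalized bias undefined: P0 = 0 (exclude such maps)")
  (mean(boot_sample$values) - P0) / P0
}

#' Coefficient of variation of a bootstrap distribution
#'
#' Sample standard deviation over mean of the B bootstrap parameter values.
#'
#' @param boot_sample a [bootstrap_distribution()] result for a scalar
#'   parameter.
#' @return Dimensionless CV (>= 0 for nonnegative parameters).
#' @export
coefficient_of_variation <- function(boot_sample) {
  stopifnot(inherits(boot_sample, "bootstrap_sample"))
  if (is.matrix(boot_sample$values))
    stop_usage("CV is defined for scalar parameters, not COGs")
  m <- mean(boot_sample$values)
  if (m == 0) stop_usage("CV undefined: bootstrap mean is 0")
  stats::sd(boot_sample$values) / m
}

#' Between-session variability index
#'
#' For each of `B` bootstrap triples (one map resampled at `k` stimuli per
#' cell from each of the three sessions) computes
#' `(Pmax - Pmin) / (Pmax + Pmin)` and returns the mean over triples.
#' Degenerate triples with `Pmax + Pmin = 0` contribute 0 (no observable
#' change); their count is attached as attribute `n_degenerate`.
#'
#' @param maps_3 list of exactly three complete [tms_map()] of one subject.
#' @param spec a scalar [parameter_spec()].
#' @param k stimuli per cell.
#' @param B number of bootstrap triples (default 1000).
#' @param seed optional RNG seed.
#' @return Scalar mean variability index in `[0, 1]`.
#' @export
between_session_variability <- function(maps_3, spec, k, B = 1000,
                                        seed = NULL) {
  if (length(maps_3) != 3L)
    stop_usage("between_session_variability needs exactly 3 session maps")
  stopifnot(inherits(spec, "parameter_spec"))
  if (spec$family == "cog")
    stop_usage("variability index is defined for scalar parameters")
  subj <- unique(vapply(maps_3, function(m) m$subject_id, character(1)))
  if (length(subj) != 1L)
    stop_usage("the three maps must come from one subject (got: %s)",
               paste(subj, collapse = ", "))
  vals <- with_seed_or_not(seed, {
    vapply(maps_3, function(m) {
      assert_complete(m)
      param_from_stats(boot_cell_stats(m, as.integer(k), as.integer(B),
                                       spec$threshold_uV), spec, m$grid)
    }, numeric(B))
  })
  vals <- matrix(vals, nrow = B) # B = 1 drops dimensions otherwise
  pmaxv <- pmax(vals[, 1], vals[, 2], vals[, 3])
  pminv <- pmin(vals[, 1], vals[, 2], vals[, 3])
  denom <- pmaxv + pminv
  v <- ifelse(denom == 0, 0, (pmaxv - pminv) / denom)
  structure(mean(v), n_degenerate = sum(denom == 0))
}

#' Bootstrap error of the centre of gravity
#'
#' Mean Euclidean distance (mm) between the COG of the experimental map and
#' the COGs of `B` maps resampled at `k` stimuli per cell. Replicates with an
#' undefined COG (all weights zero) are skipped; their count is attached as
#' attribute `n_undefined`.
#'
#' @param map a complete [tms_map()] with a defined COG.
#' @param weighting COG weighting variant (see [center_of_gravity()]).
#' @param k stimuli per cell.
#' @param B bootstrap replicates (default 1000).
#' @param seed optional RNG seed.
#' @param threshold_uV detection threshold (default 50).
#' @return Mean COG displacement in mm.
#' @export
cog_error <- function(map, weighting = "probability", k, B = 1000,
                      seed = NULL, threshold_uV = 50) {
  cog0 <- center_of_gravity(map, weighting, threshold_uV) # errors if undefined
  spec <- parameter_spec("cog", weighting, threshold_uV)
  boot <- bootstrap_distribution(map, spec, k, B, seed)
  d <- sqrt((boot$values[, 1] - cog0[1])^2 + (boot$values[, 2] - cog0[2])^2)
  structure(mean(d, na.rm = TRUE), n_undefined = sum(is.na(d)))
}

#' Bootstrap accuracy profile of a session set
#'
#' For every map, parameter specification and stimuli-per-cell value computes
#' the normalized bias and CV (scalar parameters) or the COG error (COG
#' parameters); for subjects with exactly three sessions also the
#' between-session variability index. Summary rows take medians across maps
#' (across subjects for the variability index), excluding undefined values.
#'
#' Maps on which the observed parameter is zero have an undefined normalized
#' bias and are excluded from the bias/CV columns (counted in `n_excluded`).
#' Each (map, spec, k) combination consumes its own RNG stream derived from
#' `seed`, so the profile is reproducible and order-independent.
#'
#' @param set a [session_set()] of complete maps.
#' @param specs list of [parameter_spec()] (default: all eight).
#' @param k_range integer vector of stimuli-per-cell values (default 1..10).
#' @param B bootstrap replicates per combination (default 1000).
#' @param seed optional master seed.
#' @return An object of class `accuracy_profile`: list with data.frames
#'   `per_map` (subject, session, family, variant, k, P0, bias, cv,
#'   cog_error_mm), `between_session` (subject, family, variant, k, v_index),
#'   `median` (family, variant, k, bias, cv, v_index, cog_error_mm), plus
#'   `n_excluded`.
#' @export
accuracy_profile <- function(set, specs = default_parameter_specs(),
                             k_range = 1:10, B = 1000, seed = NULL) {
  stopifnot(inherits(set, "session_set"))
  if (length(set) == 0L) stop_usage("empty session set")
  maps <- unclass(set)
  stream <- 0L
  per_map <- list()
  for (m in maps) {
    for (sp in specs) {
      p0 <- tryCatch(map_parameter(m, sp), error = function(e) NULL)
      for (k in k_range) {
        stream <- stream + 1L
        s_k <- derive_seed(seed, stream)
        if (sp$family == "cog") {
          err <- if (is.null(p0)) NA_real_ else
            as.numeric(cog_error(m, sp$variant, k, B, s_k, sp$threshold_uV))
          row <- data.frame(P0 = NA_real_, bias = NA_real_, cv = NA_real_,
                            cog_error_mm = err)
        } else {
          boot <- bootstrap_distribution(m, sp, k, B, s_k)
          bias <- if (p0 == 0) NA_real_ else normalized_bias(boot, p0)
          cv <- if (mean(boot$values) == 0) NA_real_ else
            coefficient_of_variation(boot)
          row <- data.frame(P0 = p0, bias = bias, cv = cv,
                            cog_error_mm = NA_real_)
        }
        per_map[[length(per_map) + 1L]] <- cbind(
          data.frame(subject = m$subject_id, session = m$session_id,
                     family = sp$family, variant = sp$variant, k = k), row)
      }
    }
  }
  per_map <- do.call(rbind, per_map)

  # between-session variability for subjects with exactly three sessions
  between <- list()
  subjects <- unique(vapply(maps, function(m) m$subject_id, character(1)))
  for (s in subjects) {
    triple <- subject_maps(set, s)
    if (length(triple) != 3L) next
    for (sp in Filter(function(x) x$family != "cog", specs)) {
      for (k in k_range) {
        stream <- stream + 1L
        v <- between_session_variability(triple, sp, k, B,
                                         derive_seed(seed, stream))
        between[[length(between) + 1L]] <- data.frame(
          subject = s, family = sp$family, variant = sp$variant, k = k,
          v_index = as.numeric(v))
      }
    }
  }
  between <- if (length(between)) do.call(rbind, between) else
    data.frame(subject = character(0), family = character(0),
               variant = character(0), k = integer(0), v_index = numeric(0))

  med <- function(x) if (all(is.na(x))) NA_real_ else
    stats::median(x, na.rm = TRUE)
  med_tab <- stats::aggregate(per_map[c("bias", "cv", "cog_error_mm")],
                              per_map[c("family", "variant", "k")],
                              med, drop = FALSE)
  if (nrow(between)) {
    vmed <- stats::aggregate(between["v_index"],
                             between[c("family", "variant", "k")], med)
    med_tab <- merge(med_tab, vmed, all.x = TRUE)
  } else {
    med_tab$v_index <- NA_real_
  }
  med_tab <- med_tab[order(med_tab$family, med_tab$variant, med_tab$k), ]
  rownames(med_tab) <- NULL
  structure(list(per_map = per_map, between_session = between,
                 median = med_tab,
                 n_excluded = sum(is.na(per_map$bias) &
                                    per_map$family != "cog")),
            class = "accuracy_profile")
}

#' @export
print.accuracy_profile <- function(x, ...) {
  cat(sprintf("<accuracy_profile> %d per-map rows, %d between-session rows, %d excluded (P0 = 0)\n",
              nrow(x$per_map), nrow(x$between_session), x$n_excluded))
  print(utils::head(x$median, 12))
  invisible(x)
}
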