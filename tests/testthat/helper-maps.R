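# Test fixtures are built in code: tiny maps with hand-chosen amplitudes and
# independent brute-force oracles for the bootstrap moments.

# A cell from an amplitude vector; NA marks a censored response.
mk_cell <- function(amps) list(amplitude_uV = as.numeric(amps),
                               censored = is.na(amps))

# A small map on a 1 x n (or n_rows x n_cols) unit grid. cell_amps is a list
# of amplitude vectors in row-major order.
mk_map <- function(cell_amps, cell_side = 1, n_rows = 1,
                   n_cols = length(cell_amps) / n_rows,
                   subject = "S1", session = "1", origin = c(0, 0)) {
  g <- grid_spec(n_rows, n_cols, cell_side, origin_xy_mm = origin,
                 peeling_depth_mm = 0)
  tms_map(g, lapply(cell_amps, mk_cell), subject_id = subject,
          session_id = session)
}

# Exact moments of a bootstrap parameter distribution by enumerating every
# joint resampling outcome (n^k per cell, product across cells). Returns the
# exact mean and *population* SD of the parameter at k stimuli per cell.
enum_boot_moments <- function(map, spec, k) {
  cells <- map$cells
  per_cell <- lapply(cells, function(ce) {
    n <- length(ce$censored)
    as.matrix(expand.grid(rep(list(seq_len(n)), k)))
  })
  combos <- as.matrix(expand.grid(lapply(per_cell, function(m)
    seq_len(nrow(m)))))
  vals <- apply(combos, 1, function(ci) {
    m2 <- map
    m2$cells <- lapply(seq_along(cells), function(j) {
      sel <- per_cell[[j]][ci[j], ]
      list(amplitude_uV = cells[[j]]$amplitude_uV[sel],
           censored = cells[[j]]$censored[sel])
    })
    map_parameter(m2, spec)
  })
  c(mean = mean(vals), sd = sqrt(mean((vals - mean(vals))^2)))
}

# Exact mean COG displacement at k stimuli/cell by full enumeration.
enum_cog_error <- function(map, weighting, k, threshold = 50) {
  cog0 <- center_of_gravity(map, weighting, threshold)
  spec <- parameter_spec("cog", weighting, threshold)
  cells <- map$cells
  per_cell <- lapply(cells, function(ce) {
    n <- length(ce$censored)
    as.matrix(expand.grid(rep(list(seq_len(n)), k)))
  })
  combos <- as.matrix(expand.grid(lapply(per_cell, function(m)
    seq_len(nrow(m)))))
  d <- apply(combos, 1, function(ci) {
    m2 <- map
    m2$cells <- lapply(seq_along(cells), function(j) {
      sel <- per_cell[[j]][ci[j], ]
      list(amplitude_uV = cells[[j]]$amplitude_uV[sel],
           censored = cells[[j]]$censored[sel])
    })
    cog <- tryCatch(center_of_gravity(m2, weighting, threshold),
                    error = function(e) c(NA_real_, NA_real_))
    sqrt(sum((cog - cog0)^2))
  })
  mean(d, na.rm = TRUE)
}

# Amplitudes strictly above threshold for null-distribution draws: lognormal
# left-censored at 50 uV with p_supra ~ 0.5.
draw_censored_sample <- function(n, meanlog = log(50), sdlog = 1,
                                 threshold = 50) {
  a <- rlnorm(n, meanlog, sdlog)
  censored_sample(a[a >= threshold], sum(a < threshold), threshold)
}

expect_map_cells_equal <- function(a, b) {
  expect_equal(length(a$cells), length(b$cells))
  for (i in seq_along(a$cells)) {
    expect_equal(a$cells[[i]]$amplitude_uV, b$cells[[i]]$amplitude_uV)
    expect_equal(a$cells[[i]]$censored, b$cells[[i]]$censored)
  }
}
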