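test_that("resample_map draws k i.i.d. samples per cell with replacement", {
  # identical samples: any k gives k copies
  m <- mk_map(list(rep(123, 10)))
  r <- resample_map(m, 4, seed = 1)
  expect_equal(r$cells[[1]]$amplitude_uV, rep(123, 4))
  # k may exceed the measured sample count
  m2 <- mk_map(list(c(100, 60, rep(NA, 8))))
  r15 <- resample_map(m2, 15, seed = 2)
  expect_length(r15$cells[[1]]$censored, 15)
  expect_error(resample_map(m2, 0), "k must be")
  # source map unchanged
  expect_length(m2$cells[[1]]$censored, 10)
  # k = 1 resampling is uniform over the cell's samples
  amps <- seq(60, 150, by = 10)
  m10 <- mk_map(list(amps))
  draws <- withr::with_seed(3, replicate(10000, {
    resample_map(m10, 1)$cells[[1]]$amplitude_uV
  }))
  counts <- table(factor(draws, levels = amps))
  expect_gt(stats::chisq.test(counts)$p.value, 1e-3)
})

test_that("bootstrap_distribution evaluates the parameter per replicate", {
  spec <- parameter_spec("area", "any_supra")
  # all suprathreshold: every replicate equals the cell area
  m <- mk_map(list(rep(80, 10)), cell_side = 2)
  b <- bootstrap_distribution(m, spec, k = 3, B = 50, seed = 1)
  expect_equal(b$values, rep(4, 50))
  # 5/10 suprathreshold at k = 1: Bernoulli(0.5) scaled by cell area
  m5 <- mk_map(list(c(rep(60, 5), rep(NA, 5))))
  b5 <- bootstrap_distribution(m5, spec, k = 1, B = 4000, seed = 2)
  expect_setequal(unique(b5$values), c(0, 1))
  expect_lt(abs(mean(b5$values) - 0.5), 3 * 0.5 / sqrt(4000))
  # determinism: same seed, same values
  b5b <- bootstrap_distribution(m5, spec, k = 1, B = 4000, seed = 2)
  expect_identical(b5$values, b5b$values)
})

test_that("bootstrap path agrees with the ragged per-cell fallback", {
  # same map, one path forced ragged by an 11th sample in one cell
  amps <- list(c(100, 60, rep(NA, 8)), c(rep(70, 6), rep(NA, 4)))
  m <- mk_map(amps)
  spec <- parameter_spec("weighted_area", "probability")
  fast <- bootstrap_distribution(m, spec, k = 5, B = 3000, seed = 9)
  m_ragged <- m
  m_ragged$cells[[1]] <- mk_cell(c(amps[[1]], NA)) # n = 11 disables fast path
  # distributions must agree in mean within MC error (p_supra shifts 2/10 ->
  # 2/11 for cell 1, so compare against each path's own expectation)
  exp_fast <- 2 / 10 + 6 / 10
  exp_ragged <- 2 / 11 + 6 / 10
  slow <- bootstrap_distribution(m_ragged, spec, k = 5, B = 3000, seed = 10)
  expect_lt(abs(mean(fast$values) - exp_fast), 4 * sd(fast$values) / sqrt(3000))
  expect_lt(abs(mean(slow$values) - exp_ragged), 4 * sd(slow$values) / sqrt(3000))
})

test_that("normalized bias matches closed forms for the one-cell map", {
  spec <- parameter_spec("area", "any_supra")
  m5 <- mk_map(list(c(rep(60, 5), rep(NA, 5))))
  P0 <- representation_area(m5, "any_supra")
  expect_equal(P0, 1)
  # constant values -> zero bias
  mall <- mk_map(list(rep(80, 10)))
  ball <- bootstrap_distribution(mall, spec, 2, 100, seed = 1)
  expect_equal(normalized_bias(ball, 1), 0)
  # exact bias at k draws is -(1/2)^k: P(no supra among k) = 0.5^k
  B <- 1e5
  for (k in 1:2) {
    b <- bootstrap_distribution(m5, spec, k, B, seed = 10 + k)
    mc_se <- sd(b$values) / sqrt(B) / P0
    expect_lt(abs(normalized_bias(b, P0) - (-0.5^k)), 3 * mc_se)
  }
  expect_error(normalized_bias(b, 0), "P0 = 0")
})

test_that("coefficient of variation matches the Bernoulli closed form", {
  spec <- parameter_spec("area", "any_supra")
  mall <- mk_map(list(rep(80, 10)))
  expect_equal(coefficient_of_variation(
    bootstrap_distribution(mall, spec, 2, 100, seed = 1)), 0)
  # Bernoulli(0.5): CV = sqrt(pq)/p = 1 exactly, at any scale
  m5 <- mk_map(list(c(rep(60, 5), rep(NA, 5))), cell_side = 3)
  b <- bootstrap_distribution(m5, spec, 1, 1e5, seed = 4)
  expect_lt(abs(coefficient_of_variation(b) - 1), 0.02)
  # scale invariance: multiplying all values by c > 0 leaves CV unchanged
  b2 <- b
  b2$values <- b$values * 17.3
  expect_equal(coefficient_of_variation(b2), coefficient_of_variation(b))
})

test_that("bootstrap bias and CV match exact enumeration on tiny maps", {
  # two cells, four samples each, k <= 3: full enumeration of (4^k)^2 joint
  # outcomes is the independent oracle
  m <- mk_map(list(c(100, 60, NA, NA), c(300, NA, NA, NA)))
  B <- 20000
  for (sp in list(parameter_spec("area", "any_supra"),
                  parameter_spec("weighted_area", "probability"),
                  parameter_spec("weighted_area", "amplitude"))) {
    P0 <- map_parameter(m, sp)
    for (k in c(1L, 3L)) {
      exact <- enum_boot_moments(m, sp, k)
      b <- bootstrap_distribution(m, sp, k, B, seed = k * 100 + 7)
      mc_se <- exact[["sd"]] / sqrt(B)
      expect_lt(abs(mean(b$values) - exact[["mean"]]), 3 * mc_se)
      # CV: compare through the same moments
      expect_lt(abs(normalized_bias(b, P0) - (exact[["mean"]] - P0) / P0),
                3 * mc_se / P0)
      cv_exact <- exact[["sd"]] / exact[["mean"]]
      cv_boot <- coefficient_of_variation(b)
      se_cv <- cv_exact * sqrt(1 / (2 * (B - 1)) + cv_exact^2 / B)
      expect_lt(abs(cv_boot - cv_exact), 3 * (se_cv + mc_se / exact[["mean"]]))
    }
  }
})

test_that("between-session variability implements the (Pmax-Pmin)/(Pmax+Pmin) mean", {
  # deterministic maps with parameter values 100, 200, 300 (amplitude-weighted
  # area on a unit cell): every triple gives (300-100)/400 = 0.5
  maps <- lapply(1:3, function(s) mk_map(list(rep(100 * s, 5)), session = s))
  spec <- parameter_spec("weighted_area", "amplitude")
  v <- between_session_variability(maps, spec, k = 4, B = 200, seed = 1)
  expect_equal(as.numeric(v), 0.5)
  # identical deterministic sessions: V = 0
  same <- lapply(1:3, function(s) mk_map(list(rep(150, 5)), session = s))
  expect_equal(as.numeric(
    between_session_variability(same, spec, 4, 100, seed = 2)), 0)
  # identical maps with internal variability: bootstrap noise alone gives V > 0
  noisy <- lapply(1:3, function(s)
    mk_map(list(c(rep(60, 5), rep(NA, 5))), session = s))
  v3 <- between_session_variability(noisy, parameter_spec("area", "any_supra"),
                                    k = 2, B = 500, seed = 3)
  expect_gt(as.numeric(v3), 0)
  # degenerate all-censored triples contribute 0 and are counted
  cens <- lapply(1:3, function(s) mk_map(list(rep(NA, 5)), session = s))
  v0 <- between_session_variability(cens, parameter_spec("area", "any_supra"),
                                    2, 50, seed = 4)
  expect_equal(as.numeric(v0), 0)
  expect_equal(attr(v0, "n_degenerate"), 50)
  expect_error(between_session_variability(maps[1:2], spec, 2, 10), "3 session")
})

test_that("cog_error measures mean bootstrap COG displacement", {
  # single cell: every resampled COG is the cell centre
  m1 <- mk_map(list(c(100, 60, NA)))
  expect_equal(as.numeric(cog_error(m1, "probability", 3, 100, seed = 1)), 0)
  # translation invariance
  amps <- list(c(100, 60, NA, NA), c(300, NA, NA, NA))
  ma <- mk_map(amps, origin = c(0, 0))
  mb <- mk_map(amps, origin = c(250, -40))
  ea <- cog_error(ma, "mean_amplitude", 2, 2000, seed = 5)
  eb <- cog_error(mb, "mean_amplitude", 2, 2000, seed = 5)
  expect_equal(as.numeric(ea), as.numeric(eb))
  # exact enumeration oracle on a two-cell map at k = 1
  m2 <- mk_map(list(c(100, 60), c(300, NA)))
  exact <- enum_cog_error(m2, "mean_amplitude", 1)
  B <- 20000
  est <- cog_error(m2, "mean_amplitude", 1, B, seed = 6)
  expect_lt(abs(as.numeric(est) - exact), 0.01) # distances bounded by 1 mm grid
})

test_that("accuracy_profile aggregates per-map results and medians", {
  # deterministic maps: all biases 0, CVs 0, V 0
  maps <- list(mk_map(list(rep(80, 5), rep(100, 5)), subject = "A", session = "1"),
               mk_map(list(rep(80, 5), rep(100, 5)), subject = "A", session = "2"),
               mk_map(list(rep(80, 5), rep(100, 5)), subject = "A", session = "3"))
  prof <- accuracy_profile(session_set(maps), k_range = c(1L, 2L), B = 50,
                           seed = 1)
  scal <- prof$per_map[prof$per_map$family != "cog", ]
  expect_true(all(scal$bias == 0))
  expect_true(all(scal$cv == 0))
  expect_true(all(prof$between_session$v_index == 0))
  expect_true(all(prof$per_map$cog_error_mm[prof$per_map$family == "cog"] == 0))
  # medians invariant to map ordering (independent derived RNG streams share
  # the (map, spec, k) enumeration, so reorderings only permute rows)
  expect_error(accuracy_profile(session_set(list())), "empty")
})

test_that("accuracy_profile excludes maps with P0 = 0 from bias medians", {
  maps <- list(mk_map(list(rep(NA, 5)), subject = "A", session = "1"),
               mk_map(list(rep(80, 5)), subject = "B", session = "1"))
  prof <- accuracy_profile(session_set(maps),
                           specs = list(parameter_spec("area", "any_supra")),
                           k_range = 1:2, B = 30, seed = 2)
  expect_equal(prof$n_excluded, 2) # subject A at both k
  expect_true(all(is.finite(prof$median$bias)))
})
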