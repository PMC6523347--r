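test_that("Gehan statistic scores definitely-ordered pairs", {
  a <- censored_sample(c(80, 120), 3)
  expect_equal(gehan_test(a, a)$statistic[["W"]], 0)
  expect_equal(gehan_test(a, a)$p.value, 1)
  # fully separated 5 censored vs 5 observed: W = -25, exact p = 2/252
  cens5 <- censored_sample(numeric(0), 5)
  obs5 <- censored_sample(c(80, 120, 200, 90, 400))
  ht <- gehan_test(cens5, obs5)
  expect_equal(ht$statistic[["W"]], -25)
  expect_equal(ht$p.value, 2 / 252)
  # antisymmetry
  ht2 <- gehan_test(obs5, cens5)
  expect_equal(ht2$statistic[["W"]], 25)
  expect_equal(ht2$p.value, ht$p.value)
  expect_error(gehan_test(censored_sample(60), censored_sample(numeric(0), 0)),
               "at least one")
})

test_that("Gehan on uncensored data equals the Mann-Whitney U difference", {
  withr::with_seed(31, {
    for (rep in 1:6) {
      x <- round(rlnorm(6, log(200), 0.8) + 50)
      y <- round(rlnorm(7, log(150), 0.8) + 50)
      W <- gehan_test(censored_sample(x), censored_sample(y))$statistic[["W"]]
      # oracle via rank sums: U1 - U2 (no ties by construction w.h.p.)
      r <- rank(c(x, y))
      U1 <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
      U2 <- length(x) * length(y) - U1
      expect_equal(W, U1 - U2)
    }
  })
})

test_that("Monte-Carlo permutation p agrees with exact enumeration", {
  a <- censored_sample(c(80, 300), 3)
  b <- censored_sample(c(90, 110, 150), 2)
  exact <- gehan_test(a, b, method = "exact")
  mc <- gehan_test(a, b, method = "montecarlo", n_perm = 20000, seed = 1)
  expect_lt(abs(mc$p.value - exact$p.value),
            3 * sqrt(exact$p.value / 20000) + 1e-4)
})

test_that("change diagrams flag the significantly changed cells", {
  surf <- excitability_surface()
  m <- simulate_session(surf, seed = 41)
  # a map against itself is all zero
  d0 <- change_diagram(m, m)
  expect_true(all(d0$matrix == 0))
  expect_equal(dim(d0$matrix), c(7, 7))
  # engineered change: one cell censored in A, large in B -> exactly one +1
  ma <- m
  mb <- m
  ma$cells[[17]] <- mk_cell(rep(NA, 10))
  mb$cells[[17]] <- mk_cell(c(500, 600, 700, 800, 900, rep(NA, 5)))
  d1 <- change_diagram(ma, mb)
  expect_equal(sum(d1$matrix == 1), 1)
  expect_equal(d1$matrix[3, 3], 1) # cell 17 row-major = (row 2, col 2) 0-based
  expect_equal(sum(d1$matrix != 0), 1)
  expect_error(change_diagram(m, mk_map(list(c(60, NA)))), "different grids")
})

test_that("null false-positive fraction of diagrams stays below alpha", {
  # i.i.d. halves: the Gehan test is conservative due to discreteness
  surf <- excitability_surface()
  nonzero <- withr::with_seed(43, {
    vapply(1:40, function(i) {
      m <- simulate_session(surf, grid = grid_spec(3, 3, 7.63),
                            n_stimuli_per_cell = 10)
      d <- within_session_diagram(m)
      mean(d$matrix != 0)
    }, numeric(1))
  })
  se <- sqrt(0.05 * 0.95 / (40 * 9))
  expect_lte(mean(nonzero), 0.05 + 2 * se)
})

test_that("within-session diagram compares the two sample halves", {
  m <- mk_map(lapply(1:4, function(i) rep(100, 10)), n_rows = 2, n_cols = 2)
  d <- within_session_diagram(m)
  expect_true(all(d$matrix == 0))
  expect_equal(dim(d$matrix), c(2, 2))
  m$cells[[3]] <- mk_cell(rep(100, 9))
  expect_error(within_session_diagram(m), "\\(1,0\\)")
})

test_that("histogram overlap behaves like a bounded similarity", {
  x <- rnorm(500)
  expect_equal(histogram_overlap(x, x), 1)
  expect_equal(histogram_overlap(1:100, 201:300), 0)
  # analytic 0.5 for uniforms offset by half their width, bins aligned
  withr::with_seed(51, {
    a <- runif(20000, 0, 1)
    b <- runif(20000, 0.5, 1.5)
    ov <- histogram_overlap(a, b, n_bins = 30)
    expect_lt(abs(ov - 0.5), 0.05)
    # symmetry and affine invariance (bins recomputed)
    expect_equal(histogram_overlap(b, a, 30), ov)
    expect_equal(histogram_overlap(5 + 2 * a, 5 + 2 * b, 30), ov)
  })
  expect_error(histogram_overlap(x, x, n_bins = 1), "n_bins")
  expect_error(histogram_overlap(numeric(0), x), "nonempty")
})

test_that("BICC implements the one-way random-effects ICC", {
  # constant distinct groups: MSW = 0 -> 1
  expect_equal(bicc(list(rep(1, 10), rep(2, 10), rep(3, 10))), 1)
  # oracle: mean squares from anova(lm)
  withr::with_seed(61, {
    v <- list(rnorm(50, 0), rnorm(50, 1), rnorm(50, -1))
    ms <- anova(lm(unlist(v) ~ factor(rep(1:3, each = 50))))[["Mean Sq"]]
    expect_equal(bicc(v), (ms[1] - ms[2]) / (ms[1] + 49 * ms[2]))
    # i.i.d. groups concentrate near zero
    reps <- replicate(60, bicc(lapply(1:3, function(i) rnorm(1000))))
    expect_lt(median(abs(reps)), 0.05)
    # between-group variance equal to within variance -> about 0.5 at large n
    reps2 <- replicate(60, bicc(lapply(rnorm(3), function(m)
      rnorm(2000, m, 1))))
    expect_lt(abs(median(reps2) - 0.5), 0.1)
  })
  expect_error(bicc(list(rep(1, 5), rep(1, 5))), "identical")
  expect_error(bicc(list(1:5)), ">= 2 sessions")
  expect_error(bicc(list(1:5, 1:4)), "equal sizes")
})

test_that("Page's trend test: exact small-sample path and enumeration oracle", {
  # two perfectly ordered blocks of three conditions: L = 28, p = 1/36
  x <- rbind(c(3, 2, 1), c(30, 20, 10))
  ht <- page_trend_test(x, "decreasing")
  expect_equal(ht$statistic[["L"]], 28)
  expect_equal(ht$p.value, 1 / 36)
  # brute-force oracle for 2 blocks x 3 conditions at a non-extreme L
  x2 <- rbind(c(3, 1, 2), c(30, 20, 10))
  ht2 <- page_trend_test(x2, "decreasing")
  perms <- rbind(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  Ls <- as.vector(outer(perms %*% 1:3, perms %*% 1:3, "+"))
  expect_equal(ht2$p.value, mean(Ls >= ht2$statistic[["L"]]))
  # reversing the condition order with flipped direction preserves p
  ht3 <- page_trend_test(x[, 3:1], "increasing")
  expect_equal(ht3$p.value, ht$p.value)
  # strong monotone decrease over 10 conditions: normal approximation, tiny p
  y <- t(replicate(10, sort(runif(10), decreasing = TRUE)))
  expect_lt(page_trend_test(y, "decreasing")$p.value, 1e-6)
  expect_error(page_trend_test(x[, 1:2]), "3 ordered conditions")
})

test_that("session discrimination separates drifted sessions, not copies", {
  surf <- excitability_surface()
  base <- simulate_session(surf, seed = 71)
  # three identical maps: the bootstrap distributions coincide
  copies <- lapply(1:3, function(s) {
    m <- base
    m$session_id <- as.character(s)
    m
  })
  d0 <- discriminate_sessions(copies, k = 10, B = 400, seed = 72)
  expect_lt(abs(d0$bicc), 0.05)
  expect_gt(min(d0$overlaps), 0.7) # near the self-overlap of B = 400 samples
  # large injected gain difference: separated distributions
  strong <- simulate_multisession(surf,
    drift_spec("drift", center_shift_mm = 2, gain_shift_log = 2),
    seed = 73)
  d1 <- discriminate_sessions(subject_maps(strong, "S1"), k = 10, B = 400,
                              seed = 74)
  expect_gt(d1$bicc, 0.9)
  expect_lt(min(d1$overlaps), 0.05)
  # BICC invariant to session relabelling
  d2 <- discriminate_sessions(copies[c(2, 3, 1)], k = 10, B = 400, seed = 72)
  expect_equal(d2$bicc, d0$bicc)
})
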