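# Censored-data statistics for comparing mapping sessions.
#
# MEP amplitudes below the detection threshold theta are left-censored: their
# true value is only known to lie in [0, theta). Cell-wise session comparisons
# therefore use Gehan's generalization of the Mann-Whitney test, which scores
# only definitely-ordered pairs. All censored values share one threshold, so
# censored < observed is always definite and censored vs censored is
# indeterminate.

#' A left-censored amplitude sample
#'
#' @param observed numeric vector of uncensored amplitudes (all >= threshold).
#' @param n_censored number of responses known only to lie below threshold.
#' @param threshold_uV the shared detection threshold.
#' @return An object of class `censored_sample`.
#' @export
censored_sample <- function(observed, n_censored = 0L, threshold_uV = 50) {
  observed <- as.numeric(observed)
  if (any(!is.finite(observed)) || any(observed < threshold_uV))
    stop_usage("observed values must be finite and >= the threshold (%g)",
               threshold_uV)
  if (!is_count(n_censored, min = 0L))
    stop_usage("n_censored must be a non-negative integer")
  if (length(observed) + n_censored < 1L)
    stop_usage("censored_sample must contain at least one response")
  structure(list(observed = observed, n_censored = as.integer(n_censored),
                 threshold_uV = threshold_uV),
            class = "censored_sample")
}

# Encoding: censored values become a common surrogate strictly below every
# observable amplitude; sign(z_i - z_j) then reproduces the Gehan U scores
# (+1 definitely greater, -1 definitely smaller, 0 indeterminate/tied).
censored_codes <- function(x) {
  stopifnot(inherits(x, "censored_sample"))
  c(x$observed, rep(-1, x$n_censored))
}

cell_to_censored <- function(cell, threshold_uV, take = NULL) {
  amp <- cell$amplitude_uV
  cen <- cell$censored
  if (!is.null(take)) {
    amp <- amp[take]
    cen <- cen[take]
  }
  supra <- !cen & amp >= threshold_uV
  supra[is.na(supra)] <- FALSE
  # uncensored sub-threshold values cannot occur in validated maps
  censored_sample(amp[supra], sum(!supra), threshold_uV)
}

# memoized exact group-assignment matrices: choose(n, na) x n logical
assignment_cache <- new.env(parent = emptyenv())
exact_assignments <- function(n, na) {
  key <- paste(n, na, sep = "_")
  if (!is.null(assignment_cache[[key]])) return(assignment_cache[[key]])
  combs <- utils::combn(n, na)
  M <- matrix(FALSE, ncol(combs), n)
  M[cbind(rep(seq_len(ncol(combs)), each = na), as.vector(combs))] <- TRUE
  assignment_cache[[key]] <- M
  M
}

gehan_W <- function(za, zb) sum(sign(outer(za, zb, "-")))

#' Gehan's generalized Mann-Whitney test for left-censored samples
#'
#' The statistic is `W = sum_ij U(a_i, b_j)` with `U = +1` when `a_i` is
#' definitely greater than `b_j`, `-1` when definitely smaller, and 0 for
#' indeterminate pairs (two censored values) and ties. Negative `W` means the
#' second sample is stochastically greater. The two-sided p-value comes from
#' the permutation distribution of `W`: exact enumeration of all group
#' assignments when the pooled size is <= 12 (or `method = "exact"`),
#' otherwise Monte-Carlo with an add-one correction.
#'
#' @param sample_a,sample_b [censored_sample()] objects sharing a threshold.
#' @param method `"auto"` (default), `"exact"` or `"montecarlo"`.
#' @param n_perm Monte-Carlo permutation count (default 9999).
#' @param seed optional RNG seed for the Monte-Carlo path.
#' @return An `htest`-like list with `statistic` (W), `p.value`, `method`,
#'   and `n_perm` (NA for exact enumeration).
#' @examples
#' a <- censored_sample(numeric(0), n_censored = 5)
#' b <- censored_sample(c(80, 120, 200, 90, 400))
#' gehan_test(a, b) # W = -25, exact p = 2/252
#' @export
gehan_test <- function(sample_a, sample_b,
                       method = c("auto", "exact", "montecarlo"),
                       n_perm = 9999, seed = NULL) {
  method <- match.arg(method)
  za <- censored_codes(sample_a)
  zb <- censored_codes(sample_b)
  if (length(za) == 0L || length(zb) == 0L)
    stop_usage("both samples must be nonempty")
  na <- length(za)
  n <- na + length(zb)
  W <- gehan_W(za, zb)
  if (method == "auto") method <- if (n <= 12L) "exact" else "montecarlo"
  z <- c(za, zb)
  S <- sign(outer(z, z, "-"))
  if (method == "exact") {
    M <- exact_assignments(n, na)
    W_perm <- rowSums((M %*% S) * !M)
    p <- mean(abs(W_perm) >= abs(W))
    used_perm <- NA_integer_
  } else {
    W_perm <- with_seed_or_not(seed, vapply(seq_len(n_perm), function(i) {
      a <- seq_len(n) %in% sample.int(n, na)
      sum(S[a, !a, drop = FALSE])
    }, numeric(1)))
    p <- (1 + sum(abs(W_perm) >= abs(W))) / (n_perm + 1)
    used_perm <- as.integer(n_perm)
  }
  structure(list(statistic = c(W = W), p.value = p,
                 method = sprintf("Gehan generalized Mann-Whitney test (%s permutation)",
                                  method),
                 alternative = "two.sided", n_perm = used_perm,
                 data.name = "sample_a vs sample_b"),
            class = "htest")
}

new_diagram <- function(mat, alpha, comparison) {
  stopifnot(all(mat %in% c(-1L, 0L, 1L)))
  structure(list(matrix = mat, alpha = alpha, comparison = comparison),
            class = "significance_diagram")
}

#' @export
print.significance_diagram <- function(x, ...) {
  cat(sprintf("<significance_diagram> %s, alpha = %g: %d+ / %d- of %d cells\n",
              x$comparison, x$alpha, sum(x$matrix == 1), sum(x$matrix == -1),
              length(x$matrix)))
  print(x$matrix)
  invisible(x)
}

#' Between-session change diagram
#'
#' Cell-wise Gehan tests between the first `n_per_cell` samples of each map.
#' Entries: `+1` where the second map's amplitudes are significantly greater
#' at uncorrected `p < alpha`, `-1` where significantly smaller, else 0.
#'
#' @param map_a,map_b complete [tms_map()]s on the same grid (sessions in
#'   chronological order: `map_b` is the later one).
#' @param n_per_cell samples used per cell from each map (default 5, the
#'   first half of a ten-stimulus session).
#' @param alpha significance level (default 0.05, uncorrected).
#' @param threshold_uV detection threshold.
#' @return A `significance_diagram` whose `matrix` has the grid's shape.
#' @export
change_diagram <- function(map_a, map_b, n_per_cell = 5, alpha = 0.05,
                           threshold_uV = 50) {
  stopifnot(inherits(map_a, "tms_map"), inherits(map_b, "tms_map"))
  if (!identical(unclass(map_a$grid), unclass(map_b$grid)))
    stop_usage("maps use different grids")
  ns_a <- lengths(lapply(map_a$cells, `[[`, "censored"))
  ns_b <- lengths(lapply(map_b$cells, `[[`, "censored"))
  if (any(ns_a < n_per_cell) || any(ns_b < n_per_cell))
    stop_usage("every cell needs >= %d samples in both maps", n_per_cell)
  take <- seq_len(n_per_cell)
  signs <- vapply(seq_along(map_a$cells), function(i) {
    ht <- gehan_test(cell_to_censored(map_a$cells[[i]], threshold_uV, take),
                     cell_to_censored(map_b$cells[[i]], threshold_uV, take))
    if (ht$p.value < alpha) -sign(ht$statistic[["W"]]) else 0
  }, numeric(1))
  mat <- matrix(as.integer(signs), map_a$grid$n_rows, map_a$grid$n_cols,
                byrow = TRUE)
  new_diagram(mat, alpha, "between-sessions")
}

#' Within-session change diagram
#'
#' Cell-wise Gehan tests between the first five and second five samples of
#' each cell of one session, quantifying within-session fluctuation on the
#' same footing as the between-session comparison.
#'
#' @param map a [tms_map()] with >= 10 samples in every cell (first 10 used).
#' @param alpha significance level (default 0.05, uncorrected).
#' @param threshold_uV detection threshold.
#' @return A `significance_diagram`; `+1` marks cells whose second half had
#'   significantly greater amplitudes.
#' @export
within_session_diagram <- function(map, alpha = 0.05, threshold_uV = 50) {
  stopifnot(inherits(map, "tms_map"))
  ns <- lengths(lapply(map$cells, `[[`, "censored"))
  if (any(ns < 10L)) {
    cc <- cell_centers(map$grid)
    i <- which(ns < 10L)[1]
    stop_usage("cell (%d,%d) has %d samples; 10 are required",
               cc[i, "row"], cc[i, "col"], ns[i])
  }
  signs <- vapply(map$cells, function(ce) {
    ht <- gehan_test(cell_to_censored(ce, threshold_uV, 1:5),
                     cell_to_censored(ce, threshold_uV, 6:10))
    if (ht$p.value < alpha) -sign(ht$statistic[["W"]]) else 0
  }, numeric(1))
  mat <- matrix(as.integer(signs), map$grid$n_rows, map$grid$n_cols,
                byrow = TRUE)
  new_diagram(mat, alpha, "within-session")
}

#' Overlap of two histograms
#'
#' Builds `n_bins` equal-width bins spanning the pooled range, normalizes each
#' sample's histogram to unit mass, and returns the summed bin-wise minimum.
#' 1 for identical distributions, 0 for disjoint supports.
#'
#' @param values_a,values_b nonempty numeric vectors.
#' @param n_bins number of bins (>= 2, default 30).
#' @return Overlap in `[0, 1]`.
#' @export
histogram_overlap <- function(values_a, values_b, n_bins = 30) {
  if (!length(values_a) || !length(values_b))
    stop_usage("both value lists must be nonempty")
  if (!is_count(n_bins, min = 2L)) stop_usage("n_bins must be >= 2")
  pooled <- range(c(values_a, values_b))
  if (diff(pooled) == 0) return(1) # all values equal: identical distributions
  breaks <- seq(pooled[1], pooled[2], length.out = n_bins + 1L)
  bin <- function(x) {
    idx <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
    tabulate(idx, nbins = n_bins) / length(x)
  }
  sum(pmin(bin(values_a), bin(values_b)))
}

#' Bootstrapping-based between-session intraclass correlation (BICC)
#'
#' One-way random-effects ICC applied to the bootstrap parameter samples of
#' the sessions: `(MSB - MSW) / (MSB + (n - 1) MSW)` with `n` values per
#' session. Not clamped: small negative values are reported as computed.
#' BICC near 0 means the session differences are indistinguishable from the
#' within-session bootstrap spread; BICC near 1 means the sessions are
#' cleanly separated.
#'
#' @param values_by_session list of >= 2 numeric vectors of equal length
#'   (>= 2 values each), one per session.
#' @return Scalar BICC in `(-1/(n-1), 1]`.
#' @export
bicc <- function(values_by_session) {
  if (!is.list(values_by_session) || length(values_by_session) < 2L)
    stop_usage("bicc needs >= 2 sessions")
  sizes <- lengths(values_by_session)
  if (length(unique(sizes)) != 1L || sizes[1] < 2L)
    stop_usage("sessions must have equal sizes >= 2")
  n <- sizes[1]
  g <- length(values_by_session)
  means <- vapply(values_by_session, mean, numeric(1))
  grand <- mean(unlist(values_by_session))
  msb <- n * sum((means - grand)^2) / (g - 1)
  msw <- sum(vapply(values_by_session, function(v) sum((v - mean(v))^2),
                    numeric(1))) / (g * (n - 1))
  if (msb == 0 && msw == 0)
    stop_usage("BICC undefined: all values identical in every session")
  (msb - msw) / (msb + (n - 1) * msw)
}

# all permutations of 1..m (m small)
perms_of <- function(m) {
  if (m == 1L) return(matrix(1L, 1, 1))
  sub <- perms_of(m - 1L)
  do.call(rbind, lapply(seq_len(m), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Page's trend test for ordered alternatives
#'
#' Tests whether values increase (or decrease) monotonically across ordered
#' conditions, using within-block rank sums: `L = sum_j j * R_j` with `R_j`
#' the rank sum of condition `j`. The p-value is one-sided for the stated
#' direction: exact (per-block permutation distribution convolved across
#' blocks) for <= 4 conditions and <= 5 blocks without ties, otherwise the
#' standard normal approximation.
#'
#' @param blocks_by_condition numeric matrix, blocks (e.g. maps) in rows and
#'   >= 3 ordered conditions (e.g. stimuli-per-cell values) in columns.
#' @param direction `"decreasing"` (default; e.g. errors shrinking with the
#'   number of stimuli) or `"increasing"`.
#' @return An `htest`-like list with `statistic` (L), `p.value`, `method`.
#' @export
page_trend_test <- function(blocks_by_condition,
                            direction = c("decreasing", "increasing")) {
  direction <- match.arg(direction)
  x <- as.matrix(blocks_by_condition)
  if (ncol(x) < 3L) stop_usage("Page's test needs >= 3 ordered conditions")
  if (nrow(x) < 2L) stop_usage("Page's test needs >= 2 blocks")
  if (direction == "decreasing") x <- -x
  ranks <- t(apply(x, 1, rank)) # mid-ranks for ties
  m <- ncol(x)
  b <- nrow(x)
  L <- sum(rep(seq_len(m), each = b) * ranks)
  has_ties <- any(apply(x, 1, anyDuplicated) > 0)
  if (m <= 4L && b <= 5L && !has_ties) {
    contrib <- perms_of(m) %*% seq_len(m) # per-block L over all m! orderings
    dist <- table(contrib) / length(contrib)
    vals <- as.numeric(names(dist))
    probs <- as.numeric(dist)
    for (i in seq_len(b - 1L)) { # convolve across blocks
      grid <- outer(vals, as.numeric(names(table(contrib))), "+")
      pr <- outer(probs, as.numeric(table(contrib) / length(contrib)))
      agg <- tapply(as.vector(pr), as.vector(grid), sum)
      vals <- as.numeric(names(agg))
      probs <- as.numeric(agg)
    }
    p <- sum(probs[vals >= L - 1e-9])
    meth <- "Page trend test (exact)"
  } else {
    mu <- b * m * (m + 1)^2 / 4
    sigma2 <- b * (m^3 - m)^2 / (144 * (m - 1))
    p <- stats::pnorm((L - mu) / sqrt(sigma2), lower.tail = FALSE)
    meth <- "Page trend test (normal approximation)"
  }
  structure(list(statistic = c(L = L), p.value = p, method = meth,
                 alternative = paste0("monotone ", direction, " trend"),
                 data.name = deparse(substitute(blocks_by_condition))),
            class = "htest")
}

#' Discriminability of three sessions of one subject
#'
#' Bootstraps `B` parameter values per session at `k` stimuli per cell, then
#' summarizes how separable the sessions are: the BICC of the three value
#' sets and the pairwise histogram overlaps. High BICC (> 0.9) with near-zero
#' overlaps indicates between-session changes exceeding the within-session
#' fluctuation.
#'
#' @param session_triple list of exactly 3 complete [tms_map()] of one
#'   subject.
#' @param spec a scalar [parameter_spec()] (default probability-weighted
#'   area, the most accurate parameter).
#' @param k stimuli per cell (default 10).
#' @param B bootstrap replicates per session (default 1000).
#' @param seed optional master seed.
#' @param n_bins histogram bins for the overlaps (default 30).
#' @return An object of class `session_discrimination`: list with `bicc`,
#'   `overlaps` (named `1-2`, `1-3`, `2-3`), and `values` (list of three
#'   length-B vectors).
#' @export
discriminate_sessions <- function(session_triple,
                                  spec = parameter_spec("weighted_area",
                                                        "probability"),
                                  k = 10, B = 1000, seed = NULL,
                                  n_bins = 30) {
  if (length(session_triple) != 3L)
    stop_usage("discriminate_sessions needs exactly 3 session maps")
  if (spec$family == "cog")
    stop_usage("session discrimination is defined for scalar parameters")
  values <- lapply(seq_len(3L), function(i) {
    bootstrap_distribution(session_triple[[i]], spec, k, B,
                           derive_seed(seed, i))$values
  })
  pairs <- list(`1-2` = c(1, 2), `1-3` = c(1, 3), `2-3` = c(2, 3))
  overlaps <- vapply(pairs, function(pr) {
    histogram_overlap(values[[pr[1]]], values[[pr[2]]], n_bins)
  }, numeric(1))
  structure(list(bicc = bicc(values), overlaps = overlaps, values = values,
                 spec = spec, k = as.integer(k), B = as.integer(B)),
            class = "session_discrimination")
}

#' @export
print.session_discrimination <- function(x, ...) {
  cat(sprintf("<session_discrimination> %s, k = %d: BICC = %.3f; overlaps %s\n",
              spec_label(x$spec), x$k, x$bicc,
              paste(sprintf("%s = %.3f", names(x$overlaps), x$overlaps),
                    collapse = ", ")))
  invisible(x)
}
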