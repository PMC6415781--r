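test_that("trajectory dissimilarity matches hand-evaluated cases", {
  # T = 2, separations {1, 3}: rbar = 2, a = sqrt(1 + 1)/2
  e <- ensemble_1d(c(0, 0), c(1, 3))
  expect_equal(trajectory_dissimilarity(e, 1, 2), sqrt(2) / 2)
  expect_equal(trajectory_dissimilarity(e, 2, 1), sqrt(2) / 2)

  # rigid co-translation at constant separation -> 0
  e2 <- ensemble_1d(1:10, 1:10 + 1)
  expect_equal(trajectory_dissimilarity(e2, 1, 2), 0)

  # identical trajectories -> 0 with duplicate warning
  e3 <- ensemble_1d(c(1, 2, 3), c(1, 2, 3))
  expect_warning(v <- trajectory_dissimilarity(e3, 1, 2), "coincident")
  expect_equal(v, 0)

  # agreement with an independently coded evaluation on random pairs
  set.seed(7)
  pos <- array(rnorm(5 * 20 * 2), dim = c(5, 20, 2))
  ens <- trajectory_ensemble(pos, seq_len(20))
  for (pair in list(c(1, 2), c(2, 5), c(3, 4))) {
    r <- sqrt((pos[pair[1], , 1] - pos[pair[2], , 1])^2 +
              (pos[pair[1], , 2] - pos[pair[2], , 2])^2)
    expect_equal(trajectory_dissimilarity(ens, pair[1], pair[2]),
                 sep_sd_from_distances(r))
  }
})

test_that("trajectory dissimilarity is scale invariant and time-grid strict", {
  set.seed(11)
  pos <- array(runif(4 * 15 * 2), dim = c(4, 15, 2))
  e <- trajectory_ensemble(pos, seq_len(15))
  e_scaled <- trajectory_ensemble(pos * 37.5, seq_len(15))
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(trajectory_dissimilarity(e, i, j),
                 trajectory_dissimilarity(e_scaled, i, j))
  expect_error(trajectory_dissimilarity(e, 2, 2), "distinct")
  e1 <- trajectory_ensemble(pos[, 1, , drop = FALSE], 1)
  expect_error(trajectory_dissimilarity(e1, 1, 2), "two time points")
})

test_that("minimum-image convention applies in periodic dimensions", {
  # two states on a ring of circumference 10, at 1 and 9: distance 2, not 8
  pos <- array(0, dim = c(2, 2, 1))
  pos[1, , 1] <- c(1, 1); pos[2, , 1] <- c(9, 9.5)
  e <- trajectory_ensemble(pos, c(0, 1), periodic_lengths = 10)
  expect_equal(pair_distances(e, 1, 2), c(2, 1.5))
  # unwrapped coordinates give the same distances
  pos2 <- pos; pos2[2, , 1] <- pos[2, , 1] + 30    # three laps ahead
  e2 <- trajectory_ensemble(pos2, c(0, 1), periodic_lengths = 10)
  expect_equal(pair_distances(e2, 1, 2), c(2, 1.5))
})

test_that("sqrt Jensen-Shannon divergence matches analytic values and bounds", {
  expect_equal(js_dissimilarity(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(js_dissimilarity(c(1, 0), c(0, 1)), sqrt(log(2)))
  # term-by-term evaluation: P=(1,0), Q=(.5,.5)
  expected <- sqrt(0.5 * log(4 / 3) + 0.25 * log(2 / 3) + 0.25 * log(2))
  expect_equal(js_dissimilarity(c(1, 0), c(0.5, 0.5)), expected,
               tolerance = 1e-12)
  expect_equal(expected, 0.4645, tolerance = 1e-4)

  set.seed(3)
  for (rep in 1:20) {
    p <- rgamma(6, 1); p <- p / sum(p)
    q <- rgamma(6, 1); q <- q / sum(q)
    v <- js_dissimilarity(p, q)
    expect_gte(v, 0)
    expect_lte(v, sqrt(log(2)) + 1e-12)
    expect_equal(v, js_dissimilarity(q, p))
  }
  expect_error(js_dissimilarity(c(1, 0), c(1, 0, 0)), "equal length")
  expect_error(js_dissimilarity(c(1.2, -0.2), c(0.5, 0.5)), "nonnegative")
})

test_that("build_adjacency makes exactly n(n-1)/2 metric evaluations and is symmetric", {
  set.seed(5)
  pos <- array(runif(7 * 10 * 2), dim = c(7, 10, 2))
  e <- trajectory_ensemble(pos, seq_len(10))
  calls <- 0L
  counting_metric <- function(states, i, j) {
    calls <<- calls + 1L
    trajectory_dissimilarity(states, i, j)
  }
  a <- build_adjacency(e, metric = counting_metric)
  expect_identical(calls, 21L)   # n(n-1)/2 with n = 7
  expect_true(isSymmetric(a))
  expect_equal(diag(a), rep(0, 7))
  expect_true(all(a[upper.tri(a)] > 0))
  # the fast path agrees with the per-pair reference implementation
  expect_equal(unname(build_adjacency(e)), a, tolerance = 1e-12)
})

test_that("fast trajectory adjacency honors periodic dimensions", {
  set.seed(9)
  pos <- array(runif(6 * 12 * 2, 0, 50), dim = c(6, 12, 2))
  e <- trajectory_ensemble(pos, seq_len(12), periodic_lengths = c(50, NA))
  a_fast <- build_adjacency(e)
  a_ref <- build_adjacency(e, metric = trajectory_dissimilarity)
  expect_equal(unname(a_fast), a_ref, tolerance = 1e-12)
})

test_that("degenerate adjacency inputs are caught", {
  pos <- array(1, dim = c(2, 3, 2))   # two identical constant states
  e <- trajectory_ensemble(pos, 1:3)
  expect_warning(a <- build_adjacency(e), "coincident")
  expect_equal(unname(a), matrix(0, 2, 2))
  # three stationary points at constant separations -> zero off-diagonal
  pos3 <- array(0, dim = c(3, 4, 2))
  pos3[2, , 1] <- 1; pos3[3, , 1] <- 2
  e3 <- trajectory_ensemble(pos3, 1:4)
  a3 <- build_adjacency(e3)
  expect_equal(unname(a3), matrix(0, 3, 3))
  expect_error(validate_adjacency(matrix(c(0, 1, 2, 0), 2)), "symmetric")
  expect_error(validate_adjacency(matrix(c(1, 2, 2, 0), 2)), "diagonal")
  expect_error(validate_adjacency(matrix(c(0, -1, -1, 0), 2)), ">= 0")
})
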