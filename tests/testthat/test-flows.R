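test_that("quadruple-eddy velocity matches its stream-function form", {
  p <- quadruple_eddy_params()
  # t = 0: a = 0, b = 1, f = x
  v0 <- quadruple_eddy_velocity(0.5, -0.5, 0, p)
  expect_equal(v0$u, -pi * 0.1 * sin(pi * 0.5) * cos(-pi * 0.5))
  expect_equal(v0$u, 0)
  expect_equal(v0$v, pi * 0.1 * cos(pi * 0.5) * sin(-pi * 0.5) * 1)
  expect_equal(v0$v, 0)

  # domain boundaries are streamlines: no normal flow
  xs <- seq(0.05, 1.95, length.out = 9)
  for (t in c(0, 2.5, 7)) {
    expect_equal(quadruple_eddy_velocity(xs, rep(1, 9), t, p)$v, rep(0, 9))
    expect_equal(quadruple_eddy_velocity(xs, rep(-1, 9), t, p)$v, rep(0, 9))
    expect_equal(quadruple_eddy_velocity(rep(0, 9), xs - 1, t, p)$u, rep(0, 9))
    expect_equal(quadruple_eddy_velocity(rep(2, 9), xs - 1, t, p)$u, rep(0, 9))
  }

  # divergence-free: finite-difference check at random interior points
  set.seed(4)
  h <- 1e-5
  for (rep in 1:25) {
    x <- runif(1, 0.1, 1.9); y <- runif(1, -0.9, 0.9); t <- runif(1, 0, 40)
    dudx <- (quadruple_eddy_velocity(x + h, y, t, p)$u -
             quadruple_eddy_velocity(x - h, y, t, p)$u) / (2 * h)
    dvdy <- (quadruple_eddy_velocity(x, y + h, t, p)$v -
             quadruple_eddy_velocity(x, y - h, t, p)$v) / (2 * h)
    expect_lt(abs(dudx + dvdy), 1e-6)
  }
})

test_that("Bickley jet velocity matches the analytic stream-function derivatives", {
  p <- bickley_params()
  # at y = 0, t = 0: sech = 1, tanh = 0
  s0 <- sum(p$eps * cos(p$k * 0))
  v0 <- bickley_velocity(0, 0, 0, p)
  expect_equal(v0$u, -p$c[3] + p$U + 2 * p$U * 0 * s0)
  expect_equal(v0$u, p$U * (1 - 0.461), tolerance = 1e-12)
  expect_equal(v0$u, 33.77, tolerance = 1e-3)

  # numerical differentiation of the stream function
  psi <- function(x, y, t) {
    p$c[3] * y - p$U * p$L * tanh(y / p$L) +
      p$U * p$L / cosh(y / p$L)^2 *
        sum(p$eps * cos(p$k * (x - p$sigma * t)))
  }
  set.seed(12)
  h <- 0.5
  for (rep in 1:20) {
    x <- runif(1, 0, 2e7); y <- runif(1, -3e6, 3e6); t <- runif(1, 0, 40) * 86400
    v <- bickley_velocity(x, y, t, p)
    u_fd <- -(psi(x, y + h, t) - psi(x, y - h, t)) / (2 * h)
    v_fd <- (psi(x + h, y, t) - psi(x - h, y, t)) / (2 * h)
    expect_equal(v$u, u_fd, tolerance = 1e-6)
    expect_equal(v$v, v_fd, tolerance = 1e-6)
  }

  # perturbation decays away from the jet (sech^2): u approaches -c3
  far <- bickley_velocity(1e7, 8e6, 1e5, p)
  expect_lt(abs(far$u + p$c[3]) / p$c[3], 0.02)
  expect_lt(abs(far$v), 0.05)
  # wave-1 spatial period approximately matches the periodic domain
  expect_equal(2 * pi / p$k[1], 2.0015e7, tolerance = 1e-4)
})

test_that("ensemble advection integrates exactly on simple fields and at fifth order", {
  zero_field <- function(x, y, t, params) list(u = 0 * x, v = 0 * x)
  p <- list(t_span = c(0, 10), domain = list(x = c(0, 1), y = c(0, 1)))
  e0 <- advect_ensemble(zero_field, 5, p, n_saved = 11, dt = 0.1, seed = 2)
  for (k in 1:11) expect_equal(e0$positions[, k, ], e0$positions[, 1, ])

  const_field <- function(x, y, t, params) list(u = rep(0.3, length(x)),
                                                v = rep(-0.2, length(x)))
  ec <- advect_ensemble(const_field, 4, p, n_saved = 6, dt = 0.5, seed = 3)
  for (k in 1:6) {
    dtk <- ec$times[k] - ec$times[1]
    expect_equal(ec$positions[, k, 1], ec$positions[, 1, 1] + 0.3 * dtk,
                 tolerance = 1e-12)
    expect_equal(ec$positions[, k, 2], ec$positions[, 1, 2] - 0.2 * dtk,
                 tolerance = 1e-12)
  }

  # solid-body rotation: halving the step cuts the endpoint error ~ 2^5
  rot <- function(x, y, t, params) list(u = -y, v = x)
  pr <- list(t_span = c(0, 2 * pi), domain = list(x = c(-1, 1), y = c(-1, 1)))
  x0 <- matrix(c(1, 0), 1, 2)
  err <- sapply(c(0.2, 0.1, 0.05), function(dt) {
    e <- advect_ensemble(rot, 2, pr, n_saved = 2, dt = dt, seed = 1,
                         x0 = rbind(x0, x0))
    sqrt(sum((e$positions[1, 2, ] - c(1, 0))^2))
  })
  expect_gt(err[1] / err[2], 2^5 * 0.7)
  expect_gt(err[2] / err[3], 2^5 * 0.7)
})

test_that("flow simulators are seeded, reproducible and respect their domains", {
  q1 <- simulate_quadruple_eddy(n = 40, seed = 5, n_saved = 21)
  q2 <- simulate_quadruple_eddy(n = 40, seed = 5, n_saved = 21)
  expect_identical(q1$positions, q2$positions)
  expect_true(all(q1$positions[, , 1] >= 0 & q1$positions[, , 1] <= 2))
  expect_true(all(q1$positions[, , 2] >= -1 & q1$positions[, , 2] <= 1))

  b <- simulate_bickley_jet(n = 15, seed = 7, n_saved = 41)
  expect_equal(b$periodic_lengths, c(2e7, NA))
  expect_equal(length(b$times), 41L)
  expect_equal(b$times[41] - b$times[1], 40 * 86400)

  ne1 <- random_noise_ensemble(10, 25, seed = 3)
  ne2 <- random_noise_ensemble(10, 25, seed = 3)
  expect_identical(ne1$positions, ne2$positions)
  expect_true(all(ne1$positions >= 0 & ne1$positions < 1))
})

test_that("noise-ensemble dissimilarities concentrate across pairs", {
  ne <- random_noise_ensemble(60, 500, seed = 11)
  a <- build_adjacency(ne)
  v <- a[upper.tri(a)]
  expect_lt(stats::sd(v) / mean(v), 0.1)
})
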