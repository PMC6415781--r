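#' Quadruple-eddy flow parameters
#'
#' Unsteady four-cell gyre on `x in [0, 2]`, `y in [-1, 1]` (dimensionless,
#' quadrant side length 1). An east-west oscillation of strength `epsilon`
#' at frequency `omega` exchanges drifters between the eastern and western
#' cells while the top/bottom cell rows rotate in opposite senses.
#'
#' @param amplitude velocity amplitude `A` (default 0.1).
#' @param epsilon oscillation strength (default 0.1).
#' @param omega oscillation frequency (default `2*pi/10`, period 10).
#' @param t_span advection interval (default `c(0, 40)`, four oscillation
#'   periods).
#' @return list of class `quadruple_eddy_params`.
#' @export
quadruple_eddy_params <- function(amplitude = 0.1, epsilon = 0.1,
                                  omega = 2 * pi / 10, t_span = c(0, 40)) {
  stopifnot(amplitude > 0, omega > 0)
  structure(list(amplitude = amplitude, epsilon = epsilon, omega = omega,
                 t_span = t_span,
                 domain = list(x = c(0, 2), y = c(-1, 1))),
            class = "quadruple_eddy_params")
}

#' Quadruple-eddy velocity field
#'
#' With `a = epsilon sin(omega t)`, `b = 1 - 2 epsilon sin(omega t)` and
#' `f = a x^2 + b x`:
#' \deqn{u = -\pi A \sin(\pi f)\cos(\pi y), \quad
#'       v = \pi A \cos(\pi f)\sin(\pi y)(2 a x + b).}
#' This is the divergence-free stream-function form
#' `psi = A sin(pi f) sin(pi y)`; the field has four closed recirculating
#' cells whose common boundaries oscillate east-west.
#'
#' @param x,y coordinates (vectorized).
#' @param t time (scalar).
#' @param params a [quadruple_eddy_params()].
#' @return list with components `u` and `v`.
#' @export
quadruple_eddy_velocity <- function(x, y, t, params = quadruple_eddy_params()) {
  a <- params$epsilon * sin(params$omega * t)
  b <- 1 - 2 * params$epsilon * sin(params$omega * t)
  f <- a * x^2 + b * x
  list(u = -pi * params$amplitude * sin(pi * f) * cos(pi * y),
       v =  pi * params$amplitude * cos(pi * f) * sin(pi * y) * (2 * a * x + b))
}

#' Bickley jet flow parameters
#'
#' Meandering zonal jet with flanking eddies, in the co-moving frame of the
#' third Rossby wave (so its eddies are quasi-steady). Stream function
#' `psi = psi0 + psi1` with
#' `psi0 = c3 y - U L tanh(y/L)` and
#' `psi1 = U L sech^2(y/L) sum_n eps_n cos(k_n (x - sigma_n t))`,
#' `k_n = 2 n / r0`. SI units (meters, seconds); the domain is periodic in
#' `x` with extent `2e7` m.
#'
#' @param U jet speed, m/s (default 62.66).
#' @param L jet width scale, m (default 1.77e6).
#' @param eps wave amplitudes (default `c(0.0075, 0.15, 0.3)`).
#' @param c_frac wave speeds as fractions of `U`
#'   (default `c(0.1446, 0.205, 0.461)`).
#' @param r0 planetary radius setting the wavenumbers, m (default 6.371e6).
#' @param t_span_days advection interval in days (default `c(0, 40)`).
#' @return list of class `bickley_params` (speeds in m/s, times in seconds).
#' @export
bickley_params <- function(U = 62.66, L = 1.77e6,
                           eps = c(0.0075, 0.15, 0.3),
                           c_frac = c(0.1446, 0.205, 0.461),
                           r0 = 6.371e6, t_span_days = c(0, 40)) {
  stopifnot(U > 0, L > 0, r0 > 0, length(eps) == 3L, length(c_frac) == 3L)
  cvec <- c_frac * U
  day <- 86400
  structure(list(U = U, L = L, eps = eps, c = cvec, sigma = cvec - cvec[3L],
                 k = 2 * (1:3) / r0, r0 = r0,
                 t_span = t_span_days * day,
                 domain = list(x = c(0, 2e7), y = c(-3e6, 3e6)),
                 periodic_x = 2e7),
            class = "bickley_params")
}

#' Bickley jet velocity field
#'
#' Analytic derivatives of the stream function: `u = -dpsi/dy`,
#' `v = dpsi/dx`. Periodic in `x` with period `2e7` m.
#'
#' @param x,y coordinates in meters (vectorized).
#' @param t time in seconds (scalar).
#' @param params a [bickley_params()].
#' @return list with components `u` and `v` in m/s.
#' @export
bickley_velocity <- function(x, y, t, params = bickley_params()) {
  yl <- y / params$L
  sech2 <- 1 / cosh(yl)^2
  th <- tanh(yl)
  s <- 0; sx <- 0
  for (n in 1:3) {
    phase <- params$k[n] * (x - params$sigma[n] * t)
    s <- s + params$eps[n] * cos(phase)
    sx <- sx + params$eps[n] * params$k[n] * sin(phase)
  }
  u <- -params$c[3L] + params$U * sech2 + 2 * params$U * sech2 * th * s
  v <- -params$U * params$L * sech2 * sx
  list(u = u, v = v)
}

#' Advect an ensemble with fixed-step fifth-order Runge-Kutta
#'
#' Initial positions are drawn uniformly over the domain from `seed`
#' (unless `x0` is given) and advanced with the fifth-order Cash-Karp
#' scheme. Each interval between consecutive saved times is covered by
#' equal substeps no longer than `dt`. In a periodic dimension the
#' velocity field is evaluated at wrapped coordinates but positions are
#' stored unwrapped, so minimum-image distances remain exact.
#'
#' @param field function `(x, y, t, params) -> list(u, v)`.
#' @param n number of particles.
#' @param params flow parameter object carrying `t_span`, `domain` and
#'   optionally `periodic_x`.
#' @param n_saved number of uniformly spaced saved times (including both
#'   endpoints).
#' @param dt maximum integrator step, in the flow's time units.
#' @param seed integer RNG seed for the initial positions.
#' @param x0 optional `n x 2` matrix of initial positions (overrides
#'   `seed` draw).
#' @param clamp clamp particles into a closed (non-periodic) domain,
#'   warning if any step lands outside; domain boundaries of the
#'   quadruple-eddy flow are invariant streamlines, so escape indicates a
#'   step-size failure.
#' @return a [trajectory_ensemble()].
#' @export
advect_ensemble <- function(field, n, params, n_saved, dt, seed = 1L,
                            x0 = NULL, clamp = FALSE) {
  if (n < 2L) stop("need at least two particles")
  dom <- params$domain
  if (is.null(x0)) {
    set.seed(as.integer(seed))
    x0 <- cbind(runif(n, dom$x[1L], dom$x[2L]),
                runif(n, dom$y[1L], dom$y[2L]))
  }
  stopifnot(nrow(x0) == n, ncol(x0) == 2L)
  times <- seq(params$t_span[1L], params$t_span[2L], length.out = n_saved)
  lper <- params$periodic_x
  wrapx <- function(x) {
    if (is.null(lper)) x
    else dom$x[1L] + (x - dom$x[1L]) %% lper
  }
  rhs <- function(x, y, t) field(wrapx(x), y, t, params)

  # Cash-Karp tableau (fifth-order solution weights)
  a2 <- c(1/5)
  a3 <- c(3/40, 9/40)
  a4 <- c(3/10, -9/10, 6/5)
  a5 <- c(-11/54, 5/2, -70/27, 35/27)
  a6 <- c(1631/55296, 175/512, 575/13824, 44275/110592, 253/4096)
  cc <- c(0, 1/5, 3/10, 3/5, 1, 7/8)
  b5 <- c(37/378, 0, 250/621, 125/594, 0, 512/1771)

  pos <- array(NA_real_, dim = c(n, n_saved, 2L))
  x <- x0[, 1L]; y <- x0[, 2L]
  pos[, 1L, 1L] <- x; pos[, 1L, 2L] <- y
  escaped <- FALSE
  for (s in seq_len(n_saved - 1L)) {
    t0 <- times[s]
    span <- times[s + 1L] - t0
    nsub <- max(1L, ceiling(span / dt - 1e-9))
    h <- span / nsub
    for (sub in seq_len(nsub)) {
      tt <- t0 + (sub - 1L) * h
      k1 <- rhs(x, y, tt)
      k2 <- rhs(x + h * a2[1]*k1$u,
                y + h * a2[1]*k1$v, tt + cc[2]*h)
      k3 <- rhs(x + h * (a3[1]*k1$u + a3[2]*k2$u),
                y + h * (a3[1]*k1$v + a3[2]*k2$v), tt + cc[3]*h)
      k4 <- rhs(x + h * (a4[1]*k1$u + a4[2]*k2$u + a4[3]*k3$u),
                y + h * (a4[1]*k1$v + a4[2]*k2$v + a4[3]*k3$v), tt + cc[4]*h)
      k5 <- rhs(x + h * (a5[1]*k1$u + a5[2]*k2$u + a5[3]*k3$u + a5[4]*k4$u),
                y + h * (a5[1]*k1$v + a5[2]*k2$v + a5[3]*k3$v + a5[4]*k4$v),
                tt + cc[5]*h)
      k6 <- rhs(x + h * (a6[1]*k1$u + a6[2]*k2$u + a6[3]*k3$u + a6[4]*k4$u + a6[5]*k5$u),
                y + h * (a6[1]*k1$v + a6[2]*k2$v + a6[3]*k3$v + a6[4]*k4$v + a6[5]*k5$v),
                tt + cc[6]*h)
      x <- x + h * (b5[1]*k1$u + b5[3]*k3$u + b5[4]*k4$u + b5[6]*k6$u)
      y <- y + h * (b5[1]*k1$v + b5[3]*k3$v + b5[4]*k4$v + b5[6]*k6$v)
      if (clamp) {
        tol <- 1e-9 * max(abs(dom$x), abs(dom$y))
        bad <- x < dom$x[1L] - tol | x > dom$x[2L] + tol |
               y < dom$y[1L] - tol | y > dom$y[2L] + tol
        if (any(bad)) escaped <- TRUE
        x <- pmin(pmax(x, dom$x[1L]), dom$x[2L])
        y <- pmin(pmax(y, dom$y[1L]), dom$y[2L])
      }
    }
    pos[, s + 1L, 1L] <- x
    pos[, s + 1L, 2L] <- y
  }
  if (escaped)
    warning("trajectories escaped the closed domain and were clamped; ",
            "consider a smaller `dt`")
  trajectory_ensemble(pos, times,
                      periodic_lengths = c(if (is.null(lper)) NA_real_ else lper,
                                           NA_real_))
}

#' Simulate quadruple-eddy drifters
#'
#' Seeds `n` drifters uniformly over the domain and advects them for four
#' east-west oscillation periods (40 time units). Defaults: integrator step
#' 0.01, 401 saved samples.
#'
#' @param n number of drifters (benchmark value 3000).
#' @param seed RNG seed.
#' @param n_saved saved time samples (default 401).
#' @param dt maximum integrator step (default 0.01).
#' @param params a [quadruple_eddy_params()].
#' @return a [trajectory_ensemble()].
#' @export
simulate_quadruple_eddy <- function(n = 3000L, seed = 1L, n_saved = 401L,
                                    dt = 0.01,
                                    params = quadruple_eddy_params()) {
  advect_ensemble(quadruple_eddy_velocity, n, params, n_saved, dt,
                  seed = seed, clamp = TRUE)
}

#' Simulate Bickley jet particles
#'
#' Seeds `n` particles uniformly over the domain and advects them for 40
#' days saved at 601 uniform steps, periodic in `x`. Default maximum
#' integrator step: 40 days / 4000.
#'
#' @param n number of particles (benchmark value 3000).
#' @param seed RNG seed.
#' @param n_saved saved time samples (default 601).
#' @param dt maximum integrator step in seconds (default 40 days / 4000).
#' @param params a [bickley_params()].
#' @return a [trajectory_ensemble()] with periodic `x`.
#' @export
simulate_bickley_jet <- function(n = 3000L, seed = 1L, n_saved = 601L,
                                 dt = 40 * 86400 / 4000,
                                 params = bickley_params()) {
  advect_ensemble(bickley_velocity, n, params, n_saved, dt, seed = seed)
}

#' Uniform-noise control ensemble
#'
#' Every position of every state at every time is an independent uniform
#' draw from the unit square: structureless data whose dendrogram should
#' keep nearly all states in one dominant branch, with only small
#' splinters at each level.
#'
#' @param n number of states.
#' @param T_ number of time points (reference condition: 2000).
#' @param seed RNG seed.
#' @return a [trajectory_ensemble()].
#' @export
random_noise_ensemble <- function(n, T_, seed = 1L) {
  if (n < 2L || T_ < 2L) stop("need n >= 2 and T >= 2")
  set.seed(as.integer(seed))
  pos <- array(runif(n * T_ * 2L), dim = c(n, T_, 2L))
  trajectory_ensemble(pos, seq_len(T_))
}
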