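# Small fixtures built in code.

# ensemble with explicit per-state 1-D positions: list of numeric vectors
ensemble_1d <- function(..., times = NULL) {
  rows <- list(...)
  T_ <- length(rows[[1L]])
  pos <- array(NA_real_, dim = c(length(rows), T_, 1L))
  for (i in seq_along(rows)) pos[i, , 1L] <- rows[[i]]
  trajectory_ensemble(pos, if (is.null(times)) seq_len(T_) else times)
}

# two-factor planted adjacency: 4 blocks = {supergroup} x {parity}; pairwise
# dissimilarity is additive in the differing factors, near-zero within blocks
planted_4block <- function(per_block = 6, f_super = 1.0, f_parity = 0.6,
                           within = 0.05, noise_sd = 0.01, seed = 42) {
  set.seed(seed)
  super <- rep(c(0, 0, 1, 1), each = per_block)
  parity <- rep(c(0, 1, 0, 1), each = per_block)
  n <- 4L * per_block
  a <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      base <- f_super * (super[i] != super[j]) +
              f_parity * (parity[i] != parity[j])
      if (base == 0) base <- within
      v <- abs(base + stats::rnorm(1, 0, noise_sd))
      a[i, j] <- a[j, i] <- v
    }
  }
  list(a = a, block = 1L + super * 2L + parity)
}

# brute-force generalized eigensolve via the nonsymmetric D^{-1} L problem
# (independent route from the package's symmetric whitening)
brute_general_eigen <- function(a) {
  d <- rowSums(a)
  es <- eigen(diag(1 / d) %*% (diag(d) - a))
  ord <- order(Re(es$values), decreasing = TRUE)
  list(values = Re(es$values)[ord],
       vectors = Re(es$vectors)[, ord, drop = FALSE])
}

# direct separation-standard-deviation dissimilarity from a distance series
sep_sd_from_distances <- function(r) {
  rbar <- mean(r)
  sqrt(sum((rbar - r)^2)) / rbar
}

random_adjacency <- function(n, seed = 1) {
  set.seed(seed)
  m <- matrix(runif(n * n, 0.2, 1), n, n)
  a <- (m + t(m)) / 2
  diag(a) <- 0
  a
}
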