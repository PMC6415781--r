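#' Trajectory-pair dissimilarity
#'
#' Standard deviation-type measure of the instantaneous separation
#' r_ij(t_k) between two trajectories, normalized by the mean separation:
#' \deqn{a_{ij} = \frac{1}{\bar r_{ij}}
#'   \Big[\sum_{k=1}^{T} (\bar r_{ij} - r_{ij}(t_k))^2\Big]^{1/2}.}
#' Drifters that move together keep a near-constant separation and score
#' close to zero; pairs straddling a structure boundary separate
#' exponentially and score high. Note the root of the *sum* over the `T`
#' samples (not the mean), so values grow with `T` at fixed noise level.
#'
#' @param ensemble a [trajectory_ensemble()] with `T >= 2`.
#' @param i,j distinct state indices.
#' @return nonnegative scalar; `0` with a warning when the two states are
#'   coincident at every time point (duplicate states).
#' @export
trajectory_dissimilarity <- function(ensemble, i, j) {
  if (n_times(ensemble) < 2L) stop("need at least two time points")
  if (i == j) stop("`i` and `j` must be distinct states")
  r <- pair_distances(ensemble, i, j)
  rbar <- mean(r)
  if (rbar == 0) {
    warning(sprintf("states %d and %d are coincident at all times (duplicates)", i, j))
    return(0)
  }
  sqrt(sum((rbar - r)^2)) / rbar
}

#' Square-root Jensen-Shannon dissimilarity
#'
#' \eqn{\sqrt{\mathrm{div}_{JS}(P\|Q)}} with
#' \eqn{\mathrm{div}_{JS} = \frac12\sum_i P_i \log(P_i/M_i) +
#' \frac12\sum_i Q_i \log(Q_i/M_i)}, `M = (P+Q)/2`, natural logarithm and
#' the convention `0 log(0/x) = 0`. The square root is a metric bounded by
#' `sqrt(log(2))`, attained at disjoint supports.
#'
#' @param p,q nonnegative numeric vectors of equal length summing to 1
#'   (within `1e-9`).
#' @return scalar in `[0, sqrt(log(2))]`.
#' @export
js_dissimilarity <- function(p, q) {
  if (length(p) != length(q)) stop("`p` and `q` must have equal length")
  if (any(p < 0) || any(q < 0)) stop("probabilities must be nonnegative")
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9)
    stop("`p` and `q` must each sum to 1 (within 1e-9)")
  m <- (p + q) / 2
  kl <- function(a) {
    ok <- a > 0
    sum(a[ok] * log(a[ok] / m[ok]))
  }
  div <- 0.5 * kl(p) + 0.5 * kl(q)
  # tiny negatives from roundoff at p ~ q
  sqrt(max(div, 0))
}

#' Build the pairwise-dissimilarity adjacency matrix
#'
#' Assembles the symmetric, zero-diagonal matrix `A` of the `n(n-1)/2`
#' pairwise dissimilarities that drives the coloring eigenproblem. Note the
#' sign convention: `A` holds DISsimilarities, so the *largest* eigenvalues
#' are the informative ones.
#'
#' @param states a [trajectory_ensemble()], a row-stochastic matrix /
#'   `transition_matrix` (rows compared by [js_dissimilarity()]), or a list
#'   of probability vectors.
#' @param metric `"trajectory"`, `"sqrt_js"`, or a symmetric function
#'   `f(states, i, j)` returning a nonnegative scalar. Defaults to the
#'   natural metric for the input type.
#' @return symmetric `n x n` matrix with `dimnames` from state labels.
#' @export
build_adjacency <- function(states, metric = NULL) {
  if (inherits(states, "trajectory_ensemble")) {
    if (is.null(metric)) metric <- "trajectory"
  } else if (inherits(states, "transition_matrix") ||
             (is.matrix(states) && is.numeric(states))) {
    if (is.null(metric)) metric <- "sqrt_js"
  } else if (is.list(states)) {
    if (is.null(metric)) metric <- "sqrt_js"
  } else stop("unsupported `states` input")

  if (is.function(metric)) return(adjacency_from_function(states, metric))
  metric <- match.arg(metric, c("trajectory", "sqrt_js"))

  if (metric == "trajectory") {
    if (!inherits(states, "trajectory_ensemble"))
      stop("metric \"trajectory\" needs a trajectory_ensemble")
    if (n_states(states) < 2L) stop("need at least two states")
    if (n_times(states) < 2L) stop("need at least two time points")
    res <- cpp_trajectory_adjacency(states$positions, states$periodic_lengths)
    a <- res$adjacency
    if (res$n_coincident > 0L)
      warning(sprintf("%d state pair(s) coincident at all times (duplicates)",
                      res$n_coincident))
    dimnames(a) <- list(states$labels, states$labels)
    return(validate_adjacency(a))
  }

  # sqrt Jensen-Shannon on rows / list of distributions
  if (inherits(states, "transition_matrix")) states <- states$probs
  if (is.list(states)) states <- do.call(rbind, lapply(states, as.numeric))
  n <- nrow(states)
  if (n < 2L) stop("need at least two states")
  a <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      v <- js_dissimilarity(states[i, ], states[j, ])
      if (!is.finite(v)) stop(sprintf("non-finite dissimilarity for pair (%d, %d)", i, j))
      a[i, j] <- a[j, i] <- v
    }
  }
  if (!is.null(rownames(states))) dimnames(a) <- list(rownames(states), rownames(states))
  validate_adjacency(a)
}

adjacency_from_function <- function(states, metric) {
  n <- if (inherits(states, "trajectory_ensemble")) n_states(states)
       else if (is.matrix(states)) nrow(states)
       else length(states)
  if (n < 2L) stop("need at least two states")
  a <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      v <- metric(states, i, j)
      if (!is.finite(v) || v < 0)
        stop(sprintf("metric returned an invalid value for pair (%d, %d)", i, j))
      a[i, j] <- a[j, i] <- v
    }
  }
  validate_adjacency(a)
}

#' Validate an adjacency (dissimilarity) matrix
#'
#' Checks symmetry, zero diagonal, finiteness and nonnegativity.
#'
#' @param a numeric square matrix.
#' @param tol symmetry tolerance.
#' @return the matrix, invisibly unchanged (diagonal forced to exact zero).
#' @export
validate_adjacency <- function(a, tol = 1e-8) {
  if (!is.matrix(a) || !is.numeric(a) || nrow(a) != ncol(a))
    stop("adjacency must be a square numeric matrix")
  if (!all(is.finite(a))) stop("adjacency entries must be finite")
  if (any(a < 0)) stop("adjacency entries must be >= 0")
  scale <- max(abs(a), 1)
  if (max(abs(a - t(a))) > tol * scale) stop("adjacency must be symmetric")
  if (max(abs(diag(a))) > tol * scale) stop("adjacency diagonal must be zero")
  a <- (a + t(a)) / 2
  diag(a) <- 0
  a
}
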