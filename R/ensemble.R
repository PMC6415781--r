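#' Trajectory ensemble container
#'
#' Bundles `n` state trajectories sampled on a shared time grid. Positions
#' are stored unwrapped; periodic dimensions are declared via
#' `periodic_lengths` and wrapping is applied only when distances are
#' computed (minimum-image convention) or when positions are exported.
#'
#' @param positions numeric array `n x T x d` (state, time, coordinate).
#' @param times strictly increasing numeric vector of length `T`.
#' @param periodic_lengths optional numeric vector of length `d`; entry `l > 0`
#'   marks a periodic dimension of extent `l`, `NA` a non-periodic one.
#' @param labels optional character state identifiers (default `"s1".."sn"`).
#'
#' @return An object of class `trajectory_ensemble` with fields `positions`,
#'   `times`, `periodic_lengths`, `labels`.
#' @export
trajectory_ensemble <- function(positions, times, periodic_lengths = NULL,
                                labels = NULL) {
  if (!is.array(positions) || length(dim(positions)) != 3L)
    stop("`positions` must be an n x T x d array")
  dm <- dim(positions)
  n <- dm[1L]; T_ <- dm[2L]; d <- dm[3L]
  if (n < 1L) stop("need at least one state")
  if (!all(is.finite(positions))) stop("positions must be finite")
  if (length(times) != T_) stop("length(times) must equal dim(positions)[2]")
  if (T_ >= 2L && any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  if (is.null(periodic_lengths)) periodic_lengths <- rep(NA_real_, d)
  if (length(periodic_lengths) != d)
    stop("`periodic_lengths` must have one entry per spatial dimension")
  if (any(!is.na(periodic_lengths) & periodic_lengths <= 0))
    stop("periodic lengths must be > 0")
  if (is.null(labels)) labels <- paste0("s", seq_len(n))
  if (length(labels) != n) stop("`labels` must have one entry per state")
  structure(
    list(positions = positions, times = as.numeric(times),
         periodic_lengths = as.numeric(periodic_lengths),
         labels = as.character(labels)),
    class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  dm <- dim(x$positions)
  per <- which(!is.na(x$periodic_lengths))
  cat(sprintf("<trajectory_ensemble: %d states, %d time points, %d dims%s>\n",
              dm[1L], dm[2L], dm[3L],
              if (length(per)) paste0(", periodic dim ",
                                      paste(per, collapse = ",")) else ""))
  invisible(x)
}

n_states <- function(ensemble) dim(ensemble$positions)[1L]
n_times  <- function(ensemble) dim(ensemble$positions)[2L]

#' Instantaneous distances between two states
#'
#' Euclidean distance at every shared time point, using the minimum-image
#' convention in periodic dimensions.
#'
#' @param ensemble a [trajectory_ensemble()].
#' @param i,j state indices.
#' @return numeric vector of length `T`.
#' @export
pair_distances <- function(ensemble, i, j) {
  dm <- dim(ensemble$positions)
  if (i < 1L || i > dm[1L] || j < 1L || j > dm[1L]) stop("state index out of range")
  d2 <- 0
  for (dd in seq_len(dm[3L])) {
    delta <- ensemble$positions[i, , dd] - ensemble$positions[j, , dd]
    l <- ensemble$periodic_lengths[dd]
    if (!is.na(l)) delta <- delta - l * round(delta / l)
    d2 <- d2 + delta^2
  }
  sqrt(d2)
}
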