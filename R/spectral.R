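#' Degree vector and graph Laplacian
#'
#' `D` is the diagonal matrix of row sums of the adjacency `A`; the graph
#' Laplacian is `L = D - A`. Every row of `L` sums to zero, so the constant
#' vector is always in its null space.
#'
#' @param a symmetric adjacency (dissimilarity) matrix, see
#'   [validate_adjacency()].
#' @return list with `degrees` (numeric vector) and `laplacian` (matrix).
#' @export
degree_and_laplacian <- function(a) {
  a <- validate_adjacency(a)
  degrees <- rowSums(a)
  if (any(degrees <= 0))
    stop("zero-degree state(s) at index ",
         paste(which(degrees <= 0), collapse = ", "),
         ": remove or merge duplicate states before coloring")
  laplacian <- diag(degrees) - a
  dimnames(laplacian) <- dimnames(a)
  list(degrees = degrees, laplacian = laplacian)
}

#' Solve the coloring eigenproblem
#'
#' Solves the generalized eigenproblem `L X = lambda D X` for all `n`
#' eigenpairs, sorted by *descending* eigenvalue. Because `A` stores
#' dissimilarities, the top eigenvector `X_1` maximizes the coloring merit
#' `z` (the generalized Rayleigh quotient) and gives the single most
#' effective partition; subsequent eigenvectors give orthogonal, weaker
#' partitions. The problem is reduced to an ordinary symmetric eigenproblem
#' by the similarity transform `M = D^{-1/2} L D^{-1/2}`.
#'
#' Conventions: eigenvectors are normalized to `X_k' D X_k = 1` (so the
#' merit of `X_k` equals `lambda_k`) and signed so that the
#' largest-magnitude entry is positive; downstream logic is invariant to
#' sign flips.
#'
#' @param a symmetric adjacency matrix with positive row sums.
#' @param tol relative residual tolerance for
#'   `||L X_k - lambda_k D X_k|| <= tol * ||D X_k||`.
#' @return object of class `csc_coloring`: `values` (descending
#'   eigenvalues), `vectors` (n x n, column k is `X_k`), `degrees`, `merits`
#'   (per-eigenvector `z`), `labels`.
#' @export
solve_coloring <- function(a, tol = 1e-8) {
  dl <- degree_and_laplacian(a)
  d <- dl$degrees
  s <- 1 / sqrt(d)
  m <- dl$laplacian * tcrossprod(s)      # D^{-1/2} L D^{-1/2}
  m <- (m + t(m)) / 2
  es <- eigen(m, symmetric = TRUE)       # descending eigenvalues
  values <- es$values
  vectors <- es$vectors * s              # X = D^{-1/2} Y, X' D X = I
  # canonical sign: largest-|entry| positive (ties -> first such entry)
  for (k in seq_along(values)) {
    i <- which.max(abs(vectors[, k]))
    if (vectors[i, k] < 0) vectors[, k] <- -vectors[, k]
  }
  values[values < 0 & values > -tol] <- 0
  # residual check on the generalized problem; one BLAS product serves both
  # the residual and the merit values z = X_k' L X_k
  lx <- dl$laplacian %*% vectors
  dx <- d * vectors
  resid <- lx - sweep(dx, 2L, values, `*`)
  rnorm_ <- sqrt(colSums(resid^2))
  dnorm_ <- sqrt(colSums(dx^2))
  worst <- max(rnorm_ / pmax(dnorm_, .Machine$double.eps))
  if (worst > tol)
    stop(sprintf("eigensolve failed to meet tolerance (worst relative residual %.3e)", worst))
  merits <- pmax(colSums(vectors * lx), 0)
  labels <- rownames(a)
  if (is.null(labels)) labels <- paste0("s", seq_along(d))
  structure(list(values = values, vectors = vectors, degrees = d,
                 merits = merits, labels = labels),
            class = "csc_coloring")
}

#' @export
print.csc_coloring <- function(x, ...) {
  n <- length(x$values)
  cat(sprintf("<csc_coloring: %d states>\n", n))
  cat("top eigenvalues (z of each partition):\n")
  print(head(round(x$values, 6), 8))
  invisible(x)
}

#' Coloring merit z of a scalar assignment
#'
#' `z = 1/2 sum_i sum_j (x_i - x_j)^2 a_ij`, optionally restricted to a
#' subset of states (both sums run over the subset). Computed as the
#' quadratic form `x' L_S x` on the subset Laplacian. For an eigenvector
#' normalized to `X' D X = 1` and the full state set, `z` equals its
#' eigenvalue.
#'
#' @param x numeric vector of scalar assignments (length `n`).
#' @param a adjacency matrix.
#' @param subset optional integer vector of state indices (default all).
#' @return nonnegative scalar; `0` for empty or singleton subsets.
#' @export
coloring_merit <- function(x, a, subset = NULL) {
  n <- nrow(a)
  if (length(x) != n) stop("`x` must have one entry per state")
  if (is.null(subset)) subset <- seq_len(n)
  subset <- as.integer(subset)
  if (length(subset) && (min(subset) < 1L || max(subset) > n))
    stop("subset index out of range")
  if (length(subset) <= 1L) return(0)
  xs <- x[subset]
  as_ <- a[subset, subset, drop = FALSE]
  ds <- rowSums(as_)
  z <- sum(ds * xs^2) - drop(crossprod(xs, as_ %*% xs))
  max(z, 0)
}

#' Export an eigen-solution to delimited text + JSON sidecar
#'
#' Writes one row per state (label plus the scalar assignment in each
#' retained eigenvector) and a JSON sidecar holding eigenvalues and merits.
#'
#' @param solution a `csc_coloring`.
#' @param path output path for the delimited table; the sidecar is written
#'   to `paste0(path, ".json")`.
#' @param depth number of leading eigenvectors to retain (default all).
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_coloring <- function(solution, path, depth = NULL, sep = "\t") {
  n <- length(solution$values)
  if (is.null(depth)) depth <- n
  depth <- min(depth, n)
  tab <- data.table::data.table(state = solution$labels)
  for (k in seq_len(depth))
    tab[[paste0("x", k)]] <- solution$vectors[, k]
  data.table::fwrite(tab, path, sep = sep)
  jsonlite::write_json(
    list(eigenvalues = solution$values[seq_len(depth)],
         merits = solution$merits[seq_len(depth)]),
    paste0(path, ".json"), digits = NA)
  invisible(path)
}
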