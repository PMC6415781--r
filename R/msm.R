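#' Row-stochastic transition matrix container
#'
#' @param probs nonnegative `n x n` matrix, each row summing to 1 within
#'   `1e-9`.
#' @param lag_note free-text provenance note.
#' @return object of class `transition_matrix`.
#' @export
transition_matrix <- function(probs, lag_note = "") {
  if (!is.matrix(probs) || nrow(probs) != ncol(probs))
    stop("`probs` must be a square matrix")
  if (any(probs < 0)) stop("transition probabilities must be >= 0")
  if (any(abs(rowSums(probs) - 1) > 1e-9))
    stop("every row must sum to 1 (within 1e-9)")
  structure(list(probs = probs, n = nrow(probs), lag_note = lag_note),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix: %d states%s>\n", x$n,
              if (nzchar(x$lag_note)) paste0(", ", x$lag_note) else ""))
  invisible(x)
}

#' Synthetic transition matrix with planted metastable blocks
#'
#' Generates a row-stochastic matrix emulating a coarse-grainable Markov
#' state model: row `i` places `intra_mass` of its probability on states in
#' its own block (Dirichlet-distributed within the block) and the remainder
#' uniformly-Dirichlet over the other states. The default scale (175
#' microstates, 9 blocks) mirrors a typical protein-folding MSM. Detailed
#' balance is not enforced by default; `reversibilize = TRUE` symmetrizes
#' the stationary flow, `p_ij <- (pi_i p_ij + pi_j p_ji) / (2 pi_i)`.
#'
#' @param n_states number of microstates (default 175).
#' @param n_blocks number of planted blocks (default 9); ignored when
#'   `block_labels` is given.
#' @param block_labels optional integer block id per state.
#' @param intra_mass fraction of each row's probability kept inside its own
#'   block; must be in `(0.5, 1]` (default 0.9).
#' @param concentration Dirichlet concentration for both the within- and
#'   out-of-block masses (default 1).
#' @param seed RNG seed.
#' @param reversibilize enforce detailed balance by stationary-flow
#'   symmetrization (default `FALSE`).
#' @return a [transition_matrix()] with attribute `block_labels`.
#' @export
synthetic_transition_matrix <- function(n_states = 175L, n_blocks = 9L,
                                        block_labels = NULL, intra_mass = 0.9,
                                        concentration = 1,
                                        seed = 1L, reversibilize = FALSE) {
  if (intra_mass <= 0.5 || intra_mass > 1)
    stop("`intra_mass` must be in (0.5, 1]")
  if (is.null(block_labels)) {
    block_labels <- sort(rep_len(seq_len(n_blocks), n_states))
  }
  n <- length(block_labels)
  if (any(tabulate(block_labels) == 0L)) stop("every block must be non-empty")
  set.seed(as.integer(seed))
  rdirichlet1 <- function(k) {
    g <- rgamma(k, shape = concentration)
    g / sum(g)
  }
  p <- matrix(0, n, n)
  for (i in seq_len(n)) {
    own <- which(block_labels == block_labels[i])
    other <- setdiff(seq_len(n), own)
    p[i, own] <- intra_mass * rdirichlet1(length(own))
    if (length(other))
      p[i, other] <- (1 - intra_mass) * rdirichlet1(length(other))
    else
      p[i, own] <- p[i, own] / intra_mass
  }
  if (reversibilize) {
    pi_ <- stationary_distribution(p)
    flow <- (pi_ * p + t(pi_ * p)) / 2
    p <- flow / rowSums(flow)
  }
  tm <- transition_matrix(p, lag_note = sprintf(
    "synthetic planted-block MSM (n=%d, blocks=%d, intra_mass=%.2f, seed=%d)",
    n, length(unique(block_labels)), intra_mass, seed))
  attr(tm, "block_labels") <- as.integer(block_labels)
  tm
}

stationary_distribution <- function(p, tol = 1e-12, max_iter = 10000L) {
  pi_ <- rep(1 / nrow(p), nrow(p))
  for (it in seq_len(max_iter)) {
    nxt <- drop(pi_ %*% p)
    if (max(abs(nxt - pi_)) < tol) return(nxt / sum(nxt))
    pi_ <- nxt
  }
  pi_ / sum(pi_)
}

#' Adjacency matrix from transition-matrix rows
#'
#' Pairwise square-root Jensen-Shannon divergence between the rows, the
#' same dissimilarity metric used by MVCA, so that the spectral coloring
#' and the Ward-linkage cross-check operate on identical inputs.
#'
#' @param tm a [transition_matrix()] or a row-stochastic matrix.
#' @return symmetric adjacency matrix.
#' @export
transition_adjacency <- function(tm) {
  probs <- if (inherits(tm, "transition_matrix")) tm$probs else tm
  build_adjacency(probs, metric = "sqrt_js")
}

#' MVCA coarse-graining (Ward-linkage clustering)
#'
#' Minimum variance clustering analysis: agglomerative hierarchical
#' clustering with Ward's minimum-variance criterion on the pairwise
#' dissimilarities (here, square-root Jensen-Shannon distances), cut into
#' `n_macrostates` clusters. Serves as an independent cross-check of the
#' sCSC macrostates.
#'
#' @param a adjacency (dissimilarity) matrix.
#' @param n_macrostates number of macrostates, `1 <= k <= n`.
#' @return integer macrostate label per state.
#' @export
mvca_cluster <- function(a, n_macrostates) {
  a <- validate_adjacency(a)
  n <- nrow(a)
  if (n_macrostates < 1L || n_macrostates > n)
    stop("`n_macrostates` must be between 1 and n")
  hc <- stats::hclust(stats::as.dist(a), method = "ward.D2")
  unname(stats::cutree(hc, k = n_macrostates))
}

#' Macrostate report
#'
#' Per-macrostate table of branch code and number of member microstates,
#' mirroring the usual summary of a coarse-grained MSM.
#'
#' @param tree an `scsc_tree` built on a transition-matrix adjacency.
#' @param depth analysis depth (default: built depth).
#' @param path optional output: a `.json` or delimited-text file.
#' @return data.frame with columns `code`, `n_microstates`,
#'   `creation_level`.
#' @export
macrostate_report <- function(tree, depth = tree$depth, path = NULL) {
  cl <- converged_clusters(tree, depth)
  df <- data.frame(
    code = vapply(cl, attr, character(1), "code"),
    n_microstates = vapply(cl, length, integer(1)),
    creation_level = vapply(cl, attr, integer(1), "creation_level"),
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  if (!is.null(path)) {
    if (tolower(tools::file_ext(path)) == "json")
      jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA)
    else data.table::fwrite(df, path, sep = "\t")
    return(invisible(df))
  }
  df
}

#' Read / write a square transition matrix as delimited text
#'
#' @param path file path.
#' @param tm a [transition_matrix()].
#' @param sep field separator (default tab).
#' @return [transition_matrix()] for the reader; `path` invisibly for the
#'   writer.
#' @export
read_transition_matrix <- function(path, sep = "auto") {
  m <- as.matrix(data.table::fread(path, sep = sep, header = FALSE))
  dimnames(m) <- NULL
  transition_matrix(m, lag_note = paste0("read from ", basename(path)))
}

#' @rdname read_transition_matrix
#' @export
write_transition_matrix <- function(tm, path, sep = "\t") {
  probs <- if (inherits(tm, "transition_matrix")) tm$probs else tm
  data.table::fwrite(data.table::as.data.table(probs), path, sep = sep,
                     col.names = FALSE)
  invisible(path)
}
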