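#' Bifurcate a scalar field into two groups
#'
#' Splits the scalar assignments of one eigenvector into two clusters by
#' average-linkage agglomerative clustering on `|x_i - x_j|`, cut at the
#' final merge (the two-cluster cut). Bit 0 is assigned to the larger
#' cluster; on a size tie, to the cluster with the smaller mean `x`. The
#' labelling is a package convention: everything downstream is invariant to
#' a global bit swap, and the split itself is invariant (up to that swap)
#' under `x -> -x` and `x -> x + c`.
#'
#' @param x finite numeric vector, length `n >= 2`.
#' @return integer vector of 0/1 labels.
#' @export
bifurcate_scalar_field <- function(x) {
  n <- length(x)
  if (n < 2L) stop("need at least two states to bifurcate")
  if (!all(is.finite(x))) stop("`x` must be finite")
  rng <- max(x) - min(x)
  if (rng <= 0 || rng < 1e-12 * max(abs(x)))
    stop("degenerate split: all scalar assignments equal")
  hc <- stats::hclust(stats::dist(x), method = "average")
  grp <- stats::cutree(hc, k = 2L)
  size1 <- sum(grp == 1L)
  size2 <- n - size1
  if (size1 != size2) {
    larger <- if (size1 > size2) 1L else 2L
  } else {
    larger <- if (mean(x[grp == 1L]) <= mean(x[grp == 2L])) 1L else 2L
  }
  as.integer(grp != larger)
}

#' Assign binary codes from the eigenvector sequence
#'
#' Walks the eigenvectors in descending-eigenvalue order; level `k`
#' bifurcates eigenvector `X_k` *globally* (all states at once) and
#' contributes bit `k` of every state's code, leading bit first. The
#' trailing constant eigenvector (`lambda = 0`) is never used, so
#' `depth <= n - 1`. A level whose eigenvector cannot be split (all entries
#' equal) is flagged inert and contributes a uniform 0 bit.
#'
#' @param solution a `csc_coloring` from [solve_coloring()].
#' @param depth number of eigenvectors to consume (`1 <= depth <= n - 1`).
#' @return object of class `binary_code_table`: `bits` (n x depth 0/1
#'   matrix), `codes` (character bit strings), `depth`, `inert` (logical per
#'   level), `labels`.
#' @export
assign_codes <- function(solution, depth) {
  n <- length(solution$values)
  depth <- as.integer(depth)
  if (depth < 1L || depth > n - 1L)
    stop("`depth` must be between 1 and n - 1")
  bits <- matrix(0L, n, depth)
  inert <- logical(depth)
  for (k in seq_len(depth)) {
    lab <- tryCatch(bifurcate_scalar_field(solution$vectors[, k]),
                    error = function(e) NULL)
    if (is.null(lab)) {
      inert[k] <- TRUE           # uniform bit, level contributes no split
    } else {
      bits[, k] <- lab
    }
  }
  codes <- apply(bits, 1L, paste, collapse = "")
  structure(list(bits = bits, codes = codes, depth = depth, inert = inert,
                 labels = solution$labels),
            class = "binary_code_table")
}

#' @export
print.binary_code_table <- function(x, ...) {
  occ <- sort(table(x$codes), decreasing = TRUE)
  cat(sprintf("<binary_code_table: %d states, depth %d, %d occupied codes>\n",
              length(x$codes), x$depth, length(occ)))
  print(head(occ, 10))
  invisible(x)
}

#' Build the occupancy dendrogram
#'
#' Prefix tree over the occupied binary codes. A node splitting at level `k`
#' gets a branch-pair length equal to the coloring merit of the globally
#' normalized eigenvector `X_k` restricted to the node's members; both
#' children inherit that length. A node whose members all receive the same
#' next bit has exactly one pass-through child (identical member set,
#' branch length 0), so every occupied code reaches the full depth.
#'
#' @param codes a `binary_code_table` from [assign_codes()].
#' @param solution the `csc_coloring` the codes came from.
#' @param a the adjacency matrix (same `n` states).
#' @return object of class `scsc_tree`: `nodes` data.frame (`id`, `parent`,
#'   `level`, `prefix`, `count`, `width`, `branch_z`, `split_z`,
#'   `passthrough`, `creation_level`, `is_leaf`), `members` (list of integer
#'   vectors per node), `depth`, `n`, `labels`.
#' @export
build_dendrogram <- function(codes, solution, a) {
  n <- length(codes$codes)
  if (nrow(a) != n || length(solution$values) != n)
    stop("codes, solution and adjacency must refer to the same states")
  depth <- codes$depth
  nodes <- list()
  members <- list()
  add_node <- function(parent, level, prefix, mem, branch_z, passthrough,
                       creation_level) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- list(id = id, parent = parent, level = level,
                         prefix = prefix, count = length(mem),
                         width = length(mem) / n, branch_z = branch_z,
                         split_z = NA_real_, passthrough = passthrough,
                         creation_level = creation_level)
    members[[id]] <<- mem
    id
  }
  root <- add_node(NA_integer_, 0L, "", seq_len(n), 0, FALSE, 0L)
  frontier <- root
  for (k in seq_len(depth)) {
    new_frontier <- integer(0)
    for (id in frontier) {
      mem <- members[[id]]
      b <- codes$bits[mem, k]
      created <- nodes[[id]]$creation_level
      if (length(unique(b)) == 1L) {
        # visual pass-through: single child, same member set
        child <- add_node(id, k, paste0(nodes[[id]]$prefix, b[1L]), mem,
                          0, TRUE, created)
        new_frontier <- c(new_frontier, child)
      } else {
        z <- coloring_merit(solution$vectors[, k], a, subset = mem)
        nodes[[id]]$split_z <- z
        for (bit in c(0L, 1L)) {
          child <- add_node(id, k, paste0(nodes[[id]]$prefix, bit),
                            mem[b == bit], z, FALSE, k)
          new_frontier <- c(new_frontier, child)
        }
      }
    }
    frontier <- new_frontier
  }
  df <- data.frame(
    id = vapply(nodes, `[[`, integer(1), "id"),
    parent = vapply(nodes, `[[`, integer(1), "parent"),
    level = vapply(nodes, `[[`, integer(1), "level"),
    prefix = vapply(nodes, `[[`, character(1), "prefix"),
    count = vapply(nodes, `[[`, integer(1), "count"),
    width = vapply(nodes, `[[`, numeric(1), "width"),
    branch_z = vapply(nodes, `[[`, numeric(1), "branch_z"),
    split_z = vapply(nodes, `[[`, numeric(1), "split_z"),
    passthrough = vapply(nodes, `[[`, logical(1), "passthrough"),
    creation_level = vapply(nodes, `[[`, integer(1), "creation_level"),
    stringsAsFactors = FALSE)
  df$is_leaf <- !(df$id %in% df$parent)
  structure(list(nodes = df, members = members, depth = depth, n = n,
                 labels = solution$labels),
            class = "scsc_tree")
}

#' @export
print.scsc_tree <- function(x, ...) {
  leaves <- x$nodes[x$nodes$is_leaf, ]
  cat(sprintf("<scsc_tree: %d states, depth %d, %d leaves>\n",
              x$n, x$depth, nrow(leaves)))
  show <- leaves[order(-leaves$count), c("prefix", "count", "creation_level")]
  rownames(show) <- NULL
  print(head(show, 12))
  invisible(x)
}

#' Converged clusters of a dendrogram
#'
#' The clusters of the system are the branches whose member set undergoes no
#' further splitting between their creation level and `depth`: the leaves of
#' the tree built to that depth. Each returned set carries its bit code,
#' creation level, and the number of levels it has survived unsplit
#' (`stable_levels = depth - creation_level`), which callers can use to
#' distinguish long-converged structures from freshly created ones.
#'
#' @param tree an `scsc_tree` from [build_dendrogram()].
#' @param depth analysis depth; must not exceed the built depth (default:
#'   the built depth).
#' @return list of integer member vectors, one per converged cluster, with
#'   attributes `code`, `creation_level`, `stable_levels` on each element;
#'   the sets are disjoint and together cover all states.
#' @export
converged_clusters <- function(tree, depth = tree$depth) {
  depth <- as.integer(depth)
  if (depth > tree$depth) stop("`depth` exceeds the built tree depth")
  at <- tree$nodes[tree$nodes$level == depth, , drop = FALSE]
  # collapse pass-through chains: report each member set once, with the
  # level at which it was created
  out <- lapply(seq_len(nrow(at)), function(r) {
    mem <- tree$members[[at$id[r]]]
    structure(mem,
              code = at$prefix[r],
              creation_level = at$creation_level[r],
              stable_levels = depth - at$creation_level[r])
  })
  names(out) <- at$prefix
  out[order(-vapply(out, length, integer(1)))]
}

#' Cluster labels from converged clusters
#'
#' Flat integer labelling of states from the output of
#' [converged_clusters()], largest cluster first.
#'
#' @param clusters list returned by [converged_clusters()].
#' @param n total number of states.
#' @return integer vector of length `n`.
#' @export
cluster_labels <- function(clusters, n) {
  lab <- integer(n)
  for (i in seq_along(clusters)) lab[clusters[[i]]] <- i
  lab
}
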