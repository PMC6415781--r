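#' Export a dendrogram to Newick
#'
#' Writes the occupancy tree as a Newick string. Pass-through chains are
#' collapsed (they add zero branch length), so the exported tree is the
#' binary tree of actual splits. Leaf and internal node labels are the
#' bit-code prefixes (leaves keep their full code); branch lengths are in z
#' units.
#'
#' @param tree an `scsc_tree`.
#' @param path optional output file; when `NULL` the string is returned.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  df <- tree$nodes
  kids <- split(df$id, factor(df$parent, levels = df$id))
  recurse <- function(id, acc_len) {
    ch <- kids[[as.character(id)]]
    if (is.null(ch) || length(ch) == 0L) {
      return(sprintf("%s:%.10g", df$prefix[id], acc_len))
    }
    if (length(ch) == 1L) {
      # pass-through: collapse into the child, accumulating (zero) length
      return(recurse(ch, acc_len + df$branch_z[ch]))
    }
    inner <- paste(vapply(ch, function(c2) recurse(c2, df$branch_z[c2]),
                          character(1)), collapse = ",")
    lab <- if (df$prefix[id] == "") "root" else df$prefix[id]
    sprintf("(%s)%s:%.10g", inner, lab, acc_len)
  }
  s <- paste0(recurse(df$id[is.na(df$parent)], 0), ";")
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' Dendrogram report
#'
#' Per-node summary table (branch code, member count, width fraction,
#' branch length in z units, creation level) mirroring the red/black label
#' annotations of the tree figures, plus a JSON writer.
#'
#' @param tree an `scsc_tree`.
#' @param path optional JSON output path.
#' @param seed optional seed to record in the JSON report.
#' @return data.frame of node statistics (invisibly when written).
#' @export
dendrogram_report <- function(tree, path = NULL, seed = NULL) {
  df <- tree$nodes
  rep_df <- df[!df$passthrough | df$level == 0L,
               c("prefix", "level", "count", "width", "branch_z",
                 "creation_level", "is_leaf")]
  names(rep_df)[1L] <- "code"
  rownames(rep_df) <- NULL
  if (!is.null(path)) {
    payload <- list(
      n_states = tree$n,
      depth = tree$depth,
      nodes = rep_df,
      converged = lapply(converged_clusters(tree), function(m)
        list(code = attr(m, "code"),
             creation_level = attr(m, "creation_level"),
             count = length(m),
             members = tree$labels[m])))
    if (!is.null(seed)) payload$seed <- seed
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
    return(invisible(rep_df))
  }
  rep_df
}

#' Plot an sCSC dendrogram
#'
#' Branch pairs are drawn at 45-degree angles: a node splitting with merit
#' `z` places its children at horizontal offsets `+/- z` and vertical drop
#' `z`, so both axes are in z units. Line width is proportional to the
#' fraction of states in the branch. Pass-through (unsplit) branches
#' continue vertically.
#'
#' @param tree an `scsc_tree`.
#' @param path optional image file (`.png` or `.pdf`); when `NULL`, plots to
#'   the active device.
#' @param labels draw bit-code (black) and member-count (red) labels.
#' @param label_depth deepest level to label (default 4).
#' @param max_lwd line width of a branch holding all states.
#' @param ... passed to [grDevices::png()] or [grDevices::pdf()].
#' @return coordinates data.frame, invisibly.
#' @export
plot_dendrogram <- function(tree, path = NULL, labels = TRUE, label_depth = 4L,
                            max_lwd = 12, ...) {
  df <- tree$nodes
  kids <- split(df$id, factor(df$parent, levels = df$id))
  xs <- ys <- rep(NA_real_, nrow(df))
  root <- df$id[is.na(df$parent)]
  xs[root] <- 0; ys[root] <- 0
  # level-sweep: children positioned from parent and split merit
  for (lv in seq_len(tree$depth)) {
    for (id in df$id[df$level == lv]) {
      p <- df$parent[id]
      z <- df$branch_z[id]
      if (df$passthrough[id]) {
        xs[id] <- xs[p]; ys[id] <- ys[p]  # zero-length continuation
      } else {
        sib <- kids[[as.character(p)]]
        sgn <- if (id == min(sib)) -1 else 1
        xs[id] <- xs[p] + sgn * z
        ys[id] <- ys[p] - z
      }
    }
  }
  opened <- FALSE
  if (!is.null(path)) {
    ext <- tolower(tools::file_ext(path))
    if (ext == "pdf") grDevices::pdf(path, ...)
    else grDevices::png(path, width = 1200, height = 900, res = 150, ...)
    opened <- TRUE
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  graphics::plot(NA, xlim = range(xs, na.rm = TRUE) + c(-1, 1) * 0.05 * max(1e-12, diff(range(xs, na.rm = TRUE))),
                 ylim = range(ys, na.rm = TRUE), xlab = "z", ylab = "z",
                 main = "sCSC dendrogram", bty = "n")
  for (id in df$id[df$level > 0L]) {
    p <- df$parent[id]
    graphics::segments(xs[p], ys[p], xs[id], ys[id],
                       lwd = max(0.4, max_lwd * df$width[id]))
    if (labels && !df$passthrough[id] && df$level[id] <= label_depth) {
      graphics::text(xs[id], ys[id], df$prefix[id], pos = 1, cex = 0.6)
      graphics::text(xs[id], ys[id], df$count[id], pos = 3, cex = 0.6,
                     col = "red")
    }
  }
  invisible(data.frame(id = df$id, x = xs, y = ys))
}
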