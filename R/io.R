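#' Read / write long-form trajectory files
#'
#' The on-disk format is long-form delimited text (comma or tab,
#' auto-detected) with columns `state_id`, `time`, `coord_1` .. `coord_d`.
#' All states must share exactly the same time grid; ragged grids are an
#' error naming the offending states.
#'
#' @param path input file.
#' @param sep field separator; `"auto"` (default) lets the reader detect
#'   comma or tab.
#' @param periodic_lengths optional per-dimension periodic extents, passed
#'   to [trajectory_ensemble()].
#' @return a [trajectory_ensemble()].
#' @export
read_trajectories <- function(path, sep = "auto", periodic_lengths = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- tryCatch(
    as.data.frame(data.table::fread(path, sep = sep, header = TRUE)),
    error = function(e) stop("failed to parse ", path, ": ", conditionMessage(e)))
  if (ncol(dt) < 3L)
    stop("expected columns state_id, time, coord_1..coord_d")
  names(dt)[1:2] <- c("state_id", "time")
  coord_cols <- names(dt)[-(1:2)]
  for (cc in c("time", coord_cols)) {
    if (!is.numeric(dt[[cc]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(dt[[cc]]))))[1L]
      stop(sprintf("non-numeric value in column '%s' near line %d", cc,
                   if (is.na(bad)) NA_integer_ else bad + 1L))
    }
  }
  ids <- unique(dt$state_id)
  n <- length(ids)
  if (n < 2L) stop("need at least two states (found ", n, ")")
  times <- sort(unique(dt$time))
  T_ <- length(times)
  counts <- table(dt$state_id)
  ragged <- names(counts)[counts != T_]
  if (length(ragged))
    stop("states with time grids differing from the shared grid: ",
         paste(head(ragged, 10), collapse = ", "))
  d <- length(coord_cols)
  pos <- array(NA_real_, dim = c(n, T_, d))
  ord <- order(match(dt$state_id, ids), dt$time)
  dts <- dt[ord, , drop = FALSE]
  if (any(dts$time != rep(times, n)))
    stop("states do not share the same time grid")
  for (dd in seq_len(d))
    pos[, , dd] <- matrix(dts[[coord_cols[dd]]], nrow = n, byrow = TRUE)
  if (any(!is.finite(pos))) stop("non-finite positions in ", path)
  trajectory_ensemble(pos, times, periodic_lengths = periodic_lengths,
                      labels = as.character(ids))
}

#' @rdname read_trajectories
#' @param ensemble a [trajectory_ensemble()].
#' @export
write_trajectories <- function(ensemble, path, sep = "\t") {
  dm <- dim(ensemble$positions)
  d <- dm[3L]
  dt <- data.table::data.table(
    state_id = rep(ensemble$labels, each = dm[2L]),
    time = rep(ensemble$times, dm[1L]))
  for (dd in seq_len(d))
    dt[[paste0("coord_", dd)]] <- as.vector(t(ensemble$positions[, , dd]))
  data.table::fwrite(dt, path, sep = sep)
  invisible(path)
}

#' Read / write a square adjacency matrix as delimited text
#'
#' Optional header row carries state labels.
#'
#' @param path file path.
#' @param a adjacency matrix.
#' @param sep field separator.
#' @param header whether the file has (writer: gets) a label header row.
#' @return validated adjacency matrix (reader); `path` invisibly (writer).
#' @export
read_adjacency <- function(path, sep = "auto", header = "auto") {
  dt <- data.table::fread(path, sep = sep, header = header)
  m <- as.matrix(dt)
  labs <- colnames(dt)
  if (!is.null(labs) && !all(grepl("^V[0-9]+$", labs)))
    dimnames(m) <- list(labs, labs)
  else dimnames(m) <- NULL
  validate_adjacency(m)
}

#' @rdname read_adjacency
#' @export
write_adjacency <- function(a, path, sep = "\t", header = TRUE) {
  dt <- data.table::as.data.table(a)
  if (header && !is.null(colnames(a))) data.table::setnames(dt, colnames(a))
  data.table::fwrite(dt, path, sep = sep, col.names = header)
  invisible(path)
}

#' Run the full sCSC pipeline
#'
#' Composes input, metric, eigensolve, coding and export stages. Input is
#' one of: a `trajectory_ensemble` / `transition_matrix` / adjacency matrix
#' object, a file path (`trajectories`, `transition_matrix` or `adjacency`
#' type), or a named simulation (`"quadruple_eddy"`, `"bickley"`,
#' `"noise"`). Deterministic given the config and seed; the JSON report
#' contains no timestamps so identical configs yield byte-identical output.
#'
#' @param input data object or file path, see above.
#' @param input_type one of `"auto"`, `"trajectories"`, `"adjacency"`,
#'   `"transition_matrix"`, `"quadruple_eddy"`, `"bickley"`, `"noise"`.
#' @param depth maximum number of eigenvectors (default 7); the walk also
#'   stops early after a level that produces no new split.
#' @param min_branch_z optional merit threshold: splits with `z` below it
#'   are suppressed (default 0, keep all).
#' @param n,seed,T_ simulation size, seed and (noise) time points, used when
#'   `input` names a simulator.
#' @param periodic_lengths for trajectory-file input.
#' @param out_prefix optional path prefix; writes `<prefix>_coloring.tsv`
#'   (+ `.json` sidecar), `<prefix>_tree.nwk`, `<prefix>_report.json`, and
#'   `<prefix>_tree.png` when `plot = TRUE`.
#' @param plot write a dendrogram image (needs `out_prefix`).
#' @param quiet suppress per-stage log messages.
#' @return list with `ensemble` (or `NULL`), `adjacency`, `solution`,
#'   `codes`, `tree`, `report`, `depth_used`, `seed`.
#' @export
run_pipeline <- function(input, input_type = "auto", depth = 7L,
                         min_branch_z = 0, n = 1000L, seed = 1L, T_ = 500L,
                         periodic_lengths = NULL, out_prefix = NULL,
                         plot = FALSE, quiet = FALSE) {
  say <- function(stage, t0) {
    if (!quiet)
      message(sprintf("[scsc] %-12s %6.2fs", stage,
                      as.numeric(proc.time()[3L]) - t0))
  }
  stage_t <- as.numeric(proc.time()[3L])
  ensemble <- NULL
  a <- NULL
  if (is.character(input) && length(input) == 1L &&
      input %in% c("quadruple_eddy", "bickley", "noise")) {
    input_type <- input
    input <- NULL
  }
  if (input_type == "auto") {
    if (inherits(input, "trajectory_ensemble")) input_type <- "trajectories"
    else if (inherits(input, "transition_matrix")) input_type <- "transition_matrix"
    else if (is.matrix(input)) input_type <- "adjacency"
    else if (is.character(input)) stop(
      "for file input, set `input_type` to \"trajectories\", \"adjacency\" or \"transition_matrix\"")
    else stop("unrecognized input")
  }
  switch(input_type,
    quadruple_eddy = { ensemble <- simulate_quadruple_eddy(n = n, seed = seed) },
    bickley        = { ensemble <- simulate_bickley_jet(n = n, seed = seed) },
    noise          = { ensemble <- random_noise_ensemble(n = n, T_ = T_, seed = seed) },
    trajectories   = {
      ensemble <- if (is.character(input))
        read_trajectories(input, periodic_lengths = periodic_lengths)
      else input
    },
    adjacency = {
      a <- if (is.character(input)) read_adjacency(input)
           else validate_adjacency(input)
    },
    transition_matrix = {
      tm <- if (is.character(input)) read_transition_matrix(input) else input
      a <- transition_adjacency(tm)
    },
    stop("unknown input_type: ", input_type))
  say("input", stage_t)

  stage_t <- as.numeric(proc.time()[3L])
  if (is.null(a)) a <- build_adjacency(ensemble)
  say("adjacency", stage_t)

  stage_t <- as.numeric(proc.time()[3L])
  solution <- solve_coloring(a)
  say("eigensolve", stage_t)

  stage_t <- as.numeric(proc.time()[3L])
  n_states_ <- nrow(a)
  depth <- min(as.integer(depth), n_states_ - 1L)
  codes <- assign_codes(solution, depth)
  if (min_branch_z > 0)
    codes <- suppress_weak_splits(codes, solution, a, min_branch_z)
  # stop early after a level that produced no new split
  depth_used <- effective_depth(codes)
  if (depth_used < depth) {
    codes$bits <- codes$bits[, seq_len(depth_used), drop = FALSE]
    codes$codes <- apply(codes$bits, 1L, paste, collapse = "")
    codes$inert <- codes$inert[seq_len(depth_used)]
    codes$depth <- depth_used
  }
  tree <- build_dendrogram(codes, solution, a)
  say("coding", stage_t)

  report <- dendrogram_report(tree)
  if (!is.null(out_prefix)) {
    stage_t <- as.numeric(proc.time()[3L])
    write_coloring(solution, paste0(out_prefix, "_coloring.tsv"),
                   depth = depth_used)
    write_newick(tree, paste0(out_prefix, "_tree.nwk"))
    dendrogram_report(tree, paste0(out_prefix, "_report.json"), seed = seed)
    if (plot) plot_dendrogram(tree, paste0(out_prefix, "_tree.png"))
    say("export", stage_t)
  }
  list(ensemble = ensemble, adjacency = a, solution = solution,
       codes = codes, tree = tree, report = report,
       depth_used = depth_used, seed = seed)
}

# depth up to (not including) the first level that refines the partition by
# no new split; an entirely split-free level ends the eigenvector walk
effective_depth <- function(codes) {
  bits <- codes$bits
  depth <- ncol(bits)
  part <- rep(0, nrow(bits))
  prev_groups <- 1L
  for (k in seq_len(depth)) {
    part <- part * 2 + bits[, k]
    g <- length(unique(part))
    if (g == prev_groups) return(max(k - 1L, 1L))
    prev_groups <- g
  }
  depth
}

# zero out bits at levels whose global split merit is below the threshold
suppress_weak_splits <- function(codes, solution, a, min_branch_z) {
  for (k in seq_len(codes$depth)) {
    if (codes$inert[k]) next
    z <- coloring_merit(solution$vectors[, k], a)
    if (z < min_branch_z) {
      codes$bits[, k] <- 0L
      codes$inert[k] <- TRUE
    }
  }
  codes$codes <- apply(codes$bits, 1L, paste, collapse = "")
  codes
}
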