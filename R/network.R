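#' Sliding-window specification
#'
#' @param length_tp window length in time points (default 50, i.e. 100 s at
#'   TR = 2 s).
#' @param step_tp step between window starts in time points (default 1, i.e.
#'   2 s at TR = 2 s).
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(length_tp = 50, step_tp = 1) {
  length_tp <- as.integer(length_tp); step_tp <- as.integer(step_tp)
  if (length_tp < 3) .stop_input("window length must be at least 3 time points")
  if (step_tp < 1) .stop_input("window step must be at least 1 time point")
  structure(list(length_tp = length_tp, step_tp = step_tp),
            class = "window_spec")
}

#' Graph-construction configuration
#'
#' How a windowed correlation matrix becomes a graph. Defaults: weighted
#' edges, negative correlations discarded, no sparsity thresholding, edge
#' length equal to the reciprocal of the correlation weight.
#'
#' @param mode `"weighted"` (edge length 1/r) or `"binary"` (edge length 1).
#' @param negative_policy `"discard"` drops negative correlations,
#'   `"absolute"` uses their absolute value.
#' @param sparsity optional fraction in (0, 1]: keep only the top
#'   `ceiling(sparsity * n * (n - 1) / 2)` edges by absolute weight, ties
#'   broken by lexicographic node-pair order.
#' @return An object of class `graph_config`.
#' @export
graph_config <- function(mode = c("weighted", "binary"),
                         negative_policy = c("discard", "absolute"),
                         sparsity = NULL) {
  mode <- match.arg(mode)
  negative_policy <- match.arg(negative_policy)
  if (!is.null(sparsity)) {
    if (!is.numeric(sparsity) || length(sparsity) != 1 ||
        sparsity <= 0 || sparsity > 1)
      .stop_input("sparsity must be a single value in (0, 1]")
  }
  structure(list(mode = mode, negative_policy = negative_policy,
                 sparsity = sparsity), class = "graph_config")
}

#' Enumerate sliding windows
#'
#' Half-open, 0-based index ranges `[k * step, k * step + length)` for
#' `k = 0 ... floor((T - length) / step)`.
#'
#' @param n_timepoints series length T.
#' @param spec a [window_spec()].
#' @return Data frame with columns `start` and `end` (0-based, half-open),
#'   one row per window.
#' @export
make_windows <- function(n_timepoints, spec = window_spec()) {
  stopifnot(inherits(spec, "window_spec"))
  n_timepoints <- as.integer(n_timepoints)
  if (n_timepoints < spec$length_tp)
    .stop_input("series of %d time points is shorter than the window (%d)",
                n_timepoints, spec$length_tp)
  k <- 0:((n_timepoints - spec$length_tp) %/% spec$step_tp)
  data.frame(start = k * spec$step_tp, end = k * spec$step_tp + spec$length_tp)
}

#' Windowed functional connectivity
#'
#' Pearson correlation matrix of all node pairs over one window. Nodes with
#' zero variance inside the window get zero correlations (with a warning) so
#' the matrix stays finite.
#'
#' @param ts a [roi_timeseries()] object.
#' @param window one row of [make_windows()] output (list or data frame with
#'   `start`, `end`, 0-based half-open).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
window_fc <- function(ts, window) {
  stopifnot(inherits(ts, "roi_ts"))
  start <- as.integer(window$start); end <- as.integer(window$end)
  if (start < 0 || end > n_timepoints(ts) || end - start < 3)
    .stop_input("window [%d, %d) out of bounds or too short for a %d-point series",
                start, end, n_timepoints(ts))
  x <- t(ts$data[, (start + 1):end, drop = FALSE])
  sds <- apply(x, 2, sd)
  r <- suppressWarnings(cor(x))
  if (any(sds == 0)) {
    warning(sprintf("%d node(s) have zero variance in window [%d, %d); correlations set to 0",
                    sum(sds == 0), start, end), call. = FALSE)
    r[sds == 0, ] <- 0
    r[, sds == 0] <- 0
  }
  diag(r) <- 1
  dimnames(r) <- list(ts$node_ids, ts$node_ids)
  r
}

#' Correlation matrix to graph
#'
#' Converts a windowed correlation matrix into an undirected graph encoded as
#' a dense edge-length matrix (0 = no edge). Negative correlations are
#' discarded or rectified per the configured policy; an optional sparsity
#' threshold keeps the strongest edges by absolute weight.
#'
#' @param fc symmetric correlation matrix with unit diagonal.
#' @param config a [graph_config()].
#' @return Object of class `fc_graph`: list with `length` (edge-length
#'   matrix), `weight` (edge-weight matrix), `mode`, `n_nodes`.
#' @export
fc_to_graph <- function(fc, config = graph_config()) {
  stopifnot(inherits(config, "graph_config"))
  fc <- as.matrix(fc)
  if (nrow(fc) != ncol(fc) || max(abs(fc - t(fc))) > 1e-10)
    .stop_input("functional-connectivity matrix must be symmetric")
  n <- nrow(fc)
  w <- fc
  diag(w) <- 0
  if (config$negative_policy == "discard") w[w < 0] <- 0 else w <- abs(w)
  if (!is.null(config$sparsity)) {
    ut <- which(upper.tri(w), arr.ind = TRUE)
    ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]   # lexicographic pairs
    vals <- w[ut]
    keep_n <- ceiling(config$sparsity * n * (n - 1) / 2)
    ord <- order(-abs(vals), seq_along(vals))           # ties: pair order
    drop_idx <- ord[-seq_len(min(keep_n, length(ord)))]
    if (length(drop_idx)) {
      di <- ut[drop_idx, , drop = FALSE]
      w[di] <- 0
      w[di[, c(2, 1), drop = FALSE]] <- 0
    }
  }
  if (all(w == 0))
    warning("graph has no edges after thresholding", call. = FALSE)
  len <- matrix(0, n, n)
  pos <- w > 0
  len[pos] <- if (config$mode == "weighted") 1 / w[pos] else 1
  structure(list(length = len, weight = w, mode = config$mode, n_nodes = n),
            class = "fc_graph")
}

#' Nodal global efficiency
#'
#' For node i, `E_i = (1 / (N - 1)) * sum_{j != i} 1 / d(i, j)` where d is
#' the shortest-path length along edge lengths; unreachable pairs contribute
#' 0. Computed by a compiled Floyd-Warshall all-pairs shortest-path kernel.
#'
#' @param graph an `fc_graph` from [fc_to_graph()], or a dense edge-length
#'   matrix (0 or non-finite = no edge).
#' @return Numeric vector of per-node efficiencies.
#' @export
nodal_efficiency <- function(graph) {
  len <- if (inherits(graph, "fc_graph")) graph$length else as.matrix(graph)
  if (nrow(len) < 2) .stop_input("graph must have at least 2 nodes")
  if (any(len < 0, na.rm = TRUE)) .stop_input("edge lengths must be non-negative")
  as.numeric(nodal_efficiency_kernel(len))
}

#' Dynamic nodal-efficiency curves
#'
#' Slides a window along the series; for each window builds the
#' functional-connectivity graph and computes nodal global efficiency.
#'
#' @param ts a [roi_timeseries()] object.
#' @param spec a [window_spec()].
#' @param config a [graph_config()].
#' @return Object of class `eff_curves`: list with `data` (node-by-window
#'   matrix), `window_starts` (0-based), `node_ids`.
#' @export
efficiency_curves <- function(ts, spec = window_spec(),
                              config = graph_config()) {
  stopifnot(inherits(ts, "roi_ts"))
  win <- make_windows(n_timepoints(ts), spec)
  eff <- matrix(NA_real_, n_nodes(ts), nrow(win),
                dimnames = list(ts$node_ids, NULL))
  for (k in seq_len(nrow(win))) {
    fc <- window_fc(ts, win[k, ])
    eff[, k] <- nodal_efficiency(fc_to_graph(fc, config))
  }
  structure(list(data = eff, window_starts = win$start, node_ids = ts$node_ids),
            class = "eff_curves")
}

#' Dynamic nodal-efficiency (dnE) correlation matrix
#'
#' Pearson correlation between every pair of nodal-efficiency curves: entry
#' (i, j) measures how synchronously the efficiencies of nodes i and j
#' fluctuate across windows. Curves with zero variance are flagged as
#' degenerate and their entries set to 0 (with a warning) rather than
#' propagating NaN.
#'
#' @param curves an `eff_curves` object from [efficiency_curves()], or a
#'   node-by-window matrix.
#' @param node_ids node identifiers when `curves` is a bare matrix.
#' @return Object of class `dne_matrix`: list with `data` (symmetric
#'   node-by-node matrix, unit diagonal, entries in \[-1, 1\]), `node_ids`,
#'   `degenerate_nodes`.
#' @export
dne_matrix <- function(curves, node_ids = NULL) {
  if (inherits(curves, "eff_curves")) {
    m <- curves$data; node_ids <- curves$node_ids
  } else {
    m <- as.matrix(curves)
    if (is.null(node_ids)) node_ids <- rownames(m)
    if (is.null(node_ids)) node_ids <- sprintf("n%03d", seq_len(nrow(m)))
  }
  if (ncol(m) < 3)
    .stop_input("dnE needs at least 3 windows, got %d", ncol(m))
  sds <- apply(m, 1, sd)
  degen <- which(sds == 0)
  r <- suppressWarnings(cor(t(m)))
  if (length(degen)) {
    warning(sprintf("%d node(s) have zero-variance efficiency curves; dnE entries set to 0: %s",
                    length(degen), paste(node_ids[degen], collapse = ", ")),
            call. = FALSE)
    r[degen, ] <- 0
    r[, degen] <- 0
  }
  diag(r) <- 1
  r <- (r + t(r)) / 2
  r[r > 1] <- 1; r[r < -1] <- -1
  dimnames(r) <- list(node_ids, node_ids)
  structure(list(data = r, node_ids = node_ids,
                 degenerate_nodes = node_ids[degen]),
            class = "dne_matrix")
}

#' @export
print.dne_matrix <- function(x, ...) {
  cat(sprintf("<dne_matrix> %d x %d, %d degenerate node(s)\n",
              nrow(x$data), ncol(x$data), length(x$degenerate_nodes)))
  invisible(x)
}

#' Write / read a dnE matrix as TSV
#'
#' TSV with node ids as header row and first column.
#'
#' @param dne a `dne_matrix`.
#' @param path file path.
#' @return `path` (write) or a `dne_matrix` (read).
#' @export
write_dne_tsv <- function(dne, path) {
  stopifnot(inherits(dne, "dne_matrix"))
  tab <- data.frame(node_id = dne$node_ids, dne$data, check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dne_tsv
#' @export
read_dne_tsv <- function(path) {
  if (!file.exists(path)) .stop_input("dnE file not found: %s", path)
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  ids <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  dimnames(m) <- list(ids, ids)
  offdiag_zero <- vapply(seq_along(ids),
                         function(i) all(m[i, -i] == 0), logical(1))
  structure(list(data = m, node_ids = ids,
                 degenerate_nodes = ids[offdiag_zero]),
            class = "dne_matrix")
}
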