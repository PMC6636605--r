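#' Read a node-to-macro-region lookup table
#'
#' TSV with columns `node_id`, `node_name`, `macro_region`, `hemisphere`;
#' one row per node, each node mapped exactly once. Any node and region
#' counts are accepted; the packaged full table has 246 nodes in 24 macro
#' regions.
#'
#' @param path file path.
#' @return Object of class `macro_map`: the validated data frame with a
#'   `regions` attribute (region labels in first-appearance order).
#' @export
read_macro_map <- function(path) {
  if (!file.exists(path)) .stop_input("macro-region table not found: %s", path)
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("node_id", "node_name", "macro_region", "hemisphere")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    .stop_input("macro-region table lacks column(s): %s",
                paste(miss, collapse = ", "))
  tab$node_id <- as.character(tab$node_id)
  if (anyDuplicated(tab$node_id))
    .stop_input("duplicate node_id in macro-region table: %s",
                paste(unique(tab$node_id[duplicated(tab$node_id)]),
                      collapse = ", "))
  structure(tab, regions = unique(tab$macro_region), class = c("macro_map",
                                                               "data.frame"))
}

#' The packaged 246-node / 24-region lookup
#'
#' Node-to-macro-region table for the 246-node Brainnetome-style
#' parcellation: 210 cortical nodes in 20 gyral macro regions plus 36
#' subcortical nodes in 4 (amygdala, hippocampus, basal ganglia, thalamus);
#' odd node indices left hemisphere, even right.
#'
#' @return A `macro_map` (see [read_macro_map()]).
#' @export
brainnetome_macro_map <- function() {
  read_macro_map(system.file("extdata", "brainnetome_246_macro.tsv",
                             package = "dnecpm", mustWork = TRUE))
}

#' Average regression weights across folds
#'
#' Arithmetic mean of the per-fold coefficient vectors, counting features
#' not selected in a fold as 0 there — so the mean carries both a feature's
#' weight and its selection frequency.
#'
#' @param per_fold_beta fold-by-feature matrix (e.g. `per_fold_beta` of a
#'   [loocv_predict()] result), or a `cv_result`.
#' @return Numeric per-feature mean weight vector.
#' @export
mean_fold_weights <- function(per_fold_beta) {
  if (inherits(per_fold_beta, "cv_result"))
    per_fold_beta <- per_fold_beta$per_fold_beta
  if (is.null(per_fold_beta)) .stop_input("no per-fold coefficients stored")
  per_fold_beta <- as.matrix(per_fold_beta)
  if (!nrow(per_fold_beta)) .stop_input("need at least one fold")
  colMeans(per_fold_beta)
}

#' Aggregate feature weights into a macro-region matrix
#'
#' Cell (A, B) is the signed mean of the mean weights over all node pairs
#' with one node in region A and the other in B (within-region pairs for
#' A = B), so positively and negatively predictive connection classes remain
#' distinguishable by sign. Region pairs spanned by no feature are 0 and
#' listed in the `empty_cells` attribute.
#'
#' @param mean_weights per-feature mean weight vector.
#' @param pair_index pair index mapping features to node pairs (from
#'   [vectorize_upper()] / [feature_matrix()]).
#' @param map a `macro_map` covering every node in `pair_index`.
#' @return Symmetric region-by-region matrix with region labels as
#'   dimnames.
#' @export
aggregate_macro <- function(mean_weights, pair_index, map) {
  stopifnot(inherits(map, "macro_map"))
  if (length(mean_weights) != nrow(pair_index))
    .stop_input("weights (%d) and pair index (%d) differ in length",
                length(mean_weights), nrow(pair_index))
  region_of <- setNames(map$macro_region, map$node_id)
  nodes <- unique(c(pair_index$node_i, pair_index$node_j))
  unmapped <- setdiff(nodes, names(region_of))
  if (length(unmapped))
    .stop_input("node(s) missing from macro-region table: %s",
                paste(unmapped, collapse = ", "))
  regions <- attr(map, "regions")
  ra <- region_of[pair_index$node_i]
  rb <- region_of[pair_index$node_j]
  # order each pair so (A,B) and (B,A) pool together
  swap <- match(ra, regions) > match(rb, regions)
  tmp <- ra[swap]; ra[swap] <- rb[swap]; rb[swap] <- tmp
  key <- paste(ra, rb, sep = "\r")
  sums <- tapply(mean_weights, key, sum)
  counts <- tapply(rep(1, length(key)), key, sum)
  out <- matrix(0, length(regions), length(regions),
                dimnames = list(regions, regions))
  parts <- strsplit(names(sums), "\r", fixed = TRUE)
  for (k in seq_along(sums)) {
    a <- parts[[k]][1]; b <- parts[[k]][2]
    out[a, b] <- out[b, a] <- sums[[k]] / counts[[k]]
  }
  filled <- matrix(FALSE, length(regions), length(regions),
                   dimnames = dimnames(out))
  for (k in seq_along(sums)) {
    a <- parts[[k]][1]; b <- parts[[k]][2]
    filled[a, b] <- filled[b, a] <- TRUE
  }
  empty <- which(!filled & upper.tri(filled, diag = TRUE), arr.ind = TRUE)
  attr(out, "empty_cells") <-
    if (nrow(empty)) paste(regions[empty[, 1]], regions[empty[, 2]], sep = "--")
    else character(0)
  out
}

#' Per-node prediction efficacy
#'
#' A node's raw score is the sum of absolute mean weights over all features
#' incident to it; scores are then min-max normalized to \[0, 1\] (all zeros
#' if no feature carries weight).
#'
#' @param mean_weights per-feature mean weight vector.
#' @param pair_index pair index mapping features to node pairs.
#' @param n_nodes total node count.
#' @return Numeric vector of length `n_nodes` in \[0, 1\].
#' @export
node_efficacy <- function(mean_weights, pair_index, n_nodes) {
  if (length(mean_weights) != nrow(pair_index))
    .stop_input("weights and pair index differ in length")
  if (max(pair_index$i, pair_index$j) > n_nodes)
    .stop_input("pair index references node beyond n_nodes")
  raw <- numeric(n_nodes)
  aw <- abs(mean_weights)
  for (k in seq_along(aw)) {
    raw[pair_index$i[k]] <- raw[pair_index$i[k]] + aw[k]
    raw[pair_index$j[k]] <- raw[pair_index$j[k]] + aw[k]
  }
  rng <- range(raw)
  if (rng[2] == rng[1]) return(numeric(n_nodes))
  (raw - rng[1]) / (rng[2] - rng[1])
}
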