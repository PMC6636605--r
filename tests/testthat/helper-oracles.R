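# Independent oracles used across the suite.

# Nodal efficiency via igraph's Dijkstra all-pairs distances (independent
# of the package's Floyd-Warshall kernel).
igraph_efficiency <- function(len) {
  n <- nrow(len)
  adj <- len
  adj[!is.finite(adj) | adj <= 0] <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  d <- igraph::distances(g, weights = igraph::E(g)$weight)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  rowSums(inv) / (n - 1)
}

# Value of the penalized objective ||y - X b||^2 + (lambda/2) ||b||_1.
lasso_objective <- function(X, y, beta, lambda) {
  sum((y - X %*% beta)^2) + (lambda / 2) * sum(abs(beta))
}

# Worst violation of the stationarity conditions of that objective:
# inactive |2 x_k' r| <= lambda/2, active 2 x_k' r = (lambda/2) sign(b_k).
kkt_violation <- function(X, y, beta, lambda) {
  g <- 2 * crossprod(X, y - X %*% beta)
  act <- beta != 0
  v_act <- if (any(act)) max(abs(g[act] - (lambda / 2) * sign(beta[act]))) else 0
  v_inact <- if (any(!act)) max(0, max(abs(g[!act])) - lambda / 2) else 0
  max(v_act, v_inact)
}

# Small standardized random regression instance.
random_instance <- function(n, p, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n) + X[, sample(p, 1)] * rnorm(1, 0, 2)
  list(X = X, y = y)
}

# Random edge-length matrix for an undirected graph on n nodes; binary or
# weighted, with the given edge density.
random_length_matrix <- function(n, weighted, density = 0.6) {
  len <- matrix(0, n, n)
  ut <- which(upper.tri(len))
  present <- runif(length(ut)) < density
  vals <- if (weighted) runif(length(ut), 0.2, 5) else rep(1, length(ut))
  len[ut[present]] <- vals[present]
  len <- len + t(len)
  len
}
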