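test_that("window enumeration matches the count formula", {
  w <- make_windows(240, window_spec(50, 1))
  expect_equal(nrow(w), 191)
  expect_equal(w$start[1], 0)
  expect_equal(w$end[191], 240)
  expect_equal(nrow(make_windows(50, window_spec(50, 1))), 1)
  expect_equal(nrow(make_windows(236, window_spec(50, 1))), 187)
  expect_error(make_windows(49, window_spec(50, 1)), "shorter")
  # formula holds across a grid of (T, length, step)
  for (T in c(60, 101, 240)) for (len in c(10, 50)) for (st in c(1, 2, 7)) {
    expect_equal(nrow(make_windows(T, window_spec(len, st))),
                 (T - len) %/% st + 1)
  }
})

test_that("windowed correlation has the expected fixed points", {
  set.seed(4)
  base <- rnorm(60)
  ts <- roi_timeseries(rbind(base, base, -base, rnorm(60)), "s1", 2)
  fc <- window_fc(ts, list(start = 0, end = 50))
  expect_equal(fc[1, 2], 1)
  expect_equal(fc[1, 3], -1)
  expect_equal(diag(fc), rep(1, 4), ignore_attr = TRUE)
  expect_equal(fc, t(fc))
  # zero-variance node handled with a warning
  ts2 <- roi_timeseries(rbind(base, rep(1, 60)), "s1", 2)
  expect_warning(fc2 <- window_fc(ts2, list(start = 0, end = 50)),
                 "zero variance")
  expect_equal(fc2[1, 2], 0)
  expect_error(window_fc(ts, list(start = 30, end = 90)), "out of bounds")
})

test_that("graph construction applies negative policy and sparsity exactly", {
  n <- 8
  fc <- matrix(0.5, n, n); diag(fc) <- 1
  g <- fc_to_graph(fc, graph_config(mode = "binary"))
  expect_true(all(g$length[upper.tri(g$length)] == 1))

  # sparsity keeps exactly ceiling(s * n (n-1) / 2) edges
  set.seed(5)
  m <- matrix(rnorm(246^2), 246)
  fc246 <- cov2cor(crossprod(m) + diag(246))
  gs <- fc_to_graph(fc246, graph_config(negative_policy = "absolute",
                                        sparsity = 0.1))
  expect_equal(sum(gs$weight[upper.tri(gs$weight)] > 0),
               ceiling(0.1 * 246 * 245 / 2))

  neg <- -abs(fc); diag(neg) <- 1
  expect_warning(ge <- fc_to_graph(neg, graph_config(negative_policy =
                                                       "discard")),
                 "no edges")
  expect_true(all(ge$length == 0))

  expect_error(fc_to_graph(matrix(rnorm(9), 3), graph_config()), "symmetric")
})

test_that("nodal efficiency matches hand computations and the igraph oracle", {
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  expect_equal(nodal_efficiency(tri), rep(1, 3))

  path <- matrix(0, 3, 3)
  path[1, 2] <- path[2, 1] <- path[2, 3] <- path[3, 2] <- 1
  expect_equal(nodal_efficiency(path), c(0.75, 1, 0.75))

  skip_if_not_installed("igraph")
  set.seed(6)
  for (rep in 1:50) {
    n <- sample(4:12, 1)
    len <- random_length_matrix(n, weighted = rep %% 2 == 0)
    expect_equal(nodal_efficiency(len), igraph_efficiency(len),
                 tolerance = 1e-10)
  }
  expect_error(nodal_efficiency(matrix(-1, 3, 3)), "non-negative")
})

test_that("efficiency curves have one column per window and detect stationarity", {
  set.seed(7)
  ts <- roi_timeseries(matrix(rnorm(6 * 240), 6, 240), "s1", 2)
  cur <- efficiency_curves(ts, window_spec(50, 1))
  expect_equal(dim(cur$data), c(6, 191))
  # near-identical node series => binary complete graph in every window
  base <- rnorm(150)
  shared <- rbind(base, base + rnorm(150, 0, 1e-3), base + rnorm(150, 0, 1e-3))
  cur2 <- efficiency_curves(roi_timeseries(shared, "s1", 2),
                            window_spec(50, 10), graph_config(mode = "binary"))
  expect_true(all(cur2$data == 1))
})

test_that("the dnE matrix is a valid correlation structure of the curves", {
  set.seed(8)
  curves <- matrix(rnorm(5 * 40), 5, 40)
  curves[2, ] <- curves[1, ]
  curves[3, ] <- -curves[1, ]
  d <- dne_matrix(curves)
  expect_equal(d$data[1, 2], 1)
  expect_equal(d$data[1, 3], -1)
  expect_true(all(abs(d$data) <= 1))
  expect_equal(d$data, t(d$data))

  curves[4, ] <- 2                      # flat curve -> degenerate node
  expect_warning(dz <- dne_matrix(curves), "zero-variance")
  expect_equal(dz$degenerate_nodes, "n004")
  expect_true(all(dz$data[4, -4] == 0))
  expect_error(dne_matrix(curves[, 1:2]), "3 windows")

  # Pearson invariance under common affine rescaling of the input signals
  ts <- roi_timeseries(matrix(rnorm(5 * 150), 5, 150), "s1", 2)
  d1 <- dne_matrix(efficiency_curves(ts, window_spec(50, 5)))
  ts2 <- roi_timeseries(ts$data * 3.7 + 11, "s1", 2)
  d2 <- dne_matrix(efficiency_curves(ts2, window_spec(50, 5)))
  expect_equal(d1$data, d2$data, tolerance = 1e-9)
})

test_that("dnE matrices survive a TSV round trip", {
  set.seed(9)
  d <- dne_matrix(matrix(rnorm(4 * 30), 4, 30))
  path <- tempfile(fileext = ".tsv")
  write_dne_tsv(d, path)
  d2 <- read_dne_tsv(path)
  expect_equal(d2$data, d$data, tolerance = 1e-12)
  expect_equal(d2$node_ids, d$node_ids)
})
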