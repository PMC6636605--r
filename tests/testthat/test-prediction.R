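test_that("upper-triangle vectorization uses row-major pair order and round-trips", {
  m <- matrix(0, 4, 4)
  m[upper.tri(m)] <- 1:6                 # column-major fill
  m <- m + t(m); diag(m) <- 1
  v <- vectorize_upper(m)
  expect_equal(v$pair_index$i, c(1, 1, 1, 2, 2, 3))
  expect_equal(v$pair_index$j, c(2, 3, 4, 3, 4, 4))
  expect_equal(v$x, m[cbind(v$pair_index$i, v$pair_index$j)])
  # reconstruction
  rec <- matrix(0, 4, 4)
  rec[cbind(v$pair_index$i, v$pair_index$j)] <- v$x
  rec <- rec + t(rec); diag(rec) <- 1
  expect_identical(rec, unname(m))

  big <- diag(246)
  expect_equal(length(vectorize_upper(big)$x), 30135)

  asym <- m; asym[1, 2] <- asym[1, 2] + 1e-6
  expect_error(vectorize_upper(asym), "symmetric")
})

test_that("the penalized fit satisfies the stationarity conditions of its objective", {
  for (seed in 1:8) {
    inst <- random_instance(n = sample(10:40, 1), p = sample(c(5, 15, 60), 1),
                            seed = seed)
    lam <- sample(c(0.02, 0.08, 0.5, 3), 1)
    m <- suppressWarnings(fit_lasso(inst$X, inst$y, lam))
    Xs <- scale(inst$X)
    yc <- inst$y - mean(inst$y)
    expect_lt(kkt_violation(Xs, yc, m$beta, lam), 1e-6)
  }
})

test_that("the penalty threshold and the unpenalized limit behave as derived", {
  inst <- random_instance(20, 10, seed = 42)
  Xs <- scale(inst$X); yc <- inst$y - mean(inst$y)
  lam_max <- 4 * max(abs(crossprod(Xs, yc)))
  m0 <- fit_lasso(inst$X, inst$y, lam_max * 1.0001)
  expect_true(all(m0$beta == 0))
  expect_equal(m0$intercept, mean(inst$y))
  m_below <- fit_lasso(inst$X, inst$y, lam_max * 0.99)
  expect_gt(sum(m_below$beta != 0), 0)

  m_ols <- fit_lasso(inst$X, inst$y, 1e-10)
  ols <- qr.coef(qr(Xs), yc)
  expect_equal(m_ols$beta, unname(ols), tolerance = 1e-6)
})

test_that("no random perturbation of the solution improves the objective", {
  inst <- random_instance(25, 8, seed = 11)
  Xs <- scale(inst$X); yc <- inst$y - mean(inst$y)
  lam <- 0.6
  m <- fit_lasso(inst$X, inst$y, lam)
  f0 <- lasso_objective(Xs, yc, m$beta, lam)
  set.seed(12)
  for (scale_p in c(1e-4, 1e-2, 0.3)) {
    pert <- matrix(rnorm(3000 * 8, 0, scale_p), 3000, 8)
    fvals <- apply(pert, 1, function(d)
      lasso_objective(Xs, yc, m$beta + d, lam))
    expect_true(all(fvals >= f0 - 1e-12))
  }
})

test_that("the fit agrees with an independent solver away from degeneracy", {
  skip_if_not_installed("glmnet")
  for (seed in 1:5) {
    inst <- random_instance(n = 30, p = 12, seed = seed + 100)
    lam <- 2
    m <- fit_lasso(inst$X, inst$y, lam)
    Xs <- scale(inst$X); yc <- inst$y - mean(inst$y)
    gl <- glmnet::glmnet(Xs, yc, lambda = lam / (4 * 30) * c(64, 16, 4, 1),
                         standardize = FALSE, intercept = FALSE,
                         thresh = 1e-14, maxit = 1e8)
    expect_equal(m$beta, as.numeric(gl$beta[, 4]), tolerance = 1e-4)
  }
})

test_that("stronger penalties never increase the L1 norm", {
  inst <- random_instance(30, 20, seed = 13)
  norms <- vapply(c(0.01, 0.05, 0.2, 1, 5, 20), function(l)
    sum(abs(fit_lasso(inst$X, inst$y, l)$beta)), numeric(1))
  expect_true(all(diff(norms) <= 1e-10))
})

test_that("leave-one-out prediction recovers a noiseless linear signal", {
  set.seed(14)
  X <- matrix(rnorm(30 * 10), 30, 10)
  y <- 3 + 2 * X[, 4]
  cv <- loocv_predict(X, y, lambda = 1e-4)
  expect_gte(cv$r, 0.99)
  expect_equal(cv$n_folds, 30)
  expect_length(cv$predictions, 30)
  expect_equal(dim(cv$per_fold_beta), c(30, 10))

  cvc <- suppressWarnings(loocv_predict(X, rep(5, 30), lambda = 0.08))
  expect_true(is.na(cvc$r))
  expect_true(is.finite(cvc$mae))

  expect_error(loocv_predict(X[1:2, ], y[1:2]), "at least 3")
})

test_that("fold models never see the held-out subject", {
  set.seed(15)
  X <- matrix(rnorm(12 * 6), 12, 6)
  y <- rnorm(12) + X[, 2]
  cv1 <- loocv_predict(X, y, lambda = 0.3)
  X_corrupt <- X
  X_corrupt[5, ] <- 1e6                 # garbage in the held-out row
  cv2 <- loocv_predict(X_corrupt, y, lambda = 0.3)
  expect_equal(cv2$per_fold_beta[5, ], cv1$per_fold_beta[5, ],
               tolerance = 1e-12)
})

test_that("evaluation metrics behave under shift, identity and anti-ordering", {
  y <- c(3, 9, 1, 7, 5)
  e1 <- evaluate_predictions(y, y)
  expect_equal(e1$r, 1)
  expect_equal(e1$mae, 0)
  e2 <- evaluate_predictions(y + 5, y, n_targets = 2)
  expect_equal(e2$r, 1)
  expect_equal(e2$mae, 5)
  expect_equal(e2$p_bonferroni, min(1, e2$p_raw * 2))
  e3 <- evaluate_predictions(rev(sort(y)), sort(y))
  expect_lt(e3$r, 0)
  e4 <- evaluate_predictions(y, rep(2, 5))
  expect_true(is.na(e4$r))
})

test_that("the permutation test is deterministic, bounded below, and detects signal", {
  cfg <- synthetic_config(n_subjects = 24, n_nodes = 8, score_range = c(20, 70),
                          signal_pairs = list(c(1, 5), c(2, 6)),
                          effect_size = 2, noise_sd = 0.15, seed = 21)
  g <- generate_dne_direct(cfg)
  fm <- feature_matrix(g$dne, g$subject_ids)
  pt <- permutation_test(fm, g$truth$scores, lambda = 0.08, n_perm = 99,
                         seed = 5)
  expect_gte(pt$p_perm, 1 / 100)        # add-one estimator floor
  expect_lte(pt$p_perm, 0.05)
  expect_length(pt$null_rs, 99)
  pt2 <- permutation_test(fm, g$truth$scores, lambda = 0.08, n_perm = 99,
                          seed = 5)
  expect_identical(pt$null_rs, pt2$null_rs)
  expect_identical(pt$p_perm, pt2$p_perm)
})
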