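#' Vectorize the upper triangle of a dnE matrix
#'
#' Flattens the strict upper triangle in row-major pair order
#' (1,2), (1,3), ..., (1,n), (2,3), ... so that feature k maps to a unique
#' node pair i < j. The pair index allows exact reconstruction of the
#' off-diagonal matrix.
#'
#' @param dne a `dne_matrix` (or a symmetric numeric matrix).
#' @return List with `x` (feature vector of length n(n-1)/2) and
#'   `pair_index` (data frame `i`, `j`, `node_i`, `node_j`).
#' @export
vectorize_upper <- function(dne) {
  if (inherits(dne, "dne_matrix")) {
    m <- dne$data; ids <- dne$node_ids
  } else {
    m <- as.matrix(dne)
    ids <- rownames(m)
    if (is.null(ids)) ids <- sprintf("n%03d", seq_len(nrow(m)))
  }
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-10)
    .stop_input("dnE matrix must be symmetric (tolerance 1e-10)")
  idx <- which(upper.tri(m), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]  # row-major i<j order
  list(x = m[idx],
       pair_index = data.frame(i = idx[, 1], j = idx[, 2],
                               node_i = ids[idx[, 1]], node_j = ids[idx[, 2]],
                               stringsAsFactors = FALSE))
}

#' Assemble the subject-by-feature matrix
#'
#' Stacks the vectorized upper triangles of per-subject dnE matrices into the
#' design matrix of the predictive model.
#'
#' @param dne_list list of `dne_matrix` objects with identical node sets.
#' @param subject_ids optional subject identifiers.
#' @return Object of class `feature_matrix`: list with `X` (subjects x
#'   features), `pair_index`, `subject_ids`.
#' @export
feature_matrix <- function(dne_list, subject_ids = NULL) {
  if (!length(dne_list)) .stop_input("empty dnE list")
  first <- vectorize_upper(dne_list[[1]])
  X <- matrix(NA_real_, length(dne_list), length(first$x))
  X[1, ] <- first$x
  for (i in seq_along(dne_list)[-1]) {
    v <- vectorize_upper(dne_list[[i]])
    if (length(v$x) != ncol(X))
      .stop_input("subject %d has %d features, expected %d", i, length(v$x),
                  ncol(X))
    X[i, ] <- v$x
  }
  if (is.null(subject_ids)) subject_ids <- sprintf("sub%03d", seq_along(dne_list))
  structure(list(X = X, pair_index = first$pair_index,
                 subject_ids = subject_ids),
            class = "feature_matrix")
}

as_X <- function(X) if (inherits(X, "feature_matrix")) X$X else as.matrix(X)

#' Fit the L1-penalized regression
#'
#' Minimizes `||y - x b||_2^2 + (lambda / 2) * ||b||_1` with features
#' standardized to zero mean / unit variance (sample SD) and y centered
#' within the training data; coefficients live in that standardized frame so
#' a single penalty acts comparably across features.
#'
#' The solver follows the piecewise-linear solution path (LARS-lasso
#' homotopy) of the stated objective from the null model down to the target
#' penalty, with cyclic coordinate descent (soft-threshold at `lambda / 4`,
#' since the gradient of the quadratic part in coordinate k is `-2 x_k' r`)
#' as a fallback on numerically degenerate paths, followed by an exact
#' least-squares polish on the selected active set. The stationarity (KKT)
#' conditions — `|2 x_k' (y - x b)| <= lambda / 2` for inactive
#' coefficients, equality with matching sign for active ones — therefore
#' hold to near machine precision.
#' For reference, the same solution is the glmnet gaussian fit with
#' `lambda_glmnet = lambda / (4 n)` and `standardize = FALSE` on the
#' standardized frame (glmnet minimizes `(1/(2n)) RSS + lambda_g ||b||_1`).
#' `lambda = 0` (testing only) falls back to least squares.
#'
#' @param X subject-by-feature matrix or [feature_matrix()].
#' @param y numeric response vector.
#' @param lambda penalty of the objective above (default 0.08).
#' @return Object of class `lasso_model`: `beta` (standardized frame, full
#'   feature length, zeros for dropped features), `beta_original` /
#'   `intercept` (original scale), `lambda`, `center`, `scale`, `kept`
#'   (indices of non-constant features), `y_mean`.
#' @export
fit_lasso <- function(X, y, lambda = 0.08) {
  X <- as_X(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y))
    .stop_input("X rows (%d) and y length (%d) differ", nrow(X), length(y))
  if (nrow(X) < 2) .stop_input("need at least 2 training subjects")
  if (anyNA(X) || any(!is.finite(X)) || anyNA(y) || any(!is.finite(y)))
    .stop_input("non-finite values in training data")
  if (lambda < 0) .stop_input("lambda must be non-negative")
  n <- nrow(X); p <- ncol(X)
  ctr <- colMeans(X)
  scl <- sqrt(pmax(colMeans(X^2) - ctr^2, 0) * n / (n - 1))
  scl[scl < 1e-12] <- 0
  kept <- which(scl > 0)
  if (length(kept) < p)
    warning(sprintf("%d zero-variance feature(s) dropped before fitting",
                    p - length(kept)), call. = FALSE)
  if (!length(kept)) .stop_input("no non-constant features to fit")
  Xs <- sweep(sweep(X[, kept, drop = FALSE], 2, ctr[kept]), 2, scl[kept], "/")
  y_mean <- mean(y)
  yc <- y - y_mean
  beta_kept <- if (lambda == 0) {
    qr.coef(qr(Xs), yc)
  } else {
    b <- as.numeric(lasso_homotopy_cpp(Xs, yc, lambda))
    if (!length(b)) b <- as.numeric(lasso_cd(Xs, yc, lambda))
    # Polish on the selected active set: with signs fixed, the minimizer
    # solves X_A'X_A b_A = X_A'y - (lambda/4) sign(b_A) exactly, sharpening
    # the stationarity conditions to machine precision. Kept only if it
    # preserves the signs and the inactive-gradient bound.
    act <- which(b != 0)
    if (length(act) && length(act) < n) {
      sg <- sign(b[act])
      XA <- Xs[, act, drop = FALSE]
      bA <- tryCatch(solve(crossprod(XA),
                           crossprod(XA, yc) - (lambda / 4) * sg),
                     error = function(e) NULL)
      if (!is.null(bA) && all(sign(bA) == sg)) {
        b2 <- numeric(length(b))
        b2[act] <- bA
        grad <- 2 * crossprod(Xs, yc - Xs %*% b2)
        if (all(abs(grad[-act]) <= lambda / 2 + 1e-9)) b <- b2
      }
    }
    b
  }
  beta_kept[is.na(beta_kept)] <- 0
  beta <- numeric(p)
  beta[kept] <- beta_kept
  beta_orig <- numeric(p)
  beta_orig[kept] <- beta_kept / scl[kept]
  structure(list(beta = beta, beta_original = beta_orig,
                 intercept = y_mean - sum(ctr[kept] * beta_orig[kept]),
                 lambda = lambda, center = ctr, scale = scl, kept = kept,
                 y_mean = y_mean, n_train = n),
            class = "lasso_model")
}

#' @export
predict.lasso_model <- function(object, newdata, ...) {
  newdata <- as_X(newdata)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  drop(newdata %*% object$beta_original) + object$intercept
}

#' @export
print.lasso_model <- function(x, ...) {
  cat(sprintf("<lasso_model> lambda = %g, %d / %d nonzero coefficients\n",
              x$lambda, sum(x$beta != 0), length(x$beta)))
  invisible(x)
}

#' Evaluate predictions against observed scores
#'
#' Pearson correlation with a two-tailed p from the t transform, Bonferroni
#' adjustment across the number of prediction targets tested (two medication
#' states in the reference design), and mean absolute error.
#'
#' @param predictions predicted scores.
#' @param y observed scores.
#' @param n_targets number of targets over which to Bonferroni-correct
#'   (default 1).
#' @return List with `r`, `p_raw`, `p_bonferroni`, `mae`. With constant `y`
#'   or constant predictions, `r` and the p values are `NA` and `mae` is
#'   still returned.
#' @export
evaluate_predictions <- function(predictions, y, n_targets = 1) {
  if (length(predictions) != length(y))
    .stop_input("predictions (%d) and y (%d) differ in length",
                length(predictions), length(y))
  if (length(y) < 3) .stop_input("need at least 3 subjects to evaluate")
  mae <- mean(abs(predictions - y))
  if (sd(y) == 0 || sd(predictions) == 0)
    return(list(r = NA_real_, p_raw = NA_real_, p_bonferroni = NA_real_,
                mae = mae))
  ct <- cor.test(predictions, y, alternative = "two.sided")
  list(r = unname(ct$estimate), p_raw = ct$p.value,
       p_bonferroni = min(1, ct$p.value * n_targets), mae = mae)
}

#' Leave-one-out cross-validated prediction
#'
#' For each subject, fits the penalized model on the remaining N - 1
#' subjects (feature standardization re-estimated within each training fold,
#' so the held-out subject never influences its own fold's model) and
#' predicts the held-out score. Fold order follows subject order.
#'
#' @param X subject-by-feature matrix or [feature_matrix()].
#' @param y observed scores (length N >= 3).
#' @param lambda penalty (default 0.08).
#' @param n_targets targets for the Bonferroni adjustment (default 1).
#' @param store_beta keep the fold-by-feature coefficient matrix (default
#'   TRUE; standardized frame).
#' @return Object of class `cv_result`: `predictions`, `per_fold_beta`,
#'   `r`, `p_raw`, `p_bonferroni`, `mae`, `n_folds`, `lambda`,
#'   `subject_ids`.
#' @export
loocv_predict <- function(X, y, lambda = 0.08, n_targets = 1,
                          store_beta = TRUE) {
  ids <- if (inherits(X, "feature_matrix")) X$subject_ids else NULL
  X <- as_X(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n != length(y)) .stop_input("X rows and y length differ")
  if (n < 3) .stop_input("leave-one-out needs at least 3 subjects")
  if (is.null(ids)) ids <- sprintf("sub%03d", seq_len(n))
  predictions <- numeric(n)
  per_fold_beta <- if (store_beta) matrix(0, n, ncol(X)) else NULL
  for (i in seq_len(n)) {
    fit <- suppressWarnings(
      fit_lasso(X[-i, , drop = FALSE], y[-i], lambda = lambda))
    predictions[i] <- predict(fit, X[i, , drop = FALSE])
    if (store_beta) per_fold_beta[i, ] <- fit$beta
  }
  ev <- evaluate_predictions(predictions, y, n_targets = n_targets)
  structure(list(predictions = predictions, per_fold_beta = per_fold_beta,
                 r = ev$r, p_raw = ev$p_raw, p_bonferroni = ev$p_bonferroni,
                 mae = ev$mae, n_folds = n, lambda = lambda,
                 subject_ids = ids),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d folds, lambda = %g: r = %s, p = %s, MAE = %.3f\n",
              x$n_folds, x$lambda,
              ifelse(is.na(x$r), "NA", sprintf("%.3f", x$r)),
              ifelse(is.na(x$p_raw), "NA", format(x$p_raw, digits = 3)),
              x$mae))
  invisible(x)
}

# Precompute, for every leave-one-out fold, the standardized training
# matrix, the held-out row in that frame, and the kept-feature index. The
# design matrix does not change across label permutations, so this cache
# turns each null iteration into bare solver calls. Skipped (NULL) when the
# cache would exceed ~1.5 GB; callers then fall back to full refits.
make_fold_cache <- function(X) {
  n <- nrow(X)
  if (as.numeric(n) * ncol(X) * (n - 1) * 8 > 1.5e9) return(NULL)
  lapply(seq_len(n), function(i) {
    Xt <- X[-i, , drop = FALSE]
    ctr <- colMeans(Xt)
    scl <- sqrt(pmax(colMeans(Xt^2) - ctr^2, 0) * (n - 1) / (n - 2))
    kept <- which(scl > 1e-12)
    Xs <- sweep(sweep(Xt[, kept, drop = FALSE], 2, ctr[kept]), 2, scl[kept],
                "/")
    xs_out <- (X[i, kept] - ctr[kept]) / scl[kept]
    list(Xs = Xs, xs_out = xs_out, kept = kept)
  })
}

# Leave-one-out Pearson r for one response vector, through the same
# standardize-fit-predict sequence as loocv_predict but without the
# active-set polish or coefficient bookkeeping (the polish refines beta at
# the 1e-5 level and does not move r at permutation resolution).
loocv_r_quick <- function(X, y, lambda, cache = NULL) {
  n <- nrow(X)
  preds <- numeric(n)
  for (i in seq_len(n)) {
    yt <- y[-i]
    ym <- mean(yt)
    if (!is.null(cache)) {
      f <- cache[[i]]
      b <- as.numeric(lasso_homotopy_cpp(f$Xs, yt - ym, lambda))
      if (!length(b)) b <- as.numeric(lasso_cd(f$Xs, yt - ym, lambda))
      preds[i] <- sum(f$xs_out * b) + ym
    } else {
      fit <- suppressWarnings(
        fit_lasso(X[-i, , drop = FALSE], yt, lambda = lambda))
      preds[i] <- predict(fit, X[i, , drop = FALSE])
    }
  }
  if (sd(preds) == 0 || sd(y) == 0) return(NA_real_)
  cor(preds, y)
}

#' Permutation test of the cross-validated correlation
#'
#' Reruns the complete leave-one-out procedure (including per-fold fitting
#' and standardization) on uniformly permuted scores; significance is the
#' one-sided add-one estimate `p = (1 + #{r_null >= r_obs}) / (1 + n_perm)`,
#' which never returns exactly 0.
#'
#' @param X subject-by-feature matrix or [feature_matrix()].
#' @param y observed scores.
#' @param lambda penalty (default 0.08).
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed for the permutation stream.
#' @return Object of class `perm_result`: `r_observed`, `null_rs`,
#'   `n_perm`, `p_perm`, `seed`.
#' @export
permutation_test <- function(X, y, lambda = 0.08, n_perm = 1000, seed = 1) {
  if (n_perm < 1) .stop_input("n_perm must be at least 1")
  X <- as_X(X)
  cache <- make_fold_cache(X)
  r_obs <- loocv_r_quick(X, y, lambda, cache)
  set.seed(seed)
  null_rs <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    yp <- sample(y)
    rb <- loocv_r_quick(X, yp, lambda, cache)
    null_rs[b] <- if (is.na(rb)) -Inf else rb
  }
  p <- (1 + sum(null_rs >= r_obs)) / (1 + n_perm)
  structure(list(r_observed = r_obs, null_rs = null_rs, n_perm = n_perm,
                 p_perm = p, seed = seed),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("<perm_result> observed r = %.3f, p = %.4g (%d permutations)\n",
              x$r_observed, x$p_perm, x$n_perm))
  invisible(x)
}
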