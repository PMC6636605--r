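#' Discard initial volumes
#'
#' Removes the first `n_discard` time points of a series, the usual allowance
#' for magnetization equilibration at the start of a resting-state scan.
#'
#' @param ts a [roi_timeseries()] object.
#' @param n_discard number of leading time points to drop (default 4).
#' @return A [roi_timeseries()] with `n_discard` fewer time points; node order
#'   unchanged.
#' @export
discard_initial_volumes <- function(ts, n_discard = 4) {
  stopifnot(inherits(ts, "roi_ts"))
  n_discard <- as.integer(n_discard)
  if (n_discard < 0) .stop_input("n_discard must be non-negative")
  if (n_discard >= n_timepoints(ts))
    .stop_input("cannot discard %d volumes from a %d-point series",
                n_discard, n_timepoints(ts))
  if (n_discard == 0) return(ts)
  roi_timeseries(ts$data[, -seq_len(n_discard), drop = FALSE],
                 subject_id = ts$subject_id, tr_seconds = ts$tr_seconds,
                 node_ids = ts$node_ids)
}

#' Framewise displacement
#'
#' Power-style framewise displacement from rigid-body realignment parameters:
#' backward differences of the six parameters, rotations converted to arc
#' length on a sphere of radius `head_radius_mm`, summed as absolute values.
#' The first frame has FD 0 by convention.
#'
#' @param motion a [motion_params()] object (translations in mm, rotations in
#'   radians).
#' @param head_radius_mm head radius used to convert rotations to millimetres
#'   (default 50).
#' @return Numeric vector of per-frame displacements (mm), same length as the
#'   number of frames.
#' @export
framewise_displacement <- function(motion, head_radius_mm = 50) {
  stopifnot(inherits(motion, "motion_params"))
  m <- motion$data
  if (nrow(m) < 2) .stop_input("framewise displacement needs at least 2 frames")
  d <- abs(diff(m))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    head_radius_mm * rowSums(d[, 4:6, drop = FALSE])
  c(0, fd)
}

#' Exclude high-motion subjects
#'
#' Partitions a cohort by mean framewise displacement: subjects whose mean FD
#' exceeds `threshold_mm` are excluded. The threshold defaults to 1 mm.
#'
#' @param manifest data frame with at least a `subject_id` column.
#' @param fd_means named numeric vector of per-subject mean FD (names are
#'   subject ids), or an unnamed vector aligned with `manifest` rows.
#' @param threshold_mm exclusion threshold in mm (default 1).
#' @return List with elements `retained` and `excluded` (data frames; the
#'   excluded one carries `mean_fd` and `reason` columns).
#' @export
exclude_high_motion <- function(manifest, fd_means, threshold_mm = 1) {
  manifest <- as.data.frame(manifest)
  ids <- as.character(manifest$subject_id)
  if (!is.null(names(fd_means))) {
    missing <- setdiff(ids, names(fd_means))
    if (length(missing))
      .stop_input("no framewise-displacement summary for subject(s): %s",
                  paste(missing, collapse = ", "))
    fd <- unname(fd_means[ids])
  } else {
    if (length(fd_means) != nrow(manifest))
      .stop_input("fd_means length (%d) does not match manifest rows (%d)",
                  length(fd_means), nrow(manifest))
    fd <- fd_means
  }
  out <- fd > threshold_mm
  excluded <- manifest[out, , drop = FALSE]
  if (nrow(excluded)) {
    excluded$mean_fd <- fd[out]
    excluded$reason <- sprintf("mean FD %.3f mm > %.3f mm", fd[out], threshold_mm)
  } else {
    excluded$mean_fd <- numeric(0)
    excluded$reason <- character(0)
  }
  list(retained = manifest[!out, , drop = FALSE], excluded = excluded)
}

#' Friston 24-parameter motion regressors
#'
#' Expands the six rigid-body parameters P into the 24-column design
#' \[P, P^2, P_lag1, P_lag1^2\]: the parameters, their squares, their one-frame
#' lags (zero-padded at the first frame), and the squared lags.
#'
#' @param motion a [motion_params()] object.
#' @return Numeric time-by-24 matrix.
#' @export
friston24 <- function(motion) {
  stopifnot(inherits(motion, "motion_params"))
  p <- motion$data
  if (nrow(p) < 2) .stop_input("friston24 needs at least 2 frames")
  lag1 <- rbind(0, p[-nrow(p), , drop = FALSE])
  out <- cbind(p, p^2, lag1, lag1^2)
  colnames(out) <- c(paste0("p", 1:6), paste0("p", 1:6, "_sq"),
                     paste0("p", 1:6, "_lag"), paste0("p", 1:6, "_lagsq"))
  out
}

#' Nuisance regression
#'
#' Replaces each node's series by the residuals of an ordinary least-squares
#' fit on an intercept plus the supplied regressor columns (e.g. Friston-24
#' motion expansion and pre-extracted global / CSF / WM signals). Residuals
#' are orthogonal to every regressor. A rank-deficient design is handled by
#' the pivoted QR least-squares solution, with a warning.
#'
#' @param ts a [roi_timeseries()] object.
#' @param regressors time-by-k numeric matrix, or `NULL` for intercept-only
#'   (demeaning).
#' @return A [roi_timeseries()] of residuals.
#' @export
nuisance_regress <- function(ts, regressors = NULL) {
  stopifnot(inherits(ts, "roi_ts"))
  y <- t(ts$data)                       # time x node
  if (is.null(regressors) || NCOL(regressors) == 0) {
    res <- sweep(y, 2, colMeans(y))
  } else {
    regressors <- as.matrix(regressors)
    if (nrow(regressors) != nrow(y))
      .stop_input("regressor rows (%d) do not match time points (%d)",
                  nrow(regressors), nrow(y))
    x <- cbind(1, regressors)
    qx <- qr(x)
    if (qx$rank < ncol(x))
      warning(sprintf("nuisance design is rank deficient (rank %d of %d); using least-squares solution",
                      qx$rank, ncol(x)), call. = FALSE)
    res <- qr.resid(qx, y)
  }
  roi_timeseries(t(res), subject_id = ts$subject_id,
                 tr_seconds = ts$tr_seconds, node_ids = ts$node_ids)
}

#' Zero-phase band-pass filter
#'
#' Applies a 4th-order Butterworth band-pass forward and backward
#' (zero-phase) to each node's series and removes the mean, retaining the
#' conventional resting-state fluctuation band. With `low_hz = 0` the filter
#' degenerates to a low-pass plus demeaning.
#'
#' @param ts a [roi_timeseries()] object.
#' @param low_hz lower cutoff in Hz (default 0.01).
#' @param high_hz upper cutoff in Hz (default 0.10); must be below the
#'   Nyquist frequency `1 / (2 * tr_seconds)`.
#' @param order filter order (default 4).
#' @return A filtered [roi_timeseries()].
#' @export
bandpass <- function(ts, low_hz = 0.01, high_hz = 0.10, order = 4) {
  stopifnot(inherits(ts, "roi_ts"))
  nyq <- 1 / (2 * ts$tr_seconds)
  if (!(low_hz >= 0 && low_hz < high_hz && high_hz < nyq))
    .stop_input("band [%g, %g] Hz invalid: need 0 <= low < high < Nyquist (%g Hz)",
                low_hz, high_hz, nyq)
  if (low_hz > 0) {
    filt <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  } else {
    filt <- signal::butter(order, high_hz / nyq, type = "low")
  }
  x <- sweep(ts$data, 1, rowMeans(ts$data))
  out <- t(apply(x, 1, function(row) signal::filtfilt(filt, row)))
  out <- sweep(out, 1, rowMeans(out))
  roi_timeseries(out, subject_id = ts$subject_id, tr_seconds = ts$tr_seconds,
                 node_ids = ts$node_ids)
}

#' Full temporal conditioning chain
#'
#' Convenience wrapper running volume discarding, nuisance regression and
#' band-pass filtering in a configurable order. Motion parameters, when
#' given, are expanded to the Friston-24 set and their leading rows dropped in
#' step with the discarded volumes; extra nuisance columns (global, CSF, WM
#' signals) are appended to the design.
#'
#' @param ts a [roi_timeseries()] object.
#' @param motion optional [motion_params()] with rows matching the series
#'   before discarding.
#' @param nuisance optional time-by-k matrix of additional regressors (rows
#'   matching the series before discarding).
#' @param n_discard leading volumes to drop (default 4).
#' @param band band-pass limits in Hz (default `c(0.01, 0.10)`).
#' @param order `"regress_first"` (default) regresses nuisance signals before
#'   filtering; `"filter_first"` filters first.
#' @return A conditioned [roi_timeseries()].
#' @export
condition_timeseries <- function(ts, motion = NULL, nuisance = NULL,
                                 n_discard = 4, band = c(0.01, 0.10),
                                 order = c("regress_first", "filter_first")) {
  order <- match.arg(order)
  t_full <- n_timepoints(ts)
  reg <- NULL
  if (!is.null(motion)) {
    if (nrow(motion$data) != t_full)
      .stop_input("motion rows (%d) do not match time points before discarding (%d)",
                  nrow(motion$data), t_full)
    reg <- friston24(motion)
  }
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != t_full)
      .stop_input("nuisance rows (%d) do not match time points before discarding (%d)",
                  nrow(nuisance), t_full)
    reg <- cbind(reg, nuisance)
  }
  out <- discard_initial_volumes(ts, n_discard)
  if (!is.null(reg) && n_discard > 0)
    reg <- reg[-seq_len(n_discard), , drop = FALSE]
  if (order == "regress_first") {
    out <- nuisance_regress(out, reg)
    out <- bandpass(out, band[1], band[2])
  } else {
    out <- bandpass(out, band[1], band[2])
    out <- nuisance_regress(out, reg)
  }
  out
}
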