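#' Synthetic-cohort configuration
#'
#' Parameters for cohorts with a planted, recoverable relation between
#' dnE connectivity and a continuous clinical-style score. Defaults mirror
#' the study conditions the pipeline targets: 62 subjects, the 246-node
#' parcellation, 240 time points at TR = 2 s, and a bounded motor-score
#' scale whose uniform draw over (20, 70) has mean 45 and SD 14.4,
#' comparable to medication-off UPDRS-III in a moderate-to-severe
#' Parkinson's cohort.
#'
#' @param n_subjects number of subjects (default 62).
#' @param n_nodes number of nodes (>= 3; default 246).
#' @param n_timepoints time points per subject (default 240).
#' @param tr_seconds sampling interval in seconds (default 2).
#' @param score_range `c(min, max)` of the true score scale (default
#'   `c(20, 70)`).
#' @param signal_pairs list of 1-based node index pairs `c(i, j)` with
#'   `i < j` carrying the planted signal (default `list(c(1, 2))`).
#' @param effect_size slope b of the planted relation, in Fisher-z units per
#'   standardized score (default 1).
#' @param baseline_z_mean Fisher-z location mu of background connectivity
#'   (default 0.3).
#' @param noise_sd Fisher-z dispersion sigma (> 0; default 0.2). In
#'   time-series mode the node-unique noise SD is `2.5 * noise_sd` against a
#'   unit-variance shared signal.
#' @param modulator_smoothness low-pass cutoff in Hz for the latent
#'   connectivity modulators (default 0.01, i.e. fluctuations slower than
#'   the sliding window).
#' @param seed integer seed; all cohort randomness derives from it.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 62, n_nodes = 246,
                             n_timepoints = 240, tr_seconds = 2,
                             score_range = c(20, 70),
                             signal_pairs = list(c(1, 2)),
                             effect_size = 1, baseline_z_mean = 0.3,
                             noise_sd = 0.2, modulator_smoothness = 0.01,
                             seed = 1) {
  chk <- function(ok, field, msg)
    if (!ok) .stop_input("invalid synthetic_config field '%s': %s", field, msg)
  chk(is.numeric(n_subjects) && n_subjects >= 3, "n_subjects", "need >= 3")
  chk(is.numeric(n_nodes) && n_nodes >= 3, "n_nodes", "need >= 3")
  chk(is.numeric(n_timepoints) && n_timepoints >= 10, "n_timepoints",
      "need >= 10")
  chk(is.numeric(tr_seconds) && tr_seconds > 0, "tr_seconds", "need > 0")
  chk(length(score_range) == 2 && score_range[1] < score_range[2],
      "score_range", "need min < max")
  chk(is.numeric(noise_sd) && noise_sd > 0, "noise_sd", "need > 0")
  chk(is.numeric(modulator_smoothness) && modulator_smoothness > 0 &&
        modulator_smoothness < 1 / (2 * tr_seconds),
      "modulator_smoothness", "need in (0, Nyquist)")
  chk(is.list(signal_pairs), "signal_pairs", "need a list of index pairs")
  for (p in signal_pairs)
    chk(length(p) == 2 && all(p >= 1) && all(p <= n_nodes) && p[1] < p[2],
        "signal_pairs", sprintf("pair (%s) must satisfy 1 <= i < j <= n_nodes",
                                paste(p, collapse = ", ")))
  structure(list(n_subjects = as.integer(n_subjects),
                 n_nodes = as.integer(n_nodes),
                 n_timepoints = as.integer(n_timepoints),
                 tr_seconds = tr_seconds, score_range = score_range,
                 signal_pairs = signal_pairs, effect_size = effect_size,
                 baseline_z_mean = baseline_z_mean, noise_sd = noise_sd,
                 modulator_smoothness = modulator_smoothness,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Per-subject substream: subject i draws from seed + 99991 * i (mod 2^31 - 1),
# so any subject is reproducible without generating the ones before it.
subject_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 99991 * i) %% 2147483647)
}

# Scores drawn uniformly over score_range under the cohort seed, plus a
# medication-on-like companion column (affine rescale of the same latent
# severity with small independent noise).
draw_scores <- function(config) {
  set.seed(config$seed)
  lo <- config$score_range[1]; hi <- config$score_range[2]
  off <- runif(config$n_subjects, lo, hi)
  on <- (off - lo) / (hi - lo) * (0.4 * (hi - lo)) + 0.1 * (hi - lo) +
    rnorm(config$n_subjects, 0, 0.04 * (hi - lo))
  list(off = off, on = on)
}

standardize <- function(x) (x - mean(x)) / sd(x)

#' Generate dnE matrices directly (stage-isolation mode)
#'
#' Plants the score relation in Fisher-z space: for subject i with
#' standardized score s, entry (p, q) is `tanh(z)` with
#' `z = mu + b * s + eps` for planted pairs and `z = mu + eps` otherwise,
#' `eps ~ N(0, sigma^2)`. Entries therefore respect the correlation range
#' (-1, 1) by construction and the planted slope b is recoverable by
#' regressing `atanh(dnE)` on s. This mode bypasses the time-series and
#' graph stages so the prediction stage can be tested in isolation.
#'
#' @param config a [synthetic_config()].
#' @return List with `dne` (list of `dne_matrix`), `truth` (scores,
#'   signal_pairs, effect_size, seed), `subject_ids`.
#' @export
generate_dne_direct <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_nodes
  sc <- draw_scores(config)
  s <- standardize(sc$off)
  ids <- sprintf("sub%03d", seq_len(config$n_subjects))
  node_ids <- sprintf("n%03d", seq_len(n))
  sig <- matrix(FALSE, n, n)
  for (p in config$signal_pairs) {
    sig[p[1], p[2]] <- TRUE; sig[p[2], p[1]] <- TRUE
  }
  dne <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    set.seed(subject_seed(config$seed, i))
    z <- matrix(0, n, n)
    ut <- upper.tri(z)
    z[ut] <- config$baseline_z_mean + rnorm(sum(ut), 0, config$noise_sd)
    z <- z + t(z)
    z[sig] <- z[sig] + config$effect_size * s[i]
    r <- tanh(z)
    diag(r) <- 1
    dimnames(r) <- list(node_ids, node_ids)
    dne[[i]] <- structure(list(data = r, node_ids = node_ids,
                               degenerate_nodes = character(0)),
                          class = "dne_matrix")
  }
  list(dne = dne, subject_ids = ids,
       truth = list(scores = sc$off, scores_on = sc$on,
                    signal_pairs = config$signal_pairs,
                    effect_size = config$effect_size, seed = config$seed))
}

# Low-pass-filtered unit-variance Gaussian modulator.
smooth_modulator <- function(n_tp, tr, cutoff_hz) {
  w <- signal::butter(2, cutoff_hz / (1 / (2 * tr)), type = "low")
  m <- signal::filtfilt(w, rnorm(n_tp))
  (m - mean(m)) / sd(m)
}

#' Generate cohort ROI time series (end-to-end mode)
#'
#' Builds node-by-time matrices whose windowed connectivity carries the
#' planted relation. Every node mixes a shared band-limited community signal
#' with unique Gaussian noise. For a planted pair (p, q), the coupling of p
#' to the community signal is slowly modulated by a latent `m1(t)` and the
#' coupling of q by `a * m1 + sqrt(1 - a^2) * m2`, where
#' `a = (tanh(effect_size * s) + 1) / 2` increases with the subject's
#' standardized score s. The efficiency curves of p and q then co-fluctuate
#' more strongly the higher the score, so the dnE entry (p, q) tracks the
#' score while all other pairs stay uninformative.
#'
#' @param config a [synthetic_config()]; `n_timepoints` must cover at least
#'   two downstream windows (>= 100 at the default window of 50).
#' @return List with `timeseries` (list of [roi_timeseries()]), `truth`,
#'   `subject_ids`.
#' @export
generate_cohort_timeseries <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$n_timepoints < 100)
    .stop_input("n_timepoints (%d) too small: need >= 100 (two 50-point windows)",
                config$n_timepoints)
  n <- config$n_nodes; tp <- config$n_timepoints; tr <- config$tr_seconds
  sc <- draw_scores(config)
  s <- standardize(sc$off)
  alpha <- (tanh(config$effect_size * s) + 1) / 2
  ids <- sprintf("sub%03d", seq_len(config$n_subjects))
  node_ids <- sprintf("n%03d", seq_len(n))
  sig_p <- vapply(config$signal_pairs, function(p) as.integer(p[1]), integer(1))
  sig_q <- vapply(config$signal_pairs, function(p) as.integer(p[2]), integer(1))
  unique_sd <- 2.5 * config$noise_sd
  base_w <- 0.6; mod_w <- 0.5    # coupling = base + mod * modulator
  bandf <- signal::butter(2, c(0.01, 0.10) / (1 / (2 * tr)), type = "pass")
  out <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    set.seed(subject_seed(config$seed, i))
    comm <- signal::filtfilt(bandf, rnorm(tp))
    comm <- (comm - mean(comm)) / sd(comm)
    static_w <- runif(n, 0.5, 0.9)
    x <- matrix(rnorm(n * tp, 0, unique_sd), n, tp)
    x <- x + static_w %o% comm
    for (k in seq_along(sig_p)) {
      m1 <- smooth_modulator(tp, tr, config$modulator_smoothness)
      m2 <- smooth_modulator(tp, tr, config$modulator_smoothness)
      mq <- alpha[i] * m1 + sqrt(1 - alpha[i]^2) * m2
      cp <- base_w + mod_w * m1
      cq <- base_w + mod_w * mq
      x[sig_p[k], ] <- rnorm(tp, 0, unique_sd) + cp * comm
      x[sig_q[k], ] <- rnorm(tp, 0, unique_sd) + cq * comm
    }
    out[[i]] <- roi_timeseries(x, subject_id = ids[i], tr_seconds = tr,
                               node_ids = node_ids)
  }
  list(timeseries = out, subject_ids = ids,
       truth = list(scores = sc$off, scores_on = sc$on,
                    signal_pairs = config$signal_pairs,
                    effect_size = config$effect_size, seed = config$seed))
}

#' Write a synthetic cohort to disk
#'
#' Writes per-subject time-series TSVs, a cohort manifest CSV with
#' medication-off-like and medication-on-like score columns, and a truth JSON
#' (signal pairs, effect size, seed, true scores) — the same formats the
#' real pipeline reads.
#'
#' @param cohort output of [generate_cohort_timeseries()].
#' @param dir output directory (created if needed).
#' @return Path of the manifest CSV, invisibly.
#' @export
write_synthetic_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(cohort$timeseries))
  for (i in seq_along(cohort$timeseries)) {
    paths[i] <- file.path(dir, paste0(cohort$subject_ids[i], "_ts.tsv"))
    write_roi_tsv(cohort$timeseries[[i]], paths[i])
  }
  manifest <- data.frame(subject_id = cohort$subject_ids,
                         timeseries_path = basename(paths),
                         updrs_off = cohort$truth$scores,
                         updrs_on = cohort$truth$scores_on)
  mpath <- file.path(dir, "manifest.csv")
  write.table(manifest, mpath, sep = ",", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(signal_pairs = lapply(cohort$truth$signal_pairs, as.integer),
         effect_size = cohort$truth$effect_size, seed = cohort$truth$seed,
         scores = cohort$truth$scores),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(mpath)
}
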