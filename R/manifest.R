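#' Load and validate a cohort manifest
#'
#' CSV with header columns `subject_id`, `timeseries_path`, optional
#' `motion_path`, and the score columns `updrs_off`, `updrs_on`. Relative
#' paths are resolved against the manifest's directory. Duplicate ids,
#' missing files and non-finite scores are reported with their row numbers.
#'
#' @param path manifest CSV path.
#' @param check_files verify referenced files exist (default TRUE).
#' @return Object of class `cohort_manifest` (a data frame with resolved
#'   paths).
#' @export
load_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) .stop_input("manifest not found: %s", path)
  tab <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
  need <- c("subject_id", "timeseries_path", "updrs_off", "updrs_on")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    .stop_input("manifest lacks column(s): %s", paste(miss, collapse = ", "))
  errs <- character(0)
  dup <- duplicated(tab$subject_id)
  if (any(dup))
    errs <- c(errs, sprintf("row %d: duplicate subject_id '%s'",
                            which(dup), tab$subject_id[dup]))
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                                file.path(base, p))
  tab$timeseries_path <- resolve(tab$timeseries_path)
  if ("motion_path" %in% colnames(tab))
    tab$motion_path <- ifelse(is.na(tab$motion_path) | tab$motion_path == "",
                              NA_character_, resolve(tab$motion_path))
  if (check_files) {
    bad <- !file.exists(tab$timeseries_path)
    if (any(bad))
      errs <- c(errs, sprintf("row %d: missing time-series file '%s'",
                              which(bad), tab$timeseries_path[bad]))
    if ("motion_path" %in% colnames(tab)) {
      badm <- !is.na(tab$motion_path) & !file.exists(tab$motion_path)
      if (any(badm))
        errs <- c(errs, sprintf("row %d: missing motion file '%s'",
                                which(badm), tab$motion_path[badm]))
    }
  }
  for (sc in c("updrs_off", "updrs_on")) {
    badsc <- !is.finite(tab[[sc]])
    if (any(badsc))
      errs <- c(errs, sprintf("row %d: non-finite %s", which(badsc), sc))
  }
  if (length(errs))
    .stop_input("invalid manifest:\n%s", paste(errs, collapse = "\n"))
  class(tab) <- c("cohort_manifest", "data.frame")
  tab
}

#' Pipeline run configuration
#'
#' Bundles every tunable of the end-to-end run. Defaults follow the
#' reference analysis: discard 4 volumes, 0.01-0.10 Hz band, window of 50
#' time points stepped by 1 TR, weighted graphs with negatives discarded,
#' penalty 0.08, 1000 permutations.
#'
#' @param tr_seconds repetition time (default 2).
#' @param n_discard leading volumes to drop (default 4).
#' @param band band-pass limits in Hz (default `c(0.01, 0.10)`).
#' @param fd_threshold_mm mean-FD exclusion threshold (default 1).
#' @param head_radius_mm head radius for FD (default 50).
#' @param window a [window_spec()] (default 50 / 1).
#' @param graph a [graph_config()] (default weighted, discard negatives).
#' @param lambda LASSO penalty (default 0.08).
#' @param n_perm permutations (default 1000).
#' @param seed integer seed for the permutation stream (default 1).
#' @param targets score columns to predict (default both medication states).
#' @param output_dir where run artifacts are written, or `NULL` to skip
#'   writing.
#' @return Object of class `run_config`.
#' @export
run_config <- function(tr_seconds = 2, n_discard = 4, band = c(0.01, 0.10),
                       fd_threshold_mm = 1, head_radius_mm = 50,
                       window = window_spec(), graph = graph_config(),
                       lambda = 0.08, n_perm = 1000, seed = 1,
                       targets = c("updrs_off", "updrs_on"),
                       output_dir = NULL) {
  stopifnot(inherits(window, "window_spec"), inherits(graph, "graph_config"))
  if (!all(targets %in% c("updrs_off", "updrs_on")))
    .stop_input("targets must be among 'updrs_off', 'updrs_on'")
  structure(list(tr_seconds = tr_seconds, n_discard = n_discard, band = band,
                 fd_threshold_mm = fd_threshold_mm,
                 head_radius_mm = head_radius_mm, window = window,
                 graph = graph, lambda = lambda, n_perm = n_perm,
                 seed = as.integer(seed), targets = targets,
                 output_dir = output_dir),
            class = "run_config")
}
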