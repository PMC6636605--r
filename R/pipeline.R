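#' Run the full prediction pipeline
#'
#' Executes, for a validated cohort manifest: motion-based exclusion (when
#' motion tables are provided), temporal conditioning, sliding-window
#' dynamic nodal-efficiency networks, leave-one-out penalized prediction of
#' each target score, permutation inference, and macro-region aggregation of
#' the fold-averaged weights. All randomness flows from `config$seed`, so an
#' identical config and inputs reproduce the report bit for bit.
#'
#' @param manifest a `cohort_manifest` from [load_manifest()], or its path.
#' @param config a [run_config()].
#' @param macro_map optional `macro_map` for weight aggregation; defaults to
#'   the packaged 246-node table when the node count matches, otherwise
#'   aggregation is skipped.
#' @param progress print per-stage progress to standard error (default
#'   FALSE).
#' @return A run report (list): metrics per target, exclusions, warnings,
#'   window count, config echo, package version. Written as `report.json`
#'   together with per-subject dnE TSVs, predictions CSV, per-fold
#'   coefficients, region matrix and node-efficacy CSVs when
#'   `config$output_dir` is set.
#' @export
run_pipeline <- function(manifest, config = run_config(), macro_map = NULL,
                         progress = FALSE) {
  if (is.character(manifest)) manifest <- load_manifest(manifest)
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (progress) message(sprintf(...))
  warnings_log <- character(0)
  note <- function(w) warnings_log <<- c(warnings_log, w)

  # --- motion screening ------------------------------------------------
  excluded <- manifest[0, , drop = FALSE]
  if ("motion_path" %in% colnames(manifest) &&
      any(!is.na(manifest$motion_path))) {
    fd_means <- vapply(seq_len(nrow(manifest)), function(i) {
      if (is.na(manifest$motion_path[i])) return(0)
      mp <- read_motion(manifest$motion_path[i], manifest$subject_id[i])
      mean(framewise_displacement(mp, config$head_radius_mm))
    }, numeric(1))
    names(fd_means) <- manifest$subject_id
    part <- exclude_high_motion(manifest, fd_means, config$fd_threshold_mm)
    excluded <- part$excluded
    manifest <- part$retained
    if (nrow(excluded))
      note(sprintf("excluded %d high-motion subject(s): %s", nrow(excluded),
                   paste(excluded$subject_id, collapse = ", ")))
  }
  n_sub <- nrow(manifest)
  if (n_sub < 3) .stop_input("fewer than 3 subjects after exclusion")

  # --- conditioning + dnE ----------------------------------------------
  dne_list <- vector("list", n_sub)
  n_windows <- NA_integer_
  for (i in seq_len(n_sub)) {
    sid <- manifest$subject_id[i]
    ts <- tryCatch(
      read_roi_tsv(manifest$timeseries_path[i], sid, config$tr_seconds),
      error = function(e) .stop_input("stage conditioning, subject %s: %s",
                                      sid, conditionMessage(e)))
    motion <- NULL
    if ("motion_path" %in% colnames(manifest) && !is.na(manifest$motion_path[i]))
      motion <- read_motion(manifest$motion_path[i], sid)
    cond <- withCallingHandlers(
      condition_timeseries(ts, motion = motion, n_discard = config$n_discard,
                           band = config$band),
      warning = function(w) { note(paste0(sid, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning") })
    curves <- withCallingHandlers(
      efficiency_curves(cond, config$window, config$graph),
      warning = function(w) { note(paste0(sid, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning") })
    n_windows <- ncol(curves$data)
    dne_list[[i]] <- withCallingHandlers(
      dne_matrix(curves),
      warning = function(w) { note(paste0(sid, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning") })
    say("dnE %d/%d (%s): %d windows", i, n_sub, sid, n_windows)
  }
  fm <- feature_matrix(dne_list, manifest$subject_id)

  # --- prediction per target -------------------------------------------
  out_dir <- config$output_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  if (!is.null(out_dir))
    for (i in seq_len(n_sub))
      write_dne_tsv(dne_list[[i]],
                    file.path(out_dir, paste0(manifest$subject_id[i],
                                              "_dne.tsv")))
  if (is.null(macro_map)) {
    mm <- tryCatch(brainnetome_macro_map(), error = function(e) NULL)
    if (!is.null(mm) && nrow(mm) == length(dne_list[[1]]$node_ids)) {
      mm$node_id <- dne_list[[1]]$node_ids   # align by node order
      macro_map <- mm
    }
  }
  results <- list()
  for (target in config$targets) {
    say("predicting %s", target)
    y <- manifest[[target]]
    cv <- suppressWarnings(
      loocv_predict(fm, y, lambda = config$lambda,
                    n_targets = length(config$targets)))
    perm <- if (config$n_perm > 0)
      suppressWarnings(
        permutation_test(fm, y, lambda = config$lambda,
                         n_perm = config$n_perm, seed = config$seed))
    else NULL
    mw <- mean_fold_weights(cv)
    agg <- if (!is.null(macro_map))
      aggregate_macro(mw, fm$pair_index, macro_map) else NULL
    eff <- node_efficacy(mw, fm$pair_index, length(dne_list[[1]]$node_ids))
    if (!is.null(out_dir)) {
      pred_tab <- data.frame(subject_id = manifest$subject_id, actual = y,
                             predicted = cv$predictions,
                             target_label = target)
      write.table(pred_tab,
                  file.path(out_dir, paste0("predictions_", target, ".csv")),
                  sep = ",", quote = FALSE, row.names = FALSE)
      write.table(data.frame(node_index = seq_along(eff), efficacy = eff),
                  file.path(out_dir, paste0("node_efficacy_", target, ".csv")),
                  sep = ",", quote = FALSE, row.names = FALSE)
      # per-fold coefficients, sparse triplet form (nonzeros only)
      nz <- which(cv$per_fold_beta != 0, arr.ind = TRUE)
      con <- gzfile(file.path(out_dir, paste0("fold_coefficients_", target,
                                              ".csv.gz")), "w")
      write.table(data.frame(fold = nz[, 1], feature = nz[, 2],
                             beta = cv$per_fold_beta[nz]),
                  con, sep = ",", quote = FALSE, row.names = FALSE)
      close(con)
      if (!is.null(agg))
        write.table(data.frame(region = rownames(agg), agg,
                               check.names = FALSE),
                    file.path(out_dir, paste0("region_matrix_", target,
                                              ".csv")),
                    sep = ",", quote = FALSE, row.names = FALSE)
    }
    results[[target]] <- list(
      cv = cv, permutation = perm, mean_weights = mw,
      region_matrix = agg, node_efficacy = eff,
      metrics = list(r = cv$r, p_raw = cv$p_raw,
                     p_bonferroni = cv$p_bonferroni, mae = cv$mae,
                     p_perm = if (is.null(perm)) NA_real_ else perm$p_perm))
  }

  report <- list(
    n_subjects = n_sub,
    n_windows = n_windows,
    n_nodes = length(dne_list[[1]]$node_ids),
    n_features = ncol(fm$X),
    excluded_subjects = excluded$subject_id,
    metrics = lapply(results, `[[`, "metrics"),
    warnings = warnings_log,
    config = list(tr_seconds = config$tr_seconds, n_discard = config$n_discard,
                  band = config$band, fd_threshold_mm = config$fd_threshold_mm,
                  head_radius_mm = config$head_radius_mm,
                  window_length_tp = config$window$length_tp,
                  window_step_tp = config$window$step_tp,
                  graph_mode = config$graph$mode,
                  negative_policy = config$graph$negative_policy,
                  sparsity = config$graph$sparsity, lambda = config$lambda,
                  n_perm = config$n_perm, seed = config$seed,
                  targets = config$targets),
    package_version = as.character(packageVersion("dnecpm")))
  if (!is.null(out_dir))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  c(report, list(results = results))
}
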