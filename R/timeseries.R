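#' ROI time-series container
#'
#' Holds one subject's node-by-time signal matrix together with its sampling
#' interval (TR) and node identifiers. This is the pipeline's raw input:
#' regional BOLD time courses already extracted from a parcellation (spatial
#' preprocessing is out of scope).
#'
#' @param data numeric node-by-time matrix (rows = nodes).
#' @param subject_id subject identifier.
#' @param tr_seconds repetition time in seconds (> 0); default 2.
#' @param node_ids optional character vector of node identifiers; defaults to
#'   rownames of `data` or `"n001"`, `"n002"`, ...
#' @return An object of class `roi_ts` with fields `data`, `subject_id`,
#'   `tr_seconds`, `node_ids`.
#' @export
roi_timeseries <- function(data, subject_id = "subj", tr_seconds = 2,
                           node_ids = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data)) .stop_input("time-series data must be numeric")
  if (anyNA(data) || any(!is.finite(data)))
    .stop_input("time series for subject '%s' contains missing or non-finite values",
                subject_id)
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1 || tr_seconds <= 0)
    .stop_input("tr_seconds must be a single positive number")
  if (is.null(node_ids)) {
    node_ids <- rownames(data)
    if (is.null(node_ids)) node_ids <- sprintf("n%03d", seq_len(nrow(data)))
  }
  if (length(node_ids) != nrow(data))
    .stop_input("node_ids length (%d) does not match node count (%d)",
                length(node_ids), nrow(data))
  rownames(data) <- node_ids
  structure(list(data = data, subject_id = as.character(subject_id),
                 tr_seconds = tr_seconds, node_ids = as.character(node_ids)),
            class = "roi_ts")
}

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf("<roi_ts> subject '%s': %d nodes x %d time points, TR = %g s\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$tr_seconds))
  invisible(x)
}

n_nodes <- function(ts) nrow(ts$data)
n_timepoints <- function(ts) ncol(ts$data)

#' Rigid-body motion parameters
#'
#' Six realignment parameters per frame: three translations (mm) followed by
#' three rotations (radians), in scanner convention. Row count must match the
#' companion time series before volume discarding.
#'
#' @param data numeric time-by-6 matrix.
#' @param subject_id subject identifier.
#' @return An object of class `motion_params`.
#' @export
motion_params <- function(data, subject_id = "subj") {
  data <- as.matrix(data)
  if (ncol(data) != 6)
    .stop_input("motion parameters must have exactly 6 columns, got %d", ncol(data))
  if (anyNA(data)) .stop_input("motion parameters contain missing values")
  structure(list(data = data, subject_id = as.character(subject_id)),
            class = "motion_params")
}

#' Read an ROI time-series TSV
#'
#' File layout: rows = time points, columns = nodes, with a header row of node
#' identifiers (the transpose of the in-memory node-by-time orientation).
#'
#' @param path file path.
#' @param subject_id subject identifier.
#' @param tr_seconds repetition time in seconds.
#' @return A [roi_timeseries()] object.
#' @export
read_roi_tsv <- function(path, subject_id = basename(path), tr_seconds = 2) {
  if (!file.exists(path)) .stop_input("time-series file not found: %s", path)
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  roi_timeseries(t(as.matrix(tab)), subject_id = subject_id,
                 tr_seconds = tr_seconds, node_ids = colnames(tab))
}

#' Write an ROI time-series TSV
#'
#' @param ts a [roi_timeseries()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_roi_tsv <- function(ts, path) {
  stopifnot(inherits(ts, "roi_ts"))
  tab <- as.data.frame(t(ts$data))
  colnames(tab) <- ts$node_ids
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a motion-parameter file
#'
#' Whitespace-delimited text with six columns (3 translations in mm, 3
#' rotations in radians), one row per frame, no header.
#'
#' @param path file path.
#' @param subject_id subject identifier.
#' @return A [motion_params()] object.
#' @export
read_motion <- function(path, subject_id = basename(path)) {
  if (!file.exists(path)) .stop_input("motion file not found: %s", path)
  tab <- read.table(path, header = FALSE)
  motion_params(as.matrix(tab), subject_id = subject_id)
}
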