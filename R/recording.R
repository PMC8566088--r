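#' Construct a gait recording
#'
#' A `gait_recording` bundles a uniformly sampled multichannel time series —
#' ten IMU channels (see [imu_channels()]) plus one footplate pressure
#' channel — with its sampling period and session metadata. Movement-pattern
#' labels, when present, are carried per sample (`NA` outside labeled
#' cycles); gait cycles extracted later inherit the label of their frames.
#'
#' @param data Data frame with columns `t_ms`, the ten IMU channels,
#'   `pressure`, and optionally `label` (integer pattern id or `NA`).
#' @param sample_period_ms Nominal sampling period in milliseconds
#'   (default 10, i.e. 100 Hz, so a 300 ms window is exactly 30 frames).
#' @param subject_id,session_id Free-form identifiers.
#' @param n_patterns Number of movement-pattern classes (default 5).
#' @return An object of class `gait_recording`.
#' @details Validation enforces: all IMU values finite, `pressure >= 0`,
#'   `t_ms` strictly increasing and uniform to within 1% of
#'   `sample_period_ms`, and labels (when present) in `1..n_patterns`.
#'   Physical units are deliberately not enforced.
#' @export
gait_recording <- function(data, sample_period_ms = 10,
                           subject_id = "s1", session_id = "d1",
                           n_patterns = 5L) {
  stopifnot(is.data.frame(data), sample_period_ms > 0)
  need <- recording_columns()
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0L) {
    stop("recording is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  data <- as.data.frame(data)[, intersect(recording_columns(TRUE), names(data))]
  rec <- structure(
    list(data = data,
         sample_period_ms = as.numeric(sample_period_ms),
         subject_id = as.character(subject_id),
         session_id = as.character(session_id),
         n_patterns = as.integer(n_patterns)),
    class = "gait_recording")
  validate_recording(rec)
  rec
}

validate_recording <- function(rec) {
  d <- rec$data
  if (nrow(d) > 0L) {
    imu <- as.matrix(d[, imu_channels()])
    if (!all(is.finite(imu))) stop("non-finite IMU values in recording")
    if (any(!is.finite(d$pressure)) || any(d$pressure < 0)) {
      stop("pressure must be finite and >= 0")
    }
    if (nrow(d) > 1L) {
      dt <- diff(d$t_ms)
      if (any(dt <= 0)) stop("t_ms must be strictly increasing")
      if (any(abs(dt - rec$sample_period_ms) > 0.01 * rec$sample_period_ms)) {
        stop("timestamps not uniform to within 1% of sample_period_ms")
      }
    }
    if (!is.null(d$label)) {
      lab <- d$label[!is.na(d$label)]
      if (length(lab) && (any(lab != round(lab)) || any(lab < 1L) ||
                          any(lab > rec$n_patterns))) {
        stop("labels must be integers in 1..", rec$n_patterns)
      }
    }
  }
  invisible(rec)
}

#' @export
print.gait_recording <- function(x, ...) {
  dur <- if (nrow(x$data)) diff(range(x$data$t_ms)) else 0
  n_lab <- if (is.null(x$data$label)) 0L else sum(!is.na(x$data$label))
  cat(sprintf(
    "<gait_recording> subject=%s session=%s: %d samples @ %g ms (%.1f s), %d labeled\n",
    x$subject_id, x$session_id, nrow(x$data), x$sample_period_ms,
    dur / 1000, n_lab))
  invisible(x)
}

#' @export
length.gait_recording <- function(x) nrow(x$data)

# IMU samples as an n x 10 numeric matrix.
imu_matrix <- function(rec) {
  as.matrix(rec$data[, imu_channels(), drop = FALSE])
}

#' Read a gait recording from CSV
#'
#' Expects the package CSV dialect: comma-separated, '.' decimal, header
#' `t_ms,imu1_ax,...,imu2_roll,pressure[,label]`, one row per sample.
#'
#' @param path File path.
#' @param sample_period_ms Sampling period; if `NULL`, inferred as the
#'   median timestamp difference.
#' @param subject_id,session_id,n_patterns Passed to [gait_recording()].
#' @return A `gait_recording`.
#' @seealso [write_recording()]
#' @export
read_recording <- function(path, sample_period_ms = NULL,
                           subject_id = "s1", session_id = "d1",
                           n_patterns = 5L) {
  d <- read.csv(path, check.names = FALSE)
  missing_cols <- setdiff(recording_columns(), names(d))
  if (length(missing_cols) > 0L) {
    stop("CSV ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (is.null(sample_period_ms)) {
    sample_period_ms <- if (nrow(d) > 1L) stats::median(diff(d$t_ms)) else 10
  }
  if (!is.null(d$label)) d$label <- as.integer(d$label)
  gait_recording(d, sample_period_ms, subject_id, session_id, n_patterns)
}

#' Write a gait recording to CSV
#'
#' Values are preserved to at least 9 significant digits, so
#' `read_recording(write_recording(rec))` round-trips within 1e-9 relative.
#'
#' @param rec A `gait_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "gait_recording"))
  d <- rec$data
  num <- vapply(d, is.numeric, logical(1)) & names(d) != "label"
  d[num] <- lapply(d[num], function(x) format(x, digits = 12, trim = TRUE,
                                              scientific = FALSE))
  write.csv(d, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
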