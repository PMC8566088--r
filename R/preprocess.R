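#' Limiting filter for random pulses
#'
#' Removes isolated random pulses from a signal (in this pipeline, the four
#' Euler-angle channels, where the orientation filter occasionally emits
#' large spikes). Whenever the absolute difference between a sample and the
#' last accepted value exceeds `threshold`, the sample is treated as noise
#' and replaced by the last accepted value (hold-last-valid), which
#' preserves length and causality.
#'
#' @param x Numeric vector (non-empty).
#' @param threshold Positive jump threshold, in the channel's units.
#' @return Filtered vector, same length as `x`; `out[1] == x[1]`.
#' @details The filter is idempotent: applying it twice gives the same
#'   output as applying it once.
#' @export
#' @examples
#' limiting_filter(c(0, 0.1, 9.9, 0.2), threshold = 1)
limiting_filter <- function(x, threshold) {
  if (length(x) == 0L) stop("empty input to limiting_filter")
  stopifnot(is.numeric(x), threshold > 0)
  out <- x
  last <- x[1]
  for (i in seq_along(x)[-1]) {
    if (abs(x[i] - last) > threshold) {
      out[i] <- last
    } else {
      last <- x[i]
    }
  }
  out
}

#' Apply the limiting filter to a recording's Euler-angle channels
#'
#' @param rec A `gait_recording`.
#' @param threshold Jump threshold in degrees (applies to all four
#'   pitch/roll channels).
#' @return The recording with filtered Euler channels.
#' @export
filter_euler_pulses <- function(rec, threshold = 20) {
  stopifnot(inherits(rec, "gait_recording"))
  if (nrow(rec$data) == 0L) return(rec)
  for (ch in euler_channels()) {
    rec$data[[ch]] <- limiting_filter(rec$data[[ch]], threshold)
  }
  rec
}

#' Detect foot-contact and foot-off events from a pressure trace
#'
#' A hysteresis state machine over the footplate pressure: a foot contact
#' (FC) fires where the pressure rises through `on_thresh` while the foot is
#' unloaded, a foot off (FO) where it falls through `off_thresh` while
#' loaded. Two debouncing guards reject isolated noise without shifting
#' event timing on clean signals: a candidate crossing is confirmed over a
#' forward window of `confirm_frames` samples (an FC requires the window
#' minimum to stay above `on_thresh` — the foot remains loaded; an FO
#' requires the window mean below `off_thresh` — the plateau is gone), and
#' candidates closer than `min_phase_ms` to the previous accepted event
#' are suppressed. A rejected candidate does not change the state, so a
#' sustained crossing still fires at the first sample where both guards
#' pass.
#'
#' @param pressure Numeric vector of footplate pressure.
#' @param on_thresh Rising threshold; must be `>= off_thresh`.
#' @param off_thresh Falling threshold.
#' @param min_phase_ms Minimum spacing between events, in ms.
#' @param sample_period_ms Sampling period used to convert `min_phase_ms`
#'   to frames.
#' @param confirm_frames Length of the forward confirmation window
#'   (1 = no confirmation).
#' @return Data frame with columns `kind` ("FC"/"FO") and `index`
#'   (1-based), alternating, strictly increasing; zero rows if no events.
#' @export
detect_gait_events <- function(pressure, on_thresh, off_thresh,
                               min_phase_ms = 100, sample_period_ms = 10,
                               confirm_frames = 5L) {
  stopifnot(on_thresh >= off_thresh, min_phase_ms >= 0, confirm_frames >= 1L)
  n <- length(pressure)
  if (n == 0L) return(data.frame(kind = character(), index = integer()))
  min_gap <- min_phase_ms / sample_period_ms
  loaded <- pressure[1] >= on_thresh
  kind <- character(0)
  index <- integer(0)
  last_idx <- -Inf
  fwd_win <- function(i) pressure[i:min(n, i + confirm_frames - 1L)]
  for (i in seq_len(n)) {
    if (!loaded && pressure[i] >= on_thresh) {
      if (i - last_idx >= min_gap && min(fwd_win(i)) >= on_thresh) {
        kind <- c(kind, "FC"); index <- c(index, i)
        last_idx <- i; loaded <- TRUE
      }
    } else if (loaded && pressure[i] < on_thresh) {
      # leaving the loaded state: the sample must at least fall below the
      # on-threshold while the confirmation mean attests full unloading
      # below the off-threshold, so a single noisy sample at the true
      # foot-off cannot delay the event
      if (i - last_idx >= min_gap && mean(fwd_win(i)) < off_thresh) {
        kind <- c(kind, "FO"); index <- c(index, i)
        last_idx <- i; loaded <- FALSE
      }
    }
  }
  data.frame(kind = kind, index = index)
}

#' Detect gait events for a recording
#'
#' Convenience wrapper around [detect_gait_events()] with thresholds as
#' fractions of the recording's maximum pressure (defaults 20% on / 10%
#' off), the hysteresis pair used throughout the pipeline.
#'
#' @param rec A `gait_recording`.
#' @param on_frac,off_frac Thresholds as fractions of max pressure.
#' @param min_phase_ms Debounce time in ms.
#' @return As [detect_gait_events()].
#' @export
gait_events <- function(rec, on_frac = 0.2, off_frac = 0.1,
                        min_phase_ms = 100) {
  stopifnot(inherits(rec, "gait_recording"))
  p <- rec$data$pressure
  pmax <- if (length(p)) max(p) else 0
  detect_gait_events(p, on_frac * pmax, off_frac * pmax,
                     min_phase_ms, rec$sample_period_ms)
}

#' A single gait cycle
#'
#' One full stride, from a foot contact (FC) to the next FC of the same
#' foot, split by the foot-off (FO) event into stance (frames
#' `1..n_stance`) and swing (the rest).
#'
#' @param frames n x 10 matrix of IMU samples (columns [imu_channels()]).
#' @param n_stance Number of stance frames; `1 <= n_stance < nrow(frames)`.
#' @param label Optional movement-pattern id.
#' @param cycle_id Identifier within the parent recording.
#' @param start_idx,fo_idx,end_idx 1-based absolute frame indices in the
#'   parent recording: first frame, first swing frame, last frame.
#' @return An object of class `gait_cycle`.
#' @export
gait_cycle <- function(frames, n_stance, label = NA_integer_,
                       cycle_id = NA_integer_, start_idx = NA_integer_,
                       fo_idx = NA_integer_, end_idx = NA_integer_) {
  frames <- as.matrix(frames)
  stopifnot(ncol(frames) == 10L, nrow(frames) >= 2L,
            n_stance >= 1L, n_stance < nrow(frames))
  structure(
    list(frames = frames, n_stance = as.integer(n_stance),
         label = as.integer(label), cycle_id = as.integer(cycle_id),
         start_idx = as.integer(start_idx), fo_idx = as.integer(fo_idx),
         end_idx = as.integer(end_idx)),
    class = "gait_cycle")
}

#' @export
print.gait_cycle <- function(x, ...) {
  cat(sprintf("<gait_cycle #%s> %d frames (%d stance / %d swing), label=%s\n",
              x$cycle_id, nrow(x$frames), x$n_stance,
              nrow(x$frames) - x$n_stance,
              ifelse(is.na(x$label), "?", x$label)))
  invisible(x)
}

stance_frames <- function(cycle) cycle$frames[seq_len(cycle$n_stance), , drop = FALSE]
swing_frames <- function(cycle) {
  cycle$frames[(cycle$n_stance + 1L):nrow(cycle$frames), , drop = FALSE]
}

#' Extract gait cycles from a recording
#'
#' One cycle per consecutive FC pair containing exactly one interior FO;
#' FC pairs lacking an interior FO (e.g. a pressure dropout) are dropped
#' with a warning. A trailing partial cycle (no closing FC) is never
#' returned. Cycle labels are the modal per-frame label over the cycle's
#' frames (`NA` when unlabeled).
#'
#' @param rec A `gait_recording`.
#' @param events Optional precomputed event table from [gait_events()].
#' @param ... Passed to [gait_events()] when `events` is `NULL`.
#' @return List of `gait_cycle` objects (possibly empty).
#' @export
extract_cycles <- function(rec, events = NULL, ...) {
  stopifnot(inherits(rec, "gait_recording"))
  if (is.null(events)) events <- gait_events(rec, ...)
  fc <- events$index[events$kind == "FC"]
  if (length(fc) < 2L) return(list())
  imu <- imu_matrix(rec)
  labels <- rec$data$label
  cycles <- list()
  dropped <- 0L
  for (ci in seq_len(length(fc) - 1L)) {
    a <- fc[ci]
    b <- fc[ci + 1L]
    fo <- events$index[events$kind == "FO" & events$index > a &
                         events$index < b]
    if (length(fo) != 1L) {
      dropped <- dropped + 1L
      next
    }
    lab <- NA_integer_
    if (!is.null(labels)) {
      lf <- labels[a:(b - 1L)]
      lf <- lf[!is.na(lf)]
      if (length(lf)) {
        tab <- table(lf)
        lab <- as.integer(names(tab)[which.max(tab)])
      }
    }
    cycles[[length(cycles) + 1L]] <- gait_cycle(
      frames = imu[a:(b - 1L), , drop = FALSE],
      n_stance = fo - a,
      label = lab, cycle_id = length(cycles) + 1L,
      start_idx = a, fo_idx = fo, end_idx = b - 1L)
  }
  if (dropped > 0L) {
    warning(dropped, " cycle(s) dropped: no single interior FO event")
  }
  cycles
}

#' Summarize a cycle list
#'
#' @param cycles List of `gait_cycle`.
#' @return Data frame: cycle_id, start_idx, fo_idx, end_idx, n_frames,
#'   n_stance, label.
#' @export
cycle_table <- function(cycles) {
  data.frame(
    cycle_id = vapply(cycles, `[[`, integer(1), "cycle_id"),
    start_idx = vapply(cycles, `[[`, integer(1), "start_idx"),
    fo_idx = vapply(cycles, `[[`, integer(1), "fo_idx"),
    end_idx = vapply(cycles, `[[`, integer(1), "end_idx"),
    n_frames = vapply(cycles, function(c) nrow(c$frames), integer(1)),
    n_stance = vapply(cycles, `[[`, integer(1), "n_stance"),
    label = vapply(cycles, `[[`, integer(1), "label"))
}

#' Segment a recording into sliding windows
#'
#' Fixed-length windows (default 300 ms) advanced by a fixed step (default
#' 10 ms, one frame at 100 Hz), the classifier's unit of data. Each window
#' is labeled by the cycle containing its *final* frame — the causal
#' convention of an online recognizer deciding "now" — and carries that
#' frame's gait phase (stance or swing). Windows whose final frame lies in
#' no extracted cycle have `NA` label and phase.
#'
#' @param rec A `gait_recording`.
#' @param window_ms,step_ms Window length and step, ms; `window_ms >=
#'   step_ms > 0`.
#' @param cycles Optional cycle list from [extract_cycles()] used to assign
#'   labels/phases; extracted on the fly when `NULL`.
#' @return An object of class `gait_windows`: list with `features`
#'   (n x W x 10 array), `label`, `phase` ("stance"/"swing"/NA),
#'   `cycle_id`, `start_idx`, `end_idx`, `window_frames`. Zero windows if
#'   the recording is shorter than one window.
#' @export
sliding_windows <- function(rec, window_ms = 300, step_ms = 10,
                            cycles = NULL) {
  stopifnot(inherits(rec, "gait_recording"),
            window_ms >= step_ms, step_ms > 0)
  W <- as.integer(round(window_ms / rec$sample_period_ms))
  step <- as.integer(round(step_ms / rec$sample_period_ms))
  stopifnot(W >= 1L, step >= 1L)
  n <- nrow(rec$data)
  if (n < W) {
    return(structure(list(
      features = array(0, dim = c(0L, W, 10L)), label = integer(0),
      phase = character(0), cycle_id = integer(0), start_idx = integer(0),
      end_idx = integer(0), window_frames = W), class = "gait_windows"))
  }
  if (is.null(cycles)) cycles <- extract_cycles(rec)
  starts <- seq.int(1L, n - W + 1L, by = step)
  ends <- starts + W - 1L
  imu <- imu_matrix(rec)
  feats <- array(0, dim = c(length(starts), W, 10L))
  for (i in seq_along(starts)) {
    feats[i, , ] <- imu[starts[i]:ends[i], , drop = FALSE]
  }
  # map each final frame to its cycle and phase
  frame_cycle <- rep(NA_integer_, n)
  frame_phase <- rep(NA_character_, n)
  for (cy in cycles) {
    idx <- cy$start_idx:cy$end_idx
    frame_cycle[idx] <- cy$cycle_id
    frame_phase[idx] <- c(rep("stance", cy$n_stance),
                          rep("swing", length(idx) - cy$n_stance))
  }
  cyc_label <- vapply(cycles, `[[`, integer(1), "label")
  wc <- frame_cycle[ends]
  structure(list(
    features = feats,
    label = ifelse(is.na(wc), NA_integer_, cyc_label[wc]),
    phase = frame_phase[ends],
    cycle_id = wc,
    start_idx = starts,
    end_idx = ends,
    window_frames = W), class = "gait_windows")
}

#' @export
print.gait_windows <- function(x, ...) {
  cat(sprintf("<gait_windows> %d windows of %d frames (%d labeled)\n",
              length(x$start_idx), x$window_frames, sum(!is.na(x$label))))
  invisible(x)
}

# Number of windows in a gait_windows object.
n_windows <- function(w) length(w$start_idx)

# Subset a gait_windows object by logical or integer index.
subset_windows <- function(w, i) {
  structure(list(
    features = w$features[i, , , drop = FALSE],
    label = w$label[i], phase = w$phase[i], cycle_id = w$cycle_id[i],
    start_idx = w$start_idx[i], end_idx = w$end_idx[i],
    window_frames = w$window_frames), class = "gait_windows")
}

# Row-bind two gait_windows objects (same window length).
bind_windows <- function(a, b) {
  stopifnot(a$window_frames == b$window_frames)
  feats <- array(0, dim = c(n_windows(a) + n_windows(b), a$window_frames, 10L))
  if (n_windows(a)) feats[seq_len(n_windows(a)), , ] <- a$features
  if (n_windows(b)) feats[n_windows(a) + seq_len(n_windows(b)), , ] <- b$features
  structure(list(
    features = feats,
    label = c(a$label, b$label), phase = c(a$phase, b$phase),
    cycle_id = c(a$cycle_id, b$cycle_id),
    start_idx = c(a$start_idx, b$start_idx),
    end_idx = c(a$end_idx, b$end_idx),
    window_frames = a$window_frames), class = "gait_windows")
}

# Flatten windows to an n x (W*10) matrix (for QDA / SVM).
flatten_windows <- function(w) {
  n <- n_windows(w)
  matrix(w$features, nrow = n)
}
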