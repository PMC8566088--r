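# Shared fixtures, all generated in code.

# a minimal valid recording data frame with constant IMU values
flat_recording_df <- function(n, pressure = rep(0, n), label = NULL,
                              period = 10) {
  d <- data.frame(t_ms = (seq_len(n) - 1) * period)
  for (ch in imu_channels()) d[[ch]] <- rep(0.5, n)
  d$pressure <- pressure
  if (!is.null(label)) d$label <- label
  d
}

# a gait_windows object built directly from a feature array (for
# classifier tests that need full control over class geometry)
make_windows <- function(features, label, phase = "stance") {
  n <- dim(features)[1]
  structure(list(
    features = features,
    label = as.integer(label),
    phase = rep_len(phase, n),
    cycle_id = seq_len(n),
    start_idx = seq_len(n),
    end_idx = seq_len(n) + dim(features)[2] - 1L,
    window_frames = dim(features)[2]), class = "gait_windows")
}

# two well-separated Gaussian classes as 30x10 windows
separable_windows <- function(n_per_class = 25, n_classes = 2, sep = 3,
                              seed = 42) {
  withr::with_seed(seed, {
    n <- n_per_class * n_classes
    feats <- array(rnorm(n * 30 * 10, sd = 0.3), c(n, 30, 10))
    label <- rep(seq_len(n_classes), each = n_per_class)
    for (k in seq_len(n_classes)) {
      feats[label == k, , ] <- feats[label == k, , ] + (k - 1) * sep
    }
    make_windows(feats, label)
  })
}

# a hand-built gait cycle with prescribed per-channel functions of phase
make_cycle <- function(n_stance, n_swing, fn = function(u, ch) 0,
                       label = 1L, cycle_id = 1L) {
  n <- n_stance + n_swing
  u <- seq(0, 1, length.out = n)
  frames <- vapply(1:10, function(ch) rep_len(fn(u, ch), n), numeric(n))
  gait_cycle(frames, n_stance = n_stance, label = label,
             cycle_id = cycle_id, start_idx = 1L, fo_idx = n_stance + 1L,
             end_idx = n)
}

unit_stats <- list(mean = rep(0, 10), sd = rep(1, 10))

# a bare autolabel result table for metric arithmetic tests
make_autolabel_result <- function(best_cost, assigned, k,
                                  suppressed = FALSE) {
  out <- data.frame(cycle_id = seq_along(best_cost),
                    assigned_pattern = as.integer(assigned),
                    best_cost = best_cost)
  out$selected <- out$best_cost < k
  out$suppressed <- rep_len(suppressed, nrow(out))
  attr(out, "k") <- k
  class(out) <- c("autolabel_result", "data.frame")
  out
}
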