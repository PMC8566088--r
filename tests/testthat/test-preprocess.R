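test_that("limiting filter replaces outlier jumps with the last accepted value", {
  expect_equal(limiting_filter(c(0, 0.1, 9.9, 0.2), threshold = 1),
               c(0, 0.1, 0.1, 0.2))
  x <- rnorm(100)
  expect_equal(limiting_filter(x, threshold = Inf), x)
  expect_equal(limiting_filter(rep(3, 10), threshold = 0.01), rep(3, 10))
  expect_error(limiting_filter(numeric(0), 1), "empty")
})

test_that("limiting filter is idempotent", {
  set.seed(7)
  for (i in 1:20) {
    x <- rnorm(200)
    x[sample(200, 10)] <- x[sample(200, 10)] + 50  # inject pulses
    f1 <- limiting_filter(x, threshold = 5)
    expect_identical(limiting_filter(f1, threshold = 5), f1)
  }
})

test_that("only Euler-angle channels pass through the recording-level filter", {
  d <- flat_recording_df(20)
  d$imu1_pitch[10] <- 500
  d$imu1_ax[10] <- 500
  rec <- filter_euler_pulses(gait_recording(d), threshold = 20)
  expect_equal(rec$data$imu1_pitch[10], 0.5)  # pulse removed
  expect_equal(rec$data$imu1_ax[10], 500)     # acceleration untouched
})

test_that("gait events alternate FC/FO on a square wave", {
  p <- rep(c(0, 0, 1, 1, 0, 0, 1, 1, 0), each = 3)
  ev <- detect_gait_events(p, 0.5, 0.5, min_phase_ms = 0)
  expect_equal(ev$kind, c("FC", "FO", "FC", "FO"))
  expect_true(all(diff(ev$index) > 0))
  expect_equal(nrow(detect_gait_events(rep(0, 50), 0.5, 0.5)), 0L)
})

test_that("debounce suppresses events inside the dead time", {
  # a 1-frame dropout in a loaded phase would fire FO+FC without debounce
  p <- c(rep(0, 5), rep(1, 10), 0, rep(1, 10), rep(0, 10))
  ev <- detect_gait_events(p, 0.5, 0.5, min_phase_ms = 50,
                           sample_period_ms = 10)
  expect_equal(ev$kind[1:2], c("FC", "FO"))
  expect_equal(sum(ev$kind == "FC"), 1L)
})

test_that("detected events stay within 2 frames of generator truth under noise", {
  for (s in 1:5) {
    cfg <- gait_gen_config(noise_sd = 0.3, pressure_noise_sd = 0.1, seed = s)
    day <- generate_day(cfg, n_cycles_per_pattern = 2)
    ev <- gait_events(day$recording)
    truth <- day$events
    expect_equal(nrow(ev), nrow(truth))
    expect_equal(ev$kind, truth$kind)
    expect_true(all(abs(ev$index - truth$index) <= 2))
  }
})

test_that("cycle extraction recovers generator truth exactly on clean data", {
  cfg <- gait_gen_config(noise_sd = 0, pulse_rate = 0,
                         pressure_noise_sd = 0, seed = 11)
  day <- generate_day(cfg, n_cycles_per_pattern = 2)
  cyc <- extract_cycles(day$recording)
  expect_length(cyc, nrow(day$truth))
  tb <- cycle_table(cyc)
  expect_equal(tb$start_idx, day$truth$start_idx)
  expect_equal(tb$fo_idx, day$truth$fo_idx)
  expect_equal(tb$end_idx, day$truth$end_idx)
  expect_equal(tb$label, day$truth$label)
  # stance/swing both non-empty by construction
  expect_true(all(tb$n_stance >= 1 & tb$n_stance < tb$n_frames))
})

test_that("partial trailing cycles and FO dropouts are excluded", {
  cfg <- gait_gen_config(noise_sd = 0, pulse_rate = 0,
                         pressure_noise_sd = 0, seed = 12)
  day <- generate_day(cfg, n_cycles_per_pattern = 2, schedule = rep(1, 10))
  # truncate mid-way through the last cycle: its closing FC disappears
  rec <- day$recording
  cut <- day$truth$fo_idx[10]
  rec$data <- rec$data[1:cut, ]
  expect_length(extract_cycles(rec), 9L)
  # drop cycle 5's FO from the event stream (a pressure dropout): the FC
  # pair bracketing it has no interior FO and is discarded
  ev <- gait_events(day$recording)
  ev <- ev[!(ev$kind == "FO" & ev$index == day$truth$fo_idx[5]), ]
  expect_warning(cyc <- extract_cycles(day$recording, events = ev),
                 "dropped")
  expect_length(cyc, 9L)
  expect_false(day$truth$start_idx[5] %in% cycle_table(cyc)$start_idx)
})

test_that("sliding window count follows the closed form", {
  rec <- gait_recording(flat_recording_df(100))  # 1000 ms at 100 Hz
  w <- sliding_windows(rec, 300, 10)
  expect_equal(length(w$start_idx), 71L)  # floor((100 - 30) / 1) + 1
  expect_equal(w$window_frames, 30L)
  expect_equal(dim(w$features), c(71L, 30L, 10L))
  # exactly one window when duration equals the window length
  w1 <- sliding_windows(gait_recording(flat_recording_df(30)), 300, 10)
  expect_equal(length(w1$start_idx), 1L)
  # empty when shorter than one window
  w0 <- sliding_windows(gait_recording(flat_recording_df(20)), 300, 10)
  expect_equal(length(w0$start_idx), 0L)
  # general closed form on a few sizes
  for (n in c(31, 57, 200)) {
    w <- sliding_windows(gait_recording(flat_recording_df(n)), 300, 10)
    expect_equal(length(w$start_idx), floor((n - 30) / 1) + 1)
  }
})

test_that("windows take the label and phase of their final frame", {
  cfg <- gait_gen_config(noise_sd = 0, pulse_rate = 0,
                         pressure_noise_sd = 0, seed = 13)
  day <- generate_transition_day(cfg, list(c(1, 3), c(2, 3)))
  cyc <- extract_cycles(day$recording)
  w <- sliding_windows(day$recording, cycles = cyc)
  tb <- cycle_table(cyc)
  # pick a window whose final frame is the first frame of the pattern-2 block
  first_p2 <- tb$start_idx[4]
  i <- which(w$end_idx == first_p2)
  expect_equal(w$label[i], 2L)
  expect_equal(w$phase[i], "stance")
  # the window one step earlier still ends in the pattern-1 block
  expect_equal(w$label[i - 1L], 1L)
  # windows ending outside any cycle are unlabeled
  expect_true(all(is.na(w$label[w$end_idx < tb$start_idx[1]])))
})
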