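#' Synthetic gait generator configuration
#'
#' Parameters of the synthetic multi-day IMU + footplate generator used to
#' exercise the whole pipeline against known ground truth. Each movement
#' pattern is a smooth quasi-periodic waveform per channel — a shared
#' harmonic base plus a pattern-specific harmonic component whose weight
#' (`pattern_separation`) dials how distinguishable the patterns are.
#' Cycles have variable duration, a stance/swing split mirrored by the
#' pressure trace (loaded in stance, near zero in swing), additive Gaussian
#' noise on the IMU channels, and occasional random pulses on the four
#' Euler-angle channels. Cross-day drift is modeled as a per-channel affine
#' perturbation (offset and gain) drawn once per day.
#'
#' @param n_patterns Number of movement patterns (default 5).
#' @param cycle_ms_mean,cycle_ms_sd Cycle duration distribution, ms
#'   (default 1000 +/- 100; durations are clipped at 40% of the mean).
#' @param stance_fraction Mean fraction of the cycle spent in stance
#'   (default 0.6).
#' @param noise_sd Additive Gaussian noise sd on the IMU channels, in
#'   waveform units (the waveforms have amplitude of order 1).
#' @param pulse_rate Per-sample probability of a random pulse on each
#'   Euler-angle channel.
#' @param pulse_magnitude Pulse amplitude (sign random).
#' @param pressure_noise_sd Noise sd on the pressure trace (plateau = 1).
#' @param day_shift_offset,day_shift_gain Scale of the per-day random
#'   channel offset and relative gain perturbation (0 = no drift).
#' @param pattern_separation Weight of the pattern-specific waveform
#'   component (default 1; smaller values make the task harder).
#' @param sample_period_ms Sampling period (default 10 ms).
#' @param waveform_seed Seed for the waveform bank, kept separate from the
#'   per-day seed so that all days of one virtual subject share waveforms.
#' @param seed Default seed for day generation.
#' @return An object of class `gait_gen_config`.
#' @export
gait_gen_config <- function(n_patterns = 5L, cycle_ms_mean = 1000,
                            cycle_ms_sd = 100, stance_fraction = 0.6,
                            noise_sd = 0.3, pulse_rate = 0.002,
                            pulse_magnitude = 30, pressure_noise_sd = 0.01,
                            day_shift_offset = 0, day_shift_gain = 0,
                            pattern_separation = 1,
                            sample_period_ms = 10, waveform_seed = 711L,
                            seed = 1L) {
  stopifnot(n_patterns >= 2L, cycle_ms_sd >= 0, noise_sd >= 0,
            stance_fraction > 0, stance_fraction < 1, pulse_rate >= 0)
  cfg <- list(n_patterns = as.integer(n_patterns),
              cycle_ms_mean = cycle_ms_mean, cycle_ms_sd = cycle_ms_sd,
              stance_fraction = stance_fraction, noise_sd = noise_sd,
              pulse_rate = pulse_rate, pulse_magnitude = pulse_magnitude,
              pressure_noise_sd = pressure_noise_sd,
              day_shift_offset = day_shift_offset,
              day_shift_gain = day_shift_gain,
              pattern_separation = pattern_separation,
              sample_period_ms = sample_period_ms,
              waveform_seed = as.integer(waveform_seed),
              seed = as.integer(seed))
  cfg$waveforms <- make_waveform_bank(cfg)
  structure(cfg, class = "gait_gen_config")
}

# Harmonic waveform bank: per channel a shared base of 3 harmonics plus a
# pattern-specific component of 3 harmonics, both with random amplitudes
# (decaying in harmonic order) and phases.
make_waveform_bank <- function(cfg) {
  n_ch <- 10L
  n_h <- 3L
  with_seed(cfg$waveform_seed, function() {
    list(
      base_amp = matrix(runif(n_ch * n_h, 0.2, 0.6), n_ch) /
        matrix(seq_len(n_h), n_ch, n_h, byrow = TRUE),
      base_phase = matrix(runif(n_ch * n_h, 0, 2 * pi), n_ch),
      pat_amp = array(runif(cfg$n_patterns * n_ch * n_h, 0.3, 1),
                      c(cfg$n_patterns, n_ch, n_h)) /
        aperm(array(seq_len(n_h), c(n_h, cfg$n_patterns, n_ch)), c(2, 3, 1)),
      pat_phase = array(runif(cfg$n_patterns * n_ch * n_h, 0, 2 * pi),
                        c(cfg$n_patterns, n_ch, n_h)),
      offset = runif(n_ch, -0.5, 0.5))
  })
}

#' Evaluate a pattern's noiseless waveform
#'
#' @param cfg A `gait_gen_config`.
#' @param pattern Pattern id.
#' @param u Vector of cycle phases in [0, 1).
#' @return `length(u)` x 10 matrix of channel values.
#' @export
pattern_waveform <- function(cfg, pattern, u) {
  wb <- cfg$waveforms
  n_h <- ncol(wb$base_phase)
  out <- matrix(0, length(u), 10L)
  for (ch in 1:10) {
    val <- rep(wb$offset[ch], length(u))
    for (h in seq_len(n_h)) {
      val <- val +
        wb$base_amp[ch, h] * sin(2 * pi * h * u + wb$base_phase[ch, h]) +
        cfg$pattern_separation * wb$pat_amp[pattern, ch, h] *
          sin(2 * pi * h * u + wb$pat_phase[pattern, ch, h])
    }
    out[, ch] <- val
  }
  out
}

#' Generate one synthetic day
#'
#' Produces a labeled recording together with exact ground truth: the
#' cycle table (start/foot-off/end frame of every cycle plus its pattern)
#' and the corresponding FC/FO event list. A short unloaded lead-in
#' precedes the first cycle and a short loaded tail follows the last one,
#' so that every generated cycle is delimited by detectable events.
#'
#' @param cfg A `gait_gen_config`.
#' @param n_cycles_per_pattern Cycles per pattern (ignored when `schedule`
#'   is an explicit vector).
#' @param schedule `"blocked"` (all cycles of pattern 1, then 2, ...),
#'   `"interleaved"` (1..S repeating), or an explicit integer vector of
#'   pattern ids, one per cycle.
#' @param seed Seed for this day's randomness (default `cfg$seed`).
#' @param day Day index; selects the day's affine channel perturbation
#'   when `day_shift_offset`/`day_shift_gain` are nonzero.
#' @param subject_id,session_id Metadata for the recording.
#' @return Object of class `synth_gait_day`: list with `recording`
#'   (labeled `gait_recording`), `truth` (data frame `cycle_id`,
#'   `start_idx`, `fo_idx`, `end_idx`, `label`), `events` (data frame
#'   `kind`, `index`), and `config`.
#' @export
generate_day <- function(cfg, n_cycles_per_pattern = 10L,
                         schedule = "blocked", seed = cfg$seed, day = 1L,
                         subject_id = "s1", session_id = paste0("d", day)) {
  stopifnot(inherits(cfg, "gait_gen_config"))
  patterns <- if (is.numeric(schedule)) {
    as.integer(schedule)
  } else if (identical(schedule, "blocked")) {
    rep(seq_len(cfg$n_patterns), each = n_cycles_per_pattern)
  } else if (identical(schedule, "interleaved")) {
    rep(seq_len(cfg$n_patterns), times = n_cycles_per_pattern)
  } else {
    stop("invalid schedule")
  }
  if (length(patterns) == 0L || any(patterns < 1L) ||
      any(patterns > cfg$n_patterns)) {
    stop("invalid schedule")
  }
  period <- cfg$sample_period_ms
  with_seed(seed, function() {
    # per-day affine drift, one draw per channel
    shift_seed <- cfg$seed + 7919L * as.integer(day)
    drift <- with_seed(shift_seed, function() {
      list(offset = cfg$day_shift_offset * rnorm(10),
           gain = 1 + cfg$day_shift_gain * rnorm(10))
    })
    n_lead <- 12L
    n_tail <- 15L
    imu_blocks <- list()
    pressure <- numeric(0)
    labels <- integer(0)
    truth <- list()
    # unloaded lead-in (noise only)
    imu_blocks[[1]] <- matrix(rnorm(n_lead * 10, sd = cfg$noise_sd),
                              n_lead, 10)
    pressure <- c(pressure, rep(0, n_lead))
    labels <- c(labels, rep(NA_integer_, n_lead))
    pos <- n_lead
    for (ci in seq_along(patterns)) {
      p <- patterns[ci]
      dur <- rnorm(1, cfg$cycle_ms_mean, cfg$cycle_ms_sd)
      dur <- max(dur, 0.4 * cfg$cycle_ms_mean)
      n_frames <- max(20L, as.integer(round(dur / period)))
      n_stance <- as.integer(round(cfg$stance_fraction * n_frames))
      n_stance <- min(max(n_stance, 5L), n_frames - 5L)
      n_swing <- n_frames - n_stance
      sf <- cfg$stance_fraction
      u <- c(sf * (seq_len(n_stance) - 1L) / n_stance,
             sf + (1 - sf) * (seq_len(n_swing) - 1L) / n_swing)
      wav <- pattern_waveform(cfg, p, u)
      wav <- sweep(sweep(wav, 2, drift$gain, "*"), 2, drift$offset, "+")
      wav <- wav + matrix(rnorm(n_frames * 10, sd = cfg$noise_sd),
                          n_frames, 10)
      imu_blocks[[length(imu_blocks) + 1L]] <- wav
      us <- (seq_len(n_stance) - 1L) / n_stance
      pr <- c(0.6 + 0.4 * sin(pi * us), rep(0, n_swing))
      pressure <- c(pressure, pr)
      labels <- c(labels, rep(p, n_frames))
      truth[[ci]] <- data.frame(
        cycle_id = ci, start_idx = pos + 1L,
        fo_idx = pos + n_stance + 1L, end_idx = pos + n_frames,
        label = p)
      pos <- pos + n_frames
    }
    # loaded tail stub closing the last cycle with a final FC
    last_p <- patterns[length(patterns)]
    tail_u <- cfg$stance_fraction * (seq_len(n_tail) - 1L) / 60
    tail_wav <- pattern_waveform(cfg, last_p, tail_u)
    tail_wav <- sweep(sweep(tail_wav, 2, drift$gain, "*"), 2,
                      drift$offset, "+") +
      matrix(rnorm(n_tail * 10, sd = cfg$noise_sd), n_tail, 10)
    imu_blocks[[length(imu_blocks) + 1L]] <- tail_wav
    us <- (seq_len(n_tail) - 1L) / 60
    pressure <- c(pressure, 0.6 + 0.4 * sin(pi * us))
    labels <- c(labels, rep(NA_integer_, n_tail))
    imu <- do.call(rbind, imu_blocks)
    # random pulses on the Euler-angle channels
    euler_idx <- match(euler_channels(), imu_channels())
    if (cfg$pulse_rate > 0) {
      for (ch in euler_idx) {
        hit <- runif(nrow(imu)) < cfg$pulse_rate
        imu[hit, ch] <- imu[hit, ch] +
          cfg$pulse_magnitude * sample(c(-1, 1), sum(hit), replace = TRUE)
      }
    }
    if (cfg$pressure_noise_sd > 0) {
      pressure <- pmax(0, pressure + rnorm(length(pressure),
                                           sd = cfg$pressure_noise_sd))
    }
    d <- data.frame(t_ms = (seq_len(nrow(imu)) - 1L) * period)
    for (ch in seq_len(10L)) d[[imu_channels()[ch]]] <- imu[, ch]
    d$pressure <- pressure
    d$label <- labels
    truth <- do.call(rbind, truth)
    nc <- nrow(truth)
    events <- data.frame(
      kind = c(rbind(rep("FC", nc), rep("FO", nc)), "FC"),
      index = c(rbind(truth$start_idx, truth$fo_idx), pos + 1L))
    structure(
      list(recording = gait_recording(d, period, subject_id, session_id,
                                      cfg$n_patterns),
           truth = truth, events = events, config = cfg),
      class = "synth_gait_day")
  })
}

#' @export
print.synth_gait_day <- function(x, ...) {
  cat(sprintf("<synth_gait_day> %d cycles, %d samples, noise_sd=%g\n",
              nrow(x$truth), nrow(x$recording$data), x$config$noise_sd))
  invisible(x)
}

#' Generate a day with pattern transitions
#'
#' Concatenated blocks of cycles, one block per segment, for exercising
#' the adjacent-cycle transition suppression.
#'
#' @param cfg A `gait_gen_config`.
#' @param segments List of `c(pattern, n_cycles)` pairs (at least 2).
#' @param seed,day,subject_id,session_id As [generate_day()].
#' @return A `synth_gait_day` whose `transitions` element lists, for each
#'   segment boundary, the index of the last cycle of the outgoing segment.
#' @export
generate_transition_day <- function(cfg, segments, seed = cfg$seed,
                                    day = 1L, subject_id = "s1",
                                    session_id = paste0("d", day)) {
  stopifnot(length(segments) >= 2L)
  counts <- vapply(segments, function(s) as.integer(s[2]), integer(1))
  if (any(counts < 1L)) stop("empty segment")
  schedule <- unlist(lapply(segments, function(s) rep(s[1], s[2])))
  out <- generate_day(cfg, schedule = schedule, seed = seed, day = day,
                      subject_id = subject_id, session_id = session_id)
  out$transitions <- cumsum(counts)[-length(counts)]
  out
}
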