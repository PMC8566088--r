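test_that("phase normalization reproduces linear channels exactly", {
  cyc <- make_cycle(20, 15, fn = function(u, ch) ch * u)
  out <- normalize_cycle(cyc, n_stance = 8, n_swing = 6, stats = unit_stats)
  expect_equal(dim(out), c(14L, 10L))
  # each sub-phase is linear in its own normalized phase; cubic splines
  # reproduce linear data exactly
  for (ch in 1:10) {
    expect_equal(out[1:8, ch],
                 seq(cyc$frames[1, ch], cyc$frames[20, ch], length.out = 8),
                 tolerance = 1e-12)
    expect_equal(out[9:14, ch],
                 seq(cyc$frames[21, ch], cyc$frames[35, ch], length.out = 6),
                 tolerance = 1e-12)
  }
})

test_that("a constant cycle z-scored at its own mean is all zero", {
  cyc <- make_cycle(10, 10, fn = function(u, ch) rep(ch, length(u)))
  out <- normalize_cycle(cyc, 6, 5, stats = list(mean = 1:10, sd = rep(1, 10)))
  expect_equal(out, matrix(0, 11, 10))
})

test_that("dense spline resampling of a sine stays within 1e-3 of the closed form", {
  n_st <- 40
  n_sw <- 40
  cyc <- make_cycle(n_st, n_sw, fn = function(u, ch) sin(2 * pi * u))
  out <- normalize_cycle(cyc, n_stance = 400, n_swing = 400,
                         stats = unit_stats)
  # reconstruct the phase grid each output row corresponds to
  u_st_in <- seq(0, 1, length.out = n_st + n_sw)[1:n_st]
  u_sw_in <- seq(0, 1, length.out = n_st + n_sw)[(n_st + 1):(n_st + n_sw)]
  u_st <- seq(u_st_in[1], u_st_in[n_st], length.out = 400)
  u_sw <- seq(u_sw_in[1], u_sw_in[n_sw], length.out = 400)
  expect_lt(max(abs(out[, 1] - sin(2 * pi * c(u_st, u_sw)))), 1e-3)
})

test_that("short phases are rejected with the cycle id", {
  cyc <- make_cycle(3, 10, label = 1L, cycle_id = 99L)
  expect_error(normalize_cycle(cyc, 10, 10, stats = unit_stats), "99")
})

test_that("templates average normalized cycles (mean over K cycles)", {
  base <- make_cycle(20, 15, fn = function(u, ch) sin(2 * pi * u + ch))
  # identical cycles: template equals the single normalized cycle
  tpl <- build_template(list(base, base, base), 10, 8, stats = unit_stats)
  expect_equal(tpl$points, normalize_cycle(base, 10, 8, unit_stats))
  expect_equal(tpl$k_cycles, 3L)
  expect_equal(nrow(tpl$points), tpl$n_stance + tpl$n_swing)
  # pointwise negatives cancel
  neg <- base
  neg$frames <- -neg$frames
  tpl0 <- build_template(list(base, neg), 10, 8, stats = unit_stats)
  expect_equal(tpl0$points, matrix(0, 18, 10), tolerance = 1e-12)
})

test_that("averaging noisy replicates shrinks deviation from the base waveform", {
  set.seed(2024)
  fn <- function(u, ch) sin(2 * pi * u + ch / 2)
  base <- make_cycle(30, 20, fn = fn)
  noisy <- lapply(1:20, function(i) {
    c <- make_cycle(30, 20, fn = fn, cycle_id = i)
    c$frames <- c$frames + matrix(rnorm(50 * 10, sd = 0.2), 50, 10)
    c
  })
  ref <- normalize_cycle(base, 60, 40, unit_stats)
  tpl <- build_template(noisy, 60, 40, stats = unit_stats)
  rms <- function(m) sqrt(mean(m^2))
  rms_template <- rms(tpl$points - ref)
  rms_single <- vapply(noisy, function(c) {
    rms(normalize_cycle(c, 60, 40, unit_stats) - ref)
  }, numeric(1))
  expect_lt(rms_template, min(rms_single))
  # roughly the 1/sqrt(K) law: expect at least a 3x reduction at K = 20
  expect_lt(rms_template, mean(rms_single) / 3)
})

test_that("template building is permutation-invariant and errors on mixed input", {
  set.seed(3)
  cycles <- lapply(1:6, function(i) {
    c <- make_cycle(15 + i, 12 + i, fn = function(u, ch) cos(2 * pi * u * ch))
    c$frames <- c$frames + matrix(rnorm((27 + 2 * i) * 10, sd = 0.1),
                                  27 + 2 * i, 10)
    c
  })
  t1 <- build_template(cycles, 20, 15)
  t2 <- build_template(rev(cycles), 20, 15)
  expect_equal(t1$points, t2$points, tolerance = 1e-12)
  # fixed output length despite different raw cycle lengths
  expect_equal(nrow(t1$points), 35L)
  mixed <- cycles
  mixed[[2]]$label <- 4L
  expect_error(build_template(mixed, 20, 15), "mixed patterns")
})

test_that("the template mean is linear over cycle subsets", {
  set.seed(8)
  cycles <- lapply(1:5, function(i) {
    c <- make_cycle(18, 12, fn = function(u, ch) sin(2 * pi * u) * ch / 5,
                    cycle_id = i)
    c$frames <- c$frames + matrix(rnorm(300, sd = 0.3), 30, 10)
    c
  })
  stats <- channel_stats(cycles)
  tA <- build_template(cycles[1:2], 10, 8, stats = stats)
  tB <- build_template(cycles[3:5], 10, 8, stats = stats)
  tAll <- build_template(cycles, 10, 8, stats = stats)
  expect_equal(tAll$points, (2 * tA$points + 3 * tB$points) / 5,
               tolerance = 1e-12)
})

test_that("a library holds one template per subject per pattern", {
  cfg <- gait_gen_config(noise_sd = 0.1, seed = 21)
  dayA <- generate_day(cfg, 2, subject_id = "sA")
  dayB <- generate_day(cfg, 2, seed = 22, subject_id = "sB")
  lib <- build_template_library(list(dayA$recording, dayB$recording))
  expect_length(lib$templates, 10L)
  expect_setequal(lib$subjects, c("sA", "sB"))
  # all of one subject's templates share that subject's channel stats
  tsA <- gaitmark:::subject_templates(lib, "sA")
  expect_length(tsA, 5L)
  for (t in tsA) expect_identical(t$stats, lib$stats$sA)
  # a missing pattern is reported by (subject, pattern)
  day3 <- generate_day(cfg, 2, seed = 23, schedule = rep(c(1, 2, 4, 5), 2),
                       subject_id = "sC")
  expect_error(build_template_library(list(day3$recording)),
               "\\(sC, 3\\)")
})

test_that("each template is nearest (by DTW) to cycles of its own pattern", {
  cfg <- gait_gen_config(noise_sd = 0.2, seed = 31)
  day <- generate_day(cfg, 4)
  lib <- build_template_library(list(day$recording))
  tpls <- gaitmark:::subject_templates(lib)
  stats <- tpls[[1]]$stats
  for (p in 1:5) {
    # the pattern's pure waveform, phase-normalized, against each template
    pure <- make_cycle(60, 40)
    pure$frames <- pattern_waveform(cfg, p, c(0.6 * (0:59) / 60,
                                              0.6 + 0.4 * (0:39) / 40))
    X <- gaitmark:::zscore_frames(pure$frames, stats)
    costs <- vapply(tpls, function(t) {
      dtw_align(X, t$points)$normalized_cost
    }, numeric(1))
    expect_equal(which.min(costs), p)
  }
})

test_that("template libraries round-trip through disk", {
  cfg <- gait_gen_config(noise_sd = 0.1, seed = 41)
  day <- generate_day(cfg, 2)
  lib <- build_template_library(list(day$recording))
  dir <- withr::local_tempdir()
  write_template_library(lib, dir)
  back <- read_template_library(dir)
  expect_length(back$templates, 5L)
  for (i in seq_along(lib$templates)) {
    expect_equal(back$templates[[i]]$points, lib$templates[[i]]$points,
                 tolerance = 1e-6)
    expect_equal(back$templates[[i]]$pattern_id,
                 lib$templates[[i]]$pattern_id)
    expect_equal(back$templates[[i]]$stats$mean,
                 lib$templates[[i]]$stats$mean, tolerance = 1e-6)
  }
})
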