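test_that("noise-free cycles are labeled by their own template with near-zero cost", {
  cfg <- gait_gen_config(noise_sd = 0, pulse_rate = 0,
                         pressure_noise_sd = 0, seed = 51)
  day <- generate_day(cfg, 2)
  cyc <- extract_cycles(day$recording)
  lib <- build_template_library(list(day$recording))
  res <- autolabel_cycles(cyc, lib, k = 0.05)
  expect_equal(res$assigned_pattern, day$truth$label)
  expect_true(all(res$best_cost < 0.05))
  expect_true(all(res$selected))
  # argmin/min consistency between the assignment and the cost table
  costs <- as.matrix(res[, paste0("cost_", 1:5)])
  expect_equal(res$assigned_pattern, apply(costs, 1, which.min))
  expect_equal(res$best_cost, apply(costs, 1, min))
})

test_that("threshold edge cases behave as limits", {
  cfg <- gait_gen_config(noise_sd = 0.2, seed = 52)
  day <- generate_day(cfg, 2)
  cyc <- extract_cycles(day$recording)
  lib <- build_template_library(list(day$recording))
  expect_error(autolabel_cycles(cyc, lib, k = 0), "k > 0")
  res <- autolabel_cycles(cyc, lib, k = Inf)
  expect_true(all(res$selected))
})

test_that("ties go to the lowest pattern id and order does not matter", {
  cfg <- gait_gen_config(noise_sd = 0, pulse_rate = 0,
                         pressure_noise_sd = 0, seed = 53)
  day <- generate_day(cfg, 2, schedule = rep(1, 4))
  cyc <- extract_cycles(day$recording)
  lib <- build_template_library(
    cycles = lapply(cyc, function(c) c),
    n_patterns = 1L)
  t1 <- lib$templates[[1]]
  t2 <- t1
  t2$pattern_id <- 2L
  # identical templates for patterns 1 and 2: exact cost tie
  res <- autolabel_cycles(cyc, list(t1, t2), k = 1)
  expect_true(all(res$assigned_pattern == 1L))
  # assignment is invariant to library order (up to the tie-break)
  cfg2 <- gait_gen_config(noise_sd = 0.3, seed = 54)
  day2 <- generate_day(cfg2, 3)
  cyc2 <- extract_cycles(day2$recording)
  lib2 <- build_template_library(list(day2$recording))
  tpls <- gaitmark:::subject_templates(lib2)
  r_fwd <- autolabel_cycles(cyc2, tpls, k = 5)
  r_rev <- autolabel_cycles(cyc2, rev(tpls), k = 5)
  expect_equal(r_fwd$assigned_pattern, r_rev$assigned_pattern)
  expect_equal(r_fwd$best_cost, r_rev$best_cost)
})

test_that("adjacent disagreement suppresses both cycles of the pair", {
  res <- make_autolabel_result(rep(0.1, 4), c(1, 1, 1, 1), k = 1)
  cyc <- lapply(1:4, function(i) make_cycle(10, 8, cycle_id = i))
  out <- postprocess_autolabels(res, cyc)
  expect_false(any(out$suppressed))
  res2 <- make_autolabel_result(rep(0.1, 4), c(1, 1, 2, 2), k = 1)
  out2 <- postprocess_autolabels(res2, cyc)
  expect_equal(which(out2$suppressed), c(2L, 3L))
  expect_error(postprocess_autolabels(res2, cyc[1:3]), "mismatch")
})

test_that("a real transition suppresses exactly the boundary pair", {
  cfg <- gait_gen_config(noise_sd = 0, pulse_rate = 0,
                         pressure_noise_sd = 0, seed = 55)
  day <- generate_transition_day(cfg, list(c(1, 5), c(2, 5)))
  expect_equal(day$transitions, 5)
  cyc <- extract_cycles(day$recording)
  lib <- build_template_library(list(day$recording), n_patterns = 2L)
  res <- postprocess_autolabels(autolabel_cycles(cyc, lib, k = 1), cyc)
  expect_equal(which(res$suppressed), c(5L, 6L))
  # k segments produce k - 1 transitions
  day3 <- generate_transition_day(cfg, list(c(1, 2), c(3, 2), c(2, 2)),
                                  seed = 56)
  expect_equal(day3$transitions, c(2, 4))
})

test_that("data selection arithmetic matches the closed form", {
  res <- make_autolabel_result(c(0.1, 0.3), c(1, 2), k = 0.2)
  w <- make_windows(array(0, c(2, 30, 10)), label = c(NA, NA))
  w$cycle_id <- c(1L, 2L)
  sel <- select_training_data(res, w)
  expect_equal(sel$dr, 0.5)
  expect_equal(n_windows <- length(sel$windows$start_idx), 1L)
  expect_equal(sel$windows$label, 1L)
  # all below threshold, none suppressed
  res2 <- make_autolabel_result(c(0.1, 0.15), c(1, 2), k = 0.2)
  expect_equal(select_training_data(res2, w)$dr, 1)
})

test_that("selection rate is monotone in k and suppression only removes", {
  set.seed(57)
  costs <- runif(40, 0, 2)
  res <- make_autolabel_result(costs, sample(1:5, 40, TRUE), k = 1)
  w <- make_windows(array(0, c(40, 30, 10)), label = rep(NA_integer_, 40),
                    phase = rep(c("stance", "swing"), 20))
  w$cycle_id <- seq_len(40)
  drs <- vapply(seq(0.1, 2.1, by = 0.25), function(k) {
    select_training_data(res, w, k = k)$dr
  }, numeric(1))
  expect_true(all(diff(drs) >= 0))
  # suppressing cycles can only shrink the selected set
  res_sup <- res
  res_sup$suppressed[sample(40, 10)] <- TRUE
  n_plain <- length(select_training_data(res, w)$windows$start_idx)
  n_sup <- length(select_training_data(res_sup, w)$windows$start_idx)
  expect_lte(n_sup, n_plain)
  # and the selected set is always a subset of all windows
  sel <- select_training_data(res_sup, w)
  expect_true(all(sel$windows$cycle_id %in% w$cycle_id))
})

test_that("swing windows of suppressed cycles are excluded, stance kept", {
  res <- make_autolabel_result(c(0.1, 0.1), c(1, 2), k = 1)
  res$suppressed <- c(TRUE, FALSE)
  w <- make_windows(array(0, c(4, 30, 10)), label = rep(NA_integer_, 4),
                    phase = c("stance", "swing", "stance", "swing"))
  w$cycle_id <- c(1L, 1L, 2L, 2L)
  sel <- select_training_data(res, w)
  expect_equal(sel$windows$cycle_id, c(1L, 2L, 2L))
  expect_equal(sel$windows$phase, c("stance", "stance", "swing"))
})

test_that("tuning k maximizes SR subject to the DR floor", {
  cfg <- gait_gen_config(noise_sd = 0.05, seed = 7)
  morning <- generate_day(cfg, 5, "interleaved", seed = 71,
                          session_id = "am")
  afternoon <- generate_day(cfg, 5, "interleaved", seed = 72,
                            session_id = "pm")
  grid <- seq(0.05, 0.5, by = 0.05)
  out <- tune_k(morning$recording, afternoon$recording, grid = grid)
  tab <- out$table
  # exhaustive check of the selection rule against the returned table
  eligible <- tab[!is.na(tab$sr) & tab$dr >= 0.9, ]
  expect_gt(nrow(eligible), 0)
  expect_gte(tab$dr[tab$k == out$k_star], 0.9)
  expect_gte(tab$sr[tab$k == out$k_star], max(eligible$sr) - 0.01)
  expect_equal(out$k_star,
               min(eligible$k[eligible$sr == max(eligible$sr)]))
  # degenerate grid returns its only member
  one <- tune_k(morning$recording, afternoon$recording, grid = 1.5)
  expect_equal(one$k_star, 1.5)
})

test_that("success rate counts correct assignments among selected cycles", {
  res <- make_autolabel_result(rep(0.1, 14), c(rep(1, 13), 2), k = 1)
  truth <- rep(1L, 14)
  expect_equal(round(autolabel_success_rate(res, truth), 4), 0.9286)
  expect_equal(autolabel_success_rate(res, c(rep(1, 13), 2L)), 1)
  # restricting to selected cycles changes the denominator
  res$selected <- c(rep(TRUE, 13), FALSE)
  expect_equal(autolabel_success_rate(res, truth), 1)
  expect_equal(autolabel_success_rate(res, truth, selected_only = FALSE),
               13 / 14)
})
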