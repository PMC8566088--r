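# Cross-day experiment harnesses. Conventions shared by all three:
# windows are labeled causally from extracted cycles, stance and swing
# classifiers are trained separately, predictions are smoothed by the
# 5-point majority vote, and RE is computed over the labeled test windows.
# Test (afternoon) windows never enter any training set.

labeled_windows <- function(rec, euler_threshold = 20, ...) {
  rec <- filter_euler_pulses(rec, euler_threshold)
  w <- sliding_windows(rec, ...)
  subset_windows(w, !is.na(w$label) & !is.na(w$phase))
}

evaluate_on <- function(models, test_windows, n_classes, vote_n = 5L,
                        sr = NA_real_, dr = NA_real_) {
  pred <- predict(models, test_windows)
  eval_report(pred, test_windows$label, n_classes, vote_n, sr = sr, dr = dr)
}

#' Cross-day training experiment
#'
#' Trains on each candidate day separately (manual labels) and evaluates
#' every resulting model on the same held-out test day, quantifying how
#' training/testing day combinations - not the calendar gap per se -
#' drive the recognition error.
#'
#' @param days List of labeled `gait_recording`s.
#' @param test_day Index into `days` of the test day.
#' @param spec A [classifier_spec()].
#' @param n_classes Number of patterns.
#' @param vote_n Majority-vote window.
#' @return Named list of `eval_report`, one per training day.
#' @export
run_cross_day <- function(days, test_day, spec, n_classes = 5L,
                          vote_n = 5L) {
  stopifnot(length(days) >= 2L, test_day >= 1L, test_day <= length(days))
  test_w <- labeled_windows(days[[test_day]])
  out <- list()
  for (i in seq_along(days)) {
    if (i == test_day) next
    models <- train_phase_models(spec, labeled_windows(days[[i]]))
    out[[paste0("D", i)]] <- evaluate_on(models, test_w, n_classes, vote_n)
  }
  out
}

#' Manual-training vs automatic-labeling strategies
#'
#' Compares the two retraining strategies on one train day / test day
#' pair, where the test day splits into a morning and an afternoon
#' session:
#' * **T** - train on the train day's manually labeled windows, test on
#'   the afternoon session.
#' * **AL** - build templates from the train day, auto-label the morning
#'   session's cycles by DTW, suppress transition swing data, keep cycles
#'   passing the threshold `k`, retrain on the train day plus the selected
#'   pseudo-labeled morning windows, and test on the afternoon session.
#'
#' The afternoon windows are never part of either training set.
#'
#' @param train_day Labeled `gait_recording`.
#' @param test_morning,test_afternoon The test day's two sessions;
#'   `test_morning`'s labels are only used for reporting SR, never for
#'   training.
#' @param spec A [classifier_spec()].
#' @param k Data-selection threshold on the normalized DTW cost.
#' @param n_classes,vote_n As elsewhere.
#' @return List with `eval_report`s `T` and `AL` (the latter carrying the
#'   morning SR/DR), plus `n_pseudo`, the number of pseudo-labeled
#'   windows added.
#' @export
run_T_vs_AL <- function(train_day, test_morning, test_afternoon, spec, k,
                        n_classes = 5L, vote_n = 5L) {
  train_w <- labeled_windows(train_day)
  test_w <- labeled_windows(test_afternoon)
  # T: manual training only
  models_T <- train_phase_models(spec, train_w)
  report_T <- evaluate_on(models_T, test_w, n_classes, vote_n)
  # AL: templates from the train day, pseudo-labels from the morning
  library <- build_template_library(list(train_day), n_patterns = n_classes)
  al <- al_training_set(train_w, test_morning, library, k)
  models_AL <- train_phase_models(spec, al$windows)
  report_AL <- evaluate_on(models_AL, test_w, n_classes, vote_n,
                           sr = al$sr, dr = al$dr)
  list(T = report_T, AL = report_AL, n_pseudo = al$n_pseudo)
}

# Auto-label a morning session against a template library and append the
# selected pseudo-labeled windows to a manual training set.
al_training_set <- function(train_w, morning, library, k,
                            euler_threshold = 20) {
  morning <- filter_euler_pulses(morning, euler_threshold)
  cycles <- extract_cycles(morning)
  res <- autolabel_cycles(cycles, library, k = k)
  res <- postprocess_autolabels(res, cycles)
  morning_w <- sliding_windows(morning, cycles = cycles)
  sel <- select_training_data(res, morning_w, k = k)
  truth <- vapply(cycles, `[[`, integer(1), "label")
  sr <- if (any(res$selected)) {
    autolabel_success_rate(res, truth)
  } else {
    NA_real_
  }
  list(windows = bind_windows(train_w, sel$windows), sr = sr, dr = sel$dr,
       n_pseudo = n_windows(sel$windows))
}

#' Template accumulation experiment
#'
#' Runs the AL strategy at increasing template-library sizes: level `ALj`
#' pools the labeled cycles of the first `j` template days into the
#' library (and their windows into the manual training base), auto-labels
#' the morning session, and tests on the afternoon session.
#'
#' @param template_days List of labeled `gait_recording`s, in accumulation
#'   order.
#' @param test_morning,test_afternoon The test day's sessions.
#' @param spec A [classifier_spec()].
#' @param k Data-selection threshold.
#' @param n_classes,vote_n As elsewhere.
#' @return Named list `AL1..ALm` of `eval_report`s.
#' @export
run_template_accumulation <- function(template_days, test_morning,
                                      test_afternoon, spec, k,
                                      n_classes = 5L, vote_n = 5L) {
  stopifnot(length(template_days) >= 2L)
  test_w <- labeled_windows(test_afternoon)
  out <- list()
  for (j in seq_along(template_days)) {
    pool <- template_days[seq_len(j)]
    cycles <- unlist(lapply(pool, extract_cycles), recursive = FALSE)
    library <- build_template_library(cycles = cycles,
                                      n_patterns = n_classes,
                                      subject_id = pool[[1]]$subject_id)
    train_w <- Reduce(bind_windows, lapply(pool, labeled_windows))
    al <- al_training_set(train_w, test_morning, library, k)
    models <- train_phase_models(spec, al$windows)
    out[[paste0("AL", j)]] <- evaluate_on(models, test_w, n_classes,
                                          vote_n, sr = al$sr, dr = al$dr)
  }
  out
}
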