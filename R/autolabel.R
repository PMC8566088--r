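#' Automatically label gait cycles by DTW template matching
#'
#' Each completed cycle is z-scored per channel, DTW-aligned to every
#' pattern template, and assigned the pattern with the smallest
#' length-normalized cost (ties broken by lowest pattern id). A cycle is
#' *selected* for downstream retraining when its best cost is below the
#' data-selection threshold `k`.
#'
#' @param cycles List of `gait_cycle` in time order.
#' @param library A `template_library` (or list of `gait_template` for one
#'   subject, one per pattern).
#' @param k Positive data-selection threshold on the normalized DTW cost.
#' @param subject_id Which subject's templates to use (default: first).
#' @param normalize `"session"` (default) z-scores the cycles with channel
#'   statistics estimated from the supplied cycle list itself, so a
#'   session-level affine drift (per-channel offset or gain change between
#'   recording days) cancels in the comparison and a threshold tuned on
#'   one day keeps selecting data on later days; `"library"` reuses the
#'   template library's statistics instead. Session statistics use only
#'   unlabeled data, so nothing leaks from manual labels.
#' @return Data frame of class `autolabel_result`, one row per cycle:
#'   `cycle_id`, `assigned_pattern`, `best_cost`, `cost_1..cost_S`,
#'   `selected`, `suppressed` (all `FALSE` until [postprocess_autolabels()]).
#' @export
autolabel_cycles <- function(cycles, library, k, subject_id = NULL,
                             normalize = c("session", "library")) {
  stopifnot(length(cycles) > 0L, k > 0)
  normalize <- match.arg(normalize)
  tpls <- if (inherits(library, "template_library")) {
    subject_templates(library,
                      if (is.null(subject_id)) library$subjects[1] else subject_id)
  } else {
    library
  }
  if (length(tpls) == 0L) stop("empty template library")
  stats <- if (normalize == "session") {
    channel_stats(cycles)
  } else {
    tpls[[1]]$stats
  }
  S <- length(tpls)
  costs <- matrix(NA_real_, nrow = length(cycles), ncol = S)
  for (ci in seq_along(cycles)) {
    X <- zscore_frames(cycles[[ci]]$frames, stats)
    for (p in seq_len(S)) {
      costs[ci, p] <- dtw_align(X, tpls[[p]]$points)$normalized_cost
    }
  }
  assigned <- apply(costs, 1, which.min)   # which.min takes lowest id on ties
  best <- costs[cbind(seq_len(nrow(costs)), assigned)]
  pattern_ids <- vapply(tpls, `[[`, integer(1), "pattern_id")
  out <- data.frame(
    cycle_id = vapply(cycles, `[[`, integer(1), "cycle_id"),
    assigned_pattern = pattern_ids[assigned],
    best_cost = best)
  cost_cols <- as.data.frame(costs)
  names(cost_cols) <- paste0("cost_", pattern_ids)
  out <- cbind(out, cost_cols)
  out$selected <- out$best_cost < k
  out$suppressed <- FALSE
  attr(out, "k") <- k
  class(out) <- c("autolabel_result", "data.frame")
  out
}

#' Suppress swing-phase data around pattern transitions
#'
#' Compares the assigned patterns of every pair of adjacent complete gait
#' cycles; where they disagree, the swing-phase data of *both* cycles are
#' flagged as suppressed and excluded from retraining. Pattern transitions
#' generally occur during swing, so this filters out the data that cannot
#' be attributed to a single pattern; stance data are retained.
#'
#' @param results An `autolabel_result` in time order.
#' @param cycles The matching cycle list (same length and order).
#' @return `results` with the `suppressed` column updated; the number of
#'   suppressed cycles is recorded in `attr(, "n_suppressed")`.
#' @export
postprocess_autolabels <- function(results, cycles) {
  stopifnot(inherits(results, "autolabel_result"))
  if (nrow(results) != length(cycles)) {
    stop("results (", nrow(results), ") and cycles (", length(cycles),
         ") length mismatch")
  }
  n <- nrow(results)
  if (n >= 2L) {
    differs <- results$assigned_pattern[-n] != results$assigned_pattern[-1]
    idx <- which(differs)
    results$suppressed[unique(c(idx, idx + 1L))] <- TRUE
  }
  attr(results, "n_suppressed") <- sum(results$suppressed)
  results
}

#' Select pseudo-labeled training windows
#'
#' Applies the threshold-`k` selection rule to auto-labeled cycles and
#' maps the surviving cycles to sliding windows: a window is kept when its
#' cycle passed the threshold and, if the cycle was flagged by
#' [postprocess_autolabels()], only its stance-phase windows are kept. Kept
#' windows receive the cycle's assigned pattern as pseudo-label.
#'
#' @param results An `autolabel_result`.
#' @param windows A `gait_windows` whose `cycle_id` refers to the same
#'   cycle list the results were computed from.
#' @param k Selection threshold; defaults to the one stored on `results`.
#' @return List: `windows` (pseudo-labeled `gait_windows`), `dr` (data
#'   selection rate: selected cycles / all complete cycles, between 0
#'   and 1), `n_selected`, `n_total`.
#' @export
select_training_data <- function(results, windows, k = attr(results, "k")) {
  stopifnot(inherits(results, "autolabel_result"), k > 0)
  sel_cycles <- results$cycle_id[results$best_cost < k]
  dr <- length(sel_cycles) / nrow(results)
  sup_cycles <- results$cycle_id[results$suppressed]
  keep <- !is.na(windows$cycle_id) & windows$cycle_id %in% sel_cycles &
    !(windows$cycle_id %in% sup_cycles & windows$phase == "swing")
  out <- subset_windows(windows, keep)
  # pseudo-label from the assignment, not the (possibly unknown) truth
  map <- results$assigned_pattern[match(out$cycle_id, results$cycle_id)]
  out$label <- as.integer(map)
  list(windows = out, dr = dr,
       n_selected = length(sel_cycles), n_total = nrow(results))
}

#' Tune the data-selection threshold k
#'
#' Reproduces the same-day morning/afternoon cross-test used to choose the
#' per-subject threshold: templates are built from the labeled morning
#' session, the afternoon cycles are auto-labeled at each candidate `k`,
#' and the success rate SR (correct assignments among selected cycles) and
#' data selection rate DR (selected / all cycles) are tabulated. The
#' returned `k_star` is the smallest grid value maximizing SR among those
#' with `DR >= dr_min`; when no candidate reaches the DR floor, the
#' candidate with the highest DR is returned with a warning.
#'
#' @param morning,afternoon Labeled `gait_recording`s from one subject.
#' @param grid Numeric vector of candidate `k` values.
#' @param dr_min Minimum acceptable data selection rate (default 0.9).
#' @param n_patterns Number of movement patterns.
#' @param euler_threshold Limiting-filter threshold applied to both
#'   recordings' Euler-angle channels before analysis.
#' @return List: `k_star` and `table` (data frame `k`, `sr`, `dr`).
#' @export
tune_k <- function(morning, afternoon, grid, dr_min = 0.9, n_patterns = 5L,
                   euler_threshold = 20) {
  stopifnot(length(grid) > 0L, all(grid > 0))
  library <- build_template_library(list(morning), n_patterns = n_patterns,
                                    euler_threshold = euler_threshold)
  if (!is.null(euler_threshold)) {
    afternoon <- filter_euler_pulses(afternoon, euler_threshold)
  }
  cycles <- extract_cycles(afternoon)
  truth <- vapply(cycles, `[[`, integer(1), "label")
  if (any(is.na(truth))) stop("afternoon recording must be fully labeled")
  res <- autolabel_cycles(cycles, library, k = max(grid))
  tab <- data.frame(k = sort(grid))
  tab$sr <- vapply(seq_len(nrow(tab)), function(i) {
    sel <- res$best_cost < tab$k[i]
    if (!any(sel)) return(NA_real_)
    mean(res$assigned_pattern[sel] == truth[sel])
  }, numeric(1))
  tab$dr <- vapply(tab$k, function(kk) mean(res$best_cost < kk), numeric(1))
  ok <- !is.na(tab$sr) & tab$dr >= dr_min
  if (any(ok)) {
    cand <- tab[ok, ]
    k_star <- min(cand$k[cand$sr == max(cand$sr)])
  } else {
    warning("no k in the grid reaches DR >= ", dr_min,
            "; returning the k with highest DR")
    k_star <- tab$k[which.max(tab$dr)]
  }
  list(k_star = k_star, table = tab)
}

#' Auto-labeling success rate
#'
#' Fraction of auto-labeled cycles whose assigned pattern matches the
#' manual label, computed over the selected cycles (the ones that would
#' enter retraining) by default.
#'
#' @param results An `autolabel_result`.
#' @param truth Integer vector of true patterns, one per cycle.
#' @param selected_only Restrict to cycles passing the `k` threshold.
#' @return SR between 0 and 1; `NaN` when no cycle qualifies.
#' @export
autolabel_success_rate <- function(results, truth, selected_only = TRUE) {
  stopifnot(nrow(results) == length(truth))
  idx <- if (selected_only) results$selected else rep(TRUE, nrow(results))
  mean(results$assigned_pattern[idx] == truth[idx])
}
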