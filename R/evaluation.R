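#' Recognition error rate
#'
#' Percentage of test units whose predicted pattern disagrees with the
#' manual label: `RE = 100 * N_mis / N_total`. Recognition accuracy is its
#' complement, `100 - RE`.
#'
#' @param pred,truth Equal-length non-empty label vectors.
#' @return RE in percent.
#' @export
recognition_error <- function(pred, truth) {
  if (length(pred) == 0L) stop("empty label streams")
  if (length(pred) != length(truth)) stop("pred and truth lengths differ")
  100 * mean(pred != truth)
}

#' Row-percentage confusion matrix
#'
#' Entry (i, j) is the percentage of test units of true pattern i that
#' were recognized as pattern j: `r_ij = 100 * s_ij / s_i` with `s_i` the
#' number of true-i units. Rows of patterns absent from the test set are
#' all zero and listed in `attr(, "empty_rows")`.
#'
#' @param pred,truth Label vectors with values in `1..n_classes`.
#' @param n_classes Number of patterns S.
#' @return S x S matrix; each occupied row sums to 100.
#' @export
confusion_matrix_pct <- function(pred, truth, n_classes) {
  stopifnot(length(pred) == length(truth))
  if (any(c(pred, truth) < 1L | c(pred, truth) > n_classes)) {
    stop("labels out of range 1..", n_classes)
  }
  counts <- matrix(0, n_classes, n_classes)
  for (i in seq_along(truth)) {
    counts[truth[i], pred[i]] <- counts[truth[i], pred[i]] + 1
  }
  row_n <- rowSums(counts)
  out <- matrix(0, n_classes, n_classes)
  occ <- row_n > 0
  out[occ, ] <- 100 * counts[occ, , drop = FALSE] / row_n[occ]
  dimnames(out) <- list(true = seq_len(n_classes), pred = seq_len(n_classes))
  attr(out, "empty_rows") <- which(!occ)
  out
}

#' N-point majority vote
#'
#' Causal smoothing of a streamed label sequence: each output is the modal
#' label of the trailing window of the last `n` predictions (the available
#' prefix during warm-up). Ties keep the previous output when it is among
#' the tied modes (otherwise the smallest tied label, so the vote never
#' emits a label absent from its window); an isolated single-label flip
#' inside a constant stream is always removed for `n >= 3`, and `n = 1`
#' is the identity.
#'
#' @param stream Non-empty label vector in time order.
#' @param n Odd window size (default 5).
#' @return Smoothed label vector, same length.
#' @export
majority_vote <- function(stream, n = 5L) {
  if (length(stream) == 0L) stop("empty stream")
  stopifnot(n >= 1L, n %% 2L == 1L)
  out <- stream
  for (i in seq_along(stream)) {
    win <- stream[max(1L, i - n + 1L):i]
    tab <- table(win)
    top <- as.integer(names(tab)[tab == max(tab)])
    if (length(top) == 1L) {
      out[i] <- top
    } else if (i > 1L && out[i - 1L] %in% top) {
      out[i] <- out[i - 1L]
    } else {
      # previous output not among the tied modes (or no previous output):
      # fall back to the smallest tied label so the vote never emits a
      # label absent from its window
      out[i] <- min(top)
    }
  }
  out
}

#' Transition success rule
#'
#' After a pattern transition, the recognizer is given five outputs to
#' catch up: the transition is successful when the new pattern appears in
#' the prediction stream within the first five outputs after the
#' transition's critical gait event.
#'
#' @param pred Label stream.
#' @param event_index Index of the critical gait event in the stream.
#' @param new_pattern The pattern entered at the transition.
#' @param horizon Number of outputs allowed (default 5).
#' @return `TRUE`/`FALSE`.
#' @export
transition_success <- function(pred, event_index, new_pattern, horizon = 5L) {
  if (event_index < 1L || event_index > length(pred)) {
    stop("event_index out of range")
  }
  upto <- min(length(pred), event_index + horizon)
  if (upto < event_index + 1L) return(FALSE)
  any(pred[(event_index + 1L):upto] == new_pattern)
}

#' Evaluation report for one experiment
#'
#' @param pred,truth Window-level label streams (equal length).
#' @param n_classes Number of patterns.
#' @param vote_n Majority-vote window applied to `pred` before scoring
#'   (`NULL` or 1 to disable).
#' @param sr,dr Optional auto-labeling success and data-selection rates to
#'   carry along.
#' @return Object of class `eval_report`: `re_percent`,
#'   `accuracy_percent`, `confusion` (row-percent matrix), `n_total`,
#'   `n_mis`, `sr`, `dr`.
#' @export
eval_report <- function(pred, truth, n_classes = 5L, vote_n = 5L,
                        sr = NA_real_, dr = NA_real_) {
  if (!is.null(vote_n) && vote_n > 1L) pred <- majority_vote(pred, vote_n)
  re <- recognition_error(pred, truth)
  structure(
    list(re_percent = re,
         accuracy_percent = 100 - re,
         confusion = confusion_matrix_pct(pred, truth, n_classes),
         n_total = length(truth),
         n_mis = sum(pred != truth),
         sr = sr, dr = dr),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> RE = %.2f%% (accuracy %.2f%%), %d / %d misrecognized",
              x$re_percent, x$accuracy_percent, x$n_mis, x$n_total))
  if (!is.na(x$sr)) cat(sprintf("; SR = %.4f", x$sr))
  if (!is.na(x$dr)) cat(sprintf("; DR = %.4f", x$dr))
  cat("\n")
  invisible(x)
}
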