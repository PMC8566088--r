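#' Classifier specification
#'
#' The four window-level classifier configurations behind one train/predict
#' interface: quadratic discriminant analysis, a one-vs-one C-SVC with a
#' polynomial kernel, a small convolutional network (two conv/average-pool
#' stages and a softmax head), and a single-layer LSTM read out at the last
#' step. QDA and SVM consume flattened windows; the networks consume the
#' frames x channels sequence.
#'
#' @param kind One of `"qda"`, `"svm"`, `"cnn"`, `"lstm"`.
#' @param seed Integer seed making training deterministic.
#' @param hyper Named list of kind-specific hyperparameters overriding the
#'   defaults: QDA `n_pca` (20); SVM `cost` (1), `degree` (3), `coef0` (1);
#'   CNN `n1` (5), `k1` (5,2), `n2` (8), `k2` (4,2), `pool` (2), `lr`
#'   (1e-3), `epochs` (40), `batch` (32); LSTM `hidden` (64), `lr` (1e-3),
#'   `epochs` (30), `batch` (32). None of these values comes from a
#'   published protocol; all are package defaults.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("qda", "svm", "cnn", "lstm"),
                            seed = 1L, hyper = list()) {
  kind <- match.arg(kind)
  structure(list(kind = kind, seed = as.integer(seed), hyper = hyper),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat(sprintf("<classifier_spec> %s (seed %d)\n", toupper(x$kind), x$seed))
  invisible(x)
}

#' Train a window classifier
#'
#' @param spec A [classifier_spec()].
#' @param windows A labeled `gait_windows` (windows with `NA` labels are
#'   dropped); at least two classes must be present.
#' @param phase Optional tag ("stance"/"swing") recorded on the model.
#' @return An object of class `gait_model`.
#' @details QDA needs a nonsingular within-class covariance, which a
#'   300-dimensional flattened window cannot provide at realistic sample
#'   sizes; the QDA route therefore projects the flattened windows onto
#'   their leading principal components (fitted on the training windows
#'   only) before discriminating.
#' @export
train_classifier <- function(spec, windows, phase = NA_character_) {
  stopifnot(inherits(spec, "classifier_spec"),
            inherits(windows, "gait_windows"))
  keep <- !is.na(windows$label)
  windows <- subset_windows(windows, keep)
  y <- windows$label
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("training data contains fewer than 2 classes")
  y_idx <- match(y, classes)
  fit <- switch(
    spec$kind,
    qda = {
      X <- flatten_windows(windows)
      n_pca <- spec$hyper$n_pca %||% 20L
      # QDA estimates one covariance per class, so the projection must
      # stay below the smallest class count
      n_pca <- min(n_pca, ncol(X), nrow(X) - 1L,
                   min(table(y_idx)) - 1L)
      pca <- prcomp(X, center = TRUE, scale. = FALSE, rank. = n_pca)
      scores <- pca$x[, seq_len(n_pca), drop = FALSE]
      list(pca = pca, n_pca = n_pca,
           qda = MASS::qda(scores, grouping = factor(y_idx)))
    },
    svm = {
      X <- flatten_windows(windows)
      e1071::svm(X, factor(y_idx), type = "C-classification",
                 kernel = "polynomial",
                 cost = spec$hyper$cost %||% 1,
                 degree = spec$hyper$degree %||% 3,
                 coef0 = spec$hyper$coef0 %||% 1,
                 scale = FALSE)
    },
    cnn = cnn_train(windows$features, y_idx, length(classes),
                    hyper = spec$hyper, seed = spec$seed),
    lstm = lstm_train(windows$features, y_idx, length(classes),
                      hyper = spec$hyper, seed = spec$seed))
  structure(list(spec = spec, kind = spec$kind, classes = classes,
                 phase = phase, window_frames = windows$window_frames,
                 fit = fit),
            class = "gait_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gait_model <- function(x, ...) {
  cat(sprintf("<gait_model> %s over classes {%s}%s\n", toupper(x$kind),
              paste(x$classes, collapse = ","),
              if (is.na(x$phase)) "" else paste0(" [", x$phase, "]")))
  invisible(x)
}

#' Predict window labels
#'
#' @param object A `gait_model`.
#' @param windows A `gait_windows` with the same window length the model
#'   was trained on.
#' @param ... Unused.
#' @return Integer label vector, one prediction per window in input order
#'   (empty for zero windows).
#' @export
predict.gait_model <- function(object, windows, ...) {
  stopifnot(inherits(windows, "gait_windows"))
  if (n_windows(windows) == 0L) return(integer(0))
  if (windows$window_frames != object$window_frames) {
    stop("window length ", windows$window_frames,
         " does not match model (", object$window_frames, ")")
  }
  idx <- switch(
    object$kind,
    qda = {
      X <- flatten_windows(windows)
      scores <- predict(object$fit$pca, X)[, seq_len(object$fit$n_pca),
                                           drop = FALSE]
      as.integer(as.character(predict(object$fit$qda, scores)$class))
    },
    svm = {
      X <- flatten_windows(windows)
      as.integer(as.character(predict(object$fit, X)))
    },
    cnn = cnn_predict(object$fit, windows$features),
    lstm = lstm_predict(object$fit, windows$features))
  object$classes[idx]
}

#' Train separate stance and swing models
#'
#' The stance and swing phases are trained and tested separately; the two
#' models never see each other's windows.
#'
#' @param spec A [classifier_spec()].
#' @param windows Labeled `gait_windows` with phase tags.
#' @return Object of class `phase_models`: list with `stance` and `swing`
#'   `gait_model`s.
#' @export
train_phase_models <- function(spec, windows) {
  structure(
    list(stance = train_classifier(
           spec, subset_windows(windows, !is.na(windows$phase) &
                                  windows$phase == "stance"), "stance"),
         swing = train_classifier(
           spec, subset_windows(windows, !is.na(windows$phase) &
                                  windows$phase == "swing"), "swing")),
    class = "phase_models")
}

#' Predict with phase-specific models
#'
#' Routes each window to the model of its gait phase and returns one label
#' per window in input order. Windows with `NA` phase get `NA`.
#'
#' @param object A `phase_models`.
#' @param windows A `gait_windows`.
#' @param ... Unused.
#' @return Integer label vector.
#' @export
predict.phase_models <- function(object, windows, ...) {
  out <- rep(NA_integer_, n_windows(windows))
  for (ph in c("stance", "swing")) {
    sel <- !is.na(windows$phase) & windows$phase == ph
    if (any(sel)) {
      out[sel] <- predict(object[[ph]], subset_windows(windows, sel))
    }
  }
  out
}

#' Count of pairwise binary classifiers in a one-vs-one SVM
#'
#' The libsvm C-SVC decomposes an S-class problem into `choose(S, 2)`
#' pairwise classifiers (10 for 5 patterns); this reads the count off a
#' trained model's decision-value layout.
#'
#' @param model A `gait_model` of kind `"svm"`.
#' @return Integer number of binary classifiers.
#' @export
svm_binary_classifier_count <- function(model) {
  stopifnot(inherits(model, "gait_model"), model$kind == "svm")
  k <- model$fit$nclasses
  # libsvm stores one rho (offset) per pairwise decision function
  stopifnot(length(model$fit$rho) == choose(k, 2))
  length(model$fit$rho)
}
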