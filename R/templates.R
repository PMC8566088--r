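#' Per-channel normalization statistics
#'
#' Mean and standard deviation of each IMU channel over the raw frames of
#' a set of cycles. These statistics are computed on the template-building
#' set only and reused to normalize any data later compared against the
#' templates, so no test information leaks into the normalization.
#'
#' @param cycles List of `gait_cycle`.
#' @return List with numeric vectors `mean` and `sd` (length 10); zero
#'   standard deviations are replaced by 1 so constant channels map to 0.
#' @export
channel_stats <- function(cycles) {
  stopifnot(length(cycles) > 0L)
  all_frames <- do.call(rbind, lapply(cycles, `[[`, "frames"))
  mu <- unname(colMeans(all_frames))
  sig <- unname(apply(all_frames, 2, sd))
  sig[!is.finite(sig) | sig == 0] <- 1
  list(mean = mu, sd = sig)
}

# z-score an n x 10 frame matrix with channel stats
zscore_frames <- function(frames, stats) {
  sweep(sweep(frames, 2, stats$mean, "-"), 2, stats$sd, "/")
}

#' Phase-normalize a gait cycle
#'
#' Resamples a cycle to a fixed length so cycles of different durations are
#' aligned at equal percentages of their stance and swing phases: the
#' stance frames are resampled to `n_stance` points and the swing frames to
#' `n_swing` points, per channel, by cubic-spline interpolation over
#' normalized phase in each sub-phase. Interpolating the two phases
#' separately pins the foot-off event to the same row in every normalized
#' cycle. Channels are z-scored with `stats`.
#'
#' @param cycle A `gait_cycle`.
#' @param n_stance,n_swing Interpolation points per phase (each >= 4, the
#'   cubic-spline minimum). Defaults 60/40: a 100-point cycle with the
#'   standard ~60% stance fraction.
#' @param stats Channel statistics from [channel_stats()].
#' @return (n_stance + n_swing) x 10 matrix, stance rows first.
#' @export
normalize_cycle <- function(cycle, n_stance = 60L, n_swing = 40L, stats) {
  stopifnot(inherits(cycle, "gait_cycle"), n_stance >= 4L, n_swing >= 4L)
  st <- stance_frames(cycle)
  sw <- swing_frames(cycle)
  if (nrow(st) < 4L || nrow(sw) < 4L) {
    stop("cycle ", cycle$cycle_id, ": phase shorter than 4 samples (",
         nrow(st), " stance / ", nrow(sw), " swing)")
  }
  resample_phase <- function(frames, n_out) {
    n_in <- nrow(frames)
    u_in <- seq(0, 1, length.out = n_in)
    u_out <- seq(0, 1, length.out = n_out)
    vapply(seq_len(ncol(frames)), function(ch) {
      spline(u_in, frames[, ch], xout = u_out, method = "fmm")$y
    }, numeric(n_out))
  }
  out <- rbind(resample_phase(st, n_stance), resample_phase(sw, n_swing))
  zscore_frames(out, stats)
}

#' Gait-pattern template
#'
#' The pointwise mean of phase-normalized, z-scored gait cycles of one
#' movement pattern: `t_m = (1/K) * sum_n a_n` over the K contributing
#' cycles. Averaging after phase normalization suppresses stride-to-stride
#' noise roughly as 1/sqrt(K).
#'
#' @param cycles List of `gait_cycle`, all with the same (non-`NA`) label.
#' @param n_stance,n_swing Interpolation points per phase.
#' @param stats Channel statistics; computed from `cycles` when `NULL`.
#' @param subject_id Identifier stored on the template.
#' @return An object of class `gait_template`: `pattern_id`, `subject_id`,
#'   `points` ((n_stance+n_swing) x 10 matrix), `n_stance`, `n_swing`,
#'   `k_cycles`, `stats`.
#' @export
build_template <- function(cycles, n_stance = 60L, n_swing = 40L,
                           stats = NULL, subject_id = "s1") {
  if (length(cycles) == 0L) stop("no cycles supplied")
  labs <- vapply(cycles, `[[`, integer(1), "label")
  ulab <- unique(labs)
  if (length(ulab) != 1L) {
    stop("mixed patterns in template input: ", paste(ulab, collapse = ", "))
  }
  if (is.null(stats)) stats <- channel_stats(cycles)
  normed <- lapply(cycles, normalize_cycle, n_stance = n_stance,
                   n_swing = n_swing, stats = stats)
  points <- Reduce(`+`, normed) / length(normed)
  structure(
    list(pattern_id = ulab, subject_id = as.character(subject_id),
         points = points, n_stance = as.integer(n_stance),
         n_swing = as.integer(n_swing), k_cycles = length(cycles),
         stats = stats),
    class = "gait_template")
}

#' @export
print.gait_template <- function(x, ...) {
  cat(sprintf(
    "<gait_template> pattern %d (subject %s): %d points (%d stance / %d swing) from %d cycles\n",
    x$pattern_id, x$subject_id, nrow(x$points), x$n_stance, x$n_swing,
    x$k_cycles))
  invisible(x)
}

#' Build a template library
#'
#' One template per movement pattern per subject, from labeled recordings
#' or from a pre-extracted cycle list. All templates of one subject share
#' channel statistics computed over that subject's labeled cycles.
#'
#' @param recordings List of labeled `gait_recording` (cycles are
#'   extracted internally), or `NULL` when `cycles` is given.
#' @param cycles Optional list of labeled `gait_cycle` (single subject)
#'   used instead of `recordings`.
#' @param n_patterns Number of movement patterns every subject must cover.
#' @param n_stance,n_swing Interpolation points per phase.
#' @param subject_id Subject id used with `cycles` input.
#' @param euler_threshold Limiting-filter threshold applied to the
#'   recordings' Euler-angle channels before cycle extraction (`NULL` to
#'   skip; ignored for `cycles` input, which is taken as preprocessed).
#' @return An object of class `template_library`: list `templates` (in
#'   subject, pattern order), vectors `subjects` and `patterns`, and
#'   per-subject `stats`.
#' @details A missing (subject, pattern) combination is an error naming
#'   every absent pair, since automatic labeling needs a complete library.
#' @export
build_template_library <- function(recordings = NULL, cycles = NULL,
                                   n_patterns = 5L, n_stance = 60L,
                                   n_swing = 40L, subject_id = "s1",
                                   euler_threshold = 20) {
  groups <- list()
  if (!is.null(cycles)) {
    groups[[subject_id]] <- cycles
  } else {
    stopifnot(length(recordings) > 0L)
    for (rec in recordings) {
      if (!is.null(euler_threshold)) {
        rec <- filter_euler_pulses(rec, euler_threshold)
      }
      cyc <- extract_cycles(rec)
      groups[[rec$subject_id]] <- c(groups[[rec$subject_id]], cyc)
    }
  }
  templates <- list()
  stats_by_subject <- list()
  missing_pairs <- character(0)
  for (sid in names(groups)) {
    cyc <- Filter(function(c) !is.na(c$label), groups[[sid]])
    labs <- vapply(cyc, `[[`, integer(1), "label")
    for (p in seq_len(n_patterns)) {
      if (!any(labs == p)) {
        missing_pairs <- c(missing_pairs, sprintf("(%s, %d)", sid, p))
      }
    }
    if (length(missing_pairs)) next
    stats <- channel_stats(cyc)
    stats_by_subject[[sid]] <- stats
    for (p in seq_len(n_patterns)) {
      templates[[length(templates) + 1L]] <- build_template(
        cyc[labs == p], n_stance = n_stance, n_swing = n_swing,
        stats = stats, subject_id = sid)
    }
  }
  if (length(missing_pairs)) {
    stop("missing (subject, pattern) pairs: ",
         paste(missing_pairs, collapse = ", "))
  }
  structure(
    list(templates = templates, subjects = names(groups),
         patterns = seq_len(n_patterns), stats = stats_by_subject),
    class = "template_library")
}

#' @export
print.template_library <- function(x, ...) {
  cat(sprintf("<template_library> %d templates: %d subject(s) x %d pattern(s)\n",
              length(x$templates), length(x$subjects), length(x$patterns)))
  invisible(x)
}

# Templates of one subject, ordered by pattern id.
subject_templates <- function(library, subject_id = library$subjects[1]) {
  tpls <- Filter(function(t) t$subject_id == subject_id, library$templates)
  tpls[order(vapply(tpls, `[[`, integer(1), "pattern_id"))]
}

#' Write a template library to a directory
#'
#' One CSV of template points per template plus a `manifest.json` with the
#' metadata (pattern, subject, phase lengths, cycle counts, channel stats).
#'
#' @param library A `template_library`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_template_library <- function(library, dir) {
  stopifnot(inherits(library, "template_library"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(patterns = library$patterns, subjects = library$subjects,
                   templates = list())
  for (i in seq_along(library$templates)) {
    t <- library$templates[[i]]
    fname <- sprintf("template_%s_p%d.csv", t$subject_id, t$pattern_id)
    pts <- as.data.frame(t$points)
    names(pts) <- imu_channels()
    write.csv(pts, file.path(dir, fname), row.names = FALSE)
    manifest$templates[[i]] <- list(
      file = fname, pattern_id = t$pattern_id, subject_id = t$subject_id,
      n_stance = t$n_stance, n_swing = t$n_swing, k_cycles = t$k_cycles,
      stats_mean = t$stats$mean, stats_sd = t$stats$sd)
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a template library written by [write_template_library()]
#'
#' @param dir Directory containing `manifest.json` and template CSVs.
#' @return A `template_library`.
#' @export
read_template_library <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  templates <- lapply(seq_len(nrow(manifest$templates)), function(i) {
    m <- manifest$templates[i, ]
    pts <- as.matrix(read.csv(file.path(dir, m$file)))
    dimnames(pts) <- NULL
    structure(
      list(pattern_id = as.integer(m$pattern_id),
           subject_id = as.character(m$subject_id),
           points = pts, n_stance = as.integer(m$n_stance),
           n_swing = as.integer(m$n_swing), k_cycles = as.integer(m$k_cycles),
           stats = list(mean = m$stats_mean[[1]], sd = m$stats_sd[[1]])),
      class = "gait_template")
  })
  stats <- list()
  for (t in templates) stats[[t$subject_id]] <- t$stats
  structure(
    list(templates = templates, subjects = unique(manifest$subjects),
         patterns = as.integer(manifest$patterns), stats = stats),
    class = "template_library")
}
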