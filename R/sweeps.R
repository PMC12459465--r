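#' Uncaging-locked sweep matrix
#'
#' Trial-aligned fluorescence data: one row per sweep (one uncaging period),
#' one column per frame. With the default 16 frames per sweep at a 0.128-s
#' frame interval each sweep spans one 2.048-s uncaging interval, and the
#' uncaging pulse falls between frames `pulse_frame` and `pulse_frame + 1`
#' (by default between the second and the third frame). The first
#' `n_baseline_sweeps` rows precede the first uncaging pulse, so uncaging
#' pulse `k` corresponds to row `n_baseline_sweeps + k`.
#'
#' @param values Numeric matrix, sweeps x frames.
#' @param frame_interval Frame interval (s), default 0.128.
#' @param pulse_frame Index of the frame after which the pulse falls
#'   (1-based, default 2).
#' @param n_baseline_sweeps Number of leading sweeps recorded without
#'   uncaging (default 7).
#' @param normalized Logical; whether rows are already per-sweep dF/F0.
#' @return An object of class `sweep_matrix`.
#' @export
sweep_matrix <- function(values, frame_interval = 0.128, pulse_frame = 2L,
                         n_baseline_sweeps = 7L, normalized = FALSE) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("'values' must be numeric")
  structure(list(values = values,
                 frames_per_sweep = ncol(values),
                 frame_interval = frame_interval,
                 pulse_frame = as.integer(pulse_frame),
                 n_baseline_sweeps = as.integer(n_baseline_sweeps),
                 normalized = normalized),
            class = "sweep_matrix")
}

#' @export
print.sweep_matrix <- function(x, ...) {
  cat(sprintf(
    "Sweep matrix: %d sweeps x %d frames (%.3f s/frame, %.3f s/sweep)%s\n",
    nrow(x$values), x$frames_per_sweep, x$frame_interval,
    x$frames_per_sweep * x$frame_interval,
    if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Segment a fluorescence trace into uncaging-locked sweeps
#'
#' Cuts the trace into consecutive non-overlapping blocks of
#' `frames_per_sweep` frames; a trailing partial block is dropped with a
#' warning. With 16 frames per sweep at 0.128 s per frame each sweep
#' corresponds to one 2.048-s uncaging interval.
#'
#' @param trace A [roi_trace()] or numeric vector of frame values.
#' @param frames_per_sweep Frames per sweep (default 16).
#' @param n_baseline_sweeps Leading sweeps recorded without uncaging
#'   (default 7).
#' @param frame_interval Frame interval (s); taken from the trace times when
#'   available, otherwise 0.128.
#' @param pulse_frame Frame after which the uncaging pulse falls (default 2).
#' @return An unnormalized [sweep_matrix()].
#' @export
segment_sweeps <- function(trace, frames_per_sweep = 16L,
                           n_baseline_sweeps = 7L,
                           frame_interval = NULL, pulse_frame = 2L) {
  if (inherits(trace, "roi_trace")) {
    v <- trace$f
    if (is.null(frame_interval) && length(trace$times) > 1L)
      frame_interval <- mean(diff(trace$times))
  } else {
    v <- as.numeric(trace)
  }
  if (is.null(frame_interval)) frame_interval <- 0.128
  frames_per_sweep <- as.integer(frames_per_sweep)
  n <- length(v)
  if (n < frames_per_sweep)
    stop(sprintf("trace of %d frames is shorter than one %d-frame sweep",
                 n, frames_per_sweep))
  n_sweeps <- n %/% frames_per_sweep
  dropped <- n - n_sweeps * frames_per_sweep
  if (dropped > 0L)
    warning(sprintf("dropped %d trailing frame%s not filling a sweep",
                    dropped, if (dropped == 1L) "" else "s"))
  m <- matrix(v[seq_len(n_sweeps * frames_per_sweep)],
              nrow = n_sweeps, ncol = frames_per_sweep, byrow = TRUE)
  sweep_matrix(m, frame_interval = frame_interval, pulse_frame = pulse_frame,
               n_baseline_sweeps = n_baseline_sweeps, normalized = FALSE)
}

#' Per-sweep dF/F0 normalization
#'
#' Each sweep is normalized to the average fluorescence of its own first
#' two frames (the frames preceding the uncaging pulse), removing the
#' cumulative effect of release and spine volume growth across sweeps:
#' `(x - b)/b` with `b = mean(first two frames)`. Sweeps with a
#' non-positive baseline are flagged invalid and set to NA.
#'
#' @param m A [sweep_matrix()].
#' @param n_norm_frames Number of leading frames averaged into the per-sweep
#'   baseline (default 2).
#' @return A normalized [sweep_matrix()] with a logical attribute
#'   `invalid_sweeps` on `$values` marking flagged rows.
#' @export
normalize_sweeps <- function(m, n_norm_frames = 2L) {
  stopifnot(inherits(m, "sweep_matrix"))
  if (m$normalized) stop("sweep matrix is already normalized")
  base <- rowMeans(m$values[, seq_len(n_norm_frames), drop = FALSE])
  invalid <- !is.finite(base) | base <= 0
  vals <- (m$values - base) / base
  vals[invalid, ] <- NA_real_
  out <- sweep_matrix(vals, frame_interval = m$frame_interval,
                      pulse_frame = m$pulse_frame,
                      n_baseline_sweeps = m$n_baseline_sweeps,
                      normalized = TRUE)
  attr(out$values, "invalid_sweeps") <- invalid
  out
}

#' Trial-average selected uncaging sweeps
#'
#' Frame-wise mean and SEM over the sweeps matching the requested uncaging
#' pulses, mapping pulse `k` to row `n_baseline_sweeps + k`; with 7 baseline
#' sweeps, pulses 2 to 18 select sweeps 9 to 25.
#'
#' @param m A normalized [sweep_matrix()].
#' @param pulses Uncaging pulse indices to average (default `2:18`).
#' @return List with `mean` and `sem` per frame, `time` (s within the
#'   sweep, frame centers at `(i-1) * frame_interval`), the selected
#'   `sweeps` (row indices), and sweep geometry.
#' @export
average_sweeps <- function(m, pulses = 2:18) {
  stopifnot(inherits(m, "sweep_matrix"))
  rows <- m$n_baseline_sweeps + pulses
  bad <- rows < 1L | rows > nrow(m$values)
  if (any(bad))
    stop(sprintf("pulse %d maps to sweep %d, outside 1..%d",
                 pulses[bad][1], rows[bad][1], nrow(m$values)))
  sel <- m$values[rows, , drop = FALSE]
  mu <- colMeans(sel, na.rm = TRUE)
  nn <- colSums(!is.na(sel))
  sem <- apply(sel, 2, sd, na.rm = TRUE) / sqrt(pmax(nn, 1))
  list(mean = mu, sem = sem,
       time = (seq_len(m$frames_per_sweep) - 1L) * m$frame_interval,
       sweeps = rows, pulse_frame = m$pulse_frame,
       frame_interval = m$frame_interval)
}

#' Peak of the uncaging-triggered response
#'
#' The mean of `dF/F0` over the three frames immediately after the uncaging
#' pulse (post-pulse latencies of one to three frame intervals; 0.128 to
#' 0.384 s at the default 0.128-s spacing).
#'
#' @param mean_trace Averaged sweep trace (as returned in `$mean` by
#'   [average_sweeps()]) or a full [average_sweeps()] result.
#' @param pulse_frame Frame after which the pulse falls (default 2).
#' @param n_frames Number of post-pulse frames averaged (default 3).
#' @return Scalar peak response.
#' @export
peak_response <- function(mean_trace, pulse_frame = 2L, n_frames = 3L) {
  if (is.list(mean_trace)) {
    if (!is.null(mean_trace$pulse_frame)) pulse_frame <- mean_trace$pulse_frame
    mean_trace <- mean_trace$mean
  }
  idx <- pulse_frame + seq_len(n_frames)
  if (max(idx) > length(mean_trace))
    stop(sprintf("trace of %d frames too short for frames %d..%d",
                 length(mean_trace), min(idx), max(idx)))
  mean(mean_trace[idx])
}

#' Paired comparison of per-spine peak responses across channels
#'
#' Two-tailed paired t test of per-spine peak responses in two channels
#' (e.g. MMP-9-SEP vs. mCherry), via [stats::t.test()]. Identical vectors
#' give `t = 0, p = 1`; a nonzero constant difference (zero variance) is a
#' degenerate case and is flagged rather than tested.
#'
#' @param peaks_a,peaks_b Per-spine peak responses, equal length, >= 3 pairs.
#' @return List with `statistic`, `p.value`, `mean_diff`, `n`, `degenerate`.
#' @export
paired_channel_comparison <- function(peaks_a, peaks_b) {
  if (length(peaks_a) != length(peaks_b))
    stop("paired vectors must have equal length")
  if (length(peaks_a) < 3L) stop("at least 3 pairs required")
  d <- peaks_a - peaks_b
  if (sd(d) == 0) {
    if (all(d == 0))
      return(list(statistic = 0, p.value = 1, mean_diff = 0,
                  n = length(d), degenerate = FALSE))
    return(list(statistic = NA_real_, p.value = NA_real_,
                mean_diff = mean(d), n = length(d), degenerate = TRUE))
  }
  tt <- t.test(peaks_a, peaks_b, paired = TRUE)
  list(statistic = unname(tt$statistic), p.value = tt$p.value,
       mean_diff = mean(d), n = length(d), degenerate = FALSE)
}
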