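#' Release-event train
#'
#' Event times from one TIRF recording, with the recording window and an
#' optional stimulation window.
#'
#' @param event_times Event times (s from recording start), sorted or
#'   sortable, all inside `recording_window`.
#' @param recording_window `c(start, end)` in s.
#' @param stim_window Optional `c(start, end)` in s, inside the recording.
#' @return An object of class `event_train`.
#' @export
event_train <- function(event_times, recording_window, stim_window = NULL) {
  event_times <- sort(as.numeric(event_times))
  if (length(recording_window) != 2L ||
      recording_window[1] >= recording_window[2])
    stop("'recording_window' must be c(start, end) with start < end")
  if (length(event_times) &&
      (min(event_times) < recording_window[1] ||
       max(event_times) > recording_window[2]))
    stop("event times must lie inside the recording window")
  if (!is.null(stim_window)) {
    if (length(stim_window) != 2L || stim_window[1] >= stim_window[2])
      stop("'stim_window' must be c(start, end) with start < end")
    if (stim_window[1] < recording_window[1] ||
        stim_window[2] > recording_window[2])
      stop("'stim_window' must lie inside the recording window")
  }
  structure(list(event_times = event_times,
                 recording_window = as.numeric(recording_window),
                 stim_window = if (is.null(stim_window)) NULL
                               else as.numeric(stim_window)),
            class = "event_train")
}

#' @export
print.event_train <- function(x, ...) {
  cat(sprintf("Event train: %d events over [%g, %g] s%s\n",
              length(x$event_times), x$recording_window[1],
              x$recording_window[2],
              if (is.null(x$stim_window)) "" else
                sprintf(", stimulation [%g, %g] s",
                        x$stim_window[1], x$stim_window[2])))
  invisible(x)
}

#' Threshold-crossing event detector for fluorescence traces
#'
#' Reference detector for synthetic data: local maxima exceeding
#' `baseline mean + threshold_sd * baseline SD`, separated by at least
#' `min_separation`. Among candidate peaks closer than `min_separation`
#' the larger one wins. The reported event time is the onset: the last
#' sub-threshold frame before the peak, plus one frame. Deterministic
#' given its inputs; a flat trace yields an empty train.
#'
#' @param trace A [roi_trace()] sampled uniformly (times in s).
#' @param threshold_sd Detection threshold in baseline SDs (default 4).
#' @param min_separation Minimum separation between events (s, default 0.5).
#' @param baseline_window Indices over which baseline mean/SD are computed;
#'   defaults to the whole trace (valid when events are sparse).
#' @param stim_window Optional stimulation window recorded in the result.
#' @return An [event_train()] spanning the trace's time range.
#' @export
detect_events <- function(trace, threshold_sd = 4, min_separation = 0.5,
                          baseline_window = NULL, stim_window = NULL) {
  stopifnot(inherits(trace, "roi_trace"))
  if (threshold_sd <= 0) stop("'threshold_sd' must be positive")
  v <- trace$f
  tt <- trace$times
  if (is.null(baseline_window)) baseline_window <- seq_along(v)
  mu <- mean(v[baseline_window])
  sdv <- sd(v[baseline_window])
  rec <- c(tt[1], tt[length(tt)])
  if (!is.finite(sdv) || sdv == 0)
    return(event_train(numeric(0), rec, stim_window))
  thr <- mu + threshold_sd * sdv
  n <- length(v)
  is_peak <- v > thr &
    v >= c(-Inf, v[-n]) &
    v >= c(v[-1], -Inf)
  cand <- which(is_peak)
  if (length(cand) == 0L) return(event_train(numeric(0), rec, stim_window))
  # greedy suppression: keep highest peaks, drop neighbours within min_separation
  cand <- cand[order(v[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in cand) {
    if (all(abs(tt[i] - tt[kept]) >= min_separation)) kept <- c(kept, i)
  }
  kept <- sort(kept)
  onset <- vapply(kept, function(i) {
    below <- which(v[seq_len(i)] <= thr)
    j <- if (length(below)) max(below) + 1L else 1L
    tt[min(j, i)]
  }, numeric(1))
  event_train(onset, rec, stim_window)
}

#' Event frequency within a time window
#'
#' Number of events in `[start, end)` divided by the window length.
#'
#' @param train An [event_train()].
#' @param window `c(start, end)` in s; by default the stimulation window
#'   when present, else the whole recording.
#' @return Frequency in Hz.
#' @export
event_frequency <- function(train, window = NULL) {
  stopifnot(inherits(train, "event_train"))
  if (is.null(window))
    window <- if (!is.null(train$stim_window)) train$stim_window
              else train$recording_window
  if (length(window) != 2L || window[2] <= window[1])
    stop("'window' must be c(start, end) with positive length")
  n <- sum(train$event_times >= window[1] & train$event_times < window[2])
  n / (window[2] - window[1])
}

#' Histogram of release times
#'
#' Bins in-window event times (pooled across trains) into left-closed,
#' right-open intervals of width `bin_width`; by default 10-s bins over the
#' 60-s stimulation window. Events exactly at the window end are excluded.
#' The bin total equals the number of in-window events.
#'
#' @param trains An [event_train()] or a list of them.
#' @param bin_width Bin width (s, default 10); must divide the window length.
#' @param window `c(start, end)` in s (default `c(0, 60)`).
#' @return Named integer vector of per-bin counts, with bin start times in
#'   attribute `"breaks"`.
#' @export
release_time_histogram <- function(trains, bin_width = 10, window = c(0, 60)) {
  if (inherits(trains, "event_train")) trains <- list(trains)
  len <- window[2] - window[1]
  if (len <= 0) stop("'window' must have positive length")
  n_bins <- len / bin_width
  if (abs(n_bins - round(n_bins)) > 1e-9)
    stop(sprintf("bin width %g does not divide the %g-s window", bin_width, len))
  n_bins <- as.integer(round(n_bins))
  times <- unlist(lapply(trains, function(tr) tr$event_times))
  times <- times[times >= window[1] & times < window[2]]
  idx <- pmin(floor((times - window[1]) / bin_width) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  breaks <- window[1] + bin_width * (0:n_bins)
  names(counts) <- sprintf("[%g,%g)", breaks[-(n_bins + 1L)], breaks[-1])
  attr(counts, "breaks") <- breaks
  counts
}

#' Rise and decay kinetics of a single release event
#'
#' `rise_time` is the 10-90% time of the rising phase (linear
#' interpolation between frames); `decay_time` is the time constant of a
#' single-exponential fit to the post-peak segment. The trace must contain
#' pre-event baseline and post-peak decay. A flat or non-decaying post-peak
#' segment flags the decay fit instead of failing.
#'
#' @param times Time stamps (s) of the event-centred trace.
#' @param values Fluorescence values.
#' @param baseline_frac Fraction of leading frames treated as baseline for
#'   the rise amplitude (default 0.1, at least 2 frames).
#' @return List with `rise_time`, `decay_time` (s; NA when flagged) and
#'   logical `decay_flagged`.
#' @export
event_kinetics <- function(times, values, baseline_frac = 0.1) {
  stopifnot(length(times) == length(values), length(values) >= 5L)
  nb <- max(2L, floor(baseline_frac * length(values)))
  base <- mean(values[seq_len(nb)])
  ipk <- which.max(values)
  amp <- values[ipk] - base
  if (amp <= 0) stop("no event above baseline in the supplied window")
  cross <- function(level) {
    y <- values[seq_len(ipk)]
    above <- which(y >= level)
    if (!length(above)) return(times[1])
    i <- above[1]
    if (i == 1L) return(times[1])
    # linear interpolation between frames i-1 and i
    times[i - 1] + (level - y[i - 1]) / (y[i] - y[i - 1]) *
      (times[i] - times[i - 1])
  }
  rise_time <- cross(base + 0.9 * amp) - cross(base + 0.1 * amp)
  post_t <- times[ipk:length(times)] - times[ipk]
  post_v <- values[ipk:length(values)] - base
  decay_time <- NA_real_
  flagged <- TRUE
  if (length(post_t) >= 4L && all(post_v > 0) && sd(post_v) > 0 &&
      post_v[length(post_v)] < post_v[1]) {
    fit <- tryCatch(
      nls(post_v ~ a * exp(-post_t / tau),
          start = list(a = post_v[1],
                       tau = max(post_t[length(post_t)] / 3, 1e-3)),
          control = nls.control(maxiter = 200, warnOnly = FALSE)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      decay_time <- coef(fit)[["tau"]]
      flagged <- FALSE
    } else {
      # nls fails on (near-)noiseless data; log-linear fit is exact there
      sl <- coef(lm(log(post_v) ~ post_t))[[2]]
      if (is.finite(sl) && sl < 0) {
        decay_time <- -1 / sl
        flagged <- FALSE
      }
    }
  }
  list(rise_time = rise_time, decay_time = decay_time,
       decay_flagged = flagged)
}

#' Field-stimulation and uncaging pulse schedules
#'
#' The LTP-inducing field-stimulation protocol: 30 bursts delivered at
#' 0.5 Hz (2-s spacing), each burst twenty 1-ms impulses at 83 Hz, total
#' duration 60 s. The uncaging protocol: 30 pulses of 6 ms at 0.5 Hz.
#'
#' @param kind `"electrical"` or `"uncaging"`.
#' @param n_repeats Number of bursts/pulses (default 30).
#' @param period Repeat period (s, default 2 = 0.5 Hz).
#' @param onset Protocol start time (s, default 0).
#' @return List with `burst_onsets` (s), `pulse_onsets` (s, all individual
#'   impulses), `pulse_width` (s), and `duration` (s).
#' @examples
#' length(stimulus_protocol("electrical")$pulse_onsets) # 600
#' @export
stimulus_protocol <- function(kind = c("electrical", "uncaging"),
                              n_repeats = 30L, period = 2, onset = 0) {
  kind <- match.arg(kind)
  burst_onsets <- onset + period * (seq_len(n_repeats) - 1L)
  if (kind == "electrical") {
    within <- (0:19) / 83
    pulse_onsets <- as.numeric(outer(within, burst_onsets, `+`))
    pulse_width <- 1e-3
  } else {
    pulse_onsets <- burst_onsets
    pulse_width <- 6e-3
  }
  list(kind = kind, burst_onsets = burst_onsets,
       pulse_onsets = sort(pulse_onsets), pulse_width = pulse_width,
       duration = n_repeats * period)
}
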