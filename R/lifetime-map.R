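#' Per-pixel TCSPC image stack
#'
#' A sequence of frames, each a 3-D photon-count array (row, column,
#' time-bin), sharing one bin configuration, plus acquisition times.
#'
#' @param frames List of 3-D arrays with identical dimensions.
#' @param frame_times Acquisition time of each frame (s), strictly increasing.
#' @param bin_edges,period As in [photon_histogram()].
#' @return An object of class `flim_stack`.
#' @export
flim_stack <- function(frames, frame_times, bin_edges, period) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  d <- dim(frames[[1]])
  if (length(d) != 3L) stop("each frame must be a 3-D array (row, col, bin)")
  for (f in frames)
    if (!identical(dim(f), d)) stop("all frames must share the same shape")
  if (d[3] != length(bin_edges) - 1L)
    stop("third frame dimension must match the number of time bins")
  if (length(frame_times) != length(frames))
    stop("'frame_times' must have one entry per frame")
  if (any(diff(frame_times) <= 0))
    stop("'frame_times' must be strictly increasing")
  if (any(diff(bin_edges) <= 0)) stop("'bin_edges' must be strictly increasing")
  structure(list(frames = frames, frame_times = as.numeric(frame_times),
                 bin_edges = as.numeric(bin_edges), period = as.numeric(period)),
            class = "flim_stack")
}

#' @export
print.flim_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("FLIM stack: %d frames of %d x %d pixels, %d time bins\n",
              length(x$frames), d[1], d[2], d[3]))
  invisible(x)
}

#' Pool a frame (or ROI) into a photon histogram
#'
#' @param stack A [flim_stack()].
#' @param frame Frame index, or `NULL` to pool every frame (as for a
#'   whole-series calibration fit).
#' @param roi Optional two-column matrix of (row, col) pixel coordinates;
#'   by default the whole frame is pooled.
#' @return A [photon_histogram()] of the summed counts.
#' @export
pool_histogram <- function(stack, frame = 1L, roi = NULL) {
  stopifnot(inherits(stack, "flim_stack"))
  frames <- if (is.null(frame)) stack$frames else stack$frames[frame]
  nb <- dim(frames[[1]])[3]
  counts <- numeric(nb)
  for (arr in frames) {
    if (is.null(roi)) {
      counts <- counts + apply(arr, 3, sum)
    } else {
      roi <- as.matrix(roi)
      if (ncol(roi) != 2L)
        stop("'roi' must be a two-column (row, col) matrix")
      counts <- counts + vapply(seq_len(nb),
                                function(b) sum(arr[, , b][roi]), numeric(1))
    }
  }
  photon_histogram(stack$bin_edges, counts, stack$period)
}

#' Mean-lifetime image from one TCSPC frame
#'
#' Computes the per-pixel mean photon arrival time and subtracts the
#' image-level offset `t0` (obtained from a whole-image [fit_decay()]) to
#' give the mean fluorescence lifetime `<tau> = <t> - t0` in every pixel.
#' Pixels with fewer than `min_photons` photons are masked out.
#'
#' @param frame A 3-D photon-count array (row, col, time-bin).
#' @param bin_edges Time-bin edges (ns).
#' @param t0 Image-level arrival-time offset (ns).
#' @param min_photons Per-pixel photon floor (default 10).
#' @return An object of class `lifetime_map` with matrices `mean_tau`
#'   (NA where masked), `photons`, and logical `mask`.
#' @export
lifetime_map <- function(frame, bin_edges, t0, min_photons = 10) {
  d <- dim(frame)
  if (length(d) != 3L) stop("'frame' must be a 3-D array (row, col, bin)")
  if (d[3] != length(bin_edges) - 1L)
    stop("'bin_edges' inconsistent with frame depth")
  centers <- (bin_edges[-length(bin_edges)] + bin_edges[-1]) / 2
  flat <- matrix(frame, nrow = d[1] * d[2], ncol = d[3])
  photons <- rowSums(flat)
  mask <- photons >= min_photons & photons > 0
  mean_t <- rep(NA_real_, length(photons))
  mean_t[mask] <- (flat[mask, , drop = FALSE] %*% centers) / photons[mask]
  structure(list(mean_tau = matrix(mean_t - t0, d[1], d[2]),
                 photons = matrix(photons, d[1], d[2]),
                 mask = matrix(mask, d[1], d[2]),
                 t0 = t0),
            class = "lifetime_map")
}

#' @export
print.lifetime_map <- function(x, ...) {
  cat(sprintf("Lifetime map %d x %d: %d/%d pixels valid, mean <tau> = %.3f ns\n",
              nrow(x$mean_tau), ncol(x$mean_tau), sum(x$mask),
              length(x$mask), mean(x$mean_tau[x$mask])))
  invisible(x)
}

#' Binding-fraction time series with baseline normalization
#'
#' @param times Frame times (s).
#' @param p_ad Binding fraction per frame (NA where masked).
#' @param baseline_window Integer indices of the pre-stimulus frames used
#'   for the baseline average.
#' @return An object of class `binding_trace` with the baseline `p_ad0` and
#'   `delta_p_ad = p_ad - p_ad0`.
#' @export
binding_trace <- function(times, p_ad, baseline_window) {
  stopifnot(length(times) == length(p_ad))
  baseline_window <- as.integer(baseline_window)
  if (length(baseline_window) < 1L ||
      any(baseline_window < 1L | baseline_window > length(p_ad)))
    stop("'baseline_window' must index into the trace")
  p_ad0 <- mean(p_ad[baseline_window], na.rm = TRUE)
  if (!is.finite(p_ad0)) stop("baseline window holds no valid points")
  structure(list(times = as.numeric(times), p_ad = as.numeric(p_ad),
                 baseline_window = baseline_window, p_ad0 = p_ad0,
                 delta_p_ad = as.numeric(p_ad) - p_ad0),
            class = "binding_trace")
}

#' ROI binding-fraction time course from a FLIM stack
#'
#' For each frame, photons inside the ROI are pooled into one histogram;
#' the pooled mean arrival time minus the image-level `t0` gives the mean
#' ROI lifetime, converted to a binding fraction by the closed-form
#' estimator [binding_fraction_from_mean()]. The trace is then normalized
#' by subtracting the averaged pre-stimulus baseline binding fraction
#' (`p_ad0`), giving `delta_p_ad = p_ad - p_ad0`. Frames whose ROI photon
#' count falls below `min_photons` are masked (NA).
#'
#' @param stack A [flim_stack()].
#' @param roi Two-column matrix of (row, col) pixel coordinates.
#' @param params A [decay_params()] from a whole-image [fit_decay()];
#'   supplies `tau_d`, `tau_ad` and `t0`.
#' @param baseline_window Indices of the pre-stimulus frames.
#' @param min_photons Per-frame ROI photon floor (default 100).
#' @param clip Passed to [binding_fraction_from_mean()].
#' @return A [binding_trace()].
#' @export
roi_binding_timecourse <- function(stack, roi, params, baseline_window,
                                   min_photons = 100, clip = FALSE) {
  stopifnot(inherits(stack, "flim_stack"), inherits(params, "decay_params"))
  roi <- as.matrix(roi)
  if (nrow(roi) < 1L) stop("'roi' must contain at least one pixel")
  n_frames <- length(stack$frames)
  p_ad <- rep(NA_real_, n_frames)
  for (i in seq_len(n_frames)) {
    h <- pool_histogram(stack, i, roi)
    if (sum(h$counts) < min_photons) next
    mt <- mean_arrival_time(h) - params$t0
    p_ad[i] <- as.numeric(binding_fraction_from_mean(mt, params$tau_d,
                                                     params$tau_ad,
                                                     clip = clip))
  }
  binding_trace(stack$frame_times, p_ad, baseline_window)
}
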