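#' Simulate a TCSPC photon histogram
#'
#' Forward simulation of the two-component decay model. Each photon is
#' assigned to the bound component with probability
#' `p_ad tau_ad / (p_d tau_d + p_ad tau_ad)` (photon yield proportional to
#' amplitude times lifetime — the convention that makes the closed-form
#' binding-fraction inversion exact), its arrival time drawn as
#' `t0 + Exponential(tau_component) + Gaussian(0, tau_g)`, and arrivals
#' outside `[0, period)` are rejected and redrawn so that no photons are
#' lost. Reproducible given `seed`.
#'
#' @param params A [decay_params()].
#' @param n_photons Number of photons (>= 1).
#' @param n_bins Number of uniform time bins (default 256).
#' @param period Laser repetition interval (ns, default 25; at least
#'   ~5 tau_d so truncation is negligible).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A [photon_histogram()] whose counts total `n_photons`.
#' @examples
#' h <- simulate_photon_histogram(decay_params(p_ad = 0.3, tau_ad = 1.3,
#'                                             t0 = 1), 1e4, seed = 7)
#' sum(h$counts)
#' @export
simulate_photon_histogram <- function(params, n_photons, n_bins = 256L,
                                      period = 25, seed = NULL) {
  stopifnot(inherits(params, "decay_params"))
  if (n_photons < 1) stop("'n_photons' must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  w_bound <- params$p_ad * params$tau_ad /
    ((1 - params$p_ad) * params$tau_d + params$p_ad * params$tau_ad)
  t <- sample_arrivals(n_photons, params, w_bound, period)
  edges <- seq(0, period, length.out = n_bins + 1L)
  counts <- tabulate(pmin(floor(t / (period / n_bins)) + 1L, n_bins),
                     nbins = n_bins)
  photon_histogram(edges, counts, period)
}

sample_arrivals <- function(n, params, w_bound, period) {
  out <- numeric(0)
  need <- n
  while (need > 0) {
    bound <- runif(need) < w_bound
    tau <- ifelse(bound, params$tau_ad, params$tau_d)
    t <- params$t0 + rexp(need, rate = 1 / tau) + rnorm(need, 0, params$tau_g)
    ok <- t >= 0 & t < period
    out <- c(out, t[ok])
    need <- n - length(out)
  }
  out
}

#' Simulate a FLIM image series with a time-varying binding fraction
#'
#' Generates per-frame per-pixel TCSPC data: pixels inside the ROI follow
#' the binding-fraction profile `p_ad_profile(t)` (spatially uniform), and
#' background pixels are donor-only (`p_ad = 0`). Photons are Poisson at
#' the pixel level: each pixel receives on average
#' `photons_per_frame / n_pixels` photons. Emulates a spine undergoing
#' TrkB activation on a dendritic background.
#'
#' @param p_ad_profile Numeric vector, binding fraction per frame.
#' @param dim Image dimensions `c(rows, cols)` (default `c(8, 8)`).
#' @param roi Two-column (row, col) matrix of ROI pixels; default the
#'   central 4 x 4 block.
#' @param photons_per_frame Expected ROI photons per frame (default 2e4).
#' @param background_photons Expected background photons per pixel per
#'   frame (default `photons_per_frame / nrow(roi) / 4`).
#' @param params Base [decay_params()] supplying lifetimes, `tau_g`, `t0`.
#' @param frame_rate Frames per second (default 7.8).
#' @param n_bins,period Histogram geometry as in
#'   [simulate_photon_histogram()].
#' @param seed Integer seed.
#' @return List with `stack` (a [flim_stack()]), `roi`, and `ground_truth`
#'   (the manifest: profile, parameters, seed).
#' @export
simulate_flim_series <- function(p_ad_profile, dim = c(8L, 8L), roi = NULL,
                                 photons_per_frame = 2e4,
                                 background_photons = NULL,
                                 params = decay_params(p_ad = 0, tau_d = 2.6,
                                                       tau_ad = 1.3,
                                                       tau_g = 0.2, t0 = 1),
                                 frame_rate = 7.8, n_bins = 64L, period = 25,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(p_ad_profile < 0 | p_ad_profile > 1))
    stop("'p_ad_profile' must lie in [0, 1]")
  if (is.null(roi)) {
    rows <- seq.int(dim[1] %/% 2 - 1L, length.out = min(4L, dim[1]))
    cols <- seq.int(dim[2] %/% 2 - 1L, length.out = min(4L, dim[2]))
    roi <- as.matrix(expand.grid(row = rows, col = cols))
  }
  roi <- as.matrix(roi)
  n_roi <- nrow(roi)
  if (is.null(background_photons))
    background_photons <- photons_per_frame / n_roi / 4
  n_frames <- length(p_ad_profile)
  edges <- seq(0, period, length.out = n_bins + 1L)
  bw <- period / n_bins
  bg <- !matrix(FALSE, dim[1], dim[2])
  bg[roi] <- FALSE
  bg_idx <- which(bg)
  frames <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    arr <- array(0L, dim = c(dim[1], dim[2], n_bins))
    # ROI photons, pooled then scattered uniformly over ROI pixels
    p_k <- decay_params(f0 = 1, p_ad = p_ad_profile[k], tau_d = params$tau_d,
                        tau_ad = params$tau_ad, tau_g = params$tau_g,
                        t0 = params$t0)
    n_ph <- rpois(1, photons_per_frame)
    if (n_ph > 0) {
      w <- p_k$p_ad * p_k$tau_ad /
        ((1 - p_k$p_ad) * p_k$tau_d + p_k$p_ad * p_k$tau_ad)
      t <- sample_arrivals(n_ph, p_k, w, period)
      pix <- sample.int(n_roi, n_ph, replace = TRUE)
      b <- pmin(floor(t / bw) + 1L, n_bins)
      lin <- roi[pix, 1] + (roi[pix, 2] - 1L) * dim[1] +
        (b - 1L) * dim[1] * dim[2]
      tb <- table(lin)
      arr[as.integer(names(tb))] <- as.integer(tb)
    }
    # donor-only background
    n_bg <- rpois(1, background_photons * length(bg_idx))
    if (n_bg > 0) {
      t <- sample_arrivals(n_bg, params, 0, period)
      pix <- sample(bg_idx, n_bg, replace = TRUE)
      b <- pmin(floor(t / bw) + 1L, n_bins)
      lin <- pix + (b - 1L) * dim[1] * dim[2]
      tb <- table(lin)
      arr[as.integer(names(tb))] <- arr[as.integer(names(tb))] +
        as.integer(tb)
    }
    frames[[k]] <- arr
  }
  stack <- flim_stack(frames, (seq_len(n_frames) - 1L) / frame_rate,
                      edges, period)
  list(stack = stack, roi = roi,
       ground_truth = list(p_ad_profile = p_ad_profile,
                           tau_d = params$tau_d, tau_ad = params$tau_ad,
                           tau_g = params$tau_g, t0 = params$t0,
                           photons_per_frame = photons_per_frame,
                           seed = seed))
}

#' Uncaging scenario for a simulated spine recording
#'
#' Describes one single-spine uncaging experiment at 7.8 Hz (0.128-s frame
#' interval): 7 baseline sweeps of 16 frames followed by 30 uncaging pulses
#' at 0.5 Hz, a spine-volume transient shared by both channels, and — in
#' `"SEP"` mode — per-pulse release transients added to the reporter
#' channel on top of the volume signal. `"Gamillus"` mode (pH-stable
#' reporter) adds no release component, so its reporter channel tracks the
#' volume channel.
#'
#' The volume transient rises with time constant `volume_rise` toward a
#' sustained plateau plus a decaying transient component; releases are
#' instantaneous steps decaying exponentially (`release_decay`), occurring
#' at each pulse with probability `release_prob` and amplitude
#' `release_amplitude` (dF/F0 units). Noise is multiplicative Gaussian
#' with SD proportional to the square root of the signal (shot-noise
#' proxy), `noise_sd` at the baseline level.
#'
#' @param reporter `"SEP"` or `"Gamillus"`.
#' @param frame_interval Frame interval (s, default 0.128).
#' @param frames_per_sweep Frames per uncaging period (default 16, i.e.
#'   2.048-s pulse spacing).
#' @param n_baseline_sweeps Sweeps before the first pulse (default 7).
#' @param n_pulses Number of uncaging pulses (default 30, at 0.5 Hz).
#' @param release_amplitude Per-pulse release step (dF/F0, default 0.15).
#' @param release_decay Release decay time constant (s, default 1.5).
#' @param release_prob Per-pulse release success probability (default 0.5).
#' @param volume_peak,volume_sustained Transient peak and sustained plateau
#'   of the volume transient (dF/F0; defaults 1.0 and 0.4).
#' @param volume_rise,volume_decay Rise and transient-decay time constants
#'   of the volume signal (s; defaults 30 and 240).
#' @param noise_sd Noise SD at baseline signal (default 0.03).
#' @param baseline_f Baseline fluorescence level (a.u., default 100).
#' @return An object of class `spine_scenario`.
#' @export
spine_scenario <- function(reporter = c("SEP", "Gamillus"),
                           frame_interval = 0.128, frames_per_sweep = 16L,
                           n_baseline_sweeps = 7L, n_pulses = 30L,
                           release_amplitude = 0.15, release_decay = 1.5,
                           release_prob = 0.5,
                           volume_peak = 1.0, volume_sustained = 0.4,
                           volume_rise = 30, volume_decay = 240,
                           noise_sd = 0.03, baseline_f = 100) {
  reporter <- match.arg(reporter)
  structure(list(reporter = reporter, frame_interval = frame_interval,
                 frames_per_sweep = as.integer(frames_per_sweep),
                 n_baseline_sweeps = as.integer(n_baseline_sweeps),
                 n_pulses = as.integer(n_pulses),
                 release_amplitude = release_amplitude,
                 release_decay = release_decay, release_prob = release_prob,
                 volume_peak = volume_peak,
                 volume_sustained = volume_sustained,
                 volume_rise = volume_rise, volume_decay = volume_decay,
                 noise_sd = noise_sd, baseline_f = baseline_f),
            class = "spine_scenario")
}

#' Simulate two-channel spine recordings
#'
#' Generates per-spine volume-channel and reporter-channel traces under a
#' [spine_scenario()]: `volume = baseline_f * (1 + transient(t))` plus
#' noise; `reporter = volume signal + release transients` (SEP mode only).
#' The ground-truth manifest lists every pulse time, release success and
#' amplitude for every spine.
#'
#' @param scenario A [spine_scenario()].
#' @param n_spines Number of spines (default 13).
#' @param seed Integer seed.
#' @return List with `spines` (each a list of `volume` and `reporter`
#'   [roi_trace()]s) and `ground_truth`.
#' @export
simulate_spine_movie <- function(scenario, n_spines = 13L, seed = NULL) {
  stopifnot(inherits(scenario, "spine_scenario"))
  if (!is.null(seed)) set.seed(seed)
  sc <- scenario
  sweep_len <- sc$frames_per_sweep * sc$frame_interval
  n_frames <- (sc$n_baseline_sweeps + sc$n_pulses) * sc$frames_per_sweep
  tt <- (seq_len(n_frames) - 1L) * sc$frame_interval
  t_on <- sc$n_baseline_sweeps * sweep_len
  # pulse midway between frames 2 and 3 of each uncaging sweep
  pulse_times <- t_on + sweep_len * (seq_len(sc$n_pulses) - 1L) +
    1.5 * sc$frame_interval
  s <- pmax(tt - t_on, 0)
  vol <- (1 - exp(-s / sc$volume_rise)) *
    (sc$volume_sustained + (sc$volume_peak - sc$volume_sustained) *
       exp(-s / sc$volume_decay))
  vol[tt < t_on] <- 0
  spines <- vector("list", n_spines)
  gt_events <- vector("list", n_spines)
  for (sp in seq_len(n_spines)) {
    success <- runif(sc$n_pulses) < sc$release_prob
    rel <- numeric(n_frames)
    if (sc$reporter == "SEP") {
      for (k in which(success)) {
        d <- tt - pulse_times[k]
        rel <- rel + ifelse(d >= 0,
                            sc$release_amplitude * exp(-d / sc$release_decay),
                            0)
      }
    }
    v_clean <- sc$baseline_f * (1 + vol)
    r_clean <- sc$baseline_f * (1 + vol + rel)
    v_noisy <- v_clean + sqrt(v_clean / sc$baseline_f) * sc$baseline_f *
      sc$noise_sd * rnorm(n_frames)
    r_noisy <- r_clean + sqrt(r_clean / sc$baseline_f) * sc$baseline_f *
      sc$noise_sd * rnorm(n_frames)
    spines[[sp]] <- list(
      volume = roi_trace(tt, v_noisy, channel = "volume",
                         baseline_n = min(7L, n_frames)),
      reporter = roi_trace(tt, r_noisy, channel = sc$reporter,
                           baseline_n = min(7L, n_frames)))
    gt_events[[sp]] <- list(pulse_times = pulse_times, success = success,
                            amplitude = sc$release_amplitude)
  }
  list(spines = spines,
       ground_truth = list(scenario = unclass(sc), n_spines = n_spines,
                           seed = seed, pulse_times = pulse_times,
                           events = gt_events))
}

#' Simulate a release-event train
#'
#' Inhomogeneous Poisson process: rate `basal_rate` outside the stimulation
#' window and `stim_rate` inside it. The default timing follows the TIRF
#' protocol — a 60-s basal movie followed by a 120-s movie whose
#' stimulation starts 4 s in and lasts 60 s, concatenated on one time axis
#' (recording 0-180 s, stimulation 64-124 s).
#'
#' @param basal_rate,stim_rate Event rates (Hz), non-negative.
#' @param recording_window `c(start, end)` s (default `c(0, 180)`).
#' @param stim_window `c(start, end)` s (default `c(64, 124)`).
#' @param seed Integer seed.
#' @return List with `train` (an [event_train()]) and `ground_truth`.
#' @export
simulate_event_train <- function(basal_rate, stim_rate,
                                 recording_window = c(0, 180),
                                 stim_window = c(64, 124), seed = NULL) {
  if (basal_rate < 0 || stim_rate < 0) stop("rates must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  segs <- rbind(c(recording_window[1], stim_window[1], basal_rate),
                c(stim_window[1], stim_window[2], stim_rate),
                c(stim_window[2], recording_window[2], basal_rate))
  times <- numeric(0)
  for (i in seq_len(nrow(segs))) {
    len <- segs[i, 2] - segs[i, 1]
    if (len <= 0 || segs[i, 3] == 0) next
    n <- rpois(1, segs[i, 3] * len)
    if (n > 0) times <- c(times, segs[i, 1] + sort(runif(n, 0, len)))
  }
  train <- event_train(times, recording_window, stim_window)
  list(train = train,
       ground_truth = list(basal_rate = basal_rate, stim_rate = stim_rate,
                           recording_window = recording_window,
                           stim_window = stim_window, seed = seed))
}
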