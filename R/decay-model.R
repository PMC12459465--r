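#' Parameter set for the two-component FLIM decay model
#'
#' Bundles the parameters of the donor fluorescence decay measured by
#' time-correlated single-photon counting (TCSPC): a mixture of free donor
#' (lifetime `tau_d`) and donor bound to the FRET acceptor (shortened
#' lifetime `tau_ad`), each convolved with a Gaussian pulse response of
#' width `tau_g` and offset by the arrival-time origin `t0`.
#'
#' The fractions are amplitude fractions: `p_ad` is the fraction of donor
#' molecules in the bound state and the free fraction is `1 - p_ad`.
#' Because photon yield is proportional to amplitude times lifetime, the
#' fraction of *photons* contributed by the bound component is
#' `p_ad * tau_ad / ((1 - p_ad) * tau_d + p_ad * tau_ad)`.
#'
#' @param f0 Peak amplitude before convolution (photon counts). Positive.
#' @param p_ad Bound-donor fraction, in `[0, 1]`.
#' @param tau_d Free-donor lifetime (ns). For eGFP-based donors 2.6 ns.
#' @param tau_ad Bound-donor lifetime (ns); must satisfy `0 < tau_ad < tau_d`.
#' @param tau_g Width of the Gaussian pulse response (ns). Positive.
#' @param t0 Arrival-time offset (ns).
#' @return An object of class `decay_params`.
#' @examples
#' decay_params(p_ad = 0.3, tau_ad = 1.3)
#' @export
decay_params <- function(f0 = 1, p_ad = 0, tau_d = 2.6, tau_ad = 1.3,
                         tau_g = 0.2, t0 = 0) {
  stopifnot(is.numeric(f0), is.numeric(p_ad), is.numeric(tau_d),
            is.numeric(tau_ad), is.numeric(tau_g), is.numeric(t0))
  if (f0 <= 0) stop("'f0' must be positive")
  if (p_ad < 0 || p_ad > 1) stop("'p_ad' must lie in [0, 1]")
  if (tau_d <= 0) stop("'tau_d' must be positive")
  if (tau_ad <= 0 || tau_ad >= tau_d)
    stop("'tau_ad' must satisfy 0 < tau_ad < tau_d")
  if (tau_g <= 0) stop("'tau_g' must be positive")
  structure(list(f0 = f0, p_ad = p_ad, tau_d = tau_d, tau_ad = tau_ad,
                 tau_g = tau_g, t0 = t0),
            class = "decay_params")
}

#' @export
print.decay_params <- function(x, ...) {
  cat("FLIM decay parameters\n")
  cat(sprintf("  p_ad = %.4f (free fraction %.4f)\n", x$p_ad, 1 - x$p_ad))
  cat(sprintf("  tau_d = %.4g ns, tau_ad = %.4g ns\n", x$tau_d, x$tau_ad))
  cat(sprintf("  tau_g = %.4g ns, t0 = %.4g ns, f0 = %.4g\n",
              x$tau_g, x$t0, x$f0))
  invisible(x)
}

#' Single exponential decay convolved with a Gaussian pulse response
#'
#' Evaluates
#' `H(t) = 1/2 exp(tau_g^2/(2 tau^2) - (t - t0)/tau) *
#'   erfc((tau_g^2 - tau (t - t0)) / (sqrt(2) tau tau_g))`,
#' the exponentially modified Gaussian that describes a mono-exponential
#' fluorescence decay blurred by instrument timing jitter of width `tau_g`.
#'
#' The naive product overflows for small `tau` because the exponential
#' prefactor explodes while erfc underflows; here both factors are folded
#' into a single exponent using the log of the normal tail
#' (`pnorm(..., log.p = TRUE)`), which is stable for all arguments.
#'
#' @param t Time points (ns).
#' @param t0 Time offset (ns).
#' @param tau Decay lifetime (ns), positive.
#' @param tau_g Gaussian pulse-response width (ns), positive.
#' @return `H(t)`, finite and non-negative, same length as `t`. Its integral
#'   over the whole line equals `tau`.
#' @examples
#' decay_component(1.5, t0 = 1, tau = 2.6, tau_g = 0.2)
#' @export
decay_component <- function(t, t0, tau, tau_g) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0)
    stop("'tau' must be a positive scalar")
  if (!is.numeric(tau_g) || length(tau_g) != 1L || tau_g <= 0)
    stop("'tau_g' must be a positive scalar")
  s <- t - t0
  a <- tau_g^2 / (2 * tau^2) - s / tau
  x <- (tau_g^2 - tau * s) / (sqrt(2) * tau * tau_g)
  # log erfc(x) = log 2 + log Phi(-x sqrt(2))
  0.5 * exp(a + log(2) + pnorm(sqrt(2) * x, lower.tail = FALSE, log.p = TRUE))
}

#' Two-component FLIM model curve
#'
#' The fluorescence decay of a donor population partially bound to a FRET
#' acceptor: `F(t) = f0 [ (1 - p_ad) H(t; tau_d) + p_ad H(t; tau_ad) ]`,
#' each component convolved with the shared Gaussian pulse response.
#'
#' @param params A [decay_params()] object.
#' @param t_grid Time points (ns) at which to evaluate the curve.
#' @return Model intensities on `t_grid`.
#' @examples
#' p <- decay_params(p_ad = 0.3, tau_ad = 1.3, t0 = 1)
#' model_curve(p, seq(0, 12, by = 0.05))
#' @export
model_curve <- function(params, t_grid) {
  stopifnot(inherits(params, "decay_params"))
  params$f0 *
    ((1 - params$p_ad) *
       decay_component(t_grid, params$t0, params$tau_d, params$tau_g) +
     params$p_ad *
       decay_component(t_grid, params$t0, params$tau_ad, params$tau_g))
}

#' Photon arrival-time histogram
#'
#' Container for binned TCSPC photon counts from one ROI or one pooled
#' image: a uniform time grid within a single laser repetition period.
#'
#' @param bin_edges Strictly increasing bin edges (ns); `length(counts) + 1`.
#' @param counts Non-negative integer photon counts per bin.
#' @param period Laser repetition interval (ns); last edge must not exceed it.
#' @return An object of class `photon_histogram`.
#' @export
photon_histogram <- function(bin_edges, counts, period) {
  stopifnot(is.numeric(bin_edges), is.numeric(counts), is.numeric(period))
  if (length(bin_edges) != length(counts) + 1L)
    stop("'bin_edges' must have exactly one more entry than 'counts'")
  if (any(diff(bin_edges) <= 0)) stop("'bin_edges' must be strictly increasing")
  if (any(counts < 0)) stop("'counts' must be non-negative")
  if (bin_edges[length(bin_edges)] > period + 1e-9)
    stop("last bin edge exceeds the laser period")
  structure(list(bin_edges = as.numeric(bin_edges),
                 counts = as.numeric(counts),
                 period = as.numeric(period)),
            class = "photon_histogram")
}

#' @export
print.photon_histogram <- function(x, ...) {
  cat(sprintf("Photon histogram: %d bins over [%.3g, %.3g] ns, %g photons\n",
              length(x$counts), x$bin_edges[1],
              x$bin_edges[length(x$bin_edges)], sum(x$counts)))
  invisible(x)
}

bin_centers <- function(hist) {
  e <- hist$bin_edges
  (e[-length(e)] + e[-1]) / 2
}

#' Mean photon arrival time of a histogram
#'
#' The count-weighted mean of the bin centers,
#' `<t> = integral(t F(t) dt) / integral(F(t) dt)` in binned form. The mean
#' fluorescence lifetime is obtained downstream as `<tau> = <t> - t0`, with
#' `t0` taken from a whole-image decay fit.
#'
#' @param hist A [photon_histogram()].
#' @return The mean arrival time (ns).
#' @export
mean_arrival_time <- function(hist) {
  stopifnot(inherits(hist, "photon_histogram"))
  n <- sum(hist$counts)
  if (n <= 0) stop("mean arrival time undefined: histogram holds no photons")
  sum(hist$counts * bin_centers(hist)) / n
}

#' Binding fraction from the mean fluorescence lifetime
#'
#' Closed-form estimator of the bound-donor fraction from the mean lifetime
#' of a two-lifetime mixture:
#' `p_ad = tau_d (tau_d - mean_tau) / ((tau_d - tau_ad) (tau_d + tau_ad - mean_tau))`.
#'
#' The identity is exact when `p_ad` is an amplitude fraction and photon
#' yield is proportional to amplitude times lifetime, so that
#' `mean_tau = (p_d tau_d^2 + p_ad tau_ad^2) / (p_d tau_d + p_ad tau_ad)`.
#' Photon noise can push the estimate outside `[0, 1]`; such values are
#' returned as-is and flagged in the `"out_of_range"` attribute. Clipping is
#' opt-in (`clip = TRUE`) because silently clipping biases averages.
#'
#' @param mean_tau Mean fluorescence lifetime(s) `<tau> = <t> - t0` (ns).
#' @param tau_d Free-donor lifetime (ns).
#' @param tau_ad Bound-donor lifetime (ns), `tau_ad < tau_d`.
#' @param clip If `TRUE`, clip estimates into `[0, 1]` after flagging.
#' @return Estimated binding fraction(s) with a logical attribute
#'   `out_of_range` marking estimates that fell outside `[0, 1]`.
#' @examples
#' binding_fraction_from_mean(2.370588, tau_d = 2.6, tau_ad = 1.3) # ~0.3
#' @export
binding_fraction_from_mean <- function(mean_tau, tau_d, tau_ad, clip = FALSE) {
  if (tau_ad >= tau_d) stop("'tau_ad' must be smaller than 'tau_d'")
  denom <- (tau_d - tau_ad) * (tau_d + tau_ad - mean_tau)
  bad <- is.finite(denom) & abs(denom) < .Machine$double.eps * 16
  if (any(bad, na.rm = TRUE))
    stop(sprintf(paste0("degenerate denominator: mean_tau = %g equals ",
                        "tau_d + tau_ad = %g"),
                 mean_tau[bad][1], tau_d + tau_ad))
  p <- tau_d * (tau_d - mean_tau) / denom
  oob <- !is.na(p) & (p < 0 | p > 1)
  if (clip) p <- pmin(pmax(p, 0), 1)
  attr(p, "out_of_range") <- oob
  p
}

#' Quality-control filter on baseline binding fraction
#'
#' Cells whose average initial (pre-stimulus) binding fraction exceeds the
#' threshold are excluded from analysis; the default threshold of 0.45
#' keeps cells with a baseline binding fraction of at most 45%.
#'
#' @param cells Numeric vector of per-cell baseline binding fractions,
#'   optionally named.
#' @param threshold Inclusion threshold in `(0, 1]`; cells with baseline
#'   `p_ad <= threshold` are retained.
#' @return The retained subset of `cells`, with a logical attribute `keep`
#'   over the original vector.
#' @examples
#' qc_filter_cells(c(a = 0.44, b = 0.46))
#' @export
qc_filter_cells <- function(cells, threshold = 0.45) {
  stopifnot(is.numeric(cells))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    stop("'threshold' must be a single value in (0, 1]")
  keep <- !is.na(cells) & cells <= threshold
  out <- cells[keep]
  attr(out, "keep") <- keep
  out
}
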