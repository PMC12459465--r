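#' ROI fluorescence trace
#'
#' A fluorescence time series summed over one region of interest, with the
#' number of pre-stimulus baseline points carried as metadata.
#'
#' @param times Time stamps, strictly increasing (seconds or minutes;
#'   [phase_averages()] expects minutes from uncaging onset).
#' @param f Summed ROI fluorescence (arbitrary units), finite.
#' @param channel Optional channel label (e.g. `"mCherry"`, `"SEP"`).
#' @param baseline_n Number of initial baseline time points (>= 1).
#' @return An object of class `roi_trace`.
#' @export
roi_trace <- function(times, f, channel = "", baseline_n = 7L) {
  stopifnot(is.numeric(times), is.numeric(f))
  if (length(times) != length(f)) stop("'times' and 'f' lengths differ")
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  if (any(!is.finite(f))) stop("'f' must be finite")
  baseline_n <- as.integer(baseline_n)
  if (baseline_n < 1L || baseline_n > length(f))
    stop("'baseline_n' must be between 1 and the trace length")
  structure(list(times = as.numeric(times), f = as.numeric(f),
                 channel = channel, baseline_n = baseline_n),
            class = "roi_trace")
}

#' @export
print.roi_trace <- function(x, ...) {
  cat(sprintf("ROI trace%s: %d points over [%.3g, %.3g]\n",
              if (nzchar(x$channel)) paste0(" (", x$channel, ")") else "",
              length(x$f), x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' Baseline-normalized fluorescence change
#'
#' Computes `dF/F0 = (F - F0)/F0`, where `F0` is the average of the first
#' `baseline_n` (by convention five to seven) pre-stimulus time points.
#' The result is invariant to multiplying the trace by any positive
#' constant and maps the baseline mean to exactly zero.
#'
#' @param trace A [roi_trace()], or a numeric vector of fluorescence values.
#' @param baseline_n Number of initial points averaged into `F0`; defaults
#'   to the trace's own `baseline_n`. Values outside `baseline_bounds`
#'   raise an error.
#' @param baseline_bounds Allowed range for `baseline_n` (default 5 to 7).
#' @return Numeric vector of `dF/F0`, with `F0` in attribute `"f0"`.
#' @examples
#' tr <- roi_trace(1:10, c(rep(2, 7), 4, 4, 3))
#' delta_f_over_f(tr)
#' @export
delta_f_over_f <- function(trace, baseline_n = NULL,
                           baseline_bounds = c(5L, 7L)) {
  if (inherits(trace, "roi_trace")) {
    f <- trace$f
    if (is.null(baseline_n)) baseline_n <- trace$baseline_n
  } else {
    f <- as.numeric(trace)
    if (is.null(baseline_n)) baseline_n <- min(7L, length(f))
  }
  baseline_n <- as.integer(baseline_n)
  if (baseline_n < baseline_bounds[1] || baseline_n > baseline_bounds[2])
    stop(sprintf("'baseline_n' = %d outside allowed range [%d, %d]",
                 baseline_n, baseline_bounds[1], baseline_bounds[2]))
  if (baseline_n > length(f)) stop("'baseline_n' exceeds trace length")
  f0 <- mean(f[seq_len(baseline_n)])
  if (f0 <= 0) stop("degenerate baseline: F0 must be positive")
  out <- (f - f0) / f0
  attr(out, "f0") <- f0
  out
}

#' Named analysis phase windows
#'
#' @param ... Named numeric length-2 vectors `c(start, end)` in minutes from
#'   uncaging onset, e.g. `transient = c(1, 3), sustained = c(12, 15)`.
#' @return An object of class `phase_windows`.
#' @examples
#' phase_windows(transient = c(1, 3), early = c(9, 11), late = c(12, 15))
#' @export
phase_windows <- function(...) {
  w <- list(...)
  if (length(w) == 0L) stop("at least one window required")
  if (is.null(names(w)) || any(!nzchar(names(w))))
    stop("every window must be named")
  for (nm in names(w)) {
    v <- w[[nm]]
    if (!is.numeric(v) || length(v) != 2L || v[1] >= v[2])
      stop(sprintf("window '%s' must be c(start, end) with start < end", nm))
  }
  structure(w, class = "phase_windows")
}

#' Per-window means of a normalized trace
#'
#' Averages trace values whose timestamps fall inside each phase window
#' (closed on both ends). Typical configurations are the transient phase
#' 1 to 3 min and sustained phases 9 to 11 and 12 to 15 min (or 15 to
#' 20 min) after uncaging onset.
#'
#' @param times Time stamps in minutes from uncaging onset.
#' @param values Normalized trace values (e.g. `dF/F0` or `delta_p_ad`).
#' @param windows A [phase_windows()] object.
#' @return Named numeric vector of window means.
#' @export
phase_averages <- function(times, values, windows) {
  stopifnot(inherits(windows, "phase_windows"),
            length(times) == length(values))
  out <- vapply(names(windows), function(nm) {
    w <- windows[[nm]]
    sel <- times >= w[1] & times <= w[2]
    if (!any(sel))
      stop(sprintf("window '%s' [%g, %g] contains no samples", nm, w[1], w[2]))
    mean(values[sel], na.rm = TRUE)
  }, numeric(1))
  names(out) <- names(windows)
  out
}

#' Expansion-microscopy size correction
#'
#' Physical expansion inflates measured sizes; the expansion factor is
#' estimated from the average nuclei area before and after expansion and
#' measured sizes are divided by it. Under `convention = "area"` the factor
#' is the literal area ratio `mean(post)/mean(pre)`; under `"linear"` it is
#' the square root of that ratio (the one-dimensional magnification). The
#' two conventions differ by a square root and must be chosen explicitly.
#'
#' @param sizes Measured sizes (nm) to correct.
#' @param pre_areas,post_areas Nuclei areas before/after expansion (um^2),
#'   positive, non-empty.
#' @param convention `"area"` or `"linear"`.
#' @return List with `corrected` sizes (nm) and the expansion `factor`.
#' @examples
#' expansion_correct(598.4, pre_areas = 100, post_areas = 400)$corrected # 149.6
#' @export
expansion_correct <- function(sizes, pre_areas, post_areas,
                              convention = c("area", "linear")) {
  convention <- match.arg(convention)
  if (length(pre_areas) == 0L || length(post_areas) == 0L)
    stop("area sets must be non-empty")
  if (any(pre_areas <= 0) || any(post_areas <= 0))
    stop("areas must be positive")
  ratio <- mean(post_areas) / mean(pre_areas)
  factor <- if (convention == "area") ratio else sqrt(ratio)
  list(corrected = sizes / factor, factor = factor, convention = convention)
}
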