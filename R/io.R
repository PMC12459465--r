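#' Analysis configuration
#'
#' Aggregates the acquisition constants and analysis defaults used across
#' the pipeline. Defaults: 7.8-Hz frame rate (0.128-s frame interval),
#' fixed free-donor lifetime 2.6 ns, QC threshold 0.45 on the baseline
#' binding fraction, photon floors of 1e4 (whole-image fit), 10 (per-pixel
#' map) and 100 (ROI per frame), 16-frame sweeps with 7 baseline sweeps
#' and averaged pulses 2-18, 10-s release-time bins over the 60-s
#' stimulation window.
#'
#' @param ... Overrides of the defaults, by name.
#' @return An object of class `analysis_config` (a named list).
#' @export
analysis_config <- function(...) {
  cfg <- list(
    frame_rate = 7.8,
    frame_interval = 0.128,
    tau_d = 2.6,
    bin_count = 64L,
    period = 25,
    qc_threshold = 0.45,
    min_photons_fit = 1e4,
    min_photons_pixel = 10,
    min_photons_roi = 100,
    frames_per_sweep = 16L,
    n_baseline_sweeps = 7L,
    pulse_frame = 2L,
    pulses = 2:18,
    baseline_n = 7L,
    event_bin_width = 10,
    stim_window = c(64, 124),
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  cfg$overrides <- names(over)
  structure(cfg, class = "analysis_config")
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Write a FLIM stack as multi-page TIFF plus JSON sidecar
#'
#' One TIFF page per time-bin, frames concatenated in order; counts are
#' stored as 16-bit integers. The sidecar records bin width, period, frame
#' rate and array dimensions so the stack can be validated on read.
#'
#' @param stack A [flim_stack()].
#' @param path Output TIFF path.
#' @param sidecar Output JSON path (default `path` with `.json`).
#' @return Invisibly, `path`.
#' @export
write_stack <- function(stack, path, sidecar = NULL) {
  stopifnot(inherits(stack, "flim_stack"))
  if (is.null(sidecar)) sidecar <- paste0(tools::file_path_sans_ext(path),
                                          ".json")
  d <- dim(stack$frames[[1]])
  mx <- max(1, vapply(stack$frames, max, numeric(1)))
  if (mx > 65535) stop("counts exceed 16-bit TIFF range")
  pages <- list()
  for (f in stack$frames)
    for (b in seq_len(d[3]))
      pages[[length(pages) + 1L]] <- f[, , b] / 65535
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  meta <- list(n_frames = length(stack$frames),
               n_rows = d[1], n_cols = d[2], n_bins = d[3],
               bin_width_ns = diff(stack$bin_edges)[1],
               period_ns = stack$period,
               frame_times_s = stack$frame_times)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a FLIM stack written by [write_stack()]
#'
#' @param path TIFF path.
#' @param sidecar JSON sidecar path (default `path` with `.json`).
#' @return A [flim_stack()].
#' @export
read_stack <- function(path, sidecar = NULL) {
  if (is.null(sidecar)) sidecar <- paste0(tools::file_path_sans_ext(path),
                                          ".json")
  if (!file.exists(path)) stop("TIFF file not found: ", path)
  if (!file.exists(sidecar))
    stop("expected JSON sidecar not found: ", sidecar)
  meta <- tryCatch(jsonlite::read_json(sidecar, simplifyVector = TRUE),
                   error = function(e)
                     stop("malformed sidecar ", sidecar, ": ",
                          conditionMessage(e)))
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e)
                      stop("malformed TIFF ", path, ": ",
                           conditionMessage(e)))
  expect_pages <- meta$n_frames * meta$n_bins
  if (length(pages) != expect_pages)
    stop(sprintf("TIFF holds %d pages but metadata implies %d (%d frames x %d bins)",
                 length(pages), expect_pages, meta$n_frames, meta$n_bins))
  frames <- vector("list", meta$n_frames)
  for (k in seq_len(meta$n_frames)) {
    arr <- array(0, dim = c(meta$n_rows, meta$n_cols, meta$n_bins))
    for (b in seq_len(meta$n_bins))
      arr[, , b] <- round(pages[[(k - 1L) * meta$n_bins + b]] * 65535)
    frames[[k]] <- arr
  }
  edges <- seq(0, by = meta$bin_width_ns, length.out = meta$n_bins + 1L)
  flim_stack(frames, meta$frame_times_s, edges, meta$period_ns)
}

#' Read/write ROI traces as CSV
#'
#' Long format with columns `time`, `value`, `channel`, `roi_id`.
#'
#' @param traces Named list of [roi_trace()]s (names become `roi_id`), or a
#'   single trace.
#' @param path CSV path.
#' @return `write_traces` invisibly returns `path`; `read_traces` returns a
#'   named list of [roi_trace()]s (one per `roi_id`/`channel` pair).
#' @export
write_traces <- function(traces, path) {
  if (inherits(traces, "roi_trace")) traces <- list(roi1 = traces)
  rows <- lapply(names(traces), function(id) {
    tr <- traces[[id]]
    data.frame(time = tr$times, value = tr$f,
               channel = if (nzchar(tr$channel)) tr$channel else "f",
               roi_id = id)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) stop("trace CSV not found: ", path)
  df <- utils::read.csv(path)
  need <- c("time", "value", "channel", "roi_id")
  if (!all(need %in% names(df)))
    stop("trace CSV must have columns: ", paste(need, collapse = ", "))
  out <- list()
  for (id in unique(df$roi_id)) {
    for (ch in unique(df$channel[df$roi_id == id])) {
      sub <- df[df$roi_id == id & df$channel == ch, ]
      sub <- sub[order(sub$time), ]
      key <- if (length(unique(df$channel[df$roi_id == id])) > 1L)
        paste(id, ch, sep = ".") else id
      out[[key]] <- roi_trace(sub$time, sub$value, channel = ch,
                              baseline_n = min(7L, nrow(sub)))
    }
  }
  out
}

#' Write pipeline outputs to a directory
#'
#' Tables go out as CSV (stable column order as supplied), the report as
#' JSON carrying the exact configuration, its hash and the seed, and
#' images as TIFF.
#'
#' @param dir Output directory (created if needed).
#' @param tables Named list of data frames.
#' @param report List of report fields; the config and its hash are added.
#' @param config The [analysis_config()] used.
#' @param images Optional named list of numeric matrices in `[0, 1]`.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(dir, tables = list(), report = list(),
                          config = analysis_config(), images = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  for (nm in names(images)) {
    p <- file.path(dir, paste0(nm, ".tiff"))
    tiff::writeTIFF(pmin(pmax(images[[nm]], 0), 1), p, bits.per.sample = 16)
    paths <- c(paths, p)
  }
  report$config <- unclass(config)
  report$config_hash <- config_hash(config)
  p <- file.path(dir, "report.json")
  jsonlite::write_json(report, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, p))
}
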