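#' Luminance image sequence
#'
#' The universal stimulus currency of the package: a stack of non-negative
#' luminance frames (arbitrary units) on a fixed retinotopic grid, sampled at
#' a constant interval `dt`.
#'
#' @param frames numeric 3D array, `time x rows x columns`, luminance in
#'   arbitrary units.  Must be finite and non-negative.
#' @param dt sample interval in seconds (> 0).
#' @param azimuth_wrap logical; `TRUE` if the column axis is periodic (a
#'   panoramic / full-circle azimuth axis), so the last column neighbours the
#'   first.
#' @return an object of class `luminance_seq`.
#' @examples
#' stim <- luminance_seq(array(1000, c(10, 3, 8)), dt = 1e-3)
#' stim
#' @export
luminance_seq <- function(frames, dt, azimuth_wrap = FALSE) {
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop("`frames` must be a 3D array (time x rows x columns)")
  }
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("`dt` must be a single positive number (seconds)")
  }
  if (anyNA(frames) || any(!is.finite(frames))) {
    stop("luminance frames must be finite")
  }
  if (min(frames) < 0) stop("luminance must be non-negative")
  structure(
    list(frames = frames, dt = dt, azimuth_wrap = isTRUE(azimuth_wrap)),
    class = "luminance_seq"
  )
}

#' @export
print.luminance_seq <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<luminance_seq> %d frames of %d x %d px, dt = %g s (%.3f s total)%s\n",
    d[1], d[2], d[3], x$dt, (d[1] - 1) * x$dt,
    if (x$azimuth_wrap) ", azimuth wraps" else ""
  ))
  cat(sprintf("  luminance range [%.4g, %.4g] a.u.\n",
              min(x$frames), max(x$frames)))
  invisible(x)
}

#' @export
dim.luminance_seq <- function(x) dim(x$frames)

#' Write / read a luminance sequence as plain text
#'
#' Stimuli are exchanged on disk as a directory holding `meta.json`
#' (`dt`, `azimuth_wrap`, dimensions) and `frames.csv`, one row per frame with
#' the pixels flattened column-major.  The same layout, with an external
#' `meta.json` sidecar, serves as the reader for precomputed (e.g. natural
#' image) sequences.
#'
#' @param stim a [luminance_seq()].
#' @param path directory to create/read.
#' @return `write_stimulus` returns `path` invisibly; `read_stimulus` returns
#'   a [luminance_seq()].
#' @export
write_stimulus <- function(stim, path) {
  stopifnot(inherits(stim, "luminance_seq"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  d <- dim(stim$frames)
  meta <- list(dt = stim$dt, azimuth_wrap = stim$azimuth_wrap,
               n_frames = d[1], rows = d[2], cols = d[3])
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  flat <- matrix(aperm(stim$frames, c(2, 3, 1)), nrow = d[1], byrow = TRUE)
  data.table::fwrite(data.table::as.data.table(flat),
                     file.path(path, "frames.csv"), col.names = FALSE)
  invisible(path)
}

#' @rdname write_stimulus
#' @export
read_stimulus <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  flat <- as.matrix(data.table::fread(file.path(path, "frames.csv"),
                                      header = FALSE))
  if (nrow(flat) != meta$n_frames || ncol(flat) != meta$rows * meta$cols) {
    stop("frames.csv does not match dimensions given in meta.json")
  }
  frames <- aperm(array(t(flat), c(meta$rows, meta$cols, meta$n_frames)),
                  c(3, 1, 2))
  luminance_seq(frames, dt = meta$dt,
                azimuth_wrap = isTRUE(meta$azimuth_wrap))
}

#' Export a time series as a two-column CSV
#'
#' @param time,value numeric vectors of equal length.
#' @param path output file.
#' @export
write_trace_csv <- function(time, value, path) {
  stopifnot(length(time) == length(value))
  data.table::fwrite(data.frame(time = time, value = value), path)
  invisible(path)
}
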