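#' Sine-grating stimulus protocols
#'
#' A grating protocol describes a pixel grid, a mean luminance, a spatial
#' wavelength and an ordered list of segments, each with a duration, a
#' temporal frequency (pattern velocity divided by wavelength), a motion
#' direction and an optional contrast override.  Directions: `"pd"` drifts
#' the pattern towards increasing column index (the preferred direction of
#' the detector array), `"nd"` the opposite, `"orthogonal"` uses a grating
#' oriented along rows drifting along the row axis (invisible to the
#' horizontal detectors), `"stationary"` shows the non-moving pattern and
#' `"blank"` a uniform field at the mean luminance.
#'
#' @param rows,cols grid size in pixels.
#' @param wavelength spatial wavelength, pixels (>= 2).
#' @param i_mean mean luminance, arbitrary units.
#' @param contrast default brightness contrast in `[0, 1]`.
#' @param segments `data.frame` built from [grating_segment()] rows.
#' @param azimuth_wrap logical, columns are periodic (default `TRUE`).
#' @return an object of class `grating_protocol`.
#' @seealso [transient_protocol()], [adaptation_protocol()],
#'   [parameter_grid()], [render_grating()]
#' @export
grating_protocol <- function(rows, cols, wavelength, i_mean = 1000,
                             contrast = 0.88, segments,
                             azimuth_wrap = TRUE) {
  stopifnot(is.data.frame(segments),
            all(c("duration", "tf", "direction", "contrast", "role")
                %in% names(segments)))
  if (any(segments$duration <= 0)) stop("segment durations must be > 0")
  if (any(segments$tf < 0)) stop("temporal frequencies must be >= 0")
  if (wavelength < 2) stop("wavelength must be >= 2 px")
  cc <- c(contrast, segments$contrast[!is.na(segments$contrast)])
  if (any(abs(cc) > 1)) stop("contrast > 1 would give negative luminance")
  ok <- segments$direction %in%
    c("pd", "nd", "orthogonal", "stationary", "blank")
  if (!all(ok)) stop("unknown segment direction: ",
                     paste(unique(segments$direction[!ok]), collapse = ", "))
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 wavelength = wavelength, i_mean = i_mean,
                 contrast = contrast, segments = segments,
                 azimuth_wrap = isTRUE(azimuth_wrap)),
            class = "grating_protocol")
}

#' @rdname grating_protocol
#' @param duration segment duration, seconds.
#' @param tf temporal frequency, Hz.
#' @param direction one of `"pd"`, `"nd"`, `"orthogonal"`, `"stationary"`,
#'   `"blank"`.
#' @param role free-text label used by the analyses to locate segments
#'   (e.g. `"transient"`, `"reference"`, `"adaptation"`, `"test"`).
#' @export
grating_segment <- function(duration, tf = 0, direction = "stationary",
                            contrast = NA_real_, role = NA_character_) {
  data.frame(duration = duration, tf = tf, direction = direction,
             contrast = contrast, role = role, stringsAsFactors = FALSE)
}

#' @export
print.grating_protocol <- function(x, ...) {
  cat(sprintf(
    "<grating_protocol> %d x %d px, lambda = %g px, I_mean = %g a.u., c = %g\n",
    x$rows, x$cols, x$wavelength, x$i_mean, x$contrast))
  cat(sprintf("  %d segments, %.3f s total\n",
              nrow(x$segments), sum(x$segments$duration)))
  invisible(x)
}

#' @export
duration.grating_protocol <- function(x) sum(x$segments$duration)

#' Total duration of a stimulus protocol, seconds
#' @param x a protocol object.
#' @export
duration <- function(x) UseMethod("duration")

protocol_steps <- function(protocol, dt) {
  as.integer(round(sum(protocol$segments$duration) / dt))
}

# Segment start times and accumulated start phases (phase is continuous
# across segment boundaries; the analytic per-segment phase makes rendering
# exactly consistent across dt refinements).
segment_table <- function(protocol) {
  seg <- protocol$segments
  sgn <- ifelse(seg$direction == "nd", -1, ifelse(
    seg$direction %in% c("stationary", "blank"), 0, 1))
  dphi <- sgn * seg$tf * seg$duration
  data.frame(
    t0 = cumsum(c(0, seg$duration))[seq_len(nrow(seg))],
    phi0 = cumsum(c(0, dphi))[seq_len(nrow(seg))],
    sgn = sgn, tf = seg$tf, direction = seg$direction,
    contrast = ifelse(is.na(seg$contrast),
                      ifelse(seg$direction == "blank", 0, protocol$contrast),
                      seg$contrast),
    role = seg$role, stringsAsFactors = FALSE
  )
}

#' Render a grating protocol into a luminance sequence
#'
#' Pixel luminance is
#' `I_mean * (1 + c * sin(2*pi*(x / lambda - phi(t))))` with the phase
#' `phi(t)` accumulating the integral of the temporal frequency across
#' segments, so the pattern drifts without luminance jumps at segment
#' boundaries.  Frames are sampled at `t = (k - 1) * dt`.
#'
#' @param protocol a [grating_protocol()].
#' @param dt frame interval, seconds.
#' @param steps optional integer range of frame indices to render (used for
#'   chunked streaming); default all.
#' @return a [luminance_seq()].
#' @export
render_grating <- function(protocol, dt = 0.001, steps = NULL) {
  stopifnot(inherits(protocol, "grating_protocol"))
  nall <- protocol_steps(protocol, dt)
  if (is.null(steps)) steps <- seq_len(nall)
  t <- (steps - 1) * dt
  tab <- segment_table(protocol)
  ends <- cumsum(protocol$segments$duration)
  seg <- findInterval(t + dt * 1e-6, c(0, ends[-length(ends)]))
  seg[seg < 1] <- 1L
  seg[seg > nrow(tab)] <- nrow(tab)
  phase <- tab$phi0[seg] + tab$sgn[seg] * tab$tf[seg] * (t - tab$t0[seg])
  ceff <- tab$contrast[seg]
  horiz <- tab$direction[seg] != "orthogonal"

  n <- length(steps)
  arr <- array(0, c(n, protocol$rows, protocol$cols))
  lam <- protocol$wavelength
  if (any(horiz)) {
    x <- seq_len(protocol$cols) - 1
    A <- matrix(2 * pi * x / lam, sum(horiz), protocol$cols, byrow = TRUE)
    L <- protocol$i_mean * (1 + ceff[horiz] * sin(A - 2 * pi * phase[horiz]))
    for (r in seq_len(protocol$rows)) arr[which(horiz), r, ] <- L
  }
  if (any(!horiz)) {
    y <- seq_len(protocol$rows) - 1
    B <- matrix(2 * pi * y / lam, sum(!horiz), protocol$rows, byrow = TRUE)
    L <- protocol$i_mean * (1 + ceff[!horiz] * sin(B - 2 * pi * phase[!horiz]))
    for (cc in seq_len(protocol$cols)) arr[which(!horiz), , cc] <- L
  }
  luminance_seq(arr, dt = dt, azimuth_wrap = protocol$azimuth_wrap)
}

#' Velocity-transient train protocol
#'
#' Constant background motion (7420 ms at the default count of eight
#' transients) superimposed with short 50 ms temporal-frequency transients at
#' 780 ms inter-onset intervals, flanked by 500 ms stationary periods.  The
#' first transient starts 390 ms after motion onset, which centres the train
#' in the motion block and leaves > 600 ms of background motion after the
#' last transient for background-response windows.
#'
#' @param background_tf,transient_tf background / transient temporal
#'   frequency, Hz.
#' @param contrast brightness contrast of the grating.
#' @param i_mean mean luminance, a.u.
#' @param n_transients number of transients (8 in the full protocol; smaller
#'   values give proportionally shortened runs for screening).
#' @param rows,cols,wavelength grid geometry (3 x 360 px, lambda 19 px).
#' @return a [grating_protocol()]; transient segments carry
#'   `role = "transient"`.
#' @export
transient_protocol <- function(background_tf = 2, transient_tf = 4,
                               contrast = 0.88, i_mean = 1000,
                               n_transients = 8, rows = 3, cols = 360,
                               wavelength = 19) {
  stopifnot(background_tf >= 0, transient_tf >= 0, n_transients >= 1)
  segs <- list(grating_segment(0.5, 0, "stationary", role = "prelude"),
               grating_segment(0.39, background_tf, "pd", role = "background"))
  for (k in seq_len(n_transients)) {
    segs <- c(segs, list(
      grating_segment(0.05, transient_tf, "pd", role = "transient"),
      grating_segment(if (k < n_transients) 0.73 else 1.52,
                      background_tf, "pd", role = "background")))
  }
  segs <- c(segs, list(grating_segment(0.5, 0, "stationary", role = "tail")))
  grating_protocol(rows, cols, wavelength, i_mean, contrast,
                   do.call(rbind, segs))
}

#' Direction-specific adaptation protocol
#'
#' Blank (500 ms), reference motion (1 s, c = 0.3, 3 Hz, PD), blank (50 ms),
#' adaptation motion (4 s, c = 0.95, 5 Hz) in the given direction,
#' immediately followed by a test identical to the reference, then blank
#' (500 ms).  Grid 90 x 90 px, wavelength 18 px, mean luminance 1000 a.u.
#'
#' @param direction adaptation direction: `"pd"`, `"nd"` or `"orthogonal"`.
#' @param ref_contrast contrast of reference and test segments (0.3; swept
#'   for contrast-gain analyses).
#' @param adapt_contrast,adapt_tf adaptation grating contrast / temporal
#'   frequency (0.95, 5 Hz).
#' @param ref_tf reference/test temporal frequency (3 Hz).
#' @param i_mean mean luminance, a.u.
#' @return a [grating_protocol()] with roles `"reference"`, `"adaptation"`,
#'   `"test"`.
#' @export
adaptation_protocol <- function(direction = c("pd", "nd", "orthogonal"),
                                ref_contrast = 0.3, adapt_contrast = 0.95,
                                adapt_tf = 5, ref_tf = 3, i_mean = 1000) {
  direction <- match.arg(direction)
  segs <- rbind(
    grating_segment(0.5, 0, "blank", role = "prelude"),
    grating_segment(1, ref_tf, "pd", contrast = ref_contrast,
                    role = "reference"),
    grating_segment(0.05, 0, "blank", role = "gap"),
    grating_segment(4, adapt_tf, direction, contrast = adapt_contrast,
                    role = "adaptation"),
    grating_segment(1, ref_tf, "pd", contrast = ref_contrast, role = "test"),
    grating_segment(0.5, 0, "blank", role = "tail")
  )
  grating_protocol(90, 90, 18, i_mean, contrast = ref_contrast, segs)
}

#' Temporal-frequency x contrast screening grid
#'
#' The 45 transient-train protocols spanning background temporal frequencies
#' 0.1--25.6 Hz (9 octave steps) and brightness contrasts 0.05--0.85 (5
#' levels).  Transient frequency is twice the background frequency
#' (`kind = "increment"`) or half of it (`kind = "decrement"`).
#'
#' @param kind `"increment"` or `"decrement"` transients.
#' @param i_mean mean luminance; the screening is run at `1e3` and,
#'   unchanged, at `1e12` a.u. to probe brightness invariance.
#' @param n_transients transients per protocol (see [transient_protocol()]).
#' @return list of 45 [grating_protocol()]s; each carries a `condition`
#'   attribute with its `tf` and `contrast`.
#' @export
parameter_grid <- function(kind = c("increment", "decrement"),
                           i_mean = 1000, n_transients = 8) {
  kind <- match.arg(kind)
  tfs <- c(0.1, 0.2, 0.4, 0.8, 1.6, 3.2, 6.4, 12.8, 25.6)
  contrasts <- c(0.05, 0.25, 0.45, 0.65, 0.85)
  out <- list()
  for (tf in tfs) {
    for (cc in contrasts) {
      ttf <- if (kind == "increment") 2 * tf else 0.5 * tf
      p <- transient_protocol(tf, ttf, contrast = cc, i_mean = i_mean,
                              n_transients = n_transients)
      attr(p, "condition") <- list(tf = tf, contrast = cc, kind = kind)
      out[[length(out) + 1L]] <- p
    }
  }
  out
}
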