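#' Run the full adaptive motion pathway over a stimulus
#'
#' Streams every frame of a luminance sequence through the whole chain --
#' adaptive photoreceptor, LMC with ON/OFF split, delay-and-correlate EMD,
#' divisive motion adaptation with adaptive exponent, linear LPTC pooling --
#' and returns the pooled LPTC trace together with retinotopic summaries.
#' The computation runs in compiled code; an equivalent pure-R chain built
#' from the exported stage functions is used in the test-suite as an
#' independent oracle.
#'
#' If the stimulus is sampled more coarsely than the model step (e.g. 100 Hz
#' renderings of 3D worlds against a 1 ms model grid), frames are linearly
#' interpolated in time.  A stimulus sampled more finely than the model step
#' is an error.
#'
#' @param stim a [luminance_seq()].
#' @param params a [pathway_params()]; `params$dt` is the integration step.
#' @param adaptation logical.  `FALSE` freezes the adaptive exponent at its
#'   resting value and bypasses the divisive stage, so the raw (unadapted)
#'   half-detector outputs are pooled -- the non-adaptive reference model.
#' @param snapshot_times times (s) at which full retinotopic detector maps
#'   are recorded (see [emd_frame]).
#' @param state filter memories from a previous call (for streaming); `NULL`
#'   starts every memory at the steady state of the first frame.
#' @param t0 time of the first step, used for labelling when streaming.
#' @return an object of class `pathway_run`: a list with `time`, `lptc`
#'   (pooled trace), `a_mean` (mean adaptive exponent), `energy_az` (matrix,
#'   time x detector columns, motion energy averaged over rows/elevations),
#'   `snapshots` (list of `emd_frame`s), `dt`, `grid`, and the final `state`.
#' @examples
#' pro <- transient_protocol(n_transients = 2)
#' run <- run_protocol(pro, pathway_params())
#' print(run)
#' @export
run_pathway <- function(stim, params = pathway_params(), adaptation = TRUE,
                        snapshot_times = NULL, state = NULL, t0 = 0) {
  stopifnot(inherits(stim, "luminance_seq"))
  if (!inherits(params, "pathway_params")) stop("params must be pathway_params")
  dt <- params$dt
  if (stim$dt < dt - 1e-12) {
    stop("stimulus dt is finer than the model dt; resample the stimulus")
  }
  snap_steps <- integer(0)
  if (!is.null(snapshot_times)) {
    snap_steps <- sort(unique(as.integer(round((snapshot_times - t0) / dt)) + 1L))
  }
  res <- pathway_core(stim$frames, stim$dt, dt, unclass(params),
                      stim$azimuth_wrap, adaptation, state, snap_steps)
  time <- t0 + (seq_len(res$nsteps) - 1) * dt
  snaps <- lapply(res$snapshots, function(s) {
    s$time <- t0 + (s$step - 1) * dt
    class(s) <- "emd_frame"
    s
  })
  structure(
    list(time = time, lptc = res$lptc, a_mean = res$a_mean,
         energy_az = res$energy_az, snapshots = snaps, dt = dt,
         grid = c(rows = dim(stim$frames)[2],
                  detectors = ncol(res$energy_az)),
         azimuth_wrap = stim$azimuth_wrap, adaptation = adaptation,
         params = params, state = res$state),
    class = "pathway_run"
  )
}

#' Run a grating protocol through the pathway
#'
#' Renders a [grating_protocol()] segment-wise (in bounded chunks, so long
#' high-resolution protocols never materialise in memory at once) and streams
#' it through [run_pathway()], carrying the filter state across chunks.
#'
#' @inheritParams run_pathway
#' @param protocol a [grating_protocol()].
#' @param chunk_steps maximal number of 1-step frames rendered at a time.
#' @return a `pathway_run` covering the whole protocol, with the protocol
#'   attached as attribute `"protocol"`.
#' @export
run_protocol <- function(protocol, params = pathway_params(),
                         adaptation = TRUE, snapshot_times = NULL,
                         chunk_steps = 2000L) {
  stopifnot(inherits(protocol, "grating_protocol"))
  dt <- params$dt
  nsteps <- protocol_steps(protocol, dt)
  state <- NULL
  pieces <- list()
  k0 <- 0L
  while (k0 < nsteps) {
    k1 <- min(k0 + chunk_steps, nsteps)
    stim <- render_grating(protocol, dt, steps = (k0 + 1):k1)
    st <- if (!is.null(snapshot_times)) {
      tt <- snapshot_times
      tt[tt >= k0 * dt - dt / 2 & tt < k1 * dt - dt / 2]
    }
    piece <- run_pathway(stim, params, adaptation, snapshot_times = st,
                         state = state, t0 = k0 * dt)
    state <- piece$state
    piece$state <- NULL
    pieces[[length(pieces) + 1L]] <- piece
    k0 <- k1
  }
  run <- pieces[[1L]]
  if (length(pieces) > 1L) {
    run$time <- do.call(c, lapply(pieces, `[[`, "time"))
    run$lptc <- do.call(c, lapply(pieces, `[[`, "lptc"))
    run$a_mean <- do.call(c, lapply(pieces, `[[`, "a_mean"))
    run$energy_az <- do.call(rbind, lapply(pieces, `[[`, "energy_az"))
    run$snapshots <- do.call(c, lapply(pieces, `[[`, "snapshots"))
  }
  run$state <- state
  attr(run, "protocol") <- protocol
  run
}

#' @export
print.pathway_run <- function(x, ...) {
  cat(sprintf(
    "<pathway_run> %d steps (%.3f s at dt = %g ms), %d x %d detectors%s\n",
    length(x$lptc), max(x$time) - min(x$time), 1e3 * x$dt,
    x$grid[["rows"]], x$grid[["detectors"]],
    if (x$adaptation) "" else " [adaptation off]"
  ))
  cat(sprintf("  LPTC range [%.4g, %.4g]; mean exponent a ends at %.3f\n",
              min(x$lptc), max(x$lptc), x$a_mean[length(x$a_mean)]))
  if (length(x$snapshots)) {
    cat(sprintf("  %d snapshot(s) at t = %s s\n", length(x$snapshots),
                paste(signif(vapply(x$snapshots, `[[`, 0, "time"), 4),
                      collapse = ", ")))
  }
  invisible(x)
}

#' @export
plot.pathway_run <- function(x, what = c("lptc", "a_mean"), ...) {
  what <- match.arg(what)
  graphics::plot(x$time, x[[what]], type = "l", xlab = "time [s]",
                 ylab = switch(what, lptc = "LPTC response",
                               a_mean = "mean adaptive exponent"), ...)
  invisible(x)
}

#' Retinotopic detector-array snapshot
#'
#' An `emd_frame` records, at one instant, the four unadapted and four
#' adapted half-detector maps (ON/OFF x PD/ND), the signed response map
#' (PD minus ND over both polarities), the motion-energy map (its absolute
#' value), the adaptive-exponent map and the pooled LPTC value.  Produced by
#' [run_pathway()] via `snapshot_times`.
#'
#' @param x an `emd_frame`.
#' @param ... unused.
#' @name emd_frame
#' @export
print.emd_frame <- function(x, ...) {
  cat(sprintf("<emd_frame> t = %.4g s, %d x %d detectors\n",
              x$time, nrow(x$signed), ncol(x$signed)))
  cat(sprintf("  |signed| max %.4g, LPTC %.4g, a in [%.3f, %.3f]\n",
              max(abs(x$signed)), x$lptc, min(x$a), max(x$a)))
  invisible(x)
}
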