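#' Response contrast between a background and a peak response
#'
#' The bounded Michelson-style statistic
#' `C_resp = |R_bg - R_pk| / (R_bg + R_pk)`:
#' 0 when the event response equals the background, approaching 1 when one
#' dwarfs the other.  Scale-invariant, so it compares adaptation states with
#' very different absolute response levels.
#'
#' @param r_bg,r_pk background and peak responses (vectors allowed).
#' @return response contrast in `[0, 1]` for non-negative inputs.
#' @examples
#' response_contrast(1, 3) # 0.5
#' @export
response_contrast <- function(r_bg, r_pk) {
  s <- r_bg + r_pk
  if (any(s <= 0)) stop("response contrast undefined: R_bg + R_pk must be > 0")
  abs(r_bg - r_pk) / s
}

new_contrast_series <- function(df, enhancement = NULL, windows = NULL) {
  structure(df, class = c("contrast_series", "data.frame"),
            enhancement = enhancement, windows = windows)
}

#' @export
print.contrast_series <- function(x, ...) {
  cat(sprintf("<contrast_series> %d events\n", nrow(x)))
  print.data.frame(x, digits = 4)
  if (!is.null(attr(x, "enhancement"))) {
    cat(sprintf("enhancement (C_last - C_first): %.4f\n",
                attr(x, "enhancement")))
  }
  invisible(x)
}

#' Enhancement score of a contrast series
#'
#' Response contrast of the last event minus that of the first; positive
#' values mean adaptation increased the relative salience of the events.
#' @param x a `contrast_series`.
#' @export
enhancement <- function(x) {
  e <- attr(x, "enhancement")
  e %||% (x$c_resp[nrow(x)] - x$c_resp[1])
}

#' Per-transient response contrasts of a transient-train run
#'
#' For every `role = "transient"` segment of the protocol the background
#' response `R_bg` is the mean LPTC trace over the 200 ms preceding the
#' transient onset, and the peak `R_pk` is the trace value within
#' `[onset, onset + 250 ms]` deviating most (in absolute value) from `R_bg`,
#' so both response increments and decrements are captured.  Contrast per
#' event by [response_contrast()]; the enhancement score is
#' `C_last - C_first`.
#'
#' @param run a `pathway_run` from [run_protocol()].
#' @param protocol the protocol; defaults to the one attached to `run`.
#' @param bg_window background-averaging window before onset, seconds.
#' @param pk_window peak-search window after onset, seconds.
#' @return a `contrast_series` with one row per transient (`onset`, `r_bg`,
#'   `r_pk`, `c_resp`) and attribute `"enhancement"`.
#' @export
transient_contrasts <- function(run, protocol = attr(run, "protocol"),
                                bg_window = 0.2, pk_window = 0.25) {
  stopifnot(inherits(run, "pathway_run"), inherits(protocol, "grating_protocol"))
  tab <- segment_table(protocol)
  onsets <- tab$t0[!is.na(tab$role) & tab$role == "transient"]
  if (!length(onsets)) stop("protocol contains no transient segments")
  if (length(onsets) > 1 && min(diff(onsets)) < bg_window + pk_window) {
    stop("analysis windows of consecutive transients overlap")
  }
  dt <- run$dt
  tr <- run$lptc
  res <- lapply(seq_along(onsets), function(k) {
    on <- onsets[k]
    i_bg <- which(run$time >= on - bg_window & run$time < on)
    i_pk <- which(run$time >= on & run$time <= on + pk_window)
    if (!length(i_bg) || !length(i_pk)) stop("windows outside trace")
    r_bg <- mean(tr[i_bg])
    r_pk <- tr[i_pk][which.max(abs(tr[i_pk] - r_bg))]
    data.frame(event = k, onset = on, r_bg = r_bg, r_pk = r_pk,
               c_resp = response_contrast(r_bg, r_pk))
  })
  df <- do.call(rbind, res)
  new_contrast_series(df, enhancement = df$c_resp[nrow(df)] - df$c_resp[1])
}

#' Motion-energy time course at one azimuth
#'
#' Average of the motion-energy map across all elevations at the detector
#' column nearest the requested azimuth (90 deg: the lateral visual field,
#' where passing objects sweep fastest and span most elevations).
#'
#' @param run a `pathway_run` on a rendered eye sequence.
#' @param eye the [eye_model()] the stimulus was rendered with.
#' @param azimuth requested azimuth, degrees.
#' @return numeric time series with attribute `"time"`.
#' @export
azimuth_energy_series <- function(run, eye, azimuth = 90) {
  stopifnot(inherits(run, "pathway_run"), inherits(eye, "eye_model"))
  ndet <- run$grid[["detectors"]]
  det_az <- eye$azimuth[seq_len(ndet)] + eye$spacing / 2
  if (azimuth < min(eye$azimuth) || azimuth > max(eye$azimuth)) {
    stop("azimuth outside the field of view")
  }
  j <- which.min(abs(det_az - azimuth))
  structure(run$energy_az[, j], time = run$time)
}

#' Bar-versus-background response contrasts
#'
#' For each bar passage the peak response `R_pk` is the maximum of the
#' series within +/- `pk_half` s of the crossing time and the background
#' `R_bg` is the series mean in a +/- `bg_half` s window centred on the
#' midpoint between this crossing and the next (for the last bar, extended
#' by half the median inter-crossing interval).  Windows are clipped to the
#' series extent; a window falling entirely outside is an error.
#'
#' @param series motion-energy series from [azimuth_energy_series()].
#' @param dt sample interval of the series, seconds.
#' @param crossings bar-crossing times, seconds ([bar_crossings()], plus any
#'   stimulus prelude).
#' @param pk_half,bg_half half-widths of the peak / background windows, s.
#' @return a `contrast_series` with one row per bar; attribute
#'   `"enhancement"` is `C_last - C_first` (the adaptation-driven contrast
#'   gain).
#' @export
bar_contrast_series <- function(series, dt, crossings, pk_half = 0.15,
                                bg_half = 0.15) {
  tt <- attr(series, "time") %||% ((seq_along(series) - 1) * dt)
  n <- length(crossings)
  gap <- if (n > 1) median(diff(crossings)) else 1
  res <- lapply(seq_len(n), function(k) {
    t_k <- crossings[k]
    mid <- if (k < n) (crossings[k] + crossings[k + 1]) / 2 else t_k + gap / 2
    i_pk <- which(tt >= t_k - pk_half & tt <= t_k + pk_half)
    i_bg <- which(tt >= mid - bg_half & tt <= mid + bg_half)
    if (!length(i_pk) || !length(i_bg)) stop("analysis window outside trace")
    r_pk <- max(series[i_pk])
    r_bg <- mean(series[i_bg])
    data.frame(bar = k, crossing = t_k, r_bg = r_bg, r_pk = r_pk,
               c_resp = response_contrast(r_bg, r_pk))
  })
  df <- do.call(rbind, res)
  new_contrast_series(df, enhancement = df$c_resp[n] - df$c_resp[1])
}

#' Contrast-gain curve and semi-saturation contrast
#'
#' `contrast_gain_curve` normalises raw responses (mean LPTC over the first
#' 300 ms of a reference or test period) by a common maximum -- by
#' convention the maximum of the before-adaptation curve.
#' `semisaturation_contrast` finds where a curve first crosses half of its
#' own maximum, interpolating linearly in log contrast; a rightward shift of
#' this point after adaptation is the signature of contrast-gain reduction.
#'
#' @param contrasts stimulus contrast levels (increasing).
#' @param response raw responses at those levels.
#' @param reference_max normalising maximum; defaults to `max(response)`.
#' @return `contrast_gain_curve`: data frame with `contrast` and normalised
#'   `response`.  `semisaturation_contrast`: the contrast at half-maximum.
#' @export
contrast_gain_curve <- function(contrasts, response, reference_max = NULL) {
  ord <- order(contrasts)
  contrasts <- contrasts[ord]; response <- response[ord]
  m <- reference_max %||% max(response)
  data.frame(contrast = contrasts, response = response / m)
}

#' @rdname contrast_gain_curve
#' @param curve a data frame from [contrast_gain_curve()].
#' @export
semisaturation_contrast <- function(curve) {
  half <- max(curve$response) / 2
  above <- which(curve$response >= half)
  i <- above[1]
  if (i == 1) return(curve$contrast[1])
  x <- log(curve$contrast[(i - 1):i])
  y <- curve$response[(i - 1):i]
  exp(x[1] + (half - y[1]) / (y[2] - y[1]) * (x[2] - x[1]))
}

#' Local response contrast and its change with adaptation
#'
#' `local_contrast_map` computes windowed Michelson contrast
#' `(max - min) / (max + min + eps)` of a retinotopic map in a sliding
#' square window.  `local_contrast_change` subtracts the local contrast of
#' the map before adaptation from that after adaptation, so positive values
#' mark loci (typically contours of nearby objects) where adaptation
#' enhanced the local response contrast.
#'
#' @param m a retinotopic map (matrix), e.g. the `energy` field of an
#'   [emd_frame].
#' @param window odd window edge length, pixels.
#' @param eps regulariser; defaults to `1e-6 * max(m)`.
#' @return matrix of the same size.
#' @export
local_contrast_map <- function(m, window = 5, eps = NULL) {
  m <- as.matrix(m)
  if (window > min(dim(m))) stop("window larger than map")
  eps <- eps %||% (1e-6 * max(m))
  h <- (window - 1) %/% 2
  nr <- nrow(m); nc <- ncol(m)
  mx <- mn <- m
  offs <- -h:h
  for (di in offs) {
    ri <- pmin(pmax(seq_len(nr) + di, 1), nr)
    for (dj in offs) {
      ci <- pmin(pmax(seq_len(nc) + dj, 1), nc)
      s <- m[ri, ci, drop = FALSE]
      mx <- pmax(mx, s)
      mn <- pmin(mn, s)
    }
  }
  (mx - mn) / (mx + mn + eps)
}

#' @rdname local_contrast_map
#' @param before,after energy maps before / after adaptation.
#' @export
local_contrast_change <- function(before, after, window = 5) {
  if (!all(dim(as.matrix(before)) == dim(as.matrix(after)))) {
    stop("maps must have the same shape")
  }
  eps <- 1e-6 * max(max(before), max(after))
  local_contrast_map(after, window, eps) - local_contrast_map(before, window, eps)
}

#' Count transient response excursions of a transient-train run
#'
#' Detrends the LPTC trace with a running median (which follows the slow
#' adaptation-driven decay but not the brief transients), rectifies, and
#' counts well-separated excursions via [count_peaks()].  Counting is
#' restricted to the constant-motion block of the protocol, excluding a
#' margin around motion onset and offset whose step responses are stimulus
#' artifacts, not velocity transients.
#'
#' @param run a `pathway_run` of a [transient_protocol()].
#' @param protocol the protocol (defaults to the attached one).
#' @param margin seconds excluded after motion onset / before offset.
#' @param detrend running-median window, seconds.
#' @inheritParams count_peaks
#' @return excursion count with attribute `"times"`.
#' @export
count_transients <- function(run, protocol = attr(run, "protocol"),
                             margin = 0.3, detrend = 0.4,
                             min_separation = 0.4, prominence = 0.5) {
  tab <- segment_table(protocol)
  moving <- !is.na(tab$role) & tab$role %in% c("background", "transient")
  if (!any(moving)) stop("protocol has no motion block")
  t0 <- min(tab$t0[moving]) + margin
  t1 <- max(tab$t0[moving] + protocol$segments$duration[moving]) - margin
  keep <- run$time >= t0 & run$time <= t1
  n <- count_peaks(run$lptc[keep], run$dt, min_separation = min_separation,
                   prominence = prominence, detrend = detrend)
  structure(as.integer(n), times = attr(n, "times") + t0)
}

#' Count well-separated peaks in a response series
#'
#' Contiguous excursions above a threshold midway (by `prominence`) between
#' a baseline (the series median by default) and the global maximum; runs
#' separated by less than `min_separation` are merged.  Used to count bar
#' passages in motion-energy series and, applied to the running-median
#' detrended LPTC trace, transient response excursions.
#'
#' @param x series; `detrend` subtracts a running median (window seconds)
#'   and rectifies, for counting transients on a decaying background.
#' @param dt sample interval, seconds.
#' @param min_separation merge distance, seconds.
#' @param prominence threshold position between baseline and maximum (0-1).
#' @param baseline override the baseline level.
#' @param detrend optional running-median window, seconds.
#' @return number of peaks; attribute `"times"` holds peak locations.
#' @export
count_peaks <- function(x, dt, min_separation = 0.4, prominence = 0.5,
                        baseline = NULL, detrend = NULL) {
  if (!is.null(detrend)) {
    k <- round(detrend / dt)
    if (k %% 2 == 0) k <- k + 1
    x <- abs(x - runmed(x, k))
    if (is.null(baseline)) baseline <- 0
  }
  baseline <- baseline %||% median(x)
  thr <- baseline + prominence * (max(x) - baseline)
  above <- x > thr
  if (!any(above)) return(structure(0L, times = numeric(0)))
  idx <- which(above)
  grp <- cumsum(c(1, diff(idx) > min_separation / dt))
  times <- vapply(split(idx, grp), function(ii) (ii[which.max(x[ii])] - 1) * dt,
                  numeric(1))
  structure(length(unique(grp)), times = unname(times))
}
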