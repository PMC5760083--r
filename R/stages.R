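#' Adaptive photoreceptor stage
#'
#' Divisive brightness adaptation: the input luminance is low-pass filtered
#' with a fast and a slow time constant and the fast branch is divided by the
#' slow branch plus a constant,
#' `PR = LP_fast(I) / (LP_slow(I) + C_PR)`.
#' The resulting saturation curve shifts with the ambient light level, which
#' keeps the output in `[0, 1)` over many decades of luminance.
#'
#' @param frame non-negative luminance frame (matrix or vector).
#' @param state filter memories, a list with `fast` and `slow`; `NULL`
#'   initialises both at the steady state of `frame`.
#' @param params a [pathway_params()].
#' @return list with `output` (photoreceptor response in `[0, 1)`) and
#'   updated `state`.
#' @examples
#' photoreceptor_stage(matrix(10, 2, 2))$output # 10/(10+10) = 0.5
#' @export
photoreceptor_stage <- function(frame, state = NULL,
                                params = pathway_params()) {
  if (anyNA(frame) || any(!is.finite(frame))) stop("luminance must be finite")
  if (min(frame) < 0) stop("luminance must be non-negative")
  if (is.null(state)) state <- list(fast = frame, slow = frame)
  f <- lowpass_step(frame, state$fast, params$pr_tau_fast, params$dt)
  s <- lowpass_step(frame, state$slow, params$pr_tau_slow, params$dt)
  list(output = f$output / (s$output + params$c_pr),
       state = list(fast = f$state, slow = s$state))
}

#' LMC stage: high-pass, ON/OFF split, Lipetz saturation
#'
#' The large monopolar cell removes the mean light level with a first-order
#' high-pass, half-wave rectifies the result into an ON (brightening) and an
#' OFF (darkening) channel -- the OFF channel carries the negative lobe as a
#' positive signal -- and saturates each channel as `x / (x + C_LMC)`.
#'
#' @param pr photoreceptor output frame.
#' @param state high-pass memory (the internal low-pass state); `NULL`
#'   initialises at steady state, i.e. zero high-pass output.
#' @param params a [pathway_params()].
#' @return list with `on`, `off` (both in `[0, 1)`) and updated `state`.
#' @export
lmc_stage <- function(pr, state = NULL, params = pathway_params()) {
  hp <- highpass_step(pr, state, params$lmc_tau_hp, params$dt)
  h <- hp$output
  on <- pmax(h, 0)
  off <- pmax(-h, 0)
  list(on = on / (on + params$c_lmc),
       off = off / (off + params$c_lmc),
       state = hp$state)
}

#' Correlation-type motion detection (one step)
#'
#' Each detector multiplies the delayed signal of one column with the
#' undelayed signal of its right-hand neighbour (preferred direction,
#' increasing column index) and mirror-symmetrically for the null direction,
#' separately in the ON and OFF channel:
#' `PD_j = LP_delay(ch_j) * ch_(j+1)`, `ND_j = ch_j * LP_delay(ch_(j+1))`.
#' Outputs are clamped at zero so that the downstream adaptive Lipetz stage
#' (which raises them to fractional powers) stays real-valued.
#'
#' @param on,off ON/OFF channel frames, `rows x columns` matrices.
#' @param state delay-filter memories `list(delay_on, delay_off)`; `NULL`
#'   initialises at steady state of the inputs.
#' @param params a [pathway_params()].
#' @param wrap logical, treat the column axis as periodic.  With `wrap` the
#'   detector count equals the number of columns, otherwise columns - 1.
#' @return list with the four non-negative half-detector maps `on_pd`,
#'   `on_nd`, `off_pd`, `off_nd` (each `rows x n_detectors`) and `state`.
#' @export
emd_correlate <- function(on, off, state = NULL, params = pathway_params(),
                          wrap = FALSE) {
  on <- as.matrix(on); off <- as.matrix(off)
  nc <- ncol(on)
  if (nc < 2) stop("retinotopic grid needs at least 2 columns")
  if (is.null(state)) state <- list(delay_on = on, delay_off = off)
  don <- lowpass_step(on, state$delay_on, params$emd_tau_delay, params$dt)
  doff <- lowpass_step(off, state$delay_off, params$emd_tau_delay, params$dt)
  j <- if (wrap) seq_len(nc) else seq_len(nc - 1)
  j2 <- if (wrap) c(seq_len(nc)[-1], 1L) else seq_len(nc)[-1]
  out <- list(
    on_pd = pmax(don$output[, j, drop = FALSE] * on[, j2, drop = FALSE], 0),
    on_nd = pmax(on[, j, drop = FALSE] * don$output[, j2, drop = FALSE], 0),
    off_pd = pmax(doff$output[, j, drop = FALSE] * off[, j2, drop = FALSE], 0),
    off_nd = pmax(off[, j, drop = FALSE] * doff$output[, j2, drop = FALSE], 0)
  )
  out$state <- list(delay_on = don$state, delay_off = doff$state)
  out
}

#' Update of the adaptive Lipetz exponent
#'
#' Forward-Euler step of
#' `da/dt = -(a - a_min) * p1 + (a_max - a) * p2 * E`,
#' clamped to `[a_min, a_max]`.  `E` is the slow-filtered,
#' direction-independent motion energy; without stimulation (`E = 0`) the
#' exponent relaxes to `a_min` with time constant `1/p1`, and for constant
#' `E` it converges to the fixed point
#' `(p1 * a_min + p2 * E * a_max) / (p1 + p2 * E)`.
#'
#' @param a current exponent array, values in `[a_min, a_max]`.
#' @param E slow motion-energy drive, non-negative, same shape as `a`.
#' @param params a [pathway_params()].
#' @param dt time step, seconds.
#' @return updated exponent array.
#' @export
adaptive_exponent_update <- function(a, E, params = pathway_params(),
                                     dt = params$dt) {
  if (any(E < 0)) stop("motion-energy drive E must be non-negative")
  a <- a + dt * (-(a - params$a_min) * params$p1 +
                   (params$a_max - a) * params$p2 * E)
  pmin(pmax(a, params$a_min), params$a_max)
}

#' Divisive motion adaptation of the half-detector outputs
#'
#' Each of the four half-detector branches of a detector is low-pass filtered
#' with the fast time constant, raised to the shared adaptive exponent `a`,
#' and divided by the slow-filtered mean of all four branches (the
#' direction-independent motion energy) plus a constant, each raised to the
#' same exponent:
#' `out = LP_fast(branch)^a / (LP_slow(mean of branches)^a + C_EMD^a)`.
#' One slow filter and one exponent are shared by the four branches of a
#' detector, which is what makes the adaptation direction-independent.
#'
#' @param branches list with non-negative maps `on_pd`, `on_nd`, `off_pd`,
#'   `off_nd` (as produced by [emd_correlate()]).
#' @param state list with `fast` (list of four), `slow` and `a`; `NULL`
#'   initialises filters at the steady state of the input and `a` at its
#'   fixed point for that drive.
#' @param params a [pathway_params()].
#' @param adaptation if `FALSE` the divisive stage is bypassed: the raw
#'   branches are returned and `a` is left untouched.
#' @return list with `adapted` (four maps, non-negative and bounded) and
#'   updated `state`.
#' @export
emd_adapt <- function(branches, state = NULL, params = pathway_params(),
                      adaptation = TRUE) {
  b <- branches[c("on_pd", "on_nd", "off_pd", "off_nd")]
  if (any(vapply(b, function(m) any(m < 0), logical(1)))) {
    stop("half-detector branches must be non-negative (rectify upstream)")
  }
  ave <- (b$on_pd + b$on_nd + b$off_pd + b$off_nd) / 4
  if (is.null(state)) {
    E0 <- ave
    a0 <- (params$p1 * params$a_min + params$p2 * E0 * params$a_max) /
      (params$p1 + params$p2 * E0)
    state <- list(fast = b, slow = ave,
                  a = pmin(pmax(a0, params$a_min), params$a_max))
  }
  slow <- lowpass_step(ave, state$slow, params$emd_tau_slow, params$dt)
  fast <- lapply(names(b), function(nm) {
    lowpass_step(b[[nm]], state$fast[[nm]], params$emd_tau_fast, params$dt)
  })
  names(fast) <- names(b)
  if (adaptation) {
    a <- adaptive_exponent_update(state$a, slow$output, params, params$dt)
    denom <- slow$output^a + params$c_emd^a
    adapted <- lapply(fast, function(f) f$output^a / denom)
  } else {
    a <- state$a
    adapted <- b
  }
  list(adapted = adapted,
       state = list(fast = lapply(fast, `[[`, "state"),
                    slow = slow$state, a = a))
}

#' Signed response and motion energy of a detector array
#'
#' The signed local response is the preferred-direction sum minus the
#' null-direction sum over both polarity channels,
#' `(ON-PD + OFF-PD) - (ON-ND + OFF-ND)`; motion energy is its absolute
#' value.
#'
#' @param maps list of four half-detector maps.
#' @return list with `signed` and `energy` maps.
#' @export
emd_signed_response <- function(maps) {
  signed <- (maps$on_pd + maps$off_pd) - (maps$on_nd + maps$off_nd)
  list(signed = signed, energy = abs(signed))
}

#' Linear wide-field pooling (LPTC)
#'
#' The tangential-cell model sums the signed response of every detector in
#' the array: preferred-direction half-detectors contribute positively,
#' null-direction half-detectors negatively, for ON and OFF alike.
#'
#' @param maps list of four half-detector maps.
#' @return scalar pooled response.
#' @export
lptc_pool <- function(maps) {
  sum(emd_signed_response(maps)$signed)
}

# Pure-R reference implementation of the full chain, used as the independent
# oracle for the compiled core.  Same ordering of updates, same cold start.
run_pathway_r <- function(stim, params = pathway_params(),
                          adaptation = TRUE) {
  stopifnot(inherits(stim, "luminance_seq"))
  if (abs(stim$dt - params$dt) > 1e-12) stop("stimulus dt must equal model dt")
  d <- dim(stim$frames)
  nsteps <- d[1]
  pr_st <- NULL; lmc_st <- NULL; emd_st <- NULL; ad_st <- NULL
  lptc <- numeric(nsteps)
  a_mean <- numeric(nsteps)
  energy_az <- NULL
  last <- NULL
  for (k in seq_len(nsteps)) {
    frame <- matrix(stim$frames[k, , ], d[2], d[3])
    pr <- photoreceptor_stage(frame, pr_st, params)
    pr_st <- pr$state
    lmc <- lmc_stage(pr$output, lmc_st, params)
    lmc_st <- lmc$state
    emd <- emd_correlate(lmc$on, lmc$off, emd_st, params,
                         wrap = stim$azimuth_wrap)
    emd_st <- emd$state
    ad <- emd_adapt(emd[c("on_pd", "on_nd", "off_pd", "off_nd")], ad_st,
                    params, adaptation = adaptation)
    ad_st <- ad$state
    resp <- emd_signed_response(ad$adapted)
    lptc[k] <- sum(resp$signed)
    a_mean[k] <- mean(ad_st$a)
    if (is.null(energy_az)) {
      energy_az <- matrix(0, nsteps, ncol(resp$energy))
    }
    energy_az[k, ] <- colMeans(resp$energy)
    last <- list(unadapted = emd[c("on_pd", "on_nd", "off_pd", "off_nd")],
                 adapted = ad$adapted, signed = resp$signed,
                 energy = resp$energy, a = ad_st$a)
  }
  list(lptc = lptc, a_mean = a_mean, energy_az = energy_az, last = last)
}
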