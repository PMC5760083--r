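#' First-order temporal filters (single step)
#'
#' One update step of a first-order low-pass / high-pass filter with the
#' exact exponential discretisation for piecewise-constant input:
#' `y_new = y + (x - y) * (1 - exp(-dt / tau))`.  The high-pass is the
#' complement `x - lowpass(x)` and shares the same memory contract.
#'
#' These scalar/array steps are the building blocks of every stage of the
#' pathway; [run_pathway()] runs the same updates in compiled code.
#'
#' @param x input sample: scalar, vector or matrix (one retinotopic frame).
#' @param state filter memory with the shape of `x`.  If omitted it is
#'   initialised at the steady state of `x` (so the first output equals the
#'   steady-state response).
#' @param tau filter time constant, seconds.
#' @param dt sample interval, seconds.
#' @return a list with `output` (same shape as `x`) and the updated `state`.
#' @examples
#' # analytic step response: 1 - exp(-1) after tau seconds
#' st <- 0
#' for (i in 1:9) {
#'   s <- lowpass_step(1, st, tau = 9e-3, dt = 1e-3)
#'   st <- s$state
#' }
#' s$output # ~0.6321
#' @export
lowpass_step <- function(x, state = NULL, tau, dt) {
  if (anyNA(x) || any(!is.finite(x))) stop("filter input must be finite")
  if (tau <= 0 || dt <= 0) stop("tau and dt must be > 0")
  if (tau <= dt) warning("tau <= dt: filter is under-resolved")
  if (is.null(state)) state <- x
  y <- state + (x - state) * (1 - exp(-dt / tau))
  list(output = y, state = y)
}

#' @rdname lowpass_step
#' @export
highpass_step <- function(x, state = NULL, tau, dt) {
  lp <- lowpass_step(x, state, tau = tau, dt = dt)
  list(output = x - lp$output, state = lp$state)
}
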