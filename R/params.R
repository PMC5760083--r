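#' Model constants of the adaptive motion pathway
#'
#' All printed constants of the pathway, with the published values as
#' defaults.  Time constants are in seconds; `c_*` are the half-saturation
#' constants of the Lipetz stages; `a_min`/`a_max` bound the adaptive EMD
#' exponent and `p1`/`p2` (in 1/s) set its recovery rate and the strength of
#' its activity-driven growth.
#'
#' @param dt model integration step, seconds.  1 ms by default; filters use
#'   the exact exponential update so results are stable under dt refinement.
#' @param pr_tau_fast,pr_tau_slow photoreceptor fast/slow low-pass time
#'   constants (9 ms, 250 ms).
#' @param c_pr photoreceptor Lipetz constant (10).
#' @param lmc_tau_hp LMC high-pass time constant (10 ms).
#' @param c_lmc LMC Lipetz constant (0.03).
#' @param emd_tau_delay EMD cross-channel delay low-pass (50 ms).
#' @param emd_tau_fast,emd_tau_slow fast/slow time constants of the divisive
#'   motion-adaptation stage (20 ms, 4 s).
#' @param c_emd EMD Lipetz constant (0.8).
#' @param a_min,a_max bounds of the adaptive exponent (0.5, 3).
#' @param p1,p2 rate constants of the exponent dynamics (30, 150; 1/s).
#' @return an object of class `pathway_params` (a validated named list).
#' @examples
#' pathway_params()
#' @export
pathway_params <- function(dt = 0.001,
                           pr_tau_fast = 0.009, pr_tau_slow = 0.250,
                           c_pr = 10,
                           lmc_tau_hp = 0.010, c_lmc = 0.03,
                           emd_tau_delay = 0.050,
                           emd_tau_fast = 0.020, emd_tau_slow = 4.0,
                           c_emd = 0.8,
                           a_min = 0.5, a_max = 3, p1 = 30, p2 = 150) {
  p <- list(dt = dt, pr_tau_fast = pr_tau_fast, pr_tau_slow = pr_tau_slow,
            c_pr = c_pr, lmc_tau_hp = lmc_tau_hp, c_lmc = c_lmc,
            emd_tau_delay = emd_tau_delay, emd_tau_fast = emd_tau_fast,
            emd_tau_slow = emd_tau_slow, c_emd = c_emd,
            a_min = a_min, a_max = a_max, p1 = p1, p2 = p2)
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1L &&
                  is.finite(x), logical(1))
  if (!all(num)) stop("all parameters must be finite scalars")
  if (dt <= 0) stop("dt must be > 0")
  taus <- c(pr_tau_fast, pr_tau_slow, lmc_tau_hp,
            emd_tau_delay, emd_tau_fast, emd_tau_slow)
  if (any(taus <= 0)) stop("all time constants must be > 0")
  if (any(taus <= dt)) {
    warning("a filter time constant is <= dt: that stage is under-resolved")
  }
  if (any(c(c_pr, c_lmc, c_emd) <= 0)) stop("Lipetz constants must be > 0")
  if (!(a_min <= a_max)) stop("a_min must be <= a_max")
  if (p1 <= 0 || p2 <= 0) stop("p1 and p2 must be > 0")
  structure(p, class = "pathway_params")
}

#' @export
print.pathway_params <- function(x, ...) {
  cat("<pathway_params>\n")
  cat(sprintf("  PR : tau_fast = %g ms, tau_slow = %g ms, C_PR = %g\n",
              1e3 * x$pr_tau_fast, 1e3 * x$pr_tau_slow, x$c_pr))
  cat(sprintf("  LMC: tau_hp = %g ms, C_LMC = %g\n",
              1e3 * x$lmc_tau_hp, x$c_lmc))
  cat(sprintf("  EMD: tau_delay = %g ms, tau_fast = %g ms, tau_slow = %g ms, C_EMD = %g\n",
              1e3 * x$emd_tau_delay, 1e3 * x$emd_tau_fast,
              1e3 * x$emd_tau_slow, x$c_emd))
  cat(sprintf("  a in [%g, %g], p1 = %g /s, p2 = %g /s; dt = %g ms\n",
              x$a_min, x$a_max, x$p1, x$p2, 1e3 * x$dt))
  invisible(x)
}
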