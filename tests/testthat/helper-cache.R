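# Session-level cache so expensive simulations are shared between the
# acceptance blocks that analyse them from different angles.
.sim_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .sim_cache, inherits = FALSE)) {
    assign(name, force(expr), envir = .sim_cache)
  }
  get(name, envir = .sim_cache, inherits = FALSE)
}

# Bar/background contrast curves for the 3D-world experiments:
# straight translation at three wall distances x 5 texture seeds, and the
# saccadic decagon condition x 3 seeds.
corridor_suite <- function() {
  cached("corridor_suite", {
    out <- list()
    for (d in c(0.55, 2, 4)) {
      for (s in 1:5) {
        r <- sim_corridor(d, seed = s, snapshot_bars = integer(0))
        out[[sprintf("tr_%g_%d", d, s)]] <- r$contrasts$c_resp
      }
      for (s in 1:3) {
        r <- sim_corridor(d, seed = s, dynamics = "decagon",
                          snapshot_bars = integer(0))
        out[[sprintf("dec_%g_%d", d, s)]] <- r$contrasts$c_resp
      }
    }
    out
  })
}

suite_median_curve <- function(suite, dynamics, d, seeds) {
  apply(sapply(seeds, function(s) {
    suite[[sprintf("%s_%g_%d", dynamics, d, s)]]
  }), 1, median)
}

# one full-length corridor run (wall 0.55 m, seed 1) incl. lateral series
corridor_reference_run <- function() {
  cached("corridor_ref", sim_corridor(0.55, seed = 1))
}

adaptation_direction_runs <- function() {
  cached("adapt_dir", sim_adaptation_direction())
}

# small grating stimulus for oracle/equivalence checks
tiny_drift_stim <- function(n_steps = 600, rows = 2, cols = 12,
                            wavelength = 6, tf = 2, contrast = 0.88) {
  segs <- rbind(grating_segment(0.1, 0, "stationary"),
                grating_segment(n_steps / 1000, tf, "pd"))
  pro <- grating_protocol(rows, cols, wavelength, 1000, contrast, segs)
  render_grating(pro, 0.001)
}
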