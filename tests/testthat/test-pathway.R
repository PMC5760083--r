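p_default <- pathway_params()

test_that("photoreceptor stage follows the divisive fixed points", {
  # constant I = 10 with C_PR = 10: steady state 10 / (10 + 10) = 0.5
  expect_equal(photoreceptor_stage(matrix(10, 2, 2))$output,
               matrix(0.5, 2, 2))
  expect_equal(photoreceptor_stage(0)$output, 0)
  # saturation: brightness of 1e6 sits at ~1, invariant across decades
  expect_equal(photoreceptor_stage(1e6)$output, 1e6 / (1e6 + 10),
               tolerance = 1e-12)
  expect_gt(photoreceptor_stage(1e6)$output, 0.99999)
  expect_error(photoreceptor_stage(-1), "non-negative")
})

test_that("LMC stage rejects DC, splits ON/OFF and saturates below 1", {
  # constant photoreceptor drive: both channels silent at steady state
  st <- NULL
  for (i in 1:100) {
    l <- lmc_stage(matrix(0.5, 2, 2), st, p_default)
    st <- l$state
  }
  expect_lt(max(l$on, l$off), 1e-6)

  # brightening step: ON transient only, during the rising phase
  l <- lmc_stage(matrix(0.5, 2, 2), NULL, p_default)
  l2 <- lmc_stage(matrix(0.7, 2, 2), l$state, p_default)
  expect_true(all(l2$on > 0))
  expect_true(all(l2$off == 0))

  # Lipetz bound: x / (x + C) < 1 for any input
  l3 <- lmc_stage(matrix(c(0.1, 5, 50, 0.9), 2, 2), NULL, p_default)
  l4 <- lmc_stage(matrix(c(90, 0.2, 7, 1), 2, 2), l3$state, p_default)
  expect_true(all(l4$on < 1, l4$off < 1, l4$on >= 0, l4$off >= 0))
})

test_that("EMD correlation is mirror-symmetric and direction-selective", {
  set.seed(42)
  nr <- 2; nc <- 8
  st <- NULL; st_m <- NULL
  for (i in 1:30) {
    on <- matrix(runif(nr * nc), nr, nc)
    off <- matrix(runif(nr * nc), nr, nc)
    e <- emd_correlate(on, off, st, p_default, wrap = FALSE)
    st <- e$state
    # mirrored stimulus: columns reversed
    em <- emd_correlate(on[, nc:1], off[, nc:1], st_m, p_default,
                        wrap = FALSE)
    st_m <- em$state
  }
  # mirroring swaps PD and ND maps exactly (up to the column flip)
  expect_equal(em$on_pd, e$on_nd[, (nc - 1):1], tolerance = 1e-12)
  expect_equal(em$off_nd, e$off_pd[, (nc - 1):1], tolerance = 1e-12)

  expect_error(emd_correlate(matrix(1, 2, 1), matrix(1, 2, 1)), "2 columns")

  # static input: once the upstream is silent the maps are zero
  z <- matrix(0, 2, 8)
  ez <- emd_correlate(z, z, NULL, p_default)
  expect_true(all(ez$on_pd == 0, ez$off_nd == 0))

  # grating drifting in PD: time-averaged PD exceeds ND at every detector
  stim <- tiny_drift_stim(n_steps = 2000, rows = 1, cols = 38,
                          wavelength = 19, tf = 2, contrast = 0.88)
  pr_st <- NULL; lmc_st <- NULL; emd_st <- NULL
  pd_sum <- nd_sum <- 0
  for (k in seq_len(dim(stim$frames)[1])) {
    fr <- matrix(stim$frames[k, , ], 1)
    pr <- photoreceptor_stage(fr, pr_st, p_default); pr_st <- pr$state
    l <- lmc_stage(pr$output, lmc_st, p_default); lmc_st <- l$state
    e <- emd_correlate(l$on, l$off, emd_st, p_default, wrap = TRUE)
    emd_st <- e$state
    if (k > 500) { # skip the stationary prelude
      pd_sum <- pd_sum + e$on_pd + e$off_pd
      nd_sum <- nd_sum + e$on_nd + e$off_nd
    }
  }
  expect_true(all(pd_sum > nd_sum))
})

test_that("adaptive exponent follows its closed-form fixed points", {
  p <- p_default
  # E = 0: relaxation to a_min with time constant 1/p1, within 5%
  a <- 3
  trace <- numeric(400)
  for (i in 1:400) {
    a <- adaptive_exponent_update(a, 0, p, dt = 1e-3)
    trace[i] <- a
  }
  expect_equal(trace[400], p$a_min, tolerance = 1e-3)
  fit <- coef(lm(log(trace[1:100] - p$a_min) ~ I((1:100) * 1e-3)))
  expect_equal(unname(-1 / fit[2]), 1 / p$p1, tolerance = 0.05)

  # constant E = 0.2 (p2 E = p1): Euler iteration converges to the root of
  # da/dt = 0, a* = (p1 a_min + p2 E a_max) / (p1 + p2 E) = 1.75
  a <- 0.5
  for (i in 1:2000) a <- adaptive_exponent_update(a, 0.2, p, dt = 1e-3)
  expect_equal(a, 1.75, tolerance = 1e-3)

  # strong drive: fixed point approaches a_max from below, and the hard
  # clamp never lets a escape [a_min, a_max] even for unstable drives
  a <- 0.5
  for (i in 1:2000) a <- adaptive_exponent_update(a, 5, p, dt = 1e-3)
  a_star <- (p$p1 * p$a_min + p$p2 * 5 * p$a_max) / (p$p1 + p$p2 * 5)
  expect_equal(a, a_star, tolerance = 1e-3)
  expect_gt(a_star, 1.75) # monotone in E
  expect_lte(adaptive_exponent_update(2.9, 1e6, p, dt = 1e-3), p$a_max)

  expect_error(adaptive_exponent_update(1, -0.1, p, 1e-3), "non-negative")
})

test_that("divisive EMD adaptation reproduces its algebraic steady states", {
  # all-zero input stays zero
  z <- matrix(0, 1, 1)
  b0 <- list(on_pd = z, on_nd = z, off_pd = z, off_nd = z)
  expect_equal(emd_adapt(b0, NULL, p_default)$adapted$on_pd, z)

  # one branch at 0.8, exponent pinned at 1 (a_min = a_max = 1):
  # EMD_ave = 0.2, steady output 0.8 / (0.2 + 0.8) = 0.8
  p1p <- pathway_params(a_min = 1, a_max = 1)
  b <- list(on_pd = matrix(0.8, 1, 1), on_nd = z, off_pd = z, off_nd = z)
  st <- NULL
  for (i in 1:40000) { # ~10 tau_slow at 1 ms
    ad <- emd_adapt(b, st, p1p)
    st <- ad$state
  }
  expect_equal(ad$adapted$on_pd[1, 1], 0.8, tolerance = 1e-3)

  expect_error(
    emd_adapt(list(on_pd = matrix(-1, 1, 1), on_nd = z, off_pd = z,
                   off_nd = z), NULL, p_default),
    "non-negative")
})

test_that("signed response and LPTC pooling are linear arithmetic", {
  m <- function(v) matrix(v, 1, 1)
  maps <- list(on_pd = m(0.3), off_pd = m(0.3), on_nd = m(0.1),
               off_nd = m(0.1))
  r <- emd_signed_response(maps)
  expect_equal(r$signed[1, 1], 0.4)
  expect_equal(r$energy[1, 1], 0.4)
  # swapping PD and ND negates signed, preserves energy
  sw <- emd_signed_response(list(on_pd = maps$on_nd, off_pd = maps$off_nd,
                                 on_nd = maps$on_pd, off_nd = maps$off_pd))
  expect_equal(sw$signed, -r$signed)
  expect_equal(sw$energy, r$energy)
  # all equal -> zero
  eq <- emd_signed_response(list(on_pd = m(2), off_pd = m(2), on_nd = m(2),
                                 off_nd = m(2)))
  expect_equal(eq$signed[1, 1], 0)

  expect_equal(lptc_pool(maps), 0.4)
  # additivity
  maps2 <- lapply(maps, function(x) x * 3)
  mapsum <- Map(`+`, maps, maps2)
  expect_equal(lptc_pool(maps) + lptc_pool(maps2), lptc_pool(mapsum))
})

test_that("compiled pathway equals the pure-R stage-by-stage chain", {
  stim <- tiny_drift_stim(n_steps = 500, rows = 2, cols = 12, wavelength = 6)
  for (ad in c(TRUE, FALSE)) {
    run <- run_pathway(stim, p_default, adaptation = ad)
    ref <- emdadapt:::run_pathway_r(stim, p_default, adaptation = ad)
    expect_equal(run$lptc, ref$lptc, tolerance = 1e-10)
    expect_equal(run$a_mean, ref$a_mean, tolerance = 1e-10)
    expect_equal(run$energy_az, ref$energy_az, tolerance = 1e-10)
  }
})

test_that("full runs respect bounds, preludes and dt refinement", {
  pro <- transient_protocol(n_transients = 2, rows = 2, cols = 38,
                            wavelength = 19)
  run <- run_protocol(pro, p_default, snapshot_times = c(1.2))

  # stationary prelude: negligible correlator output at its end
  pre <- abs(run$lptc[run$time > 0.4 & run$time < 0.5])
  motion <- max(abs(run$lptc[run$time > 0.6]))
  expect_lt(max(pre), 0.01 * motion)

  # adaptive exponent bounded at all times and in the snapshot map
  s <- run$snapshots[[1]]
  expect_true(all(s$a >= p_default$a_min & s$a <= p_default$a_max))
  expect_true(all(run$a_mean >= p_default$a_min - 1e-12 &
                    run$a_mean <= p_default$a_max + 1e-12))
  # adapted maps non-negative and bounded
  expect_true(all(unlist(s$adapted) >= 0))
  expect_true(all(is.finite(unlist(s$adapted))))

  # exact exponential updates: halving dt changes the trace by < 2%
  p_half <- pathway_params(dt = 5e-4)
  run2 <- run_protocol(pro, p_half)
  common <- seq(1, length(run2$lptc), by = 2)[seq_along(run$lptc)]
  expect_lt(max(abs(run2$lptc[common] - run$lptc)) / max(abs(run$lptc)),
            0.02)

  # dt mismatch: stimulus finer than the model grid is rejected
  stim_fine <- render_grating(pro, 5e-4, steps = 1:100)
  expect_error(run_pathway(stim_fine, p_default), "finer")
})

test_that("with frozen slow state and unit exponent the adapted response is a
           monotone transform of the unadapted one", {
  suppressWarnings({
    p_eq <- pathway_params(emd_tau_slow = 1e9, emd_tau_fast = 1e-6,
                           a_min = 1, a_max = 1)
    stim <- tiny_drift_stim(n_steps = 400, rows = 2, cols = 12, wavelength = 6)
    run <- run_pathway(stim, p_eq, snapshot_times = c(0.25, 0.35))
  })
  for (s in run$snapshots) {
    u <- unlist(s$unadapted)
    a <- unlist(s$adapted)
    expect_equal(cor(rank(u), rank(a)), 1, tolerance = 1e-12)
  }
})

test_that("prolonged motion adapts the response while the unadapted branch
           stays level", {
  segs <- rbind(grating_segment(0.5, 0, "stationary"),
                grating_segment(7.5, 2, "pd"))
  pro <- grating_protocol(1, 38, 19, 1000, 0.88, segs)
  run <- run_protocol(pro, p_default)
  run0 <- run_protocol(pro, p_default, adaptation = FALSE)
  win <- function(r, t0, t1) mean(r$lptc[r$time >= t0 & r$time < t1])
  expect_lt(win(run, 7.3, 7.8) / win(run, 0.9, 1.4), 0.95)
  expect_gt(win(run0, 7.3, 7.8) / win(run0, 0.9, 1.4), 0.9)
})

test_that("brightness adaptation keeps the response pattern across eight
           decades of mean luminance", {
  r3 <- sim_transients(n_transients = 2, i_mean = 1e3)
  r12 <- sim_transients(n_transients = 2, i_mean = 1e12)
  expect_gt(cor(r3$run$lptc, r12$run$lptc), 0.99)
  expect_lt(mean(abs(r3$run$lptc - r12$run$lptc)) / max(abs(r3$run$lptc)),
            0.05)
})
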