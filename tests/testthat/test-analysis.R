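test_that("response contrast is bounded, exact and scale-invariant", {
  expect_equal(response_contrast(1, 1), 0)
  expect_equal(response_contrast(1, 3), 0.5)
  set.seed(1)
  a <- runif(50, 0.01, 10); b <- runif(50, 0.01, 10); k <- runif(50, 0.1, 100)
  expect_equal(response_contrast(k * a, k * b), response_contrast(a, b))
  expect_true(all(response_contrast(a, b) >= 0 &
                    response_contrast(a, b) <= 1))
  expect_error(response_contrast(0, 0), "undefined")
})

fake_run <- function(lptc, dt = 1e-3) {
  structure(list(time = (seq_along(lptc) - 1) * dt, lptc = lptc, dt = dt),
            class = "pathway_run")
}

test_that("per-transient contrasts recover hand-computed values", {
  pro <- transient_protocol(n_transients = 8)
  tab <- emdadapt:::segment_table(pro)
  onsets <- tab$t0[!is.na(tab$role) & tab$role == "transient"]
  n <- emdadapt:::protocol_steps(pro, 1e-3)
  tt <- (seq_len(n) - 1) * 1e-3

  # constant trace: every contrast 0, enhancement 0
  ct0 <- transient_contrasts(fake_run(rep(2, n)), pro)
  expect_true(all(ct0$c_resp == 0))
  expect_equal(enhancement(ct0), 0)

  # rectangular peaks ramping 2.0 -> 3.0 on background 1.0:
  # C_first = 1/3, C_last = 0.5, enhancement = 1/6
  x <- rep(1, n)
  heights <- seq(2, 3, length.out = 8)
  for (k in 1:8) x[tt >= onsets[k] & tt < onsets[k] + 0.05] <- heights[k]
  ct <- transient_contrasts(fake_run(x), pro)
  expect_equal(ct$r_bg, rep(1, 8))
  expect_equal(ct$r_pk, heights)
  expect_equal(ct$c_resp[1], 1 / 3)
  expect_equal(ct$c_resp[8], 0.5)
  expect_equal(enhancement(ct), 0.5 - 1 / 3)

  # overlapping windows are rejected
  expect_error(transient_contrasts(fake_run(x), pro, bg_window = 0.5,
                                   pk_window = 0.5), "overlap")
})

test_that("bar/background contrasts recover hand-computed values", {
  dt <- 1e-3
  tt <- seq(0, 9, by = dt)
  crossings <- 1:8
  x <- rep(1, length(tt))
  x[tt > 7.6] <- 0.5                    # background halves before bar 8
  for (k in crossings) x[abs(tt - k) < 0.05] <- 2 # constant peaks
  ser <- structure(x, time = tt)
  ct <- bar_contrast_series(ser, dt, crossings)
  expect_equal(ct$c_resp[1], 1 / 3)
  expect_equal(ct$c_resp[8], (2 - 0.5) / 2.5)
  expect_gt(enhancement(ct), 0)

  # flat series: all contrasts zero
  ctf <- bar_contrast_series(structure(rep(1, length(tt)), time = tt),
                             dt, crossings)
  expect_true(all(ctf$c_resp == 0))

  expect_error(
    bar_contrast_series(structure(x[1:100], time = tt[1:100]), dt, crossings),
    "window")
})

test_that("azimuth energy series picks the lateral detector column", {
  eye <- eye_model()
  run <- structure(
    list(time = 1:5 * 1e-3,
         energy_az = matrix(0, 5, length(eye$azimuth) - 1),
         grid = c(rows = 91, detectors = length(eye$azimuth) - 1)),
    class = "pathway_run")
  expect_equal(as.numeric(azimuth_energy_series(run, eye, 90)), rep(0, 5))
  run$energy_az[, 45] <- 7
  expect_equal(as.numeric(azimuth_energy_series(run, eye, 89.5)), rep(7, 5))
  expect_error(azimuth_energy_series(run, eye, 200), "field of view")
})

test_that("contrast gain curves and semi-saturation behave analytically", {
  cc <- exp(seq(log(0.005), log(1), length.out = 20))
  resp <- cc / (cc + 0.1) # Naka-Rushton with c50 = 0.1... at half of max
  curve <- contrast_gain_curve(cc, resp)
  expect_equal(max(curve$response), 1)
  # oracle: solve r(c) = max(r)/2 on a fine grid
  fine <- exp(seq(log(0.005), log(1), length.out = 20000))
  oracle <- fine[which.min(abs(fine / (fine + 0.1) - max(resp) / 2))]
  expect_equal(semisaturation_contrast(curve), oracle, tolerance = 0.02)
  # normalising against a larger reference maximum scales the curve down
  curve2 <- contrast_gain_curve(cc, resp, reference_max = 2 * max(resp))
  expect_equal(max(curve2$response), 0.5)
})

test_that("local contrast maps detect modulation changes", {
  m <- matrix(1, 12, 12)
  expect_true(all(local_contrast_change(m, m) == 0))

  xg <- outer(rep(1, 12), sin(2 * pi * (1:12) / 6))
  before <- 1 + 0.2 * xg
  after <- 1 + 0.4 * xg
  chg <- local_contrast_change(before, after, window = 5)
  expect_true(all(chg >= 0))
  expect_gt(max(chg), 0.1)
  # hand-checked window statistic at an interior cell
  w_b <- before[4:8, 4:8]; w_a <- after[4:8, 4:8]
  eps <- 1e-6 * max(after)
  expect_equal(chg[6, 6],
               (max(w_a) - min(w_a)) / (max(w_a) + min(w_a) + eps) -
                 (max(w_b) - min(w_b)) / (max(w_b) + min(w_b) + eps),
               tolerance = 1e-12)
  expect_error(local_contrast_map(m, window = 15), "window")
})

test_that("peak counting finds well-separated excursions", {
  dt <- 1e-3
  tt <- seq(0, 10, by = dt)
  x <- 0.5 + 0 * tt
  peaks_at <- c(1, 2.5, 4, 6, 8.5)
  for (pk in peaks_at) x[abs(tt - pk) < 0.05] <- 2
  n <- count_peaks(x, dt, min_separation = 0.5)
  expect_equal(as.integer(n), 5)
  expect_equal(attr(n, "times"), peaks_at, tolerance = 0.06)
  expect_equal(as.integer(count_peaks(rep(1, 100) + 1e-9 * runif(100), dt)),
               1L) # degenerate flat-ish series: at most one "peak"
})
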