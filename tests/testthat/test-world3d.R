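test_that("cloud textures have 1/f^2 spectra, exact means and seeds", {
  tx <- cloud_texture(c(512, 512), 2, i_mean = 1000, contrast = 0.3,
                      seed = 7)
  expect_equal(spectral_slope(tx), -2, tolerance = 0.3)
  expect_lt(abs(mean(tx$luminance) / 1000 - 1), 0.01)
  expect_true(all(tx$luminance >= 0))
  # determinism: identical seed, bit-identical texture
  tx2 <- cloud_texture(c(512, 512), 2, i_mean = 1000, contrast = 0.3,
                       seed = 7)
  expect_identical(tx$luminance, tx2$luminance)
  expect_false(identical(
    tx$luminance, cloud_texture(c(512, 512), 2, seed = 8)$luminance))
  # contrasts that would clip > 1% of pixels are rejected
  expect_error(cloud_texture(c(64, 64), 1, contrast = 0.6, seed = 1),
               "clip")
  expect_error(cloud_texture(c(32, 32), 1), "64")
})

test_that("corridor scenes scale the wall with distance", {
  sc <- corridor_scene(0.55, seed = 1)
  wall <- sc$panels[[1]]
  expect_equal(wall$v[3], 1.1)              # 1.1 m high at 0.55 m
  expect_equal(wall$u[1], 16)               # 16 m long
  expect_equal(length(sc$bar_centers), 8)   # 1 bar/s over 8 s
  sc2 <- corridor_scene(2, seed = 1)
  expect_equal(sc2$panels[[1]]$v[3], 1.1 * 2 / 0.55) # similar triangles
  expect_equal(sc2$panels[[1]]$u[1], 16 * 2 / 0.55)
  # texture pixel count unchanged -> element size scales with distance
  expect_equal(dim(sc2$panels[[1]]$texture), dim(wall$texture))
  expect_error(corridor_scene(0.4), "farther")
})

test_that("the decagonal arena closes around the matched trajectory", {
  sc <- decagon_scene(0.55, seed = 1)
  walls <- Filter(function(p) grepl("^wall", p$name), sc$panels)
  expect_length(walls, 10)
  # per-side geometry identical up to rotation: equal side lengths
  lens <- vapply(walls, function(p) sqrt(sum(p$u^2)), numeric(1))
  expect_equal(max(lens) - min(lens), 0, tolerance = 1e-9)
  expect_equal(length(sc$bar_centers), 1)
  # bar sits 0.5 m outside the flight path side
  geo <- emdadapt:::decagon_geometry()
  b <- sc$bar_centers[[1]]
  expect_equal(sqrt(b[1]^2 + b[2]^2), geo$apothem + 0.5, tolerance = 1e-9)
})

test_that("translation trajectory is straight and uniform", {
  tr <- translation_trajectory(8, 1, 0.01)
  expect_equal(sum(sqrt(diff(tr$x)^2 + diff(tr$y)^2)), 8)
  expect_equal(var(tr$yaw), 0)
  fit <- lm(x ~ time, data = tr)
  expect_lt(max(abs(resid(fit))), 1e-12)
})

test_that("the saccade profile integrates to exactly 36 degrees", {
  pr <- saccade_yaw_profile(dt = 1e-3)
  expect_equal(sum(pr$v_yaw * 1e-3) * 180 / pi, 36, tolerance = 1e-12)
  expect_true(all(pr$v_yaw > 0))
  # Gaussian symmetry about tc = 10.5 ms
  expect_equal(pr$v_yaw[10], pr$v_yaw[11])
  expect_equal(pr$v_yaw[1], pr$v_yaw[20])
  expect_true(which.max(pr$v_yaw) %in% c(10, 11))
  # finer sampling preserves the integral exactly
  pr4 <- saccade_yaw_profile(dt = 2.5e-4)
  expect_equal(sum(pr4$v_yaw * 2.5e-4) * 180 / pi, 36, tolerance = 1e-12)
  expect_error(saccade_yaw_profile(dt = 3e-4), "divide")
})

test_that("the decagon trajectory realises the semi-natural dynamics", {
  tr <- decagon_trajectory(8, 0.01)
  expect_equal(max(tr$time), 8)
  # ten 36-degree saccades per 1-s cycle, clockwise
  expect_equal((tr$yaw[1] - tr$yaw[length(tr$yaw)]) * 180 / pi, 8 * 360,
               tolerance = 1e-9)
  sacc <- attr(tr, "saccade_times")
  expect_equal(length(sacc) / max(tr$time), 10) # saccade rate 10 /s
  # total path length matches the straight 8 m trajectory
  expect_equal(sum(sqrt(diff(tr$x)^2 + diff(tr$y)^2)), 8, tolerance = 1e-9)
  # position continuous: no jump larger than one translation step
  expect_lt(max(sqrt(diff(tr$x)^2 + diff(tr$y)^2)), 1.25 * 0.01 + 1e-9)
  # yaw continuous
  expect_lt(max(abs(diff(tr$yaw))), 30 * pi / 180)
})

test_that("bar crossings are found at the lateral passage times", {
  sc <- corridor_scene(0.55, seed = 1)
  tr <- translation_trajectory(8, 1, 0.01)
  expect_equal(bar_crossings(sc, tr), seq(0.5, 7.5), tolerance = 0.011)
  scd <- decagon_scene(0.55, seed = 1)
  trd <- decagon_trajectory(8, 0.01)
  cr <- bar_crossings(scd, trd)
  expect_length(cr, 8)
  expect_equal(diff(cr), rep(1, 7), tolerance = 0.02) # 1 bar/s
})

test_that("ray casting reproduces the analytic scene geometry", {
  eye <- eye_model()
  # empty scene: uniform background everywhere
  empty <- emdadapt:::new_scene(list(), background = 777, bar_centers = list())
  tr1 <- translation_trajectory(0.01, 1, 0.01)
  st <- render_eye_sequence(empty, tr1, eye)
  expect_true(all(st$frames == 777))

  # wall 1.1 m high at 0.55 m, eye at mid-height: spans +/- 45 deg elevation
  sc <- corridor_scene(0.55, seed = 1)
  wall_only <- sc; wall_only$panels <- sc$panels[1]
  st <- render_eye_sequence(wall_only, tr1, eye)
  col90 <- which.min(abs(eye$azimuth - 90))
  prof <- st$frames[1, , col90]
  sky <- abs(eye$elevation) > 47
  wallband <- abs(eye$elevation) < 43
  expect_true(all(prof[sky] == sc$background))
  expect_gt(sd(prof[wallband]), 1)

  # a 5-cm bar at 0.5 m subtends ~5.7 deg: ~3 columns at 2 deg
  bar_only <- sc; bar_only$panels <- sc$panels[2]; # bar at x = 0.5
  tr_at_bar <- translation_trajectory(0.01, 1, 0.01)
  tr_at_bar$x <- tr_at_bar$x + 0.5 # eye directly abeam of the bar
  st <- render_eye_sequence(bar_only, tr_at_bar, eye)
  row0 <- which(eye$elevation == 0)
  cols_hit <- which(st$frames[1, row0, ] != sc$background)
  expect_true(length(cols_hit) %in% 2:4)
  expect_equal(mean(eye$azimuth[cols_hit]), 90, tolerance = 3)
})

test_that("pure rotation shifts a panoramic image along azimuth", {
  eye_pan <- eye_model(azimuth = c(0, 358), elevation = c(-60, 60))
  sc <- decagon_scene(0.55, seed = 3)
  df <- data.frame(time = c(0, 0.01), x = 0, y = 0, z = 0,
                   yaw = c(0, -36 * pi / 180))
  tr <- emdadapt:::new_trajectory(df, dt = 0.01)
  st <- render_eye_sequence(sc, tr, eye_pan)
  # -36 deg yaw = +18 columns at 2 deg spacing, exactly (grid-aligned)
  shifted <- st$frames[1, , c(163:180, 1:162)]
  expect_equal(st$frames[2, , ], shifted, tolerance = 1e-12)
})

test_that("retinal angular wall velocity follows v/d at 90 deg azimuth", {
  eye <- eye_model(azimuth = c(75, 105), elevation = c(-30, 30))
  est_shift_px <- function(a, b) {
    lags <- -6:6
    cc <- vapply(lags, function(k) {
      ia <- seq_along(a); ib <- ia + k
      ok <- ib >= 1 & ib <= length(b)
      cor(a[ia[ok]], b[ib[ok]])
    }, numeric(1))
    i <- which.max(cc)
    if (i == 1 || i == length(cc)) return(lags[i])
    den <- cc[i - 1] - 2 * cc[i] + cc[i + 1]
    lags[i] + if (den != 0) 0.5 * (cc[i - 1] - cc[i + 1]) / den else 0
  }
  for (d in c(0.55, 2, 4)) {
    sc <- corridor_scene(d, seed = 2)
    sc$panels <- sc$panels[1] # wall only
    tr <- translation_trajectory(1, 1, 0.01)
    st <- render_eye_sequence(sc, tr, eye)
    v_pred <- (1 / d) * 180 / pi # deg/s
    gap <- max(1L, round(2 * 2 / (v_pred * 0.01))) # aim for ~2 px shift
    rows <- abs(eye$elevation) <= 20
    shifts <- vapply(seq(1, 100 - gap, by = 7), function(i) {
      a <- colMeans(st$frames[i, rows, ])
      b <- colMeans(st$frames[i + gap, rows, ])
      est_shift_px(a, b)
    }, numeric(1))
    v_est <- mean(shifts) * 2 / (gap * 0.01) # deg/s
    expect_equal(v_est, v_pred, tolerance = 0.1)
  }
})

test_that("rendering is deterministic for a given seed and config", {
  sc1 <- corridor_scene(0.55, seed = 5)
  sc2 <- corridor_scene(0.55, seed = 5)
  tr <- translation_trajectory(0.05, 1, 0.01)
  eye <- eye_model(azimuth = c(80, 100), elevation = c(-20, 20))
  expect_identical(render_eye_sequence(sc1, tr, eye)$frames,
                   render_eye_sequence(sc2, tr, eye)$frames)
})
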