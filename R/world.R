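#' Spherical eye sampling grid
#'
#' Uniform azimuth x elevation grid of viewing directions.  Azimuth 0 deg is
#' the flight (gaze) direction, 90 deg is lateral to the left; elevation 0 is
#' the horizon.  The default covers the left hemisphere at the fly's ~2 deg
#' inter-ommatidial resolution.  Horizontal (azimuthal) motion detectors are
#' formed between neighbouring azimuth columns.
#'
#' @param azimuth,elevation `c(min, max)` limits in degrees.
#' @param spacing angular grid spacing, degrees.
#' @return object of class `eye_model` with fields `azimuth`, `elevation`
#'   (degree vectors) and `spacing`.
#' @export
eye_model <- function(azimuth = c(0, 180), elevation = c(-90, 90),
                      spacing = 2) {
  stopifnot(spacing > 0, diff(azimuth) > 0, diff(elevation) > 0)
  structure(list(azimuth = seq(azimuth[1], azimuth[2], by = spacing),
                 elevation = seq(elevation[1], elevation[2], by = spacing),
                 spacing = spacing),
            class = "eye_model")
}

#' @export
print.eye_model <- function(x, ...) {
  cat(sprintf(
    "<eye_model> azimuth %g..%g deg x elevation %g..%g deg at %g deg (%d x %d directions)\n",
    min(x$azimuth), max(x$azimuth), min(x$elevation), max(x$elevation),
    x$spacing, length(x$elevation), length(x$azimuth)))
  invisible(x)
}

# --- scenes -----------------------------------------------------------------

# A panel is a textured rectangle: corner p0, edge vectors u (horizontal
# extent) and v (vertical extent), plus the unit normal.
make_panel <- function(p0, u, v, texture, name = "") {
  n <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  nn <- sqrt(sum(n^2))
  if (nn == 0 || sqrt(sum(u^2)) == 0 || sqrt(sum(v^2)) == 0) {
    stop("degenerate panel")
  }
  if (is.null(texture)) stop("every panel needs a texture")
  list(p0 = p0, u = u, v = v, n = n / nn, texture = texture, name = name)
}

new_scene <- function(panels, background, bar_centers, meta = list()) {
  structure(list(panels = panels, background = background,
                 bar_centers = bar_centers, meta = meta),
            class = "scene3d")
}

#' @export
print.scene3d <- function(x, ...) {
  cat(sprintf("<scene3d> %d panels (%d bars), background %g a.u.\n",
              length(x$panels), length(x$bar_centers), x$background))
  invisible(x)
}

# Texture pixel size at the reference wall distance (0.55 m).  One degree at
# the closest object (0.5 m) is ~8.7 mm; sampling at <= 8.6 mm keeps texture
# granularity at >= 4x the angular Nyquist of the 2-degree eye.
.base_px_m <- 1.1 / 128

#' Corridor scene: a row of bars in front of a wall
#'
#' A wall (1.1 m high, 16 m long at the reference distance of 0.55 m) and
#' eight bars (5 cm wide, 1 m high, 1 m apart, 0.5 m from the flight line)
#' parallel to the x axis, all textured with seeded 1/f^2 cloud patterns.
#' For wall distances of 2 m and 4 m the wall's height, length and texture
#' element size are scaled by `wall_distance / 0.55`, so its retinal
#' projection and texture granularity match the reference case and only the
#' background retinal velocity changes.
#'
#' @param wall_distance distance trajectory-to-wall, metres (0.55, 2 or 4 in
#'   the benchmark scenarios; any value > 0.5 is accepted).
#' @param seed texture seed; wall and every bar get independent sub-seeded
#'   patterns.
#' @param i_mean mean luminance of textures and background sky, a.u.
#' @param texture_contrast rms contrast of the cloud textures.
#' @param n_bars number of bars (8: one passed per second at 1 m/s).
#' @return a `scene3d`; bar centre coordinates are stored in `bar_centers`.
#' @export
corridor_scene <- function(wall_distance = 0.55, seed = 1, i_mean = 1000,
                           texture_contrast = 0.3, n_bars = 8) {
  if (wall_distance <= 0.5) {
    stop("wall must be farther than the bar row (0.5 m)")
  }
  scale <- wall_distance / 0.55
  wall_h <- 1.1 * scale
  wall_l <- 16 * scale
  wall_tex <- cloud_texture(c(128, 2048), c(wall_h, wall_l), i_mean,
                            texture_contrast, seed = seed * 131 + 1)
  panels <- list(make_panel(
    p0 = c(4 - wall_l / 2, wall_distance, -wall_h / 2),
    u = c(wall_l, 0, 0), v = c(0, 0, wall_h),
    texture = wall_tex$luminance, name = "wall"))
  bar_centers <- list()
  for (i in seq_len(n_bars)) {
    bt <- cloud_texture(c(128, 64), c(1, 0.05), i_mean, texture_contrast,
                        seed = seed * 131 + 1 + i)
    xc <- i - 0.5
    panels[[length(panels) + 1L]] <- make_panel(
      p0 = c(xc - 0.025, 0.5, -0.5), u = c(0.05, 0, 0), v = c(0, 0, 1),
      texture = bt$luminance, name = sprintf("bar%d", i))
    bar_centers[[i]] <- c(xc, 0.5, 0)
  }
  new_scene(panels, background = i_mean, bar_centers = bar_centers,
            meta = list(kind = "corridor", wall_distance = wall_distance,
                        seed = seed, i_mean = i_mean,
                        texture_contrast = texture_contrast))
}

# Regular-decagon geometry shared by trajectory and arena: the 1-m-per-cycle
# flight path is a decagon with 0.1 m sides, traversed clockwise so that the
# arena (outside the path) lies in the left visual field.
decagon_geometry <- function() {
  r_t <- 0.1 / (2 * sin(pi / 10))
  ang <- pi / 2 - (0:10) * (2 * pi / 10)
  verts <- cbind(r_t * cos(ang), r_t * sin(ang))
  list(r_traj = r_t, apothem = r_t * cos(pi / 10), verts = verts)
}

#' Decagonal arena scene for the saccadic-flight condition
#'
#' A decagonal wall surrounding the decagonal flight path at the given
#' perpendicular distance, with one bar (5 cm x 1 m, as in the corridor)
#' placed 0.5 m outside the midpoint of one path side.  The bar is passed
#' once per 1-s trajectory cycle, so the bar-passage rate (1 bar/s) matches
#' the straight corridor.  Wall height and texture element size follow the
#' same `wall_distance / 0.55` scaling as [corridor_scene()].
#'
#' @inheritParams corridor_scene
#' @param bar_side index (0-9) of the path side carrying the bar.
#' @return a `scene3d`.
#' @export
decagon_scene <- function(wall_distance = 0.55, seed = 1, i_mean = 1000,
                          texture_contrast = 0.3, bar_side = 5) {
  if (wall_distance <= 0.5) {
    stop("wall must be farther than the bar (0.5 m)")
  }
  geo <- decagon_geometry()
  scale <- wall_distance / 0.55
  wall_h <- 1.1 * scale
  px <- .base_px_m * scale
  apo_w <- geo$apothem + wall_distance
  r_w <- apo_w / cos(pi / 10)
  ang <- pi / 2 - (0:10) * (2 * pi / 10)
  wv <- cbind(r_w * cos(ang), r_w * sin(ang))
  panels <- list()
  for (j in 1:10) {
    a <- wv[j, ]; b <- wv[j + 1, ]
    side_len <- sqrt(sum((b - a)^2))
    tex <- cloud_texture(c(128, max(64, round(side_len / px))),
                         c(wall_h, side_len), i_mean, texture_contrast,
                         seed = seed * 131 + 20 + j)
    panels[[j]] <- make_panel(
      p0 = c(a[1], a[2], -wall_h / 2),
      u = c(b[1] - a[1], b[2] - a[2], 0), v = c(0, 0, wall_h),
      texture = tex$luminance, name = sprintf("wall%d", j))
  }
  j <- bar_side + 1L
  a <- geo$verts[j, ]; b <- geo$verts[j + 1, ]
  h <- (b - a) / sqrt(sum((b - a)^2))     # heading along the side
  n_out <- c(-h[2], h[1])                  # left of heading = outward (CW path)
  m <- (a + b) / 2 + 0.5 * n_out
  bt <- cloud_texture(c(128, 64), c(1, 0.05), i_mean, texture_contrast,
                      seed = seed * 131 + 2)
  panels[[length(panels) + 1L]] <- make_panel(
    p0 = c(m[1] - 0.025 * h[1], m[2] - 0.025 * h[2], -0.5),
    u = c(0.05 * h[1], 0.05 * h[2], 0), v = c(0, 0, 1),
    texture = bt$luminance, name = "bar")
  new_scene(panels, background = i_mean,
            bar_centers = list(c(m[1], m[2], 0)),
            meta = list(kind = "decagon", wall_distance = wall_distance,
                        seed = seed, bar_side = bar_side, i_mean = i_mean,
                        texture_contrast = texture_contrast))
}

# --- trajectories -----------------------------------------------------------

new_trajectory <- function(df, dt, saccade_times = numeric(0)) {
  stopifnot(all(diff(df$time) > 0))
  structure(df, class = c("trajectory3d", "data.frame"), dt = dt,
            saccade_times = saccade_times)
}

#' Straight constant-speed translation
#'
#' @param duration flight duration, seconds (8 s covers the eight bar
#'   passages at 1 m/s).
#' @param speed flight speed, m/s.
#' @param dt pose sampling interval, seconds (0.01 = 100 Hz frames).
#' @return a `trajectory3d` data frame with columns `time, x, y, z, yaw`
#'   (yaw in radians; roll and pitch are identically zero).
#' @export
translation_trajectory <- function(duration = 8, speed = 1, dt = 0.01) {
  t <- seq(0, duration, by = dt)
  new_trajectory(data.frame(time = t, x = speed * t, y = 0, z = 0, yaw = 0),
                 dt = dt)
}

#' Saccadic yaw-velocity profile
#'
#' The 20-ms saccade: discrete Gaussian weights
#' `G(t) = exp(-((t - tc) / sigma)^2 / 2)` evaluated at t = 1..20 ms with
#' tc = 10.5 ms and sigma = 3.5 ms, normalised so that the integrated turn is
#' exactly 36 degrees.  Velocity is piecewise constant within each
#' millisecond, so `dt` must divide 1 ms.
#'
#' @param dt sample interval, seconds.
#' @return data frame with `time` (seconds, end of each step) and `v_yaw`
#'   (rad/s); attribute `"turn_rad"` holds the exact total turn.
#' @export
saccade_yaw_profile <- function(dt = 0.001) {
  sub <- 0.001 / dt
  if (abs(sub - round(sub)) > 1e-9) stop("dt must divide 1 ms")
  tms <- 1:20
  g <- exp(-0.5 * ((tms - 10.5) / 3.5)^2)
  d_ms <- (36 * pi / 180) * g / sum(g) # rad turned within each millisecond
  v_ms <- d_ms / 0.001                 # rad/s, constant within the ms
  v <- rep(v_ms, each = round(sub))
  structure(data.frame(time = seq(dt, 0.020, by = dt), v_yaw = v),
            turn_rad = 36 * pi / 180)
}

# cumulative turn angle (rad) tau seconds into a saccade
saccade_turn_at <- function(tau) {
  g <- exp(-0.5 * ((1:20 - 10.5) / 3.5)^2)
  cum <- c(0, cumsum((36 * pi / 180) * g / sum(g)))
  approx(seq(0, 0.020, by = 0.001), cum, xout = pmin(pmax(tau, 0), 0.020),
         rule = 2)$y
}

#' Semi-natural saccadic trajectory around a decagon
#'
#' Each second of straight 1 m flight is bent into one cycle of a decagon:
#' ten 80-ms pure translations along the 0.1 m sides (at 1.25 m/s, conserving
#' total path length) alternating with 20-ms pure rotations of 36 degrees
#' ([saccade_yaw_profile()]) at the corners.  Ten saccades per second; total
#' length and duration match the straight trajectory.  Roll and pitch stay
#' zero; the path is traversed clockwise so the arena lies to the left.
#'
#' @param cycles number of 1-s decagon cycles (8).
#' @param dt pose sampling interval, seconds.
#' @return a `trajectory3d`; attribute `"saccade_times"` holds the 10*cycles
#'   saccade onset times.
#' @export
decagon_trajectory <- function(cycles = 8, dt = 0.01) {
  geo <- decagon_geometry()
  verts <- geo$verts
  head2 <- t(vapply(1:10, function(j) {
    h <- verts[j + 1, ] - verts[j, ]
    h / sqrt(sum(h^2))
  }, numeric(2)))
  yaw0 <- atan2(head2[1, 2], head2[1, 1])
  speed <- 0.1 / 0.08
  t <- seq(0, cycles, by = dt)
  s <- pmin(floor(t / 0.1 + 1e-9), 10 * cycles - 1)
  j <- s %% 10 + 1
  t_loc <- t - s * 0.1
  translating <- t_loc < 0.08 - 1e-9
  x <- y <- yaw <- numeric(length(t))
  for (i in seq_along(t)) {
    if (translating[i]) {
      p <- verts[j[i], ] + head2[j[i], ] * speed * t_loc[i]
      x[i] <- p[1]; y[i] <- p[2]
      yaw[i] <- yaw0 - s[i] * (2 * pi / 10)
    } else {
      x[i] <- verts[j[i] + 1, 1]; y[i] <- verts[j[i] + 1, 2]
      yaw[i] <- yaw0 - s[i] * (2 * pi / 10) - saccade_turn_at(t_loc[i] - 0.08)
    }
  }
  sacc <- as.vector(outer(0.08 + (0:9) * 0.1, 0:(cycles - 1), "+"))
  new_trajectory(data.frame(time = t, x = x, y = y, z = 0, yaw = yaw),
                 dt = dt, saccade_times = sort(sacc))
}

#' Bar-passage times along a trajectory
#'
#' Finds, for every bar in the scene, the times at which the agent's
#' distance to the bar is locally minimal (i.e. the bar passes the lateral
#' visual field).  Minima closer together than `min_gap` are merged, keeping
#' the closest approach.
#'
#' @param scene a `scene3d` with `bar_centers`.
#' @param trajectory a `trajectory3d`.
#' @param min_gap minimal separation between passages, seconds.
#' @return sorted vector of passage times (seconds).
#' @export
bar_crossings <- function(scene, trajectory, min_gap = 0.3) {
  out <- numeric(0)
  w <- max(1L, round(min_gap / attr(trajectory, "dt") / 2))
  for (b in scene$bar_centers) {
    d <- sqrt((trajectory$x - b[1])^2 + (trajectory$y - b[2])^2)
    n <- length(d)
    is_min <- vapply(seq_len(n), function(i) {
      lo <- max(1L, i - w); hi <- min(n, i + w)
      d[i] <= min(d[lo:hi]) && (d[i] < d[lo] || d[i] < d[hi])
    }, logical(1))
    idx <- which(is_min)
    if (!length(idx)) next
    grp <- cumsum(c(1, diff(idx) > w))
    for (g in unique(grp)) {
      ii <- idx[grp == g]
      out <- c(out, trajectory$time[ii[which.min(d[ii])]])
    }
  }
  sort(out)
}
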