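#' Ray-cast a scene onto the spherical eye along a trajectory
#'
#' For every pose of the trajectory and every viewing direction of the eye
#' grid, a ray is cast from the eye position along the yaw-rotated direction;
#' the pixel takes the texture value (nearest-neighbour lookup) of the
#' nearest intersected panel, or the background luminance if no panel is
#' hit.  The eye sits at the vertical midline of bars and walls (z = 0).
#'
#' Rendering runs at the trajectory's sampling rate (100 Hz by default);
#' [run_pathway()] linearly interpolates the frames onto its 1-ms grid.
#'
#' @param scene a `scene3d` ([corridor_scene()], [decagon_scene()]).
#' @param trajectory a `trajectory3d`.
#' @param eye an [eye_model()].
#' @param prelude seconds of stationary prelude: the first pose is held this
#'   long before motion starts, letting onset transients of the pathway die
#'   out.  Event times (e.g. [bar_crossings()]) shift by the same amount.
#' @param supersample sub-rays per ommatidium and axis: each eye pixel is
#'   the box average of `supersample^2` rays covering its angular cell.
#'   This emulates the spatial acceptance of an ommatidium; with pure point
#'   sampling (`supersample = 1`), texture detail finer than the eye's
#'   resolution aliases into strong spurious motion-detector input.
#' @return a [luminance_seq()] with `dt` equal to the trajectory sampling
#'   interval; attribute `"prelude"` carries the prelude duration.
#' @export
render_eye_sequence <- function(scene, trajectory, eye = eye_model(),
                                prelude = 0, supersample = 2) {
  stopifnot(inherits(scene, "scene3d"), inherits(trajectory, "trajectory3d"),
            inherits(eye, "eye_model"))
  dt <- attr(trajectory, "dt")
  ss <- as.integer(supersample)
  stopifnot(ss >= 1)
  sub <- (seq_len(ss) - (ss + 1) / 2) / ss # cell-centred sub-offsets
  el <- (rep(eye$elevation, each = ss) +
           rep(sub * eye$spacing, length(eye$elevation))) * pi / 180
  az <- (rep(eye$azimuth, each = ss) +
           rep(sub * eye$spacing, length(eye$azimuth))) * pi / 180
  nel <- length(el); naz <- length(az)
  ce <- cos(el); se <- sin(el)
  dirz <- matrix(se, nel, naz)
  # block-averaging operators collapsing the sub-ray grid to the eye grid
  kr <- matrix(0, length(eye$elevation), nel)
  kr[cbind(rep(seq_along(eye$elevation), each = ss), seq_len(nel))] <- 1 / ss
  kc <- matrix(0, naz, length(eye$azimuth))
  kc[cbind(seq_len(naz), rep(seq_along(eye$azimuth), each = ss))] <- 1 / ss

  n_pre <- round(prelude / dt)
  nfr <- nrow(trajectory)
  frames <- array(0, c(n_pre + nfr, length(eye$elevation),
                       length(eye$azimuth)))

  for (i in seq_len(nfr)) {
    pos <- c(trajectory$x[i], trajectory$y[i], trajectory$z[i])
    azw <- trajectory$yaw[i] + az
    dirx <- outer(ce, cos(azw))
    diry <- outer(ce, sin(azw))
    tmin <- matrix(Inf, nel, naz)
    lum <- matrix(scene$background, nel, naz)
    for (p in scene$panels) {
      num <- sum((p$p0 - pos) * p$n)
      lu2 <- sum(p$u^2); lv2 <- sum(p$v^2)
      if (abs(num) < 1e-9) {
        # eye lies in the panel's plane; inside the rectangle is an error
        rel <- pos - p$p0
        su0 <- sum(rel * p$u) / lu2; sv0 <- sum(rel * p$v) / lv2
        if (su0 > 0 && su0 < 1 && sv0 > 0 && sv0 < 1) {
          stop("eye position lies inside panel ", p$name)
        }
        next
      }
      dn <- dirx * p$n[1] + diry * p$n[2] + dirz * p$n[3]
      tt <- num / dn
      better <- is.finite(tt) & tt > 1e-9 & tt < tmin
      if (!any(better)) next
      du <- dirx * p$u[1] + diry * p$u[2] + dirz * p$u[3]
      dv <- dirx * p$v[1] + diry * p$v[2] + dirz * p$v[3]
      cu <- sum((pos - p$p0) * p$u)
      cv <- sum((pos - p$p0) * p$v)
      su <- (cu + tt * du) / lu2
      sv <- (cv + tt * dv) / lv2
      hit <- better & su >= 0 & su < 1 & sv >= 0 & sv < 1
      if (!any(hit)) next
      tex <- p$texture
      ri <- floor(sv[hit] * nrow(tex)) + 1
      ci <- floor(su[hit] * ncol(tex)) + 1
      lum[hit] <- tex[cbind(ri, ci)]
      tmin[hit] <- tt[hit]
    }
    frames[n_pre + i, , ] <- if (ss > 1) kr %*% lum %*% kc else lum
  }
  if (n_pre > 0) {
    for (k in seq_len(n_pre)) frames[k, , ] <- frames[n_pre + 1, , ]
  }
  out <- luminance_seq(frames, dt = dt,
                       azimuth_wrap = abs(diff(range(eye$azimuth)) - 360 +
                                            eye$spacing) < 1e-9)
  attr(out, "prelude") <- n_pre * dt
  out
}
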