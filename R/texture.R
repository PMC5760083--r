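#' Random cloud texture with 1/f^2 power spectrum
#'
#' Spectral synthesis of the natural-image-like textures used on walls and
#' bars: a white-noise field is filtered in the Fourier domain with an
#' amplitude proportional to 1/f (so power falls as 1/f^2 with spatial
#' frequency f), the DC component is set to the mean luminance and the
#' fluctuation is scaled to the requested rms contrast.  Negative pixels --
#' rare at realistic contrasts -- are clipped at zero; if more than 1% of
#' pixels would clip, the contrast is rejected.
#'
#' @param shape `c(rows, cols)` in pixels, each >= 64.
#' @param world_size `c(height, width)` of the patch in metres (scalar for a
#'   square patch).
#' @param i_mean mean luminance, a.u.
#' @param contrast rms contrast (sd of luminance / mean luminance).
#' @param seed integer seed; the same seed gives a bit-identical texture.
#' @return an object of class `cloud_texture` with fields `luminance`
#'   (rows x cols matrix), `world_size`, `i_mean`, `contrast`, `seed`.
#' @examples
#' tx <- cloud_texture(c(64, 64), world_size = 1, seed = 1)
#' abs(mean(tx$luminance) / tx$i_mean - 1) < 0.01
#' @export
cloud_texture <- function(shape, world_size, i_mean = 1000, contrast = 0.3,
                          seed = 1) {
  shape <- as.integer(rep(shape, length.out = 2))
  if (any(shape < 64)) stop("texture shape must be at least 64 x 64")
  world_size <- rep(world_size, length.out = 2)
  nr <- shape[1]; nc <- shape[2]
  z <- with_seed(seed, matrix(rnorm(nr * nc), nr, nc))
  # physical spatial frequency (cycles/m): pixels need not be square
  f <- sqrt(outer((fft_freq(nr) * nr / world_size[1])^2,
                  (fft_freq(nc) * nc / world_size[2])^2, "+"))
  amp <- 1 / f
  amp[1, 1] <- 0 # DC handled separately
  x <- Re(fft(fft(z) * amp, inverse = TRUE)) / (nr * nc)
  x <- x * (contrast * i_mean / sd(as.vector(x))) + i_mean
  frac_neg <- mean(x < 0)
  if (frac_neg > 0.01) {
    stop(sprintf("contrast %.3g would clip %.2f%% of pixels (> 1%%)",
                 contrast, 100 * frac_neg))
  }
  x[x < 0] <- 0
  structure(list(luminance = x, world_size = world_size, i_mean = i_mean,
                 contrast = contrast, seed = seed),
            class = "cloud_texture")
}

#' @export
print.cloud_texture <- function(x, ...) {
  cat(sprintf(
    "<cloud_texture> %d x %d px covering %.3g x %.3g m, I_mean = %g, rms contrast = %g, seed = %d\n",
    nrow(x$luminance), ncol(x$luminance), x$world_size[1], x$world_size[2],
    x$i_mean, x$contrast, x$seed))
  invisible(x)
}

# DFT sample frequencies in cycles/pixel (like numpy's fftfreq)
fft_freq <- function(n) {
  c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[seq_len(n)] / n
}

#' Radially averaged log-log power-spectrum slope
#'
#' Diagnostic for the 1/f^2 construction: azimuthally averages the 2D power
#' spectrum into log-spaced frequency rings and fits a straight line to
#' log(power) against log(frequency).  A 1/f^2 texture has slope ~ -2.
#'
#' @param x a matrix or a [cloud_texture()].
#' @param f_range frequency range (cycles/pixel) used for the fit.
#' @return the fitted slope.
#' @export
spectral_slope <- function(x, f_range = c(0.01, 0.35)) {
  if (inherits(x, "cloud_texture")) x <- x$luminance
  x <- x - mean(x)
  p <- Mod(fft(x))^2
  f <- sqrt(outer(fft_freq(nrow(x))^2, fft_freq(ncol(x))^2, "+"))
  keep <- f >= f_range[1] & f <= f_range[2]
  bins <- cut(log(f[keep]), breaks = 24)
  lf <- tapply(log(f[keep]), bins, mean)
  lp <- log(tapply(p[keep], bins, mean))
  ok <- is.finite(lf) & is.finite(lp)
  unname(coef(lm(lp[ok] ~ lf[ok]))[2])
}
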