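# Fourier-space blur/sharpen: every structure factor is scaled by
# exp(-B s^2 / 4) with s = |(h/a, k/b, l/c)| in 1/A, the crystallographic
# temperature-factor convention (so a blurred point source has real-space
# sigma^2 = B / (8 pi^2)). Optional finer-grid resampling zero-pads in
# reciprocal space (band-limited interpolation).

# reciprocal-frequency index along one axis: 0, 1, ..., n/2, -(n/2-1), ..., -1
freq_index <- function(n) {
  h <- seq_len(n) - 1
  h[h > n / 2] <- h[h > n / 2] - n
  h
}

# s^2 array (1/A^2) for a grid of dims d in a cell
s_squared_grid <- function(d, cell) {
  hx <- (freq_index(d[1]) / cell[1])^2
  hy <- (freq_index(d[2]) / cell[2])^2
  hz <- (freq_index(d[3]) / cell[3])^2
  outer(outer(hx, hy, `+`), hz, `+`)
}

# zero-pad a centred (fftshift-free) spectrum F (dims d) into dims d2 >= d
pad_spectrum <- function(F, d2) {
  d <- dim(F)
  out <- array(0 + 0i, dim = d2)
  src <- lapply(d, function(n) {
    h <- freq_index(n)
    h
  })
  # destination index for frequency h in an axis of length n2
  for_axis <- function(h, n2) ifelse(h >= 0, h + 1, n2 + h + 1)
  ix <- for_axis(src[[1]], d2[1])
  iy <- for_axis(src[[2]], d2[2])
  iz <- for_axis(src[[3]], d2[3])
  out[ix, iy, iz] <- F
  out
}

#' Blur or sharpen a density map
#'
#' Positive `B` blurs, negative sharpens; the mean (s = 0 term) is always
#' preserved. `resample_factor > 1` additionally resamples the map on a
#' finer grid over the same box by reciprocal-space zero-padding.
#'
#' @param m A `density_map`.
#' @param B blurring temperature factor in A^2.
#' @param resample_factor grid refinement factor (>= 1).
#' @return A `density_map` on the same box.
#' @export
sharpen_blur <- function(m, B, resample_factor = 1) {
  if (!is.finite(B)) stop("B must be finite")
  if (resample_factor < 1) stop("resample_factor must be >= 1")
  d <- dim(m$grid)
  F <- stats::fft(m$grid)
  F <- F * exp(-B * s_squared_grid(d, m$cell) / 4)
  if (resample_factor > 1) {
    d2 <- round(d * resample_factor)
    F <- pad_spectrum(F, d2)
    scale <- prod(d2) / prod(d)
    g <- Re(stats::fft(F, inverse = TRUE)) / prod(d2) * scale
  } else {
    g <- Re(stats::fft(F, inverse = TRUE)) / prod(d)
  }
  density_map(g, cell = m$cell, origin = m$origin)
}

#' Generate several sharpened/blurred maps from one transform
#'
#' @param m A `density_map`.
#' @param B_list numeric vector of temperature factors (A^2).
#' @return List of `density_map`s, one per entry of `B_list`.
#' @export
multi_sharpen <- function(m, B_list) {
  if (!length(B_list)) stop("B_list must be non-empty")
  d <- dim(m$grid)
  F <- stats::fft(m$grid)
  s2 <- s_squared_grid(d, m$cell)
  lapply(B_list, function(B) {
    if (!is.finite(B)) stop("B must be finite")
    g <- Re(stats::fft(F * exp(-B * s2 / 4), inverse = TRUE)) / prod(d)
    density_map(g, cell = m$cell, origin = m$origin)
  })
}
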