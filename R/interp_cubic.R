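# Tricubic (Catmull-Rom) map interpolation for the refinement target. The
# trilinear interpolant is piecewise linear, so its local maxima sit on grid
# nodes and gradient refinement pins atoms to the grid; the C1 cubic kernel
# removes that bias. Values outside the grid evaluate to 0.

catmull_rom_w <- function(t) {
  cbind(w0 = -0.5 * t + t^2 - 0.5 * t^3,
        w1 = 1 - 2.5 * t^2 + 1.5 * t^3,
        w2 = 0.5 * t + 2 * t^2 - 1.5 * t^3,
        w3 = -0.5 * t^2 + 0.5 * t^3)
}

catmull_rom_dw <- function(t) {
  cbind(w0 = -0.5 + 2 * t - 1.5 * t^2,
        w1 = -5 * t + 4.5 * t^2,
        w2 = 0.5 + 4 * t - 4.5 * t^2,
        w3 = -t + 1.5 * t^2)
}

# cubic interpolation + gradient; returns list(value, gradient n x 3)
interpolate_density_cubic <- function(m, p, gradient = TRUE) {
  p <- if (is.null(dim(p))) matrix(p, ncol = 3) else as.matrix(p)
  d <- dim(m$grid)
  np <- nrow(p)
  fx <- (p[, 1] - m$origin[1]) / m$spacing[1] + 1
  fy <- (p[, 2] - m$origin[2]) / m$spacing[2] + 1
  fz <- (p[, 3] - m$origin[3]) / m$spacing[3] + 1
  oob <- fx < 1 | fy < 1 | fz < 1 | fx > d[1] | fy > d[2] | fz > d[3]
  val <- numeric(np)
  grad <- matrix(0, np, 3)
  ok <- which(!oob)
  if (length(ok)) {
    x0 <- pmin(pmax(floor(fx[ok]), 1), d[1] - 1); tx <- fx[ok] - x0
    y0 <- pmin(pmax(floor(fy[ok]), 1), d[2] - 1); ty <- fy[ok] - y0
    z0 <- pmin(pmax(floor(fz[ok]), 1), d[3] - 1); tz <- fz[ok] - z0
    wx <- catmull_rom_w(tx); wy <- catmull_rom_w(ty); wz <- catmull_rom_w(tz)
    if (gradient) {
      dwx <- catmull_rom_dw(tx); dwy <- catmull_rom_dw(ty)
      dwz <- catmull_rom_dw(tz)
    }
    g <- m$grid
    nok <- length(ok)
    v <- numeric(nok); gx <- numeric(nok); gy <- numeric(nok)
    gz <- numeric(nok)
    for (a in 0:3) {
      ia <- x0 + a - 1
      inx <- ia >= 1 & ia <= d[1]
      for (b in 0:3) {
        ib <- y0 + b - 1
        iny <- inx & ib >= 1 & ib <= d[2]
        for (cc in 0:3) {
          ic <- z0 + cc - 1
          use <- iny & ic >= 1 & ic <= d[3]
          if (!any(use)) next
          gv <- numeric(nok)
          gv[use] <- g[cbind(ia[use], ib[use], ic[use])]
          v <- v + gv * wx[, a + 1] * wy[, b + 1] * wz[, cc + 1]
          if (gradient) {
            gx <- gx + gv * dwx[, a + 1] * wy[, b + 1] * wz[, cc + 1]
            gy <- gy + gv * wx[, a + 1] * dwy[, b + 1] * wz[, cc + 1]
            gz <- gz + gv * wx[, a + 1] * wy[, b + 1] * dwz[, cc + 1]
          }
        }
      }
    }
    val[ok] <- v
    if (gradient)
      grad[ok, ] <- cbind(gx / m$spacing[1], gy / m$spacing[2],
                          gz / m$spacing[3])
  }
  list(value = val, gradient = grad)
}
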