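# Density maps on orthogonal grids: MRC/CCP4 (mode 2) I/O, trilinear
# interpolation with gradients, atom-density scoring, and blob navigation.
# Grid values are stored in an nx x ny x nz array, x fastest (MRC layout);
# node (i,j,k) sits at origin + ((i,j,k) - 1) * spacing.

#' Create a density map object
#'
#' @param grid 3D numeric array of density values (x index fastest).
#' @param cell sampled box lengths (a, b, c) in Angstroms (orthogonal axes);
#'   defaults to `dim(grid) * spacing` when `spacing` is given.
#' @param origin position of grid node (1,1,1) in Angstroms.
#' @param spacing voxel size per axis; derived from cell when omitted.
#' @return An object of class `density_map`.
#' @export
density_map <- function(grid, cell = NULL, origin = c(0, 0, 0),
                        spacing = NULL) {
  grid <- as.array(grid)
  if (length(dim(grid)) != 3 || any(dim(grid) < 2))
    stop("grid must be a 3D array with at least 2 nodes per axis")
  if (!all(is.finite(grid))) stop("grid contains non-finite values")
  if (is.null(cell)) {
    if (is.null(spacing)) stop("give either cell or spacing")
    cell <- dim(grid) * spacing
  }
  cell <- as.numeric(cell)
  spacing <- cell / dim(grid)
  if (any(spacing <= 0)) stop("spacing must be positive")
  structure(list(grid = grid, cell = cell, origin = as.numeric(origin),
                 spacing = spacing),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf(
    "<density_map> %d x %d x %d grid, spacing %.3f x %.3f x %.3f A\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.2f, %.2f, %.2f) A; range [%.4g, %.4g], mean %.4g\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$grid), max(x$grid), mean(x$grid)))
  invisible(x)
}

#' Read an MRC/CCP4 map (mode 2)
#'
#' Only orthogonal cells (all angles 90 degrees) are supported.
#'
#' @param path MRC file path.
#' @return A `density_map`.
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop("no such map file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  ints <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- ints[1]; ny <- ints[2]; nz <- ints[3]; mode <- ints[4]
  mxyz <- ints[8:10]
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  cellb <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  mapcrs <- readBin(con, "integer", n = 3, size = 4, endian = "little")
  if (mode != 2)
    stop("unsupported MRC mode ", mode, " (only mode 2, 32-bit float)")
  if (nx <= 0 || ny <= 0 || nz <= 0 || nx * ny * nz > 1e9)
    stop("format error: corrupt MRC header (bad dimensions)")
  if (any(abs(cellb - 90) > 1e-3))
    stop("unsupported cell: non-orthogonal angles (",
         paste(sprintf("%.1f", cellb), collapse = ", "),
         "); only orthogonal maps are handled")
  if (!all(mapcrs == c(1, 2, 3)))
    stop("unsupported axis order (MAPC,MAPR,MAPS must be 1,2,3)")
  seek(con, 4 * 22)
  readBin(con, "numeric", n = 3, size = 4, endian = "little") # dmin/dmax/dmean
  ispg <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  nsymbt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  seek(con, 4 * 49)
  origin <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  maptag <- readChar(con, 4, useBytes = TRUE)
  if (!identical(substr(maptag, 1, 3), "MAP"))
    stop("format error: missing MAP stamp in MRC header")
  seek(con, 1024 + nsymbt)
  vals <- readBin(con, "numeric", n = nx * ny * nz, size = 4,
                  endian = "little")
  if (length(vals) != nx * ny * nz)
    stop("format error: truncated MRC data section")
  spacing <- cella / mxyz
  density_map(array(vals, dim = c(nx, ny, nz)),
              cell = spacing * c(nx, ny, nz), origin = origin)
}

#' Write an MRC/CCP4 map (mode 2)
#'
#' @param m A `density_map`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_map <- function(m, path) {
  d <- dim(m$grid)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d); wi(2)                 # NX NY NZ, MODE
  wi(c(0, 0, 0)); wi(d)        # NxSTART, Mx
  wf(m$cell); wf(c(90, 90, 90))
  wi(c(1, 2, 3))
  wf(c(min(m$grid), max(m$grid), mean(m$grid)))
  wi(1); wi(0)                 # ISPG, NSYMBT
  wi(rep(0L, 25))              # EXTRA (words 25-49)
  wf(m$origin)                 # ORIGIN (words 50-52)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  wi(16708L)                   # MACHST little-endian stamp 0x44 0x41 0 0
  wf(stats::sd(as.numeric(m$grid)))
  wi(0L)                       # NLABL
  wi(rep(0L, 200))             # labels
  writeBin(as.numeric(m$grid), con, size = 4, endian = "little")
  invisible(path)
}

#' Trilinear interpolation of map density
#'
#' Points outside the grid return 0; the result carries an `out_of_bounds`
#' attribute (logical vector).
#'
#' @param m A `density_map`.
#' @param p a length-3 position or an n x 3 matrix of positions (A).
#' @return Numeric vector of interpolated densities.
#' @export
interpolate_density <- function(m, p) {
  p <- if (is.null(dim(p))) matrix(p, ncol = 3) else as.matrix(p)
  d <- dim(m$grid)
  # fractional grid coordinate (1-based)
  fx <- (p[, 1] - m$origin[1]) / m$spacing[1] + 1
  fy <- (p[, 2] - m$origin[2]) / m$spacing[2] + 1
  fz <- (p[, 3] - m$origin[3]) / m$spacing[3] + 1
  oob <- fx < 1 | fy < 1 | fz < 1 | fx > d[1] | fy > d[2] | fz > d[3]
  out <- numeric(nrow(p))
  ok <- which(!oob)
  if (length(ok)) {
    x0 <- pmin(floor(fx[ok]), d[1] - 1); tx <- fx[ok] - x0
    y0 <- pmin(floor(fy[ok]), d[2] - 1); ty <- fy[ok] - y0
    z0 <- pmin(floor(fz[ok]), d[3] - 1); tz <- fz[ok] - z0
    g <- m$grid
    idx <- function(i, j, k) g[cbind(i, j, k)]
    out[ok] <-
      idx(x0,     y0,     z0)     * (1 - tx) * (1 - ty) * (1 - tz) +
      idx(x0 + 1, y0,     z0)     * tx       * (1 - ty) * (1 - tz) +
      idx(x0,     y0 + 1, z0)     * (1 - tx) * ty       * (1 - tz) +
      idx(x0,     y0,     z0 + 1) * (1 - tx) * (1 - ty) * tz +
      idx(x0 + 1, y0 + 1, z0)     * tx       * ty       * (1 - tz) +
      idx(x0 + 1, y0,     z0 + 1) * tx       * (1 - ty) * tz +
      idx(x0,     y0 + 1, z0 + 1) * (1 - tx) * ty       * tz +
      idx(x0 + 1, y0 + 1, z0 + 1) * tx       * ty       * tz
  }
  attr(out, "out_of_bounds") <- oob
  out
}

# Gradient of the trilinear interpolant at each point: n x 3 matrix
# (zero outside the grid, matching the zero density contribution there).
interpolate_density_gradient <- function(m, p) {
  p <- if (is.null(dim(p))) matrix(p, ncol = 3) else as.matrix(p)
  d <- dim(m$grid)
  fx <- (p[, 1] - m$origin[1]) / m$spacing[1] + 1
  fy <- (p[, 2] - m$origin[2]) / m$spacing[2] + 1
  fz <- (p[, 3] - m$origin[3]) / m$spacing[3] + 1
  oob <- fx < 1 | fy < 1 | fz < 1 | fx > d[1] | fy > d[2] | fz > d[3]
  grad <- matrix(0, nrow(p), 3)
  ok <- which(!oob)
  if (length(ok)) {
    x0 <- pmin(floor(fx[ok]), d[1] - 1); tx <- fx[ok] - x0
    y0 <- pmin(floor(fy[ok]), d[2] - 1); ty <- fy[ok] - y0
    z0 <- pmin(floor(fz[ok]), d[3] - 1); tz <- fz[ok] - z0
    g <- m$grid
    v000 <- g[cbind(x0,     y0,     z0)]
    v100 <- g[cbind(x0 + 1, y0,     z0)]
    v010 <- g[cbind(x0,     y0 + 1, z0)]
    v001 <- g[cbind(x0,     y0,     z0 + 1)]
    v110 <- g[cbind(x0 + 1, y0 + 1, z0)]
    v101 <- g[cbind(x0 + 1, y0,     z0 + 1)]
    v011 <- g[cbind(x0,     y0 + 1, z0 + 1)]
    v111 <- g[cbind(x0 + 1, y0 + 1, z0 + 1)]
    dx <- (v100 - v000) * (1 - ty) * (1 - tz) + (v110 - v010) * ty * (1 - tz) +
      (v101 - v001) * (1 - ty) * tz + (v111 - v011) * ty * tz
    dy <- (v010 - v000) * (1 - tx) * (1 - tz) + (v110 - v100) * tx * (1 - tz) +
      (v011 - v001) * (1 - tx) * tz + (v111 - v101) * tx * tz
    dz <- (v001 - v000) * (1 - tx) * (1 - ty) + (v101 - v100) * tx * (1 - ty) +
      (v011 - v010) * (1 - tx) * ty + (v111 - v110) * tx * ty
    grad[ok, ] <- cbind(dx / m$spacing[1], dy / m$spacing[2],
                        dz / m$spacing[3])
  }
  grad
}

#' Atom-density fit score
#'
#' Sum over atoms of occupancy x atomic number x interpolated density
#' (higher is better). Atoms outside the map contribute zero.
#'
#' @param m A `density_map`.
#' @param atoms atoms data.frame (element, x, y, z, occ) or `rs_structure`.
#' @return Single numeric score.
#' @export
density_fit_score <- function(m, atoms) {
  if (inherits(atoms, "rs_structure")) atoms <- atoms$atoms
  if (!nrow(atoms)) stop("empty atom list")
  w <- atoms$occ * atomic_number(atoms$element)
  sum(w * interpolate_density(m, as.matrix(atoms[, c("x", "y", "z")])))
}

#' Find the first density blob along a segment
#'
#' Walks from `p_front` toward `p_back` in steps, recording a density profile
#' from the first sample above `contour` until a sample drops below it (or
#' the segment ends); returns the density-weighted mean position of that
#' profile. A front point already above contour starts a profile immediately.
#'
#' @param m A `density_map`.
#' @param p_front,p_back segment end points (A).
#' @param contour density threshold.
#' @param step step length in Angstroms (default: half the minimum grid
#'   spacing).
#' @return list(centre=, peak=, extent=) or NULL when no sample exceeds the
#'   contour.
#' @export
find_blob_along_segment <- function(m, p_front, p_back, contour,
                                    step = NULL) {
  p_front <- as.numeric(p_front); p_back <- as.numeric(p_back)
  seg <- p_back - p_front
  len <- vnorm(seg)
  if (len < 1e-9) stop("p_front and p_back coincide")
  if (is.null(step)) step <- min(m$spacing) / 2
  if (step <= 0) stop("step must be positive")
  ts <- seq(0, len, by = step)
  pts <- sweep(outer(ts, unitv(seg)), 2, p_front, `+`)  # n x 3
  rho <- interpolate_density(m, pts)
  above <- rho > contour
  if (!any(above)) return(NULL)
  first <- which(above)[1]
  run_end <- first
  while (run_end < length(ts) && above[run_end + 1]) run_end <- run_end + 1
  sel <- first:run_end
  w <- rho[sel]
  centre <- colSums(pts[sel, , drop = FALSE] * w) / sum(w)
  list(centre = centre, peak = max(w),
       extent = ts[run_end] - ts[first])
}
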