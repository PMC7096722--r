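# Synthetic density maps: each atom contributes a single Gaussian with
# amplitude occ * Z and width sigma^2 = B / (8 pi^2) (the blur-factor
# convention, so map-space and model-space B values compose). A one-Gaussian
# atom is a deliberate simplification of multi-Gaussian scattering factors;
# it gives closed-form checks for the Fourier operations.

#' Synthesize a Gaussian-atom density map from a model
#'
#' @param s `rs_structure` (or atoms data.frame).
#' @param spacing voxel size in A (default 0.8).
#' @param padding box padding around the model in A (default 5).
#' @param atom_b Gaussian atom temperature factor in A^2 (default 40,
#'   roughly a 3 A-resolution appearance).
#' @param origin optional fixed origin; otherwise bounding box - padding.
#' @param dims optional fixed grid dimensions.
#' @return A `density_map`.
#' @export
synthesize_map <- function(s, spacing = 0.8, padding = 5, atom_b = 40,
                           origin = NULL, dims = NULL) {
  atoms <- if (inherits(s, "rs_structure")) s$atoms else as.data.frame(s)
  if (!nrow(atoms)) stop("cannot synthesize a map from an empty model")
  if (atom_b <= 0) stop("atom_b must be positive")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (is.null(origin)) origin <- apply(xyz, 2, min) - padding
  if (is.null(dims))
    dims <- pmax(2L, as.integer(ceiling((apply(xyz, 2, max) + padding -
                                           origin) / spacing)) + 1L)
  sigma2 <- atom_b / (8 * pi^2)
  cutoff <- 4.5 * sqrt(sigma2)
  w <- atoms$occ * atomic_number(atoms$element)
  grid <- array(0, dim = dims)
  ax <- origin[1] + (seq_len(dims[1]) - 1) * spacing
  ay <- origin[2] + (seq_len(dims[2]) - 1) * spacing
  az <- origin[3] + (seq_len(dims[3]) - 1) * spacing
  for (i in seq_len(nrow(xyz))) {
    p <- xyz[i, ]
    ix <- which(abs(ax - p[1]) <= cutoff)
    iy <- which(abs(ay - p[2]) <= cutoff)
    iz <- which(abs(az - p[3]) <= cutoff)
    if (!length(ix) || !length(iy) || !length(iz)) next
    ex <- exp(-(ax[ix] - p[1])^2 / (2 * sigma2))
    ey <- exp(-(ay[iy] - p[2])^2 / (2 * sigma2))
    ez <- exp(-(az[iz] - p[3])^2 / (2 * sigma2))
    grid[ix, iy, iz] <- grid[ix, iy, iz] +
      w[i] * outer(outer(ex, ey), ez)
  }
  density_map(grid, cell = dims * spacing, origin = origin)
}
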