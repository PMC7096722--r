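# Small 3D vector/rotation toolkit. Positions are length-3 numeric vectors or
# n x 3 matrices throughout the package; angles are degrees at the API surface.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Angle subtended at `b` by `a` and `c`
#'
#' @param a,b,c Cartesian positions (length-3 numeric).
#' @return Angle in degrees in \[0, 180\].
#' @export
bond_angle <- function(a, b, c) {
  u <- unitv(a - b)
  v <- unitv(c - b)
  rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

#' Torsion angle of four points
#'
#' Standard IUPAC convention: looking down b2->b3, the angle from the plane
#' (b1,b2,b3) to (b2,b3,b4); cis = 0, range (-180, 180].
#'
#' @param p1,p2,p3,p4 Cartesian positions (length-3 numeric).
#' @return Torsion angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unitv(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- rad2deg(atan2(y, x))
  if (ang <= -180) ang <- ang + 360
  ang
}

# Map any angle (degrees) into (-180, 180]
wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y <= -180] <- y[y <= -180] + 360
  # exactly -180 maps to 180
  y[abs(y + 180) < 1e-12] <- 180
  y
}

# Rotation matrix about unit axis by angle (degrees), Rodrigues form
rotation_matrix <- function(axis, angle_deg) {
  u <- unitv(axis)
  th <- deg2rad(angle_deg)
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) * ct + st * K + (1 - ct) * (u %o% u)
}

# Rotate rows of xyz (n x 3) about an axis through `point` along `axis`
rotate_about_axis <- function(xyz, point, axis, angle_deg) {
  R <- rotation_matrix(axis, angle_deg)
  xyz <- as.matrix(xyz)
  sweep(sweep(xyz, 2, point) %*% t(R), 2, point, `+`)
}

# Place atom D given positions of A (bonded neighbour), B, C and internal
# coordinates: |DA| = bond, angle D-A-B (deg), torsion D-A-B-C (deg).
place_internal <- function(a, b, c, bond, angle_deg, torsion_deg) {
  ang <- deg2rad(angle_deg)
  tor <- deg2rad(torsion_deg)
  ab <- unitv(a - b)              # direction B -> A
  n <- cross3(b - c, ab)
  if (vnorm(n) < 1e-10) {
    # degenerate reference plane; pick any perpendicular
    n <- cross3(ab, if (abs(ab[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0))
  }
  n <- unitv(n)
  m <- cross3(n, ab)
  d_local <- c(-bond * cos(ang),
               bond * sin(ang) * cos(tor),
               -bond * sin(ang) * sin(tor))
  a + d_local[1] * ab + d_local[2] * m + d_local[3] * n
}

# Signed chiral volume (A^3) of centre with three neighbours, (n1-c).((n2-c)x(n3-c))
chiral_volume <- function(centre, n1, n2, n3) {
  sum((n1 - centre) * cross3(n2 - centre, n3 - centre))
}

# Least-squares RMSD between two n x 3 coordinate sets (no superposition)
coord_rmsd <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(all(dim(x) == dim(y)))
  sqrt(mean(rowSums((x - y)^2)))
}

# Uniform random rotation axis (sphere point picking) using the active RNG
random_unit_axis <- function() {
  z <- stats::runif(1, -1, 1)
  phi <- stats::runif(1, 0, 2 * pi)
  r <- sqrt(max(0, 1 - z^2))
  c(r * cos(phi), r * sin(phi), z)
}
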