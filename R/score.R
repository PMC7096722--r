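# Real-space refinement target: weighted sum of restraint energies minus
# map_weight times the density fit score. Gradients are analytic for every
# term (the best-fit plane gradient is exact by the envelope theorem since
# the plane minimises the squared distances).

#' Refinement configuration
#'
#' @param map_weight weight of the density term relative to geometry.
#' @param max_iter maximum minimiser iterations.
#' @param convergence_tol stop when the score improvement per cycle falls
#'   below this value.
#' @param rng_seed seed for stochastic operations (jiggle fit).
#' @param restraint_weights named per-class weight overrides.
#' @return list of class `refinement_config`.
#' @export
refinement_config <- function(map_weight = 1, max_iter = 400,
                              convergence_tol = 1e-6, rng_seed = 1L,
                              restraint_weights = NULL) {
  stopifnot(map_weight >= 0, max_iter >= 1)
  cfg <- list(map_weight = map_weight, max_iter = as.integer(max_iter),
              convergence_tol = convergence_tol,
              rng_seed = as.integer(rng_seed),
              restraint_weights = restraint_weights)
  class(cfg) <- "refinement_config"
  cfg
}

# best-fit plane of points (rows of xyz): returns list(normal, centroid, dist)
fit_plane <- function(xyz) {
  cen <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, cen))
  normal <- sv$v[, 3]
  list(normal = normal, centroid = cen,
       dist = drop(sweep(xyz, 2, cen) %*% normal))
}

#' Total refinement score and gradients
#'
#' total = sum of per-class restraint energies - map_weight x density fit.
#' Angles/torsions are scored in degrees against their sigmas; torsions use
#' the nearest periodic image.
#'
#' @param s An `rs_structure`.
#' @param restraints A `restraint_set` (GM restraints may be attached in its
#'   `gm` field).
#' @param map optional `density_map` (NULL: geometry only).
#' @param cfg A `refinement_config`.
#' @return list(breakdown = named energies (class `score_breakdown`),
#'   gradient = n x 3 matrix of d total / d position).
#' @export
total_score <- function(s, restraints, map = NULL,
                        cfg = refinement_config()) {
  xyz <- coords(s)
  n <- nrow(xyz)
  grad <- matrix(0, n, 3)
  w <- restraints$weights
  if (!is.null(cfg$restraint_weights))
    w[names(cfg$restraint_weights)] <- cfg$restraint_weights
  bad <- function(idx) any(idx < 1 | idx > n)
  terms <- c(bond = 0, angle = 0, torsion = 0, plane = 0, chiral = 0,
             nonbonded = 0, gm = 0, density = 0)

  b <- restraints$bonds
  if (nrow(b)) {
    if (bad(c(b$i, b$j))) stop("bond restraint references missing atom")
    dv <- xyz[b$i, , drop = FALSE] - xyz[b$j, , drop = FALSE]
    d <- sqrt(rowSums(dv^2))
    z <- (d - b$target) / b$sigma
    terms["bond"] <- w["bond"] * sum(z^2)
    gmag <- w["bond"] * 2 * z / b$sigma
    gv <- dv * (gmag / d)
    for (k in 1:3) {
      grad[, k] <- grad[, k] +
        tabulate2(b$i, gv[, k], n) - tabulate2(b$j, gv[, k], n)
    }
  }

  a <- restraints$angles
  if (nrow(a)) {
    if (bad(c(a$i, a$j, a$k))) stop("angle restraint references missing atom")
    u <- xyz[a$i, , drop = FALSE] - xyz[a$j, , drop = FALSE]
    v <- xyz[a$k, , drop = FALSE] - xyz[a$j, , drop = FALSE]
    nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
    uh <- u / nu; vh <- v / nv
    ct <- pmax(-1, pmin(1, rowSums(uh * vh)))
    st <- sqrt(pmax(1e-12, 1 - ct^2))
    theta <- rad2deg(acos(ct))
    z <- (theta - a$target) / a$sigma
    terms["angle"] <- w["angle"] * sum(z^2)
    pref <- w["angle"] * 2 * z / a$sigma * (180 / pi)
    gi <- (uh * ct - vh) / (nu * st) * pref
    gk <- (vh * ct - uh) / (nv * st) * pref
    for (k in 1:3) {
      grad[, k] <- grad[, k] + tabulate2(a$i, gi[, k], n) +
        tabulate2(a$k, gk[, k], n) - tabulate2(a$j, gi[, k] + gk[, k], n)
    }
  }

  tr <- restraints$torsions
  if (nrow(tr)) {
    if (bad(c(tr$i, tr$j, tr$k, tr$l)))
      stop("torsion restraint references missing atom")
    b1 <- xyz[tr$j, , drop = FALSE] - xyz[tr$i, , drop = FALSE]
    b2 <- xyz[tr$k, , drop = FALSE] - xyz[tr$j, , drop = FALSE]
    b3 <- xyz[tr$l, , drop = FALSE] - xyz[tr$k, , drop = FALSE]
    n1 <- rowcross(b1, b2); n2 <- rowcross(b2, b3)
    nb2 <- sqrt(rowSums(b2^2))
    m1 <- rowcross(n1, b2 / nb2)
    x <- rowSums(n1 * n2); y <- rowSums(m1 * n2)
    theta <- rad2deg(atan2(y, x))
    period_span <- 360 / tr$period
    delta <- wrap180(theta - tr$target)
    delta <- delta - period_span * round(delta / period_span)
    z <- delta / tr$sigma
    terms["torsion"] <- w["torsion"] * sum(z^2)
    pref <- w["torsion"] * 2 * z / tr$sigma * (180 / pi)
    sq1 <- rowSums(n1^2); sq2 <- rowSums(n2^2)
    dthi <- n1 * (nb2 / sq1)
    dthl <- -n2 * (nb2 / sq2)
    c12 <- rowSums(b1 * b2) / nb2^2
    c32 <- rowSums(b3 * b2) / nb2^2
    dthj <- -dthi * (1 + c12) + dthl * c32
    dthk <- dthi * c12 - dthl * (1 + c32)
    for (k in 1:3) {
      grad[, k] <- grad[, k] + tabulate2(tr$i, dthi[, k] * pref, n) +
        tabulate2(tr$j, dthj[, k] * pref, n) +
        tabulate2(tr$k, dthk[, k] * pref, n) +
        tabulate2(tr$l, dthl[, k] * pref, n)
    }
  }

  if (length(restraints$planes)) {
    e <- 0
    for (p in restraints$planes) {
      if (bad(p$idx)) stop("plane restraint references missing atom")
      fp <- fit_plane(xyz[p$idx, , drop = FALSE])
      e <- e + sum((fp$dist / p$sigma)^2)
      g <- outer(2 * fp$dist / p$sigma^2, fp$normal) * w["plane"]
      grad[p$idx, ] <- grad[p$idx, ] + g
    }
    terms["plane"] <- w["plane"] * e
  }

  ch <- restraints$chirals
  if (nrow(ch)) {
    if (bad(c(ch$c, ch$i, ch$j, ch$k)))
      stop("chiral restraint references missing atom")
    for (q in seq_len(nrow(ch))) {
      rc <- xyz[ch$c[q], ]; r1 <- xyz[ch$i[q], ]
      r2 <- xyz[ch$j[q], ]; r3 <- xyz[ch$k[q], ]
      v1 <- r1 - rc; v2 <- r2 - rc; v3 <- r3 - rc
      V <- sum(v1 * cross3(v2, v3))
      z <- (V - ch$target[q]) / ch$sigma[q]
      terms["chiral"] <- terms["chiral"] + w["chiral"] * z^2
      pref <- w["chiral"] * 2 * z / ch$sigma[q]
      g1 <- cross3(v2, v3); g2 <- cross3(v3, v1); g3 <- cross3(v1, v2)
      grad[ch$i[q], ] <- grad[ch$i[q], ] + pref * g1
      grad[ch$j[q], ] <- grad[ch$j[q], ] + pref * g2
      grad[ch$k[q], ] <- grad[ch$k[q], ] + pref * g3
      grad[ch$c[q], ] <- grad[ch$c[q], ] - pref * (g1 + g2 + g3)
    }
  }

  nb <- restraints$nonbonded
  if (nrow(nb)) {
    dv <- xyz[nb$i, , drop = FALSE] - xyz[nb$j, , drop = FALSE]
    d <- sqrt(rowSums(dv^2))
    pen <- d < nb$rmin
    if (any(pen)) {
      z <- (nb$rmin[pen] - d[pen]) / nb$sigma[pen]
      terms["nonbonded"] <- w["nonbonded"] * sum(z^2)
      gmag <- -w["nonbonded"] * 2 * z / nb$sigma[pen]
      gv <- dv[pen, , drop = FALSE] * (gmag / d[pen])
      for (k in 1:3) {
        grad[, k] <- grad[, k] + tabulate2(nb$i[pen], gv[, k], n) -
          tabulate2(nb$j[pen], gv[, k], n)
      }
    }
  }

  gm <- restraints$gm
  if (!is.null(gm) && nrow(gm)) {
    dv <- xyz[gm$i, , drop = FALSE] - xyz[gm$j, , drop = FALSE]
    d <- sqrt(rowSums(dv^2))
    res <- gm_residual(d, gm$target, gm$sigma, gm$alpha)
    terms["gm"] <- w["gm"] * sum(res$energy)
    gv <- dv * (w["gm"] * res$gradient / d)
    for (k in 1:3) {
      grad[, k] <- grad[, k] + tabulate2(gm$i, gv[, k], n) -
        tabulate2(gm$j, gv[, k], n)
    }
  }

  if (!is.null(map) && cfg$map_weight > 0) {
    wz <- s$atoms$occ * atomic_number(s$atoms$element)
    den <- interpolate_density_cubic(map, xyz)
    terms["density"] <- -cfg$map_weight * sum(wz * den$value)
    grad <- grad - cfg$map_weight * den$gradient * wz
  }

  breakdown <- c(total = sum(terms), terms)
  class(breakdown) <- "score_breakdown"
  list(breakdown = breakdown, gradient = grad)
}

#' @export
print.score_breakdown <- function(x, ...) {
  cat("score breakdown:\n")
  for (nm in names(x))
    cat(sprintf("  %-10s %12.4f\n", nm, unclass(x)[nm]))
  invisible(x)
}

# sum `val` into bins `idx` over 1..n (fast scatter-add)
tabulate2 <- function(idx, val, n) {
  out <- numeric(n)
  agg <- rowsum(val, idx)
  out[as.integer(rownames(agg))] <- agg
  out
}

rowcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}
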