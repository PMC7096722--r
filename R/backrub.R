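# Backrub rotamer fitting: the moving set (all atoms of residue i, C and O
# of residue i-1, N of residue i+1) rotates rigidly about the Calpha(i-1) ->
# Calpha(i+1) axis; the two flanking peptide units then back-rotate about
# their own Calpha-Calpha vectors to restore the carbonyl O of residue i-1
# and the amide N of residue i+1 toward their start positions. The full
# motion preserves main-chain geometry closely: the central residue's tau
# (N-CA-C angle) is exactly invariant, and the flanking residues' tau
# changes stay small (median well under 2 degrees over a +/-10 degree
# sweep). Each backbone hypothesis is combined with the rotamers of the
# residue type and scored against density and clashes.

#' Backrub rotation axis for a residue
#'
#' The axis runs through Calpha(i-1) along the unit vector toward
#' Calpha(i+1).
#'
#' @param s An `rs_structure`.
#' @param chain,seqnum,inscode the central residue i.
#' @return list(point=, dir=) of the axis.
#' @export
backrub_axis <- function(s, chain, seqnum, inscode = "") {
  ca_prev <- atom_pos(s, chain, seqnum - 1, "CA")
  ca_next <- atom_pos(s, chain, seqnum + 1, "CA")
  if (is.null(ca_prev) || is.null(ca_next))
    stop("no backrub axis: residue ", chain, "/", seqnum,
         " lacks a neighbour Calpha (chain terminus)")
  list(point = ca_prev, dir = unitv(ca_next - ca_prev))
}

# row indices of the backrub moving set: all atoms of residue i, C and O of
# residue i-1, N of residue i+1
backrub_moving_set <- function(s, chain, seqnum, inscode = "") {
  a <- s$atoms
  own <- which(a$chain == chain & a$seqnum == seqnum & a$inscode == inscode)
  prev <- which(a$chain == chain & a$seqnum == seqnum - 1 &
                  a$atom %in% c("C", "O"))
  nxt <- which(a$chain == chain & a$seqnum == seqnum + 1 & a$atom == "N")
  list(own = own, prev = prev, nxt = nxt, all = c(own, prev, nxt))
}

# best rotation angle (degrees) about (point, axis) bringing `moving` as
# close as possible to `target`
best_restoring_angle <- function(moving, target, point, axis) {
  obj <- function(th)
    sum((rotate_about_axis(matrix(moving, 1), point, axis, th) - target)^2)
  stats::optimize(obj, c(-30, 30))$minimum
}

#' Generate backrub backbone hypotheses
#'
#' Applies `n_steps` rotations evenly spanning `[-angle_range,
#' +angle_range]` degrees (0 included for odd `n_steps`) rigidly to the
#' moving set; with `back_rotate` (the default) the flanking peptide units
#' then counter-rotate about their Calpha-Calpha vectors to restore
#' O(i-1) and N(i+1) toward their start positions.
#'
#' @param s An `rs_structure`.
#' @param chain,seqnum the central residue.
#' @param angle_range half-range in degrees (default 10).
#' @param n_steps number of hypotheses (default 21).
#' @param back_rotate apply the peptide back-rotations (default TRUE).
#' @return list of list(angle=, xyz= moved coordinates of the moving set,
#'   idx= moving-set row indices).
#' @export
generate_backrub_hypotheses <- function(s, chain, seqnum, angle_range = 10,
                                        n_steps = 21, back_rotate = TRUE) {
  if (n_steps < 1) stop("n_steps must be >= 1")
  ax <- backrub_axis(s, chain, seqnum)
  mv <- backrub_moving_set(s, chain, seqnum)
  xyz0 <- coords(s)[mv$all, , drop = FALSE]
  n_own <- length(mv$own)
  i_prev <- if (length(mv$prev)) n_own + seq_along(mv$prev) else integer(0)
  i_nxt <- if (length(mv$nxt)) n_own + length(mv$prev) + 1L else integer(0)
  o_prev_row <- which(s$atoms$atom[mv$prev] == "O")
  ca_prev <- atom_pos(s, chain, seqnum - 1, "CA")
  ca_next <- atom_pos(s, chain, seqnum + 1, "CA")
  ca_i_row <- which(s$atoms$atom[mv$own] == "CA")
  angles <- if (n_steps == 1) 0 else
    seq(-angle_range, angle_range, length.out = n_steps)
  lapply(angles, function(ang) {
    xyz <- rotate_about_axis(xyz0, ax$point, ax$dir, ang)
    if (back_rotate && ang != 0) {
      ca_i <- xyz[ca_i_row, ]
      if (length(i_prev) && length(o_prev_row)) {
        axis1 <- ca_i - ca_prev
        th1 <- best_restoring_angle(xyz[i_prev[o_prev_row], ],
                                    xyz0[i_prev[o_prev_row], ],
                                    ca_prev, axis1)
        xyz[i_prev, ] <- rotate_about_axis(xyz[i_prev, , drop = FALSE],
                                           ca_prev, axis1, th1)
      }
      if (length(i_nxt)) {
        axis2 <- ca_next - ca_i
        th2 <- best_restoring_angle(xyz[i_nxt, ], xyz0[i_nxt, ], ca_i, axis2)
        xyz[i_nxt, ] <- rotate_about_axis(xyz[i_nxt, , drop = FALSE],
                                          ca_i, axis2, th2)
      }
    }
    list(angle = ang, xyz = xyz, idx = mv$all)
  })
}

#' Place a rotamer's side chain by internal coordinates
#'
#' Rebuilds CB and beyond on the residue's current backbone with the given
#' chi angles; the measured chi dihedrals of the result reproduce the
#' requested values.
#'
#' @param s An `rs_structure`.
#' @param chain,seqnum the residue.
#' @param chis chi angles in degrees.
#' @return The `rs_structure` with the side chain replaced.
#' @export
place_rotamer_side_chain <- function(s, chain, seqnum, chis) {
  a <- s$atoms
  rows <- a$chain == chain & a$seqnum == seqnum
  rtype <- a$resname[rows][1]
  if (rtype == "GLY") stop("glycine has no side chain to place")
  if (!rtype %in% names(SIDE_CHAIN_ZMAT))
    stop("unsupported residue type ", rtype)
  swap_side_chain(s, chain, seqnum, rtype, chis = chis)
}

#' Steric clash penalty between a candidate atom set and its environment
#'
#' Sum over candidate-environment pairs of max(0, r_min - d)^2 with r_min
#' the sum of the element contact radii. Pairs bonded across the peptide
#' junctions must be excluded by the caller. Symmetry mates are never
#' considered.
#'
#' @param cand data.frame of candidate atoms (element, x, y, z).
#' @param env data.frame of environment atoms.
#' @param radii named contact-radius table (A).
#' @return Non-negative penalty.
#' @export
clash_score <- function(cand, env, radii = VDW_RADII) {
  if (!nrow(cand) || !nrow(env)) return(0)
  cx <- as.matrix(cand[, c("x", "y", "z")])
  ex <- as.matrix(env[, c("x", "y", "z")])
  r1 <- radii[cand$element]; r1[is.na(r1)] <- 1.7
  r2 <- radii[env$element]; r2[is.na(r2)] <- 1.7
  d2 <- outer(rowSums(cx^2), rowSums(ex^2), `+`) - 2 * cx %*% t(ex)
  d <- sqrt(pmax(d2, 0))
  rmin <- outer(unname(r1), unname(r2), `+`)
  sum(pmax(0, rmin - d)^2)
}

# contact scale applied to the vdW table inside the combined backrub score:
# overlaps shallower than ~15% of the radii sum are normal packing
BACKRUB_CLASH_SCALE <- 0.85

#' Backrub rotamer fit of one residue against density
#'
#' Enumerates (backrub angle x rotamer) hypotheses, scores each as
#' `w_density * density fit - w_clash * clash penalty` against the fixed
#' environment, and replaces the residue (plus the flanking peptide atoms)
#' only when the best hypothesis strictly beats the current coordinates.
#' Residues without rotamers (GLY/ALA) are fitted with backbone-only
#' hypotheses.
#'
#' @param s An `rs_structure`.
#' @param chain,seqnum the residue to fit.
#' @param map A `density_map`.
#' @param angle_range,n_steps backrub sweep (default +/-10 degrees, 21
#'   steps).
#' @param w_density,w_clash score weights (default 1 each).
#' @param back_rotate peptide back-rotation stage (default TRUE).
#' @param rotamer_lib rotamer library (list form).
#' @return list(structure=, accepted=, best= hypothesis info).
#' @export
backrub_rotamer_fit <- function(s, chain, seqnum, map, angle_range = 10,
                                n_steps = 21, w_density = 1, w_clash = 1,
                                back_rotate = TRUE,
                                rotamer_lib = ROTAMER_LIB) {
  a <- s$atoms
  rows <- which(a$chain == chain & a$seqnum == seqnum)
  if (!length(rows)) stop("no residue ", chain, "/", seqnum)
  rtype <- a$resname[rows[1]]
  rotamers <- rotamer_lib[[rtype]]
  backbone_only <- is.null(rotamers)
  if (backbone_only) rotamers <- list(list("fixed", 1, numeric(0)))
  mv <- backrub_moving_set(s, chain, seqnum)
  env_idx <- setdiff(seq_len(nrow(a)), mv$all)
  # junction atoms covalently bonded to the moving set
  junction <- which(a$chain == chain & a$atom == "CA" &
                      a$seqnum %in% c(seqnum - 1, seqnum + 1))
  env_idx <- setdiff(env_idx, junction)
  env <- a[env_idx, , drop = FALSE]
  clash_radii <- VDW_RADII * BACKRUB_CLASH_SCALE
  score_candidate <- function(st) {
    cand <- st$atoms[backrub_moving_set(st, chain, seqnum)$all, ,
                     drop = FALSE]
    w_density * density_fit_score(map, cand) -
      w_clash * clash_score(cand, env, clash_radii)
  }
  current_score <- score_candidate(s)
  hyps <- generate_backrub_hypotheses(s, chain, seqnum, angle_range,
                                      n_steps, back_rotate)
  best <- list(score = -Inf, structure = NULL)
  for (h in hyps) {
    st <- s
    nx <- coords(st); nx[h$idx, ] <- h$xyz; coords(st) <- nx
    for (r in rotamers) {
      st2 <- st
      if (!backbone_only && rtype != "ALA")
        st2 <- place_rotamer_side_chain(st2, chain, seqnum, r[[3]])
      sc <- score_candidate(st2)
      if (sc > best$score)
        best <- list(score = sc, structure = st2, angle = h$angle,
                     rotamer = r[[1]])
    }
  }
  # improvements below the density-interpolation noise floor are not real
  margin <- max(1e-9, 5e-3 * abs(current_score))
  accepted <- best$score > current_score + margin
  list(structure = if (accepted) best$structure else s,
       accepted = accepted,
       best = list(score = best$score, current = current_score,
                   angle = if (accepted) best$angle else 0,
                   rotamer = if (accepted) best$rotamer else NA))
}
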