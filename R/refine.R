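# Gradient-driven real-space refinement: zone/chain refinement (L-BFGS-B on
# the free atoms), rigid-body refinement of a fragment against density,
# stochastic "jiggle" fitting, and register-nudge hypothesis models.

#' Refine a zone of a structure against restraints and density
#'
#' Minimises [total_score()] over the atoms matched by `sel`; all other
#' atoms stay fixed but still contribute to restraints that span the zone
#' boundary. The optimisation runs in cycles of L-BFGS-B with the best model
#' kept, so the reported score trace is non-increasing.
#'
#' @param s An `rs_structure`.
#' @param sel selection of free atoms (string, parsed selection, or logical
#'   mask); NULL refines everything.
#' @param restraints A `restraint_set`; NULL builds standard restraints.
#' @param map optional `density_map`.
#' @param cfg A `refinement_config`.
#' @return list(structure=, breakdown=, trace= per-cycle scores,
#'   converged= flag) of class `refine_result`.
#' @export
refine_zone <- function(s, sel = NULL, restraints = NULL, map = NULL,
                        cfg = refinement_config()) {
  free <- if (is.null(sel)) rep(TRUE, n_atoms(s))
    else if (is.logical(sel)) sel
    else selection_mask(s, sel)
  if (!any(free)) stop("empty refinement selection")
  if (is.null(restraints)) restraints <- build_standard_restraints(s)
  xyz0 <- coords(s)
  fidx <- which(free)
  pack <- function(xyz) as.numeric(t(xyz[fidx, , drop = FALSE]))
  unpack <- function(par) {
    xyz <- xyz0
    xyz[fidx, ] <- matrix(par, ncol = 3, byrow = TRUE)
    xyz
  }
  eval_at <- function(par) {
    st <- s; coords(st) <- unpack(par)
    total_score(st, restraints, map, cfg)
  }
  fn <- function(par) eval_at(par)$breakdown[["total"]]
  gr <- function(par) as.numeric(t(eval_at(par)$gradient[fidx, , drop = FALSE]))
  par <- pack(xyz0)
  best_par <- par
  best_f <- fn(par)
  trace <- best_f
  cycles <- max(1L, ceiling(cfg$max_iter / 50))
  converged <- FALSE
  for (cy in seq_len(cycles)) {
    opt <- stats::optim(best_par, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = 50, factr = 1e4))
    if (opt$value < best_f - 1e-12) {
      improvement <- best_f - opt$value
      best_f <- opt$value
      best_par <- opt$par
    } else {
      improvement <- 0
    }
    trace <- c(trace, best_f)
    if (improvement < cfg$convergence_tol) { converged <- TRUE; break }
  }
  out <- s
  coords(out) <- unpack(best_par)
  final <- total_score(out, restraints, map, cfg)
  res <- list(structure = out, breakdown = final$breakdown, trace = trace,
              converged = converged)
  class(res) <- "refine_result"
  res
}

#' @export
print.refine_result <- function(x, ...) {
  cat(sprintf("<refine_result> score %.4f -> %.4f over %d cycle(s)%s\n",
              x$trace[1], x$trace[length(x$trace)], length(x$trace) - 1,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

rigid_params_apply <- function(xyz, par, pivot) {
  R <- rotation_matrix(c(1, 0, 0), par[1]) %*%
    rotation_matrix(c(0, 1, 0), par[2]) %*%
    rotation_matrix(c(0, 0, 1), par[3])
  sweep(sweep(xyz, 2, pivot) %*% t(R), 2, pivot + par[4:6], `+`)
}

#' Rigid-body refinement of a fragment against density
#'
#' Maximises the density fit score over the six rigid parameters (Euler
#' angles about the fragment centroid plus translation); internal geometry
#' is exactly preserved.
#'
#' @param s An `rs_structure`.
#' @param frag_sel selection of the fragment (string/parsed/logical mask).
#' @param map A `density_map`.
#' @param cfg A `refinement_config`.
#' @return list(transform = list(rotation, translation, pivot), structure=,
#'   score=) where structure is `s` with the fragment moved.
#' @export
rigid_body_refine <- function(s, frag_sel, map, cfg = refinement_config()) {
  mask <- if (is.logical(frag_sel)) frag_sel else selection_mask(s, frag_sel)
  fidx <- which(mask)
  if (length(fidx) < 3) stop("fragment needs at least 3 atoms")
  xyz <- coords(s)[fidx, , drop = FALSE]
  if (qr(sweep(xyz, 2, colMeans(xyz)))$rank < 2)
    stop("degenerate (collinear) fragment")
  w <- s$atoms$occ[fidx] * atomic_number(s$atoms$element[fidx])
  pivot <- colMeans(xyz)
  fn <- function(par)
    -sum(w * interpolate_density(map, rigid_params_apply(xyz, par, pivot)))
  opt <- stats::optim(rep(0, 6), fn, method = "BFGS",
                      control = list(maxit = cfg$max_iter, reltol = 1e-10))
  # polish with a simplex pass (robust to interpolation kinks)
  opt2 <- stats::optim(opt$par, fn, method = "Nelder-Mead",
                       control = list(maxit = 400, reltol = 1e-12))
  if (opt2$value < opt$value) opt <- opt2
  par <- opt$par
  out <- s
  newxyz <- coords(s)
  newxyz[fidx, ] <- rigid_params_apply(xyz, par, pivot)
  coords(out) <- newxyz
  R <- rotation_matrix(c(1, 0, 0), par[1]) %*%
    rotation_matrix(c(0, 1, 0), par[2]) %*%
    rotation_matrix(c(0, 0, 1), par[3])
  list(transform = list(rotation = R, translation = par[4:6], pivot = pivot),
       structure = out, score = -opt$value)
}

#' Stochastic rigid ("jiggle") fit of a fragment into density
#'
#' Draws `n_trials` random rigid transforms (rotation angle uniform in
#' \[0, max_rot_deg\] about a uniformly random axis through the fragment
#' centroid; translation components uniform in +/-max_trans_A), scores each
#' by density fit, rigid-body refines the best `n_keep`, and replaces the
#' fragment only when the best refined score strictly beats the starting
#' score. Fully reproducible for a fixed `cfg$rng_seed`; trials are
#' evaluated independently so their order cannot change the result.
#'
#' @param s An `rs_structure`.
#' @param frag_sel fragment selection.
#' @param map A `density_map`.
#' @param n_trials number of random hypotheses (default 400).
#' @param max_rot_deg rotation range in degrees (default 30).
#' @param max_trans_A translation range in A (default 6).
#' @param n_keep how many top hypotheses to refine (default 5).
#' @param cfg A `refinement_config` (seed source).
#' @return list(structure=, score=, accepted=, start_score=).
#' @export
jiggle_fit <- function(s, frag_sel, map, n_trials = 400, max_rot_deg = 30,
                       max_trans_A = 6, n_keep = 5,
                       cfg = refinement_config()) {
  stopifnot(n_trials >= 1, n_keep >= 1)
  n_keep <- min(n_keep, n_trials)
  mask <- if (is.logical(frag_sel)) frag_sel else selection_mask(s, frag_sel)
  fidx <- which(mask)
  if (length(fidx) < 3) stop("fragment needs at least 3 atoms")
  xyz <- coords(s)[fidx, , drop = FALSE]
  w <- s$atoms$occ[fidx] * atomic_number(s$atoms$element[fidx])
  pivot <- colMeans(xyz)
  start_score <- sum(w * interpolate_density(map, xyz))
  set.seed(cfg$rng_seed)
  trials <- lapply(seq_len(n_trials), function(i) {
    axis <- random_unit_axis()
    ang <- stats::runif(1, 0, max_rot_deg)
    tr <- stats::runif(3, -max_trans_A, max_trans_A)
    list(axis = axis, ang = ang, tr = tr)
  })
  scores <- vapply(trials, function(t) {
    moved <- sweep(rotate_about_axis(xyz, pivot, t$axis, t$ang), 2, t$tr, `+`)
    sum(w * interpolate_density(map, moved))
  }, numeric(1))
  ord <- order(-scores)[seq_len(n_keep)]
  best <- list(score = start_score, xyz = xyz)
  # strict-improvement margin: refined-score differences below the rigid
  # optimiser's tolerance are numerical noise, not real improvements
  margin <- max(1e-9, 1e-3 * abs(start_score))
  for (k in ord) {
    t <- trials[[k]]
    moved <- sweep(rotate_about_axis(xyz, pivot, t$axis, t$ang), 2, t$tr, `+`)
    st <- s
    nx <- coords(s); nx[fidx, ] <- moved; coords(st) <- nx
    rb <- rigid_body_refine(st, mask, map, cfg)
    if (rb$score > best$score + margin) {
      best <- list(score = rb$score, xyz = coords(rb$structure)[fidx, ,
                                                               drop = FALSE])
    }
  }
  accepted <- best$score > start_score + margin
  out <- s
  if (accepted) {
    nx <- coords(s); nx[fidx, ] <- best$xyz; coords(out) <- nx
  }
  list(structure = out, score = if (accepted) best$score else start_score,
       accepted = accepted, start_score = start_score)
}

#' Generate and refine a register-shift hypothesis
#'
#' Re-threads the sequence within the zone: residue at position p takes the
#' residue type previously at position p - offset, with the side chain
#' rebuilt at the most probable rotamer on the existing backbone. Positions
#' whose source falls outside the zone keep their current type (stub). The
#' hypothesis is then refined with self distance restraints generated from
#' the pre-shift model. The input model is not modified.
#'
#' @param s An `rs_structure`.
#' @param zone_sel selection covering the zone (a residue range).
#' @param offset signed register shift (|offset| >= 1).
#' @param map optional `density_map` used in the refinement.
#' @param cfg A `refinement_config`.
#' @param gm_limit self-restraint distance limit (A).
#' @param refine run the refinement step (TRUE by default).
#' @return The hypothesis `rs_structure`.
#' @export
nudge_register <- function(s, zone_sel, offset, map = NULL,
                           cfg = refinement_config(), gm_limit = 4.2,
                           refine = TRUE) {
  offset <- as.integer(offset)
  if (offset == 0) stop("offset 0 is not a register hypothesis")
  sel <- if (is.character(zone_sel)) parse_selection(zone_sel) else zone_sel
  rt <- residue_table(s)
  zone <- rt[rt$chain == sel$chain &
               (is.na(sel$start) |
                  (rt$seqnum >= sel$start & rt$seqnum <= sel$end)), ,
             drop = FALSE]
  nz <- nrow(zone)
  if (nz < abs(offset) + 2)
    stop("zone of ", nz, " residues is too small for offset ", offset)
  old_types <- zone$resname
  hyp <- s
  for (p in seq_len(nz)) {
    src <- p - offset
    new_type <- if (src >= 1 && src <= nz) old_types[src] else old_types[p]
    hyp <- swap_side_chain(hyp, zone$chain[p], zone$seqnum[p], new_type,
                           inscode = zone$inscode[p])
  }
  if (refine) {
    rs <- build_standard_restraints(hyp)
    gm <- generate_self_gm_restraints(
      s, sel = paste0("//", sel$chain, "/",
                      min(zone$seqnum), "-", max(zone$seqnum), "/N,CA,C,O"),
      limit = gm_limit)
    # remap atom rows of the pre-shift model onto the hypothesis model
    key_s <- paste(atom_res_keys(s), s$atoms$atom)
    key_h <- paste(atom_res_keys(hyp), hyp$atoms$atom)
    gm$i <- match(key_s[gm$i], key_h)
    gm$j <- match(key_s[gm$j], key_h)
    rs$gm <- gm[!is.na(gm$i) & !is.na(gm$j), , drop = FALSE]
    hyp <- refine_zone(hyp, zone_sel, rs, map, cfg)$structure
  }
  hyp
}
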