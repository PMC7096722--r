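# Validation suite: Ramachandran and Kleywegt analysis, rotamer
# probabilities, B-factor statistics, per-residue density fit, and
# dictionary-based ligand distortion. Reports are plain data.frames; TSV and
# JSON writers live in the CLI layer.

#' Backbone phi/psi of one residue
#'
#' @param s An `rs_structure`.
#' @param chain,seqnum,inscode the residue.
#' @return c(phi=, psi=) in degrees, or NULL at a terminus (flanking C/N
#'   missing).
#' @export
phi_psi <- function(s, chain, seqnum, inscode = "") {
  Cm <- atom_pos(s, chain, seqnum - 1, "C")
  N <- atom_pos(s, chain, seqnum, "N", inscode)
  CA <- atom_pos(s, chain, seqnum, "CA", inscode)
  C <- atom_pos(s, chain, seqnum, "C", inscode)
  Np <- atom_pos(s, chain, seqnum + 1, "N")
  if (is.null(Cm) || is.null(N) || is.null(CA) || is.null(C) || is.null(Np))
    return(NULL)
  c(phi = dihedral_angle(Cm, N, CA, C), psi = dihedral_angle(N, CA, C, Np))
}

# Ramachandran basin parameters per class: (phi, psi, sd_phi, sd_psi, weight)
RAMA_BASINS <- list(
  general = rbind(c(-63, -43, 13, 13, 1.0), c(-120, 130, 25, 20, 0.9),
                  c(-65, 145, 18, 18, 0.6), c(57, 40, 11, 11, 0.15)),
  ile_val = rbind(c(-62, -45, 11, 11, 0.8), c(-115, 125, 20, 16, 1.0),
                  c(-70, 145, 15, 15, 0.4)),
  gly = rbind(c(-63, -41, 15, 15, 0.8), c(63, 41, 15, 15, 0.8),
              c(-85, 170, 25, 22, 0.7), c(85, -170, 25, 22, 0.7),
              c(-90, 0, 22, 22, 0.3), c(90, 0, 22, 22, 0.3)),
  pro = rbind(c(-62, -35, 10, 13, 1.0), c(-62, 145, 10, 16, 0.8)),
  pre_pro = rbind(c(-63, -43, 12, 12, 0.7), c(-120, 130, 25, 20, 1.0),
                  c(-135, 75, 16, 16, 0.35), c(55, 40, 10, 10, 0.2))
)
RAMA_BASINS$all <- do.call(rbind, RAMA_BASINS[c("general", "gly", "pro")])

rama_density <- function(phi, psi, basins) {
  v <- 0
  for (q in seq_len(nrow(basins))) {
    b <- basins[q, ]
    v <- v + b[5] * exp(-0.5 * ((wrap180(phi - b[1]) / b[3])^2 +
                                  (wrap180(psi - b[2]) / b[4])^2))
  }
  v
}

#' Ramachandran probability tables
#'
#' Per-class (all, general, ile_val, gly, pro, pre_pro) 2D grids over
#' (phi, psi), peak-normalised to 1, synthesized from wrapped-Gaussian basin
#' mixtures placed at the classical basin centres. Grid step and the
#' preferred/allowed cutoffs are customisable.
#'
#' @param step grid step in degrees (default 5).
#' @param preferred_min,allowed_min probability cutoffs (relative to peak).
#' @return An object of class `rama_tables`.
#' @export
rama_tables <- function(step = 5, preferred_min = 0.02,
                        allowed_min = 0.002) {
  stopifnot(preferred_min > allowed_min, allowed_min > 0)
  axis <- seq(-180, 180 - step, by = step)
  grids <- lapply(RAMA_BASINS, function(basins) {
    g <- outer(axis, axis, function(p, q) rama_density(p, q, basins))
    g / max(g)
  })
  structure(list(grids = grids, axis = axis, step = step,
                 preferred_min = preferred_min, allowed_min = allowed_min),
            class = "rama_tables")
}

#' @export
print.rama_tables <- function(x, ...) {
  cat(sprintf(
    "<rama_tables> classes %s; %d-degree grid; preferred >= %g, allowed >= %g\n",
    paste(names(x$grids), collapse = "/"), x$step, x$preferred_min,
    x$allowed_min))
  invisible(x)
}

rama_lookup <- function(tables, class, phi, psi) {
  g <- tables$grids[[class]]
  i <- findInterval(wrap180(phi), c(tables$axis, 180), rightmost.closed = TRUE)
  j <- findInterval(wrap180(psi), c(tables$axis, 180), rightmost.closed = TRUE)
  g[cbind(pmin(pmax(i, 1), length(tables$axis)),
          pmin(pmax(j, 1), length(tables$axis)))]
}

# residue class assignment; pre-Pro takes precedence over Ile/Val
rama_class <- function(res_type, next_type) {
  if (!is.na(next_type) && next_type == "PRO") return("pre_pro")
  if (res_type == "GLY") return("gly")
  if (res_type == "PRO") return("pro")
  if (res_type %in% c("ILE", "VAL")) return("ile_val")
  "general"
}

#' Ramachandran report
#'
#' One row per residue with defined phi/psi: class, relative probability,
#' category (preferred/allowed/outlier) and plot marker (triangle for Gly,
#' square for Pro, circle otherwise).
#'
#' @param s An `rs_structure`.
#' @param tables A `rama_tables` (default: built-in).
#' @param sel optional selection restricting the residues.
#' @param outliers_only return only outlier rows.
#' @return list(points = data.frame, summary = counts and percentages) of
#'   class `rama_report`.
#' @export
rama_report <- function(s, tables = rama_tables(), sel = NULL,
                        outliers_only = FALSE) {
  rt <- residue_table(s)
  if (!is.null(sel)) {
    ps <- if (is.character(sel)) parse_selection(sel) else sel
    keep <- rt$chain == ps$chain
    if (!is.na(ps$start)) keep <- keep & rt$seqnum >= ps$start &
        rt$seqnum <= ps$end
    rt <- rt[keep, , drop = FALSE]
  }
  rows <- list()
  for (i in seq_len(nrow(rt))) {
    pp <- phi_psi(s, rt$chain[i], rt$seqnum[i], rt$inscode[i])
    if (is.null(pp)) next
    nxt <- rt$resname[match(paste(rt$chain[i], rt$seqnum[i] + 1),
                            paste(rt$chain, rt$seqnum))]
    cls <- rama_class(rt$resname[i], nxt)
    prob <- rama_lookup(tables, cls, pp["phi"], pp["psi"])
    cat_ <- if (prob >= tables$preferred_min) "preferred"
      else if (prob >= tables$allowed_min) "allowed" else "outlier"
    marker <- if (rt$resname[i] == "GLY") "triangle"
      else if (rt$resname[i] == "PRO") "square" else "circle"
    rows[[length(rows) + 1]] <- data.frame(
      chain = rt$chain[i], seqnum = rt$seqnum[i], resname = rt$resname[i],
      phi = unname(pp["phi"]), psi = unname(pp["psi"]), class = cls,
      probability = unname(prob), category = cat_, marker = marker,
      stringsAsFactors = FALSE)
  }
  points <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chain = character(), seqnum = integer(),
               resname = character(), phi = numeric(), psi = numeric(),
               class = character(), probability = numeric(),
               category = character(), marker = character())
  counts <- c(preferred = sum(points$category == "preferred"),
              allowed = sum(points$category == "allowed"),
              outlier = sum(points$category == "outlier"))
  summary <- list(counts = counts,
                  percent = if (nrow(points)) 100 * counts / nrow(points)
                            else counts * NA_real_,
                  n = nrow(points))
  if (outliers_only)
    points <- points[points$category == "outlier", , drop = FALSE]
  structure(list(points = points, summary = summary),
            class = "rama_report")
}

#' @export
print.rama_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<rama_report> %d residues: %d preferred (%.1f%%), %d allowed (%.1f%%), %d outliers (%.1f%%)\n",
    s$n, s$counts["preferred"], s$percent["preferred"], s$counts["allowed"],
    s$percent["allowed"], s$counts["outlier"], s$percent["outlier"]))
  invisible(x)
}

# paired phi/psi for two chains; by seqnum when the shared residues agree in
# type, else by sequence alignment
kleywegt_pairs <- function(s1, chain_a, s2, chain_b) {
  rt1 <- residue_table(s1); rt1 <- rt1[rt1$chain == chain_a, ]
  rt2 <- residue_table(s2); rt2 <- rt2[rt2$chain == chain_b, ]
  if (!nrow(rt1) || !nrow(rt2)) stop("empty chain in Kleywegt comparison")
  common <- intersect(rt1$seqnum, rt2$seqnum)
  types_match <- length(common) > 0 &&
    all(rt1$resname[match(common, rt1$seqnum)] ==
          rt2$resname[match(common, rt2$seqnum)])
  if (types_match) return(data.frame(seq1 = common, seq2 = common))
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("chains differ in type at shared residue numbers and Biostrings ",
         "is not available for alignment-based pairing")
  a1 <- chain_sequence(s1, chain_a); a2 <- chain_sequence(s2, chain_b)
  al <- Biostrings::pairwiseAlignment(a1, a2)
  p1 <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  p2 <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  i1 <- 0L; i2 <- 0L; seq1 <- integer(0); seq2 <- integer(0)
  for (col in seq_along(p1)) {
    if (p1[col] != "-") i1 <- i1 + 1L
    if (p2[col] != "-") i2 <- i2 + 1L
    if (p1[col] != "-" && p2[col] != "-") {
      seq1 <- c(seq1, rt1$seqnum[i1]); seq2 <- c(seq2, rt2$seqnum[i2])
    }
  }
  if (!length(seq1)) stop("no common residues between the chains")
  data.frame(seq1 = seq1, seq2 = seq2)
}

#' Kleywegt comparison of two (NCS-related) chains
#'
#' Computes the Ramachandran-space torus distance
#' sqrt(dphi^2 + dpsi^2) (both wrapped to (-180, 180]) for each paired
#' residue and returns the `top_n` most distant pairs, sorted descending.
#'
#' @param s1,s2 `rs_structure`s (may be the same object).
#' @param chain_a,chain_b chains to compare.
#' @param top_n how many pairs to keep (default 50, the classical plot
#'   default).
#' @return data.frame (seqnum_a, seqnum_b, phi_a, psi_a, phi_b, psi_b,
#'   torus_distance), at most `top_n` rows.
#' @export
kleywegt_compare <- function(s1, chain_a, s2 = s1, chain_b, top_n = 50) {
  pairs <- kleywegt_pairs(s1, chain_a, s2, chain_b)
  rows <- list()
  for (q in seq_len(nrow(pairs))) {
    ppa <- phi_psi(s1, chain_a, pairs$seq1[q])
    ppb <- phi_psi(s2, chain_b, pairs$seq2[q])
    if (is.null(ppa) || is.null(ppb)) next
    td <- sqrt(wrap180(ppa["phi"] - ppb["phi"])^2 +
                 wrap180(ppa["psi"] - ppb["psi"])^2)
    rows[[length(rows) + 1]] <- data.frame(
      seqnum_a = pairs$seq1[q], seqnum_b = pairs$seq2[q],
      phi_a = unname(ppa["phi"]), psi_a = unname(ppa["psi"]),
      phi_b = unname(ppb["phi"]), psi_b = unname(ppb["psi"]),
      torus_distance = unname(td), stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no comparable residues with defined phi/psi")
  out <- do.call(rbind, rows)
  out <- out[order(-out$torus_distance), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_n)
}

#' Nearest-rotamer analysis
#'
#' For each residue with a rotamer set, reports the nearest library rotamer
#' by wrapped chi-space distance and its prior probability; GLY/ALA are
#' skipped. Exact ties go to the lower-index (more probable) rotamer.
#'
#' @param s An `rs_structure`.
#' @param sel optional selection.
#' @param rotamer_lib rotamer library (list form).
#' @return data.frame (chain, seqnum, resname, rotamer, probability,
#'   chi_distance).
#' @export
rotamer_analysis <- function(s, sel = NULL, rotamer_lib = ROTAMER_LIB) {
  rt <- residue_table(s)
  if (!is.null(sel)) {
    ps <- if (is.character(sel)) parse_selection(sel) else sel
    keep <- rt$chain == ps$chain
    if (!is.na(ps$start)) keep <- keep & rt$seqnum >= ps$start &
        rt$seqnum <= ps$end
    rt <- rt[keep, , drop = FALSE]
  }
  rows <- list()
  for (i in seq_len(nrow(rt))) {
    rl <- rotamer_lib[[rt$resname[i]]]
    if (is.null(rl)) next
    chis <- measure_chis(s, rt$chain[i], rt$seqnum[i], rt$inscode[i])
    if (!length(chis) || anyNA(chis)) next
    dists <- vapply(rl, function(r) chi_distance(chis, r[[3]]), numeric(1))
    k <- which.min(dists)   # which.min returns the first (lower index) tie
    rows[[length(rows) + 1]] <- data.frame(
      chain = rt$chain[i], seqnum = rt$seqnum[i], resname = rt$resname[i],
      rotamer = rl[[k]][[1]], probability = rl[[k]][[2]],
      chi_distance = dists[k], stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(chain = character(), seqnum = integer(),
                      resname = character(), rotamer = character(),
                      probability = numeric(), chi_distance = numeric()))
  do.call(rbind, rows)
}

#' B-factor statistics
#'
#' Occupancy-unweighted mean and median over the selected atoms, plus
#' per-residue means. The median is robust to a few extreme values (a hot
#' water does not move it, unlike the mean).
#'
#' @param s An `rs_structure`.
#' @param sel optional selection.
#' @return list(mean=, median=, per_residue= data.frame).
#' @export
b_factor_stats <- function(s, sel = NULL) {
  mask <- if (is.null(sel)) rep(TRUE, n_atoms(s)) else selection_mask(s, sel)
  if (!any(mask)) stop("empty selection")
  a <- s$atoms[mask, , drop = FALSE]
  key <- res_key(a$chain, a$seqnum, a$inscode)
  agg <- tapply(a$b, key, mean)
  first <- !duplicated(key)
  per_res <- data.frame(chain = a$chain[first], seqnum = a$seqnum[first],
                        resname = a$resname[first],
                        mean_b = as.numeric(agg[key[first]]),
                        stringsAsFactors = FALSE)
  list(mean = mean(a$b), median = stats::median(a$b), per_residue = per_res)
}

#' Per-residue density fit
#'
#' Mean of occupancy x atomic-number-weighted interpolated density over each
#' residue's atoms (normalised by atom count); residues outside the map
#' score 0.
#'
#' @param s An `rs_structure`.
#' @param map A `density_map`.
#' @param sel optional selection.
#' @return data.frame (chain, seqnum, resname, fit).
#' @export
density_fit_graph <- function(s, map, sel = NULL) {
  mask <- if (is.null(sel)) rep(TRUE, n_atoms(s)) else selection_mask(s, sel)
  a <- s$atoms[mask, , drop = FALSE]
  rho <- interpolate_density(map, as.matrix(a[, c("x", "y", "z")]))
  contrib <- a$occ * atomic_number(a$element) * rho
  key <- res_key(a$chain, a$seqnum, a$inscode)
  agg <- tapply(contrib, key, mean)
  first <- !duplicated(key)
  data.frame(chain = a$chain[first], seqnum = a$seqnum[first],
             resname = a$resname[first],
             fit = as.numeric(agg[key[first]]), stringsAsFactors = FALSE)
}

#' Dictionary-based distortion analysis of one residue/ligand
#'
#' z-scores of every bond, angle and torsion template of the dictionary
#' entry against the observed geometry (torsions use the nearest periodic
#' image), with per-class RMS z summaries. Invariant under rigid motion.
#'
#' @param s An `rs_structure`.
#' @param chain,seqnum,inscode the residue.
#' @param dict A `monomer_dictionary`.
#' @return list(bonds=, angles=, torsions= data.frames with z columns,
#'   rms_z = named per-class RMS) of class `distortion_report`.
#' @export
ligand_distortion <- function(s, chain, seqnum, inscode = "",
                              dict = default_dictionary()) {
  a <- s$atoms
  rows <- which(a$chain == chain & a$seqnum == seqnum &
                  a$inscode == inscode)
  if (!length(rows)) stop("no residue ", chain, "/", seqnum)
  rtype <- a$resname[rows[1]]
  entry <- dict[[rtype]]
  if (is.null(entry)) stop("no dictionary entry for residue type ", rtype)
  p <- function(nm) atom_pos(s, chain, seqnum, nm, inscode)
  have <- function(nms) all(nms %in% a$atom[rows])
  b <- entry$bonds
  bz <- do.call(rbind, lapply(seq_len(nrow(b)), function(q) {
    if (!have(c(b$atom1[q], b$atom2[q]))) return(NULL)
    obs <- vnorm(p(b$atom1[q]) - p(b$atom2[q]))
    data.frame(atom1 = b$atom1[q], atom2 = b$atom2[q], target = b$target[q],
               observed = obs, z = (obs - b$target[q]) / b$sigma[q])
  }))
  an <- entry$angles
  az <- if (!is.null(an)) do.call(rbind, lapply(seq_len(nrow(an)), function(q) {
    if (!have(c(an$atom1[q], an$atom2[q], an$atom3[q]))) return(NULL)
    obs <- bond_angle(p(an$atom1[q]), p(an$atom2[q]), p(an$atom3[q]))
    data.frame(atom1 = an$atom1[q], atom2 = an$atom2[q],
               atom3 = an$atom3[q], target = an$target[q], observed = obs,
               z = (obs - an$target[q]) / an$sigma[q])
  })) else NULL
  tr <- entry$torsions
  tz <- if (!is.null(tr)) do.call(rbind, lapply(seq_len(nrow(tr)), function(q) {
    if (!have(c(tr$atom1[q], tr$atom2[q], tr$atom3[q], tr$atom4[q])))
      return(NULL)
    obs <- dihedral_angle(p(tr$atom1[q]), p(tr$atom2[q]), p(tr$atom3[q]),
                          p(tr$atom4[q]))
    span <- 360 / tr$period[q]
    delta <- wrap180(obs - tr$target[q])
    delta <- delta - span * round(delta / span)
    data.frame(id = tr$id[q], target = tr$target[q], observed = obs,
               z = delta / tr$sigma[q])
  })) else NULL
  rms <- function(x) if (is.null(x) || !nrow(x)) NA_real_ else
    sqrt(mean(x$z^2))
  structure(list(bonds = bz, angles = az, torsions = tz,
                 rms_z = c(bond = rms(bz), angle = rms(az),
                           torsion = rms(tz))),
            class = "distortion_report")
}

#' @export
print.distortion_report <- function(x, ...) {
  cat(sprintf("<distortion_report> RMS z: bond %.3f, angle %.3f%s\n",
              x$rms_z["bond"], x$rms_z["angle"],
              if (!is.na(x$rms_z["torsion"]))
                sprintf(", torsion %.3f", x$rms_z["torsion"]) else ""))
  invisible(x)
}
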