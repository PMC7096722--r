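# Restraint generation: dictionary geometry (bonds, angles, torsions, planes,
# chirals), peptide links, nonbonded contacts, metal LINK bonds, and robust
# Geman-McClure self distance restraints. Restraints reference atom row
# indices of the structure they were generated from.

GM_DEFAULT_ALPHA <- 0.01
GM_DEFAULT_SIGMA <- 0.8
NB_DEFAULT_SIGMA <- 0.3
NB_SCALE <- 0.88          # reduced-contact factor on vdW radii sums
NB_NO_PAIR_RMIN <- 2.80   # potential H-bond donors/acceptors (N/O vs N/O)
NB_CUTOFF <- 4.0

new_restraint_set <- function() {
  structure(list(
    bonds = data.frame(i = integer(), j = integer(), target = numeric(),
                       sigma = numeric()),
    angles = data.frame(i = integer(), j = integer(), k = integer(),
                        target = numeric(), sigma = numeric()),
    torsions = data.frame(i = integer(), j = integer(), k = integer(),
                          l = integer(), target = numeric(),
                          sigma = numeric(), period = integer()),
    planes = list(),
    chirals = data.frame(c = integer(), i = integer(), j = integer(),
                         k = integer(), target = numeric(),
                         sigma = numeric()),
    nonbonded = data.frame(i = integer(), j = integer(), rmin = numeric(),
                           sigma = numeric()),
    gm = data.frame(i = integer(), j = integer(), target = numeric(),
                    sigma = numeric(), alpha = numeric()),
    weights = c(bond = 1, angle = 1, torsion = 1, plane = 1, chiral = 1,
                nonbonded = 1, gm = 1)), class = "restraint_set")
}

#' @export
print.restraint_set <- function(x, ...) {
  cat(sprintf(
    "<restraint_set> %d bond, %d angle, %d torsion, %d plane, %d chiral, %d nonbonded, %d GM\n",
    nrow(x$bonds), nrow(x$angles), nrow(x$torsions), length(x$planes),
    nrow(x$chirals), nrow(x$nonbonded), nrow(x$gm)))
  invisible(x)
}

# atom row index lookup for one residue: named integer vector
residue_atom_index <- function(a, rows) {
  stats::setNames(rows, a$atom[rows])
}

# all covalent bonds as an index-pair matrix: dictionary intra-residue bonds,
# peptide C-N links between consecutive residues, and LINK records.
covalent_pairs <- function(s, dict = default_dictionary()) {
  a <- s$atoms
  keys <- atom_res_keys(s)
  pairs <- list()
  for (key in unique(keys)) {
    rows <- which(keys == key)
    rt <- a$resname[rows[1]]
    entry <- dict[[rt]]
    if (is.null(entry)) next
    idx <- residue_atom_index(a, rows)
    b <- entry$bonds
    hit <- b$atom1 %in% names(idx) & b$atom2 %in% names(idx)
    if (any(hit))
      pairs[[length(pairs) + 1]] <- cbind(idx[b$atom1[hit]], idx[b$atom2[hit]])
  }
  rt <- residue_table(s)
  if (nrow(rt) > 1) {
    for (i in seq_len(nrow(rt) - 1)) {
      if (rt$chain[i] != rt$chain[i + 1]) next
      if (rt$seqnum[i + 1] - rt$seqnum[i] != 1) next
      ci <- which(keys == res_key(rt$chain[i], rt$seqnum[i], rt$inscode[i]) &
                    a$atom == "C")
      ni <- which(keys == res_key(rt$chain[i + 1], rt$seqnum[i + 1],
                                  rt$inscode[i + 1]) & a$atom == "N")
      if (length(ci) && length(ni))
        pairs[[length(pairs) + 1]] <- cbind(ci[1], ni[1])
    }
  }
  l <- s$links
  if (nrow(l)) {
    for (q in seq_len(nrow(l))) {
      i1 <- which(keys == res_key(l$chain1[q], l$seqnum1[q], l$inscode1[q]) &
                    a$atom == l$atom1[q])
      i2 <- which(keys == res_key(l$chain2[q], l$seqnum2[q], l$inscode2[q]) &
                    a$atom == l$atom2[q])
      if (length(i1) && length(i2))
        pairs[[length(pairs) + 1]] <- cbind(i1[1], i2[1])
    }
  }
  if (!length(pairs)) return(matrix(integer(), ncol = 2))
  do.call(rbind, pairs)
}

# sparse bonded-graph distances up to depth 3: returns a character set of
# "i:j" keys (i < j) for graph distance 1, 2 and 3
bonded_exclusion_keys <- function(pairs, max_depth = 3) {
  if (!nrow(pairs)) return(character(0))
  adj <- split(c(pairs[, 2], pairs[, 1]), c(pairs[, 1], pairs[, 2]))
  keyfun <- function(i, j) paste(pmin(i, j), pmax(i, j), sep = ":")
  seen <- new.env(parent = emptyenv())
  for (v in names(adj)) adj[[v]] <- unique(adj[[v]])
  out <- character(0)
  for (v in as.integer(names(adj))) {
    # BFS to depth max_depth
    frontier <- v; dist <- stats::setNames(0L, v)
    for (dd in seq_len(max_depth)) {
      nxt <- unique(unlist(adj[as.character(frontier)], use.names = FALSE))
      nxt <- nxt[!as.character(nxt) %in% names(dist)]
      if (!length(nxt)) break
      dist[as.character(nxt)] <- dd
      frontier <- nxt
    }
    reach <- as.integer(names(dist)[dist > 0])
    reach <- reach[reach > v]
    if (length(reach)) out <- c(out, keyfun(v, reach))
  }
  unique(out)
}

all_pairs_within <- function(xyz, limit) {
  # index pairs (i < j) with distance <= limit, plus the distances
  n <- nrow(xyz)
  if (n < 2) return(data.frame(i = integer(), j = integer(), d = numeric()))
  dm <- as.matrix(stats::dist(xyz))
  hit <- which(upper.tri(dm) & dm <= limit, arr.ind = TRUE)
  data.frame(i = hit[, 1], j = hit[, 2], d = dm[hit])
}

#' Build standard geometry restraints
#'
#' Intra-residue bond/angle/torsion/plane/chiral restraints from the monomer
#' dictionary, inter-residue peptide restraints (C-N bond 1.329 A, link
#' angles, planar trans peptide), and nonbonded contact pairs for all
#' non-excluded atom pairs within a cutoff (1-2, 1-3 and 1-4 neighbours and
#' metal-link pairs are excluded).
#'
#' @param s An `rs_structure`.
#' @param dict A `monomer_dictionary` (default: built-in).
#' @param sel optional selection (string or parsed) restricting the residues.
#' @param nonbonded_cutoff pair cutoff in A for contact restraints.
#' @param include_torsions include side-chain torsion restraints (default
#'   TRUE).
#' @return A `restraint_set`.
#' @export
build_standard_restraints <- function(s, dict = default_dictionary(),
                                      sel = NULL,
                                      nonbonded_cutoff = NB_CUTOFF,
                                      include_torsions = TRUE) {
  a <- s$atoms
  keys <- atom_res_keys(s)
  in_sel <- if (is.null(sel)) rep(TRUE, nrow(a)) else selection_mask(s, sel)
  rs <- new_restraint_set()
  g <- BB_GEOM
  rt <- residue_table(s)
  rt_keys <- res_key(rt$chain, rt$seqnum, rt$inscode)
  sel_res <- unique(keys[in_sel])
  bonds <- list(); angles <- list(); torsions <- list(); chirals <- list()
  for (key in sel_res) {
    rows <- which(keys == key)
    rtype <- a$resname[rows[1]]
    entry <- dict[[rtype]]
    if (is.null(entry)) {
      if (length(rows) == 1) next   # single-atom residue (ion/water O): no internal geometry
      stop("no dictionary entry for residue type ", rtype)
    }
    idx <- residue_atom_index(a, rows)
    nm <- names(idx)
    b <- entry$bonds
    hit <- b$atom1 %in% nm & b$atom2 %in% nm
    if (any(hit))
      bonds[[length(bonds) + 1]] <- data.frame(
        i = unname(idx[b$atom1[hit]]), j = unname(idx[b$atom2[hit]]),
        target = b$target[hit], sigma = b$sigma[hit])
    an <- entry$angles
    if (!is.null(an)) {
      hit <- an$atom1 %in% nm & an$atom2 %in% nm & an$atom3 %in% nm
      if (any(hit))
        angles[[length(angles) + 1]] <- data.frame(
          i = unname(idx[an$atom1[hit]]), j = unname(idx[an$atom2[hit]]),
          k = unname(idx[an$atom3[hit]]),
          target = an$target[hit], sigma = an$sigma[hit])
    }
    tr <- entry$torsions
    if (include_torsions && !is.null(tr)) {
      hit <- tr$atom1 %in% nm & tr$atom2 %in% nm & tr$atom3 %in% nm &
        tr$atom4 %in% nm
      if (any(hit))
        torsions[[length(torsions) + 1]] <- data.frame(
          i = unname(idx[tr$atom1[hit]]), j = unname(idx[tr$atom2[hit]]),
          k = unname(idx[tr$atom3[hit]]), l = unname(idx[tr$atom4[hit]]),
          target = tr$target[hit], sigma = tr$sigma[hit],
          period = tr$period[hit])
    }
    for (p in entry$planes) {
      if (all(p$atoms %in% nm))
        rs$planes[[length(rs$planes) + 1]] <-
          list(idx = unname(idx[p$atoms]), sigma = p$sigma)
    }
    ch <- entry$chirals
    if (!is.null(ch)) {
      hit <- ch$centre %in% nm & ch$atom1 %in% nm & ch$atom2 %in% nm &
        ch$atom3 %in% nm
      if (any(hit))
        chirals[[length(chirals) + 1]] <- data.frame(
          c = unname(idx[ch$centre[hit]]), i = unname(idx[ch$atom1[hit]]),
          j = unname(idx[ch$atom2[hit]]), k = unname(idx[ch$atom3[hit]]),
          target = ch$target[hit], sigma = ch$sigma[hit])
    }
  }
  # peptide links between consecutive selected residues
  sel_pos <- which(rt_keys %in% sel_res)
  for (i in sel_pos) {
    if (i + 1 > nrow(rt)) next
    if (!(rt_keys[i + 1] %in% sel_res)) next
    if (rt$chain[i] != rt$chain[i + 1]) next
    if (rt$seqnum[i + 1] - rt$seqnum[i] != 1) next
    at <- function(pos, name) {
      w <- which(keys == rt_keys[pos] & a$atom == name)
      if (length(w)) w[1] else NA_integer_
    }
    CAi <- at(i, "CA"); Ci <- at(i, "C"); Oi <- at(i, "O")
    Ni1 <- at(i + 1, "N"); CAi1 <- at(i + 1, "CA")
    if (is.na(Ci) || is.na(Ni1)) next
    bonds[[length(bonds) + 1]] <- data.frame(
      i = Ci, j = Ni1, target = g$b_C_N[1], sigma = g$b_C_N[2])
    if (!is.na(CAi))
      angles[[length(angles) + 1]] <- data.frame(
        i = CAi, j = Ci, k = Ni1, target = g$a_CA_C_N[1],
        sigma = g$a_CA_C_N[2])
    if (!is.na(Oi))
      angles[[length(angles) + 1]] <- data.frame(
        i = Oi, j = Ci, k = Ni1, target = g$a_O_C_N[1], sigma = g$a_O_C_N[2])
    if (!is.na(CAi1))
      angles[[length(angles) + 1]] <- data.frame(
        i = Ci, j = Ni1, k = CAi1, target = g$a_C_N_CA[1],
        sigma = g$a_C_N_CA[2])
    if (!is.na(CAi) && !is.na(CAi1)) {
      torsions[[length(torsions) + 1]] <- data.frame(
        i = CAi, j = Ci, k = Ni1, l = CAi1, target = 180, sigma = 5,
        period = 1L)
      if (!is.na(Oi))
        rs$planes[[length(rs$planes) + 1]] <-
          list(idx = c(CAi, Ci, Oi, Ni1, CAi1), sigma = 0.03)
    }
  }
  bindup <- function(lst, proto) if (length(lst)) do.call(rbind, lst) else proto
  rs$bonds <- bindup(bonds, rs$bonds)
  rs$angles <- bindup(angles, rs$angles)
  rs$torsions <- bindup(torsions, rs$torsions)
  rs$chirals <- bindup(chirals, rs$chirals)
  # nonbonded pairs among selected atoms
  metal <- metal_link_restraints(s, quiet = TRUE)
  rs$bonds <- rbind(rs$bonds, metal$bonds)
  sel_idx <- which(in_sel)
  if (length(sel_idx) > 1 && nonbonded_cutoff > 0) {
    cp <- covalent_pairs(s, dict)
    excl <- bonded_exclusion_keys(cp, 3)
    if (nrow(metal$suppressed))
      excl <- c(excl, paste(pmin(metal$suppressed$i, metal$suppressed$j),
                            pmax(metal$suppressed$i, metal$suppressed$j),
                            sep = ":"))
    pw <- all_pairs_within(coords(s)[sel_idx, , drop = FALSE],
                           nonbonded_cutoff)
    gi <- sel_idx[pw$i]; gj <- sel_idx[pw$j]
    keep <- !(paste(pmin(gi, gj), pmax(gi, gj), sep = ":") %in% excl) &
      keys[gi] != keys[gj]   # intra-residue contacts are governed by the dictionary
    gi <- gi[keep]; gj <- gj[keep]
    if (length(gi)) {
      e1 <- a$element[gi]; e2 <- a$element[gj]
      r1 <- VDW_RADII[e1]; r1[is.na(r1)] <- 1.7
      r2 <- VDW_RADII[e2]; r2[is.na(r2)] <- 1.7
      rmin <- NB_SCALE * (r1 + r2)
      hb <- e1 %in% c("N", "O") & e2 %in% c("N", "O")
      rmin[hb] <- pmin(rmin[hb], NB_NO_PAIR_RMIN)
      rs$nonbonded <- data.frame(i = gi, j = gj, rmin = unname(rmin),
                                 sigma = NB_DEFAULT_SIGMA)
    }
  }
  rs
}

#' Generate robust self distance restraints
#'
#' One Geman-McClure restraint per unordered atom pair within the selection
#' whose current distance is at most `limit` and which is not a 1-2 or 1-3
#' bonded pair; the target is the current distance, so the set encodes the
#' starting model's local geometry.
#'
#' @param s An `rs_structure` (the reference model).
#' @param sel optional selection; default whole structure.
#' @param limit distance cutoff in A (4.2 classically; 6-7 with more CPU or
#'   for side-chain-less models).
#' @param alpha Geman-McClure robustness parameter (>= 0).
#' @param sigma restraint sigma in A (default 0.8, a typical esd for
#'   long-range reference-model distance restraints at low resolution).
#' @param dict dictionary used to derive the bonded graph.
#' @return data.frame (i, j, target, sigma, alpha) of GM restraints.
#' @export
generate_self_gm_restraints <- function(s, sel = NULL, limit = 4.2,
                                        alpha = GM_DEFAULT_ALPHA,
                                        sigma = GM_DEFAULT_SIGMA,
                                        dict = default_dictionary()) {
  if (limit <= 0) stop("limit must be positive")
  in_sel <- if (is.null(sel)) rep(TRUE, n_atoms(s)) else selection_mask(s, sel)
  sel_idx <- which(in_sel)
  if (!length(sel_idx)) stop("empty selection")
  pw <- all_pairs_within(coords(s)[sel_idx, , drop = FALSE], limit)
  gi <- sel_idx[pw$i]; gj <- sel_idx[pw$j]
  cp <- covalent_pairs(s, dict)
  excl <- bonded_exclusion_keys(cp, 2)   # 1-2 and 1-3 only
  keep <- !(paste(pmin(gi, gj), pmax(gi, gj), sep = ":") %in% excl)
  data.frame(i = gi[keep], j = gj[keep], target = pw$d[keep],
             sigma = sigma, alpha = alpha, row.names = NULL)
}

#' Geman-McClure residual and derivative
#'
#' With z = (d - target)/sigma the energy is z^2 / (1 + alpha z^2): harmonic
#' near the target, saturating at 1/alpha for large deviations (alpha = 0
#' recovers the plain harmonic).
#'
#' @param d observed distance(s), A.
#' @param target,sigma,alpha restraint parameters (vectorised).
#' @return list(energy=, gradient=) where gradient is d energy / d d.
#' @export
gm_residual <- function(d, target, sigma, alpha = GM_DEFAULT_ALPHA) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  if (any(d < 0)) stop("distance must be non-negative")
  z <- (d - target) / sigma
  den <- 1 + alpha * z^2
  list(energy = z^2 / den,
       gradient = 2 * z / (den^2 * sigma))
}

#' Bond restraints for metal LINK records
#'
#' For each LINK whose one end is a metal and whose other end is a nitrogen,
#' oxygen or sulfur ligand atom, emits a bond restraint with an element-pair
#' target from the built-in table; the pair is also reported as suppressed so
#' nonbonded generation skips it. Other LINKs are ignored; unresolvable
#' endpoints produce a warning and are skipped.
#'
#' @param s An `rs_structure` with parsed links.
#' @param table named numeric vector overriding the built-in
#'   "METAL:ELEMENT" target table.
#' @param sigma bond sigma in A.
#' @param quiet suppress dangling-link warnings.
#' @return list(bonds = data.frame(i, j, target, sigma),
#'   suppressed = data.frame(i, j)).
#' @export
metal_link_restraints <- function(s, table = METAL_BOND_TABLE, sigma = 0.05,
                                  quiet = FALSE) {
  a <- s$atoms
  keys <- atom_res_keys(s)
  bonds <- list(); supp <- list()
  l <- s$links
  if (nrow(l)) for (q in seq_len(nrow(l))) {
    i1 <- which(keys == res_key(l$chain1[q], l$seqnum1[q], l$inscode1[q]) &
                  a$atom == l$atom1[q])
    i2 <- which(keys == res_key(l$chain2[q], l$seqnum2[q], l$inscode2[q]) &
                  a$atom == l$atom2[q])
    if (!length(i1) || !length(i2)) {
      if (!quiet)
        warning("dangling LINK record skipped: ", l$atom1[q], "/",
                l$atom2[q])
      next
    }
    i1 <- i1[1]; i2 <- i2[1]
    e1 <- a$element[i1]; e2 <- a$element[i2]
    if (e2 %in% METAL_ELEMENTS && !(e1 %in% METAL_ELEMENTS)) {
      tmp <- i1; i1 <- i2; i2 <- tmp
      tmp <- e1; e1 <- e2; e2 <- tmp
    }
    if (!(e1 %in% METAL_ELEMENTS) || !(e2 %in% c("N", "O", "S"))) next
    key <- paste0(e1, ":", e2)
    if (!key %in% names(table)) next
    bonds[[length(bonds) + 1]] <- data.frame(
      i = i1, j = i2, target = unname(table[key]), sigma = sigma)
    supp[[length(supp) + 1]] <- data.frame(i = i1, j = i2)
  }
  list(bonds = if (length(bonds)) do.call(rbind, bonds) else
         data.frame(i = integer(), j = integer(), target = numeric(),
                    sigma = numeric()),
       suppressed = if (length(supp)) do.call(rbind, supp) else
         data.frame(i = integer(), j = integer()))
}
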