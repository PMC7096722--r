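# Ideal-geometry builders: free-standing residue templates (used to derive
# the monomer dictionary and to rebuild side chains) and polypeptide fixtures.

parse_torsion_spec <- function(spec, chis) {
  # "chi2+120", "chi1", "180" -> numeric degrees
  if (is.numeric(spec)) return(spec)
  m <- regmatches(spec, regexec("^chi([0-9])([+-][0-9.]+)?$", spec))[[1]]
  if (length(m)) {
    k <- as.integer(m[2])
    if (k > length(chis)) stop("torsion spec needs chi", k, " but only ",
                               length(chis), " supplied")
    off <- if (nzchar(m[3])) as.numeric(m[3]) else 0
    return(chis[k] + off)
  }
  as.numeric(spec)
}

top_rotamer_chis <- function(res_type) {
  rl <- ROTAMER_LIB[[res_type]]
  if (is.null(rl)) return(numeric(0))
  probs <- vapply(rl, function(r) r[[2]], numeric(1))
  rl[[which.max(probs)]][[3]]
}

#' Build a free-standing ideal-geometry residue
#'
#' Places backbone N, CA, C, O (and CB for non-glycine) at dictionary-ideal
#' internal coordinates, then constructs the side chain from the embedded
#' z-matrix with the requested chi angles.
#'
#' @param res_type three-letter residue code (one of the 20 amino acids).
#' @param chis numeric chi angles in degrees; defaults to the most probable
#'   rotamer of `res_type`.
#' @return data.frame with columns atom, element, x, y, z.
#' @export
build_residue_template <- function(res_type, chis = NULL) {
  res_type <- toupper(res_type)
  if (!res_type %in% names(SIDE_CHAIN_ZMAT))
    stop("unsupported residue type: ", res_type)
  if (is.null(chis)) chis <- top_rotamer_chis(res_type)
  g <- BB_GEOM
  pos <- list(N = c(0, 0, 0), CA = c(g$b_N_CA[1], 0, 0))
  pos$C <- place_internal(pos$CA, pos$N, c(0, 0, 1), g$b_CA_C[1],
                          g$a_N_CA_C[1], 0)
  pos$O <- place_internal(pos$C, pos$CA, pos$N, g$b_C_O[1], g$a_CA_C_O[1], 180)
  el <- c(N = "N", CA = "C", C = "C", O = "O")
  if (res_type != "GLY") {
    pos$CB <- place_internal(pos$CA, pos$N, pos$C, g$b_CA_CB[1],
                             g$a_N_CA_CB[1], g$t_CB_improper)
    el["CB"] <- "C"
  }
  for (row in SIDE_CHAIN_ZMAT[[res_type]]) {
    tor <- parse_torsion_spec(row$tor, chis)
    pos[[row$atom]] <- place_internal(pos[[row$a1]], pos[[row$a2]],
                                      pos[[row$a3]], row$bond, row$angle, tor)
    el[row$atom] <- row$el
  }
  nm <- names(pos)
  data.frame(atom = nm, element = unname(el[nm]),
             x = vapply(pos, `[`, numeric(1), 1),
             y = vapply(pos, `[`, numeric(1), 2),
             z = vapply(pos, `[`, numeric(1), 3),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Build the toy ligand template
#'
#' Chlorobenzene with a methyl-carbon anchor; the C1-C2 bond is rotatable
#' (used by torsion-flip examples).
#'
#' @return data.frame with columns atom, element, x, y, z.
#' @export
build_toy_ligand <- function() {
  pos <- list(C1 = c(0, 0, 0))
  el <- c(C1 = "C")
  dummy <- c(0, 1, 0)
  for (row in TOY_LIGAND_ZMAT) {
    a1 <- pos[[row$a1]]
    if (is.na(row$a2)) {           # C2: along +x from C1
      pos[[row$atom]] <- a1 + c(row$bond, 0, 0)
    } else if (is.na(row$a3)) {    # C3: in xy-plane
      pos[[row$atom]] <- place_internal(a1, pos[[row$a2]], dummy,
                                        row$bond, row$angle, 0)
    } else {
      pos[[row$atom]] <- place_internal(a1, pos[[row$a2]], pos[[row$a3]],
                                        row$bond, row$angle,
                                        as.numeric(row$tor))
    }
    el[row$atom] <- row$el
  }
  nm <- names(pos)
  data.frame(atom = nm, element = unname(el[nm]),
             x = vapply(pos, `[`, numeric(1), 1),
             y = vapply(pos, `[`, numeric(1), 2),
             z = vapply(pos, `[`, numeric(1), 3),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Generate an ideal-geometry polypeptide
#'
#' Backbone built by internal coordinates at fixed (phi, psi, omega); side
#' chains placed at the most probable rotamer. `conformation = "helix"` uses
#' (-57, -47), `"strand"` (-120, 120); explicit `phi`/`psi` override.
#'
#' @param sequence one-letter amino-acid sequence (e.g. "AAAAA"), or a single
#'   integer n meaning poly-ALA of length n.
#' @param conformation "helix" or "strand".
#' @param phi,psi,omega backbone torsions in degrees (override conformation).
#' @param chain_id chain identifier for the result.
#' @param start_seqnum first residue number.
#' @param b B-factor assigned to every atom (A^2).
#' @return An `rs_structure`.
#' @export
make_ideal_polypeptide <- function(sequence, conformation = c("helix", "strand"),
                                   phi = NULL, psi = NULL, omega = 180,
                                   chain_id = "A", start_seqnum = 1L, b = 20) {
  conformation <- match.arg(conformation)
  if (is.numeric(sequence) && length(sequence) == 1)
    sequence <- paste(rep("A", sequence), collapse = "")
  seq1 <- strsplit(toupper(sequence), "")[[1]]
  if (!all(seq1 %in% names(AA_THREE)))
    stop("invalid one-letter code(s): ",
         paste(unique(seq1[!seq1 %in% names(AA_THREE)]), collapse = ""))
  if (is.null(phi)) phi <- if (conformation == "helix") -57 else -120
  if (is.null(psi)) psi <- if (conformation == "helix") -47 else 120
  n <- length(seq1)
  g <- BB_GEOM
  # backbone trace
  N <- CA <- C <- vector("list", n)
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(g$b_N_CA[1], 0, 0)
  C[[1]] <- place_internal(CA[[1]], N[[1]], c(0, 0, 1), g$b_CA_C[1],
                           g$a_N_CA_C[1], 0)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      N[[i + 1]] <- place_internal(C[[i]], CA[[i]], N[[i]], g$b_C_N[1],
                                   g$a_CA_C_N[1], psi)
      CA[[i + 1]] <- place_internal(N[[i + 1]], C[[i]], CA[[i]], g$b_N_CA[1],
                                    g$a_C_N_CA[1], omega)
      C[[i + 1]] <- place_internal(CA[[i + 1]], N[[i + 1]], C[[i]],
                                   g$b_CA_C[1], g$a_N_CA_C[1], phi)
    }
  }
  rows <- list()
  for (i in seq_len(n)) {
    rt <- AA_THREE[[seq1[i]]]
    pos <- list(N = N[[i]], CA = CA[[i]], C = C[[i]])
    el <- c(N = "N", CA = "C", C = "C")
    if (i < n) {
      pos$O <- place_internal(C[[i]], N[[i + 1]], CA[[i + 1]], g$b_C_O[1],
                              g$a_O_C_N[1], 0)
    } else {
      pos$O <- place_internal(C[[i]], CA[[i]], N[[i]], g$b_C_O[1],
                              g$a_CA_C_O[1], wrap180(psi + 180))
    }
    el["O"] <- "O"
    if (rt != "GLY") {
      pos$CB <- place_internal(CA[[i]], N[[i]], C[[i]], g$b_CA_CB[1],
                               g$a_N_CA_CB[1], g$t_CB_improper)
      el["CB"] <- "C"
    }
    chis <- top_rotamer_chis(rt)
    for (row in SIDE_CHAIN_ZMAT[[rt]]) {
      pos[[row$atom]] <- place_internal(pos[[row$a1]], pos[[row$a2]],
                                        pos[[row$a3]], row$bond, row$angle,
                                        parse_torsion_spec(row$tor, chis))
      el[row$atom] <- row$el
    }
    nm <- names(pos)
    rows[[i]] <- data.frame(
      chain = chain_id, seqnum = start_seqnum + i - 1L, inscode = "",
      resname = rt, atom = nm, altloc = "", element = unname(el[nm]),
      x = vapply(pos, `[`, numeric(1), 1),
      y = vapply(pos, `[`, numeric(1), 2),
      z = vapply(pos, `[`, numeric(1), 3),
      occ = 1, b = b, row.names = NULL, stringsAsFactors = FALSE)
  }
  rs_structure(do.call(rbind, rows), title = "ideal polypeptide")
}

#' Build the toy ligand as a one-residue structure
#'
#' @param chain_id,seqnum placement of the ligand residue.
#' @param b B-factor for all atoms.
#' @return An `rs_structure` with one residue of type "TOY".
#' @export
make_toy_ligand <- function(chain_id = "X", seqnum = 1L, b = 20) {
  tpl <- build_toy_ligand()
  atoms <- data.frame(chain = chain_id, seqnum = as.integer(seqnum),
                      inscode = "", resname = "TOY", atom = tpl$atom,
                      altloc = "", element = tpl$element,
                      x = tpl$x, y = tpl$y, z = tpl$z, occ = 1, b = b,
                      stringsAsFactors = FALSE)
  rs_structure(atoms, title = "toy ligand")
}

#' Build side-chain atom positions on an existing backbone
#'
#' CB is reconstructed from N, CA, C by the ideal improper torsion; the rest
#' of the side chain follows the z-matrix with the given chi angles.
#'
#' @param N,CA,C backbone atom positions (length-3 numeric).
#' @param res_type three-letter residue code.
#' @param chis chi angles in degrees (defaults to the top rotamer).
#' @return data.frame atom/element/x/y/z for CB and beyond (empty for GLY).
#' @export
build_side_chain_positions <- function(N, CA, C, res_type, chis = NULL) {
  res_type <- toupper(res_type)
  if (!res_type %in% names(SIDE_CHAIN_ZMAT))
    stop("unsupported residue type: ", res_type)
  if (res_type == "GLY")
    return(data.frame(atom = character(), element = character(),
                      x = numeric(), y = numeric(), z = numeric()))
  if (is.null(chis)) chis <- top_rotamer_chis(res_type)
  g <- BB_GEOM
  pos <- list(N = N, CA = CA, C = C)
  el <- character(0)
  pos$CB <- place_internal(CA, N, C, g$b_CA_CB[1], g$a_N_CA_CB[1],
                           g$t_CB_improper)
  el["CB"] <- "C"
  for (row in SIDE_CHAIN_ZMAT[[res_type]]) {
    pos[[row$atom]] <- place_internal(pos[[row$a1]], pos[[row$a2]],
                                      pos[[row$a3]], row$bond, row$angle,
                                      parse_torsion_spec(row$tor, chis))
    el[row$atom] <- row$el
  }
  nm <- names(el)
  data.frame(atom = nm, element = unname(el),
             x = vapply(pos[nm], `[`, numeric(1), 1),
             y = vapply(pos[nm], `[`, numeric(1), 2),
             z = vapply(pos[nm], `[`, numeric(1), 3),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Replace one residue's side chain (CB onwards) in place; backbone untouched.
# Returns the structure with the residue's atoms swapped for backbone +
# rebuilt side chain of `new_type`.
swap_side_chain <- function(s, chain, seqnum, new_type, chis = NULL,
                            inscode = "") {
  a <- s$atoms
  in_res <- a$chain == chain & a$seqnum == seqnum & a$inscode == inscode
  if (!any(in_res)) stop("no residue ", chain, "/", seqnum)
  bb_names <- c("N", "CA", "C", "O", "OXT")
  keep <- a[in_res & a$atom %in% bb_names, , drop = FALSE]
  keep$resname <- new_type
  Np <- atom_pos(s, chain, seqnum, "N", inscode)
  CAp <- atom_pos(s, chain, seqnum, "CA", inscode)
  Cp <- atom_pos(s, chain, seqnum, "C", inscode)
  if (is.null(Np) || is.null(CAp) || is.null(Cp))
    stop("residue ", chain, "/", seqnum, " lacks backbone atoms")
  sc <- build_side_chain_positions(Np, CAp, Cp, new_type, chis)
  scrows <- if (nrow(sc)) data.frame(
    chain = chain, seqnum = as.integer(seqnum), inscode = inscode,
    resname = new_type, atom = sc$atom, altloc = "", element = sc$element,
    x = sc$x, y = sc$y, z = sc$z, occ = keep$occ[1], b = keep$b[1],
    stringsAsFactors = FALSE) else NULL
  before <- a[seq_len(nrow(a)) < which(in_res)[1] & !in_res, , drop = FALSE]
  after <- a[seq_len(nrow(a)) > which(in_res)[1] & !in_res, , drop = FALSE]
  s$atoms <- rbind(before, keep, scrows, after)
  s
}

#' Apply a rigid transform and/or coordinate noise to a structure
#'
#' @param s An `rs_structure`.
#' @param rotation_axis,rotation_deg rigid rotation about the centroid.
#' @param translation length-3 translation (A).
#' @param noise_A standard deviation of isotropic Gaussian coordinate noise.
#' @param seed RNG seed for the noise (required when noise_A > 0).
#' @return Perturbed `rs_structure`.
#' @export
perturb_structure <- function(s, rotation_axis = c(0, 0, 1), rotation_deg = 0,
                              translation = c(0, 0, 0), noise_A = 0,
                              seed = NULL) {
  xyz <- coords(s)
  if (rotation_deg != 0) {
    cen <- colMeans(xyz)
    xyz <- rotate_about_axis(xyz, cen, rotation_axis, rotation_deg)
  }
  xyz <- sweep(xyz, 2, translation, `+`)
  if (noise_A > 0) {
    if (!is.null(seed)) set.seed(seed)
    xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, noise_A), ncol = 3)
  }
  coords(s) <- xyz
  s
}
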