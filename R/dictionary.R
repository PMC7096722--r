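# Monomer restraint dictionary: per residue/ligand type, atoms plus bond /
# angle / torsion / plane / chiral templates. The built-in dictionary is
# derived by measuring the ideal-coordinate templates, so restraint targets
# and the builders agree exactly. External dictionaries in the mmCIF
# restraint dialect (_chem_comp_bond / _angle / _tor / _plane_atom / _chir)
# can be read and merged.

DEFAULT_BOND_SIGMA <- 0.020
DEFAULT_ANGLE_SIGMA <- 2.0
DEFAULT_TORSION_SIGMA <- 20.0
DEFAULT_PLANE_SIGMA <- 0.02
DEFAULT_CHIRAL_SIGMA <- 0.20

# intra-residue bond list (atom-name pairs) for a residue type
residue_bond_pairs <- function(res_type) {
  res_type <- toupper(res_type)
  if (res_type == "TOY") return(TOY_LIGAND_BONDS)
  if (!res_type %in% names(SIDE_CHAIN_ZMAT))
    stop("no topology for residue type ", res_type)
  bonds <- list(c("N", "CA"), c("CA", "C"), c("C", "O"))
  if (res_type != "GLY") bonds <- c(bonds, list(c("CA", "CB")))
  for (row in SIDE_CHAIN_ZMAT[[res_type]])
    bonds <- c(bonds, list(c(row$a1, row$atom)))
  if (res_type %in% names(RING_CLOSURES))
    bonds <- c(bonds, RING_CLOSURES[[res_type]])
  bonds
}

# adjacency list from bond pairs
bond_adjacency <- function(bonds, atoms) {
  adj <- stats::setNames(vector("list", length(atoms)), atoms)
  for (b in bonds) {
    adj[[b[1]]] <- c(adj[[b[1]]], b[2])
    adj[[b[2]]] <- c(adj[[b[2]]], b[1])
  }
  adj
}

derive_monomer_entry <- function(res_type) {
  res_type <- toupper(res_type)
  tpl <- if (res_type == "TOY") build_toy_ligand() else
    build_residue_template(res_type)
  p <- function(nm) unlist(tpl[tpl$atom == nm, c("x", "y", "z")], use.names = FALSE)
  bonds <- residue_bond_pairs(res_type)
  bsig <- function(a1, a2) {
    key <- paste(sort(c(a1, a2)), collapse = "-")
    bb <- c("CA-N" = BB_GEOM$b_N_CA[2], "C-CA" = BB_GEOM$b_CA_C[2],
            "C-O" = BB_GEOM$b_C_O[2], "CA-CB" = BB_GEOM$b_CA_CB[2])
    if (key %in% names(bb)) unname(bb[key]) else DEFAULT_BOND_SIGMA
  }
  bond_df <- do.call(rbind, lapply(bonds, function(b) {
    data.frame(atom1 = b[1], atom2 = b[2],
               target = vnorm(p(b[1]) - p(b[2])), sigma = bsig(b[1], b[2]),
               stringsAsFactors = FALSE)
  }))
  adj <- bond_adjacency(bonds, tpl$atom)
  ang_rows <- list()
  for (centre in tpl$atom) {
    nb <- sort(unique(adj[[centre]]))
    if (length(nb) < 2) next
    for (i in seq_len(length(nb) - 1)) for (j in seq(i + 1, length(nb))) {
      ang_rows[[length(ang_rows) + 1]] <- data.frame(
        atom1 = nb[i], atom2 = centre, atom3 = nb[j],
        target = bond_angle(p(nb[i]), p(centre), p(nb[j])),
        sigma = DEFAULT_ANGLE_SIGMA, stringsAsFactors = FALSE)
    }
  }
  angle_df <- do.call(rbind, ang_rows)
  # chi torsions (proteins) or rotatable-bond torsions (toy ligand)
  tor_rows <- list()
  if (res_type == "TOY") {
    for (tt in TOY_TORSIONS) {
      q <- tt$atoms
      tor_rows[[length(tor_rows) + 1]] <- data.frame(
        id = paste0("tor", length(tor_rows) + 1),
        atom1 = q[1], atom2 = q[2], atom3 = q[3], atom4 = q[4],
        target = dihedral_angle(p(q[1]), p(q[2]), p(q[3]), p(q[4])),
        sigma = DEFAULT_TORSION_SIGMA, period = tt$period,
        stringsAsFactors = FALSE)
    }
  } else if (res_type %in% names(CHI_ATOMS)) {
    periods <- CHI_PERIODS[[res_type]]
    for (k in seq_along(CHI_ATOMS[[res_type]])) {
      q <- CHI_ATOMS[[res_type]][[k]]
      tor_rows[[length(tor_rows) + 1]] <- data.frame(
        id = paste0("chi", k),
        atom1 = q[1], atom2 = q[2], atom3 = q[3], atom4 = q[4],
        target = dihedral_angle(p(q[1]), p(q[2]), p(q[3]), p(q[4])),
        sigma = DEFAULT_TORSION_SIGMA, period = as.integer(periods[k]),
        stringsAsFactors = FALSE)
    }
  }
  torsion_df <- if (length(tor_rows)) do.call(rbind, tor_rows) else NULL
  planes <- list()
  if (res_type %in% names(PLANAR_GROUPS)) {
    for (k in seq_along(PLANAR_GROUPS[[res_type]])) {
      planes[[k]] <- list(id = paste0("plan", k),
                          atoms = PLANAR_GROUPS[[res_type]][[k]],
                          sigma = DEFAULT_PLANE_SIGMA)
    }
  }
  chir_rows <- list()
  add_chir <- function(centre, n1, n2, n3) {
    data.frame(id = paste0("chir", length(chir_rows) + 1),
               centre = centre, atom1 = n1, atom2 = n2, atom3 = n3,
               target = chiral_volume(p(centre), p(n1), p(n2), p(n3)),
               sigma = DEFAULT_CHIRAL_SIGMA, stringsAsFactors = FALSE)
  }
  if (!res_type %in% c("GLY", "TOY"))
    chir_rows[[length(chir_rows) + 1]] <- add_chir("CA", "N", "C", "CB")
  if (res_type == "THR")
    chir_rows[[length(chir_rows) + 1]] <- add_chir("CB", "CA", "OG1", "CG2")
  if (res_type == "ILE")
    chir_rows[[length(chir_rows) + 1]] <- add_chir("CB", "CA", "CG1", "CG2")
  chiral_df <- if (length(chir_rows)) do.call(rbind, chir_rows) else NULL
  list(res_type = res_type,
       atoms = tpl[, c("atom", "element")],
       bonds = bond_df, angles = angle_df, torsions = torsion_df,
       planes = planes, chirals = chiral_df)
}

#' Built-in monomer restraint dictionary
#'
#' Entries for the 20 standard amino acids plus the toy ligand "TOY".
#' Bond/angle/chiral targets are measured from the package's ideal-coordinate
#' templates (Engh-Huber-style values), so geometry built by the fixture
#' generators scores zero distortion against this dictionary.
#'
#' @return An object of class `monomer_dictionary` (a named list of entries).
#' @export
default_dictionary <- function() {
  env <- .rsfit_cache
  if (is.null(env$dict)) {
    types <- c(unname(AA_THREE), "TOY")
    dict <- stats::setNames(lapply(types, derive_monomer_entry), types)
    class(dict) <- "monomer_dictionary"
    env$dict <- dict
  }
  env$dict
}

.rsfit_cache <- new.env(parent = emptyenv())

#' @export
print.monomer_dictionary <- function(x, ...) {
  cat(sprintf("<monomer_dictionary> %d entries: %s\n", length(x),
              paste(names(x), collapse = " ")))
  invisible(x)
}

#' Read a restraint dictionary in the mmCIF chem_comp dialect
#'
#' Understands `_chem_comp_atom`, `_chem_comp_bond`, `_chem_comp_angle`,
#' `_chem_comp_tor`, `_chem_comp_plane_atom` and `_chem_comp_chir`
#' categories (value_dist / value_angle with their esds).
#'
#' @param path file path of the dictionary.
#' @return A `monomer_dictionary`.
#' @export
read_restraint_dictionary <- function(path) {
  if (!file.exists(path)) stop("no such dictionary file: ", path)
  cif <- parse_cif(readLines(path, warn = FALSE))
  atoms <- cif[["_chem_comp_atom"]]
  if (is.null(atoms)) stop("dictionary parse failure: no _chem_comp_atom loop")
  dict <- list()
  for (comp in unique(atoms$comp_id)) {
    sel <- function(df) if (is.null(df)) NULL else df[df$comp_id == comp, , drop = FALSE]
    at <- sel(atoms)
    entry_atoms <- data.frame(atom = at$atom_id,
                              element = toupper(at$type_symbol),
                              stringsAsFactors = FALSE)
    known <- entry_atoms$atom
    chk <- function(x) {
      bad <- setdiff(x, known)
      if (length(bad)) stop("dictionary entry ", comp,
                            " references unknown atoms: ",
                            paste(bad, collapse = ", "))
    }
    bd <- sel(cif[["_chem_comp_bond"]])
    bond_df <- NULL
    if (!is.null(bd) && nrow(bd)) {
      chk(c(bd$atom_id_1, bd$atom_id_2))
      bond_df <- data.frame(atom1 = bd$atom_id_1, atom2 = bd$atom_id_2,
                            target = as.numeric(bd$value_dist),
                            sigma = as.numeric(bd$value_dist_esd),
                            stringsAsFactors = FALSE)
    }
    an <- sel(cif[["_chem_comp_angle"]])
    angle_df <- NULL
    if (!is.null(an) && nrow(an)) {
      chk(c(an$atom_id_1, an$atom_id_2, an$atom_id_3))
      angle_df <- data.frame(atom1 = an$atom_id_1, atom2 = an$atom_id_2,
                             atom3 = an$atom_id_3,
                             target = as.numeric(an$value_angle),
                             sigma = as.numeric(an$value_angle_esd),
                             stringsAsFactors = FALSE)
    }
    tr <- sel(cif[["_chem_comp_tor"]])
    torsion_df <- NULL
    if (!is.null(tr) && nrow(tr)) {
      chk(c(tr$atom_id_1, tr$atom_id_2, tr$atom_id_3, tr$atom_id_4))
      torsion_df <- data.frame(id = tr$id, atom1 = tr$atom_id_1,
                               atom2 = tr$atom_id_2, atom3 = tr$atom_id_3,
                               atom4 = tr$atom_id_4,
                               target = as.numeric(tr$value_angle),
                               sigma = as.numeric(tr$value_angle_esd),
                               period = as.integer(tr$period),
                               stringsAsFactors = FALSE)
    }
    pl <- sel(cif[["_chem_comp_plane_atom"]])
    planes <- list()
    if (!is.null(pl) && nrow(pl)) {
      chk(pl$atom_id)
      for (pid in unique(pl$plane_id)) {
        pp <- pl[pl$plane_id == pid, ]
        planes[[length(planes) + 1]] <-
          list(id = pid, atoms = pp$atom_id,
               sigma = as.numeric(pp$dist_esd[1]))
      }
    }
    ch <- sel(cif[["_chem_comp_chir"]])
    chiral_df <- NULL
    if (!is.null(ch) && nrow(ch)) {
      chk(c(ch$atom_id_centre, ch$atom_id_1, ch$atom_id_2, ch$atom_id_3))
      chiral_df <- data.frame(id = ch$id, centre = ch$atom_id_centre,
                              atom1 = ch$atom_id_1, atom2 = ch$atom_id_2,
                              atom3 = ch$atom_id_3,
                              target = as.numeric(ch$volume_sign),
                              sigma = DEFAULT_CHIRAL_SIGMA,
                              stringsAsFactors = FALSE)
    }
    dict[[comp]] <- list(res_type = comp, atoms = entry_atoms,
                         bonds = bond_df, angles = angle_df,
                         torsions = torsion_df, planes = planes,
                         chirals = chiral_df)
  }
  class(dict) <- "monomer_dictionary"
  dict
}

#' Write a restraint dictionary in the mmCIF chem_comp dialect
#'
#' @param dict A `monomer_dictionary`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_restraint_dictionary <- function(dict, path) {
  out <- c("data_restraint_dictionary", "#")
  addcat <- function(category, rows) {
    if (is.null(rows) || !nrow(rows)) return(invisible(NULL))
    out <<- c(out, format_cif_loop(category, rows), "#")
  }
  bind <- function(field) {
    do.call(rbind, lapply(dict, function(e) {
      df <- e[[field]]
      if (is.null(df) || !nrow(df)) return(NULL)
      cbind(comp_id = e$res_type, df, stringsAsFactors = FALSE)
    }))
  }
  atoms <- bind("atoms")
  names(atoms) <- c("comp_id", "atom_id", "type_symbol")
  addcat("_chem_comp_atom", atoms)
  b <- bind("bonds")
  if (!is.null(b)) names(b) <- c("comp_id", "atom_id_1", "atom_id_2",
                                 "value_dist", "value_dist_esd")
  addcat("_chem_comp_bond", b)
  a <- bind("angles")
  if (!is.null(a)) names(a) <- c("comp_id", "atom_id_1", "atom_id_2",
                                 "atom_id_3", "value_angle",
                                 "value_angle_esd")
  addcat("_chem_comp_angle", a)
  tr <- bind("torsions")
  if (!is.null(tr)) names(tr) <- c("comp_id", "id", "atom_id_1", "atom_id_2",
                                   "atom_id_3", "atom_id_4", "value_angle",
                                   "value_angle_esd", "period")
  addcat("_chem_comp_tor", tr)
  pl <- do.call(rbind, lapply(dict, function(e) {
    if (!length(e$planes)) return(NULL)
    do.call(rbind, lapply(e$planes, function(p) {
      data.frame(comp_id = e$res_type, plane_id = p$id, atom_id = p$atoms,
                 dist_esd = p$sigma, stringsAsFactors = FALSE)
    }))
  }))
  addcat("_chem_comp_plane_atom", pl)
  ch <- bind("chirals")
  if (!is.null(ch)) names(ch) <- c("comp_id", "id", "atom_id_centre",
                                   "atom_id_1", "atom_id_2", "atom_id_3",
                                   "volume_sign", "volume_sign_esd")
  addcat("_chem_comp_chir", ch)
  writeLines(out, path)
  invisible(path)
}
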