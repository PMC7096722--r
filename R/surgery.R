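# Fragment surgery: replace-fragment (write refined coordinates back into the
# master molecule), merge-molecules (add with fresh chain ids) and
# merge-ligand (adopt the nearest chain, number above its last residue).

#' Replace master-molecule atoms with fragment atoms
#'
#' Positions (and occupancy/B) of master atoms matched by chain, residue,
#' atom name and altloc are overwritten from the fragment; everything else is
#' untouched. Every fragment residue must already exist in the master.
#'
#' @param master,frag `rs_structure` objects.
#' @return The updated master.
#' @export
replace_fragment <- function(master, frag) {
  if (!n_atoms(frag)) return(master)
  mk <- atom_res_keys(master)
  fk <- atom_res_keys(frag)
  missing_res <- setdiff(unique(fk), unique(mk))
  if (length(missing_res))
    stop("fragment residues absent from master: ",
         paste(gsub("\\|", "/", missing_res), collapse = ", "))
  fid <- paste(fk, frag$atoms$atom, frag$atoms$altloc)
  mid <- paste(mk, master$atoms$atom, master$atoms$altloc)
  idx <- match(fid, mid)
  hit <- !is.na(idx)
  cols <- c("x", "y", "z", "occ", "b")
  master$atoms[idx[hit], cols] <- frag$atoms[hit, cols]
  master
}

# first chain id not in `used`: A-Z, a-z, 0-9, then two-character ids
next_free_chain_id <- function(used) {
  pool <- c(LETTERS, letters, as.character(0:9))
  free <- setdiff(pool, used)
  if (length(free)) return(free[1])
  for (p in pool) for (q in pool) {
    id <- paste0(p, q)
    if (!id %in% used) return(id)
  }
  stop("no free chain id available")
}

#' Merge two molecules
#'
#' All atoms of `addition` are appended to `master`; chain ids that collide
#' with existing ones are remapped to the first unused id (A-Z, a-z, 0-9,
#' then two-character ids, which require mmCIF output).
#'
#' @param master,addition `rs_structure` objects.
#' @return Combined `rs_structure`.
#' @export
merge_molecules <- function(master, addition) {
  if (!n_atoms(addition)) return(master)
  used <- unique(master$atoms$chain)
  add <- addition$atoms
  add_links <- addition$links
  for (ch in unique(add$chain)) {
    if (ch %in% used) {
      new_id <- next_free_chain_id(c(used, unique(add$chain)))
      add$chain[add$chain == ch] <- new_id
      if (nrow(add_links)) {
        add_links$chain1[add_links$chain1 == ch] <- new_id
        add_links$chain2[add_links$chain2 == ch] <- new_id
      }
      used <- c(used, new_id)
    } else {
      used <- c(used, ch)
    }
  }
  rs_structure(rbind(master$atoms, add), rbind(master$links, add_links),
               master$title)
}

#' Merge a ligand into the nearest chain
#'
#' The ligand joins the chain whose minimum atom-atom distance to the ligand
#' is smallest (ties broken by lexicographically smaller chain id) and is
#' numbered `gap` above that chain's highest residue number.
#'
#' @param master non-empty `rs_structure`.
#' @param ligand_residue one-residue `rs_structure` or an atoms data.frame.
#' @param gap residue-number gap above the chain maximum (default 1).
#' @return The master with the ligand appended.
#' @export
merge_ligand <- function(master, ligand_residue, gap = 1L) {
  if (!n_atoms(master)) stop("master structure is empty")
  lig <- if (inherits(ligand_residue, "rs_structure")) ligand_residue$atoms
         else as.data.frame(ligand_residue)
  if (!nrow(lig)) stop("ligand has no atoms")
  lxyz <- as.matrix(lig[, c("x", "y", "z")])
  a <- master$atoms
  chains <- sort(unique(a$chain))
  dmin <- vapply(chains, function(ch) {
    cxyz <- as.matrix(a[a$chain == ch, c("x", "y", "z")])
    min(sqrt(pmax(outer(rowSums(lxyz^2), rowSums(cxyz^2), `+`) -
                    2 * lxyz %*% t(cxyz), 0)))
  }, numeric(1))
  target <- chains[which.min(dmin)]   # which.min takes the first (lowest id)
  lig$chain <- target
  lig$seqnum <- max(a$seqnum[a$chain == target]) + as.integer(gap)
  lig$inscode <- ""
  rs_structure(rbind(a, lig), master$links, master$title)
}
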