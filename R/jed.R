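# Torsion ("JED") flips: the dictionary torsion restraint's periodicity
# defines a small set of angle deltas; applying one rotates the smaller
# rigid half of the molecule about the rotatable bond.

#' Torsion-flip angle deltas for a periodicity
#'
#' All nonzero multiples of 360/period mapped into (-180, 180], duplicates
#' removed; period 3 gives +/-120, period 2 gives 180. Period 1 falls back
#' to a plain 180-degree flip so every rotatable bond has at least one flip.
#'
#' @param t a torsion restraint row (with a `period` column) or an integer
#'   periodicity.
#' @return Numeric vector of deltas in degrees, sorted decreasing by
#'   absolute value preference order (positive first).
#' @export
torsion_flip_deltas <- function(t) {
  period <- if (is.list(t) || is.data.frame(t)) t$period[1] else t
  period <- as.integer(period)
  if (is.na(period) || period < 1) stop("period must be >= 1")
  if (period == 1) return(180)
  deltas <- wrap180((seq_len(period - 1)) * 360 / period)
  sort(unique(round(deltas, 9)), decreasing = TRUE)
}

# connected component of `start` in the residue bond graph after deleting
# the bond a1-a2 (names); NULL if the graph stays connected (ring bond)
split_by_bond <- function(bonds, atoms, a1, a2) {
  adj <- stats::setNames(vector("list", length(atoms)), atoms)
  for (b in bonds) {
    if ((b[1] == a1 && b[2] == a2) || (b[1] == a2 && b[2] == a1)) next
    adj[[b[1]]] <- c(adj[[b[1]]], b[2])
    adj[[b[2]]] <- c(adj[[b[2]]], b[1])
  }
  bfs <- function(start) {
    seen <- start
    frontier <- start
    while (length(frontier)) {
      nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    seen
  }
  side1 <- bfs(a1)
  if (a2 %in% side1) return(NULL)
  list(side1 = side1, side2 = bfs(a2))
}

#' Apply a torsion flip about a rotatable bond
#'
#' Splits the residue's covalent graph at the bond and rotates the smaller
#' component (the larger if `reverse`) rigidly about the bond axis by
#' `delta` degrees. Bond lengths and angles within each component are
#' unchanged; a bond inside a ring cannot be flipped.
#'
#' @param s An `rs_structure`.
#' @param chain,seqnum residue holding the bond.
#' @param bond_atoms character pair of atom names, e.g. `c("C1", "C2")`.
#' @param delta rotation in degrees (see [torsion_flip_deltas()]).
#' @param reverse rotate the larger component instead.
#' @param dict monomer dictionary for the bond graph.
#' @return The flipped `rs_structure`.
#' @export
apply_jed_flip <- function(s, chain, seqnum, bond_atoms, delta,
                           reverse = FALSE, dict = default_dictionary()) {
  a <- s$atoms
  rows <- which(a$chain == chain & a$seqnum == seqnum)
  if (!length(rows)) stop("no residue ", chain, "/", seqnum)
  rtype <- a$resname[rows[1]]
  entry <- dict[[rtype]]
  if (is.null(entry)) stop("no dictionary entry for ", rtype)
  bonds <- lapply(seq_len(nrow(entry$bonds)),
                  function(i) c(entry$bonds$atom1[i], entry$bonds$atom2[i]))
  nm <- a$atom[rows]
  if (!all(bond_atoms %in% nm))
    stop("bond atoms not present in residue: ",
         paste(setdiff(bond_atoms, nm), collapse = ", "))
  halves <- split_by_bond(bonds, entry$atoms$atom, bond_atoms[1],
                          bond_atoms[2])
  if (is.null(halves))
    stop("bond ", bond_atoms[1], "-", bond_atoms[2],
         " is part of a ring and cannot be flipped")
  moving_names <- if (xor(length(halves$side1) <= length(halves$side2),
                          reverse)) halves$side1 else halves$side2
  # the bond atoms themselves lie on the axis; keep them fixed
  moving_names <- setdiff(moving_names, bond_atoms)
  if (!length(moving_names)) return(s)
  p1 <- atom_pos(s, chain, seqnum, bond_atoms[1])
  p2 <- atom_pos(s, chain, seqnum, bond_atoms[2])
  mrows <- rows[nm %in% moving_names]
  xyz <- as.matrix(a[mrows, c("x", "y", "z")])
  s$atoms[mrows, c("x", "y", "z")] <-
    rotate_about_axis(xyz, p1, p2 - p1, delta)
  s
}
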