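# Hierarchical-model container. Atoms are kept in a single data frame (one
# row per atom) ordered chain -> seqnum -> inscode; residues and chains are
# derived groupings, which keeps selection and surgery vectorised.

#' Create a macromolecular structure object
#'
#' @param atoms data.frame with columns chain, seqnum, inscode, resname, atom,
#'   altloc, element, x, y, z, occ, b.
#' @param links data.frame of LINK records (may be empty); columns chain1,
#'   seqnum1, inscode1, atom1, chain2, seqnum2, inscode2, atom2, link_type,
#'   dist.
#' @param title character title string.
#' @return An object of class `rs_structure`.
#' @export
rs_structure <- function(atoms = empty_atoms(), links = empty_links(),
                         title = "") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  need <- c("chain", "seqnum", "inscode", "resname", "atom", "altloc",
            "element", "x", "y", "z", "occ", "b")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms missing columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms)) {
    stopifnot(all(is.finite(atoms$x)), all(is.finite(atoms$y)),
              all(is.finite(atoms$z)))
    if (any(atoms$occ < 0 | atoms$occ > 1)) stop("occupancy outside [0,1]")
    if (any(atoms$b < 0)) stop("negative B-factor")
  }
  structure(list(atoms = atoms, links = links, title = title),
            class = "rs_structure")
}

empty_atoms <- function() {
  data.frame(chain = character(), seqnum = integer(), inscode = character(),
             resname = character(), atom = character(), altloc = character(),
             element = character(), x = numeric(), y = numeric(),
             z = numeric(), occ = numeric(), b = numeric(),
             stringsAsFactors = FALSE)
}

empty_links <- function() {
  data.frame(chain1 = character(), seqnum1 = integer(), inscode1 = character(),
             atom1 = character(), chain2 = character(), seqnum2 = integer(),
             inscode2 = character(), atom2 = character(),
             link_type = character(), dist = numeric(),
             stringsAsFactors = FALSE)
}

#' @export
print.rs_structure <- function(x, ...) {
  a <- x$atoms
  nres <- if (nrow(a)) nrow(unique(a[c("chain", "seqnum", "inscode")])) else 0L
  cat(sprintf("<rs_structure> %d chain(s), %d residue(s), %d atom(s)",
              length(unique(a$chain)), nres, nrow(a)))
  if (nrow(x$links)) cat(sprintf(", %d LINK(s)", nrow(x$links)))
  if (nzchar(x$title)) cat("\n  title: ", x$title, sep = "")
  cat("\n")
  invisible(x)
}

#' @export
summary.rs_structure <- function(object, ...) {
  a <- object$atoms
  for (ch in unique(a$chain)) {
    aa <- a[a$chain == ch, ]
    cat(sprintf("chain %s: residues %d-%d (%d), %d atoms\n", ch,
                min(aa$seqnum), max(aa$seqnum),
                nrow(unique(aa[c("seqnum", "inscode")])), nrow(aa)))
  }
  invisible(object)
}

# residue key strings (chain|seqnum|inscode)
res_key <- function(chain, seqnum, inscode = "") {
  paste(chain, seqnum, inscode, sep = "|")
}

atom_res_keys <- function(s) {
  with(s$atoms, res_key(chain, seqnum, inscode))
}

#' Coordinates of a structure as an n x 3 matrix
#' @param s An `rs_structure`.
#' @return Numeric matrix with columns x, y, z.
#' @export
coords <- function(s) {
  as.matrix(s$atoms[, c("x", "y", "z")])
}

#' @rdname coords
#' @param value replacement n x 3 coordinate matrix.
#' @export
`coords<-` <- function(s, value) {
  value <- as.matrix(value)
  stopifnot(nrow(value) == nrow(s$atoms), ncol(value) == 3)
  s$atoms$x <- value[, 1]; s$atoms$y <- value[, 2]; s$atoms$z <- value[, 3]
  s
}

#' Number of atoms in a structure
#' @param s An `rs_structure`.
#' @return Integer atom count.
#' @export
n_atoms <- function(s) nrow(s$atoms)

#' Position of a named atom in one residue
#'
#' NULL if absent; with several altlocs, the highest-occupancy one is used.
#' @param s An `rs_structure`.
#' @param chain,seqnum,inscode the residue.
#' @param name atom name (e.g. "CA").
#' @return Length-3 numeric position or NULL.
#' @export
atom_pos <- function(s, chain, seqnum, name, inscode = "") {
  a <- s$atoms
  i <- which(a$chain == chain & a$seqnum == seqnum & a$inscode == inscode &
               a$atom == name)
  if (!length(i)) return(NULL)
  if (length(i) > 1) i <- i[which.max(a$occ[i])]
  c(a$x[i], a$y[i], a$z[i])
}

#' Residues of a structure in order
#' @param s An `rs_structure`.
#' @return data.frame with chain, seqnum, inscode, resname.
#' @export
residue_table <- function(s) {
  a <- s$atoms
  if (!nrow(a)) {
    return(data.frame(chain = character(), seqnum = integer(),
                      inscode = character(), resname = character()))
  }
  key <- res_key(a$chain, a$seqnum, a$inscode)
  first <- !duplicated(key)
  data.frame(chain = a$chain[first], seqnum = a$seqnum[first],
             inscode = a$inscode[first], resname = a$resname[first],
             stringsAsFactors = FALSE)
}

#' One-letter sequence of a chain
#' @param s An `rs_structure`.
#' @param chain_id chain identifier.
#' @return Character scalar (unknown residues become "X").
#' @export
chain_sequence <- function(s, chain_id) {
  rt <- residue_table(s)
  rt <- rt[rt$chain == chain_id, ]
  one <- AA_ONE[rt$resname]
  one[is.na(one)] <- "X"
  paste(one, collapse = "")
}

# order atoms canonically (chain, seqnum, inscode, preserving input atom order
# within a residue)
order_atoms <- function(atoms) {
  atoms[order(atoms$chain, atoms$seqnum, atoms$inscode), , drop = FALSE]
}

#' Per-atom RMSD between two structures with identical atom lists
#' @param s1,s2 `rs_structure` objects with matching atoms.
#' @return RMSD in Angstroms.
#' @export
structure_rmsd <- function(s1, s2) {
  stopifnot(n_atoms(s1) == n_atoms(s2))
  k1 <- paste(atom_res_keys(s1), s1$atoms$atom)
  k2 <- paste(atom_res_keys(s2), s2$atoms$atom)
  m <- match(k1, k2)
  if (anyNA(m)) stop("atom lists differ")
  coord_rmsd(coords(s1), coords(s2)[m, , drop = FALSE])
}
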