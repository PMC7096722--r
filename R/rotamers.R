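# Rotamer library access: compact penultimate-style chi-angle sets with
# prior probabilities, exportable/importable as TSV so users can swap in a
# fuller library.

#' The rotamer library as a data.frame
#'
#' @param lib optional library in list form (default: built-in).
#' @return data.frame with columns res_type, name, prob, chi1..chi4 (NA for
#'   absent chis).
#' @export
rotamer_library <- function(lib = ROTAMER_LIB) {
  rows <- list()
  for (rt in names(lib)) {
    for (r in lib[[rt]]) {
      chis <- rep(NA_real_, 4)
      chis[seq_along(r[[3]])] <- r[[3]]
      rows[[length(rows) + 1]] <- data.frame(
        res_type = rt, name = r[[1]], prob = r[[2]],
        chi1 = chis[1], chi2 = chis[2], chi3 = chis[3], chi4 = chis[4],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write / read a rotamer library as TSV
#'
#' @param lib data.frame from [rotamer_library()].
#' @param path TSV file path.
#' @return `read_rotamer_library` returns the library in the internal list
#'   form; `write_rotamer_library` returns the path invisibly.
#' @export
write_rotamer_library <- function(lib, path) {
  utils::write.table(lib, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rotamer_library
#' @export
read_rotamer_library <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  out <- list()
  for (i in seq_len(nrow(df))) {
    chis <- unlist(df[i, c("chi1", "chi2", "chi3", "chi4")])
    chis <- unname(chis[!is.na(chis)])
    out[[df$res_type[i]]] <- c(out[[df$res_type[i]]],
                               list(list(df$name[i], df$prob[i], chis)))
  }
  out
}

#' Measured chi angles of one residue
#' @param s An `rs_structure`.
#' @param chain,seqnum,inscode the residue.
#' @return Numeric chi angles in degrees (NA where atoms are missing);
#'   length 0 for residues without chis.
#' @export
measure_chis <- function(s, chain, seqnum, inscode = "") {
  a <- s$atoms
  rows <- a$chain == chain & a$seqnum == seqnum & a$inscode == inscode
  rtype <- a$resname[rows][1]
  defs <- CHI_ATOMS[[rtype]]
  if (is.null(defs)) return(numeric(0))
  vapply(defs, function(q) {
    ps <- lapply(q, function(nm) atom_pos(s, chain, seqnum, nm, inscode))
    if (any(vapply(ps, is.null, logical(1)))) return(NA_real_)
    dihedral_angle(ps[[1]], ps[[2]], ps[[3]], ps[[4]])
  }, numeric(1))
}

# wrapped chi-space distance between two chi vectors (degrees, RMS over chis)
chi_distance <- function(c1, c2) {
  k <- min(length(c1), length(c2))
  if (k == 0) return(NA_real_)
  sqrt(mean(wrap180(c1[seq_len(k)] - c2[seq_len(k)])^2))
}
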