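# PDB (fixed-column) and mmCIF reading/writing. The reader keeps altlocs,
# insertion codes and LINK records; the PDB writer refuses multi-character
# chain ids (mmCIF handles those).

#' Read a macromolecular structure
#'
#' @param path file path (PDB or mmCIF).
#' @param format "pdb", "mmcif" or "auto" (by extension, falling back to
#'   content sniffing).
#' @return An `rs_structure`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(nzchar(trimws(lines))))
    stop("format error: empty structure file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif"
      else if (ext %in% c("pdb", "ent")) "pdb"
      else if (any(grepl("^data_|^loop_", lines))) "mmcif" else "pdb"
  }
  if (format == "pdb") read_pdb_lines(lines) else read_mmcif_lines(lines)
}

read_pdb_lines <- function(lines) {
  recs <- substr(lines, 1, 6)
  ai <- which(recs %in% c("ATOM  ", "HETATM"))
  if (!length(ai)) stop("format error: no ATOM/HETATM records")
  al <- lines[ai]
  num <- function(x, what, ln) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) & nzchar(trimws(x)))
    if (length(bad))
      stop("format error at line ", ln[bad[1]], ": bad ", what, " field")
    v
  }
  f <- function(a, b) trimws(substr(al, a, b))
  x <- num(substr(al, 31, 38), "x", ai)
  y <- num(substr(al, 39, 46), "y", ai)
  z <- num(substr(al, 47, 54), "z", ai)
  if (anyNA(c(x, y, z))) stop("format error: missing coordinates")
  occ <- num(substr(al, 55, 60), "occupancy", ai); occ[is.na(occ)] <- 1
  b <- num(substr(al, 61, 66), "B-factor", ai); b[is.na(b)] <- 0
  element <- f(77, 78)
  name <- f(13, 16)
  element[element == ""] <- element_of(name[element == ""])
  atoms <- data.frame(
    chain = f(22, 22), seqnum = as.integer(num(substr(al, 23, 26), "resSeq", ai)),
    inscode = f(27, 27), resname = f(18, 20), atom = name,
    altloc = f(17, 17), element = toupper(element),
    x = x, y = y, z = z, occ = occ, b = b, stringsAsFactors = FALSE)
  li <- which(recs == "LINK  ")
  links <- empty_links()
  if (length(li)) {
    ll <- lines[li]
    g <- function(a, b) trimws(substr(ll, a, b))
    links <- data.frame(
      chain1 = g(22, 22), seqnum1 = as.integer(g(23, 26)), inscode1 = g(27, 27),
      atom1 = g(13, 16),
      chain2 = g(52, 52), seqnum2 = as.integer(g(53, 56)), inscode2 = g(57, 57),
      atom2 = g(43, 46),
      link_type = "link",
      dist = suppressWarnings(as.numeric(g(74, 78))),
      stringsAsFactors = FALSE)
  }
  ti <- which(recs == "TITLE ")
  title <- if (length(ti)) paste(trimws(substr(lines[ti], 11, 80)),
                                 collapse = " ") else ""
  rs_structure(atoms, links, title)
}

read_mmcif_lines <- function(lines) {
  cif <- parse_cif(lines)
  as_ <- cif[["_atom_site"]]
  if (is.null(as_)) stop("format error: no _atom_site category in mmCIF")
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% names(as_)) return(as_[[nm]])
    NULL
  }
  chain <- pick("auth_asym_id", "label_asym_id")
  seqnum <- pick("auth_seq_id", "label_seq_id")
  if (is.null(chain) || is.null(seqnum))
    stop("format error: _atom_site lacks chain/seq columns")
  ins <- pick("pdbx_PDB_ins_code"); if (is.null(ins)) ins <- ""
  ins[ins %in% c(".", "?")] <- ""
  alt <- pick("label_alt_id"); if (is.null(alt)) alt <- ""
  alt[alt %in% c(".", "?")] <- ""
  occ <- pick("occupancy"); if (is.null(occ)) occ <- 1
  bb <- pick("B_iso_or_equiv"); if (is.null(bb)) bb <- 0
  atoms <- data.frame(
    chain = chain, seqnum = as.integer(seqnum), inscode = ins,
    resname = pick("label_comp_id", "auth_comp_id"),
    atom = pick("label_atom_id", "auth_atom_id"),
    altloc = alt, element = toupper(pick("type_symbol")),
    x = as.numeric(pick("Cartn_x")), y = as.numeric(pick("Cartn_y")),
    z = as.numeric(pick("Cartn_z")),
    occ = as.numeric(occ), b = as.numeric(bb), stringsAsFactors = FALSE)
  links <- empty_links()
  sc <- cif[["_struct_conn"]]
  if (!is.null(sc)) {
    links <- data.frame(
      chain1 = sc$ptnr1_auth_asym_id, seqnum1 = as.integer(sc$ptnr1_auth_seq_id),
      inscode1 = "", atom1 = sc$ptnr1_label_atom_id,
      chain2 = sc$ptnr2_auth_asym_id, seqnum2 = as.integer(sc$ptnr2_auth_seq_id),
      inscode2 = "", atom2 = sc$ptnr2_label_atom_id,
      link_type = sc$conn_type_id,
      dist = suppressWarnings(as.numeric(sc$pdbx_dist_value)),
      stringsAsFactors = FALSE)
  }
  rs_structure(atoms, links, "")
}

format_pdb_atom_name <- function(name, element) {
  # 1-char-element names shorter than 4 chars start at column 14
  out <- ifelse(nchar(name) >= 4 | nchar(element) >= 2,
                formatC(name, width = -4),
                formatC(paste0(" ", name), width = -4))
  substr(out, 1, 4)
}

#' Write a macromolecular structure
#'
#' PDB keeps the usual 3-decimal coordinate precision; mmCIF writes full
#' double precision so that a read/write round trip is exact.
#'
#' @param s An `rs_structure`.
#' @param path output file path.
#' @param format "pdb" or "mmcif" ("auto" picks by extension).
#' @return Invisibly, `path`.
#' @export
write_structure <- function(s, path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  a <- s$atoms
  if (format == "pdb") {
    if (any(nchar(a$chain) > 1) || (nrow(s$links) && any(nchar(c(s$links$chain1, s$links$chain2)) > 1)))
      stop("chain id too long for the PDB format; write mmCIF instead")
    if (any(a$seqnum > 9999 | a$seqnum < -999))
      stop("residue number out of PDB range; write mmCIF instead")
    out <- character(0)
    if (nzchar(s$title)) out <- c(out, sprintf("TITLE     %s", s$title))
    if (nrow(s$links)) {
      l <- s$links
      out <- c(out, sprintf(
        "LINK        %-4s%1s%3s %1s%4d%1s               %-4s%1s%3s %1s%4d%1s %6s %6s  %5s",
        format_pdb_atom_name(l$atom1, element_of(l$atom1)), "", "",
        l$chain1, l$seqnum1, l$inscode1,
        format_pdb_atom_name(l$atom2, element_of(l$atom2)), "", "",
        l$chain2, l$seqnum2, l$inscode2,
        "", "", ifelse(is.na(l$dist), "", sprintf("%5.2f", l$dist))))
    }
    rec <- ifelse(a$resname %in% unname(AA_THREE), "ATOM  ", "HETATM")
    out <- c(out, sprintf(
      "%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      rec, seq_len(nrow(a)), format_pdb_atom_name(a$atom, a$element),
      a$altloc, a$resname, a$chain, a$seqnum, a$inscode,
      a$x, a$y, a$z, a$occ, a$b, a$element), "END")
    writeLines(out, path)
  } else {
    df <- data.frame(
      group_PDB = ifelse(a$resname %in% unname(AA_THREE), "ATOM", "HETATM"),
      id = seq_len(nrow(a)), type_symbol = a$element,
      label_atom_id = a$atom,
      label_alt_id = ifelse(a$altloc == "", ".", a$altloc),
      label_comp_id = a$resname, auth_asym_id = a$chain,
      auth_seq_id = a$seqnum,
      pdbx_PDB_ins_code = ifelse(a$inscode == "", ".", a$inscode),
      Cartn_x = sprintf("%.17g", a$x), Cartn_y = sprintf("%.17g", a$y),
      Cartn_z = sprintf("%.17g", a$z),
      occupancy = sprintf("%.17g", a$occ),
      B_iso_or_equiv = sprintf("%.17g", a$b), stringsAsFactors = FALSE)
    out <- c("data_rsfit", "#", format_cif_loop("_atom_site", df), "#")
    if (nrow(s$links)) {
      l <- s$links
      conn <- data.frame(
        id = seq_len(nrow(l)),
        conn_type_id = ifelse(is.na(l$link_type) | l$link_type == "",
                              "covale", l$link_type),
        ptnr1_auth_asym_id = l$chain1, ptnr1_auth_seq_id = l$seqnum1,
        ptnr1_label_atom_id = l$atom1,
        ptnr2_auth_asym_id = l$chain2, ptnr2_auth_seq_id = l$seqnum2,
        ptnr2_label_atom_id = l$atom2,
        pdbx_dist_value = ifelse(is.na(l$dist), ".", sprintf("%.3f", l$dist)),
        stringsAsFactors = FALSE)
      out <- c(out, format_cif_loop("_struct_conn", conn), "#")
    }
    writeLines(out, path)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
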