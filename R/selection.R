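# CCP4/mmdb-style atom selection paths: "//CHAIN/START-END[/ATOMNAME]".

#' Parse an atom selection expression
#'
#' Dialect: `//CHAIN` (whole chain), `//CHAIN/START-END`, `//CHAIN/NUM`,
#' optionally followed by `/ATOMNAME` (comma-separated names allowed).
#' En-dashes are accepted in ranges.
#'
#' @param raw selection string, e.g. `"//A/50-100"`.
#' @return list with elements chain, start, end (NA when absent) and
#'   atom_names (NULL for all).
#' @export
parse_selection <- function(raw) {
  if (!is.character(raw) || length(raw) != 1 || !nzchar(raw))
    stop("unparseable selection: expected a single string")
  x <- gsub("–", "-", raw)
  if (!startsWith(x, "//")) stop("unparseable selection '", raw,
                                 "': must start with //")
  parts <- strsplit(substring(x, 3), "/", fixed = TRUE)[[1]]
  if (!length(parts) || !nzchar(parts[1]))
    stop("unparseable selection '", raw, "': missing chain id")
  chain <- parts[1]
  start <- end <- NA_integer_
  atom_names <- NULL
  if (length(parts) >= 2 && nzchar(parts[2])) {
    rng <- parts[2]
    m <- regmatches(rng, regexec("^(-?[0-9]+)(?:-(-?[0-9]+))?$", rng))[[1]]
    if (!length(m)) stop("unparseable selection '", raw,
                         "': bad residue range '", rng, "'")
    start <- as.integer(m[2])
    end <- if (nzchar(m[3])) as.integer(m[3]) else start
    if (end < start) stop("unparseable selection '", raw,
                          "': range end before start")
  }
  if (length(parts) >= 3 && nzchar(parts[3]))
    atom_names <- toupper(strsplit(parts[3], ",", fixed = TRUE)[[1]])
  if (length(parts) > 3) stop("unparseable selection '", raw, "'")
  list(chain = chain, start = start, end = end, atom_names = atom_names)
}

#' Canonical form of a selection
#' @param sel a parsed selection (from [parse_selection()]) or string.
#' @return Canonical selection string.
#' @export
format_selection <- function(sel) {
  if (is.character(sel)) sel <- parse_selection(sel)
  out <- paste0("//", sel$chain)
  if (!is.na(sel$start)) {
    out <- paste0(out, "/", sel$start,
                  if (sel$end != sel$start) paste0("-", sel$end) else "")
  } else if (!is.null(sel$atom_names)) {
    out <- paste0(out, "/")
  }
  if (!is.null(sel$atom_names))
    out <- paste0(out, "/", paste(sel$atom_names, collapse = ","))
  out
}

# logical index of atoms matched by a selection
selection_mask <- function(s, sel) {
  if (is.character(sel)) sel <- parse_selection(sel)
  a <- s$atoms
  m <- a$chain == sel$chain
  if (!is.na(sel$start)) m <- m & a$seqnum >= sel$start & a$seqnum <= sel$end
  if (!is.null(sel$atom_names)) m <- m & a$atom %in% sel$atom_names
  m
}

#' Extract a fragment as a deep copy
#'
#' @param s An `rs_structure`.
#' @param sel selection string or parsed selection.
#' @return A new `rs_structure` holding copies of the matching residues; an
#'   empty selection gives an empty structure with a warning.
#' @export
select_fragment <- function(s, sel) {
  m <- selection_mask(s, sel)
  if (!any(m)) {
    warning("empty selection: ",
            if (is.character(sel)) sel else format_selection(sel))
    return(rs_structure(title = s$title))
  }
  keys <- atom_res_keys(s)
  l <- s$links
  keep_links <- if (nrow(l)) {
    k1 <- res_key(l$chain1, l$seqnum1, l$inscode1) %in% keys[m]
    k2 <- res_key(l$chain2, l$seqnum2, l$inscode2) %in% keys[m]
    l[k1 & k2, , drop = FALSE]
  } else l
  rs_structure(s$atoms[m, , drop = FALSE], keep_links, s$title)
}
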