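# Minimal mmCIF tokenizer/parser: enough of the dialect for atom_site tables
# and chem_comp restraint dictionaries (loop_ blocks, quoted values, comments).

cif_tokenize_line <- function(line) {
  # returns character vector of tokens, honouring '...' and "..." quoting
  line <- sub("#.*$", "", line)
  out <- character(0)
  i <- 1L; n <- nchar(line)
  while (i <= n) {
    ch <- substr(line, i, i)
    if (grepl("^[ \t]$", ch)) { i <- i + 1L; next }
    if (ch == "'" || ch == '"') {
      j <- i + 1L
      while (j <= n && substr(line, j, j) != ch) j <- j + 1L
      out <- c(out, substr(line, i + 1L, j - 1L))
      i <- j + 1L
    } else {
      j <- i
      while (j <= n && !grepl("^[ \t]$", substr(line, j, j))) j <- j + 1L
      out <- c(out, substr(line, i, j - 1L))
      i <- j
    }
  }
  out
}

# Parse all loop_ blocks in a CIF file into data.frames keyed by category
# (e.g. "_atom_site"). Non-loop key-value pairs are returned under "$scalars".
parse_cif <- function(lines) {
  loops <- list()
  scalars <- character(0)
  i <- 1L; n <- length(lines)
  while (i <= n) {
    line <- trimws(lines[i])
    if (identical(tolower(line), "loop_")) {
      i <- i + 1L
      tags <- character(0)
      while (i <= n && grepl("^_", trimws(lines[i]))) {
        tags <- c(tags, trimws(lines[i])); i <- i + 1L
      }
      vals <- character(0)
      while (i <= n) {
        l2 <- trimws(lines[i])
        if (l2 == "" || grepl("^(_|loop_|data_|#)", l2, ignore.case = TRUE))
          break
        vals <- c(vals, cif_tokenize_line(lines[i]))
        i <- i + 1L
      }
      if (length(tags) && length(vals)) {
        ncol <- length(tags)
        if (length(vals) %% ncol != 0)
          stop("mmCIF parse failure in loop over ", tags[1],
               ": ragged value count")
        m <- matrix(vals, ncol = ncol, byrow = TRUE)
        df <- as.data.frame(m, stringsAsFactors = FALSE)
        names(df) <- sub("^_[^.]+\\.", "", tags)
        cat_name <- sub("\\..*$", "", tags[1])
        if (is.null(loops[[cat_name]])) {
          loops[[cat_name]] <- df
        } else {
          loops[[cat_name]] <- rbind(loops[[cat_name]], df)
        }
      }
    } else {
      if (grepl("^_", line)) scalars <- c(scalars, line)
      i <- i + 1L
    }
  }
  loops[["$scalars"]] <- scalars
  loops
}

cif_quote <- function(x) {
  x <- as.character(x)
  x[x == ""] <- "."
  needs <- grepl("[ '\"]", x)
  x[needs] <- paste0('"', x[needs], '"')
  x
}

format_cif_loop <- function(category, df) {
  header <- c("loop_", paste0(category, ".", names(df)))
  cols <- lapply(df, cif_quote)
  widths <- vapply(cols, function(cc) max(nchar(cc)), integer(1))
  body <- do.call(paste, c(mapply(formatC, cols, width = widths,
                                  SIMPLIFY = FALSE,
                                  MoreArgs = list(flag = "-")),
                           list(sep = " ")))
  c(header, body)
}
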