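# Apply an externally generated pairwise FASTA alignment to a chain:
# substitutions become side-chain swaps at the best rotamer, target-side gaps
# become deletions, model-side gaps are recorded as insertions (not built).

#' Read a two-sequence FASTA alignment
#'
#' @param path FASTA file with exactly two gapped sequences (model first,
#'   target second); gaps are "-".
#' @return list(model=, target=) of upper-case gapped strings.
#' @export
read_fasta_alignment <- function(path) {
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  if (length(seqs) != 2)
    stop("alignment FASTA must contain exactly 2 sequences, found ",
         length(seqs))
  list(model = toupper(as.character(seqs[[1]])),
       target = toupper(as.character(seqs[[2]])))
}

#' Derive a mutation plan from a pairwise alignment
#'
#' The ungapped model-side sequence must equal the chain's one-letter
#' sequence. Columns where both sides have residues but they differ become
#' substitutions; target gaps become deletions; model gaps are recorded as
#' insertions (reported, never built).
#'
#' @param s An `rs_structure`.
#' @param chain_id chain to align.
#' @param alignment list(model=, target=) of gapped strings, a character
#'   vector of length 2, or a FASTA file path.
#' @return An object of class `mutation_plan` with data.frames `mutations`
#'   (seqnum, from_type, to_type), `deletions` (seqnum, res_type) and
#'   `insertions` (after_seqnum, res_type).
#' @export
align_and_mutate <- function(s, chain_id, alignment) {
  if (is.character(alignment) && length(alignment) == 1 &&
        file.exists(alignment))
    alignment <- read_fasta_alignment(alignment)
  if (is.character(alignment) && length(alignment) == 2)
    alignment <- list(model = toupper(alignment[1]),
                      target = toupper(alignment[2]))
  model <- strsplit(alignment$model, "")[[1]]
  target <- strsplit(alignment$target, "")[[1]]
  if (length(model) != length(target))
    stop("aligned sequences differ in length")
  rt <- residue_table(s)
  rt <- rt[rt$chain == chain_id, , drop = FALSE]
  if (!nrow(rt)) stop("no residues in chain ", chain_id)
  chain_seq <- strsplit(chain_sequence(s, chain_id), "")[[1]]
  model_seq <- model[model != "-"]
  if (length(model_seq) != length(chain_seq))
    stop("alignment mismatch: model side has ", length(model_seq),
         " residues, chain ", chain_id, " has ", length(chain_seq))
  bad <- which(model_seq != chain_seq)
  if (length(bad))
    stop("alignment mismatch at chain position ", bad[1], ": model '",
         model_seq[bad[1]], "' vs chain '", chain_seq[bad[1]], "'")
  mutations <- deletions <- insertions <- list()
  mi <- 0L  # model residue counter
  for (col in seq_along(model)) {
    mc <- model[col]; tc <- target[col]
    if (mc != "-") mi <- mi + 1L
    if (mc != "-" && tc != "-" && mc != tc) {
      mutations[[length(mutations) + 1]] <- data.frame(
        seqnum = rt$seqnum[mi], from_type = AA_THREE[[mc]],
        to_type = AA_THREE[[tc]], stringsAsFactors = FALSE)
    } else if (mc != "-" && tc == "-") {
      deletions[[length(deletions) + 1]] <- data.frame(
        seqnum = rt$seqnum[mi], res_type = AA_THREE[[mc]],
        stringsAsFactors = FALSE)
    } else if (mc == "-" && tc != "-") {
      after <- if (mi >= 1L) rt$seqnum[mi] else rt$seqnum[1] - 1L
      insertions[[length(insertions) + 1]] <- data.frame(
        after_seqnum = after, res_type = AA_THREE[[tc]],
        stringsAsFactors = FALSE)
    }
  }
  bindor <- function(x, proto) if (length(x)) do.call(rbind, x) else proto
  plan <- list(
    chain = chain_id,
    mutations = bindor(mutations, data.frame(seqnum = integer(),
                                             from_type = character(),
                                             to_type = character())),
    deletions = bindor(deletions, data.frame(seqnum = integer(),
                                             res_type = character())),
    insertions = bindor(insertions, data.frame(after_seqnum = integer(),
                                               res_type = character())))
  class(plan) <- "mutation_plan"
  plan
}

#' @export
print.mutation_plan <- function(x, ...) {
  cat(sprintf("<mutation_plan> chain %s: %d mutation(s), %d deletion(s), %d insertion(s)%s\n",
              x$chain, nrow(x$mutations), nrow(x$deletions),
              nrow(x$insertions),
              if (nrow(x$insertions)) " [insertions recorded, not built]" else ""))
  if (nrow(x$mutations))
    cat(paste0("  ", x$mutations$seqnum, " ", x$mutations$from_type, " -> ",
               x$mutations$to_type, collapse = "\n"), "\n")
  invisible(x)
}

#' Apply a mutation plan
#'
#' Substitutions replace the side chain with the most probable rotamer of the
#' new type (backbone untouched); deletions remove residues; insertions are
#' left unbuilt (no de novo building). Residue numbering is preserved.
#'
#' @param s An `rs_structure`.
#' @param plan A `mutation_plan` from [align_and_mutate()].
#' @return The mutated `rs_structure`.
#' @export
apply_mutation_plan <- function(s, plan) {
  stopifnot(inherits(plan, "mutation_plan"))
  if (nrow(plan$mutations)) {
    for (i in seq_len(nrow(plan$mutations))) {
      m <- plan$mutations[i, ]
      cur <- s$atoms$resname[s$atoms$chain == plan$chain &
                               s$atoms$seqnum == m$seqnum][1]
      if (!identical(cur, m$from_type))
        stop("plan out of date: residue ", m$seqnum, " is ", cur,
             ", expected ", m$from_type)
      s <- swap_side_chain(s, plan$chain, m$seqnum, m$to_type)
    }
  }
  if (nrow(plan$deletions)) {
    drop <- s$atoms$chain == plan$chain &
      s$atoms$seqnum %in% plan$deletions$seqnum
    s$atoms <- s$atoms[!drop, , drop = FALSE]
  }
  s
}
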