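#' Plain-sequence alignment parameters
#'
#' Defaults follow the MAFFT-style nucleotide scoring used for ITS work:
#' a 200 PAM / k = 2 analogue (match 1.9, mismatch -1.1) with gap opening
#' 1.53 and extension 0.123.
#'
#' @param match,mismatch substitution scores.
#' @param gap_open,gap_ext affine gap costs (positive).
#' @export
align_params <- function(match = 1.9, mismatch = -1.1,
                         gap_open = 1.53, gap_ext = 0.123) {
  stopifnot(gap_open >= 0, gap_ext >= 0)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_ext = gap_ext,
                 mode = "SEQUENCE_ONLY"), class = "align_params")
}

#' Sequence-structure alignment parameters
#'
#' Scores for the combined 12-letter alphabet: sequence match 50 /
#' mismatch 0, structure-state agreement weighted by \code{struct_weight}
#' through a RIBOSUM-style state matrix (identical states 1, opening vs
#' closing bracket 0.25, paired vs unpaired 0), and affine indels
#' (opening 800, extension 50 on the cost scale).
#'
#' @param struct_weight weight on the structure-state agreement.
#' @param gap_open,gap_ext affine gap costs.
#' @param match,mismatch sequence-letter scores.
#' @export
seqstruct_align_params <- function(struct_weight = 200, gap_open = 800,
                                   gap_ext = 50, match = 50, mismatch = 0) {
  structure(list(struct_weight = struct_weight, gap_open = gap_open,
                 gap_ext = gap_ext, match = match, mismatch = mismatch,
                 mode = "SEQ_STRUCT"), class = "seqstruct_align_params")
}

# ---- profile machinery -----------------------------------------------------

# A profile is a K x L frequency matrix over an alphabet (gaps contribute
# nothing to columns).  aln is a character matrix of symbols / "-".
profile_of <- function(aln, alphabet) {
  K <- length(alphabet)
  L <- ncol(aln)
  P <- matrix(0, K, L)
  for (k in seq_len(K)) {
    P[k, ] <- colSums(aln == alphabet[k])
  }
  P / nrow(aln)
}

merge_alignments <- function(alnA, alnB, S, alphabet, gap_open, gap_ext) {
  PA <- profile_of(alnA, alphabet)
  PB <- profile_of(alnB, alphabet)
  M <- crossprod(PA, S %*% PB)
  path <- .gotoh_path_cpp(M, gap_open, gap_ext)
  L <- length(path$a)
  out <- matrix("-", nrow(alnA) + nrow(alnB), L)
  ia <- path$a > 0
  out[seq_len(nrow(alnA)), ia] <- alnA[, path$a[ia], drop = FALSE]
  ib <- path$b > 0
  out[nrow(alnA) + seq_len(nrow(alnB)), ib] <- alnB[, path$b[ib], drop = FALSE]
  out
}

kmer_distances <- function(token_rows, k = 6L) {
  n <- length(token_rows)
  km <- lapply(token_rows, function(tok) {
    if (length(tok) < k) return(table(paste(tok, collapse = "")))
    idx <- seq_len(length(tok) - k + 1L)
    table(vapply(idx, function(i) paste(tok[i:(i + k - 1L)], collapse = ""),
                 character(1)))
  })
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- intersect(names(km[[i]]), names(km[[j]]))
      common <- sum(pmin(km[[i]][shared], km[[j]][shared]))
      d[i, j] <- d[j, i] <-
        1 - common / min(sum(km[[i]]), sum(km[[j]]))
    }
  }
  d
}

# Progressive alignment of tokenized rows over an arbitrary alphabet with a
# substitution matrix S, guide tree from k-mer distances (UPGMA), plus one
# round of leave-one-out refinement.
progressive_align <- function(token_rows, ids, S, alphabet,
                              gap_open, gap_ext, refine = TRUE) {
  n <- length(token_rows)
  if (n == 1) {
    warning("single record: passthrough alignment")
    m <- matrix(token_rows[[1]], nrow = 1)
    rownames(m) <- ids
    return(m)
  }
  d <- kmer_distances(token_rows)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  # merge in hclust order
  alns <- lapply(token_rows, function(tok) matrix(tok, nrow = 1))
  members <- as.list(seq_len(n))
  for (s in seq_len(nrow(hc$merge))) {
    pick <- function(v) if (v < 0) -v else n + v
    a <- pick(hc$merge[s, 1]); b <- pick(hc$merge[s, 2])
    merged <- merge_alignments(alns[[a]], alns[[b]], S, alphabet,
                               gap_open, gap_ext)
    alns[[n + s]] <- merged
    members[[n + s]] <- c(members[[a]], members[[b]])
  }
  aln <- alns[[n + nrow(hc$merge)]]
  ord <- members[[n + nrow(hc$merge)]]
  aln <- aln[order(ord), , drop = FALSE]
  if (refine && n > 2) {
    for (i in seq_len(n)) {
      rest <- aln[-i, , drop = FALSE]
      keep <- colSums(rest != "-") > 0
      rest <- rest[, keep, drop = FALSE]
      self <- matrix(token_rows[[i]], nrow = 1)
      merged <- merge_alignments(rest, self, S, alphabet, gap_open, gap_ext)
      # merged rows 1..n-1 are `rest` in order, the last row is record i
      aln <- merged[order(c(seq_len(n)[-i], i)), , drop = FALSE]
    }
  }
  rownames(aln) <- ids
  aln
}

#' Multiple sequence alignment of ITS records
#'
#' Progressive alignment (guide tree from shared k-mer distances, UPGMA
#' merge order) with affine gaps, followed by one round of leave-one-out
#' iterative refinement.  Deterministic given input order.
#'
#' @param records an \code{its_records} data frame (>= 2 rows), or a named
#'   character vector of sequences.
#' @param params an \code{align_params} object.
#' @return an \code{its_alignment}: list with \code{ids} and \code{aln}
#'   (character vector of equal-length gapped rows).
#' @export
msa <- function(records, params = align_params()) {
  if (inherits(records, "its_records")) {
    seqs <- records$seq; ids <- records$id
  } else {
    seqs <- unname(unlist(records)); ids <- names(records)
    if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  }
  alphabet <- c("A", "C", "G", "T")
  S <- matrix(params$mismatch, 4, 4, dimnames = list(alphabet, alphabet))
  diag(S) <- params$match
  toks <- strsplit(toupper(chartr("U", "T", seqs)), "")
  am <- progressive_align(toks, ids, S, alphabet,
                          params$gap_open, params$gap_ext)
  structure(list(ids = ids, aln = apply(am, 1, paste, collapse = ""),
                 params = params), class = "its_alignment")
}

#' @export
print.its_alignment <- function(x, ...) {
  cat("its_alignment: ", length(x$ids), " rows x ", nchar(x$aln[1]),
      " columns\n", sep = "")
  invisible(x)
}

#' Alignment as a character matrix
#' @param x an \code{its_alignment}.
#' @export
aln_matrix <- function(x) {
  m <- do.call(rbind, strsplit(x$aln, ""))
  rownames(m) <- x$ids
  m
}

SS_STATES <- c("(", ")", ".")

#' Encode a sequence plus structure into the combined 12-letter alphabet
#'
#' Each position becomes one of 12 symbols: 4 bases x {opening-paired,
#' closing-paired, unpaired}, written as two-character tokens such as
#' \code{"A("}, \code{"C."}, \code{"U)"}.
#'
#' @param seq sequence (RNA or DNA letters).
#' @param ss a \code{secondary_structure} (or a dot-bracket string of the
#'   same length).
#' @return character vector of tokens, class \code{seqstruct_encoding}.
#' @export
encode_seqstruct <- function(seq, ss) {
  db <- if (inherits(ss, "secondary_structure")) ss$structure else ss
  s <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  d <- strsplit(db, "")[[1]]
  if (length(s) != length(d)) stop("sequence/structure length mismatch")
  if (!all(d %in% SS_STATES)) stop("invalid dot-bracket state")
  structure(paste0(s, d), class = "seqstruct_encoding")
}

#' Decode a combined-alphabet encoding back into sequence and structure
#' @param enc a \code{seqstruct_encoding}.
#' @return list with \code{seq} and \code{structure}.
#' @export
decode_seqstruct <- function(enc) {
  list(seq = paste(substr(enc, 1, 1), collapse = ""),
       structure = paste(substr(enc, 2, 2), collapse = ""))
}

seqstruct_alphabet <- function() {
  as.vector(outer(c("A", "C", "G", "U"), SS_STATES, paste0))
}

seqstruct_submatrix <- function(params) {
  alphabet <- seqstruct_alphabet()
  base <- substr(alphabet, 1, 1)
  state <- substr(alphabet, 2, 2)
  # RIBOSUM-style state agreement: identical 1, open/close 0.25, vs unpaired 0
  state_sim <- function(a, b) {
    if (a == b) 1
    else if (a %in% c("(", ")") && b %in% c("(", ")")) 0.25
    else 0
  }
  K <- length(alphabet)
  S <- matrix(0, K, K, dimnames = list(alphabet, alphabet))
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      S[i, j] <- ifelse(base[i] == base[j], params$match, params$mismatch) +
        params$struct_weight * state_sim(state[i], state[j])
    }
  }
  S
}

#' Multiple alignment of sequence-structure encodings
#'
#' Progressive global alignment over the 12-letter alphabet: sequence
#' match/mismatch (50/0) plus structure-state agreement weighted by the
#' structure weight, with affine indels (opening 800, extension 50).
#' Deterministic given input order.
#'
#' @param encodings named list of \code{seqstruct_encoding} vectors.
#' @param params a \code{seqstruct_align_params} object.
#' @return a \code{seqstruct_alignment}: list with \code{ids}, \code{aln}
#'   (matrix of tokens, gap "-"), \code{seq_rows} and \code{struct_rows}
#'   (gapped strings), and the scoring parameters.
#' @export
seqstruct_align <- function(encodings, params = seqstruct_align_params()) {
  if (length(encodings) < 2) stop("need at least two encoded records")
  ok <- vapply(encodings, inherits, logical(1), "seqstruct_encoding")
  if (!all(ok)) stop("all inputs must be seqstruct encodings (mixed input)")
  ids <- names(encodings)
  if (is.null(ids)) ids <- paste0("seq", seq_along(encodings))
  S <- seqstruct_submatrix(params)
  alphabet <- seqstruct_alphabet()
  am <- progressive_align(lapply(encodings, unclass), ids, S, alphabet,
                          params$gap_open, params$gap_ext)
  seq_rows <- apply(am, 1, function(r) {
    paste(ifelse(r == "-", "-", substr(r, 1, 1)), collapse = "")
  })
  struct_rows <- apply(am, 1, function(r) {
    paste(ifelse(r == "-", "-", substr(r, 2, 2)), collapse = "")
  })
  structure(list(ids = ids, aln = am, seq_rows = seq_rows,
                 struct_rows = struct_rows, params = params),
            class = "seqstruct_alignment")
}

#' Pairwise alignment score under the package scoring schemes
#'
#' Global affine-gap (Gotoh) score of two tokenized rows; exposed mainly so
#' alignment behaviour can be audited against hand-computed scores.
#'
#' @param tok_a,tok_b token vectors (plain bases or 12-letter tokens).
#' @param S substitution matrix over the token alphabet.
#' @param gap_open,gap_ext affine gap costs.
#' @export
pairwise_score <- function(tok_a, tok_b, S, gap_open, gap_ext) {
  alphabet <- rownames(S)
  A <- matrix(tok_a, nrow = 1)
  B <- matrix(tok_b, nrow = 1)
  M <- crossprod(profile_of(A, alphabet), S %*% profile_of(B, alphabet))
  .gotoh_path_cpp(M, gap_open, gap_ext)$score
}
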