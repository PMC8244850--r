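#' @useDynLib its2ss, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

GROUP_LEVELS <- c("AMPELOMYCES", "PUTATIVE_G1", "PUTATIVE_G2", "OUTGROUP")

IUPAC_DNA <- c("A", "C", "G", "T", "N",
               "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Construct a set of ITS sequence records
#'
#' Records are stored as a data frame with one row per sequence: accession-like
#' \code{id}, free-text \code{description}, uppercase DNA \code{seq} (RNA input
#' is normalized U to T with \code{rna_origin} flagged), and an optional
#' \code{group} label.
#'
#' @param id character vector of unique sequence identifiers.
#' @param seq character vector of sequences over the IUPAC DNA/RNA alphabet.
#' @param description optional free text per record.
#' @param group optional group label per record (see \code{\link{read_manifest}}).
#' @return a data frame of class \code{its_records}.
#' @export
its_records <- function(id, seq, description = "", group = NA_character_) {
  id <- as.character(id)
  if (anyDuplicated(id)) {
    stop("duplicate sequence ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  seq <- toupper(as.character(seq))
  rna_origin <- grepl("U", seq, fixed = TRUE)
  seq <- gsub("U", "T", seq, fixed = TRUE)
  if (any(!nzchar(seq))) stop("empty sequence for id: ",
                              paste(id[!nzchar(seq)], collapse = ", "))
  bad <- vapply(strsplit(seq, ""), function(ch) any(!ch %in% IUPAC_DNA), logical(1))
  if (any(bad)) {
    stop("sequence with characters outside the IUPAC alphabet: ",
         paste(id[bad], collapse = ", "))
  }
  out <- data.frame(id = id, description = rep_len(as.character(description), length(id)),
                    seq = seq, group = rep_len(as.character(group), length(id)),
                    rna_origin = rna_origin, stringsAsFactors = FALSE)
  class(out) <- c("its_records", "data.frame")
  out
}

#' Read a multi-entry FASTA file into ITS records
#'
#' Lowercase and RNA (U) input are normalized to uppercase DNA; the original
#' RNA alphabet is noted in the \code{rna_origin} column.
#'
#' @param path FASTA file.
#' @return an \code{its_records} data frame.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) stop("empty FASTA dataset: ", path)
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop("malformed FASTA header at line ", nonblank[1], " of ", path)
  }
  entries <- seqinr::read.fasta(path, as.string = TRUE, seqtype = "DNA",
                                forceDNAtolower = FALSE, whole.header = TRUE)
  headers <- vapply(entries, function(e) attr(e, "Annot"), character(1))
  headers <- sub("^>", "", headers)
  id <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1)
  desc <- sub("^\\S+\\s*", "", headers)
  seqs <- vapply(entries, function(e) as.character(e)[1], character(1))
  its_records(id = id, seq = seqs, description = desc)
}

#' Write ITS records to FASTA
#'
#' @param records an \code{its_records} data frame.
#' @param path output file; sequences are wrapped at 60 columns.
#' @export
write_fasta <- function(records, path) {
  stopifnot(inherits(records, "its_records"))
  nm <- ifelse(nzchar(records$description),
               paste(records$id, records$description),
               records$id)
  seqinr::write.fasta(strsplit(records$seq, ""), names = nm,
                      file.out = path, nbchar = 60)
  invisible(path)
}

#' Read a group manifest (id to group label)
#'
#' The manifest is delimited text with columns \code{id} and \code{group}
#' (an optional \code{note} column records provenance).  Labels are
#' case-folded and must be one of \code{AMPELOMYCES}, \code{PUTATIVE_G1},
#' \code{PUTATIVE_G2}, \code{OUTGROUP}.
#'
#' @param path manifest file (TSV with header).
#' @return a data frame of class \code{group_manifest}.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "group") %in% names(tab))) {
    stop("manifest must have columns 'id' and 'group'")
  }
  tab$group <- toupper(trimws(tab$group))
  bad <- !tab$group %in% GROUP_LEVELS
  if (any(bad)) {
    stop("unknown group label(s) in rows ",
         paste(which(bad), collapse = ", "), ": ",
         paste(unique(tab$group[bad]), collapse = ", "))
  }
  if (anyDuplicated(tab$id)) {
    stop("duplicate ids in manifest: ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "))
  }
  if (is.null(tab$note)) tab$note <- ""
  out <- tab[, c("id", "group", "note")]
  class(out) <- c("group_manifest", "data.frame")
  out
}

#' Attach manifest group labels to records
#'
#' Manifest ids absent from the records (and records without a manifest row)
#' are reported via warnings, never silently dropped.
#'
#' @param records an \code{its_records} data frame.
#' @param manifest a \code{group_manifest}.
#' @return \code{records} with the \code{group} column filled in.
#' @export
assign_groups <- function(records, manifest) {
  stopifnot(inherits(records, "its_records"), inherits(manifest, "group_manifest"))
  missing_in_fasta <- setdiff(manifest$id, records$id)
  if (length(missing_in_fasta)) {
    warning("manifest ids absent from the sequence set: ",
            paste(missing_in_fasta, collapse = ", "))
  }
  unlabeled <- setdiff(records$id, manifest$id)
  if (length(unlabeled)) {
    warning("records without a manifest label: ",
            paste(unlabeled, collapse = ", "))
  }
  records$group <- manifest$group[match(records$id, manifest$id)]
  records
}

#' Write a report table as TSV
#'
#' @param rows a data frame (or rectangular list of rows).
#' @param path output path.
#' @param decimals optional named integer vector mapping column names to the
#'   number of decimals to render (numeric columns only); unnamed columns are
#'   written at full precision.
#' @export
write_table <- function(rows, path, decimals = NULL) {
  if (!is.data.frame(rows)) {
    if (!is.list(rows) || length(rows) == 0) {
      rows <- as.data.frame(rows)
    } else {
      lens <- lengths(rows)
      if (length(unique(lens)) > 1) stop("ragged rows: lengths ",
                                         paste(lens, collapse = ", "))
      rows <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    }
  }
  out <- rows
  if (!is.null(decimals)) {
    for (nm in names(decimals)) {
      if (nm %in% names(out) && is.numeric(out[[nm]])) {
        out[[nm]] <- formatC(out[[nm]], format = "f", digits = decimals[[nm]])
      }
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
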