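#' Delimitation parameters
#'
#' Degenerate-consensus anchor motifs for the conserved ends of the 18S,
#' 5.8S and start of the 28S rRNA genes, with a mismatch budget and an
#' E-value-like significance threshold.  The shipped defaults are fungal
#' (ascomycete) consensus strings; the 5.8S gene is delimited as the span
#' from the start of the 5.8S start-motif hit to the end of the 5.8S
#' end-motif hit, ITS1 and ITS2 are the flanking spans.
#'
#' @param motif_18S_end consensus for the 3' end of 18S (ITS1 starts after it).
#' @param motif_5_8S_start,motif_5_8S_end consensus for the first and last
#'   stretches of the 5.8S gene.
#' @param motif_28S_start consensus for the 5' start of 28S (ITS2 ends at it).
#' @param max_mismatches mismatch budget per motif.
#' @param evalue_threshold significance gate for accepting a motif hit.
#' @param min_its2_len minimum ITS2 length (nt) for structure work.
#' @param max_its_len reference maximum ITS length (bp) used for
#'   normalization (primer-bounded amplicon maximum).
#' @return a \code{delimit_params} list.
#' @export
delimit_params <- function(motif_18S_end = "GTAGGTGAACCTGCGGAAGGATCATTA",
                           motif_5_8S_start = "CAACTTTCAGCAACGGATCTCTTGG",
                           motif_5_8S_end = "AACACGGCCGGACTGGAGTTA",
                           motif_28S_start = "AGGCTTTAGTTCGGTTCACACAACA",
                           max_mismatches = 4L,
                           evalue_threshold = 0.001,
                           min_its2_len = 150L,
                           max_its_len = 697L) {
  stopifnot(evalue_threshold > 0, min_its2_len >= 1,
            max_its_len >= min_its2_len)
  structure(list(motif_18S_end = toupper(motif_18S_end),
                 motif_5_8S_start = toupper(motif_5_8S_start),
                 motif_5_8S_end = toupper(motif_5_8S_end),
                 motif_28S_start = toupper(motif_28S_start),
                 max_mismatches = as.integer(max_mismatches),
                 evalue_threshold = evalue_threshold,
                 min_its2_len = as.integer(min_its2_len),
                 max_its_len = as.integer(max_its_len)),
            class = "delimit_params")
}

# IUPAC degenerate code -> compatible plain bases
iupac_expand <- function(ch) {
  switch(ch,
         A = "A", C = "C", G = "G", T = "T", U = "T",
         R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
         K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
         D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
         N = c("A", "C", "G", "T"),
         stop("unknown IUPAC code: ", ch))
}

# Scan one degenerate motif over a sequence, returning the best hit
# (fewest mismatches, leftmost) plus an analytic E-value: the expected
# number of equally-good-or-better hits in iid uniform random sequence,
# computed from the Poisson-binomial mismatch distribution of the motif.
scan_motif <- function(seq, motif, max_mismatches) {
  s <- strsplit(seq, "")[[1]]
  m <- strsplit(motif, "")[[1]]
  L <- length(s); W <- length(m)
  if (L < W) {
    return(list(found = FALSE, start = NA_integer_, end = NA_integer_,
                mismatches = NA_integer_, evalue = NA_real_))
  }
  allowed <- lapply(m, iupac_expand)
  # mismatch count at every offset
  mis <- integer(L - W + 1L)
  for (k in seq_len(W)) {
    ok <- s[k:(L - W + k)] %in% allowed[[k]]
    mis <- mis + !ok
  }
  best <- which.min(mis)
  bm <- mis[best]
  if (bm > max_mismatches) {
    return(list(found = FALSE, start = NA_integer_, end = NA_integer_,
                mismatches = bm, evalue = NA_real_))
  }
  # Poisson-binomial: P(mismatches <= bm) at one offset of random sequence
  p_match <- vapply(allowed, function(a) length(a) / 4, numeric(1))
  dp <- c(1, rep(0, W))   # dp[k+1] = P(k mismatches) over processed positions
  for (p in p_match) {
    dp <- dp * p + c(0, dp[-length(dp)]) * (1 - p)
  }
  pval <- sum(dp[seq_len(bm + 1L)])
  list(found = TRUE, start = best - 1L, end = best - 1L + W,
       mismatches = bm, evalue = (L - W + 1L) * pval)
}

#' Locate the conserved flanking motifs of the ITS region
#'
#' Finds the best hit of each anchor motif (18S end, 5.8S start, 5.8S end,
#' 28S start) under the mismatch budget, and reports an analytic E-value for
#' each hit (expected count of equally good hits in an iid random sequence of
#' the same length).  Hits failing the E-value gate are reported as absent.
#'
#' @param rec a single record: either one row of an \code{its_records} data
#'   frame or a plain sequence string.
#' @param params a \code{delimit_params} object.
#' @return a data frame with one row per motif: \code{motif, found, start,
#'   end, mismatches, evalue} (0-based, half-open coordinates).
#' @export
find_flank_motifs <- function(rec, params = delimit_params()) {
  seq <- if (is.character(rec)) toupper(rec[1]) else rec$seq[1]
  motifs <- c(motif_18S_end = params$motif_18S_end,
              motif_5_8S_start = params$motif_5_8S_start,
              motif_5_8S_end = params$motif_5_8S_end,
              motif_28S_start = params$motif_28S_start)
  rows <- lapply(names(motifs), function(nm) {
    h <- scan_motif(seq, motifs[[nm]], params$max_mismatches)
    sig <- h$found && !is.na(h$evalue) && h$evalue < params$evalue_threshold
    data.frame(motif = nm, found = sig,
               start = if (sig) h$start else NA_integer_,
               end = if (sig) h$end else NA_integer_,
               mismatches = h$mismatches,
               evalue = h$evalue, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!out$found[out$motif == "motif_5_8S_start"] &&
      !out$found[out$motif == "motif_5_8S_end"]) {
    stop(errorCondition(
      paste0("NO_ANCHOR: no significant 5.8S motif hit; ",
             "sequence cannot be delimited"),
      class = c("its2ss_no_anchor", "error", "condition")))
  }
  out
}

#' Partition a record into 18S flank, ITS1, 5.8S, ITS2 and 28S flank
#'
#' The 5.8S gene is the span from the 5.8S start-motif hit to the end of the
#' 5.8S end-motif hit; ITS1 is everything between the 18S flank (when its
#' end motif is found) and the 5.8S; ITS2 runs from the 5.8S end to the 28S
#' start motif (or the sequence end, flagged incomplete, when the 28S flank
#' is missing).  Coordinates are 0-based half-open; the five regions tile the
#' sequence exactly.
#'
#' @param rec one record (row of \code{its_records}) or a sequence string.
#' @param hits optional precomputed motif table from
#'   \code{\link{find_flank_motifs}}.
#' @param params a \code{delimit_params} object.
#' @return an \code{its_partition}: data frame with columns \code{region,
#'   start, end, complete}.
#' @export
delimit_its <- function(rec, hits = NULL, params = delimit_params()) {
  seq <- if (is.character(rec)) toupper(rec[1]) else rec$seq[1]
  n <- nchar(seq)
  if (is.null(hits)) hits <- find_flank_motifs(seq, params)
  g <- function(nm, col) hits[[col]][hits$motif == nm]
  if (!g("motif_5_8S_start", "found") || !g("motif_5_8S_end", "found")) {
    stop(errorCondition("NO_ANCHOR: both 5.8S anchors are required",
                        class = c("its2ss_no_anchor", "error", "condition")))
  }
  s58_start <- g("motif_5_8S_start", "start")
  s58_end <- g("motif_5_8S_end", "end")
  if (s58_end <= s58_start) {
    stop(errorCondition(
      "INCONSISTENT_ANCHORS: 5.8S end motif precedes its start motif",
      class = c("its2ss_inconsistent_anchors", "error", "condition")))
  }
  has18 <- g("motif_18S_end", "found")
  has28 <- g("motif_28S_start", "found")
  f18_end <- if (has18) g("motif_18S_end", "end") else 0L
  f28_start <- if (has28) g("motif_28S_start", "start") else n
  if (has18 && f18_end > s58_start) {
    stop(errorCondition("INCONSISTENT_ANCHORS: 18S end inside the 5.8S span",
                        class = c("its2ss_inconsistent_anchors", "error",
                                  "condition")))
  }
  if (has28 && f28_start < s58_end) {
    stop(errorCondition("INCONSISTENT_ANCHORS: 28S start inside the 5.8S span",
                        class = c("its2ss_inconsistent_anchors", "error",
                                  "condition")))
  }
  out <- data.frame(
    region = c("flank18S", "ITS1", "r5.8S", "ITS2", "flank28S"),
    start = c(0L, f18_end, s58_start, s58_end, f28_start),
    end = c(f18_end, s58_start, s58_end, f28_start, n),
    complete = c(has18, has18, TRUE, has28, has28),
    stringsAsFactors = FALSE)
  class(out) <- c("its_partition", "data.frame")
  out
}

#' Extract one region's sequence from a partitioned record
#'
#' @param rec a record row or sequence string.
#' @param part an \code{its_partition}.
#' @param region one of \code{"flank18S", "ITS1", "r5.8S", "ITS2", "flank28S"}.
#' @return the region's sequence (possibly empty).
#' @export
region_seq <- function(rec, part, region) {
  seq <- if (is.character(rec)) toupper(rec[1]) else rec$seq[1]
  i <- match(region, part$region)
  if (is.na(i)) stop("unknown region: ", region)
  if (part$end[i] <= part$start[i]) return("")
  substr(seq, part$start[i] + 1L, part$end[i])
}

#' Hybridize the 5.8S 3' tail with the 28S 5' head (proximal stem)
#'
#' Computes the optimal antiparallel duplex between the last \code{window}
#' nucleotides of 5.8S and the first \code{window} nucleotides of the 28S
#' flank under the nearest-neighbor stacking model (dG at 37 C, companion
#' dH along the optimal pairing).  The free-nucleotide counts are taken at
#' the ITS2-proximal end of the duplex (3' of 5.8S, 5' of 28S); the pattern
#' is \code{TYPICAL} iff exactly one free nucleotide remains on each strand.
#' A 28S flank shorter than the stem window yields an \code{UNMODELABLE}
#' result (not an error), as does a pair-free duplex.
#'
#' @param part an \code{its_partition}.
#' @param rec the corresponding record or sequence string.
#' @param window stem window per strand in nt (default 25).
#' @param params nearest-neighbor parameters from \code{\link{turner_params}}.
#' @return a \code{hybrid_result} list: \code{dG}, \code{dH} (kcal/mol),
#'   \code{paired_positions}, \code{free_nt_5_8S}, \code{free_nt_28S},
#'   \code{pattern}.
#' @export
hybridize_stem <- function(part, rec, window = 25L, params = turner_params()) {
  tail58 <- region_seq(rec, part, "r5.8S")
  head28 <- region_seq(rec, part, "flank28S")
  unmod <- function() {
    structure(list(dG = 0, dH = 0, paired_positions = NULL,
                   free_nt_5_8S = NA_integer_, free_nt_28S = NA_integer_,
                   pattern = "UNMODELABLE"), class = "hybrid_result")
  }
  if (nchar(head28) < window || nchar(tail58) < window) return(unmod())
  s1 <- substr(tail58, nchar(tail58) - window + 1L, nchar(tail58))
  s2 <- substr(head28, 1L, window)
  lt <- loop_penalty_tables(2L * window)
  res <- .duplex_cpp(base_codes(s1), base_codes(s2),
                     params$stack_dg, params$stack_dh,
                     lt$bulge, lt$internal,
                     params$duplex_init_dg, params$duplex_init_dh,
                     params$max_interior)
  if (is.na(res$dg_tenths) || res$dg_tenths > 0L) return(unmod())
  free1 <- window - max(res$pairs1)
  free2 <- min(res$pairs2) - 1L
  pattern <- if (free1 == 1L && free2 == 1L) "TYPICAL" else "VARIANT_MULTI_FREE"
  structure(list(
    dG = res$dg_tenths / 10,
    dH = res$dh_tenths / 10,
    paired_positions = cbind(pos_5_8S = res$pairs1, pos_28S = res$pairs2),
    free_nt_5_8S = free1, free_nt_28S = free2,
    pattern = pattern), class = "hybrid_result")
}

#' Classify proximal-stem stability (pseudogene screen)
#'
#' Stems weaker than the flexibility band destabilize the fold and flag
#' rDNA pseudogene candidates.  Boundaries are inclusive on the FLEXIBLE
#' side: dG in [flex_lower, flex_upper] is FLEXIBLE, weaker (greater) dG is
#' DESTABILIZED, stronger (smaller) is STABLE.
#'
#' @param hr a \code{hybrid_result} with pattern other than UNMODELABLE.
#' @param flex_upper,flex_lower band limits in kcal/mol (defaults -15, -19).
#' @return one of \code{"STABLE"}, \code{"FLEXIBLE"}, \code{"DESTABILIZED"}.
#' @export
flag_pseudogene_candidate <- function(hr, flex_upper = -15, flex_lower = -19) {
  stopifnot(inherits(hr, "hybrid_result"))
  if (hr$pattern == "UNMODELABLE") {
    stop("stability is undefined for an UNMODELABLE stem")
  }
  if (hr$dG > flex_upper) "DESTABILIZED"
  else if (hr$dG >= flex_lower) "FLEXIBLE"
  else "STABLE"
}
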