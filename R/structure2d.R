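#' Fold an ITS2 sequence into its minimum-free-energy secondary structure
#'
#' Pseudoknot-free MFE folding by dynamic programming over hairpin, stack,
#' bulge, internal-loop and affine multibranch terms of the shipped
#' nearest-neighbor model.  Deterministic: ties are resolved in a fixed
#' order favouring 5'-most pairing.
#'
#' @param its2_seq sequence (DNA or RNA letters; T and U are equivalent).
#' @param model an \code{nn_params} energy model from \code{\link{turner_params}}.
#' @return a \code{secondary_structure}: list with \code{seq} (RNA),
#'   \code{structure} (dot-bracket), \code{mfe} (kcal/mol) and
#'   \code{mfe_tenths} (exact integer form).
#' @export
fold_mfe <- function(its2_seq, model = turner_params()) {
  seq <- toupper(its2_seq[1])
  codes <- base_codes(seq)   # errors on non-RNA symbols
  n <- length(codes)
  if (n < 50 || n > 400) {
    warning("sequence length ", n, " nt is outside the expected 50-400 nt range")
  }
  lt <- loop_penalty_tables(n)
  res <- .fold_mfe_cpp(codes, model$stack_dg, lt$hairpin, lt$bulge, lt$internal,
                       model$ml_a, model$ml_b, model$ml_c,
                       model$min_hairpin, model$max_interior)
  structure(list(seq = chartr("T", "U", seq),
                 structure = res$structure,
                 mfe = res$mfe_tenths / 10,
                 mfe_tenths = res$mfe_tenths,
                 model_version = model$version),
            class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(x$seq, "\n", x$structure, "\n", sprintf("mfe = %.1f kcal/mol", x$mfe),
      "\n", sep = "")
  invisible(x)
}

#' Pairing table from a dot-bracket string
#'
#' @param db dot-bracket string (balanced, pseudoknot-free).
#' @return integer vector; element i is the partner of position i, 0 if unpaired.
#' @export
pair_table <- function(db) {
  ch <- strsplit(db, "")[[1]]
  pt <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (length(stack) == 0) stop("unbalanced dot-bracket at position ", i)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j
      pt[j] <- i
    } else if (ch[i] != ".") {
      stop("unexpected character '", ch[i], "' in dot-bracket")
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket: unmatched '('")
  pt
}

# Directly enclosed base pairs inside pair (i,j) (or inside the exterior
# loop when i = 0, j = n + 1), plus the unpaired count of the loop.
enclosed_pairs <- function(pt, i, j) {
  ks <- integer(0)
  unpaired <- 0L
  k <- i + 1L
  while (k < j) {
    if (pt[k] == 0) {
      unpaired <- unpaired + 1L
      k <- k + 1L
    } else {
      ks <- c(ks, k)
      k <- pt[k] + 1L
    }
  }
  list(branches = ks, unpaired = unpaired)
}

#' Independent energy evaluation of a secondary structure
#'
#' Re-computes the free energy of a given dot-bracket structure by loop
#' decomposition in R, using the same integer parameter tables as the
#' folding engine but none of its code path.  Serves as the energy audit:
#' for any structure reported by \code{\link{fold_mfe}} the result equals
#' the reported MFE exactly.
#'
#' @param ss a \code{secondary_structure} (or list with \code{seq} and
#'   \code{structure}).
#' @param model an \code{nn_params} energy model.
#' @return energy in kcal/mol (attribute \code{tenths} holds the exact
#'   integer form).
#' @export
structure_energy <- function(ss, model = turner_params()) {
  seq <- chartr("T", "U", toupper(ss$seq))
  ch <- strsplit(seq, "")[[1]]
  pt <- pair_table(ss$structure)
  n <- length(pt)
  if (length(ch) != n) stop("sequence/structure length mismatch")
  lt <- loop_penalty_tables(n)
  total <- 0L
  pairs_open <- which(pt > seq_along(pt))
  for (i in pairs_open) {
    j <- pt[i]
    enc <- enclosed_pairs(pt, i, j)
    nb <- length(enc$branches)
    if (nb == 0) {
      total <- total + lt$hairpin[enc$unpaired + 1L]
    } else if (nb == 1) {
      k <- enc$branches[1]; l <- pt[k]
      u1 <- k - i - 1L; u2 <- j - l - 1L
      if (u1 == 0 && u2 == 0) {
        p1 <- pair_name(ch[i], ch[j]); p2 <- pair_name(ch[k], ch[l])
        if (is.na(p1) || is.na(p2)) stop("non-canonical pair in structure")
        total <- total + model$stack_dg[p1, p2]
      } else if (u1 == 0 || u2 == 0) {
        total <- total + lt$bulge[u1 + u2 + 1L]
      } else {
        total <- total + lt$internal[u1 + u2 + 1L]
      }
    } else {
      total <- total + model$ml_a + model$ml_b * (nb + 0L) +
        model$ml_c * enc$unpaired
    }
  }
  # multibranch: closing pair contributes ml_a (added above); each branch of a
  # multiloop additionally costs ml_b, which the loop above charged for the
  # enclosed branches; the exterior loop is free.
  structure(total / 10, tenths = total)
}

#' Decompose a four-fingered ITS2 structure into helices and rings
#'
#' Identifies the helices radiating from the exterior loop (descending
#' through a basal stem into the first multiloop when the exterior holds a
#' single stem), orders them 5' to 3' and, when exactly four are present,
#' labels them I-IV.  Each helix is walked from its outermost pair to its
#' terminal loop, counting stacked pairs, internal loops and bulges.
#' Rings are the single-stranded spans between consecutive helices; the
#' ring between helices I and IV is the joined exterior span (3' side of
#' helix IV followed by the 5' side of helix I, matching the circular
#' layout of the molecule).
#'
#' @param ss a \code{secondary_structure}.
#' @return a \code{helix_set}: list with \code{n_helices},
#'   \code{four_fingered} flag, per-helix table \code{helices}
#'   (outer_start, outer_end, paired, internal_loops, bulges,
#'   terminal_loop), \code{loops} (per-helix loop detail), \code{rings}
#'   (ring sequences as DNA), and \code{helix_seqs}.
#' @export
decompose_helices <- function(ss) {
  seq <- chartr("T", "U", toupper(ss$seq))
  ch <- strsplit(seq, "")[[1]]
  pt <- pair_table(ss$structure)
  n <- length(pt)
  ext <- enclosed_pairs(pt, 0L, n + 1L)
  tops <- ext$branches
  basal <- NULL
  if (length(tops) == 1L) {
    # single basal stem: descend until the first multiloop
    i <- tops[1]; j <- pt[i]
    repeat {
      enc <- enclosed_pairs(pt, i, j)
      if (length(enc$branches) >= 2L) {
        basal <- c(i, j)
        tops <- enc$branches
        break
      }
      if (length(enc$branches) == 0L) break   # lone hairpin: one helix
      i <- enc$branches[1]; j <- pt[i]
    }
  }
  helices <- lapply(tops, function(i) walk_helix(pt, ch, i))
  nh <- length(helices)
  htab <- do.call(rbind, lapply(helices, function(h) {
    data.frame(outer_start = h$outer_start, outer_end = h$outer_end,
               paired = h$paired, internal_loops = h$internal_loops,
               bulges = h$bulges, terminal_loop = h$terminal_loop)
  }))
  dna <- function(i, j) {
    if (j < i) return("")
    chartr("U", "T", paste(ch[i:j], collapse = ""))
  }
  rings <- list()
  if (nh >= 2) {
    for (k in seq_len(nh - 1L)) {
      rings[[paste0("ring_", k, "_", k + 1L)]] <-
        dna(htab$outer_end[k] + 1L, htab$outer_start[k + 1L] - 1L)
    }
  }
  lo <- if (is.null(basal)) 1L else basal[1] + 1L
  hi <- if (is.null(basal)) n else basal[2] - 1L
  rings[["ring_first_last"]] <- paste0(dna(htab$outer_end[nh] + 1L, hi),
                                       dna(lo, htab$outer_start[1] - 1L))
  helix_seqs <- mapply(function(s, e) dna(s, e),
                       htab$outer_start, htab$outer_end)
  structure(list(n_helices = nh,
                 four_fingered = nh == 4L,
                 helices = htab,
                 loops = lapply(helices, `[[`, "loops"),
                 rings = rings,
                 helix_seqs = helix_seqs,
                 basal = basal),
            class = "helix_set")
}

# Walk one helix from its outermost pair inward; record every interruption.
walk_helix <- function(pt, ch, i0) {
  i <- i0; j <- pt[i0]
  paired <- 1L; internal_loops <- 0L; bulges <- 0L
  terminal_loop <- NA_integer_
  loops <- list()
  repeat {
    enc <- enclosed_pairs(pt, i, j)
    nb <- length(enc$branches)
    if (nb == 0L) {
      terminal_loop <- enc$unpaired
      break
    }
    if (nb >= 2L) {
      # nested multiloop inside a finger: stop the walk here
      terminal_loop <- NA_integer_
      break
    }
    k <- enc$branches[1]; l <- pt[k]
    u1 <- k - i - 1L; u2 <- j - l - 1L
    if (u1 > 0L || u2 > 0L) {
      type <- if (u1 == 0L || u2 == 0L) "bulge" else "internal"
      if (type == "bulge") bulges <- bulges + 1L else
        internal_loops <- internal_loops + 1L
      side1 <- if (u1 > 0L) paste(ch[(i + 1L):(k - 1L)], collapse = "") else ""
      side2 <- if (u2 > 0L) paste(ch[(l + 1L):(j - 1L)], collapse = "") else ""
      loops[[length(loops) + 1L]] <-
        list(type = type, u1 = u1, u2 = u2, side1 = side1, side2 = side2)
    }
    paired <- paired + 1L
    i <- k; j <- l
  }
  list(outer_start = i0, outer_end = pt[i0], paired = paired,
       internal_loops = internal_loops, bulges = bulges,
       terminal_loop = terminal_loop, loops = loops)
}

#' Detect the diagnostic ITS2 motifs
#'
#' Flags the U-U mismatch on helix II (a 1x1 internal loop with U opposite
#' U), the helix III motif (UGG, UGGU, or UGGU with a separate UU), the
#' ring sequence between helices I and IV, the spacer between helices II
#' and III, and whether that spacer is adenine-rich (three or more
#' consecutive A).  Motif letters are matched on the DNA alphabet with U/T
#' equivalence.
#'
#' @param hs a \code{helix_set} from \code{\link{decompose_helices}}.
#' @return a \code{motif_report} list.
#' @export
detect_motifs <- function(hs) {
  stopifnot(inherits(hs, "helix_set"))
  uu <- FALSE; uu_pos <- NA_integer_
  helix3_motif <- NA_character_
  ring14 <- hs$rings[["ring_first_last"]]
  spacer23 <- NA_character_
  if (hs$four_fingered) {
    for (lp in hs$loops[[2]]) {
      if (lp$type == "internal" && lp$u1 == 1L && lp$u2 == 1L &&
          lp$side1 == "U" && lp$side2 == "U") {
        uu <- TRUE
        break
      }
    }
    h3 <- hs$helix_seqs[[3]]
    if (grepl("TGGT", h3, fixed = TRUE)) {
      rest <- gsub("TGGT", "----", h3, fixed = TRUE)
      helix3_motif <- if (grepl("TT", rest, fixed = TRUE)) "UGGU+UU" else "UGGU"
    } else if (grepl("TGG", h3, fixed = TRUE)) {
      helix3_motif <- "UGG"
    }
    spacer23 <- hs$rings[["ring_2_3"]]
  }
  structure(list(uu_mismatch_helixII = uu,
                 helixIII_motif = helix3_motif,
                 ring_I_IV = ring14,
                 spacer_II_III = spacer23,
                 aaa_spacer = !is.na(spacer23) &&
                   grepl("AAA", spacer23, fixed = TRUE)),
            class = "motif_report")
}

ring_matches <- function(ring, target, max_mismatch = 1L) {
  if (is.null(ring) || is.na(ring) || nchar(ring) != nchar(target)) return(FALSE)
  a <- strsplit(ring, "")[[1]]; b <- strsplit(target, "")[[1]]
  sum(a != b) <= max_mismatch
}

#' Classify an ITS2 structure into the diagnostic models
#'
#' Rule cascade over the four-helix decomposition and motif report:
#' structures without exactly four helices are UNCLASSIFIED; a TCCATG-like
#' ring between helices I and IV with only the U-U motif marks the putative
#' (non-Ampelomyces) pattern; a GTACCC-like ring with the UGG motif marks
#' the Model 1 family (Model 7 when the ring carries the U-substituted
#' TTACCC variant); a GTCTCC/GTGTCC-like ring with UGGU+UU and the large
#' 12-nt helix II terminal loop marks Model 2 (Model 3 when helix III shows
#' four bulges); an adenine-rich II-III spacer with UGGU and an internal
#' loop in helix I marks Models 4-6 (Model 6 when helix IV is a 3-bp stack
#' closing a CCC loop, otherwise split on the helix III loop/bulge layout).
#' Ring matching allows one mismatch by default; ties are broken by rule
#' order.
#'
#' @param hs a \code{helix_set}.
#' @param mr a \code{motif_report}.
#' @param max_ring_mismatch mismatches tolerated in ring comparison.
#' @return a \code{model_label}: list with \code{label} and \code{evidence}.
#' @export
classify_model <- function(hs, mr, max_ring_mismatch = 1L) {
  stopifnot(inherits(hs, "helix_set"), inherits(mr, "motif_report"))
  lab <- function(label, evidence) {
    structure(list(label = label, evidence = evidence), class = "model_label")
  }
  if (!hs$four_fingered) {
    return(lab("UNCLASSIFIED", character(0)))
  }
  ev <- character(0)
  if (mr$uu_mismatch_helixII) ev <- c(ev, "U-U mismatch on helix II")
  if (!is.na(mr$helixIII_motif)) {
    ev <- c(ev, paste0(mr$helixIII_motif, " motif on helix III"))
  }
  ring <- mr$ring_I_IV
  h <- hs$helices
  # (b) putative pattern
  if (ring_matches(ring, "TCCATG", max_ring_mismatch) &&
      is.na(mr$helixIII_motif)) {
    return(lab("PUTATIVE", c(ev, "TCCATG ring between helices I and IV",
                             "no helix III motif")))
  }
  # (c) Model 1 family
  if (ring_matches(ring, "GTACCC", max_ring_mismatch) &&
      !is.na(mr$helixIII_motif) && mr$helixIII_motif == "UGG") {
    ev <- c(ev, paste0("GTACCC-like ring (", ring, ")"))
    if (identical(ring, "TTACCC")) {
      return(lab("M7", c(ev, "U-substituted ring variant")))
    }
    return(lab("M1", ev))
  }
  # (d) Model 2 family (text ring GTCTCC; figure legend ring GTGTCC --
  # both accepted, the matched variant is reported in the evidence)
  m2ring <- ring_matches(ring, "GTCTCC", max_ring_mismatch) ||
    ring_matches(ring, "GTGTCC", max_ring_mismatch)
  if (m2ring && !is.na(mr$helixIII_motif) && mr$helixIII_motif == "UGGU+UU" &&
      !is.na(h$terminal_loop[2]) && h$terminal_loop[2] == 12L) {
    ev <- c(ev, paste0("GTCTCC/GTGTCC-like ring (", ring, ")"),
            "12-nt helix II terminal loop")
    if (h$bulges[3] == 4L) {
      return(lab("M3", c(ev, "four bulges in helix III")))
    }
    return(lab("M2", ev))
  }
  # (e) Models 4-6
  if (isTRUE(mr$aaa_spacer) && !is.na(mr$helixIII_motif) &&
      mr$helixIII_motif %in% c("UGGU", "UGGU+UU") &&
      h$internal_loops[1] >= 1L) {
    ev <- c(ev, "A-rich spacer between helices II and III",
            "internal loop in helix I")
    loop4 <- hs$loops[[4]]
    term4 <- h$terminal_loop[4]
    seq4 <- hs$helix_seqs[[4]]
    ccc_loop <- !is.na(term4) && term4 == 3L && h$paired[4] == 3L &&
      grepl("CCC", seq4, fixed = TRUE)
    if (ccc_loop) {
      return(lab("M6", c(ev, "helix IV 3-bp stack with CCC terminal loop")))
    }
    if (h$bulges[3] > h$internal_loops[3]) {
      return(lab("M5", c(ev, "bulge-dominated helix III")))
    }
    return(lab("M4", c(ev, "loop-dominated helix III")))
  }
  lab("UNCLASSIFIED", character(0))
}

#' Consensus of aligned ITS2 sequence-structures
#'
#' Column-wise majority base and majority structural state over aligned
#' rows, with per-column conservation equal to the majority fraction.
#' Gap-containing columns are retained (\code{gap_policy = "keep"}) or
#' removed (\code{"drop"}).
#'
#' @param seq_rows character vector of aligned sequences (equal lengths,
#'   gaps as '-').
#' @param struct_rows character vector of aligned dot-bracket strings
#'   (same dimensions, gaps as '-').
#' @param gap_policy \code{"keep"} or \code{"drop"}.
#' @return list with \code{consensus_seq}, \code{consensus_struct},
#'   \code{conservation} (numeric in [0, 1] per kept column) and
#'   \code{columns} (original column indices kept).
#' @export
consensus_structure <- function(seq_rows, struct_rows,
                                gap_policy = c("keep", "drop")) {
  gap_policy <- match.arg(gap_policy)
  if (length(seq_rows) == 0) stop("empty input")
  L <- unique(nchar(seq_rows))
  if (length(L) != 1 || !all(nchar(struct_rows) == L)) {
    stop("rows must have equal length")
  }
  sm <- do.call(rbind, strsplit(toupper(seq_rows), ""))
  tm <- do.call(rbind, strsplit(struct_rows, ""))
  keep <- seq_len(L)
  if (gap_policy == "drop") {
    keep <- which(colSums(sm == "-") == 0)
  }
  if (length(keep) == 0) stop("no columns left after dropping gap columns")
  maj <- function(x) {
    tb <- sort(table(x), decreasing = TRUE)
    c(names(tb)[1], unname(tb)[1] / length(x))
  }
  ms <- apply(sm[, keep, drop = FALSE], 2, maj)
  mt <- apply(tm[, keep, drop = FALSE], 2, maj)
  cons_seq <- paste(ms[1, ], collapse = "")
  cons_struct <- paste(mt[1, ], collapse = "")
  conservation <- (as.numeric(ms[2, ]) + as.numeric(mt[2, ])) / 2
  list(consensus_seq = cons_seq, consensus_struct = cons_struct,
       conservation = conservation, columns = keep)
}
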