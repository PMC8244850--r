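# Constructive synthetic datasets: every record carries its ground truth
# (region boundaries, planted secondary structure, model label), so the
# whole pipeline is testable without any sequence download.

revcomp_dna <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

# helix construction elements (outer -> inner)
hx_p <- function(top) list(kind = "p", top = top)
hx_il <- function(side1, side2) list(kind = "il", s1 = side1, s2 = side2)
hx_tl <- function(loop) list(kind = "tl", loop = loop)

# Build one hairpin helix from its element list; returns seq + dot-bracket.
build_helix <- function(elems) {
  top <- character(0); top_db <- character(0)
  bot <- character(0); bot_db <- character(0)
  terminal <- NULL
  for (e in elems) {
    if (e$kind == "p") {
      top <- c(top, e$top); top_db <- c(top_db, strrep("(", nchar(e$top)))
      bot <- c(bot, revcomp_dna(e$top))
      bot_db <- c(bot_db, strrep(")", nchar(e$top)))
    } else if (e$kind == "il") {
      top <- c(top, e$s1); top_db <- c(top_db, strrep(".", nchar(e$s1)))
      bot <- c(bot, e$s2); bot_db <- c(bot_db, strrep(".", nchar(e$s2)))
    } else {
      terminal <- e$loop
    }
  }
  if (is.null(terminal)) stop("helix needs a terminal loop")
  seq <- paste0(paste(top, collapse = ""), terminal,
                paste(rev(bot), collapse = ""))
  db <- paste0(paste(top_db, collapse = ""), strrep(".", nchar(terminal)),
               paste(rev(bot_db), collapse = ""))
  list(seq = seq, db = db)
}

assemble_its2 <- function(lead, helices, spacers, tail) {
  stopifnot(length(spacers) == length(helices) - 1L)
  seq <- lead; db <- strrep(".", nchar(lead))
  for (i in seq_along(helices)) {
    seq <- paste0(seq, helices[[i]]$seq)
    db <- paste0(db, helices[[i]]$db)
    if (i < length(helices)) {
      seq <- paste0(seq, spacers[i])
      db <- paste0(db, strrep(".", nchar(spacers[i])))
    }
  }
  list(seq = paste0(seq, tail), db = paste0(db, strrep(".", nchar(tail))))
}

# Positions (1-based) that carry diagnostic information and must never be
# mutated: computed from a template's annotation spans.
protect_span <- function(seq, sub) {
  hits <- gregexpr(sub, seq, fixed = TRUE)[[1]]
  if (hits[1] < 0) return(integer(0))
  unlist(lapply(hits, function(i) i:(i + nchar(sub) - 1L)))
}

# Frozen template designs: arm blocks were chosen by a design-time search
# so that (i) MFE folding recovers the planted four-helix structure exactly,
# (ii) the folding energy lies in the band reported for the corresponding
# group, and (iii) the model label survives per-record compensatory pair
# flips in >= 95% of draws.  Loops alternate A/C (no contiguous
# complementary partner exists anywhere in the molecule), diagnostic motif
# loops carry the G/T letters.
ITS2_DESIGNS <- list(
  M1 = list(
    seq = paste0("GAAGGAAGAGACACCTCTCCCTTCCAAGGAATGGGAACACACACATCCCTTTCCTAT",
                 "AGAAAAAAACGGAAAGAAACAAAGAAAAACTGGCCTTTTCCTTTATTTCCTTCCATT",
                 "TTCTTCTCAGAGAGAGAGGACACCCTCCCTCTCGTACCC"),
    db = paste0("(((((.((((....)))).)))))..(((((.((((.........)))).)))))..",
                "((((.((((.((((.((((.((((.((((......)))).)))).)))).)))).))",
                ")).))))..(((((.((((....)))).)))))......"),
    protect = c("CTGGCC", "GTACCC")),
  M7 = list(
    seq = paste0("AGGGAAAAGAACACTCTTCTCCCTCAAGGAATGGGAACACACACATCCCTTTCCTAT",
                 "GAAGAAGAGCAAAGAAAAGCAGAAAGAAGCTGGCCCTTCCTTCTACTTTCCTTTACT",
                 "CTCCTTCCCAAGAGAAAGAACACTCTTCCTCTTTTACCC"),
    db = paste0("(((((.((((....)))).)))))..(((((.((((.........)))).)))))..",
                "((((.((((.((((.((((.((((.((((......)))).)))).)))).)))).))",
                ")).))))..(((((.((((....)))).)))))......"),
    protect = c("CTGGCC", "TTACCC")),
  M2 = list(
    seq = paste0("AAGGGAGAGGACACCCTCCCCCTTCAGAGAGTAAAGAACACACACACACTCTTTTCT",
                 "CTCAAGAATTAAGACGGAAAAGAAACTGGTCTTTCTCTTCCATCTTCTTCTAAAAGG",
                 "AAGGAAACACTTCCCTCCTTGTCTCC"),
    db = paste0("(((((.((((....)))).)))))..(((((.(((((............))))).))",
                "))).((((..((((.((((.(((((......))))).)))).)))).))))..((((",
                "(.((((....)))).)))))......"),
    protect = c("CTGGTC", "TT", "GTCTCC", "ACACACACACAC")),
  M4 = list(
    seq = paste0("GAGGAAGGAGACACCTCCCTCCTCCAAAAAGTGAGGACACACACCTCTCTTTTAAAA",
                 "AAGAGAGACGAAAAAAAAGGCTGGTCCCTTTTCTTTCATCTCCCTTTCAGGGGAAAG",
                 "AAACACTTCTCTCCCCGAACCC"),
    db = paste0("(((((.((((....)))).)))))..(((((.((((.......)))).)))))...(",
                "(((.((((.((((.((((((......)))))).)))).)))).))))..(((((.((",
                "((....)))).)))))......"),
    protect = c("CTGGTC", "AAA")),
  M6 = list(
    seq = paste0("GAGGAAGAAGACACCTTCCTCCTCCAGAGGATGGAAACACACATTCCTTCCTCAAAA",
                 "AGAAAGGACGGAGAAGGGGACTGGTCTCCCCTCCTCCATCCTCTCTTCAGGGCCCCC",
                 "CGAACCCAAC"),
    db = paste0("(((((.((((....)))).)))))..(((((.((((.......)))).)))))...(",
                "(((.((((.((((.((((((......)))))).)))).)))).))))..(((...))",
                ")........."),
    protect = c("CTGGTC", "AAA", "GGGCCCCCC")),
  PUTATIVE = list(
    seq = paste0("AAAGAAAGGGAACACTCCCCTTCTTTCAAAAAATAGGAACACACACATCCTTTTTTT",
                 "ACAAAAAAAAAAACAGAAGAAAAAACGAAAACACACACACTTTCATTTTTCCTTCTA",
                 "TTTTTCTTTTTCCGGGAAAAAAAACACTTTTCTTCCCTCCATG"),
    db = paste0("((((((.((((....)))).))))))..(((((.((((.........)))).)))))",
                "..(((((.(((((.(((((.(((((.((((..........)))).))))).))))).",
                "))))).)))))..(((((.((((....)))).)))))......"),
    protect = c("TCCATG"))
)

#' Designed ITS2 templates for each structural model
#'
#' Frozen constructive designs: four stems whose arms were selected so the
#' MFE fold recovers the planted structure, with linkers carrying the
#' model diagnostics (ring between helices I and IV, U-U mismatch on helix
#' II, helix III motif, spacer composition).  PUTATIVE2 and OUTGROUP are
#' sequence-diverged variants of the putative template (deterministic
#' compensatory pair flips outside helix III), giving the second putative
#' group and the outgroup distinct sequences over a shared fold class.
#'
#' @param model one of \code{"M1", "M2", "M4", "M6", "M7", "PUTATIVE",
#'   "PUTATIVE2", "OUTGROUP"}.
#' @return list with \code{seq}, \code{db} (planted structure),
#'   \code{model} (expected classifier label) and \code{protected}
#'   (1-based positions that within-group mutation must not touch).
#' @export
its2_template <- function(model) {
  base_name <- switch(model,
                      PUTATIVE2 = , OUTGROUP = "PUTATIVE",
                      model)
  d <- ITS2_DESIGNS[[base_name]]
  if (is.null(d)) stop("unknown template model: ", model)
  tmpl <- finalize_template(d$seq, d$db, base_name, d$protect)
  if (model %in% c("PUTATIVE2", "OUTGROUP")) {
    tmpl <- diverge_template(tmpl,
                             seed = if (model == "PUTATIVE2") 104729L
                                    else 224737L,
                             n_swaps = 12L, n_loop_subs = 0L)
  }
  tmpl
}

finalize_template <- function(seq, db, model, protect_strings) {
  prot <- sort(unique(unlist(lapply(protect_strings, protect_span,
                                    seq = seq))))
  if (model == "PUTATIVE") {
    # helix III must stay free of the Ampelomyces TGG motif letters
    hs <- decompose_helices(list(seq = seq, structure = db))
    h3 <- hs$helices[3, ]
    prot <- sort(unique(c(prot, seq.int(h3$outer_start, h3$outer_end))))
  }
  # motif letters never mutate: protect unpaired T and G positions too
  pt <- pair_table(db)
  ch <- strsplit(seq, "")[[1]]
  prot <- sort(unique(c(prot, which(pt == 0 & ch %in% c("T", "G")))))
  list(seq = seq, db = db, model = model, protected = prot)
}

# Structure-preserving mutation: compensatory flips of randomly chosen base
# pairs (the two partners exchange letters, e.g. G-C -> C-G), optionally
# plus substitution of unprotected loop positions with non-pairing bases.
mutate_template <- function(tmpl, n_swaps, n_loop_subs) {
  ch <- strsplit(tmpl$seq, "")[[1]]
  pt <- pair_table(tmpl$db)
  paired <- which(pt > seq_along(pt))
  paired <- paired[!(paired %in% tmpl$protected) & !(pt[paired] %in% tmpl$protected)]
  if (n_swaps > 0 && length(paired) > 0) {
    pick <- sample(paired, min(n_swaps, length(paired)))
    for (i in pick) {
      tmp <- ch[i]; ch[i] <- ch[pt[i]]; ch[pt[i]] <- tmp
    }
  }
  loops <- setdiff(which(pt == 0), tmpl$protected)
  if (n_loop_subs > 0 && length(loops) > 0) {
    pick <- sample(loops, min(n_loop_subs, length(loops)))
    ch[pick] <- sample(c("A", "C"), length(pick), replace = TRUE)
  }
  out <- tmpl
  out$seq <- paste(ch, collapse = "")
  out
}

diverge_template <- function(tmpl, seed, n_swaps, n_loop_subs) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  mutate_template(tmpl, n_swaps, n_loop_subs)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

# random sequence with an exact A/T composition (count rounded from the
# target fraction, positions and letters random)
random_seq <- function(n, at_frac) {
  n_at <- round(n * at_frac)
  letters_at <- sample(c("A", "T"), n_at, replace = TRUE)
  letters_gc <- sample(c("G", "C"), n - n_at, replace = TRUE)
  ch <- character(n)
  pos <- sample.int(n, n_at)
  ch[pos] <- letters_at
  ch[-pos] <- letters_gc
  if (n_at == 0) ch <- letters_gc
  if (n_at == n) { ch <- character(n); ch[pos] <- letters_at }
  paste(ch, collapse = "")
}

# The fixed synthetic 5.8S gene: start anchor + filler + end anchor, 157 nt.
syn_5_8s <- function(params = delimit_params()) {
  start <- params$motif_5_8S_start
  end <- params$motif_5_8S_end
  fill_len <- 157L - nchar(start) - nchar(end)
  filler <- paste0("TTCTGGCATCGATGAAGAACGCAGCTAAATGCGATAAGTAATGTGAATTGCAGAA",
                   "TTCAGTGAATCATCGAATCTTTGAACGCACATTGCGCCCCTTGGTATTCCGAGGG")
  filler <- paste0(filler, filler)
  # controlled non-pairing tail just upstream of the end anchor
  filler <- paste0(substr(filler, 1, fill_len - 4L), "ACAC")
  paste0(start, filler, end)
}

#' Specification of one synthetic group
#'
#' @param label group label (one of the four study groups).
#' @param n number of records.
#' @param target_model ITS2 template model for the group.
#' @param its1_len_range min/max ITS1 length (nt); lengths are sampled
#'   uniformly and realized by deleting from the group ITS1 template.
#' @param its1_at A/T fraction of the group's ITS1 template.
#' @param divergence within-group substitution rate on ITS1 (per site).
#' @param struct_swaps,loop_subs per-record structure-preserving ITS2
#'   mutations (compensatory pair swaps / loop substitutions).
#' @param indel_mode where ITS1 deletions are placed: UNIFORM, HEAD, TAIL
#'   or BOTH_ENDS.
#' @export
group_spec <- function(label, n, target_model,
                       its1_len_range = c(184L, 193L), its1_at = 0.60,
                       divergence = 0.01, struct_swaps = 1L, loop_subs = 0L,
                       indel_mode = c("UNIFORM", "HEAD", "TAIL", "BOTH_ENDS")) {
  indel_mode <- match.arg(indel_mode)
  stopifnot(label %in% GROUP_LEVELS, n >= 1,
            its1_len_range[1] <= its1_len_range[2])
  structure(list(label = label, n = as.integer(n),
                 target_model = target_model,
                 its1_len_range = as.integer(its1_len_range),
                 its1_at = its1_at, divergence = divergence,
                 struct_swaps = as.integer(struct_swaps),
                 loop_subs = as.integer(loop_subs),
                 indel_mode = indel_mode), class = "group_spec")
}

#' Default study configuration
#'
#' Four groups emulating the study conditions: Ampelomyces sensu stricto
#' (Model 1 structures, ITS around 492-502 bp), two putative groups and the
#' outgroup (putative-pattern structures, ITS around 446-457 bp), with
#' n = 5 for the three small groups.
#'
#' @param n_ampelomyces Ampelomyces group size (default 30).
#' @param flank18,flank28 flanking 18S/28S lengths (nt).
#' @param master_seed seed from which all record seeds derive.
#' @param groups optional list of \code{group_spec}s overriding the default.
#' @export
study_config <- function(n_ampelomyces = 30L, flank18 = 40L, flank28 = 40L,
                         master_seed = 20210630L, groups = NULL) {
  if (is.null(groups)) {
    groups <- list(
      group_spec("AMPELOMYCES", n_ampelomyces, "M1",
                 its1_len_range = c(182L, 192L), its1_at = 0.59,
                 indel_mode = "UNIFORM"),
      group_spec("PUTATIVE_G1", 5L, "PUTATIVE",
                 its1_len_range = c(139L, 143L), its1_at = 0.52,
                 struct_swaps = 0L, indel_mode = "HEAD"),
      group_spec("PUTATIVE_G2", 5L, "PUTATIVE2",
                 its1_len_range = c(140L, 142L), its1_at = 0.52,
                 struct_swaps = 0L, indel_mode = "BOTH_ENDS"),
      group_spec("OUTGROUP", 5L, "OUTGROUP",
                 its1_len_range = c(139L, 139L), its1_at = 0.52,
                 struct_swaps = 0L, indel_mode = "TAIL"))
  }
  labs <- vapply(groups, `[[`, character(1), "label")
  if (anyDuplicated(labs)) stop("duplicate group labels")
  structure(list(groups = groups, flank18 = as.integer(flank18),
                 flank28 = as.integer(flank28),
                 master_seed = as.integer(master_seed)),
            class = "study_config")
}

# A group's shared pool of candidate ITS1 deletion events: non-overlapping
# spans placed in the mode-dependent zone (the first 100 nt for HEAD, the
# last 40 for TAIL, both for BOTH_ENDS, anywhere for UNIFORM).  Records
# realize their length by deleting a subset of these shared events, so the
# alignment shows a small number of distinct indel signatures.
build_indel_pool <- function(len, max_del, mode) {
  if (max_del == 0L) {
    return(data.frame(start = integer(0), len = integer(0)))
  }
  lens <- integer(0)
  k <- 1L
  while (sum(lens) < max_del + 2L) {
    lens <- c(lens, 1L + (k - 1L) %% 3L)
    k <- k + 1L
  }
  head_zone <- seq_len(min(100L, len))
  tail_zone <- seq.int(max(1L, len - 40L), len)
  zone <- switch(mode,
                 UNIFORM = seq_len(len),
                 HEAD = head_zone,
                 TAIL = tail_zone,
                 BOTH_ENDS = c(head_zone, tail_zone))
  starts <- integer(0)
  taken <- integer(0)
  for (l in lens) {
    for (try in 1:200) {
      st <- zone[sample.int(length(zone), 1L)]
      span <- st:(st + l - 1L)
      if (max(span) <= len && !any(span %in% taken)) {
        starts <- c(starts, st)
        taken <- c(taken, span)
        break
      }
    }
  }
  data.frame(start = starts, len = lens[seq_along(starts)])
}

# choose a subset of pool events whose total deleted length equals k
choose_indel_events <- function(pool, k) {
  if (k == 0L) return(integer(0))
  n <- nrow(pool)
  subsets <- which(vapply(seq_len(2^n) - 1L, function(mask) {
    sum(pool$len[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0]) == k
  }, logical(1))) - 1L
  if (length(subsets) == 0) stop("no indel-event subset matches length ", k)
  mask <- subsets[sample.int(length(subsets), 1L)]
  which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
}

#' Generate one synthetic record with its ground truth
#'
#' @param spec a \code{group_spec}.
#' @param index record index within the group.
#' @param ctx generation context from \code{\link{generate_study}}
#'   (templates, flanks, group ITS1 templates, seeds); built automatically
#'   when absent.
#' @return list with \code{record} (1-row \code{its_records}) and
#'   \code{truth} (boundaries, planted structure and model, stem design).
#' @export
generate_record <- function(spec, index, ctx = NULL) {
  if (is.null(ctx)) ctx <- study_context(study_config(groups = list(spec)))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed((ctx$master_seed %% 100000L) * 20011L + ctx$group_index[[spec$label]] *
             1009L + index)
  tmpl <- ctx$its2_templates[[spec$label]]
  its2 <- mutate_template(tmpl, spec$struct_swaps, spec$loop_subs)
  if (nchar(its2$seq) < 1) stop("infeasible spec: empty ITS2")
  its1_t <- ctx$its1_templates[[spec$label]]
  len_choices <- seq(spec$its1_len_range[1], spec$its1_len_range[2])
  len_target <- len_choices[sample.int(length(len_choices), 1)]
  if (len_target > nchar(its1_t)) stop("infeasible spec: ITS1 template too short")
  pool <- ctx$indel_pools[[spec$label]]
  ev <- choose_indel_events(pool, nchar(its1_t) - len_target)
  del <- unlist(lapply(ev, function(e) {
    pool$start[e]:(pool$start[e] + pool$len[e] - 1L)
  }))
  ch1 <- strsplit(its1_t, "")[[1]]
  if (length(del)) ch1 <- ch1[-del]
  nsub <- stats::rbinom(1, length(ch1), spec$divergence)
  if (nsub > 0) {
    pos <- sample(length(ch1), nsub)
    ch1[pos] <- vapply(ch1[pos], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1))
  }
  its1 <- paste(ch1, collapse = "")
  seq <- paste0(ctx$flank18_seq, its1, ctx$s58, its2$seq, ctx$flank28_seq)
  id <- sprintf("SYN_%s_%03d", gsub("[^A-Z0-9]", "", spec$label), index)
  rec <- its_records(id = id, seq = seq,
                     description = paste0("synthetic ", spec$label,
                                          " model ", tmpl$model),
                     group = spec$label)
  b <- cumsum(c(nchar(ctx$flank18_seq), nchar(its1), 157L, nchar(its2$seq)))
  truth <- list(id = id, group = spec$label, model = tmpl$model,
                its1_start = b[1], its1_end = b[2],
                s58_start = b[2], s58_end = b[3],
                its2_start = b[3], its2_end = b[4],
                its2_seq = its2$seq, its2_db = its2$db)
  list(record = rec, truth = truth)
}

study_context <- function(cfg) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  params <- delimit_params()
  labs <- vapply(cfg$groups, `[[`, character(1), "label")
  ctx <- list(master_seed = cfg$master_seed,
              group_index = stats::setNames(as.list(seq_along(labs)), labs),
              s58 = syn_5_8s(params))
  set.seed(cfg$master_seed %% 100000L + 17L)
  ctx$flank18_seq <- paste0(random_seq(cfg$flank18 - nchar(params$motif_18S_end),
                                       0.5),
                            params$motif_18S_end)
  ctx$flank28_seq <- paste0(params$motif_28S_start,
                            random_seq(cfg$flank28 - nchar(params$motif_28S_start),
                                       0.5))
  ctx$its2_templates <- list()
  ctx$its1_templates <- list()
  ctx$indel_pools <- list()
  # the putative groups and the outgroup are related fungi: their ITS1
  # templates derive from one shared base at moderate divergence, while the
  # Ampelomyces ITS1 is an independent sequence (different genus)
  nonamp <- Filter(function(g) g$label != "AMPELOMYCES", cfg$groups)
  base <- NULL
  if (length(nonamp)) {
    set.seed(cfg$master_seed %% 100000L + 7919L)
    base_len <- max(vapply(nonamp, function(g) g$its1_len_range[2],
                           integer(1)))
    base <- random_seq(base_len, nonamp[[1]]$its1_at)
  }
  derive_rate <- c(PUTATIVE_G1 = 0, PUTATIVE_G2 = 0.08, OUTGROUP = 0.12)
  for (g in cfg$groups) {
    set.seed(cfg$master_seed %% 100000L + 31L * ctx$group_index[[g$label]])
    ctx$its2_templates[[g$label]] <- its2_template(g$target_model)
    if (g$label == "AMPELOMYCES" || is.null(base)) {
      ctx$its1_templates[[g$label]] <- random_seq(g$its1_len_range[2],
                                                  g$its1_at)
    } else {
      rate <- derive_rate[[g$label]]
      if (is.null(rate) || is.na(rate)) rate <- 0.1
      ch <- strsplit(base, "")[[1]]
      nsub <- round(length(ch) * rate)
      if (nsub > 0) {
        pos <- sample(length(ch), nsub)
        ch[pos] <- vapply(ch[pos], function(b) {
          sample(setdiff(c("A", "C", "G", "T"), b), 1)
        }, character(1))
      }
      ctx$its1_templates[[g$label]] <-
        paste(ch[seq_len(g$its1_len_range[2])], collapse = "")
    }
    ctx$indel_pools[[g$label]] <-
      build_indel_pool(g$its1_len_range[2],
                       g$its1_len_range[2] - g$its1_len_range[1],
                       g$indel_mode)
  }
  ctx
}

#' Generate a complete labeled synthetic study
#'
#' @param cfg a \code{study_config}.
#' @param out_dir optional directory; when given, FASTA, manifest and truth
#'   tables are written there.
#' @return list with \code{records} (\code{its_records}), \code{manifest}
#'   (\code{group_manifest}) and \code{truth} (per-record ground truth
#'   table including planted boundaries and model labels).
#' @export
generate_study <- function(cfg = study_config(), out_dir = NULL) {
  stopifnot(inherits(cfg, "study_config"))
  ctx <- study_context(cfg)
  recs <- list(); truths <- list()
  for (g in cfg$groups) {
    for (i in seq_len(g$n)) {
      r <- generate_record(g, i, ctx)
      recs[[length(recs) + 1L]] <- r$record
      truths[[length(truths) + 1L]] <- r$truth
    }
  }
  records <- do.call(rbind, recs)
  class(records) <- c("its_records", "data.frame")
  if (anyDuplicated(records$id)) stop("duplicate record ids in study")
  truth <- do.call(rbind, lapply(truths, function(t) {
    data.frame(id = t$id, group = t$group, model = t$model,
               its1_start = t$its1_start, its1_end = t$its1_end,
               s58_start = t$s58_start, s58_end = t$s58_end,
               its2_start = t$its2_start, its2_end = t$its2_end,
               its2_seq = t$its2_seq, its2_db = t$its2_db,
               stringsAsFactors = FALSE)
  }))
  manifest <- data.frame(id = records$id, group = records$group,
                         note = "synthetic", stringsAsFactors = FALSE)
  class(manifest) <- c("group_manifest", "data.frame")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(records, file.path(out_dir, "study.fasta"))
    write_table(manifest, file.path(out_dir, "manifest.tsv"))
    write_table(truth, file.path(out_dir, "truth.tsv"))
  }
  list(records = records, manifest = manifest, truth = truth)
}
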