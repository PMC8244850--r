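#' Pipeline configuration
#'
#' Exactly one of a real input (FASTA + manifest paths) or a synthetic
#' \code{\link{study_config}} must be active.
#'
#' @param fasta,manifest input file paths (real-data mode).
#' @param synthetic a \code{study_config} (synthetic mode).
#' @param delimit a \code{\link{delimit_params}} object.
#' @param energy an \code{\link{turner_params}} energy model.
#' @param rate a \code{\link{rate_model}} for distances/trees (study
#'   convention: gamma shape 5 for distances).
#' @param seqstruct a \code{\link{seqstruct_align_params}} object.
#' @param bootstrap_reps replicates for distance SEs and tree supports.
#' @param out_dir output directory for the report bundle.
#' @param seed master seed; every stochastic stage derives its stream from it.
#' @param stem_window proximal-stem window (nt per strand).
#' @export
pipeline_config <- function(fasta = NULL, manifest = NULL, synthetic = NULL,
                            delimit = delimit_params(),
                            energy = turner_params(),
                            rate = rate_model(alpha = 5),
                            seqstruct = seqstruct_align_params(),
                            bootstrap_reps = 1000L,
                            out_dir = tempfile("its2ss_run"),
                            seed = 1L, stem_window = 25L) {
  real <- !is.null(fasta)
  if (real == !is.null(synthetic)) {
    stop("exactly one of (fasta, synthetic) must be given")
  }
  if (real && is.null(manifest)) stop("real input needs a manifest")
  structure(list(fasta = fasta, manifest = manifest, synthetic = synthetic,
                 delimit = delimit, energy = energy, rate = rate,
                 seqstruct = seqstruct,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 out_dir = out_dir, seed = as.integer(seed),
                 stem_window = as.integer(stem_window)),
            class = "pipeline_config")
}

seed_stream <- function(master, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(master) * 7919 + h) %% 2147483587)
}

#' Run the full ITS2 sequence-structure analysis
#'
#' Executes delimitation, sequence statistics (group summaries,
#' Kruskal-Wallis/Dunn, indel events), proximal-stem hybridization with
#' stability classes, MFE folding with model classification, the combined
#' sequence-structure alignment, log-det/K2P distances with bootstrap SEs,
#' NJ trees with supports and pruning log-likelihood, consensus structures
#' and the barcode-gap report.  Every artifact is written under the
#' configured output directory together with a parameter manifest; a stage
#' failure produces a partial bundle plus an error summary and skips the
#' stages downstream of it.
#'
#' @param cfg a \code{pipeline_config}.
#' @return the bundle as a list (also written to disk); component
#'   \code{errors} holds per-stage failures, \code{counts} the per-stage
#'   accounting (delimited / modelable / folded / classified).
#' @export
run_pipeline <- function(cfg = pipeline_config(synthetic = study_config())) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  bundle <- list(errors = list(), counts = list())
  logf <- file.path(cfg$out_dir, "run.log")
  logmsg <- function(...) {
    cat(format(Sys.time(), "%H:%M:%S"), " ", sprintf(...), "\n",
        sep = "", file = logf, append = TRUE)
  }
  stage <- function(name, expr) {
    if (length(bundle$errors) > 0) {
      logmsg("stage %s skipped (earlier failure)", name)
      return(NULL)
    }
    tryCatch(expr, error = function(e) {
      bundle$errors[[name]] <<- conditionMessage(e)
      logmsg("stage %s FAILED: %s", name, conditionMessage(e))
      NULL
    })
  }

  # ---- input ----
  inp <- stage("input", {
    if (!is.null(cfg$synthetic)) {
      study <- generate_study(cfg$synthetic, out_dir = file.path(cfg$out_dir,
                                                                 "input"))
      list(records = study$records, truth = study$truth)
    } else {
      recs <- read_fasta(cfg$fasta)
      man <- read_manifest(cfg$manifest)
      list(records = assign_groups(recs, man), truth = NULL)
    }
  })
  if (is.null(inp)) return(finish_bundle(bundle, cfg))
  records <- inp$records
  bundle$records <- records
  bundle$truth <- inp$truth
  logmsg("input: %d records", nrow(records))

  # ---- delimitation + hybridization ----
  delim <- stage("delimit", {
    parts <- list(); hyb <- list()
    for (i in seq_len(nrow(records))) {
      rec <- records[i, ]
      part <- tryCatch(delimit_its(rec, params = cfg$delimit),
                       error = function(e) NULL)
      parts[[rec$id]] <- part
      hyb[[rec$id]] <- if (is.null(part)) NULL else
        hybridize_stem(part, rec, cfg$stem_window, cfg$energy)
    }
    list(parts = parts, hyb = hyb)
  })
  if (is.null(delim)) return(finish_bundle(bundle, cfg))
  bundle$partitions <- delim$parts
  bundle$hybridization <- delim$hyb
  ok_ids <- names(Filter(Negate(is.null), delim$parts))
  bundle$counts$total <- nrow(records)
  bundle$counts$delimited <- length(ok_ids)
  hyb_tab <- do.call(rbind, lapply(ok_ids, function(id) {
    h <- delim$hyb[[id]]
    data.frame(id = id, dG = h$dG, dH = h$dH, pattern = h$pattern,
               free_5_8S = h$free_nt_5_8S, free_28S = h$free_nt_28S,
               stability = if (h$pattern == "UNMODELABLE") NA_character_
                           else flag_pseudogene_candidate(h))
  }))
  bundle$hyb_table <- hyb_tab
  bundle$counts$modelable <- sum(hyb_tab$pattern != "UNMODELABLE")
  bundle$counts$typical <- sum(hyb_tab$pattern == "TYPICAL")
  write_table(hyb_tab, file.path(cfg$out_dir, "hybridization.tsv"),
              decimals = c(dG = 1, dH = 1))
  part_tab <- do.call(rbind, lapply(ok_ids, function(id) {
    p <- delim$parts[[id]]
    data.frame(id = id, region = p$region, start = p$start + 1L,
               end = p$end, complete = p$complete)
  }))
  write_table(part_tab, file.path(cfg$out_dir, "partitions.tsv"))
  logmsg("delimited %d/%d; modelable stems %d", length(ok_ids),
         nrow(records), bundle$counts$modelable)

  # ---- sequence statistics ----
  stats_out <- stage("stats", {
    summ <- group_summary(records, delim$parts, cfg$delimit$max_its_len)
    lens <- lapply(split(records$id, records$group), function(ids) {
      vapply(ids, function(id) {
        p <- delim$parts[[id]]
        if (is.null(p)) return(NA_real_)
        sum(p$end[2:4] - p$start[2:4])
      }, numeric(1))
    })
    lens <- lapply(lens, function(x) x[!is.na(x)])
    lens <- lens[lengths(lens) > 0]
    kw <- kruskal_wallis(lens)
    dunn <- dunn_posthoc(lens, kw)
    dunn$group1 <- names(lens)[dunn$group1]
    dunn$group2 <- names(lens)[dunn$group2]
    list(summary = summ, kw = kw, dunn = dunn)
  })
  if (!is.null(stats_out)) {
    bundle$group_summary <- stats_out$summary
    bundle$kw <- stats_out$kw
    bundle$dunn <- stats_out$dunn
    write_table(stats_out$summary, file.path(cfg$out_dir, "group_summary.tsv"),
                decimals = c(len_mean = 1, len_sem = 3, norm_mean = 2,
                             norm_sem = 3, at_min = 2, at_max = 2,
                             gc_min = 2, gc_max = 2))
    write_table(data.frame(H = stats_out$kw$H, df = stats_out$kw$df,
                           p = stats_out$kw$p),
                file.path(cfg$out_dir, "kruskal_wallis.tsv"),
                decimals = c(H = 2))
    write_table(stats_out$dunn, file.path(cfg$out_dir, "dunn.tsv"),
                decimals = c(z = 3))
  }

  # ---- ITS1 indel analysis ----
  indel <- stage("indels", {
    its1 <- vapply(ok_ids, function(id) {
      region_seq(records[records$id == id, ], delim$parts[[id]], "ITS1")
    }, character(1))
    if (length(its1) < 2) stop("not enough delimited ITS1 sequences")
    aln <- msa(stats::setNames(its1, ok_ids))
    count_indel_events(aln$aln)
  })
  if (!is.null(indel)) {
    bundle$indels <- indel
    write_table(indel$events, file.path(cfg$out_dir, "indel_events.tsv"))
  }

  # ---- folding + classification ----
  fold_out <- stage("fold", {
    rows <- list(); structs <- list()
    for (id in ok_ids) {
      its2 <- region_seq(records[records$id == id, ], delim$parts[[id]], "ITS2")
      if (nchar(its2) < cfg$delimit$min_its2_len / 3) next
      ss <- suppressWarnings(fold_mfe(its2, cfg$energy))
      hs <- decompose_helices(ss)
      mr <- detect_motifs(hs)
      lab <- classify_model(hs, mr)
      structs[[id]] <- list(ss = ss, hs = hs, mr = mr, label = lab$label)
      rows[[id]] <- data.frame(
        id = id, length = nchar(its2), mfe = ss$mfe,
        n_helices = hs$n_helices, model = lab$label,
        uu_helixII = mr$uu_mismatch_helixII,
        helixIII_motif = ifelse(is.na(mr$helixIII_motif), "",
                                mr$helixIII_motif),
        ring_I_IV = ifelse(is.null(mr$ring_I_IV) || is.na(mr$ring_I_IV), "",
                           mr$ring_I_IV),
        structure = ss$structure)
    }
    list(tab = do.call(rbind, rows), structs = structs)
  })
  if (is.null(fold_out)) return(finish_bundle(bundle, cfg))
  bundle$structures <- fold_out$structs
  bundle$structure_table <- fold_out$tab
  bundle$counts$folded <- nrow(fold_out$tab)
  bundle$counts$classified <- sum(fold_out$tab$model != "UNCLASSIFIED")
  write_table(fold_out$tab, file.path(cfg$out_dir, "structures.tsv"),
              decimals = c(mfe = 1))
  db_lines <- unlist(lapply(names(fold_out$structs), function(id) {
    s <- fold_out$structs[[id]]$ss
    c(paste0(">", id), s$seq, s$structure)
  }))
  writeLines(db_lines, file.path(cfg$out_dir, "structures.dbn"))
  logmsg("folded %d, classified %d", bundle$counts$folded,
         bundle$counts$classified)

  # ---- sequence-structure alignment, distances, trees ----
  phylo <- stage("phylo", {
    ids <- names(fold_out$structs)
    enc <- lapply(ids, function(id) {
      s <- fold_out$structs[[id]]$ss
      encode_seqstruct(s$seq, s)
    })
    names(enc) <- ids
    ssa <- seqstruct_align(enc, cfg$seqstruct)
    groups <- stats::setNames(records$group[match(ids, records$id)], ids)
    gap <- group_mean_distances(ssa, groups, "logdet", cfg$rate,
                                bootstrap_reps = cfg$bootstrap_reps,
                                seed = seed_stream(cfg$seed, "gapboot"))
    dm_nona <- its_distance_matrix(ssa, "logdet", cfg$rate, saturated = "cap")
    tree <- bootstrap_supports(ssa, reps = cfg$bootstrap_reps,
                               seed = seed_stream(cfg$seed, "treeboot"),
                               rate = cfg$rate)
    lik <- tree_likelihood(tree, ssa,
                           rate_model("K2P", alpha = 1, categories = 4L),
                           optimize = "edges+shape")
    list(ssa = ssa, gap = gap, dm = dm_nona, tree = tree, lik = lik)
  })
  if (!is.null(phylo)) {
    bundle$seqstruct_alignment <- phylo$ssa
    bundle$gap_report <- phylo$gap
    bundle$distance_matrix <- phylo$dm
    bundle$tree <- phylo$tree
    bundle$loglik <- phylo$lik$loglik
    bundle$gamma_shape <- phylo$lik$rate$alpha
    writeLines(paste0(">", phylo$ssa$ids, "\n", phylo$ssa$seq_rows),
               file.path(cfg$out_dir, "seqstruct_alignment.fasta"))
    utils::write.table(round(phylo$dm, 5),
                       file.path(cfg$out_dir, "distance_matrix.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    between <- phylo$gap$between
    utils::write.table(round(between, 4),
                       file.path(cfg$out_dir, "group_distances.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    utils::write.table(round(phylo$gap$between_se, 4),
                       file.path(cfg$out_dir, "group_distances_se.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    ape::write.tree(phylo$tree, file.path(cfg$out_dir, "tree.nwk"))
    write_table(data.frame(loglik = phylo$lik$loglik,
                           gamma_shape = phylo$lik$rate$alpha,
                           barcode_gap = phylo$gap$barcode_gap,
                           min_inter = phylo$gap$min_inter,
                           max_intra = max(phylo$gap$max_intra, na.rm = TRUE)),
                file.path(cfg$out_dir, "gap_report.tsv"),
                decimals = c(loglik = 2, gamma_shape = 3, min_inter = 4,
                             max_intra = 4))
    logmsg("barcode gap: %s (min inter %.4f, max intra %.4f); loglik %.2f",
           phylo$gap$barcode_gap, phylo$gap$min_inter,
           max(phylo$gap$max_intra, na.rm = TRUE), phylo$lik$loglik)
  }

  # ---- consensus structures per group ----
  cons <- stage("consensus", {
    if (is.null(phylo)) stop("no alignment available")
    out <- list()
    groups <- records$group[match(phylo$ssa$ids, records$id)]
    for (g in unique(groups)) {
      sel <- which(groups == g)
      if (length(sel) < 2) next
      out[[g]] <- list(
        with_gaps = consensus_structure(phylo$ssa$seq_rows[sel],
                                        phylo$ssa$struct_rows[sel], "keep"),
        without_gaps = consensus_structure(phylo$ssa$seq_rows[sel],
                                           phylo$ssa$struct_rows[sel], "drop"))
    }
    out
  })
  if (!is.null(cons)) {
    bundle$consensus <- cons
    lines <- unlist(lapply(names(cons), function(g) {
      c(paste0(">", g, " with_gaps"), cons[[g]]$with_gaps$consensus_seq,
        cons[[g]]$with_gaps$consensus_struct,
        paste0(">", g, " without_gaps"), cons[[g]]$without_gaps$consensus_seq,
        cons[[g]]$without_gaps$consensus_struct)
    }))
    writeLines(lines, file.path(cfg$out_dir, "consensus.dbn"))
  }

  finish_bundle(bundle, cfg)
}

finish_bundle <- function(bundle, cfg) {
  manifest <- list(seed = cfg$seed, bootstrap_reps = cfg$bootstrap_reps,
                   stem_window = cfg$stem_window,
                   energy_version = cfg$energy$version,
                   rate = list(model = cfg$rate$model, alpha = cfg$rate$alpha),
                   counts = bundle$counts,
                   errors = bundle$errors)
  yaml::write_yaml(manifest, file.path(cfg$out_dir, "run_manifest.yaml"))
  if (length(bundle$errors)) {
    yaml::write_yaml(bundle$errors, file.path(cfg$out_dir, "errors.yaml"))
  }
  bundle$out_dir <- cfg$out_dir
  invisible(bundle)
}
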