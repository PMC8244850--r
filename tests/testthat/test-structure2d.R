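test_that("a designed hairpin folds exactly and matches the hand-summed energy", {
  p <- turner_params()
  stem <- "GGCGAGGCAC"
  rc <- chartr("ACGU", "UGCA",
               paste(rev(strsplit(stem, "")[[1]]), collapse = ""))
  hp <- paste0(stem, "AAAA", rc)
  ss <- suppressWarnings(fold_mfe(hp, p))
  expect_equal(ss$structure,
               paste0(strrep("(", 10), "....", strrep(")", 10)))
  # hand summation: 9 stacks + hairpin(4)
  pr <- strsplit(stem, "")[[1]]
  rcch <- rev(strsplit(rc, "")[[1]])
  pnames <- paste0(pr, chartr("ACGU", "ACGU", rcch))
  hand <- its2ss:::loop_penalty_tables(24)$hairpin[5] +
    sum(vapply(1:9, function(k) p$stack_dg[pnames[k], pnames[k + 1]],
               integer(1)))
  expect_equal(ss$mfe_tenths, hand)
})

test_that("poly-A folds to the open chain at zero energy", {
  ss <- fold_mfe(strrep("A", 60))
  expect_equal(ss$mfe, 0)
  expect_false(grepl("[()]", ss$structure))
})

test_that("non-RNA symbols after normalization are rejected", {
  expect_error(fold_mfe(paste0(strrep("A", 60), "N")), "non-RNA")
})

test_that("energy audit: independent re-evaluation reproduces the MFE exactly", {
  set.seed(55)
  p <- turner_params()
  for (k in 1:40) {
    n <- sample(40:120, 1)
    s <- paste(sample(c("A", "C", "G", "U"), n, replace = TRUE,
                      prob = c(.3, .2, .25, .25)), collapse = "")
    ss <- suppressWarnings(fold_mfe(s, p))
    audit <- structure_energy(ss, p)
    expect_identical(attr(audit, "tenths"), ss$mfe_tenths)
  }
})

test_that("MFE pair count never exceeds the Nussinov maximum (<=30 nt)", {
  set.seed(66)
  for (k in 1:150) {
    n <- sample(10:30, 1)
    s <- paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
    ss <- suppressWarnings(fold_mfe(s))
    npairs <- sum(strsplit(ss$structure, "")[[1]] == "(")
    expect_lte(npairs, nussinov_max_pairs(s))
  }
})

test_that("folding is deterministic", {
  t <- its2_template("M1")
  a <- suppressWarnings(fold_mfe(t$seq))
  b <- suppressWarnings(fold_mfe(t$seq))
  expect_identical(a$structure, b$structure)
  expect_identical(decompose_helices(a), decompose_helices(b))
})

test_that("helix decomposition identifies stems, loops and rings", {
  # single hairpin
  hs1 <- decompose_helices(list(seq = "GGGGCAAAAGCCCC",
                                structure = "((((......))))"))
  expect_equal(hs1$n_helices, 1)
  expect_false(hs1$four_fingered)
  expect_equal(hs1$helices$terminal_loop[1], 6)

  # four designed stems with linkers: planted coordinates recovered
  t <- its2_template("M1")
  ss <- suppressWarnings(fold_mfe(t$seq))
  hs <- decompose_helices(ss)
  expect_true(hs$four_fingered)
  expect_equal(hs$n_helices, 4)
  # helix III strictly longest in paired positions
  expect_true(all(hs$helices$paired[3] > hs$helices$paired[-3]))
  # Model-1 signature: five internal loops, 6-nt terminal loop on helix III
  expect_equal(hs$helices$internal_loops[3], 5)
  expect_equal(hs$helices$terminal_loop[3], 6)
  # ring between helices I and IV carries the conserved sequence
  expect_equal(hs$rings$ring_first_last, "GTACCC")
})

test_that("motif detection flags the diagnostic features", {
  t1 <- its2_template("M1")
  ss1 <- suppressWarnings(fold_mfe(t1$seq))
  mr1 <- detect_motifs(decompose_helices(ss1))
  expect_true(mr1$uu_mismatch_helixII)
  expect_equal(mr1$helixIII_motif, "UGG")
  expect_equal(mr1$ring_I_IV, "GTACCC")
  expect_false(mr1$aaa_spacer)

  tp <- its2_template("PUTATIVE")
  ssp <- suppressWarnings(fold_mfe(tp$seq))
  mrp <- detect_motifs(decompose_helices(ssp))
  expect_equal(mrp$ring_I_IV, "TCCATG")
  expect_true(is.na(mrp$helixIII_motif))

  t4 <- its2_template("M4")
  ss4 <- suppressWarnings(fold_mfe(t4$seq))
  mr4 <- detect_motifs(decompose_helices(ss4))
  expect_true(mr4$aaa_spacer)
  expect_true(mr4$helixIII_motif %in% c("UGGU", "UGGU+UU"))
})

test_that("the model classifier follows the rule cascade", {
  for (want in c("M1", "M2", "M4", "M6", "M7", "PUTATIVE")) {
    t <- its2_template(want)
    ss <- suppressWarnings(fold_mfe(t$seq))
    hs <- decompose_helices(ss)
    lab <- classify_model(hs, detect_motifs(hs))
    expect_equal(lab$label, want)
    expect_gt(length(lab$evidence), 0)
  }
  # not four helices -> UNCLASSIFIED with empty evidence
  hs1 <- decompose_helices(list(seq = "GGGGCAAAAGCCCC",
                                structure = "((((......))))"))
  lab1 <- classify_model(hs1, detect_motifs(hs1))
  expect_equal(lab1$label, "UNCLASSIFIED")
  expect_equal(length(lab1$evidence), 0)
})

test_that("model energies of the templates fall in the reported bands", {
  for (m in c("M1", "M2", "M4", "M6", "M7")) {
    ss <- suppressWarnings(fold_mfe(its2_template(m)$seq))
    expect_gte(ss$mfe, -47.3)
    expect_lte(ss$mfe, -36.8)
  }
  for (m in c("PUTATIVE", "PUTATIVE2", "OUTGROUP")) {
    ss <- suppressWarnings(fold_mfe(its2_template(m)$seq))
    expect_gte(ss$mfe, -35.9)
    expect_lte(ss$mfe, -25.8)
  }
})

test_that("consensus structures follow the majority with per-column conservation", {
  rows_s <- c("ACGU", "ACGU", "ACGU")
  rows_t <- c("((..", "((..", "((..")
  cs <- consensus_structure(rows_s, rows_t)
  expect_equal(cs$consensus_seq, "ACGU")
  expect_equal(cs$consensus_struct, "((..")
  expect_equal(cs$conservation, rep(1, 4))

  cs2 <- consensus_structure(c("ACGU", "AGGU"), c("....", "...."))
  expect_equal(cs2$conservation[2], 0.75)  # split base, agreeing state

  # with-gaps vs without-gaps modes differ exactly at gap columns
  rows3_s <- c("AC-U", "ACGU")
  rows3_t <- c("..-.", "....")
  keep <- consensus_structure(rows3_s, rows3_t, "keep")
  drop <- consensus_structure(rows3_s, rows3_t, "drop")
  expect_equal(keep$columns, 1:4)
  expect_equal(drop$columns, c(1, 2, 4))
  expect_error(consensus_structure(character(0), character(0)), "empty")
})
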