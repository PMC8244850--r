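test_that("planted motifs are recovered at their exact offsets", {
  p <- delimit_params()
  set.seed(11)
  lead <- its2ss:::random_seq(30, 0.5)
  seq <- paste0(lead, p$motif_5_8S_start, its2ss:::random_seq(60, 0.5),
                p$motif_5_8S_end)
  hits <- find_flank_motifs(seq, p)
  h <- hits[hits$motif == "motif_5_8S_start", ]
  expect_true(h$found)
  expect_equal(h$start, 30)
  expect_equal(h$mismatches, 0)

  # one substitution within the mismatch budget is reported as such
  mm <- paste0(substr(seq, 1, 34), "G", substr(seq, 36, nchar(seq)))
  if (substr(seq, 35, 35) == "G") {
    mm <- paste0(substr(seq, 1, 34), "C", substr(seq, 36, nchar(seq)))
  }
  hits2 <- find_flank_motifs(mm, p)
  expect_equal(hits2$mismatches[hits2$motif == "motif_5_8S_start"], 1)
})

test_that("random sequences rarely reach motif significance (Monte-Carlo null)", {
  p <- delimit_params()
  set.seed(77)
  n_sig <- 0L
  trials <- 300L
  for (k in seq_len(trials)) {
    s <- its2ss:::random_seq(500, 0.5)
    h <- its2ss:::scan_motif(s, p$motif_5_8S_start, max_mismatches = 25L)
    if (!is.na(h$evalue) && h$evalue < p$evalue_threshold) n_sig <- n_sig + 1L
  }
  expect_lt(n_sig / trials, 0.01)
})

test_that("no 5.8S anchor raises a NO_ANCHOR condition", {
  set.seed(5)
  expect_error(find_flank_motifs(its2ss:::random_seq(400, 0.5)),
               class = "its2ss_no_anchor")
})

test_that("delimitation recovers the designed region lengths", {
  p <- delimit_params()
  set.seed(21)
  its1 <- its2ss:::random_seq(188, 0.6)
  its2 <- its2ss:::random_seq(152, 0.5)
  seq <- paste0(p$motif_18S_end, its1, its2ss:::syn_5_8s(p), its2,
                p$motif_28S_start)
  part <- delimit_its(seq, params = p)
  g <- function(r) part$end[part$region == r] - part$start[part$region == r]
  expect_equal(g("ITS1"), 188)
  expect_equal(g("r5.8S"), 157)
  expect_equal(g("ITS2"), 152)
  expect_true(all(part$complete))
  # partition conservation: regions tile the sequence
  expect_equal(sum(part$end - part$start), nchar(seq))
  expect_equal(part$start[-1], part$end[-5])
})

test_that("missing 28S flank flags ITS2 incomplete with boundary at the end", {
  p <- delimit_params()
  set.seed(22)
  seq <- paste0(p$motif_18S_end, its2ss:::random_seq(150, 0.6),
                its2ss:::syn_5_8s(p), its2ss:::random_seq(140, 0.5))
  part <- delimit_its(seq, params = p)
  i <- which(part$region == "ITS2")
  expect_false(part$complete[i])
  expect_equal(part$end[i], nchar(seq))
})

test_that("duplex energy of a perfect helix equals the hand-summed stack terms", {
  p <- turner_params()
  s1 <- "GGCAUGCC"
  s2 <- "GGCAUGCC"   # its own reverse complement
  lt <- its2ss:::loop_penalty_tables(16)
  d <- its2ss:::.duplex_cpp(its2ss:::base_codes(s1), its2ss:::base_codes(s2),
                   p$stack_dg, p$stack_dh, lt$bulge, lt$internal,
                   p$duplex_init_dg, p$duplex_init_dh, p$max_interior)
  # hand summation over the seven stacks of the 8-bp duplex
  pairs <- c("GC", "GC", "CG", "AU", "UA", "GC", "CG", "CG")
  hand_dg <- p$duplex_init_dg +
    sum(vapply(seq_len(7), function(k) p$stack_dg[pairs[k], pairs[k + 1]],
               integer(1)))
  hand_dh <- p$duplex_init_dh +
    sum(vapply(seq_len(7), function(k) p$stack_dh[pairs[k], pairs[k + 1]],
               integer(1)))
  expect_equal(d$dg_tenths, hand_dg)
  expect_equal(d$dh_tenths, hand_dh)
  expect_equal(length(d$pairs1), 8)
})

test_that("stem hybridization of generated records is TYPICAL at the reported energies", {
  study <- generate_study(study_config(n_ampelomyces = 2))
  rec <- study$records[1, ]
  part <- delimit_its(rec)
  h <- hybridize_stem(part, rec)
  expect_equal(h$pattern, "TYPICAL")
  expect_equal(h$free_nt_5_8S, 1L)
  expect_equal(h$free_nt_28S, 1L)
  expect_equal(h$dG, -19.0, tolerance = 1e-9)
  expect_lt(abs(h$dH - (-147.1)), 1.5)
  expect_lte(h$dG, 0)
})

test_that("non-complementary strands and short 28S flanks give UNMODELABLE", {
  part <- data.frame(region = c("flank18S", "ITS1", "r5.8S", "ITS2",
                                "flank28S"),
                     start = c(0L, 0L, 0L, 30L, 60L),
                     end = c(0L, 0L, 30L, 60L, 70L),
                     complete = TRUE)
  class(part) <- c("its_partition", "data.frame")
  # 10-nt 28S flank < 25-nt window
  seq <- paste0(strrep("A", 60), strrep("C", 10))
  h <- hybridize_stem(part, seq)
  expect_equal(h$pattern, "UNMODELABLE")
  expect_equal(h$dG, 0)

  # full windows but zero complementarity (A-rich vs A-rich)
  part$end[5] <- 70L; part$start[5] <- 40L; part$end[4] <- 40L
  seq2 <- paste0(strrep("A", 40), strrep("A", 30))
  part2 <- part; part2$start <- c(0L, 0L, 0L, 40L, 45L)
  part2$end <- c(0L, 0L, 40L, 45L, 70L)
  h2 <- hybridize_stem(part2, seq2)
  expect_equal(h2$pattern, "UNMODELABLE")
})

test_that("a single mismatch never strengthens a perfect duplex", {
  p <- turner_params()
  lt <- its2ss:::loop_penalty_tables(40)
  dup <- function(s1, s2) {
    its2ss:::.duplex_cpp(its2ss:::base_codes(s1), its2ss:::base_codes(s2),
                p$stack_dg, p$stack_dh, lt$bulge, lt$internal,
                p$duplex_init_dg, p$duplex_init_dh, p$max_interior)$dg_tenths
  }
  set.seed(33)
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  nonpair <- list(A = "C", C = "A", G = "A", U = "C")  # breaks WC and GU
  for (k in 1:20) {
    s1 <- paste(sample(c("A", "C", "G", "U"), 12, replace = TRUE),
                collapse = "")
    s2 <- paste(rev(comp[strsplit(s1, "")[[1]]]), collapse = "")
    d0 <- dup(s1, s2)
    pos <- sample(12, 1)
    ch <- strsplit(s1, "")[[1]]
    ch[pos] <- nonpair[[ch[pos]]]
    d1 <- dup(paste(ch, collapse = ""), s2)
    expect_gte(d1, d0)
  }
})

test_that("stem stability classes follow the reported thresholds", {
  mk <- function(dg) structure(list(dG = dg, pattern = "TYPICAL"),
                               class = "hybrid_result")
  expect_equal(flag_pseudogene_candidate(mk(-13.7)), "DESTABILIZED")
  expect_equal(flag_pseudogene_candidate(mk(-15)), "FLEXIBLE")
  expect_equal(flag_pseudogene_candidate(mk(-16.9)), "FLEXIBLE")
  expect_equal(flag_pseudogene_candidate(mk(-19)), "FLEXIBLE")
  expect_equal(flag_pseudogene_candidate(mk(-19.1)), "STABLE")
  un <- structure(list(dG = 0, pattern = "UNMODELABLE"),
                  class = "hybrid_result")
  expect_error(flag_pseudogene_candidate(un), "UNMODELABLE")
})
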