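test_that("plain MSA behaves on identical, near-identical and degenerate input", {
  a <- msa(c(s1 = "ACGTACGT", s2 = "ACGTACGT"))
  expect_equal(unname(a$aln[1]), "ACGTACGT")
  expect_equal(unname(a$aln[2]), "ACGTACGT")

  b <- msa(c(s1 = "ACGT", s2 = "ACT"))
  expect_equal(unname(b$aln[1]), "ACGT")
  expect_equal(unname(b$aln[2]), "AC-T")

  # pairwise affine score equals the hand-computed value: 3 matches - one
  # 1-column gap opening
  prm <- align_params()
  S <- matrix(prm$mismatch, 4, 4,
              dimnames = list(c("A", "C", "G", "T"), c("A", "C", "G", "T")))
  diag(S) <- prm$match
  sc <- pairwise_score(strsplit("ACGT", "")[[1]], strsplit("ACT", "")[[1]],
                       S, prm$gap_open, prm$gap_ext)
  expect_equal(sc, 3 * prm$match - prm$gap_open)

  expect_warning(single <- msa(c(only = "ACGT")), "single")

  # conservation: degapping returns the originals; width >= longest input
  set.seed(71)
  seqs <- vapply(1:5, function(i) {
    paste(sample(c("A", "C", "G", "T"), sample(40:50, 1), replace = TRUE),
          collapse = "")
  }, character(1))
  names(seqs) <- paste0("r", 1:5)
  al <- msa(seqs)
  expect_gte(nchar(al$aln[1]), max(nchar(seqs)))
  expect_equal(unname(vapply(al$aln, function(x) gsub("-", "", x),
                             character(1))),
               unname(seqs))
})

test_that("sequence-structure encoding is a bijection over the 12-letter alphabet", {
  enc <- encode_seqstruct("ACGU", "(..)")
  expect_equal(unclass(enc), c("A(", "C.", "G.", "U)"))
  dec <- decode_seqstruct(enc)
  expect_equal(dec$seq, "ACGU")
  expect_equal(dec$structure, "(..)")

  # all-unpaired degenerates to the sequence alphabet
  enc2 <- encode_seqstruct("ACGU", "....")
  expect_equal(substr(unclass(enc2), 1, 1), c("A", "C", "G", "U"))
  expect_true(all(substr(enc2, 2, 2) == "."))

  expect_error(encode_seqstruct("ACGU", "(.)"), "mismatch")
  set.seed(72)
  for (k in 1:10) {
    n <- sample(20:60, 1)
    s <- paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
    ss <- suppressWarnings(fold_mfe(s))
    d <- decode_seqstruct(encode_seqstruct(ss$seq, ss))
    expect_equal(d$seq, ss$seq)
    expect_equal(d$structure, ss$structure)
  }
})

test_that("sequence-structure alignment scores structure agreement", {
  t <- its2_template("M1")
  ss <- suppressWarnings(fold_mfe(t$seq))
  e1 <- encode_seqstruct(ss$seq, ss)
  al <- seqstruct_align(list(a = e1, b = e1))
  expect_false(any(grepl("-", al$seq_rows, fixed = TRUE)))

  # same sequences, different structures: pairwise score strictly below the
  # identical-structure score
  prm <- seqstruct_align_params()
  S <- its2ss:::seqstruct_submatrix(prm)
  alt <- strrep(".", nchar(ss$seq))
  e2 <- encode_seqstruct(ss$seq, alt)
  s_same <- pairwise_score(unclass(e1), unclass(e1), S, prm$gap_open,
                           prm$gap_ext)
  s_diff <- pairwise_score(unclass(e1), unclass(e2), S, prm$gap_open,
                           prm$gap_ext)
  expect_lt(s_diff, s_same)

  expect_error(seqstruct_align(list(a = e1, b = "ACGU")), "mixed|encodings")

  # base-pair partners keep their relative order through alignment columns
  t2 <- its2_template("M7")
  ss2 <- suppressWarnings(fold_mfe(t2$seq))
  al2 <- seqstruct_align(list(a = encode_seqstruct(ss$seq, ss),
                              b = encode_seqstruct(ss2$seq, ss2)))
  for (r in 1:2) {
    row <- al2$struct_rows[r]
    pt <- pair_table(gsub("-", ".", row))
    orig <- pair_table(list(ss, ss2)[[r]]$structure)
    # positions map monotonically, so partner order is preserved
    nong <- which(strsplit(row, "")[[1]] != "-")
    expect_equal(length(nong), length(orig))
    expect_true(all(diff(nong) > 0))
  }
})

test_that("K2P distance matches the closed form and flags saturation", {
  expect_equal(as.numeric(k2p_distance("ACGT", "ACGT")), 0)
  d <- its2ss:::k2p_from_pq(0.1, 0.05, Inf)
  expect_equal(round(as.numeric(d), 4), 0.1702)
  expect_equal(as.numeric(d), -0.5 * log(0.75) - 0.25 * log(0.9))
  sat <- its2ss:::k2p_from_pq(0.5, 0.25, Inf)
  expect_true(is.na(sat))
  expect_true(attr(sat, "saturated"))
  # Q = 0 reduces to the two-state transition-only closed form
  d2 <- its2ss:::k2p_from_pq(0.1, 0, Inf)
  expect_equal(as.numeric(d2), -0.5 * log(1 - 0.2))
})

test_that("distances are symmetric, zero on identity, and recover simulated truth", {
  set.seed(73)
  pair <- simulate_k2p_pair(10000, 0.1)
  rate <- rate_model(alpha = Inf)
  dk <- k2p_distance(pair$a, pair$b, rate)
  dl <- logdet_distance(pair$a, pair$b, rate)
  P <- mean(pair$a != pair$b &
              (pair$a %in% c("A", "G")) == (pair$b %in% c("A", "G")))
  Q <- mean(pair$a != pair$b) - P
  se <- k2p_analytic_se(P, Q, 10000)
  expect_lt(abs(as.numeric(dk) - 0.1), 3 * se)
  expect_lt(abs(as.numeric(dl) - 0.1), 3 * se)

  expect_equal(as.numeric(k2p_distance(pair$a, pair$b, rate)),
               as.numeric(k2p_distance(pair$b, pair$a, rate)))
  expect_equal(as.numeric(logdet_distance(pair$a, pair$a, rate)), 0)

  # log-det invariance under simultaneous base relabeling
  perm <- c(A = "G", C = "T", G = "A", T = "C")
  a2 <- perm[pair$a]; b2 <- perm[pair$b]
  expect_equal(as.numeric(logdet_distance(a2, b2, rate)),
               as.numeric(dl), tolerance = 1e-12)
})

test_that("NJ reconstructs additive matrices exactly", {
  # four-point construction with known branch lengths
  tr4 <- ape::read.tree(text = "((a:0.1,b:0.2):0.05,c:0.3,d:0.4);")
  dm4 <- ape::cophenetic.phylo(tr4)
  nj4 <- nj_tree(dm4)
  expect_equal(as.numeric(ape::dist.topo(nj4, tr4)), 0)
  expect_equal(sort(nj4$edge.length), sort(tr4$edge.length),
               tolerance = 1e-10)

  # three taxa: closed-form edge lengths
  dm3 <- matrix(c(0, 0.3, 0.4, 0.3, 0, 0.5, 0.4, 0.5, 0), 3, 3,
                dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  nj3 <- nj_tree(dm3)
  ex <- c(x = (0.3 + 0.4 - 0.5) / 2, y = (0.3 + 0.5 - 0.4) / 2,
          z = (0.4 + 0.5 - 0.3) / 2)
  got <- nj3$edge.length[match(match(c("x", "y", "z"), nj3$tip.label),
                               nj3$edge[, 2])]
  expect_equal(unname(got), unname(ex), tolerance = 1e-10)

  expect_error(nj_tree(matrix(c(0, NA, NA, 0), 2, 2)), "non-finite")
})

test_that("NJ recovers 100 random additive trees (n <= 12)", {
  ok <- 0
  for (k in 1:100) {
    ra <- random_additive(4 + (k %% 9), seed = 1000 + k)
    nj <- nj_tree(ra$dm)
    if (as.numeric(ape::dist.topo(nj, ra$tree)) == 0 &&
        max(abs(sort(nj$edge.length) - sort(ra$tree$edge.length))) < 1e-8) {
      ok <- ok + 1
    }
  }
  expect_equal(ok, 100)
})

test_that("pruning likelihood equals brute-force enumeration for small trees", {
  set.seed(74)
  for (k in 1:3) {
    ntax <- sample(4:5, 1)
    tr <- ape::rtree(ntax, br = function(n) runif(n, 0.05, 0.6))
    tr <- ape::unroot(tr)
    m <- matrix(sample(c("A", "C", "G", "T"), ntax * 6, replace = TRUE),
                ntax, 6)
    rownames(m) <- tr$tip.label
    rate <- rate_model("K2P", alpha = 0.7, categories = 3, kappa = 2.5)
    got <- its2ss:::pruning_loglik(tr, m, rate)
    want <- brute_force_loglik(tr, m, rate)
    expect_equal(got, want, tolerance = 1e-6)
  }
  # missing data: gaps marginalize cleanly
  tr <- ape::unroot(ape::rtree(4, br = function(n) runif(n, 0.1, 0.4)))
  m <- matrix(c("A", "-", "G", "T", "C", "C", "C", "C"), 4, 2)
  rownames(m) <- tr$tip.label
  rate <- rate_model("K2P", alpha = Inf, categories = 1)
  expect_equal(its2ss:::pruning_loglik(tr, m, rate),
               brute_force_loglik(tr, m, rate), tolerance = 1e-6)
})

test_that("likelihood limits behave: identical tips at t -> 0 and alpha -> inf", {
  tr <- ape::read.tree(text = "(a:1e-8,b:1e-8);")
  m <- matrix(c("A", "A"), 2, 1, dimnames = list(c("a", "b"), NULL))
  ll <- its2ss:::pruning_loglik(tr, m, rate_model(alpha = Inf, categories = 1))
  expect_equal(ll, log(0.25), tolerance = 1e-4)

  # very large alpha reproduces the homogeneous-rate likelihood
  tr2 <- ape::unroot(ape::rtree(5, br = function(n) runif(n, 0.05, 0.5)))
  set.seed(75)
  m2 <- matrix(sample(c("A", "C", "G", "T"), 5 * 20, replace = TRUE), 5, 20)
  rownames(m2) <- tr2$tip.label
  hom <- its2ss:::pruning_loglik(tr2, m2, rate_model(alpha = Inf,
                                                     categories = 1))
  big <- its2ss:::pruning_loglik(tr2, m2, rate_model(alpha = 1e6,
                                                     categories = 4))
  expect_equal(big, hom, tolerance = 1e-4)
})

test_that("branch lengths from tree_likelihood are locally optimal", {
  set.seed(76)
  tr <- ape::unroot(ape::rtree(5, br = function(n) runif(n, 0.05, 0.5)))
  m <- matrix(sample(c("A", "C", "G", "T"), 5 * 60, replace = TRUE), 5, 60)
  rownames(m) <- tr$tip.label
  rate <- rate_model("K2P", alpha = Inf, categories = 1)
  fit <- tree_likelihood(tr, m, rate, optimize = "edges")
  for (e in sample(seq_along(fit$tree$edge.length), 3)) {
    for (delta in c(-0.01, 0.01)) {
      tr2 <- fit$tree
      tr2$edge.length[e] <- max(tr2$edge.length[e] + delta, 1e-8)
      ll2 <- its2ss:::pruning_loglik(tr2, m, rate)
      expect_lte(ll2, fit$loglik + 1e-5)
    }
  }
})

test_that("bootstrap supports are seeded, bounded and saturate on strong signal", {
  set.seed(77)
  tr <- ape::unroot(ape::rtree(6, br = function(n) runif(n, 0.3, 0.6)))
  # simulate strongly tree-like data: many sites from the tree itself
  m <- ape::as.character.DNAbin(
    ape::as.DNAbin(phangorn::simSeq(tr, l = 10000)))
  m <- toupper(m)
  t1 <- bootstrap_supports(m, reps = 50, seed = 9)
  t2 <- bootstrap_supports(m, reps = 50, seed = 9)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_true(all(t1$node.label >= 0 & t1$node.label <= 100))
  internal <- t1$node.label[-1]   # drop the root pseudo-bipartition
  expect_true(all(internal >= 99))

  r1 <- bootstrap_supports(m, reps = 1, seed = 2)
  expect_true(all(r1$node.label %in% c(0, 100)))
  expect_error(bootstrap_supports(m, reps = 0), "reps")
})

test_that("group mean distances, bootstrap SEs and the barcode gap are coherent", {
  # two groups of identical sequences: between mean 0, SE 0
  m <- rbind(a1 = strsplit(strrep("ACGT", 25), "")[[1]],
             a2 = strsplit(strrep("ACGT", 25), "")[[1]],
             b1 = strsplit(strrep("ACGT", 25), "")[[1]])
  g <- c(a1 = "G1", a2 = "G1", b1 = "G2")
  rep0 <- group_mean_distances(m, g, "k2p", rate_model(alpha = Inf),
                               bootstrap_reps = 30, seed = 1)
  expect_equal(rep0$between["G1", "G2"], 0)
  expect_equal(rep0$between_se["G1", "G2"], 0)

  # hand-built case: between mean = average over the cross pairs
  set.seed(78)
  p1 <- simulate_k2p_pair(400, 0.05)
  p2 <- simulate_k2p_pair(400, 0.30)
  m2 <- rbind(x = p1$a, y = p1$b, z = p2$b)
  g2 <- c(x = "A", y = "A", z = "B")
  rate <- rate_model(alpha = Inf)
  repB <- group_mean_distances(m2, g2, "k2p", rate, bootstrap_reps = 10,
                               seed = 1)
  dxz <- as.numeric(k2p_distance(m2["x", ], m2["z", ], rate))
  dyz <- as.numeric(k2p_distance(m2["y", ], m2["z", ], rate))
  expect_equal(repB$between["A", "B"], mean(c(dxz, dyz)))

  # bootstrap SE close to the analytic K2P standard error
  set.seed(79)
  p3 <- simulate_k2p_pair(5000, 0.1)
  m3 <- rbind(u = p3$a, v = p3$b)
  g3 <- c(u = "U", v = "V")
  repC <- group_mean_distances(m3, g3, "k2p", rate, bootstrap_reps = 400,
                               seed = 5)
  P <- mean(p3$a != p3$b &
              (p3$a %in% c("A", "G")) == (p3$b %in% c("A", "G")))
  Q <- mean(p3$a != p3$b) - P
  se_analytic <- k2p_analytic_se(P, Q, 5000)
  expect_lt(abs(repC$between_se["U", "V"] - se_analytic) / se_analytic, 0.2)
})
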