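test_that("nucleotide content excludes ambiguity codes from both terms", {
  expect_equal(nucleotide_content("ATAT")$at_pct, 100)
  expect_equal(nucleotide_content("ATAT")$gc_pct, 0)
  cc <- nucleotide_content("ACGT")
  expect_equal(cc$at_pct, 50)
  expect_equal(cc$gc_pct, 50)
  cc2 <- nucleotide_content("ACGTN")
  expect_equal(cc2$counted_bases, 4)
  expect_equal(cc2$at_pct, 50)
  expect_error(nucleotide_content("NNN"), "undefined")
  expect_error(nucleotide_content(""), "empty")
})

test_that("normalized length reproduces the printed table values", {
  expect_equal(normalized_length(139), 19.94)
  expect_equal(normalized_length(157), 22.52)
  expect_equal(normalized_length(697), 100.00)
  expect_warning(v <- normalized_length(700), "maximum")
  expect_gt(v, 100)
})

test_that("Kruskal-Wallis H matches hand evaluation and handles degeneracy", {
  r <- kruskal_wallis(list(c(1, 2), c(3, 4)))
  expect_equal(r$H, 2.4)
  expect_equal(r$df, 1)

  same <- kruskal_wallis(list(c(5, 5), c(5, 5), c(5, 5), c(5, 5)))
  expect_equal(same$H, 0)
  expect_equal(same$p, 1)
  expect_equal(same$df, 3)

  expect_error(kruskal_wallis(list(1:3)), "two groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "empty")

  # invariance under strictly monotone transforms
  set.seed(9)
  g <- list(rnorm(8), rnorm(6, 1), rnorm(7, 2))
  expect_equal(kruskal_wallis(g)$H, kruskal_wallis(lapply(g, exp))$H)

  # tie-corrected H equals plain H when no ties exist
  x <- unlist(g)
  H_plain <- 12 / (length(x) * (length(x) + 1)) *
    sum(lengths(g) * tapply(rank(x), rep(seq_along(g), lengths(g)), mean)^2) -
    3 * (length(x) + 1)
  expect_equal(kruskal_wallis(g)$H, H_plain, tolerance = 1e-10)
})

test_that("Kruskal-Wallis agrees with a permutation null within Monte-Carlo error", {
  set.seed(101)
  g <- list(c(3.1, 4.5, 2.2, 5.0), c(4.0, 6.1, 5.5), c(1.2, 2.8, 3.3, 2.0))
  obs <- kruskal_wallis(g)
  pooled <- unlist(g)
  sizes <- lengths(g)
  reps <- 4000
  count <- 0
  for (r in seq_len(reps)) {
    x <- sample(pooled)
    gs <- split(x, rep(seq_along(sizes), sizes))
    if (kruskal_wallis(gs)$H >= obs$H - 1e-12) count <- count + 1
  }
  p_perm <- count / reps
  mc_err <- 3 * sqrt(p_perm * (1 - p_perm) / reps) + 0.02
  expect_lt(abs(p_perm - obs$p), mc_err + 0.05)
})

test_that("Dunn post-hoc has the documented structure and symmetry", {
  g <- list(c(2, 2, 2), c(2, 2, 2))
  kw <- kruskal_wallis(g)
  d <- dunn_posthoc(g, kw)
  expect_equal(d$z, 0)
  expect_equal(d$p, 1)

  g2 <- list(1:10, 101:110)
  kw2 <- kruskal_wallis(g2)
  d2 <- dunn_posthoc(g2, kw2)
  expect_lt(d2$p, 0.01)

  # antisymmetry under group order swap
  g3 <- list(c(1, 5, 3), c(9, 7, 8))
  kw3 <- kruskal_wallis(g3)
  kw3r <- kruskal_wallis(rev(g3))
  expect_equal(dunn_posthoc(g3, kw3)$z, -dunn_posthoc(rev(g3), kw3r)$z)
  expect_equal(dunn_posthoc(g3, kw3)$p, dunn_posthoc(rev(g3), kw3r)$p)

  # sequencing: omnibus required first
  expect_error(dunn_posthoc(g3), "kruskal_wallis")
  expect_error(dunn_posthoc(g3, kw2), "match")
})

test_that("Dunn p-values track a permutation null on small groups", {
  set.seed(202)
  g <- list(c(1.0, 2.5, 3.1, 0.7), c(2.2, 4.0, 3.6, 5.1))
  kw <- kruskal_wallis(g)
  d <- dunn_posthoc(g, kw)
  pooled <- unlist(g); sizes <- lengths(g)
  reps <- 5000
  zobs <- abs(d$z[1])
  count <- 0
  for (r in seq_len(reps)) {
    x <- sample(pooled)
    gs <- split(x, rep(1:2, sizes))
    zr <- dunn_posthoc(gs, kruskal_wallis(gs))$z[1]
    if (abs(zr) >= zobs - 1e-12) count <- count + 1
  }
  expect_lt(abs(count / reps - d$p[1]), 0.08)
})

test_that("indel events count distinct gap-run signatures", {
  expect_equal(count_indel_events(c("ACGT", "ACGT"))$I, 0)

  r <- count_indel_events(c("AC---GT", "ACTTTGT"))
  expect_equal(r$I, 1)
  expect_equal(r$events$span, 3)

  # two rows sharing one run plus a shifted run in a third
  rows <- c("AC-TGGT", "AC-TGGT", "ACGT-GT")
  r2 <- count_indel_events(rows)
  expect_equal(r2$I, 2)
  expect_equal(r2$I, count_events_exhaustive(rows))
  expect_equal(r2$events$n_rows, c(2, 1))

  # invariance under row reordering
  set.seed(31)
  rows3 <- c("A--CGTT", "AC--GTT", "A--CGTT", "ACGT--T")
  for (k in 1:5) {
    expect_equal(count_indel_events(sample(rows3))$I,
                 count_indel_events(rows3)$I)
  }

  expect_warning(r4 <- count_indel_events(c("A-C", "A-G")), "all-gap")
  expect_equal(r4$I, 0)
})

test_that("group summaries match brute-force recomputation", {
  study <- generate_study(study_config(n_ampelomyces = 6))
  parts <- lapply(seq_len(nrow(study$records)), function(i) {
    delimit_its(study$records[i, ])
  })
  names(parts) <- study$records$id
  gs <- group_summary(study$records, parts)

  # 5.8S constant at 157 with zero SEM in every group
  s58 <- gs[gs$region == "r5.8S", ]
  expect_true(all(s58$len_min == 157 & s58$len_max == 157))
  expect_true(all(s58$len_sem == 0))
  expect_true(all(s58$norm_mean == 22.52))

  # brute-force ITS1 mean/SEM for the Ampelomyces group
  amp_ids <- study$records$id[study$records$group == "AMPELOMYCES"]
  lens <- vapply(amp_ids, function(id) {
    p <- parts[[id]]
    p$end[p$region == "ITS1"] - p$start[p$region == "ITS1"]
  }, numeric(1))
  row <- gs[gs$group == "AMPELOMYCES" & gs$region == "ITS1", ]
  expect_equal(row$len_mean, mean(lens))
  expect_equal(row$len_sem, sd(lens) / sqrt(length(lens)))
  expect_equal(row$len_min, min(lens))
})
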