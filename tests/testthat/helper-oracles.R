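# Independent oracles used across the suite.  These deliberately avoid the
# package's own computational paths.

# maximum number of nested base pairs (Nussinov) with min hairpin loop 3
nussinov_max_pairs <- function(seq) {
  ch <- strsplit(chartr("TU", "UU", toupper(seq)), "")[[1]]
  can_pair <- function(a, b) {
    paste0(a, b) %in% c("AU", "UA", "CG", "GC", "GU", "UG")
  }
  n <- length(ch)
  if (n < 5) return(0L)
  N <- matrix(0L, n, n)
  for (span in 4:(n - 1)) {
    for (i in 1:(n - span)) {
      j <- i + span
      best <- N[i, j - 1]
      for (k in i:(j - 4)) {
        if (can_pair(ch[k], ch[j])) {
          left <- if (k > i) N[i, k - 1] else 0L
          best <- max(best, left + N[k + 1, j - 1] + 1L)
        }
      }
      N[i, j] <- best
    }
  }
  N[1, n]
}

# brute-force tree log-likelihood by summation over all internal-node states
brute_force_loglik <- function(tree, m, rate) {
  bases <- c("A", "C", "G", "T")
  Q <- its2ss:::rate_matrix(rate)
  rates <- its2ss:::gamma_rates(rate$alpha, rate$categories)
  # matrix exponential by scaling-and-squaring Taylor series (independent of
  # the eigendecomposition used in the package)
  mexp <- function(A) {
    s <- max(0, ceiling(log2(max(1e-12, norm(A, "1")))))
    A <- A / 2^s
    X <- diag(4); term <- diag(4)
    for (k in 1:30) {
      term <- term %*% A / k
      X <- X + term
    }
    for (k in seq_len(s)) X <- X %*% X
    X
  }
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  m <- m[tree$tip.label, , drop = FALSE]
  S <- ncol(m)
  total <- 0
  for (site in seq_len(S)) {
    obs <- match(m[, site], bases)
    site_lik <- 0
    for (r in rates) {
      P_edges <- lapply(seq_len(nrow(tree$edge)), function(e) {
        mexp(Q * tree$edge.length[e] * r)
      })
      states <- as.matrix(expand.grid(rep(list(1:4), nnode)))
      lik_r <- 0
      for (a in seq_len(nrow(states))) {
        st <- states[a, ]
        node_state <- function(v) {
          if (v <= ntip) obs[v] else st[v - ntip]
        }
        pr <- 0.25   # root frequency
        ok <- TRUE
        for (e in seq_len(nrow(tree$edge))) {
          par <- node_state(tree$edge[e, 1])
          chd <- node_state(tree$edge[e, 2])
          if (is.na(chd)) next   # missing tip: marginalize = factor 1
          pr <- pr * P_edges[[e]][par, chd]
          if (pr == 0) { ok <- FALSE; break }
        }
        if (ok) lik_r <- lik_r + pr
      }
      site_lik <- site_lik + lik_r / length(rates)
    }
    total <- total + log(site_lik)
  }
  unname(total)
}

# analytic large-sample SE of the K2P distance (Kimura 1980)
k2p_analytic_se <- function(P, Q, n) {
  c1 <- 1 / (1 - 2 * P - Q)
  c2 <- 1 / (1 - 2 * Q)
  c3 <- (c1 + c2) / 2
  sqrt((c1^2 * P + c3^2 * Q - (c1 * P + c3 * Q)^2) / n)
}

# simulate a pair of sequences at K2P distance d (kappa = ts/tv rate ratio)
simulate_k2p_pair <- function(L, d, kappa = 2) {
  bt <- d / (kappa + 2)     # beta * t
  at <- kappa * bt          # alpha * t
  p_same <- 0.25 + 0.25 * exp(-4 * bt) + 0.5 * exp(-2 * (at + bt))
  p_ts <- 0.25 + 0.25 * exp(-4 * bt) - 0.5 * exp(-2 * (at + bt))
  p_tv <- 0.25 - 0.25 * exp(-4 * bt)
  bases <- c("A", "C", "G", "T")
  ts_of <- c(A = "G", C = "T", G = "A", T = "C")
  tv1 <- c(A = "C", C = "A", G = "C", T = "A")
  tv2 <- c(A = "T", C = "G", G = "T", T = "G")
  a <- sample(bases, L, replace = TRUE)
  r <- stats::runif(L)
  b <- a
  ts_sel <- r >= p_same & r < p_same + p_ts
  b[ts_sel] <- ts_of[a[ts_sel]]
  tv_sel <- r >= p_same + p_ts
  half <- stats::runif(L) < 0.5
  b[tv_sel & half] <- tv1[a[tv_sel & half]]
  b[tv_sel & !half] <- tv2[a[tv_sel & !half]]
  list(a = a, b = b)
}

# random additive distance matrix from a random tree with positive lengths
random_additive <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.05, 0.5))
  tr <- ape::unroot(tr)
  list(tree = tr, dm = ape::cophenetic.phylo(tr))
}

# exhaustive-signature indel-event count (independent of the rle-based path)
count_events_exhaustive <- function(rows) {
  sigs <- character(0)
  for (r in rows) {
    ch <- strsplit(r, "")[[1]]
    run <- NULL
    for (i in seq_along(ch)) {
      if (ch[i] == "-") {
        run <- c(run, i)
      } else if (!is.null(run)) {
        sigs <- c(sigs, paste(range(run), collapse = ":"))
        run <- NULL
      }
    }
    if (!is.null(run)) sigs <- c(sigs, paste(range(run), collapse = ":"))
  }
  length(unique(sigs))
}

make_test_record <- function(its1_len = 188, its2 = NULL) {
  p <- delimit_params()
  if (is.null(its2)) its2 <- its2_template("M1")$seq
  set.seed(4242)
  its1 <- its2ss:::random_seq(its1_len, 0.6)
  seq <- paste0(p$motif_18S_end, its1, its2ss:::syn_5_8s(p), its2,
                p$motif_28S_start, its2ss:::random_seq(15, 0.5))
  its_records(id = "TREC1", seq = seq)
}
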