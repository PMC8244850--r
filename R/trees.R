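#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ (Q-criterion) topology; negative branch lengths are clamped
#' to zero and flagged.  Deterministic given the taxon order.
#'
#' @param dm symmetric distance matrix with taxon dimnames.
#' @return an \code{ape::phylo} tree; attribute \code{clamped} counts
#'   branches clamped at zero.
#' @export
nj_tree <- function(dm) {
  dm <- unclass(dm)
  if (any(!is.finite(dm))) stop("non-finite entries in distance matrix")
  if (nrow(dm) < 3) stop("need at least 3 taxa")
  tr <- ape::nj(stats::as.dist(dm))
  clamped <- sum(tr$edge.length < 0)
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "clamped") <- clamped
  tr
}

# discrete-gamma category rates (mean of equal-probability slices)
gamma_rates <- function(alpha, k) {
  if (!is.finite(alpha)) return(rep(1, k))
  q <- stats::qgamma((0:k) / k, shape = alpha, rate = alpha)
  k * diff(stats::pgamma(q, shape = alpha + 1, rate = alpha))
}

# normalized rate matrix for the model (mean rate 1 under freq)
rate_matrix <- function(rate) {
  f <- rate$freq
  Q <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                       c("A", "C", "G", "T")))
  # transversions rate 1, transitions kappa (A-G) / kappa2 (C-T)
  for (i in 1:4) {
    for (j in 1:4) {
      if (i == j) next
      ts <- (i == 1 && j == 3) || (i == 3 && j == 1) ||
        (i == 2 && j == 4) || (i == 4 && j == 2)
      r <- if (!ts) 1 else if (i %in% c(1, 3)) rate$kappa else rate$kappa2
      Q[i, j] <- r * f[j]
    }
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(f * diag(Q))
  Q / mu
}

# transition probability matrices per edge length x rate category
prob_matrices <- function(Q, lens, rates) {
  eig <- eigen(Q)
  Vi <- solve(eig$vectors)
  lapply(lens, function(t) {
    lapply(rates, function(r) {
      P <- Re(eig$vectors %*% diag(exp(eig$values * t * r)) %*% Vi)
      P[P < 0] <- 0
      P
    })
  })
}

#' Log-likelihood of a tree by Felsenstein pruning
#'
#' K2P or TN93 substitution model with discrete-gamma rate variation among
#' sites; gaps and ambiguity codes are treated as missing data.  Branch
#' lengths can optionally be optimized one-dimensionally (coordinate
#' descent, tolerance 1e-6) and the gamma shape estimated on the fixed
#' topology.
#'
#' @param tree an \code{ape::phylo} whose tip labels match the alignment rows.
#' @param alignment alignment accepted by \code{\link{its_distance_matrix}}.
#' @param rate a \code{rate_model}.
#' @param optimize \code{"none"}, \code{"edges"} or \code{"edges+shape"}.
#' @return list with \code{loglik}, the (possibly updated) \code{tree} and
#'   \code{rate}.
#' @export
tree_likelihood <- function(tree, alignment, rate = rate_model(),
                            optimize = c("none", "edges", "edges+shape")) {
  optimize <- match.arg(optimize)
  m <- alignment_chars(alignment)
  if (ncol(m) == 0) stop("zero-length alignment")
  if (!setequal(tree$tip.label, rownames(m))) {
    stop("tree tips must match alignment rows")
  }
  m <- m[tree$tip.label, , drop = FALSE]
  ll_fun <- function(lens, alpha) {
    r <- rate; r$alpha <- alpha
    pruning_loglik(tree, m, r, lens)
  }
  lens <- pmax(tree$edge.length, 1e-8)
  if (optimize %in% c("edges", "edges+shape")) {
    for (sweep in 1:2) {
      for (e in seq_along(lens)) {
        f <- function(x) { l <- lens; l[e] <- x; -ll_fun(l, rate$alpha) }
        opt <- stats::optimize(f, c(1e-8, 10), tol = 1e-6)
        lens[e] <- opt$minimum
      }
    }
  }
  alpha <- rate$alpha
  if (optimize == "edges+shape") {
    opt <- stats::optimize(function(a) -ll_fun(lens, a), c(0.05, 100),
                           tol = 1e-4)
    alpha <- opt$minimum
  }
  tree$edge.length <- lens
  out_rate <- rate; out_rate$alpha <- alpha
  list(loglik = ll_fun(lens, alpha), tree = tree, rate = out_rate)
}

pruning_loglik <- function(tree, m, rate, lens = tree$edge.length) {
  bases <- c("A", "C", "G", "T")
  S <- ncol(m)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  Q <- rate_matrix(rate)
  rates <- gamma_rates(rate$alpha, rate$categories)
  Pm <- prob_matrices(Q, pmax(lens, 1e-9), rates)
  tr <- ape::reorder.phylo(tree, "postorder")
  # map edge lengths back to original edge order
  edge_map <- match(paste(tr$edge[, 1], tr$edge[, 2]),
                    paste(tree$edge[, 1], tree$edge[, 2]))
  ncat <- length(rates)
  total <- 0
  # partials[[node]][[cat]] : 4 x S
  partials <- vector("list", ntip + nnode)
  scalelog <- matrix(0, ntip + nnode, S)
  tipL <- function(i) {
    x <- match(m[i, ], bases)
    L <- matrix(0, 4, S)
    L[cbind(rep(1:4, S), rep(seq_len(S), each = 4))] <- 1  # default all 1
    obs <- !is.na(x)
    L[, obs] <- 0
    L[cbind(x[obs], which(obs))] <- 1
    L
  }
  for (i in seq_len(ntip)) {
    partials[[i]] <- rep(list(tipL(i)), ncat)
  }
  for (k in seq_len(nrow(tr$edge))) {
    # process nodes in postorder: accumulate child contributions
    parent <- tr$edge[k, 1]; child <- tr$edge[k, 2]
    Pk <- Pm[[edge_map[k]]]
    contrib <- lapply(seq_len(ncat), function(cc) Pk[[cc]] %*% partials[[child]][[cc]])
    if (is.null(partials[[parent]])) {
      partials[[parent]] <- contrib
      scalelog[parent, ] <- colSums(scalelog[c(child), , drop = FALSE])
    } else {
      partials[[parent]] <- lapply(seq_len(ncat), function(cc) {
        partials[[parent]][[cc]] * contrib[[cc]]
      })
      scalelog[parent, ] <- scalelog[parent, ] + scalelog[child, ]
    }
    # rescale to avoid underflow
    mx <- do.call(pmax, lapply(partials[[parent]], function(M) apply(M, 2, max)))
    mx[mx == 0] <- 1
    partials[[parent]] <- lapply(partials[[parent]], function(M) {
      sweep(M, 2, mx, "/")
    })
    scalelog[parent, ] <- scalelog[parent, ] + log(mx)
  }
  root <- tr$edge[nrow(tr$edge), 1]
  site_lik <- Reduce(`+`, lapply(partials[[root]], function(M) {
    colSums(M * rate$freq)
  })) / ncat
  sum(log(site_lik) + scalelog[root, ])
}

#' Bootstrap supports for a tree builder
#'
#' Column-resampled replicates; the support of each internal bipartition of
#' the full-data tree is the percentage of replicates containing it.
#' Seeded and bit-reproducible.
#'
#' @param alignment alignment accepted by \code{\link{its_distance_matrix}}.
#' @param builder function taking a character matrix and returning a
#'   \code{phylo} tree; defaults to NJ on log-det distances.
#' @param reps number of replicates (>= 1).
#' @param seed RNG seed.
#' @param rate rate model for the default builder.
#' @return the full-data tree with \code{node.label} holding supports (%).
#' @export
bootstrap_supports <- function(alignment, builder = NULL, reps = 1000L,
                               seed = 1L, rate = rate_model(alpha = 5)) {
  if (reps < 1) stop("reps must be >= 1")
  m <- alignment_chars(alignment)
  if (is.null(builder)) {
    builder <- function(mat) nj_tree(its_distance_matrix(mat, "logdet", rate,
                                                        saturated = "cap"))
  }
  main <- builder(m)
  set.seed(seed)
  btrees <- vector("list", reps)
  for (r in seq_len(reps)) {
    idx <- sample.int(ncol(m), ncol(m), replace = TRUE)
    btrees[[r]] <- builder(m[, idx, drop = FALSE])
  }
  class(btrees) <- "multiPhylo"
  counts <- ape::prop.clades(main, btrees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  main$node.label <- round(100 * counts / reps)
  main
}
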