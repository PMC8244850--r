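#' Substitution-rate model for distances and likelihoods
#'
#' @param model \code{"K2P"} (Kimura two-parameter) or \code{"TN93"}
#'   (Tamura-Nei).
#' @param alpha gamma shape for rate variation among sites (\code{Inf} =
#'   homogeneous rates; the distance default follows the study convention
#'   of 5).
#' @param categories number of discrete gamma categories (trees only).
#' @param kappa transition/transversion rate ratio (K2P; also the A-G rate
#'   of TN93).
#' @param kappa2 C-T transition rate for TN93 (defaults to \code{kappa}).
#' @param freq base frequencies (A, C, G, T); TN93 only, default uniform.
#' @export
rate_model <- function(model = c("K2P", "TN93"), alpha = 5, categories = 4L,
                       kappa = 2, kappa2 = NULL, freq = rep(0.25, 4)) {
  model <- match.arg(model)
  stopifnot(alpha > 0, categories >= 1, kappa > 0, length(freq) == 4,
            abs(sum(freq) - 1) < 1e-8)
  structure(list(model = model, alpha = alpha,
                 categories = as.integer(categories),
                 kappa = kappa, kappa2 = if (is.null(kappa2)) kappa else kappa2,
                 freq = freq), class = "rate_model")
}

as_base_vec <- function(row) {
  if (length(row) == 1 && nchar(row[1]) > 1) {
    row <- strsplit(row, "")[[1]]
  }
  chartr("U", "T", toupper(row))
}

#' Kimura two-parameter distance between two aligned rows
#'
#' Pairwise deletion of columns where either row is a gap or ambiguity
#' code; \code{d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)} with transition
#' proportion P and transversion proportion Q, or the gamma-corrected form
#' when the rate model's shape is finite.  Saturated comparisons (log
#' arguments at or below zero) return \code{NA} with attribute
#' \code{saturated = TRUE}.
#'
#' @param row_a,row_b aligned sequences (strings or character vectors).
#' @param rate a \code{rate_model}; only \code{alpha} is used.
#' @return distance in substitutions/site.
#' @export
k2p_distance <- function(row_a, row_b, rate = rate_model(alpha = Inf)) {
  a <- as_base_vec(row_a); b <- as_base_vec(row_b)
  stopifnot(length(a) == length(b))
  use <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[use]; b <- b[use]
  n <- length(a)
  if (n == 0) return(structure(NA_real_, saturated = TRUE))
  purine <- c("A", "G")
  ts <- a != b & ((a %in% purine) == (b %in% purine))
  tv <- a != b & ((a %in% purine) != (b %in% purine))
  k2p_from_pq(sum(ts) / n, sum(tv) / n, rate$alpha)
}

k2p_from_pq <- function(P, Q, alpha = Inf) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(structure(NA_real_, saturated = TRUE))
  if (is.finite(alpha)) {
    d <- alpha / 2 * (w1^(-1 / alpha) - 1) + alpha / 4 * (w2^(-1 / alpha) - 1)
  } else {
    d <- -0.5 * log(w1) - 0.25 * log(w2)
  }
  structure(d, saturated = FALSE)
}

#' Log-det (Tamura-Kumar) distance between two aligned rows
#'
#' Determinant-based distance robust to compositional heterogeneity:
#' \code{d = -1/4 [ log det(F) - 1/2 log(det Da det Db) ]} for the pairwise
#' joint-frequency matrix F and the diagonal marginal matrices, with the
#' standard gamma-rate correction (shape from the rate model, study default
#' 5) applied through the log transform.  A singular joint matrix returns
#' \code{NA} flagged saturated.
#'
#' @inheritParams k2p_distance
#' @export
logdet_distance <- function(row_a, row_b, rate = rate_model(alpha = 5)) {
  a <- as_base_vec(row_a); b <- as_base_vec(row_b)
  stopifnot(length(a) == length(b))
  bases <- c("A", "C", "G", "T")
  use <- a %in% bases & b %in% bases
  a <- a[use]; b <- b[use]
  if (length(a) == 0) return(structure(NA_real_, saturated = TRUE))
  F <- table(factor(a, bases), factor(b, bases)) / length(a)
  logdet_from_joint(unclass(F), rate$alpha)
}

logdet_from_joint <- function(F, alpha = Inf) {
  fa <- rowSums(F); fb <- colSums(F)
  detF <- det(F)
  if (detF <= 0 || any(fa == 0) || any(fb == 0)) {
    return(structure(NA_real_, saturated = TRUE))
  }
  r <- detF / sqrt(prod(fa) * prod(fb))
  if (r <= 0) return(structure(NA_real_, saturated = TRUE))
  if (is.finite(alpha)) {
    d <- alpha / 4 * (r^(-1 / alpha) - 1)
  } else {
    d <- -log(r) / 4
  }
  structure(max(d, 0), saturated = FALSE)
}

# joint-code matrix: one row per pair, one column per alignment column;
# 0 = excluded column, else 1..16 indexing the 4x4 joint cell
joint_codes <- function(m) {
  bases <- c("A", "C", "G", "T")
  n <- nrow(m)
  code <- match(m, bases)               # matrix of 1..4 / NA
  dim(code) <- dim(m)
  pairs <- utils::combn(n, 2)
  J <- matrix(0L, ncol(pairs), ncol(m))
  for (p in seq_len(ncol(pairs))) {
    ca <- code[pairs[1, p], ]; cb <- code[pairs[2, p], ]
    ok <- !is.na(ca) & !is.na(cb)
    J[p, ok] <- (ca[ok] - 1L) * 4L + cb[ok]
  }
  list(J = J, pairs = pairs)
}

dist_from_counts <- function(n16, method, alpha) {
  N <- sum(n16)
  if (N == 0) return(structure(NA_real_, saturated = TRUE))
  F <- matrix(n16 / N, 4, 4, byrow = TRUE)   # row = first sequence
  if (method == "logdet") return(logdet_from_joint(F, alpha))
  ts <- F[1, 3] + F[3, 1] + F[2, 4] + F[4, 2]
  tv <- sum(F) - sum(diag(F)) - ts
  k2p_from_pq(ts, tv, alpha)
}

#' Pairwise distance matrix over an alignment
#'
#' @param alignment an \code{its_alignment}, \code{seqstruct_alignment}
#'   (sequence rows are used) or character matrix.
#' @param method \code{"k2p"} or \code{"logdet"}.
#' @param saturated how to report saturated pairs: \code{"na"} (flagged
#'   missing) or \code{"cap"} (finite ceiling, for tree building).
#' @param rate a \code{rate_model} supplying the gamma shape.
#' @return symmetric matrix (class \code{its_dist}) with zero diagonal;
#'   saturated entries are \code{NA} (or, with \code{saturated = "cap"},
#'   replaced by 1.5 times the largest finite distance) and counted in
#'   attribute \code{n_saturated}.
#' @export
its_distance_matrix <- function(alignment, method = c("logdet", "k2p"),
                                rate = rate_model(alpha = 5),
                                saturated = c("na", "cap")) {
  method <- match.arg(method)
  saturated <- match.arg(saturated)
  m <- alignment_chars(alignment)
  jc <- joint_codes(m)
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  nsat <- 0L
  for (p in seq_len(ncol(jc$pairs))) {
    cnt <- tabulate(jc$J[p, ], 16L)
    d <- dist_from_counts(cnt, method, rate$alpha)
    if (is.na(d)) nsat <- nsat + 1L
    i <- jc$pairs[1, p]; j <- jc$pairs[2, p]
    D[i, j] <- D[j, i] <- as.numeric(d)
  }
  if (saturated == "cap" && nsat > 0L) {
    cap <- if (all(is.na(D[upper.tri(D)]))) 1 else
      1.5 * max(D[upper.tri(D)], na.rm = TRUE)
    D[is.na(D)] <- cap
  }
  structure(D, n_saturated = nsat, method = method, class = c("its_dist", "matrix"))
}

alignment_chars <- function(alignment) {
  if (inherits(alignment, "its_alignment")) return(aln_matrix(alignment))
  if (inherits(alignment, "seqstruct_alignment")) {
    m <- do.call(rbind, strsplit(alignment$seq_rows, ""))
    rownames(m) <- alignment$ids
    return(chartr("U", "T", m))
  }
  if (is.matrix(alignment)) return(chartr("U", "T", toupper(alignment)))
  m <- do.call(rbind, strsplit(chartr("U", "T", toupper(alignment)), ""))
  rownames(m) <- names(alignment)
  m
}

#' Between-group mean distances, bootstrap SEs and the barcode-gap report
#'
#' Between-group mean = average distance over all cross pairs; standard
#' errors by resampling alignment columns.  The barcode gap flag compares
#' the smallest between-group pairwise distance with the largest
#' within-group pairwise distance.
#'
#' @param alignment alignment accepted by \code{\link{its_distance_matrix}}.
#' @param groups named character vector or factor: group label per row id.
#' @param method,rate passed to the distance computation.
#' @param bootstrap_reps column-resampling replicates for the SEs.
#' @param seed RNG seed for the resampling.
#' @return a \code{gap_report}: list with \code{between} (mean matrix),
#'   \code{between_se}, \code{max_intra} (per group), \code{min_inter},
#'   \code{barcode_gap} flag and the full distance matrix.
#' @export
group_mean_distances <- function(alignment, groups,
                                 method = c("logdet", "k2p"),
                                 rate = rate_model(alpha = 5),
                                 bootstrap_reps = 1000L, seed = 1L) {
  method <- match.arg(method)
  m <- alignment_chars(alignment)
  ids <- rownames(m)
  grp <- as.character(groups[ids])
  if (anyNA(grp)) stop("groups must cover all alignment rows")
  keep_groups <- names(which(table(grp) >= 1))
  jc <- joint_codes(m)
  np <- ncol(jc$pairs)
  pair_groups <- cbind(grp[jc$pairs[1, ]], grp[jc$pairs[2, ]])
  full_d <- vapply(seq_len(np), function(p) {
    as.numeric(dist_from_counts(tabulate(jc$J[p, ], 16L), method, rate$alpha))
  }, numeric(1))
  glev <- sort(unique(grp))
  k <- length(glev)
  pair_key <- function(g1, g2) paste(pmin(g1, g2), pmax(g1, g2), sep = "|")
  keys <- pair_key(pair_groups[, 1], pair_groups[, 2])
  between <- matrix(NA_real_, k, k, dimnames = list(glev, glev))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      sel <- keys == pair_key(glev[i], glev[j])
      if (any(sel)) between[i, j] <- mean(full_d[sel], na.rm = TRUE)
    }
  }
  # bootstrap SEs over alignment columns
  between_se <- matrix(NA_real_, k, k, dimnames = list(glev, glev))
  if (bootstrap_reps >= 2) {
    set.seed(seed)
    L <- ncol(m)
    boot_means <- array(NA_real_, c(bootstrap_reps, k, k))
    for (r in seq_len(bootstrap_reps)) {
      idx <- sample.int(L, L, replace = TRUE)
      db <- vapply(seq_len(np), function(p) {
        as.numeric(dist_from_counts(tabulate(jc$J[p, idx], 16L),
                                    method, rate$alpha))
      }, numeric(1))
      for (i in seq_len(k)) {
        for (j in seq_len(k)) {
          if (j < i) next
          sel <- keys == pair_key(glev[i], glev[j])
          if (any(sel)) {
            bm <- mean(db[sel], na.rm = TRUE)
            boot_means[r, i, j] <- boot_means[r, j, i] <- bm
          }
        }
      }
    }
    for (i in seq_len(k)) {
      for (j in seq_len(k)) {
        between_se[i, j] <- stats::sd(boot_means[, i, j], na.rm = TRUE)
      }
    }
  }
  intra_sel <- pair_groups[, 1] == pair_groups[, 2]
  max_intra <- vapply(glev, function(g) {
    sel <- intra_sel & pair_groups[, 1] == g
    vals <- full_d[sel]
    vals <- vals[!is.na(vals)]
    if (length(vals)) max(vals) else NA_real_
  }, numeric(1))
  inter_d <- full_d[!intra_sel]
  inter_d <- inter_d[!is.na(inter_d)]
  min_inter <- if (length(inter_d)) min(inter_d) else NA_real_
  gap <- !is.na(min_inter) && all(is.na(max_intra) | min_inter > max_intra)
  structure(list(between = between, between_se = between_se,
                 max_intra = max_intra, min_inter = min_inter,
                 barcode_gap = gap, distances = full_d,
                 pair_groups = pair_groups, method = method),
            class = "gap_report")
}
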