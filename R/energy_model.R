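#' Nearest-neighbor RNA energy model
#'
#' Loads the versioned nearest-neighbor stacking table shipped with the
#' package (Turner-2004-style free energies at 37 degrees C and companion
#' enthalpies) and assembles the full 6x6 stack matrices over the canonical
#' pair alphabet \code{AU, UA, CG, GC, GU, UG} by symmetric completion:
#' reading a helix from the opposite strand leaves the stack unchanged,
#' i.e. \code{E(ab, cd) = E(dc, ba)}.  Loop penalties (hairpin, bulge,
#' internal, affine multibranch) are simplified length-dependent terms;
#' energies are handled internally as integer tenths of kcal/mol so that
#' independent re-evaluation of a reported structure is exact.
#'
#' @param temperature folding temperature in degrees C; only 37 is
#'   parameterized and other values are rejected.
#' @return an object of class \code{nn_params}: stack matrices (tenths of
#'   kcal/mol), duplex initiation terms, loop penalty generators and
#'   multibranch coefficients, plus the parameter-table version tag.
#' @export
turner_params <- function(temperature = 37) {
  if (temperature != 37) {
    stop("only the 37 C parameterization is shipped")
  }
  path <- system.file("extdata", "nn_stacks_v1.tsv", package = "its2ss",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  pairs <- c("AU", "UA", "CG", "GC", "GU", "UG")
  dg <- matrix(NA_integer_, 6, 6, dimnames = list(pairs, pairs))
  dh <- matrix(NA_integer_, 6, 6, dimnames = list(pairs, pairs))
  flip <- function(p) paste0(substr(p, 2, 2), substr(p, 1, 1))
  for (r in seq_len(nrow(tab))) {
    p1 <- tab$pair1[r]; p2 <- tab$pair2[r]
    g <- as.integer(round(tab$dg37[r] * 10))
    h <- as.integer(round(tab$dh[r] * 10))
    s1 <- flip(p2); s2 <- flip(p1)   # symmetric partner
    for (key in list(c(p1, p2), c(s1, s2))) {
      old <- dg[key[1], key[2]]
      if (!is.na(old) && old != g) {
        stop("conflicting stack entries for ", key[1], "/", key[2])
      }
      dg[key[1], key[2]] <- g
      dh[key[1], key[2]] <- h
    }
  }
  if (anyNA(dg)) stop("incomplete stack table")
  structure(list(
    version = "turner2004-v1",
    temperature = temperature,
    pairs = pairs,
    stack_dg = dg,
    stack_dh = dh,
    duplex_init_dg = 41L,   # +4.1 kcal/mol duplex initiation
    duplex_init_dh = 36L,
    ml_a = 34L, ml_b = 4L, ml_c = 0L,
    min_hairpin = 3L,
    max_interior = 30L
  ), class = "nn_params")
}

#' @export
print.nn_params <- function(x, ...) {
  cat("Nearest-neighbor RNA parameters (", x$version, ", ",
      x$temperature, " C)\n", sep = "")
  cat("  pair alphabet:", paste(x$pairs, collapse = " "), "\n")
  invisible(x)
}

# Length-indexed loop penalty vectors (tenths of kcal/mol), element k+1 is
# the penalty for an unpaired span of k nucleotides.  Jacobson-Stockmayer
# style logarithmic extrapolation beyond the tabulated short lengths.
loop_penalty_tables <- function(n) {
  inf <- 100000000L
  len <- 0:n
  hairpin <- rep(inf, n + 1L)
  base_h <- c(54L, 56L, 57L, 54L, 60L, 55L, 64L)   # loops 3..9
  for (k in 3:min(9, n)) hairpin[k + 1L] <- base_h[k - 2L]
  if (n > 9) {
    k <- 10:n
    hairpin[k + 1L] <- 64L + as.integer(round(17.5 * log(k / 9)))
  }
  bulge <- rep(inf, n + 1L)
  base_b <- c(38L, 28L, 32L, 36L, 40L, 44L)        # bulges 1..6
  for (k in 1:min(6, n)) bulge[k + 1L] <- base_b[k]
  if (n > 6) {
    k <- 7:n
    bulge[k + 1L] <- 44L + as.integer(round(17.5 * log(k / 6)))
  }
  internal <- rep(inf, n + 1L)
  base_i <- c(10L, 15L, 17L, 18L, 20L)             # totals 2..6
  for (k in 2:min(6, n)) internal[k + 1L] <- base_i[k - 1L]
  if (n > 6) {
    k <- 7:n
    internal[k + 1L] <- 20L + as.integer(round(17.5 * log(k / 6)))
  }
  list(hairpin = hairpin, bulge = bulge, internal = internal)
}

# Map an RNA/DNA string to integer codes A=0, C=1, G=2, U/T=3.
base_codes <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  chars[chars == "T"] <- "U"
  codes <- match(chars, c("A", "C", "G", "U")) - 1L
  if (anyNA(codes)) {
    stop("non-RNA symbol in sequence: ",
         paste(unique(chars[is.na(codes)]), collapse = ", "))
  }
  codes
}

pair_name <- function(a, b) {
  key <- paste0(a, b)
  ok <- c("AU", "UA", "CG", "GC", "GU", "UG")
  if (key %in% ok) key else NA_character_
}
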