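#' Nucleotide pair-base content of a sequence
#'
#' A/T and G/C content as total percentages.  IUPAC ambiguity codes
#' (including N) are excluded from both numerator and denominator.
#'
#' @param seq sequence string (DNA or RNA letters).
#' @return list with \code{at_pct}, \code{gc_pct} and \code{counted_bases}.
#' @export
nucleotide_content <- function(seq) {
  if (!nzchar(seq)) stop("empty sequence")
  ch <- strsplit(chartr("U", "T", toupper(seq)), "")[[1]]
  at <- sum(ch %in% c("A", "T"))
  gc <- sum(ch %in% c("G", "C"))
  counted <- at + gc
  if (counted == 0) stop("undefined content: no unambiguous bases")
  list(at_pct = 100 * at / counted, gc_pct = 100 * gc / counted,
       counted_bases = counted)
}

#' Normalize a sequence length to the primer-bounded maximum
#'
#' Lengths are expressed as a percentage of the maximum ITS amplicon length
#' expected from the ITS1f/ITS4 primer pair (697 bp by default) and rendered
#' at two decimals by truncation, matching the convention of the source
#' report tables.
#'
#' @param len_bp sequence length in bp.
#' @param ref_bp reference maximum (default 697).
#' @return percentage, truncated to 2 decimals.
#' @export
normalized_length <- function(len_bp, ref_bp = 697L) {
  stopifnot(len_bp >= 0, ref_bp > 0)
  if (any(len_bp > ref_bp)) {
    warning("sequence longer than the primer-bounded maximum (", ref_bp, " bp)")
  }
  trunc(100 * len_bp / ref_bp * 100) / 100
}

#' Kruskal-Wallis rank sum test across groups
#'
#' Tie-corrected H statistic with a chi-squared reference distribution on
#' k - 1 degrees of freedom (delegated to \code{stats::kruskal.test}).
#'
#' @param groups list of k >= 2 non-empty numeric vectors.
#' @return a \code{kw_result}: list with \code{H}, \code{df}, \code{p} and
#'   the group sizes.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) stop("need at least two groups")
  if (any(lengths(groups) == 0)) stop("empty group")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1L) {
    res <- list(H = 0, df = length(groups) - 1L, p = 1)
  } else {
    kt <- stats::kruskal.test(x, g)
    res <- list(H = unname(kt$statistic), df = unname(kt$parameter),
                p = kt$p.value)
  }
  structure(c(res, list(n = lengths(groups))), class = "kw_result")
}

#' Dunn post-hoc pairwise comparisons
#'
#' Standard Dunn z statistics with tie correction on the pooled ranks;
#' two-sided p-values with no multiplicity adjustment.  Must follow the
#' omnibus \code{\link{kruskal_wallis}} test on the same groups.
#'
#' @param groups list of numeric vectors (same as the omnibus call).
#' @param omnibus the \code{kw_result} from \code{\link{kruskal_wallis}};
#'   required, to enforce the test sequencing.
#' @return data frame with columns \code{group1, group2, z, p}.
#' @export
dunn_posthoc <- function(groups, omnibus) {
  if (missing(omnibus) || !inherits(omnibus, "kw_result")) {
    stop("run kruskal_wallis() on the same groups first")
  }
  if (!identical(unname(omnibus$n), unname(lengths(groups)))) {
    stop("omnibus result does not match these groups")
  }
  k <- length(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_len(k), lengths(groups))
  r <- rank(x)
  N <- length(x)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, g, mean)
  n <- lengths(groups)
  out <- list()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      sd_ij <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[i] + 1 / n[j]))
      z <- if (sd_ij == 0) 0 else (rbar[i] - rbar[j]) / sd_ij
      out[[length(out) + 1L]] <- data.frame(
        group1 = i, group2 = j, z = unname(z),
        p = 2 * stats::pnorm(-abs(unname(z))))
    }
  }
  do.call(rbind, out)
}

#' Count insertion-deletion events in an alignment
#'
#' An indel event is a distinct gap-run signature: an identical maximal run
#' of gap columns shared by one or more rows counts once, however many rows
#' share it.  Columns consisting entirely of gaps are stripped (with a
#' warning) before counting.
#'
#' @param alignment character vector of equal-length aligned rows (gap '-'),
#'   or a character matrix of single characters.
#' @return an \code{indel_report}: list with \code{I} (event count),
#'   \code{events} (data frame: start, end, span, n_rows, rows) and
#'   \code{profile} (event start columns).
#' @export
count_indel_events <- function(alignment) {
  m <- if (is.matrix(alignment)) alignment else
    do.call(rbind, strsplit(alignment, ""))
  if (is.null(dim(m)) || any(apply(m, 1, length) != ncol(m))) {
    stop("alignment rows must have equal length")
  }
  all_gap <- colSums(m == "-") == nrow(m)
  if (any(all_gap)) {
    warning("stripping ", sum(all_gap), " all-gap column(s)")
    m <- m[, !all_gap, drop = FALSE]
  }
  sig <- list()
  for (r in seq_len(nrow(m))) {
    isgap <- m[r, ] == "-"
    if (!any(isgap)) next
    rl <- rle(isgap)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    for (k in which(rl$values)) {
      key <- paste0(starts[k], "-", ends[k])
      sig[[key]] <- c(sig[[key]], r)
    }
  }
  if (length(sig) == 0) {
    return(structure(list(I = 0L,
                          events = data.frame(start = integer(0),
                                              end = integer(0),
                                              span = integer(0),
                                              n_rows = integer(0),
                                              rows = character(0)),
                          profile = integer(0)), class = "indel_report"))
  }
  starts <- as.integer(sub("-.*", "", names(sig)))
  ends <- as.integer(sub(".*-", "", names(sig)))
  ord <- order(starts, ends)
  ev <- data.frame(start = starts[ord], end = ends[ord],
                   span = ends[ord] - starts[ord] + 1L,
                   n_rows = vapply(sig[ord], length, integer(1)),
                   rows = vapply(sig[ord], paste, character(1), collapse = ","),
                   row.names = NULL)
  structure(list(I = nrow(ev), events = ev, profile = ev$start),
            class = "indel_report")
}

#' Per-group, per-region sequence summary
#'
#' Emulates the characterization tables: per group and region (full ITS,
#' ITS1, 5.8S, ITS2), length min/max/mean/SEM, normalized-length mean/SEM
#' and A/T, G/C content ranges.
#'
#' @param records an \code{its_records} data frame with group labels.
#' @param partitions named list of \code{its_partition} objects, one per
#'   record id.
#' @param ref_bp normalization reference (default 697).
#' @return data frame with one row per group x region.
#' @export
group_summary <- function(records, partitions, ref_bp = 697L) {
  stopifnot(inherits(records, "its_records"))
  groups <- unique(records$group[!is.na(records$group)])
  skipped <- sum(is.na(records$group))
  if (skipped > 0) {
    warning(skipped, " record(s) without a group label omitted from summary")
  }
  sem <- function(x) if (length(x) < 2) 0 else stats::sd(x) / sqrt(length(x))
  rows <- list()
  for (grp in groups) {
    ids <- records$id[!is.na(records$group) & records$group == grp]
    for (region in c("ITS", "ITS1", "r5.8S", "ITS2")) {
      lens <- numeric(0); ats <- numeric(0); gcs <- numeric(0)
      for (id in ids) {
        part <- partitions[[id]]
        if (is.null(part)) next
        rec <- records[records$id == id, ]
        if (region == "ITS") {
          s <- paste0(region_seq(rec, part, "ITS1"),
                      region_seq(rec, part, "r5.8S"),
                      region_seq(rec, part, "ITS2"))
        } else {
          s <- region_seq(rec, part, region)
        }
        if (!nzchar(s)) next
        cc <- nucleotide_content(s)
        lens <- c(lens, nchar(s))
        ats <- c(ats, cc$at_pct)
        gcs <- c(gcs, cc$gc_pct)
      }
      if (length(lens) == 0) next
      norm <- normalized_length(lens, ref_bp)
      rows[[length(rows) + 1L]] <- data.frame(
        group = grp, region = region, n = length(lens),
        len_min = min(lens), len_max = max(lens),
        len_mean = mean(lens), len_sem = sem(lens),
        norm_mean = mean(norm), norm_sem = sem(norm),
        at_min = min(ats), at_max = max(ats),
        gc_min = min(gcs), gc_max = max(gcs))
    }
  }
  do.call(rbind, rows)
}
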