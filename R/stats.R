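# Coordinate arithmetic, breakpoint clustering, control-fragment
# construction and exact enrichment statistics for deletion breakpoint
# sets. All genomic arithmetic is 1-based inclusive: a deletion spanning
# coordinates (p, d) removes d - p + 1 bases.

#' Deletion size from breakpoint coordinates
#'
#' @param proximal,distal 1-based positions of the first and last deleted
#'   base (vectorized).
#' @return `distal - proximal + 1` in bp.
#' @export
deletion_size <- function(proximal, distal) {
  if (any(distal < proximal)) stop("distal must be >= proximal")
  as.numeric(distal) - as.numeric(proximal) + 1
}

#' Separation between two breakpoints
#'
#' Inclusive convention, consistent with [deletion_size()]: two identical
#' positions are separated by 1.
#'
#' @param a,b Positions.
#' @return `abs(b - a) + 1` in bp.
#' @export
breakpoint_separation <- function(a, b) {
  abs(as.numeric(b) - as.numeric(a)) + 1
}

#' Densest k-breakpoint window
#'
#' Among all k-subsets of the sorted coordinates, finds the one with the
#' smallest inclusive span (the optimum is always a run of consecutive
#' sorted coordinates); ties resolve to the leftmost window.
#'
#' @param coords Numeric positions.
#' @param k Window size (number of breakpoints), `k <= length(coords)`.
#' @return List: `span` (inclusive bp), `members` (the k coordinates),
#'   `span_kb` (span/1000 rounded half-up to one decimal).
#' @export
min_span_window <- function(coords, k) {
  n <- length(coords)
  if (k > n) stop("k exceeds the number of coordinates")
  s <- sort(coords)
  if (k == 1L) {
    return(list(span = 1, members = s[1L], span_kb = round_half_up(1/1000, 1)))
  }
  spans <- s[k:n] - s[1:(n - k + 1L)] + 1
  i <- which.min(spans)                      # which.min takes the leftmost tie
  list(span = spans[i], members = s[i:(i + k - 1L)],
       span_kb = round_half_up(spans[i] / 1000, 1L))
}

#' Tile control regions into fixed-size fragments
#'
#' Builds a control dataset by tiling each region from its start into
#' non-overlapping fragments of `frag_len` bp (trailing remainder
#' discarded) and assigning each fragment a hypothetical breakpoint at its
#' midpoint, between fragment nucleotides `frag_len/2` and
#' `frag_len/2 + 1`.
#'
#' @param regions Data frame with `start`, `end` half-open region specs
#'   (`end` exclusive, so a "29,118,000-29,148,000" region spans 30 kb),
#'   and optionally `contig`.
#' @param frag_len Fragment length in bp (even, >= 2).
#' @return Data frame of fragments: contig, start, end (1-based
#'   inclusive), hypothetical_breakpoint (position of the base 5' of the
#'   midpoint cut).
#' @export
fragmentize_control <- function(regions, frag_len) {
  stopifnot(frag_len >= 2L, all(c("start", "end") %in% names(regions)))
  out <- list()
  for (i in seq_len(nrow(regions))) {
    s <- as.numeric(regions$start[i]); e <- as.numeric(regions$end[i])
    nfrag <- floor((e - s) / frag_len)
    if (nfrag < 1L) next
    starts <- s + (seq_len(nfrag) - 1L) * frag_len
    out[[length(out) + 1L]] <- data.frame(
      contig = if ("contig" %in% names(regions)) regions$contig[i] else "ctrl",
      start = starts, end = starts + frag_len - 1,
      hypothetical_breakpoint = starts + frag_len / 2 - 1,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(contig = character(0), start = numeric(0),
                      end = numeric(0), hypothetical_breakpoint = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Two-tailed Fisher exact test on a 2x2 table
#'
#' Exact conditional test: with fixed margins, the two-tailed p-value is
#' the sum of hypergeometric probabilities of all tables at most as
#' probable as the observed one (within a 1e-7 relative tolerance). The
#' odds ratio is the sample estimate `ad/bc`, flagged undefined when a
#' margin is zero or `bc = 0`.
#'
#' @param table 2x2 integer matrix (rows: case/control, columns:
#'   feature present/absent).
#' @return List with class `enrichment_result`: `table`, `odds_ratio`,
#'   `p_two_tailed`, `odds_defined`.
#' @export
fisher_exact_two_tailed <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2L, 2L)), all(table >= 0),
            all(table == round(table)))
  a <- table[1L, 1L]; b <- table[1L, 2L]
  c_ <- table[2L, 1L]; d <- table[2L, 2L]
  r <- a + b; s <- c_ + d; m <- a + c_
  if (r == 0 || s == 0 || m == 0 || (b + d) == 0) {
    return(structure(list(table = table, odds_ratio = NA_real_,
                          p_two_tailed = 1, odds_defined = FALSE),
                     class = "enrichment_result"))
  }
  support <- max(0, m - s):min(r, m)
  probs <- stats::dhyper(support, r, s, m)
  p_obs <- stats::dhyper(a, r, s, m)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  odds_defined <- (b * c_) > 0
  or <- if (odds_defined) (a * d) / (b * c_) else NA_real_
  structure(list(table = table, odds_ratio = or, p_two_tailed = p,
                 odds_defined = odds_defined),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> OR=%s, two-tailed P=%.4g\n",
              if (x$odds_defined) sprintf("%.3g", x$odds_ratio) else "undef",
              x$p_two_tailed))
  invisible(x)
}

#' Feature presence over fragments or breakpoint flanks
#'
#' Marks each query interval (fragment or breakpoint flank) as
#' feature-present when any feature interval overlaps it
#' (inclusive-coordinate overlap) on the same contig.
#'
#' @param queries Data frame with contig, start, end (1-based inclusive).
#' @param features Data frame with contig, start, end.
#' @return List: `present` (logical per query), `n_present`, `n_absent`,
#'   and `counts_row` (`c(present, absent)`, ready for a 2x2 table).
#' @export
count_feature_overlap <- function(queries, features) {
  stopifnot(all(c("contig", "start", "end") %in% names(queries)))
  nq <- nrow(queries)
  present <- logical(nq)
  if (nrow(features) > 0L) {
    if (!all(features$contig %in% c(queries$contig, features$contig))) {
      stop("contig namespace mismatch")
    }
    for (ctg in unique(queries$contig)) {
      qi <- which(queries$contig == ctg)
      fi <- which(features$contig == ctg)
      if (!length(fi)) next
      qr <- IRanges::IRanges(start = queries$start[qi],
                             end = queries$end[qi])
      fr <- IRanges::IRanges(start = features$start[fi],
                             end = features$end[fi])
      present[qi] <- IRanges::countOverlaps(qr, fr) > 0L
    }
  }
  list(present = present, n_present = sum(present),
       n_absent = nq - sum(present),
       counts_row = c(present = sum(present), absent = nq - sum(present)))
}

#' Label a breakpoint position within an interval annotation
#'
#' Returns the label of the containing annotation interval, or
#' "between <left> and <right>" when the position falls in a gap between
#' two labeled intervals.
#'
#' @param bp Position (1-based).
#' @param annotation Data frame with start, end, label; intervals must be
#'   non-overlapping. Positions outside the annotated range raise an
#'   error.
#' @return Character label.
#' @export
locate_breakpoint_in_annotation <- function(bp, annotation) {
  ann <- annotation[order(annotation$start), , drop = FALSE]
  if (any(utils::head(ann$end, -1L) >= utils::tail(ann$start, -1L))) {
    stop("annotation intervals must be non-overlapping")
  }
  if (bp < ann$start[1L] || bp > ann$end[nrow(ann)]) {
    stop("position ", bp, " outside the annotated range")
  }
  hit <- which(ann$start <= bp & ann$end >= bp)
  if (length(hit) == 1L) return(ann$label[hit])
  left <- max(which(ann$end < bp))
  sprintf("between %s and %s", ann$label[left], ann$label[left + 1L])
}
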