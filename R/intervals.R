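# Genomic interval containers and the interval engine.
#
# Intervals are plain data.frames in 0-based half-open (BED-native)
# coordinates: columns chrom, start, end, name, score, strand. All overlap
# arithmetic ignores strand; strand is carried only for strand-aware tag
# collapsing and gene models.

#' Construct a validated genomic interval table
#'
#' The package-wide interval container: a `data.frame` with columns
#' `chrom`, `start`, `end`, `name`, `score`, `strand` in 0-based half-open
#' coordinates. Every function that accepts "intervals" accepts the output
#' of this constructor (or any data.frame with at least `chrom`, `start`,
#' `end`).
#'
#' @param chrom character chromosome names (non-empty).
#' @param start 0-based inclusive start positions.
#' @param end 0-based exclusive end positions; must satisfy `end > start`.
#' @param name identifiers; defaults to `"<chrom>:<start>-<end>"`.
#' @param score non-negative numeric scores; default 0.
#' @param strand one of `"+"`, `"-"`, `"."`; default `"."`.
#' @return a `data.frame` of intervals.
#' @examples
#' gintervals("chr1", 100, 200, name = "pk1", score = 5)
#' @export
gintervals <- function(chrom, start, end, name = NULL, score = NULL, strand = NULL) {
  start <- as.numeric(start); end <- as.numeric(end)
  n <- if (length(start) == 0L || length(end) == 0L) 0L
  else max(length(chrom), length(start), length(end))
  if (n == 0L) { chrom <- character(); start <- numeric(); end <- numeric() }
  if (n > 0) {
    if (!all(c(length(chrom), length(start), length(end)) %in% c(1L, n)))
      stop_f("chrom/start/end lengths differ")
    chrom <- rep_len(as.character(chrom), n)
    start <- rep_len(start, n); end <- rep_len(end, n)
  }
  if (n > 0 && (any(is.na(start)) || any(is.na(end)) || any(start != floor(start)) || any(end != floor(end))))
    stop_f("interval coordinates must be integers")
  if (any(!nzchar(chrom))) stop_f("chrom names must be non-empty")
  bad <- which(end <= start)
  if (length(bad)) stop_f("end <= start for interval %d (%s:%s-%s)",
                          bad[1], chrom[bad[1]], start[bad[1]], end[bad[1]])
  name <- name %||% sprintf("%s:%.0f-%.0f", chrom, start, end)
  score <- score %||% rep(0, n)
  if (any(score < 0)) stop_f("scores must be non-negative")
  strand <- strand %||% rep(".", n)
  if (n > 0 && !all(strand %in% c("+", "-", "."))) stop_f("strand must be one of +, -, .")
  data.frame(chrom = as.character(chrom), start = start, end = end,
             name = as.character(name), score = as.numeric(score),
             strand = as.character(strand), stringsAsFactors = FALSE)
}

# Coerce an interval table to GRanges (1-based closed) for the IRanges engine.
as_granges <- function(x) {
  GenomicRanges::GRanges(seqnames = x$chrom,
                         ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
                         strand = "*")
}

#' Intersect two interval sets
#'
#' Reports every pair `(i, j)` where interval `i` of `a` and `j` of `b` lie
#' on the same chromosome and share at least `min_overlap_bp` bases. Strand
#' is ignored; the half-open convention means intervals sharing only a
#' boundary coordinate do not intersect.
#'
#' @param a,b interval data.frames (see [gintervals()]).
#' @param min_overlap_bp minimum shared bases for a pair to be reported
#'   (default 1).
#' @return data.frame with columns `index_a`, `index_b`, `overlap_bp`.
#' @export
intersect_sets <- function(a, b, min_overlap_bp = 1L) {
  if (!is_count(min_overlap_bp) || min_overlap_bp < 1)
    stop_f("min_overlap_bp must be a positive integer")
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(data.frame(index_a = integer(), index_b = integer(), overlap_bp = numeric()))
  # suppress the benign "no sequence levels in common" note for disjoint
  # chromosome sets
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(as_granges(a), as_granges(b),
                                minoverlap = as.integer(min_overlap_bp)))
  ia <- S4Vectors::queryHits(hits); ib <- S4Vectors::subjectHits(hits)
  ov <- pmin(a$end[ia], b$end[ib]) - pmax(a$start[ia], b$start[ib])
  data.frame(index_a = ia, index_b = ib, overlap_bp = ov)
}

#' Merge intervals within a gap tolerance
#'
#' Transitively merges intervals whose gap is at most `max_gap` bp (a gap of
#' 0 merges book-ended intervals). Output is sorted by (chrom, start) and
#' each input interval is assigned to exactly one merged region.
#'
#' @param intervals interval data.frame.
#' @param max_gap maximum gap (bp) bridged when merging; default 0.
#' @return data.frame of merged regions with columns `chrom`, `start`,
#'   `end`, `name`, `score` (sum of constituent scores), `strand`,
#'   `n_constituents`, plus attribute `"assignment"`: for each input row the
#'   index of its merged region.
#' @export
merge_intervals <- function(intervals, max_gap = 0L) {
  if (!is.numeric(max_gap) || length(max_gap) != 1L || max_gap < 0)
    stop_f("max_gap must be a non-negative number of bases")
  if (nrow(intervals) == 0L) {
    out <- gintervals(character(), numeric(), numeric())
    out$n_constituents <- integer()
    attr(out, "assignment") <- integer()
    return(out)
  }
  gr <- as_granges(intervals)
  red <- GenomicRanges::reduce(gr, min.gapwidth = as.integer(max_gap) + 1L,
                               ignore.strand = TRUE)
  # with min.gapwidth = g+1, ranges separated by a gap <= g are merged;
  # every input range is contained in exactly one reduced region
  hit <- GenomicRanges::findOverlaps(gr, red)
  assignment <- integer(nrow(intervals))
  assignment[S4Vectors::queryHits(hit)] <- S4Vectors::subjectHits(hit)
  counts <- tabulate(assignment, nbins = length(red))
  out <- gintervals(as.character(GenomicRanges::seqnames(red)),
                    GenomicRanges::start(red) - 1L,
                    GenomicRanges::end(red))
  out$score <- as.numeric(tapply(intervals$score, factor(assignment, levels = seq_along(red)),
                                 sum, default = 0))
  out$n_constituents <- counts
  attr(out, "assignment") <- assignment
  out
}
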