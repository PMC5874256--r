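# Superenhancer identification: stitch clustered peaks, quantify tag
# signal, rank, and cut the rank-signal curve where its slope reaches 1
# (ROSE-style geometry).

#' Stitch peaks into candidate superenhancer regions
#'
#' Transitively merges peaks whose gaps are at most `stitch_bp` (inclusive
#' boundary: peaks exactly `stitch_bp` apart are stitched). Peaks falling
#' fully inside a TSS-exclusion window can be removed before stitching.
#'
#' @param peaks interval data.frame.
#' @param stitch_bp maximum stitched gap (default 12500).
#' @param tss_exclusion optional interval data.frame (e.g. promoter
#'   windows); peaks fully contained in any window are dropped first.
#' @return data.frame of stitched regions: `chrom`, `start`, `end`, `name`
#'   (`SR_<i>`), `n_constituents`, `constituents` (comma-joined peak
#'   names), plus attribute `"assignment"` mapping retained peaks to
#'   regions.
#' @export
stitch_peaks <- function(peaks, stitch_bp = 12500L, tss_exclusion = NULL) {
  if (stitch_bp < 0) stop_f("stitch_bp must be >= 0")
  if (!is.null(tss_exclusion) && nrow(tss_exclusion) && nrow(peaks)) {
    ov <- intersect_sets(peaks, tss_exclusion)
    if (nrow(ov)) {
      contained <- ov$overlap_bp == (peaks$end[ov$index_a] - peaks$start[ov$index_a])
      drop <- unique(ov$index_a[contained])
      if (length(drop)) peaks <- peaks[-drop, , drop = FALSE]
    }
  }
  merged <- merge_intervals(peaks, max_gap = stitch_bp)
  assignment <- attr(merged, "assignment")
  merged$name <- sprintf("SR_%d", seq_len(nrow(merged)))
  merged$constituents <- vapply(seq_len(nrow(merged)), function(i)
    paste(peaks$name[assignment == i], collapse = ","), "")
  attr(merged, "assignment") <- assignment
  merged
}

#' Rank-signal cutoff for superenhancer calling
#'
#' Ranks and signals are scaled to the unit square; the cutoff is the
#' signal at the point where a slope-1 line is tangent to the
#' ascending-sorted signal curve, located by brute-force minimization of
#' `y - x`. Regions with signal strictly above the cutoff are
#' superenhancers. All-equal signals are a degenerate geometry: no call is
#' made and the result is flagged.
#'
#' @param signals numeric vector of per-region signal totals (any order).
#' @return list: `cutoff` (signal value), `index` (position in the
#'   ascending sort), `sorted` (ascending signals), `x`, `y` (scaled curve
#'   coordinates), `degenerate` flag.
#' @export
superenhancer_cutoff <- function(signals) {
  n <- length(signals)
  if (n < 3L) stop_f("need >= 3 regions for a rank-signal cutoff")
  s <- sort(signals)
  if (s[1L] == s[n]) {
    return(list(cutoff = Inf, index = NA_integer_, sorted = s,
                x = (seq_len(n) - 1) / (n - 1), y = rep(0, n), degenerate = TRUE))
  }
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s - s[1L]) / (s[n] - s[1L])
  d <- y - x
  ties <- which(d <= min(d) + 1e-12)
  idx <- max(ties)  # a tie plateau (e.g. a perfectly linear curve) cuts at
                    # its upper end, so a degenerate geometry calls nothing
  list(cutoff = s[idx], index = idx, sorted = s, x = x, y = y,
       degenerate = length(ties) > 1L)
}

#' Call superenhancers from peaks and tags
#'
#' Stitch -> per-region tag totals (optionally minus depth-scaled control,
#' floored at 0) -> rank-signal cutoff -> calls. Rank 1 is the
#' highest-signal region; the superenhancer set is an upward-closed suffix
#' of the signal ranking.
#'
#' @param peaks interval data.frame of TF peaks.
#' @param tags interval data.frame of read positions.
#' @param stitch_bp stitching distance (default 12500).
#' @param control_tags optional interval data.frame of control/input reads;
#'   subtracted after scaling by the tag-depth ratio.
#' @param tss_exclusion optional promoter windows passed to
#'   [stitch_peaks()].
#' @param tag_mode `"five_prime"` or `"midpoint"`.
#' @return data.frame of stitched regions with `signal`, `rank`,
#'   `is_super`; attributes `"cutoff"` and `"degenerate"`.
#' @export
call_superenhancers <- function(peaks, tags, stitch_bp = 12500L,
                                control_tags = NULL, tss_exclusion = NULL,
                                tag_mode = "five_prime") {
  regions <- stitch_peaks(peaks, stitch_bp, tss_exclusion)
  if (nrow(regions) < 3L) stop_f("fewer than 3 stitched regions")
  count_in <- function(tg) {
    pos <- tag_positions(tg, tag_mode)
    iv <- gintervals(tg$chrom, pos, pos + 1)
    ov <- intersect_sets(regions, iv)
    tabulate(ov$index_a, nbins = nrow(regions))
  }
  signal <- count_in(tags)
  if (!is.null(control_tags) && nrow(control_tags)) {
    scale <- nrow(tags) / nrow(control_tags)
    signal <- pmax(0, signal - scale * count_in(control_tags))
  }
  regions$signal <- signal
  cut <- superenhancer_cutoff(signal)
  regions$rank <- rank(-signal, ties.method = "first")
  regions$is_super <- if (cut$degenerate) FALSE else signal > cut$cutoff
  regions <- regions[order(regions$rank), , drop = FALSE]
  rownames(regions) <- NULL
  attr(regions, "cutoff") <- cut$cutoff
  attr(regions, "degenerate") <- cut$degenerate
  regions
}
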