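# BED reading/writing with the error contract the pipeline needs:
# malformed lines are rejected with their line number, track/browser/comment
# lines are tolerated, and missing name/score columns get defaults.

#' Read a BED file into an interval table
#'
#' Accepts BED3 and wider. `track`, `browser`, `#` comment and blank lines
#' are skipped. Missing names become `"<chrom>:<start>-<end>"`; missing
#' scores become 0. Coordinates are kept 0-based half-open as in the file.
#'
#' @param path path to a BED file.
#' @param minimal_columns minimum number of columns a data line must have
#'   (default 3).
#' @return interval data.frame in file order (see [gintervals()]).
#' @export
parse_bed <- function(path, minimal_columns = 3L) {
  if (!file.exists(path)) stop_f("BED file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !(grepl("^(track|browser)\\b", lines) | grepl("^#", lines) | !nzchar(trimws(lines)))
  idx <- which(keep)
  if (!length(idx)) return(gintervals(character(), numeric(), numeric()))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < minimal_columns))
    stop_f("line %d: expected >= %d tab-separated columns, found %d",
           idx[which(nf < minimal_columns)[1]], minimal_columns, min(nf))
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) | end != floor(end))
  if (length(bad)) stop_f("line %d: non-integer coordinates", idx[bad[1]])
  bad <- which(end <= start)
  if (length(bad)) stop_f("line %d: end <= start", idx[bad[1]])
  name <- ifelse(nf >= 4L, vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else "", ""), "")
  score <- ifelse(nf >= 5L,
                  suppressWarnings(as.numeric(vapply(fields, function(f) if (length(f) >= 5L) f[[5L]] else "0", ""))),
                  0)
  score[is.na(score)] <- 0
  strand <- ifelse(nf >= 6L, vapply(fields, function(f) if (length(f) >= 6L) f[[6L]] else ".", ""), ".")
  strand[!strand %in% c("+", "-", ".")] <- "."
  name[!nzchar(name)] <- sprintf("%s:%.0f-%.0f", chrom, start, end)[!nzchar(name)]
  gintervals(chrom, start, end, name = name, score = score, strand = strand)
}

#' Write intervals to a BED6 file
#'
#' Round-trips exactly through [parse_bed()]: coordinates, names and scores
#' are preserved bit-for-bit.
#'
#' @param intervals interval data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(intervals)) {
    writeLines(sprintf("%s\t%.0f\t%.0f\t%s\t%s\t%s",
                       intervals$chrom, intervals$start,
                       intervals$end, intervals$name,
                       format(intervals$score, trim = TRUE, scientific = FALSE),
                       intervals$strand %||% "."), con)
  }
  invisible(path)
}
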