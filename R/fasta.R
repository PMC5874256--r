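# FASTA access with 0-based half-open semantics at the package boundary.

#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return a [Biostrings::DNAStringSet] named by the first word of each
#'   header.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop_f("FASTA not found: %s", path)
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Extract a subsequence in 0-based half-open coordinates
#'
#' @param genome a `DNAStringSet` from [read_genome()].
#' @param chrom chromosome name (exact match).
#' @param start,end 0-based half-open range; clipped to chromosome bounds
#'   with a warning when out of range.
#' @return character string of length `end - start` (or shorter if clipped).
#' @export
fetch_sequence <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) stop_f("chromosome %s not in FASTA", chrom)
  len <- length(genome[[chrom]])
  s <- max(0, start); e <- min(end, len)
  if (s != start || e != end) warning(sprintf("range %s:%d-%d clipped to chromosome bounds", chrom, start, end))
  if (e <= s) return("")
  as.character(Biostrings::subseq(genome[[chrom]], start = s + 1, end = e))
}
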