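# Peak-centered tag-density matrices and peak/gene-level overlap statistics.

# Collapse tag intervals to single-bp positions: strand-aware 5' ends
# (default) or midpoints.
tag_positions <- function(tags, mode = c("five_prime", "midpoint")) {
  mode <- match.arg(mode)
  if (mode == "five_prime") {
    ifelse(tags$strand == "-", tags$end - 1, tags$start)
  } else {
    floor((tags$start + tags$end) / 2)
  }
}

#' Peak-centered tag-density matrix
#'
#' Row `i`, column `j` counts tags whose (5'-end or midpoint) position falls
#' in `[center_i - flank + (j-1)*bin, center_i - flank + j*bin)`.
#'
#' @param centers interval data.frame; row centers anchor the windows.
#' @param tags interval data.frame of read positions.
#' @param flank half-window in bp (default 3000).
#' @param bin bin width in bp (default 100); must divide `flank`.
#' @param tag_mode `"five_prime"` (strand-aware, default) or `"midpoint"`.
#' @param per_million scale counts to tags-per-million sequenced (default
#'   FALSE).
#' @return object of class `tag_matrix`: `matrix` (regions x bins),
#'   `bin`, `flank`, `n_tags`.
#' @export
tag_density_matrix <- function(centers, tags, flank = 3000L, bin = 100L,
                               tag_mode = "five_prime", per_million = FALSE) {
  if (flank %% bin != 0) stop_f("flank must be divisible by bin")
  ncol <- 2L * flank %/% bin
  ctr <- floor((centers$start + centers$end) / 2)
  pos <- tag_positions(tags, tag_mode)
  mat <- matrix(0, nrow = nrow(centers), ncol = ncol)
  for (ch in unique(centers$chrom)) {
    p <- sort(pos[tags$chrom == ch])
    ri <- which(centers$chrom == ch)
    if (!length(p)) next
    for (i in ri) {
      edges <- ctr[i] - flank + bin * (0:ncol)
      mat[i, ] <- diff(findInterval(edges - 1, p))
    }
  }
  if (per_million) mat <- mat * 1e6 / max(1, nrow(tags))
  structure(list(matrix = mat, bin = bin, flank = flank, n_tags = nrow(tags)),
            class = "tag_matrix")
}

#' Peak-set overlap statistics
#'
#' Peak-to-peak overlap is many-to-many, so "shared" is reported from both
#' anchorings: `shared_a` peaks of A overlap >= 1 peak of B and vice versa.
#' The Venn-style `shared` count is anchored on B (by convention the
#' smaller set); both per-set shared fractions are reported so asymmetric
#' co-binding (a small factor occupying a sliver of a large peak set) is
#' expressible.
#'
#' @param a,b interval data.frames.
#' @return list: `n_a`, `n_b`, `shared_a`, `shared_b`, `only_a`, `only_b`,
#'   `frac_a_shared`, `frac_b_shared`, `venn` (only_a, shared, only_b;
#'   B-anchored).
#' @export
peakset_overlap <- function(a, b) {
  ov <- intersect_sets(a, b)
  shared_a <- length(unique(ov$index_a))
  shared_b <- length(unique(ov$index_b))
  list(n_a = nrow(a), n_b = nrow(b),
       shared_a = shared_a, shared_b = shared_b,
       only_a = nrow(a) - shared_a, only_b = nrow(b) - shared_b,
       frac_a_shared = if (nrow(a)) shared_a / nrow(a) else NA_real_,
       frac_b_shared = if (nrow(b)) shared_b / nrow(b) else NA_real_,
       venn = c(only_a = nrow(a) - shared_a, shared = shared_b,
                only_b = nrow(b) - shared_b))
}

#' Fraction of nearest-TSS target genes shared by two peak sets
#'
#' A gene is associated with a peak set iff it is the nearest-TSS gene of at
#' least one peak (by peak center).
#'
#' @param peaks_a,peaks_b interval data.frames.
#' @param genes a `gene_models` object.
#' @return list: `genes_a`, `genes_b` (sorted ids), `n_shared`, `jaccard`,
#'   `frac_a_shared`, `frac_b_shared`, `degenerate` flag for an empty set.
#' @export
gene_overlap_fraction <- function(peaks_a, peaks_b, genes) {
  gene_set <- function(p) {
    if (!nrow(p)) return(character())
    ctr <- floor((p$start + p$end) / 2)
    nt <- nearest_tss(p$chrom, ctr, genes)
    sort(unique(nt$gene_id[!is.na(nt$gene_id)]))
  }
  ga <- gene_set(peaks_a); gb <- gene_set(peaks_b)
  shared <- intersect(ga, gb)
  degenerate <- length(ga) == 0L || length(gb) == 0L
  list(genes_a = ga, genes_b = gb, n_shared = length(shared),
       jaccard = if (length(union(ga, gb))) length(shared) / length(union(ga, gb)) else 0,
       frac_a_shared = if (length(ga)) length(shared) / length(ga) else 0,
       frac_b_shared = if (length(gb)) length(shared) / length(gb) else 0,
       degenerate = degenerate)
}
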