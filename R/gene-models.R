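# Gene models and TSS-anchored annotation.
#
# A gene model set is an S3 object: list(genes = data.frame, exons = named
# list of 2-column matrices (start, end), 0-based half-open). The genes
# table carries gene_id, symbol, chrom, strand, tss, tes, tx_start, tx_end
# and (when the source provides them) cds_start/cds_end, which enable the
# 5'UTR/3'UTR annotation categories.

new_gene_models <- function(genes, exons) {
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes on %d chromosome(s)\n",
              nrow(x$genes), length(unique(x$genes$chrom))))
  invisible(x)
}

validate_gene <- function(gene_id, strand, exons) {
  if (nrow(exons) == 0L) stop_f("gene %s has zero exons", gene_id)
  if (length(strand) > 1L) stop_f("gene %s has mixed strands", gene_id)
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (nrow(exons) > 1L && any(exons[-1L, 1L] < exons[-nrow(exons), 2L]))
    stop_f("gene %s has overlapping exons", gene_id)
  exons
}

build_gene_table <- function(ids, symbols, chroms, strands, exon_list,
                             cds_start = NULL, cds_end = NULL) {
  tx_start <- vapply(exon_list, function(e) min(e[, 1L]), 0)
  tx_end <- vapply(exon_list, function(e) max(e[, 2L]), 0)
  # minus-strand TSS is the half-open end of the last exon (so a + gene
  # over [s,e) has tss = s and a - gene tss = e)
  tss <- ifelse(strands == "+", tx_start, tx_end)
  tes <- ifelse(strands == "+", tx_end, tx_start)
  genes <- data.frame(gene_id = ids, symbol = symbols, chrom = chroms,
                      strand = strands, tss = tss, tes = tes,
                      tx_start = tx_start, tx_end = tx_end,
                      stringsAsFactors = FALSE)
  if (!is.null(cds_start)) {
    genes$cds_start <- cds_start
    genes$cds_end <- cds_end
  }
  ord <- order(genes$gene_id)
  genes <- genes[ord, , drop = FALSE]
  rownames(genes) <- NULL
  new_gene_models(genes, exon_list[ord])
}

parse_gtf_attr <- function(attr, key) {
  pat <- sprintf('%s "([^"]*)"', key)
  m <- regexpr(pat, attr)
  out <- rep(NA_character_, length(attr))
  hit <- m != -1L
  out[hit] <- sub(pat, "\\1", regmatches(attr, m))
  out
}

#' Load gene models from GTF or refFlat
#'
#' GTF exon features (1-based inclusive) are converted to internal 0-based
#' half-open coordinates; the TSS is the strand-aware transcription start.
#' refFlat rows (geneName, name, chrom, strand, txStart, txEnd, cdsStart,
#' cdsEnd, exonCount, exonStarts, exonEnds) are already 0-based half-open.
#' One model is built per `gene_id` (GTF) / `name` (refFlat); genes with no
#' exons or mixed strands are rejected.
#'
#' @param path input file.
#' @param dialect `"gtf"` or `"refflat"`.
#' @return a `gene_models` object.
#' @export
load_gene_models <- function(path, dialect = c("gtf", "refflat")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_f("gene model file not found: %s", path)
  if (dialect == "gtf") load_gtf(path) else load_refflat(path)
}

load_gtf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  if (!length(lines)) stop_f("empty GTF: %s", path)
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 9L)) stop_f("GTF line with fewer than 9 fields")
  feature <- vapply(f, `[[`, "", 3L)
  keep <- feature == "exon"
  if (!any(keep)) stop_f("GTF contains no exon features")
  f <- f[keep]
  chrom <- vapply(f, `[[`, "", 1L)
  start1 <- as.numeric(vapply(f, `[[`, "", 4L))   # 1-based inclusive
  end1 <- as.numeric(vapply(f, `[[`, "", 5L))
  strand <- vapply(f, `[[`, "", 7L)
  attr9 <- vapply(f, `[[`, "", 9L)
  gene_id <- parse_gtf_attr(attr9, "gene_id")
  symbol <- parse_gtf_attr(attr9, "gene_name")
  if (anyNA(gene_id)) stop_f("GTF exon feature without gene_id attribute")
  symbol[is.na(symbol)] <- gene_id[is.na(symbol)]
  ids <- sort(unique(gene_id))
  exon_list <- vector("list", length(ids)); names(exon_list) <- ids
  chroms <- strands <- symbols <- character(length(ids))
  for (i in seq_along(ids)) {
    sel <- gene_id == ids[i]
    st <- unique(strand[sel])
    ex <- cbind(start = start1[sel] - 1, end = end1[sel])  # to 0-based half-open
    exon_list[[i]] <- validate_gene(ids[i], st, ex)
    if (length(unique(chrom[sel])) > 1L) stop_f("gene %s spans chromosomes", ids[i])
    chroms[i] <- chrom[sel][1L]; strands[i] <- st
    symbols[i] <- symbol[sel][1L]
  }
  build_gene_table(ids, symbols, chroms, strands, exon_list)
}

load_refflat <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("geneName", "name", "chrom", "strand",
                                         "txStart", "txEnd", "cdsStart", "cdsEnd",
                                         "exonCount", "exonStarts", "exonEnds"),
                           comment.char = "#")
  ids <- tab$name
  if (anyDuplicated(ids)) stop_f("duplicate refFlat gene ids")
  exon_list <- vector("list", nrow(tab)); names(exon_list) <- ids
  for (i in seq_len(nrow(tab))) {
    es <- as.numeric(strsplit(sub(",$", "", tab$exonStarts[i]), ",")[[1L]])
    ee <- as.numeric(strsplit(sub(",$", "", tab$exonEnds[i]), ",")[[1L]])
    if (!length(es)) stop_f("gene %s has zero exons", ids[i])
    if (length(es) != tab$exonCount[i]) stop_f("gene %s exonCount mismatch", ids[i])
    exon_list[[i]] <- validate_gene(ids[i], tab$strand[i], cbind(start = es, end = ee))
  }
  build_gene_table(ids, tab$geneName, tab$chrom, tab$strand, exon_list,
                   cds_start = tab$cdsStart, cds_end = tab$cdsEnd)
}

#' Nearest transcription start site
#'
#' For each query position, the same-chromosome gene minimizing the absolute
#' distance to its TSS. Ties are broken by the lexicographically smallest
#' `gene_id`, making assignment deterministic. The signed distance is
#' reported relative to gene orientation: negative upstream of the TSS,
#' positive downstream.
#'
#' @param chrom,pos query chromosome(s) and 0-based position(s); recycled to
#'   a common length.
#' @param genes a `gene_models` object.
#' @return data.frame with columns `chrom`, `pos`, `gene_id`, `symbol`,
#'   `signed_distance`; positions on chromosomes without genes get
#'   `NA` gene_id.
#' @export
nearest_tss <- function(chrom, pos, genes) {
  stopifnot(inherits(genes, "gene_models"))
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(as.character(chrom), n); pos <- rep_len(as.numeric(pos), n)
  g <- genes$genes
  if (nrow(g) == 0L) stop_f("no genes loaded")
  out_id <- rep(NA_character_, n); out_sym <- rep(NA_character_, n)
  out_d <- rep(NA_real_, n)
  for (ch in unique(chrom)) {
    qi <- which(chrom == ch)
    gi <- which(g$chrom == ch)
    if (!length(gi)) next
    tss <- g$tss[gi]; ids <- g$gene_id[gi]
    # genes table is sorted by gene_id, so the first index at the minimal
    # distance is the lexicographic tie-winner
    for (q in qi) {
      d <- abs(pos[q] - tss)
      j <- gi[which.min(d)]
      out_id[q] <- g$gene_id[j]; out_sym[q] <- g$symbol[j]
      out_d[q] <- if (g$strand[j] == "+") pos[q] - g$tss[j] else g$tss[j] - pos[q]
    }
  }
  data.frame(chrom = chrom, pos = pos, gene_id = out_id, symbol = out_sym,
             signed_distance = out_d, stringsAsFactors = FALSE)
}

#' Annotate peaks relative to gene anatomy
#'
#' Each peak is categorized by the position of its center with precedence
#' promoter-TSS > TTS > 5'UTR > 3'UTR > exon > intron > intergenic.
#' UTR categories require CDS coordinates (refFlat input); without them,
#' exonic positions are reported as `exon`. The nearest gene and the signed
#' TSS distance (strand-aware, negative upstream) are always reported.
#'
#' @param peaks interval data.frame.
#' @param genes a `gene_models` object.
#' @param promoter_window bp around the TSS counted as promoter (default 1000).
#' @param tts_window bp around the transcription end site counted as TTS
#'   (default 1000).
#' @return data.frame: peak columns plus `category`, `nearest_gene`,
#'   `symbol`, `signed_distance_to_tss`.
#' @export
annotate_peaks <- function(peaks, genes, promoter_window = 1000L, tts_window = 1000L) {
  stopifnot(promoter_window > 0)
  centers <- floor((peaks$start + peaks$end) / 2)
  nt <- nearest_tss(peaks$chrom, centers, genes)
  g <- genes$genes
  category <- rep("intergenic", nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    if (is.na(nt$gene_id[i])) next
    ch <- peaks$chrom[i]; p <- centers[i]
    if (abs(nt$signed_distance[i]) <= promoter_window) { category[i] <- "promoter-TSS"; next }
    gi <- which(g$chrom == ch)
    near_tts <- any(abs(p - g$tes[gi]) <= tts_window)
    if (near_tts) { category[i] <- "TTS"; next }
    host <- gi[g$tx_start[gi] <= p & p < g$tx_end[gi]]
    if (!length(host)) next
    j <- host[1L]
    ex <- genes$exons[[j]]
    in_exon <- any(ex[, 1L] <= p & p < ex[, 2L])
    if (!in_exon) { category[i] <- "intron"; next }
    if (!is.null(g$cds_start) && !is.na(g$cds_start[j]) && g$cds_start[j] < g$cds_end[j]) {
      if (p < g$cds_start[j]) {
        category[i] <- if (g$strand[j] == "+") "5'UTR" else "3'UTR"
        next
      }
      if (p >= g$cds_end[j]) {
        category[i] <- if (g$strand[j] == "+") "3'UTR" else "5'UTR"
        next
      }
    }
    category[i] <- "exon"
  }
  out <- peaks
  out$category <- category
  out$nearest_gene <- nt$gene_id
  out$symbol <- nt$symbol
  out$signed_distance_to_tss <- nt$signed_distance
  out
}

#' Distribution of peak-to-TSS distances
#'
#' Counts peaks by the absolute TSS distance of their centers into ordered
#' distance bins. The final bin is open-ended, so the bins partition
#' `[0, Inf)` and counts conserve the number of peaks (peaks on gene-less
#' chromosomes are reported separately as `unassigned`).
#'
#' @param peaks interval data.frame.
#' @param genes a `gene_models` object.
#' @param bin_edges_bp strictly increasing edges starting at 0; default
#'   `c(0, 1e3, 1e4, 1e5)` giving bins 0-1 kb, 1-10 kb, 10-100 kb, >100 kb.
#' @return list with `bins` (data.frame: label, lower, upper, count) and
#'   `unassigned` count.
#' @export
tss_distance_distribution <- function(peaks, genes, bin_edges_bp = c(0, 1e3, 1e4, 1e5)) {
  if (bin_edges_bp[1L] != 0 || any(diff(bin_edges_bp) <= 0))
    stop_f("bin edges must start at 0 and be strictly increasing")
  centers <- floor((peaks$start + peaks$end) / 2)
  nt <- nearest_tss(peaks$chrom, centers, genes)
  d <- abs(nt$signed_distance)
  edges <- c(bin_edges_bp, Inf)
  counts <- table(cut(d[!is.na(d)], breaks = edges, right = FALSE, include.lowest = TRUE))
  labels <- sprintf("[%s,%s)", format(edges[-length(edges)], trim = TRUE, scientific = FALSE),
                    format(edges[-1L], trim = TRUE, scientific = FALSE))
  list(bins = data.frame(label = labels,
                         lower = edges[-length(edges)], upper = edges[-1L],
                         count = as.integer(counts)),
       unassigned = sum(is.na(d)))
}
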