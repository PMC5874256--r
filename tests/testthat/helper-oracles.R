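# Independent brute-force oracles and small fixture builders. The oracles
# are deliberately naive (plain loops / O(n*m) scans) and never call the
# package paths they are used to check.

rand_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 2000, max_w = 60) {
  start <- sample.int(max_pos, n, replace = TRUE)
  w <- sample.int(max_w, n, replace = TRUE)
  gintervals(sample(chroms, n, replace = TRUE), start, start + w,
             name = sprintf("iv%03d", seq_len(n)),
             score = round(stats::runif(n, 0, 10), 3))
}

# all-vs-all overlap scan
bf_intersect <- function(a, b, min_ov = 1) {
  out <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
    if (ov >= min_ov)
      out[[length(out) + 1L]] <- data.frame(index_a = i, index_b = j, overlap_bp = ov)
  }
  if (!length(out)) return(data.frame(index_a = integer(), index_b = integer(),
                                      overlap_bp = numeric()))
  do.call(rbind, out)
}

# set of covered base positions per chromosome
bf_cover <- function(iv) {
  cov <- list()
  for (i in seq_len(nrow(iv))) {
    ch <- iv$chrom[i]
    cov[[ch]] <- union(cov[[ch]], seq(iv$start[i], iv$end[i] - 1))
  }
  lapply(cov, sort)
}

# exhaustive nearest-TSS scan over a plain gene table
bf_nearest <- function(chrom, pos, gene_df) {
  vapply(seq_along(chrom), function(i) {
    cand <- gene_df[gene_df$chrom == chrom[i], , drop = FALSE]
    if (!nrow(cand)) return(NA_character_)
    d <- abs(pos[i] - cand$tss)
    sort(cand$gene_id[d == min(d)])[1L]
  }, "")
}

# build a gene_models object by writing and re-reading a GTF
make_genes <- function(gene_id, chrom, strand, exons, symbol = gene_id) {
  chrom <- rep_len(chrom, length(gene_id))
  strand <- rep_len(strand, length(gene_id))
  symbol <- rep_len(symbol, length(gene_id))
  lines <- character()
  for (i in seq_along(gene_id)) {
    ex <- exons[[i]]  # 0-based half-open
    lines <- c(lines, sprintf(
      "%s\ttest\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; gene_name \"%s\";",
      chrom[i], ex[, 1] + 1L, ex[, 2], strand[i], gene_id[i], symbol[i]))
  }
  path <- withr::local_tempfile(fileext = ".gtf", .local_envir = parent.frame())
  writeLines(lines, path)
  load_gene_models(path, "gtf")
}

# exact hypergeometric upper tail by explicit subset enumeration
bf_hyper_tail <- function(k, K, n, N) {
  subsets <- utils::combn(N, n)
  hits <- colSums(subsets <= K)  # elements 1..K are the category
  mean(hits >= k)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
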