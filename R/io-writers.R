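# Writers for the text formats the pipeline emits and re-reads.

#' Write gene models as GTF
#'
#' Emits one `exon` feature per exon, 1-based inclusive coordinates, with
#' `gene_id` and `gene_name` attributes.
#'
#' @param genes a `gene_models` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path) {
  g <- genes$genes
  lines <- character(0)
  for (i in seq_len(nrow(g))) {
    ex <- genes$exons[[i]]
    lines <- c(lines, sprintf(
      "%s\tevnet\texon\t%.0f\t%.0f\t.\t%s\t.\tgene_id \"%s\"; gene_name \"%s\";",
      g$chrom[i], ex[, 1L] + 1, ex[, 2L], g$strand[i], g$gene_id[i], g$symbol[i]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write gene models as refFlat
#'
#' 0-based half-open refFlat columns; `cdsStart`/`cdsEnd` collapse to the
#' transcript start when no CDS is recorded (non-coding convention).
#'
#' @inheritParams write_gtf
#' @return `path`, invisibly.
#' @export
write_refflat <- function(genes, path) {
  g <- genes$genes
  lines <- vapply(seq_len(nrow(g)), function(i) {
    ex <- genes$exons[[i]]
    cds_s <- if (!is.null(g$cds_start)) g$cds_start[i] else g$tx_start[i]
    cds_e <- if (!is.null(g$cds_end)) g$cds_end[i] else g$tx_start[i]
    sprintf("%s\t%s\t%s\t%s\t%.0f\t%.0f\t%.0f\t%.0f\t%d\t%s\t%s",
            g$symbol[i], g$gene_id[i], g$chrom[i], g$strand[i],
            g$tx_start[i], g$tx_end[i], cds_s, cds_e, nrow(ex),
            paste0(sprintf("%.0f", ex[, 1L]), collapse = ",", recycle0 = TRUE),
            paste0(sprintf("%.0f", ex[, 2L]), collapse = ","))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a SNP panel as the canonical TSV
#'
#' Converts the internal 0-based position back to the 1-based `POS`
#' column.
#'
#' @param snps data.frame with `snp_id`, `chrom`, `pos` and `P_<group>`
#'   columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_snp_table <- function(snps, path) {
  pcols <- grep("^P_", names(snps), value = TRUE)
  out <- data.frame(SNP_ID = snps$snp_id, CHR = snps$chrom, POS = snps$pos + 1,
                    check.names = FALSE)
  for (pc in pcols) out[[pc]] <- snps[[pc]]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a gene-set collection as GMT
#'
#' @param collection named list of member vectors (optionally carrying a
#'   `description` attribute).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection), function(id) {
    m <- collection[[id]]
    paste(c(id, attr(m, "description") %||% id, as.character(m)), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write an expression matrix as TSV
#'
#' @param mat numeric matrix with gene symbols as rownames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(symbol = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix TSV
#'
#' @param path TSV with a `symbol` column followed by sample columns.
#' @return numeric matrix, symbols as rownames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE)
  m <- as.matrix(df[setdiff(names(df), "symbol")])
  rownames(m) <- df$symbol
  m
}
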