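# GWAS variant panels: six association groups (femoral neck / lumbar spine
# BMD, each for men / women / pooled samples), one P-value column per group.

#' Canonical association group labels
#'
#' Femoral-neck (FN) and lumbar-spine (LS) bone-mineral-density association
#' P-values, each reported for men, women and pooled samples.
#' @export
SNP_GROUPS <- c("FN_MEN", "FN_WOMEN", "FN_POOLED", "LS_MEN", "LS_WOMEN", "LS_POOLED")

#' Read a GWAS SNP summary table
#'
#' Expects a TSV with header `SNP_ID, CHR, POS` plus one `P_<group>` column
#' per association group (extra columns are ignored). `POS` is 1-based (GWAS
#' convention) and converted to the internal 0-based point position.
#'
#' @param path TSV file.
#' @return data.frame with `snp_id`, `chrom`, `pos` (0-based) and the
#'   `P_<group>` columns present in the file.
#' @export
read_snp_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  need <- c("SNP_ID", "CHR", "POS")
  if (!all(need %in% names(tab))) stop_f("SNP table must have columns %s", paste(need, collapse = ", "))
  pcols <- intersect(paste0("P_", SNP_GROUPS), names(tab))
  if (!length(pcols)) stop_f("SNP table has no P_<group> columns")
  out <- data.frame(snp_id = as.character(tab$SNP_ID), chrom = as.character(tab$CHR),
                    pos = as.numeric(tab$POS) - 1, stringsAsFactors = FALSE)
  if (anyDuplicated(out$snp_id)) stop_f("duplicate SNP ids in panel")
  for (pc in pcols) {
    p <- as.numeric(tab[[pc]])
    if (any(p < 0 | p > 1, na.rm = TRUE)) stop_f("column %s has P outside [0,1]", pc)
    out[[pc]] <- p
  }
  out
}

#' Filter variants on per-group association P-values
#'
#' A variant passes when its P-value is at or below `alpha` (inclusive
#' threshold) in at least one selected group; with `all_groups = TRUE` it
#' must pass in every selected group. All P-value columns are retained.
#'
#' @param variants data.frame from [read_snp_table()].
#' @param alpha significance threshold in (0, 1]; default 0.05 (`alpha = 1`
#'   degenerately retains every variant).
#' @param groups subset of [SNP_GROUPS] to consider; default: all groups
#'   present in the table.
#' @param all_groups require the threshold in every selected group rather
#'   than any (default `FALSE`).
#' @return the passing subset of `variants`.
#' @export
filter_snps_by_pvalue <- function(variants, alpha = 0.05, groups = NULL, all_groups = FALSE) {
  stopifnot(alpha > 0, alpha <= 1)
  have <- sub("^P_", "", grep("^P_", names(variants), value = TRUE))
  groups <- groups %||% have
  bad <- setdiff(groups, SNP_GROUPS)
  if (length(bad)) stop_f("unknown group label(s): %s", paste(bad, collapse = ", "))
  if (!all(groups %in% have)) stop_f("group(s) missing from table: %s",
                                     paste(setdiff(groups, have), collapse = ", "))
  pm <- as.matrix(variants[paste0("P_", groups)])
  hit <- pm <= alpha
  hit[is.na(hit)] <- FALSE
  keep <- if (all_groups) rowSums(hit) == length(groups) else rowSums(hit) > 0
  variants[keep, , drop = FALSE]
}
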