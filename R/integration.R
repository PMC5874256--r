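# The enhancer-variant integration pipeline: partition active enhancers by
# transcription-factor binding, overlay a filtered GWAS panel, assign genes
# by nearest TSS, and quantify the bound/non-bound SNP-density contrast.

#' Partition active enhancers by TF binding
#'
#' An H3K27Ac region is "bound" iff it shares at least one bp with at least
#' one TF ChIP-seq peak. A TF peak overlapping several enhancers contributes
#' a constituent to each (so the peak-in-enhancer count can exceed the
#' number of distinct peaks).
#'
#' @param h3k27ac_regions interval data.frame of active-enhancer regions.
#' @param tf_peaks interval data.frame of TF ChIP-seq peaks.
#' @param tf_label label stored on the classes (e.g. `"PU.1"`).
#' @return list with `enhancers` (the input regions plus `bound` flag and
#'   `n_tf_peaks`), `constituents` (enhancer index -> peak index pairs) and
#'   `counts` (n_bound, n_non_bound, n_total, n_tf_peaks_in_bound).
#' @export
partition_enhancers_by_tf <- function(h3k27ac_regions, tf_peaks, tf_label = "TF") {
  if (nrow(h3k27ac_regions) == 0L || nrow(tf_peaks) == 0L)
    stop_f("both enhancer regions and TF peaks must be non-empty")
  ov <- intersect_sets(h3k27ac_regions, tf_peaks)
  enh <- h3k27ac_regions
  enh$bound <- seq_len(nrow(enh)) %in% ov$index_a
  enh$n_tf_peaks <- tabulate(ov$index_a, nbins = nrow(enh))
  counts <- list(n_bound = sum(enh$bound),
                 n_non_bound = sum(!enh$bound),
                 n_total = nrow(enh),
                 n_tf_peaks_in_bound = nrow(ov))
  list(enhancers = enh, constituents = ov, counts = counts, tf_label = tf_label)
}

#' Overlay SNPs on partitioned enhancers
#'
#' A SNP lies in an enhancer iff `start <= pos < end` (half-open). SNPs
#' hitting both a bound and a non-bound enhancer are credited to the bound
#' class and flagged in `both_classes`.
#'
#' @param classes output of [partition_enhancers_by_tf()].
#' @param passing_variants filtered variant data.frame.
#' @return list with `assignments` (snp_id, enhancer index, enhancer name,
#'   bound flag; one row per SNP-enhancer hit), `bound_snps`,
#'   `non_bound_snps` (unique snp_id vectors, disjoint), `both_classes`
#'   (flagged snp_ids) and `counts`.
#' @export
overlay_snps_on_enhancers <- function(classes, passing_variants) {
  enh <- classes$enhancers
  v <- passing_variants
  snp_iv <- gintervals(v$chrom, v$pos, v$pos + 1, name = v$snp_id)
  ov <- intersect_sets(snp_iv, enh)
  assignments <- data.frame(snp_id = v$snp_id[ov$index_a],
                            enhancer_index = ov$index_b,
                            enhancer = enh$name[ov$index_b],
                            bound = enh$bound[ov$index_b],
                            stringsAsFactors = FALSE)
  in_bound <- unique(assignments$snp_id[assignments$bound])
  in_non_bound <- unique(assignments$snp_id[!assignments$bound])
  both <- intersect(in_bound, in_non_bound)
  non_bound_only <- setdiff(in_non_bound, in_bound)
  list(assignments = assignments,
       bound_snps = in_bound,
       non_bound_snps = non_bound_only,
       both_classes = both,
       counts = list(n_bound_snps = length(in_bound),
                     n_non_bound_snps = length(non_bound_only),
                     n_outside = nrow(v) - length(in_bound) - length(non_bound_only),
                     n_both_flagged = length(both)))
}

#' Assign nearest genes to overlaid SNPs
#'
#' Maps every class-assigned SNP to the gene with the nearest TSS and
#' produces de-duplicated per-class gene lists. SNPs on chromosomes without
#' genes are reported unassigned.
#'
#' @param overlay output of [overlay_snps_on_enhancers()].
#' @param variants the variant data.frame the overlay was computed from.
#' @param genes a `gene_models` object.
#' @return `overlay` extended with `gene_table` (snp_id, class, gene_id,
#'   symbol, signed_distance), `bound_genes`, `non_bound_genes` and
#'   `unassigned_snps`.
#' @export
assign_nearest_genes <- function(overlay, variants, genes) {
  ids <- c(overlay$bound_snps, overlay$non_bound_snps)
  cls <- rep(c("bound", "non_bound"),
             c(length(overlay$bound_snps), length(overlay$non_bound_snps)))
  v <- variants[match(ids, variants$snp_id), , drop = FALSE]
  nt <- nearest_tss(v$chrom, v$pos, genes)
  gene_table <- data.frame(snp_id = ids, class = cls, gene_id = nt$gene_id,
                           symbol = nt$symbol, signed_distance = nt$signed_distance,
                           stringsAsFactors = FALSE)
  overlay$gene_table <- gene_table
  overlay$bound_genes <- sort(unique(gene_table$gene_id[cls == "bound" & !is.na(gene_table$gene_id)]))
  overlay$non_bound_genes <- sort(unique(gene_table$gene_id[cls == "non_bound" & !is.na(gene_table$gene_id)]))
  overlay$unassigned_snps <- gene_table$snp_id[is.na(gene_table$gene_id)]
  overlay
}

#' TF peaks near passing SNPs
#'
#' Retains each TF peak for which some passing SNP lies within
#' `[start - window, end + window)` — i.e. the point-to-peak distance is at
#' most `window` bp, with the extended interval half-open on the right. The
#' retained peaks are then annotated with their nearest-TSS gene.
#'
#' @param tf_peaks interval data.frame.
#' @param passing_variants filtered variant data.frame.
#' @param window bp flank (default 500).
#' @param genes optional `gene_models`; when given, gene annotation is added.
#' @return list with `peaks` (retained subset, with `nearest_gene` when
#'   `genes` is supplied) and `genes` (unique gene ids, or NULL).
#' @export
peaks_near_snps <- function(tf_peaks, passing_variants, window = 500L, genes = NULL) {
  stopifnot(window >= 0)
  ext <- tf_peaks
  ext$start <- pmax(0, ext$start - window)
  ext$end <- ext$end + window
  snp_iv <- gintervals(passing_variants$chrom, passing_variants$pos,
                       passing_variants$pos + 1, name = passing_variants$snp_id)
  ov <- intersect_sets(ext, snp_iv)
  keep <- sort(unique(ov$index_a))
  peaks <- tf_peaks[keep, , drop = FALSE]
  gene_ids <- NULL
  if (!is.null(genes) && nrow(peaks)) {
    centers <- floor((peaks$start + peaks$end) / 2)
    nt <- nearest_tss(peaks$chrom, centers, genes)
    peaks$nearest_gene <- nt$gene_id
    gene_ids <- sort(unique(nt$gene_id[!is.na(nt$gene_id)]))
  }
  list(peaks = peaks, genes = gene_ids)
}

#' Bound vs non-bound SNP-density enrichment
#'
#' Tests whether SNP density (SNPs per enhancer bp) differs between bound
#' and non-bound enhancers via a 2x2 table of (SNPs, non-SNP bp) by class,
#' Fisher's exact test. With a zero cell the point estimate uses the
#' Haldane-Anscombe 0.5 correction and is flagged.
#'
#' @param overlay output of [overlay_snps_on_enhancers()].
#' @param classes output of [partition_enhancers_by_tf()].
#' @return list: `odds_ratio` (sample OR), `p_value`, `table`,
#'   `haldane_corrected` flag.
#' @export
bound_vs_unbound_enrichment <- function(overlay, classes) {
  enh <- classes$enhancers
  bp_bound <- sum(enh$end[enh$bound] - enh$start[enh$bound])
  bp_non <- sum(enh$end[!enh$bound] - enh$start[!enh$bound])
  if (bp_bound == 0 || bp_non == 0) stop_f("a class has zero enhancer bp")
  s_b <- length(overlay$bound_snps)
  s_n <- length(overlay$non_bound_snps)
  tab <- matrix(c(s_b, bp_bound - s_b, s_n, bp_non - s_n), nrow = 2, byrow = TRUE,
                dimnames = list(c("bound", "non_bound"), c("snp", "bp_without_snp")))
  haldane <- any(tab == 0)
  t2 <- if (haldane) tab + 0.5 else tab
  or <- (t2[1, 1] / t2[1, 2]) / (t2[2, 1] / t2[2, 2])
  p <- stats::fisher.test(round(tab))$p.value
  list(odds_ratio = or, p_value = p, table = tab, haldane_corrected = haldane)
}

#' Run the full enhancer-variant integration pipeline
#'
#' filter -> partition -> overlay -> gene assignment -> density enrichment
#' (-> optional functional enrichment), writing per-class outputs and a JSON
#' summary. Any stage error aborts with the stage name.
#'
#' @param config list with elements `h3k27ac` (BED path), `tf_peaks` (BED
#'   path), `snps` (TSV path), `genes` (path), `gene_dialect`, `alpha`,
#'   `groups`, `all_groups`, `window`, `tf_label`, `gene_sets` (optional GMT
#'   path), `seed`.
#' @param outdir output directory (created).
#' @return invisible list with all stage results plus `files` written.
#' @export
run_integration <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) stop_f("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  enh <- stage("load_enhancers", parse_bed(config$h3k27ac))
  tf <- stage("load_tf_peaks", parse_bed(config$tf_peaks))
  variants <- stage("load_snps", read_snp_table(config$snps))
  genes <- stage("load_genes", load_gene_models(config$genes,
                                                dialect = config$gene_dialect %||% "gtf"))
  passing <- stage("filter_snps",
                   filter_snps_by_pvalue(variants, alpha = config$alpha %||% 0.05,
                                         groups = config$groups,
                                         all_groups = isTRUE(config$all_groups)))
  classes <- stage("partition", partition_enhancers_by_tf(enh, tf, config$tf_label %||% "TF"))
  overlay <- stage("overlay", overlay_snps_on_enhancers(classes, passing))
  overlay <- stage("assign_genes", assign_nearest_genes(overlay, passing, genes))
  near <- stage("peaks_near_snps",
                peaks_near_snps(tf, passing, window = config$window %||% 500L, genes = genes))
  enrich <- stage("density_enrichment", bound_vs_unbound_enrichment(overlay, classes))

  files <- c(bound_enhancers = file.path(outdir, "bound_enhancers.bed"),
             non_bound_enhancers = file.path(outdir, "non_bound_enhancers.bed"),
             snp_assignments = file.path(outdir, "snp_assignments.tsv"),
             gene_lists = file.path(outdir, "snp_genes.tsv"),
             near_peaks = file.path(outdir, "peaks_near_snps.bed"),
             summary = file.path(outdir, "integration_summary.json"))
  e <- classes$enhancers
  write_bed(e[e$bound, , drop = FALSE], files[["bound_enhancers"]])
  write_bed(e[!e$bound, , drop = FALSE], files[["non_bound_enhancers"]])
  utils::write.table(overlay$assignments, files[["snp_assignments"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(overlay$gene_table, files[["gene_lists"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_bed(near$peaks[, c("chrom", "start", "end", "name", "score", "strand")],
            files[["near_peaks"]])
  config_echo <- config[setdiff(names(config), "seed")]
  for (pf in intersect(c("h3k27ac", "tf_peaks", "snps", "genes"), names(config_echo)))
    config_echo[[pf]] <- basename(config_echo[[pf]])  # keep the echo relocatable
  summary <- list(config = config_echo,
                  seed = config$seed,
                  n_variants = nrow(variants), n_passing = nrow(passing),
                  counts = c(classes$counts, overlay$counts),
                  n_bound_genes = length(overlay$bound_genes),
                  n_non_bound_genes = length(overlay$non_bound_genes),
                  n_peaks_near_snps = nrow(near$peaks),
                  odds_ratio = enrich$odds_ratio, fisher_p = enrich$p_value)
  jsonlite::write_json(summary, files[["summary"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(classes = classes, overlay = overlay, near = near,
                 enrichment = enrich, passing = passing, files = files))
}
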