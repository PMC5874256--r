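# Configuration-driven orchestration: emit the synthetic inputs, run every
# analysis stage in dependency order, checksum the outputs, and write a
# human-readable + machine-readable report.

#' Emit a complete synthetic input bundle
#'
#' Runs every generator, writes the exact text formats the analysis
#' modules read (FASTA, GTF, BED, TSV, GMT, JASPAR), records ground truth
#' as JSON, and self-audits: SNP class labels and enhancer bound flags are
#' re-derived from the emitted files by a brute-force scan and must match
#' the recorded truth exactly.
#'
#' @param config a `sim_config`.
#' @param outdir directory to populate.
#' @return invisible list: `files` (named paths), `truth`, and the
#'   in-memory simulation objects.
#' @export
simulate_all <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ga <- simulate_genome_annotation(config)
  land <- simulate_enhancer_landscape(config, ga$genes)
  panel <- simulate_snp_panel(config, land, ga$genes)
  mot <- simulate_sequences_with_motifs(config, ga$genome, panel$snps, panel$truth)
  tagsim <- simulate_tags(config)
  expr <- simulate_ortholog_expression(config)
  sets <- simulate_gene_sets(config, ga$genes$genes$gene_id,
                             spike = panel$truth$bound_genes)
  expr_sets <- simulate_gene_sets(config, rownames(expr$human),
                                  spike = names(which(expr$truth$shape == 1 &
                                                        expr$truth$concordant)))
  f <- c(genome = "genome.fa", genes_gtf = "genes.gtf", genes_refflat = "genes.refflat",
         h3k27ac = "h3k27ac.bed", tf_peaks = "tf_peaks.bed", snps = "snps.tsv",
         pwm = "motif.jaspar", se_peaks = "se_peaks.bed", tags = "tags.bed",
         expr_mouse = "expr_mouse.tsv", expr_human = "expr_human.tsv",
         gene_sets = "gene_sets.gmt", expr_sets = "expr_sets.gmt",
         truth = "truth.json")
  files <- stats::setNames(file.path(outdir, f), names(f))
  Biostrings::writeXStringSet(mot$genome, files[["genome"]], width = 80L)
  write_gtf(ga$genes, files[["genes_gtf"]])
  write_refflat(ga$genes, files[["genes_refflat"]])
  write_bed(land$enhancers, files[["h3k27ac"]])
  write_bed(land$tf_peaks, files[["tf_peaks"]])
  write_snp_table(panel$snps, files[["snps"]])
  write_jaspar_counts(files[["pwm"]])
  write_bed(tagsim$peaks, files[["se_peaks"]])
  write_bed(tagsim$tags, files[["tags"]])
  write_expression_tsv(expr$mouse, files[["expr_mouse"]])
  write_expression_tsv(expr$human, files[["expr_human"]])
  write_gmt(sets, files[["gene_sets"]])
  write_gmt(expr_sets, files[["expr_sets"]])
  truth <- list(enhancer_bound = land$truth$bound,
                snp_class = as.list(panel$truth$class),
                snp_associated = as.list(panel$truth$associated),
                bound_snps = panel$truth$bound_snps,
                non_bound_snps = panel$truth$non_bound_snps,
                bound_lead_snps = panel$truth$bound_lead_snps,
                non_bound_lead_snps = panel$truth$non_bound_lead_snps,
                bound_genes = panel$truth$bound_genes,
                non_bound_genes = panel$truth$non_bound_genes,
                motif_instances = mot$truth,
                se_peaks = tagsim$truth$se_peaks,
                concordant_tfs = names(which(expr$truth$concordant)),
                expr_shape = as.list(expr$truth$shape))
  jsonlite::write_json(truth, files[["truth"]], auto_unbox = TRUE, digits = NA)
  audit_simulation(files, truth)
  invisible(list(files = files, truth = truth, config = config,
                 genome = mot$genome, genes = ga$genes, landscape = land,
                 panel = panel, motifs = mot, tagsim = tagsim, expr = expr,
                 gene_sets = sets, expr_sets = expr_sets))
}

# The default simulated motif, written as a JASPAR count matrix.
write_jaspar_counts <- function(path) {
  consensus <- c("A", "A", "A", "G", "A", "G", "G", "A", "A", "G")
  counts <- matrix(1, 4, length(consensus), dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(consensus)) counts[consensus[j], j] <- 97
  lines <- c(">PU1_like synthetic",
             vapply(rownames(counts), function(b)
               sprintf("%s [ %s ]", b, paste(counts[b, ], collapse = " ")), ""))
  writeLines(lines, path)
  invisible(path)
}

# Re-derive labels from the emitted files with plain linear scans and
# compare against recorded truth.
audit_simulation <- function(files, truth) {
  enh <- parse_bed(files[["h3k27ac"]])
  tf <- parse_bed(files[["tf_peaks"]])
  bound <- vapply(seq_len(nrow(enh)), function(i) {
    sel <- tf$chrom == enh$chrom[i]
    any(tf$start[sel] < enh$end[i] & enh$start[i] < tf$end[sel])
  }, TRUE)
  if (!identical(bound, unlist(truth$enhancer_bound, use.names = FALSE)))
    stop_f("simulation self-audit failed: enhancer bound flags")
  snps <- read_snp_table(files[["snps"]])
  class <- vapply(seq_len(nrow(snps)), function(i) {
    sel <- enh$chrom == snps$chrom[i] & enh$start <= snps$pos[i] & snps$pos[i] < enh$end
    if (!any(sel)) return("outside")
    if (any(bound[sel])) "bound" else "non_bound"
  }, "")
  if (!identical(class, unlist(truth$snp_class, use.names = FALSE)))
    stop_f("simulation self-audit failed: SNP class labels")
  invisible(TRUE)
}

pipeline_stages <- c("simulate", "integrate", "motif-density", "enrich",
                     "gsea", "tagmatrix", "superenhancer", "kinetics")

#' Run the configured pipeline end to end
#'
#' Stages run in dependency order (`simulate` first; every analysis stage
#' reads the emitted files, never in-memory objects, so each stage is
#' independently reproducible). Any stage failure aborts with the stage
#' name. A run manifest (config echo, seed, package version, per-file md5
#' checksums) is written last; identical config + seed give identical
#' checksums for every data file.
#'
#' @param config a YAML file path or an equivalent nested list; see the
#'   packaged `demo_config.yaml`. Must contain a `seed` unless `seed` is
#'   given.
#' @param outdir output directory.
#' @param seed optional override of the config seed.
#' @param stages subset of stages to run (default: all).
#' @return invisible manifest list.
#' @export
run_config <- function(config, outdir, seed = NULL, stages = pipeline_stages) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad)) stop_f("unknown stage(s): %s", paste(bad, collapse = ", "))
  seed <- seed %||% config$seed
  if (is.null(seed)) stop_f("config validation: 'seed' is required")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  scfg <- do.call(sim_config, c(list(seed = seed), config$simulate))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) stop_f("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  results <- list(seed = seed)
  sim_dir <- file.path(outdir, "sim")
  sim_files <- stats::setNames(
    file.path(sim_dir, c("genome.fa", "genes.gtf", "h3k27ac.bed", "tf_peaks.bed",
                         "snps.tsv", "motif.jaspar", "se_peaks.bed", "tags.bed",
                         "expr_mouse.tsv", "expr_human.tsv", "gene_sets.gmt",
                         "expr_sets.gmt", "truth.json")),
    c("genome", "genes_gtf", "h3k27ac", "tf_peaks", "snps", "pwm", "se_peaks",
      "tags", "expr_mouse", "expr_human", "gene_sets", "expr_sets", "truth"))
  if ("simulate" %in% stages)
    stage("simulate", simulate_all(scfg, sim_dir))
  if (!file.exists(sim_files[["snps"]]))
    stop_f("stage inputs missing: run the 'simulate' stage first")
  icfg <- config$integrate %||% list()
  if ("integrate" %in% stages) {
    results$integration <- stage("integrate", run_integration(
      list(h3k27ac = sim_files[["h3k27ac"]], tf_peaks = sim_files[["tf_peaks"]],
           snps = sim_files[["snps"]], genes = sim_files[["genes_gtf"]],
           gene_dialect = "gtf", alpha = icfg$alpha %||% scfg$alpha,
           all_groups = isTRUE(icfg$all_groups), window = icfg$window %||% 500L,
           tf_label = icfg$tf_label %||% "TF", seed = seed),
      file.path(outdir, "integration")))
  }
  if ("motif-density" %in% stages) {
    results$motif <- stage("motif-density", run_motif_stage(
      sim_files, config$motif %||% list(), file.path(outdir, "motif")))
  }
  if ("enrich" %in% stages) {
    results$enrich <- stage("enrich", run_enrich_stage(
      sim_files, file.path(outdir, "enrich")))
  }
  if ("gsea" %in% stages) {
    gcfg <- config$gsea %||% list()
    results$gsea <- stage("gsea", run_gsea_stage(
      sim_files, n_perm = gcfg$n_perm %||% 1000L, seed = child_seed(seed, 11),
      file.path(outdir, "gsea")))
  }
  if ("tagmatrix" %in% stages) {
    tcfg <- config$tagmatrix %||% list()
    results$tagmatrix <- stage("tagmatrix", run_tagmatrix_stage(
      sim_files, k = tcfg$k %||% 2L, seed = child_seed(seed, 12),
      file.path(outdir, "tagmatrix")))
  }
  if ("superenhancer" %in% stages) {
    results$superenhancer <- stage("superenhancer", run_superenhancer_stage(
      sim_files, config$superenhancer %||% list(), file.path(outdir, "superenhancer")))
  }
  if ("kinetics" %in% stages) {
    kcfg <- config$kinetics %||% list()
    results$kinetics <- stage("kinetics", run_kinetics_stage(
      sim_files, r_min = kcfg$r_min %||% scfg$r_min, k = kcfg$k %||% 4L,
      seed = child_seed(seed, 13), file.path(outdir, "kinetics")))
  }
  manifest <- write_manifest(config, seed, outdir)
  report <- write_report(manifest, results, outdir)
  invisible(c(manifest, list(results = results, report = report)))
}

run_motif_stage <- function(sim_files, mcfg, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  genome <- read_genome(sim_files[["genome"]])
  pwms <- load_pwms(sim_files[["pwm"]])
  truth <- jsonlite::read_json(sim_files[["truth"]])
  snps <- read_snp_table(sim_files[["snps"]])
  window <- mcfg$window %||% 500L
  # anchor on the lead (sentinel) SNP per enhancer: co-located tagging
  # SNPs share one binding site and would double-count it
  pos_of <- function(ids) snps[match(unlist(ids), snps$snp_id), c("chrom", "pos", "snp_id")]
  fg_pos <- pos_of(truth$bound_lead_snps); names(fg_pos)[3] <- "name"
  bg_pos <- pos_of(truth$non_bound_lead_snps); names(bg_pos)[3] <- "name"
  fg <- positional_density_profile(hits_around_positions(genome, fg_pos, window, pwms),
                                   bin_bp = mcfg$bin_bp %||% 25L)
  bg <- positional_density_profile(hits_around_positions(genome, bg_pos, window, pwms),
                                   bin_bp = mcfg$bin_bp %||% 25L)
  enr <- motif_enrichment_ratio(fg, bg, core_bp = mcfg$core_bp %||% 150L)
  utils::write.table(fg$bins, file.path(outdir, "profile_bound.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bg$bins, file.path(outdir, "profile_non_bound.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(core_mass_bound = enr$core_mass_fg, ratio = enr$ratio,
                            binomial_p = enr$binomial_p, n_fg = fg$n_positions,
                            n_bg = bg$n_positions),
                       file.path(outdir, "motif_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  list(profile_fg = fg, profile_bg = bg, enrichment = enr)
}

run_enrich_stage <- function(sim_files, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  truth <- jsonlite::read_json(sim_files[["truth"]])
  genes <- load_gene_models(sim_files[["genes_gtf"]], "gtf")
  collection <- read_gmt(sim_files[["gene_sets"]])
  res <- enrich_gene_list(unlist(truth$bound_genes), collection, genes$genes$gene_id)
  utils::write.table(res, file.path(outdir, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  res
}

run_gsea_stage <- function(sim_files, n_perm, seed, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  mouse <- read_expression_tsv(sim_files[["expr_mouse"]])
  collection <- read_gmt(sim_files[["expr_sets"]])
  nt <- ncol(mouse)
  late <- colnames(mouse)[(nt %/% 2 + 1):nt]
  early <- colnames(mouse)[1:(nt %/% 2)]
  ranked <- rank_genes_by_contrast(mouse, late, early, metric = "signal2noise")
  res <- gsea_significance(ranked, collection, n_perm = n_perm, seed = seed)
  utils::write.table(res, file.path(outdir, "gsea.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  res
}

run_tagmatrix_stage <- function(sim_files, k, seed, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  peaks <- parse_bed(sim_files[["se_peaks"]])
  tags <- parse_bed(sim_files[["tags"]])
  tm <- tag_density_matrix(peaks, tags)
  km <- centered_kmeans(tm$matrix, k = k, seed = seed)
  out <- data.frame(peak = peaks$name, cluster = km$cluster, order = order(km$order))
  utils::write.table(cbind(out, as.data.frame(tm$matrix)),
                     file.path(outdir, "tag_matrix.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(tag_matrix = tm, kmeans = km)
}

run_superenhancer_stage <- function(sim_files, secfg, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  peaks <- parse_bed(sim_files[["se_peaks"]])
  tags <- parse_bed(sim_files[["tags"]])
  calls <- call_superenhancers(peaks, tags, stitch_bp = secfg$stitch_bp %||% 12500L)
  utils::write.table(calls[c("chrom", "start", "end", "name", "n_constituents",
                             "constituents", "signal", "rank", "is_super")],
                     file.path(outdir, "superenhancers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_bed(calls[calls$is_super, c("chrom", "start", "end", "name", "score", "strand")],
            file.path(outdir, "superenhancers.bed"))
  calls
}

run_kinetics_stage <- function(sim_files, r_min, k, seed, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  mouse <- read_expression_tsv(sim_files[["expr_mouse"]])
  human <- read_expression_tsv(sim_files[["expr_human"]])
  retained <- orthologous_similarity_filter(mouse, human, r_min = r_min)
  clusters <- cluster_kinetics(retained, mouse, human, k = k, seed = seed)
  out <- cbind(retained, cluster = clusters$assignment[retained$mouse_symbol])
  utils::write.table(out, file.path(outdir, "kinetics_clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(retained = retained, clusters = clusters)
}

write_manifest <- function(config, seed, outdir) {
  files <- list.files(outdir, recursive = TRUE, full.names = TRUE)
  files <- files[!basename(files) %in% c("run_manifest.json", "report.txt", "report.json")]
  sums <- tools::md5sum(files)
  manifest <- list(config = config, seed = seed,
                   version = as.character(utils::packageVersion("evnet")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   files = data.frame(path = sub(paste0("^", outdir, "/?"), "", files),
                                      md5 = unname(sums)))
  jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

#' Write the run report
#'
#' Plain-text and JSON summaries of the headline quantities of a run:
#' per-class SNP/gene counts, top enrichments, motif central-core mass,
#' superenhancer count, retained-ortholog count.
#'
#' @param manifest manifest list from a run.
#' @param results per-stage results list.
#' @param outdir directory to write `report.txt` / `report.json` into.
#' @return invisible list (the JSON payload).
#' @export
write_report <- function(manifest, results, outdir) {
  j <- list(seed = results$seed)
  lines <- c("evnet run report", sprintf("seed: %s", results$seed), "")
  if (!is.null(results$integration)) {
    ct <- results$integration$overlay$counts
    pc <- results$integration$classes$counts
    j$integration <- c(pc, ct,
                       list(odds_ratio = results$integration$enrichment$odds_ratio,
                            fisher_p = results$integration$enrichment$p_value))
    lines <- c(lines, "[integration]",
               sprintf("  enhancers: %d bound / %d non-bound of %d",
                       pc$n_bound, pc$n_non_bound, pc$n_total),
               sprintf("  unique SNPs: %d in bound, %d in non-bound enhancers",
                       ct$n_bound_snps, ct$n_non_bound_snps),
               sprintf("  bound-class genes: %d; density odds ratio %.2f (Fisher P %.3g)",
                       length(results$integration$overlay$bound_genes),
                       results$integration$enrichment$odds_ratio,
                       results$integration$enrichment$p_value), "")
  }
  if (!is.null(results$motif)) {
    e <- results$motif$enrichment
    j$motif <- list(core_mass = e$core_mass_fg, ratio = e$ratio, p = e$binomial_p)
    lines <- c(lines, "[motif density]",
               sprintf("  central-core hit mass (bound class): %.2f", e$core_mass_fg),
               sprintf("  bound/non-bound core density ratio: %.2f", e$ratio), "")
  }
  if (!is.null(results$enrich) && nrow(results$enrich)) {
    top <- results$enrich[1, ]
    j$enrich <- list(top_set = top$set_id, p = top$p, q = top$q)
    lines <- c(lines, "[gene-set enrichment]",
               sprintf("  top set %s: k=%d/%d, P=%.3g, q=%.3g",
                       top$set_id, top$k, top$K, top$p, top$q), "")
  }
  if (!is.null(results$gsea) && nrow(results$gsea)) {
    top <- results$gsea[1, ]
    j$gsea <- list(top_set = top$set_id, es = top$es, nes = top$nes, p = top$p)
    lines <- c(lines, "[GSEA]",
               sprintf("  top set %s: ES=%.2f, NES=%.2f, P=%.3g",
                       top$set_id, top$es, top$nes, top$p), "")
  }
  if (!is.null(results$superenhancer)) {
    n_super <- sum(results$superenhancer$is_super)
    j$superenhancer <- list(n_regions = nrow(results$superenhancer), n_super = n_super)
    lines <- c(lines, "[superenhancers]",
               sprintf("  %d stitched regions, %d called super",
                       nrow(results$superenhancer), n_super), "")
  }
  if (!is.null(results$kinetics)) {
    j$kinetics <- list(n_retained = nrow(results$kinetics$retained))
    lines <- c(lines, "[kinetics]",
               sprintf("  %d orthologs retained as kinetically concordant",
                       nrow(results$kinetics$retained)), "")
  }
  writeLines(lines, file.path(outdir, "report.txt"))
  jsonlite::write_json(j, file.path(outdir, "report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(j)
}
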