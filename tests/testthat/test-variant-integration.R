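# Variant filtering and the enhancer-variant integration pipeline.

make_panel <- function(snp_id, chrom, pos, p = NULL) {
  df <- data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                   stringsAsFactors = FALSE)
  if (is.null(p)) p <- matrix(0.01, nrow(df), 6)
  colnames(p) <- paste0("P_", SNP_GROUPS)
  cbind(df, as.data.frame(p))
}

test_that("P-value filter is inclusive, per-group, and validates labels", {
  p <- rbind(c(0.04, 0.9, 0.9, 0.9, 0.9, 0.9),
             rep(0.05, 6),
             rep(0.9, 6))
  v <- make_panel(c("rs1", "rs2", "rs3"), "chr1", c(10, 20, 30), p)
  kept <- filter_snps_by_pvalue(v, alpha = 0.05)
  expect_setequal(kept$snp_id, c("rs1", "rs2"))  # 0.05 is retained (inclusive)
  expect_true(all(paste0("P_", SNP_GROUPS) %in% names(kept)))
  # all-groups rule
  expect_equal(filter_snps_by_pvalue(v, all_groups = TRUE)$snp_id, "rs2")
  expect_error(filter_snps_by_pvalue(v, groups = "FN_CHILDREN"), "unknown group")
  # degenerate threshold keeps everything
  expect_equal(nrow(filter_snps_by_pvalue(v, alpha = 1)), 3L)
})

test_that("uniform-null P-values pass a single-group filter at ~alpha rate", {
  withr::local_seed(99)
  n <- 10000
  p <- matrix(stats::runif(n * 6), n, 6)
  v <- make_panel(sprintf("rs%05d", 1:n), "chr1", seq_len(n), p)
  kept <- filter_snps_by_pvalue(v, alpha = 0.05, groups = "FN_MEN")
  expect_lt(abs(nrow(kept) / n - 0.05), 3 * sqrt(0.05 * 0.95 / n))
  # lowering alpha never enlarges the passing set
  stricter <- filter_snps_by_pvalue(v, alpha = 0.01, groups = "FN_MEN")
  expect_true(all(stricter$snp_id %in% kept$snp_id))
})

test_that("SNP table reader converts 1-based POS and checks structure", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(c("SNP_ID", "CHR", "POS", paste0("P_", SNP_GROUPS), "EXTRA"), collapse = "\t"),
               paste(c("rs1", "chr1", "101", rep("0.5", 6), "x"), collapse = "\t")), path)
  v <- read_snp_table(path)
  expect_equal(v$pos, 100)           # internal 0-based
  expect_false("EXTRA" %in% names(v))
  writeLines(c(paste(c("SNP_ID", "CHR", "POS", "P_FN_MEN"), collapse = "\t"),
               paste(c("rs1", "chr1", "101", "1.5"), collapse = "\t")), path)
  expect_error(read_snp_table(path), "outside")
})

test_that("enhancer partition reflects >=1 bp TF overlap and conserves counts", {
  enh <- gintervals("chr1", c(0, 1000, 2000), c(500, 1500, 2500), name = c("e1", "e2", "e3"))
  tf <- gintervals("chr1", c(100, 1400), c(200, 1450), name = c("p1", "p2"))
  cls <- partition_enhancers_by_tf(enh, tf)
  expect_equal(cls$enhancers$bound, c(TRUE, TRUE, FALSE))
  expect_equal(cls$counts$n_bound + cls$counts$n_non_bound, 3L)
  # one peak spanning two adjacent enhancers contributes to both
  enh2 <- gintervals("chr1", c(0, 500), c(500, 1000), name = c("a", "b"))
  spanning <- gintervals("chr1", 400, 600, name = "span")
  cls2 <- partition_enhancers_by_tf(enh2, spanning)
  expect_equal(cls2$counts$n_bound, 2L)
  expect_equal(cls2$counts$n_tf_peaks_in_bound, 2L)
  expect_error(partition_enhancers_by_tf(enh[0, ], tf), "non-empty")
})

test_that("overlay uses half-open membership and credits dual hits to bound", {
  enh <- gintervals("chr1", c(100, 200, 150), c(200, 300, 250),
                    name = c("bound1", "nb1", "nb2"))
  tf <- gintervals("chr1", 120, 130)
  cls <- partition_enhancers_by_tf(enh, tf)
  v <- make_panel(c("at_start", "at_end", "in_both", "outside"),
                  "chr1", c(100, 300, 180, 999))
  ov <- overlay_snps_on_enhancers(cls, v)
  expect_true("at_start" %in% ov$bound_snps)        # pos == start is inside
  expect_false("at_end" %in% c(ov$bound_snps, ov$non_bound_snps))  # pos == end is not
  expect_true("in_both" %in% ov$bound_snps)         # dual-class SNP -> bound
  expect_false("in_both" %in% ov$non_bound_snps)
  expect_equal(ov$both_classes, "in_both")
  expect_equal(ov$counts$n_outside, 2L)
})

test_that("overlay counts recover a constructed planting exactly", {
  withr::local_seed(21)
  enh <- gintervals("chr1", seq(0, 999000, by = 1000), seq(400, 999400, by = 1000),
                    name = sprintf("e%04d", 1:1000))
  tf <- gintervals("chr1", enh$start[1:400] + 10, enh$start[1:400] + 60)
  cls <- partition_enhancers_by_tf(enh, tf)
  pos <- c(enh$start[sample(1:400, 300, replace = TRUE)] + 100,        # bound
           enh$start[sample(401:1000, 100, replace = TRUE)] + 100,     # non-bound
           700 + 1000 * (0:599))                                       # gaps
  v <- make_panel(sprintf("rs%04d", seq_along(pos)), "chr1", pos)
  ov <- overlay_snps_on_enhancers(cls, v)
  expect_equal(ov$counts$n_bound_snps, 300L)
  expect_equal(ov$counts$n_non_bound_snps, 100L)
})

test_that("gene assignment de-duplicates and matches the brute-force scan", {
  g <- make_genes(c("gA", "gB"), "chr1", c("+", "+"),
                  list(cbind(1000, 2000), cbind(9000, 9500)))
  enh <- gintervals("chr1", c(900, 1200), c(1100, 1400), name = c("e1", "e2"))
  tf <- gintervals("chr1", c(950, 1250), c(1000, 1300))
  cls <- partition_enhancers_by_tf(enh, tf)
  v <- make_panel(c("rs1", "rs2"), "chr1", c(950, 1250))
  ov <- assign_nearest_genes(overlay_snps_on_enhancers(cls, v), v, g)
  expect_equal(ov$bound_genes, "gA")   # two SNPs, one unique gene
  expect_identical(ov$gene_table$gene_id,
                   bf_nearest(rep("chr1", 2), c(950, 1250), g$genes))
})

test_that("peaks_near_snps windows are half-open on the right", {
  peaks <- gintervals("chr1", 1000, 1100, name = "pk")
  at_left_edge <- make_panel("rs1", "chr1", 500)
  expect_equal(nrow(peaks_near_snps(peaks, at_left_edge, window = 500)$peaks), 1L)
  at_right_limit <- make_panel("rs1", "chr1", 1600)
  expect_equal(nrow(peaks_near_snps(peaks, at_right_limit, window = 500)$peaks), 0L)
  just_inside <- make_panel("rs1", "chr1", 1599)
  expect_equal(nrow(peaks_near_snps(peaks, just_inside, window = 500)$peaks), 1L)
  # window 0 degenerates to SNP-inside-peak
  inside <- make_panel("rs1", "chr1", 1000)
  outside <- make_panel("rs1", "chr1", 1100)
  expect_equal(nrow(peaks_near_snps(peaks, inside, window = 0)$peaks), 1L)
  expect_equal(nrow(peaks_near_snps(peaks, outside, window = 0)$peaks), 0L)
})

test_that("peaks_near_snps equals a brute-force distance check and is monotone", {
  withr::local_seed(31)
  peaks <- rand_intervals(60)
  v <- make_panel(sprintf("rs%03d", 1:80), sample(c("chr1", "chr2"), 80, replace = TRUE),
                  sample.int(2100, 80))
  for (w in c(0, 10, 50)) {
    got <- peaks_near_snps(peaks, v, window = w)$peaks$name
    keep <- vapply(seq_len(nrow(peaks)), function(i) {
      sel <- v$chrom == peaks$chrom[i]
      any(v$pos[sel] >= peaks$start[i] - w & v$pos[sel] < peaks$end[i] + w)
    }, TRUE)
    expect_identical(got, peaks$name[keep])
  }
  narrow <- peaks_near_snps(peaks, v, window = 10)$peaks$name
  wide <- peaks_near_snps(peaks, v, window = 50)$peaks$name
  expect_true(all(narrow %in% wide))  # widening never shrinks the set
})

test_that("density enrichment gives OR=1, P=1 on a balanced table", {
  enh <- gintervals("chr1", c(0, 100), c(20, 120), name = c("b", "n"))
  tf <- gintervals("chr1", 0, 5)
  cls <- partition_enhancers_by_tf(enh, tf)
  v <- make_panel(sprintf("rs%02d", 1:20), "chr1", c(0:9, 100:109))
  ov <- overlay_snps_on_enhancers(cls, v)
  enr <- bound_vs_unbound_enrichment(ov, cls)
  expect_equal(unname(enr$table[1, ]), c(10, 10))
  expect_equal(unname(enr$table[2, ]), c(10, 10))
  expect_equal(enr$odds_ratio, 1)
  expect_equal(enr$p_value, 1)
  expect_false(enr$haldane_corrected)
})

test_that("run_integration recovers fixture truth and reruns byte-identically", {
  cfg <- sim_config(seed = 77, n_snps = 2000, n_enhancers = 300, n_genes = 80,
                    n_tf_only_peaks = 100, tag_depth = 50000, n_background_peaks = 150)
  simdir <- withr::local_tempdir()
  sim <- simulate_all(cfg, simdir)
  icfg <- list(h3k27ac = sim$files[["h3k27ac"]], tf_peaks = sim$files[["tf_peaks"]],
               snps = sim$files[["snps"]], genes = sim$files[["genes_gtf"]],
               gene_dialect = "gtf", alpha = 0.05, seed = 77)
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  res <- run_integration(icfg, out1)
  expect_equal(res$classes$counts$n_bound, sum(sim$truth$enhancer_bound))
  expect_setequal(res$overlay$bound_snps, sim$truth$bound_snps)
  expect_setequal(res$overlay$non_bound_snps, sim$truth$non_bound_snps)
  expect_equal(res$overlay$bound_genes, sim$truth$bound_genes)
  expect_equal(res$overlay$non_bound_genes, sim$truth$non_bound_genes)
  run_integration(icfg, out2)
  for (f in names(res$files)) {
    expect_identical(unname(tools::md5sum(file.path(out1, basename(res$files[[f]])))),
                     unname(tools::md5sum(file.path(out2, basename(res$files[[f]])))))
  }
  # a broken stage aborts with the stage name
  bad <- icfg; bad$snps <- file.path(simdir, "missing.tsv")
  expect_error(suppressWarnings(run_integration(bad, withr::local_tempdir())), "load_snps")
})
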