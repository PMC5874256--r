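# Tag matrices, centered K-means, overlap statistics, superenhancers.

test_that("tag matrix places tags in the right bins and conserves totals", {
  center <- gintervals("chr1", 10000, 10200)  # center at 10100
  tags <- gintervals("chr1", 10100, 10101, strand = "+")
  tm <- tag_density_matrix(center, tags, flank = 3000, bin = 100)
  expect_equal(ncol(tm$matrix), 60L)
  expect_equal(tm$matrix[1, 31], 1)  # offset 3000 falls in column 31
  expect_equal(sum(tm$matrix), 1)
  expect_error(tag_density_matrix(center, tags, flank = 3000, bin = 70), "divisible")

  withr::local_seed(33)
  centers <- gintervals("chr1", seq(5000, 95000, by = 5000),
                        seq(5200, 95200, by = 5000))
  pos <- sample.int(100000, 5000, replace = TRUE)
  tags <- gintervals("chr1", pos, pos + 1, strand = "+")
  tm <- tag_density_matrix(centers, tags)
  # conservation oracle: per-tag assignment count by brute force
  ctr <- floor((centers$start + centers$end) / 2)
  manual <- 0
  for (p in pos) manual <- manual + sum(p >= ctr - 3000 & p < ctr + 3000)
  expect_equal(sum(tm$matrix), manual)
  # uniform tags: column means flat within 3 sigma of Poisson
  cm <- colMeans(tm$matrix)
  lambda <- mean(cm)
  expect_true(all(abs(cm - lambda) < 3 * sqrt(lambda / nrow(centers))))
})

test_that("5' tag collapsing is strand aware", {
  center <- gintervals("chr1", 900, 1100)  # center 1000
  minus_tag <- gintervals("chr1", 995, 1035, strand = "-")  # 5' end at 1034
  tm <- tag_density_matrix(center, minus_tag, flank = 100, bin = 10)
  expect_equal(which(tm$matrix[1, ] == 1), 14L)  # (1034 - 900)/10 + 1
  mid <- tag_density_matrix(center, minus_tag, flank = 100, bin = 10,
                            tag_mode = "midpoint")
  expect_equal(which(mid$matrix[1, ] == 1), 12L)  # midpoint 1015
})

test_that("centered K-means recovers planted row shapes deterministically", {
  withr::local_seed(35)
  n <- 200
  rising <- seq(-1, 1, length.out = 20)
  shapes <- rbind(rising, -rising)
  truth <- sample(1:2, n, replace = TRUE)
  mat <- shapes[truth, ] + matrix(stats::rnorm(n * 20, 0, 0.1), n, 20) +
    stats::rnorm(n, 5, 1)  # row offsets are removed by centering
  km <- centered_kmeans(mat, k = 2, seed = 9)
  expect_gte(ari(km$cluster, truth), 0.95)
  km2 <- centered_kmeans(mat, k = 2, seed = 9)
  expect_identical(km$cluster, km2$cluster)
  expect_identical(km$order, km2$order)
  # k = 1: single cluster, ordering covers all rows
  km1 <- centered_kmeans(mat, k = 1, seed = 9)
  expect_true(all(km1$cluster == 1L))
  expect_setequal(km1$order, seq_len(n))
  expect_error(centered_kmeans(mat, k = 0, seed = 1), "between")
  expect_error(centered_kmeans(mat, k = n + 1, seed = 1), "between")
})

test_that("constant rows are flagged and fall to the tie-rule cluster", {
  withr::local_seed(36)
  mat <- rbind(matrix(stats::rnorm(80), 8, 10), rep(3, 10))
  km <- centered_kmeans(mat, k = 2, seed = 4)
  expect_equal(km$flagged, 9L)
  expect_equal(length(km$cluster), 9L)
})

test_that("peak-set overlap expresses asymmetric co-binding", {
  a <- gintervals("chr1", c(0, 100), c(50, 150))
  b <- gintervals("chr2", c(0, 100), c(50, 150))
  disjoint <- peakset_overlap(a, b)
  expect_equal(disjoint$shared_a, 0L)
  expect_equal(unname(disjoint$venn["shared"]), 0L)
  same <- peakset_overlap(a, a)
  expect_equal(same$frac_a_shared, 1)
  expect_equal(same$frac_b_shared, 1)
  # ~90% of a small B inside ~5% of a large A
  withr::local_seed(38)
  a <- gintervals("chr1", seq(0, by = 1000, length.out = 2000),
                  seq(300, by = 1000, length.out = 2000))
  host <- sample.int(100, 108, replace = TRUE)  # inside the first 100 A peaks
  b_in <- gintervals("chr1", a$start[host] + 50, a$start[host] + 150)
  b_out <- gintervals("chr1", seq(2500000, by = 5000, length.out = 12),
                      seq(2500100, by = 5000, length.out = 12))
  b <- gintervals(c(b_in$chrom, b_out$chrom), c(b_in$start, b_out$start),
                  c(b_in$end, b_out$end))
  ov <- peakset_overlap(a, b)
  expect_lt(abs(ov$frac_a_shared - 0.05), 0.02)
  expect_equal(ov$frac_b_shared, 0.9)
})

test_that("gene-level sharing reports Jaccard and per-set fractions", {
  tss <- seq(10000, by = 10000, length.out = 20)
  g <- make_genes(sprintf("g%02d", 1:20), "chr1", rep("+", 20),
                  lapply(tss, function(s) cbind(s, s + 1000)))
  peaks_at <- function(idx) gintervals("chr1", tss[idx] - 100, tss[idx] + 100)
  same <- gene_overlap_fraction(peaks_at(1:10), peaks_at(1:10), g)
  expect_equal(same$frac_a_shared, 1)
  shared <- gene_overlap_fraction(peaks_at(1:10), peaks_at(2:10), g)
  expect_equal(shared$frac_a_shared, 0.9)
  expect_equal(shared$frac_b_shared, 1)
  empty <- gene_overlap_fraction(peaks_at(1:10), peaks_at(integer()), g)
  expect_true(empty$degenerate)
  expect_equal(empty$frac_b_shared, 0)
})

test_that("stitching honours the inclusive gap rule and matches components", {
  p <- gintervals("chr1", c(0, 13500), c(1000, 14000))
  expect_equal(nrow(stitch_peaks(p, 12500)), 1L)     # gap exactly 12500
  p2 <- gintervals("chr1", c(0, 13501), c(1000, 14000))
  expect_equal(nrow(stitch_peaks(p2, 12500)), 2L)    # gap 12501
  # graph connected-components oracle on random instances
  withr::local_seed(41)
  for (rep in 1:10) {
    n <- 40
    s <- sort(sample.int(200000, n))
    pk <- gintervals("chr1", s, s + sample.int(500, n, replace = TRUE),
                     name = sprintf("p%02d", 1:n))
    st <- stitch_peaks(pk, 3000)
    g <- igraph::make_empty_graph(n, directed = FALSE)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      gap <- max(pk$start[i], pk$start[j]) - min(pk$end[i], pk$end[j])
      if (gap <= 3000) g <- igraph::add_edges(g, c(i, j))
    }
    comp <- igraph::components(g)$membership
    expect_equal(nrow(st), max(comp))
    got <- attr(st, "assignment")
    expect_equal(length(unique(paste(got, comp))), max(comp))  # same partition
  }
  # TSS exclusion removes fully-contained peaks before stitching
  excl <- gintervals("chr1", 0, 1200)
  st <- stitch_peaks(p, 12500, tss_exclusion = excl)
  expect_equal(st$start, 13500)
})

test_that("rank-signal cutoff has the documented geometry", {
  # one dominant point among 99 equal signals: exactly one superenhancer
  cut <- superenhancer_cutoff(c(rep(1, 99), 100))
  expect_equal(cut$cutoff, 1)
  expect_false(cut$degenerate)
  expect_equal(sum(c(rep(1, 99), 100) > cut$cutoff), 1L)
  # perfectly linear curve: degenerate, cutoff at the top, nothing called
  lin <- superenhancer_cutoff(seq(0, 99))
  expect_true(lin$degenerate)
  expect_equal(sum(seq(0, 99) > lin$cutoff), 0L)
  expect_true(superenhancer_cutoff(rep(5, 10))$degenerate)
  expect_error(superenhancer_cutoff(c(1, 2)), ">= 3")
  # convex curve y = x^4: tangency at x = (1/4)^(1/3)
  x <- seq(0, 1, length.out = 1000)
  cut4 <- superenhancer_cutoff(x^4)
  analytic <- (1 / 4)^(1 / 3)
  expect_lte(abs(cut4$index - (which.min(abs(x - analytic)))), 1)
})

test_that("call_superenhancers ranks planted loci first and is reproducible", {
  cfg <- sim_config(seed = 55, tag_depth = 80000, n_background_peaks = 200)
  sim <- simulate_tags(cfg)
  calls <- call_superenhancers(sim$peaks, sim$tags)
  planted <- vapply(sim$truth$se_peaks, function(v) v[1], "")
  top5 <- calls$constituents[1:5]
  expect_true(all(vapply(planted, function(p) any(grepl(p, top5, fixed = TRUE)), TRUE)))
  expect_true(all(calls$is_super[1:5]))
  # the superenhancer set is upward-closed in signal
  expect_true(all(diff(calls$signal) <= 0))
  expect_true(all(calls$is_super == (calls$signal > attr(calls, "cutoff"))))
  # a zero-count control changes nothing
  far_ctrl <- gintervals("tchr1", 1, 2, strand = "+")
  with_ctrl <- call_superenhancers(sim$peaks, sim$tags,
                                   control_tags = far_ctrl[0, , drop = FALSE])
  expect_equal(calls$signal, with_ctrl$signal)
  rerun <- call_superenhancers(sim$peaks, sim$tags)
  expect_identical(calls, rerun)
})
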