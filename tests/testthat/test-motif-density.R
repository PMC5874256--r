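# PWM construction, log2-odds scanning, and positional density profiles.

test_that("pwm_build normalizes counts and scores a uniform matrix as zero", {
  counts <- matrix(c(10, 0, 0, 0,  0, 10, 0, 0,  2, 2, 3, 3), nrow = 4)
  pwm <- pwm_build(counts, pseudocount = 0.8)
  expect_equal(colSums(pwm$probs), rep(1, 3))
  uniform <- pwm_build(matrix(1, 4, 5), pseudocount = 0.8)
  expect_equal(unname(uniform$score), matrix(0, 4, 5))
  expect_equal(uniform$max_score, 0)
  # probability matrix passes through unchanged at pseudocount 0
  probs <- matrix(c(0.7, 0.1, 0.1, 0.1), 4, 2)
  expect_equal(unname(pwm_build(probs, pseudocount = 0)$probs), probs)
  expect_error(pwm_build(matrix(0, 4, 2), pseudocount = 0), "all-zero")
})

test_that("JASPAR reader handles bracketed count rows", {
  path <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(">MA0001.1 TEST",
               "A [ 10  2  0  0  4  1 ]",
               "C [  1  1  0 12  2  2 ]",
               "G [  1 10 12  0  2  2 ]",
               "T [  0  1  0  0  4  7 ]"), path)
  pwms <- load_pwms(path)
  expect_named(pwms, "MA0001.1")
  expect_equal(ncol(pwms[[1]]$probs), 6L)
  expect_equal(colSums(pwms[[1]]$probs), rep(1, 6))
})

sharp_pwm <- function(consensus = "ACGTAC", p = 0.94) {
  letters4 <- c("A", "C", "G", "T")
  cons <- strsplit(consensus, "")[[1]]
  counts <- matrix((1 - p) / 3 * 100, 4, length(cons),
                   dimnames = list(letters4, NULL))
  for (j in seq_along(cons)) counts[cons[j], j] <- p * 100
  pwm_build(counts, name = "sharp", pseudocount = 0)
}

test_that("consensus sequence scores at the PWM maximum at offset 0", {
  pwm <- sharp_pwm("ACGTAC")
  hits <- scan_sequence("ACGTAC", pwm, threshold = -Inf)
  top <- hits[which.max(hits$score), ]
  expect_equal(top$start, 0)
  expect_equal(top$strand, "+")
  expect_equal(top$score, sum(log2(apply(pwm$probs, 2, max) / 0.25)))
})

test_that("palindromic PWMs hit both strands at the same positions", {
  pwm <- sharp_pwm("ACGCGT")  # reverse complement of ACGCGT is ACGCGT
  withr::local_seed(5)
  seq <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  hits <- scan_sequence(seq, pwm, threshold = -Inf)
  fw <- hits[hits$strand == "+", ]
  rv <- hits[hits$strand == "-", ]
  expect_equal(fw$start, rv$start)
  expect_equal(fw$score, rv$score)
})

test_that("scanning matches per-offset rescoring and counts all windows", {
  pwm <- sharp_pwm("GATAAG")
  withr::local_seed(8)
  letters4 <- c("A", "C", "G", "T")
  for (rep in 1:20) {
    seq <- paste(sample(letters4, 60, replace = TRUE), collapse = "")
    hits <- scan_sequence(seq, pwm, threshold = -Inf)
    # threshold -Inf scores every window once per strand
    expect_equal(nrow(hits), 2 * (60 - 6 + 1))
    # independent rescoring: loop over offsets, sum log2 odds by hand
    chars <- strsplit(seq, "")[[1]]
    rc <- rev(chartr("ACGT", "TGCA", chars))
    for (h in sample(nrow(hits), 5)) {
      row <- hits[h, ]
      window <- if (row$strand == "+") chars[(row$start + 1):(row$start + 6)]
      else rc[(60 - row$start - 6 + 1):(60 - row$start)]
      manual <- sum(vapply(seq_len(6), function(j)
        log2(pwm$probs[window[j], j] / 0.25), 0))
      expect_equal(row$score, manual)
    }
  }
})

test_that("reverse-complement consistency: mirrored offsets, same scores", {
  pwm <- sharp_pwm("GGATGT")
  withr::local_seed(12)
  seq <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE), collapse = "")
  rcseq <- paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "")[[1]]), collapse = "")
  a <- scan_sequence(seq, pwm, threshold = -Inf)
  b <- scan_sequence(rcseq, pwm, threshold = -Inf)
  # a hit at start s on + of seq appears at start len-L-s on - of rcseq
  mirror <- function(h, strand) sort(h$score[h$strand == strand])
  expect_equal(mirror(a, "+"), mirror(b, "-"))
  expect_equal(mirror(a, "-"), mirror(b, "+"))
  a_fw <- a[a$strand == "+", ]
  b_rv <- b[b$strand == "-", ]
  expect_equal(sort(80 - 6 - a_fw$start), sort(b_rv$start))
})

test_that("windows containing N are skipped", {
  pwm <- sharp_pwm("AAAAAA")
  hits <- scan_sequence("AAANAAAAAA", pwm, threshold = -Inf)
  # of the 5 windows only the one starting at 4 avoids the N at index 3
  expect_equal(hits$start[hits$strand == "+"], 4)
  expect_equal(nrow(hits), 2L)
  expect_equal(nrow(scan_sequence("ACG", pwm)), 0L)  # shorter than L
})

test_that("hits_around_positions recovers planted offsets", {
  withr::local_seed(19)
  pwm <- sharp_pwm("TTGACGTCAA", p = 0.97)
  base <- paste(sample(c("A", "C", "G", "T"), 40000, replace = TRUE,
                       prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
  anchors <- seq(1000, 39000, by = 2000)
  offsets <- sample(-60:50, length(anchors), replace = TRUE)
  for (i in seq_along(anchors)) {
    s <- anchors[i] + offsets[i]
    substr(base, s + 1, s + 10) <- "TTGACGTCAA"
  }
  genome <- Biostrings::DNAStringSet(c(chrT = base))
  pos <- data.frame(chrom = "chrT", pos = anchors)
  res <- hits_around_positions(genome, pos, window = 500, pwm)
  # every planted instance is rediscovered at its planted start offset
  found <- res$hits[res$hits$score >= pwm$threshold, ]
  expect_true(all(offsets %in% found$offset_start[found$strand == "+"] |
                    offsets %in% found$offset_start[found$strand == "-"]))
  planted_found <- mapply(function(i, off)
    any(found$position_index == i & found$offset_start == off),
    seq_along(anchors), offsets)
  expect_true(all(planted_found))
  # window 0 yields no hits
  expect_equal(nrow(hits_around_positions(genome, pos, window = 0, pwm)$hits), 0L)
  # missing chromosome warns and is skipped
  expect_warning(hits_around_positions(genome, data.frame(chrom = "chrZ", pos = 1),
                                       window = 10, pwm), "not in FASTA")
})

test_that("density profile bins conserve hits and normalize per position per bp", {
  hits <- data.frame(offset_center = rep(0L, 12))
  prof <- positional_density_profile(hits, bin_bp = 25, n_positions = 4, window = 500)
  expect_equal(sum(prof$bins$count), 12L)
  central <- which(prof$bins$lower == 0)
  expect_equal(prof$bins$count[central], 12L)
  expect_equal(prof$bins$density[central], 12 / (4 * 25))
  expect_error(positional_density_profile(hits, bin_bp = 30, n_positions = 4, window = 500),
               "divide")
  expect_error(positional_density_profile(hits, bin_bp = 25, n_positions = 0, window = 500),
               "positions")
})

test_that("uniform hits give a flat profile; planted core mass concentrates", {
  withr::local_seed(23)
  uni <- data.frame(offset_center = sample(-500:499, 10000, replace = TRUE))
  prof <- positional_density_profile(uni, bin_bp = 25, n_positions = 100, window = 500)
  expect_lt(max(prof$bins$density) / min(prof$bins$density), 1.5)
  # 80% of hits within +/-75 bp -> >= 70% of mass in the central 150 bp
  n <- 5000
  core <- data.frame(offset_center = c(sample(-75:74, round(0.8 * n), replace = TRUE),
                                       sample(c(-500:-76, 75:499), round(0.2 * n),
                                              replace = TRUE)))
  prof2 <- positional_density_profile(core, bin_bp = 25, n_positions = 100, window = 500)
  enr <- motif_enrichment_ratio(prof2, prof, core_bp = 150)
  expect_gte(enr$core_mass_fg, 0.7)
  # fg core density (0.8*5000 + 0.15 flank)/15000 vs uniform bg 10000*0.15/15000
  expect_equal(enr$ratio, 2.77, tolerance = 0.15)
  expect_lt(enr$binomial_p, 1e-10)
})

test_that("enrichment ratio is 1 for identical profiles and flags empty cores", {
  withr::local_seed(29)
  hits <- data.frame(offset_center = sample(-500:499, 2000, replace = TRUE))
  prof <- positional_density_profile(hits, bin_bp = 25, n_positions = 50, window = 500)
  self <- motif_enrichment_ratio(prof, prof)
  expect_equal(self$ratio, 1)
  expect_false(self$infinite)
  # two-sided binomial P equals the exact closed form recomputed by hand
  pc <- evnet:::profile_core(prof, 150)
  d <- stats::dbinom(0:pc$total_count, pc$total_count, 150 / 1000)
  manual <- sum(d[d <= d[pc$core_count + 1] * (1 + 1e-7)])
  expect_equal(self$binomial_p, manual, tolerance = 1e-9)
  empty_bg <- data.frame(offset_center = c(-400, 400))
  prof0 <- positional_density_profile(empty_bg, bin_bp = 25, n_positions = 50, window = 500)
  enr <- motif_enrichment_ratio(prof, prof0)
  expect_true(enr$infinite)
  expect_equal(enr$ratio, Inf)
})
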