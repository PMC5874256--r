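# Synthetic-data generators. Every generator is a pure function of
# (config, seed): reruns are bit-identical. The generators emulate the
# statistical structure the analysis assumes -- active-enhancer landscapes
# with a controlled TF-bound fraction, GWAS panels with density-enriched
# SNPs in bound enhancers, motif instances planted near bound-class SNPs,
# tag pileups with a few dominant stitched loci, and two-species expression
# courses with a planted concordant subset -- and record ground truth for
# round-trip validation.

#' Simulation configuration with study-scale defaults
#'
#' Defaults describe the emulated study conditions: a 2 x 1 Mb genome with
#' 200 genes, ~1000 active-enhancer regions of which 40% are TF-bound,
#' a 10 000-SNP panel with 3x SNP density inside bound enhancers and a
#' spike-and-uniform P-value model (Beta(0.1, 1) signal, Uniform null) over
#' the six association groups, motif instances planted within +/-75 bp of
#' 80% of bound-class SNPs, a tag landscape with 5 dominant multi-peak
#' stitched loci among 500 background peaks, and 200 two-species
#' 4-time-point expression courses with 75 concordant genes at noise sd
#' 0.2.
#'
#' @param seed integer seed (mandatory).
#' @param ... overrides for any default field.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed, ...) {
  if (missing(seed)) stop_f("seed is mandatory")
  cfg <- list(
    seed = as.integer(seed),
    # genome
    n_chrom = 2L, chrom_length = 1e6, gc = 0.45,
    n_genes = 200L, promoter_window = 1000L,
    # enhancer landscape (widths at the typical H3K27Ac-region scale)
    n_enhancers = 1000L, enhancer_width = c(400L, 1200L),
    tf_bound_fraction = 0.4, n_tf_only_peaks = 300L,
    tf_peak_width = c(200L, 400L),
    # SNP panel
    n_snps = 10000L, snp_enrichment_factor = 3,
    assoc_fraction = 0.15, beta_a = 0.1, alpha = 0.05,
    # motifs
    plant_rate = 0.8, plant_offset = 75L,
    # tag landscape (own coordinate system; no sequence needed)
    tag_chrom_length = 1e7, tag_n_chrom = 2L, tag_depth = 200000L,
    tag_enrichment = 8, n_background_peaks = 500L, se_peak_width = 300L,
    n_se_loci = 5L, peaks_per_locus = 8L, se_signal_boost = 12,
    se_gap = c(2000L, 9000L),
    # expression kinetics
    n_tfs = 200L, concordant_fraction = 75 / 200, noise_sd = 0.2,
    n_timepoints = 4L, r_min = 0.5,
    # gene sets
    n_gene_sets = 10L, gene_set_size = 25L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop_f("unknown config field(s): %s", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "sim_config")
}

# Default motif: a sharp 10-bp PU.1-like purine-rich consensus
# (AAAGAGGAAG core), as count matrix.
default_sim_pwm <- function() {
  consensus <- c("A", "A", "A", "G", "A", "G", "G", "A", "A", "G")
  counts <- matrix(1, 4, length(consensus), dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(consensus)) counts[consensus[j], j] <- 97
  pwm_build(counts, name = "PU1_like", pseudocount = 0)
}

runif_int <- function(n, lo, hi) lo + floor(stats::runif(n) * (hi - lo + 1))

# Place n non-overlapping intervals of the given widths, avoiding a
# forbidden interval set. Exact free-segment bookkeeping: a segment with
# enough capacity is sampled with probability proportional to the number
# of admissible offsets, then split, so dense landscapes place without
# rejection failures.
place_intervals <- function(n, width_range, chrom_names, chrom_lens,
                            forbidden = NULL) {
  free <- list()  # rows: chrom index, start, end
  for (ci in seq_along(chrom_names)) {
    segs <- data.frame(start = 0, end = chrom_lens[ci])
    if (!is.null(forbidden) && nrow(forbidden)) {
      fb <- forbidden[forbidden$chrom == chrom_names[ci], , drop = FALSE]
      if (nrow(fb)) {
        fb <- fb[order(fb$start), , drop = FALSE]
        cur <- 0; out <- list()
        for (k in seq_len(nrow(fb))) {
          if (fb$start[k] > cur) out[[length(out) + 1L]] <- c(cur, fb$start[k])
          cur <- max(cur, fb$end[k])
        }
        if (cur < chrom_lens[ci]) out[[length(out) + 1L]] <- c(cur, chrom_lens[ci])
        segs <- if (length(out)) as.data.frame(do.call(rbind, out)) else
          data.frame(numeric(), numeric())
        names(segs) <- c("start", "end")
      }
    }
    if (nrow(segs)) free[[length(free) + 1L]] <- cbind(ci = ci, segs)
  }
  free <- do.call(rbind, free)
  chrom <- character(n); start <- numeric(n); end <- numeric(n)
  for (i in seq_len(n)) {
    w <- runif_int(1, width_range[1], width_range[2])
    cap <- pmax(0, (free$end - free$start) - w + 1)
    if (all(cap == 0)) stop_f("could not place interval %d: no free segment of %d bp left", i, w)
    k <- sample.int(nrow(free), 1, prob = cap)
    s <- free$start[k] + floor(stats::runif(1) * cap[k])
    chrom[i] <- chrom_names[free$ci[k]]; start[i] <- s; end[i] <- s + w
    left <- data.frame(ci = free$ci[k], start = free$start[k], end = s)
    right <- data.frame(ci = free$ci[k], start = s + w, end = free$end[k])
    keep <- rbind(left[left$end > left$start, ], right[right$end > right$start, ])
    free <- rbind(free[-k, , drop = FALSE], keep)
  }
  gintervals(chrom, start, end)
}

#' Simulate a genome with gene annotation
#'
#' Random sequence at the configured GC content; genes are placed without
#' overlap in per-chromosome slots, each with 2-8 exons on a random strand
#' (the gene span starts and ends with an exon, so the TSS falls on the
#' strand-aware span boundary).
#'
#' @param config a `sim_config`.
#' @return list: `genome` (`DNAStringSet`), `genes` (`gene_models`).
#' @export
simulate_genome_annotation <- function(config) {
  with_seed(child_seed(config$seed, 1), {
    chrom_names <- paste0("chr", seq_len(config$n_chrom))
    lens <- rep(config$chrom_length, config$n_chrom)
    p <- c(A = (1 - config$gc) / 2, C = config$gc / 2, G = config$gc / 2, T = (1 - config$gc) / 2)
    seqs <- vapply(lens, function(L)
      paste(sample(names(p), L, replace = TRUE, prob = p), collapse = ""), "")
    genome <- Biostrings::DNAStringSet(seqs)
    names(genome) <- chrom_names
    per_chrom <- diff(round(seq(0, config$n_genes, length.out = config$n_chrom + 1)))
    ids <- sprintf("G%04d", seq_len(config$n_genes))
    gene_rows <- list(); exon_list <- list()
    g <- 0L
    for (ci in seq_len(config$n_chrom)) {
      nc <- per_chrom[ci]
      if (nc == 0L) next
      slot <- floor(lens[ci] / nc)
      if (slot < 1200) stop_f("genes will not fit: need chromosome length >= %d", nc * 1200)
      for (j in seq_len(nc)) {
        g <- g + 1L
        span_max <- min(slot - 400, 8000)
        span <- runif_int(1, 1000, span_max)
        s <- (j - 1) * slot + runif_int(1, 100, slot - span - 200)
        n_ex <- runif_int(1, 2, 8)
        cuts <- sort(sample(seq(s + 1, s + span - 1), 2 * (n_ex - 1)))
        bounds <- c(s, cuts, s + span)
        ex <- cbind(start = bounds[seq(1, length(bounds), 2)],
                    end = bounds[seq(2, length(bounds), 2)])
        strand <- sample(c("+", "-"), 1)
        gene_rows[[g]] <- list(id = ids[g], chrom = paste0("chr", ci), strand = strand)
        exon_list[[g]] <- ex
      }
    }
    genes <- build_gene_table(vapply(gene_rows, `[[`, "", "id"),
                              vapply(gene_rows, `[[`, "", "id"),
                              vapply(gene_rows, `[[`, "", "chrom"),
                              vapply(gene_rows, `[[`, "", "strand"),
                              exon_list)
    list(genome = genome, genes = genes)
  })
}

#' Simulate the active-enhancer landscape
#'
#' Non-overlapping H3K27Ac regions placed away from promoter windows;
#' exactly `round(tf_bound_fraction * n_enhancers)` of them receive an
#' embedded TF peak (fully inside the region), and `n_tf_only_peaks`
#' additional TF peaks are scattered outside every enhancer, so TF-only
#' binding exists as in real landscapes.
#'
#' @param config a `sim_config`.
#' @param genes a `gene_models` object (for promoter avoidance).
#' @return list: `enhancers`, `tf_peaks` (interval data.frames), `truth`
#'   (`bound` logical per enhancer, `embedded_peak` name per bound
#'   enhancer).
#' @export
simulate_enhancer_landscape <- function(config, genes) {
  with_seed(child_seed(config$seed, 2), {
    chrom_names <- paste0("chr", seq_len(config$n_chrom))
    lens <- stats::setNames(rep(config$chrom_length, config$n_chrom), chrom_names)
    g <- genes$genes
    promoters <- gintervals(g$chrom, pmax(0, g$tss - config$promoter_window),
                            g$tss + config$promoter_window)
    enh <- place_intervals(config$n_enhancers, config$enhancer_width,
                           chrom_names, lens, forbidden = promoters)
    enh$name <- sprintf("enh_%04d", seq_len(nrow(enh)))
    n_bound <- round(config$tf_bound_fraction * config$n_enhancers)
    bound_idx <- sort(sample.int(config$n_enhancers, n_bound))
    bound <- seq_len(config$n_enhancers) %in% bound_idx
    pk_chrom <- character(0); pk_s <- numeric(0); pk_e <- numeric(0); pk_name <- character(0)
    for (i in bound_idx) {
      w <- runif_int(1, config$tf_peak_width[1],
                     min(config$tf_peak_width[2], enh$end[i] - enh$start[i]))
      s <- runif_int(1, enh$start[i], enh$end[i] - w)
      pk_chrom <- c(pk_chrom, enh$chrom[i]); pk_s <- c(pk_s, s); pk_e <- c(pk_e, s + w)
      pk_name <- c(pk_name, sprintf("tf_in_%s", enh$name[i]))
    }
    scattered <- place_intervals(config$n_tf_only_peaks, config$tf_peak_width,
                                 chrom_names, lens, forbidden = enh)
    tf <- gintervals(c(pk_chrom, scattered$chrom), c(pk_s, scattered$start),
                     c(pk_e, scattered$end),
                     name = c(pk_name, sprintf("tf_only_%04d", seq_len(nrow(scattered)))))
    list(enhancers = enh, tf_peaks = tf,
         truth = list(bound = bound,
                      embedded_peak = stats::setNames(pk_name, enh$name[bound_idx])))
  })
}

# Locate points in a set of non-overlapping intervals: returns the row
# index of the containing interval or NA. Plain findInterval on sorted
# starts per chromosome; independent of the production overlap engine.
point_in_intervals <- function(chrom, pos, iv) {
  out <- rep(NA_integer_, length(pos))
  for (ch in unique(chrom)) {
    rows <- which(iv$chrom == ch)
    if (!length(rows)) next
    ord <- rows[order(iv$start[rows])]
    qi <- which(chrom == ch)
    k <- findInterval(pos[qi], iv$start[ord])
    hit <- k > 0 & pos[qi] < iv$end[ord][pmax(k, 1L)]
    out[qi[hit]] <- ord[k[hit]]
  }
  out
}

# Generator-internal brute-force nearest-TSS scan (independent of the
# production path) used to record ground-truth gene lists.
brute_nearest_gene <- function(chrom, pos, genes) {
  g <- genes$genes
  vapply(seq_along(chrom), function(i) {
    cand <- g[g$chrom == chrom[i], , drop = FALSE]
    if (!nrow(cand)) return(NA_character_)
    d <- abs(pos[i] - cand$tss)
    hit <- cand$gene_id[d == min(d)]
    sort(hit)[1L]
  }, "")
}

#' Simulate a GWAS SNP panel over the landscape
#'
#' SNP positions are drawn with per-bp density multiplied by
#' `snp_enrichment_factor` inside bound enhancers. A random
#' `assoc_fraction` of SNPs is truly associated: those draw Beta(beta_a, 1)
#' P-values in a random non-empty subset of the six groups (Uniform
#' elsewhere); null SNPs draw Uniform(0,1) in every group. Ground truth
#' records each SNP's positional class (bound / non_bound / outside, by a
#' brute-force scan of the landscape), its association flag, and the
#' per-class gene lists of the P <= alpha passing SNPs (brute-force
#' nearest-TSS).
#'
#' @param config a `sim_config`.
#' @param landscape output of [simulate_enhancer_landscape()].
#' @param genes a `gene_models` object.
#' @return list: `snps` (data.frame ready for [write_snp_table()]),
#'   `truth` (`class`, `associated`, `passing`, `bound_snps`,
#'   `non_bound_snps`, `bound_genes`, `non_bound_genes`).
#' @export
simulate_snp_panel <- function(config, landscape, genes) {
  with_seed(child_seed(config$seed, 3), {
    enh <- landscape$enhancers
    bound_enh <- enh[landscape$truth$bound, , drop = FALSE]
    lens <- stats::setNames(rep(config$chrom_length, config$n_chrom),
                            paste0("chr", seq_len(config$n_chrom)))
    genome_bp <- sum(lens)
    bound_bp <- sum(bound_enh$end - bound_enh$start)
    f <- config$snp_enrichment_factor
    p_bound <- f * bound_bp / (genome_bp + (f - 1) * bound_bp)
    n <- config$n_snps
    in_bound_draw <- stats::runif(n) < p_bound
    chrom <- character(n); pos <- numeric(n)
    # draws inside bound enhancers: uniform over bound bp
    widths <- bound_enh$end - bound_enh$start
    nb <- sum(in_bound_draw)
    if (nb) {
      ei <- sample.int(nrow(bound_enh), nb, replace = TRUE, prob = widths)
      chrom[in_bound_draw] <- bound_enh$chrom[ei]
      pos[in_bound_draw] <- bound_enh$start[ei] +
        floor(stats::runif(nb) * (bound_enh$end[ei] - bound_enh$start[ei]))
    }
    # complement draws: uniform over the genome, rejecting bound-enhancer bp
    todo <- which(!in_bound_draw)
    while (length(todo)) {
      ci <- sample.int(length(lens), length(todo), replace = TRUE)
      cand_chrom <- names(lens)[ci]
      cand_pos <- floor(stats::runif(length(todo)) * lens[ci])
      inside <- !is.na(point_in_intervals(cand_chrom, cand_pos, bound_enh))
      chrom[todo] <- cand_chrom; pos[todo] <- cand_pos
      todo <- todo[inside]
    }
    snp_id <- sprintf("rs%06d", seq_len(n))
    assoc <- logical(n)
    assoc[sample.int(n, round(config$assoc_fraction * n))] <- TRUE
    pmat <- matrix(stats::runif(n * 6), n, 6, dimnames = list(NULL, paste0("P_", SNP_GROUPS)))
    for (i in which(assoc)) {
      grp <- which(stats::runif(6) < 0.5)
      if (!length(grp)) grp <- sample.int(6, 1)
      pmat[i, grp] <- stats::rbeta(length(grp), config$beta_a, 1)
    }
    snps <- data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                       stringsAsFactors = FALSE)
    snps <- cbind(snps, as.data.frame(pmat))
    # ground-truth positional class: enhancers are non-overlapping, so a
    # findInterval membership scan suffices (and stays independent of the
    # production overlap engine)
    enh_idx <- point_in_intervals(chrom, pos, enh)
    class <- ifelse(is.na(enh_idx), "outside",
                    ifelse(landscape$truth$bound[pmax(enh_idx, 1L)], "bound", "non_bound"))
    passing <- apply(pmat, 1, min) <= config$alpha
    bound_snps <- snp_id[passing & class == "bound"]
    non_bound_snps <- snp_id[passing & class == "non_bound"]
    # lead SNP per enhancer: among passing SNPs in an enhancer, the one
    # with the smallest best P-value (ties by snp_id) -- the standard
    # sentinel-SNP convention for locus-level follow-up
    enh_of <- enh_idx
    best_p <- apply(pmat, 1, min)
    lead_in <- function(cls_label) {
      idx <- which(passing & class == cls_label)
      if (!length(idx)) return(character())
      ord <- idx[order(best_p[idx], snp_id[idx])]
      sort(snp_id[ord[!duplicated(enh_of[ord])]])
    }
    bound_lead_snps <- lead_in("bound")
    non_bound_lead_snps <- lead_in("non_bound")
    bound_genes <- sort(unique(brute_nearest_gene(chrom[passing & class == "bound"],
                                                  pos[passing & class == "bound"], genes)))
    non_bound_genes <- sort(unique(brute_nearest_gene(chrom[passing & class == "non_bound"],
                                                      pos[passing & class == "non_bound"], genes)))
    list(snps = snps,
         truth = list(class = stats::setNames(class, snp_id),
                      associated = stats::setNames(assoc, snp_id),
                      passing = stats::setNames(passing, snp_id),
                      bound_snps = bound_snps, non_bound_snps = non_bound_snps,
                      bound_lead_snps = bound_lead_snps,
                      non_bound_lead_snps = non_bound_lead_snps,
                      bound_genes = bound_genes[!is.na(bound_genes)],
                      non_bound_genes = non_bound_genes[!is.na(non_bound_genes)]))
  })
}

#' Plant motif instances near bound-class lead SNPs
#'
#' Emulates one functional TF binding site per bound enhancer: a
#' PWM-sampled instance is written near `plant_rate` of the bound-class
#' lead SNPs (one sentinel SNP per enhancer, see
#' [simulate_snp_panel()]), with the instance center drawn uniformly
#' within `+/-(plant_offset - L)` of the SNP (so the whole instance stays
#' inside the core window), on a random strand. Instances colliding with a
#' chromosome edge are resampled.
#'
#' @param config a `sim_config`.
#' @param genome `DNAStringSet` to patch.
#' @param snps,snp_truth output of [simulate_snp_panel()] (`snps`,
#'   `truth`).
#' @param pwm `pwm` object to sample instances from; default
#'   [default_sim_pwm()].
#' @return list: `genome` (patched), `truth` (data.frame snp_id, chrom,
#'   start, strand, instance), `pwm`.
#' @export
simulate_sequences_with_motifs <- function(config, genome, snps, snp_truth,
                                           pwm = default_sim_pwm()) {
  with_seed(child_seed(config$seed, 4), {
    L <- ncol(pwm$probs)
    targets <- snp_truth$bound_lead_snps
    n_plant <- round(config$plant_rate * length(targets))
    planted <- if (n_plant) sort(sample(targets, n_plant)) else character()
    seqs <- as.character(genome)
    rows <- list()
    max_c <- config$plant_offset - L
    for (id in planted) {
      i <- match(id, snps$snp_id)
      ch <- snps$chrom[i]; p <- snps$pos[i]
      len <- nchar(seqs[[ch]])
      repeat {
        centre <- p + runif_int(1, -max_c, max_c)
        start <- centre - L %/% 2
        if (start >= 0 && start + L <= len) break
      }
      inst <- paste(vapply(seq_len(L), function(j)
        sample(c("A", "C", "G", "T"), 1, prob = pwm$probs[, j]), ""), collapse = "")
      strand <- sample(c("+", "-"), 1)
      written <- if (strand == "+") inst else revcomp(inst)
      substr(seqs[[ch]], start + 1, start + L) <- written
      rows[[length(rows) + 1L]] <- data.frame(snp_id = id, chrom = ch, start = start,
                                              strand = strand, instance = inst,
                                              stringsAsFactors = FALSE)
    }
    patched <- Biostrings::DNAStringSet(seqs)
    names(patched) <- names(genome)
    truth <- if (length(rows)) do.call(rbind, rows) else
      data.frame(snp_id = character(), chrom = character(), start = numeric(),
                 strand = character(), instance = character())
    list(genome = patched, truth = truth, pwm = pwm)
  })
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1L]]), collapse = ""))
}

#' Simulate a tag landscape with planted superenhancer loci
#'
#' Uses its own (sequence-free) coordinate system. `n_background_peaks`
#' singleton peaks and `n_se_loci` clustered loci (each `peaks_per_locus`
#' peaks with gaps below the stitching distance) are placed; tags comprise
#' a uniform background plus `(tag_enrichment - 1) x` uniform-expectation
#' extra tags per peak, multiplied by `se_signal_boost` inside planted
#' loci. The total tag count equals `tag_depth` exactly. With
#' `tag_enrichment = 1` every tag is background and the landscape is flat.
#'
#' @param config a `sim_config`.
#' @return list: `peaks`, `tags` (interval data.frames), `chrom_lens`,
#'   `truth` (`se_peaks`: list of peak-name vectors per planted locus).
#' @export
simulate_tags <- function(config) {
  with_seed(child_seed(config$seed, 5), {
    chrom_names <- paste0("tchr", seq_len(config$tag_n_chrom))
    lens <- stats::setNames(rep(config$tag_chrom_length, config$tag_n_chrom), chrom_names)
    w <- config$se_peak_width
    locus_span <- config$peaks_per_locus * (w + config$se_gap[2]) + 20000
    loci <- place_intervals(config$n_se_loci, c(locus_span, locus_span),
                            chrom_names, lens)
    pk <- list(); se_peaks <- vector("list", config$n_se_loci)
    for (l in seq_len(config$n_se_loci)) {
      s <- loci$start[l]
      names_l <- character(config$peaks_per_locus)
      for (j in seq_len(config$peaks_per_locus)) {
        names_l[j] <- sprintf("se%d_p%d", l, j)
        pk[[length(pk) + 1L]] <- data.frame(chrom = loci$chrom[l], start = s, end = s + w,
                                            name = names_l[j], stringsAsFactors = FALSE)
        s <- s + w + runif_int(1, config$se_gap[1], config$se_gap[2])
      }
      se_peaks[[l]] <- names_l
    }
    planted <- do.call(rbind, pk)
    # background singletons avoid the planted loci (padded by the stitch
    # scale so background never merges into a planted region)
    pad <- gintervals(loci$chrom, pmax(0, loci$start - 15000), loci$end + 15000)
    bg <- place_intervals(config$n_background_peaks, c(w, w), chrom_names, lens,
                          forbidden = pad)
    bg$name <- sprintf("bg_%04d", seq_len(nrow(bg)))
    peaks <- gintervals(c(planted$chrom, bg$chrom), c(planted$start, bg$start),
                        c(planted$end, bg$end), name = c(planted$name, bg$name))
    genome_bp <- sum(lens)
    unif_exp <- config$tag_depth * w / genome_bp
    extra_bg_peak <- round((config$tag_enrichment - 1) * unif_exp)
    extra_se_peak <- round(config$se_signal_boost * (config$tag_enrichment - 1) * unif_exp)
    is_se <- grepl("^se", peaks$name)
    extra <- ifelse(is_se, extra_se_peak, extra_bg_peak)
    n_extra <- sum(extra)
    if (n_extra >= config$tag_depth) stop_f("tag_depth too small for the configured enrichment")
    tag_chrom <- character(0); tag_pos <- numeric(0)
    for (i in which(extra > 0)) {
      tag_chrom <- c(tag_chrom, rep(peaks$chrom[i], extra[i]))
      tag_pos <- c(tag_pos, peaks$start[i] +
                     floor(stats::runif(extra[i]) * (peaks$end[i] - peaks$start[i])))
    }
    n_bg <- config$tag_depth - n_extra
    ci <- sample.int(length(lens), n_bg, replace = TRUE)
    tag_chrom <- c(tag_chrom, names(lens)[ci])
    tag_pos <- c(tag_pos, floor(stats::runif(n_bg) * lens[ci]))
    tags <- gintervals(tag_chrom, tag_pos, tag_pos + 1,
                       name = sprintf("tag_%06d", seq_along(tag_pos)),
                       strand = rep("+", length(tag_pos)))
    list(peaks = peaks, tags = tags, chrom_lens = lens,
         truth = list(se_peaks = se_peaks))
  })
}

# Kinetic shape library over 4 time points: pairwise Pearson <= 0.
kinetic_shapes <- function() {
  rbind(rising = c(0, 1, 2, 3),
        falling = c(3, 2, 1, 0),
        transient_up = c(0, 3, 3, 0),
        transient_down = c(3, 0, 0, 3))
}

#' Simulate two-species expression time courses
#'
#' Concordant genes share one kinetic shape across species (plus
#' N(0, noise_sd) noise); discordant genes draw two distinct,
#' non-positively-correlated shapes. Mouse symbols use sentence case and
#' human symbols upper case to exercise case-insensitive ortholog
#' matching.
#'
#' @param config a `sim_config`.
#' @return list: `mouse`, `human` (matrices, genes x time points),
#'   `truth` (`concordant` logical named by upper-case symbol, `shape`
#'   mouse-shape index).
#' @export
simulate_ortholog_expression <- function(config) {
  with_seed(child_seed(config$seed, 6), {
    shapes <- kinetic_shapes()
    if (config$n_timepoints != ncol(shapes))
      shapes <- t(apply(shapes, 1, function(s)
        stats::approx(seq_along(s), s, n = config$n_timepoints)$y))
    n <- config$n_tfs
    n_conc <- round(config$concordant_fraction * n)
    conc <- logical(n); conc[sample.int(n, n_conc)] <- TRUE
    sym_up <- sprintf("TF%03d", seq_len(n))
    sym_mouse <- paste0(substr(sym_up, 1, 1), tolower(substr(sym_up, 2, nchar(sym_up))))
    shape_m <- sample.int(nrow(shapes), n, replace = TRUE)
    shape_h <- shape_m
    cc <- stats::cor(t(shapes))
    for (i in which(!conc)) {
      alt <- which(cc[shape_m[i], ] <= 0)
      shape_h[i] <- if (length(alt)) sample(rep(alt, 2), 1) else
        (shape_m[i] %% nrow(shapes)) + 1
    }
    noise <- function() matrix(stats::rnorm(n * config$n_timepoints, 0, config$noise_sd),
                               n, config$n_timepoints)
    mouse <- 8 + shapes[shape_m, , drop = FALSE] + noise()
    human <- 8 + shapes[shape_h, , drop = FALSE] + noise()
    dimnames(mouse) <- list(sym_mouse, paste0("m_T", seq_len(config$n_timepoints) - 1))
    dimnames(human) <- list(sym_up, paste0("h_T", seq_len(config$n_timepoints) - 1))
    list(mouse = mouse, human = human,
         truth = list(concordant = stats::setNames(conc, sym_up),
                      shape = stats::setNames(shape_m, sym_up)))
  })
}

#' Simulate a toy gene-set collection over the annotated genes
#'
#' Random sets drawn from the gene universe; the first set is optionally
#' spiked with genes from a provided list so enrichment is recoverable.
#'
#' @param config a `sim_config`.
#' @param universe character vector of gene ids.
#' @param spike optional genes over-represented in the first set.
#' @return named list of gene sets (GMT-style).
#' @export
simulate_gene_sets <- function(config, universe, spike = NULL) {
  with_seed(child_seed(config$seed, 7), {
    sets <- list()
    for (i in seq_len(config$n_gene_sets)) {
      members <- sample(universe, min(config$gene_set_size, length(universe)))
      if (i == 1L && !is.null(spike)) {
        take <- utils::head(spike, ceiling(config$gene_set_size / 2))
        members <- unique(c(take, members))[seq_len(min(config$gene_set_size, length(universe)))]
      }
      s <- sort(members)
      attr(s, "description") <- sprintf("synthetic set %d", i)
      sets[[sprintf("SET_%02d", i)]] <- s
    }
    sets
  })
}
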