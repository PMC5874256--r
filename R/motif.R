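# Position weight matrices, log2-odds scanning, and SNP-centered positional
# density profiles.

#' Build a PWM from a count or probability matrix
#'
#' Counts are converted to probabilities with a JASPAR-style pseudocount
#' distributed by the background (`p = (count + pc*bg) / (colsum + pc)`).
#' The default hit threshold is a fraction of the maximum achievable
#' log2-odds score.
#'
#' @param mat 4 x L numeric matrix, rows A, C, G, T (counts or
#'   probabilities).
#' @param name motif name.
#' @param background length-4 background probabilities (sums to 1); default
#'   uniform.
#' @param pseudocount JASPAR-style pseudocount (default 0.8); 0 leaves a
#'   probability matrix untouched.
#' @param threshold_frac default hit threshold as a fraction of the maximum
#'   achievable score (default 0.6).
#' @return object of class `pwm`: probabilities, log2-odds score matrix,
#'   `max_score`, `threshold`.
#' @export
pwm_build <- function(mat, name = "motif", background = rep(0.25, 4),
                      pseudocount = 0.8, threshold_frac = 0.6) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4L || ncol(mat) < 1L) stop_f("PWM matrix must be 4 x L with L >= 1")
  if (abs(sum(background) - 1) > 1e-9) stop_f("background must sum to 1")
  rownames(mat) <- c("A", "C", "G", "T")
  cs <- colSums(mat)
  if (any(cs == 0) && pseudocount == 0) stop_f("all-zero PWM column with zero pseudocount")
  probs <- sweep(mat + pseudocount * background, 2, cs + pseudocount, "/")
  probs <- sweep(probs, 2, colSums(probs), "/")  # guard FP drift
  score <- log2(sweep(probs, 1, background, "/"))
  max_score <- sum(apply(score, 2, max))
  structure(list(name = name, probs = probs, background = background,
                 pseudocount = pseudocount, score = score,
                 max_score = max_score, threshold = threshold_frac * max_score),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm %s: L=%d, max log2-odds %.2f, threshold %.2f\n",
              x$name, ncol(x$probs), x$max_score, x$threshold))
  invisible(x)
}

#' Load JASPAR-format PWMs
#'
#' Reads `.jaspar`/`.pfm` files: a `>name` header followed by four rows
#' (optionally prefixed `A [ ... ]` etc.) of counts or probabilities.
#'
#' @param path file with one or more matrices.
#' @inheritParams pwm_build
#' @return list of `pwm` objects, named.
#' @export
load_pwms <- function(path, background = rep(0.25, 4), pseudocount = 0.8,
                      threshold_frac = 0.6) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (!length(heads)) stop_f("no JASPAR headers (>) in %s", path)
  out <- list()
  bounds <- c(heads, length(lines) + 1L)
  for (i in seq_along(heads)) {
    name <- sub("^>\\s*", "", lines[heads[i]])
    name <- strsplit(name, "\\s+")[[1L]][1L]
    body <- lines[(heads[i] + 1L):(bounds[i + 1L] - 1L)]
    if (length(body) < 4L) stop_f("matrix %s has fewer than 4 rows", name)
    rows <- lapply(body[1:4], function(l) {
      l <- sub("^[ACGTacgt]\\s*", "", l)
      l <- gsub("\\[|\\]", " ", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1L]])
    })
    if (length(unique(lengths(rows))) != 1L) stop_f("ragged matrix %s", name)
    out[[name]] <- pwm_build(do.call(rbind, rows), name = name,
                             background = background, pseudocount = pseudocount,
                             threshold_frac = threshold_frac)
  }
  out
}

# Map a DNA string to row indices 1..4 (A,C,G,T); anything else -> NA.
seq_to_idx <- function(seq) {
  x <- match(strsplit(toupper(seq), "")[[1L]], c("A", "C", "G", "T"))
  x
}

score_windows <- function(x, score) {
  L <- ncol(score); n <- length(x)
  nw <- n - L + 1L
  if (nw < 1L) return(numeric(0))
  sc <- numeric(nw)
  for (j in seq_len(L)) {
    v <- score[, j][x[j:(j + nw - 1L)]]
    sc <- sc + v  # NA (from N bases) propagates and the window is skipped
  }
  sc
}

#' Scan a sequence with a PWM
#'
#' Scores every window with the log2-odds sum
#' `s(w) = sum_j log2(p_j(w_j) / bg(w_j))` and reports windows with
#' `s >= threshold`. The reverse strand is scored on the reverse complement
#' and reported at the forward-strand start coordinate. Windows containing
#' `N` are skipped.
#'
#' @param seq character DNA string over A/C/G/T/N.
#' @param pwm a `pwm` object.
#' @param both_strands scan the reverse strand too (default TRUE).
#' @param threshold override the PWM's stored threshold (use `-Inf` to score
#'   every window).
#' @return data.frame with `start` (0-based window start), `center` (0-based
#'   window center, `start + floor(L/2)`), `strand`, `score`.
#' @export
scan_sequence <- function(seq, pwm, both_strands = TRUE, threshold = NULL) {
  stopifnot(inherits(pwm, "pwm"))
  threshold <- threshold %||% pwm$threshold
  x <- seq_to_idx(seq)
  L <- ncol(pwm$score)
  empty <- data.frame(start = integer(), center = integer(),
                      strand = character(), score = numeric())
  if (length(x) < L) return(empty)
  res <- list()
  fw <- score_windows(x, pwm$score)
  hit <- which(!is.na(fw) & fw >= threshold)
  if (length(hit))
    res[[1L]] <- data.frame(start = hit - 1L, strand = "+", score = fw[hit])
  if (both_strands) {
    # reverse complement scoring == scanning with the row- and
    # column-reversed score matrix at the same forward coordinates
    rc <- pwm$score[4:1, L:1, drop = FALSE]
    rv <- score_windows(x, rc)
    hit <- which(!is.na(rv) & rv >= threshold)
    if (length(hit))
      res[[length(res) + 1L]] <- data.frame(start = hit - 1L, strand = "-", score = rv[hit])
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  out$center <- out$start + L %/% 2L
  out <- out[order(out$start, out$strand), c("start", "center", "strand", "score")]
  rownames(out) <- NULL
  out
}

#' Collect motif hits in windows around genomic positions
#'
#' Extracts `[pos - window, pos + window)` around each position, scans with
#' every PWM, and records hit offsets relative to the position. Windows
#' extending past chromosome ends are clipped and flagged; positions on
#' chromosomes missing from the FASTA are skipped with a warning.
#'
#' @param genome `DNAStringSet` from [read_genome()].
#' @param positions data.frame with `chrom`, `pos` (0-based) and optionally
#'   `name`.
#' @param window flank size in bp (default 500).
#' @param pwms list of `pwm` objects.
#' @param threshold optional threshold override passed to [scan_sequence()].
#' @return list of class `motif_hits`: `hits` (position_index, name, pwm,
#'   offset_start, offset_center, strand, score), `n_positions`, `window`,
#'   `clipped` (indices).
#' @export
hits_around_positions <- function(genome, positions, window = 500L, pwms,
                                  threshold = NULL) {
  stopifnot(window >= 0)
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  hits <- list(); clipped <- integer()
  for (i in seq_len(nrow(positions))) {
    ch <- positions$chrom[i]; p <- positions$pos[i]
    if (!ch %in% names(genome)) {
      warning(sprintf("position %d: chromosome %s not in FASTA; skipped", i, ch))
      next
    }
    len <- length(genome[[ch]])
    s <- p - window; e <- p + window
    if (s < 0 || e > len) clipped <- c(clipped, i)
    s0 <- max(0, s)
    seq <- suppressWarnings(fetch_sequence(genome, ch, s0, min(e, len)))
    for (pw in pwms) {
      h <- scan_sequence(seq, pw, threshold = threshold)
      if (!nrow(h)) next
      hits[[length(hits) + 1L]] <- data.frame(
        position_index = i,
        name = if ("name" %in% names(positions)) positions$name[i] else as.character(i),
        pwm = pw$name,
        offset_start = h$start + s0 - p,
        offset_center = h$center + s0 - p,
        strand = h$strand, score = h$score, stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(position_index = integer(), name = character(), pwm = character(),
               offset_start = integer(), offset_center = integer(),
               strand = character(), score = numeric())
  structure(list(hits = hits, n_positions = nrow(positions), window = window,
                 clipped = clipped),
            class = "motif_hits")
}

#' Positional density profile of motif hits
#'
#' Bins hits by the offset of the motif-window center relative to the
#' anchoring position. Density is per anchoring position per bp:
#' `count / (n_positions * bin_bp)`.
#'
#' @param hits a `motif_hits` object (or a data.frame with `offset_center`
#'   plus explicit `n_positions` and `window`).
#' @param bin_bp bin width (default 25); must divide `2 * window`.
#' @param n_positions,window required when `hits` is a bare data.frame.
#' @return object of class `density_profile`: data.frame `bins` (lower,
#'   upper, count, density), `n_positions`, `window`, `bin_bp`, `n_hits`.
#' @export
positional_density_profile <- function(hits, bin_bp = 25L, n_positions = NULL,
                                       window = NULL) {
  if (inherits(hits, "motif_hits")) {
    n_positions <- hits$n_positions; window <- hits$window; hits <- hits$hits
  }
  if (is.null(n_positions) || n_positions < 1L) stop_f("no anchoring positions")
  if (is.null(window) || window < 1L) stop_f("window must be positive")
  if ((2 * window) %% bin_bp != 0) stop_f("bin_bp must divide 2*window")
  edges <- seq(-window, window, by = bin_bp)
  off <- hits$offset_center
  off <- off[off >= -window & off < window]
  counts <- as.integer(table(cut(off, breaks = edges, right = FALSE)))
  structure(list(bins = data.frame(lower = edges[-length(edges)], upper = edges[-1L],
                                   count = counts,
                                   density = counts / (n_positions * bin_bp)),
                 n_positions = n_positions, window = window, bin_bp = bin_bp,
                 n_hits = sum(counts)),
            class = "density_profile")
}

# Count hits and bp inside the central core of a profile.
profile_core <- function(profile, core_bp) {
  b <- profile$bins
  half <- core_bp / 2
  core <- b$lower >= -half & b$upper <= half
  if (!any(core)) stop_f("core_bp smaller than one bin")
  list(core_count = sum(b$count[core]), total_count = sum(b$count),
       core_bp = sum(b$upper[core] - b$lower[core]),
       total_bp = sum(b$upper - b$lower))
}

#' Foreground vs background central-core motif enrichment
#'
#' Compares the hit density inside the central `core_bp` window between a
#' foreground profile (e.g. TF-bound-class SNPs) and a background profile
#' (e.g. non-bound-class SNPs). Also reports a two-sided exact binomial test
#' of the foreground's core-vs-flank hit split against the uniform
#' expectation.
#'
#' @param profile_fg,profile_bg `density_profile` objects with identical
#'   binning.
#' @param core_bp width of the central core (default 150).
#' @return list: `ratio` (fg core density / bg core density; `Inf` with
#'   `infinite = TRUE` when the background core is empty), `binomial_p`,
#'   `core_mass_fg` (fraction of foreground hits in the core).
#' @export
motif_enrichment_ratio <- function(profile_fg, profile_bg, core_bp = 150L) {
  if (!identical(profile_fg$bins$lower, profile_bg$bins$lower))
    stop_f("profiles must share binning")
  fg <- profile_core(profile_fg, core_bp)
  bg <- profile_core(profile_bg, core_bp)
  dens_fg <- fg$core_count / (profile_fg$n_positions * fg$core_bp)
  dens_bg <- bg$core_count / (profile_bg$n_positions * bg$core_bp)
  infinite <- dens_bg == 0
  ratio <- if (infinite) Inf else dens_fg / dens_bg
  p <- if (fg$total_count > 0)
    stats::binom.test(fg$core_count, fg$total_count,
                      p = fg$core_bp / fg$total_bp)$p.value
  else NA_real_
  list(ratio = ratio, binomial_p = p,
       core_mass_fg = if (fg$total_count > 0) fg$core_count / fg$total_count else NA_real_,
       infinite = infinite)
}
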