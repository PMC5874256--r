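# Cross-species expression kinetics: probeset collapse, ortholog
# concordance filtering, clustering over the combined time course, and
# relative qPCR quantification.

#' Collapse probesets to gene symbols
#'
#' Per symbol, retains the single probeset whose row mean is highest (ties
#' broken by probeset id). Unmapped probes are dropped and counted.
#'
#' @param probe_matrix numeric matrix, probes x samples, rownames = probe
#'   ids.
#' @param probe_map data.frame with columns `probe_id`, `symbol` (each
#'   probe maps to at most one symbol).
#' @return numeric matrix, symbols x samples, with attributes
#'   `"n_unmapped"` and `"chosen_probe"` (named by symbol).
#' @export
collapse_probesets <- function(probe_matrix, probe_map) {
  if (!nrow(probe_map)) stop_f("empty probe map")
  if (anyDuplicated(probe_map$probe_id)) stop_f("probe mapped to more than one symbol")
  sym <- probe_map$symbol[match(rownames(probe_matrix), probe_map$probe_id)]
  unmapped <- is.na(sym) | !nzchar(sym)
  m <- probe_matrix[!unmapped, , drop = FALSE]
  sym <- sym[!unmapped]
  means <- rowMeans(m)
  ord <- order(sym, -means, rownames(m))   # per symbol: best mean, then probe id
  first <- !duplicated(sym[ord])
  pick <- ord[first]
  out <- m[pick, , drop = FALSE]
  rownames(out) <- sym[pick]
  out <- out[order(rownames(out)), , drop = FALSE]
  attr(out, "n_unmapped") <- sum(unmapped)
  attr(out, "chosen_probe") <- stats::setNames(rownames(m)[pick][order(sym[pick])],
                                               sort(sym[pick]))
  out
}

#' Filter orthologs on cross-species kinetics similarity
#'
#' Pearson correlation between the two species' time profiles; a gene is
#' retained iff `r >= r_min`. Symbols are matched case-insensitively
#' (mouse Nfatc1 <-> human NFATC1) unless an explicit two-column ortholog
#' map (`mouse`, `human`) is given. Genes missing in either species or with
#' a zero-variance profile are dropped and logged.
#'
#' @param mouse,human numeric matrices, genes x time points (equal time
#'   point counts), rownames = symbols.
#' @param r_min retention threshold on Pearson r (default 0.5).
#' @param ortholog_map optional data.frame with columns `mouse`, `human`.
#' @return data.frame of retained pairs: `mouse_symbol`, `human_symbol`,
#'   `r`; attributes `"dropped_missing"`, `"dropped_zero_variance"`, and
#'   `"all_pairs"` (every scored pair with its r).
#' @export
orthologous_similarity_filter <- function(mouse, human, r_min = 0.5,
                                          ortholog_map = NULL) {
  if (ncol(mouse) != ncol(human)) stop_f("species must share the time-point count")
  if (is.null(ortholog_map)) {
    mu <- toupper(rownames(mouse))
    hu <- toupper(rownames(human))
    common <- intersect(mu, hu)
    ortholog_map <- data.frame(mouse = rownames(mouse)[match(common, mu)],
                               human = rownames(human)[match(common, hu)],
                               stringsAsFactors = FALSE)
    dropped_missing <- sum(!mu %in% common) + sum(!hu %in% common)
  } else {
    present <- ortholog_map$mouse %in% rownames(mouse) &
      ortholog_map$human %in% rownames(human)
    dropped_missing <- sum(!present)
    ortholog_map <- ortholog_map[present, , drop = FALSE]
  }
  mm <- mouse[ortholog_map$mouse, , drop = FALSE]
  hm <- human[ortholog_map$human, , drop = FALSE]
  sd_m <- apply(mm, 1, stats::sd); sd_h <- apply(hm, 1, stats::sd)
  zero_var <- sd_m == 0 | sd_h == 0
  r <- rep(NA_real_, nrow(mm))
  ok <- !zero_var
  if (any(ok))
    r[ok] <- vapply(which(ok), function(i) stats::cor(mm[i, ], hm[i, ]), 0)
  pairs <- data.frame(mouse_symbol = ortholog_map$mouse,
                      human_symbol = ortholog_map$human,
                      r = r, stringsAsFactors = FALSE)
  retained <- pairs[!zero_var & r >= r_min, , drop = FALSE]
  rownames(retained) <- NULL
  attr(retained, "dropped_missing") <- dropped_missing
  attr(retained, "dropped_zero_variance") <- sum(zero_var)
  attr(retained, "all_pairs") <- pairs
  retained
}

#' Cluster retained orthologs over the combined time course
#'
#' Builds each gene's profile as the concatenated mouse then human time
#' points (e.g. 4 + 4 = 8 samples) and clusters with
#' [centered_kmeans()].
#'
#' @param retained output of [orthologous_similarity_filter()].
#' @param mouse,human the expression matrices the pairs refer to.
#' @param k number of clusters.
#' @param seed integer seed.
#' @param ... passed to [centered_kmeans()].
#' @return list: `assignment` (named by mouse symbol), `centroids`
#'   (k x combined samples), `profiles` (the clustered matrix), `kmeans`
#'   (full [centered_kmeans()] result).
#' @export
cluster_kinetics <- function(retained, mouse, human, k, seed, ...) {
  if (k > nrow(retained)) stop_f("k exceeds the number of retained genes")
  profiles <- cbind(mouse[retained$mouse_symbol, , drop = FALSE],
                    human[retained$human_symbol, , drop = FALSE])
  rownames(profiles) <- retained$mouse_symbol
  km <- centered_kmeans(profiles, k, seed = seed, ...)
  list(assignment = stats::setNames(km$cluster, rownames(profiles)),
       centroids = km$centroids, profiles = profiles, kmeans = km)
}

#' Relative expression by the 2^-ddCt method
#'
#' `dCt = Ct_target - Ct_housekeeping` per condition;
#' `ddCt = dCt_condition - dCt_reference`; fold = `2^-ddCt`.
#'
#' @param ct_table data.frame with columns `condition`, `ct_target`,
#'   `ct_housekeeping` (one row per condition, e.g. averaged technical
#'   replicates).
#' @param condition,reference condition labels present in the table.
#' @return fold change (numeric scalar).
#' @export
delta_delta_ct <- function(ct_table, condition, reference) {
  need <- c("condition", "ct_target", "ct_housekeeping")
  if (!all(need %in% names(ct_table))) stop_f("ct_table needs columns %s", paste(need, collapse = ", "))
  row_of <- function(label) {
    i <- which(ct_table$condition == label)
    if (!length(i)) stop_f("condition '%s' not in table", label)
    i[1L]
  }
  ic <- row_of(condition); ir <- row_of(reference)
  if (anyNA(ct_table$ct_housekeeping[c(ic, ir)])) stop_f("missing housekeeping Ct")
  if (anyNA(ct_table$ct_target[c(ic, ir)])) stop_f("missing target Ct")
  dct_c <- ct_table$ct_target[ic] - ct_table$ct_housekeeping[ic]
  dct_r <- ct_table$ct_target[ir] - ct_table$ct_housekeeping[ir]
  2^-(dct_c - dct_r)
}
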