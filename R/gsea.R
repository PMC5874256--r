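# Gene Set Enrichment Analysis: weighted Kolmogorov-Smirnov running sum,
# gene-set permutation null, NES normalization, and NES-pooled FDR.

#' Rank genes by a two-group contrast
#'
#' @param expr numeric matrix, genes x samples, log2 scale, rownames =
#'   symbols.
#' @param group_a,group_b column names or indices of the two groups.
#' @param metric `"signal2noise"` (`(mu_a - mu_b) / (sd_a + sd_b)`, GSEA's
#'   default; needs >= 2 samples per group, otherwise falls back to log2fc
#'   with a warning) or `"log2fc"` (difference of group means on the log2
#'   scale).
#' @param sd_floor denominator floor applied per group sd under
#'   signal2noise (default 0.01 of the absolute group mean, minimum 0.01);
#'   floored genes are flagged in the `flagged` attribute.
#' @return data.frame `symbol`, `metric`, sorted descending; ties broken by
#'   symbol.
#' @export
rank_genes_by_contrast <- function(expr, group_a, group_b,
                                   metric = c("signal2noise", "log2fc"),
                                   sd_floor = 0.01) {
  metric <- match.arg(metric)
  a <- expr[, group_a, drop = FALSE]
  b <- expr[, group_b, drop = FALSE]
  if (ncol(a) < 1L || ncol(b) < 1L) stop_f("each group needs >= 1 sample")
  if (metric == "signal2noise" && (ncol(a) < 2L || ncol(b) < 2L)) {
    warning("signal2noise needs >= 2 samples per group; falling back to log2fc")
    metric <- "log2fc"
  }
  mu_a <- rowMeans(a); mu_b <- rowMeans(b)
  flagged <- character()
  if (metric == "log2fc") {
    m <- mu_a - mu_b
  } else {
    sd_a <- apply(a, 1, stats::sd); sd_b <- apply(b, 1, stats::sd)
    fa <- pmax(sd_floor * abs(mu_a), sd_floor)
    fb <- pmax(sd_floor * abs(mu_b), sd_floor)
    flagged <- rownames(expr)[sd_a < fa | sd_b < fb]
    m <- (mu_a - mu_b) / (pmax(sd_a, fa) + pmax(sd_b, fb))
  }
  out <- data.frame(symbol = rownames(expr), metric = m, stringsAsFactors = FALSE)
  out <- out[order(-out$metric, out$symbol), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "flagged") <- flagged
  out
}

# Core ES computation on a descending-sorted metric vector and a logical
# membership vector. Returns ES, its position, and the running sum.
es_running_sum <- function(metric, member, weight_p = 1) {
  N <- length(metric); K <- sum(member)
  if (K == 0L || K == N) stop_f("gene set must hit a proper subset of the ranked list")
  w <- abs(metric)^weight_p
  wsum <- sum(w[member])
  inc <- if (wsum > 0) ifelse(member, w / wsum, 0) else ifelse(member, 1 / K, 0)
  dec <- ifelse(member, 0, 1 / (N - K))
  rs <- cumsum(inc - dec)
  pos <- which.max(abs(rs))
  list(es = rs[pos], position = pos, running_sum = rs)
}

#' GSEA enrichment score for one gene set
#'
#' Weighted KS running sum over the ranked list: each set member increments
#' by `|metric|^p` (normalized over members), each miss decrements by
#' `1/(N-K)`. The ES is the extremum of the running sum by absolute value;
#' the leading edge contains the members at or before the extremum
#' (positive ES) or after it (negative ES). The running sum ends at 0 by
#' construction, which is asserted on every call.
#'
#' @param ranked data.frame from [rank_genes_by_contrast()] (columns
#'   `symbol`, `metric`, descending).
#' @param set character vector of member symbols.
#' @param weight_p metric weighting exponent (default 1; 0 gives the
#'   unweighted KS statistic).
#' @return list: `es`, `position`, `leading_edge`, `running_sum`.
#' @export
gsea_enrichment_score <- function(ranked, set, weight_p = 1) {
  member <- toupper(ranked$symbol) %in% toupper(set)
  if (!any(member)) stop_f("gene set has no member in the ranked list")
  r <- es_running_sum(ranked$metric, member, weight_p)
  stopifnot(abs(r$running_sum[length(r$running_sum)]) < 1e-9)
  leading <- if (r$es >= 0) ranked$symbol[seq_len(r$position)][member[seq_len(r$position)]]
  else ranked$symbol[r$position:nrow(ranked)][member[r$position:nrow(ranked)]]
  list(es = r$es, position = r$position, leading_edge = leading,
       running_sum = r$running_sum)
}

#' Permutation significance for GSEA
#'
#' `gene_set` mode draws size-matched random member sets from the ranked
#' list (appropriate when there are too few samples for label shuffling);
#' `phenotype` mode shuffles sample labels and requires the sample-level
#' expression matrix. NES is the ES divided by the mean absolute null ES of
#' the same sign; the nominal P is the fraction of same-sign null ES at
#' least as extreme; FDR follows the NES-pooling procedure. Reproducible
#' under `seed`.
#'
#' @param ranked ranked list (see [rank_genes_by_contrast()]).
#' @param collection named list of gene sets.
#' @param n_perm permutations per set (default 1000; >= 100 required for
#'   FDR reporting).
#' @param mode `"gene_set"` (default) or `"phenotype"`.
#' @param seed integer seed (required).
#' @param weight_p metric weighting exponent.
#' @param expr,group_a,group_b,metric passed through for phenotype mode.
#' @return data.frame: `set_id`, `size`, `es`, `nes`, `p`, `fdr`,
#'   `leading_edge` (comma-joined).
#' @export
gsea_significance <- function(ranked, collection, n_perm = 1000L,
                              mode = c("gene_set", "phenotype"), seed,
                              weight_p = 1, expr = NULL, group_a = NULL,
                              group_b = NULL, metric = "signal2noise") {
  mode <- match.arg(mode)
  if (n_perm < 100L) stop_f("n_perm must be >= 100 for FDR reporting")
  if (missing(seed)) stop_f("seed is required")
  if (mode == "phenotype" && is.null(expr))
    stop_f("phenotype mode requires the sample-level expression matrix")
  syms <- toupper(ranked$symbol)
  N <- nrow(ranked)
  with_seed(seed, {
    obs <- lapply(names(collection), function(id) {
      member <- syms %in% toupper(collection[[id]])
      if (!any(member) || all(member)) return(NULL)
      r <- gsea_enrichment_score(ranked, collection[[id]], weight_p)
      list(id = id, size = sum(member), es = r$es,
           leading = paste(r$leading_edge, collapse = ","))
    })
    obs <- Filter(Negate(is.null), obs)
    if (!length(obs)) stop_f("no gene set overlaps the ranked list")
    null_es <- vector("list", length(obs))
    if (mode == "gene_set") {
      for (i in seq_along(obs)) {
        K <- obs[[i]]$size
        null_es[[i]] <- vapply(seq_len(n_perm), function(b) {
          member <- logical(N)
          member[sample.int(N, K)] <- TRUE
          es_running_sum(ranked$metric, member, weight_p)$es
        }, 0)
      }
    } else {
      labels <- c(group_a, group_b)
      na <- length(group_a)
      perm_ranked <- lapply(seq_len(n_perm), function(b) {
        sh <- sample(labels)
        rank_genes_by_contrast(expr, sh[seq_len(na)], sh[-seq_len(na)], metric = metric)
      })
      for (i in seq_along(obs)) {
        set <- collection[[obs[[i]]$id]]
        null_es[[i]] <- vapply(perm_ranked, function(rk)
          gsea_enrichment_score(rk, set, weight_p)$es, 0)
      }
    }
    res <- data.frame(set_id = vapply(obs, `[[`, "", "id"),
                      size = vapply(obs, `[[`, 0L, "size"),
                      es = vapply(obs, `[[`, 0, "es"),
                      stringsAsFactors = FALSE)
    res$nes <- NA_real_; res$p <- NA_real_
    null_nes <- vector("list", length(obs))
    for (i in seq_along(obs)) {
      es <- res$es[i]; nul <- null_es[[i]]
      same <- if (es >= 0) nul[nul >= 0] else nul[nul < 0]
      denom <- mean(abs(same))
      res$nes[i] <- if (length(same) && denom > 0) es / denom else NA_real_
      res$p[i] <- if (length(same)) sum(abs(same) >= abs(es)) / length(same) else 0
      pos <- nul[nul >= 0]; neg <- nul[nul < 0]
      null_nes[[i]] <- c(if (length(pos) && mean(pos) > 0) pos / mean(pos) else numeric(),
                         if (length(neg)) neg / mean(-neg) else numeric())
    }
    pooled <- unlist(null_nes)
    res$fdr <- vapply(seq_len(nrow(res)), function(i) {
      nes <- res$nes[i]
      if (is.na(nes)) return(NA_real_)
      if (nes >= 0) {
        num <- mean(pooled >= nes)
        den <- mean(res$nes >= nes, na.rm = TRUE)
      } else {
        num <- mean(pooled <= nes)
        den <- mean(res$nes <= nes, na.rm = TRUE)
      }
      min(1, if (den > 0) num / den else NA_real_)
    }, 0)
    res$leading_edge <- vapply(obs, `[[`, "", "leading")
    res[order(res$p, res$set_id), , drop = FALSE]
  })
}
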