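# Centered K-means: Lloyd iterations under 1 - Pearson correlation of
# mean-centered rows (the "centered" similarity of classic expression
# clustering tools), with restarts and deterministic seeding.

# Standardize rows to zero mean, unit norm; constant rows become all-zero
# (correlation 0 with everything).
standardize_rows <- function(mat) {
  c_mat <- mat - rowMeans(mat)
  nrm <- sqrt(rowSums(c_mat^2))
  flagged <- nrm == 0
  nrm[flagged] <- 1
  list(z = c_mat / nrm, flagged = which(flagged))
}

#' Centered K-means clustering of row profiles
#'
#' Distance between a row and a centroid is `1 - cor(row, centroid)` after
#' mean-centering, equivalent to spherical K-means on standardized rows, so
#' Lloyd updates (centroid = mean of standardized member rows) never
#' increase the objective; this is asserted at every iteration. The best of
#' `n_restarts` random initializations (by within-cluster distance sum) is
#' returned; results are deterministic under `seed`. Constant
#' (zero-variance) rows have correlation 0 with every centroid and fall to
#' the lowest-index cluster by the tie rule; they are reported in
#' `flagged`.
#'
#' @param mat numeric matrix (rows = profiles).
#' @param k number of clusters (`1 <= k <= nrow(mat)`).
#' @param seed integer seed (required).
#' @param max_iter Lloyd iteration cap per restart (default 100).
#' @param n_restarts random restarts (default 10).
#' @return list: `cluster` (row assignments), `order` (rows sorted by
#'   cluster then distance-to-centroid), `centroids` (k x ncol, mean of
#'   centered member rows), `objective`, `flagged` (constant row indices).
#' @export
centered_kmeans <- function(mat, k, seed, max_iter = 100L, n_restarts = 10L) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  if (k < 1L || k > n) stop_f("k must be between 1 and nrow(mat)")
  if (missing(seed)) stop_f("seed is required")
  st <- standardize_rows(mat)
  z <- st$z
  run_once <- function() {
    centroid_z <- z[sample.int(n, k), , drop = FALSE]
    assign_prev <- rep(0L, n)
    obj_prev <- Inf
    for (iter in seq_len(max_iter)) {
      cz <- centroid_z - rowMeans(centroid_z)
      cn <- sqrt(rowSums(cz^2)); cn[cn == 0] <- 1
      cz <- cz / cn
      sim <- z %*% t(cz)                 # n x k correlations
      assign <- max.col(sim, ties.method = "first")
      obj <- sum(1 - sim[cbind(seq_len(n), assign)])
      stopifnot(obj <= obj_prev + 1e-8)  # Lloyd monotonicity
      if (identical(assign, assign_prev)) break
      assign_prev <- assign; obj_prev <- obj
      for (j in seq_len(k)) {
        members <- which(assign == j)
        if (length(members)) centroid_z[j, ] <- colMeans(z[members, , drop = FALSE])
        # empty cluster keeps its previous centroid
      }
    }
    list(assign = assign, obj = obj)
  }
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      cand <- run_once()
      if (is.null(best) || cand$obj < best$obj - 1e-12) best <- cand
    }
    assign <- best$assign
    centroids <- matrix(0, k, ncol(mat))
    dist_to_centroid <- numeric(n)
    centered <- mat - rowMeans(mat)
    for (j in seq_len(k)) {
      members <- which(assign == j)
      if (!length(members)) next
      centroids[j, ] <- colMeans(centered[members, , drop = FALSE])
      cz <- centroids[j, ] - mean(centroids[j, ])
      cn <- sqrt(sum(cz^2)); if (cn == 0) cn <- 1
      dist_to_centroid[members] <- 1 - as.vector(z[members, , drop = FALSE] %*% (cz / cn))
    }
    list(cluster = assign,
         order = order(assign, dist_to_centroid),
         centroids = centroids,
         objective = best$obj,
         flagged = st$flagged)
  })
}
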