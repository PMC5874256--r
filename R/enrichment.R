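# Hypergeometric gene-set enrichment with BH correction.

#' Read a GMT gene-set collection
#'
#' `set_id TAB description TAB member1 TAB member2 ...` per line. Members
#' are uppercased and de-duplicated.
#'
#' @param path GMT file.
#' @return named list of character vectors, with a `description` attribute
#'   on each element.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (l in lines) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop_f("GMT line with fewer than 3 fields: %s", f[1L])
    members <- unique(toupper(f[-(1:2)]))
    members <- members[nzchar(members)]
    attr(members, "description") <- f[2L]
    out[[f[1L]]] <- members
  }
  out
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` where `X` counts category members among `n` draws without
#' replacement from a universe of `N` containing `K` category members.
#' Computed as an exact sum of log-binomial terms.
#'
#' @param k observed hits.
#' @param K category size in the universe.
#' @param n draw (query) size.
#' @param N universe size.
#' @return probability in (0, 1].
#' @export
hypergeometric_tail <- function(k, K, n, N) {
  if (!all(vapply(list(k, K, n, N), is_count, TRUE))) stop_f("counts must be non-negative integers")
  if (k > min(K, n) || K > N || n > N) stop_f("inconsistent counts: k=%d K=%d n=%d N=%d", k, K, n, N)
  if (k == 0) return(1)
  i <- k:min(K, n)
  lg <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(lg)
  min(1, exp(m + log(sum(exp(lg - m)))))
}

#' Hypergeometric enrichment of a gene list against a collection
#'
#' One upper-tail hypergeometric test per gene set with at least one query
#' hit, BH-adjusted across tested sets. Symbols are uppercase-normalized;
#' query and set members are intersected with the universe first.
#'
#' @param query character vector of gene symbols.
#' @param collection named list of gene sets (see [read_gmt()]).
#' @param universe character vector of all eligible symbols (e.g. every
#'   gene in the annotation).
#' @return data.frame sorted by P (ties by set id): `set_id`, `k`, `K`,
#'   `n`, `N`, `p`, `q`.
#' @export
enrich_gene_list <- function(query, collection, universe) {
  query <- unique(toupper(query))
  universe <- unique(toupper(universe))
  query <- intersect(query, universe)
  if (!length(query)) stop_f("empty query after universe intersection")
  n <- length(query); N <- length(universe)
  rows <- lapply(names(collection), function(id) {
    members <- intersect(toupper(collection[[id]]), universe)
    k <- length(intersect(query, members))
    if (k == 0L) return(NULL)
    data.frame(set_id = id, k = k, K = length(members), n = n, N = N,
               p = hypergeometric_tail(k, length(members), n, N),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) return(data.frame(set_id = character(), k = integer(), K = integer(),
                                       n = integer(), N = integer(), p = numeric(), q = numeric()))
  rows$q <- stats::p.adjust(rows$p, method = "BH")
  rows <- rows[order(rows$p, rows$set_id), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}
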