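#' Over-representation analysis with the one-sided Fisher test
#'
#' For every gene set, tests whether the query list overlaps it more than
#' expected by chance within the stated universe. The p-value is the upper
#' hypergeometric tail
#' `p = sum_{i >= k} C(K, i) C(N - K, n - i) / C(N, n)`
#' (equivalent to a one-sided Fisher exact test on the 2x2 table), where `N`
#' is the universe size, `K` the set size in the universe, `n` the query
#' size in the universe and `k` the observed overlap. Query genes outside
#' the universe are dropped (with a message); set members are restricted to
#' the universe and sets that become empty are removed. Benjamini-Hochberg
#' q-values are reported alongside, but results are ranked by raw p.
#'
#' @param query character vector of query gene ids.
#' @param sets named list of gene-set member vectors (e.g. from
#'   [read_gmt()]).
#' @param universe character vector: the gene background (all genes
#'   measured).
#' @return data frame sorted by (p, set): `set`, `k`, `K`, `n`, `N`, `p`,
#'   `q`, `score` where `score = (k/n) / (K/N)` is the enrichment score
#'   (ratio of observed to expected overlap proportion).
#' @export
#' @examples
#' sets <- list(A = c("g1", "g2", "g3"), B = c("g4", "g5"))
#' fisher_enrich(c("g1", "g2"), sets, universe = paste0("g", 1:20))
fisher_enrich <- function(query, sets, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty gene universe", call. = FALSE)
  query <- unique(as.character(query))
  n_out <- sum(!query %in% universe)
  if (n_out > 0L) {
    message(sprintf("fisher_enrich: dropping %d query gene(s) outside the universe",
                    n_out))
    query <- query[query %in% universe]
  }
  if (length(query) == 0L)
    stop("query has no genes in the universe", call. = FALSE)
  sets <- lapply(sets, function(s) intersect(unique(as.character(s)), universe))
  sets <- sets[vapply(sets, length, integer(1)) > 0L]
  N <- length(universe)
  n <- length(query)
  res <- do.call(rbind, lapply(names(sets), function(id) {
    K <- length(sets[[id]])
    k <- length(intersect(sets[[id]], query))
    # upper tail P(X >= k) for X ~ Hypergeometric(N, K, n)
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set = id, k = k, K = K, n = n, N = N, p = p,
               score = (k / n) / (K / N), stringsAsFactors = FALSE)
  }))
  if (is.null(res))
    return(data.frame(set = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      q = numeric(), score = numeric(),
                      stringsAsFactors = FALSE))
  res$q <- bh_adjust(res$p)
  res <- res[order(res$p, res$set),
             c("set", "k", "K", "n", "N", "p", "q", "score"), drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up false-discovery-rate adjustment with monotonicity
#' enforcement; returned q-values satisfy `p <= q <= 1`.
#'
#' @param p numeric vector of p-values.
#' @return numeric vector of q-values in the input order.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}
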