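#' Threshold a scored protein-protein interaction table into a network
#'
#' Retains edges whose combined confidence score is at least `min_score`
#' (inclusive, matching the usual "high confidence >= 0.7" setting) and
#' drops isolated proteins. Scores may arrive on the unit scale or in the
#' STRING-style 0-999 integer dialect; when any score exceeds 1 the whole
#' column is divided by 1000 before thresholding.
#'
#' @param edges data frame with columns `protein1`, `protein2`,
#'   `combined_score`.
#' @param min_score threshold in \[0, 1\] (default 0.7).
#' @return undirected igraph over the retained edges with a `score` edge
#'   attribute.
#' @export
threshold_ppi <- function(edges, min_score = 0.7) {
  stopifnot(all(c("protein1", "protein2", "combined_score") %in% names(edges)))
  if (!is.numeric(min_score) || min_score < 0 || min_score > 1)
    stop("'min_score' must be in [0, 1]", call. = FALSE)
  score <- edges$combined_score
  if (length(score) && max(score) > 1) score <- score / 1000
  if (length(score) && (any(!is.finite(score)) || any(score < 0) || any(score > 1)))
    stop("combined scores outside [0, 1] after scale normalization",
         call. = FALSE)
  if (any(edges$protein1 == edges$protein2))
    stop("self-interactions are not allowed", call. = FALSE)
  keep <- which(score >= min_score)
  if (length(keep) == 0L)
    return(igraph::make_empty_graph(n = 0, directed = FALSE))
  kept <- data.frame(from = edges$protein1[keep], to = edges$protein2[keep],
                     score = score[keep], stringsAsFactors = FALSE)
  # collapse duplicate unordered pairs, keeping the first record
  key <- ifelse(kept$from < kept$to,
                paste(kept$from, kept$to), paste(kept$to, kept$from))
  kept <- kept[!duplicated(key), , drop = FALSE]
  kept <- kept[order(kept$from, kept$to), , drop = FALSE]
  igraph::graph_from_data_frame(kept, directed = FALSE)
}

#' Rank PPI hub genes by degree
#'
#' Degree ranking with full tie expansion; shares its implementation with
#' [rank_hubs()].
#'
#' @inheritParams rank_hubs
#' @return data frame `node`, `degree`.
#' @export
degree_hubs <- function(network, k = Inf) {
  rank_hubs(network, k = k)
}

#' Node and edge counts of a network
#'
#' @param network an igraph object (after thresholding and isolate
#'   removal).
#' @return named list with `nodes` and `edges`.
#' @export
network_summary <- function(network) {
  list(nodes = igraph::vcount(network), edges = igraph::ecount(network))
}
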