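#' Normalize RNA identifiers
#'
#' Case-folds identifiers to lower case, trims whitespace, and corrects the
#' frequent `"has-miR"` misspelling of the human miRNA prefix to
#' `"hsa-mir"`. Applied to a data frame of interaction records it normalizes
#' the `miRNA` and `target` columns and collapses duplicates that differ
#' only by spelling.
#'
#' @param x character vector of ids, or an interaction data frame with
#'   columns `miRNA`, `target` (and optionally `database`).
#' @return object of the same shape with normalized ids (duplicate records
#'   removed for data frames).
#' @export
#' @examples
#' normalize_ids("has-miR-204-5p")  # "hsa-mir-204-5p"
normalize_ids <- function(x) {
  norm <- function(v) sub("^has-", "hsa-", tolower(trimws(as.character(v))))
  if (is.data.frame(x)) {
    stopifnot(all(c("miRNA", "target") %in% names(x)))
    x$miRNA <- norm(x$miRNA)
    x$target <- norm(x$target)
    x <- unique(x)
    rownames(x) <- NULL
    x
  } else {
    norm(x)
  }
}

#' Filter miRNA-target pairs by multi-database evidence
#'
#' A (miRNA, target) pair is retained only if it is listed in at least
#' `min_db` distinct source databases; duplicate records within one database
#' count once. The conventional default requires presence in at least 3
#' databases.
#'
#' @param tables an interaction data frame with columns `miRNA`, `target`,
#'   `database`, or a list of such data frames (one per database) that is
#'   row-bound first.
#' @param min_db minimum number of distinct supporting databases (>= 1).
#' @return data frame `miRNA`, `target`, `evidence` (distinct database
#'   count), sorted by (miRNA, target).
#' @export
filter_by_evidence <- function(tables, min_db = 3L) {
  min_db <- assert_count(min_db, "min_db")
  if (is.data.frame(tables)) tab <- tables else tab <- do.call(rbind, tables)
  stopifnot(all(c("miRNA", "target", "database") %in% names(tab)))
  tab <- unique(tab[, c("miRNA", "target", "database")])
  if (nrow(tab) == 0L)
    return(data.frame(miRNA = character(), target = character(),
                      evidence = integer(), stringsAsFactors = FALSE))
  key <- paste(tab$miRNA, tab$target, sep = "\t")
  counts <- table(key)
  keep <- names(counts)[counts >= min_db]
  parts <- strsplit(keep, "\t", fixed = TRUE)
  out <- data.frame(miRNA = vapply(parts, `[`, "", 1L),
                    target = vapply(parts, `[`, "", 2L),
                    evidence = as.integer(counts[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$miRNA, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble sign-consistent ceRNA triples
#'
#' Emits every (lncRNA, miRNA, mRNA) combination for which the
#' miRNA-lncRNA pair and the miRNA-mRNA pair are both present in the
#' supplied interaction tables, all three members are differentially
#' expressed, and the directions obey the ceRNA consistency rule: the lncRNA
#' and the mRNA share one direction and the miRNA has the opposite one (a
#' sponge lncRNA sequesters the miRNA and thereby de-represses the mRNA, so
#' both polarity patterns up/down/up and down/up/down qualify).
#'
#' @param de_lnc,de_mir,de_mrna DE data frames (as from [screen_de()]) for
#'   the three RNA classes.
#' @param lnc_mir_pairs data frame with columns `miRNA`, `target` (the
#'   lncRNA); single-source, so no evidence threshold is applied.
#' @param mir_mrna_pairs data frame with columns `miRNA`, `target` (the
#'   mRNA) and optionally `evidence` (as from [filter_by_evidence()]).
#' @return data frame of triples sorted by (lncRNA, miRNA, mRNA):
#'   `lncRNA`, `lnc_direction`, `miRNA`, `mir_direction`, `mRNA`,
#'   `mrna_direction`, `evidence`, `polarity` (`"miRNA-up"` or
#'   `"miRNA-down"`). Interaction tables and DE ids are assumed already
#'   normalized ([normalize_ids()]) and evidence-filtered.
#' @export
assemble_triples <- function(de_lnc, de_mir, de_mrna,
                             lnc_mir_pairs, mir_mrna_pairs) {
  empty <- data.frame(lncRNA = character(), lnc_direction = character(),
                      miRNA = character(), mir_direction = character(),
                      mRNA = character(), mrna_direction = character(),
                      evidence = integer(), polarity = character(),
                      stringsAsFactors = FALSE)
  if (nrow(de_lnc) == 0L || nrow(de_mir) == 0L || nrow(de_mrna) == 0L ||
      nrow(lnc_mir_pairs) == 0L || nrow(mir_mrna_pairs) == 0L)
    return(empty)

  lm <- unique(lnc_mir_pairs[, c("miRNA", "target")])
  names(lm) <- c("miRNA", "lncRNA")
  mm <- mir_mrna_pairs
  if (!"evidence" %in% names(mm)) mm$evidence <- NA_integer_
  mm <- unique(mm[, c("miRNA", "target", "evidence")])
  names(mm) <- c("miRNA", "mRNA", "evidence")

  lm <- lm[lm$lncRNA %in% de_lnc$feature & lm$miRNA %in% de_mir$feature, ,
           drop = FALSE]
  mm <- mm[mm$mRNA %in% de_mrna$feature & mm$miRNA %in% de_mir$feature, ,
           drop = FALSE]
  if (nrow(lm) == 0L || nrow(mm) == 0L) return(empty)

  cand <- merge(lm, mm, by = "miRNA")
  if (nrow(cand) == 0L) return(empty)
  cand$lnc_direction <- de_lnc$direction[match(cand$lncRNA, de_lnc$feature)]
  cand$mir_direction <- de_mir$direction[match(cand$miRNA, de_mir$feature)]
  cand$mrna_direction <- de_mrna$direction[match(cand$mRNA, de_mrna$feature)]
  ok <- cand$lnc_direction == cand$mrna_direction &
    cand$lnc_direction != cand$mir_direction
  out <- cand[ok, , drop = FALSE]
  if (nrow(out) == 0L) return(empty)
  out$polarity <- paste0("miRNA-", out$mir_direction)
  out <- out[order(out$lncRNA, out$miRNA, out$mRNA),
             c("lncRNA", "lnc_direction", "miRNA", "mir_direction",
               "mRNA", "mrna_direction", "evidence", "polarity"),
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Materialize a ceRNA network from triples
#'
#' Deduplicates the nodes and edges implied by a triple table into an
#' undirected igraph: every triple contributes one lncRNA-miRNA and one
#' miRNA-mRNA edge. Vertices carry `class` and `direction` attributes, edges
#' a `kind` attribute; the network is bipartite between miRNAs and the
#' other classes, with no self-loops or duplicate edges.
#'
#' @param triples data frame from [assemble_triples()].
#' @return an igraph object (possibly empty).
#' @export
build_cerna_network <- function(triples) {
  if (nrow(triples) == 0L)
    return(igraph::make_empty_graph(n = 0, directed = FALSE))
  nodes <- unique(rbind(
    data.frame(name = triples$lncRNA, class = "lncRNA",
               direction = triples$lnc_direction, stringsAsFactors = FALSE),
    data.frame(name = triples$miRNA, class = "miRNA",
               direction = triples$mir_direction, stringsAsFactors = FALSE),
    data.frame(name = triples$mRNA, class = "mRNA",
               direction = triples$mrna_direction, stringsAsFactors = FALSE)))
  nodes <- nodes[order(nodes$name), , drop = FALSE]
  edges <- unique(rbind(
    data.frame(from = triples$lncRNA, to = triples$miRNA,
               kind = "lncRNA-miRNA", stringsAsFactors = FALSE),
    data.frame(from = triples$miRNA, to = triples$mRNA,
               kind = "miRNA-mRNA", stringsAsFactors = FALSE)))
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}

#' Rank network nodes by degree
#'
#' Sorts nodes by degree (number of incident edges) descending, breaking
#' ties by node id ascending, and returns the top `k` with full tie
#' expansion: every node tied with the k-th degree is included. Used both
#' for ceRNA networks and for PPI hub screening.
#'
#' @param network an igraph object.
#' @param k number of top nodes requested (default all nodes).
#' @return data frame `node`, `degree` (plus `class` when the network has a
#'   class vertex attribute), sorted as ranked.
#' @export
rank_hubs <- function(network, k = Inf) {
  if (igraph::vcount(network) == 0L)
    return(data.frame(node = character(), degree = integer(),
                      stringsAsFactors = FALSE))
  deg <- igraph::degree(network)
  ord <- order(-deg, names(deg))
  deg <- deg[ord]
  if (is.finite(k) && k < length(deg)) {
    cutoff <- deg[[k]]
    deg <- deg[deg >= cutoff]
  }
  out <- data.frame(node = names(deg), degree = as.integer(unname(deg)),
                    stringsAsFactors = FALSE)
  if ("class" %in% igraph::vertex_attr_names(network))
    out$class <- igraph::vertex_attr(network, "class",
                                     index = out$node)
  rownames(out) <- NULL
  out
}
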