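# Plain-text readers/writers for the pipeline's standard formats: expression
# TSV (first column `feature`, header = sample ids), sample-metadata TSV,
# 3-column interaction TSV, GMT gene sets, SIF and GraphML networks.

#' Write / read an expression matrix as TSV
#'
#' The first column (`feature`) holds feature ids; remaining columns are
#' samples.
#'
#' @param matrix numeric feature x sample matrix with dimnames.
#' @param path file path.
#' @return `read_expression_tsv()` returns the numeric matrix.
#' @export
write_expression_tsv <- function(matrix, path) {
  df <- data.frame(feature = rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read / write gene sets in GMT format
#'
#' GMT is tab-separated: set id, description, then member genes. Reading
#' delegates to `fgsea::gmtPathways()`.
#'
#' @param sets named list of character vectors.
#' @param path file path.
#' @param descriptions optional character vector of set descriptions
#'   (defaults to the set ids).
#' @return `read_gmt()` returns a named list of member vectors.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- names(sets)
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Export a network in SIF and GraphML formats
#'
#' SIF rows are `node <TAB> interaction-kind <TAB> node`; the edge `kind`
#' attribute (or `"interacts"`) supplies the relation. GraphML export keeps
#' all node/edge attributes and goes through `igraph::write_graph()`.
#'
#' @param network an igraph object.
#' @param path output path (extension decides nothing; use both helpers).
#' @return the path, invisibly.
#' @export
write_sif <- function(network, path) {
  if (igraph::ecount(network) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  el <- igraph::as_edgelist(network)
  kind <- if ("kind" %in% igraph::edge_attr_names(network))
    igraph::edge_attr(network, "kind") else rep("interacts", nrow(el))
  writeLines(paste(el[, 1L], kind, el[, 2L], sep = "\t"), path)
  invisible(path)
}

#' @rdname write_sif
#' @export
write_graphml <- function(network, path) {
  igraph::write_graph(network, path, format = "graphml")
  invisible(path)
}
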