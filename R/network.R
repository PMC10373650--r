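#' Build a directed gene-interaction network from a scored edge list
#'
#' Edges with confidence below `threshold` are dropped (the STRING
#' high-confidence cut of 0.8 is the default). When the input carries no
#' orientation (`directed = FALSE`, the fallback used when no inferred
#' directed network is supplied) every kept edge is expanded into both
#' directions. Self-loops and, after filtering, isolated nodes are removed.
#'
#' @param edges A data frame. Either three columns (`node_a`, `node_b`,
#'   `score` on a \[0, 1\] scale, as returned by [read_scored_edges()]) or two
#'   columns (`from`, `to`), in which case all scores are taken as 1.
#' @param threshold Minimum confidence in \[0, 1\] for an edge to be kept.
#' @param directed If `TRUE` the rows are already oriented source -> target;
#'   if `FALSE` each row yields both directions.
#' @return An `smfe_network` object.
#' @examples
#' net <- build_network(
#'   data.frame(node_a = c("A", "B"), node_b = c("B", "C"),
#'              score = c(0.9, 0.7)),
#'   threshold = 0.8
#' )
#' net$nodes
#' @export
build_network <- function(edges, threshold = 0.8, directed = FALSE) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold < 0 || threshold > 1) {
    abort("threshold must be a single number in [0, 1]")
  }
  edges <- as_tibble(edges)
  if (ncol(edges) == 2L) {
    edges$score <- 1
  } else if (ncol(edges) < 2L) {
    abort("edge list needs at least 2 columns")
  }
  from <- as.character(edges[[1L]])
  to <- as.character(edges[[2L]])
  score <- as.numeric(edges[[3L]])
  if (anyNA(score) || any(score < 0 | score > 1)) {
    abort("edge scores must lie in [0, 1]; run read_scored_edges() for STRING input")
  }
  keep <- score >= threshold & from != to
  from <- from[keep]
  to <- to[keep]
  if (!directed) {
    tmp <- from
    from <- c(from, to)
    to <- c(to, tmp)
  }
  el <- unique(tibble(from = from, to = to))
  el <- arrange(el, .data$from, .data$to)
  if (nrow(el) == 0L) {
    warn("no edges pass the confidence threshold; network is empty")
  }
  new_smfe_network(el)
}

new_smfe_network <- function(edge_tbl) {
  nodes <- sort(unique(c(edge_tbl$from, edge_tbl$to)))
  structure(list(edges = edge_tbl, nodes = nodes), class = "smfe_network")
}

#' @export
print.smfe_network <- function(x, ...) {
  cat(sprintf("<smfe_network> %d nodes, %d directed edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' @export
format.smfe_network <- function(x, ...) {
  sprintf("<smfe_network> %d nodes, %d directed edges",
          length(x$nodes), nrow(x$edges))
}

# internal: neighbor list per center under a neighbor mode
neighbor_edges <- function(net, neighbor_mode = c("out", "in", "both")) {
  neighbor_mode <- match.arg(neighbor_mode)
  el <- net$edges
  switch(neighbor_mode,
    out = el,
    `in` = tibble(from = el$to, to = el$from),
    both = unique(bind_rows(el, tibble(from = el$to, to = el$from)))
  )
}

#' Extract a gene's local network (center plus first-order neighbors)
#'
#' The local network of a center gene consists of the center and its
#' first-order neighbors in the directed global network -- by default the
#' out-neighbors, matching the flow reading of the transition probabilities
#' (probability is transmitted from the center along its outgoing edges).
#' Neighbors are returned sorted by gene identifier so every downstream sum
#' is reproducible.
#'
#' @param net An `smfe_network`.
#' @param gene Center gene identifier; must be a node of `net`.
#' @param neighbor_mode Which neighbors form the local network: `"out"`
#'   (default), `"in"`, or `"both"`.
#' @return A list with elements `center` (the gene) and `neighbors`
#'   (character vector, possibly empty), of class `smfe_local_network`.
#' @export
local_network <- function(net, gene, neighbor_mode = "out") {
  stopifnot(inherits(net, "smfe_network"))
  if (!gene %in% net$nodes) abort(sprintf("unknown gene '%s'", gene))
  el <- neighbor_edges(net, neighbor_mode)
  nb <- sort(unique(el$to[el$from == gene]))
  structure(list(center = gene, neighbors = nb), class = "smfe_local_network")
}

#' Genes with enough neighbors to receive a local sMFE score
#'
#' The differential score divides by `log(M)` where `M` is the neighbor
#' count, which is zero at `M = 1` and undefined at `M = 0`, so only genes
#' with at least `min_neighbors` (default 2) neighbors are scoreable.
#' Excluded genes may still appear as neighbors of others.
#'
#' @inheritParams local_network
#' @param min_neighbors Minimum neighbor count (default 2).
#' @return Sorted character vector of scoreable gene identifiers.
#' @export
scoreable_genes <- function(net, min_neighbors = 2L, neighbor_mode = "out") {
  stopifnot(inherits(net, "smfe_network"))
  el <- neighbor_edges(net, neighbor_mode)
  deg <- table(el$from)
  sort(names(deg)[deg >= min_neighbors])
}

# internal: restrict to genes present in an expression matrix, drop
# resulting self-contained orphans
map_network <- function(net, genes, quiet = FALSE) {
  missing <- setdiff(net$nodes, genes)
  if (length(missing) > 0L && !quiet) {
    warn(sprintf("%d network gene(s) absent from the expression data were dropped (e.g. %s)",
                 length(missing), toString(head(missing, 3L))))
  }
  el <- net$edges
  keep <- el$from %in% genes & el$to %in% genes
  new_smfe_network(el[keep, , drop = FALSE])
}
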