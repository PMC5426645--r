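#' Construct a PPI network
#'
#' A `ppi_network` is a simple undirected graph over opaque protein
#' identifiers.  Edges are stored canonically (lexicographically smaller
#' endpoint first), self-loops are dropped and duplicates collapsed, so
#' `(u, v)` and `(v, u)` always compare equal.
#'
#' @param edges two-column character matrix or data frame of endpoint
#'   pairs; may be `NULL` or zero-row for an edgeless network.
#' @param nodes optional character vector of node identifiers.  Nodes
#'   appearing in `edges` are always included; `nodes` adds isolated
#'   proteins on top.
#'
#' @return An object of class `ppi_network`: a list with `nodes`
#'   (sorted character vector) and `edges` (n x 2 character matrix in
#'   canonical order, sorted rows, no duplicates).
#' @export
#' @examples
#' net <- ppi_network(rbind(c("B", "A"), c("A", "C")))
#' net$edges
ppi_network <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges) || NROW(edges) == 0L) {
    em <- matrix(character(), ncol = 2L)
  } else {
    if (is.data.frame(edges)) edges <- as.matrix(edges[, 1:2])
    if (!is.matrix(edges) || ncol(edges) < 2L)
      stop("`edges` must be a two-column matrix or data frame")
    storage.mode(edges) <- "character"
    em <- canonical_pairs(edges[, 1L], edges[, 2L])
    em <- em[em[, 1L] != em[, 2L], , drop = FALSE]      # self-loops out
    em <- em[!duplicated(pair_key(em[, 1L], em[, 2L])), , drop = FALSE]
    em <- em[order(em[, 1L], em[, 2L]), , drop = FALSE]
  }
  all_nodes <- sort(unique(c(as.character(em), as.character(nodes))))
  structure(list(nodes = all_nodes, edges = em), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("ppi_network: %d proteins, %d interactions\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' @export
summary.ppi_network <- function(object, ...) {
  deg <- node_degrees(object)
  cat(sprintf("ppi_network: %d proteins, %d interactions\n",
              length(object$nodes), nrow(object$edges)))
  if (length(deg)) {
    cat(sprintf("degree: min %d, median %g, max %d; isolated: %d\n",
                min(deg), stats::median(deg), max(deg), sum(deg == 0L)))
  }
  invisible(object)
}

# canonical (u, v) with u <= v, as a two-column character matrix
canonical_pairs <- function(u, v) {
  u <- as.character(u); v <- as.character(v)
  swap <- u > v
  cbind(ifelse(swap, v, u), ifelse(swap, u, v))
}

# stable string key for a canonical pair; "\r" cannot occur in sane IDs
pair_key <- function(u, v) paste(u, v, sep = "\r")

# keys of all edges of a network
edge_keys <- function(net) pair_key(net$edges[, 1L], net$edges[, 2L])

#' Degrees of all nodes
#' @param net a [ppi_network()].
#' @return Named integer vector over `net$nodes`.
#' @export
node_degrees <- function(net) {
  deg <- integer(length(net$nodes))
  names(deg) <- net$nodes
  if (nrow(net$edges)) {
    tab <- table(factor(as.character(net$edges), levels = net$nodes))
    deg[] <- as.integer(tab)
  }
  deg
}

#' Convert to an igraph graph
#' @param net a [ppi_network()].
#' @return An undirected `igraph` graph with vertex names `net$nodes`.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  igraph::graph_from_data_frame(
    as.data.frame(net$edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = net$nodes, stringsAsFactors = FALSE))
}

#' Add predicted links to a network
#'
#' Returns the union of an original network and a set of predicted pairs.
#' The predicted pairs must be new: scoring only ever considers unlinked
#' pairs, so a predicted pair duplicating an existing edge is an error.
#'
#' @param original a [ppi_network()].
#' @param predicted two-column character matrix of canonical pairs (as
#'   returned by [predict_links()]), disjoint from `original`'s edges.
#' @return A new `ppi_network`; `original` is unchanged.
#' @export
augment_network <- function(original, predicted) {
  stopifnot(inherits(original, "ppi_network"))
  if (is.null(predicted) || NROW(predicted) == 0L) return(original)
  if (is.data.frame(predicted)) predicted <- as.matrix(predicted[, 1:2])
  storage.mode(predicted) <- "character"
  pm <- canonical_pairs(predicted[, 1L], predicted[, 2L])
  if (any(pm[, 1L] == pm[, 2L]))
    stop("predicted pairs must not be self-loops")
  dup <- pair_key(pm[, 1L], pm[, 2L]) %in% edge_keys(original)
  if (any(dup))
    stop("predicted pair(s) already present in the original network: ",
         paste(pm[dup, 1L], pm[dup, 2L], sep = "-", collapse = ", "))
  ppi_network(rbind(original$edges, pm), nodes = original$nodes)
}

#' All unlinked pairs of a network
#'
#' Enumerates the canonical node pairs of `net` that are not edges.
#' Intended for small and moderate networks (the stage-1 scorer works on
#' the correlation matrix directly and never materialises this).
#'
#' @param net a [ppi_network()].
#' @param nodes optional subset of nodes to enumerate over.
#' @return Two-column character matrix of canonical unlinked pairs.
#' @export
unlinked_pairs <- function(net, nodes = NULL) {
  if (is.null(nodes)) nodes <- net$nodes
  nodes <- sort(unique(nodes))
  n <- length(nodes)
  if (n < 2L) return(matrix(character(), ncol = 2L))
  idx <- utils::combn(n, 2L)
  pairs <- cbind(nodes[idx[1L, ]], nodes[idx[2L, ]])
  keep <- !(pair_key(pairs[, 1L], pairs[, 2L]) %in% edge_keys(net))
  pairs[keep, , drop = FALSE]
}
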