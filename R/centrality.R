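#' Protein centrality measures
#'
#' Computes one of six node centralities on a PPI network:
#' \describe{
#'   \item{DC}{degree centrality.}
#'   \item{BC}{shortest-path betweenness.}
#'   \item{CC}{closeness, component-restricted and scaled by
#'     `(component size - 1) / (N - 1)` so that disconnected graphs are
#'     handled without infinite distances (isolated nodes score 0).}
#'   \item{EC}{principal-eigenvector centrality, by power iteration on
#'     `A + I` (the shift breaks two-periodic oscillation on bipartite
#'     graphs without changing the eigenvector) to an L-infinity
#'     tolerance of 1e-10, normalised to unit maximum, all entries
#'     nonnegative.}
#'   \item{SC}{subgraph centrality, the diagonal of the matrix
#'     exponential of the adjacency matrix,
#'     `SC(i) = sum_k (A^k)_ii / k!`, via symmetric eigendecomposition.}
#'   \item{NC}{sum over incident edges of the edge clustering
#'     coefficient `ECC(u, v) = z(u, v) / min(d_u - 1, d_v - 1)`, where
#'     `z` counts triangles containing the edge and `ECC = 0` when the
#'     denominator is 0.}
#' }
#' Further scorers can be plugged in through the registry (see
#' [register_centrality()]).
#'
#' @param net a nonempty [ppi_network()].
#' @param method method name; one of the registry's entries.
#' @return Named numeric vector of scores over `net$nodes`.
#' @export
#' @examples
#' tri <- ppi_network(rbind(c("A", "B"), c("B", "C"), c("A", "C")))
#' centrality(tri, "NC")  # every node 2
centrality <- function(net, method) {
  stopifnot(inherits(net, "ppi_network"))
  if (!length(net$nodes)) stop("network is empty")
  fun <- .centrality_registry[[method]]
  if (is.null(fun))
    stop("unknown centrality method '", method, "'; registered: ",
         paste(names(.centrality_registry), collapse = ", "))
  out <- fun(net)
  out[net$nodes]
}

.centrality_registry <- new.env(parent = emptyenv())

#' Register a centrality scorer
#'
#' @param name method name.
#' @param fun function taking a `ppi_network` and returning a named
#'   numeric vector over its nodes.
#' @return Invisibly, `name`.
#' @export
register_centrality <- function(name, fun) {
  stopifnot(is.character(name), is.function(fun))
  assign(name, fun, envir = .centrality_registry)
  invisible(name)
}

#' Names of the registered centrality methods
#' @return Character vector.
#' @export
centrality_methods <- function() sort(ls(.centrality_registry))

# dense adjacency matrix with node dimnames
adjacency_dense <- function(net) {
  n <- length(net$nodes)
  a <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges)) {
    a[net$edges] <- 1
    a[net$edges[, c(2L, 1L), drop = FALSE]] <- 1
  }
  a
}

centrality_dc <- function(net) as.numeric(node_degrees(net)) |>
  stats::setNames(net$nodes)

centrality_bc <- function(net) {
  g <- as_igraph(net)
  b <- igraph::betweenness(g, directed = FALSE)
  stats::setNames(as.numeric(b), igraph::V(g)$name)
}

centrality_cc <- function(net) {
  n <- length(net$nodes)
  d <- igraph::distances(as_igraph(net))
  sapply(net$nodes, function(u) {
    reach <- is.finite(d[u, ]) & colnames(d) != u
    m <- sum(reach) + 1L                       # component size
    if (m <= 1L || n <= 1L) return(0)
    ((m - 1L) / sum(d[u, reach])) * ((m - 1L) / (n - 1L))
  })
}

centrality_ec <- function(net, tol = 1e-10, max_iter = 100000L) {
  a <- adjacency_dense(net)
  n <- nrow(a)
  if (all(a == 0)) return(stats::setNames(numeric(n), net$nodes))
  v <- rep(1 / sqrt(n), n)
  for (i in seq_len(max_iter)) {
    w <- as.numeric(a %*% v) + v               # (A + I) v
    w <- w / sqrt(sum(w * w))
    if (max(abs(w - v)) < tol) { v <- w; break }
    v <- w
  }
  v <- pmax(v, 0)
  stats::setNames(v / max(v), net$nodes)
}

centrality_sc <- function(net) {
  a <- adjacency_dense(net)
  e <- eigen(a, symmetric = TRUE)
  stats::setNames(as.numeric((e$vectors^2) %*% exp(e$values)), net$nodes)
}

# triangles on each edge: z(u, v) = |N(u) intersect N(v)|
edge_triangles <- function(net, a = adjacency_dense(net)) {
  if (!nrow(net$edges)) return(integer())
  a2 <- a %*% a
  as.integer(round(a2[net$edges]))
}

centrality_nc <- function(net) {
  out <- stats::setNames(numeric(length(net$nodes)), net$nodes)
  if (!nrow(net$edges)) return(out)
  deg <- node_degrees(net)
  z <- edge_triangles(net)
  denom <- pmin(deg[net$edges[, 1L]], deg[net$edges[, 2L]]) - 1L
  ecc <- ifelse(denom > 0L, z / denom, 0)
  for (i in seq_len(nrow(net$edges))) {
    out[net$edges[i, 1L]] <- out[net$edges[i, 1L]] + ecc[[i]]
    out[net$edges[i, 2L]] <- out[net$edges[i, 2L]] + ecc[[i]]
  }
  out
}

local({
  register_centrality("DC", centrality_dc)
  register_centrality("BC", centrality_bc)
  register_centrality("CC", centrality_cc)
  register_centrality("EC", centrality_ec)
  register_centrality("SC", centrality_sc)
  register_centrality("NC", centrality_nc)
})

#' Rank proteins by a centrality score
#'
#' Proteins are sorted in descending score order; ties are broken by
#' lexicographic protein identifier (recorded in the result).
#'
#' @param scores named numeric vector covering all network nodes.
#' @param method label stored with the ranking.
#' @return Object of class `centrality_ranking`: data frame `protein`,
#'   `score`, `rank` (1-based), with attributes `method` and
#'   `tie_break`.
#' @export
rank_centrality <- function(scores, method = "centrality") {
  o <- order(-scores, names(scores))
  out <- data.frame(protein = names(scores)[o],
                    score = as.numeric(scores)[o],
                    rank = seq_along(scores),
                    stringsAsFactors = FALSE)
  structure(out, class = c("centrality_ranking", "data.frame"),
            method = method, tie_break = "lexicographic")
}

#' @export
print.centrality_ranking <- function(x, n = 6L, ...) {
  cat(sprintf("centrality_ranking (%s): %d proteins, ties broken %s\n",
              attr(x, "method"), nrow(x), attr(x, "tie_break")))
  print.data.frame(utils::head(x, n))
  invisible(x)
}

# rank positions as a named integer vector
rank_positions <- function(ranking) {
  stats::setNames(ranking$rank, ranking$protein)
}

#' Essential proteins among the top-ranked fractions
#'
#' For each fraction `f`, counts the gold-standard essential proteins
#' among the top `floor(f * N)` ranked proteins.
#'
#' @param ranking a [rank_centrality()] result.
#' @param essential character vector of gold-standard essential
#'   proteins.
#' @param fractions numeric fractions in `(0, 1]`.
#' @return Data frame `fraction`, `top_n`, `n_essential`.
#' @export
topk_essential_counts <- function(ranking, essential,
                                  fractions = c(0.05, 0.10, 0.15, 0.20)) {
  stopifnot(all(fractions > 0), all(fractions <= 1))
  n <- nrow(ranking)
  data.frame(
    fraction = fractions,
    top_n = vapply(fractions, function(f) as.integer(floor(f * n)), 0L),
    n_essential = vapply(fractions, function(f)
      sum(ranking$protein[seq_len(floor(f * n))] %in% essential), 0L))
}

#' Precision-recall and jackknife curve data
#'
#' At each rank cutoff `k`: precision `hits(k) / k`, recall
#' `hits(k) / |essential in network|`, and the jackknife value
#' `hits(k)` (cumulative essentials).  Emitted as a table, not a plot.
#'
#' @param ranking a [rank_centrality()] result.
#' @param essential character vector of essential proteins.
#' @return Data frame `rank`, `hits`, `precision`, `recall`.
#' @export
evaluation_curves <- function(ranking, essential) {
  hit <- ranking$protein %in% essential
  hits <- cumsum(hit)
  total <- sum(hit)
  data.frame(rank = ranking$rank, hits = hits,
             precision = hits / ranking$rank,
             recall = if (total > 0) hits / total else NA_real_)
}
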