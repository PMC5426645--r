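#' Random walk with restart similarity scores
#'
#' For each seed node `x` the stationary vector `p_x` of
#' `p = (1 - c) W p + c e_x` is computed by iteration on the
#' column-normalised adjacency matrix `W` until the L1 change falls
#' below `tol`; the pairwise score is the symmetrised
#' `s(x, y) = p_x[y] + p_y[x]`.  A column of an isolated node is set to
#' teleport back to itself (logged via `message()`).
#'
#' @param net a nonempty [ppi_network()].
#' @param restart restart probability `c` in `(0, 1)` (default 0.8).
#' @param tol L1 convergence tolerance (default 1e-10).
#' @param max_iter iteration cap.
#' @return Symmetric numeric matrix over `net$nodes` (class
#'   `similarity_matrix`, attribute `method = "RWR"`).
#' @export
rwr_scores <- function(net, restart = 0.8, tol = 1e-10, max_iter = 10000L) {
  stopifnot(restart > 0, restart < 1)
  if (!length(net$nodes)) stop("network is empty")
  a <- adjacency_dense(net)
  cs <- colSums(a)
  iso <- cs == 0
  if (any(iso)) {
    message(sprintf("rwr_scores: %d isolated node(s) teleport to themselves",
                    sum(iso)))
    diag(a)[iso] <- 1
    cs[iso] <- 1
  }
  w <- sweep(a, 2L, cs, `/`)
  n <- nrow(w)
  p <- diag(n)                                  # all seeds at once
  for (i in seq_len(max_iter)) {
    p_new <- (1 - restart) * (w %*% p)
    diag(p_new) <- diag(p_new) + restart
    if (max(colSums(abs(p_new - p))) < tol) { p <- p_new; break }
    p <- p_new
  }
  dimnames(p) <- list(net$nodes, net$nodes)
  s <- p + t(p)
  structure(s, class = c("similarity_matrix", "matrix", "array"),
            method = "RWR", stationary = p)
}

#' Local random walk similarity scores
#'
#' A `t`-step simple random walk started from each node: with
#' `pi_x(t)` the `t`-step occupation distribution, the score is
#' `s(x, y) = q_x pi_x(t)[y] + q_y pi_y(t)[x]` with the initial-density
#' weight `q_x = degree(x) / (2 |E|)`.  The exact-`t` variant is the
#' default; the superposed variant sums the walks over `1..t`.
#'
#' @param net a nonempty [ppi_network()] with at least one edge.
#' @param steps walk length `t >= 1` (default 3).
#' @param variant `"exact"` (default) or `"superposed"`.
#' @return Symmetric nonnegative numeric matrix over `net$nodes` (class
#'   `similarity_matrix`, attribute `method = "LRW"`).
#' @export
lrw_scores <- function(net, steps = 3L, variant = c("exact", "superposed")) {
  variant <- match.arg(variant)
  stopifnot(steps >= 1L)
  if (!length(net$nodes)) stop("network is empty")
  a <- adjacency_dense(net)
  deg <- rowSums(a)
  m2 <- sum(deg)                                 # 2 |E|
  if (m2 == 0) stop("network has no edges")
  rs <- ifelse(deg == 0, 1, deg)
  tr <- a / rs                                   # row-stochastic transitions
  diag(tr)[deg == 0] <- 1
  pw <- tr
  acc <- if (variant == "superposed") tr else NULL
  if (steps > 1L) for (i in seq_len(steps - 1L)) {
    pw <- pw %*% tr
    if (variant == "superposed") acc <- acc + pw
  }
  m <- if (variant == "superposed") acc else pw
  q <- deg / m2
  s <- q * m                                     # rows scaled by q_x
  s <- s + t(s)
  dimnames(s) <- list(net$nodes, net$nodes)
  structure(s, class = c("similarity_matrix", "matrix", "array"),
            method = "LRW")
}

#' Select top-scored unlinked pairs at a matched proportion
#'
#' Takes the top `floor(proportion * |E|)` unlinked pairs by similarity
#' score, descending, with ties broken lexicographically on the
#' canonical pair; the result is disjoint from the existing edges.
#'
#' @param sim a `similarity_matrix` over the network's nodes.
#' @param net the [ppi_network()] the scores were computed on.
#' @param proportion positive fraction of `|E|` to select.
#' @return Two-column character matrix of predicted pairs.  If fewer
#'   unlinked pairs exist than requested, all are returned with a
#'   warning.
#' @export
predict_by_proportion <- function(sim, net, proportion) {
  stopifnot(proportion > 0)
  n_sel <- floor(proportion * nrow(net$edges))
  pairs <- unlinked_pairs(net)
  if (!nrow(pairs) || n_sel == 0)
    return(matrix(character(), ncol = 2L))
  score <- sim[cbind(pairs[, 1L], pairs[, 2L])]
  o <- order(-score, pairs[, 1L], pairs[, 2L])
  if (n_sel > nrow(pairs)) {
    warning("fewer unlinked pairs than requested; returning all")
    n_sel <- nrow(pairs)
  }
  pairs[o[seq_len(n_sel)], , drop = FALSE]
}
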