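#' Stage 1: predict links between unlinked protein pairs
#'
#' Scores every unlinked pair of network nodes by the Pearson
#' correlation of their expression profiles and — for pairs passing the
#' correlation gate — by GO semantic similarity.  A pair is predicted
#' when `pcc >= pcc_threshold` and, if the GO filter is enabled
#' (`go_threshold > 0`), `go_sim >= go_threshold`.  Comparisons are
#' inclusive, so results are deterministic at ties.  GO similarity is
#' only ever computed for correlation-passing pairs (the two-stage
#' filter), which also bounds compute.
#'
#' @param net a [ppi_network()].
#' @param expr an [expression_matrix()].
#' @param ann an `annotation_map` (may be `NULL` when `go_threshold = 0`).
#' @param dag a `go_dag` (may be `NULL` when `go_threshold = 0`).
#' @param pcc_threshold correlation threshold in `(0, 1)`.
#' @param go_threshold GO similarity threshold in `[0, 1]`; 0 disables
#'   the GO filter.
#' @param missing forwarded to [pair_pcc()].
#' @return List with `predicted` (two-column character matrix of
#'   canonical pairs) and `scores` (data frame `u`, `v`, `pcc`,
#'   `go_sim` for the correlation-passing pairs; `go_sim` is `NA` when
#'   the GO filter is disabled).
#' @export
predict_links <- function(net, expr, ann = NULL, dag = NULL,
                          pcc_threshold = 0.95, go_threshold = 0,
                          missing = c("undefined", "pairwise")) {
  stopifnot(pcc_threshold > 0, pcc_threshold < 1,
            go_threshold >= 0, go_threshold <= 1)
  if (go_threshold > 0 && (is.null(ann) || is.null(dag)))
    stop("GO filter requested but `ann`/`dag` not supplied")
  cm <- pcc_matrix(expr, net$nodes, missing = match.arg(missing))
  cm[!is.finite(cm)] <- 0
  n <- length(net$nodes)
  pass <- which(upper.tri(cm) & cm >= pcc_threshold, arr.ind = TRUE)
  if (nrow(pass)) {
    u <- net$nodes[pass[, 1L]]
    v <- net$nodes[pass[, 2L]]
    linked <- pair_key(u, v) %in% edge_keys(net)
    u <- u[!linked]; v <- v[!linked]
    pccs <- cm[pass][!linked]
  } else {
    u <- v <- character(); pccs <- numeric()
  }
  scores <- data.frame(u = u, v = v, pcc = pccs, go_sim = NA_real_,
                       stringsAsFactors = FALSE)
  if (go_threshold > 0 && nrow(scores)) {
    cache <- profile_cache(unique(c(u, v)), ann, dag)
    scores$go_sim <- mapply(function(a, b)
      profile_sim(cache[[a]], cache[[b]]), u, v, USE.NAMES = FALSE)
    keep <- scores$go_sim >= go_threshold
  } else {
    keep <- rep(TRUE, nrow(scores))
  }
  predicted <- canonical_pairs(scores$u[keep], scores$v[keep])
  if (nrow(predicted))
    predicted <- predicted[order(predicted[, 1L], predicted[, 2L]), ,
                           drop = FALSE]
  o <- order(scores$u, scores$v)
  list(predicted = predicted, scores = scores[o, , drop = FALSE])
}

#' Proportion of added links
#'
#' The number of predicted links relative to the size of the original
#' network (the quantity tabulated against threshold choices).
#'
#' @param predicted two-column matrix of predicted pairs, disjoint from
#'   the original edges.
#' @param original a [ppi_network()] with at least one edge.
#' @return `nrow(predicted) / nrow(original$edges)`.
#' @export
added_proportion <- function(predicted, original) {
  stopifnot(inherits(original, "ppi_network"))
  if (!nrow(original$edges)) stop("original network has no edges")
  if (NROW(predicted) &&
      any(pair_key(predicted[, 1L], predicted[, 2L]) %in% edge_keys(original)))
    stop("predicted pairs must be disjoint from the original edges")
  NROW(predicted) / nrow(original$edges)
}

#' Added-link proportions over a threshold grid
#'
#' @param net,expr,ann,dag as in [predict_links()].
#' @param grid data frame with columns `pcc_threshold` and
#'   `go_threshold` (one row per configuration, kept in order).
#' @return Data frame `pcc_threshold`, `go_threshold`, `n_predicted`,
#'   `proportion`.
#' @export
proportion_table <- function(net, expr, ann = NULL, dag = NULL, grid) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1L,
            all(c("pcc_threshold", "go_threshold") %in% names(grid)))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    fit <- predict_links(net, expr, ann, dag,
                         pcc_threshold = grid$pcc_threshold[[i]],
                         go_threshold = grid$go_threshold[[i]])
    data.frame(pcc_threshold = grid$pcc_threshold[[i]],
               go_threshold = grid$go_threshold[[i]],
               n_predicted = nrow(fit$predicted),
               proportion = added_proportion(fit$predicted, net))
  })
  do.call(rbind, rows)
}
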