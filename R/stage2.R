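#' Top-K overlap and set differences between two rankings
#'
#' Intersects and differences the top-K protein sets of an original and
#' an augmented-network ranking, splitting every cell by gold-standard
#' essentiality.
#'
#' @param rank_ori,rank_new [rank_centrality()] results on the original
#'   and the augmented network.
#' @param K cutoff; must not exceed either ranking's length.
#' @param essential character vector of gold-standard essential
#'   proteins.  Only listed proteins count as essential (unclassified
#'   proteins count as non-hits).
#' @return One-row data frame with columns `K`, `n_intersect`,
#'   `n_new_only`, `n_ori_only` and each of those split into
#'   `*_essential` / `*_nonessential`.
#' @export
set_difference_table <- function(rank_ori, rank_new, K, essential) {
  if (K > nrow(rank_ori) || K > nrow(rank_new))
    stop("K exceeds a ranking's length")
  top_ori <- rank_ori$protein[seq_len(K)]
  top_new <- rank_new$protein[seq_len(K)]
  cells <- list(intersect = intersect(top_new, top_ori),
                new_only  = setdiff(top_new, top_ori),
                ori_only  = setdiff(top_ori, top_new))
  ess <- lapply(cells, function(s) sum(s %in% essential))
  data.frame(K = K,
             n_intersect = length(cells$intersect),
             n_intersect_essential = ess$intersect,
             n_intersect_nonessential = length(cells$intersect) - ess$intersect,
             n_new_only = length(cells$new_only),
             n_new_only_essential = ess$new_only,
             n_new_only_nonessential = length(cells$new_only) - ess$new_only,
             n_ori_only = length(cells$ori_only),
             n_ori_only_essential = ess$ori_only,
             n_ori_only_nonessential = length(cells$ori_only) - ess$ori_only)
}

#' Select rescued essential candidate proteins
#'
#' A protein qualifies as a candidate when it (a) is gold-standard
#' essential, (b) ranks in the top `K` under the augmented networks
#' (by default under at least one of the methods, in network 1 AND in
#' network 2), and (c) is absent from the top `K` under every method on
#' the original network.  A qualifying candidate is flagged
#' *deep-ranked* when its original-network rank exceeds `R` (by default
#' under all of the methods); the deep-ranked subset is the one whose
#' incident predicted links are taken forward for validation.
#'
#' @param ranks_ori,ranks_new1,ranks_new2 named lists of
#'   [rank_centrality()] results, one per method, for the original and
#'   the two augmented networks.
#' @param methods methods to use (default `c("DC", "NC", "SC")`).
#' @param K top cutoff (default 200).
#' @param R deep-rank threshold, `R >= K` (default 1000; use a smaller
#'   value when the essential set is small).
#' @param essential character vector of gold-standard essential
#'   proteins.
#' @param topk_rule quantifier for the top-K membership test over
#'   methods: `"any"` (default) or `"all"`.
#' @param deep_rule quantifier for the deep-rank test: `"all"`
#'   (default) or `"any"`.
#' @return Data frame `protein`, one `rank_ori_<method>` column per
#'   method, `deep_ranked`; ordered by protein.  Result is invariant to
#'   the order in which the rankings are supplied.
#' @export
select_candidates <- function(ranks_ori, ranks_new1, ranks_new2,
                              methods = c("DC", "NC", "SC"),
                              K = 200, R = 1000, essential,
                              topk_rule = c("any", "all"),
                              deep_rule = c("all", "any")) {
  topk_rule <- match.arg(topk_rule)
  deep_rule <- match.arg(deep_rule)
  if (R < K) stop("rank threshold R must be >= K")
  need <- function(lst, nm) {
    if (!all(methods %in% names(lst)))
      stop("missing ranking(s) for ", nm, ": ",
           paste(setdiff(methods, names(lst)), collapse = ", "))
    lst[methods]
  }
  ranks_ori <- need(ranks_ori, "original network")
  ranks_new1 <- need(ranks_new1, "network 1")
  ranks_new2 <- need(ranks_new2, "network 2")

  pos <- function(lst) lapply(lst, rank_positions)
  p_ori <- pos(ranks_ori); p_n1 <- pos(ranks_new1); p_n2 <- pos(ranks_new2)
  universe <- sort(unique(unlist(lapply(p_ori, names), use.names = FALSE)))
  # a protein missing from a ranking is treated as rank infinity
  rank_of <- function(p, plist, m) {
    r <- plist[[m]][p]
    ifelse(is.na(r), Inf, r)
  }
  over_methods <- function(plist, rule, test) {
    vals <- matrix(FALSE, length(universe), length(methods))
    for (j in seq_along(methods))
      vals[, j] <- test(rank_of(universe, plist, methods[[j]]))
    if (rule == "any") rowSums(vals) > 0 else rowSums(vals) == length(methods)
  }
  in_topk_n1 <- over_methods(p_n1, topk_rule, function(r) r <= K)
  in_topk_n2 <- over_methods(p_n2, topk_rule, function(r) r <= K)
  in_topk_ori <- over_methods(p_ori, "any", function(r) r <= K)
  qualifies <- (universe %in% essential) & in_topk_n1 & in_topk_n2 &
    !in_topk_ori
  deep <- over_methods(p_ori, deep_rule, function(r) r > R)

  cand <- universe[qualifies]
  out <- data.frame(protein = cand, stringsAsFactors = FALSE)
  for (m in methods)
    out[[paste0("rank_ori_", m)]] <- as.numeric(rank_of(cand, p_ori, m))
  out$deep_ranked <- deep[qualifies]
  out[order(out$protein), , drop = FALSE]
}

#' Predicted links incident to candidate proteins
#'
#' @param candidates character vector of candidate proteins (typically
#'   the deep-ranked subset of [select_candidates()]).
#' @param predicted two-column matrix of predicted pairs.
#' @return The rows of `predicted` with at least one endpoint among
#'   `candidates`.  Empty `candidates` yields an empty set with a
#'   warning.
#' @export
incident_predicted_edges <- function(candidates, predicted) {
  if (!length(candidates)) {
    warning("no candidate proteins; selected edge set is empty")
    return(matrix(character(), ncol = 2L))
  }
  if (NROW(predicted) == 0L) return(matrix(character(), ncol = 2L))
  keep <- predicted[, 1L] %in% candidates | predicted[, 2L] %in% candidates
  predicted[keep, , drop = FALSE]
}

#' Validate predicted links against a reference interaction set
#'
#' A predicted link is confirmed when it is present in the reference set
#' with confidence at least `min_conf` (the customary high-confidence
#' cut is 0.7).
#'
#' @param edges two-column matrix of predicted pairs.
#' @param ref a `reference_set`.
#' @param min_conf minimum confidence in `[0, 1]`.
#' @return List with `n`, `confirmed`, `fraction` (0 with a warning
#'   when `n = 0`) and the confirmed pairs.
#' @export
validate_edges <- function(edges, ref, min_conf = 0.7) {
  stopifnot(inherits(ref, "reference_set"),
            min_conf >= 0, min_conf <= 1)
  n <- NROW(edges)
  if (n == 0L) {
    warning("no edges to validate")
    return(list(n = 0L, confirmed = 0L, fraction = 0,
                confirmed_edges = matrix(character(), ncol = 2L)))
  }
  cp <- canonical_pairs(edges[, 1L], edges[, 2L])
  ref_keys <- pair_key(ref$pairs[, 1L], ref$pairs[, 2L])
  conf <- stats::setNames(ref$confidence, ref_keys)
  got <- conf[pair_key(cp[, 1L], cp[, 2L])]
  ok <- !is.na(got) & got >= min_conf
  list(n = n, confirmed = sum(ok), fraction = sum(ok) / n,
       confirmed_edges = cp[ok, , drop = FALSE])
}
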