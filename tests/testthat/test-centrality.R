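# brute-force oracles: triangle counting for NC, tabulation for DC
brute_dc <- function(net) {
  sapply(net$nodes, function(u)
    sum(net$edges[, 1L] == u | net$edges[, 2L] == u))
}

brute_nc <- function(net) {
  a <- dense_adj(net)
  deg <- rowSums(a)
  out <- setNames(numeric(length(net$nodes)), net$nodes)
  for (i in seq_len(nrow(net$edges))) {
    u <- net$edges[i, 1L]; v <- net$edges[i, 2L]
    z <- sum(a[u, ] * a[v, ])
    d <- min(deg[[u]], deg[[v]]) - 1
    ecc <- if (d > 0) z / d else 0
    out[[u]] <- out[[u]] + ecc; out[[v]] <- out[[v]] + ecc
  }
  out
}

test_that("triangle graph: unit degree and clustering expectations", {
  tri <- triangle_net()
  expect_equal(unname(centrality(tri, "DC")), rep(2, 3))
  expect_equal(unname(centrality(tri, "NC")), rep(2, 3))
  expect_error(centrality(tri, "XX"), "registered")
})

test_that("DC and NC agree with exhaustive counting on sampled small graphs", {
  for (i in 1:200) {
    net <- random_net(sample(3:12, 1L), runif(1, 0.1, 0.9), seed = 1000 + i)
    if (!nrow(net$edges)) next
    expect_equal(centrality(net, "DC"), brute_dc(net) + 0)
    expect_equal(centrality(net, "NC"), brute_nc(net), tolerance = 1e-12)
  }
})

test_that("subgraph centrality matches the truncated power series", {
  for (i in 1:5) {
    net <- random_net(50, 0.05, seed = 2000 + i)
    a <- dense_adj(net)
    series <- diag(nrow(a)) * 0; pk <- diag(nrow(a))
    for (k in 1:25) {
      pk <- pk %*% a
      series <- series + pk / factorial(k)
    }
    oracle <- 1 + diag(series)
    expect_lt(max(abs(centrality(net, "SC") - oracle)), 1e-8)
  }
})

test_that("eigenvector and betweenness cross-check against igraph", {
  net <- random_net(40, 0.12, seed = 31)
  g <- as_igraph(net)
  ec <- centrality(net, "EC")
  ig <- igraph::eigen_centrality(g)$vector[net$nodes]
  expect_equal(unname(ec), unname(ig), tolerance = 1e-6)
  bc <- centrality(net, "BC")
  expect_equal(unname(bc),
               unname(igraph::betweenness(g, directed = FALSE)[net$nodes]))
})

test_that("closeness is component-restricted and scaled", {
  # two components: P3 path (A-B-C) and a K2 (D-E)
  net <- ppi_network(rbind(c("A", "B"), c("B", "C"), c("D", "E")))
  cc <- centrality(net, "CC")
  expect_equal(cc[["B"]], (2 / 2) * (2 / 4))
  expect_equal(cc[["A"]], (2 / 3) * (2 / 4))
  expect_equal(cc[["D"]], (1 / 1) * (1 / 4))
  iso <- ppi_network(rbind(c("A", "B")), nodes = c("A", "B", "Z"))
  expect_equal(centrality(iso, "CC")[["Z"]], 0)
})

test_that("edge addition never decreases endpoint degree; NC is label-invariant", {
  net <- random_net(15, 0.2, seed = 77)
  extra <- unlinked_pairs(net)[1L, , drop = FALSE]
  aug <- augment_network(net, extra)
  d0 <- centrality(net, "DC"); d1 <- centrality(aug, "DC")
  expect_true(all(d1[extra[1, ]] > d0[extra[1, ]]))
  expect_true(all(d1 >= d0))
  # relabel nodes by a random permutation: NC values travel with labels
  set.seed(5)
  relab <- setNames(sample(sprintf("Q%02d", 1:15)), net$nodes)
  pnet <- ppi_network(cbind(relab[net$edges[, 1L]], relab[net$edges[, 2L]]),
                      nodes = unname(relab))
  nc <- centrality(net, "NC"); pnc <- centrality(pnet, "NC")
  expect_equal(unname(pnc[relab[net$nodes]]), unname(nc), tolerance = 1e-12)
})

test_that("ranking sorts descending with lexicographic tie-break", {
  rk <- rank_centrality(c(A = 3, B = 1, C = 3), "DC")
  expect_identical(rk$protein, c("A", "C", "B"))
  expect_identical(rk$rank, 1:3)
  all_tied <- rank_centrality(c(B = 1, A = 1, C = 1))
  expect_identical(all_tied$protein, c("A", "B", "C"))
  single <- rank_centrality(c(X = 0.5))
  expect_identical(single$rank, 1L)
})

test_that("top-fraction essential counts and curves match cumulative scans", {
  scores <- setNames(100:1, sprintf("P%03d", 1:100))
  rk <- rank_centrality(scores)
  ess10 <- sprintf("P%03d", 1:10)          # exactly the top 10
  got <- topk_essential_counts(rk, ess10, fractions = c(0.1, 1.0))
  expect_equal(got$n_essential, c(10L, 10L))
  # random essential set: brute-force membership scan at several cutoffs
  set.seed(8)
  ess <- sample(names(scores), 30)
  got <- topk_essential_counts(rk, ess, fractions = c(0.05, 0.2, 0.5))
  for (i in seq_len(nrow(got)))
    expect_equal(got$n_essential[[i]],
                 sum(rk$protein[seq_len(got$top_n[[i]])] %in% ess))
  curves <- evaluation_curves(rk, ess)
  expect_equal(curves$hits, cumsum(rk$protein %in% ess))
  expect_equal(curves$precision, curves$hits / seq_len(100))
  expect_equal(curves$recall, curves$hits / 30)
  perfect <- evaluation_curves(rank_centrality(
    setNames(c(2, 2, 1, 1), c("a", "b", "c", "d"))), c("a", "b"))
  expect_equal(perfect$precision[1:2], c(1, 1))
  expect_equal(perfect$recall[2], 1)
})
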