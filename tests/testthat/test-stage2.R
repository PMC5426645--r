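mk_ranking <- function(ids) rank_centrality(setNames(rev(seq_along(ids)), ids))

test_that("set-difference cells follow naive set arithmetic", {
  ids <- sprintf("P%02d", 1:20)
  ess <- ids[c(1, 3, 5, 7, 9)]
  same <- mk_ranking(ids)
  row <- set_difference_table(same, same, K = 10, essential = ess)
  expect_equal(row$n_intersect, 10L)
  expect_equal(row$n_new_only, 0L)
  expect_equal(row$n_ori_only, 0L)
  expect_equal(row$n_intersect_essential, 5L)

  flipped <- mk_ranking(rev(ids))
  row <- set_difference_table(same, flipped, K = 10, essential = ess)
  expect_equal(row$n_intersect, 0L)
  expect_equal(row$n_new_only, 10L)
  expect_equal(row$n_ori_only, 10L)

  set.seed(33)
  for (i in 1:10) {
    a <- mk_ranking(sample(ids)); b <- mk_ranking(sample(ids))
    K <- sample(3:15, 1)
    row <- set_difference_table(a, b, K = K, essential = ess)
    ta <- a$protein[1:K]; tb <- b$protein[1:K]
    expect_equal(row$n_intersect, length(intersect(tb, ta)))
    expect_equal(row$n_new_only_essential, sum(setdiff(tb, ta) %in% ess))
    expect_equal(row$n_ori_only_nonessential,
                 sum(!setdiff(ta, tb) %in% ess))
    expect_equal(row$n_intersect + row$n_new_only, K)
    expect_equal(row$n_intersect_essential + row$n_intersect_nonessential,
                 row$n_intersect)
  }
  expect_error(set_difference_table(same, same, K = 25, essential = ess),
               "exceeds")
})

test_that("candidate selection applies the essential/top-K/deep-rank rule", {
  ids <- sprintf("P%02d", 1:30)
  ess <- c("P20", "P25")
  # original: P20 ranks 29th (deep), P25 ranks 21st (outside top-K but not
  # deep), P30 last (non-essential); augmented networks lift all three
  others <- setdiff(ids, c("P20", "P25", "P30"))
  ori_order <- c(others[1:20], "P25", others[21:27], "P20", "P30")
  new_order <- c("P20", "P25", "P30", others)
  ro <- list(DC = mk_ranking(ori_order), NC = mk_ranking(ori_order),
             SC = mk_ranking(ori_order))
  rn <- list(DC = mk_ranking(new_order), NC = mk_ranking(new_order),
             SC = mk_ranking(new_order))
  got <- select_candidates(ro, rn, rn, K = 5, R = 25, essential = ess)
  expect_setequal(got$protein, c("P20", "P25"))   # P30 fails essentiality
  expect_identical(got$deep_ranked, c(TRUE, FALSE))
  expect_equal(got$rank_ori_DC[got$protein == "P20"], 29)

  # absent from top-K in only ONE augmented network: not a candidate
  got1 <- select_candidates(ro, rn, ro, K = 5, R = 25, essential = ess)
  expect_equal(nrow(got1), 0L)

  # already top-K in the original under one method: excluded
  ro2 <- ro
  ro2$SC <- mk_ranking(c("P20", setdiff(ids, "P20")))
  got2 <- select_candidates(ro2, rn, rn, K = 5, R = 25, essential = ess)
  expect_setequal(got2$protein, "P25")

  # invariant to the order in which rankings are listed
  got3 <- select_candidates(ro[c(3, 1, 2)], rn[c(2, 3, 1)], rn,
                            K = 5, R = 25, essential = ess)
  expect_identical(got3, got)
  expect_error(select_candidates(ro, rn, rn, K = 10, R = 5, essential = ess),
               ">= K")
})

test_that("deep-rank flag honours both quantifiers", {
  ids <- sprintf("P%02d", 1:30)
  ess <- "P28"
  # P28 is deep under DC/NC but not SC
  deep2 <- c(setdiff(ids, "P28"), "P28")           # rank 30
  shallow <- c(ids[1:10], "P28", setdiff(ids[11:30], "P28"))  # rank 11
  ro <- list(DC = mk_ranking(deep2), NC = mk_ranking(deep2),
             SC = mk_ranking(shallow))
  rn <- list(DC = mk_ranking(c("P28", setdiff(ids, "P28"))),
             NC = mk_ranking(ids), SC = mk_ranking(ids))
  all_rule <- select_candidates(ro, rn, rn, K = 5, R = 20, essential = ess)
  expect_false(all_rule$deep_ranked)
  any_rule <- select_candidates(ro, rn, rn, K = 5, R = 20, essential = ess,
                                deep_rule = "any")
  expect_true(any_rule$deep_ranked)
})

test_that("incident edge collection filters by endpoint membership", {
  pred <- rbind(c("X", "A"), c("B", "C"))
  expect_identical(incident_predicted_edges("X", pred),
                   pred[1L, , drop = FALSE])
  expect_warning(none <- incident_predicted_edges(character(), pred),
                 "empty")
  expect_equal(nrow(none), 0L)
})

test_that("validation counts confirmations above the confidence cut", {
  ref <- reference_set(c("A", "C", "E"), c("B", "D", "F"),
                       c(0.9, 0.69, 0.7))
  v <- validate_edges(rbind(c("B", "A"), c("C", "D"), c("E", "F"),
                            c("X", "Y")), ref)
  expect_equal(v$n, 4L)
  expect_equal(v$confirmed, 2L)       # 0.9 and 0.70 pass, 0.69 fails
  expect_equal(v$fraction, 0.5)
  allin <- validate_edges(rbind(c("A", "B")), ref, min_conf = 0.7)
  expect_equal(allin$fraction, 1)
  expect_warning(v0 <- validate_edges(matrix(character(), ncol = 2), ref),
                 "no edges")
  expect_equal(v0$fraction, 0)
})
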