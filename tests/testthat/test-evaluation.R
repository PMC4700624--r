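# Precision, recall, improvement and node-level ROC/AUC.

# A fan graph whose chains cover controllable node sets: S - m_i - E.
fan_chain_set <- function(n = 10) {
  mids <- sprintf("m%02d", seq_len(n))
  g <- igraph::graph_from_edgelist(
    rbind(cbind("S", mids), cbind(mids, "E")), directed = FALSE)
  find_chains(g, "S", "E", k = 3)
}

test_that("precision and recall follow TP/(TP+FP) and TP/P", {
  cs <- fan_chain_set(10)                          # covers m01..m10
  gs <- c("m01", "m02", "m03")
  pr <- precision_recall(cs, gs)
  expect_equal(pr$TP, 3); expect_equal(pr$FP, 7)
  expect_equal(pr$precision, 0.3)
  expect_equal(pr$recall, 1)
  # partial selection: chains covering m01..m03, positives {m01, m02, m09}
  sel <- cs[1:3]
  pr2 <- precision_recall(sel, c("m01", "m02", "m09"))
  expect_equal(pr2$recall, 2 / 3)
  expect_equal(pr2$precision, 2 / 3)
})

test_that("start and end nodes never count toward the evaluation", {
  cs <- fan_chain_set(4)
  pr <- precision_recall(cs, c("S", "E", "m01"))   # S, E ignored in P
  expect_equal(pr$n_positives, 1)
  expect_equal(pr$TP, 1)
  expect_equal(pr$FP, 3)
})

test_that("empty selections are flagged, with recall 0", {
  cs <- fan_chain_set(4)
  pr <- precision_recall(cs[integer(0)], "m01")
  expect_true(pr$empty_selection)
  expect_true(is.na(pr$precision))
  expect_equal(pr$recall, 0)
  expect_error(precision_recall(cs, "not_in_network"), "no gold-standard")
})

test_that("recall is monotone non-decreasing as the selection grows", {
  cs <- fan_chain_set(10)
  cs$scores$s <- seq(1, 0.1, by = -0.1)
  gs <- c("m02", "m05", "m08")
  recalls <- vapply(1:10, function(n)
    precision_recall(select_chains(cs, "s", top_n = n), gs)$recall, 0)
  expect_true(all(diff(recalls) >= 0))
  expect_equal(recalls[10], 1)                     # all chains: max recall
})

test_that("improvement is the ratio of ranked to random-baseline precision", {
  cs <- fan_chain_set(10)
  cs$scores$s <- c(1, 0.9, 0.8, seq(0.7, 0.1, length.out = 7))
  gs <- c("m01", "m02", "m03")
  # perfect ranking: top 3 chains cover exactly the positives
  imp <- improvement(cs, gs, "s", top_n = 3, B = 400, seed = 1)
  expect_equal(imp$precision, 1)
  expect_equal(imp$improvement, 1 / imp$baseline_precision)
  # the baseline for 3-of-10 single-node chains has expected precision 0.3
  expect_lt(abs(imp$baseline_precision - 0.3), 0.05)
  # selecting everything makes ranked and random selections identical
  imp_all <- improvement(cs, gs, "s", top_n = 10, B = 50, seed = 1)
  expect_equal(imp_all$improvement, 1)
})

test_that("rankings drawn at random average improvement 1", {
  cs <- fan_chain_set(10)
  gs <- c("m01", "m02", "m03")
  set.seed(13)
  imps <- vapply(1:200, function(i) {
    cs$scores$noise <- runif(10)
    improvement(cs, gs, "noise", top_n = 5, B = 100,
                seed = i)$improvement
  }, 0)
  expect_lt(abs(mean(imps) - 1), 0.15)
})

test_that("improvement reproduces the reported 2.5-fold ceiling arithmetic", {
  expect_equal(0.30 / 0.12, 2.5)
  # and is reproducible from its seed
  cs <- fan_chain_set(8)
  cs$scores$s <- seq(0.8, 0.1, by = -0.1)
  a <- improvement(cs, c("m01", "m03"), "s", top_n = 4, B = 100, seed = 9)
  b <- improvement(cs, c("m01", "m03"), "s", top_n = 4, B = 100, seed = 9)
  expect_identical(a, b)
})

test_that("AUC matches hand-computed and brute-force Mann-Whitney values", {
  cs <- fan_chain_set(4)
  cs$scores$s <- c(1, 0.8, 0.6, 0.4)               # ranks m01 < m02 < ...
  # positives ranked 1st and 3rd of 4 candidates -> AUC 0.75
  r <- roc_auc(cs, c("m01", "m03"), "s")
  expect_equal(r$auc, 0.75)
  # perfect ranking
  expect_equal(roc_auc(cs, c("m01", "m02"), "s")$auc, 1)
  expect_error(roc_auc(cs, sprintf("m%02d", 1:4), "s"), "negative")
  # ROC curve starts at (0,0) and ends at (1,1)
  expect_equal(unlist(r$roc[1, ]), c(FPR = 0, TPR = 0))
  expect_equal(unlist(r$roc[nrow(r$roc), ]), c(FPR = 1, TPR = 1))
})

test_that("AUC equals the normalized Mann-Whitney count on random cases", {
  set.seed(17)
  for (i in 1:10) {
    n <- 8
    cs <- fan_chain_set(n)
    cs$scores$s <- runif(n)
    gs <- sample(sprintf("m%02d", 1:n), 3)
    got <- roc_auc(cs, gs, "s")$auc
    # brute force: fraction of positive-negative pairs ranked correctly,
    # ties counted half, over the node ranking implied by the chain ranking
    ranked <- rank_chains(cs, "s")
    noderank <- setNames(rep(Inf, n), sprintf("m%02d", 1:n))
    for (j in seq_len(n_chains(ranked))) {
      mid <- setdiff(ranked$chains[[j]], c("S", "E"))
      noderank[mid] <- pmin(noderank[mid], j)
    }
    pos <- names(noderank) %in% gs
    cnt <- 0; tot <- 0
    for (a in which(pos)) for (b in which(!pos)) {
      tot <- tot + 1
      if (noderank[a] < noderank[b]) cnt <- cnt + 1
      else if (noderank[a] == noderank[b]) cnt <- cnt + 0.5
    }
    expect_equal(got, cnt / tot)
  }
})

test_that("nodes absent from every chain rank last in the ROC", {
  # m04 reachable only through a long route: with k = 3 it is in no chain
  mids <- sprintf("m%02d", 1:3)
  g <- igraph::graph_from_edgelist(
    rbind(cbind("S", mids), cbind(mids, "E"),
          c("m01", "x1"), c("x1", "m04"), c("m04", "E")),
    directed = FALSE)
  cs <- find_chains(g, "S", "E", k = 3)
  cs$scores$s <- seq(n_chains(cs), 1)
  # positives = covered m01 vs uncovered m04: covered must rank higher
  r <- roc_auc(cs, "m01", "s")
  r2 <- roc_auc(cs, "m04", "s")
  expect_gt(r$auc, r2$auc)
})

test_that("evaluate_chains bundles the metrics consistently", {
  cs <- fan_chain_set(10)
  cs$scores$s <- seq(1, 0.1, by = -0.1)
  ev <- evaluate_chains(cs, c("m01", "m02", "m05"), "s", top_n = 3,
                        B = 200, seed = 2)
  expect_s3_class(ev, "chainrank_eval")
  expect_equal(ev$TP, 2)
  expect_equal(ev$precision, 2 / 3)
  expect_equal(ev$recall, 2 / 3)
  expect_true(ev$auc > 0.5)
  expect_output(print(ev), "precision 0.667")
})
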