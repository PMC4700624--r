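# Node scores, chain scores and the three combination strategies.

test_that("connectivity score inverts degree: hubs score 1", {
  p <- igraph::graph_from_edgelist(cbind(c("A", "B"), c("B", "C")),
                                   directed = FALSE)
  expect_equal(connectivity_score(p), c(A = 2, B = 1, C = 2))
  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("H", paste0("L", 1:4))
  sc <- connectivity_score(star)
  expect_equal(sc[["H"]], 1)
  expect_true(all(sc[paste0("L", 1:4)] == 4))
  ring <- igraph::make_ring(6)
  igraph::V(ring)$name <- letters[1:6]
  expect_true(all(connectivity_score(ring) == 1))  # regular graph
})

test_that("fold-change score is log2(case/control) on shared ids", {
  expect_equal(fold_change_score(c(g1 = 8), c(g1 = 2)), c(g1 = 2))
  expect_equal(fold_change_score(c(g1 = 3), c(g1 = 3)), c(g1 = 0))
  expect_equal(fold_change_score(c(g1 = 1), c(g1 = 4)), c(g1 = -2))
  expect_equal(fold_change_score(c(a = 2, b = 4), c(b = 1, c = 9)),
               c(b = 2))
  expect_error(fold_change_score(c(a = 0), c(a = 1)), "positive")
  expect_error(fold_change_score(c(a = 1), c(b = 1)), "no shared")
})

test_that("chain score is the length-normalized sum of element scores", {
  t <- c(a = 1, b = 2, c = 3)
  expect_equal(chain_score(c("a", "b", "c"), t), 2)
  expect_equal(chain_score(c("S", "C1", "E"), c(S = 0, C1 = 1, E = 0)), 1 / 3)
  # constant scores remove length bias entirely
  const <- setNames(rep(7, 6), letters[1:6])
  expect_equal(chain_score(letters[1:2], const), 7)
  expect_equal(chain_score(letters[1:6], const), 7)
})

test_that("chain score is equivariant under uniform score translation", {
  set.seed(5)
  t <- setNames(rnorm(8), letters[1:8])
  for (i in 1:10) {
    ch <- sample(letters[1:8], sample(2:6, 1))
    delta <- rnorm(1)
    expect_equal(chain_score(ch, t + delta), chain_score(ch, t) + delta)
  }
})

test_that("weighted-sum combination follows c_k = sum_j w_j s_kj", {
  t1 <- c(x = 0.5, y = 1, z = 0)                  # already normalized form
  t2 <- c(x = 1, y = 0, z = 0.5)
  comb <- combined_weighted_sum(list(a = t1, b = t2), c(1, 1))
  expect_equal(comb[["x"]], 1.5)
  # weight (1, 0) projects onto the first normalized table
  expect_equal(combined_weighted_sum(list(a = t1, b = t2), c(1, 0)),
               normalize_scores(t1))
  # equal weights over three tables = plain sum of normalized scores
  t3 <- c(x = 2, y = 4, z = 6)
  comb3 <- combined_weighted_sum(list(t1, t2, t3), c(1, 1, 1))
  expect_equal(comb3,
               normalize_scores(t1) + normalize_scores(t2) +
                 normalize_scores(t3))
  expect_error(combined_weighted_sum(list(a = t1, b = t2), c(0, 0)),
               "positive")
  expect_error(combined_weighted_sum(list(a = t1), c(1, 2)), "one weight per")
})

test_that("single table with weight one is the identity on normalized scores", {
  t <- c(u = 3, v = 9, w = 6)
  expect_equal(combined_weighted_sum(list(t), 1), normalize_scores(t))
})

test_that("chain_scores fills one column per table over a chain set", {
  cs <- find_chains(toy_network(), "S", "E", k = 4)
  t <- c(S = 0, C1 = 1, C2 = 1, E = 0)
  cs <- chain_scores(cs, list(sig = t))
  df <- as.data.frame(cs)
  expect_equal(df$sig[df$chain == "S|C1|E"], 1 / 3)
  expect_equal(df$sig[df$chain == "S|C1|C2|E"], 1 / 2)
})

test_that("selection by top fraction keeps the right count", {
  cs <- make_ten_chain_set()
  q <- select_chains(cs, "s1", top_frac = 0.25)    # quartile of 10 -> 3
  expect_equal(n_chains(q), 3L)
  q8 <- select_chains(cs[1:8], "s1", top_frac = 0.25)
  expect_equal(n_chains(q8), 2L)                   # quartile of 8 -> 2
  expect_error(select_chains(cs, "s1"), "exactly one")
  expect_error(select_chains(cs, "nope", top_n = 2), "unknown score")
})

test_that("filter-then-rerank equals independent set algebra", {
  cs <- make_ten_chain_set()
  got <- combined_filter(cs, filter_by = "s1", rerank_by = "s2",
                         p_cutoff = 0.05)
  pass <- which(cs$pvalues$s1 <= 0.05)
  expect_setequal(got$id, cs$id[pass])
  expect_identical(got$id, cs$id[pass][order(-cs$scores$s2[pass],
                                             cs$id[pass])])
  # threshold admitting everything is a pure re-ranking
  all_in <- combined_filter(cs, "s1", "s2", p_cutoff = 1)
  expect_identical(all_in$id, cs$id[order(-cs$scores$s2, cs$id)])
  # subset invariant
  expect_true(all(got$id %in% cs$id))
})

test_that("intersection keeps chains passing every threshold simultaneously", {
  cs <- make_ten_chain_set()
  got <- combined_intersection(cs, list(s1 = list(p_cutoff = 0.05),
                                        s2 = list(p_cutoff = 0.05)))
  expected <- intersect(which(cs$pvalues$s1 <= 0.05),
                        which(cs$pvalues$s2 <= 0.05))
  expect_setequal(got$id, cs$id[expected])
  single <- combined_intersection(cs, list(s1 = list(p_cutoff = 0.05)))
  expect_setequal(single$id, cs$id[cs$pvalues$s1 <= 0.05])
  expect_warning(
    empty <- combined_intersection(cs, list(s1 = list(p_cutoff = 0.011),
                                            s2 = list(p_cutoff = 0.011))),
    "empty")
  expect_equal(n_chains(empty), 0L)
})

test_that("intersection and filter results are subsets of single-score selections", {
  set.seed(31)
  for (i in 1:10) {
    cs <- make_ten_chain_set(shuffle_seed = i)
    thr <- runif(2, 0.05, 0.9)
    both <- suppressWarnings(
      combined_intersection(cs, list(s1 = list(p_cutoff = thr[1]),
                                     s2 = list(p_cutoff = thr[2]))))
    only1 <- select_chains(cs, "s1", p_cutoff = thr[1])
    only2 <- select_chains(cs, "s2", p_cutoff = thr[2])
    expect_true(all(both$id %in% only1$id))
    expect_true(all(both$id %in% only2$id))
    filt <- combined_filter(cs, "s1", "s2", p_cutoff = thr[1])
    expect_setequal(filt$id, only1$id)
  }
})
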