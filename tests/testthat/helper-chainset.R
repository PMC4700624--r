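# A fixed 10-chain set over a fan graph (S - m_i - E for i = 1..10), with
# two scores and hand-chosen p-values, for combination-strategy tests.
#
# Defaults: s1 decreasing with p-values (.01 .02 .03 .05 .1 .2 .3 .5 .8 1),
# so exactly chains 1-4 pass p1 <= 0.05; s2/s2_p chosen so exactly chains
# 2, 4, 6, 10 pass p2 <= 0.05 and the 0.011 cutoffs select disjoint chains.
make_ten_chain_set <- function(shuffle_seed = NULL) {
  mids <- sprintf("m%02d", 1:10)
  g <- igraph::graph_from_edgelist(
    rbind(cbind("S", mids), cbind(mids, "E")), directed = FALSE)
  cs <- find_chains(g, "S", "E", k = 3)
  stopifnot(identical(cs$id, paste0("S|", mids, "|E")))
  if (is.null(shuffle_seed)) {
    cs$scores <- data.frame(s1 = seq(1, 0.1, by = -0.1),
                            s2 = c(.3, .9, .1, .7, .5, .95, .2, .6, .4, .05))
    cs$pvalues <- data.frame(s1 = c(.01, .02, .03, .05, .1, .2, .3, .5, .8, 1),
                             s2 = c(.3, .02, .9, .04, .5, .01, .7, .2, .6,
                                    .05))
  } else {
    set.seed(shuffle_seed)
    s1 <- runif(10); s2 <- runif(10)
    cs$scores <- data.frame(s1 = s1, s2 = s2)
    # p-values consistent with score order (higher score, lower p)
    cs$pvalues <- data.frame(s1 = (11 - rank(s1)) / 10,
                             s2 = (11 - rank(s2)) / 10)
  }
  cs
}
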