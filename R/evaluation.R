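#' Candidate-positive set from a gold-standard node list
#'
#' The positives `P` are the gold-standard nodes that are present in the query
#' network but are not start or end nodes (those are inputs to the search and
#' would trivially inflate performance).
#'
#' @param gs character vector of gold-standard node identifiers.
#' @param x a `chain_set` (supplies the network and query).
#' @return character vector `P`.
#' @export
gold_positives <- function(gs, x) {
  stopifnot(inherits(x, "chain_set"))
  setdiff(intersect(unique(as.character(gs)), igraph::V(x$graph)$name),
          c(x$query$start, x$query$end))
}

# Unique candidate nodes covered by a chain selection, start/end excluded.
selected_nodes <- function(x) {
  setdiff(unique(unlist(x$chains)), c(x$query$start, x$query$end))
}

#' Precision and recall of a chain selection against a gold standard
#'
#' The nodes covered by the selected chains (start and end excluded, each
#' node counted once however many chains contain it) are compared with the
#' positive set: `Precision = TP / (TP + FP)` and `Recall = TP / |P|`.
#'
#' @param sel a `chain_set` selection (e.g. from [select_chains()]).
#' @param gs gold-standard node list (character vector).
#' @return a list with `TP`, `FP`, `precision`, `recall`, `n_chains`,
#'   `n_positives`. With an empty selection, precision is `NA` (flagged by
#'   `empty_selection = TRUE`) and recall 0.
#' @export
precision_recall <- function(sel, gs) {
  stopifnot(inherits(sel, "chain_set"))
  P <- gold_positives(gs, sel)
  if (length(P) == 0L) stop("no gold-standard positives in the network")
  U <- selected_nodes(sel)
  TP <- length(intersect(U, P))
  FP <- length(setdiff(U, P))
  list(TP = TP, FP = FP,
       precision = if (TP + FP > 0L) TP / (TP + FP) else NA_real_,
       recall = TP / length(P),
       n_chains = n_chains(sel), n_positives = length(P),
       empty_selection = n_chains(sel) == 0L)
}

#' Improvement of a ranking over random chain selection
#'
#' The precision of the ranked selection divided by the mean precision of `B`
#' uniform random selections (without replacement) of the same number of
#' chains from the full chain set. An uninformative ranking gives improvement
#' near 1; values above 1 quantify the benefit of the scores.
#'
#' @param x the full `chain_set` (scored, and with p-values when a p-value
#'   cutoff is used).
#' @param gs gold-standard node list.
#' @param by score name used for ranking.
#' @param top_n,top_frac,p_cutoff selection rule; give exactly one.
#' @param B number of random baseline resamples (default 1000).
#' @param seed seed for the baseline resampling.
#' @return a list with `improvement` (`Inf` flag when every baseline resample
#'   has precision 0), `precision`, `baseline_precision`, `baseline_se` (the
#'   Monte-Carlo standard error), and the selection size.
#' @export
improvement <- function(x, gs, by, top_n = NULL, top_frac = NULL,
                        p_cutoff = NULL, B = 1000L, seed = 1L) {
  stopifnot(inherits(x, "chain_set"), B >= 1L)
  sel <- select_chains(x, by, top_n = top_n, top_frac = top_frac,
                       p_cutoff = p_cutoff)
  pr <- precision_recall(sel, gs)
  m <- n_chains(sel)
  base <- with_seed(seed, vapply(seq_len(B), function(b) {
    take <- sample(n_chains(x), m)
    p <- precision_recall(x[take], gs)$precision
    if (is.na(p)) 0 else p
  }, 0))
  bp <- mean(base)
  list(improvement = if (bp > 0) pr$precision / bp else Inf,
       precision = pr$precision, recall = pr$recall,
       baseline_precision = bp,
       baseline_se = stats::sd(base) / sqrt(B),
       n_selected = m, B = B, seed = seed)
}

#' Node-level ROC curve and AUC of a chain ranking
#'
#' Every candidate node (network node that is neither start nor end) is
#' scored by the best rank of any chain containing it under the `by` ranking;
#' nodes contained in no chain are tied after all chain-covered nodes. With
#' the positives defined by the gold standard, the ROC curve is traced over
#' this node ranking (ties share midpoint ranks) and the AUC computed by the
#' trapezoidal rule, which equals the Mann-Whitney statistic normalized by
#' (#positives x #negatives).
#'
#' @param x a scored `chain_set`.
#' @param gs gold-standard node list.
#' @param by score name used for ranking the chains.
#' @return a list with `auc` and `roc`, a data frame of (FPR, TPR) points.
#' @export
roc_auc <- function(x, gs, by) {
  stopifnot(inherits(x, "chain_set"))
  ranked <- rank_chains(x, by)
  nodes <- setdiff(igraph::V(x$graph)$name, c(x$query$start, x$query$end))
  P <- gold_positives(gs, x)
  if (length(P) == 0L || length(P) == length(nodes))
    stop("need at least one positive and one negative candidate node")
  best <- setNames(rep(Inf, length(nodes)), nodes)
  for (i in seq_len(n_chains(ranked))) {
    ch <- setdiff(ranked$chains[[i]], c(x$query$start, x$query$end))
    upd <- ch[best[ch] > i]
    best[upd] <- i
  }
  score <- -best                                  # higher = better-ranked
  lab <- nodes %in% P
  rk <- rank(score, ties.method = "average")      # midranks for ties
  n1 <- sum(lab); n0 <- sum(!lab)
  auc <- (sum(rk[lab]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # ROC points at each distinct threshold, best score first
  ord <- order(-score)
  tp <- cumsum(lab[ord]); fp <- cumsum(!lab[ord])
  cut <- which(!duplicated(score[ord], fromLast = TRUE))  # last of each tie group
  roc <- data.frame(FPR = c(0, fp[cut] / n0), TPR = c(0, tp[cut] / n1))
  list(auc = auc, roc = roc, n_positives = n1, n_negatives = n0)
}

#' Full evaluation report for a ranked chain set
#'
#' Bundles [precision_recall()], [improvement()] and [roc_auc()] for one
#' selection rule.
#'
#' @inheritParams improvement
#' @return an object of class `chainrank_eval`.
#' @export
evaluate_chains <- function(x, gs, by, top_n = NULL, top_frac = NULL,
                            p_cutoff = NULL, B = 1000L, seed = 1L) {
  imp <- improvement(x, gs, by, top_n = top_n, top_frac = top_frac,
                     p_cutoff = p_cutoff, B = B, seed = seed)
  roc <- roc_auc(x, gs, by)
  pr <- precision_recall(select_chains(x, by, top_n = top_n,
                                       top_frac = top_frac,
                                       p_cutoff = p_cutoff), gs)
  structure(list(
    by = by,
    selection = list(top_n = top_n, top_frac = top_frac, p_cutoff = p_cutoff),
    TP = pr$TP, FP = pr$FP,
    precision = imp$precision, recall = imp$recall,
    improvement = imp$improvement,
    baseline_precision = imp$baseline_precision,
    baseline_se = imp$baseline_se,
    n_selected = imp$n_selected,
    auc = roc$auc, roc = roc$roc,
    n_positives = roc$n_positives
  ), class = "chainrank_eval")
}

#' @export
print.chainrank_eval <- function(x, ...) {
  sel <- x$selection[!vapply(x$selection, is.null, TRUE)]
  cat(sprintf("Evaluation of ranking by '%s' (%s = %s)\n", x$by,
              names(sel)[1], format(sel[[1]])))
  cat(sprintf("  selected chains: %d, positives in network: %d\n",
              x$n_selected, x$n_positives))
  cat(sprintf("  precision %.3f, recall %.3f, improvement %.2f (baseline %.3f +/- %.3f)\n",
              x$precision, x$recall, x$improvement, x$baseline_precision,
              2 * x$baseline_se))
  cat(sprintf("  node-level AUC %.3f\n", x$auc))
  invisible(x)
}
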