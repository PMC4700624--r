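#' Connectivity score: inverted degree centrality
#'
#' `score(v) = (max degree - degree(v)) + 1`, so the most connected (hub-like)
#' node scores 1 and sparsely connected, context-specific nodes score highest.
#' Hubs participate in many generic processes; inverting the degree favours
#' chains through specific rather than promiscuous interactors.
#'
#' @param net an undirected igraph graph with named vertices.
#' @return a score table (named numeric vector over all network nodes).
#' @export
connectivity_score <- function(net) {
  stopifnot(igraph::is_igraph(net), igraph::vcount(net) > 0L)
  d <- igraph::degree(net)
  setNames(max(d) - d + 1, igraph::V(net)$name)
}

#' Fold-change score from case/control expression values
#'
#' `score = log2(case / control)` on the identifiers shared by both mappings.
#'
#' @param case_expr,control_expr named numeric vectors of strictly positive
#'   expression values.
#' @return a score table over the shared identifiers.
#' @export
fold_change_score <- function(case_expr, control_expr) {
  ids <- intersect(names(case_expr), names(control_expr))
  if (length(ids) == 0L) stop("no shared identifiers between case and control")
  ca <- case_expr[ids]; co <- control_expr[ids]
  if (any(!is.finite(ca)) || any(!is.finite(co)) || any(ca <= 0) ||
      any(co <= 0))
    stop("expression values must be finite and strictly positive")
  setNames(log2(ca / co), ids)
}

#' Score a single chain against a score table
#'
#' The chain score is the sum of the element scores of its `l` nodes divided
#' by `l` (i.e. their mean), which removes the systematic advantage longer
#' chains would gain under a plain sum.
#'
#' @param chain character vector of node identifiers.
#' @param table a score table; nodes missing from it take the table minimum.
#' @return the chain score, a single number.
#' @export
chain_score <- function(chain, table) {
  stopifnot(is.character(chain), length(chain) >= 1L)
  miss <- setdiff(chain, names(table))
  v <- setNames(rep(min(table), length(chain)), chain)
  v[chain %in% names(table)] <- table[chain[chain %in% names(table)]]
  if (length(miss) > 0L)
    message(sprintf("chain_score: %d node(s) without a score assigned the table minimum",
                    length(miss)))
  mean(v)
}

#' Compute chain scores for every chain of a chain set
#'
#' Adds one score column per table to the chain set. Each table is first
#' extended to the full node set of the query network (missing nodes take the
#' table minimum, reported once per table).
#'
#' @param x a `chain_set`.
#' @param tables a named list of score tables, or a single score table (then
#'   `name` supplies its label).
#' @param name score label used when `tables` is a single unnamed table.
#' @return `x` with score columns filled in.
#' @export
chain_scores <- function(x, tables, name = "score") {
  stopifnot(inherits(x, "chain_set"))
  if (is.numeric(tables)) tables <- setNames(list(tables), name)
  stopifnot(is.list(tables), !is.null(names(tables)))
  nodes <- igraph::V(x$graph)$name
  idx <- lapply(x$chains, match, table = nodes)
  for (nm in names(tables)) {
    vals <- align_scores(x$graph, tables[[nm]], label = nm)
    x$scores[[nm]] <- vapply(idx, function(ix) mean(vals[ix]), 0)
  }
  x
}

#' Combine score tables as a weighted sum of normalized scores
#'
#' Each table is min-max normalized to [0, 1] (see [normalize_scores()]) and
#' the combined score of a node is the weighted sum of its normalized scores,
#' `c_k = sum_j w_j s_kj`. Tables are first extended to the union of their
#' node sets (missing nodes take the table minimum). The result is itself a
#' score table, usable for chain scoring.
#'
#' @param tables named list of score tables.
#' @param weights numeric vector of non-negative weights, one per table;
#'   at least one must be positive. Defaults to equal weights.
#' @return the combined score table.
#' @export
combined_weighted_sum <- function(tables, weights = rep(1, length(tables))) {
  stopifnot(is.list(tables), length(tables) >= 1L)
  if (length(weights) != length(tables))
    stop("need one weight per score table")
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("weights must be finite and non-negative")
  if (all(weights == 0)) stop("at least one weight must be positive")
  ids <- sort(unique(unlist(lapply(tables, names))))
  acc <- setNames(rep(0, length(ids)), ids)
  for (j in seq_along(tables)) {
    t_j <- tables[[j]]
    full <- setNames(rep(min(t_j), length(ids)), ids)
    full[names(t_j)[names(t_j) %in% ids]] <- t_j[names(t_j) %in% ids]
    acc <- acc + weights[j] * normalize_scores(full)
  }
  acc
}

# Resolve a selection rule on a ranked chain set. Exactly one of top_n,
# top_frac, p_cutoff may be given.
selection_index <- function(x, by, top_n = NULL, top_frac = NULL,
                            p_cutoff = NULL) {
  given <- c(!is.null(top_n), !is.null(top_frac), !is.null(p_cutoff))
  if (sum(given) != 1L)
    stop("give exactly one of top_n, top_frac, p_cutoff")
  if (!is.null(p_cutoff)) {
    stopifnot(p_cutoff > 0, p_cutoff <= 1)
    which(chain_column(x, by, use_pvalue = TRUE) <= p_cutoff)
  } else {
    n <- if (!is.null(top_n)) top_n else ceiling(top_frac * n_chains(x))
    stopifnot(n >= 0)
    ord <- order(-chain_column(x, by), x$id, method = "radix")
    ord[seq_len(min(n, n_chains(x)))]
  }
}

#' Select top chains by score rank or p-value cutoff
#'
#' @param x a `chain_set` with the relevant column computed.
#' @param by score name the selection refers to.
#' @param top_n keep the `n` best-scoring chains.
#' @param top_frac keep the best-scoring fraction (e.g. `0.25` for the top
#'   quartile; the count is rounded up).
#' @param p_cutoff keep chains with empirical p-value of `by` at most this
#'   value.
#' @return the selected `chain_set`, ranked by `by`.
#' @export
select_chains <- function(x, by, top_n = NULL, top_frac = NULL,
                          p_cutoff = NULL) {
  stopifnot(inherits(x, "chain_set"))
  idx <- selection_index(x, by, top_n, top_frac, p_cutoff)
  rank_chains(x[idx], by, use_pvalue = !is.null(p_cutoff))
}

#' Filter-then-rerank combination of two scores
#'
#' Pre-filters the chains with a threshold on a first score (a p-value cutoff
#' or a top fraction of its ranking) and re-ranks the surviving chains by a
#' second score (descending score, or ascending p-value when
#' `rerank_by_pvalue = TRUE`).
#'
#' @param x a `chain_set` with both scores computed.
#' @param filter_by name of the filtering score.
#' @param rerank_by name of the re-ranking score.
#' @param p_cutoff,top_frac threshold for the filter; give exactly one.
#' @param rerank_by_pvalue re-rank by the p-value of `rerank_by`.
#' @return the filtered `chain_set`, ordered by the re-ranking score.
#' @export
combined_filter <- function(x, filter_by, rerank_by, p_cutoff = NULL,
                            top_frac = NULL, rerank_by_pvalue = FALSE) {
  stopifnot(inherits(x, "chain_set"))
  idx <- selection_index(x, filter_by, top_frac = top_frac,
                         p_cutoff = p_cutoff)
  rank_chains(x[idx], rerank_by, use_pvalue = rerank_by_pvalue)
}

#' Intersection combination: chains passing every threshold simultaneously
#'
#' Keeps only the chains that satisfy all given criteria at once, e.g. an
#' empirical p-value of at most 0.05 under two different scores, or
#' membership in the top quartile of two rankings.
#'
#' @param x a `chain_set` with the named scores computed.
#' @param specs a named list, one element per score: each either
#'   `list(p_cutoff = ...)` or `list(top_frac = ...)` (or `list(top_n = ...)`).
#' @param display_by score whose ranking orders the result (defaults to the
#'   first spec); ordered by its p-value when `display_by_pvalue = TRUE`.
#' @param display_by_pvalue logical.
#' @return the intersected `chain_set`, ranked by `display_by`.
#' @export
combined_intersection <- function(x, specs, display_by = names(specs)[1L],
                                  display_by_pvalue = FALSE) {
  stopifnot(inherits(x, "chain_set"), is.list(specs), length(specs) >= 1L,
            !is.null(names(specs)))
  keep <- seq_len(n_chains(x))
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    idx <- selection_index(x, nm, top_n = sp$top_n, top_frac = sp$top_frac,
                           p_cutoff = sp$p_cutoff)
    keep <- intersect(keep, idx)
  }
  if (length(keep) == 0L)
    warning("intersection of chain selections is empty")
  rank_chains(x[sort(keep)], display_by, use_pvalue = display_by_pvalue)
}
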