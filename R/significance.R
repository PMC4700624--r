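#' Configuration of the randomized-network null model
#'
#' Chain significance is assessed against networks randomized by repeated
#' double-edge swaps, which preserve every node's degree exactly, with the
#' node-to-score assignment shuffled alongside. The defaults (100 replicates,
#' 10 attempted swaps per edge) give p-value resolution of about 0.01 while
#' mixing the edge set well at the network sizes the method targets.
#'
#' @param replicates number of random networks `R` (default 100).
#' @param swap_multiplier attempted double-edge swaps per network edge
#'   (default 10).
#' @param seed master random seed; every replicate derives its own stream
#'   from it, so results are fully reproducible.
#' @param shuffle_scores also permute the node-to-score assignment in each
#'   replicate (default `TRUE`). The permutation is drawn once per replicate
#'   and applied jointly to all score tables, preserving within-node
#'   correlation between scores.
#' @return an object of class `null_model_config`.
#' @export
null_model_config <- function(replicates = 100L, swap_multiplier = 10L,
                              seed = 1L, shuffle_scores = TRUE) {
  stopifnot(replicates >= 1L, swap_multiplier >= 1L, is.numeric(seed))
  structure(list(replicates = as.integer(replicates),
                 swap_multiplier = as.integer(swap_multiplier),
                 seed = as.integer(seed),
                 shuffle_scores = isTRUE(shuffle_scores)),
            class = "null_model_config")
}

#' Randomize a network while preserving every node degree
#'
#' Applies `swap_multiplier * ecount(net)` attempted double-edge swaps
#' (swaps creating self-loops or parallel edges are rejected), yielding a
#' simple undirected network with the identical node set and degree
#' sequence. Deterministic given the config seed and replicate index.
#'
#' @param net an undirected simple igraph graph (at least 2 edges).
#' @param config a [null_model_config()].
#' @param replicate_index replicate number (selects the random stream).
#' @return the rewired igraph graph.
#' @export
rewire_preserving_degrees <- function(net, config = null_model_config(),
                                      replicate_index = 1L) {
  stopifnot(igraph::is_igraph(net))
  if (igraph::ecount(net) < 2L) stop("need at least 2 edges to swap")
  out <- with_seed(derive_seed(config$seed, replicate_index),
    igraph::rewire(net, igraph::keeping_degseq(
      loops = FALSE, niter = config$swap_multiplier * igraph::ecount(net))))
  if (identical(canonical_edge_ids(out), canonical_edge_ids(net)))
    warning("rewiring left the network unchanged (topology too rigid to swap)")
  out
}

# Empirical p-value with a +1 pseudo-count in numerator and denominator:
# the fraction of replicate top scores matching or beating s, never 0.
pv_formula <- function(tops, s, R) (1 + sum(tops >= s)) / (R + 1)

canonical_edge_ids <- function(g) {
  el <- igraph::as_edgelist(g)
  sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "\r"))
}

#' Empirical chain p-values from degree-preserving random networks
#'
#' For each of `R` replicates the network is rewired with degrees preserved,
#' the node-to-score assignment is shuffled, and the chain search is rerun
#' with the original query; the replicate contributes its top chain score
#' `m_r` (or `-Inf` when the randomized network yields no chain, so that
#' disconnected replicates count against no real chain rather than being
#' redrawn). The p-value of an observed chain with score `s` is
#'
#' \deqn{p = (1 + \#\{r : m_r \ge s\}) / (R + 1)}
#'
#' the fraction of random networks whose best chain matches or beats it, with
#' a pseudo-count so an empirical p-value is never exactly 0. P-values are
#' monotone non-increasing in `s` by construction.
#'
#' @param x a `chain_set` produced by [find_chains()].
#' @param tables named list of score tables (the same ones used for chain
#'   scoring), or a single table.
#' @param config a [null_model_config()].
#' @param name label used when `tables` is a single unnamed table.
#' @return `x` with score columns (computed if absent) and one p-value column
#'   per table.
#' @export
chain_pvalues <- function(x, tables, config = null_model_config(),
                          name = "score") {
  stopifnot(inherits(x, "chain_set"), inherits(config, "null_model_config"))
  if (is.numeric(tables)) tables <- setNames(list(tables), name)
  if (config$replicates < 20L)
    warning("fewer than 20 replicates: p-value resolution is coarse")
  missing_scores <- setdiff(names(tables), names(x$scores))
  if (length(missing_scores) > 0L)
    x <- chain_scores(x, tables[missing_scores])
  net <- x$graph
  nodes <- igraph::V(net)$name
  aligned <- lapply(names(tables), function(nm)
    suppressMessages(align_scores(net, tables[[nm]], label = nm)))
  names(aligned) <- names(tables)

  R <- config$replicates
  tops <- matrix(-Inf, nrow = R, ncol = length(tables),
                 dimnames = list(NULL, names(tables)))
  for (r in seq_len(R)) {
    g_r <- suppressWarnings(
      rewire_preserving_degrees(net, config, replicate_index = r))
    perm <- if (config$shuffle_scores)
      with_seed(derive_seed(config$seed, R + r), sample(length(nodes)))
    else seq_along(nodes)
    cs_r <- suppressWarnings(
      find_chains(g_r, x$query$start, x$query$end, x$query$k,
                  x$query$allow_endpoint_interior))
    if (n_chains(cs_r) == 0L) next
    idx <- lapply(cs_r$chains, match, table = nodes)
    for (nm in names(tables)) {
      vals <- aligned[[nm]][perm]              # shuffled node->score map
      tops[r, nm] <- max(vapply(idx, function(ix) mean(vals[ix]), 0))
    }
  }
  for (nm in names(tables)) {
    s <- x$scores[[nm]]
    x$pvalues[[nm]] <- vapply(s, function(si) pv_formula(tops[, nm], si, R), 0)
  }
  x$null_model <- config
  x$null_top_scores <- tops
  x
}
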