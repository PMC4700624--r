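# The chain_set container: all chains found for one query, plus any chain
# scores and empirical p-values computed on them. Chains are stored as a list
# of character vectors; scores and p-values as parallel data frames.

new_chain_set <- function(chains, query, graph) {
  n <- length(chains)
  structure(list(
    chains  = chains,
    id      = vapply(chains, paste, "", collapse = "|"),
    length  = vapply(chains, length, 0L),
    scores  = as.data.frame(matrix(nrow = n, ncol = 0L)),
    pvalues = as.data.frame(matrix(nrow = n, ncol = 0L)),
    query   = query,
    graph   = graph
  ), class = "chain_set")
}

#' Number of chains in a chain set
#' @param x a `chain_set`.
#' @return integer count.
#' @export
n_chains <- function(x) {
  stopifnot(inherits(x, "chain_set"))
  length(x$chains)
}

#' @export
`[.chain_set` <- function(x, i, ...) {
  out <- x
  out$chains  <- x$chains[i]
  out$id      <- x$id[i]
  out$length  <- x$length[i]
  out$scores  <- x$scores[i, , drop = FALSE]
  out$pvalues <- x$pvalues[i, , drop = FALSE]
  rownames(out$scores) <- rownames(out$pvalues) <- NULL
  out
}

#' @export
as.data.frame.chain_set <- function(x, ...) {
  df <- data.frame(chain = x$id, length = x$length,
                   stringsAsFactors = FALSE)
  for (nm in names(x$scores)) df[[nm]] <- x$scores[[nm]]
  for (nm in names(x$pvalues)) df[[paste0(nm, "_p")]] <- x$pvalues[[nm]]
  df
}

#' @export
print.chain_set <- function(x, n = 6L, ...) {
  cat(sprintf("Chain set: %d chain(s), start {%s} -> end {%s}, max length %d\n",
              n_chains(x), paste(x$query$start, collapse = ","),
              paste(x$query$end, collapse = ","), x$query$k))
  if (ncol(x$scores) > 0L)
    cat("Scores:", paste(names(x$scores), collapse = ", "), "\n")
  if (ncol(x$pvalues) > 0L)
    cat("P-values:", paste(names(x$pvalues), collapse = ", "), "\n")
  if (n_chains(x) > 0L) print(head(as.data.frame(x), n))
  if (n_chains(x) > n) cat("... (", n_chains(x) - n, " more)\n", sep = "")
  invisible(x)
}

# Canonical lexicographic order on node sequences: element-wise comparison,
# a proper prefix sorting first.
chain_order <- function(chains) {
  if (length(chains) == 0L) return(integer(0))
  kmax <- max(vapply(chains, length, 0L))
  cols <- lapply(seq_len(kmax), function(j)
    vapply(chains, function(ch) if (length(ch) >= j) ch[[j]] else "", ""))
  do.call(order, c(cols, list(method = "radix")))
}

#' Rank the chains of a chain set by a score or p-value
#'
#' Higher scores rank first; lower p-values rank first. Ties are broken
#' lexicographically by node sequence so rankings are deterministic.
#'
#' @param x a `chain_set` with the named column computed.
#' @param by name of a score (ranked descending) or, with `use_pvalue = TRUE`,
#'   of a p-value column (ranked ascending).
#' @param use_pvalue rank by the empirical p-value of `by` instead of its
#'   score.
#' @return the reordered `chain_set`.
#' @export
rank_chains <- function(x, by, use_pvalue = FALSE) {
  stopifnot(inherits(x, "chain_set"))
  v <- chain_column(x, by, use_pvalue)
  key <- if (use_pvalue) v else -v
  ord <- order(key, x$id, method = "radix")
  x[ord]
}

chain_column <- function(x, by, use_pvalue = FALSE) {
  pool <- if (use_pvalue) x$pvalues else x$scores
  if (!by %in% names(pool))
    stop("unknown ", if (use_pvalue) "p-value" else "score", " name: '", by,
         "' (available: ", paste(names(pool), collapse = ", "), ")")
  pool[[by]]
}

#' Write a chain table to TSV
#'
#' One row per chain: the node path joined by `"|"`, its length in nodes and
#' every computed score and p-value (`<score>_p` columns).
#'
#' @param x a `chain_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chains <- function(x, path) {
  stopifnot(inherits(x, "chain_set"))
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a chain table written by [write_chains()]
#'
#' @param path path to the TSV file.
#' @return a data frame with a `chain` column (`"|"`-separated node path),
#'   `length`, and any score / p-value columns.
#' @export
read_chains <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, quote = "")
  if (!"chain" %in% names(df)) stop("not a chain table (no 'chain' column): ",
                                    path)
  df
}

#' Assemble selected chains into a context-specific subnetwork
#'
#' Takes the union of nodes and consecutive-pair edges over the chains of a
#' (typically top-ranked) chain set. Each node carries an `occurrence`
#' attribute: the number of selected chains containing it, the quantity used
#' to size nodes when the subnetwork is drawn.
#'
#' @param x a non-empty `chain_set` (usually a selection, see
#'   [select_chains()]).
#' @return an undirected igraph graph, a subgraph of the query network, with
#'   vertex attribute `occurrence`.
#' @export
assemble_subnetwork <- function(x) {
  stopifnot(inherits(x, "chain_set"))
  if (n_chains(x) == 0L) stop("empty chain selection")
  nodes <- unique(unlist(x$chains))
  edges <- unique(do.call(rbind, lapply(x$chains, function(ch) {
    if (length(ch) < 2L) return(NULL)
    e <- cbind(ch[-length(ch)], ch[-1L])
    t(apply(e, 1L, sort))                       # undirected: canonical order
  })))
  occ <- table(factor(unlist(lapply(x$chains, unique)), levels = nodes))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, length(setdiff(nodes, igraph::V(g)$name)),
                            name = setdiff(nodes, igraph::V(g)$name))
  igraph::V(g)$occurrence <- as.integer(occ[igraph::V(g)$name])
  g
}

#' Write an assembled subnetwork to GraphML or TSV
#'
#' GraphML output carries the `occurrence` node attribute inline; TSV output
#' writes the edge list to `path` and the node occurrence table to
#' `<path>.nodes.tsv`.
#'
#' @param x a non-empty `chain_set` selection.
#' @param path output path.
#' @param format `"graphml"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_subnetwork <- function(x, path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  g <- assemble_subnetwork(x)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    write_network(g, path, format = "tsv")
    nd <- data.frame(node = igraph::V(g)$name,
                     occurrence = igraph::V(g)$occurrence)
    write.table(nd, paste0(path, ".nodes.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}
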