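#' Enumerate all bounded-length chains between start and end nodes
#'
#' Finds every simple path (chain) of at most `k` nodes whose first node lies
#' in the start set and whose last node lies in the end set, by a depth-limited
#' depth-first search. The search is exhaustive within the depth limit, so the
#' result is exactly the set of such paths; the depth limit is what keeps the
#' otherwise factorial "all simple paths" problem tractable on interaction
#' networks, where biological relevance decays with distance beyond the
#' shortest path.
#'
#' Chain length is counted in nodes, not edges: a direct edge between a start
#' and an end node is a chain of length 2. By default start and end nodes act
#' as traversal terminals — they may not occur in the interior of a chain
#' (mirroring evaluation practice, which excludes start and end proteins);
#' set `allow_endpoint_interior = TRUE` to lift this. Output order is
#' canonical (lexicographic by node sequence), so results are reproducible.
#'
#' @param net an undirected igraph graph with named vertices.
#' @param start,end character vectors of node identifiers; both must be
#'   subsets of the network's nodes.
#' @param k maximum chain length in nodes (`k >= 2`).
#' @param allow_endpoint_interior logical; permit start/end nodes as interior
#'   chain nodes (default `FALSE`).
#' @return a `chain_set` holding every qualifying chain exactly once.
#' @examples
#' g <- igraph::graph_from_edgelist(
#'   cbind(c("S", "C1", "C1", "C2"), c("C1", "E", "C2", "E")),
#'   directed = FALSE)
#' find_chains(g, "S", "E", k = 4)
#' @export
find_chains <- function(net, start, end, k, allow_endpoint_interior = FALSE) {
  q <- validate_query(net, start, end, k, allow_endpoint_interior)
  nodes <- igraph::V(net)$name
  # adjacency lists, 0-based, sorted for a deterministic traversal
  adj <- lapply(igraph::adjacent_vertices(net, igraph::V(net)),
                function(v) sort(as.integer(v)) - 1L)
  paths <- .dfs_chains(adj,
                       start_idx = sort(match(q$start, nodes)) - 1L,
                       is_start = nodes %in% q$start,
                       is_end = nodes %in% q$end,
                       k = as.integer(k),
                       allow_interior = isTRUE(allow_endpoint_interior))
  chains <- lapply(paths, function(ix) nodes[ix + 1L])
  chains <- chains[chain_order(chains)]
  if (length(chains) == 0L && !q$reachable)
    warning("no start-end connection within ", k, " nodes; empty chain set")
  new_chain_set(chains, q, net)
}

validate_query <- function(net, start, end, k, allow_endpoint_interior) {
  stopifnot(igraph::is_igraph(net))
  if (is.null(igraph::V(net)$name)) stop("network nodes must be named")
  nodes <- igraph::V(net)$name
  start <- unique(as.character(start))
  end <- unique(as.character(end))
  if (length(start) == 0L || length(end) == 0L)
    stop("start and end sets must be non-empty")
  missing <- setdiff(c(start, end), nodes)
  if (length(missing) > 0L)
    stop("start/end node(s) absent from network: ",
         paste(missing, collapse = ", "))
  if (!is.numeric(k) || length(k) != 1L || k < 2L)
    stop("k must be a single number >= 2 (chain length in nodes)")
  d <- suppressWarnings(
    min(igraph::distances(net, v = start, to = end)))
  list(start = start, end = end, k = as.integer(k),
       allow_endpoint_interior = isTRUE(allow_endpoint_interior),
       reachable = is.finite(d) && d + 1 <= k)
}

#' Restrict a network to nodes that can lie on a bounded-length chain
#'
#' Returns the induced subgraph on the nodes `v` whose BFS distance to the
#' nearest start node plus distance to the nearest end node is at most
#' `k - 1` edges — exactly the nodes that can sit on some start-to-end walk
#' of at most `k` nodes. Start and end nodes are always retained. Because
#' every simple path of length at most `k` nodes lies within this set,
#' pre-filtering with it never changes the result of [find_chains()] while
#' shrinking the search space, often substantially.
#'
#' @inheritParams find_chains
#' @return the induced igraph subgraph.
#' @export
select_proximity_subnetwork <- function(net, start, end, k) {
  q <- validate_query(net, start, end, k, FALSE)
  nodes <- igraph::V(net)$name
  ds <- suppressWarnings(apply(
    igraph::distances(net, v = q$start, to = igraph::V(net)), 2L, min))
  de <- suppressWarnings(apply(
    igraph::distances(net, v = q$end, to = igraph::V(net)), 2L, min))
  keep <- (ds + de) <= (k - 1)
  keep[nodes %in% c(q$start, q$end)] <- TRUE
  if (!q$reachable)
    warning("no start-end connection within ", k,
            " nodes; proximity subnetwork has no interior")
  igraph::induced_subgraph(net, which(keep))
}
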