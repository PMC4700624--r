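# Independent oracles and small graph builders shared across tests.

# Fig-style toy network: S-C1, C1-E, C1-C2, C2-E.
toy_network <- function() {
  igraph::graph_from_edgelist(
    cbind(c("S", "C1", "C1", "C2"), c("C1", "E", "C2", "E")),
    directed = FALSE)
}

# Cache of all injective index sequences (permutation prefixes) by (n, len).
.perm_cache <- new.env(parent = emptyenv())

# All injective sequences over 1..n of each length 1..maxlen, as a list of
# integer matrices (one row per sequence).
perm_prefixes <- function(n, maxlen = n) {
  key <- paste0("n", n)
  if (is.null(.perm_cache[[key]])) {
    out <- list(matrix(seq_len(n), ncol = 1L))
    for (l in seq_len(n)[-1L]) {
      prev <- out[[l - 1L]]
      r <- nrow(prev)
      big <- prev[rep(seq_len(r), times = n), , drop = FALSE]
      nxt <- rep(seq_len(n), each = r)
      used <- rowSums(big == nxt) > 0L
      out[[l]] <- cbind(big, nxt)[!used, , drop = FALSE]
    }
    .perm_cache[[key]] <- out
  }
  .perm_cache[[key]][seq_len(min(maxlen, n))]
}

# Brute-force chain enumeration: every injective node sequence of length
# 2..k is checked against the adjacency matrix and the endpoint/interior
# policy. Returns a sorted character vector of "|"-joined chains.
brute_force_chains <- function(g, start, end, k, allow_interior = FALSE) {
  nodes <- igraph::V(g)$name
  n <- length(nodes)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  seqs <- perm_prefixes(n, min(k, n))
  res <- character(0)
  s_idx <- which(nodes %in% start)
  e_idx <- which(nodes %in% end)
  for (l in 2:min(k, n)) {
    M <- seqs[[l]]
    ok <- M[, 1L] %in% s_idx & M[, l] %in% e_idx
    for (j in seq_len(l - 1L)) {
      if (!any(ok)) break
      ok <- ok & A[cbind(M[, j], M[, j + 1L])] > 0
    }
    if (!allow_interior && l > 2L) {
      for (j in 2:(l - 1L))
        ok <- ok & !(M[, j] %in% s_idx & !(M[, j] %in% e_idx)) &
          !(M[, j] %in% e_idx)
    }
    if (any(ok))
      res <- c(res, apply(M[ok, , drop = FALSE], 1L,
                          function(ix) paste(nodes[ix], collapse = "|")))
  }
  sort(res)
}

# Second independent oracle built on igraph's own simple-path enumeration.
igraph_oracle_chains <- function(g, start, end, k, allow_interior = FALSE) {
  nodes <- igraph::V(g)$name
  res <- character(0)
  for (s in intersect(start, nodes)) {
    to <- intersect(end, nodes)
    paths <- igraph::all_simple_paths(g, from = s, to = to, cutoff = k - 1)
    for (p in paths) {
      ch <- nodes[as.integer(p)]
      if (length(ch) < 2L) next
      if (!allow_interior && length(ch) > 2L) {
        inner <- ch[-c(1L, length(ch))]
        if (any(inner %in% end)) next
        if (any(inner %in% start & !(inner %in% end))) next
      }
      res <- c(res, paste(ch, collapse = "|"))
    }
  }
  sort(unique(res))
}

# Random named ER graph for property tests.
random_named_graph <- function(n, p = 0.4) {
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
  g
}
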