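#' Synthetic benchmark: a known pathway planted in a random background network
#'
#' Generates an undirected network consisting of a random background graph
#' (Erdős–Rényi `G(n, m)` or Barabási–Albert preferential attachment, the
#' latter mimicking the heavy-tailed degree distributions of protein
#' interaction networks), a planted simple path of `planted_len` nodes
#' between fresh start and end nodes, optional decoy start-to-end paths
#' routed through background nodes, and optional random attachment edges
#' anchoring every planted node in the background. The planted interior
#' nodes form the gold standard; score tables assign gold-standard nodes
#' (including start and end) draws from one distribution and background
#' nodes draws from another, so the separation `(mu_gs - mu_bg) / sigma`
#' controls how recoverable the planted pathway is.
#'
#' Background nodes that end up with no edges are dropped (interaction
#' networks contain no isolated proteins); with `n_edges = 0`, `n_decoys = 0`
#' and `attach = 0` the network is therefore exactly the planted path.
#'
#' Default sizes (300 background nodes, 850 edges, an 8-node planted path)
#' match the magnitude of the muscle-specific use case the method was
#' designed around.
#'
#' @param n_nodes background node count.
#' @param n_edges background edge count (Erdős–Rényi model).
#' @param model `"gnm"` (Erdős–Rényi, default) or `"ba"`
#'   (Barabási–Albert).
#' @param pa_m edges added per step for the `"ba"` model.
#' @param planted_len planted path length in nodes, including start and end
#'   (`>= 2`).
#' @param n_decoys number of decoy start-to-end paths threaded through
#'   randomly chosen background nodes (each of `planted_len` nodes).
#' @param attach random edges from each planted node into the background.
#' @param scores a named list of score models, each a list with elements
#'   `mu_gs`, `mu_bg`, `sigma` and optional `dist` (`"normal"` or
#'   `"lognormal"`, the latter for heavy-tailed evidence scores such as
#'   study-occurrence counts).
#' @param seed random seed; identical spec + seed gives identical output.
#' @return a list with `network` (igraph), `scores` (named list of score
#'   tables), `gold_standard` (planted interior nodes), `start`, `end`,
#'   `planted_chain` (the full planted node sequence) and `k`
#'   (= `planted_len`, the natural search depth for the fixture).
#' @export
make_fixture <- function(n_nodes = 300L, n_edges = 850L,
                         model = c("gnm", "ba"), pa_m = 3L,
                         planted_len = 8L, n_decoys = 8L, attach = 2L,
                         scores = list(
                           relevance = list(mu_gs = 3, mu_bg = 0, sigma = 1)),
                         seed = 1L) {
  model <- match.arg(model)
  if (planted_len < 2L) stop("planted_len must be at least 2")
  if (n_nodes < 1L) stop("need a positive background node count")
  n_interior <- planted_len - 2L
  if (n_decoys > 0L && n_nodes < n_interior)
    stop("background too small for decoy paths")
  with_seed(seed, {
    bg_names <- sprintf("b%03d", seq_len(n_nodes))
    bg <- switch(model,
      gnm = igraph::sample_gnm(n_nodes, min(n_edges,
                                            n_nodes * (n_nodes - 1) / 2)),
      ba  = igraph::as_undirected(
        igraph::sample_pa(n_nodes, m = pa_m, directed = TRUE), "collapse"))
    igraph::V(bg)$name <- bg_names

    interior <- if (n_interior > 0L) sprintf("P%02d", seq_len(n_interior))
                else character(0)
    path_nodes <- c("S", interior, "E")
    el <- cbind(path_nodes[-length(path_nodes)], path_nodes[-1L])

    g <- igraph::add_vertices(bg, length(path_nodes), name = path_nodes)
    g <- igraph::add_edges(g, t(el))

    if (n_decoys > 0L && n_interior > 0L) {
      for (d in seq_len(n_decoys)) {
        via <- sample(bg_names, n_interior)
        seqd <- c("S", via, "E")
        g <- igraph::add_edges(g, t(cbind(seqd[-length(seqd)], seqd[-1L])))
      }
    }
    if (attach > 0L) {
      for (v in path_nodes)
        g <- igraph::add_edges(g, t(cbind(v, sample(bg_names, attach))))
    }
    g <- igraph::simplify(g)
    iso <- which(igraph::degree(g) == 0L & !(igraph::V(g)$name %in% path_nodes))
    if (length(iso) > 0L) g <- igraph::delete_vertices(g, iso)

    nodes <- igraph::V(g)$name
    gs_all <- path_nodes                           # elevated-score nodes
    tabs <- lapply(scores, function(sp) {
      dist <- if (is.null(sp$dist)) "normal" else sp$dist
      drawn <- ifelse(nodes %in% gs_all,
                      draw_scores(length(nodes), sp$mu_gs, sp$sigma, dist),
                      draw_scores(length(nodes), sp$mu_bg, sp$sigma, dist))
      setNames(drawn, nodes)
    })

    list(network = g, scores = tabs, gold_standard = interior,
         start = "S", end = "E", planted_chain = path_nodes,
         k = planted_len)
  })
}

draw_scores <- function(n, mu, sigma, dist) {
  switch(dist,
         normal = rnorm(n, mu, sigma),
         lognormal = rlnorm(n, meanlog = mu, sdlog = sigma),
         stop("unknown score distribution: ", dist))
}

#' Write a fixture to disk in the package's standard formats
#'
#' Writes `network.graphml`, `scores.tsv`, `gold_standard.txt`, `start.txt`
#' and `end.txt` under `dir`.
#'
#' @param fx a fixture from [make_fixture()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fx, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_network(fx$network, file.path(dir, "network.graphml"), "graphml")
  write_scores(fx$scores, file.path(dir, "scores.tsv"))
  writeLines(fx$gold_standard, file.path(dir, "gold_standard.txt"))
  writeLines(fx$start, file.path(dir, "start.txt"))
  writeLines(fx$end, file.path(dir, "end.txt"))
  invisible(dir)
}
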