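#' Rank bounded-length interaction chains between start and end nodes
#'
#' The high-level entry point: restricts the network to the proximity
#' subnetwork of the query (optional), enumerates every chain of at most `k`
#' nodes from the start set to the end set, scores each chain under every
#' supplied score table (mean node score over the chain), optionally adds a
#' combined weighted-sum score, and computes empirical p-values against
#' degree-preserving randomized networks with shuffled scores.
#'
#' @param net an undirected igraph graph with named vertices, or a file path
#'   accepted by [read_network()].
#' @param start,end character vectors of start / end node identifiers.
#' @param k maximum chain length in nodes.
#' @param scores a named list of score tables (named numeric vectors). When
#'   `NULL`, the topological connectivity score of the (full) network is
#'   used.
#' @param combine optional weight vector (one weight per score table): adds a
#'   `combined` score table, the weighted sum of the normalized tables.
#' @param null_model a [null_model_config()], or `NULL` to skip p-values.
#' @param proximity_filter pre-restrict the search to the proximity
#'   subnetwork (never changes the result; default `TRUE`).
#' @param allow_endpoint_interior see [find_chains()].
#' @return an object of class `chainrank`: a list with `chains` (a
#'   `chain_set` carrying scores and p-values), `network` (the full input
#'   network), `query`, `tables`, and `null_model`.
#' @examples
#' fx <- make_fixture(n_nodes = 40, n_edges = 80, planted_len = 5,
#'                    n_decoys = 2, seed = 1)
#' fit <- chainrank(fx$network, fx$start, fx$end, k = 5, scores = fx$scores,
#'                  null_model = null_model_config(replicates = 30))
#' fit
#' @export
chainrank <- function(net, start, end, k, scores = NULL, combine = NULL,
                      null_model = null_model_config(),
                      proximity_filter = TRUE,
                      allow_endpoint_interior = FALSE) {
  if (is.character(net) && length(net) == 1L) net <- read_network(net)
  if (is.null(scores))
    scores <- list(connectivity = connectivity_score(net))
  stopifnot(is.list(scores), !is.null(names(scores)))
  if (!is.null(combine))
    scores$combined <- combined_weighted_sum(scores, combine)
  search_net <- if (proximity_filter)
    select_proximity_subnetwork(net, start, end, k) else net
  cs <- find_chains(search_net, start, end, k, allow_endpoint_interior)
  cs <- chain_scores(cs, scores)
  if (!is.null(null_model) && n_chains(cs) > 0L)
    cs <- chain_pvalues(cs, scores, null_model)
  structure(list(chains = cs, network = net, query = cs$query,
                 tables = scores, null_model = null_model,
                 call = match.call()),
            class = "chainrank")
}

#' @export
print.chainrank <- function(x, ...) {
  cat("ChainRank query\n")
  cat(sprintf("  network: %d nodes, %d edges (search space: %d nodes, %d edges)\n",
              igraph::vcount(x$network), igraph::ecount(x$network),
              igraph::vcount(x$chains$graph), igraph::ecount(x$chains$graph)))
  cat(sprintf("  start {%s} -> end {%s}, max chain length %d nodes\n",
              paste(x$query$start, collapse = ","),
              paste(x$query$end, collapse = ","), x$query$k))
  cat(sprintf("  chains found: %d; scores: %s\n", n_chains(x$chains),
              paste(names(x$chains$scores), collapse = ", ")))
  invisible(x)
}

#' @export
summary.chainrank <- function(object, by = names(object$chains$scores)[1L],
                              n = 10L, ...) {
  cat(sprintf("Top %d chains by '%s':\n", n, by))
  ranked <- rank_chains(object$chains, by)
  print(head(as.data.frame(ranked), n))
  invisible(object)
}

#' @export
as.data.frame.chainrank <- function(x, ...) as.data.frame(x$chains)

#' Extract the subnetwork assembled from top-ranked chains
#'
#' @param x a `chainrank` object.
#' @param by score name used for selection.
#' @param top_n,top_frac,p_cutoff selection rule; give exactly one.
#' @return an igraph subnetwork with an `occurrence` vertex attribute (see
#'   [assemble_subnetwork()]).
#' @export
subnetwork <- function(x, by = names(x$chains$scores)[1L], top_n = NULL,
                       top_frac = NULL, p_cutoff = NULL) {
  stopifnot(inherits(x, "chainrank"))
  assemble_subnetwork(select_chains(x$chains, by, top_n = top_n,
                                    top_frac = top_frac,
                                    p_cutoff = p_cutoff))
}

#' @export
plot.chainrank <- function(x, by = names(x$chains$scores)[1L], top_n = 25L,
                           ...) {
  g <- subnetwork(x, by = by, top_n = top_n)
  occ <- igraph::V(g)$occurrence
  role <- ifelse(igraph::V(g)$name %in% x$query$start, "start",
                 ifelse(igraph::V(g)$name %in% x$query$end, "end", "chain"))
  igraph::plot.igraph(
    g,
    vertex.size = 6 + 10 * occ / max(occ),
    vertex.color = c(start = "gold", end = "tomato", chain = "skyblue")[role],
    vertex.label.cex = 0.7, ...)
  invisible(g)
}

#' Run the full pipeline from a configuration file or list
#'
#' Executes search, scoring, significance, selection, subnetwork assembly
#' and (when a gold-standard file is given) evaluation, writing every stage
#' output plus a parameter log under `out_dir`. A run is fully reproducible
#' from its configuration.
#'
#' The configuration (YAML file or named list) understands:
#' \describe{
#'   \item{network}{path to a SIF/TSV/GraphML network (required)}
#'   \item{scores}{path to a TSV score table file; omit to use the
#'     connectivity score}
#'   \item{start, end}{paths to one-id-per-line node lists (required)}
#'   \item{gold}{path to a gold-standard node list (optional)}
#'   \item{k}{maximum chain length in nodes (required)}
#'   \item{combine}{weight vector for an additional combined score}
#'   \item{replicates, swap_multiplier, seed, shuffle_scores}{null-model
#'     settings (defaults 100 / 10 / 1 / true)}
#'   \item{select_by}{score name used for selection (default: first score)}
#'   \item{top_n / top_frac / p_cutoff}{selection rule (default
#'     `p_cutoff: 0.015`, falling back to `top_n: 50` when no chain passes)}
#'   \item{baseline_resamples}{evaluation baseline resamples (default 1000)}
#' }
#'
#' @param config path to a YAML file, or a named list with the same fields.
#' @param out_dir output directory (default `"chainrank_run"`).
#' @return the `chainrank` object, invisibly; stage outputs are written to
#'   `out_dir` (`chains.tsv`, `selected.tsv`, `subnetwork.graphml`,
#'   `evaluation.tsv`, `run_log.txt`).
#' @export
run_pipeline <- function(config, out_dir = "chainrank_run") {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  need <- setdiff(c("network", "start", "end", "k"), names(config))
  if (length(need) > 0L)
    stop("config is missing required field(s): ", paste(need, collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- file.path(out_dir, "run_log.txt")
  logmsg <- function(...) cat(sprintf(...), "\n", sep = "", file = log,
                              append = TRUE)
  cat("chainrank run\n", file = log)
  logmsg("config: %s", paste(deparse(config), collapse = " "))

  stage <- function(name, expr) {
    tryCatch(withCallingHandlers(expr,
               message = function(m) { logmsg("[%s] %s", name,
                                             trimws(conditionMessage(m)))
                                       invokeRestart("muffleMessage") },
               warning = function(w) { logmsg("[%s] warning: %s", name,
                                             trimws(conditionMessage(w)))
                                       invokeRestart("muffleWarning") }),
             error = function(e) stop("stage '", name, "' failed: ",
                                      conditionMessage(e), call. = FALSE))
  }

  net <- stage("read", read_network(config$network))
  start <- stage("read", readLines(config$start, warn = FALSE))
  end <- stage("read", readLines(config$end, warn = FALSE))
  start <- start[nzchar(start)]; end <- end[nzchar(end)]
  tabs <- if (!is.null(config$scores)) stage("read",
                                             read_scores(config$scores))
          else NULL
  nm <- null_model_config(
    replicates = config$replicates %||% 100L,
    swap_multiplier = config$swap_multiplier %||% 10L,
    seed = config$seed %||% 1L,
    shuffle_scores = config$shuffle_scores %||% TRUE)
  logmsg("null model: R=%d Q=%d seed=%d shuffle=%s", nm$replicates,
         nm$swap_multiplier, nm$seed, nm$shuffle_scores)

  fit <- stage("search+score+pvalue",
               chainrank(net, start, end, k = config$k, scores = tabs,
                         combine = config$combine, null_model = nm))
  logmsg("chains found: %d", n_chains(fit$chains))
  stage("write", write_chains(fit$chains, file.path(out_dir, "chains.tsv")))

  by <- config$select_by %||% names(fit$chains$scores)[1L]
  sel <- stage("select", {
    if (!is.null(config$top_n) || !is.null(config$top_frac) ||
        !is.null(config$p_cutoff)) {
      select_chains(fit$chains, by, top_n = config$top_n,
                    top_frac = config$top_frac, p_cutoff = config$p_cutoff)
    } else {
      s <- select_chains(fit$chains, by, p_cutoff = 0.015)
      if (n_chains(s) == 0L) {
        logmsg("no chain passes p <= 0.015; falling back to top 50")
        s <- select_chains(fit$chains, by, top_n = 50L)
      }
      s
    }
  })
  logmsg("selected chains (by %s): %d", by, n_chains(sel))
  stage("write", write_chains(sel, file.path(out_dir, "selected.tsv")))
  if (n_chains(sel) > 0L)
    stage("assemble", write_subnetwork(sel, file.path(out_dir,
                                                      "subnetwork.graphml")))

  if (!is.null(config$gold)) {
    gs <- stage("read", readLines(config$gold, warn = FALSE))
    ev <- stage("evaluate", evaluate_chains(
      fit$chains, gs, by,
      top_n = if (n_chains(sel) > 0L) n_chains(sel) else 1L,
      B = config$baseline_resamples %||% 1000L, seed = nm$seed))
    df <- data.frame(metric = c("TP", "FP", "precision", "recall",
                                "improvement", "baseline_precision", "auc"),
                     value = c(ev$TP, ev$FP, ev$precision, ev$recall,
                               ev$improvement, ev$baseline_precision,
                               ev$auc))
    write.table(df, file.path(out_dir, "evaluation.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    logmsg("evaluation: precision=%.3f recall=%.3f improvement=%.2f auc=%.3f",
           ev$precision, ev$recall, ev$improvement, ev$auc)
    fit$evaluation <- ev
  } else {
    logmsg("no gold-standard file given; evaluation skipped")
  }
  invisible(fit)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
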