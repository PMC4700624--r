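#' Read an undirected network from SIF, TSV edge list or GraphML
#'
#' Networks are modelled as undirected simple [igraph][igraph::igraph-package]
#' graphs with character node names. Self-loops are dropped and duplicate
#' edges collapsed on read; the numbers of dropped items are reported as a
#' message.
#'
#' The SIF dialect is whitespace-delimited `source interaction target`
#' records; the interaction type token is discarded (edges represent
#' undirected physical binding). A TSV edge list has two (or three) columns,
#' source and target first; a third column is ignored. GraphML is read via
#' igraph.
#'
#' @param path path to the network file.
#' @param format one of `"auto"`, `"sif"`, `"tsv"`, `"graphml"`. `"auto"`
#'   guesses from the file extension.
#' @return an undirected simple igraph graph with `name` vertex attribute.
#' @seealso [write_network()], [read_scores()]
#' @export
read_network <- function(path, format = c("auto", "sif", "tsv", "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("network file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, sif = "sif", graphml = "graphml",
                     xml = "graphml", "tsv")
  }
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    if (is.null(igraph::V(g)$name))
      igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
    g <- igraph::as_undirected(g, mode = "collapse")
    return(clean_network(g, what = path))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lines <- lines[keep]
  if (length(lines) == 0L) stop("empty network in ", path)
  tok <- strsplit(trimws(lines), "[ \t]+")
  el <- matrix(character(0), ncol = 2)
  for (i in seq_along(tok)) {
    tk <- tok[[i]]
    if (format == "sif") {
      if (length(tk) == 1L) next                      # isolated node record
      if (length(tk) < 3L)
        stop("malformed SIF line ", which(keep)[i], " in ", path, ": ",
             lines[i])
      # middle token is the interaction type; SIF permits several targets
      el <- rbind(el, cbind(tk[1L], tk[3:length(tk)]))
    } else {
      if (length(tk) < 2L)
        stop("malformed edge-list line ", which(keep)[i], " in ", path, ": ",
             lines[i])
      el <- rbind(el, tk[1:2])
    }
  }
  if (nrow(el) == 0L) stop("empty network in ", path)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  clean_network(g, what = path)
}

# Drop self-loops and collapse duplicate edges, with a count message.
clean_network <- function(g, what = "network") {
  n_loop <- sum(igraph::which_loop(g))
  gs <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  n_multi <- igraph::ecount(g) - n_loop - igraph::ecount(gs)
  if (n_loop + n_multi > 0L)
    message(sprintf("%s: dropped %d self-loop(s) and %d duplicate edge(s)",
                    what, n_loop, n_multi))
  if (igraph::vcount(gs) == 0L) stop("empty network")
  gs
}

#' Write a network to TSV edge list, SIF or GraphML
#'
#' @param net an igraph graph with named vertices.
#' @param path output path.
#' @param format `"tsv"`, `"sif"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("tsv", "sif", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(net, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(net)
    lines <- if (format == "sif") paste(el[, 1], "pp", el[, 2])
             else paste(el[, 1], el[, 2], sep = "\t")
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read node score tables from a TSV file
#'
#' The file must have a header row; the first column holds node identifiers
#' and every further column one numeric score. Node identifiers are opaque,
#' case-sensitive strings.
#'
#' @param path path to the TSV file.
#' @return a named list of score tables, each a named numeric vector
#'   (node id -> score).
#' @export
read_scores <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", quote = "")
  if (ncol(df) < 2L) stop("no score columns in ", path)
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate node rows in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- list()
  for (j in 2:ncol(df)) {
    raw <- df[[j]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val))
    if (length(bad) > 0L)
      stop(sprintf("non-numeric score cell in %s: row %d, column '%s' (%s)",
                   path, bad[1L], names(df)[j], raw[bad[1L]]))
    if (!any(is.finite(val)))
      stop("score column '", names(df)[j], "' has no finite values in ", path)
    out[[names(df)[j]]] <- setNames(val, ids)
  }
  out
}

#' Write score tables to a TSV file
#'
#' @param tables named list of score tables (named numeric vectors).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(tables, path) {
  stopifnot(length(tables) >= 1L, !is.null(names(tables)))
  ids <- sort(unique(unlist(lapply(tables, names))))
  df <- data.frame(node = ids, check.names = FALSE)
  for (nm in names(tables)) df[[nm]] <- unname(tables[[nm]][ids])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Min-max normalize a score table to [0, 1]
#'
#' Maps the maximum value to 1 and the minimum to 0. A constant (or
#' single-entry) table maps to all 1.0 so that a degenerate score is neutral
#' under weighted summation rather than annihilating.
#'
#' @param x a score table (named numeric vector) with at least one entry.
#' @return the normalized table.
#' @export
normalize_scores <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 1L, all(is.finite(x)))
  rng <- range(x)
  if (rng[1] == rng[2]) return(setNames(rep(1, length(x)), names(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

# Extend a score table to every node of a network: nodes without a score
# receive the table's minimum (unknown evidence ranks lowest). Reports a
# count of filled-in nodes. Scores for nodes absent from the network are
# dropped silently (the table may cover a larger universe).
align_scores <- function(net, x, label = "score") {
  nodes <- igraph::V(net)$name
  have <- names(x)[names(x) %in% nodes]
  miss <- setdiff(nodes, names(x))
  out <- setNames(rep(min(x), length(nodes)), nodes)
  out[have] <- x[have]
  if (length(miss) > 0L)
    message(sprintf(
      "%s: %d network node(s) without a score assigned the table minimum",
      label, length(miss)))
  out
}
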