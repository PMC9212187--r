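# Seven node-level graph measures on binary undirected brain graphs.
#
# Conventions for disconnected graphs: path-length means are taken over
# reachable nodes only (isolated node -> 0), efficiencies count
# unreachable pairs as 1/inf = 0.  All quantities stay finite without
# graph-dependent imputation.

as_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected",
                                      diag = FALSE)
}

node_index <- function(g, v) {
  i <- match(v, g$roi_labels)
  if (is.na(i)) abort(sprintf("Unknown node `%s`.", v))
  i
}

#' Node-level graph measures
#'
#' The seven measures computed per node of a binary undirected
#' `brain_graph`:
#' * `degree_centrality` - number of edges incident to the node;
#' * `betweenness_centrality` - proportion of shortest paths between all
#'   other node pairs that pass through the node, normalised by
#'   `(N-1)(N-2)/2`;
#' * `average_path_length` - mean shortest-path length from the node to
#'   the nodes reachable from it (0 for an isolated node);
#' * `clustering_coefficient` - fraction of the node's neighbour pairs
#'   that are themselves connected (0 when degree < 2);
#' * `cost` - the node's share of possible connections, `deg/(N-1)`;
#' * `local_efficiency` - global efficiency of the subgraph induced on the
#'   node's neighbours (0 when degree < 2);
#' * `global_efficiency` - mean inverse shortest-path length from the node
#'   to every other node, with unreachable pairs contributing 0.
#'
#' @param g A `brain_graph` from [threshold_adjacency()].
#' @param v A node label.
#' @return A single number.
#' @name node_measures
NULL

#' @rdname node_measures
#' @export
degree_centrality <- function(g, v) {
  i <- node_index(g, v)
  sum(g$adjacency[i, ])
}

#' @rdname node_measures
#' @export
betweenness_centrality <- function(g, v) {
  i <- node_index(g, v)
  n <- length(g$roi_labels)
  if (n < 3) return(0)
  b <- igraph::betweenness(as_igraph(g), v = i, directed = FALSE)
  unname(b / ((n - 1) * (n - 2) / 2))
}

#' @rdname node_measures
#' @export
average_path_length <- function(g, v) {
  i <- node_index(g, v)
  d <- igraph::distances(as_igraph(g), v = i)[1, -i]
  d <- d[is.finite(d)]
  if (length(d) == 0) return(0)
  mean(d)
}

#' @rdname node_measures
#' @export
clustering_coefficient <- function(g, v) {
  i <- node_index(g, v)
  nb <- which(g$adjacency[i, ] == 1L)
  k <- length(nb)
  if (k < 2) return(0)
  sum(g$adjacency[nb, nb]) / 2 / (k * (k - 1) / 2)
}

#' @rdname node_measures
#' @export
cost <- function(g, v) {
  i <- node_index(g, v)
  n <- length(g$roi_labels)
  if (n < 2) abort("Cost is undefined for a graph with fewer than 2 nodes.")
  sum(g$adjacency[i, ]) / (n - 1)
}

#' @rdname node_measures
#' @export
local_efficiency <- function(g, v) {
  i <- node_index(g, v)
  nb <- which(g$adjacency[i, ] == 1L)
  if (length(nb) < 2) return(0)
  sub <- g$adjacency[nb, nb, drop = FALSE]
  gsub <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected",
                                              diag = FALSE)
  d <- igraph::distances(gsub)
  inv <- 1 / d[upper.tri(d)]
  mean(ifelse(is.finite(inv), inv, 0))
}

#' @rdname node_measures
#' @export
global_efficiency <- function(g, v) {
  i <- node_index(g, v)
  d <- igraph::distances(as_igraph(g), v = i)[1, -i]
  mean(ifelse(is.finite(1 / d), 1 / d, 0))
}

measure_names <- function() {
  c("degree_centrality", "betweenness_centrality", "average_path_length",
    "clustering_coefficient", "cost", "local_efficiency",
    "global_efficiency")
}

#' Compute all seven measures for every node of a graph
#'
#' Vectorised equivalent of the single-node operations in
#' [node_measures]; one row per node, one column per measure.
#'
#' @param g A `brain_graph`.
#' @return A tibble with columns `node` plus the seven measures.
#' @export
compute_measure_set <- function(g) {
  stopifnot(inherits(g, "brain_graph"))
  a <- g$adjacency
  n <- nrow(a)
  ig <- as_igraph(g)
  deg <- as.numeric(rowSums(a))

  btw <- if (n < 3) rep(0, n) else {
    igraph::betweenness(ig, directed = FALSE) / ((n - 1) * (n - 2) / 2)
  }

  d <- igraph::distances(ig)
  diag(d) <- NA
  apl <- apply(d, 1, function(row) {
    f <- row[is.finite(row) & !is.na(row)]
    if (length(f) == 0) 0 else mean(f)
  })
  geff <- apply(d, 1, function(row) {
    inv <- 1 / row[!is.na(row)]
    mean(ifelse(is.finite(inv), inv, 0))
  })

  clu <- igraph::transitivity(ig, type = "local", isolates = "zero")
  clu[deg < 2] <- 0

  leff <- vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] == 1L)
    if (length(nb) < 2) return(0)
    sub <- igraph::graph_from_adjacency_matrix(a[nb, nb, drop = FALSE],
                                               mode = "undirected", diag = FALSE)
    dd <- igraph::distances(sub)
    inv <- 1 / dd[upper.tri(dd)]
    mean(ifelse(is.finite(inv), inv, 0))
  }, numeric(1))

  tibble::tibble(
    node = g$roi_labels,
    degree_centrality = deg,
    betweenness_centrality = as.numeric(btw),
    average_path_length = as.numeric(apl),
    clustering_coefficient = as.numeric(clu),
    cost = deg / (n - 1),
    local_efficiency = leff,
    global_efficiency = as.numeric(geff)
  )
}
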