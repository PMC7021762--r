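#' Undirected, unweighted, connected network
#'
#' `frail_network()` is the basic container for the networks the package
#' operates on: a simple, undirected, unweighted graph given by a symmetric
#' binary adjacency matrix with zero diagonal. The graph must be connected
#' (every pair of nodes joined by a path) and have at least two nodes, so
#' that the random-walk transition system built on top of it has a unique
#' stationary state.
#'
#' @param adjacency Square symmetric numeric matrix with entries in `{0, 1}`
#'   and zero diagonal.
#' @param labels Optional character vector of node labels. Defaults to the
#'   matrix dimnames, or `"n1"`, `"n2"`, ... when absent.
#' @return An object of class `frail_network` with fields `adjacency`
#'   (labelled matrix), `labels`, `m` (node count) and `graph` (the igraph
#'   representation used for topological queries).
#' @examples
#' net <- frail_network(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)),
#'                      labels = c("a", "b", "c"))
#' node_degrees(net)
#' @export
frail_network <- function(adjacency, labels = NULL) {
  if (!is.matrix(adjacency) || !is.numeric(adjacency)) {
    stop("`adjacency` must be a numeric matrix", call. = FALSE)
  }
  m <- nrow(adjacency)
  if (m != ncol(adjacency)) stop("`adjacency` must be square", call. = FALSE)
  if (m < 2) stop("a network needs at least 2 nodes", call. = FALSE)
  if (!isTRUE(all.equal(adjacency, t(adjacency), tolerance = 0))) {
    stop("`adjacency` must be symmetric (undirected network)", call. = FALSE)
  }
  if (!all(adjacency %in% c(0, 1))) {
    stop("`adjacency` must be binary (unweighted network)", call. = FALSE)
  }
  if (any(diag(adjacency) != 0)) {
    stop("`adjacency` must have a zero diagonal (no self-loops)", call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- rownames(adjacency) %||% paste0("n", seq_len(m))
  }
  labels <- as.character(labels)
  if (length(labels) != m) stop("`labels` length must equal the node count", call. = FALSE)
  if (anyDuplicated(labels)) stop("node labels must be unique", call. = FALSE)
  dimnames(adjacency) <- list(labels, labels)
  graph <- igraph::graph_from_adjacency_matrix(adjacency, mode = "undirected")
  if (igraph::components(graph)$no != 1L) {
    stop("the network must be connected", call. = FALSE)
  }
  structure(
    list(adjacency = adjacency, labels = labels, m = m, graph = graph),
    class = "frail_network"
  )
}

#' Coerce to a frail_network
#'
#' Accepts an adjacency matrix, an igraph graph, or a two-column edge-list
#' data frame (one undirected edge per row; duplicate and reversed edges are
#' collapsed).
#'
#' @param x Object to coerce.
#' @param ... Passed on to methods.
#' @return A [frail_network()].
#' @export
as_frail_network <- function(x, ...) UseMethod("as_frail_network")

#' @export
as_frail_network.frail_network <- function(x, ...) x

#' @export
as_frail_network.matrix <- function(x, ...) frail_network(x, ...)

#' @export
as_frail_network.igraph <- function(x, ...) {
  adj <- as.matrix(igraph::as_adjacency_matrix(x, sparse = FALSE))
  adj[adj > 1] <- 1
  frail_network(adj, ...)
}

#' @export
as_frail_network.data.frame <- function(x, ...) {
  if (ncol(x) < 2) stop("an edge list needs two columns", call. = FALSE)
  from <- as.character(x[[1]])
  to <- as.character(x[[2]])
  if (any(from == to)) stop("self-loops are not allowed", call. = FALSE)
  labels <- sort(unique(c(from, to)))
  adj <- matrix(0, length(labels), length(labels), dimnames = list(labels, labels))
  adj[cbind(from, to)] <- 1
  adj[cbind(to, from)] <- 1
  frail_network(adj)
}

#' @export
print.frail_network <- function(x, ...) {
  cat(sprintf(
    "<frail_network> %d nodes, %d edges\n", x$m, sum(x$adjacency) / 2
  ))
  cat("  nodes:", paste(utils::head(x$labels, 8), collapse = ", "),
      if (x$m > 8) "..." else "", "\n")
  invisible(x)
}

#' Node degrees of a network
#'
#' @param network A [frail_network()] (or anything [as_frail_network()] accepts).
#' @return Named integer vector of node degrees.
#' @export
node_degrees <- function(network) {
  network <- as_frail_network(network)
  colSums(network$adjacency)
}

#' Complete network fixture
#'
#' Builds the complete graph on `m` nodes. On \eqn{K_M} the random-walk
#' Laplacian has eigenvalues \eqn{\{0, M/(M-1)\}}, so the Fiedler number is
#' \eqn{M/(M-1)} — a convenient closed-form fixture.
#'
#' @param m Number of nodes (at least 2).
#' @param labels Optional node labels.
#' @return A [frail_network()].
#' @export
make_complete_network <- function(m = 20, labels = NULL) {
  if (!is.numeric(m) || length(m) != 1 || m < 2) {
    stop("`m` must be a single integer >= 2", call. = FALSE)
  }
  frail_network(matrix(1, m, m) - diag(m), labels = labels)
}

#' Random connected network fixtures
#'
#' Seeded generators for the two random-graph families used throughout the
#' test suites: Erdős–Rényi \eqn{G(m, p)} (resampled with an incremented
#' seed until connected, up to `max_tries`) and Barabási–Albert preferential
#' attachment (connected by construction).
#'
#' @param kind `"erdos_renyi"` or `"preferential_attachment"`.
#' @param m Number of nodes.
#' @param p Edge probability (Erdős–Rényi).
#' @param edges_per_node Edges added per new node (preferential attachment);
#'   `1` yields a tree with `m - 1` edges.
#' @param seed Integer seed; generation is reproducible given the seed.
#' @param max_tries Connectivity retry cap for Erdős–Rényi.
#' @return A [frail_network()].
#' @export
make_random_network <- function(kind = c("erdos_renyi", "preferential_attachment"),
                                m = 20, p = 0.3, edges_per_node = 2,
                                seed = 1, max_tries = 50) {
  kind <- match.arg(kind)
  if (kind == "preferential_attachment") {
    set.seed(seed)
    g <- igraph::sample_pa(m, m = edges_per_node, directed = FALSE)
    return(as_frail_network(g))
  }
  for (try in seq_len(max_tries)) {
    set.seed(seed + try - 1L)
    g <- igraph::sample_gnp(m, p)
    if (igraph::components(g)$no == 1L) {
      if (try > 1L) message("erdos_renyi: connected after ", try, " tries")
      return(as_frail_network(g))
    }
  }
  stop("could not draw a connected Erdos-Renyi graph in ", max_tries, " tries",
       call. = FALSE)
}
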