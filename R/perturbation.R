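#' Environment-node perturbation of a network
#'
#' Encodes a set of altered ("query") nodes as a Laplacian perturbation
#' \eqn{\Delta L_\varepsilon} of the master equation extended by one
#' environment node (slot 0). Each query node \eqn{q} exchanges information
#' with the environment through symmetric rates
#' \eqn{\pi_{q0} = \pi_{0q}}, and the matched diagonal entries keep both
#' \eqn{\Delta L} and \eqn{L_0 + \Delta L} Laplacian (zero column sums):
#' \deqn{\Delta L_\varepsilon = \sum_{q \in S} r\,(e_0 - e_q)(e_0 - e_q)^T.}
#'
#' Two coupling conventions are supported. The default, `"per_query"`, sets
#' the per-connection rate \eqn{r = \varepsilon}; frailness is then weakly
#' increasing under the addition of query nodes (the monotonic property) and
#' the smallest intensity at which any configuration can diverge is the
#' Fiedler number. `"split"` divides the total intensity across the query
#' set, \eqn{r = \varepsilon/Q}, which makes the environment column of the
#' extended transition matrix stochastic at \eqn{\varepsilon = 1}
#' (\eqn{\pi_{q0} = 1/Q}) but is anti-monotonic in the query count: the same
#' total input spread over more nodes perturbs the network less. See the
#' methods vignette for why `"per_query"` is the score's default.
#'
#' @param ts A [transition_system()].
#' @param query Character vector of query-node labels (or integer indices);
#'   at least one node, all present in the network.
#' @param epsilon Nonnegative coupling intensity \eqn{\varepsilon}.
#' @param coupling `"per_query"` (rate \eqn{\varepsilon} per connection) or
#'   `"split"` (rate \eqn{\varepsilon/Q}).
#' @return An object of class `perturbation` with the
#'   \eqn{(M+1)\times(M+1)} matrix `delta_l` (index 1 = environment), the
#'   resolved query labels and the per-connection `rate`.
#' @examples
#' ts <- transition_system(make_complete_network(5))
#' pert <- perturbation(ts, c("n1", "n2"), epsilon = 1)
#' colSums(pert$delta_l)  # all zero: Laplacian structure
#' @export
perturbation <- function(ts, query, epsilon = 1,
                         coupling = c("per_query", "split")) {
  stopifnot(inherits(ts, "transition_system"))
  coupling <- match.arg(coupling)
  if (length(query) == 0) stop("the query set must be nonempty", call. = FALSE)
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon < 0) {
    stop("`epsilon` must be a single nonnegative number", call. = FALSE)
  }
  idx <- resolve_nodes(ts, query)
  q <- length(idx)
  rate <- if (coupling == "per_query") epsilon else epsilon / q
  m <- ts$m
  delta_l <- matrix(0, m + 1, m + 1,
                    dimnames = list(c(".env", ts$labels), c(".env", ts$labels)))
  delta_l[1, 1] <- rate * q
  for (i in idx) {
    delta_l[i + 1, 1] <- -rate
    delta_l[1, i + 1] <- -rate
    delta_l[i + 1, i + 1] <- rate
  }
  structure(
    list(query = ts$labels[idx], idx = idx, q = q, epsilon = epsilon,
         coupling = coupling, rate = rate, delta_l = delta_l, m = m),
    class = "perturbation"
  )
}

# map labels or indices to validated integer node indices
resolve_nodes <- function(ts, nodes) {
  if (is.numeric(nodes)) {
    idx <- as.integer(nodes)
    if (any(idx < 1 | idx > ts$m)) {
      stop("node index out of range", call. = FALSE)
    }
  } else {
    idx <- match(as.character(nodes), ts$labels)
    if (anyNA(idx)) {
      stop("unknown node label: ",
           paste(nodes[is.na(idx)], collapse = ", "), call. = FALSE)
    }
  }
  unique(idx)
}

#' Extend the Laplacian with a decoupled environment node
#'
#' Returns the \eqn{(M+1)\times(M+1)} matrix \eqn{L_0} whose first row and
#' column (the environment slot) are zero and whose remaining block is the
#' network Laplacian. Its kernel is two-dimensional, spanned by the
#' environment unit vector \eqn{e_0} and \eqn{(0, p_s)^T}.
#'
#' @param ts A [transition_system()].
#' @return The extended Laplacian matrix.
#' @export
extend_laplacian <- function(ts) {
  stopifnot(inherits(ts, "transition_system"))
  m <- ts$m
  l0 <- matrix(0, m + 1, m + 1,
               dimnames = list(c(".env", ts$labels), c(".env", ts$labels)))
  l0[2:(m + 1), 2:(m + 1)] <- ts$laplacian
  l0
}

#' @export
print.perturbation <- function(x, ...) {
  cat(sprintf(
    "<perturbation> Q = %d query nodes (%s%s), epsilon = %g, coupling = %s\n",
    x$q, paste(utils::head(x$query, 6), collapse = ", "),
    if (x$q > 6) ", ..." else "", x$epsilon, x$coupling
  ))
  invisible(x)
}
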