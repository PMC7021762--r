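#' Kernel-deflated projected perturbation
#'
#' Applies the detailed-balance transform that removes the stationary-mode
#' component from the projected perturbation:
#' \deqn{\Delta L'_{kj} = \bar{\Delta L}_{kj} -
#'   \frac{\bar{\Delta L}_{k1}}{\bar{\Delta L}_{11}} \bar{\Delta L}_{1j}.}
#' Row and column of the stationary mode vanish identically, and any
#' rank-one (single-query-node) perturbation is annihilated exactly — the
#' structural reason a single alteration always has null frailness.
#'
#' @param proj A [project_perturbation()] result.
#' @return The \eqn{(M+1)\times(M+1)} matrix \eqn{\Delta L'} (same index
#'   convention as `proj$bar`: slot 1 = environment mode, slot 2 =
#'   stationary mode).
#' @export
delta_l_prime <- function(proj) {
  stopifnot(inherits(proj, "projected_perturbation"))
  bar <- proj$bar
  if (proj$epsilon == 0) return(bar * 0)
  if (abs(bar[2, 2]) < 1e-14) {
    stop("inconsistent perturbation: vanishing stationary-mode projection ",
         "at positive epsilon", call. = FALSE)
  }
  bar - outer(bar[, 2], bar[2, ]) / bar[2, 2]
}

#' Network frailness of a query-node configuration
#'
#' The frailness score \eqn{\rho} measures how strongly a set of
#' simultaneously altered nodes, coupled to an environment node at
#' intensity \eqn{\varepsilon}, perturbs the stationary information flow of
#' the network: \eqn{\rho = \|\Delta L'_\varepsilon\| / \lambda_F}, where
#' \eqn{\Delta L'} is the kernel-deflated projected perturbation and
#' \eqn{\lambda_F} the Fiedler number. The norm is the
#' \eqn{\lambda_F}-weighted operator norm
#' \eqn{\|X\| = \lambda_F\,\|\Lambda^{-1/2} X \Lambda^{-1/2}\|_2} over the
#' non-kernel network modes (\eqn{\Lambda} the diagonal of nonzero
#' eigenvalues), under which \eqn{\rho\,\varepsilon' / \varepsilon < 1} is
#' the exact convergence condition of the iterative scheme: the analytic
#' critical threshold is \eqn{\mu = \varepsilon / \rho(\varepsilon)}.
#' A Frobenius variant on the same weighted matrix is available; it upper
#' bounds the spectral value.
#'
#' \eqn{\rho \ge 0} always; \eqn{\rho = 0} iff the query set has a single
#' node or \eqn{\varepsilon = 0}; \eqn{\rho} is linear in \eqn{\varepsilon};
#' and with the default `"per_query"` coupling \eqn{\rho} never decreases
#' when a query node is added (the monotonic property). Small \eqn{\rho}
#' means a resilient configuration, large \eqn{\rho} a frail one.
#'
#' @param ts A [transition_system()].
#' @param query Query-node labels or indices.
#' @param epsilon Coupling intensity (default 1, the conventional reporting
#'   scale).
#' @param norm `"spectral"` (default; exact threshold correspondence) or
#'   `"frobenius"`.
#' @param coupling Passed to [perturbation()].
#' @return Object of class `frailness` with fields `rho`, `mu_analytic`
#'   (`Inf` when `rho == 0`), `lambda_f`, `epsilon`, `q`, `query`, `norm`,
#'   `coupling` and the matrix `delta_l_prime`.
#' @examples
#' ts <- transition_system(make_complete_network(20))
#' frailness(ts, c("n1", "n2"))$rho     # (M-1)/M = 0.95 on K_20
#' frailness(ts, "n1")$rho              # single alteration: exactly 0
#' @export
frailness <- function(ts, query, epsilon = 1,
                      norm = c("spectral", "frobenius"),
                      coupling = c("per_query", "split")) {
  stopifnot(inherits(ts, "transition_system"))
  norm <- match.arg(norm)
  coupling <- match.arg(coupling)
  idx <- resolve_nodes(ts, query)
  q <- length(idx)
  if (q == 1L || epsilon == 0) {
    # rank-one perturbations are annihilated exactly by the kernel deflation
    dlp <- matrix(0, ts$m + 1, ts$m + 1)
    rho <- 0
  } else {
    proj <- project_perturbation(perturbation(ts, idx, epsilon, coupling), ts)
    dlp <- delta_l_prime(proj)
    rho <- weighted_norm(dlp, ts, norm)
  }
  structure(
    list(rho = rho,
         mu_analytic = if (rho > 0) epsilon / rho else Inf,
         lambda_f = ts$lambda_f, epsilon = epsilon, q = q,
         query = ts$labels[idx], norm = norm, coupling = coupling,
         delta_l_prime = dlp, m = ts$m),
    class = "frailness"
  )
}

# lambda_F-weighted norm of the deflated perturbation over non-kernel modes
weighted_norm <- function(dlp, ts, norm) {
  m <- ts$m
  idx <- seq(3, m + 1)
  w <- 1 / sqrt(ts$eigenvalues[2:m])
  k_mat <- w * t(w * t(dlp[idx, idx, drop = FALSE]))
  k_mat <- (k_mat + t(k_mat)) / 2
  if (norm == "spectral") {
    max(abs(eigen(k_mat, symmetric = TRUE, only.values = TRUE)$values))
  } else {
    sqrt(sum(k_mat^2))
  }
}

#' @export
print.frailness <- function(x, ...) {
  cat(sprintf(
    "<frailness> Q = %d, epsilon = %g: rho = %.6g, mu_analytic = %.6g (lambda_F = %.6g)\n",
    x$q, x$epsilon, x$rho, x$mu_analytic, x$lambda_f
  ))
  invisible(x)
}

#' @rdname frailness
#' @param x A `frailness` object.
#' @param ... Unused.
#' @export
tidy.frailness <- function(x, ...) {
  tibble::tibble(
    query = paste(x$query, collapse = ","),
    q = x$q,
    epsilon = x$epsilon,
    rho = x$rho,
    mu_analytic = x$mu_analytic,
    lambda_f = x$lambda_f
  )
}

#' @rdname frailness
#' @export
glance.frailness <- function(x, ...) {
  tibble::tibble(
    m = x$m, q = x$q, epsilon = x$epsilon, rho = x$rho,
    mu_analytic = x$mu_analytic, lambda_f = x$lambda_f,
    norm = x$norm, coupling = x$coupling
  )
}

# fast numeric rho for cohort loops: rank-structured projection, no
# intermediate objects
frailness_rho <- function(ts, idx, epsilon = 1, norm = "spectral",
                          coupling = "per_query") {
  q <- length(idx)
  if (q <= 1L || epsilon == 0) return(0)
  rate <- if (coupling == "per_query") epsilon else epsilon / q
  m <- ts$m
  v <- ts$eigenvectors
  # delta_L = rate * sum_q w w^T with w = e0 - e_q;
  # bar = rate * sum_q (B^T G w)(w^T B)^T
  a <- rbind(ts$env_metric, -t(v[idx, , drop = FALSE]) %*%
               diag(1 / ts$p_s[idx], nrow = q))
  b <- rbind(1, -t(v[idx, , drop = FALSE]))
  bar <- rate * (a %*% t(b))
  dlp <- bar - outer(bar[, 2], bar[2, ]) / bar[2, 2]
  weighted_norm(dlp, ts, norm)
}

#' Global network efficiency under node removal
#'
#' Network efficiency is the mean inverse shortest-path length over ordered
#' node pairs, \eqn{NE = \frac{1}{M(M-1)} \sum_{i \ne j} 1/d(i,j)} with
#' \eqn{1/\infty = 0} for disconnected pairs. `NE_prime` is the same
#' quantity on the subgraph induced by the surviving nodes (with its own
#' size normalization), and `nne = NE'/NE` is the normalized efficiency of
#' the network hit by the removal — the classical topology-based comparator
#' of the spectral frailness score.
#'
#' @param network A [frail_network()] or anything coercible.
#' @param removed Labels of the removed (query) nodes; may be empty.
#' @return One-row tibble with `ne`, `ne_prime`, `nne`, `n_removed`,
#'   `n_surviving`.
#' @examples
#' p3 <- frail_network(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
#' network_efficiency(p3)$ne          # 5/6
#' network_efficiency(p3, "n2")$nne   # 0: the surviving pair disconnects
#' @export
network_efficiency <- function(network, removed = character()) {
  network <- as_frail_network(network)
  removed <- as.character(removed)
  unknown <- setdiff(removed, network$labels)
  if (length(unknown)) {
    stop("unknown node label: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  ne <- efficiency_of(network$graph)
  surviving <- setdiff(network$labels, removed)
  if (length(surviving) < 2) {
    warning("fewer than 2 surviving nodes; NE' set to 0")
    ne_prime <- 0
  } else {
    sub <- igraph::induced_subgraph(network$graph, surviving)
    ne_prime <- efficiency_of(sub)
  }
  tibble::tibble(
    ne = ne, ne_prime = ne_prime, nne = ne_prime / ne,
    n_removed = length(removed), n_surviving = length(surviving)
  )
}

efficiency_of <- function(graph) {
  n <- igraph::vcount(graph)
  if (n < 2) return(0)
  d <- igraph::distances(graph)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (n * (n - 1))
}
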