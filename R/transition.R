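#' Column-normalize an adjacency matrix
#'
#' Divides each column of the adjacency matrix by its degree, yielding the
#' column-stochastic transition matrix \eqn{\Pi} of the simple random walk:
#' \eqn{\pi_{kj} = A_{kj} / \mathrm{deg}(j)}.
#'
#' @param network A [frail_network()] or adjacency matrix.
#' @return Column-stochastic matrix \eqn{\Pi} (every column sums to 1).
#' @export
column_normalize <- function(network) {
  network <- as_frail_network(network)
  deg <- colSums(network$adjacency)
  if (any(deg == 0)) {
    stop("isolated node: ", paste(network$labels[deg == 0], collapse = ", "),
         call. = FALSE)
  }
  sweep(network$adjacency, 2, deg, "/")
}

#' Build the master-equation transition system
#'
#' Constructs the operator backbone used by every downstream computation:
#' the column-stochastic transition matrix \eqn{\Pi}, the Laplacian
#' \eqn{L = D - \Pi} (here \eqn{D = I} because \eqn{\Pi} is column
#' stochastic), the stationary distribution \eqn{p_s} (the normalized kernel
#' of \eqn{L}; for the undirected column-normalized walk
#' \eqn{(p_s)_k = \mathrm{deg}(k)/\sum_j \mathrm{deg}(j)}), the
#' detailed-balance metric \eqn{G = \mathrm{diag}(1/p_s)} in which \eqn{L}
#' is self-adjoint, and the G-orthonormal eigenbasis with ascending real
#' eigenvalues \eqn{0 = \lambda_1 < \lambda_2 = \lambda_F \le \dots}.
#'
#' The eigenproblem is solved through the similarity transform
#' \eqn{G^{1/2} L G^{-1/2}}, which is symmetric exactly when detailed balance
#' holds; the returned eigenvectors are therefore G-orthonormal including
#' within degenerate eigenspaces. The zero-mode eigenvector is stored as
#' \eqn{p_s} itself (its G-norm is 1).
#'
#' @param network A [frail_network()] or anything [as_frail_network()] accepts.
#' @param env_metric Positive metric weight assigned to the environment slot
#'   when the basis is extended; results downstream of the kernel projections
#'   do not depend on it.
#' @param kernel_tol Threshold below which an eigenvalue counts as zero.
#' @param symmetry_tol Tolerance for the detailed-balance (self-adjointness)
#'   check at construction.
#' @return An object of class `transition_system`.
#' @examples
#' ts <- transition_system(make_complete_network(20))
#' ts$lambda_f  # 20/19
#' @export
transition_system <- function(network, env_metric = 1,
                              kernel_tol = 1e-10, symmetry_tol = 1e-8) {
  network <- as_frail_network(network)
  stopifnot(env_metric > 0, kernel_tol > 0, symmetry_tol > 0)
  m <- network$m
  pi_mat <- column_normalize(network)
  lap <- diag(m) - pi_mat
  deg <- colSums(network$adjacency)
  p_s <- deg / sum(deg)
  metric <- 1 / p_s
  if (max(abs(lap %*% p_s)) > kernel_tol) {
    stop("stationary distribution failed the kernel check", call. = FALSE)
  }
  if (!check_self_adjoint(lap, metric, tol = symmetry_tol)) {
    stop("Laplacian is not self-adjoint in the detailed-balance metric",
         call. = FALSE)
  }
  s <- sqrt(p_s)
  lap_sym <- (1 / s) * t(t(lap) * s)          # diag(1/s) %*% L %*% diag(s)
  lap_sym <- (lap_sym + t(lap_sym)) / 2
  eig <- eigen(lap_sym, symmetric = TRUE)
  ord <- order(eig$values)
  eigenvalues <- eig$values[ord]
  vecs <- s * eig$vectors[, ord, drop = FALSE]  # G-orthonormal
  n_zero <- sum(abs(eigenvalues) < kernel_tol)
  if (n_zero != 1L) {
    stop("expected exactly one zero eigenvalue, found ", n_zero, call. = FALSE)
  }
  eigenvalues[1] <- 0
  vecs[, 1] <- p_s
  # extended basis: column 1 = environment unit vector e0, column 2 = (0, p_s)
  basis_ext <- matrix(0, m + 1, m + 1)
  basis_ext[1, 1] <- 1
  basis_ext[2:(m + 1), 2:(m + 1)] <- vecs
  structure(
    list(
      network = network,
      pi = pi_mat,
      laplacian = lap,
      p_s = stats::setNames(p_s, network$labels),
      metric = stats::setNames(metric, network$labels),
      env_metric = env_metric,
      metric_ext = c(env_metric, metric),
      eigenvalues = eigenvalues,
      eigenvectors = vecs,
      basis_ext = basis_ext,
      lambda_f = eigenvalues[2],
      m = m,
      labels = network$labels,
      kernel_tol = kernel_tol,
      symmetry_tol = symmetry_tol
    ),
    class = "transition_system"
  )
}

#' Check self-adjointness of a Laplacian in a diagonal metric
#'
#' \eqn{L} is self-adjoint under the scalar product
#' \eqn{u \cdot w = \sum_k u_k g_k w_k} iff \eqn{G L} is symmetric, which for
#' the random-walk Laplacian is the detailed-balance (reversibility)
#' condition of the stationary state.
#'
#' @param x A `transition_system` or a Laplacian matrix.
#' @param metric Diagonal metric as a positive vector (ignored when `x` is a
#'   `transition_system`).
#' @param tol Entrywise symmetry tolerance.
#' @return `TRUE` iff `metric * x` is symmetric within `tol`.
#' @export
check_self_adjoint <- function(x, metric = NULL, tol = 1e-8) {
  if (inherits(x, "transition_system")) {
    metric <- x$metric
    x <- x$laplacian
  }
  if (is.null(metric)) stop("`metric` is required for a matrix input", call. = FALSE)
  gl <- metric * x
  max(abs(gl - t(gl))) <= tol
}

#' @export
print.transition_system <- function(x, ...) {
  cat(sprintf(
    "<transition_system> %d nodes; lambda_F = %.6g; spectral range [0, %.6g]\n",
    x$m, x$lambda_f, max(x$eigenvalues)
  ))
  invisible(x)
}

#' @rdname transition_system
#' @param x A `transition_system`.
#' @param ... Unused.
#' @export
tidy.transition_system <- function(x, ...) {
  tibble::tibble(
    node = x$labels,
    degree = as.integer(colSums(x$network$adjacency)),
    stationary_prob = unname(x$p_s)
  )
}

#' @rdname transition_system
#' @export
glance.transition_system <- function(x, ...) {
  tibble::tibble(
    m = x$m,
    n_edges = sum(x$network$adjacency) / 2,
    lambda_fiedler = x$lambda_f,
    lambda_max = max(x$eigenvalues),
    n_zero_modes = sum(abs(x$eigenvalues) < x$kernel_tol)
  )
}
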