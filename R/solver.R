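#' Project a perturbation onto the extended eigenbasis
#'
#' Computes \eqn{\bar{\Delta L}_{kj} = v_k \cdot \Delta L\, v_j} in the
#' extended G-orthonormal basis \eqn{\{e_0, v_1 = (0, p_s), v_2, \dots,
#' v_M\}}, where the scalar product carries the detailed-balance metric
#' (environment slot weighted by `ts$env_metric`). Row/column 1 of the
#' result is the environment mode \eqn{e_0}; row/column 2 is the stationary
#' mode \eqn{v_1}.
#'
#' @param pert A [perturbation()].
#' @param ts The [transition_system()] the perturbation was built on.
#' @return Object of class `projected_perturbation` holding the matrix
#'   `bar` and the perturbation metadata.
#' @export
project_perturbation <- function(pert, ts) {
  stopifnot(inherits(pert, "perturbation"), inherits(ts, "transition_system"))
  if (pert$m != ts$m) stop("dimension mismatch between perturbation and system",
                           call. = FALSE)
  b <- ts$basis_ext
  bar <- crossprod(b, ts$metric_ext * (pert$delta_l %*% b))
  structure(
    list(bar = bar, epsilon = pert$epsilon, q = pert$q, query = pert$query,
         idx = pert$idx, coupling = pert$coupling, rate = pert$rate, m = ts$m),
    class = "projected_perturbation"
  )
}

#' Iterative spectral scheme for the perturbed stationary state
#'
#' Runs the fixed-point iteration for the coefficients of the perturbed
#' stationary state in the ansatz
#' \eqn{p^*_s = \hat p + \alpha\, p_s + e_0}, with \eqn{\hat p = \sum_{k>1}
#' c_k v_k} orthogonal to both kernel directions:
#' \deqn{\lambda_k c_{n,k} = -\sum_{j>1} c_{n-1,j} \bar{\Delta L}_{kj}
#'   - \alpha_{n-1} \bar{\Delta L}_{k1} - \bar{\Delta L}_{k0},}
#' starting from \eqn{\hat p_0 = 0}, \eqn{\alpha_0 = 1}. The default
#' `variant = "consistent"` closes the update with
#' \eqn{\alpha_n = (-\sum_{j>1} c_{n,j} \bar{\Delta L}_{1j}
#'   - \bar{\Delta L}_{10}) / \bar{\Delta L}_{11}}, the form obtained by
#' projecting the stationary condition on the \eqn{v_1} mode; its fixed
#' point coincides with the direct kernel solution. The `"literal"` variant
#' divides the constant term by \eqn{\bar{\Delta L}_{00}} instead and is
#' retained for comparison only — its fixed point does not satisfy the
#' stationary equation unless \eqn{\bar{\Delta L}_{00} = \bar{\Delta L}_{11}}.
#'
#' The iteration converges iff \eqn{\varepsilon} is below the critical
#' threshold \eqn{\mu}; beyond it the dominant (negative) eigenvalue of the
#' iteration matrix leaves the unit disc and the scheme diverges in an
#' oscillatory fashion. When `max_iter` is exhausted without meeting either
#' the tolerance or the divergence bound, the returned `trending` field
#' reports whether the update deltas were still contracting.
#'
#' @param proj A [project_perturbation()] result.
#' @param ts The matching [transition_system()].
#' @param tol Convergence tolerance on the sup-norm update of the
#'   coefficient vector.
#' @param max_iter Iteration cap.
#' @param divergence_bound Sup-norm bound on the coefficients beyond which
#'   the scheme is declared diverged.
#' @param variant `"consistent"` (default) or `"literal"`; see Details.
#' @param init Optional initial coefficient vector (length \eqn{M-1})
#'   replacing the zero start \eqn{\hat p_0 = 0}. Used by
#'   [critical_threshold()] to probe stability with a generic initial
#'   condition: on highly symmetric networks the forcing can be exactly
#'   orthogonal to the critical eigendirection, in which case the zero-start
#'   iteration converges even above the threshold.
#' @return Object of class `scheme_state` with `status`
#'   (`"converged"`, `"diverged"`, `"max_iter"`), iteration count `n`,
#'   coefficients `c`, `alpha`, the network part `p_hat`, the stationary
#'   vector `p_star` (length \eqn{M+1}, renormalized to sum 1 when
#'   available), the per-iteration update deltas `delta_trace`, and
#'   `trending`.
#' @export
iterate_scheme <- function(proj, ts, tol = 1e-10, max_iter = 20000,
                           divergence_bound = 1e6,
                           variant = c("consistent", "literal"),
                           init = NULL) {
  stopifnot(inherits(proj, "projected_perturbation"),
            inherits(ts, "transition_system"))
  variant <- match.arg(variant)
  stopifnot(tol > 0, max_iter >= 1)
  m <- ts$m
  bar <- proj$bar
  idx <- seq(3, m + 1)                      # modes k = 2..M
  lam <- ts$eigenvalues[2:m]
  bar_blk <- bar[idx, idx, drop = FALSE]
  bar_k1 <- bar[idx, 2]
  bar_k0 <- bar[idx, 1]
  bar_1j <- bar[2, idx]
  cur <- init %||% rep(0, m - 1)
  if (length(cur) != m - 1) stop("`init` must have length M - 1", call. = FALSE)
  alpha <- 1
  status <- "max_iter"
  deltas <- numeric(max_iter)
  n_deltas <- 0L
  n_done <- max_iter
  for (n in seq_len(max_iter)) {
    rhs <- -(bar_blk %*% cur) - alpha * bar_k1 - bar_k0
    nxt <- as.vector(rhs) / lam
    if (!all(is.finite(nxt)) || max(abs(nxt)) > divergence_bound) {
      status <- "diverged"
      n_done <- n
      cur <- nxt
      break
    }
    alpha <- if (bar[2, 2] == 0) {
      alpha                       # zero perturbation: stationary mode untouched
    } else if (variant == "consistent") {
      (-sum(nxt * bar_1j) - bar[2, 1]) / bar[2, 2]
    } else {
      -sum(nxt * bar_1j) / bar[2, 2] - bar[2, 1] / bar[1, 1]
    }
    if (!is.finite(alpha)) {
      status <- "diverged"
      n_done <- n
      cur <- nxt
      break
    }
    delta <- max(abs(nxt - cur))
    n_deltas <- n_deltas + 1L
    deltas[n_deltas] <- delta
    cur <- nxt
    if (delta < tol) {
      status <- "converged"
      n_done <- n
      break
    }
  }
  deltas <- deltas[seq_len(n_deltas)]
  trending <- scheme_trending(deltas)
  p_hat <- NULL
  p_star <- NULL
  if (status != "diverged" && all(is.finite(cur))) {
    p_hat <- as.vector(ts$eigenvectors[, 2:m, drop = FALSE] %*% cur)
    raw <- c(1, p_hat + alpha * ts$p_s)
    p_star <- raw / sum(raw)
    names(p_star) <- c(".env", ts$labels)
  }
  structure(
    list(status = status, n = n_done, c = cur, alpha = alpha,
         p_hat = p_hat, p_star = p_star, delta_trace = deltas,
         trending = trending, variant = variant, epsilon = proj$epsilon),
    class = "scheme_state"
  )
}

# classify the tail of the update deltas: contracting vs expanding
scheme_trending <- function(deltas) {
  n <- length(deltas)
  if (n < 4) return(NA_character_)
  tail_len <- max(2L, n %/% 4L)
  early <- deltas[seq(n - 2L * tail_len + 1L, n - tail_len)]
  late <- deltas[seq(n - tail_len + 1L, n)]
  if (stats::median(late) <= stats::median(early)) "contracting" else "expanding"
}

#' Does a scheme run count as converging?
#'
#' `TRUE` for a converged state, and for a `max_iter` state whose update
#' deltas were still contracting (the regime arbitrarily close below the
#' critical threshold, where the geometric rate makes strict tolerance
#' convergence unreachable in any fixed budget).
#'
#' @param state A `scheme_state`.
#' @return Logical.
#' @export
scheme_converges <- function(state) {
  stopifnot(inherits(state, "scheme_state"))
  state$status == "converged" ||
    (state$status == "max_iter" && identical(state$trending, "contracting"))
}

#' Direct (kernel) solution of the perturbed stationary state
#'
#' The brute-force oracle for the iterative scheme: the stationary state of
#' the perturbed master equation is the one-dimensional kernel of
#' \eqn{L_0 + \Delta L_\varepsilon}, computed by dense SVD and normalized to
#' sum 1.
#'
#' @param pert A [perturbation()] with `epsilon > 0`.
#' @param ts The matching [transition_system()].
#' @param tol Relative singular-value threshold for kernel detection.
#' @return Named numeric vector of length \eqn{M+1} summing to 1 (first
#'   entry = environment).
#' @export
perturbed_stationary_direct <- function(pert, ts, tol = 1e-10) {
  stopifnot(inherits(pert, "perturbation"), inherits(ts, "transition_system"))
  if (pert$epsilon <= 0) {
    stop("degenerate stationary state: the kernel is two-dimensional at epsilon = 0",
         call. = FALSE)
  }
  k_mat <- extend_laplacian(ts) + pert$delta_l
  sv <- svd(k_mat)
  d <- sv$d
  if (d[length(d) - 1] <= tol * d[1]) {
    stop("degenerate stationary state: kernel dimension exceeds 1", call. = FALSE)
  }
  v <- sv$v[, length(d)]
  if (sum(v) < 0) v <- -v
  p <- v / sum(v)
  names(p) <- c(".env", ts$labels)
  p
}

#' Critical perturbation intensity by bisection
#'
#' Finds the intensity \eqn{\hat\mu} at which the iterative scheme switches
#' from converging to diverging, by bisection on \eqn{\varepsilon}. The
#' bracket defaults to \eqn{[\lambda_F/10,\, 10\lambda_F]}; the upper end is
#' doubled (up to \eqn{2^{10}\lambda_F}) until divergence is observed. If no
#' divergence is found below the cap — the case for every single-node query
#' set — the sentinel `Inf` is returned with a warning.
#'
#' @param ts A [transition_system()].
#' @param query Query-node labels or indices.
#' @param lo,hi Initial bracket; defaults as above.
#' @param tol Absolute bisection tolerance; default \eqn{10^{-3}\lambda_F}.
#' @param coupling Passed to [perturbation()].
#' @param max_doublings Doubling cap for the upper bracket end.
#' @param probe_noise Amplitude of the deterministic generic initial
#'   condition used by the stability probes (see [iterate_scheme()]'s
#'   `init`).
#' @param ... Passed to [iterate_scheme()].
#' @return Object of class `critical_threshold`: `mu_hat` (bisection),
#'   `mu_analytic` (\eqn{\varepsilon/\rho(\varepsilon)} from [frailness()]),
#'   the final bracket, and a status.
#' @export
critical_threshold <- function(ts, query, lo = NULL, hi = NULL, tol = NULL,
                               coupling = c("per_query", "split"),
                               max_doublings = 10, probe_noise = 1e-8, ...) {
  stopifnot(inherits(ts, "transition_system"))
  coupling <- match.arg(coupling)
  lam_f <- ts$lambda_f
  lo <- lo %||% (lam_f / 10)
  hi <- hi %||% (10 * lam_f)
  tol <- tol %||% (1e-3 * lam_f)
  stopifnot(lo > 0, hi > lo, tol > 0)
  fr <- frailness(ts, query, epsilon = 1, coupling = coupling)
  mu_analytic <- fr$mu_analytic
  init <- probe_noise * sin(seq_len(ts$m - 1))
  probe <- function(eps) {
    st <- iterate_scheme(
      project_perturbation(perturbation(ts, query, eps, coupling), ts), ts,
      init = init, ...
    )
    scheme_converges(st)
  }
  if (!probe(lo)) {
    stop("scheme does not converge at the lower bracket end", call. = FALSE)
  }
  cap <- 2^max_doublings * lam_f
  while (probe(hi)) {
    if (hi >= cap) {
      warning("no divergence found below the intensity cap; ",
              "returning Inf (rank-deficient perturbations never diverge)")
      return(structure(
        list(mu_hat = Inf, mu_analytic = mu_analytic, lo = hi, hi = Inf,
             tol = tol, status = "no_divergence", query = fr$query,
             lambda_f = lam_f),
        class = "critical_threshold"
      ))
    }
    lo <- hi
    hi <- min(2 * hi, cap)
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (probe(mid)) lo <- mid else hi <- mid
  }
  structure(
    list(mu_hat = (lo + hi) / 2, mu_analytic = mu_analytic, lo = lo, hi = hi,
         tol = tol, status = "bracketed", query = fr$query, lambda_f = lam_f),
    class = "critical_threshold"
  )
}

#' @export
print.critical_threshold <- function(x, ...) {
  cat(sprintf(
    "<critical_threshold> mu_hat = %.6g (bisection), mu_analytic = %.6g, lambda_F = %.6g\n",
    x$mu_hat, x$mu_analytic, x$lambda_f
  ))
  invisible(x)
}

#' @rdname critical_threshold
#' @param x A `critical_threshold`.
#' @param ... Unused.
#' @export
tidy.critical_threshold <- function(x, ...) {
  tibble::tibble(
    query = paste(x$query, collapse = ","),
    mu_hat = x$mu_hat,
    mu_analytic = x$mu_analytic,
    lambda_f = x$lambda_f,
    status = x$status
  )
}

#' Stationary probability currents of the perturbed system
#'
#' At the perturbed stationary state \eqn{p^*_s}, the net current from node
#' \eqn{k} to node \eqn{i} is \eqn{J_{ik} = \pi^*_{ik} (p^*_s)_k -
#' \pi^*_{ki} (p^*_s)_i}, where \eqn{\pi^*} are the perturbed transition
#' rates (network rates plus environment exchange). \eqn{J} is exactly
#' antisymmetric and vanishes identically when the perturbed chain is
#' reversible — in particular at \eqn{\varepsilon \to 0}, and for any
#' \eqn{\varepsilon} on vertex-transitive networks such as complete graphs,
#' where the uniform stationary state balances every environment cycle.
#'
#' @param pert A [perturbation()] with positive intensity.
#' @param ts The matching [transition_system()].
#' @param include_environment Include the environment row/column in the
#'   total intensity \eqn{I = \sum_{i,k} |J_{ik}|} (ordered pairs)?
#' @param p_star Optional stationary vector (length \eqn{M+1}); defaults to
#'   the direct kernel solution.
#' @return Object of class `current_field` with the \eqn{(M+1)^2} matrix
#'   `j` and the scalar `intensity`.
#' @export
stationary_currents <- function(pert, ts, include_environment = TRUE,
                                p_star = NULL) {
  stopifnot(inherits(pert, "perturbation"), inherits(ts, "transition_system"))
  if (is.null(p_star)) p_star <- perturbed_stationary_direct(pert, ts)
  k_mat <- extend_laplacian(ts) + pert$delta_l
  pi_star <- -k_mat
  diag(pi_star) <- 0
  flow <- sweep(pi_star, 2, p_star, "*")
  j <- flow - t(flow)
  j_eff <- if (include_environment) j else j[-1, -1, drop = FALSE]
  structure(
    list(j = j, intensity = sum(abs(j_eff)), epsilon = pert$epsilon,
         query = pert$query, include_environment = include_environment),
    class = "current_field"
  )
}

#' @export
print.current_field <- function(x, ...) {
  cat(sprintf("<current_field> epsilon = %g, intensity I = %.6g\n",
              x$epsilon, x$intensity))
  invisible(x)
}

#' @rdname stationary_currents
#' @param x A `current_field`.
#' @param ... Unused.
#' @export
tidy.current_field <- function(x, ...) {
  lab <- rownames(x$j)
  n <- length(lab)
  out <- tibble::tibble(
    from = rep(lab, each = n),        # column index k: source node
    to = rep(lab, times = n),         # row index i: destination node
    current = as.vector(x$j)          # column-major: J[i, k]
  )
  out[out$from != out$to, ]
}

#' Scan the current intensity across perturbation intensities
#'
#' Evaluates the total stationary current intensity \eqn{I(\varepsilon)}
#' over an increasing grid and locates the critical signature. With the
#' default `method = "scheme"` each grid point uses the iterative scheme
#' under a fixed iteration budget: below the critical threshold \eqn{\mu}
#' the scheme converges and \eqn{I} follows the smooth quasi-static branch,
#' while at \eqn{\mu} the oscillatory divergence of the scheme inflates the
#' reconstructed state and \eqn{I} jumps — the non-linearity that marks the
#' threshold. The flagged point (`is_first_peak`) is the first interior
#' local maximum of \eqn{I} when one occurs before the largest single-step
#' jump, otherwise the grid point at the top of that jump. With
#' `method = "direct"` the exact kernel stationary state is used at every
#' \eqn{\varepsilon}; that curve is smooth through \eqn{\mu} (the stationary
#' state itself is analytic in \eqn{\varepsilon}) and carries no threshold
#' signature.
#'
#' @param ts A [transition_system()].
#' @param query Query-node labels or indices.
#' @param eps_grid Strictly increasing positive grid with at least 3 points.
#' @param method `"scheme"` (finite-budget iteration; default) or `"direct"`.
#' @param coupling Passed to [perturbation()].
#' @param scan_iter Iteration budget per grid point for `method = "scheme"`.
#' @param include_environment Passed to the intensity computation.
#' @return A tibble of class `intensity_scan` with columns `epsilon`,
#'   `intensity`, `converged`, `is_first_peak`.
#' @export
intensity_scan <- function(ts, query, eps_grid,
                           method = c("scheme", "direct"),
                           coupling = c("per_query", "split"),
                           scan_iter = 300, include_environment = TRUE) {
  stopifnot(inherits(ts, "transition_system"))
  method <- match.arg(method)
  coupling <- match.arg(coupling)
  if (length(query) == 0) stop("the query set must be nonempty", call. = FALSE)
  if (length(eps_grid) < 3) stop("`eps_grid` needs at least 3 points", call. = FALSE)
  if (any(eps_grid <= 0) || any(diff(eps_grid) <= 0)) {
    stop("`eps_grid` must be positive and strictly increasing", call. = FALSE)
  }
  n <- length(eps_grid)
  intensity <- numeric(n)
  converged <- logical(n)
  for (i in seq_len(n)) {
    pert <- perturbation(ts, query, eps_grid[i], coupling)
    if (method == "direct") {
      p <- perturbed_stationary_direct(pert, ts)
      converged[i] <- TRUE
    } else {
      st <- iterate_scheme(project_perturbation(pert, ts), ts,
                           max_iter = scan_iter, divergence_bound = 1e12)
      converged[i] <- st$status == "converged"
      p <- scheme_scan_state(st, ts)
    }
    intensity[i] <- stationary_currents(pert, ts, include_environment,
                                        p_star = p)$intensity
  }
  first_peak <- detect_first_peak(intensity)
  out <- tibble::tibble(
    epsilon = eps_grid,
    intensity = intensity,
    converged = converged,
    is_first_peak = seq_len(n) == first_peak
  )
  class(out) <- c("intensity_scan", class(out))
  out
}

# reconstruct a (renormalized) state from whatever the budgeted scheme left
scheme_scan_state <- function(st, ts) {
  m <- ts$m
  cur <- st$c
  cur[!is.finite(cur)] <- 0
  p_hat <- as.vector(ts$eigenvectors[, 2:m, drop = FALSE] %*% cur)
  alpha <- if (is.finite(st$alpha)) st$alpha else 0
  raw <- c(1, p_hat + alpha * ts$p_s)
  raw / sum(abs(raw))
}

# first prominent interior local maximum if it precedes the largest forward
# jump, otherwise the upper endpoint of that jump; prominence is measured
# against the dynamic range so that numerical wiggles on a flat branch are
# ignored
detect_first_peak <- function(intensity, min_prominence = 0.05) {
  n <- length(intensity)
  rng <- max(intensity) - min(intensity)
  peaks <- which(diff(sign(diff(intensity))) == -2) + 1L
  if (length(peaks) && rng > 0) {
    prom <- intensity[peaks] -
      pmin(intensity[peaks - 1L], intensity[peaks + 1L])
    peaks <- peaks[prom >= min_prominence * rng]
  }
  jump <- which.max(diff(intensity)) + 1L
  cand <- c(peaks[peaks <= jump], jump)
  if (length(cand) == 0) return(NA_integer_)
  min(cand)
}

#' @export
print.intensity_scan <- function(x, ...) {
  pk <- x$epsilon[x$is_first_peak]
  cat(sprintf("<intensity_scan> %d grid points; critical signature at eps = %s\n",
              nrow(x), if (length(pk)) format(pk) else "none"))
  NextMethod()
}
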