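#' Plot an intensity scan
#'
#' Line plot of the stationary current intensity \eqn{I(\varepsilon)} with
#' the detected critical signature marked by a vertical line.
#'
#' @param object An [intensity_scan()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.intensity_scan <- function(object, ...) {
  pk <- object$epsilon[object$is_first_peak]
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$epsilon,
                                            y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$converged), size = 1.4) +
    ggplot2::labs(x = expression(epsilon), y = "current intensity I",
                  colour = "scheme converged") +
    ggplot2::theme_minimal()
  if (length(pk)) {
    p <- p + ggplot2::geom_vline(xintercept = pk, linetype = "dashed")
  }
  p
}

#' Scatter plot of the Gene Frailness Index components
#'
#' Co-occurrence fraction \eqn{\sigma} (log scale) against the normalized
#' median frailness \eqn{\rho'}, with the most destabilizing genes
#' labelled.
#'
#' @param gfi A [gene_frailness_index()] table.
#' @param label_top Number of genes (by `rho_prime`) to label.
#' @return A ggplot object.
#' @export
plot_gfi <- function(gfi, label_top = 6) {
  lab <- utils::head(dplyr::arrange(gfi, dplyr::desc(.data$rho_prime)),
                     label_top)
  ggplot2::ggplot(gfi, ggplot2::aes(x = .data$sigma, y = .data$rho_prime)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$m_star), alpha = 0.7) +
    ggplot2::geom_text(data = lab, ggplot2::aes(label = .data$gene),
                       vjust = -0.6, size = 3) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(sigma ~ "(co-occurrence fraction, log)"),
                  y = expression(rho * "'" ~ "(normalized median frailness)"),
                  size = "m*") +
    ggplot2::theme_minimal()
}

#' Frailness distribution by number of co-occurring mutations
#'
#' Box plot of per-sample frailness grouped by \eqn{m^*}, the spectral
#' counterpart of the efficiency-vs-removal curves of classical topological
#' scoring.
#'
#' @param sample_rho A [sample_frailness()] table.
#' @param include_null Include single-mutation (null-frailness) samples?
#' @return A ggplot object.
#' @export
plot_frailness_by_mstar <- function(sample_rho, include_null = TRUE) {
  d <- if (include_null) sample_rho else
    sample_rho[!sample_rho$null_frailness, ]
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$m_star), y = .data$rho)) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::labs(x = "co-occurring mutations m*", y = expression(rho)) +
    ggplot2::theme_minimal()
}

#' Heatmap of stationary currents
#'
#' Tile plot of the antisymmetric current matrix \eqn{J} at the perturbed
#' stationary state.
#'
#' @param object A [stationary_currents()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.current_field <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$from, y = .data$to,
                                  fill = .data$current)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = "from node", y = "to node",
                  fill = expression(J[ik])) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
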