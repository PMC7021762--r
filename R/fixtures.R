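#' Specification for a synthetic mutation cohort
#'
#' Describes the statistical shape of a simulated binary mutation cohort on
#' a network: a few high-frequency "driver-like" genes (assigned to the
#' highest-degree nodes) plus a long power-law tail of rarely mutated
#' genes, mimicking the heavily skewed per-gene mutation frequencies of
#' real tumour cohorts in which most mutation configurations involve one of
#' a couple of recurrent drivers. Optionally a frailness-generating effect
#' is planted: a fraction of samples co-mutate the top driver with one
#' randomly chosen degree-one (marginal) gene.
#'
#' @param n_samples Number of samples.
#' @param driver_freq Mutation probabilities of the driver genes (assigned
#'   to the highest-degree nodes, in this order).
#' @param tail_exponent Power-law exponent of the remaining genes' rank-
#'   frequency law (probability of the r-th tail gene proportional to
#'   \eqn{r^{-\gamma}}).
#' @param tail_mean Mean mutation probability of the tail genes (the
#'   power-law profile is rescaled to this mean).
#' @param planted_effect Plant driver + marginal-gene co-mutations?
#' @param planted_fraction Fraction of samples carrying the planted pair.
#' @param seed Integer seed; generation is fully reproducible.
#' @param n_genes Optional; must equal the network size when given.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 200, driver_freq = c(0.35, 0.25),
                       tail_exponent = 1.5, tail_mean = 0.03,
                       planted_effect = FALSE, planted_fraction = 0.25,
                       seed = 1, n_genes = NULL) {
  stopifnot(n_samples >= 1,
            all(driver_freq > 0 & driver_freq < 1),
            tail_exponent > 0,
            tail_mean > 0 && tail_mean < 1,
            planted_fraction >= 0 && planted_fraction <= 1)
  structure(
    list(n_samples = as.integer(n_samples), driver_freq = driver_freq,
         tail_exponent = tail_exponent, tail_mean = tail_mean,
         planted_effect = isTRUE(planted_effect),
         planted_fraction = planted_fraction, seed = as.integer(seed),
         n_genes = n_genes),
    class = "cohort_spec"
  )
}

#' Per-gene mutation probabilities implied by a cohort specification
#'
#' Drivers take `driver_freq` on the highest-degree nodes (ties broken by
#' label); the remaining genes follow the rescaled power law, assigned in
#' decreasing-degree order so that mutation frequency tracks connectivity —
#' marginal (degree-one) genes sit in the rare tail, as in real tumour
#' cohorts where the recurrently mutated genes are the well-connected
#' drivers.
#'
#' @param spec A [cohort_spec()].
#' @param network The network the cohort lives on.
#' @return Named numeric vector of probabilities in (0, 1).
#' @export
mutation_freq_law <- function(spec, network) {
  network <- as_frail_network(network)
  m <- network$m
  n_drv <- length(spec$driver_freq)
  if (!is.null(spec$n_genes) && spec$n_genes != m) {
    stop("`n_genes` in the specification does not match the network size",
         call. = FALSE)
  }
  if (m <= n_drv) stop("network too small for the driver set", call. = FALSE)
  deg <- node_degrees(network)
  drivers <- names(sort(deg, decreasing = TRUE))[seq_len(n_drv)]
  tail_genes <- setdiff(names(sort(deg, decreasing = TRUE)), drivers)
  raw <- seq_along(tail_genes)^(-spec$tail_exponent)
  p_tail <- pmin(raw * spec$tail_mean / mean(raw), 0.95)
  p <- stats::setNames(numeric(m), network$labels)
  p[drivers] <- spec$driver_freq
  p[tail_genes] <- p_tail
  p
}

#' Generate a synthetic binary mutation cohort
#'
#' Samples the genes-by-samples matrix gene-wise Bernoulli from the
#' frequency law of the specification. With `planted_effect`, a random
#' `planted_fraction` of the samples additionally carry the top driver
#' gene and one randomly chosen degree-one gene — the co-occurring
#' central + marginal configuration that generates high frailness.
#'
#' @param spec A [cohort_spec()].
#' @param network The network supplying gene labels and degrees.
#' @return A [mutation_matrix()] (genes x samples).
#' @export
make_mutation_cohort <- function(spec, network) {
  stopifnot(inherits(spec, "cohort_spec"))
  network <- as_frail_network(network)
  p <- mutation_freq_law(spec, network)
  m <- network$m
  n <- spec$n_samples
  set.seed(spec$seed)
  a <- matrix(stats::rbinom(m * n, 1, rep(p, times = n)), nrow = m,
              dimnames = list(network$labels,
                              sprintf("s%03d", seq_len(n))))
  if (spec$planted_effect) {
    deg <- node_degrees(network)
    marginals <- names(deg)[deg == 1]
    if (length(marginals) == 0) {
      stop("planted effect requires at least one degree-one gene", call. = FALSE)
    }
    driver <- names(sort(deg, decreasing = TRUE))[1]
    n_pl <- round(spec$planted_fraction * n)
    carriers <- sample(n, n_pl)
    for (j in carriers) {
      a[driver, j] <- 1
      a[sample(marginals, 1), j] <- 1
    }
  }
  mutation_matrix(a)
}

#' Synthetic gene network with marginal periphery
#'
#' Builds the network shape the planted-effect cohort generator targets: a
#' dense Erdős–Rényi signalling core plus `n_marginal` degree-one genes,
#' each attached to the core through its own degree-two linker node. The
#' peripheral genes play the role of growth-factor-like regulators sitting
#' at the edge of the cascade: they are the nodes with the largest
#' slow-mode (Fiedler) amplitude, so co-mutating one of them with a central
#' driver produces the characteristically frail configurations, while the
#' linkers — the only other peripheral nodes — have low degree and hence a
#' rare-tail mutation frequency.
#'
#' @param m_core Core size.
#' @param n_marginal Number of degree-one peripheral genes (`leaf1`, ...).
#' @param p_core Core edge probability.
#' @param seed Integer seed (core draw and stalk anchoring).
#' @return A [frail_network()] with `m_core + 2 * n_marginal` nodes.
#' @export
make_leafy_network <- function(m_core = 24, n_marginal = 6, p_core = 0.3,
                               seed = 1) {
  stopifnot(n_marginal >= 1, n_marginal <= m_core)
  core <- make_random_network("erdos_renyi", m = m_core, p = p_core,
                              seed = seed)
  edges <- igraph::as_edgelist(core$graph)
  set.seed(seed + 1000L)
  anchors <- sample(core$labels, n_marginal)
  stalks <- paste0("stalk", seq_len(n_marginal))
  leaves <- paste0("leaf", seq_len(n_marginal))
  as_frail_network(as.data.frame(rbind(
    edges, cbind(stalks, anchors), cbind(leaves, stalks)
  )))
}

#' Write a complete set of synthetic pipeline inputs
#'
#' Generates a connected preferential-attachment network, a GMT file of
#' gene sets (random connected neighbourhoods of the network), and a
#' long-tailed mutation matrix, and writes the three standard input files
#' (`edges.tsv`, `pathways.gmt`, `mutations.tsv`) to `dir`.
#'
#' @param dir Output directory (created if needed).
#' @param m Network size.
#' @param n_sets Number of gene sets.
#' @param set_size_range Inclusive size range the sampled sets are drawn
#'   from.
#' @param spec A [cohort_spec()]; its seed also drives the network and the
#'   set sampling.
#' @return Invisibly, a named list of the three file paths.
#' @export
simulate_cohort_inputs <- function(dir, m = 60, n_sets = 6,
                                   set_size_range = c(12, 30),
                                   spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  net <- make_random_network("preferential_attachment", m = m,
                             edges_per_node = 2, seed = spec$seed)
  set.seed(spec$seed + 1L)
  sets <- lapply(seq_len(n_sets), function(i) {
    size <- sample(seq(set_size_range[1], set_size_range[2]), 1)
    start <- sample(net$labels, 1)
    grow_neighbourhood(net, start, size)
  })
  names(sets) <- sprintf("SET%02d", seq_len(n_sets))
  muts <- make_mutation_cohort(spec, net)
  paths <- list(
    edges = file.path(dir, "edges.tsv"),
    gmt = file.path(dir, "pathways.gmt"),
    mutations = file.path(dir, "mutations.tsv")
  )
  write_edge_list(net, paths$edges, seed = spec$seed)
  write_gmt(sets, paths$gmt,
            descriptions = rep("synthetic gene set", n_sets))
  write_mutation_matrix(muts, paths$mutations, seed = spec$seed)
  invisible(paths)
}

# breadth-first neighbourhood of `size` nodes around a start node
grow_neighbourhood <- function(network, start, size) {
  ord <- igraph::bfs(network$graph, root = start, order = TRUE)$order
  igraph::V(network$graph)$name[ord[seq_len(min(size, network$m))]]
}
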