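#' Binary genes-by-samples mutation matrix
#'
#' Validates and tags a binary matrix \eqn{a_{ij}} with \eqn{a_{ij} = 1} iff
#' sample \eqn{j} carries at least one mutation in gene \eqn{i}. Row names
#' are gene labels, column names sample labels; both must be unique.
#'
#' @param x Numeric matrix with entries in `{0, 1}` and complete, unique
#'   dimnames.
#' @return The matrix with class `mutation_matrix` prepended.
#' @export
mutation_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("`x` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("gene (row) and sample (column) labels are required", call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) stop("duplicate gene labels", call. = FALSE)
  if (anyDuplicated(colnames(x))) stop("duplicate sample labels", call. = FALSE)
  bad <- which(!(x %in% c(0, 1)))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(x)) + 1
    j <- ((bad[1] - 1) %/% nrow(x)) + 1
    stop(sprintf("non-binary value %s at gene '%s', sample '%s'",
                 format(x[bad[1]]), rownames(x)[i], colnames(x)[j]),
         call. = FALSE)
  }
  class(x) <- c("mutation_matrix", class(x))
  x
}

#' @export
print.mutation_matrix <- function(x, ...) {
  cat(sprintf("<mutation_matrix> %d genes x %d samples; %d alterations\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}

#' @rdname mutation_matrix
#' @param x A `mutation_matrix`.
#' @param ... Unused.
#' @export
tidy.mutation_matrix <- function(x, ...) {
  idx <- which(unclass(x) == 1, arr.ind = TRUE)
  tibble::tibble(
    gene = rownames(x)[idx[, 1]],
    sample = colnames(x)[idx[, 2]]
  ) |> dplyr::arrange(.data$sample, .data$gene)
}

#' Extract pathway subnetworks from a PPI network
#'
#' For every gene set, induces the subgraph of the interaction network on
#' its member genes, keeps the largest connected component, and retains the
#' pathway iff that component has between `min_size` and `max_size` nodes
#' and the pathway name matches none of the exclusion patterns. Pathways
#' with no gene mapped on the network are dropped (and logged in the
#' `dropped` attribute, together with every other dropped set and its
#' reason).
#'
#' @param ppi Interaction network ([frail_network()] or coercible).
#' @param gene_sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param min_size,max_size Size bounds on the largest connected component.
#' @param exclude Character vector of regular expressions; a pathway whose
#'   name matches any of them (case-insensitively) is excluded.
#' @return Tibble with columns `pathway`, `n_set` (genes in the set),
#'   `n_mapped` (genes found on the PPI), `size` (largest-component nodes)
#'   and the list-column `network` of [frail_network()] objects; dropped
#'   sets in `attr(, "dropped")`.
#' @export
extract_pathway_networks <- function(ppi, gene_sets, min_size = 10,
                                     max_size = 500, exclude = NULL) {
  ppi <- as_frail_network(ppi)
  if (length(gene_sets) == 0) stop("`gene_sets` is empty", call. = FALSE)
  if (is.null(names(gene_sets)) || anyDuplicated(names(gene_sets))) {
    stop("`gene_sets` must have unique names", call. = FALSE)
  }
  stopifnot(min_size <= max_size)
  kept <- list()
  dropped <- list()
  for (nm in names(gene_sets)) {
    if (!is.null(exclude) &&
        any(vapply(exclude, grepl, logical(1), x = nm, ignore.case = TRUE))) {
      dropped[[nm]] <- "excluded by name pattern"
      next
    }
    genes <- intersect(unique(gene_sets[[nm]]), ppi$labels)
    if (length(genes) == 0) {
      dropped[[nm]] <- "no gene mapped on the network"
      next
    }
    sub <- igraph::induced_subgraph(ppi$graph, genes)
    comp <- igraph::components(sub)
    biggest <- which.max(comp$csize)
    members <- igraph::V(sub)$name[comp$membership == biggest]
    size <- length(members)
    if (size < min_size || size > max_size) {
      dropped[[nm]] <- sprintf("largest component size %d outside [%d, %d]",
                               size, min_size, max_size)
      next
    }
    kept[[nm]] <- tibble::tibble(
      pathway = nm,
      n_set = length(unique(gene_sets[[nm]])),
      n_mapped = length(genes),
      size = size,
      network = list(as_frail_network(
        igraph::induced_subgraph(ppi$graph, members)
      ))
    )
  }
  if (length(dropped)) {
    message(length(dropped), " gene set(s) dropped (see attr 'dropped')")
  }
  out <- dplyr::bind_rows(kept)
  if (nrow(out) == 0) {
    out <- tibble::tibble(pathway = character(), n_set = integer(),
                          n_mapped = integer(), size = integer(),
                          network = list())
  }
  attr(out, "dropped") <- tibble::tibble(
    pathway = names(dropped),
    reason = unlist(dropped, use.names = FALSE) %||% character()
  )
  out
}

# per-sample query sets on a network: overlap of mutated genes with nodes
sample_queries <- function(network, mutations) {
  network <- as_frail_network(network)
  stopifnot(inherits(mutations, "mutation_matrix"))
  genes <- intersect(rownames(mutations), network$labels)
  sub <- unclass(mutations)[genes, , drop = FALSE]
  queries <- lapply(seq_len(ncol(sub)), function(j) genes[sub[, j] == 1])
  keep <- lengths(queries) > 0
  tibble::tibble(
    sample = colnames(mutations)[keep],
    m_star = lengths(queries)[keep],
    query = queries[keep],
    null_frailness = lengths(queries)[keep] < 2
  )
}

#' Per-sample frailness on a pathway network
#'
#' For each sample, the query set is the intersection of its mutated genes
#' with the network nodes. Samples with no mutated gene on the network are
#' excluded; samples with a single mutated gene are recorded with
#' \eqn{\rho = 0} and flagged `null_frailness` (at least two co-occurring
#' alterations are needed to perturb the stationary flow); samples with two
#' or more get the spectral frailness score.
#'
#' @param network The pathway network ([frail_network()] or coercible).
#' @param mutations A [mutation_matrix()].
#' @param epsilon,norm,coupling Passed to the frailness computation.
#' @return Tibble with columns `sample`, `m_star` (number of co-occurring
#'   mutations on the network), `rho`, `null_frailness`, and the list-column
#'   `query`.
#' @export
sample_frailness <- function(network, mutations, epsilon = 1,
                             norm = c("spectral", "frobenius"),
                             coupling = c("per_query", "split")) {
  norm <- match.arg(norm)
  coupling <- match.arg(coupling)
  network <- as_frail_network(network)
  tab <- sample_queries(network, mutations)
  ts <- transition_system(network)
  tab$rho <- vapply(tab$query, function(g) {
    frailness_rho(ts, match(g, ts$labels), epsilon, norm, coupling)
  }, numeric(1))
  tab[, c("sample", "m_star", "rho", "null_frailness", "query")]
}

#' Gene-pair co-occurrence table with mean frailness
#'
#' For each unordered gene pair co-mutated (on the network) in at least one
#' sample, reports the number of such samples and the mean frailness
#' \eqn{\langle\rho\rangle} across all samples carrying the pair — possibly
#' among further mutations. Pairs never co-mutated are absent. The number
#' of candidate pairs among the network's \eqn{G} genes, \eqn{G(G-1)/2}, is
#' attached as attribute `n_candidate_pairs` when `network` is supplied.
#'
#' @param sample_rho Output of [sample_frailness()].
#' @param network Optional [frail_network()] for the candidate-pair count.
#' @return Tibble with columns `gene_a`, `gene_b` (sorted within pair),
#'   `n_samples`, `mean_rho`.
#' @export
pair_cooccurrence <- function(sample_rho, network = NULL) {
  stopifnot(all(c("sample", "rho", "query") %in% names(sample_rho)))
  multi <- sample_rho[lengths(sample_rho$query) >= 2, ]
  rows <- purrr::map2(multi$query, multi$rho, function(g, r) {
    p <- utils::combn(sort(g), 2)
    tibble::tibble(gene_a = p[1, ], gene_b = p[2, ], rho = r)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(gene_a = character(), gene_b = character(),
                          n_samples = integer(), mean_rho = numeric())
  } else {
    out <- out |>
      dplyr::group_by(.data$gene_a, .data$gene_b) |>
      dplyr::summarise(n_samples = dplyr::n(), mean_rho = mean(.data$rho),
                       .groups = "drop")
  }
  if (!is.null(network)) {
    network <- as_frail_network(network)
    attr(out, "n_candidate_pairs") <- choose(network$m, 2)
  }
  out
}

#' Number of candidate gene pairs on a network
#'
#' @param network A [frail_network()] or coercible.
#' @return `choose(m, 2)` for the `m` network genes.
#' @export
n_candidate_pairs <- function(network) {
  choose(as_frail_network(network)$m, 2)
}

#' Gene Frailness Index
#'
#' A two-component per-gene summary of a cohort frailness analysis on one
#' network \eqn{W}. For gene \eqn{g}: \eqn{m^*_{W,g}} is the number of
#' samples in which \eqn{g} is mutated together with at least one other
#' mutated gene of \eqn{W}; \eqn{\sigma_{W,g} = m^*_{W,g}/n_{samples}} is
#' its co-occurrence fraction; \eqn{\tilde\rho_{W,g}} is the median
#' frailness over samples carrying \eqn{g} (restricted, by default, to
#' samples with non-null frailness); and \eqn{\rho'_{W,g} =
#' \tilde\rho_{W,g} / \max_i \tilde\rho_{W,i}} normalizes by the per-network
#' maximum so the index is comparable across networks. The GFI of \eqn{g}
#' is the pair \eqn{(\sigma_{W,g}, \rho'_{W,g})}.
#'
#' @param sample_rho Output of [sample_frailness()].
#' @param n_samples Denominator of \eqn{\sigma}: the total cohort size by
#'   convention (not only samples with signal on this network).
#' @param include_null Also include single-mutation (null-frailness) samples
#'   in the \eqn{\tilde\rho} median? Default `FALSE`.
#' @return Tibble with columns `gene`, `m_star`, `sigma`, `rho_tilde`,
#'   `rho_prime`, sorted by decreasing `rho_prime`.
#' @export
gene_frailness_index <- function(sample_rho, n_samples,
                                 include_null = FALSE) {
  stopifnot(is.numeric(n_samples), n_samples >= 1)
  multi <- sample_rho[!sample_rho$null_frailness, ]
  if (nrow(multi) == 0) {
    stop("no sample with non-null frailness on this network", call. = FALSE)
  }
  med_pool <- if (include_null) sample_rho else multi
  genes <- sort(unique(unlist(multi$query)))
  m_star <- vapply(genes, function(g) {
    sum(vapply(multi$query, function(s) g %in% s, logical(1)))
  }, integer(1))
  rho_tilde <- vapply(genes, function(g) {
    has <- vapply(med_pool$query, function(s) g %in% s, logical(1))
    stats::median(med_pool$rho[has])
  }, numeric(1))
  top <- max(rho_tilde)
  rho_prime <- if (top > 0) rho_tilde / top else {
    message("all median frailness values are zero; rho_prime set to 0")
    rep(0, length(genes))
  }
  tibble::tibble(
    gene = genes, m_star = unname(m_star), sigma = unname(m_star) / n_samples,
    rho_tilde = unname(rho_tilde), rho_prime = unname(rho_prime)
  ) |> dplyr::arrange(dplyr::desc(.data$rho_prime), .data$gene)
}

#' Hypergeometric test for marginal mutations among the least resilient samples
#'
#' Tests whether the `top_n` samples with the highest frailness (the least
#' resilient) are enriched in marginal mutations — query sets containing at
#' least one gene of degree `marginal_degree` or less in the network. The
#' population is the set of samples with non-null frailness; ranking ties
#' are broken deterministically (frailness descending, then sample label
#' ascending). The reported p-value is the upper hypergeometric tail
#' \eqn{P(X \ge x)}.
#'
#' @param network The pathway network.
#' @param sample_rho Output of [sample_frailness()].
#' @param top_n Number of least-resilient samples drawn.
#' @param min_patients Minimum population size; below it the test is
#'   skipped (`status = "skipped"`, `p_value = NA`).
#' @param marginal_degree Degree threshold defining a marginal gene
#'   (default 1: leaves of the network).
#' @param scores Optional named numeric vector (by sample) replacing the
#'   frailness ranking — used e.g. for permutation-null calibration.
#' @return One-row tibble: `n_population`, `n_success`, `n_drawn`, `x_top`,
#'   `p_value`, `status`.
#' @export
marginal_enrichment <- function(network, sample_rho, top_n = 10,
                                min_patients = 20, marginal_degree = 1,
                                scores = NULL) {
  network <- as_frail_network(network)
  pop <- sample_rho[!sample_rho$null_frailness, ]
  n_pop <- nrow(pop)
  if (n_pop < min_patients) {
    return(tibble::tibble(
      n_population = n_pop, n_success = NA_integer_, n_drawn = NA_integer_,
      x_top = NA_integer_, p_value = NA_real_, status = "skipped"
    ))
  }
  deg <- node_degrees(network)
  success <- vapply(pop$query, function(g) any(deg[g] <= marginal_degree),
                    logical(1))
  rank_by <- if (is.null(scores)) pop$rho else unname(scores[pop$sample])
  ord <- order(-rank_by, pop$sample)
  n_draw <- min(top_n, n_pop)
  x <- sum(success[ord[seq_len(n_draw)]])
  k <- sum(success)
  p <- stats::phyper(x - 1, k, n_pop - k, n_draw, lower.tail = FALSE)
  tibble::tibble(
    n_population = n_pop, n_success = k, n_drawn = n_draw, x_top = as.integer(x),
    p_value = p, status = "ok"
  )
}

#' Cohort-level frailness analysis across pathway networks
#'
#' The end-to-end genomics pipeline: extract pathway subnetworks from the
#' interaction network, score every sample's mutation configuration on each
#' of them, and assemble the co-occurrence, Gene Frailness Index and
#' marginal-enrichment tables.
#'
#' @param ppi Interaction network ([frail_network()] or coercible).
#' @param gene_sets Named list of gene vectors (see [read_gmt()]).
#' @param mutations A [mutation_matrix()].
#' @param epsilon,norm,coupling Passed to the frailness computation.
#' @param min_size,max_size,exclude Passed to [extract_pathway_networks()].
#' @param top_n,min_patients,marginal_degree Passed to
#'   [marginal_enrichment()].
#' @return Object of class `cohort_frailness`: a list with tibbles
#'   `networks`, `sample_rho`, `pairs`, `gfi`, `enrichment`, plus the
#'   parameters used.
#' @export
cohort_frailness <- function(ppi, gene_sets, mutations, epsilon = 1,
                             norm = c("spectral", "frobenius"),
                             coupling = c("per_query", "split"),
                             min_size = 10, max_size = 500, exclude = NULL,
                             top_n = 10, min_patients = 20,
                             marginal_degree = 1) {
  norm <- match.arg(norm)
  coupling <- match.arg(coupling)
  stopifnot(inherits(mutations, "mutation_matrix"))
  networks <- extract_pathway_networks(ppi, gene_sets, min_size, max_size,
                                       exclude)
  n_samples <- ncol(mutations)
  sample_rho <- list(); pairs <- list(); gfi <- list(); enr <- list()
  for (i in seq_len(nrow(networks))) {
    nm <- networks$pathway[i]
    w <- networks$network[[i]]
    sr <- sample_frailness(w, mutations, epsilon, norm, coupling)
    message(sprintf("pathway %s: %d nodes, %d samples with signal",
                    nm, w$m, sum(!sr$null_frailness)))
    sample_rho[[nm]] <- dplyr::mutate(sr, pathway = nm, .before = 1)
    pairs[[nm]] <- dplyr::mutate(pair_cooccurrence(sr, w), pathway = nm,
                                 .before = 1)
    if (any(!sr$null_frailness)) {
      gfi[[nm]] <- dplyr::mutate(gene_frailness_index(sr, n_samples),
                                 pathway = nm, .before = 1)
    }
    enr[[nm]] <- dplyr::mutate(
      marginal_enrichment(w, sr, top_n, min_patients, marginal_degree),
      pathway = nm, .before = 1
    )
  }
  structure(
    list(
      networks = networks,
      sample_rho = dplyr::bind_rows(sample_rho),
      pairs = dplyr::bind_rows(pairs),
      gfi = dplyr::bind_rows(gfi),
      enrichment = dplyr::bind_rows(enr),
      params = list(epsilon = epsilon, norm = norm, coupling = coupling,
                    min_size = min_size, max_size = max_size,
                    exclude = exclude, top_n = top_n,
                    min_patients = min_patients,
                    marginal_degree = marginal_degree,
                    n_samples = n_samples)
    ),
    class = "cohort_frailness"
  )
}

#' @export
print.cohort_frailness <- function(x, ...) {
  cat(sprintf(
    "<cohort_frailness> %d pathway networks, %d samples; %d (network, sample) scores\n",
    nrow(x$networks), x$params$n_samples, nrow(x$sample_rho)
  ))
  ok <- x$enrichment$status == "ok"
  if (any(ok)) {
    cat(sprintf("  marginal enrichment tested on %d networks; %d with p < 0.05\n",
                sum(ok), sum(x$enrichment$p_value[ok] < 0.05)))
  }
  invisible(x)
}

#' Permutation-null calibration of the marginal-enrichment test
#'
#' Generates `n_rep` cohorts from a no-effect specification and applies the
#' marginal-enrichment test with a ranking drawn independently of the
#' mutation profiles (a permutation of the samples). Under this null the
#' top-`top_n` draw is a simple random sample of the population, so the
#' number of marginal-mutation carriers among them is exactly
#' hypergeometric; the column `alpha_star` reports, per replicate, the
#' largest attainable rejection level below `alpha` given the discreteness
#' of the test statistic. Note that randomizing mutations *without*
#' randomizing the ranking is not a null for this test: frailness itself
#' ranks marginal-mutation configurations highly, which is precisely the
#' effect the test is designed to detect.
#'
#' @param network Network for the replicate cohorts.
#' @param spec A [cohort_spec()] with `planted_effect = FALSE`.
#' @param n_rep Number of replicates.
#' @param alpha Nominal level.
#' @param top_n,min_patients,marginal_degree Test parameters.
#' @param seed Integer seed for the replicate stream.
#' @return Tibble with one row per replicate: `replicate`, `n_population`,
#'   `n_success`, `p_value`, `reject`, `alpha_star`.
#' @export
enrichment_null_calibration <- function(network, spec, n_rep = 500,
                                        alpha = 0.05, top_n = 10,
                                        min_patients = 20,
                                        marginal_degree = 1, seed = 1) {
  network <- as_frail_network(network)
  stopifnot(inherits(spec, "cohort_spec"))
  if (isTRUE(spec$planted_effect)) {
    stop("calibration requires a null (no planted effect) specification",
         call. = FALSE)
  }
  deg <- node_degrees(network)
  out <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    spec_r <- spec
    spec_r$seed <- seed + r - 1L
    muts <- make_mutation_cohort(spec_r, network)
    tab <- sample_queries(network, muts)
    tab$rho <- 0
    set.seed(seed + 5e5 + r)
    scores <- stats::setNames(sample(seq_len(nrow(tab))), tab$sample)
    res <- marginal_enrichment(network, tab, top_n, min_patients,
                               marginal_degree, scores = scores)
    res$alpha_star <- if (res$status == "ok") {
      attainable_level(res$n_population, res$n_success, res$n_drawn, alpha)
    } else NA_real_
    out[[r]] <- dplyr::mutate(res, replicate = r, .before = 1)
  }
  res <- dplyr::bind_rows(out)
  res$reject <- !is.na(res$p_value) & res$p_value < alpha
  res
}

# largest attainable rejection probability below `alpha` for the discrete
# upper-tail hypergeometric test with population n_pop, k successes, n drawn
attainable_level <- function(n_pop, k, n, alpha) {
  x <- 0:n
  tails <- stats::phyper(x - 1, k, n_pop - k, n, lower.tail = FALSE)
  ok <- tails < alpha
  if (!any(ok)) return(0)
  tails[which(ok)[1]]
}
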