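# fixtures shared across the suite; everything is generated in code

path3 <- function() {
  frail_network(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)),
                labels = c("a", "b", "c"))
}

er8 <- function(seed = 42) make_random_network("erdos_renyi", m = 8, p = 0.45,
                                               seed = seed)

er20 <- function(seed = 7) make_random_network("erdos_renyi", m = 20, p = 0.25,
                                               seed = seed)

# random query set of size q on a transition system
random_query <- function(ts, q) sample(ts$labels, q)

# reference projection computed with dense matrices only (independent of the
# rank-structured fast path)
dense_rho <- function(ts, query, epsilon = 1, coupling = "per_query") {
  proj <- project_perturbation(perturbation(ts, query, epsilon, coupling), ts)
  dlp <- delta_l_prime(proj)
  m <- ts$m
  idx <- seq(3, m + 1)
  w <- 1 / sqrt(ts$eigenvalues[2:m])
  k <- w * t(w * t(dlp[idx, idx]))
  max(svd((k + t(k)) / 2)$d)
}

# small planted / null cohorts on a preferential-attachment network
pa_network <- function(m = 30, seed = 5) {
  make_random_network("preferential_attachment", m = m, edges_per_node = 2,
                      seed = seed)
}

# breadth-first gene set of a given size around a start node
grow_set <- function(net, size, start_idx = 1) {
  ord <- igraph::bfs(net$graph, root = net$labels[start_idx],
                     order = TRUE)$order
  list(genes = igraph::V(net$graph)$name[ord[seq_len(min(size, net$m))]])
}

# clique of 6 central nodes plus 25 degree-one leaves hanging off c1:
# queries within the clique carry no marginal gene, (c1, leaf) queries do
leafy_net <- function(n_leaves = 25) {
  core <- t(utils::combn(paste0("c", 1:6), 2))
  leaves <- cbind("c1", paste0("l", seq_len(n_leaves)))
  as_frail_network(as.data.frame(rbind(core, leaves)))
}

# hand-built ranked sample table for the enrichment test: n samples, the
# first n_marginal carry a (c1, leaf) marginal query, the rest clique pairs;
# rho ranks marginal samples on top unless marginal_on_top = FALSE
synthetic_ranked_samples <- function(net, n, n_marginal,
                                     marginal_on_top = TRUE) {
  stopifnot(n_marginal <= n)
  cliq <- t(utils::combn(paste0("c", 2:6), 2))
  queries <- vector("list", n)
  for (i in seq_len(n)) {
    queries[[i]] <- if (i <= n_marginal) {
      c("c1", paste0("l", ((i - 1) %% 25) + 1))
    } else {
      cliq[((i - 1) %% nrow(cliq)) + 1, ]
    }
  }
  marg_rank <- if (marginal_on_top) rev(seq_len(n)) else seq_len(n)
  tibble::tibble(
    sample = sprintf("s%02d", seq_len(n)),
    m_star = lengths(queries),
    rho = marg_rank / n,
    null_frailness = FALSE,
    query = queries
  )
}

# preferential-attachment core with extra degree-one leaves: the shape the
# planted-effect generator needs (hubs to mutate frequently, leaves to pair
# them with)
leafy_pa <- function(m_core = 24, n_leaves = 6, seed = 5) {
  core <- make_random_network("preferential_attachment", m = m_core,
                              edges_per_node = 2, seed = seed)
  e <- igraph::as_edgelist(core$graph)
  set.seed(seed + 1000)
  leaves <- cbind(paste0("leaf", seq_len(n_leaves)),
                  sample(core$labels, n_leaves, replace = TRUE))
  as_frail_network(as.data.frame(rbind(e, leaves)))
}
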