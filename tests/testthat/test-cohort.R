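make_test_muts <- function(genes, samples, pairs) {
  a <- matrix(0, length(genes), length(samples),
              dimnames = list(genes, samples))
  for (s in names(pairs)) a[pairs[[s]], s] <- 1
  mutation_matrix(a)
}

test_that("mutation matrix validation names the offending entry", {
  a <- matrix(c(0, 1, 2, 0), 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(mutation_matrix(a), "gene 'g1', sample 's2'")
  b <- matrix(0, 2, 2, dimnames = list(c("g1", "g1"), c("s1", "s2")))
  expect_error(mutation_matrix(b), "duplicate gene")
})

test_that("pathway extraction filters by size and keeps the largest component", {
  ppi <- pa_network(m = 40, seed = 11)
  labs <- ppi$labels
  # a set whose induced subgraph splits: take 12 connected + 3 far nodes
  big <- grow_set(ppi, 12)
  sets <- list(
    keep = big$genes,
    too_small = grow_set(ppi, 5)$genes,
    unmapped = c("x1", "x2", "x3")
  )
  suppressMessages(
    res <- extract_pathway_networks(ppi, sets, min_size = 10, max_size = 30)
  )
  expect_identical(res$pathway, "keep")
  expect_gte(res$size[1], 10)
  dropped <- attr(res, "dropped")
  expect_setequal(dropped$pathway, c("too_small", "unmapped"))
  # exclusion pattern removes by name, case-insensitively
  suppressMessages(
    res2 <- extract_pathway_networks(ppi, sets, min_size = 3, max_size = 30,
                                     exclude = "KEEP")
  )
  expect_false("keep" %in% res2$pathway)
})

test_that("largest connected component is selected from a split set", {
  # path a-b-c-d-e plus far pair f-g attached at the end: the set
  # {a,b,c,f,g} induces components {a,b,c} and {f,g}
  edges <- data.frame(
    from = c("a", "b", "c", "d", "e", "f"),
    to = c("b", "c", "d", "e", "f", "g")
  )
  ppi <- as_frail_network(edges)
  suppressMessages(
    res <- extract_pathway_networks(ppi, list(s = c("a", "b", "c", "f", "g")),
                                    min_size = 2, max_size = 10)
  )
  expect_identical(res$size, 3L)
  expect_setequal(res$network[[1]]$labels, c("a", "b", "c"))
})

test_that("per-sample frailness flags null and excludes empty intersections", {
  net <- er8()
  genes <- c(net$labels, "off_network")
  muts <- make_test_muts(genes, c("s1", "s2", "s3", "s4"), list(
    s1 = c("n1", "n2"),          # two on-network mutations
    s2 = "n3",                   # single: null frailness
    s3 = "off_network",          # nothing on the network: excluded
    s4 = c("n1", "n2")           # identical profile to s1
  ))
  sr <- sample_frailness(net, muts)
  expect_setequal(sr$sample, c("s1", "s2", "s4"))
  expect_identical(sr$rho[sr$sample == "s2"], 0)
  expect_true(sr$null_frailness[sr$sample == "s2"])
  expect_gt(sr$rho[sr$sample == "s1"], 0)
  expect_identical(sr$rho[sr$sample == "s1"], sr$rho[sr$sample == "s4"])
})

test_that("pair table counts candidate pairs and supports singleton means", {
  net <- make_random_network("preferential_attachment", m = 73, seed = 3)
  expect_identical(n_candidate_pairs(net), choose(73, 2))
  expect_identical(n_candidate_pairs(net), 2628)

  small <- er8()
  muts <- make_test_muts(small$labels, c("s1", "s2", "s3"), list(
    s1 = c("n1", "n2"),
    s2 = c("n1", "n2", "n3"),
    s3 = c("n5", "n6")
  ))
  sr <- sample_frailness(small, muts)
  pt <- pair_cooccurrence(sr, small)
  expect_identical(attr(pt, "n_candidate_pairs"), choose(8, 2))
  # pair (n1, n2) in two samples; (n5, n6) in exactly one
  expect_identical(pt$n_samples[pt$gene_a == "n1" & pt$gene_b == "n2"], 2L)
  single <- pt[pt$gene_a == "n5" & pt$gene_b == "n6", ]
  expect_equal(single$mean_rho, sr$rho[sr$sample == "s3"])
  # never co-mutated pairs are absent
  expect_false(any(pt$gene_a == "n7" | pt$gene_b == "n7"))
  # every mean_rho is reproducible from the recorded query sets
  for (i in seq_len(nrow(pt))) {
    carriers <- sr[vapply(sr$query, function(g) {
      all(c(pt$gene_a[i], pt$gene_b[i]) %in% g)
    }, logical(1)), ]
    expect_equal(pt$mean_rho[i], mean(carriers$rho))
  }
})

test_that("gene frailness index satisfies its normalization contracts", {
  net <- er8()
  muts <- make_test_muts(net$labels, sprintf("s%d", 1:5), list(
    s1 = c("n1", "n2"),
    s2 = c("n1", "n3"),
    s3 = c("n2", "n3", "n4"),
    s4 = "n5",
    s5 = c("n1", "n2")
  ))
  sr <- sample_frailness(net, muts)
  gfi <- gene_frailness_index(sr, n_samples = 5)
  expect_true(all(gfi$sigma >= 0 & gfi$sigma <= 1))
  expect_true(all(gfi$rho_prime >= 0 & gfi$rho_prime <= 1))
  expect_equal(max(gfi$rho_prime), 1)
  # m* = sigma * n_samples round-trips exactly
  expect_equal(gfi$sigma * 5, gfi$m_star, tolerance = 1e-14)
  # n1 is mutated (with others) in s1, s2, s5
  expect_identical(gfi$m_star[gfi$gene == "n1"], 3L)
  # n5 appears only in a null-frailness sample: not in the index
  expect_false("n5" %in% gfi$gene)
  # a gene in exactly one non-null sample has rho_tilde equal to that rho
  expect_equal(gfi$rho_tilde[gfi$gene == "n4"],
               sr$rho[sr$sample == "s3"])
})

test_that("hypergeometric tail matches the closed form", {
  # all 10 drawn are successes among 10/20: p = 1/choose(20,10)
  p <- stats::phyper(9, 10, 10, 10, lower.tail = FALSE)
  expect_equal(p, 1 / choose(20, 10), tolerance = 1e-12)
  expect_equal(p, 5.412544e-06, tolerance = 1e-6)
  net <- leafy_net()
  sr <- synthetic_ranked_samples(net, n = 20, n_marginal = 10)
  res <- marginal_enrichment(net, sr, top_n = 10, min_patients = 20)
  expect_identical(res$n_population, 20L)
  expect_identical(res$n_success, 10L)
  expect_identical(res$x_top, 10L)
  expect_equal(res$p_value, 1 / choose(20, 10), tolerance = 1e-12)
})

test_that("degenerate enrichment cases give p = 1", {
  net <- leafy_net()
  # x = 0: no success in the top draw
  sr0 <- synthetic_ranked_samples(net, n = 20, n_marginal = 5,
                                  marginal_on_top = FALSE)
  r0 <- marginal_enrichment(net, sr0, top_n = 10, min_patients = 20)
  expect_identical(r0$x_top, 0L)
  expect_equal(r0$p_value, 1)
  # K = N: every sample carries a marginal mutation
  sr_all <- synthetic_ranked_samples(net, n = 20, n_marginal = 20)
  r_all <- marginal_enrichment(net, sr_all, top_n = 10, min_patients = 20)
  expect_equal(r_all$p_value, 1)
})

test_that("enrichment respects min_patients and breaks ties deterministically", {
  net <- leafy_net()
  sr <- synthetic_ranked_samples(net, n = 10, n_marginal = 5)
  expect_identical(
    marginal_enrichment(net, sr, min_patients = 20)$status, "skipped"
  )
  # equal rho everywhere: ranking must fall back to the sample label
  sr2 <- synthetic_ranked_samples(net, n = 25, n_marginal = 12)
  sr2$rho <- 1
  r_a <- marginal_enrichment(net, sr2, top_n = 10, min_patients = 20)
  r_b <- marginal_enrichment(net, sr2[sample(nrow(sr2)), ], top_n = 10,
                             min_patients = 20)
  expect_identical(r_a$p_value, r_b$p_value)
  expect_identical(r_a$x_top, r_b$x_top)
})

test_that("cohort driver assembles consistent tables end to end", {
  ppi <- make_leafy_network(m_core = 26, seed = 21)
  sets <- list(P1 = grow_set(ppi, 15)$genes, P2 = grow_set(ppi, 14, 7)$genes)
  spec <- cohort_spec(n_samples = 60, seed = 17, planted_effect = TRUE)
  muts <- make_mutation_cohort(spec, ppi)
  suppressMessages(
    res <- cohort_frailness(ppi, sets, muts, min_size = 5, max_size = 40,
                            min_patients = 10)
  )
  expect_s3_class(res, "cohort_frailness")
  expect_setequal(unique(res$sample_rho$pathway), c("P1", "P2"))
  expect_true(all(res$gfi$rho_prime <= 1))
  # recomputing rho from a recorded query set reproduces the table value
  row <- res$sample_rho[!res$sample_rho$null_frailness, ][1, ]
  w <- res$networks$network[[match(row$pathway, res$networks$pathway)]]
  ts <- transition_system(w)
  expect_equal(frailness(ts, row$query[[1]])$rho, row$rho, tolerance = 1e-12)
})
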