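test_that("kernel deflation zeroes the stationary-mode row and column", {
  ts <- transition_system(er8())
  proj <- project_perturbation(perturbation(ts, c("n1", "n4"), 1), ts)
  dlp <- delta_l_prime(proj)
  expect_lt(max(abs(dlp[2, ])), 1e-12)
  expect_lt(max(abs(dlp[, 2])), 1e-12)
})

test_that("rank-one (single-query) perturbations are annihilated", {
  ts <- transition_system(er8())
  for (node in c("n1", "n5", "n8")) {
    proj <- project_perturbation(perturbation(ts, node, 1), ts)
    expect_lt(max(abs(delta_l_prime(proj))), 1e-12)
    expect_identical(frailness(ts, node)$rho, 0)
    expect_identical(frailness(ts, node)$mu_analytic, Inf)
  }
})

test_that("frailness is linear in epsilon and mu_analytic is its reciprocal", {
  ts <- transition_system(er20())
  s <- c("n1", "n7", "n13")
  f1 <- frailness(ts, s, epsilon = 1)
  f2 <- frailness(ts, s, epsilon = 2)
  expect_equal(f2$rho, 2 * f1$rho, tolerance = 1e-12)
  expect_equal(f1$mu_analytic, 1 / f1$rho, tolerance = 1e-14)
  expect_equal(f2$mu_analytic, f1$mu_analytic, tolerance = 1e-12)
  dlp1 <- f1$delta_l_prime
  dlp2 <- f2$delta_l_prime
  expect_equal(dlp2, 2 * dlp1, tolerance = 1e-12)
})

test_that("complete-graph frailness has the closed form (M-1)/M", {
  for (m in c(8, 20)) {
    ts <- transition_system(make_complete_network(m))
    for (q in c(2, 3, m - 1)) {
      rho <- frailness(ts, ts$labels[seq_len(q)])$rho
      expect_equal(rho, (m - 1) / m, tolerance = 1e-10)
    }
    # critical threshold then equals the Fiedler number exactly
    expect_equal(frailness(ts, ts$labels[1:2])$mu_analytic, ts$lambda_f,
                 tolerance = 1e-10)
  }
})

test_that("adding a query node never decreases frailness (exhaustive)", {
  ts <- transition_system(er8())
  labs <- ts$labels
  pair_rho <- matrix(NA_real_, 8, 8)
  for (i in 1:7) for (j in (i + 1):8) {
    pair_rho[i, j] <- frailness(ts, labs[c(i, j)])$rho
  }
  for (i in 1:6) for (j in (i + 1):7) for (k in (j + 1):8) {
    r3 <- frailness(ts, labs[c(i, j, k)])$rho
    expect_gte(r3 + 1e-10, pair_rho[i, j])
    expect_gte(r3 + 1e-10, pair_rho[i, k])
    expect_gte(r3 + 1e-10, pair_rho[j, k])
  }
})

test_that("monotonic property holds on random draws from both graph families", {
  set.seed(2024)
  nets <- list(
    make_random_network("erdos_renyi", m = 25, p = 0.2, seed = 31),
    make_random_network("preferential_attachment", m = 25, seed = 32)
  )
  for (net in nets) {
    ts <- transition_system(net)
    for (rep in 1:100) {
      trio <- sample(ts$labels, 3)
      r2 <- frailness(ts, trio[1:2])$rho
      r3 <- frailness(ts, trio)$rho
      expect_gte(r3 + 1e-10, r2)
    }
  }
})

test_that("frobenius norm upper bounds the spectral norm", {
  ts <- transition_system(er20())
  s <- c("n2", "n9", "n16")
  expect_gte(frailness(ts, s, norm = "frobenius")$rho,
             frailness(ts, s, norm = "spectral")$rho)
})

test_that("the fast cohort path agrees with the dense projection route", {
  ts <- transition_system(er20())
  set.seed(6)
  for (q in 2:5) {
    s <- random_query(ts, q)
    fast <- frailness(ts, s)$rho
    expect_equal(fast, dense_rho(ts, s), tolerance = 1e-10)
  }
})

test_that("frailness is not determined by the query count alone", {
  ts <- transition_system(pa_network())
  set.seed(9)
  rhos <- replicate(12, frailness(ts, random_query(ts, 2))$rho)
  expect_gt(diff(range(rhos)), 1e-3)
})

test_that("network efficiency matches hand-computed values", {
  k5 <- make_complete_network(5)
  eff <- network_efficiency(k5)
  expect_equal(eff$ne, 1)
  expect_equal(eff$nne, 1)
  p3 <- path3()
  expect_equal(network_efficiency(p3)$ne, 5 / 6, tolerance = 1e-14)
  mid <- network_efficiency(p3, removed = "b")
  expect_equal(mid$ne_prime, 0)
  expect_equal(mid$nne, 0)
  expect_error(network_efficiency(p3, removed = "zzz"), "zzz")
  expect_warning(network_efficiency(p3, removed = c("a", "b")), "surviving")
})
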