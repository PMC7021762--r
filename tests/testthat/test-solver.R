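test_that("projection is zero at epsilon = 0 and linear in epsilon", {
  ts <- transition_system(er8())
  s <- c("n2", "n6")
  p0 <- project_perturbation(perturbation(ts, s, 0), ts)
  expect_true(all(p0$bar == 0))
  b1 <- project_perturbation(perturbation(ts, s, 1), ts)$bar
  b2 <- project_perturbation(perturbation(ts, s, 2), ts)$bar
  expect_equal(b2, 2 * b1, tolerance = 1e-13)
})

test_that("single-query projection is a rank-one bilinear form", {
  ts <- transition_system(er8())
  bar <- project_perturbation(perturbation(ts, "n4", 1), ts)$bar
  expect_lt(svd(bar)$d[2] / svd(bar)$d[1], 1e-12)
})

test_that("scheme converges immediately with zero forcing", {
  ts <- transition_system(er8())
  st <- iterate_scheme(project_perturbation(perturbation(ts, "n1", 0), ts), ts)
  expect_identical(st$status, "converged")
  expect_identical(st$n, 1L)
  expect_true(all(abs(st$p_hat) < 1e-14))
})

test_that("scheme fixed point matches the direct kernel oracle", {
  set.seed(101)
  n_cases <- 25
  worst <- 0
  for (i in seq_len(n_cases)) {
    net <- make_random_network("erdos_renyi", m = sample(8:16, 1), p = 0.4,
                               seed = 1000 + i)
    ts <- transition_system(net)
    s <- random_query(ts, sample(2:4, 1))
    mu <- frailness(ts, s)$mu_analytic
    eps <- stats::runif(1, 0.1, 0.8) * mu
    pert <- perturbation(ts, s, eps)
    st <- iterate_scheme(project_perturbation(pert, ts), ts)
    expect_identical(st$status, "converged")
    direct <- perturbed_stationary_direct(pert, ts)
    worst <- max(worst, max(abs(st$p_star - direct)))
  }
  expect_lt(worst, 1e-8)
})

test_that("the literal scheme variant disagrees with the oracle", {
  ts <- transition_system(er8())
  s <- c("n1", "n2", "n5")
  mu <- frailness(ts, s)$mu_analytic
  pert <- perturbation(ts, s, 0.5 * mu)
  proj <- project_perturbation(pert, ts)
  direct <- perturbed_stationary_direct(pert, ts)
  lit <- iterate_scheme(proj, ts, variant = "literal")
  expect_gt(max(abs(lit$p_star - direct)), 1e-3)
})

test_that("direct kernel solution satisfies its contracts", {
  ts <- transition_system(er20())
  set.seed(8)
  s <- random_query(ts, 3)
  pert <- perturbation(ts, s, 0.3)
  p <- perturbed_stationary_direct(pert, ts)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_true(all(p >= -1e-12))
  expect_lt(max(abs((extend_laplacian(ts) + pert$delta_l) %*% p)), 1e-10)
  expect_error(perturbed_stationary_direct(perturbation(ts, s, 0), ts),
               "degenerate")
})

test_that("small perturbations leave the network close to p_s", {
  ts <- transition_system(path3())
  pert <- perturbation(ts, "a", 1e-6)
  p <- perturbed_stationary_direct(pert, ts)
  net_part <- p[-1] / sum(p[-1])
  expect_equal(unname(net_part), unname(ts$p_s), tolerance = 1e-4)
})

test_that("convergence dichotomy follows the frailness threshold", {
  set.seed(77)
  for (i in 1:20) {
    net <- make_random_network("erdos_renyi", m = sample(8:14, 1), p = 0.4,
                               seed = 300 + i)
    ts <- transition_system(net)
    s <- random_query(ts, sample(2:4, 1))
    rho1 <- frailness(ts, s)$rho
    for (f in c(0.9, 1.1)) {
      st <- iterate_scheme(
        project_perturbation(perturbation(ts, s, f / rho1), ts), ts
      )
      expect_identical(scheme_converges(st), f < 1)
    }
  }
})

test_that("bisection threshold agrees with the analytic threshold", {
  set.seed(5)
  for (i in 1:5) {
    net <- make_random_network("erdos_renyi", m = 12, p = 0.4, seed = 600 + i)
    ts <- transition_system(net)
    s <- random_query(ts, 3)
    ct <- critical_threshold(ts, s)
    expect_identical(ct$status, "bracketed")
    expect_lt(abs(ct$mu_hat - ct$mu_analytic) / ct$mu_analytic, 0.1)
  }
})

test_that("single-node queries never diverge: bisection returns Inf", {
  ts <- transition_system(er8())
  expect_warning(ct <- critical_threshold(ts, "n3"), "no divergence")
  expect_identical(ct$mu_hat, Inf)
  expect_identical(ct$mu_analytic, Inf)
})

test_that("results are invariant under reshuffled degenerate eigenbases", {
  # K20 has an (M-1)-fold degenerate eigenvalue: any G-orthonormal rotation
  # of that eigenspace must leave rho and the stationary state unchanged
  ts <- transition_system(make_complete_network(20))
  s <- c("n3", "n11", "n17")
  rho_ref <- frailness(ts, s)$rho
  set.seed(4)
  rot <- qr.Q(qr(matrix(stats::rnorm(19^2), 19)))
  ts2 <- ts
  ts2$eigenvectors[, 2:20] <- ts$eigenvectors[, 2:20] %*% rot
  ts2$basis_ext[2:21, 3:21] <- ts2$eigenvectors[, 2:20]
  expect_equal(dense_rho(ts2, s), rho_ref, tolerance = 1e-8)
  st1 <- iterate_scheme(project_perturbation(perturbation(ts, s, 0.4), ts), ts)
  st2 <- iterate_scheme(project_perturbation(perturbation(ts2, s, 0.4), ts2), ts2)
  expect_equal(st1$p_star, st2$p_star, tolerance = 1e-8)
})

test_that("environment metric weight does not affect rho or the threshold", {
  net <- er8()
  s <- c("n2", "n7")
  rhos <- vapply(c(0.5, 1, 2), function(g0) {
    ts <- transition_system(net, env_metric = g0)
    frailness(ts, s)$rho
  }, numeric(1))
  expect_equal(rhos[1], rhos[2], tolerance = 1e-12)
  expect_equal(rhos[3], rhos[2], tolerance = 1e-12)
})

test_that("stationary currents are antisymmetric and vanish in the weak limit", {
  ts <- transition_system(er20())
  set.seed(2)
  s <- random_query(ts, 3)
  cf <- stationary_currents(perturbation(ts, s, 0.5), ts)
  expect_equal(cf$j, -t(cf$j), tolerance = 1e-15)
  weak <- stationary_currents(perturbation(ts, s, 1e-9), ts)
  expect_lt(max(abs(weak$j)), 1e-6)
  expect_lt(weak$intensity, 1e-6)
  # network-only intensity excludes the environment row/column
  cf_net <- stationary_currents(perturbation(ts, s, 0.5), ts,
                                include_environment = FALSE)
  expect_lt(cf_net$intensity, cf$intensity)
})

test_that("complete graphs stay reversible under perturbation: zero currents", {
  ts <- transition_system(make_complete_network(10))
  cf <- stationary_currents(perturbation(ts, c("n1", "n5", "n8"), 0.7), ts)
  expect_lt(max(abs(cf$j)), 1e-12)
})

test_that("intensity scan flags the critical signature near mu", {
  ts <- transition_system(er20())
  set.seed(12)
  s <- random_query(ts, 3)
  mu <- frailness(ts, s)$mu_analytic
  grid <- seq(0.2 * mu, 2 * mu, length.out = 31)
  scan <- intensity_scan(ts, s, grid)
  expect_identical(nrow(scan), 31L)
  peak <- scan$epsilon[scan$is_first_peak]
  expect_length(peak, 1)
  expect_lt(abs(peak - mu), diff(grid)[1] + 1e-12)
  # the sub-threshold branch is monotone increasing well below mu
  low <- scan$intensity[scan$epsilon < mu / 2]
  expect_true(all(diff(low) > 0))
  expect_error(intensity_scan(ts, s, c(1, 2)), "at least 3")
  expect_error(intensity_scan(ts, character(), grid), "nonempty")
})
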