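test_that("network covariance matches closed forms", {
  # no edges, unit scale
  expect_equal(network_to_covariance(gaussian_network(matrix(0, 2, 2))),
               diag(2))
  # single partial correlation r: (I - Omega)^-1 = [[1, r], [r, 1]] / (1 - r^2)
  net <- gaussian_network(matrix(c(0, 0.5, 0.5, 0), 2))
  expect_equal(network_to_covariance(net),
               matrix(c(4, 2, 2, 4) / 3, 2), tolerance = 1e-12)
})

test_that("covariance <-> network round trips on random valid models", {
  set.seed(101)
  for (p in 2:8) {
    net <- random_network(p)
    sig <- network_to_covariance(net)
    back <- covariance_to_network(sig)
    expect_lt(max(abs(back$omega - net$omega)), 1e-8)
    expect_lt(max(abs(back$delta - net$delta)), 1e-8)
    expect_lt(max(abs(network_to_covariance(back) - sig)), 1e-8)
  }
})

test_that("covariance_to_network standardizes the precision matrix", {
  # diagonal covariance: empty network, delta = marginal SDs
  net <- covariance_to_network(diag(c(1, 4, 9)))
  expect_equal(net$omega, matrix(0, 3, 3))
  expect_equal(net$delta, c(1, 2, 3))
  # bivariate: partial equals marginal correlation
  net2 <- covariance_to_network(matrix(c(1, 0.5, 0.5, 1), 2))
  expect_equal(net2$omega[1, 2], 0.5, tolerance = 1e-12)
  # chain X -> Y -> Z: the X-Z partial correlation vanishes
  # (moment oracle: y = 0.8 x + e1, z = 0.7 y + e2, unit-variance noise)
  sxx <- 1
  syy <- 0.8^2 + 1
  szz <- 0.7^2 * syy + 1
  sxy <- 0.8
  syz <- 0.7 * syy
  sxz <- 0.7 * 0.8
  sig <- matrix(c(sxx, sxy, sxz, sxy, syy, syz, sxz, syz, szz), 3)
  net3 <- covariance_to_network(sig)
  expect_lt(abs(net3$omega[1, 3]), 1e-12)
  expect_gt(net3$omega[1, 2], 0)
  expect_gt(net3$omega[2, 3], 0)
})

test_that("non-positive-definite inputs raise typed errors", {
  expect_error(covariance_to_network(matrix(c(1, 2, 2, 1), 2)),
               class = "lvgvar_not_pd")
  bad <- matrix(c(0, 0.999, 0.999, 0), 2)
  bad3 <- rbind(cbind(bad, c(0.999, 0.999)), c(0.999, 0.999, 0))
  expect_error(network_to_covariance(gaussian_network(bad3)),
               class = "lvgvar_not_pd")
})

test_that("implied marginal correlations are scale-free", {
  net <- random_network(5, seed = 7)
  expect_equal(implied_marginal_correlations(gaussian_network(matrix(0, 3, 3))),
               diag(3))
  r1 <- implied_marginal_correlations(net)
  net2 <- gaussian_network(net$omega, delta = 2 * net$delta)
  expect_equal(implied_marginal_correlations(net2), r1, tolerance = 1e-12)
  # consistent with the covariance route
  expect_equal(r1, stats::cov2cor(network_to_covariance(net)),
               tolerance = 1e-12)
})

test_that("stationary covariance solves the Lyapunov identity", {
  # B = 0 reduces to the innovation covariance
  inn <- random_network(3, seed = 3)
  ts0 <- temporal_structure(matrix(0, 3, 3), inn)
  expect_equal(stationary_covariance(ts0), network_to_covariance(inn))
  # scalar closed form sigma0 = sigma_zeta / (1 - b^2)
  ts1 <- temporal_structure(matrix(0.5, 1, 1), gaussian_network(matrix(0, 1, 1)))
  expect_equal(stationary_covariance(ts1)[1, 1], 4 / 3, tolerance = 1e-12)
  # random stable systems, iterative fixed-point recursion as oracle
  set.seed(11)
  for (i in 1:5) {
    B <- random_stable_beta(3)
    sz <- network_to_covariance(random_network(3))
    s0 <- stationary_covariance(list(beta = B, sigma_zeta = sz))
    s_it <- sz
    for (k in 1:500) s_it <- B %*% s_it %*% t(B) + sz
    expect_lt(max(abs(s0 - s_it)), 1e-8)
    expect_lt(max(abs(s0 - (B %*% s0 %*% t(B) + sz))), 1e-8)
  }
})

test_that("nonstationary coefficients are rejected", {
  expect_error(stationary_covariance(list(beta = diag(2), sigma_zeta = diag(2))),
               class = "lvgvar_not_stationary")
  expect_error(temporal_structure(diag(1.2, 2),
                                  gaussian_network(matrix(0, 2, 2))),
               class = "lvgvar_not_stationary")
})

test_that("lag covariances follow the recursion", {
  set.seed(21)
  B <- random_stable_beta(3)
  s0 <- stationary_covariance(list(beta = B,
                                   sigma_zeta = network_to_covariance(random_network(3))))
  expect_equal(lag_covariance(B, s0, 0), s0)
  expect_equal(lag_covariance(matrix(0.5, 1, 1), matrix(4 / 3, 1, 1), 1),
               matrix(2 / 3, 1, 1))
  expect_equal(lag_covariance(B, s0, 2), B %*% (B %*% s0), tolerance = 1e-12)
  expect_error(lag_covariance(B, s0, -1))
  # geometric decay for stable systems
  norms <- vapply(c(1, 5, 10, 20), function(k) max(abs(lag_covariance(B, s0, k))), 0)
  expect_true(all(diff(norms) < 0))
})

test_that("partial directed correlations standardize the temporal network", {
  inn <- random_network(3, seed = 31)
  tz <- temporal_structure(matrix(0, 3, 3), inn)
  expect_equal(standardize_temporal(tz), matrix(0, 3, 3))
  set.seed(32)
  B <- random_stable_beta(3)
  td <- temporal_structure(B, inn)
  pdc <- standardize_temporal(td)
  expect_true(all(abs(pdc) < 1))
  expect_equal(sign(pdc), sign(B))
  # scalar: monotone increasing in |b| at fixed innovation variance
  grid <- seq(0.05, 0.9, by = 0.05)
  vals <- vapply(grid, function(b) {
    standardize_temporal(temporal_structure(matrix(b, 1, 1),
                                            gaussian_network(matrix(0, 1, 1))))[1, 1]
  }, 0)
  expect_true(all(diff(vals) > 0))
})

test_that("stability check returns the spectral radius", {
  expect_equal(check_stability(diag(0.5, 2)),
               list(radius = 0.5, stable = TRUE))
  st <- check_stability(diag(2))
  expect_equal(st$radius, 1)
  expect_false(st$stable)
  expect_error(check_stability(matrix(1, 2, 3)))
  # characteristic-polynomial root oracle
  set.seed(41)
  B <- matrix(rnorm(9), 3, 3)
  cp <- c(-det(B),
          B[1, 1] * B[2, 2] + B[1, 1] * B[3, 3] + B[2, 2] * B[3, 3] -
            B[1, 2] * B[2, 1] - B[1, 3] * B[3, 1] - B[2, 3] * B[3, 2],
          -sum(diag(B)), 1)
  expect_equal(check_stability(B)$radius, max(Mod(polyroot(cp))),
               tolerance = 1e-8)
})

test_that("networks export to edge lists and labeled CSV", {
  net <- random_network(4, seed = 51)
  f1 <- tempfile(fileext = ".csv")
  el <- network_edge_list(net, f1, labels = c("a", "b", "c", "d"))
  expect_equal(nrow(el), 6)
  back <- utils::read.csv(f1)
  expect_equal(back$weight, el$weight)
  expect_equal(back$node_i, el$node_i)
  f2 <- tempfile(fileext = ".csv")
  m <- network_matrix_csv(net, f2, labels = c("a", "b", "c", "d"))
  back2 <- utils::read.csv(f2, row.names = 1)
  expect_equal(unname(as.matrix(back2)), unname(m), tolerance = 1e-12)
  unlink(c(f1, f2))
})
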