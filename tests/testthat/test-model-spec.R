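test_that("observed lag-k covariance combines loadings and residuals", {
  s <- matrix(c(1, 0.3, 0.3, 1), 2)
  expect_equal(implied_observed_lagk(diag(2), s, matrix(0, 2, 2), 0), s)
  # single factor, three unit loadings, unit latent variance, residuals 0.5
  lam <- matrix(1, 3, 1)
  out <- implied_observed_lagk(lam, matrix(1, 1, 1), rep(0.5, 3), 0)
  expect_equal(out, matrix(1, 3, 3) + diag(0.5, 3))
  # residuals only enter at lag 0
  set.seed(61)
  lam2 <- matrix(rnorm(6), 3, 2)
  sk <- crossprod(matrix(rnorm(4), 2))
  expect_equal(implied_observed_lagk(lam2, sk, rep(9, 3), 1),
               lam2 %*% sk %*% t(lam2))
  expect_error(implied_observed_lagk(lam2, diag(3), rep(0, 3), 0))
})

test_that("ts implied moments have the Toeplitz layout", {
  # no temporal or contemporaneous structure: block diagonal, zero lag block
  spec <- observed_gvar(2)
  im <- ts_implied_moments(spec)
  expect_equal(dim(im$sigma), c(4, 4))
  expect_equal(im$sigma[3:4, 1:2], matrix(0, 2, 2), ignore_attr = TRUE)
  expect_equal(im$sigma[3:4, 3:4], diag(2), ignore_attr = TRUE)
  # scalar latent: lag-0 entry sigma0 = 1/(1-b^2), lagged entry b * sigma0
  spec1 <- observed_gvar(1, beta = matrix(0.5, 1, 1))
  im1 <- ts_implied_moments(spec1)
  expect_equal(im1$sigma[2, 2], 4 / 3, tolerance = 1e-12)
  expect_equal(im1$sigma[2, 1], 2 / 3, tolerance = 1e-12)
  expect_equal(im1$mu, c(spec1$mu_star$value, spec1$measurement$tau$value))
})

test_that("ts lag-0 block is independent of the saturated lead block", {
  spec <- tiny_ts_model()
  im1 <- ts_implied_moments(spec)
  spec$star_chol$value <- spec$star_chol$value + diag(0.5, 3)
  spec$mu_star$value <- spec$mu_star$value + 1
  im2 <- ts_implied_moments(spec)
  expect_equal(im2$sigma[4:6, 4:6], im1$sigma[4:6, 4:6])
  expect_equal(im2$sigma[4:6, 1:3], im1$sigma[4:6, 1:3])
  expect_equal(im2$mu[4:6], im1$mu[4:6])
  expect_false(isTRUE(all.equal(im2$sigma[1:3, 1:3], im1$sigma[1:3, 1:3])))
})

test_that("ts implied moments match a long simulated series", {
  gen <- tiny_ts_model()
  im <- ts_implied_moments(gen)
  dat <- simulate_ts(gen, 60000, seed = 62)
  aug <- build_augmented(dat)
  emp_cov <- stats::cov(aug, use = "complete.obs")
  # current-block and lagged-block moments within sampling error
  expect_lt(max(abs(emp_cov[4:6, 4:6] - im$sigma[4:6, 4:6])), 0.06)
  expect_lt(max(abs(emp_cov[4:6, 1:3] - im$sigma[4:6, 1:3])), 0.06)
})

test_that("panel implied moments follow the block-Toeplitz structure", {
  spec <- tiny_panel_model()
  im <- panel_implied_moments(spec)
  p <- 4
  blk <- function(s, t) im$sigma[(s - 1) * p + 1:p, (t - 1) * p + 1:p]
  # diagonal blocks identical; blocks depend on |s - t| only
  expect_equal(blk(1, 1), blk(2, 2))
  expect_equal(blk(2, 2), blk(3, 3))
  expect_equal(blk(2, 1), blk(3, 2))
  expect_equal(blk(1, 2), t(blk(2, 1)))
  expect_equal(im$mu, rep(im$mu[1:p], 3))
})

test_that("degenerate panel variance components reduce the structure", {
  # no between variation and no temporal effects: zero off-diagonal blocks
  spec <- tiny_panel_model()
  spec$beta$value[] <- 0
  spec$delta_between$value[] <- 0
  spec$resid_between$value[] <- 0
  im <- panel_implied_moments(spec)
  expect_equal(im$sigma[5:8, 1:4], matrix(0, 4, 4))
  # no within variation: a pure trait model, all blocks identical
  spec2 <- tiny_panel_model()
  spec2$delta_zeta$value[] <- 0
  spec2$measurement$resid$value[] <- 0
  im2 <- panel_implied_moments(spec2)
  expect_equal(im2$sigma[5:8, 1:4], im2$sigma[1:4, 1:4])
  expect_equal(im2$sigma[9:12, 1:4], im2$sigma[1:4, 1:4])
})

test_that("panel implied moments match simulated subjects", {
  gen <- tiny_panel_model()
  im <- panel_implied_moments(gen)
  dat <- simulate_panel(gen, 100000, seed = 63)
  emp <- crossprod(sweep(dat$values, 2, colMeans(dat$values))) / nrow(dat$values)
  expect_lt(max(abs(emp - im$sigma)), 5 / sqrt(100000) * max(diag(im$sigma)) * 2)
  expect_lt(max(abs(colMeans(dat$values) - im$mu)), 0.05)
})

test_that("presence mask removes absent indicator-wave combinations", {
  spec <- tiny_panel_model()
  spec$presence[2, 3] <- FALSE
  im <- panel_implied_moments(spec)
  expect_equal(dim(im$sigma), c(11, 11))
  full <- tiny_panel_model()
  imf <- panel_implied_moments(full)
  keep <- setdiff(1:12, 10)
  expect_equal(im$sigma, imf$sigma[keep, keep])
})

test_that("parameter counting and degrees of freedom", {
  # observed GVAR with saturated networks is just identified
  spec <- observed_gvar(3)
  expect_equal(degrees_of_freedom(spec), 0)
  # fixing one edge frees one moment
  spec2 <- spec_fix_edge(spec, "temporal", 1, 2)
  expect_equal(degrees_of_freedom(spec2), 1)
  spec3 <- spec_fix_edge(spec2, "contemporaneous", 3, 2)
  expect_equal(degrees_of_freedom(spec3), 2)
  expect_equal(count_free_parameters(spec) - count_free_parameters(spec3), 2)
})

test_that("free parameters round trip through the vector interface", {
  for (spec in list(tiny_ts_model(), tiny_panel_model())) {
    v <- spec_get_free(spec)
    set.seed(64)
    v2 <- v + stats::runif(length(v), -0.01, 0.01)
    spec2 <- spec_set_free(spec, v2)
    expect_equal(unname(spec_get_free(spec2)), unname(v2))
    # symmetric components stay symmetric
    expect_equal(spec2$omega_zeta$value, t(spec2$omega_zeta$value))
  }
  expect_error(spec_set_free(tiny_ts_model(), 1:3))
})

test_that("edge fixing and freeing updates both triangles", {
  spec <- tiny_panel_model()
  spec2 <- spec_fix_edge(spec, "between", 1, 2)
  expect_equal(spec2$omega_between$value[1, 2], 0)
  expect_false(spec2$omega_between$free[2, 1])
  spec3 <- spec_free_edge(spec2, "between", 2, 1, value = 0.1)
  expect_equal(spec3$omega_between$value[1, 2], 0.1)
  expect_true(spec3$omega_between$free[1, 2])
  expect_error(spec_fix_edge(spec, "between_nonsense", 1, 2))
})

test_that("model configs round trip through YAML", {
  spec <- read_model_config(system.file("extdata", "liss_structure.yaml",
                                        package = "lvgvar"))
  expect_s3_class(spec, "panel_lvgvar_spec")
  expect_equal(spec$n_y, 22)
  expect_equal(spec$n_eta, 6)
  expect_false(spec$resid_between$free[2])  # SE2 between residual fixed
  f <- tempfile(fileext = ".yaml")
  write_model_config(spec, f)
  spec2 <- read_model_config(f)
  expect_equal(param_table(spec2), param_table(spec))
  unlink(f)
})
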