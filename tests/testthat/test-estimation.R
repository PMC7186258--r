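test_that("ML fit function matches its closed forms and the density sum", {
  p <- 4
  md <- moment_data(list(covariance = diag(p), means = rep(0, p), n = 50))
  expect_equal(ml_fit_value(md, rep(0, p), diag(p)), p)
  # saturated minimum: F = p + ln|S|
  set.seed(71)
  X <- matrix(rnorm(50 * p), 50, p) %*% chol(crossprod(matrix(rnorm(p * p), p)))
  md2 <- moment_data(X)
  expect_equal(ml_fit_value(md2, md2$mean, md2$cov),
               p + as.numeric(determinant(md2$cov)$modulus), tolerance = 1e-10)
  # F equals (-2/n) * sum of case log densities minus the normal constant
  mu <- rnorm(p)
  sig <- crossprod(matrix(rnorm(p * p), p)) + diag(p)
  L <- chol(sig)
  loglik <- sum(apply(X, 1, function(z) {
    d <- backsolve(L, z - mu, transpose = TRUE)
    -0.5 * (p * log(2 * pi) + 2 * sum(log(diag(L))) + sum(d^2))
  }))
  expect_equal(ml_fit_value(md2, mu, sig),
               -2 / 50 * loglik - p * log(2 * pi), tolerance = 1e-8)
})

test_that("FIML fit function reduces to ML and handles patterns", {
  set.seed(72)
  X <- matrix(rnorm(40 * 3), 40, 3)
  md <- moment_data(X)
  mu <- rnorm(3); sig <- crossprod(matrix(rnorm(9), 3)) + diag(3)
  expect_equal(fiml_fit_value(md, mu, sig), ml_fit_value(md, mu, sig))
  # two equal-size patterns over disjoint variable sets of an uncorrelated
  # covariance: direct evaluation oracle from the printed sum
  X2 <- matrix(rnorm(40 * 4), 40, 4)
  X2[1:20, 3:4] <- NA
  X2[21:40, 1:2] <- NA
  md2 <- moment_data(X2)
  sig4 <- diag(c(1, 2, 3, 4))
  mu4 <- c(0, 0, 0, 0)
  direct <- 0
  for (rows in list(1:20, 21:40)) {
    idx <- which(!is.na(X2[rows[1], ]))
    xi <- X2[rows, idx]
    m <- colMeans(xi)
    S <- crossprod(sweep(xi, 2, m)) / length(rows)
    si <- sig4[idx, idx]
    d <- m - mu4[idx]
    direct <- direct + length(rows) *
      (sum(diag(S %*% solve(si))) + d %*% solve(si) %*% d +
         as.numeric(determinant(si)$modulus))
  }
  expect_equal(fiml_fit_value(md2, mu4, sig4), as.numeric(direct) / 40)
  # a singleton pattern carries no covariance contribution
  X3 <- matrix(rnorm(3 * 2), 3, 2)
  X3[1, 2] <- NA
  md3 <- moment_data(X3)
  pat1 <- md3$patterns[[which(vapply(md3$patterns, function(p) p$n_i, 0) == 1)]]
  expect_equal(pat1$cov, matrix(0, 1, 1))
  hand <- (log(1) + pat1$mean^2) # trace term zero, unit sigma
  full <- md3$patterns[[which(vapply(md3$patterns, function(p) p$n_i, 0) == 2)]]
  hand_full <- 2 * (sum(diag(full$cov)) + sum(full$mean^2) + 0)
  expect_equal(fiml_fit_value(md3, c(0, 0), diag(2)),
               as.numeric(hand + hand_full) / 3)
})

test_that("FIML with artificially split complete patterns equals ML", {
  set.seed(73)
  X <- matrix(rnorm(60 * 3), 60, 3)
  md <- moment_data(X)
  split_md <- md
  mk <- function(rows) {
    m <- colMeans(X[rows, ])
    list(idx = 1:3, n_i = length(rows), mean = m,
         cov = crossprod(sweep(X[rows, ], 2, m)) / length(rows))
  }
  split_md$patterns <- list(mk(1:25), mk(26:60))
  split_md$complete <- FALSE
  mu <- rnorm(3); sig <- crossprod(matrix(rnorm(9), 3)) + diag(3)
  expect_equal(fiml_fit_value(split_md, mu, sig), ml_fit_value(md, mu, sig),
               tolerance = 1e-10)
})

test_that("all-missing rows are a data error", {
  X <- matrix(rnorm(10), 5, 2)
  X[3, ] <- NA
  expect_error(moment_data(X), class = "lvgvar_data_error")
})

test_that("EM saturated moments are the incomplete-data optimum", {
  set.seed(74)
  X <- matrix(rnorm(150 * 3), 150, 3) %*% chol(crossprod(matrix(rnorm(9), 3)) + diag(3))
  X[1:30, 1] <- NA
  X[61:90, 3] <- NA
  md <- moment_data(X)
  sat <- saturated_moments(md)
  expect_true(sat$converged)
  # no perturbation improves the FIML value
  for (i in 1:10) {
    mu2 <- sat$mu + rnorm(3, 0, 0.02)
    s2 <- sat$sigma + 0.02 * crossprod(matrix(rnorm(9), 3)) / 3
    expect_gt(fiml_fit_value(md, mu2, s2), sat$fit_value)
  }
})

test_that("fitting the generating ts model recovers its parameters", {
  gen <- tiny_ts_model()
  dat <- simulate_ts(gen, 2000, seed = 75, n_blocks = 4)
  fit <- fit_lvgvar(gen, dat)
  expect_true(fit$converged)
  est <- fit$estimates
  expect_equal(est$est[est$id == "beta[1,1]"], 0.5, tolerance = 0.1)
  expect_equal(est$est[est$id == "lambda[2,1]"], 0.8, tolerance = 0.08)
  expect_equal(est$est[est$id == "lambda[3,1]"], 0.7, tolerance = 0.08)
  expect_equal(est$est[est$id == "delta_zeta[1,1]"], 1, tolerance = 0.12)
  # estimates are within 3 reported standard errors of the truth
  truth <- c("beta[1,1]" = 0.5, "lambda[2,1]" = 0.8, "lambda[3,1]" = 0.7)
  for (id in names(truth)) {
    r <- est[est$id == id, ]
    expect_lt(abs(r$est - truth[[id]]) / r$se, 3.5)
  }
})

test_that("a saturated model fits exactly with zero degrees of freedom", {
  spec <- observed_gvar(2)
  set.seed(76)
  gen <- observed_gvar(2, beta = matrix(c(0.4, 0.1, 0, 0.3), 2),
                       omega = matrix(c(0, 0.2, 0.2, 0), 2))
  dat <- simulate_ts(gen, 300, seed = 77)
  fit <- fit_lvgvar(spec, dat)
  expect_true(fit$converged)
  expect_equal(fit$df, 0)
  expect_lt(fit$indices$chi_square, 0.02)
})

test_that("refitting from the solution reproduces the solution", {
  gen <- tiny_ts_model()
  dat <- simulate_ts(gen, 300, seed = 78)
  fit <- fit_lvgvar(gen, dat)
  fit2 <- fit_lvgvar(fit$spec, dat, start = "spec")
  expect_equal(fit2$fit_value, fit$fit_value, tolerance = 1e-7)
  expect_equal(fit2$theta, fit$theta, tolerance = 1e-3)
})

test_that("reported standard errors calibrate against replicate scatter", {
  gen <- observed_gvar(2, beta = matrix(c(0.4, 0.15, 0, 0.3), 2),
                       omega = matrix(c(0, 0.25, 0.25, 0), 2))
  ests <- ses <- matrix(NA_real_, 40, 2)
  for (r in 1:40) {
    dat <- simulate_ts(gen, 400, seed = 7000 + r)
    fit <- fit_lvgvar(observed_gvar(2), dat, indices = FALSE)
    if (!fit$converged) next
    e <- fit$estimates
    rows <- match(c("beta[1,2]", "omega_zeta[2,1]"), e$id)
    ests[r, ] <- e$est[rows]
    ses[r, ] <- e$se[rows]
  }
  ok <- stats::complete.cases(ests)
  expect_gt(sum(ok), 30)
  ratio <- apply(ests[ok, ], 2, stats::sd) / colMeans(ses[ok, ])
  expect_true(all(ratio > 0.7 & ratio < 1.4))
})

test_that("fit indices are internally consistent", {
  gen <- tiny_ts_model()
  dat <- simulate_ts(gen, 500, seed = 79)
  fit <- fit_lvgvar(gen, dat)
  ind <- fit$indices
  n <- fit$n
  expect_equal(ind$chi_square, n * (fit$fit_value - fit$saturated$fit_value),
               tolerance = 1e-8)
  expect_equal(ind$rmsea,
               sqrt(max(0, ind$chi_square - ind$df) / (ind$df * n)))
  expect_equal(ind$aic, fit$minus2_loglik + 2 * fit$k)
  expect_equal(ind$bic, fit$minus2_loglik + fit$k * log(n))
  # interval bounds invert the noncentral chi-square probabilities
  if (ind$rmsea_upper > 0) {
    lam_up <- ind$rmsea_upper^2 * ind$df * n
    expect_equal(stats::pchisq(ind$chi_square, ind$df, ncp = lam_up), 0.05,
                 tolerance = 1e-5)
  }
  expect_true(ind$cfi >= 0 && ind$cfi <= 1)
  expect_true(ind$tli >= 0 && ind$tli <= 1)
})

test_that("nested fits compare on the chi-square and information scales", {
  gen <- observed_gvar(2, beta = matrix(c(0.4, 0.15, 0, 0.3), 2),
                       omega = matrix(c(0, 0.25, 0.25, 0), 2))
  dat <- simulate_ts(gen, 400, seed = 80)
  full <- fit_lvgvar(observed_gvar(2), dat)
  nested <- fit_lvgvar(spec_fix_edge(observed_gvar(2), "temporal", 2, 1), dat)
  cmp <- compare_fits(nested, full)
  expect_equal(cmp$delta_df, 1)
  expect_equal(cmp$delta_chisq,
               nested$n * (nested$fit_value - full$fit_value))
  expect_equal(cmp$delta_chisq,
               nested$indices$chi_square - full$indices$chi_square,
               tolerance = 1e-6)
  expect_equal(cmp$delta_aic, cmp$delta_chisq - 2 * 1, tolerance = 1e-6)
  # identical fits: zero differences, p = 1
  cmp0 <- compare_fits(full, full)
  expect_equal(cmp0$delta_chisq, 0)
  expect_equal(cmp0$p, 1)
  expect_error(compare_fits(full, nested))
})
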