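# A minimal hand-built fit object is enough to exercise the pruning
# selection logic with known p-values.
fake_fit_with_p <- function(p_temporal) {
  spec <- observed_gvar(3)
  pt <- param_table(spec)
  est <- data.frame(id = pt$id, matrix = pt$matrix, row = pt$row,
                    col = pt$col, family = pt$family,
                    searchable = pt$searchable, est = 0.2, se = 0.1,
                    z = 2, p = 0.5, stringsAsFactors = FALSE)
  est <- est[pt$free, ]
  # give the three upper off-diagonal temporal edges the target p-values,
  # everything else clearly significant
  est$p[] <- 1e-6
  ids <- c("beta[1,2]", "beta[1,3]", "beta[2,3]")
  est$p[match(ids, est$id)] <- p_temporal
  structure(list(spec = spec, estimates = est, converged = TRUE),
            class = "lvgvar_fit")
}

retained <- function(spec, ids) {
  pt <- param_table(spec)
  pt$free[match(ids, pt$id)]
}

test_that("pruning applies the multiplicity adjustments stepwise", {
  ids <- c("beta[1,2]", "beta[1,3]", "beta[2,3]")
  # Holm at alpha = 0.05: 0.001 * 3 = 0.003 survives; 0.03 * 2 = 0.06 stops
  # the step-down sequence, taking 0.04 with it
  out <- prune(fake_fit_with_p(c(0.001, 0.03, 0.04)), alpha = 0.05,
               adjustment = "holm")
  expect_equal(retained(out, ids), c(TRUE, FALSE, FALSE))
  # Benjamini-Hochberg at alpha = 0.05 with thresholds (0.0167, 0.0333, 0.05):
  # 0.01 and 0.02 survive, 0.20 does not
  out2 <- prune(fake_fit_with_p(c(0.01, 0.02, 0.20)), alpha = 0.05,
                adjustment = "fdr")
  expect_equal(retained(out2, ids), c(TRUE, TRUE, FALSE))
  # all significant: specification unchanged
  out3 <- prune(fake_fit_with_p(c(1e-5, 1e-5, 1e-5)), alpha = 0.05,
                adjustment = "bonferroni")
  expect_true(all(retained(out3, ids)))
})

test_that("unadjusted pruning retains a superset of Bonferroni", {
  set.seed(81)
  for (i in 1:20) {
    p3 <- stats::runif(3, 0, 0.2)
    none <- retained(prune(fake_fit_with_p(p3), 0.05, "none"),
                     c("beta[1,2]", "beta[1,3]", "beta[2,3]"))
    bonf <- retained(prune(fake_fit_with_p(p3), 0.05, "bonferroni"),
                     c("beta[1,2]", "beta[1,3]", "beta[2,3]"))
    expect_true(all(none >= bonf))
  }
})

test_that("pruning without p-values is a search error", {
  ff <- fake_fit_with_p(c(0.5, 0.5, 0.5))
  ff$estimates$p <- NA_real_
  expect_error(prune(ff), class = "lvgvar_search_error")
})

test_that("modification indices approximate the refit chi-square drop", {
  set.seed(82)
  for (i in 1:3) {
    B <- matrix(0, 2, 2)
    diag(B) <- runif(2, 0.2, 0.4)
    B[2, 1] <- runif(1, 0.25, 0.4)  # the edge we will constrain away
    gen <- observed_gvar(2, beta = B, omega = matrix(c(0, 0.2, 0.2, 0), 2))
    dat <- simulate_ts(gen, 500, seed = 8200 + i)
    constrained <- spec_fix_edge(observed_gvar(2), "temporal", 2, 1)
    fit0 <- fit_lvgvar(constrained, dat)
    mi <- modification_indices(fit0)
    expect_equal(nrow(mi), 1)
    expect_equal(mi$id, "beta[2,1]")
    freed <- fit_lvgvar(observed_gvar(2), dat)
    delta <- fit0$indices$chi_square - freed$indices$chi_square
    expect_gt(mi$mi, 0)
    expect_lt(abs(mi$mi - delta) / delta, 0.25)
  }
})

test_that("modification indices of truly absent edges behave like chi-square(1)", {
  set.seed(83)
  mis <- numeric(25)
  gen <- observed_gvar(2, beta = diag(c(0.3, 0.3)),
                       omega = matrix(c(0, 0.2, 0.2, 0), 2))
  for (r in 1:25) {
    dat <- simulate_ts(gen, 400, seed = 8300 + r)
    fit <- fit_lvgvar(spec_fix_edge(spec_fix_edge(observed_gvar(2),
                                                  "temporal", 1, 2),
                                    "temporal", 2, 1), dat,
                      indices = FALSE)
    mi <- modification_indices(fit)
    mis[r] <- mi$mi[mi$id == "beta[1,2]"]
  }
  expect_true(mean(mis, na.rm = TRUE) > 0.4 && mean(mis, na.rm = TRUE) < 2.2)
})

test_that("a model with saturated networks has no modification indices", {
  dat <- simulate_ts(observed_gvar(2, beta = diag(0.3, 2)), 200, seed = 84)
  fit <- fit_lvgvar(observed_gvar(2), dat, indices = FALSE)
  expect_equal(nrow(modification_indices(fit)), 0)
})

test_that("stepup adds a dominant missing edge and stops", {
  B <- matrix(0, 2, 2); diag(B) <- 0.3; B[2, 1] <- 0.45
  gen <- observed_gvar(2, beta = B, omega = matrix(c(0, 0.2, 0.2, 0), 2))
  dat <- simulate_ts(gen, 1500, seed = 85)
  start <- observed_gvar(2)
  for (e in list(c(1, 2), c(2, 1))) {
    start <- spec_fix_edge(start, "temporal", e[1], e[2])
  }
  fit0 <- fit_lvgvar(start, dat)
  out <- stepup(fit0, alpha = 0.01)
  tr <- attr(out, "search_trace")
  added <- tr$id[tr$action == "add"]
  expect_true("beta[2,1]" %in% added)
  expect_false("beta[1,2]" %in% added)
  expect_lte(out$indices$bic, fit0$indices$bic)
  # saturated input returns unchanged
  sat_fit <- fit_lvgvar(observed_gvar(2), dat)
  out2 <- stepup(sat_fit, alpha = 0.01)
  expect_equal(out2$indices$bic, sat_fit$indices$bic)
  expect_equal(nrow(attr(out2, "search_trace")), 0)
})

test_that("modelsearch improves BIC monotonically and stabilizes", {
  B <- matrix(0, 2, 2); diag(B) <- 0.35; B[2, 1] <- 0.4
  gen <- observed_gvar(2, beta = B, omega = matrix(c(0, 0.3, 0.3, 0), 2))
  dat <- simulate_ts(gen, 1200, seed = 86)
  fit <- fit_lvgvar(observed_gvar(2), dat)
  out <- modelsearch(fit, alpha = 0.01)
  tr <- attr(out, "search_trace")
  if (nrow(tr) > 0) {
    expect_true(all(tr$bic_after < tr$bic_before))
    expect_true(all(diff(tr$bic_after) < 0))
  }
  expect_lte(out$indices$bic, fit$indices$bic)
  # a second pass from the optimum accepts nothing
  out2 <- modelsearch(out, alpha = 0.01)
  expect_equal(out2$indices$bic, out$indices$bic)
  expect_equal(nrow(attr(out2, "search_trace")), 0)
})

test_that("search strategies only ever touch searchable network parameters", {
  gen <- tiny_ts_model()
  dat <- simulate_ts(gen, 400, seed = 87)
  out <- search_pipeline(gen, dat, alpha = 0.05, adjustment = "none",
                         strategy = "modelsearch")
  pt_in <- param_table(gen)
  pt_out <- param_table(out$spec)
  non_search <- !pt_in$searchable
  expect_equal(pt_out$free[non_search], pt_in$free[non_search])
})

test_that("the full strategy-adjustment-alpha grid is expressible", {
  cfg <- sim_config(tiny_ts_model(), sample_sizes = 100, replicates = 1)
  expect_equal(nrow(cfg$variants), 24)
  expect_setequal(unique(cfg$variants$strategy),
                  c("prune", "stepup", "modelsearch"))
  expect_setequal(unique(cfg$variants$adjustment),
                  c("none", "bonferroni", "holm", "fdr"))
  expect_setequal(unique(cfg$variants$alpha), c(0.01, 0.05))
})
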