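# Estimation engine: compiles a specification into fast closures mapping the
# free-parameter vector to implied moments, and provides the ML/FIML
# objective, its gradient (analytic in (mu, Sigma), chained through a
# finite-difference Jacobian of the structure map), and the expected (Fisher)
# information used for standard errors and modification indices.

STABILITY_MARGIN <- 1e-6

compile_model <- function(spec) {
  pt <- param_table(spec)
  fr <- pt[pt$free, , drop = FALSE]
  mats0 <- mats_of(spec)
  meta <- meta_of(spec)
  plans <- list()
  for (nm in unique(fr$matrix)) {
    sel <- which(fr$matrix == nm)
    val <- mats0[[nm]]
    if (is.matrix(val)) {
      li <- (fr$col[sel] - 1L) * nrow(val) + fr$row[sel]
      mi <- if (symmetric_component(nm))
        (fr$row[sel] - 1L) * nrow(val) + fr$col[sel] else NULL
    } else {
      li <- fr$row[sel]; mi <- NULL
    }
    plans[[nm]] <- list(theta_pos = sel, li = li, mi = mi)
  }
  set_theta <- function(theta) {
    mats <- mats0
    for (nm in names(plans)) {
      pl <- plans[[nm]]
      v <- theta[pl$theta_pos]
      mats[[nm]][pl$li] <- v
      if (!is.null(pl$mi)) mats[[nm]][pl$mi] <- v
    }
    mats
  }
  build <- function(theta) moments_from_mats(set_theta(theta), meta)
  list(spec = spec, pt = pt, fr = fr, meta = meta, d = nrow(fr),
       set_theta = set_theta, build = build,
       jtype = jacobian_type(fr, meta),
       trans = fr$trans, theta0 = fr$value)
}

# Parameters whose derivative of (mu, Sigma) has a closed form: intercepts
# and saturated means touch only the mean; the saturated-block Cholesky and
# the residual deviations touch Sigma linearly (in simple positions). All
# remaining parameters (loadings, temporal coefficients, partials, scalings)
# enter nonlinearly and use finite differences of the structure map.
jacobian_type <- function(fr, meta) {
  tp <- rep("fd", nrow(fr))
  if (meta$kind == "ts") {
    tp[fr$matrix == "tau"] <- "mu_tau"
    tp[fr$matrix == "mu_star"] <- "mu_star"
    tp[fr$matrix == "star_chol"] <- "star"
    if (meta$resid_type == "chol") tp[fr$matrix == "resid"] <- "resid_w"
  } else {
    tp[fr$matrix == "tau"] <- "mu_tau"
    if (meta$resid_type == "chol") {
      tp[fr$matrix == "resid"] <- "resid_w"
      tp[fr$matrix == "resid_between"] <- "resid_b"
    }
  }
  tp
}

theta_to_unc <- function(theta, trans) {
  u <- theta
  u[trans == "log"] <- log(theta[trans == "log"])
  u[trans == "atanh"] <- atanh(theta[trans == "atanh"])
  u
}

unc_to_theta <- function(u, trans) {
  theta <- u
  theta[trans == "log"] <- exp(u[trans == "log"])
  theta[trans == "atanh"] <- tanh(u[trans == "atanh"])
  theta
}

# d theta / d u, elementwise
unc_jacobian <- function(theta, trans) {
  j <- rep(1, length(theta))
  j[trans == "log"] <- theta[trans == "log"]
  j[trans == "atanh"] <- 1 - theta[trans == "atanh"]^2
  j
}

# Fit value at implied moments; +Inf-like penalty when infeasible
engine_fit_value <- function(engine, theta, md) {
  mom <- engine$build(theta)
  if (is.null(mom$sigma) || mom$radius >= 1 - STABILITY_MARGIN) {
    return(list(value = 1e10 + 1e6 * max(0, mom$radius - (1 - STABILITY_MARGIN)),
                feasible = FALSE, reason = "nonstationary"))
  }
  val <- tryCatch(fiml_fit_value(md, mom$mu, mom$sigma),
                  lvgvar_not_pd = function(e) NULL)
  if (is.null(val)) {
    return(list(value = 1e10, feasible = FALSE, reason = "sigma_not_pd"))
  }
  list(value = val, feasible = TRUE, mom = mom)
}

# dF/dSigma (full symmetric convention, F the FIML fit value) and dF/dmu
fit_value_gradient_musigma <- function(md, mu, sigma) {
  p <- length(mu)
  W <- matrix(0, p, p)
  v <- numeric(p)
  for (pat in md$patterns) {
    idx <- pat$idx
    L <- chol_or_null(sigma[idx, idx, drop = FALSE], tol = 1e-14)
    if (is.null(L)) stop_not_pd("sigma (pattern submatrix)")
    Sinv <- chol2inv(L)
    d <- pat$mean - mu[idx]
    Sinv_d <- Sinv %*% d
    Wi <- Sinv - Sinv %*% pat$cov %*% Sinv - tcrossprod(Sinv_d)
    W[idx, idx] <- W[idx, idx] + pat$n_i * Wi
    v[idx] <- v[idx] + pat$n_i * (-2 * Sinv_d)
  }
  list(W = W / md$n, v = v / md$n)
}

# Jacobian of the structure map at theta (natural scale): columns are
# d mu / d theta_j stacked with vec(d Sigma / d theta_j). Closed forms are
# used where available (see jacobian_type), central finite differences of
# the structure map elsewhere.
structure_jacobian <- function(engine, theta, cols = NULL, base = NULL,
                               forward = FALSE) {
  d <- engine$d
  if (is.null(cols)) cols <- seq_len(d)
  meta <- engine$meta
  mats <- engine$set_theta(theta)
  if (is.null(base)) base <- moments_from_mats(mats, meta)
  p <- length(base$mu)
  n_y <- meta$n_y
  keep <- if (meta$kind == "panel" && !all(meta$keep)) which(meta$keep) else NULL
  full_p <- if (meta$kind == "panel") n_y * meta$n_waves else 2L * n_y
  Jmu <- matrix(0, p, length(cols))
  Jsig <- matrix(0, p * p, length(cols))
  fr <- engine$fr
  for (k in seq_along(cols)) {
    j <- cols[k]
    type <- engine$jtype[j]
    row_j <- fr$row[j]
    if (type == "mu_tau") {
      dmu <- numeric(full_p)
      if (meta$kind == "ts") dmu[n_y + row_j] <- 1
      else dmu[row_j + n_y * (seq_len(meta$n_waves) - 1L)] <- 1
      Jmu[, k] <- if (is.null(keep)) dmu else dmu[keep]
    } else if (type == "mu_star") {
      Jmu[row_j, k] <- 1
    } else if (type == "star") {
      L <- mats$star_chol
      ds <- matrix(0, full_p, full_p)
      i <- row_j; jj <- fr$col[j]
      ds[i, seq_len(n_y)] <- L[, jj]
      ds[seq_len(n_y), i] <- ds[seq_len(n_y), i] + L[, jj]
      Jsig[, k] <- as.vector(ds)
    } else if (type == "resid_w") {
      s2 <- 2 * theta[j]
      ds <- matrix(0, full_p, full_p)
      if (meta$kind == "ts") {
        ds[n_y + row_j, n_y + row_j] <- s2
      } else {
        for (w in seq_len(meta$n_waves)) {
          pos <- (w - 1L) * n_y + row_j
          ds[pos, pos] <- s2
        }
      }
      if (!is.null(keep)) ds <- ds[keep, keep, drop = FALSE]
      Jsig[, k] <- as.vector(ds)
    } else if (type == "resid_b") {
      s2 <- 2 * theta[j]
      ds <- matrix(0, full_p, full_p)
      pos <- row_j + n_y * (seq_len(meta$n_waves) - 1L)
      ds[pos, pos] <- s2
      if (!is.null(keep)) ds <- ds[keep, keep, drop = FALSE]
      Jsig[, k] <- as.vector(ds)
    } else if (forward) {
      eps <- 1e-7 * max(1, abs(theta[j]))
      tp <- theta; tp[j] <- tp[j] + eps
      mp <- engine$build(tp)
      Jmu[, k] <- (mp$mu - base$mu) / eps
      Jsig[, k] <- (as.vector(mp$sigma) - as.vector(base$sigma)) / eps
    } else {
      eps <- 1e-6 * max(1, abs(theta[j]))
      tp <- theta; tp[j] <- tp[j] + eps
      tm <- theta; tm[j] <- tm[j] - eps
      mp <- engine$build(tp)
      mm <- engine$build(tm)
      Jmu[, k] <- (mp$mu - mm$mu) / (2 * eps)
      Jsig[, k] <- (as.vector(mp$sigma) - as.vector(mm$sigma)) / (2 * eps)
    }
  }
  list(mu = Jmu, sigma = Jsig, p = p)
}

engine_gradient <- function(engine, theta, md) {
  mom <- engine$build(theta)
  if (is.null(mom$sigma) || mom$radius >= 1 - STABILITY_MARGIN) {
    return(rep(0, engine$d))
  }
  gr <- tryCatch(fit_value_gradient_musigma(md, mom$mu, mom$sigma),
                 lvgvar_not_pd = function(e) NULL)
  if (is.null(gr)) return(rep(0, engine$d))
  J <- structure_jacobian(engine, theta, base = mom, forward = TRUE)
  as.numeric(crossprod(J$mu, gr$v) + crossprod(J$sigma, as.vector(gr$W)))
}

# Expected (Fisher) information of (n/2) * F at theta for the given columns
# of the structure Jacobian (defaults to all free parameters).
expected_information <- function(engine, theta, md, J = NULL) {
  mom <- engine$build(theta)
  if (is.null(J)) J <- structure_jacobian(engine, theta)
  p <- J$p
  d <- ncol(J$mu)
  info <- matrix(0, d, d)
  for (pat in md$patterns) {
    idx <- pat$idx
    L <- chol_or_null(mom$sigma[idx, idx, drop = FALSE], tol = 1e-14)
    if (is.null(L)) stop_not_pd("sigma (pattern submatrix)")
    Sinv <- chol2inv(L)
    Jmu_i <- J$mu[idx, , drop = FALSE]
    sub_lin <- as.vector(outer(idx, (idx - 1L) * p, `+`))
    Av <- J$sigma[sub_lin, , drop = FALSE]
    pi <- length(idx)
    Mv <- matrix(0, pi * pi, d)
    for (j in seq_len(d)) {
      A <- matrix(Av[, j], pi, pi)
      Mv[, j] <- as.vector(Sinv %*% A %*% Sinv)
    }
    info <- info + pat$n_i * (crossprod(Jmu_i, Sinv %*% Jmu_i) +
                                0.5 * crossprod(Mv, Av))
  }
  (info + t(info)) / 2
}

# ---------------------------------------------------------------------------

prepare_data <- function(spec, data) {
  if (inherits(data, "lvgvar_dataset")) {
    if (data$kind == "timeseries") {
      if (!inherits(spec, "ts_lvgvar_spec")) {
        stop("time-series data require a ts_lvgvar_spec", call. = FALSE)
      }
      return(moment_data(build_augmented(data)))
    }
    if (data$kind == "panel") {
      if (!inherits(spec, "panel_lvgvar_spec")) {
        stop("panel data require a panel_lvgvar_spec", call. = FALSE)
      }
      return(moment_data(data$values))
    }
    return(moment_data(data))
  }
  if (is.matrix(data) || is.data.frame(data)) return(moment_data(as.matrix(data)))
  moment_data(data)
}

expected_dim <- function(spec) {
  if (inherits(spec, "ts_lvgvar_spec")) 2L * spec$n_y else sum(spec$presence)
}

# Default documented starting values: free loadings 1, empty networks,
# B = 0.1 I, scalings and residuals split from the saturated variances,
# means/saturated block from the (EM) saturated moments.
default_start <- function(spec, sat) {
  m <- spec$measurement
  n_y <- spec$n_y; n_e <- spec$n_eta
  spec$beta$value <- diag(0.1, n_e)
  spec$omega_zeta$value <- matrix(0, n_e, n_e)
  lam <- m$lambda$value
  lam[m$lambda$free] <- 1
  spec$measurement$lambda$value <- lam
  if (inherits(spec, "ts_lvgvar_spec")) {
    cur <- n_y + seq_len(n_y)
    vars <- diag(sat$sigma)[cur]
    spec$measurement$tau$value <- sat$mu[cur]
    spec$mu_star$value <- sat$mu[seq_len(n_y)]
    s_star <- sat$sigma[seq_len(n_y), seq_len(n_y), drop = FALSE]
    L <- chol_or_null(s_star)
    if (is.null(L)) L <- chol(s_star + diag(0.05 * mean(diag(s_star)), n_y))
    spec$star_chol$value <- t(L)
    fac_var <- factor_indicator_variance(spec, vars)
    if (any(spec$delta_zeta$free)) spec$delta_zeta$value <- sqrt(0.5 * fac_var)
    spec$measurement$resid$value <-
      start_resid(0.5 * vars, m$resid$type, m$resid$free,
                  spec$measurement$resid$value)
  } else {
    # average observed variance per indicator across present waves
    n_t <- spec$n_waves
    keep <- as.vector(spec$presence)
    full_mu <- numeric(n_y * n_t); full_var <- rep(NA_real_, n_y * n_t)
    full_mu[keep] <- sat$mu; full_var[keep] <- diag(sat$sigma)
    mu_mat <- matrix(full_mu, n_y, n_t)
    var_mat <- matrix(full_var, n_y, n_t)
    tau <- rowMeans(mu_mat * spec$presence, na.rm = TRUE)
    vars <- rowMeans(var_mat, na.rm = TRUE)
    spec$measurement$tau$value <- ifelse(is.finite(tau), tau, 0)
    vars[!is.finite(vars)] <- 1
    fac_var <- factor_indicator_variance(spec, vars)
    if (any(spec$delta_zeta$free)) spec$delta_zeta$value <- sqrt(0.25 * fac_var)
    if (any(spec$delta_between$free)) spec$delta_between$value <- sqrt(0.25 * fac_var)
    spec$measurement$resid$value <-
      start_resid(0.25 * vars, m$resid$type, m$resid$free,
                  spec$measurement$resid$value)
    spec$resid_between$value <-
      start_resid(0.25 * vars, spec$resid_between$type,
                  spec$resid_between$free, spec$resid_between$value)
  }
  spec
}

factor_indicator_variance <- function(spec, vars) {
  lam <- spec$measurement$lambda$value
  vapply(seq_len(spec$n_eta), function(f) {
    idx <- which(lam[, f] != 0 | spec$measurement$lambda$free[, f])
    mean(vars[idx])
  }, 0)
}

start_resid <- function(variances, type, free, current) {
  out <- if (type == "chol") sqrt(pmax(variances, 1e-4)) else pmax(variances, 1e-4)
  out[!free] <- current[!free]
  out
}

#' Fit an lvgvar model specification to data
#'
#' Minimizes the ML or FIML fit function over the free parameters of the
#' specification, on an unconstrained reparameterization (log scalings,
#' atanh partial correlations, unconstrained temporal coefficients with
#' stationarity enforced by penalty). Numerical failures do not raise: the
#' returned object carries `converged = FALSE` with a typed reason.
#'
#' @param spec A `ts_lvgvar_spec` or `panel_lvgvar_spec`.
#' @param data A [timeseries_dataset()] (augmented internally),
#'   [panel_dataset()], [moments_dataset()], numeric matrix, or
#'   [moment_data()].
#' @param method `"fiml"` (default; required with missing data) or `"ml"`.
#' @param start `"default"` for the documented starting values, `"spec"` to
#'   start from the values currently in `spec` (warm start).
#' @param se Compute standard errors from the expected information.
#' @param indices Compute chi-square and fit indices.
#' @param max_iter Optimizer iteration cap.
#' @param saturated Optionally, a precomputed [saturated_moments()] result
#'   for `data` (reused across refits during model search).
#' @param reltol Relative convergence tolerance on the fit value.
#' @return Object of class `lvgvar_fit`: the estimated spec, a parameter
#'   table with estimates, standard errors and p-values, fit value,
#'   log-likelihood, chi-square, degrees of freedom, fit indices, and
#'   convergence diagnostics.
#' @export
fit_lvgvar <- function(spec, data, method = c("fiml", "ml"),
                       start = c("default", "spec"), se = TRUE,
                       indices = TRUE, max_iter = 1000, saturated = NULL,
                       reltol = 1e-9) {
  method <- match.arg(method)
  start <- match.arg(start)
  md <- prepare_data(spec, data)
  pdim <- expected_dim(spec)
  if (md$p != pdim) {
    stop(sprintf("data dimension (%d) does not match the specification (%d)",
                 md$p, pdim), call. = FALSE)
  }
  if (method == "ml" && !isTRUE(md$complete)) {
    stop("ml estimation requires complete data; use method = 'fiml'", call. = FALSE)
  }
  if (is.null(saturated)) saturated <- saturated_moments(md)
  spec_default <- default_start(spec, saturated)
  spec_try <- if (start == "default") spec_default else spec
  run_opt <- function(spec0) {
    engine <- compile_model(spec0)
    theta0 <- engine$theta0 <- spec_get_free(spec0)
    trans <- engine$trans
    u0 <- theta_to_unc(theta0, trans)
    if (!engine_fit_value(engine, theta0, md)$feasible) return(NULL)
    fn <- function(u) engine_fit_value(engine, unc_to_theta(u, trans), md)$value
    gr <- function(u) {
      theta <- unc_to_theta(u, trans)
      engine_gradient(engine, theta, md) * unc_jacobian(theta, trans)
    }
    opt <- tryCatch(
      stats::optim(u0, fn, gr, method = "BFGS",
                   control = list(maxit = max_iter, reltol = reltol)),
      error = function(e) NULL)
    if (is.null(opt)) return(NULL)
    theta_hat <- unc_to_theta(opt$par, trans)
    final <- engine_fit_value(engine, theta_hat, md)
    if (!final$feasible) return(NULL)
    list(engine = engine, opt = opt, theta_hat = theta_hat, final = final,
         spec0 = spec0)
  }
  res <- run_opt(spec_try)
  # a warm start can be infeasible (or lead the optimizer astray) after
  # structural changes; fall back to the documented default starting values
  if (is.null(res) && start == "spec") res <- run_opt(spec_default)
  if (is.null(res)) {
    return(failed_fit(spec, md, method, "sigma_not_pd_or_optimizer_error"))
  }
  spec <- res$spec0
  engine <- res$engine
  opt <- res$opt
  theta_hat <- res$theta_hat
  final <- res$final
  spec_hat <- spec_set_free(spec, theta_hat)
  fr <- engine$fr
  est <- data.frame(id = fr$id, matrix = fr$matrix, row = fr$row, col = fr$col,
                    family = fr$family, searchable = fr$searchable,
                    est = theta_hat, se = NA_real_, z = NA_real_,
                    p = NA_real_, stringsAsFactors = FALSE)
  fit <- structure(list(
    spec = spec_hat, data = md, method = method,
    theta = theta_hat, engine = engine, estimates = est,
    fit_value = final$value,
    minus2_loglik = md$n * final$value + loglik_constant(md),
    n = md$n, k = engine$d,
    df = degrees_of_freedom(spec_hat),
    saturated = saturated,
    converged = opt$convergence == 0,
    diagnostics = list(optim_convergence = opt$convergence,
                       message = opt$message %||% "",
                       counts = opt$counts, reason = "ok")
  ), class = "lvgvar_fit")
  if (se) fit <- add_standard_errors(fit)
  if (indices) fit <- chi_square_and_indices(fit)
  fit
}

failed_fit <- function(spec, md, method, reason) {
  structure(list(spec = spec, data = md, method = method, theta = NULL,
                 estimates = NULL, fit_value = NA_real_,
                 minus2_loglik = NA_real_, n = md$n,
                 k = sum(param_table(spec)$free),
                 df = degrees_of_freedom(spec), saturated = NULL,
                 converged = FALSE,
                 diagnostics = list(reason = reason)),
            class = "lvgvar_fit")
}

add_standard_errors <- function(fit) {
  info <- tryCatch(
    expected_information(fit$engine, fit$theta, fit$data),
    error = function(e) NULL)
  fit$information <- info
  acov <- if (!is.null(info)) tryCatch(solve(info), error = function(e) NULL)
          else NULL
  if (is.null(acov) || any(!is.finite(diag(acov))) || any(diag(acov) < 0)) {
    fit$diagnostics$se <- "information_singular"
    return(fit)
  }
  fit$acov <- acov
  fit$estimates$se <- sqrt(diag(acov))
  fit$estimates$z <- fit$estimates$est / fit$estimates$se
  fit$estimates$p <- 2 * stats::pnorm(-abs(fit$estimates$z))
  fit$diagnostics$se <- "ok"
  fit
}

#' Standard errors and p-values of a fitted model
#'
#' Standard errors come from the inverse expected information of the
#' objective at the optimum; p-values are two-sided normal. Fixed parameters
#' have no entries.
#'
#' @param fit A converged `lvgvar_fit`.
#' @return Data frame with one row per free parameter.
#' @export
standard_errors <- function(fit) {
  stopifnot(inherits(fit, "lvgvar_fit"))
  if (!isTRUE(fit$converged)) stop("fit did not converge", call. = FALSE)
  if (is.null(fit$estimates$se) || all(is.na(fit$estimates$se))) {
    stop("standard errors unavailable (singular information)", call. = FALSE)
  }
  fit$estimates[, c("id", "matrix", "row", "col", "family", "searchable",
                    "est", "se", "z", "p")]
}

#' Chi-square and fit indices
#'
#' Fills the chi-square (\eqn{n (\hat F_{model} - \hat F_{saturated})}),
#' RMSEA with its noncentral confidence interval, AIC/BIC, and incremental
#' indices (NFI, PNFI, TLI/NNFI, RFI, IFI, RNI, CFI) against an independence
#' baseline with free means and variances and zero covariances. With zero
#' degrees of freedom the incremental indices are reported absent.
#'
#' @param fit A converged `lvgvar_fit`.
#' @param ci_quantiles Noncentral chi-square quantiles used for the RMSEA
#'   interval bounds.
#' @return The fit with an `indices` list filled in.
#' @export
chi_square_and_indices <- function(fit, ci_quantiles = c(0.95, 0.05)) {
  stopifnot(inherits(fit, "lvgvar_fit"))
  if (!isTRUE(fit$converged)) return(fit)
  md <- fit$data
  n <- md$n
  f_sat <- fit$saturated$fit_value
  chisq <- max(0, n * (fit$fit_value - f_sat))
  df <- fit$df
  p_chisq <- if (df > 0) stats::pchisq(chisq, df, lower.tail = FALSE) else NA_real_
  bm <- baseline_moments(md)
  f_base <- fiml_fit_value(md, bm$mu, bm$sigma)
  chisq_base <- max(0, n * (f_base - f_sat))
  p <- md$p
  df_base <- (p + p * (p + 1) / 2) - 2 * p
  rmsea <- if (df > 0) sqrt(max(0, chisq - df) / (df * n)) else NA_real_
  ci <- if (df > 0) rmsea_interval(chisq, df, n, ci_quantiles) else c(NA, NA)
  k <- fit$k
  aic <- fit$minus2_loglik + 2 * k
  bic <- fit$minus2_loglik + k * log(n)
  inc <- if (df > 0 && chisq_base > 0 && df_base > 0) {
    tb_db <- chisq_base / df_base
    t_d <- chisq / df
    clamp01 <- function(x) min(1, max(0, x))
    list(nfi = (chisq_base - chisq) / chisq_base,
         pnfi = (df / df_base) * (chisq_base - chisq) / chisq_base,
         tli = clamp01((tb_db - t_d) / (tb_db - 1)),
         nnfi = clamp01((tb_db - t_d) / (tb_db - 1)),
         rfi = (tb_db - t_d) / tb_db,
         ifi = (chisq_base - chisq) / (chisq_base - df),
         rni = ((chisq_base - df_base) - (chisq - df)) / (chisq_base - df_base),
         cfi = clamp01(1 - max(0, chisq - df) /
                         max(0, chisq - df, chisq_base - df_base)))
  } else {
    list(nfi = NA_real_, pnfi = NA_real_, tli = NA_real_, nnfi = NA_real_,
         rfi = NA_real_, ifi = NA_real_, rni = NA_real_, cfi = NA_real_)
  }
  fit$indices <- c(list(chi_square = chisq, df = df, p_value = p_chisq,
                        rmsea = rmsea, rmsea_lower = ci[1], rmsea_upper = ci[2],
                        aic = aic, bic = bic,
                        chi_square_baseline = chisq_base,
                        df_baseline = df_base), inc)
  fit
}

# RMSEA interval bounds from noncentral chi-square root finding:
# the bound at quantile q solves pchisq(T, df, ncp) = q.
rmsea_interval <- function(chisq, df, n, quantiles = c(0.95, 0.05)) {
  bound <- function(q) {
    if (stats::pchisq(chisq, df, ncp = 0) < q) return(0)
    upper <- max(chisq * 2, df * 2, 10)
    while (stats::pchisq(chisq, df, ncp = upper) > q) upper <- upper * 2
    lam <- stats::uniroot(function(l) stats::pchisq(chisq, df, ncp = l) - q,
                          c(0, upper), tol = 1e-8)$root
    sqrt(lam / (df * n))
  }
  c(bound(quantiles[1]), bound(quantiles[2]))
}

#' Compare two nested fits
#'
#' Likelihood-ratio difference test plus AIC/BIC differences. Both fits must
#' be on the same data and the nested model must have no free parameters
#' beyond the full model's.
#'
#' @param fit_nested,fit_full Converged `lvgvar_fit` objects.
#' @return List with `delta_chisq`, `delta_df`, `p`, `delta_aic`,
#'   `delta_bic` (nested minus full).
#' @export
compare_fits <- function(fit_nested, fit_full) {
  stopifnot(inherits(fit_nested, "lvgvar_fit"), inherits(fit_full, "lvgvar_fit"))
  if (fit_nested$n != fit_full$n || fit_nested$data$p != fit_full$data$p) {
    stop("fits are not on the same data", call. = FALSE)
  }
  if (fit_nested$k > fit_full$k) {
    stop("first argument must be the nested (more constrained) model", call. = FALSE)
  }
  delta_chisq <- fit_nested$n * (fit_nested$fit_value - fit_full$fit_value)
  delta_df <- fit_full$k - fit_nested$k
  p <- if (delta_df > 0) {
    stats::pchisq(max(0, delta_chisq), delta_df, lower.tail = FALSE)
  } else if (abs(delta_chisq) < 1e-8) 1 else NA_real_
  list(delta_chisq = delta_chisq, delta_df = delta_df, p = p,
       delta_aic = (fit_nested$indices$aic %||% NA_real_) -
         (fit_full$indices$aic %||% NA_real_),
       delta_bic = (fit_nested$indices$bic %||% NA_real_) -
         (fit_full$indices$bic %||% NA_real_))
}

#' @export
print.lvgvar_fit <- function(x, ...) {
  cat("lvgvar model fit (", class(x$spec)[1], ", ", x$method, ")\n", sep = "")
  if (!isTRUE(x$converged)) {
    cat("  NOT converged:", x$diagnostics$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf("  free parameters: %d   df: %d   n: %d\n", x$k, x$df, x$n))
  if (!is.null(x$indices)) {
    with(x$indices, {
      cat(sprintf("  chi-square(%d) = %.2f, p = %s\n", df, chi_square,
                  format.pval(p_value, digits = 3)))
      cat(sprintf("  RMSEA = %.3f (%.3f - %.3f)   CFI = %.3f   TLI = %.3f\n",
                  rmsea, rmsea_lower, rmsea_upper, cfi, tli))
      cat(sprintf("  AIC = %.2f   BIC = %.2f\n", aic, bic))
    })
  }
  invisible(x)
}
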