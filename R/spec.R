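#' Measurement model for a set of indicators
#'
#' Linear factor measurement model \eqn{y = \tau + \Lambda \eta + \varepsilon}.
#' The loading pattern is given as a numeric matrix: zero entries are
#' structural zeros, nonzero entries are loadings (used as starting/current
#' values). Identification follows one of two schemes: `"loadings"` fixes the
#' first nonzero loading of every factor to its given value (typically 1) and
#' leaves latent scalings free; `"scaling"` frees all pattern loadings and
#' fixes the latent scaling parameters to one.
#'
#' @param lambda Numeric loading pattern matrix, indicators in rows, latent
#'   variables in columns. Every column needs at least one nonzero entry.
#' @param tau Intercept vector (defaults to zeros, free).
#' @param residual Residual variance parameterization: `"chol"` (default)
#'   estimates standard-deviation-scale parameters whose square is the
#'   variance, keeping variances nonnegative; `"variance"` estimates the
#'   variances directly (kept positive on a log scale during optimization).
#' @param residual_values Starting residual variances (default 1).
#' @param identification `"loadings"` or `"scaling"`, see above.
#' @param lambda_free Optional logical matrix overriding the free pattern for
#'   the loadings.
#' @param residual_free Optional logical vector fixing selected residual
#'   variances (e.g. all `FALSE` at zero for an observed-variable model).
#' @return Object of class `measurement_model`.
#' @export
measurement_model <- function(lambda, tau = NULL,
                              residual = c("chol", "variance"),
                              residual_values = NULL,
                              identification = c("loadings", "scaling"),
                              lambda_free = NULL, residual_free = NULL) {
  lambda <- as.matrix(lambda)
  residual <- match.arg(residual)
  identification <- match.arg(identification)
  n_y <- nrow(lambda)
  n_e <- ncol(lambda)
  if (any(colSums(lambda != 0) == 0)) {
    stop("every latent variable needs at least one nonzero loading", call. = FALSE)
  }
  if (is.null(lambda_free)) {
    lambda_free <- lambda != 0
    if (identification == "loadings") {
      for (f in seq_len(n_e)) {
        first <- which(lambda[, f] != 0)[1]
        lambda_free[first, f] <- FALSE
      }
    }
  } else {
    lambda_free <- as.matrix(lambda_free)
  }
  if (is.null(tau)) tau <- rep(0, n_y)
  if (is.null(residual_values)) residual_values <- rep(1, n_y)
  resid_par <- if (residual == "chol") sqrt(residual_values) else residual_values
  if (is.null(residual_free)) residual_free <- rep(TRUE, n_y)
  structure(list(
    lambda = list(value = lambda, free = lambda_free),
    tau = list(value = as.numeric(tau), free = rep(TRUE, n_y)),
    resid = list(type = residual, value = as.numeric(resid_par),
                 free = residual_free),
    identification = identification,
    n_y = n_y, n_eta = n_e,
    indicator_labels = rownames(lambda) %||% paste0("y", seq_len(n_y)),
    latent_labels = colnames(lambda) %||% paste0("eta", seq_len(n_e))
  ), class = "measurement_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Observed-variable measurement model
#'
#' The identity measurement model (loadings fixed to an identity matrix,
#' residual variances fixed to zero) under which the latent GVAR reduces to
#' a GVAR between the observed variables themselves.
#'
#' @param labels Variable labels (or a count).
#' @return A [measurement_model()].
#' @export
observed_measurement <- function(labels) {
  if (is.numeric(labels) && length(labels) == 1) {
    labels <- paste0("y", seq_len(labels))
  }
  p <- length(labels)
  lam <- diag(p)
  dimnames(lam) <- list(labels, labels)
  measurement_model(lam, residual_values = rep(0, p),
                    lambda_free = matrix(FALSE, p, p),
                    residual_free = rep(FALSE, p))
}

resid_variances <- function(resid) {
  if (resid$type == "chol") resid$value^2 else resid$value
}

# Shared constructor pieces for the latent GVAR blocks of a spec.
gvar_block <- function(n_e, beta = NULL, omega = NULL, delta = NULL,
                       delta_free = TRUE) {
  if (is.null(beta)) beta <- matrix(0, n_e, n_e)
  if (is.null(omega)) omega <- matrix(0, n_e, n_e)
  if (is.null(delta)) delta <- rep(1, n_e)
  list(beta = list(value = as.matrix(beta), free = matrix(TRUE, n_e, n_e)),
       omega = list(value = as.matrix(omega), free = matrix(TRUE, n_e, n_e)),
       delta = list(value = as.numeric(delta), free = rep(delta_free, n_e)))
}

#' Model specification for the single-subject latent GVAR (ts-lvgvar)
#'
#' Assembles the measurement model, the latent temporal/contemporaneous
#' structure, and the saturated lead block used in the Toeplitz estimation
#' device. Latent means are fixed to zero (single-subject identification), so
#' the stacked mean is \eqn{(\mu^*, \tau)}. The stacked covariance of the
#' paired vector \eqn{(y_t, y_{t+1})} has a saturated upper-left block
#' \eqn{\Sigma^*} with its own parameters (so duplicating the data when
#' augmenting does not distort the degrees of freedom), the model-implied
#' lag-0 block in the lower right, and the lag-1 block off the diagonal.
#'
#' @param measurement A [measurement_model()].
#' @param beta,omega_zeta,delta_zeta Optional starting values for the latent
#'   temporal coefficients, contemporaneous partial correlations, and
#'   contemporaneous scalings (defaults: zero matrices, unit scalings; all
#'   temporal and contemporaneous edges free).
#' @return Object of class `ts_lvgvar_spec`.
#' @export
ts_model_spec <- function(measurement, beta = NULL, omega_zeta = NULL,
                          delta_zeta = NULL) {
  stopifnot(inherits(measurement, "measurement_model"))
  n_e <- measurement$n_eta
  n_y <- measurement$n_y
  blk <- gvar_block(n_e, beta, omega_zeta, delta_zeta,
                    delta_free = measurement$identification == "loadings")
  Lfree <- matrix(FALSE, n_y, n_y)
  Lfree[lower.tri(Lfree, diag = TRUE)] <- TRUE
  structure(list(
    measurement = measurement,
    beta = blk$beta, omega_zeta = blk$omega, delta_zeta = blk$delta,
    mu_star = list(value = rep(0, n_y), free = rep(TRUE, n_y)),
    star_chol = list(value = diag(n_y), free = Lfree),
    n_y = n_y, n_eta = n_e
  ), class = c("ts_lvgvar_spec", "lvgvar_spec"))
}

#' Model specification for the panel latent GVAR (panel-lvgvar)
#'
#' The measurement model (loadings and intercepts) is shared between the
#' within- and between-subject levels (measurement invariance). The within
#' level carries the fixed-effect temporal and contemporaneous networks plus
#' within-subject residual variances; the between level carries a GGM on the
#' latent subject means plus between-subject residual variances. Latent
#' stationary means are fixed to zero by default (the intercepts absorb
#' them). At least three waves are required.
#'
#' @param measurement A [measurement_model()].
#' @param n_waves Number of measurement waves (>= 3).
#' @param beta,omega_zeta,delta_zeta Starting values for the within-level
#'   temporal/contemporaneous structure (defaults as in [ts_model_spec()]).
#' @param omega_between,delta_between Starting values for the between-subject
#'   latent network.
#' @param between_residual_values Starting between-subject residual variances.
#' @param fix_between_residual Optional indicator indices whose between-level
#'   residual variance is fixed to zero (the handling used when an estimate
#'   hits the zero boundary).
#' @param presence Optional logical indicator-by-wave matrix; variables absent
#'   at a wave are cut from the stacked mean and covariance.
#' @return Object of class `panel_lvgvar_spec`.
#' @export
panel_model_spec <- function(measurement, n_waves = 3, beta = NULL,
                             omega_zeta = NULL, delta_zeta = NULL,
                             omega_between = NULL, delta_between = NULL,
                             between_residual_values = NULL,
                             fix_between_residual = integer(0),
                             presence = NULL) {
  stopifnot(inherits(measurement, "measurement_model"))
  if (n_waves < 3) stop("panel-lvgvar requires at least three waves", call. = FALSE)
  n_e <- measurement$n_eta
  n_y <- measurement$n_y
  blk <- gvar_block(n_e, beta, omega_zeta, delta_zeta,
                    delta_free = measurement$identification == "loadings")
  if (is.null(omega_between)) omega_between <- matrix(0, n_e, n_e)
  if (is.null(delta_between)) delta_between <- rep(1, n_e)
  if (is.null(between_residual_values)) between_residual_values <- rep(1, n_y)
  rb_par <- if (measurement$resid$type == "chol") sqrt(between_residual_values)
            else between_residual_values
  rb_free <- rep(TRUE, n_y)
  if (length(fix_between_residual)) {
    rb_par[fix_between_residual] <- 0
    rb_free[fix_between_residual] <- FALSE
  }
  if (is.null(presence)) presence <- matrix(TRUE, n_y, n_waves)
  structure(list(
    measurement = measurement,
    beta = blk$beta, omega_zeta = blk$omega, delta_zeta = blk$delta,
    omega_between = list(value = as.matrix(omega_between),
                         free = matrix(TRUE, n_e, n_e)),
    delta_between = list(value = as.numeric(delta_between),
                         free = rep(measurement$identification == "loadings", n_e)),
    resid_between = list(type = measurement$resid$type, value = rb_par,
                         free = rb_free),
    n_waves = n_waves, presence = as.matrix(presence),
    n_y = n_y, n_eta = n_e
  ), class = c("panel_lvgvar_spec", "lvgvar_spec"))
}

# ---------------------------------------------------------------------------
# Parameter table: one row per model parameter (free or fixed), in a fixed
# order so that a free-parameter vector has a stable layout.

lower_pairs <- function(p) {
  idx <- which(lower.tri(matrix(0, p, p)), arr.ind = TRUE)
  idx[order(idx[, 2], idx[, 1]), , drop = FALSE]
}

pt_block <- function(mat_name, comp, rows, cols, searchable = FALSE,
                     family = NA_character_, trans = "none") {
  n <- length(rows)
  data.frame(matrix = rep(mat_name, n), row = rows, col = cols,
             value = comp$value[cbind(rows, cols)],
             free = comp$free[cbind(rows, cols)],
             searchable = rep(searchable, n), family = rep(family, n),
             trans = rep(trans, n), stringsAsFactors = FALSE)
}

pt_vector <- function(mat_name, comp, trans = "none") {
  n <- length(comp$value)
  data.frame(matrix = rep(mat_name, n), row = seq_len(n), col = rep(1L, n),
             value = comp$value, free = comp$free,
             searchable = rep(FALSE, n), family = rep(NA_character_, n),
             trans = rep(trans, n), stringsAsFactors = FALSE)
}

#' Parameter table of a model specification
#'
#' One row per model parameter (free and fixed), with the matrix it lives in,
#' its indices, current value, free/fixed status, whether it is a searchable
#' network parameter, and its network family (`temporal`, `contemporaneous`,
#' `between`).
#'
#' @param spec A `ts_lvgvar_spec` or `panel_lvgvar_spec`.
#' @return A data frame.
#' @export
param_table <- function(spec) {
  m <- spec$measurement
  n_y <- spec$n_y; n_e <- spec$n_eta
  lam_idx <- which(m$lambda$value != 0 | m$lambda$free, arr.ind = TRUE)
  lam_idx <- lam_idx[order(lam_idx[, 2], lam_idx[, 1]), , drop = FALSE]
  out <- list(
    pt_block("lambda", m$lambda, lam_idx[, 1], lam_idx[, 2]),
    pt_vector("tau", m$tau),
    pt_block("beta", spec$beta,
             rep(seq_len(n_e), n_e), rep(seq_len(n_e), each = n_e),
             searchable = TRUE, family = "temporal"),
    {
      lp <- lower_pairs(n_e)
      pt_block("omega_zeta", spec$omega_zeta, lp[, 1], lp[, 2],
               searchable = TRUE, family = "contemporaneous", trans = "atanh")
    },
    pt_vector("delta_zeta", spec$delta_zeta, trans = "log"),
    pt_vector("resid",
              list(value = spec$measurement$resid$value,
                   free = spec$measurement$resid$free),
              trans = if (m$resid$type == "variance") "log" else "none")
  )
  if (inherits(spec, "ts_lvgvar_spec")) {
    Lidx <- which(lower.tri(matrix(0, n_y, n_y), diag = TRUE), arr.ind = TRUE)
    Lidx <- Lidx[order(Lidx[, 2], Lidx[, 1]), , drop = FALSE]
    sc <- pt_block("star_chol", spec$star_chol, Lidx[, 1], Lidx[, 2])
    sc$trans[sc$row == sc$col] <- "log"
    out <- c(out, list(pt_vector("mu_star", spec$mu_star), sc))
  } else {
    lp <- lower_pairs(n_e)
    out <- c(out, list(
      pt_block("omega_between", spec$omega_between, lp[, 1], lp[, 2],
               searchable = TRUE, family = "between", trans = "atanh"),
      pt_vector("delta_between", spec$delta_between, trans = "log"),
      pt_vector("resid_between",
                list(value = spec$resid_between$value,
                     free = spec$resid_between$free),
                trans = if (m$resid$type == "variance") "log" else "none")
    ))
  }
  pt <- do.call(rbind, out)
  pt$id <- paste0(pt$matrix, "[", pt$row, ",", pt$col, "]")
  rownames(pt) <- NULL
  pt
}

# Access the component list holding a parameter matrix; measurement-owned
# components live inside spec$measurement.
spec_component <- function(spec, name) {
  switch(name,
         lambda = spec$measurement$lambda,
         tau = spec$measurement$tau,
         resid = spec$measurement$resid,
         spec[[name]])
}

`spec_component<-` <- function(spec, name, value) {
  if (name %in% c("lambda", "tau", "resid")) spec$measurement[[name]] <- value
  else spec[[name]] <- value
  spec
}

symmetric_component <- function(name) {
  name %in% c("omega_zeta", "omega_between")
}

#' Extract the free-parameter vector of a specification
#' @param spec A model specification.
#' @return Named numeric vector of free parameters (natural scale).
#' @export
spec_get_free <- function(spec) {
  pt <- param_table(spec)
  stats::setNames(pt$value[pt$free], pt$id[pt$free])
}

#' Insert a free-parameter vector into a specification
#' @param spec A model specification.
#' @param values Numeric vector in the order of [spec_get_free()].
#' @return The updated specification.
#' @export
spec_set_free <- function(spec, values) {
  pt <- param_table(spec)
  fr <- pt[pt$free, ]
  if (length(values) != nrow(fr)) stop("wrong parameter vector length", call. = FALSE)
  for (nm in unique(fr$matrix)) {
    comp <- spec_component(spec, nm)
    sel <- fr$matrix == nm
    if (is.matrix(comp$value)) {
      comp$value[cbind(fr$row[sel], fr$col[sel])] <- values[sel]
      if (symmetric_component(nm)) {
        comp$value[cbind(fr$col[sel], fr$row[sel])] <- values[sel]
      }
    } else {
      comp$value[fr$row[sel]] <- values[sel]
    }
    spec_component(spec, nm) <- comp
  }
  spec
}

#' Fix or free a searchable network edge
#'
#' @param spec A model specification.
#' @param family `"temporal"`, `"contemporaneous"` or `"between"`.
#' @param i,j Edge indices (for the symmetric families the order is
#'   irrelevant; for `"temporal"`, `i` is the target and `j` the source).
#' @param value Value to set when fixing (default 0) or starting value when
#'   freeing.
#' @return The updated specification.
#' @export
spec_fix_edge <- function(spec, family, i, j, value = 0) {
  edge_update(spec, family, i, j, free = FALSE, value = value)
}

#' @rdname spec_fix_edge
#' @export
spec_free_edge <- function(spec, family, i, j, value = 0) {
  edge_update(spec, family, i, j, free = TRUE, value = value)
}

edge_update <- function(spec, family, i, j, free, value) {
  nm <- switch(family, temporal = "beta", contemporaneous = "omega_zeta",
               between = "omega_between",
               stop("unknown edge family: ", family, call. = FALSE))
  comp <- spec_component(spec, nm)
  if (is.null(comp)) stop("family not present in this specification", call. = FALSE)
  comp$value[i, j] <- value
  comp$free[i, j] <- free
  if (nm != "beta") {
    comp$value[j, i] <- value
    comp$free[j, i] <- free
  }
  spec_component(spec, nm) <- comp
  spec
}

# ---------------------------------------------------------------------------
# Implied moment structures

#' Observed-variable lag-k covariance implied by a measurement model
#'
#' \eqn{\Lambda \Sigma_k \Lambda^\top + \Sigma^{(\varepsilon)}} at lag 0 and
#' \eqn{\Lambda \Sigma_k \Lambda^\top} at positive lags (residuals are not
#' autocorrelated).
#'
#' @param measurement A [measurement_model()] or a loading matrix.
#' @param latent_lagk Latent lag-k covariance matrix.
#' @param residual_cov Residual covariance matrix (or variance vector).
#' @param k Lag.
#' @return Implied observed lag-k covariance.
#' @export
implied_observed_lagk <- function(measurement, latent_lagk, residual_cov, k) {
  lambda <- if (inherits(measurement, "measurement_model"))
    measurement$lambda$value else as.matrix(measurement)
  latent_lagk <- as.matrix(latent_lagk)
  if (ncol(lambda) != nrow(latent_lagk)) stop("nonconformable dimensions", call. = FALSE)
  out <- lambda %*% latent_lagk %*% t(lambda)
  if (k == 0) {
    if (is.matrix(residual_cov)) out <- out + residual_cov
    else out <- out + diag(as.numeric(residual_cov), nrow(out))
  }
  out
}

# Extract the raw value matrices and structural metadata of a spec, the form
# consumed by the moment builders (and, parameter-by-parameter, by the
# estimation engine's finite-difference Jacobian).
mats_of <- function(spec) {
  m <- spec$measurement
  mats <- list(lambda = m$lambda$value, tau = m$tau$value,
               beta = spec$beta$value, omega_zeta = spec$omega_zeta$value,
               delta_zeta = spec$delta_zeta$value, resid = m$resid$value)
  if (inherits(spec, "ts_lvgvar_spec")) {
    mats$mu_star <- spec$mu_star$value
    mats$star_chol <- spec$star_chol$value
  } else {
    mats$omega_between <- spec$omega_between$value
    mats$delta_between <- spec$delta_between$value
    mats$resid_between <- spec$resid_between$value
  }
  mats
}

meta_of <- function(spec) {
  list(kind = if (inherits(spec, "ts_lvgvar_spec")) "ts" else "panel",
       n_y = spec$n_y, n_eta = spec$n_eta,
       n_waves = spec$n_waves %||% NA_integer_,
       resid_type = spec$measurement$resid$type,
       keep = if (inherits(spec, "panel_lvgvar_spec")) as.vector(spec$presence)
              else NULL)
}

var_of_resid <- function(values, type) if (type == "chol") values^2 else values

ggm_covariance_raw <- function(omega, delta) {
  p <- length(delta)
  K <- solve(diag(p) - omega)
  sz <- delta * K * rep(delta, each = p)
  (sz + t(sz)) / 2
}

# Core moment builder. Returns list(mu, sigma, radius); never errors on a
# non-stationary beta (callers decide whether that is an error or an
# infeasible point to be penalized) unless the Kronecker system is singular.
moments_from_mats <- function(mats, meta) {
  lambda <- mats$lambda
  theta_w <- var_of_resid(mats$resid, meta$resid_type)
  B <- mats$beta
  radius <- max(Mod(eigen(B, only.values = TRUE)$values))
  if (radius >= 1) return(list(mu = NULL, sigma = NULL, radius = radius))
  sz <- ggm_covariance_raw(mats$omega_zeta, mats$delta_zeta)
  s0_eta <- lyapunov_solve(B, sz)
  n_y <- meta$n_y
  if (meta$kind == "ts") {
    s0_y <- lambda %*% s0_eta %*% t(lambda) + diag(theta_w, n_y)
    s1_y <- lambda %*% (B %*% s0_eta) %*% t(lambda)
    s_star <- tcrossprod(mats$star_chol)
    sigma <- rbind(cbind(s_star, t(s1_y)), cbind(s1_y, s0_y))
    mu <- c(mats$mu_star, mats$tau)
  } else {
    n_t <- meta$n_waves
    sb_eta <- ggm_covariance_raw(mats$omega_between, mats$delta_between)
    theta_b <- var_of_resid(mats$resid_between, meta$resid_type)
    sb_y <- lambda %*% sb_eta %*% t(lambda) + diag(theta_b, n_y)
    lag_y <- vector("list", n_t)
    sk <- s0_eta
    for (k in 0:(n_t - 1)) {
      blk <- lambda %*% sk %*% t(lambda)
      if (k == 0) blk <- blk + diag(theta_w, n_y)
      lag_y[[k + 1]] <- blk
      sk <- B %*% sk
    }
    sigma <- matrix(0, n_t * n_y, n_t * n_y)
    for (s in seq_len(n_t)) for (t in seq_len(n_t)) {
      rows <- (s - 1) * n_y + seq_len(n_y)
      cols <- (t - 1) * n_y + seq_len(n_y)
      sigma[rows, cols] <- sb_y +
        if (s >= t) lag_y[[s - t + 1]] else t(lag_y[[t - s + 1]])
    }
    mu <- rep(mats$tau, n_t)
    if (!all(meta$keep)) {
      sigma <- sigma[meta$keep, meta$keep, drop = FALSE]
      mu <- mu[meta$keep]
    }
  }
  list(mu = mu, sigma = (sigma + t(sigma)) / 2, radius = radius)
}

stop_not_stationary <- function(radius) {
  stop(structure(class = c("lvgvar_not_stationary", "error", "condition"),
                 list(message = sprintf(
                   "temporal coefficients not stationary (spectral radius %.4f)",
                   radius), call = sys.call(-1))))
}

#' Implied stacked mean and Toeplitz covariance of a ts-lvgvar specification
#'
#' @param spec A `ts_lvgvar_spec`.
#' @return List with `mu` (length 2 n_y) and `sigma` (2 n_y x 2 n_y): the
#'   upper-left block is the saturated lead block, the lower-right block the
#'   model-implied lag-0 covariance, and the off-diagonal blocks the lag-1
#'   covariance.
#' @export
ts_implied_moments <- function(spec) {
  stopifnot(inherits(spec, "ts_lvgvar_spec"))
  out <- moments_from_mats(mats_of(spec), meta_of(spec))
  if (is.null(out$sigma)) stop_not_stationary(out$radius)
  out[c("mu", "sigma")]
}

#' Implied stacked mean and block-Toeplitz covariance of a panel-lvgvar
#' specification
#'
#' The stacked vector holds all indicators at wave 1, then wave 2, etc. Block
#' (s, t) equals the between-subject covariance plus the within lag-|s-t|
#' covariance (plus within residual variances on the diagonal blocks);
#' stationarity makes every block depend on |s-t| only. Variables absent per
#' the presence mask are cut from the result.
#'
#' @param spec A `panel_lvgvar_spec`.
#' @return List with `mu` and `sigma`.
#' @export
panel_implied_moments <- function(spec) {
  stopifnot(inherits(spec, "panel_lvgvar_spec"))
  out <- moments_from_mats(mats_of(spec), meta_of(spec))
  if (is.null(out$sigma)) stop_not_stationary(out$radius)
  out[c("mu", "sigma")]
}

#' Implied moments of a model specification
#' @param spec A model specification.
#' @return List with `mu` and `sigma` for the stacked observed vector.
#' @export
implied_moments <- function(spec) {
  if (inherits(spec, "ts_lvgvar_spec")) ts_implied_moments(spec)
  else panel_implied_moments(spec)
}

#' Number of free parameters of a specification
#' @param spec A model specification.
#' @return Integer count.
#' @export
count_free_parameters <- function(spec) {
  sum(param_table(spec)$free)
}

#' Degrees of freedom of a specification
#'
#' Number of first- and second-order sample moments of the stacked observed
#' vector minus the number of free parameters. The saturated lead-block
#' parameters of the ts setting count as free, so the duplication of data in
#' the Toeplitz layout does not inflate the degrees of freedom.
#'
#' @param spec A model specification.
#' @return Integer degrees of freedom.
#' @export
degrees_of_freedom <- function(spec) {
  p <- if (inherits(spec, "ts_lvgvar_spec")) 2L * spec$n_y
       else sum(spec$presence)
  n_moments <- p + p * (p + 1) / 2
  as.integer(n_moments - count_free_parameters(spec))
}
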