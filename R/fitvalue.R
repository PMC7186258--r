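#' Summary-moment representation of a data matrix
#'
#' Splits a data matrix into missingness-pattern groups, each carrying its
#' variable-index set, group size, group means and group covariance (divisor
#' n_i; a singleton group has a zero covariance contribution). Complete data
#' yield a single pattern.
#'
#' @param x Numeric matrix (cases x variables, `NA` for missing), a
#'   `moments` [moments_dataset()], or a list with `covariance`, `means`, `n`.
#' @return Object of class `moment_data` with fields `n`, `p`, `labels`,
#'   `patterns` (list of `idx`, `n_i`, `mean`, `cov`) and, for complete data,
#'   `mean` and `cov` of the full sample.
#' @export
moment_data <- function(x) {
  if (inherits(x, "moment_data")) return(x)
  if (inherits(x, "lvgvar_dataset") && x$kind == "moments") {
    x <- list(covariance = x$covariance, means = x$means, n = x$n,
              labels = x$labels)
  }
  if (is.list(x) && !is.null(x$covariance)) {
    p <- length(x$means)
    labels <- x$labels %||% colnames(x$covariance) %||% paste0("z", seq_len(p))
    pat <- list(list(idx = seq_len(p), n_i = x$n, mean = as.numeric(x$means),
                     cov = unname(as.matrix(x$covariance))))
    return(structure(list(n = x$n, p = p, labels = labels, patterns = pat,
                          complete = TRUE, mean = pat[[1]]$mean,
                          cov = pat[[1]]$cov), class = "moment_data"))
  }
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  labels <- colnames(x) %||% paste0("z", seq_len(p))
  miss <- is.na(x)
  if (any(rowSums(!miss) == 0)) {
    stop(structure(class = c("lvgvar_data_error", "error", "condition"),
                   list(message = "rows with all variables missing are not allowed",
                        call = sys.call())))
  }
  key <- apply(miss, 1, function(r) paste(which(!r), collapse = ","))
  patterns <- lapply(split(seq_len(n), key), function(rows) {
    idx <- which(!miss[rows[1], ])
    xi <- x[rows, idx, drop = FALSE]
    n_i <- length(rows)
    m <- colMeans(xi)
    cv <- if (n_i == 1) matrix(0, length(idx), length(idx))
          else crossprod(sweep(xi, 2, m)) / n_i
    list(idx = idx, n_i = n_i, mean = m, cov = cv)
  })
  names(patterns) <- NULL
  if (length(patterns) == 0) {
    stop(structure(class = c("lvgvar_data_error", "error", "condition"),
                   list(message = "no observed data", call = sys.call())))
  }
  complete <- length(patterns) == 1 && length(patterns[[1]]$idx) == p
  out <- structure(list(n = n, p = p, labels = labels, patterns = patterns,
                        complete = complete), class = "moment_data")
  if (complete) {
    out$mean <- patterns[[1]]$mean
    out$cov <- patterns[[1]]$cov
  }
  out
}

#' @export
print.moment_data <- function(x, ...) {
  cat("Moment data: n =", x$n, ", p =", x$p, ",", length(x$patterns),
      "missingness pattern(s)\n")
  invisible(x)
}

# log|Sigma| and solve steps via a Cholesky factor
chol_logdet <- function(L) 2 * sum(log(diag(L)))

#' Maximum-likelihood fit function
#'
#' \deqn{F_{ML} = \mathrm{trace}(\bar S \Sigma^{-1}) +
#'   (\bar z - \mu)^\top \Sigma^{-1} (\bar z - \mu) - \ln|\Sigma^{-1}|,}
#' proportional to \eqn{-2/n} times the log-likelihood up to an additive
#' constant. Requires complete data (a single full pattern).
#'
#' @param data A [moment_data()] (complete) or anything coercible to one.
#' @param mu Model-implied mean vector.
#' @param sigma Model-implied covariance matrix (positive definite).
#' @return The fit-function value.
#' @export
ml_fit_value <- function(data, mu, sigma) {
  data <- moment_data(data)
  if (!isTRUE(data$complete)) {
    stop("ml_fit_value requires complete data; use fiml_fit_value", call. = FALSE)
  }
  L <- chol_or_null(sigma, tol = 1e-14)
  if (is.null(L)) stop_not_pd("sigma")
  d <- data$mean - mu
  Sinv_d <- backsolve(L, forwardsolve(t(L), d))
  Sinv <- chol2inv(L)
  sum(Sinv * data$cov) + sum(d * Sinv_d) + chol_logdet(L)
}

#' Full-information maximum-likelihood fit function
#'
#' \deqn{F_{FIML} = \frac{1}{n} \sum_i n_i \left(
#'   \mathrm{trace}(S_i \Sigma_i^{-1}) +
#'   (\bar z_i - \mu_i)^\top \Sigma_i^{-1} (\bar z_i - \mu_i) -
#'   \ln|\Sigma_i^{-1}| \right)}
#' summed over missingness-pattern groups; with a single complete pattern
#' this equals [ml_fit_value()].
#'
#' @inheritParams ml_fit_value
#' @return The fit-function value.
#' @export
fiml_fit_value <- function(data, mu, sigma) {
  data <- moment_data(data)
  acc <- 0
  for (pat in data$patterns) {
    si <- sigma[pat$idx, pat$idx, drop = FALSE]
    L <- chol_or_null(si, tol = 1e-14)
    if (is.null(L)) stop_not_pd("sigma (pattern submatrix)")
    d <- pat$mean - mu[pat$idx]
    Sinv_d <- backsolve(L, forwardsolve(t(L), d))
    val <- sum(chol2inv(L) * pat$cov) + sum(d * Sinv_d) + chol_logdet(L)
    acc <- acc + pat$n_i * val
  }
  acc / data$n
}

# Additive constant linking the fit value to -2 log L:
# -2 lnL = n * F + log(2*pi) * sum_i n_i p_i
loglik_constant <- function(data) {
  log(2 * pi) * sum(vapply(data$patterns, function(p) p$n_i * length(p$idx), 0))
}

#' Saturated (unstructured) moments of possibly incomplete data
#'
#' Maximum-likelihood mean vector and covariance matrix under no structure.
#' For complete data these are the sample moments; with missing data they
#' are computed by expectation-maximization over the missingness-pattern
#' groups.
#'
#' @param data A [moment_data()] or coercible.
#' @param tol Convergence tolerance on the fit value.
#' @param max_iter Iteration cap.
#' @return List with `mu`, `sigma`, `fit_value` (the FIML fit value at the
#'   solution) and `converged`.
#' @export
saturated_moments <- function(data, tol = 1e-8, max_iter = 500) {
  data <- moment_data(data)
  p <- data$p
  if (isTRUE(data$complete)) {
    f <- ml_fit_value(data, data$mean, data$cov)
    return(list(mu = data$mean, sigma = data$cov, fit_value = f,
                converged = TRUE))
  }
  # start from available-case moments, ridged to be positive definite
  start <- availablecase_moments(data)
  mu <- start$mu
  sigma <- start$sigma
  f_old <- Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    sumx <- numeric(p)
    sumxx <- matrix(0, p, p)
    for (pat in data$patterns) {
      o <- pat$idx
      m <- setdiff(seq_len(p), o)
      n_i <- pat$n_i
      xo_xo <- n_i * (pat$cov + tcrossprod(pat$mean))
      sumx[o] <- sumx[o] + n_i * pat$mean
      sumxx[o, o] <- sumxx[o, o] + xo_xo
      if (length(m)) {
        Soo_inv <- solve(sigma[o, o, drop = FALSE])
        A <- sigma[m, o, drop = FALSE] %*% Soo_inv
        a <- mu[m] - A %*% mu[o]
        Cmm <- sigma[m, m, drop = FALSE] - A %*% sigma[o, m, drop = FALSE]
        xm_bar <- a + A %*% pat$mean
        sumx[m] <- sumx[m] + n_i * xm_bar
        xm_xo <- n_i * (a %*% rbind(pat$mean)) + A %*% xo_xo
        sumxx[m, o] <- sumxx[m, o] + xm_xo
        sumxx[o, m] <- sumxx[o, m] + t(xm_xo)
        xm_xm <- n_i * (Cmm + tcrossprod(xm_bar) +
                          A %*% pat$cov %*% t(A))
        sumxx[m, m] <- sumxx[m, m] + xm_xm
      }
    }
    mu <- sumx / data$n
    sigma <- sumxx / data$n - tcrossprod(mu)
    sigma <- (sigma + t(sigma)) / 2
    f_new <- tryCatch(fiml_fit_value(data, mu, sigma), error = function(e) Inf)
    if (is.finite(f_new) && abs(f_old - f_new) < tol) {
      converged <- TRUE
      f_old <- f_new
      break
    }
    f_old <- f_new
  }
  list(mu = mu, sigma = sigma, fit_value = f_old, converged = converged)
}

# Pairwise available-case moments, ridged until positive definite. Used to
# start EM and to seed saturated starting values.
availablecase_moments <- function(data) {
  p <- data$p
  sx <- numeric(p); nx <- numeric(p)
  sxy <- matrix(0, p, p); nxy <- matrix(0, p, p)
  for (pat in data$patterns) {
    o <- pat$idx
    sx[o] <- sx[o] + pat$n_i * pat$mean
    nx[o] <- nx[o] + pat$n_i
    sxy[o, o] <- sxy[o, o] + pat$n_i * (pat$cov + tcrossprod(pat$mean))
    nxy[o, o] <- nxy[o, o] + pat$n_i
  }
  mu <- sx / pmax(nx, 1)
  exy <- sxy / pmax(nxy, 1)
  sigma <- exy - tcrossprod(mu)
  sigma[nxy == 0] <- 0
  diag(sigma)[diag(nxy) == 0] <- 1
  sigma <- (sigma + t(sigma)) / 2
  ridge <- 0
  while (is.null(chol_or_null(sigma + ridge * diag(p))) && ridge < 10) {
    ridge <- if (ridge == 0) 1e-6 * max(diag(sigma)) else ridge * 10
  }
  list(mu = mu, sigma = sigma + ridge * diag(p))
}

# Independence baseline: free means and variances, zero covariances. With a
# diagonal covariance the likelihood factorizes per variable, so the MLE is
# each variable's observed-case mean and variance (divisor n_obs).
baseline_moments <- function(data) {
  data <- moment_data(data)
  p <- data$p
  sx <- numeric(p); sxx <- numeric(p); nx <- numeric(p)
  for (pat in data$patterns) {
    o <- pat$idx
    sx[o] <- sx[o] + pat$n_i * pat$mean
    sxx[o] <- sxx[o] + pat$n_i * (diag(pat$cov) + pat$mean^2)
    nx[o] <- nx[o] + pat$n_i
  }
  mu <- sx / nx
  v <- sxx / nx - mu^2
  list(mu = mu, sigma = diag(v, p))
}
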