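#' Gaussian graphical model (partial-correlation network)
#'
#' A Gaussian graphical model (GGM) parameterizes a covariance matrix as
#' \deqn{\Sigma = \Delta (I - \Omega)^{-1} \Delta,}
#' where \eqn{\Omega} is a symmetric matrix with zero diagonal holding partial
#' correlations on the off-diagonal, and \eqn{\Delta} is a diagonal scaling
#' matrix on the standard-deviation scale. Edges absent from the network
#' (`mask = FALSE`) have their partial correlation fixed to zero.
#'
#' @param omega Square symmetric numeric matrix of partial correlations with
#'   zero diagonal; all entries must lie in (-1, 1).
#' @param delta Positive diagonal scaling entries, either a vector or a
#'   diagonal matrix. Defaults to unit scaling.
#' @param mask Symmetric logical edge-inclusion matrix with zero (FALSE)
#'   diagonal. Defaults to `omega != 0` off-diagonal... any entry with
#'   `mask = FALSE` must have `omega = 0`.
#' @return An object of class `gaussian_network` with elements `omega`,
#'   `delta` (vector) and `mask`.
#' @examples
#' net <- gaussian_network(matrix(c(0, .5, .5, 0), 2))
#' network_to_covariance(net)
#' @export
gaussian_network <- function(omega, delta = NULL, mask = NULL) {
  omega <- as.matrix(omega)
  p <- nrow(omega)
  if (ncol(omega) != p) stop("omega must be square", call. = FALSE)
  if (max(abs(omega - t(omega))) > 1e-10) stop("omega must be symmetric", call. = FALSE)
  if (any(abs(diag(omega)) > 1e-12)) stop("omega must have a zero diagonal", call. = FALSE)
  if (any(abs(omega[row(omega) != col(omega)]) >= 1)) {
    stop("partial correlations must lie strictly in (-1, 1)", call. = FALSE)
  }
  omega <- (omega + t(omega)) / 2
  diag(omega) <- 0
  if (is.null(delta)) delta <- rep(1, p)
  if (is.matrix(delta)) delta <- diag(delta)
  if (length(delta) != p) stop("delta has wrong length", call. = FALSE)
  if (any(delta <= 0)) stop("delta entries must be positive", call. = FALSE)
  if (is.null(mask)) {
    mask <- omega != 0
  } else {
    mask <- as.matrix(mask)
    if (!identical(dim(mask), dim(omega))) stop("mask has wrong dimensions", call. = FALSE)
    mask <- mask | t(mask)
    diag(mask) <- FALSE
    if (any(omega[!mask] != 0)) stop("omega must be zero where mask is FALSE", call. = FALSE)
  }
  structure(list(omega = omega, delta = as.numeric(delta), mask = mask),
            class = "gaussian_network")
}

#' @export
print.gaussian_network <- function(x, ...) {
  cat("Gaussian graphical model with", nrow(x$omega), "nodes and",
      sum(x$mask[upper.tri(x$mask)]), "included edges\n")
  invisible(x)
}

# Symmetric PD check via Cholesky with a relative tolerance on the smallest
# pivot; returns the factor or NULL.
chol_or_null <- function(x, tol = 1e-10) {
  L <- tryCatch(chol(x), error = function(e) NULL)
  if (is.null(L)) return(NULL)
  d <- diag(L)^2
  if (any(d <= tol * max(d))) return(NULL)
  L
}

stop_not_pd <- function(what) {
  stop(structure(class = c("lvgvar_not_pd", "error", "condition"),
                 list(message = paste0(what, " is not positive definite"),
                      call = sys.call(-1))))
}

#' Covariance matrix implied by a Gaussian graphical model
#'
#' Computes \eqn{\Sigma = \Delta (I - \Omega)^{-1} \Delta}.
#'
#' @param net A [gaussian_network()].
#' @return Symmetric positive-definite covariance matrix.
#' @export
network_to_covariance <- function(net) {
  stopifnot(inherits(net, "gaussian_network"))
  p <- nrow(net$omega)
  IminO <- diag(p) - net$omega
  L <- chol_or_null(IminO)
  if (is.null(L)) stop_not_pd("I - Omega")
  K <- chol2inv(L)
  sig <- net$delta * K * rep(net$delta, each = p)
  sig <- (sig + t(sig)) / 2
  dimnames(sig) <- dimnames(net$omega)
  sig
}

#' Gaussian graphical model obtained from a covariance matrix
#'
#' Inverts the covariance matrix, standardizes the precision matrix and
#' negates its off-diagonal to obtain partial correlations:
#' \eqn{\omega_{ij} = -\kappa_{ij}/\sqrt{\kappa_{ii}\kappa_{jj}}} with
#' \eqn{K = \Sigma^{-1}}, and \eqn{\delta_i = \kappa_{ii}^{-1/2}}.
#'
#' @param sigma Symmetric positive-definite covariance matrix.
#' @return A [gaussian_network()]; the round trip through
#'   [network_to_covariance()] reproduces `sigma`.
#' @export
covariance_to_network <- function(sigma) {
  sigma <- as.matrix(sigma)
  if (max(abs(sigma - t(sigma))) > 1e-8 * max(1, max(abs(sigma)))) {
    stop("sigma must be symmetric", call. = FALSE)
  }
  L <- chol_or_null(sigma)
  if (is.null(L)) stop_not_pd("sigma")
  K <- chol2inv(L)
  d <- sqrt(diag(K))
  omega <- -K / tcrossprod(d)
  diag(omega) <- 0
  gaussian_network(omega, delta = 1 / d)
}

#' Model-implied marginal correlations of a Gaussian graphical model
#'
#' Standardizes \eqn{(I-\Omega)^{-1}} to a correlation matrix. The result is
#' independent of the scaling matrix \eqn{\Delta}.
#'
#' @param net A [gaussian_network()].
#' @return Correlation matrix.
#' @export
implied_marginal_correlations <- function(net) {
  stopifnot(inherits(net, "gaussian_network"))
  p <- nrow(net$omega)
  L <- chol_or_null(diag(p) - net$omega)
  if (is.null(L)) stop_not_pd("I - Omega")
  out <- stats::cov2cor(chol2inv(L))
  dimnames(out) <- dimnames(net$omega)
  out
}

#' Temporal structure of a graphical VAR model
#'
#' Couples a lag-1 coefficient matrix `beta` (the temporal network; entry
#' \eqn{b_{ij}} is the effect of variable j at occasion t-1 on variable i at
#' occasion t) with a GGM on the innovations (the contemporaneous network).
#'
#' @param beta Square coefficient matrix with spectral radius strictly below 1.
#' @param innovation A [gaussian_network()] for the innovation covariance,
#'   with the same dimension as `beta`.
#' @param mask Optional logical inclusion matrix for `beta`; entries with
#'   `mask = FALSE` must be zero. Defaults to `beta != 0`.
#' @return Object of class `temporal_structure`.
#' @export
temporal_structure <- function(beta, innovation, mask = NULL) {
  beta <- as.matrix(beta)
  stopifnot(inherits(innovation, "gaussian_network"))
  if (nrow(beta) != ncol(beta)) stop("beta must be square", call. = FALSE)
  if (nrow(beta) != nrow(innovation$omega)) {
    stop("innovation dimension must equal beta dimension", call. = FALSE)
  }
  st <- check_stability(beta)
  if (!st$stable) {
    stop(structure(class = c("lvgvar_not_stationary", "error", "condition"),
                   list(message = sprintf(
                     "beta is not stationary (spectral radius %.4f)", st$radius),
                     call = sys.call())))
  }
  if (is.null(mask)) mask <- beta != 0
  structure(list(beta = beta, innovation = innovation, mask = as.matrix(mask)),
            class = "temporal_structure")
}

#' Spectral-radius stability check for a lag-1 coefficient matrix
#'
#' @param beta Square numeric matrix.
#' @param tol Stability margin; the process is reported stable when the
#'   spectral radius is below `1 - tol`.
#' @return List with `radius` (largest eigenvalue modulus) and `stable`.
#' @export
check_stability <- function(beta, tol = 1e-6) {
  beta <- as.matrix(beta)
  if (nrow(beta) != ncol(beta)) stop("beta must be square", call. = FALSE)
  radius <- max(Mod(eigen(beta, only.values = TRUE)$values))
  list(radius = radius, stable = radius < 1 - tol)
}

#' Stationary covariance of a lag-1 VAR process
#'
#' Solves \eqn{\mathrm{vec}(\Sigma_0) = (I \otimes I - B \otimes B)^{-1}
#' \mathrm{vec}(\Sigma^{(\zeta)})}, i.e. the discrete Lyapunov equation
#' \eqn{\Sigma_0 = B \Sigma_0 B^\top + \Sigma^{(\zeta)}}.
#'
#' @param temporal A [temporal_structure()], or a list with elements `beta`
#'   and an innovation covariance `sigma_zeta`.
#' @return Stationary covariance matrix \eqn{\Sigma_0}.
#' @export
stationary_covariance <- function(temporal) {
  if (inherits(temporal, "temporal_structure")) {
    beta <- temporal$beta
    sz <- network_to_covariance(temporal$innovation)
  } else {
    beta <- as.matrix(temporal$beta)
    sz <- as.matrix(temporal$sigma_zeta)
  }
  st <- check_stability(beta)
  if (!st$stable) {
    stop(structure(class = c("lvgvar_not_stationary", "error", "condition"),
                   list(message = sprintf(
                     "cannot compute stationary covariance: spectral radius %.4f",
                     st$radius), call = sys.call())))
  }
  lyapunov_solve(beta, sz)
}

# vec/Kronecker linear solve of the discrete Lyapunov equation.
lyapunov_solve <- function(beta, sigma_zeta) {
  p <- nrow(beta)
  A <- diag(p * p) - kronecker(beta, beta)
  s0 <- solve(A, as.vector(sigma_zeta))
  s0 <- matrix(s0, p, p)
  (s0 + t(s0)) / 2
}

#' Stationary lag-k covariance of a lag-1 VAR process
#'
#' Applies the recursion \eqn{\Sigma_k = B \Sigma_{k-1}}, so
#' \eqn{\Sigma_k = B^k \Sigma_0}; the entry (i, j) is
#' \eqn{\mathrm{cov}(\eta_{i,t+k}, \eta_{j,t})}.
#'
#' @param beta Lag-1 coefficient matrix.
#' @param sigma0 Stationary (lag-0) covariance matrix.
#' @param k Nonnegative integer lag.
#' @return \eqn{B^k \Sigma_0}.
#' @export
lag_covariance <- function(beta, sigma0, k) {
  if (length(k) != 1 || k < 0 || k != round(k)) {
    stop("k must be a nonnegative integer", call. = FALSE)
  }
  out <- as.matrix(sigma0)
  beta <- as.matrix(beta)
  for (i in seq_len(k)) out <- beta %*% out
  out
}

#' Standardize temporal coefficients to partial directed correlations
#'
#' Rescales the lag-1 coefficient matrix to partial directed correlations
#' (PDC), a bounded standardization suited to drawing directed networks:
#' \deqn{\mathrm{PDC}_{ij} = b_{ij} / \sqrt{\sigma_{ii}\,\kappa_{jj} + b_{ij}^2},}
#' with \eqn{\sigma} the innovation covariance and \eqn{\kappa} its inverse
#' (Wild et al. 2010, standardization of VAR coefficients). Entries lie in
#' (-1, 1), preserve the sign of `beta`, and are zero exactly where `beta` is.
#'
#' @param temporal A [temporal_structure()].
#' @return Matrix of partial directed correlations.
#' @export
standardize_temporal <- function(temporal) {
  stopifnot(inherits(temporal, "temporal_structure"))
  sz <- network_to_covariance(temporal$innovation)
  L <- chol_or_null(sz)
  if (is.null(L)) stop_not_pd("innovation covariance")
  kappa <- chol2inv(L)
  B <- temporal$beta
  p <- nrow(B)
  denom <- sqrt(outer(diag(sz), diag(kappa)) + B^2)
  B / denom
}

#' Export a network as a weighted edge list
#'
#' Writes one row per unordered node pair with the edge weight and an
#' inclusion flag, as plain text (CSV).
#'
#' @param net A [gaussian_network()], or a matrix of weights (e.g. a temporal
#'   network), in which case ordered pairs are written.
#' @param path File to write; when `NULL` the data frame is returned only.
#' @param labels Optional node labels.
#' @return Invisibly, the edge-list data frame with columns `node_i`,
#'   `node_j`, `weight`, `included`.
#' @export
network_edge_list <- function(net, path = NULL, labels = NULL) {
  if (inherits(net, "gaussian_network")) {
    w <- net$omega
    mask <- net$mask
    idx <- which(upper.tri(w), arr.ind = TRUE)
  } else {
    w <- as.matrix(net)
    mask <- w != 0
    idx <- which(row(w) > 0 & col(w) > 0, arr.ind = TRUE)
  }
  if (is.null(labels)) labels <- if (!is.null(rownames(w))) rownames(w) else
    paste0("V", seq_len(nrow(w)))
  out <- data.frame(node_i = labels[idx[, 1]], node_j = labels[idx[, 2]],
                    weight = w[idx], included = mask[idx],
                    stringsAsFactors = FALSE)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Export a network as a labeled square matrix in CSV
#'
#' @param net A [gaussian_network()] or a matrix.
#' @param path File to write.
#' @param labels Optional node labels.
#' @return Invisibly, the matrix written.
#' @export
network_matrix_csv <- function(net, path, labels = NULL) {
  w <- if (inherits(net, "gaussian_network")) net$omega else as.matrix(net)
  if (!is.null(labels)) dimnames(w) <- list(labels, labels)
  if (is.null(rownames(w))) {
    dimnames(w) <- list(paste0("V", seq_len(nrow(w))), paste0("V", seq_len(ncol(w))))
  }
  utils::write.csv(w, path, row.names = TRUE)
  invisible(w)
}
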