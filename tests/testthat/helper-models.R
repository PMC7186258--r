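# Small model constructors shared across tests.

# Random valid Gaussian graphical model of dimension p (diagonally dominant
# partial-correlation matrix, so I - Omega is positive definite).
random_network <- function(p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  O <- matrix(0, p, p)
  O[lower.tri(O)] <- stats::runif(p * (p - 1) / 2, -0.9, 0.9) / p
  O <- O + t(O)
  gaussian_network(O, delta = stats::runif(p, 0.5, 2))
}

# Random stable lag-1 coefficient matrix (scaled below unit spectral radius).
random_stable_beta <- function(p, radius = 0.7) {
  B <- matrix(stats::rnorm(p * p, 0, 1), p, p)
  r <- max(Mod(eigen(B, only.values = TRUE)$values))
  B * (radius / r)
}

# One-factor, three-indicator ts model; df = 8 when fit saturated.
tiny_ts_model <- function(b = 0.5, resid = 0.3) {
  mm <- measurement_model(matrix(c(1, 0.8, 0.7), 3, 1),
                          residual_values = rep(resid, 3))
  spec <- ts_model_spec(mm)
  spec$beta$value <- matrix(b, 1, 1)
  spec
}

# Observed-variable (identity measurement) GVAR between p variables.
observed_gvar <- function(p, beta = NULL, omega = NULL) {
  spec <- ts_model_spec(observed_measurement(p))
  if (!is.null(beta)) spec$beta$value <- beta
  if (!is.null(omega)) spec$omega_zeta$value <- as.matrix(omega)
  spec
}

# Two-factor (2 + 2 indicators) panel model with sparse true networks.
tiny_panel_model <- function() {
  lam <- matrix(0, 4, 2)
  lam[1:2, 1] <- c(1, 0.8)
  lam[3:4, 2] <- c(1, 0.9)
  mm <- measurement_model(lam, residual_values = rep(0.25, 4))
  B <- matrix(c(0.3, 0.2, 0, 0.25), 2, 2)  # one cross-lagged effect 1 -> 2
  OW <- matrix(c(0, 0.3, 0.3, 0), 2, 2)
  OB <- matrix(c(0, -0.25, -0.25, 0), 2, 2)
  panel_model_spec(mm, n_waves = 3, beta = B, omega_zeta = OW,
                   delta_zeta = c(0.6, 0.6), omega_between = OB,
                   delta_between = c(0.7, 0.7),
                   between_residual_values = rep(0.2, 4))
}
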