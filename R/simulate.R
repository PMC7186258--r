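# Generative simulators for both settings, edge-recovery metrics, and the
# simulation-study harness.

# Evaluate code under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic replicate-level substream seeds from a master seed,
# kept below 2^31.
derive_seed <- function(master, i) {
  as.integer((as.double(master) %% 65536 * 30269 + i * 7919 + 104729) %%
               2147483647)
}

rmvnorm_chol <- function(n, mu, L) {
  # L: upper Cholesky factor (chol output), sigma = t(L) %*% L
  z <- matrix(stats::rnorm(n * length(mu)), n)
  sweep(z %*% L, 2, mu, `+`)
}

sim_matrices <- function(spec) {
  m <- spec$measurement
  list(lambda = m$lambda$value, tau = m$tau$value,
       theta_w = var_of_resid(m$resid$value, m$resid$type),
       beta = spec$beta$value,
       sigma_zeta = ggm_covariance_raw(spec$omega_zeta$value,
                                       spec$delta_zeta$value))
}

#' Simulate single-subject time-series data from a ts-lvgvar model
#'
#' The latent series follows \eqn{\eta_t = B \eta_{t-1} + \zeta_t} with
#' innovations drawn from the contemporaneous GGM covariance; observations
#' are \eqn{y_t = \tau + \Lambda \eta_t + \varepsilon_t} with independent
#' residuals. A burn-in period started from the stationary distribution is
#' discarded.
#'
#' @param spec A `ts_lvgvar_spec` holding the generating values (the
#'   saturated lead-block parameters are ignored).
#' @param n_occasions Number of measurement occasions returned.
#' @param burn_in Occasions discarded before recording (default 100).
#' @param seed Seed making the draw reproducible.
#' @param n_blocks Number of blocks (e.g. days) the series is split into;
#'   temporal pairs are not formed across block boundaries when the data are
#'   augmented. Blocks split the single generated series (the generating
#'   process itself is not interrupted).
#' @return A [timeseries_dataset()].
#' @export
simulate_ts <- function(spec, n_occasions, burn_in = 100, seed = NULL,
                        n_blocks = 1) {
  stopifnot(inherits(spec, "ts_lvgvar_spec"))
  sm <- sim_matrices(spec)
  st <- check_stability(sm$beta)
  if (!st$stable) stop_not_stationary(st$radius)
  run <- function() {
    n_e <- spec$n_eta; n_y <- spec$n_y
    Lz <- chol(sm$sigma_zeta)
    s0 <- lyapunov_solve(sm$beta, sm$sigma_zeta)
    eta <- as.numeric(rmvnorm_chol(1, rep(0, n_e), chol(s0)))
    total <- n_occasions + burn_in
    out <- matrix(NA_real_, n_occasions, n_y)
    for (t in seq_len(total)) {
      eta <- as.numeric(sm$beta %*% eta) +
        as.numeric(rmvnorm_chol(1, rep(0, n_e), Lz))
      if (t > burn_in) {
        i <- t - burn_in
        out[i, ] <- sm$tau + as.numeric(sm$lambda %*% eta) +
          stats::rnorm(n_y, 0, sqrt(sm$theta_w))
      }
    }
    colnames(out) <- spec$measurement$indicator_labels
    blocks <- sort(rep_len(seq_len(n_blocks), n_occasions))
    timeseries_dataset(out, blocks = blocks)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Simulate multi-wave panel data from a panel-lvgvar model
#'
#' Subject means are drawn from the between-subject model (latent means from
#' the between GGM covariance, residual means from the between residual
#' variances); within-subject deviations follow the stationary latent GVAR,
#' with the first wave drawn exactly from the stationary distribution.
#' Observations pass through the shared measurement model.
#'
#' @param spec A `panel_lvgvar_spec` holding the generating values.
#' @param n_subjects Number of subjects.
#' @param n_waves Number of waves (defaults to the specification's).
#' @param seed Seed making the draw reproducible.
#' @return A [panel_dataset()] with columns `item@w<wave>`.
#' @export
simulate_panel <- function(spec, n_subjects, n_waves = NULL, seed = NULL) {
  stopifnot(inherits(spec, "panel_lvgvar_spec"))
  if (is.null(n_waves)) n_waves <- spec$n_waves
  sm <- sim_matrices(spec)
  st <- check_stability(sm$beta)
  if (!st$stable) stop_not_stationary(st$radius)
  sigma_b_eta <- ggm_covariance_raw(spec$omega_between$value,
                                    spec$delta_between$value)
  theta_b <- var_of_resid(spec$resid_between$value, spec$resid_between$type)
  run <- function() {
    n_e <- spec$n_eta; n_y <- spec$n_y
    s0 <- lyapunov_solve(sm$beta, sm$sigma_zeta)
    L0 <- chol_factor_or_zero(s0)
    Lz <- chol_factor_or_zero(sm$sigma_zeta)
    Lb <- chol_factor_or_zero(sigma_b_eta)
    mu_eta <- rmvnorm_chol(n_subjects, rep(0, n_e), Lb)
    mu_eps <- matrix(stats::rnorm(n_subjects * n_y, 0,
                                  rep(sqrt(theta_b), each = n_subjects)),
                     n_subjects, n_y)
    mu_y <- rep(sm$tau, each = n_subjects) + mu_eta %*% t(sm$lambda) + mu_eps
    out <- matrix(NA_real_, n_subjects, n_y * n_waves)
    xi <- rmvnorm_chol(n_subjects, rep(0, n_e), L0)
    for (w in seq_len(n_waves)) {
      if (w > 1) {
        xi <- xi %*% t(sm$beta) + rmvnorm_chol(n_subjects, rep(0, n_e), Lz)
      }
      eps <- matrix(stats::rnorm(n_subjects * n_y, 0,
                                 rep(sqrt(sm$theta_w), each = n_subjects)),
                    n_subjects, n_y)
      out[, (w - 1) * n_y + seq_len(n_y)] <- mu_y + xi %*% t(sm$lambda) + eps
    }
    colnames(out) <- as.vector(outer(spec$measurement$indicator_labels,
                                     seq_len(n_waves),
                                     function(i, w) paste0(i, "@w", w)))
    panel_dataset(out)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# Cholesky factor that tolerates an exactly zero matrix (degenerate
# variance components are legitimate generating values).
chol_factor_or_zero <- function(sigma) {
  if (all(sigma == 0)) return(matrix(0, nrow(sigma), ncol(sigma)))
  chol(sigma)
}

#' Edge-recovery metrics between a generating and an estimated specification
#'
#' Sensitivity is the proportion of true edges also included in the
#' estimated model; specificity the proportion of true missing edges also
#' excluded; the correlation is the Pearson correlation between true and
#' estimated weights over all searchable network entries. An edge counts as
#' included when its parameter is free with a nonzero value (a pruned edge
#' is fixed at zero).
#'
#' @param true_spec Generating specification (edges = nonzero values).
#' @param estimated_spec Estimated specification (edges = free searchable
#'   parameters).
#' @return List with `sensitivity`, `specificity`, `correlation` and the
#'   underlying counts (`NA` where undefined, e.g. no true edges).
#' @export
edge_metrics <- function(true_spec, estimated_spec) {
  pt_true <- param_table(true_spec)
  pt_est <- param_table(estimated_spec)
  st <- pt_true[pt_true$searchable, , drop = FALSE]
  se <- pt_est[pt_est$searchable, , drop = FALSE]
  if (!identical(st$id, se$id)) {
    stop("specifications have different searchable edge sets", call. = FALSE)
  }
  true_edge <- st$value != 0
  est_edge <- se$free & se$value != 0
  n_true <- sum(true_edge)
  n_null <- sum(!true_edge)
  sens <- if (n_true > 0) sum(true_edge & est_edge) / n_true else NA_real_
  spcf <- if (n_null > 0) sum(!true_edge & !est_edge) / n_null else NA_real_
  est_w <- ifelse(se$free, se$value, 0)
  corr <- if (stats::sd(st$value) > 0 && stats::sd(est_w) > 0) {
    stats::cor(st$value, est_w)
  } else NA_real_
  list(sensitivity = sens, specificity = spcf, correlation = corr,
       n_true_edges = n_true, n_true_missing = n_null)
}

#' Configuration of a simulation study
#'
#' @param spec Generating specification (`ts_lvgvar_spec` or
#'   `panel_lvgvar_spec`).
#' @param sample_sizes Numbers of occasions (ts) or subjects (panel).
#' @param variants Data frame with columns `strategy`, `adjustment`, `alpha`;
#'   defaults to the full grid of 3 strategies x 4 adjustments x 2 alpha
#'   levels.
#' @param replicates Replicates per condition.
#' @param seed Master seed; replicate-level seeds are derived substreams so
#'   any cell is reproducible in isolation.
#' @return A `sim_config` list.
#' @export
sim_config <- function(spec, sample_sizes, variants = NULL, replicates = 100,
                       seed = 1) {
  if (is.null(variants)) {
    variants <- expand.grid(strategy = c("prune", "stepup", "modelsearch"),
                            adjustment = c("none", "bonferroni", "holm", "fdr"),
                            alpha = c(0.01, 0.05),
                            stringsAsFactors = FALSE)
  }
  stopifnot(replicates >= 1, all(sample_sizes > 0))
  structure(list(spec = spec, sample_sizes = sample_sizes,
                 variants = variants, replicates = replicates, seed = seed),
            class = "sim_config")
}

#' Run a simulation study
#'
#' For each sample size and replicate, data are simulated from the
#' generating model and every estimator variant (strategy x adjustment x
#' alpha) is run on the same dataset, sharing the initial saturated fit.
#' Failed estimations are counted against the success rate, never imputed.
#'
#' @param config A [sim_config()].
#' @param cache_dir Optional directory for per-(size, replicate) result
#'   caching, making interrupted studies resumable.
#' @param progress Print a line per cell.
#' @return Tidy data frame: one row per sample size x variant with mean
#'   sensitivity, specificity and correlation over successful replicates,
#'   and the success rate.
#' @export
run_study <- function(config, cache_dir = NULL, progress = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  spec <- config$spec
  is_ts <- inherits(spec, "ts_lvgvar_spec")
  # base spec with all searchable edges free, the starting point of search
  rows <- list()
  for (n in config$sample_sizes) {
    for (rep_i in seq_len(config$replicates)) {
      key <- sprintf("n%d_r%d", n, rep_i)
      cell <- NULL
      cache_file <- if (!is.null(cache_dir)) file.path(cache_dir, paste0(key, ".rds"))
      if (!is.null(cache_file) && file.exists(cache_file)) {
        cell <- readRDS(cache_file)
      }
      if (is.null(cell)) {
        seed_i <- derive_seed(config$seed, match(n, config$sample_sizes) * 10000 + rep_i)
        dat <- if (is_ts) simulate_ts(spec, n, seed = seed_i)
               else simulate_panel(spec, n, seed = seed_i)
        sat_spec <- saturate_networks(spec)
        base_fit <- tryCatch(fit_lvgvar(sat_spec, dat),
                             error = function(e) NULL)
        fit_cache <- new.env(parent = emptyenv())
        cell <- lapply(seq_len(nrow(config$variants)), function(v) {
          vr <- config$variants[v, ]
          out <- tryCatch(
            search_pipeline(sat_spec, dat, alpha = vr$alpha,
                            adjustment = vr$adjustment, strategy = vr$strategy,
                            base_fit = base_fit, cache = fit_cache),
            error = function(e) NULL)
          if (is.null(out) || !isTRUE(out$converged)) {
            list(success = FALSE)
          } else {
            c(list(success = TRUE), edge_metrics(spec, out$spec))
          }
        })
        if (!is.null(cache_file)) {
          dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
          saveRDS(cell, cache_file)
        }
      }
      for (v in seq_len(nrow(config$variants))) {
        m <- cell[[v]]
        rows[[length(rows) + 1]] <- data.frame(
          n = n, replicate = rep_i,
          strategy = config$variants$strategy[v],
          adjustment = config$variants$adjustment[v],
          alpha = config$variants$alpha[v],
          success = m$success,
          sensitivity = m$sensitivity %||% NA_real_,
          specificity = m$specificity %||% NA_real_,
          correlation = m$correlation %||% NA_real_,
          stringsAsFactors = FALSE)
      }
      if (progress) {
        message(sprintf("cell %s done", key))
      }
    }
  }
  raw <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(
    split(raw, list(raw$n, raw$strategy, raw$adjustment, raw$alpha),
          drop = TRUE),
    function(g) {
      ok <- g[g$success, , drop = FALSE]
      data.frame(n = g$n[1], strategy = g$strategy[1],
                 adjustment = g$adjustment[1], alpha = g$alpha[1],
                 replicates = nrow(g), success_rate = mean(g$success),
                 sensitivity = mean(ok$sensitivity, na.rm = TRUE),
                 specificity = mean(ok$specificity, na.rm = TRUE),
                 correlation = mean(ok$correlation, na.rm = TRUE),
                 stringsAsFactors = FALSE)
    }))
  rownames(agg) <- NULL
  attr(agg, "replicate_level") <- raw
  agg
}

#' Free all searchable network edges of a specification
#'
#' Returns the fully connected variant of a specification (every temporal,
#' contemporaneous and between edge free), the starting point of the search
#' pipeline.
#'
#' @param spec A model specification.
#' @return The saturated-network specification.
#' @export
saturate_networks <- function(spec) {
  pt <- param_table(spec)
  sr <- pt[pt$searchable & !pt$free, , drop = FALSE]
  for (r in seq_len(nrow(sr))) {
    spec <- spec_free_edge(spec, sr$family[r], sr$row[r], sr$col[r],
                           value = sr$value[r])
  }
  spec
}

# ---------------------------------------------------------------------------
# Bundled generating models. Dimensions mirror the empirical examples
# (5 factors / 14 indicators for the time-series setting; 6 factors / 22
# indicators, 3 waves for the panel setting); network entries use the
# published point estimates where available, remaining values (loadings,
# scalings, residual variances, intercepts) are fixed stand-ins documented
# here.

bundled_loadings <- function(sizes, labels_prefix, latent_labels) {
  n_y <- sum(sizes)
  lam <- matrix(0, n_y, length(sizes))
  loads <- c(1, 0.9, 0.8, 0.85, 0.75)
  k <- 1
  for (f in seq_along(sizes)) {
    for (j in seq_len(sizes[f])) {
      lam[k, f] <- loads[(j - 1) %% length(loads) + 1]
      k <- k + 1
    }
  }
  rownames(lam) <- unlist(lapply(seq_along(sizes), function(f)
    paste0(labels_prefix[f], seq_len(sizes[f]))))
  colnames(lam) <- latent_labels
  lam
}

#' Bundled generating model for the time-series setting
#'
#' Five latent factors measured by 14 indicators (3/3/3/3/2). Temporal
#' coefficients: autoregressions 0.22, 0.50, 0.35, 0.37, 0.29 and one
#' cross-lagged effect F2 -> F1 of -0.22; contemporaneous partial
#' correlations connect F1 negatively to the other four factors (-0.43,
#' -0.54, -0.35, -0.24); unit contemporaneous scalings, residual variances
#' 0.4, zero intercepts.
#'
#' @return A `ts_lvgvar_spec` holding the generating values.
#' @export
bundled_ts_model <- function() {
  lam <- bundled_loadings(c(3, 3, 3, 3, 2), paste0("F", 1:5, "_"),
                          paste0("F", 1:5))
  mm <- measurement_model(lam, residual_values = rep(0.4, 14))
  B <- diag(c(0.22, 0.50, 0.35, 0.37, 0.29))
  B[1, 2] <- -0.22  # F2 at t-1 predicts F1 at t
  O <- matrix(0, 5, 5)
  O[2, 1] <- -0.43; O[3, 1] <- -0.54; O[4, 1] <- -0.35; O[5, 1] <- -0.24
  O <- O + t(O)
  ts_model_spec(mm, beta = B, omega_zeta = O, delta_zeta = rep(1, 5))
}

#' Bundled generating model for the panel setting
#'
#' Six latent factors (self-esteem, pessimism, optimism, life satisfaction,
#' positive affect, negative affect) measured by 22 indicators
#' (3/3/3/5/4/4) over 3 waves. The sparse temporal matrix, within
#' contemporaneous partial correlations and between-subject partial
#' correlations hold the published point estimates; scalings are 0.5
#' (within) and 0.6 (between), residual variances 0.25 at both levels,
#' intercepts 4 (7-point-scale stand-in).
#'
#' @return A `panel_lvgvar_spec` holding the generating values.
#' @export
bundled_panel_model <- function() {
  pre <- c("SE", "Pes", "Opt", "LS", "PA", "NA")
  lam <- bundled_loadings(c(3, 3, 3, 5, 4, 4), paste0(pre, "_"), pre)
  mm <- measurement_model(lam, tau = rep(4, 22),
                          residual_values = rep(0.25, 22))
  # temporal effects, B[target, source]
  B <- matrix(0, 6, 6, dimnames = list(pre, pre))
  B["Pes", "SE"] <- 0.16
  B["NA", "Pes"] <- 0.13
  B["Pes", "Opt"] <- -0.20
  B["SE", "LS"] <- 0.11
  B["Opt", "LS"] <- 0.28
  B["LS", "LS"] <- 0.09
  # within contemporaneous partial correlations
  OW <- matrix(0, 6, 6, dimnames = list(pre, pre))
  ow <- function(i, j, v) OW[i, j] <<- OW[j, i] <<- v
  ow("Opt", "SE", 0.20); ow("LS", "SE", 0.17); ow("PA", "SE", 0.11)
  ow("NA", "SE", -0.11); ow("Opt", "Pes", -0.36); ow("NA", "Pes", 0.15)
  ow("LS", "Opt", 0.32); ow("PA", "Opt", 0.21); ow("NA", "Opt", -0.13)
  ow("NA", "LS", -0.10); ow("NA", "PA", 0.14)
  # between-subject partial correlations
  OB <- matrix(0, 6, 6, dimnames = list(pre, pre))
  ob <- function(i, j, v) OB[i, j] <<- OB[j, i] <<- v
  ob("Opt", "SE", 0.33); ob("LS", "SE", 0.19); ob("PA", "SE", 0.34)
  ob("NA", "SE", -0.25); ob("Opt", "Pes", -0.39); ob("LS", "Pes", -0.13)
  ob("PA", "Pes", 0.14); ob("NA", "Pes", 0.17); ob("LS", "Opt", 0.33)
  ob("PA", "Opt", 0.25); ob("NA", "Opt", -0.14); ob("NA", "LS", -0.11)
  ob("NA", "PA", 0.22)
  panel_model_spec(mm, n_waves = 3, beta = B, omega_zeta = OW,
                   delta_zeta = rep(0.5, 6), omega_between = OB,
                   delta_between = rep(0.6, 6),
                   between_residual_values = rep(0.25, 22))
}
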