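# Human-editable model configuration files (YAML): factor structure,
# indicator lists, identification and residual choices, wave count, presence
# mask, and fixed between-level residuals. The bundled example config
# mirrors the 22-indicator / 6-factor personality-panel structure.

#' Read a model specification from a YAML configuration
#'
#' The configuration names the kind (`ts` or `panel`), the factors with
#' their indicator lists (simple structure; the first indicator per factor
#' carries the scaling constraint under `identification: loadings`), and the
#' options of [measurement_model()], [ts_model_spec()] and
#' [panel_model_spec()]. See the bundled example:
#' `system.file("extdata", "liss_structure.yaml", package = "lvgvar")`.
#'
#' @param path YAML file path.
#' @return A `ts_lvgvar_spec` or `panel_lvgvar_spec` with saturated (all
#'   free) networks.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$kind) || !cfg$kind %in% c("ts", "panel")) {
    stop("config needs kind: ts or panel", call. = FALSE)
  }
  if (is.null(cfg$factors) || !length(cfg$factors)) {
    stop("config needs a non-empty factors map", call. = FALSE)
  }
  indicators <- unlist(cfg$factors, use.names = FALSE)
  if (anyDuplicated(indicators)) {
    stop("an indicator may load on one factor only in a config", call. = FALSE)
  }
  lam <- matrix(0, length(indicators), length(cfg$factors),
                dimnames = list(indicators, names(cfg$factors)))
  for (f in names(cfg$factors)) lam[cfg$factors[[f]], f] <- 1
  mm <- measurement_model(
    lam,
    residual = cfg$residual %||% "chol",
    identification = cfg$identification %||% "loadings")
  if (cfg$kind == "ts") {
    spec <- ts_model_spec(mm)
  } else {
    fix_b <- integer(0)
    if (!is.null(cfg$fixed_between_residual)) {
      fix_b <- match(cfg$fixed_between_residual, indicators)
      if (anyNA(fix_b)) stop("unknown indicator in fixed_between_residual",
                             call. = FALSE)
    }
    presence <- NULL
    n_waves <- cfg$waves %||% 3
    if (!is.null(cfg$absent)) {
      presence <- matrix(TRUE, length(indicators), n_waves,
                         dimnames = list(indicators, NULL))
      for (a in cfg$absent) presence[a$item, a$wave] <- FALSE
    }
    spec <- panel_model_spec(mm, n_waves = n_waves,
                             fix_between_residual = fix_b,
                             presence = presence)
  }
  spec
}

#' Write the configuration of a specification to YAML
#'
#' Serializes the factor structure and options of a specification built from
#' a simple-structure measurement model; round-trips through
#' [read_model_config()].
#'
#' @param spec A model specification.
#' @param path Output YAML path.
#' @return Invisibly, the path.
#' @export
write_model_config <- function(spec, path) {
  m <- spec$measurement
  lam <- m$lambda$value != 0 | m$lambda$free
  if (any(rowSums(lam) != 1)) {
    stop("only simple-structure models serialize to a config", call. = FALSE)
  }
  factors <- lapply(seq_len(ncol(lam)), function(f)
    m$indicator_labels[lam[, f]])
  names(factors) <- m$latent_labels
  cfg <- list(kind = if (inherits(spec, "ts_lvgvar_spec")) "ts" else "panel",
              identification = m$identification,
              residual = m$resid$type,
              factors = factors)
  if (inherits(spec, "panel_lvgvar_spec")) {
    cfg$waves <- spec$n_waves
    fixed_b <- which(!spec$resid_between$free & spec$resid_between$value == 0)
    if (length(fixed_b)) {
      cfg$fixed_between_residual <- m$indicator_labels[fixed_b]
    }
    if (!all(spec$presence)) {
      holes <- which(!spec$presence, arr.ind = TRUE)
      cfg$absent <- lapply(seq_len(nrow(holes)), function(i)
        list(item = m$indicator_labels[holes[i, 1]],
             wave = unname(holes[i, 2])))
    }
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}
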