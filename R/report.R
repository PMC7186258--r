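# Result export: fit reports (text + JSON) and network edge lists.

#' Write a fit report
#'
#' Writes a human-readable text summary (`<prefix>_summary.txt`), a
#' structured JSON summary (`<prefix>_fit.json`, requires jsonlite), the
#' parameter estimates (`<prefix>_estimates.csv`), and edge lists of the
#' estimated networks (`<prefix>_<family>_edges.csv`).
#'
#' @param fit A converged `lvgvar_fit`.
#' @param prefix Output path prefix.
#' @return Invisibly, the vector of files written.
#' @export
write_fit_report <- function(fit, prefix) {
  stopifnot(inherits(fit, "lvgvar_fit"))
  files <- character(0)
  txt <- paste0(prefix, "_summary.txt")
  con <- file(txt, "w")
  sink(con)
  print(fit)
  sink()
  close(con)
  files <- c(files, txt)
  if (!is.null(fit$estimates)) {
    est_csv <- paste0(prefix, "_estimates.csv")
    utils::write.csv(fit$estimates, est_csv, row.names = FALSE)
    files <- c(files, est_csv)
  }
  if (requireNamespace("jsonlite", quietly = TRUE) && !is.null(fit$indices)) {
    js <- paste0(prefix, "_fit.json")
    jsonlite::write_json(
      list(converged = fit$converged, n = fit$n, free_parameters = fit$k,
           df = fit$df, fit_value = fit$fit_value,
           minus2_loglik = fit$minus2_loglik, indices = fit$indices),
      js, auto_unbox = TRUE, digits = NA)
    files <- c(files, js)
  }
  for (net in estimated_networks(fit)) {
    f <- paste0(prefix, "_", net$family, "_edges.csv")
    network_edge_list(net$object, f, labels = net$labels)
    files <- c(files, f)
  }
  invisible(files)
}

# The estimated network matrices of a fitted model, as exportable objects.
estimated_networks <- function(fit) {
  spec <- fit$spec
  labels <- spec$measurement$latent_labels
  out <- list(
    list(family = "temporal",
         object = spec$beta$value, labels = labels),
    list(family = "contemporaneous",
         object = gaussian_network(spec$omega_zeta$value,
                                   spec$delta_zeta$value,
                                   mask = spec$omega_zeta$free),
         labels = labels))
  if (inherits(spec, "panel_lvgvar_spec")) {
    out <- c(out, list(
      list(family = "between",
           object = gaussian_network(spec$omega_between$value,
                                     spec$delta_between$value,
                                     mask = spec$omega_between$free),
           labels = labels)))
  }
  out
}
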