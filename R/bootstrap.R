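# Case-drop bootstrap for structure stability: resample, rerun the full
# search pipeline, tally signed edge inclusions.

#' Case-drop resampling
#'
#' Removes a fixed proportion of cases. For time-series data a contiguous
#' block of occasions is removed, starting from an occasion chosen at
#' random; when the block would run past the end of the series the remainder
#' is removed from the start (wrap rule; set `wrap = FALSE` to truncate at
#' the series end instead, removing fewer cases). For panel data a uniformly
#' random subject subset is removed. `ceiling(proportion * n)` cases are
#' dropped.
#'
#' @param data A [timeseries_dataset()] or [panel_dataset()].
#' @param proportion Proportion of cases to drop, in \[0, 1).
#' @param mode `"block"` (time series) or `"subjects"` (panel); defaults to
#'   the mode matching the data kind.
#' @param seed Seed making the draw reproducible.
#' @param wrap Wrap the dropped block around the series end (default TRUE).
#' @return The subsetted dataset.
#' @export
casedrop_resample <- function(data, proportion, mode = NULL, seed = NULL,
                              wrap = TRUE) {
  stopifnot(inherits(data, "lvgvar_dataset"))
  if (proportion < 0 || proportion >= 1) {
    stop("proportion must lie in [0, 1)", call. = FALSE)
  }
  if (is.null(mode)) mode <- if (data$kind == "timeseries") "block" else "subjects"
  if (data$kind == "timeseries" && mode != "block") {
    stop("time-series data use mode = 'block'", call. = FALSE)
  }
  if (data$kind == "panel" && mode != "subjects") {
    stop("panel data use mode = 'subjects'", call. = FALSE)
  }
  n <- nrow(data$values)
  n_drop <- ceiling(proportion * n)
  if (n - n_drop < 2) {
    stop(structure(class = c("lvgvar_data_error", "error", "condition"),
                   list(message = "resampling would leave fewer than 2 cases",
                        call = sys.call())))
  }
  if (n_drop == 0) return(data)
  pick <- function() {
    if (mode == "block") {
      start <- sample.int(n, 1)
      idx <- start + seq_len(n_drop) - 1L
      if (wrap) ((idx - 1L) %% n) + 1L else idx[idx <= n]
    } else {
      sample.int(n, n_drop)
    }
  }
  drop_idx <- if (is.null(seed)) pick() else with_seed(seed, pick())
  keep <- setdiff(seq_len(n), drop_idx)
  if (data$kind == "timeseries") {
    timeseries_dataset(data$values[keep, , drop = FALSE],
                       blocks = data$blocks[keep],
                       occasions = data$occasions[keep])
  } else {
    out <- data
    out$values <- data$values[keep, , drop = FALSE]
    out
  }
}

#' Case-drop bootstrap of the model-search pipeline
#'
#' For each replicate the data are resampled with [casedrop_resample()], the
#' full pipeline (saturated fit, pruning, search strategy) is rerun, and the
#' signed included edges of the final model are recorded. Failed replicates
#' are counted, never imputed. Replicate-level seeds are derived
#' deterministically from the master seed, so an identical master seed
#' reproduces the summary exactly.
#'
#' @param data A [timeseries_dataset()] or [panel_dataset()].
#' @param spec The saturated model specification.
#' @param n_boot Number of bootstrap replicates.
#' @param proportion Proportion of cases dropped per replicate (default
#'   0.25).
#' @param alpha,adjustment,strategy Search settings, see [search_pipeline()].
#' @param seed Master seed.
#' @param mode Resampling mode, see [casedrop_resample()].
#' @return Object of class `bootstrap_summary`: per-edge inclusion counts
#'   split by sign, inclusion proportions, a co-inclusion count matrix, and
#'   the settings.
#' @export
bootstrap_search <- function(data, spec, n_boot = 1000, proportion = 0.25,
                             alpha = 0.01, adjustment = "none",
                             strategy = "modelsearch", seed = 1,
                             mode = NULL) {
  stopifnot(inherits(data, "lvgvar_dataset"))
  pt <- param_table(saturate_networks(spec))
  edges <- pt[pt$searchable, c("id", "family", "row", "col")]
  n_e <- nrow(edges)
  pos <- neg <- numeric(n_e)
  co <- matrix(0, n_e, n_e, dimnames = list(edges$id, edges$id))
  succeeded <- 0
  for (b in seq_len(n_boot)) {
    seed_b <- derive_seed(seed, b)
    res <- tryCatch({
      dat_b <- casedrop_resample(data, proportion, mode = mode, seed = seed_b)
      out <- search_pipeline(spec, dat_b, alpha = alpha,
                             adjustment = adjustment, strategy = strategy)
      if (!isTRUE(out$converged)) NULL else out
    }, error = function(e) NULL)
    if (is.null(res)) next
    succeeded <- succeeded + 1
    pt_b <- param_table(res$spec)
    se_b <- pt_b[pt_b$searchable, , drop = FALSE]
    inc <- se_b$free & se_b$value != 0
    pos <- pos + (inc & se_b$value > 0)
    neg <- neg + (inc & se_b$value < 0)
    co[inc, inc] <- co[inc, inc] + 1
  }
  edges$count <- pos + neg
  edges$pos_count <- pos
  edges$neg_count <- neg
  edges$proportion <- if (succeeded > 0) edges$count / succeeded else NA_real_
  structure(list(edges = edges, coinclusion = co, attempted = n_boot,
                 succeeded = succeeded,
                 settings = list(proportion = proportion, alpha = alpha,
                                 adjustment = adjustment, strategy = strategy,
                                 mode = mode, seed = seed)),
            class = "bootstrap_summary")
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat("Case-drop bootstrap:", x$succeeded, "of", x$attempted,
      "replicates succeeded (drop proportion",
      x$settings$proportion, ")\n")
  inc <- x$edges[x$edges$count > 0, , drop = FALSE]
  cat(nrow(inc), "edges included at least once\n")
  invisible(x)
}

#' Merge two bootstrap summaries with identical settings
#'
#' Counts are additive, so stability summaries computed in separate batches
#' can be combined.
#'
#' @param a,b `bootstrap_summary` objects run with the same settings (apart
#'   from the seed).
#' @return The merged `bootstrap_summary`.
#' @export
merge_bootstrap <- function(a, b) {
  stopifnot(inherits(a, "bootstrap_summary"), inherits(b, "bootstrap_summary"))
  sa <- a$settings; sb <- b$settings
  if (!identical(sa[setdiff(names(sa), "seed")], sb[setdiff(names(sb), "seed")]) ||
      !identical(a$edges$id, b$edges$id)) {
    stop("summaries have different settings or edge sets", call. = FALSE)
  }
  out <- a
  out$edges$count <- a$edges$count + b$edges$count
  out$edges$pos_count <- a$edges$pos_count + b$edges$pos_count
  out$edges$neg_count <- a$edges$neg_count + b$edges$neg_count
  out$attempted <- a$attempted + b$attempted
  out$succeeded <- a$succeeded + b$succeeded
  out$edges$proportion <- if (out$succeeded > 0) out$edges$count / out$succeeded
                          else NA_real_
  out$coinclusion <- a$coinclusion + b$coinclusion
  out
}

#' Export a bootstrap summary as tabular counts
#'
#' One CSV panel per network family mirroring the published layout
#' (temporal / contemporaneous / between), with total, positive and negative
#' inclusion counts, plus a proportion-weighted edge list.
#'
#' @param summary A `bootstrap_summary`.
#' @param path Prefix for the written files
#'   (`<path>_<family>.csv`, `<path>_edges.csv`).
#' @return Invisibly, the per-family list of data frames.
#' @export
write_bootstrap_summary <- function(summary, path) {
  stopifnot(inherits(summary, "bootstrap_summary"))
  fams <- split(summary$edges, summary$edges$family)
  for (fam in names(fams)) {
    utils::write.csv(fams[[fam]],
                     paste0(path, "_", fam, ".csv"), row.names = FALSE)
  }
  el <- summary$edges[summary$edges$count > 0,
                      c("id", "family", "row", "col", "proportion")]
  utils::write.csv(el, paste0(path, "_edges.csv"), row.names = FALSE)
  invisible(fams)
}
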