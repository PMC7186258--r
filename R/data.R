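#' Datasets for lvgvar modeling
#'
#' Light containers validating the three input kinds: single-subject time
#' series (occasions in temporal order, a block identifier delimiting valid
#' consecutive pairs, e.g. days), multi-wave panel data (one row per subject,
#' columns indicator-by-wave), and summary moments (covariance + means + n).
#' Missing values are carried as `NA` and never imputed.
#'
#' @param values Numeric matrix of observations (occasions x variables).
#' @param blocks Block identifier per occasion (e.g. day); consecutive pairs
#'   are only formed within a block. Defaults to a single block.
#' @param occasions Numeric occasion index, strictly increasing within blocks.
#' @return An object of class `lvgvar_dataset`.
#' @export
timeseries_dataset <- function(values, blocks = NULL, occasions = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  labels <- colnames(values) %||% paste0("y", seq_len(ncol(values)))
  if (anyDuplicated(labels)) stop("duplicate variable labels", call. = FALSE)
  colnames(values) <- labels
  n <- nrow(values)
  if (is.null(blocks)) blocks <- rep(1L, n)
  if (length(blocks) != n) stop("block identifier has wrong length", call. = FALSE)
  if (is.null(occasions)) occasions <- seq_len(n)
  if (length(occasions) != n) stop("occasion index has wrong length", call. = FALSE)
  for (b in unique(blocks)) {
    occ <- occasions[blocks == b]
    if (any(diff(occ) <= 0)) {
      stop(sprintf("occasions not strictly increasing within block %s", b),
           call. = FALSE)
    }
  }
  structure(list(kind = "timeseries", values = values, labels = labels,
                 blocks = blocks, occasions = as.numeric(occasions)),
            class = "lvgvar_dataset")
}

#' @rdname timeseries_dataset
#' @param wide Numeric matrix, one row per subject, columns named
#'   `item@wave` (e.g. `SE1@2013`) or described by `layout`.
#' @param layout Optional data frame with columns `column`, `item`, `wave`
#'   mapping column names to indicators and waves.
#' @export
panel_dataset <- function(wide, layout = NULL) {
  wide <- as.matrix(wide)
  storage.mode(wide) <- "double"
  cols <- colnames(wide)
  if (is.null(cols)) stop("panel data need column names", call. = FALSE)
  if (anyDuplicated(cols)) stop("duplicate column labels", call. = FALSE)
  if (is.null(layout)) {
    parts <- strsplit(cols, "@", fixed = TRUE)
    if (any(lengths(parts) != 2)) {
      stop("panel columns must follow the item@wave convention or a layout map",
           call. = FALSE)
    }
    layout <- data.frame(column = cols,
                         item = vapply(parts, `[[`, "", 1),
                         wave = vapply(parts, `[[`, "", 2),
                         stringsAsFactors = FALSE)
  }
  if (!all(cols %in% layout$column)) stop("layout does not cover all columns", call. = FALSE)
  items <- unique(layout$item)
  waves <- unique(layout$wave)
  # wave-major stacked order: all items at wave 1, then wave 2, ...
  presence <- matrix(FALSE, length(items), length(waves),
                     dimnames = list(items, waves))
  ord <- character(0)
  for (w in waves) for (it in items) {
    cl <- layout$column[layout$item == it & layout$wave == w]
    if (length(cl) == 1) {
      presence[it, w] <- TRUE
      ord <- c(ord, cl)
    } else if (length(cl) > 1) {
      stop(sprintf("item %s mapped twice at wave %s", it, w), call. = FALSE)
    }
  }
  structure(list(kind = "panel", values = wide[, ord, drop = FALSE],
                 labels = items, waves = waves, presence = presence,
                 layout = layout), class = "lvgvar_dataset")
}

#' @rdname timeseries_dataset
#' @param covariance Symmetric sample covariance matrix (divisor n).
#' @param means Sample mean vector.
#' @param n Number of cases.
#' @export
moments_dataset <- function(covariance, means, n) {
  covariance <- as.matrix(covariance)
  if (nrow(covariance) != ncol(covariance) ||
      max(abs(covariance - t(covariance))) >
        1e-8 * max(1, max(abs(covariance)))) {
    stop("covariance must be square and symmetric", call. = FALSE)
  }
  if (length(means) != nrow(covariance)) stop("means have wrong length", call. = FALSE)
  labels <- colnames(covariance) %||% names(means) %||%
    paste0("y", seq_len(length(means)))
  structure(list(kind = "moments", covariance = covariance,
                 means = as.numeric(means), n = n, labels = labels),
            class = "lvgvar_dataset")
}

#' @export
print.lvgvar_dataset <- function(x, ...) {
  switch(x$kind,
    timeseries = cat("Time-series dataset:", nrow(x$values), "occasions x",
                     ncol(x$values), "variables in", length(unique(x$blocks)),
                     "block(s)\n"),
    panel = cat("Panel dataset:", nrow(x$values), "subjects,",
                length(x$labels), "indicators x", length(x$waves), "waves\n"),
    moments = cat("Moment dataset:", length(x$means), "variables, n =", x$n, "\n"))
  invisible(x)
}

read_csv_checked <- function(path, na_strings) {
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(unique(nf)) > 1) {
    bad <- which(nf != nf[1])[1]
    stop(sprintf("ragged CSV: line %d has %d fields, expected %d",
                 bad, nf[bad], nf[1]), call. = FALSE)
  }
  utils::read.csv(path, na.strings = na_strings, check.names = FALSE)
}

#' Read a single-subject time-series CSV
#'
#' @param path CSV path; one row per measurement occasion in temporal order.
#' @param block_column Name of the column delimiting blocks (e.g. day);
#'   optional.
#' @param occasion_column Name of the numeric occasion-index column; optional.
#' @param na_strings Tokens treated as missing (empty cells always are).
#' @return A `timeseries` [timeseries_dataset()].
#' @export
read_timeseries <- function(path, block_column = NULL, occasion_column = NULL,
                            na_strings = c("", "NA")) {
  df <- read_csv_checked(path, na_strings)
  blocks <- NULL; occasions <- NULL
  if (!is.null(block_column)) {
    if (!block_column %in% names(df)) stop("block column not found", call. = FALSE)
    blocks <- df[[block_column]]
    df[[block_column]] <- NULL
  }
  if (!is.null(occasion_column)) {
    occasions <- df[[occasion_column]]
    df[[occasion_column]] <- NULL
  }
  timeseries_dataset(as.matrix(df), blocks = blocks, occasions = occasions)
}

#' Read a wide panel CSV (columns item@wave)
#'
#' @param path CSV path, one row per subject.
#' @param id_column Optional subject-identifier column, dropped from the data.
#' @param layout Optional layout map, see [panel_dataset()].
#' @param na_strings Missing-value tokens.
#' @return A `panel` [panel_dataset()].
#' @export
read_panel <- function(path, id_column = NULL, layout = NULL,
                       na_strings = c("", "NA")) {
  df <- read_csv_checked(path, na_strings)
  if (!is.null(id_column)) df[[id_column]] <- NULL
  panel_dataset(as.matrix(df), layout = layout)
}

#' Read summary moments (covariance CSV + means CSV + n)
#'
#' @param cov_path CSV holding a labeled square covariance matrix (first
#'   column = row labels).
#' @param means_path CSV with columns `label` and `mean`.
#' @param n Number of cases.
#' @return A `moments` [moments_dataset()].
#' @export
read_moments <- function(cov_path, means_path, n) {
  cv <- utils::read.csv(cov_path, check.names = FALSE)
  rn <- cv[[1]]
  cv <- as.matrix(cv[, -1, drop = FALSE])
  rownames(cv) <- rn
  if (!identical(rownames(cv), colnames(cv))) {
    stop("covariance row and column labels disagree", call. = FALSE)
  }
  mn <- utils::read.csv(means_path, check.names = FALSE)
  if (!all(c("label", "mean") %in% names(mn))) {
    stop("means file needs columns 'label' and 'mean'", call. = FALSE)
  }
  if (!identical(mn$label, rownames(cv))) {
    stop("means labels do not match covariance labels", call. = FALSE)
  }
  moments_dataset(cv, stats::setNames(mn$mean, mn$label), n)
}

#' Write a dataset back to CSV
#'
#' Values round-trip through [read_timeseries()] / [read_panel()]; missing
#' cells are written empty.
#'
#' @param dataset A `lvgvar_dataset`.
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "lvgvar_dataset"))
  if (dataset$kind == "timeseries") {
    df <- data.frame(block = dataset$blocks, occasion = dataset$occasions,
                     dataset$values, check.names = FALSE)
  } else if (dataset$kind == "panel") {
    df <- as.data.frame(dataset$values)
  } else stop("moment datasets are written with write_moments", call. = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_dataset
#' @param cov_path,means_path Output paths for the two moment files.
#' @export
write_moments <- function(dataset, cov_path, means_path) {
  stopifnot(identical(dataset$kind, "moments"))
  cv <- dataset$covariance
  dimnames(cv) <- list(dataset$labels, dataset$labels)
  utils::write.csv(data.frame(label = rownames(cv), cv, check.names = FALSE),
                   cov_path, row.names = FALSE)
  utils::write.csv(data.frame(label = dataset$labels, mean = dataset$means),
                   means_path, row.names = FALSE)
  invisible(cov_path)
}

#' Augmented (paired-occasion) data matrix for Toeplitz estimation
#'
#' For each occasion t a row holds the previous occasion's values followed by
#' the current values; the first occasion of every block gets missing lead
#' values, so effects crossing block boundaries (e.g. overnight) are removed.
#' The row count equals the occasion count.
#'
#' @param dataset A `timeseries` dataset.
#' @return Numeric matrix with `2 * n_y` columns (`<var>.lag`, then `<var>`).
#' @export
build_augmented <- function(dataset) {
  stopifnot(inherits(dataset, "lvgvar_dataset"),
            identical(dataset$kind, "timeseries"))
  y <- dataset$values
  n <- nrow(y); p <- ncol(y)
  lag <- matrix(NA_real_, n, p)
  blocks <- dataset$blocks
  same_block <- c(FALSE, blocks[-1] == blocks[-n])
  lag[same_block, ] <- y[which(same_block) - 1L, , drop = FALSE]
  out <- cbind(lag, y)
  colnames(out) <- c(paste0(colnames(y), ".lag"), colnames(y))
  out
}

#' Remove significant linear trends from a time series
#'
#' Each variable is regressed on the occasion index; when the slope is
#' significant at `alpha` the scores are replaced by the regression
#' residuals, otherwise left unchanged. Constant variables are skipped with a
#' warning.
#'
#' @param dataset A `timeseries` dataset.
#' @param alpha Significance level of the slope test (default 0.05).
#' @return The dataset with detrended values and an attribute `detrended`
#'   naming the variables that were replaced.
#' @export
detrend <- function(dataset, alpha = 0.05) {
  stopifnot(inherits(dataset, "lvgvar_dataset"),
            identical(dataset$kind, "timeseries"))
  y <- dataset$values
  tt <- dataset$occasions
  affected <- character(0)
  for (j in seq_len(ncol(y))) {
    obs <- !is.na(y[, j])
    if (sum(obs) < 3) next
    if (stats::var(y[obs, j]) == 0) {
      warning("skipping constant variable ", colnames(y)[j], call. = FALSE)
      next
    }
    fit <- stats::lm(y[, j] ~ tt)
    # an exact trend triggers the harmless perfect-fit warning in summary.lm
    sm <- suppressWarnings(summary(fit))
    pv <- sm$coefficients["tt", "Pr(>|t|)"]
    # an exact trend leaves zero residual variance and an undefined t-test
    if (!is.finite(pv)) pv <- if (abs(stats::coef(fit)["tt"]) > 0) 0 else 1
    if (pv < alpha) {
      y[obs, j] <- stats::residuals(fit)
      affected <- c(affected, colnames(y)[j])
    }
  }
  dataset$values <- y
  attr(dataset, "detrended") <- affected
  dataset
}
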