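# Sparse-structure search over the network parameters (temporal,
# contemporaneous and between-subject edges): significance pruning with
# multiplicity adjustments, score-test modification indices, step-up edge
# addition, and the combined BIC-optimizing stepwise search.

adjustment_method <- function(adjustment) {
  switch(adjustment, none = "none", bonferroni = "bonferroni",
         holm = "holm", fdr = "BH",
         stop("unknown adjustment: ", adjustment, call. = FALSE))
}

#' Prune non-significant network edges
#'
#' Fixes to zero every searchable network parameter whose (adjusted) p-value
#' exceeds `alpha`. The multiplicity-adjustment family is all searchable
#' parameters within one network matrix (temporal, contemporaneous and
#' between-subject networks are separate families). Non-network parameters
#' are untouched. The returned specification must be refit.
#'
#' @param fit A converged `lvgvar_fit` with standard errors.
#' @param alpha Significance level.
#' @param adjustment One of `"none"`, `"bonferroni"`, `"holm"`, `"fdr"`
#'   (Benjamini-Hochberg).
#' @return The pruned model specification.
#' @export
prune <- function(fit, alpha = 0.01,
                  adjustment = c("none", "bonferroni", "holm", "fdr")) {
  stopifnot(inherits(fit, "lvgvar_fit"))
  adjustment <- match.arg(adjustment)
  est <- fit$estimates
  sel <- which(est$searchable)
  if (length(sel) == 0) return(fit$spec)
  if (any(is.na(est$p[sel]))) {
    stop(structure(class = c("lvgvar_search_error", "error", "condition"),
                   list(message = "pruning requires p-values for all searchable parameters",
                        call = sys.call())))
  }
  spec <- fit$spec
  for (fam in unique(est$family[sel])) {
    rows <- sel[est$family[sel] == fam]
    padj <- stats::p.adjust(est$p[rows], method = adjustment_method(adjustment))
    drop <- rows[padj > alpha]
    for (r in drop) {
      spec <- spec_fix_edge(spec, est$family[r], est$row[r], est$col[r])
    }
  }
  spec
}

# Extended engine in which all currently fixed searchable edges are freed at
# their fixed value; used for score tests. Returns the engine, the extended
# theta, and index maps into it.
extended_engine <- function(fit) {
  spec <- fit$spec
  pt <- param_table(spec)
  cand <- pt[pt$searchable & !pt$free, , drop = FALSE]
  spec_ext <- spec
  for (r in seq_len(nrow(cand))) {
    spec_ext <- spec_free_edge(spec_ext, cand$family[r], cand$row[r],
                               cand$col[r], value = cand$value[r])
  }
  engine <- compile_model(spec_ext)
  theta <- spec_get_free(spec_ext)
  list(engine = engine, theta = theta,
       free_ids = fit$estimates$id, cand_ids = cand$id, cand = cand)
}

#' Modification indices for fixed network edges
#'
#' Score-test approximation of the chi-square decrease from freeing each
#' searchable edge currently fixed at zero: the squared gradient of the
#' objective at the constraint divided by the effective curvature (expected
#' information, partialing out the free parameters).
#'
#' @param fit A converged `lvgvar_fit`.
#' @return Data frame with one row per constrained searchable edge: `id`,
#'   `family`, `row`, `col`, `mi`, `p` (reference chi-square with 1 df).
#'   Zero rows when the networks are saturated.
#' @export
modification_indices <- function(fit) {
  stopifnot(inherits(fit, "lvgvar_fit"))
  if (!isTRUE(fit$converged)) stop("fit did not converge", call. = FALSE)
  ext <- extended_engine(fit)
  cand <- ext$cand
  if (nrow(cand) == 0) {
    return(data.frame(id = character(0), family = character(0),
                      row = integer(0), col = integer(0),
                      mi = numeric(0), p = numeric(0)))
  }
  md <- fit$data
  g <- engine_gradient(ext$engine, ext$theta, md) * (md$n / 2)
  info <- expected_information(ext$engine, ext$theta, md)
  ids <- ext$engine$fr$id
  ci <- match(ext$cand_ids, ids)
  fi <- setdiff(seq_along(ids), ci)
  mi <- rep(NA_real_, length(ci))
  den <- rep(NA_real_, length(ci))
  Iff <- info[fi, fi, drop = FALSE]
  X <- tryCatch(solve(Iff, info[fi, ci, drop = FALSE]), error = function(e) NULL)
  if (!is.null(X)) {
    den <- diag(info)[ci] - colSums(info[fi, ci, drop = FALSE] * X)
    ok <- is.finite(den) & den > 1e-12
    mi[ok] <- g[ci][ok]^2 / den[ok]
  }
  data.frame(id = cand$id, family = cand$family, row = cand$row,
             col = cand$col, mi = mi,
             p = stats::pchisq(mi, 1, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

# Sparse structures visited during a search are identified by which
# searchable edges are free; refits are memoized on that signature so
# revisited structures (also across search variants on the same data) are
# not refit.
edge_signature <- function(spec) {
  pt <- param_table(spec)
  paste(pt$id[pt$searchable & pt$free], collapse = ";")
}

refit <- function(fit, spec_new, cache = NULL, reltol = 1e-9) {
  if (is.null(cache)) {
    return(fit_lvgvar(spec_new, fit$data, method = fit$method, start = "spec",
                      saturated = fit$saturated, reltol = reltol))
  }
  key <- edge_signature(spec_new)
  hit <- cache[[key]]
  if (!is.null(hit) && attr(hit, "reltol") <= reltol) return(hit)
  out <- fit_lvgvar(spec_new, fit$data, method = fit$method, start = "spec",
                    saturated = fit$saturated, reltol = reltol)
  attr(out, "reltol") <- reltol
  cache[[key]] <- out
  out
}

trace_row <- function(action, id, bic_before, bic_after, stat) {
  data.frame(action = action, id = id, bic_before = bic_before,
             bic_after = bic_after, stat = stat, stringsAsFactors = FALSE)
}

#' Step-up model search
#'
#' Iteratively frees the constrained edge with the strongest modification
#' index (among those significant at `alpha`), refits, and keeps the change
#' only while BIC strictly decreases.
#'
#' @param fit A converged `lvgvar_fit`.
#' @param alpha Significance level for candidate modification indices.
#' @param max_steps Iteration cap.
#' @param cache Optional environment memoizing refits by sparse-structure
#'   signature (shared across strategies on the same data).
#' @return The best `lvgvar_fit`, with the accepted/rejected step log in
#'   `attr(, "search_trace")`.
#' @export
stepup <- function(fit, alpha = 0.01, max_steps = 50, cache = NULL) {
  stopifnot(inherits(fit, "lvgvar_fit"))
  trace <- trace_row(character(0), character(0), numeric(0), numeric(0),
                     numeric(0))
  current <- fit
  for (step in seq_len(max_steps)) {
    mi <- modification_indices(current)
    mi <- mi[is.finite(mi$mi) & mi$p < alpha, , drop = FALSE]
    if (nrow(mi) == 0) break
    best <- mi[order(-mi$mi, mi$id), ][1, ]
    spec_new <- spec_free_edge(current$spec, best$family, best$row, best$col)
    cand_fit <- refit(current, spec_new, cache, reltol = 1e-8)
    if (!isTRUE(cand_fit$converged)) break
    if (cand_fit$indices$bic < current$indices$bic) {
      trace <- rbind(trace, trace_row("add", best$id, current$indices$bic,
                                      cand_fit$indices$bic, best$mi))
      current <- cand_fit
    } else {
      trace <- rbind(trace, trace_row("reject_add", best$id,
                                      current$indices$bic,
                                      cand_fit$indices$bic, best$mi))
      break
    }
  }
  attr(current, "search_trace") <- trace
  current
}

#' BIC-optimizing stepwise model search
#'
#' Starting from a converged fit (typically after pruning), repeatedly
#' evaluates single-edge changes: freeing constrained edges whose
#' modification index is significant at `alpha`, and fixing free edges that
#' are not significant at `alpha`. Each candidate is refit; the single change
#' with the largest BIC improvement is accepted per iteration (ties prefer
#' removal over addition, then lexicographic parameter order). The search
#' stops when no candidate improves BIC, so the final BIC never exceeds the
#' input BIC.
#'
#' @param fit A converged `lvgvar_fit`.
#' @param alpha Significance level gating the candidate set.
#' @param max_steps Iteration cap.
#' @param cache Optional refit-memoization environment, see [stepup()].
#' @return The BIC-optimal `lvgvar_fit` found, with the step log in
#'   `attr(, "search_trace")`.
#' @export
modelsearch <- function(fit, alpha = 0.01, max_steps = 50, cache = NULL) {
  stopifnot(inherits(fit, "lvgvar_fit"))
  trace <- trace_row(character(0), character(0), numeric(0), numeric(0),
                     numeric(0))
  current <- fit
  logn <- log(fit$n)
  for (step in seq_len(max_steps)) {
    cands <- list()
    mi <- modification_indices(current)
    mi <- mi[is.finite(mi$mi) & mi$p < alpha, , drop = FALSE]
    if (nrow(mi)) {
      for (r in seq_len(nrow(mi))) {
        # freeing an edge drops chi-square by about its modification index
        # at the cost of one BIC penalty term
        cands[[length(cands) + 1]] <- list(
          action = "add", id = mi$id[r], stat = mi$mi[r],
          predicted = mi$mi[r] - logn,
          spec = spec_free_edge(current$spec, mi$family[r], mi$row[r], mi$col[r]))
      }
    }
    est <- current$estimates
    rem <- which(est$searchable & !is.na(est$p) & est$p > alpha)
    for (r in rem) {
      # fixing an edge raises chi-square by about its Wald statistic and
      # recovers one BIC penalty term
      cands[[length(cands) + 1]] <- list(
        action = "remove", id = est$id[r], stat = est$p[r],
        predicted = logn - est$z[r]^2,
        spec = spec_fix_edge(current$spec, est$family[r], est$row[r], est$col[r]))
    }
    if (length(cands) == 0) break
    # Deterministic evaluation order: predicted BIC improvement first, with
    # removals preferred and lexicographic ids breaking ties. Actual
    # improvements are measured by refitting; evaluation stops once no
    # remaining candidate's score/Wald prediction can plausibly beat the
    # best measured improvement (factor-2 safety margin).
    ord <- order(-vapply(cands, function(c) c$predicted, 0),
                 vapply(cands, function(c) c$action != "remove", TRUE),
                 vapply(cands, function(c) c$id, ""))
    cands <- cands[ord]
    best <- NULL
    best_gain <- 0
    for (cand in cands) {
      # candidates are sorted by predicted gain, so stop once the remaining
      # predictions are hopeless (far below zero, or far below the best
      # measured gain)
      if (is.null(best)) {
        if (cand$predicted < -15) break
      } else if (best_gain > 2 * cand$predicted + 2) break
      cf <- refit(current, cand$spec, cache, reltol = 1e-8)
      if (!isTRUE(cf$converged)) next
      gain <- current$indices$bic - cf$indices$bic
      if (gain > 1e-9 && gain > best_gain + 1e-9) {
        best <- list(fit = cf, action = cand$action, id = cand$id,
                     stat = cand$stat)
        best_gain <- gain
      }
    }
    if (is.null(best)) break
    trace <- rbind(trace, trace_row(best$action, best$id,
                                    current$indices$bic,
                                    best$fit$indices$bic, best$stat))
    current <- best$fit
  }
  attr(current, "search_trace") <- trace
  current
}

#' Full estimation pipeline: saturated fit, prune, then search
#'
#' Runs the staged search workflow used throughout: (1) fit the model with
#' fully connected networks, (2) fix to zero all network edges not
#' significant at `alpha` (with the chosen multiplicity adjustment) and
#' refit, (3) optionally continue with step-up addition or the BIC-optimizing
#' stepwise search.
#'
#' @param spec The saturated model specification.
#' @param data Data accepted by [fit_lvgvar()].
#' @param alpha Significance level used throughout.
#' @param adjustment Multiplicity adjustment for the pruning step.
#' @param strategy `"prune"` (stop after pruning), `"stepup"`, or
#'   `"modelsearch"`.
#' @param method Estimation method passed to [fit_lvgvar()].
#' @param base_fit Optionally, an already-computed saturated fit (reused when
#'   several strategies are run on the same data).
#' @param cache Optional refit-memoization environment, see [stepup()].
#' @return An `lvgvar_fit` with attributes `search_trace` and
#'   `search_settings`; `NULL` fit value and `converged = FALSE` when the
#'   base estimation failed.
#' @export
search_pipeline <- function(spec, data, alpha = 0.01,
                            adjustment = c("none", "bonferroni", "holm", "fdr"),
                            strategy = c("modelsearch", "prune", "stepup"),
                            method = "fiml", base_fit = NULL, cache = NULL) {
  adjustment <- match.arg(adjustment)
  strategy <- match.arg(strategy)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  if (is.null(base_fit)) base_fit <- fit_lvgvar(spec, data, method = method)
  settings <- list(alpha = alpha, adjustment = adjustment, strategy = strategy)
  if (!isTRUE(base_fit$converged) || identical(base_fit$diagnostics$se, "information_singular")) {
    attr(base_fit, "search_settings") <- settings
    return(base_fit)
  }
  pruned_spec <- prune(base_fit, alpha = alpha, adjustment = adjustment)
  pruned <- refit(base_fit, pruned_spec, cache)
  if (!isTRUE(pruned$converged)) {
    attr(pruned, "search_settings") <- settings
    return(pruned)
  }
  out <- switch(strategy,
                prune = pruned,
                stepup = stepup(pruned, alpha = alpha, cache = cache),
                modelsearch = modelsearch(pruned, alpha = alpha, cache = cache))
  attr(out, "search_settings") <- settings
  out
}
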