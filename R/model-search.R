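# Iterative unidimensionality search: drop as few indicators as possible to
# reach a good-fitting single-factor model, breaking ties by AIC/BIC.

#' Prune a single-factor model to good fit
#'
#' Fits the full single-factor model first; if it already meets the
#' good-fit conjunction the search stops with zero drops. Otherwise, at each
#' level `k = 1..max_drop`, every one of the `choose(p, k)` drop-k
#' candidates is fitted; if any are good-fitting the search stops at that
#' level and, among the good candidates, the one with the lowest AIC and
#' BIC is retained. When AIC and BIC disagree, both winners are reported
#' and the BIC choice is selected (the consistency-favoring criterion).
#' Candidates that fail to converge or are inadmissible never enter the
#' good-fit set but remain in the audit trail.
#'
#' @param data Data with the indicator columns.
#' @param spec Single-factor [cfa_spec()] with at least 4 indicators
#'   (3-indicator models are just-identified and cannot be judged by fit).
#' @param cutoffs Good-fit thresholds, see [good_fit()].
#' @param max_drop Maximum number of indicators to drop (default 2).
#' @param ... Passed to [fit_cfa()].
#' @return Object of class `prune_result`: `status` ("good" or
#'   "exhausted"), `dropped` (character vector), `fit` (retained fit),
#'   `spec` (retained spec), `candidates` (audit data frame of every fit
#'   with indices and verdicts), `aic_choice`, `bic_choice`,
#'   `tie_break_used`.
#' @export
prune_search <- function(data, spec, cutoffs = list(cfi = 0.95, tli = 0.95,
                                                    rmsea = 0.08, srmr = 0.08),
                         max_drop = 2L, ...) {
  stopifnot(inherits(spec, "cfa_spec"))
  if (length(spec$factor_names) != 1L)
    stop("prune_search operates on single-factor models")
  p <- length(spec$indicators)
  if (p < 4L)
    stop("need at least 4 indicators (a 3-indicator model is just-identified)")
  fname <- spec$factor_names[1L]
  audit <- list()
  fit_candidate <- function(drop) {
    keep <- setdiff(spec$indicators, drop)
    sp <- cfa_spec(stats::setNames(list(keep), fname),
                   identification = spec$identification,
                   meanstructure = spec$meanstructure)
    fit <- fit_cfa(data, sp, ...)
    row <- fit_summary_row(fit, model = if (length(drop))
      paste("drop", paste(drop, collapse = "+")) else "full")
    row$level <- length(drop)
    row$dropped <- paste(drop, collapse = "+")
    row$good <- good_fit(fit, cutoffs)
    audit[[length(audit) + 1L]] <<- row
    list(fit = fit, spec = sp, drop = drop, good = row$good,
         aic = fit$aic, bic = fit$bic)
  }
  full <- fit_candidate(character(0))
  result <- function(status, chosen, aic_choice = NULL, bic_choice = NULL,
                     tie = FALSE) {
    structure(list(status = status, dropped = chosen$drop, fit = chosen$fit,
                   spec = chosen$spec,
                   candidates = do.call(rbind, audit),
                   aic_choice = aic_choice, bic_choice = bic_choice,
                   tie_break_used = tie),
              class = "prune_result")
  }
  if (full$good) return(result("good", full))
  for (k in seq_len(max_drop)) {
    if (p - k < 4L) break
    combos <- utils::combn(spec$indicators, k, simplify = FALSE)
    cands <- lapply(combos, fit_candidate)
    good <- Filter(function(cc) cc$good, cands)
    if (length(good)) {
      aics <- vapply(good, `[[`, numeric(1), "aic")
      bics <- vapply(good, `[[`, numeric(1), "bic")
      i_aic <- which.min(aics)
      i_bic <- which.min(bics)
      chosen <- good[[i_bic]]
      return(result("good", chosen,
                    aic_choice = paste(good[[i_aic]]$drop, collapse = "+"),
                    bic_choice = paste(good[[i_bic]]$drop, collapse = "+"),
                    tie = i_aic != i_bic))
    }
  }
  result("exhausted", full)
}

#' @export
print.prune_result <- function(x, ...) {
  cat("Pruning search:", x$status, "\n")
  if (length(x$dropped)) cat("  dropped:", paste(x$dropped, collapse = ", "), "\n")
  else cat("  no indicators dropped\n")
  if (isTRUE(x$tie_break_used))
    cat("  AIC preferred", x$aic_choice, "but BIC choice", x$bic_choice,
        "was selected\n")
  cat("  candidates fitted:", nrow(x$candidates), "\n")
  invisible(x)
}

#' Compare per-task, flat, and second-order factor structures
#'
#' Fits (a) one single-factor model per task on that task's unit columns,
#' (b) a flat model with every unit loading on one factor, and (c) the
#' second-order model with task factors under a General ERN, all on the
#' same cases, and reports a fit-index table with good-fit verdicts.
#'
#' @param data Data containing all unit columns.
#' @param tasks Task labels.
#' @param n_units Units per task.
#' @param cutoffs Good-fit thresholds.
#' @param ... Passed to [fit_cfa()].
#' @return List with `table` (one row per model) and `fits` (named list of
#'   `cfa_fit` objects).
#' @export
compare_structures <- function(data, tasks, n_units = 5L,
                               cutoffs = list(cfi = 0.95, tli = 0.95,
                                              rmsea = 0.08, srmr = 0.08),
                               ...) {
  fac <- lapply(tasks, function(t) paste0(t, "_u", seq_len(n_units)))
  names(fac) <- tasks
  fits <- list()
  for (t in tasks)
    fits[[t]] <- fit_cfa(data, cfa_spec(fac[t]), ...)
  fits[["flat"]] <- fit_cfa(data,
                            cfa_spec(list(general = unlist(fac, use.names = FALSE))),
                            ...)
  fits[["second_order"]] <- fit_cfa(data, cfa_spec(fac, second_order = TRUE),
                                    ...)
  tab <- do.call(rbind, lapply(names(fits), function(nm)
    fit_summary_row(fits[[nm]], model = nm)))
  tab$good <- vapply(fits, good_fit, logical(1), cutoffs = cutoffs)
  list(table = tab, fits = fits)
}
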