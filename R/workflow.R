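# End-to-end workflow: simulate -> (epochs ->) extract -> fit -> search ->
# scores -> validity, with seeded per-stage substreams and CSV/JSON outputs.

#' Derive a per-stage seed from the run seed
#'
#' A single run seed governs every stage through a documented derivation
#' (the stage name is hashed into an offset), so individual stages can be
#' re-run stably without replaying earlier stages' random draws.
#'
#' @param seed Integer run seed.
#' @param stage Stage name.
#' @return Integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% 100003L
  as.integer((as.numeric(seed) + 10007 * h) %% 2147483629)
}

#' Fit the per-domain trait measurement models
#'
#' One single-factor CFA per trait domain with its facets as indicators,
#' pruned to good fit where necessary. Domains with only three facets are
#' just-identified and cannot be judged by fit; they are fitted as-is.
#'
#' @param facets Facet score table from [simulate_facets()].
#' @param config The configuration.
#' @param cutoffs Good-fit thresholds.
#' @param max_drop Maximum facets to drop per domain.
#' @return List with `table` (fit rows for every retained model),
#'   `searches` (named list of `prune_result` or `cfa_fit`), and `scores`
#'   (participant x domain latent score table).
#' @export
fit_trait_models <- function(facets, config,
                             cutoffs = list(cfi = 0.95, tli = 0.95,
                                            rmsea = 0.08, srmr = 0.08),
                             max_drop = 2L) {
  searches <- list()
  rows <- list()
  scores <- data.frame(participant_id = facets$participant_id)
  for (inst in names(config$trait_structure)) {
    st <- config$trait_structure[[inst]]
    for (d in names(st)) {
      cols <- facet_columns(config, inst, d)
      spec <- cfa_spec(stats::setNames(list(cols), d))
      if (length(cols) < 4L) {
        fit <- fit_cfa(facets, spec)
        searches[[d]] <- fit
        row <- fit_summary_row(fit, model = d)
        row$status <- "just-identified"
      } else {
        sr <- prune_search(facets, spec, cutoffs = cutoffs,
                           max_drop = max_drop)
        searches[[d]] <- sr
        fit <- sr$fit
        row <- fit_summary_row(fit, model = d)
        row$status <- sr$status
        row$dropped <- paste(sr$dropped, collapse = "+")
      }
      rows[[d]] <- row
      fs <- regression_factor_scores(fit, facets,
                                     id = facets$participant_id)
      scores[[d]] <- fs[[d]]
    }
  }
  list(table = do.call(rbind, lapply(rows, function(r) {
    if (is.null(r$dropped)) r$dropped <- ""
    r
  })), searches = searches, scores = scores)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes every stage end to end: latent population, facet scores, trial
#' simulation with adaptive behavior, trial screening and ERN-matrix
#' extraction, per-task/flat/second-order CFAs with pruning where needed,
#' trait-domain CFAs, regression factor scores, the ERN x trait MTMM
#' matrix, convergent/discriminant hypothesis scoring, and profile
#' similarities. Optionally writes every table to `out_dir` together with a
#' resolved-configuration snapshot.
#'
#' @param config An [population_config()].
#' @param out_dir Output directory (created if needed); `NULL` = no files.
#' @param seed Run seed (defaults to `config$seed`).
#' @param cutoffs Good-fit thresholds.
#' @param max_drop Maximum indicators dropped during pruning.
#' @return List of class `ern_run` with the stage artifacts: `latents`,
#'   `facets`, `trials`, `extraction`, `structure` (fit comparison),
#'   `task_searches`, `trait_models`, `ern_scores`, `mtmm`, `hypotheses`,
#'   `profiles`, `timings`.
#' @export
run_pipeline <- function(config = population_config(), out_dir = NULL,
                         seed = config$seed,
                         cutoffs = list(cfi = 0.95, tli = 0.95,
                                        rmsea = 0.08, srmr = 0.08),
                         max_drop = 2L) {
  t_start <- Sys.time()
  timings <- list()
  tick <- local({
    last <- Sys.time()
    function(stage) {
      now <- Sys.time()
      timings[[stage]] <<- as.numeric(difftime(now, last, units = "secs"))
      last <<- now
    }
  })

  latents <- simulate_population(config, seed = stage_seed(seed, "population"))
  tick("population")
  facets <- simulate_facets(latents, config, seed = stage_seed(seed, "facets"))
  tick("facets")
  sim <- simulate_trial_amplitudes(latents, config,
                                   seed = stage_seed(seed, "trials"))
  tick("trials")
  extraction <- extract_ern_matrix(sim$trials, config)
  tick("extract")

  mat <- extraction$matrix$data
  tasks <- config$tasks
  structure_cmp <- compare_structures(mat, tasks, n_units = config$n_units,
                                      cutoffs = cutoffs)
  # prune any task that is not already good-fitting
  task_searches <- list()
  task_fits <- list()
  for (t in tasks) {
    if (good_fit(structure_cmp$fits[[t]], cutoffs)) {
      task_fits[[t]] <- structure_cmp$fits[[t]]
    } else {
      sr <- prune_search(mat,
                         cfa_spec(stats::setNames(
                           list(paste0(t, "_u", seq_len(config$n_units))), t)),
                         cutoffs = cutoffs, max_drop = max_drop)
      task_searches[[t]] <- sr
      task_fits[[t]] <- sr$fit
    }
  }
  tick("fit")

  trait_models <- fit_trait_models(facets, config, cutoffs = cutoffs,
                                   max_drop = max_drop)
  tick("traits")

  # latent ERN scores: per-task scores from the (pruned) single-factor
  # models, General ERN from the second-order model; second-order task
  # scores kept as a labeled variant
  ern_scores <- data.frame(participant_id = mat$participant_id)
  for (t in tasks) {
    fs <- regression_factor_scores(task_fits[[t]], mat,
                                   id = mat$participant_id)
    ern_scores[[t]] <- fs[[t]]
  }
  so_scores <- regression_factor_scores(structure_cmp$fits$second_order, mat,
                                        id = mat$participant_id)
  ern_scores$general <- so_scores$general
  ern_scores_so <- so_scores
  colnames(ern_scores_so) <- c("participant_id", "general",
                               paste0(tasks, "_so"))
  tick("scores")

  mtmm <- correlate_scores(ern_scores, trait_models$scores)
  hyp <- evaluate_hypotheses(mtmm, hypothesis_pairs(tasks))
  instruments <- lapply(config$trait_structure, names)
  profiles <- profile_similarity(mtmm, instruments)
  tick("validity")

  run <- structure(list(
    config = config, seed = seed,
    latents = latents, facets = facets, trials = sim$trials,
    unit_truth = sim$unit_truth, extraction = extraction,
    structure = structure_cmp, task_searches = task_searches,
    task_fits = task_fits, trait_models = trait_models,
    ern_scores = ern_scores, ern_scores_second_order = ern_scores_so,
    mtmm = mtmm, hypotheses = hyp, profiles = profiles,
    timings = timings,
    elapsed = as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  ), class = "ern_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.ern_run <- function(x, ...) {
  cat("ERN pipeline run: n =", nrow(x$latents), "participants, seed", x$seed,
      sprintf("(%.1f s)\n", x$elapsed))
  cat("  structure fits:\n")
  tb <- x$structure$table
  for (i in seq_len(nrow(tb)))
    cat(sprintf("    %-13s chi2(%d) = %7.2f  CFI %.3f  SRMR %.3f  %s\n",
                tb$model[i], tb$df[i], tb$chi2[i], tb$cfi[i], tb$srmr[i],
                if (tb$good[i]) "good" else "not good"))
  cat(sprintf("  convergent %.0f%% / discriminant %.0f%% of hypothesis pairs\n",
              x$hypotheses$convergent_pct, x$hypotheses$discriminant_pct))
  invisible(x)
}

# Serialize every table of a run to CSV/JSON. write.csv output is
# deterministic, so reruns under the same seed are byte-identical.
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wp <- function(df, nm) utils::write.csv(df, file.path(out_dir, nm),
                                          row.names = FALSE)
  wp(run$latents, "latents.csv")
  wp(run$facets, "facets.csv")
  wp(run$trials, "trials.csv")
  wp(run$extraction$matrix$data, "ern_matrix.csv")
  rs <- run$extraction$matrix$reasons
  wp(data.frame(participant_id = rownames(rs), rs, check.names = FALSE),
     "ern_matrix_reasons.csv")
  if (!is.null(run$extraction$removed) && nrow(run$extraction$removed))
    wp(run$extraction$removed, "removal_log.csv")
  wp(run$structure$table, "fit_table.csv")
  search_rows <- lapply(names(run$task_searches), function(t) {
    df <- run$task_searches[[t]]$candidates
    df$task <- t
    df
  })
  if (length(search_rows)) wp(do.call(rbind, search_rows), "search_table.csv")
  wp(run$trait_models$table, "trait_fit_table.csv")
  wp(run$ern_scores, "ern_scores.csv")
  wp(run$ern_scores_second_order, "ern_scores_second_order.csv")
  wp(run$trait_models$scores, "trait_scores.csv")
  r <- run$mtmm$r
  wp(data.frame(measure = rownames(r), r, check.names = FALSE), "mtmm.csv")
  eff <- run$mtmm$effect
  wp(data.frame(measure = rownames(eff), eff, check.names = FALSE),
     "mtmm_effects.csv")
  prof_rows <- do.call(rbind, lapply(names(run$profiles), function(inst) {
    S <- run$profiles[[inst]]
    data.frame(instrument = inst, measure = rownames(S), S,
               check.names = FALSE)
  }))
  wp(prof_rows, "profile_similarity.csv")
  summary <- list(
    seed = run$seed, n_participants = nrow(run$latents),
    convergent_pct = run$hypotheses$convergent_pct,
    discriminant_pct = run$hypotheses$discriminant_pct,
    n_error_free_units = sum(run$extraction$matrix$reasons == "no-error-unit",
                             na.rm = TRUE),
    structure_good = stats::setNames(as.list(run$structure$table$good),
                                     run$structure$table$model))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg <- run$config
  cfg_json <- lapply(cfg, function(x) if (is.matrix(x))
    list(dimnames = dimnames(x), values = x) else x)
  jsonlite::write_json(cfg_json, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}

#' Generate small packaged example inputs
#'
#' Writes seeded synthetic datasets (trial table, facet table, latent
#' table, configuration snapshot) to a directory; `size = "tiny"` uses 12
#' participants, `"default"` the configured sample size.
#'
#' @param out_dir Output directory.
#' @param size "tiny" or "default".
#' @param seed Seed.
#' @return The output directory, invisibly.
#' @export
make_fixtures <- function(out_dir, size = c("tiny", "default"), seed = 1L) {
  size <- match.arg(size)
  n <- if (size == "tiny") 12L else 93L
  config <- population_config(n_participants = n, seed = seed)
  latents <- simulate_population(config, seed = stage_seed(seed, "population"))
  facets <- simulate_facets(latents, config, seed = stage_seed(seed, "facets"))
  sim <- simulate_trial_amplitudes(latents, config,
                                   seed = stage_seed(seed, "trials"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(latents, file.path(out_dir, "latents.csv"),
                   row.names = FALSE)
  utils::write.csv(facets, file.path(out_dir, "facets.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$trials, file.path(out_dir, "trials.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(size = size, seed = seed, n_participants = n),
                       file.path(out_dir, "fixture_config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
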