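# Behavioral simulator: block-wise adaptive presentation time and a logistic
# psychometric function for error probability.

# Error probability at presentation time t (ms) for a given task; monotone
# decreasing in t. x0 is placed so that an average participant commits
# errors at `target_error_rate` at the initial presentation time.
error_probability <- function(time_ms, config, task, ability_shift = 0) {
  s <- config$error_slope[[task]]
  p0 <- config$target_error_rate
  x0 <- config$presentation_start[[task]] - s * log(1 / p0 - 1)
  1 / (1 + exp((time_ms - (x0 + ability_shift)) / s))
}

# Staircase update given the previous block's accuracy.
adapt_presentation_time <- function(time_ms, accuracy, config, task) {
  band <- config$accuracy_band
  step <- config$presentation_step[[task]]
  if (accuracy < band[1L]) time_ms <- time_ms + step
  else if (accuracy > band[2L]) time_ms <- time_ms - step
  max(time_ms, step)
}

#' Simulate one participant's trial results for one task
#'
#' Trials are organized in blocks (default 10 blocks of 30 trials). The
#' stimulus presentation time starts at the task's initial value and is
#' lengthened by one step if the previous block's accuracy fell below the
#' band and shortened by one step if it exceeded it, which keeps long-run
#' accuracy inside the configured band. Error probability is a logistic,
#' monotone-decreasing function of presentation time, shifted per
#' participant by an ability offset.
#'
#' @param config An [population_config()].
#' @param task Task label.
#' @param ability_shift Participant ability offset in ms (positive = more
#'   error-prone at a given presentation time).
#' @return Data frame with `block`, `trial_index`, `presentation_ms`,
#'   `error_prob`, and `result` ("correct" or "error").
#' @export
simulate_behavior <- function(config, task, ability_shift = 0) {
  stopifnot(inherits(config, "ern_config"), task %in% config$tasks)
  n_blocks <- config$n_blocks
  per_block <- config$n_trials_per_task / n_blocks
  if (per_block != round(per_block))
    stop("n_trials_per_task must be divisible by n_blocks")
  time_ms <- config$presentation_start[[task]]
  out <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    p_err <- error_probability(time_ms, config, task, ability_shift)
    res <- ifelse(stats::runif(per_block) < p_err, "error", "correct")
    out[[b]] <- data.frame(
      block = b,
      trial_index = (b - 1L) * per_block + seq_len(per_block),
      presentation_ms = time_ms, error_prob = p_err, result = res,
      stringsAsFactors = FALSE)
    time_ms <- adapt_presentation_time(time_ms, mean(res == "correct"),
                                       config, task)
  }
  do.call(rbind, out)
}

#' Simulate trial-level amplitudes for the whole sample
#'
#' For each participant and task, behavior is simulated first (unless
#' supplied); correct trials get `baseline + trial noise` and error trials
#' additionally carry the participant's true unit-level ERN, which follows
#' the configured second-order factor model:
#' `ern_mean_t + ern_sd_t * (lambda_tu * task_factor + sqrt(1 - lambda_tu^2)
#' * unit_noise)`. Units are the `n_units` consecutive blocks of
#' `n_trials / n_units` trials.
#'
#' @param latents Latent table from [simulate_population()].
#' @param config The configuration.
#' @param seed Seed (defaults to `config$seed + 2`).
#' @param trial_noise_sd Override for the trial measurement noise SD.
#' @param unit_noise If `FALSE`, unit residuals are suppressed (unit true
#'   scores are exactly loading * task factor, useful for noiseless
#'   round-trip checks).
#' @return List with `trials` (long data frame: `participant_id`, `task`,
#'   `trial_index`, `block`, `unit`, `result`, `amplitude`) and `unit_truth`
#'   (long data frame of true unit ERN values per participant, task, unit).
#' @export
simulate_trial_amplitudes <- function(latents, config,
                                      seed = config$seed + 2L,
                                      trial_noise_sd = config$trial_noise_sd,
                                      unit_noise = TRUE) {
  stopifnot(inherits(config, "ern_config"))
  set.seed(seed)
  n <- nrow(latents)
  tasks <- config$tasks
  n_units <- config$n_units
  unit_size <- config$n_trials_per_task / n_units
  baseline <- config$correct_mean + config$correct_sd * stats::rnorm(n)
  trials <- vector("list", n * length(tasks))
  truth <- vector("list", n * length(tasks))
  k <- 0L
  for (i in seq_len(n)) {
    ability <- stats::rnorm(length(tasks)) # per-task ability shifts
    for (ti in seq_along(tasks)) {
      t <- tasks[ti]
      k <- k + 1L
      beh <- simulate_behavior(config, t, ability[ti] * config$ability_sd[[t]])
      eta <- latents[[paste0("task_", t)]][i]
      lam <- config$unit_loadings[t, ]
      resid <- if (unit_noise) config$unit_residual_sd[t, ] * stats::rnorm(n_units) else 0
      ern_true <- config$ern_mean[[t]] + config$ern_sd[[t]] * lam * eta + resid
      unit <- ceiling(beh$trial_index / unit_size)
      amp <- baseline[i] + stats::rnorm(nrow(beh), 0, trial_noise_sd)
      err <- beh$result == "error"
      amp[err] <- amp[err] + ern_true[unit[err]]
      trials[[k]] <- data.frame(
        participant_id = latents$participant_id[i], task = t,
        trial_index = beh$trial_index, block = beh$block, unit = unit,
        result = beh$result, amplitude = amp, stringsAsFactors = FALSE)
      truth[[k]] <- data.frame(
        participant_id = latents$participant_id[i], task = t,
        unit = seq_len(n_units), ern_true = ern_true,
        stringsAsFactors = FALSE)
    }
  }
  list(trials = do.call(rbind, trials), unit_truth = do.call(rbind, truth))
}

#' Simulate unit-level ERN indicators directly
#'
#' Draws the 20 (task x unit) ERN indicators straight from the latent model,
#' without the trial layer: indicator value = `ern_mean_t + ern_sd_t *
#' (lambda_tu * task_factor + sqrt(1 - lambda_tu^2) * unit_noise)` plus
#' optional indicator-level measurement noise. Used for factor-model
#' simulations (parameter recovery, structure discrimination) where the
#' trial layer is irrelevant.
#'
#' @param latents Latent table.
#' @param config The configuration.
#' @param seed Seed (defaults to `config$seed + 3`).
#' @param measurement_sd Extra indicator-level noise SD in microvolt.
#' @return Numeric matrix (participants x task*units) with columns
#'   `<task>_u<unit>`; row names are participant ids.
#' @export
simulate_unit_scores <- function(latents, config, seed = config$seed + 3L,
                                 measurement_sd = 0) {
  stopifnot(inherits(config, "ern_config"))
  set.seed(seed)
  n <- nrow(latents)
  tasks <- config$tasks
  n_units <- config$n_units
  X <- matrix(NA_real_, n, length(tasks) * n_units)
  colnames(X) <- unit_column_names(tasks, n_units)
  rownames(X) <- latents$participant_id
  for (ti in seq_along(tasks)) {
    t <- tasks[ti]
    eta <- latents[[paste0("task_", t)]]
    for (u in seq_len(n_units)) {
      lam <- config$unit_loadings[t, u]
      X[, (ti - 1L) * n_units + u] <-
        config$ern_mean[[t]] + config$ern_sd[[t]] * lam * eta +
        config$unit_residual_sd[t, u] * stats::rnorm(n) +
        if (measurement_sd > 0) stats::rnorm(n, 0, measurement_sd) else 0
    }
  }
  X
}

#' Column names of the unit-level ERN matrix
#' @param tasks Task labels.
#' @param n_units Units per task.
#' @return Character vector `<task>_u<unit>` in task-major order.
#' @export
unit_column_names <- function(tasks, n_units = 5L) {
  as.vector(t(outer(tasks, seq_len(n_units),
                    function(a, b) paste0(a, "_u", b))))
}

#' True measurement-model parameters implied by a configuration
#'
#' @param config The configuration.
#' @param measurement_sd Indicator-level measurement noise SD assumed on top
#'   of the unit residuals (as in [simulate_unit_scores()]).
#' @return List with `lambda` (per-unit loadings in microvolt per latent SD,
#'   named as unit columns), `gamma` (per-task general loadings), `theta`
#'   (unit residual variances including any measurement noise), and `mu`
#'   (unit means).
#' @export
true_parameters <- function(config, measurement_sd = 0) {
  tasks <- config$tasks
  n_units <- config$n_units
  nm <- unit_column_names(tasks, n_units)
  lambda <- as.vector(t(config$unit_loadings * config$ern_sd[tasks]))
  theta <- as.vector(t(config$unit_residual_sd^2)) + measurement_sd^2
  mu <- rep(config$ern_mean[tasks], each = n_units)
  list(lambda = stats::setNames(lambda, nm),
       gamma = config$general_loadings,
       theta = stats::setNames(theta, nm),
       mu = stats::setNames(mu, nm))
}
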