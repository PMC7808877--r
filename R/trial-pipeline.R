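# Trial-level pipeline: per-bin outlier screening, unit binning,
# error-minus-correct ERN differences, and between-subject screening.

#' Screen trial-level amplitude outliers within participant/task/result bins
#'
#' Within each participant x task x result bin, the mean and (sample) SD of
#' the amplitudes are computed and trials whose amplitude deviates from the
#' bin mean by strictly more than `sd_mult` SDs are removed. Bins with fewer
#' than two trials (SD undefined) are left unscreened and logged.
#'
#' @param trials Trial table with `participant_id`, `task`, `result`,
#'   `amplitude`.
#' @param sd_mult SD multiplier (default 3).
#' @return List with `trials` (kept rows), `removed` (removed rows plus a
#'   `reason` column), and `bins` (per-bin log: n, n_removed, screened
#'   flag).
#' @export
screen_trial_outliers <- function(trials, sd_mult = 3) {
  key <- interaction(trials$participant_id, trials$task, trials$result,
                     drop = TRUE)
  idx <- split(seq_len(nrow(trials)), key)
  removed_idx <- integer(0)
  bins <- vector("list", length(idx))
  for (b in seq_along(idx)) {
    ii <- idx[[b]]
    a <- trials$amplitude[ii]
    screened <- length(a) >= 2L
    rm_b <- integer(0)
    if (screened) {
      s <- stats::sd(a)
      m <- mean(a)
      if (s > 0) rm_b <- ii[abs(a - m) > sd_mult * s]
    }
    removed_idx <- c(removed_idx, rm_b)
    first <- ii[1L]
    bins[[b]] <- data.frame(
      participant_id = trials$participant_id[first],
      task = trials$task[first], result = trials$result[first],
      n = length(ii), n_removed = length(rm_b), screened = screened,
      stringsAsFactors = FALSE)
  }
  removed <- trials[removed_idx, , drop = FALSE]
  if (nrow(removed)) removed$reason <- "trial-outlier"
  list(trials = trials[setdiff(seq_len(nrow(trials)), removed_idx), ,
                       drop = FALSE],
       removed = removed, bins = do.call(rbind, bins))
}

#' Assign trials to consecutive units by trial number
#'
#' Unit membership is defined by the original trial number (`unit =
#' ceiling(trial_index / unit_size)`), regardless of result and regardless
#' of any trials removed by screening, so removals never shift other
#' trials' unit assignment.
#'
#' @param trials Trial table with `trial_index`.
#' @param unit_size Trials per unit (default 60).
#' @param n_trials Total trials per task (default 300); indices outside
#'   `1..n_trials` are an error.
#' @return The trial table with a `unit` column (re)computed.
#' @export
bin_units <- function(trials, unit_size = 60L, n_trials = 300L) {
  ti <- trials$trial_index
  if (any(ti < 1L | ti > n_trials))
    stop("trial_index outside 1..", n_trials)
  trials$unit <- as.integer(ceiling(ti / unit_size))
  trials
}

#' Per-unit error-minus-correct ERN amplitudes
#'
#' For every participant x task x unit cell, `ern = mean(error amplitudes) -
#' mean(correct amplitudes)`; the cell is missing when either side has no
#' trials (e.g. an error-free unit).
#'
#' @param trials Screened, unit-binned trial table.
#' @param tasks,units Optional label sets defining the complete grid
#'   (defaults to the values present).
#' @return Data frame `participant_id`, `task`, `unit`, `n_correct`,
#'   `n_error`, `ern` (NA when undefined).
#' @export
compute_unit_ern <- function(trials, tasks = unique(trials$task),
                             units = sort(unique(trials$unit))) {
  grid <- expand.grid(participant_id = unique(trials$participant_id),
                      task = tasks, unit = units,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key_t <- paste(trials$participant_id, trials$task, trials$unit)
  err <- trials$result == "error"
  key_g <- paste(grid$participant_id, grid$task, grid$unit)
  m_err <- tapply(trials$amplitude[err], key_t[err], mean)
  m_cor <- tapply(trials$amplitude[!err], key_t[!err], mean)
  n_err <- tapply(err, key_t, sum)
  n_cor <- tapply(!err, key_t, sum)
  grid$n_correct <- as.integer(ifelse(is.na(n_cor[key_g]), 0L, n_cor[key_g]))
  grid$n_error <- as.integer(ifelse(is.na(n_err[key_g]), 0L, n_err[key_g]))
  grid$ern <- as.numeric(m_err[key_g]) - as.numeric(m_cor[key_g])
  grid
}

#' Per-task grand-average ERN (ignoring units)
#'
#' Task-wide error mean minus task-wide correct mean; missing when the task
#' has no error (or no correct) trials for that participant.
#'
#' @param trials Screened trial table.
#' @param tasks Optional task label set.
#' @return Data frame `participant_id`, `task`, `n_correct`, `n_error`,
#'   `ern`.
#' @export
compute_grand_ern <- function(trials, tasks = unique(trials$task)) {
  grid <- expand.grid(participant_id = unique(trials$participant_id),
                      task = tasks, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  key_t <- paste(trials$participant_id, trials$task)
  key_g <- paste(grid$participant_id, grid$task)
  err <- trials$result == "error"
  m_err <- tapply(trials$amplitude[err], key_t[err], mean)
  m_cor <- tapply(trials$amplitude[!err], key_t[!err], mean)
  n_err <- tapply(err, key_t, sum)
  n_cor <- tapply(!err, key_t, sum)
  grid$n_correct <- as.integer(ifelse(is.na(n_cor[key_g]), 0L, n_cor[key_g]))
  grid$n_error <- as.integer(ifelse(is.na(n_err[key_g]), 0L, n_err[key_g]))
  grid$ern <- as.numeric(m_err[key_g]) - as.numeric(m_cor[key_g])
  grid
}

#' Assemble the participants x (task, unit) ERN matrix
#'
#' Wide matrix with one column per task x unit cell (`<task>_u<unit>`) plus
#' one grand-average column per task (`<task>_grand`), and a parallel
#' reason-code mask. Initially missing cells (error-free units) carry the
#' reason `"no-error-unit"`; participant x task exclusions given in
#' `exclusions` mask whole tasks with reason `"excluded-task"`.
#'
#' @param unit_ern Output of [compute_unit_ern()].
#' @param grand_ern Output of [compute_grand_ern()].
#' @param tasks Task order for the columns.
#' @param n_units Units per task.
#' @param exclusions Optional data frame `participant_id`, `task` of
#'   excluded participant-task combinations.
#' @return Object of class `ern_matrix`: list with `data` (data frame,
#'   first column `participant_id`), `reasons` (character matrix, NA =
#'   observed), `tasks`, `n_units`.
#' @export
build_ern_matrix <- function(unit_ern, grand_ern,
                             tasks = unique(unit_ern$task),
                             n_units = max(unit_ern$unit),
                             exclusions = NULL) {
  ids <- unique(unit_ern$participant_id)
  unit_cols <- unit_column_names(tasks, n_units)
  grand_cols <- paste0(tasks, "_grand")
  cols <- c(unit_cols, grand_cols)
  M <- matrix(NA_real_, length(ids), length(cols),
              dimnames = list(ids, cols))
  M[cbind(match(unit_ern$participant_id, ids),
          match(paste0(unit_ern$task, "_u", unit_ern$unit), cols))] <-
    unit_ern$ern
  M[cbind(match(grand_ern$participant_id, ids),
          match(paste0(grand_ern$task, "_grand"), cols))] <- grand_ern$ern
  reasons <- matrix(NA_character_, length(ids), length(cols),
                    dimnames = dimnames(M))
  reasons[is.na(M)] <- "no-error-unit"
  if (!is.null(exclusions) && nrow(exclusions)) {
    for (i in seq_len(nrow(exclusions))) {
      cc <- c(paste0(exclusions$task[i], "_u", seq_len(n_units)),
              paste0(exclusions$task[i], "_grand"))
      M[exclusions$participant_id[i], cc] <- NA_real_
      reasons[exclusions$participant_id[i], cc] <- "excluded-task"
    }
  }
  structure(list(
    data = data.frame(participant_id = ids, M, check.names = FALSE,
                      row.names = NULL),
    reasons = reasons, tasks = tasks, n_units = n_units),
    class = "ern_matrix")
}

#' Mask between-subject outliers, column by column
#'
#' For each column of the ERN matrix (every unit column and every
#' grand-average column), values deviating from the cross-participant mean
#' by strictly more than `sd_mult` SDs are masked with reason
#' `"between-subject-outlier"`. A single pass is made (no re-iteration
#' after masking) and columns are treated independently.
#'
#' @param mat An `ern_matrix`.
#' @param sd_mult SD multiplier (default 3).
#' @return The masked `ern_matrix`, with an added `n_masked` count.
#' @export
screen_between_subject_outliers <- function(mat, sd_mult = 3) {
  stopifnot(inherits(mat, "ern_matrix"))
  cols <- setdiff(colnames(mat$data), "participant_id")
  n_masked <- 0L
  for (cc in cols) {
    x <- mat$data[[cc]]
    ok <- !is.na(x)
    if (sum(ok) < 2L) next
    m <- mean(x[ok]); s <- stats::sd(x[ok])
    if (s == 0) next
    out <- ok & abs(x - m) > sd_mult * s
    if (any(out)) {
      mat$data[[cc]][out] <- NA_real_
      mat$reasons[out, cc] <- "between-subject-outlier"
      n_masked <- n_masked + sum(out)
    }
  }
  mat$n_masked <- n_masked
  mat
}

#' @export
print.ern_matrix <- function(x, ...) {
  cat("ERN matrix:", nrow(x$data), "participants x", ncol(x$data) - 1L,
      "columns (", length(x$tasks), "tasks x", x$n_units,
      "units + grand averages )\n")
  miss <- table(x$reasons[!is.na(x$reasons)])
  if (length(miss)) {
    cat("missing cells:\n")
    for (nm in names(miss)) cat("  ", nm, ":", miss[[nm]], "\n")
  } else cat("no missing cells\n")
  invisible(x)
}

#' Run the full trial-to-matrix extraction
#'
#' Convenience wrapper: trial-level outlier screening, unit binning, unit
#' and grand ERN computation, matrix assembly, and between-subject
#' screening.
#'
#' @param trials Scored trial table.
#' @param config The configuration (for task order and unit size).
#' @param sd_mult SD multiplier for both screening stages.
#' @param exclusions Optional participant x task exclusion table.
#' @return List with `matrix` (`ern_matrix`), `removed` (trial removal
#'   log), `bins` (bin log).
#' @export
extract_ern_matrix <- function(trials, config, sd_mult = 3,
                               exclusions = NULL) {
  scr <- screen_trial_outliers(trials, sd_mult = sd_mult)
  unit_size <- config$n_trials_per_task / config$n_units
  tr <- bin_units(scr$trials, unit_size = unit_size,
                  n_trials = config$n_trials_per_task)
  ue <- compute_unit_ern(tr, tasks = config$tasks,
                         units = seq_len(config$n_units))
  ge <- compute_grand_ern(tr, tasks = config$tasks)
  mat <- build_ern_matrix(ue, ge, tasks = config$tasks,
                          n_units = config$n_units, exclusions = exclusions)
  mat <- screen_between_subject_outliers(mat, sd_mult = sd_mult)
  list(matrix = mat, removed = scr$removed, bins = scr$bins)
}
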