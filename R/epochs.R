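# Response-locked epoch synthesis: waveforms on a -400..798 ms grid at
# 500 Hz (2 ms steps, 600 samples), channels Fz and Cz.

epoch_time_axis <- function(from = -400, to = 798, by = 2) seq(from, to, by = by)

#' Simulate response-locked epoch waveforms for scored trials
#'
#' Builds one epoch per trial row: background noise plus, on error trials, a
#' negative deflection in the 10-110 ms scoring window. Each channel is
#' adjusted so that, after baseline correction over -400..-200 ms, the mean
#' over the 10-110 ms window equals the trial's `amplitude` exactly, making
#' the generator-scorer round trip an identity in the artifact-free case. A
#' configured fraction of epochs receives an injected artifact (a voltage
#' step, a steep drift, or a flat channel) for rejection testing.
#'
#' @param trials Data frame with `participant_id`, `task`, `trial_index`,
#'   `result`, `amplitude`.
#' @param config The configuration (only used for its seed).
#' @param artifact_fraction Fraction of epochs receiving an artifact.
#' @param noise_sd Background noise SD in microvolt.
#' @param channels Channel names (first two are used for scoring).
#' @param seed Seed.
#' @return List of epochs; each epoch is a list with `participant_id`,
#'   `task`, `trial_index`, `result`, `target`, `artifact` (NA or one of
#'   "step", "drift", "flatline"), `time_ms`, and `data` (samples x
#'   channels matrix, microvolt).
#' @export
simulate_epochs <- function(trials, config = NULL, artifact_fraction = 0,
                            noise_sd = 4, channels = c("Fz", "Cz"),
                            seed = if (is.null(config)) 1L else config$seed + 4L) {
  set.seed(seed)
  tm <- epoch_time_axis()
  ns <- length(tm)
  base_w <- which(tm >= -400 & tm <= -200)
  score_w <- which(tm >= 10 & tm <= 110)
  n <- nrow(trials)
  art <- rep(NA_character_, n)
  if (artifact_fraction > 0) {
    hit <- stats::runif(n) < artifact_fraction
    art[hit] <- sample(c("step", "drift", "flatline"), sum(hit), replace = TRUE)
  }
  lapply(seq_len(n), function(i) {
    target <- trials$amplitude[i]
    data <- matrix(stats::rnorm(ns * length(channels), 0, noise_sd), ns,
                   dimnames = list(NULL, channels))
    # smooth ERN-like deflection centered in the scoring window
    shape <- -exp(-((tm - 60) / 45)^2)
    for (ch in channels) {
      x <- data[, ch] + shape * abs(target)
      # enforce exact post-baseline scoring-window mean = target
      adj <- target - (mean(x[score_w]) - mean(x[base_w]))
      x[score_w] <- x[score_w] + adj
      data[, ch] <- x
    }
    a <- art[i]
    if (!is.na(a)) {
      ch <- sample(channels, 1L)
      if (a == "step") {
        at <- sample(200:400, 1L)
        data[at:ns, ch] <- data[at:ns, ch] + 250
      } else if (a == "drift") {
        # 3 uV per sample = 300 uV across any 200 ms window, with no
        # adjacent-sample step above 50 uV
        data[, ch] <- data[, ch] + 3 * seq_len(ns)
      } else {
        data[, ch] <- 0
      }
    }
    list(participant_id = trials$participant_id[i], task = trials$task[i],
         trial_index = trials$trial_index[i], result = trials$result[i],
         target = target, artifact = a, time_ms = tm, data = data)
  })
}

#' Write / read one epoch as CSV
#'
#' Plain-text exchange format: a `time_ms` column followed by one column per
#' channel, in microvolt.
#' @param epoch An epoch (list with `time_ms` and `data`).
#' @param path File path.
#' @export
epoch_write_csv <- function(epoch, path) {
  df <- data.frame(time_ms = epoch$time_ms, epoch$data, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname epoch_write_csv
#' @export
epoch_read_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  list(time_ms = df$time_ms,
       data = as.matrix(df[, setdiff(colnames(df), "time_ms"), drop = FALSE]))
}
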