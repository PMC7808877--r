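# Epoch scoring: baseline correction, channel-level artifact rejection, and
# mean-amplitude scoring of response-locked epochs.

#' Baseline-correct an epoch
#'
#' Subtracts, per channel, the mean voltage over the baseline window
#' (default -400 to -200 ms, endpoints inclusive) from every sample.
#'
#' @param epoch Epoch (list with `time_ms` and `data`, samples x channels).
#' @param window Baseline window in ms, `c(from, to)`.
#' @return The epoch with corrected `data`.
#' @export
baseline_correct <- function(epoch, window = c(-400, -200)) {
  tm <- epoch$time_ms
  w <- which(tm >= window[1L] & tm <= window[2L])
  if (!length(w) || min(tm) > window[1L] || max(tm) < window[2L])
    stop("epoch does not cover the baseline window ",
         window[1L], "..", window[2L], " ms")
  epoch$data <- sweep(epoch$data, 2L, colMeans(epoch$data[w, , drop = FALSE]))
  epoch$baseline_corrected <- TRUE
  epoch
}

# max - min over every sliding window of `width` samples; O(n * w), n = 600.
sliding_range <- function(x, width) {
  n <- length(x)
  if (width > n) stop("window longer than epoch")
  vapply(seq_len(n - width + 1L), function(i) {
    xs <- x[i:(i + width - 1L)]
    max(xs) - min(xs)
  }, numeric(1))
}

#' Channel-level artifact rejection
#'
#' Flags a channel when (a) any absolute difference between adjacent samples
#' exceeds `step` microvolt, (b) any sliding window of `range_ms` has a
#' max-minus-min voltage difference above `range`, or (c) any sliding window
#' of `flat_ms` has a difference below `flat` (flatline). Window widths on
#' the 2 ms grid include both endpoints (`range_ms = 200` means 101
#' samples). The epoch is rejected when any required channel is flagged.
#'
#' @param epoch A (baseline-corrected) epoch.
#' @param criteria Named list of thresholds: `step` (50), `range` (200),
#'   `range_ms` (200), `flat` (0.5), `flat_ms` (100), all strict
#'   inequalities.
#' @param channels Channels evaluated; defaults to all channels present.
#' @param sliding If `FALSE`, tiled (non-overlapping) windows are used
#'   instead of sliding windows.
#' @return List of class `rejection_report`: `kept` (logical), `channel`
#'   (per-channel kept flag), and `violations` (named list of violated
#'   criterion codes per channel).
#' @export
reject_artifacts <- function(epoch,
                             criteria = list(step = 50, range = 200,
                                             range_ms = 200, flat = 0.5,
                                             flat_ms = 100),
                             channels = colnames(epoch$data),
                             sliding = TRUE) {
  tm <- epoch$time_ms
  dt <- tm[2L] - tm[1L]
  w_range <- as.integer(criteria$range_ms / dt) + 1L
  w_flat <- as.integer(criteria$flat_ms / dt) + 1L
  viol <- list()
  ch_ok <- stats::setNames(logical(length(channels)), channels)
  for (ch in channels) {
    x <- epoch$data[, ch]
    v <- character(0)
    if (any(abs(diff(x)) > criteria$step)) v <- c(v, "step")
    if (sliding) {
      rr <- sliding_range(x, w_range)
      fr <- sliding_range(x, w_flat)
    } else {
      tile <- function(width) {
        starts <- seq(1L, length(x) - width + 1L, by = width)
        vapply(starts, function(i) {
          xs <- x[i:(i + width - 1L)]
          max(xs) - min(xs)
        }, numeric(1))
      }
      rr <- tile(w_range)
      fr <- tile(w_flat)
    }
    if (any(rr > criteria$range)) v <- c(v, "range")
    if (any(fr < criteria$flat)) v <- c(v, "flatline")
    ch_ok[ch] <- length(v) == 0L
    viol[[ch]] <- v
  }
  structure(list(kept = all(ch_ok), channel = ch_ok, violations = viol),
            class = "rejection_report")
}

#' Score a trial from its epoch
#'
#' Mean over the scoring window (default 10-110 ms, endpoints inclusive) of
#' the per-sample average of the scoring channels (default Fz and Cz).
#'
#' @param epoch A baseline-corrected, artifact-free epoch.
#' @param window Scoring window in ms.
#' @param channels Channels averaged before scoring.
#' @return Amplitude in microvolt.
#' @export
score_trial <- function(epoch, window = c(10, 110), channels = c("Fz", "Cz")) {
  miss <- setdiff(channels, colnames(epoch$data))
  if (length(miss)) stop("required channel(s) missing: ",
                         paste(miss, collapse = ", "))
  tm <- epoch$time_ms
  w <- which(tm >= window[1L] & tm <= window[2L])
  if (!length(w) || min(tm) > window[1L] || max(tm) < window[2L])
    stop("epoch does not cover the scoring window")
  mean(rowMeans(epoch$data[w, channels, drop = FALSE]))
}

#' Score a set of epochs into a trial table
#'
#' Applies baseline correction, artifact rejection (on the scoring channels)
#' and mean-amplitude scoring to each epoch; rejected epochs are dropped
#' from the trial table and reported separately.
#'
#' @param epochs List of epochs as produced by [simulate_epochs()].
#' @param criteria Rejection thresholds, see [reject_artifacts()].
#' @param channels Scoring (and rejection) channels.
#' @return List with `trials` (data frame of scored, kept trials) and
#'   `rejections` (data frame with one row per rejected epoch and the
#'   violated criteria collapsed with "+").
#' @export
score_epochs <- function(epochs,
                         criteria = list(step = 50, range = 200,
                                         range_ms = 200, flat = 0.5,
                                         flat_ms = 100),
                         channels = c("Fz", "Cz")) {
  rows <- vector("list", length(epochs))
  rej <- vector("list", length(epochs))
  for (i in seq_along(epochs)) {
    ep <- baseline_correct(epochs[[i]])
    rep_i <- reject_artifacts(ep, criteria, channels = channels)
    if (rep_i$kept) {
      rows[[i]] <- data.frame(
        participant_id = ep$participant_id, task = ep$task,
        trial_index = ep$trial_index, result = ep$result,
        amplitude = score_trial(ep, channels = channels),
        stringsAsFactors = FALSE)
    } else {
      rej[[i]] <- data.frame(
        participant_id = ep$participant_id, task = ep$task,
        trial_index = ep$trial_index,
        criteria = paste(unique(unlist(rep_i$violations)), collapse = "+"),
        stringsAsFactors = FALSE)
    }
  }
  list(trials = do.call(rbind, rows[!vapply(rows, is.null, TRUE)]),
       rejections = do.call(rbind, rej[!vapply(rej, is.null, TRUE)]))
}
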