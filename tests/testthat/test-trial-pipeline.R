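# Trial pipeline: outlier screening, unit binning, ERN differences,
# between-subject screening.

toy_trials <- function(amps, result = "correct", task = "arrow",
                       pid = "p1") {
  data.frame(participant_id = pid, task = task,
             trial_index = seq_along(amps), result = result,
             amplitude = amps, stringsAsFactors = FALSE)
}

test_that("3-SD screening matches hand arithmetic on a constructed bin", {
  # bin {0 x9, 100}: mean 10, sd 30.55; |100 - 10| = 90 < 3*30.55 -> kept
  amps <- c(rep(0, 9), 100)
  expect_lt(abs(100 - mean(amps)), 3 * sd(amps))
  scr <- screen_trial_outliers(toy_trials(amps))
  expect_equal(nrow(scr$trials), 10)
  # a more extreme value is removed: {0 x19, 100} -> sd 22.94, 95 > 68.8
  amps2 <- c(rep(0, 19), 100)
  expect_gt(abs(100 - mean(amps2)), 3 * sd(amps2))
  scr2 <- screen_trial_outliers(toy_trials(amps2))
  expect_equal(nrow(scr2$trials), 19)
  expect_equal(scr2$removed$amplitude, 100)
  expect_equal(scr2$removed$reason, "trial-outlier")
})

test_that("identical amplitudes and tiny bins are left unscreened", {
  scr <- screen_trial_outliers(toy_trials(rep(2.5, 8)))
  expect_equal(nrow(scr$trials), 8)
  scr1 <- screen_trial_outliers(toy_trials(5))
  expect_equal(nrow(scr1$trials), 1)
  expect_false(scr1$bins$screened)
})

test_that("screening is binwise: eight bins for a complete participant", {
  set.seed(5)
  tr <- expand.grid(task = c("arrow", "social", "unpleasant", "pleasant"),
                    result = c("correct", "error"), trial_index = 1:10,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tr$participant_id <- "p1"
  tr$amplitude <- rnorm(nrow(tr))
  scr <- screen_trial_outliers(tr)
  expect_equal(nrow(scr$bins), 8)
  # conservation per bin
  expect_equal(sum(scr$bins$n), nrow(tr))
  expect_equal(nrow(scr$trials) + nrow(scr$removed), nrow(tr))
})

test_that("unit binning follows trial numbers exactly", {
  tr <- toy_trials(rep(0, 5))
  tr$trial_index <- c(1L, 60L, 61L, 120L, 300L)
  out <- bin_units(tr)
  expect_equal(out$unit, c(1L, 1L, 2L, 2L, 5L))
  tr$trial_index[1] <- 301L
  expect_error(bin_units(tr), "trial_index")
  # complete task partitions into 60-per-unit
  tr300 <- toy_trials(rep(0, 300))
  expect_equal(as.integer(table(bin_units(tr300)$unit)), rep(60L, 5))
  # removing trials does not shift unit assignment of others
  tr2 <- bin_units(toy_trials(rep(0, 300))[-(1:30), ])
  expect_equal(min(tr2$unit), 1L)
  expect_equal(sum(tr2$unit == 1L), 30L)
})

test_that("unit ERN is the error minus correct mean, missing without errors", {
  tr <- rbind(
    toy_trials(c(-4, -4), result = "error"),
    toy_trials(c(2, 2, 2), result = "correct"))
  tr$trial_index <- 1:5
  ue <- compute_unit_ern(bin_units(tr))
  expect_equal(ue$ern[ue$unit == 1], -6)
  # zero-error unit is missing
  tr2 <- toy_trials(rep(1, 70), result = "correct")
  tr2$trial_index <- 1:70
  ue2 <- compute_unit_ern(bin_units(tr2))
  expect_true(all(is.na(ue2$ern)))
  expect_equal(ue2$n_error, c(0L, 0L))
  # equal error and correct means give zero
  tr3 <- rbind(toy_trials(c(3, 3), result = "error"),
               toy_trials(c(3, 3), result = "correct"))
  tr3$trial_index <- 1:4
  expect_equal(compute_unit_ern(bin_units(tr3))$ern[1], 0)
})

test_that("grand ERN pools the task and differs from the unit mean", {
  # errors concentrated in unit 1; grand pooling is an unequal-weight mean
  tr <- rbind(
    data.frame(participant_id = "p1", task = "arrow", trial_index = 1:3,
               result = "error", amplitude = c(-6, -6, -8)),
    data.frame(participant_id = "p1", task = "arrow", trial_index = 61L,
               result = "error", amplitude = -2),
    data.frame(participant_id = "p1", task = "arrow",
               trial_index = c(4:10, 62:70), result = "correct",
               amplitude = 0))
  tr <- bin_units(tr)
  ue <- compute_unit_ern(tr)
  ge <- compute_grand_ern(tr)
  grand <- mean(c(-6, -6, -8, -2)) - 0
  expect_equal(ge$ern, grand)
  expect_false(isTRUE(all.equal(grand, mean(ue$ern, na.rm = TRUE))))
  # grand ERN defined even when only one unit has errors
  tr1 <- rbind(
    data.frame(participant_id = "p1", task = "arrow", trial_index = 1L,
               result = "error", amplitude = -5),
    data.frame(participant_id = "p1", task = "arrow", trial_index = 61:300,
               result = "correct", amplitude = 1))
  ge1 <- compute_grand_ern(bin_units(tr1))
  expect_equal(ge1$ern, -6)
})

test_that("between-subject screening masks constructed column outliers", {
  set.seed(9)
  n <- 40
  ue <- expand.grid(participant_id = sprintf("p%02d", 1:n), task = "arrow",
                    unit = 1:5, KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE)
  ue$n_correct <- 50L; ue$n_error <- 10L
  ue$ern <- rnorm(nrow(ue), -5, 1)
  # plant an outlier at mean + 8 SD in arrow unit 1
  i <- which(ue$unit == 1)[1]
  col1 <- ue$ern[ue$unit == 1]
  ue$ern[i] <- mean(col1) + 8 * sd(col1)
  ge <- compute_grand_ern(data.frame(participant_id = ue$participant_id[1],
                                     task = "arrow", trial_index = 1:2,
                                     result = c("error", "correct"),
                                     amplitude = c(-5, 0)))
  mat <- build_ern_matrix(ue, ge, tasks = "arrow", n_units = 5)
  out <- screen_between_subject_outliers(mat)
  expect_true(is.na(out$data$arrow_u1[1]))
  expect_equal(out$reasons[1, "arrow_u1"], "between-subject-outlier")
  # other columns untouched
  expect_equal(out$data$arrow_u2, mat$data$arrow_u2)
  # identical values -> nothing masked
  ue$ern <- -5
  mat2 <- screen_between_subject_outliers(
    build_ern_matrix(ue, ge, tasks = "arrow", n_units = 5))
  expect_equal(mat2$n_masked, 0L)
})

test_that("matrix layout, reason codes, and exclusions partition missingness", {
  cfg <- tiny_config(n = 8, seed = 110)
  lat <- simulate_population(cfg)
  sim <- simulate_trial_amplitudes(lat, cfg)
  excl <- data.frame(participant_id = lat$participant_id[1], task = "pleasant",
                     stringsAsFactors = FALSE)
  ex <- extract_ern_matrix(sim$trials, cfg, exclusions = excl)
  mat <- ex$matrix
  expect_equal(ncol(mat$data) - 1L, 4 * 5 + 4)
  expect_true(all(is.na(mat$data[1, paste0("pleasant_u", 1:5)])))
  expect_equal(unname(mat$reasons[1, "pleasant_grand"]), "excluded-task")
  # every masked cell has exactly one reason; every observed cell has none
  M <- as.matrix(mat$data[, -1])
  expect_true(all(is.na(M) == !is.na(mat$reasons)))
  expect_true(all(mat$reasons[!is.na(mat$reasons)] %in%
                    c("no-error-unit", "between-subject-outlier",
                      "excluded-task")))
})

test_that("pipeline is deterministic and exact under zero noise", {
  cfg <- population_config(n_participants = 5, trial_noise_sd = 0, seed = 115)
  lat <- simulate_population(cfg)
  sim <- simulate_trial_amplitudes(lat, cfg, trial_noise_sd = 0)
  ex1 <- extract_ern_matrix(sim$trials, cfg)
  ex2 <- extract_ern_matrix(sim$trials, cfg)
  expect_identical(ex1, ex2)
  # unit ERN cells equal the configured true unit scores exactly
  truth <- sim$unit_truth
  for (k in seq_len(nrow(truth))) {
    v <- ex1$matrix$data[ex1$matrix$data$participant_id == truth$participant_id[k],
                         paste0(truth$task[k], "_u", truth$unit[k])]
    if (!is.na(v)) expect_equal(v, truth$ern_true[k], tolerance = 1e-9)
  }
})
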