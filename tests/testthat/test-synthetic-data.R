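# Synthetic-data generator: latent structure, behavior, amplitudes, facets.

test_that("population latents honor the configured second-order structure", {
  cfg <- population_config(seed = 7)
  lat <- simulate_population(cfg, n = 93)
  expect_equal(nrow(lat), 93)
  expect_true(all(paste0("dist_", cfg$tasks) %in% colnames(lat)))
  # degenerate case: unit general loadings make task factors equal the
  # general factor
  cfg1 <- population_config(general_loadings = c(arrow = 1, social = 1,
                                                 unpleasant = 1, pleasant = 1),
                            seed = 8)
  lat1 <- simulate_population(cfg1, n = 50)
  for (t in cfg1$tasks)
    expect_equal(lat1[[paste0("task_", t)]], lat1$general, tolerance = 1e-12)
})

test_that("zero trait-ERN targets give near-zero empirical correlations", {
  zero <- default_trait_ern_corr() * 0
  cfg <- population_config(trait_ern_corr = zero, seed = 21)
  lat <- simulate_population(cfg, n = 2000)
  doms <- rownames(cfg$trait_ern_corr)
  r_gen <- sapply(doms, function(d) cor(lat$general, lat[[d]]))
  expect_true(all(abs(r_gen) < 0.1))
})

test_that("nonzero targets are recovered at large n", {
  cfg <- population_config(seed = 22)
  lat <- simulate_population(cfg, n = 4000)
  tgt <- cfg$trait_ern_corr
  for (t in cfg$tasks) {
    r <- sapply(rownames(tgt), function(d) cor(lat[[paste0("task_", t)]],
                                               lat[[d]]))
    expect_true(all(abs(r - tgt[, t]) < 0.06),
                label = paste("task", t, "trait correlations near target"))
  }
})

test_that("invalid configurations are rejected with diagnostics", {
  expect_error(population_config(n_trials_per_task = 301), "divisible")
  expect_error(population_config(general_loadings = c(arrow = 1.2, social = .7,
                                                      unpleasant = .8,
                                                      pleasant = .6)),
               "general_loadings")
  expect_error(population_config(unit_loadings = 0), "unit_loadings")
  # an overly strong trait-ERN coupling breaks positive semidefiniteness
  strong <- default_trait_ern_corr(r_effect = 0.95)
  expect_error(population_config(trait_ern_corr = strong),
               "positive semidefinite|unreachable")
})

test_that("adaptive staircase follows the accuracy band rules", {
  cfg <- population_config(seed = 30)
  # direct rule checks
  expect_equal(ernfactor:::adapt_presentation_time(200, 0.95, cfg, "arrow"), 180)
  expect_equal(ernfactor:::adapt_presentation_time(200, 0.70, cfg, "arrow"), 220)
  expect_equal(ernfactor:::adapt_presentation_time(200, 0.80, cfg, "arrow"), 200)
  expect_equal(ernfactor:::adapt_presentation_time(400, 0.95, cfg, "social"), 360)
  # error probability is monotone decreasing in presentation time
  p <- ernfactor:::error_probability(seq(100, 500, 50), cfg, "arrow")
  expect_true(all(diff(p) < 0))
  # long-run accuracy stays near the band
  set.seed(31)
  acc <- replicate(60, mean(simulate_behavior(cfg, "arrow",
                                              rnorm(1, 0, 20))$result == "correct"))
  expect_gt(mean(acc), 0.72)
  expect_lt(mean(acc), 0.93)
})

test_that("behavior has the block structure and binomial error counts", {
  cfg <- population_config(seed = 32)
  beh <- simulate_behavior(cfg, "social")
  expect_equal(nrow(beh), 300)
  expect_equal(as.integer(table(beh$block)), rep(30L, 10L))
  expect_equal(beh$presentation_ms[1], 400)
  # stationary p = 0.15 implies 9 expected errors per 60-trial unit
  expect_equal(60 * 0.15, 9)
})

test_that("trial amplitudes follow the configured unit-level model", {
  cfg <- population_config(n_participants = 6, trial_noise_sd = 0, seed = 40)
  lat <- simulate_population(cfg)
  sim <- simulate_trial_amplitudes(lat, cfg, unit_noise = FALSE,
                                   trial_noise_sd = 0)
  tr <- sim$trials
  # with zero noise and no unit residuals, the error-correct difference in a
  # unit equals loading * ern_sd * task factor + task mean, identical across
  # units with equal loadings
  for (i in 1:3) {
    pid <- lat$participant_id[i]
    for (t in cfg$tasks) {
      sub <- tr[tr$participant_id == pid & tr$task == t, ]
      agg <- compute_unit_ern(bin_units(sub))
      vals <- agg$ern[!is.na(agg$ern)]
      if (length(vals) > 1) expect_lt(max(vals) - min(vals), 1e-9)
      expected <- cfg$ern_mean[[t]] +
        cfg$ern_sd[[t]] * cfg$unit_loadings[t, 1] * lat[[paste0("task_", t)]][i]
      if (length(vals)) expect_equal(vals[1], unname(expected),
                                     tolerance = 1e-9)
    }
  }
})

test_that("generated unit covariance matches the model-implied covariance", {
  cfg <- population_config(seed = 50)
  X <- unit_data(5000, seed = 51, config = cfg)
  truth <- true_parameters(cfg)
  fac <- task_factor_list(cfg$tasks, cfg$n_units)
  spec <- cfa_spec(fac, second_order = TRUE)
  imp <- implied_covariance(spec, list(lambda = truth$lambda,
                                       theta = truth$theta,
                                       gamma = truth$gamma))
  S <- cov(X) * (nrow(X) - 1) / nrow(X)
  frob <- sqrt(sum((S - imp$sigma)^2)) / sqrt(sum(imp$sigma^2))
  expect_lt(frob, 0.08)
  # the error is Monte-Carlo noise, not structure: a misspecified implied
  # covariance (no general factor) is an order of magnitude further away
  imp0 <- implied_covariance(spec, list(lambda = truth$lambda,
                                        theta = truth$theta,
                                        gamma = rep(1e-6, 4)))
  frob0 <- sqrt(sum((S - imp0$sigma)^2)) / sqrt(sum(imp$sigma^2))
  expect_gt(frob0, 5 * frob)
})

test_that("facet tables have the configured layout and loadings", {
  cfg <- population_config(n_participants = 400, seed = 60)
  lat <- simulate_population(cfg)
  fc <- simulate_facets(lat, cfg)
  expect_equal(sum(startsWith(colnames(fc), "ffm_")), 30)
  expect_equal(sum(startsWith(colnames(fc), "pid_")), 25)
  expect_equal(length(facet_columns(cfg, "pid", "negative_affectivity")), 7)
  expect_equal(length(facet_columns(cfg, "pid", "psychoticism")), 3)
  # facet-domain correlation approximates the configured loading
  r <- cor(fc$ffm_neuroticism_f1, lat$neuroticism)
  expect_equal(r, cfg$facet_loading, tolerance = 0.1)
  # degenerate: loading 1 makes facets equal the domain
  cfg1 <- population_config(n_participants = 20, facet_loading = 1, seed = 61)
  lat1 <- simulate_population(cfg1)
  fc1 <- simulate_facets(lat1, cfg1)
  expect_equal(fc1$ffm_openness_f3, lat1$openness, tolerance = 1e-12)
})

test_that("identical seeds reproduce identical outputs", {
  cfg <- tiny_config(n = 5, seed = 70)
  a <- simulate_trial_amplitudes(simulate_population(cfg), cfg)
  b <- simulate_trial_amplitudes(simulate_population(cfg), cfg)
  expect_identical(a, b)
})
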