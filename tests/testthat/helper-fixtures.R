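# Shared fixtures: small configurations and generators used across tests.

tiny_config <- function(n = 12L, seed = 101L, ...) {
  population_config(n_participants = n, seed = seed, ...)
}

# Unit-level indicator data straight from the latent model (no trial layer).
unit_data <- function(n, seed, config = NULL, ...) {
  if (is.null(config)) config <- population_config(n_participants = n,
                                                   seed = seed, ...)
  latents <- simulate_population(config, n = n, seed = seed)
  simulate_unit_scores(latents, config, seed = seed + 1L)
}

# Single-factor data with known standardized loadings.
single_factor_data <- function(n, lambda, seed, mean = 0) {
  set.seed(seed)
  eta <- rnorm(n)
  X <- sapply(seq_along(lambda), function(j)
    mean + lambda[j] * eta + rnorm(n, 0, sqrt(1 - lambda[j]^2)))
  colnames(X) <- paste0("u", seq_along(lambda))
  X
}

task_factor_list <- function(tasks = c("arrow", "social", "unpleasant",
                                       "pleasant"), n_units = 5L) {
  out <- lapply(tasks, function(t) paste0(t, "_u", seq_len(n_units)))
  names(out) <- tasks
  out
}

# A clean epoch: low-amplitude sinusoid on both channels.
clean_epoch <- function(amplitude = 20, freq_hz = 10) {
  tm <- seq(-400, 798, by = 2)
  x <- amplitude * sin(2 * pi * freq_hz * tm / 1000)
  list(time_ms = tm, data = cbind(Fz = x, Cz = x))
}
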