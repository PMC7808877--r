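#' Configuration of the simulated study population
#'
#' Collects every parameter of the generative model: a General ERN factor,
#' task-specific factors, unit-level structure, trial-level noise, the
#' adaptive-behavior (presentation-time staircase) model, and the
#' personality trait structure with its coupling to the ERN factors.
#'
#' The generative latent model mirrors the second-order measurement model:
#' each task factor is `a_t * general + sqrt(1 - a_t^2) * disturbance`, with
#' `a_t` the per-task general loading; the true unit-level ERN (in microvolt)
#' is `ern_mean_t + ern_sd_t * (lambda_tu * task_factor +
#' sqrt(1 - lambda_tu^2) * unit_noise)`, so units have standardized loading
#' `lambda_tu` on their task factor and variance `ern_sd_t^2`.
#'
#' @param n_participants Number of participants (default 93).
#' @param tasks Ordered task labels.
#' @param n_trials_per_task Trials per task (default 300), divisible by
#'   `n_units`.
#' @param n_units Number of consecutive trial units per task (default 5).
#' @param n_blocks Number of presentation blocks (default 10, 30 trials each).
#' @param general_loadings Named per-task loading of the task factor on the
#'   General ERN, each in (0, 1].
#' @param unit_loadings Matrix (tasks x units) of standardized unit loadings
#'   in (0, 1], or a single number recycled.
#' @param ern_mean Named per-task mean unit ERN in microvolt (negative =
#'   larger ERN).
#' @param ern_sd Named per-task SD of the true unit ERN in microvolt.
#' @param unit_residual_sd Optional matrix of unit residual SDs in microvolt;
#'   by default derived as `ern_sd * sqrt(1 - unit_loadings^2)` so that
#'   standardized loadings equal `unit_loadings` exactly.
#' @param correct_mean,correct_sd Mean and between-participant SD of the
#'   correct-trial baseline amplitude (microvolt).
#' @param trial_noise_sd Within-trial measurement noise SD (microvolt).
#' @param presentation_start Named per-task initial presentation time (ms).
#' @param presentation_step Named per-task staircase step (ms).
#' @param accuracy_band Accuracy band maintained by the staircase
#'   (default c(0.75, 0.90)).
#' @param error_slope Named per-task logistic scale (ms) of the
#'   presentation-time -> error-probability curve.
#' @param target_error_rate Error probability at the initial presentation
#'   time for an average participant (default 0.175, the band midpoint).
#' @param ability_sd Between-participant SD of the ability shift (ms) applied
#'   to the psychometric curve.
#' @param trait_structure Named list of instruments; each instrument is a
#'   named list mapping domain names to facet counts. Defaults to a 5-domain
#'   general-trait instrument with 6 facets each (30 facets) and a 5-domain
#'   maladaptive instrument with 7/5/3/5/5 facets (25 facets).
#' @param facet_loading Standardized loading of each facet on its domain.
#' @param domain_cor Correlation matrix across all trait domains (rows and
#'   columns in the order the domains appear in `trait_structure`). Default:
#'   exchangeable 0.2 within instrument plus +/-0.5 between matched
#'   general/maladaptive pairs (negative for the reversed domains).
#' @param trait_ern_corr Matrix (domains x c("general", tasks)) of target
#'   correlations between each latent trait domain and the General ERN /
#'   task-specific factors. Default encodes the convergent-validity
#'   hypothesis pattern at |r| = 0.25.
#' @param seed Integer seed recorded in the config and used by the
#'   simulation entry points.
#' @return An object of class `ern_config`.
#' @export
population_config <- function(
    n_participants = 93L,
    tasks = c("arrow", "social", "unpleasant", "pleasant"),
    n_trials_per_task = 300L,
    n_units = 5L,
    n_blocks = 10L,
    general_loadings = c(arrow = 0.75, social = 0.70, unpleasant = 0.80,
                         pleasant = 0.60),
    unit_loadings = 0.65,
    ern_mean = c(arrow = -6, social = -5, unpleasant = -5, pleasant = -4),
    ern_sd = c(arrow = 3, social = 3, unpleasant = 3, pleasant = 3),
    unit_residual_sd = NULL,
    correct_mean = 2, correct_sd = 2,
    trial_noise_sd = 8,
    presentation_start = c(arrow = 200, social = 400, unpleasant = 400,
                           pleasant = 400),
    presentation_step = c(arrow = 20, social = 40, unpleasant = 40,
                          pleasant = 40),
    accuracy_band = c(0.75, 0.90),
    error_slope = c(arrow = 40, social = 80, unpleasant = 80, pleasant = 80),
    target_error_rate = 0.175,
    ability_sd = c(arrow = 20, social = 40, unpleasant = 40, pleasant = 40),
    trait_structure = default_trait_structure(),
    facet_loading = 0.7,
    domain_cor = NULL,
    trait_ern_corr = NULL,
    seed = 1L) {
  tasks <- as.character(tasks)
  nt <- length(tasks)
  if (n_trials_per_task %% n_units != 0L)
    stop("n_trials_per_task must be divisible by n_units")
  named_per_task <- function(x, what) {
    if (length(x) == 1L && is.null(names(x))) x <- stats::setNames(rep(x, nt), tasks)
    if (is.null(names(x)) && length(x) == nt) names(x) <- tasks
    if (!all(tasks %in% names(x))) stop("'", what, "' must name every task")
    x[tasks]
  }
  general_loadings <- named_per_task(general_loadings, "general_loadings")
  if (any(general_loadings <= 0 | general_loadings > 1))
    stop("general_loadings must lie in (0, 1]")
  ern_mean <- named_per_task(ern_mean, "ern_mean")
  ern_sd <- named_per_task(ern_sd, "ern_sd")
  presentation_start <- named_per_task(presentation_start, "presentation_start")
  presentation_step <- named_per_task(presentation_step, "presentation_step")
  error_slope <- named_per_task(error_slope, "error_slope")
  ability_sd <- named_per_task(ability_sd, "ability_sd")
  if (length(unit_loadings) == 1L)
    unit_loadings <- matrix(unit_loadings, nt, n_units)
  unit_loadings <- as.matrix(unit_loadings)
  if (!all(dim(unit_loadings) == c(nt, n_units)))
    stop("unit_loadings must be a tasks x units matrix")
  if (any(unit_loadings <= 0 | unit_loadings > 1))
    stop("unit_loadings must lie in (0, 1]")
  dimnames(unit_loadings) <- list(tasks, paste0("u", seq_len(n_units)))
  if (is.null(unit_residual_sd))
    unit_residual_sd <- sweep(sqrt(1 - unit_loadings^2), 1L, ern_sd, "*")
  unit_residual_sd <- as.matrix(unit_residual_sd)
  if (!all(dim(unit_residual_sd) == c(nt, n_units)))
    stop("unit_residual_sd must be a tasks x units matrix")

  domains <- unlist(lapply(trait_structure, names), use.names = FALSE)
  if (anyDuplicated(domains)) stop("trait domain names must be unique")
  if (is.null(domain_cor)) domain_cor <- default_domain_cor(trait_structure)
  domain_cor <- as.matrix(domain_cor)
  if (!all(dim(domain_cor) == length(domains)))
    stop("domain_cor must be square over the ", length(domains), " domains")
  if (is.null(dimnames(domain_cor))) dimnames(domain_cor) <- list(domains, domains)
  if (max(abs(domain_cor - t(domain_cor))) > 1e-10)
    stop("domain_cor must be symmetric")
  if (min(eigen((domain_cor + t(domain_cor)) / 2, symmetric = TRUE,
                only.values = TRUE)$values) < -1e-8)
    stop("trait domain intercorrelation matrix is not positive semidefinite")
  if (is.null(trait_ern_corr))
    trait_ern_corr <- default_trait_ern_corr(trait_structure, tasks)
  trait_ern_corr <- as.matrix(trait_ern_corr)
  if (!all(rownames(trait_ern_corr) == domains) ||
      !all(colnames(trait_ern_corr) == c("general", tasks)))
    stop("trait_ern_corr must be a domains x c('general', tasks) matrix")

  cfg <- structure(list(
    n_participants = as.integer(n_participants), tasks = tasks,
    n_trials_per_task = as.integer(n_trials_per_task),
    n_units = as.integer(n_units), n_blocks = as.integer(n_blocks),
    general_loadings = general_loadings, unit_loadings = unit_loadings,
    ern_mean = ern_mean, ern_sd = ern_sd,
    unit_residual_sd = unit_residual_sd,
    correct_mean = correct_mean, correct_sd = correct_sd,
    trial_noise_sd = trial_noise_sd,
    presentation_start = presentation_start,
    presentation_step = presentation_step,
    accuracy_band = accuracy_band, error_slope = error_slope,
    target_error_rate = target_error_rate, ability_sd = ability_sd,
    trait_structure = trait_structure, facet_loading = facet_loading,
    domain_cor = domain_cor, trait_ern_corr = trait_ern_corr,
    seed = as.integer(seed)
  ), class = "ern_config")
  # validate the joint latent structure once at construction
  invisible(latent_cov_matrix(cfg))
  cfg
}

#' Default trait-domain structure
#'
#' A general-trait instrument with five domains of six facets each (30
#' facets) and a maladaptive instrument with five domains of 7/5/3/5/5
#' facets (25 facets).
#' @return Named list of instruments, each mapping domains to facet counts.
#' @export
default_trait_structure <- function() {
  list(
    ffm = c(neuroticism = 6L, extraversion = 6L, openness = 6L,
            agreeableness = 6L, conscientiousness = 6L),
    pid = c(negative_affectivity = 7L, detachment = 5L, psychoticism = 3L,
            antagonism = 5L, disinhibition = 5L)
  )
}

default_domain_cor <- function(trait_structure) {
  domains <- unlist(lapply(trait_structure, names), use.names = FALSE)
  k <- length(domains)
  inst <- rep(names(trait_structure), vapply(trait_structure, length, 1L))
  R <- diag(k)
  dimnames(R) <- list(domains, domains)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i != j && inst[i] == inst[j]) R[i, j] <- 0.2
  }
  # matched general/maladaptive pairs; sign is negative where the
  # maladaptive domain is the inverse pole of the general-trait domain
  pairs <- list(c("neuroticism", "negative_affectivity", 0.5),
                c("extraversion", "detachment", -0.5),
                c("openness", "psychoticism", 0.4),
                c("agreeableness", "antagonism", -0.5),
                c("conscientiousness", "disinhibition", -0.5))
  for (pr in pairs) {
    a <- pr[[1]]; b <- pr[[2]]
    if (a %in% domains && b %in% domains)
      R[a, b] <- R[b, a] <- as.numeric(pr[[3]])
  }
  R
}

#' Default trait-ERN correlation targets
#'
#' Encodes the convergent-validity hypothesis pattern at |r| = `r_effect`:
#' the arrow-task and General ERN are enhanced with higher Neuroticism and
#' Conscientiousness (and their maladaptive counterparts), the social task
#' with Extraversion and Agreeableness, the unpleasant task with
#' Neuroticism, and the pleasant task with Extraversion. "Enhanced" means a
#' more negative amplitude, so hypothesized correlations are negative for
#' general-trait domains and positive for reversed maladaptive domains
#' (detachment, antagonism, disinhibition).
#'
#' @param trait_structure As in [population_config()].
#' @param tasks Task labels.
#' @param r_effect Absolute target correlation on hypothesized pairs.
#' @return domains x c("general", tasks) matrix.
#' @export
default_trait_ern_corr <- function(trait_structure = default_trait_structure(),
                                   tasks = c("arrow", "social", "unpleasant",
                                             "pleasant"),
                                   r_effect = 0.25) {
  domains <- unlist(lapply(trait_structure, names), use.names = FALSE)
  M <- matrix(0, length(domains), length(tasks) + 1L,
              dimnames = list(domains, c("general", tasks)))
  hyp <- hypothesis_pairs(tasks)
  for (i in seq_len(nrow(hyp))) {
    if (hyp$domain[i] %in% domains && hyp$measure[i] %in% colnames(M))
      M[hyp$domain[i], hyp$measure[i]] <- hyp$direction[i] * r_effect
  }
  M
}

# Joint correlation matrix over (general, task disturbances, trait domains).
# Disturbance correlations are solved so that the realized correlation
# between each domain and each task factor hits the configured target:
#   cor(domain, task) = a_t * cor(domain, general)
#                       + sqrt(1 - a_t^2) * cor(domain, disturbance_t)
latent_cov_matrix <- function(config) {
  tasks <- config$tasks
  nt <- length(tasks)
  domains <- rownames(config$trait_ern_corr)
  nd <- length(domains)
  a <- config$general_loadings
  r_g <- config$trait_ern_corr[, "general"]
  k <- 1L + nt + nd
  S <- diag(k)
  nm <- c("general", paste0("d_", tasks), domains)
  dimnames(S) <- list(nm, nm)
  for (j in seq_len(nd)) {
    S["general", domains[j]] <- S[domains[j], "general"] <- r_g[j]
    for (t in seq_len(nt)) {
      rt <- config$trait_ern_corr[j, tasks[t]]
      if (1 - a[t]^2 < 1e-12) {
        # degenerate task (loading 1): the task factor IS the general
        # factor, so the task-level target is ignored
        next
      }
      rd <- (rt - a[t] * r_g[j]) / sqrt(1 - a[t]^2)
      if (abs(rd) > 1)
        stop("trait_ern_corr target for (", domains[j], ", ", tasks[t],
             ") is unreachable given the general loading")
      S[paste0("d_", tasks[t]), domains[j]] <-
        S[domains[j], paste0("d_", tasks[t])] <- rd
    }
  }
  S[domains, domains] <- config$domain_cor
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("joint trait-ERN latent correlation matrix is not positive ",
         "semidefinite (offending block: trait-ERN coupling); weaken ",
         "trait_ern_corr or domain_cor")
  S
}

#' Simulate the latent population
#'
#' Draws, per participant, a standard-normal General ERN score, one
#' disturbance per task, and standardized trait-domain scores, jointly from
#' the configured correlation structure. Task factors are computed as
#' `a_t * general + sqrt(1 - a_t^2) * disturbance_t`.
#'
#' @param config An [population_config()] object.
#' @param n Number of participants (defaults to `config$n_participants`).
#' @param seed Seed (defaults to `config$seed`).
#' @return Data frame with `participant_id`, `general`, one `dist_<task>`
#'   and one `task_<task>` column per task, and one column per trait domain.
#' @export
simulate_population <- function(config, n = config$n_participants,
                                seed = config$seed) {
  stopifnot(inherits(config, "ern_config"))
  S <- latent_cov_matrix(config)
  set.seed(seed)
  Z <- MASS::mvrnorm(n, mu = rep(0, ncol(S)), Sigma = S)
  if (n == 1L) Z <- matrix(Z, 1L)
  colnames(Z) <- colnames(S)
  tasks <- config$tasks
  a <- config$general_loadings
  out <- data.frame(participant_id = sprintf("p%03d", seq_len(n)),
                    general = Z[, "general"])
  for (t in tasks) {
    out[[paste0("dist_", t)]] <- Z[, paste0("d_", t)]
    out[[paste0("task_", t)]] <- a[t] * Z[, "general"] +
      sqrt(1 - a[t]^2) * Z[, paste0("d_", t)]
  }
  for (d in rownames(config$trait_ern_corr)) out[[d]] <- Z[, d]
  class(out) <- c("latent_table", "data.frame")
  out
}

#' Simulate facet scores from latent trait domains
#'
#' Each facet is `facet_loading * domain + sqrt(1 - facet_loading^2) *
#' residual`, standardized in the population.
#'
#' @param latents A latent table from [simulate_population()].
#' @param config The configuration.
#' @param seed Seed (defaults to `config$seed + 1`).
#' @return Data frame with `participant_id` and one column per facet, named
#'   `<instrument>_<domain>_f<k>`.
#' @export
simulate_facets <- function(latents, config, seed = config$seed + 1L) {
  stopifnot(inherits(config, "ern_config"))
  set.seed(seed)
  n <- nrow(latents)
  out <- data.frame(participant_id = latents$participant_id)
  l <- config$facet_loading
  for (inst in names(config$trait_structure)) {
    st <- config$trait_structure[[inst]]
    for (d in names(st)) {
      if (!d %in% colnames(latents)) stop("latent table lacks domain ", d)
      for (k in seq_len(st[[d]])) {
        out[[paste(inst, d, paste0("f", k), sep = "_")]] <-
          l * latents[[d]] + sqrt(1 - l^2) * stats::rnorm(n)
      }
    }
  }
  out
}

#' Facet column names for one trait domain
#' @param config The configuration.
#' @param instrument Instrument name in `config$trait_structure`.
#' @param domain Domain name.
#' @return Character vector of facet column names.
#' @export
facet_columns <- function(config, instrument, domain) {
  st <- config$trait_structure[[instrument]]
  if (is.null(st) || !domain %in% names(st))
    stop("unknown instrument/domain: ", instrument, "/", domain)
  paste(instrument, domain, paste0("f", seq_len(st[[domain]])), sep = "_")
}
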