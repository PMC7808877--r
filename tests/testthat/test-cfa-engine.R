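# CFA engine: implied covariance, FIML estimation, fit indices.

test_that("implied covariance matches hand algebra and a path-tracing oracle", {
  spec <- cfa_spec(list(f = c("a", "b", "c")))
  # zero loadings -> diagonal Theta
  out0 <- implied_covariance(spec, list(lambda = c(0, 0, 0),
                                        theta = c(1, 2, 3)))
  expect_equal(unname(out0$sigma), diag(c(1, 2, 3)))
  # unit loadings, phi = 1, Theta = I -> off-diagonals 1, diagonals 2
  out1 <- implied_covariance(spec, list(lambda = c(1, 1, 1),
                                        theta = c(1, 1, 1)))
  expect_equal(unname(out1$sigma), matrix(1, 3, 3) + diag(3))

  # second-order 4x5 model vs brute-force path tracing
  fac <- task_factor_list()
  so <- cfa_spec(fac, second_order = TRUE)
  set.seed(1)
  lambda <- runif(20, .4, .9)
  theta <- runif(20, .3, .8)
  gamma <- c(.75, .7, .8, .6)
  imp <- implied_covariance(so, list(lambda = lambda, theta = theta,
                                     gamma = gamma))
  task_of <- rep(1:4, each = 5)
  oracle <- matrix(0, 20, 20)
  for (i in 1:20) for (j in 1:20) {
    # path: i <- task_i <- general -> task_j -> j, plus the direct
    # within-task disturbance path when task_i == task_j
    v <- lambda[i] * lambda[j] * gamma[task_of[i]] * gamma[task_of[j]]
    if (task_of[i] == task_of[j])
      v <- v + lambda[i] * lambda[j] * (1 - gamma[task_of[i]]^2)
    if (i == j) v <- v + theta[i]
    oracle[i, j] <- v
  }
  expect_lt(max(abs(unname(imp$sigma) - oracle)), 1e-12)
})

test_that("complete-data single-factor ML matches the triad closed form", {
  X <- single_factor_data(200, c(.8, .7, .6), seed = 3)
  fit <- fit_cfa(X, cfa_spec(list(f = colnames(X))),
                 control = list(iter.max = 4000, eval.max = 8000,
                                rel.tol = 1e-15, x.tol = 1e-12))
  S <- cov(X) * (nrow(X) - 1) / nrow(X)
  l1 <- sqrt(S[1, 2] * S[1, 3] / S[2, 3])
  l2 <- sqrt(S[1, 2] * S[2, 3] / S[1, 3])
  l3 <- sqrt(S[1, 3] * S[2, 3] / S[1, 2])
  expect_lt(max(abs(abs(fit$lambda) - c(l1, l2, l3))), 1e-6)
  expect_equal(fit$df, 0)
  expect_lt(fit$chi2, 1e-6)
})

test_that("FIML equals the complete-data Gaussian loglik without missingness", {
  X <- single_factor_data(150, c(.8, .7, .6, .5), seed = 4)
  pat <- ernfactor:::fiml_patterns(X)
  mu <- colMeans(X) + 0.1
  sigma <- cov(X) + diag(0.05, 4)
  ll_fiml <- ernfactor:::fiml_loglik_moments(mu, sigma, pat)
  # direct casewise multivariate-normal loglik at the same parameters
  ll_direct <- sum(apply(X, 1, function(x) {
    k <- length(x)
    -0.5 * (k * log(2 * pi) + determinant(sigma)$modulus +
              t(x - mu) %*% solve(sigma) %*% (x - mu))
  }))
  expect_equal(ll_fiml, ll_direct, tolerance = 1e-8)
})

test_that("standardized loadings agree with factanal on complete data", {
  X <- single_factor_data(300, c(.8, .7, .6, .75, .65), seed = 5)
  fit <- fit_cfa(X, cfa_spec(list(f = colnames(X))))
  fa <- factanal(X, factors = 1)
  std <- abs(fit$lambda) / sqrt(diag(fit$sat_sigma))
  expect_equal(unname(std), as.numeric(fa$loadings), tolerance = 1e-3)
})

test_that("likelihood is invariant to indicator order and identification", {
  X <- single_factor_data(120, c(.8, .7, .6, .75, .65), seed = 6)
  ctrl <- list(iter.max = 2000, eval.max = 4000, rel.tol = 1e-14)
  f_var <- fit_cfa(X, cfa_spec(list(f = colnames(X))), control = ctrl)
  f_mark <- fit_cfa(X, cfa_spec(list(f = colnames(X)),
                                identification = "marker"), control = ctrl)
  expect_equal(f_var$loglik, f_mark$loglik, tolerance = 1e-8)
  perm <- c(3, 1, 5, 2, 4)
  f_perm <- fit_cfa(X[, perm], cfa_spec(list(f = colnames(X)[perm])),
                    control = ctrl)
  expect_equal(f_var$loglik, f_perm$loglik, tolerance = 1e-8)

  cfg <- population_config(n_participants = 150, seed = 7)
  Xu <- unit_data(150, seed = 8, config = cfg)
  so <- task_factor_list()
  s_var <- fit_cfa(Xu, cfa_spec(so, second_order = TRUE), control = ctrl)
  s_mark <- fit_cfa(Xu, cfa_spec(so, second_order = TRUE,
                                 identification = "marker"), control = ctrl)
  expect_equal(s_var$loglik, s_mark$loglik, tolerance = 1e-7)
  expect_equal(s_var$n_params, s_mark$n_params)
})

test_that("degrees of freedom follow the moment-count formula", {
  cfg <- population_config(n_participants = 200, seed = 9)
  Xu <- unit_data(200, seed = 10, config = cfg)
  flat <- fit_cfa(Xu, cfa_spec(list(g = colnames(Xu))))
  expect_equal(flat$df, 170)            # 210 moments - 40 covariance params
  so <- fit_cfa(Xu, cfa_spec(task_factor_list(), second_order = TRUE))
  expect_equal(so$df, 166)              # 210 - 44
  task1 <- fit_cfa(Xu[, 1:5], cfa_spec(list(t = colnames(Xu)[1:5])))
  expect_equal(task1$df, 5)             # 15 - 10
  # nesting: the flat model is the gamma -> 1 boundary of the second-order
  expect_gte(so$loglik, flat$loglik - 1e-6)
})

test_that("known 5-indicator loadings are recovered at n = 2000", {
  lam <- c(.8, .7, .6, .75, .65)
  X <- single_factor_data(2000, lam, seed = 11)
  fit <- fit_cfa(X, cfa_spec(list(f = colnames(X))))
  expect_true(all(abs(abs(fit$lambda) - lam) < 0.05))
  expect_true(fit$converged && fit$admissible)
})

test_that("FIML handles missing cells and degrades gracefully", {
  lam <- c(.8, .7, .6, .75, .65)
  X <- single_factor_data(500, lam, seed = 12)
  set.seed(13)
  X[sample(length(X), 250)] <- NA
  fit <- fit_cfa(X, cfa_spec(list(f = colnames(X))))
  expect_true(fit$converged)
  expect_true(all(abs(abs(fit$lambda) - lam) < 0.12))
  expect_equal(fit$n_used, 500)
  # EM saturated loglik is an upper bound for the structured model
  expect_gte(fit$loglik_saturated, fit$loglik - 1e-6)
})

test_that("fit indices follow their formulas at the boundary cases", {
  # chi2 == df -> RMSEA 0; saturated -> CFI 1
  idx <- ernfactor:::fit_index_values(chi2 = 5, df = 5, chi2_b = 100,
                                      df_b = 10, n = 100,
                                      s = diag(2), sigma = diag(2))
  expect_equal(idx$rmsea, 0)
  idx2 <- ernfactor:::fit_index_values(chi2 = 0, df = 3, chi2_b = 80,
                                       df_b = 10, n = 100,
                                       s = diag(2), sigma = diag(2))
  expect_equal(idx2$cfi, 1)
  # frozen cross-check on a fixed small dataset: indices recomputed from
  # their definitions using the fitted chi-squares
  X <- single_factor_data(80, c(.7, .6, .8, .5), seed = 14)
  fit <- fit_cfa(X, cfa_spec(list(f = colnames(X))))
  chi2 <- 2 * (fit$loglik_saturated - fit$loglik)
  chi2_b <- 2 * (fit$loglik_saturated - fit$loglik_baseline)
  cfi_ref <- 1 - max(chi2 - fit$df, 0) /
    max(chi2 - fit$df, chi2_b - fit$df_baseline, 0)
  tli_ref <- ((chi2_b / fit$df_baseline) - (chi2 / fit$df)) /
    ((chi2_b / fit$df_baseline) - 1)
  rmsea_ref <- sqrt(max(chi2 - fit$df, 0) / (fit$df * (fit$n_used - 1)))
  expect_equal(fit$cfi, cfi_ref, tolerance = 1e-10)
  expect_equal(fit$tli, tli_ref, tolerance = 1e-10)
  expect_equal(fit$rmsea, rmsea_ref, tolerance = 1e-10)
  # RMSEA CI brackets the point estimate and inverts the noncentral chi2
  expect_lte(fit$rmsea_ci_lower, fit$rmsea + 1e-12)
  expect_gte(fit$rmsea_ci_upper, fit$rmsea - 1e-12)
  if (fit$rmsea_ci_upper > 0) {
    ncp_u <- fit$rmsea_ci_upper^2 * fit$df * (fit$n_used - 1)
    expect_equal(pchisq(fit$chi2, fit$df, ncp = ncp_u), 0.05,
                 tolerance = 1e-6)
  }
  # information criteria identities
  expect_equal(fit$aic, -2 * fit$loglik + 2 * fit$n_params)
  expect_equal(fit$bic, -2 * fit$loglik + log(fit$n_used) * fit$n_params)
})

test_that("the good-fit rule is an inclusive conjunction", {
  fake <- structure(list(cfi = .96, tli = .95, rmsea = .08, srmr = .08,
                         converged = TRUE, admissible = TRUE),
                    class = "cfa_fit")
  expect_true(good_fit(fake))
  fake$cfi <- .94
  expect_false(good_fit(fake))
  fake$cfi <- .99; fake$tli <- NA_real_   # saturated: undefined fails
  expect_false(good_fit(fake))
  fake$tli <- .99; fake$admissible <- FALSE
  expect_false(good_fit(fake))
})

test_that("analytic gradients match numerical differentiation", {
  cfg <- population_config(n_participants = 60, seed = 15)
  Xu <- unit_data(60, seed = 16, config = cfg)
  spec <- cfa_spec(task_factor_list(), second_order = TRUE)
  pmap <- ernfactor:::cfa_pmap(spec)
  pat <- ernfactor:::fiml_patterns(Xu)
  sat <- ernfactor:::saturated_moments(Xu, pat)
  par <- ernfactor:::cfa_start_values(spec, pmap, sat)
  g_an <- ernfactor:::fiml_objective(par, spec, pmap, pat,
                                     gradient = TRUE)$gradient
  f <- function(p) ernfactor:::fiml_objective(p, spec, pmap, pat)
  h <- 1e-6
  g_num <- vapply(seq_along(par), function(i) {
    e <- numeric(length(par)); e[i] <- h
    (f(par + e) - f(par - e)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(g_an - g_num)) / max(1, max(abs(g_num))), 1e-5)
})

test_that("Heywood cases are flagged inadmissible", {
  # two indicators nearly collinear force a negative residual variance
  set.seed(17)
  n <- 60
  eta <- rnorm(n)
  X <- cbind(u1 = eta + rnorm(n, 0, .05), u2 = eta + rnorm(n, 0, .05),
             u3 = .2 * eta + rnorm(n), u4 = .2 * eta + rnorm(n))
  fit <- fit_cfa(X, cfa_spec(list(f = colnames(X))))
  if (any(fit$theta < 0)) {
    expect_true(fit$heywood)
    expect_false(fit$admissible)
    expect_false(good_fit(fit))
  } else succeed("no Heywood case materialized for this draw")
})
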