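# Full-information maximum likelihood CFA estimation.
#
# The casewise Gaussian likelihood is evaluated per missingness pattern using
# sufficient statistics (count, mean, within-pattern scatter), so each
# objective evaluation costs O(#patterns * p^3) regardless of n. Analytic
# gradients are propagated from d ll / d Sigma and d ll / d mu through the
# loading structure.

# Group rows of X (matrix, NA = missing) by missingness pattern and cache
# sufficient statistics.
fiml_patterns <- function(X) {
  obs <- !is.na(X)
  keep <- rowSums(obs) > 0L
  X <- X[keep, , drop = FALSE]
  obs <- obs[keep, , drop = FALSE]
  key <- apply(obs, 1L, function(z) paste(as.integer(z), collapse = ""))
  groups <- split(seq_len(nrow(X)), key)
  pats <- lapply(groups, function(idx) {
    o <- which(obs[idx[1L], ])
    Xo <- X[idx, o, drop = FALSE]
    n_g <- nrow(Xo)
    xbar <- colMeans(Xo)
    Xc <- sweep(Xo, 2L, xbar)
    list(obs = o, n = n_g, xbar = xbar, A = crossprod(Xc))
  })
  list(patterns = pats, n = nrow(X), complete = all(obs),
       dropped = sum(!keep))
}

# Observed-data log-likelihood of (mu, sigma) given cached pattern stats.
fiml_loglik_moments <- function(mu, sigma, pat) {
  ll <- 0
  for (g in pat$patterns) {
    o <- g$obs
    R <- tryCatch(chol(sigma[o, o, drop = FALSE]), error = function(e) NULL)
    if (is.null(R)) return(-Inf)
    d <- g$xbar - mu[o]
    W <- chol2inv(R)
    ll <- ll - 0.5 * (g$n * length(o) * log(2 * pi) +
                      2 * g$n * sum(log(diag(R))) +
                      sum(W * (g$A + g$n * tcrossprod(d))))
  }
  ll
}

# Negative log-likelihood and analytic gradient for a parameter vector.
fiml_objective <- function(par, spec, pmap, pat, gradient = FALSE) {
  u <- cfa_unpack(par, spec, pmap)
  p <- pmap$p
  sigma <- u$Lambda %*% u$Phi %*% t(u$Lambda)
  diag(sigma) <- diag(sigma) + u$theta
  ll <- 0
  G <- matrix(0, p, p)   # d ll / d Sigma (full, symmetric)
  gmu <- numeric(p)
  for (g in pat$patterns) {
    o <- g$obs
    R <- tryCatch(chol(sigma[o, o, drop = FALSE]), error = function(e) NULL)
    if (is.null(R)) {
      if (gradient) return(list(value = 1e12, gradient = rep(0, length(par))))
      return(1e12)
    }
    W <- chol2inv(R)
    d <- g$xbar - u$mu[o]
    T_g <- g$A + g$n * tcrossprod(d)
    ll <- ll - 0.5 * (g$n * length(o) * log(2 * pi) +
                      2 * g$n * sum(log(diag(R))) + sum(W * T_g))
    if (gradient) {
      G[o, o] <- G[o, o] + 0.5 * (W %*% T_g %*% W - g$n * W)
      gmu[o] <- gmu[o] + g$n * drop(W %*% d)
    }
  }
  if (!gradient) return(-ll)
  # chain rule: Sigma = Lambda Phi Lambda' + Theta
  GLP <- G %*% u$Lambda %*% u$Phi
  g_lambda_full <- 2 * GLP[cbind(seq_len(p), pmap$fac_of)]
  g_theta <- diag(G)
  g_struct <- numeric(length(pmap$idx_struct))
  if (spec$second_order) {
    M <- crossprod(u$Lambda, G %*% u$Lambda)   # d ll / d Phi
    if (pmap$marker) {
      m <- pmap$m
      g_gamma <- 2 * u$phi_g * drop(M %*% u$gamma)
      g_struct <- c(g_gamma[-1L], drop(crossprod(u$gamma, M %*% u$gamma)), diag(M))
    } else {
      g_struct <- 2 * drop(M %*% u$gamma) - 2 * u$gamma * diag(M)
    }
  } else if (pmap$m == 1L && pmap$marker) {
    g_struct <- sum(u$Lambda[, 1L] * drop(G %*% u$Lambda[, 1L]))
  }
  grad <- numeric(length(par))
  grad[pmap$idx_lambda] <- g_lambda_full[pmap$lambda_free]
  grad[pmap$idx_theta] <- g_theta
  if (length(pmap$idx_struct)) grad[pmap$idx_struct] <- g_struct
  if (spec$meanstructure) grad[pmap$idx_mu] <- gmu
  list(value = -ll, gradient = -grad)
}

# Saturated (unstructured) Gaussian model under missingness, fitted by EM.
# With complete data the closed form is used. Returns the ML mean, the ML
# covariance (divisor n), and the maximized observed-data log-likelihood.
saturated_moments <- function(X, pat, tol = 1e-10, max_iter = 1000L) {
  p <- ncol(X)
  if (pat$complete) {
    mu <- colMeans(X)
    Xc <- sweep(X, 2L, mu)
    sigma <- crossprod(Xc) / nrow(X)
    return(list(mu = mu, sigma = sigma, loglik = fiml_loglik_moments(mu, sigma, pat),
                iterations = 0L))
  }
  # start from available-case moments, ridged to positive definiteness
  mu <- colMeans(X, na.rm = TRUE)
  sigma <- stats::cov(X, use = "pairwise.complete.obs")
  sigma[is.na(sigma)] <- 0
  e <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(e) < 1e-6 * max(e))
    sigma <- sigma + diag(max(e) * 1e-4 + 1e-8, p)
  ll_old <- fiml_loglik_moments(mu, sigma, pat)
  for (it in seq_len(max_iter)) {
    T1 <- numeric(p)
    T2 <- matrix(0, p, p)
    for (g in pat$patterns) {
      o <- g$obs
      mm <- setdiff(seq_len(p), o)
      n_g <- g$n
      S_obs <- g$A / n_g + tcrossprod(g$xbar)          # E[x_o x_o'] about origin
      if (!length(mm)) {
        T1[o] <- T1[o] + n_g * g$xbar
        T2[o, o] <- T2[o, o] + n_g * S_obs
      } else {
        B <- sigma[mm, o, drop = FALSE] %*% solve(sigma[o, o, drop = FALSE])
        C <- sigma[mm, mm, drop = FALSE] - B %*% sigma[o, mm, drop = FALSE]
        d <- g$xbar - mu[o]
        m_mean <- mu[mm] + drop(B %*% d)               # mean of conditional means
        T1[o] <- T1[o] + n_g * g$xbar
        T1[mm] <- T1[mm] + n_g * m_mean
        # E over cases of x_m x_o' = B * E[x_o x_o'] + (mu_m - B mu_o) xbar'
        cross <- B %*% (g$A + n_g * tcrossprod(g$xbar, g$xbar)) / 1 +
          n_g * tcrossprod(mu[mm] - drop(B %*% mu[o]), g$xbar)
        T2[o, o] <- T2[o, o] + n_g * S_obs
        T2[mm, o] <- T2[mm, o] + cross
        T2[o, mm] <- T2[o, mm] + t(cross)
        # E[x_m x_m'] = n C + sum over cases of mhat mhat'
        Mdev <- B %*% g$A %*% t(B)                     # scatter of conditional means
        T2[mm, mm] <- T2[mm, mm] + n_g * C + Mdev + n_g * tcrossprod(m_mean)
      }
    }
    mu <- T1 / pat$n
    sigma <- T2 / pat$n - tcrossprod(mu)
    sigma <- (sigma + t(sigma)) / 2
    ll <- fiml_loglik_moments(mu, sigma, pat)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      return(list(mu = mu, sigma = sigma, loglik = ll, iterations = it))
    }
    ll_old <- ll
  }
  warning("saturated-model EM did not converge in ", max_iter, " iterations")
  list(mu = mu, sigma = sigma, loglik = ll_old, iterations = max_iter)
}

# Independence baseline under FIML: diagonal covariance, free means. The
# likelihood separates per variable, so each variable's ML solution uses its
# observed cases (variance with divisor n_j).
baseline_loglik <- function(X) {
  ll <- 0
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    x <- x[!is.na(x)]
    v <- mean((x - mean(x))^2)
    ll <- ll - 0.5 * length(x) * (log(2 * pi) + log(v) + 1)
  }
  ll
}

cfa_start_values <- function(spec, pmap, sat) {
  vj <- pmax(diag(sat$sigma), 1e-6)
  # principal-axis start per factor block: S_f ~ lambda lambda' + Theta
  lambda0 <- 0.7 * sqrt(vj)
  theta0 <- 0.5 * vj
  for (j in seq_len(pmap$m)) {
    idx <- which(pmap$fac_of == j)
    if (length(idx) >= 2L) {
      Sf <- sat$sigma[idx, idx, drop = FALSE]
      e <- eigen((Sf + t(Sf)) / 2, symmetric = TRUE)
      l <- sqrt(max(e$values[1L], 1e-8)) * e$vectors[, 1L]
      if (sum(l) < 0) l <- -l
      lambda0[idx] <- l
      theta0[idx] <- pmax(diag(Sf) - l^2, 0.05 * diag(Sf))
    }
  }
  if (pmap$marker) {
    # rescale so the marker indicator's loading is 1
    for (j in seq_len(pmap$m)) {
      idx <- which(pmap$fac_of == j)
      lambda0[idx] <- lambda0[idx] / lambda0[pmap$first_of_factor[j]]
    }
  }
  start <- numeric(pmap$n_par)
  start[pmap$idx_lambda] <- lambda0[pmap$lambda_free]
  start[pmap$idx_theta] <- theta0
  if (spec$second_order) {
    if (pmap$marker) {
      m <- pmap$m
      start[pmap$idx_struct] <- c(rep(1, m - 1L),
                                  0.5 * mean(vj) * 0.49,
                                  rep(0.5 * mean(vj) * 0.25, m))
    } else {
      start[pmap$idx_struct] <- rep(0.7, pmap$m)
    }
  } else if (pmap$m == 1L && pmap$marker) {
    start[pmap$idx_struct] <- 0.49 * vj[pmap$first_of_factor[1L]]
  }
  if (spec$meanstructure) start[pmap$idx_mu] <- sat$mu
  start
}

#' Fit a confirmatory factor model by (full-information) maximum likelihood
#'
#' Maximizes the casewise Gaussian log-likelihood over each case's
#' observed-variable pattern, so rows with missing indicators contribute the
#' likelihood of their observed sub-vector (no imputation, no listwise
#' deletion). With complete data this coincides with the usual
#' sample-covariance ML solution. The chi-square statistic is computed
#' against the unstructured (saturated) Gaussian model, which is itself
#' estimated by EM when cells are missing; the incremental-fit baseline is
#' the independence model (free means and variances) on the same cases.
#'
#' @param data Data frame or matrix containing the indicator columns
#'   (`NA` = missing). Rows with no observed indicator are dropped.
#' @param spec A [cfa_spec()].
#' @param starts Number of optimizer starts; the first uses moment-based
#'   start values, the rest jitter them. The best converged solution wins.
#' @param max_restarts Additional jittered restarts attempted when no start
#'   converges.
#' @param control Control list passed to [stats::nlminb()].
#' @param seed_jitter Integer seed used only to make jittered restarts
#'   reproducible.
#' @return An object of class `cfa_fit`: estimates (`lambda`, `theta`,
#'   `gamma`/`psi`, `mu`), `loglik`, `n_params`, `chi2`, `df`, `p_value`,
#'   `cfi`, `tli`, `rmsea` (with 90% CI), `srmr`, `aic`, `bic`, `converged`,
#'   `admissible`, `heywood`, `n_used`, plus the implied and saturated
#'   moments.
#' @seealso [good_fit()], [prune_search()], [regression_factor_scores()]
#' @export
fit_cfa <- function(data, spec, starts = 1L, max_restarts = 9L,
                    control = list(iter.max = 2000L, eval.max = 4000L,
                                   rel.tol = 1e-12),
                    seed_jitter = 1L) {
  stopifnot(inherits(spec, "cfa_spec"))
  miss <- setdiff(spec$indicators, colnames(data))
  if (length(miss)) stop("indicator(s) not in data: ", paste(miss, collapse = ", "))
  X <- as.matrix(as.data.frame(data)[, spec$indicators, drop = FALSE])
  storage.mode(X) <- "double"
  pat <- fiml_patterns(X)
  if (pat$n < 3L) stop("need at least 3 cases with observed indicators")
  pmap <- cfa_pmap(spec)
  sat <- saturated_moments(X[rowSums(!is.na(X)) > 0L, , drop = FALSE], pat)
  start0 <- cfa_start_values(spec, pmap, sat)

  obj <- function(par) fiml_objective(par, spec, pmap, pat, gradient = FALSE)
  gr <- function(par) fiml_objective(par, spec, pmap, pat, gradient = TRUE)$gradient

  rng <- local({ set.seed(seed_jitter); function(k) stats::rnorm(k, 0, 0.15) })
  best <- NULL
  n_try <- max(1L, starts) + max_restarts
  for (i in seq_len(n_try)) {
    par0 <- if (i == 1L) start0 else start0 * (1 + rng(length(start0))) + rng(length(start0)) * 0.05
    opt <- tryCatch(
      stats::nlminb(par0, obj, gradient = gr, control = control),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$objective)) next
    # nlminb can report "false convergence" at a genuine optimum when the
    # tolerance is very tight; accept a small scaled gradient as converged
    gnorm <- max(abs(gr(opt$par)))
    conv <- (opt$convergence == 0L ||
               gnorm < 1e-4 * max(1, abs(opt$objective))) &&
      opt$objective < 1e11
    cand <- list(opt = opt, converged = conv)
    if (is.null(best) || opt$objective < best$opt$objective - 1e-9 ||
        (conv && !best$converged && opt$objective <= best$opt$objective + 1e-6))
      best <- cand
    if (i >= max(1L, starts) && !is.null(best) && best$converged) break
  }
  if (is.null(best)) stop("optimization failed from all starting values")

  u <- cfa_unpack(best$opt$par, spec, pmap)
  ll <- -best$opt$objective
  implied <- u$Lambda %*% u$Phi %*% t(u$Lambda) + diag(u$theta, pmap$p)
  dimnames(implied) <- list(spec$indicators, spec$indicators)

  n_params <- pmap$n_par
  q_cov <- n_params - if (spec$meanstructure) pmap$p else 0L
  p_star <- pmap$p * (pmap$p + 1L) / 2L
  df <- p_star - q_cov
  chi2 <- max(0, 2 * (sat$loglik - ll))
  n <- pat$n

  heywood <- any(u$theta < 0) ||
    (spec$second_order && (any(u$psi < -1e-8) ||
                           (pmap$marker && u$phi_g < 0))) ||
    (!spec$second_order && pmap$marker && u$Phi[1L, 1L] < 0)
  admissible <- best$converged && !heywood

  # baseline (independence) model on the same cases
  Xu <- X[rowSums(!is.na(X)) > 0L, , drop = FALSE]
  ll_b <- baseline_loglik(Xu)
  chi2_b <- max(0, 2 * (sat$loglik - ll_b))
  df_b <- p_star - pmap$p

  idx <- fit_index_values(chi2, df, chi2_b, df_b, n, sat$sigma, implied)

  fit <- list(
    spec = spec, lambda = stats::setNames(
      u$Lambda[cbind(seq_len(pmap$p), pmap$fac_of)], spec$indicators),
    theta = stats::setNames(u$theta, spec$indicators),
    gamma = if (spec$second_order) stats::setNames(u$gamma, spec$factor_names),
    psi = if (spec$second_order) stats::setNames(u$psi, spec$factor_names),
    phi_g = u$phi_g,
    phi = if (!spec$second_order) u$Phi,
    mu = stats::setNames(u$mu, spec$indicators),
    Lambda = u$Lambda, Phi = u$Phi,
    implied_sigma = implied,
    sat_mu = sat$mu, sat_sigma = sat$sigma,
    loglik = ll, loglik_saturated = sat$loglik, loglik_baseline = ll_b,
    n_params = n_params, n_used = n, n_dropped = pat$dropped,
    chi2 = chi2, df = df, p_value = if (df > 0) stats::pchisq(chi2, df, lower.tail = FALSE) else NA_real_,
    chi2_baseline = chi2_b, df_baseline = df_b,
    cfi = idx$cfi, tli = idx$tli, rmsea = idx$rmsea,
    rmsea_ci_lower = idx$rmsea_ci_lower, rmsea_ci_upper = idx$rmsea_ci_upper,
    srmr = idx$srmr,
    aic = -2 * ll + 2 * n_params,
    bic = -2 * ll + log(n) * n_params,
    converged = best$converged, heywood = heywood, admissible = admissible,
    em_iterations = sat$iterations
  )
  class(fit) <- "cfa_fit"
  fit
}

#' @export
print.cfa_fit <- function(x, digits = 3, ...) {
  cat("CFA fit (FIML), n =", x$n_used, "\n")
  cat(sprintf("  chi2(%d) = %.*f, p = %s\n", x$df, digits, x$chi2,
              if (is.na(x$p_value)) "NA" else formatC(x$p_value, digits = 3, format = "f")))
  cat(sprintf("  CFI = %.*f  TLI = %s  RMSEA = %.*f [%.*f, %.*f]  SRMR = %.*f\n",
              digits, x$cfi,
              if (is.na(x$tli)) "NA" else formatC(x$tli, digits = digits, format = "f"),
              digits, x$rmsea, digits, x$rmsea_ci_lower, digits, x$rmsea_ci_upper,
              digits, x$srmr))
  cat(sprintf("  loglik = %.3f  AIC = %.2f  BIC = %.2f  params = %d\n",
              x$loglik, x$aic, x$bic, x$n_params))
  if (!x$converged) cat("  WARNING: optimizer did not converge\n")
  if (x$heywood) cat("  WARNING: Heywood case (negative variance); fit inadmissible\n")
  invisible(x)
}
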