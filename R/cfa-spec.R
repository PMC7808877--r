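#' Define a confirmatory factor model
#'
#' Builds a model specification in which every indicator loads on exactly one
#' first-order factor, optionally with a single second-order ("general")
#' factor over all first-order factors. This covers the three model shapes
#' used for unit-level ERN data: a single factor per task, a flat
#' single-factor model over all units, and the second-order model in which
#' task factors load on a General ERN.
#'
#' Two identification schemes are supported. Under `"variance"` (default) all
#' loadings are free and every latent variable has unit variance: first-order
#' factor variances are fixed to 1, and in the second-order model each
#' disturbance is constrained to `1 - gamma^2` so that first-order factors
#' remain standardized while the general factor has variance 1. Under
#' `"marker"` the first loading of each factor (and the first second-order
#' loading) is fixed to 1 with factor/disturbance variances free. Both
#' schemes parameterize the same covariance structure and reach the same
#' maximized likelihood.
#'
#' @param factors Named list mapping factor names to character vectors of
#'   indicator names. Indicators must be unique across factors.
#' @param second_order If `TRUE`, add a general factor on which all
#'   first-order factors load. Requires at least two first-order factors.
#' @param identification `"variance"` or `"marker"` (see Details).
#' @param meanstructure If `TRUE` (default) indicator means are free model
#'   parameters, estimated jointly under full-information maximum likelihood.
#' @return An object of class `cfa_spec`.
#' @examples
#' cfa_spec(list(arrow = paste0("arrow_u", 1:5)))
#' @export
cfa_spec <- function(factors, second_order = FALSE,
                     identification = c("variance", "marker"),
                     meanstructure = TRUE) {
  identification <- match.arg(identification)
  if (!is.list(factors) || is.null(names(factors)) || any(names(factors) == ""))
    stop("'factors' must be a named list of indicator vectors")
  indicators <- unlist(factors, use.names = FALSE)
  if (anyDuplicated(indicators))
    stop("every indicator must load on exactly one first-order factor")
  if (any(lengths(factors) < 1L)) stop("each factor needs at least one indicator")
  m <- length(factors)
  if (second_order && m < 2L)
    stop("a second-order factor requires at least two first-order factors")
  structure(list(
    indicators = indicators,
    factors = factors,
    factor_names = names(factors),
    second_order = isTRUE(second_order),
    identification = identification,
    meanstructure = isTRUE(meanstructure)
  ), class = "cfa_spec")
}

#' @export
print.cfa_spec <- function(x, ...) {
  cat("CFA model specification\n")
  for (f in x$factor_names)
    cat("  ", f, " =~ ", paste(x$factors[[f]], collapse = " + "), "\n", sep = "")
  if (x$second_order)
    cat("  general =~ ", paste(x$factor_names, collapse = " + "), "\n", sep = "")
  cat("  identification: ", x$identification,
      if (x$meanstructure) " (means modeled)" else "", "\n", sep = "")
  invisible(x)
}

# Index map from a spec: which factor each indicator belongs to, and the
# layout of the free-parameter vector.
cfa_pmap <- function(spec) {
  p <- length(spec$indicators)
  m <- length(spec$factor_names)
  fac_of <- integer(p)
  first_of_factor <- integer(m)
  k <- 1L
  for (j in seq_len(m)) {
    idx <- match(spec$factors[[j]], spec$indicators)
    fac_of[idx] <- j
    first_of_factor[j] <- idx[1L]
  }
  marker <- spec$identification == "marker"
  lambda_free <- rep(TRUE, p)
  if (marker) lambda_free[first_of_factor] <- FALSE

  names_l <- paste0("lambda.", spec$indicators)[lambda_free]
  names_t <- paste0("theta.", spec$indicators)
  names_s <- character(0)
  if (spec$second_order) {
    if (marker) {
      names_s <- c(paste0("gamma.", spec$factor_names[-1L]), "phi.general",
                   paste0("psi.", spec$factor_names))
    } else {
      names_s <- paste0("gamma.", spec$factor_names)
    }
  } else if (m == 1L && marker) {
    names_s <- "phi.factor"
  } else if (m > 1L) {
    stop("multiple first-order factors require second_order = TRUE")
  }
  names_mu <- if (spec$meanstructure) paste0("mu.", spec$indicators) else character(0)
  nm <- c(names_l, names_t, names_s, names_mu)
  n_l <- sum(lambda_free)
  list(p = p, m = m, fac_of = fac_of, first_of_factor = first_of_factor,
       marker = marker, lambda_free = lambda_free,
       idx_lambda = seq_len(n_l),
       idx_theta = n_l + seq_len(p),
       idx_struct = n_l + p + seq_along(names_s),
       idx_mu = n_l + p + length(names_s) + seq_along(names_mu),
       n_par = length(nm), par_names = nm)
}

# Expand a free-parameter vector into model matrices.
# Returns Lambda (p x m), theta (p), Phi (m x m), mu (p), plus the
# second-order pieces (gamma, psi, phi_g) when present.
cfa_unpack <- function(par, spec, pmap) {
  p <- pmap$p; m <- pmap$m
  lambda <- numeric(p)
  lambda[pmap$lambda_free] <- par[pmap$idx_lambda]
  if (pmap$marker) lambda[pmap$first_of_factor] <- 1
  Lambda <- matrix(0, p, m)
  Lambda[cbind(seq_len(p), pmap$fac_of)] <- lambda
  theta <- par[pmap$idx_theta]
  gamma <- NULL; psi <- NULL; phi_g <- NULL
  if (spec$second_order) {
    s <- par[pmap$idx_struct]
    if (pmap$marker) {
      gamma <- c(1, s[seq_len(m - 1L)])
      phi_g <- s[m]
      psi <- s[m + seq_len(m)]
      Phi <- phi_g * tcrossprod(gamma) + diag(psi, m)
    } else {
      gamma <- s
      phi_g <- 1
      psi <- 1 - gamma^2
      Phi <- tcrossprod(gamma) + diag(psi, m)
    }
  } else if (m == 1L) {
    Phi <- matrix(if (pmap$marker) par[pmap$idx_struct] else 1, 1, 1)
  }
  mu <- if (spec$meanstructure) par[pmap$idx_mu] else numeric(p)
  list(Lambda = Lambda, theta = theta, Phi = Phi, mu = mu,
       gamma = gamma, psi = psi, phi_g = phi_g)
}

#' Model-implied covariance matrix (and means)
#'
#' Computes `Sigma = Lambda Phi Lambda' + Theta`, expanding the factor
#' covariance `Phi` through the second-order layer when the model has one
#' (`Phi = phi_g * gamma gamma' + Psi`).
#'
#' @param spec A [cfa_spec()].
#' @param params Named list with `lambda` (per-indicator loadings, in the
#'   order of `spec$indicators`), `theta` (residual variances), and, for
#'   second-order models, `gamma` (second-order loadings) plus optional
#'   `psi` (disturbances; defaults to `1 - gamma^2`) and `phi_g` (general
#'   factor variance, default 1). For a single-factor model an optional
#'   `phi` gives the factor variance (default 1). Optional `mu` gives means.
#' @return List with `sigma` (p x p) and `mu` (length p).
#' @export
implied_covariance <- function(spec, params) {
  p <- length(spec$indicators); m <- length(spec$factor_names)
  lambda <- params$lambda; theta <- params$theta
  if (length(lambda) != p || length(theta) != p)
    stop("'lambda' and 'theta' must match the number of indicators (", p, ")")
  pmap <- cfa_pmap(spec)
  Lambda <- matrix(0, p, m)
  Lambda[cbind(seq_len(p), pmap$fac_of)] <- lambda
  if (spec$second_order) {
    gamma <- params$gamma
    if (length(gamma) != m) stop("'gamma' must have one loading per first-order factor")
    psi <- if (is.null(params$psi)) 1 - gamma^2 else params$psi
    phi_g <- if (is.null(params$phi_g)) 1 else params$phi_g
    Phi <- phi_g * tcrossprod(gamma) + diag(psi, m)
  } else {
    phi <- if (is.null(params$phi)) rep(1, m) else params$phi
    Phi <- diag(phi, m)
  }
  sigma <- Lambda %*% Phi %*% t(Lambda) + diag(theta, p)
  dimnames(sigma) <- list(spec$indicators, spec$indicators)
  mu <- if (is.null(params$mu)) numeric(p) else params$mu
  names(mu) <- spec$indicators
  list(sigma = sigma, mu = mu)
}
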