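# Validity analyses: regression-method latent scores, the ERN x trait
# multitrait-multimethod matrix, convergent/discriminant hypothesis scoring,
# and Fisher-z profile similarities.

#' Regression-method (Thurstone) factor scores
#'
#' Per case, the latent score vector is the conditional expectation
#' `Phi_xi Lambda' Sigma_obs^-1 (x_obs - mu_obs)` restricted to that case's
#' observed-variable pattern, so missing indicators are handled patternwise
#' rather than by deletion. For a second-order model, scores for the
#' general factor and every first-order factor are returned.
#'
#' @param fit A converged, admissible `cfa_fit`.
#' @param data Data containing the fit's indicator columns; rows with no
#'   observed indicator get missing scores.
#' @param id Optional vector of case identifiers (defaults to row names).
#' @return Data frame: `participant_id` plus one column per latent variable
#'   (the general factor first for second-order models).
#' @export
regression_factor_scores <- function(fit, data, id = NULL) {
  stopifnot(inherits(fit, "cfa_fit"))
  spec <- fit$spec
  X <- as.matrix(as.data.frame(data)[, spec$indicators, drop = FALSE])
  if (is.null(id)) {
    id <- rownames(X)
    if (is.null(id)) id <- as.character(seq_len(nrow(X)))
  }
  m <- length(spec$factor_names)
  # latent vector xi, its covariance, and its covariance with indicators
  if (spec$second_order) {
    gamma <- unname(fit$gamma)
    psi <- unname(fit$psi)
    phi_g <- fit$phi_g
    Phi_eta <- phi_g * tcrossprod(gamma) + diag(psi, m)
    Phi_xi <- rbind(c(phi_g, phi_g * gamma),
                    cbind(phi_g * gamma, Phi_eta))
    cov_xi_x <- rbind(phi_g * gamma, Phi_eta) %*% t(fit$Lambda)
    xi_names <- c("general", spec$factor_names)
  } else {
    Phi_xi <- fit$Phi
    cov_xi_x <- fit$Phi %*% t(fit$Lambda)
    xi_names <- spec$factor_names
  }
  sigma <- fit$implied_sigma
  mu <- fit$mu
  scores <- matrix(NA_real_, nrow(X), length(xi_names),
                   dimnames = list(NULL, xi_names))
  obs <- !is.na(X)
  key <- apply(obs, 1L, function(z) paste(as.integer(z), collapse = ""))
  for (kk in unique(key)) {
    rows <- which(key == kk)
    o <- which(obs[rows[1L], ])
    if (!length(o)) next
    W <- solve(sigma[o, o, drop = FALSE])
    B <- cov_xi_x[, o, drop = FALSE] %*% W
    D <- sweep(X[rows, o, drop = FALSE], 2L, mu[o])
    scores[rows, ] <- D %*% t(B)
  }
  out <- data.frame(participant_id = id, scores, check.names = FALSE,
                    row.names = NULL)
  attr(out, "score_cov") <- Phi_xi
  out
}

#' The default convergent-validity hypothesis pairs
#'
#' Encodes which ERN measure is expected to relate to which trait domain,
#' with the expected correlation sign (negative = enhanced, more negative,
#' ERN with higher trait; positive for reversed maladaptive domains). The
#' arrow task and the General ERN pair with Neuroticism and
#' Conscientiousness (and their maladaptive counterparts), the social task
#' with the interpersonal domains, the unpleasant task with
#' negative-affect domains, and the pleasant task with Extraversion (and
#' reversed Detachment).
#'
#' @param tasks Task labels.
#' @return Data frame `measure`, `domain`, `direction` (-1 or +1).
#' @export
hypothesis_pairs <- function(tasks = c("arrow", "social", "unpleasant",
                                       "pleasant")) {
  rows <- list(
    c("arrow", "neuroticism", -1), c("arrow", "conscientiousness", -1),
    c("arrow", "negative_affectivity", -1), c("arrow", "disinhibition", 1),
    c("social", "extraversion", -1), c("social", "agreeableness", -1),
    c("social", "detachment", 1), c("social", "antagonism", 1),
    c("unpleasant", "neuroticism", -1),
    c("unpleasant", "negative_affectivity", -1),
    c("pleasant", "extraversion", -1), c("pleasant", "detachment", 1),
    c("general", "neuroticism", -1), c("general", "conscientiousness", -1),
    c("general", "negative_affectivity", -1), c("general", "disinhibition", 1))
  df <- data.frame(measure = vapply(rows, `[[`, "", 1L),
                   domain = vapply(rows, `[[`, "", 2L),
                   direction = as.numeric(vapply(rows, `[[`, "", 3L)),
                   stringsAsFactors = FALSE)
  df[df$measure %in% c(tasks, "general"), ]
}

#' Correlate ERN scores with trait scores (MTMM matrix)
#'
#' Pearson correlations of every ERN measure with every trait domain over
#' their overlapping cases, with Cohen effect-size flags (|r| >= .10 small,
#' >= .30 medium, >= .50 large, thresholds inclusive). Cells with fewer
#' than `min_n` overlapping cases are marked unavailable.
#'
#' @param ern_scores Data frame: `participant_id` + one column per ERN
#'   measure.
#' @param trait_scores Data frame: `participant_id` + one column per trait
#'   domain.
#' @param min_n Minimum pairwise n (default 3).
#' @return Object of class `mtmm`: list with `r` (measures x domains), `n`,
#'   `p_value` and `effect` (character matrix "", "small", "medium",
#'   "large", or NA when unavailable).
#' @export
correlate_scores <- function(ern_scores, trait_scores, min_n = 3L) {
  measures <- setdiff(colnames(ern_scores), "participant_id")
  domains <- setdiff(colnames(trait_scores), "participant_id")
  idx <- match(ern_scores$participant_id, trait_scores$participant_id)
  R <- matrix(NA_real_, length(measures), length(domains),
              dimnames = list(measures, domains))
  N <- P <- R
  for (i in seq_along(measures)) for (j in seq_along(domains)) {
    x <- ern_scores[[measures[i]]]
    y <- trait_scores[[domains[j]]][idx]
    ok <- !is.na(x) & !is.na(y)
    N[i, j] <- sum(ok)
    if (sum(ok) >= min_n && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0) {
      ct <- stats::cor.test(x[ok], y[ok])
      R[i, j] <- unname(ct$estimate)
      P[i, j] <- ct$p.value
    }
  }
  eff <- effect_size_flag(R)
  structure(list(r = R, n = N, p_value = P, effect = eff), class = "mtmm")
}

#' Cohen effect-size flag for a correlation
#' @param r Correlation value(s).
#' @return "", "small", "medium" or "large" (inclusive thresholds .10, .30,
#'   .50); NA for missing input.
#' @export
effect_size_flag <- function(r) {
  out <- ifelse(is.na(r), NA_character_,
                ifelse(abs(r) >= 0.50, "large",
                       ifelse(abs(r) >= 0.30, "medium",
                              ifelse(abs(r) >= 0.10, "small", ""))))
  if (is.matrix(r)) dimnames(out) <- dimnames(r)
  out
}

#' @export
print.mtmm <- function(x, digits = 2, ...) {
  cat("MTMM correlation matrix (", nrow(x$r), " ERN measures x ",
      ncol(x$r), " trait domains)\n", sep = "")
  print(round(x$r, digits))
  invisible(x)
}

#' Score convergent and discriminant validity against a hypothesis set
#'
#' Convergent % is the share of hypothesized (measure, domain) pairs whose
#' observed correlation reaches at least a small effect (|r| >= .10) in the
#' expected direction; discriminant % is the share of non-hypothesized
#' pairs with |r| < .10.
#'
#' @param mtmm An `mtmm` object (or a plain correlation matrix).
#' @param hypotheses Data frame `measure`, `domain`, `direction`; defaults
#'   to [hypothesis_pairs()].
#' @param small Threshold for a small effect (default 0.10, inclusive).
#' @return List with `convergent_pct`, `discriminant_pct`, `n_expected`,
#'   `n_unexpected`, and the per-pair detail table.
#' @export
evaluate_hypotheses <- function(mtmm, hypotheses = hypothesis_pairs(),
                                small = 0.10) {
  R <- if (inherits(mtmm, "mtmm")) mtmm$r else as.matrix(mtmm)
  detail <- expand.grid(measure = rownames(R), domain = colnames(R),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key_h <- paste(hypotheses$measure, hypotheses$domain)
  key_d <- paste(detail$measure, detail$domain)
  detail$expected <- key_d %in% key_h
  detail$direction <- hypotheses$direction[match(key_d, key_h)]
  detail$r <- R[cbind(detail$measure, detail$domain)]
  detail$hit <- ifelse(detail$expected,
                       !is.na(detail$r) & abs(detail$r) >= small &
                         sign(detail$r) == detail$direction,
                       !is.na(detail$r) & abs(detail$r) < small)
  conv <- detail$hit[detail$expected]
  disc <- detail$hit[!detail$expected]
  list(convergent_pct = 100 * mean(conv),
       discriminant_pct = 100 * mean(disc),
       n_expected = sum(detail$expected),
       n_unexpected = sum(!detail$expected),
       detail = detail)
}

#' Fisher-z profile similarity of ERN measures
#'
#' Each ERN measure's profile is its vector of correlations with the trait
#' domains of one instrument; profiles are Fisher-z transformed
#' (`atanh(r)`, with |r| clamped at 0.9999 to keep z finite) and the
#' similarity of two measures is the Pearson correlation of their z
#' profiles (the alerting-r construction).
#'
#' @param mtmm An `mtmm` object or correlation matrix (measures x domains).
#' @param instruments Named list mapping instrument labels to the domain
#'   columns forming each profile; default: all domains as one instrument.
#' @return Named list (one per instrument) of symmetric measures x measures
#'   similarity matrices with unit diagonal.
#' @export
profile_similarity <- function(mtmm, instruments = NULL) {
  R <- if (inherits(mtmm, "mtmm")) mtmm$r else as.matrix(mtmm)
  if (is.null(instruments)) instruments <- list(all = colnames(R))
  lapply(instruments, function(doms) {
    miss <- setdiff(doms, colnames(R))
    if (length(miss)) stop("domains not in matrix: ", paste(miss, collapse = ", "))
    if (length(doms) < 3L) stop("a profile needs at least 3 trait correlations")
    Z <- t(apply(R[, doms, drop = FALSE], 1L, fisher_z))
    S <- stats::cor(t(Z), use = "pairwise.complete.obs")
    diag(S) <- 1
    S
  })
}

#' Fisher z transform with clamping
#' @param r Correlations; |r| is clamped at `clamp` (with a warning) so the
#'   transform stays finite.
#' @export
fisher_z <- function(r, clamp = 0.9999) {
  if (any(abs(r) > clamp, na.rm = TRUE)) {
    warning("correlations with |r| > ", clamp, " clamped before the Fisher ",
            "z transform")
    r <- pmin(pmax(r, -clamp), clamp)
  }
  atanh(r)
}
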