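# Residual-stratification nonlinear MR -----------------------------------
#
# Stratifying on raw exposure would condition on a collider (exposure is
# affected by both the genetic score and confounders); instead the sample is
# stratified on residual exposure - observed exposure minus the mean-centred
# genetic contribution - inside which linear per-stratum IV estimates remain
# unbiased and can be compared across strata to characterise nonlinearity.

#' Residual exposure after removing the genetic contribution
#'
#' Regresses the exposure on the genetic risk score (plus covariates) and
#' subtracts the mean-centred genetic contribution
#' `grs * beta_grs - mean(grs * beta_grs)` from the observed exposure, so the
#' residual keeps the observed exposure's mean and units.
#'
#' @param exposure Exposure in hours/day (NA allowed, e.g. post-QC).
#' @param grs Genetic risk score.
#' @param covariates Optional covariate data.frame (adjusting the fit only).
#' @return List with `residual` (same length as input, NA propagated),
#'   `beta_grs`, `se_grs`, `n`.
#' @export
residual_exposure <- function(exposure, grs, covariates = NULL) {
  .assert(all(is.finite(grs)), "'grs' must be finite")
  .assert(var(grs) > 0, "zero variance in genetic risk score")
  keep <- .complete_rows(exposure, covariates)
  y <- exposure[keep]
  z <- grs[keep]
  C <- .cov_matrix(if (!is.null(covariates))
                     as.data.frame(covariates)[keep, , drop = FALSE],
                   length(y))
  fit <- .snp_linear(matrix(z, ncol = 1), y, C)
  g <- grs * fit$beta
  g_centred <- g - mean(g[keep])
  residual <- exposure - g_centred
  list(residual = residual, beta_grs = fit$beta, se_grs = fit$se,
       n = length(y))
}

#' Stratify residual exposure
#'
#' Quantile scheme: near-equal-sized groups cut on stable ranks (ties broken
#' by position, so group sizes differ by at most the tie count at the
#' boundaries). Fixed scheme: half-open intervals `[lo, hi)` between the
#' supplied increasing boundaries, with open ends below the first and at or
#' above the last boundary.
#'
#' @param residual Residual exposure vector (NA propagates).
#' @param k Number of quantile groups (3 or 5 in practice).
#' @param boundaries Strictly increasing numeric boundaries for the fixed
#'   scheme (used instead of `k` when supplied).
#' @param min_per_stratum Minimum non-missing values required per quantile
#'   group (default 50).
#' @return Integer stratum assignment (1-based, NA propagated).
#' @export
stratify_residual <- function(residual, k = 5, boundaries = NULL,
                              min_per_stratum = 50) {
  ok <- !is.na(residual)
  assignment <- rep(NA_integer_, length(residual))
  if (!is.null(boundaries)) {
    .assert(!is.unsorted(boundaries, strictly = TRUE),
            "fixed boundaries must be strictly increasing")
    assignment[ok] <- findInterval(residual[ok], boundaries) + 1L
    return(assignment)
  }
  .assert(.is_count(k) && k >= 2, "'k' must be an integer >= 2")
  m <- sum(ok)
  .assert(m >= k * min_per_stratum,
          sprintf("quantile stratification needs at least %d non-missing values",
                  k * min_per_stratum))
  x <- residual[ok]
  .assert(var(x) > 0, "degenerate residual distribution: all values identical")
  r <- rank(x, ties.method = "first")
  assignment[ok] <- as.integer(floor((r - 1) * k / m) + 1L)
  assignment
}

.fit_slope <- function(z, y, C, family) {
  if (family == "linear") {
    .snp_linear(matrix(z, ncol = 1), y, C)
  } else if (ncol(C) == 1L) {
    .snp_logistic_fast(matrix(z, ncol = 1), y)
  } else {
    .snp_logistic_glm(matrix(z, ncol = 1), y, C)
  }
}

#' Per-stratum Wald-ratio IV estimates
#'
#' Within each stratum the genetic score's exposure association (`grs_beta`,
#' hours per allele) and outcome association (log-odds or outcome units per
#' allele) are estimated with the requested covariates, and their ratio gives
#' the stratum causal estimate per 1 h/day with a first-order delta SE.
#' Strata with no cases (or no controls) for a binary outcome yield missing
#' estimates with a warning rather than an error, so rare outcomes do not
#' crash the pipeline. The recorded `mean_exposure` is the mean *observed*
#' reported duration in the stratum, which is what per-stratum estimates are
#' regressed against downstream.
#'
#' @param grs Genetic risk score.
#' @param exposure Observed (reported) exposure in hours/day.
#' @param outcome Outcome vector (0/1 for logistic).
#' @param assignment Stratum assignment from [stratify_residual()].
#' @param covariates Optional covariate data.frame.
#' @param family `"logistic"` (binary outcomes) or `"linear"` (birthweight).
#' @return `data.frame` of class `stratum_estimates`: `stratum`, `n`,
#'   `n_cases`, `mean_exposure`, `grs_beta`, `grs_se`, `beta_iv`, `se_iv`,
#'   `ci_low`, `ci_high`, `pval`.
#' @export
stratum_wald <- function(grs, exposure, outcome, assignment,
                         covariates = NULL,
                         family = c("logistic", "linear")) {
  family <- match.arg(family)
  strata <- sort(unique(assignment[!is.na(assignment)]))
  rows <- lapply(strata, function(s) {
    in_s <- !is.na(assignment) & assignment == s
    keep <- in_s & .complete_rows(outcome, covariates) & !is.na(exposure)
    y <- outcome[keep]
    z <- grs[keep]
    x <- exposure[keep]
    n <- sum(keep)
    cs <- if (family == "logistic") sum(y) else NA_integer_
    base <- data.frame(stratum = s, n = n, n_cases = cs,
                       mean_exposure = mean(x),
                       grs_beta = NA_real_, grs_se = NA_real_,
                       beta_iv = NA_real_, se_iv = NA_real_,
                       ci_low = NA_real_, ci_high = NA_real_,
                       pval = NA_real_)
    if (family == "logistic" && (cs == 0 || cs == n)) {
      warning(sprintf("stratum %d has no %s; estimate set missing", s,
                      if (cs == 0) "cases" else "controls"), call. = FALSE)
      return(base)
    }
    C <- .cov_matrix(if (!is.null(covariates))
                       as.data.frame(covariates)[keep, , drop = FALSE], n)
    fx <- .snp_linear(matrix(z, ncol = 1), x, C)
    fy <- .fit_slope(z, y, C, family)
    base$grs_beta <- fx$beta
    base$grs_se <- fx$se
    base$beta_iv <- fy$beta / fx$beta
    base$se_iv <- fy$se / abs(fx$beta)
    ci <- .norm_ci(base$beta_iv, base$se_iv)
    base$ci_low <- ci[1]; base$ci_high <- ci[2]
    base$pval <- .norm_p(base$beta_iv, base$se_iv)
    base
  })
  out <- do.call(rbind, rows)
  class(out) <- c("stratum_estimates", "data.frame")
  out
}

.usable <- function(beta, se) is.finite(beta) & is.finite(se) & se > 0

#' Cochran's Q across stratum estimates
#'
#' Tests whether per-stratum IV estimates differ more than their sampling
#' error allows: `Q = sum((beta_g - pooled)^2 / se_g^2)` against chi-squared
#' with (strata - 1) df; p < 0.05 suggests heterogeneity, i.e. evidence
#' against one common linear effect.
#'
#' @param estimates A `stratum_estimates` table (or any data.frame with
#'   `beta_iv` and `se_iv`).
#' @return List with `q`, `df`, `pval`, `pooled`.
#' @export
heterogeneity_across_strata <- function(estimates) {
  b <- estimates$beta_iv
  se <- estimates$se_iv
  ok <- .usable(b, se)
  .assert(sum(ok) >= 2L, "need at least 2 strata with finite estimates")
  b <- b[ok]; se <- se[ok]
  w <- 1 / se^2
  pooled <- sum(w * b) / sum(w)
  q <- sum(w * (b - pooled)^2)
  df <- sum(ok) - 1L
  list(q = q, df = df, pval = pchisq(q, df, lower.tail = FALSE),
       pooled = pooled)
}

#' Meta-regression nonlinearity test
#'
#' Weighted least squares of per-stratum IV estimates on the stratum mean of
#' observed sleep duration (weights `1/se^2`, known-variance fixed-effect
#' SEs). A non-zero slope indicates the causal effect changes with the
#' exposure level - evidence against a single linear effect; under a
#' quadratic truth the fitted slope estimates twice the curvature, since the
#' derivative of a quadratic is linear in the exposure.
#'
#' @inheritParams heterogeneity_across_strata
#' @return List with `slope`, `se`, `pval`, `intercept`.
#' @export
nonlinearity_metareg <- function(estimates) {
  b <- estimates$beta_iv
  se <- estimates$se_iv
  x <- estimates$mean_exposure
  ok <- .usable(b, se) & is.finite(x)
  .assert(sum(ok) >= 3L, "meta-regression needs at least 3 strata")
  b <- b[ok]; se <- se[ok]; x <- x[ok]
  .assert(var(x) > 0, "zero variance in stratum mean exposure")
  fit <- .wls_fixed(cbind(1, x), b, 1 / se^2)
  slope <- fit$beta[2]
  slope_se <- sqrt(fit$vcov[2, 2])
  list(slope = slope, se = slope_se, pval = .norm_p(slope, slope_se),
       intercept = fit$beta[1])
}

#' IV-exposure constancy across strata
#'
#' The per-stratum Wald approach assumes the score-exposure association is
#' the same in every stratum; this applies the heterogeneity Q and the
#' meta-regression (against mean observed duration) to the per-stratum
#' `grs_beta` estimates to check that assumption.
#'
#' @inheritParams heterogeneity_across_strata
#' @return List with `q`, `df`, `q_pval`, `slope`, `slope_se`, `slope_pval`
#'   (meta-regression entries NA when fewer than 3 strata are usable).
#' @export
iv_constancy <- function(estimates) {
  d <- data.frame(beta_iv = estimates$grs_beta, se_iv = estimates$grs_se,
                  mean_exposure = estimates$mean_exposure)
  q <- heterogeneity_across_strata(d)
  mr <- if (sum(.usable(d$beta_iv, d$se_iv) & is.finite(d$mean_exposure)) >= 3)
    nonlinearity_metareg(d)
  else list(slope = NA_real_, se = NA_real_, pval = NA_real_)
  list(q = q$q, df = q$df, q_pval = q$pval,
       slope = mr$slope, slope_se = mr$se, slope_pval = mr$pval)
}
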