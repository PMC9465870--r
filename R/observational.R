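# Observational categorical / midpoint models ----------------------------
#
# The multivariable-regression arm: confounder-adjusted models of outcome on
# sleep-duration category - indicator coding against the 8-9 h/day reference
# versus midpoint-linear coding (3.5, 6.5, 8.5, 11 h/day) - compared by a
# likelihood-ratio test for nonlinearity, with Rubin's-rules pooling of
# per-imputation results.

.mvreg_frame <- function(outcome, category, confounders, reference) {
  category <- factor(as.character(category),
                     levels = levels(categorize_exposure(integer())))
  category <- droplevels(category)
  df <- data.frame(.y = outcome, .cat = category)
  if (!is.null(confounders)) df <- cbind(df, as.data.frame(confounders))
  rows <- which(complete.cases(df))
  df <- df[rows, , drop = FALSE]
  df$.cat <- droplevels(df$.cat)
  .assert(nlevels(df$.cat) >= 2L, "need at least 2 exposure categories")
  .assert(reference %in% levels(df$.cat), "empty reference category")
  df$.cat <- relevel(df$.cat, ref = reference)
  list(df = df, rows = rows)
}

.mvreg_family <- function(family) {
  .assert(family %in% c("logistic", "linear"),
          "'family' must be \"logistic\" or \"linear\"")
  family
}

.fit_glm <- function(formula, df, family) {
  if (family == "logistic") {
    .assert(all(df$.y %in% c(0, 1)), "binary outcome required for logistic")
    glm(formula, data = df, family = binomial())
  } else {
    glm(formula, data = df, family = gaussian())
  }
}

#' Categorical (indicator-coded) exposure model
#'
#' Logistic (binary outcomes) or linear (birthweight) regression of the
#' outcome on sleep-duration category indicators, comparing each of <=5,
#' 6-7 and >=10 h/day with the 8-9 h/day reference, adjusted for the
#' supplied confounders. The reference category carries effect 0 by
#' construction. Coefficients with |beta| > 15 on the log-odds scale are
#' flagged as separated (`separated = TRUE`) rather than trusted.
#'
#' @param outcome Outcome vector (0/1 for logistic, grams for linear).
#' @param category Exposure categories from [categorize_exposure()].
#' @param confounders Optional confounder data.frame.
#' @param family `"logistic"` or `"linear"`.
#' @param reference Reference category (default `"8-9"`).
#' @return List of class `mvreg_fit` with `estimates` (per non-reference
#'   category: `beta`, `se`, `ci_low`, `ci_high`, `pval`, `separated`),
#'   `log_lik`, `n`, `rows`, `family`, `model = "categorical"`.
#' @export
fit_categorical_model <- function(outcome, category, confounders = NULL,
                                  family = c("logistic", "linear"),
                                  reference = "8-9") {
  family <- .mvreg_family(match.arg(family))
  fr <- .mvreg_frame(outcome, category, confounders, reference)
  fit <- .fit_glm(.y ~ ., fr$df, family)
  cf <- summary(fit)$coefficients
  idx <- grep("^\\.cat", rownames(cf))
  .assert(length(idx) >= 1L, "no category contrasts estimable")
  if (family == "logistic") {
    .assert(sum(fr$df$.y) > 0, "outcome has zero cases")
  }
  beta <- cf[idx, 1]; se <- cf[idx, 2]
  z <- qnorm(0.975)
  est <- data.frame(category = sub("^\\.cat", "", rownames(cf)[idx]),
                    beta = beta, se = se,
                    ci_low = beta - z * se, ci_high = beta + z * se,
                    pval = 2 * pnorm(-abs(beta / se)),
                    separated = family == "logistic" & abs(beta) > 15,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(estimates = est, log_lik = as.numeric(logLik(fit)),
                 n = nrow(fr$df), rows = fr$rows, family = family,
                 reference = reference, model = "categorical",
                 n_categories = nlevels(fr$df$.cat)),
            class = "mvreg_fit")
}

#' Midpoint-coded (linear) exposure model
#'
#' The same regression with the categories recoded to their midpoints (3.5,
#' 6.5, 8.5, 11 h/day) entering as a single linear term, giving a per-hour
#' estimate. This model is nested in the categorical model, enabling the
#' likelihood-ratio nonlinearity test.
#'
#' @inheritParams fit_categorical_model
#' @return List of class `mvreg_fit` with `estimate` (per-hour `beta`, `se`,
#'   `ci_low`, `ci_high`, `pval`), `log_lik`, `n`, `rows`, `family`,
#'   `model = "midpoint"`.
#' @export
fit_midpoint_model <- function(outcome, category, confounders = NULL,
                               family = c("logistic", "linear"),
                               reference = "8-9") {
  family <- .mvreg_family(match.arg(family))
  fr <- .mvreg_frame(outcome, category, confounders, reference)
  df <- fr$df
  df$.hours <- midpoint_code(df$.cat)
  df$.cat <- NULL
  fit <- .fit_glm(.y ~ ., df, family)
  cf <- summary(fit)$coefficients
  beta <- cf[".hours", 1]; se <- cf[".hours", 2]
  z <- qnorm(0.975)
  structure(list(estimate = data.frame(beta = beta, se = se,
                                       ci_low = beta - z * se,
                                       ci_high = beta + z * se,
                                       pval = 2 * pnorm(-abs(beta / se)),
                                       row.names = NULL),
                 log_lik = as.numeric(logLik(fit)),
                 n = nrow(df), rows = fr$rows, family = family,
                 reference = reference, model = "midpoint",
                 n_categories = length(unique(df$.hours))),
            class = "mvreg_fit")
}

#' Likelihood-ratio test of nonlinearity across categories
#'
#' Compares the categorical model against the nested midpoint-linear model:
#' statistic `2 (LL_categorical - LL_midpoint)` (non-negative by nesting) on
#' `(categories - 1) - 1` df, i.e. 2 df with all four categories present.
#'
#' @param categorical_fit,midpoint_fit `mvreg_fit` objects fitted to the
#'   same rows, confounders and family.
#' @return List with `statistic`, `df`, `pval`.
#' @export
lrt_nonlinearity <- function(categorical_fit, midpoint_fit) {
  .assert(inherits(categorical_fit, "mvreg_fit") &&
            inherits(midpoint_fit, "mvreg_fit"), "need two mvreg_fit objects")
  .assert(categorical_fit$model == "categorical" &&
            midpoint_fit$model == "midpoint",
          "supply the categorical fit first, the midpoint fit second")
  .assert(identical(categorical_fit$family, midpoint_fit$family),
          "fits use different families")
  .assert(identical(categorical_fit$rows, midpoint_fit$rows),
          "fits use different rows; models are not nested")
  stat <- max(0, 2 * (categorical_fit$log_lik - midpoint_fit$log_lik))
  df <- (categorical_fit$n_categories - 1L) - 1L
  .assert(df >= 1L, "too few categories for a nonlinearity test")
  list(statistic = stat, df = df, pval = pchisq(stat, df, lower.tail = FALSE))
}

#' Pool per-imputation results by Rubin's rules
#'
#' Pools an estimate fitted on each of m imputed datasets: pooled estimate =
#' mean; total variance `T = W + (1 + 1/m) B` with `W` the mean
#' within-imputation variance and `B` the between-imputation variance of the
#' estimates; small-sample df `(m - 1) (1 + W / ((1 + 1/m) B))^2` with
#' t-based inference (normal when B = 0). The imputation engine itself is
#' external; this consumes any per-imputation fitted results.
#'
#' @param estimates Per-imputation point estimates (length m >= 2).
#' @param variances Per-imputation squared standard errors, all > 0.
#' @return List of class `pooled_result`: `estimate`, `w`, `b`, `t`, `se`,
#'   `df`, `pval`, `ci_low`, `ci_high`, `m`.
#' @export
#' @examples
#' rubins_rules(c(1, 3), c(1, 1))  # pooled 2, T = 4
rubins_rules <- function(estimates, variances) {
  m <- length(estimates)
  .assert(m >= 2L,
          "need at least 2 imputations (between-imputation variance undefined)")
  .assert(length(variances) == m && all(variances > 0),
          "variances must be positive, one per imputation")
  pooled <- mean(estimates)
  w <- mean(variances)
  b <- var(estimates)
  tt <- w + (1 + 1 / m) * b
  se <- sqrt(tt)
  if (b > 0) {
    df <- (m - 1) * (1 + w / ((1 + 1 / m) * b))^2
    pval <- 2 * pt(-abs(pooled / se), df)
    tcrit <- qt(0.975, df)
  } else {
    df <- Inf
    pval <- 2 * pnorm(-abs(pooled / se))
    tcrit <- qnorm(0.975)
  }
  structure(list(estimate = pooled, w = w, b = b, t = tt, se = se, df = df,
                 pval = pval, ci_low = pooled - tcrit * se,
                 ci_high = pooled + tcrit * se, m = m),
            class = "pooled_result")
}

#' Read per-imputation results and pool them
#'
#' Reads a tab-delimited file with header `imputation estimate variance`
#' (one row per imputed dataset, as produced by any external imputation
#' engine) and pools it with [rubins_rules()].
#'
#' @param path File path.
#' @return A `pooled_result`.
#' @export
pool_imputation_file <- function(path) {
  df <- read.delim(path)
  .assert(all(c("imputation", "estimate", "variance") %in% names(df)),
          "file must have columns: imputation estimate variance")
  rubins_rules(df$estimate, df$variance)
}

#' Complete-records filter
#'
#' Drops rows with any missing value among the named variables and reports
#' per-variable missingness, mirroring complete-records sensitivity
#' analyses.
#'
#' @param data A `data.frame`.
#' @param variables Column names that must be observed.
#' @return List with `data` (filtered), `n_in`, `n_out`, `missing_per_variable`.
#' @export
complete_records <- function(data, variables) {
  .assert(all(variables %in% names(data)),
          paste("unknown variable(s):",
                paste(setdiff(variables, names(data)), collapse = ", ")))
  sub <- data[, variables, drop = FALSE]
  keep <- complete.cases(sub)
  list(data = data[keep, , drop = FALSE], n_in = nrow(data),
       n_out = sum(keep),
       missing_per_variable = vapply(sub, function(v) sum(is.na(v)),
                                     integer(1)))
}
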