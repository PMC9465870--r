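# Linear two-sample MR estimators ----------------------------------------
#
# Causal-effect estimators on harmonized per-SNP summary statistics:
# Wald ratio, inverse-variance weighted (zero-intercept weighted
# regression), MR-Egger, weighted median, leave-one-out, and fixed-effects
# meta-analysis across cohorts. Inference is normal-theory throughout, as
# appropriate for summary statistics from large samples.

.mr_row <- function(method, beta, se, k, q = NA_real_, q_df = NA_real_,
                    egger_intercept = NA_real_, intercept_se = NA_real_) {
  ci <- .norm_ci(beta, se)
  data.frame(method = method, beta = beta, se = se,
             ci_low = ci[1], ci_high = ci[2], pval = .norm_p(beta, se),
             k = k, q = q,
             q_pval = if (is.na(q)) NA_real_ else pchisq(q, q_df,
                                                         lower.tail = FALSE),
             egger_intercept = egger_intercept,
             intercept_se = intercept_se,
             intercept_pval = if (is.na(egger_intercept)) NA_real_
                              else .norm_p(egger_intercept, intercept_se),
             stringsAsFactors = FALSE, row.names = NULL)
}

.h_data <- function(h) {
  if (inherits(h, "harmonized_set")) h$data else as.data.frame(h)
}

#' Wald ratio estimate
#'
#' Causal estimate `beta_zy / beta_zx` for a single instrument. The default
#' standard error is the first-order delta approximation
#' `se_zy / |beta_zx|`; `second_order = TRUE` adds the term propagating
#' uncertainty in the instrument-exposure association,
#' `sqrt(se_zy^2/beta_zx^2 + beta_zy^2 se_zx^2 / beta_zx^4)`.
#'
#' @param beta_zx,se_zx Instrument-exposure association and SE.
#' @param beta_zy,se_zy Instrument-outcome association and SE.
#' @param second_order Use the second-order delta SE (default FALSE).
#' @return One-row `data.frame` with the estimate, SE, 95% CI and p-value.
#' @export
#' @examples
#' wald_ratio(0.1, 0.01, 0.05, 0.02)
wald_ratio <- function(beta_zx, se_zx, beta_zy, se_zy,
                       second_order = FALSE) {
  .assert(is.finite(beta_zx) && beta_zx != 0,
          "Wald ratio undefined: beta_zx is zero")
  beta <- beta_zy / beta_zx
  se <- if (second_order) {
    sqrt(se_zy^2 / beta_zx^2 + beta_zy^2 * se_zx^2 / beta_zx^4)
  } else {
    se_zy / abs(beta_zx)
  }
  .mr_row("wald_ratio", beta, se, k = 1L)
}

#' Inverse-variance weighted MR estimate
#'
#' Slope of the zero-intercept weighted regression of SNP-outcome on
#' SNP-exposure associations with weights `1/se_zy^2`; algebraically the
#' inverse-variance weighted mean of the per-SNP Wald ratios with weights
#' `beta_zx^2 / se_zy^2`. Between-SNP heterogeneity is summarised by
#' Cochran's Q on k-1 df. Under the multiplicative random-effects model
#' (default) the SE is inflated by `sqrt(max(1, Q/(k-1)))`, which is robust
#' to the between-SNP heterogeneity seen for several perinatal outcomes;
#' `effects_model = "fixed"` gives the unscaled SE.
#'
#' @param h A `harmonized_set` (or its `data` data.frame).
#' @param effects_model `"random"` (multiplicative, default) or `"fixed"`.
#' @return One-row `data.frame` (method `"ivw"`) with heterogeneity columns.
#' @export
mr_ivw <- function(h, effects_model = c("random", "fixed")) {
  effects_model <- match.arg(effects_model)
  d <- .h_data(h)
  k <- nrow(d)
  .assert(k >= 1L, "IVW needs at least one SNP")
  .assert(all(d$se_out > 0), "all outcome SEs must be positive")
  w <- d$beta_exp^2 / d$se_out^2
  ratio <- d$beta_out / d$beta_exp
  beta <- sum(w * ratio) / sum(w)
  se <- 1 / sqrt(sum(w))
  q <- q_df <- NA_real_
  if (k >= 2L) {
    q <- sum(w * (ratio - beta)^2)
    q_df <- k - 1L
    if (effects_model == "random") se <- se * sqrt(max(1, q / (k - 1)))
  }
  out <- .mr_row(if (effects_model == "random") "ivw_mre" else "ivw_fe",
                 beta, se, k, q, q_df)
  out$method <- "ivw"
  out
}

#' MR-Egger regression
#'
#' Weighted regression of SNP-outcome on SNP-exposure associations with a
#' free intercept (weights `1/se_zy^2`). Instrument-exposure associations
#' are first oriented non-negative, flipping the outcome association
#' accordingly, which the intercept's interpretation as average directional
#' pleiotropy requires and which makes the result invariant to the reported
#' allele orientation. The SE is inflated by `sqrt(max(1, Q_egger/(k-2)))`.
#'
#' @inheritParams mr_ivw
#' @return One-row `data.frame` (method `"mr_egger"`) carrying the slope as
#'   the causal estimate plus `egger_intercept`, `intercept_se`,
#'   `intercept_pval`.
#' @export
mr_egger <- function(h) {
  d <- .h_data(h)
  k <- nrow(d)
  .assert(k >= 3L, "MR-Egger needs at least 3 SNPs")
  s <- ifelse(d$beta_exp < 0, -1, 1)
  bx <- abs(d$beta_exp)
  by <- s * d$beta_out
  .assert(length(unique(bx)) > 1L,
          "MR-Egger collinear: no variation in instrument-exposure associations")
  w <- 1 / d$se_out^2
  X <- cbind(1, bx)
  fit <- .wls_fixed(X, by, w)
  q <- sum(w * fit$resid^2)
  scale <- sqrt(max(1, q / (k - 2)))
  se_slope <- sqrt(fit$vcov[2, 2]) * scale
  se_int <- sqrt(fit$vcov[1, 1]) * scale
  .mr_row("mr_egger", fit$beta[2], se_slope, k, q, k - 2L,
          egger_intercept = fit$beta[1], intercept_se = se_int)
}

# Weighted median of ratio estimates at standardized midpoint cumulative
# weights s_j = (cum_j - w_j/2) / sum(w).
.weighted_median_point <- function(ratio, w) {
  ord <- order(ratio)
  r <- ratio[ord]
  ws <- w[ord]
  s <- (cumsum(ws) - ws / 2) / sum(ws)
  if (0.5 <= s[1]) return(r[1])
  if (0.5 >= s[length(s)]) return(r[length(r)])
  approx(s, r, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median MR estimate
#'
#' Orders the per-SNP Wald ratios and interpolates at cumulative
#' inverse-variance weight 0.5 (weights `beta_zx^2/se_zy^2`, midpoint
#' cumulative convention), giving an estimate that is consistent as long as
#' valid instruments carry at least half the weight. The SE is the standard
#' deviation of the estimate over parametric resamples of the summary
#' statistics from their normal sampling distributions.
#'
#' @inheritParams mr_ivw
#' @param n_boot Number of parametric bootstrap resamples (default 1000).
#' @param seed RNG seed for the bootstrap (mandatory for reproducibility).
#' @return One-row `data.frame` (method `"weighted_median"`).
#' @export
mr_weighted_median <- function(h, n_boot = 1000L, seed) {
  d <- .h_data(h)
  k <- nrow(d)
  .assert(k >= 3L, "weighted median needs at least 3 SNPs")
  .assert(!missing(seed), "'seed' is mandatory for the bootstrap SE")
  est <- .weighted_median_point(d$beta_out / d$beta_exp,
                                d$beta_exp^2 / d$se_out^2)
  .seed(seed)
  boots <- vapply(seq_len(n_boot), function(i) {
    bx <- rnorm(k, d$beta_exp, d$se_exp)
    by <- rnorm(k, d$beta_out, d$se_out)
    .weighted_median_point(by / bx, bx^2 / d$se_out^2)
  }, numeric(1))
  .mr_row("weighted_median", est, sd(boots), k)
}

#' Leave-one-out IVW analysis
#'
#' Re-estimates IVW k times, omitting one SNP each time, to expose single
#' variants driving the pooled estimate.
#'
#' @inheritParams mr_ivw
#' @return `data.frame` with one IVW row per omitted SNP, labeled by
#'   `omitted` snp_id.
#' @export
mr_leave_one_out <- function(h, effects_model = c("random", "fixed")) {
  effects_model <- match.arg(effects_model)
  d <- .h_data(h)
  .assert(nrow(d) >= 2L, "leave-one-out needs at least 2 SNPs")
  rows <- lapply(seq_len(nrow(d)), function(j) {
    r <- mr_ivw(d[-j, , drop = FALSE], effects_model)
    r$omitted <- d$snp_id[j]
    r
  })
  do.call(rbind, rows)
}

#' Fixed-effects inverse-variance meta-analysis
#'
#' Pools estimates across studies (or across the two crossed halves of a
#' split cross-over design) with inverse-variance weights, and reports
#' between-study heterogeneity as Cochran's Q on S-1 df.
#'
#' @param beta Estimates, or a data.frame holding `beta` and `se` columns.
#' @param se Standard errors (ignored when `beta` is a data.frame).
#' @return List with `beta`, `se`, `ci_low`, `ci_high`, `pval`, `weights`
#'   (normalized to sum 1), `q_between`, `q_df`, `q_between_pval`, `s`.
#' @export
meta_fixed <- function(beta, se = NULL) {
  if (is.data.frame(beta)) {
    se <- beta$se
    beta <- beta$beta
  }
  .assert(length(beta) >= 1L, "meta-analysis needs at least one estimate")
  .assert(length(se) == length(beta) && all(se > 0),
          "all SEs must be positive")
  w <- 1 / se^2
  pooled <- sum(w * beta) / sum(w)
  pse <- 1 / sqrt(sum(w))
  s <- length(beta)
  q <- if (s >= 2L) sum((beta - pooled)^2 / se^2) else NA_real_
  ci <- .norm_ci(pooled, pse)
  list(beta = pooled, se = pse, ci_low = ci[1], ci_high = ci[2],
       pval = .norm_p(pooled, pse), weights = w / sum(w),
       q_between = q, q_df = if (s >= 2L) s - 1L else NA_integer_,
       q_between_pval = if (s >= 2L) pchisq(q, s - 1L, lower.tail = FALSE)
                        else NA_real_,
       s = s)
}

#' Restrict a harmonized set to a named instrument subset
#'
#' Sensitivity analyses re-run IVW on nested instrument subsets (e.g. the
#' replicated SNPs of a discovery panel); membership lists are supplied by
#' configuration.
#'
#' @param h A `harmonized_set`.
#' @param subsets Named list of snp_id character vectors.
#' @param subset Name of the subset to apply.
#' @return A `harmonized_set` restricted to the subset, exclusions logged.
#' @export
snp_subset <- function(h, subset, subsets) {
  .assert(inherits(h, "harmonized_set"), "'h' must be a harmonized_set")
  .assert(subset %in% names(subsets),
          sprintf("unknown subset label '%s'", subset))
  ids <- subsets[[subset]]
  keep <- h$data$snp_id %in% ids
  .assert(any(keep), "subset membership is disjoint from the instrument set")
  dropped <- h$data$snp_id[!keep]
  excl <- h$exclusions
  if (length(dropped)) {
    excl <- rbind(excl, data.frame(snp_id = dropped,
                                   reason = paste0("not_in_subset:", subset),
                                   stringsAsFactors = FALSE))
  }
  structure(list(data = h$data[keep, , drop = FALSE], exclusions = excl),
            class = "harmonized_set")
}

#' Crossed MR over a split cohort
#'
#' Runs IVW with exposure associations from half A against outcome
#' associations from half B and vice versa, then combines the two crossed
#' estimates by fixed-effects inverse-variance meta-analysis.
#'
#' @param split A `split_crossover` object.
#' @param outcome Outcome name present in the split.
#' @inheritParams mr_ivw
#' @param palindrome_policy Passed to [harmonize()].
#' @return List with `ab`, `ba` (IVW rows) and `pooled` ([meta_fixed()]
#'   result).
#' @export
mr_crossed <- function(split, outcome,
                       effects_model = c("random", "fixed"),
                       palindrome_policy = "drop_ambiguous") {
  effects_model <- match.arg(effects_model)
  .assert(inherits(split, "split_crossover"), "'split' must be a split_crossover")
  .assert(outcome %in% names(split$a$outcomes),
          sprintf("outcome '%s' not present in split", outcome))
  h_ab <- harmonize(split$a$exposure, split$b$outcomes[[outcome]],
                    palindrome_policy)
  h_ba <- harmonize(split$b$exposure, split$a$outcomes[[outcome]],
                    palindrome_policy)
  ab <- mr_ivw(h_ab, effects_model)
  ba <- mr_ivw(h_ba, effects_model)
  list(ab = ab, ba = ba,
       pooled = meta_fixed(c(ab$beta, ba$beta), c(ab$se, ba$se)))
}
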