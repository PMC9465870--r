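# Pattern classification of nonlinear effects ----------------------------
#
# Per-stratum estimates, read together with the overall linear two-sample
# estimate, fall into recognisable dose-response patterns: e.g. a lowest
# stratum whose CI sits entirely below the null with a highest stratum
# entirely above it - while the overall linear estimate is null - marks a
# U shape, both short and long duration raising risk. The rule table is
# shipped as editable configuration rather than code.

#' Default pattern rule table
#'
#' Reads the ordered rule table from the package's `pattern_rules.json`
#' config. Each rule has a `label` and a `when` block of flag requirements;
#' the first rule whose requirements all hold wins. Available flags:
#' `lowest_sig_neg`, `lowest_sig_pos`, `highest_sig_neg`, `highest_sig_pos`
#' (does the lowest/highest stratum CI exclude the null, and on which side),
#' `any_stratum_sig`, `linear_sig`, `linear_sig_pos`, `linear_sig_neg`
#' (same for the overall linear estimate).
#'
#' @param path Optional path to an alternative JSON rule table.
#' @return List of rules.
#' @export
default_pattern_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "pattern_rules.json", package = "sleepmr")
  }
  jsonlite::read_json(path, simplifyVector = FALSE)
}

.pattern_flags <- function(estimates, linear, null_value = 0) {
  ok <- .usable(estimates$beta_iv, estimates$se_iv)
  if (sum(ok) < 2L) return(NULL)
  e <- estimates[ok, ]
  lo <- e[1, ]
  hi <- e[nrow(e), ]
  sig_neg <- function(r) is.finite(r$ci_high) && r$ci_high < null_value
  sig_pos <- function(r) is.finite(r$ci_low) && r$ci_low > null_value
  lin_pos <- !is.null(linear) && sig_pos(linear)
  lin_neg <- !is.null(linear) && sig_neg(linear)
  list(lowest_sig_neg = sig_neg(lo), lowest_sig_pos = sig_pos(lo),
       highest_sig_neg = sig_neg(hi), highest_sig_pos = sig_pos(hi),
       any_stratum_sig = any(e$ci_high < null_value | e$ci_low > null_value),
       linear_sig = lin_pos || lin_neg,
       linear_sig_pos = lin_pos, linear_sig_neg = lin_neg)
}

#' Classify the dose-response pattern of stratum estimates
#'
#' Applies the rule table to the ordered per-stratum estimates (log-odds per
#' 1 h/day, with 95% CIs) and the overall linear MR estimate. Missing or
#' unusable stratum estimates lead to `"inconclusive"`, never an error.
#'
#' @param estimates `stratum_estimates` ordered by stratum.
#' @param linear One-row MR estimate data.frame (e.g. from [mr_ivw()]) with
#'   `ci_low`/`ci_high`, or `NULL`.
#' @param rules Rule table (default [default_pattern_rules()]).
#' @param null_value Null effect on the estimation scale (0 for log-odds and
#'   mean differences).
#' @return Pattern label string.
#' @export
classify_pattern <- function(estimates, linear = NULL,
                             rules = default_pattern_rules(),
                             null_value = 0) {
  flags <- .pattern_flags(estimates, linear, null_value)
  if (is.null(flags)) return("inconclusive")
  for (rule in rules) {
    req <- rule$when
    hit <- all(vapply(names(req), function(f) {
      identical(flags[[f]], req[[f]])
    }, logical(1)))
    if (hit) return(rule$label)
  }
  "inconclusive"
}
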