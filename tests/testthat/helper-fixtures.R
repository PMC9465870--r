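# Shared fixture builders: everything is generated in code at test time.

make_panel <- function(k = 10, seed = 42, beta = 0.02) {
  set.seed(seed)
  snp_panel(sprintf("rs%03d", seq_len(k)),
            eaf = runif(k, 0.2, 0.8),
            beta_exposure = beta * sample(c(-1, 1), k, replace = TRUE))
}

# Small cohort with a linear log-odds effect, used for plumbing tests.
make_cohort <- function(n = 2000, k = 10, seed = 7, slope = 0.1,
                        prevalence = 0.2, target_r2 = 0.02) {
  simulate_cohort(
    n = n, panel = make_panel(k),
    shapes = list(outcome = effect_shape("linear", slope = slope),
                  birthweight = effect_shape("linear", slope = 80)),
    baseline_prevalence = c(outcome = prevalence),
    target_r2 = target_r2, seed = seed)
}

# Random harmonized instrument set (already aligned), for estimator tests.
make_harmonized <- function(k = 10, seed = 1, causal = 0.2,
                            pleiotropy = 0) {
  set.seed(seed)
  bx <- runif(k, 0.02, 0.1)
  se_x <- runif(k, 0.002, 0.01)
  se_y <- runif(k, 0.01, 0.05)
  by <- causal * bx + pleiotropy + rnorm(k, sd = se_y)
  data.frame(snp_id = sprintf("rs%03d", seq_len(k)),
             effect_allele = "A", other_allele = "G",
             beta_exp = bx, se_exp = se_x, eaf_exp = 0.3,
             beta_out = by, se_out = se_y, eaf_out = 0.3)
}

# Stratum-estimate table built directly, for test constructions.
make_strata <- function(beta, se, mean_exposure = seq_along(beta) + 5,
                        grs_beta = rep(0.02, length(beta)),
                        grs_se = rep(0.002, length(beta))) {
  z <- qnorm(0.975)
  out <- data.frame(stratum = seq_along(beta), n = 1000, n_cases = 100,
                    mean_exposure = mean_exposure, grs_beta = grs_beta,
                    grs_se = grs_se, beta_iv = beta, se_iv = se,
                    ci_low = beta - z * se, ci_high = beta + z * se,
                    pval = 2 * pnorm(-abs(beta / se)))
  class(out) <- c("stratum_estimates", "data.frame")
  out
}
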