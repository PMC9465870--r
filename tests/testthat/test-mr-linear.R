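# Linear MR estimators against closed-form, brute-force and independent
# package oracles.

test_that("Wald ratio arithmetic and delta-method SEs", {
  w <- wald_ratio(0.1, 0.01, 0.05, 0.02)
  expect_equal(w$beta, 0.5)
  expect_equal(w$se, 0.2)
  expect_equal(wald_ratio(0.1, 0.01, 0, 0.02)$beta, 0)
  expect_error(wald_ratio(0, 0.01, 0.05, 0.02), "zero")

  # second-order delta SE tracks the Monte-Carlo SD of the ratio at SNR >= 10
  bx <- 0.5; sx <- 0.05; by <- 0.3; sy <- 0.03
  w2 <- wald_ratio(bx, sx, by, sy, second_order = TRUE)
  set.seed(1)
  draws <- rnorm(1e6, by, sy) / rnorm(1e6, bx, sx)
  expect_lt(abs(w2$se / sd(draws) - 1), 0.05)
})

test_that("IVW equals the weighted mean of ratios and the zero-intercept fit", {
  # hand-arithmetic instance: ratios (2, 4), weights (1, 1) -> 3, Q = 2
  d <- data.frame(beta_exp = c(1, 1), se_exp = 0.1, beta_out = c(2, 4),
                  se_out = c(1, 1))
  fe <- mr_ivw(d, "fixed")
  expect_equal(fe$beta, 3.0)
  expect_equal(fe$q, 2.0)

  # k = 1 degenerates to the Wald ratio
  one <- mr_ivw(d[1, ], "fixed")
  wr <- wald_ratio(1, 0.1, 2, 1)
  expect_equal(one$beta, wr$beta)
  expect_equal(one$se, wr$se)

  # exact proportionality: slope recovered, Q = 0
  dp <- data.frame(beta_exp = c(0.02, 0.05, 0.08), se_exp = 0.01,
                   beta_out = 1.7 * c(0.02, 0.05, 0.08), se_out = 0.01)
  expect_equal(mr_ivw(dp, "fixed")$beta, 1.7, tolerance = 1e-12)
  expect_equal(mr_ivw(dp, "fixed")$q, 0, tolerance = 1e-12)

  for (s in 1:20) {
    h <- make_harmonized(k = 10, seed = s)
    est <- mr_ivw(h, "fixed")
    # weighted-mean-of-ratios form
    wgt <- h$beta_exp^2 / h$se_out^2
    expect_equal(est$beta, sum(wgt * h$beta_out / h$beta_exp) / sum(wgt),
                 tolerance = 1e-10)
    # zero-intercept weighted regression form
    fit <- lm(beta_out ~ 0 + beta_exp, data = h, weights = 1 / se_out^2)
    expect_equal(est$beta, unname(coef(fit)), tolerance = 1e-10)
  }

  # multiplicative random effects only ever widens the SE
  h <- make_harmonized(k = 20, seed = 3)
  expect_gte(mr_ivw(h, "random")$se, mr_ivw(h, "fixed")$se)
  expect_error(mr_ivw(transform(h, se_out = 0)), "positive")
})

test_that("IVW agrees with fixed-effect meta-analysis of Wald ratios (metafor)", {
  skip_if_not_installed("metafor")
  h <- make_harmonized(k = 15, seed = 9)
  est <- mr_ivw(h, "fixed")
  rma <- metafor::rma(yi = h$beta_out / h$beta_exp,
                      sei = h$se_out / abs(h$beta_exp), method = "FE")
  expect_equal(est$beta, as.numeric(rma$beta), tolerance = 1e-8)
  expect_equal(est$se, rma$se, tolerance = 1e-8)
  expect_equal(est$q, rma$QE, tolerance = 1e-8)
})

test_that("MR-Egger recovers exact lines and is orientation-invariant", {
  bx <- c(0.02, 0.04, 0.06, 0.09)
  d <- data.frame(beta_exp = bx, se_exp = 0.005,
                  beta_out = 0.03 + 1.5 * bx, se_out = 0.02)
  eg <- mr_egger(d)
  expect_equal(eg$beta, 1.5, tolerance = 1e-10)
  expect_equal(eg$egger_intercept, 0.03, tolerance = 1e-10)
  expect_equal(eg$q, 0, tolerance = 1e-10)

  # with no pleiotropy and equal weights the slope equals fixed-effect IVW
  d0 <- make_harmonized(k = 10, seed = 4)
  d0$se_out <- 0.02
  # force an exact zero intercept by generating on the line
  d0$beta_out <- 0.8 * d0$beta_exp
  expect_equal(mr_egger(d0)$beta, mr_ivw(d0, "fixed")$beta, tolerance = 1e-10)

  # flipping reported orientations of some SNPs changes nothing
  h <- make_harmonized(k = 12, seed = 11, pleiotropy = 0.02)
  flip <- rep(c(1, -1), 6)
  h2 <- transform(h, beta_exp = beta_exp * flip, beta_out = beta_out * flip)
  expect_equal(mr_egger(h), mr_egger(h2))

  # directional pleiotropy shows up in the intercept
  set.seed(12)
  k <- 78
  hp <- data.frame(beta_exp = runif(k, 0.01, 0.05), se_exp = 0.002,
                   se_out = 0.01)
  hp$beta_out <- 0.1 * hp$beta_exp + 0.05 + rnorm(k, sd = hp$se_out)
  egp <- mr_egger(hp)
  expect_lt(abs(egp$egger_intercept - 0.05), 3 * egp$intercept_se)

  expect_error(mr_egger(d[1:2, ]), "3")
  expect_error(mr_egger(transform(d, beta_exp = 0.05)), "collinear")
})

test_that("weighted median matches symmetry, breakdown and grid oracles", {
  eq <- data.frame(beta_exp = 1, se_exp = 0.01, beta_out = c(1, 2, 3),
                   se_out = 1)
  expect_equal(mr_weighted_median(eq, n_boot = 10, seed = 1)$beta, 2)

  dom <- data.frame(beta_exp = c(100, 0.1, 0.1), se_exp = 0.01,
                    beta_out = c(500, 0.02, 0.03), se_out = c(1, 1, 1))
  expect_equal(mr_weighted_median(dom, n_boot = 10, seed = 1)$beta, 5,
               tolerance = 1e-4)

  # dense-grid percentile oracle using the midpoint cumulative convention
  grid_oracle <- function(ratio, w) {
    ord <- order(ratio)
    r <- ratio[ord]; ws <- w[ord]
    s <- (cumsum(ws) - ws / 2) / sum(ws)
    grid <- seq(min(r), max(r), length.out = 200001)
    sg <- approx(r, s, xout = grid, rule = 2, ties = "ordered")$y
    grid[which.min(abs(sg - 0.5))]
  }
  for (s in 1:10) {
    h <- make_harmonized(k = 10, seed = 100 + s)
    est <- mr_weighted_median(h, n_boot = 10, seed = 1)$beta
    expect_equal(est,
                 grid_oracle(h$beta_out / h$beta_exp,
                             h$beta_exp^2 / h$se_out^2),
                 tolerance = 1e-3)
  }

  h <- make_harmonized(k = 10, seed = 2)
  expect_identical(mr_weighted_median(h, n_boot = 200, seed = 7),
                   mr_weighted_median(h, n_boot = 200, seed = 7))
  expect_error(mr_weighted_median(h[1:2, ], n_boot = 10, seed = 1), "3")
})

test_that("leave-one-out exposes the omitted SNP", {
  same <- data.frame(beta_exp = c(0.02, 0.04, 0.05), se_exp = 0.01,
                     beta_out = 2 * c(0.02, 0.04, 0.05), se_out = 0.01)
  loo <- mr_leave_one_out(same, "fixed")
  expect_equal(loo$beta, rep(2, 3), tolerance = 1e-10)

  h <- make_harmonized(k = 10, seed = 6, causal = 1)
  h$beta_out[4] <- h$beta_out[4] + 0.5      # planted outlier
  full <- mr_ivw(h, "fixed")$beta
  loo2 <- mr_leave_one_out(h, "fixed")
  expect_equal(loo2$omitted[which.max(abs(loo2$beta - full))],
               h$snp_id[4])

  two <- h[1:2, ]
  loo3 <- mr_leave_one_out(two, "fixed")
  expect_equal(loo3$beta[1], two$beta_out[2] / two$beta_exp[2])
  expect_equal(loo3$beta[2], two$beta_out[1] / two$beta_exp[1])
  expect_error(mr_leave_one_out(h[1, ]), "2")
})

test_that("fixed-effects meta-analysis pools with inverse-variance weights", {
  single <- meta_fixed(0.4, 0.1)
  expect_equal(single$beta, 0.4)
  expect_equal(single$se, 0.1)

  m <- meta_fixed(c(0, 2), c(1, 1))
  expect_equal(m$beta, 1.0)
  expect_equal(m$se, 1 / sqrt(2))
  expect_equal(m$q_between, 2.0)
  expect_equal(sum(m$weights), 1)

  eq <- meta_fixed(c(0.1, 0.5, 0.3), c(0.2, 0.2, 0.2))
  expect_equal(eq$beta, 0.3)
  expect_error(meta_fixed(numeric(0), numeric(0)), "one estimate")
})

test_that("instrument subsets filter by configured membership", {
  h0 <- make_harmonized(k = 78, seed = 13)
  hs <- structure(list(data = h0,
                       exclusions = data.frame(snp_id = character(),
                                               reason = character())),
                  class = "harmonized_set")
  subsets <- list(full = h0$snp_id,
                  replicated = sample(h0$snp_id, 10),
                  other = c("zzz1", "zzz2"))
  expect_equal(nrow(snp_subset(hs, "full", subsets)$data), 78)
  sub <- snp_subset(hs, "replicated", subsets)
  expect_setequal(sub$data$snp_id, subsets$replicated)
  expect_equal(sum(grepl("not_in_subset", sub$exclusions$reason)), 68)
  expect_error(snp_subset(hs, "other", subsets), "disjoint")
  expect_error(snp_subset(hs, "nope", subsets), "unknown subset")
})

test_that("rescaling exposure units divides every causal estimate by the factor", {
  h <- make_harmonized(k = 12, seed = 14)
  c_fac <- 2.5
  h2 <- transform(h, beta_exp = beta_exp * c_fac, se_exp = se_exp * c_fac)
  expect_equal(mr_ivw(h2, "fixed")$beta, mr_ivw(h, "fixed")$beta / c_fac,
               tolerance = 1e-10)
  expect_equal(mr_egger(h2)$beta, mr_egger(h)$beta / c_fac,
               tolerance = 1e-10)
  expect_equal(mr_weighted_median(h2, n_boot = 10, seed = 2)$beta,
               mr_weighted_median(h, n_boot = 10, seed = 2)$beta / c_fac,
               tolerance = 1e-10)
})
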