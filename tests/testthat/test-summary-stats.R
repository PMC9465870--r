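# Summary statistics: QC, risk score, per-SNP models, split cross-over,
# harmonization and instrument strength.

test_that("exposure QC blanks implausible hours and keeps the boundaries", {
  qc <- exposure_qc(c(1, 2, 7, 12, 13))
  expect_equal(qc$hours, c(NA, 2, 7, 12, NA))
  expect_equal(qc$n_excluded, 2)

  ok <- exposure_qc(c(2, 5, 12, NA))
  expect_equal(ok$hours, c(2, 5, 12, NA))
  expect_equal(ok$n_excluded, 0)

  allout <- exposure_qc(c(1, 13, 23))
  expect_true(all(is.na(allout$hours)))

  expect_error(exposure_qc(c(7.5, 8)), "integer")
})

test_that("unweighted GRS counts duration-increasing alleles", {
  g <- matrix(0, 4, 3)
  expect_equal(build_grs(g, rep(TRUE, 3)), rep(0, 4))
  # a decreasing effect allele contributes 2 - dosage
  expect_equal(build_grs(matrix(2, 1, 1), FALSE), 0)

  set.seed(8)
  G <- matrix(sample(0:2, 50, replace = TRUE), 10, 5)
  inc <- sample(c(TRUE, FALSE), 5, replace = TRUE)
  brute <- numeric(10)
  for (i in 1:10) for (k in 1:5) {
    brute[i] <- brute[i] + if (inc[k]) G[i, k] else 2 - G[i, k]
  }
  expect_equal(build_grs(G, inc), brute)

  # relabeling alleles with consistently updated orientation changes nothing
  G_flipped <- G
  G_flipped[, 2] <- 2 - G[, 2]
  inc_flipped <- inc
  inc_flipped[2] <- !inc[2]
  expect_equal(build_grs(G_flipped, inc_flipped), brute)

  expect_error(build_grs(G, inc[1:3]), "orientation")
})

test_that("per-SNP associations match deterministic and calibrated oracles", {
  p <- make_panel(5)
  G <- simulate_genotypes(p, 500, seed = 61)
  exact <- estimate_snp_trait(G[, 1, drop = FALSE], 3 * G[, 1], family = "linear")
  expect_equal(exact$beta, 3, tolerance = 1e-10)
  expect_equal(exact$se, 0, tolerance = 1e-8)

  # permutation null: p-values are calibrated across 78 SNPs x 20 replicates
  p78 <- make_panel(78)
  G78 <- simulate_genotypes(p78, 2000, seed = 62)
  set.seed(63)
  hits <- vapply(1:20, function(i) {
    y <- rnorm(2000)
    mean(estimate_snp_trait(G78, y, family = "linear")$pval < 0.05)
  }, numeric(1))
  frac <- mean(hits)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / (78 * 20)))
})

test_that("logistic per-SNP effects are recovered and separation is flagged", {
  p1 <- snp_panel("rs1", 0.3, 0.02)
  G <- simulate_genotypes(p1, 100000, seed = 71)
  set.seed(72)
  y <- rbinom(100000, 1, plogis(-2 + 0.1 * G[, 1]))
  a <- estimate_snp_trait(G, y, family = "logistic")
  expect_lt(abs(a$beta - 0.1), 3 * a$se)

  ysep <- as.integer(G[1:500, 1] >= 1)
  flagged <- estimate_snp_trait(G[1:500, , drop = FALSE], ysep,
                                family = "logistic")
  expect_true(is.na(flagged$se))

  expect_error(
    estimate_snp_trait(G[1:100, , drop = FALSE], rep(0L, 100),
                       family = "logistic", trait_name = "stillbirth"),
    "stillbirth")
})

test_that("fetal adjustment separates maternal from transmitted effects", {
  p <- make_panel(10, seed = 81)
  G <- simulate_genotypes(p, 20000, seed = 82)
  Fg <- simulate_fetal_genotypes(G, p, seed = 83)
  set.seed(84)

  # outcome driven only by the fetal genotype: the maternal association is
  # half the fetal effect through transmission, and vanishes on adjustment
  y_fetal <- drop(Fg %*% rep(0.2, 10)) + rnorm(20000)
  res <- adjust_for_fetal(G, Fg, y_fetal, family = "linear", panel = p)
  mc_se <- sd(res$unadjusted$beta) / sqrt(10)
  expect_lt(abs(mean(res$unadjusted$beta) - 0.1), 3 * mc_se)
  expect_lt(abs(mean(res$adjusted$beta)), 3 * sd(res$adjusted$beta) / sqrt(10))

  # outcome driven only by the maternal genotype: adjustment changes little
  y_mat <- drop(G %*% rep(0.2, 10)) + rnorm(20000)
  res2 <- adjust_for_fetal(G, Fg, y_mat, family = "linear", panel = p)
  expect_lt(max(abs(res2$adjusted$beta - res2$unadjusted$beta)), 0.05)

  y_null <- rnorm(20000)
  res3 <- adjust_for_fetal(G, Fg, y_null, family = "linear", panel = p)
  expect_lt(abs(mean(res3$unadjusted$beta)), 0.01)
  expect_lt(abs(mean(res3$adjusted$beta)), 0.01)

  expect_error(adjust_for_fetal(G, NULL, y_null), "absent")
})

test_that("split cross-over partitions the cohort and scales SEs by sqrt(2)", {
  co <- make_cohort(n = 1000, k = 20, seed = 91)
  sp <- split_crossover(co, "outcome", seed = 92)
  expect_equal(lengths(sp$indices), c(a = 500L, b = 500L))
  expect_equal(sort(c(sp$indices$a, sp$indices$b)), 1:1000)
  expect_length(intersect(sp$indices$a, sp$indices$b), 0)

  sp2 <- split_crossover(co, "outcome", seed = 92)
  expect_identical(sp$indices, sp2$indices)

  co_odd <- make_cohort(n = 1001, k = 20, seed = 91)
  sp_odd <- split_crossover(co_odd, "outcome", seed = 93)
  expect_equal(lengths(sp_odd$indices), c(a = 500L, b = 501L))

  # half-sample SEs are ~ sqrt(2) times the full-sample SEs
  full <- estimate_snp_trait(co$genotypes, exposure_qc(co$exposure_reported)$hours,
                             family = "linear", panel = co$panel)
  ratio <- mean(c(sp$a$exposure$se, sp$b$exposure$se) / full$se)
  expect_lt(abs(ratio - sqrt(2)), 0.1)

  expect_error(split_crossover(make_cohort(n = 100), "outcome"), "200")
})

test_that("harmonization aligns alleles, drops ambiguous palindromes, logs exclusions", {
  e <- data.frame(snp_id = c("rs1", "rs2", "rs3", "rs4", "rs5"),
                  effect_allele = c("A", "C", "A", "A", "G"),
                  other_allele = c("G", "T", "T", "C", "A"),
                  eaf = c(0.3, 0.4, 0.50, 0.2, 0.6),
                  beta = c(0.1, 0.2, 0.1, 0.1, 0.05),
                  se = 0.02, pval = 0.5, n = 1000)
  o <- data.frame(snp_id = c("rs1", "rs2", "rs3", "rs4", "rs6"),
                  effect_allele = c("G", "C", "A", "A", "A"),
                  other_allele = c("A", "T", "T", "G", "G"),
                  eaf = c(0.7, 0.4, 0.5, 0.2, 0.1),
                  beta = c(0.3, 0.1, 0.2, 0.2, 0.4),
                  se = 0.05, pval = 0.5, n = 1000)
  h <- harmonize(e, o)
  # rs1: swapped orientation flips the outcome beta and complements eaf
  expect_equal(h$data$beta_out[h$data$snp_id == "rs1"], -0.3)
  expect_equal(h$data$eaf_out[h$data$snp_id == "rs1"], 0.3)
  # rs2: identical orientation unchanged
  expect_equal(h$data$beta_out[h$data$snp_id == "rs2"], 0.1)
  reasons <- setNames(h$exclusions$reason, h$exclusions$snp_id)
  expect_equal(unname(reasons["rs3"]), "palindromic_ambiguous")  # A/T, MAF 0.5
  expect_equal(unname(reasons["rs4"]), "allele_mismatch")        # A/C vs A/G
  expect_equal(unname(reasons["rs5"]), "missing_in_outcome")
  expect_equal(unname(reasons["rs6"]), "missing_in_exposure")

  keep_all <- harmonize(e, o, palindrome_policy = "keep")
  expect_true("rs3" %in% keep_all$data$snp_id)
  expect_error(harmonize(e[4, ], o[1, ]), "empty")

  log_path <- file.path(tempdir(), "exclusions.tsv")
  write_exclusions(h, log_path)
  back <- utils::read.delim(log_path)
  expect_setequal(back$snp_id, h$exclusions$snp_id)
  unlink(log_path)
})

test_that("harmonization is involutive for downstream estimates", {
  h0 <- make_harmonized(k = 12, seed = 5)
  e <- data.frame(snp_id = h0$snp_id, effect_allele = "A", other_allele = "G",
                  eaf = 0.3, beta = h0$beta_exp, se = h0$se_exp,
                  pval = 0.5, n = 1000)
  o <- data.frame(snp_id = h0$snp_id, effect_allele = "A", other_allele = "G",
                  eaf = 0.3, beta = h0$beta_out, se = h0$se_out,
                  pval = 0.5, n = 1000)
  o_flipped <- transform(o, effect_allele = "G", other_allele = "A",
                         beta = -beta, eaf = 1 - eaf)
  h1 <- harmonize(e, o)
  h2 <- harmonize(e, o_flipped)
  expect_equal(mr_ivw(h1), mr_ivw(h2))
  expect_equal(mr_egger(h1), mr_egger(h2))
  expect_equal(mr_weighted_median(h1, n_boot = 50, seed = 1),
               mr_weighted_median(h2, n_boot = 50, seed = 1))
})

test_that("the F-statistic equals t^2 and matches its R^2 identity", {
  set.seed(101)
  z <- rnorm(500)
  x <- 0.2 * z + rnorm(500)
  cv <- data.frame(a = rnorm(500))
  fs <- f_statistic(z, x, cv)
  fit <- lm(x ~ z + a, data = cbind(data.frame(z = z, x = x), cv))
  expect_equal(fs$f_statistic, summary(fit)$coefficients["z", 3]^2,
               tolerance = 1e-10)

  fs0 <- f_statistic(z, x)
  r2 <- fs0$r_squared
  expect_equal(fs0$f_statistic, r2 * (500 - 2) / (1 - r2), tolerance = 1e-10)

  # null instrument: E[F] ~ 1
  set.seed(102)
  fnull <- vapply(1:500, function(i) {
    f_statistic(rnorm(100), rnorm(100))$f_statistic
  }, numeric(1))
  expect_lt(abs(mean(fnull) - 1), 0.25)

  expect_error(f_statistic(rep(1, 10), rnorm(10)), "zero variance")
})

test_that("summary-statistic files round-trip with the documented header", {
  a <- estimate_snp_trait(simulate_genotypes(make_panel(4), 300, seed = 1),
                          rnorm(300), family = "linear", panel = make_panel(4))
  path <- file.path(tempdir(), "sumstats.tsv")
  write_sumstats(a, path)
  expect_identical(readLines(path, n = 1),
                   "snp_id\teffect_allele\tother_allele\teaf\tbeta\tse\tpval\tn")
  back <- read_sumstats(path)
  expect_equal(back$beta, a$beta)
  # readers tolerate extra columns
  df <- utils::read.delim(path)
  df$extra <- 1
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_equal(read_sumstats(path)$se, a$se)
  unlink(path)
})
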