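# Synthetic cohort generator --------------------------------------------
#
# Individual-level cohorts with the statistical structure the MR and
# observational analyses assume, and known ground truth for recovery tests.

#' Simulate Hardy-Weinberg genotype dosages for an instrument panel
#'
#' Each dosage is the sum of two independent Bernoulli(eaf) allele draws;
#' SNP columns are independent (the panel is assumed to be in linkage
#' equilibrium).
#'
#' @param panel A [snp_panel].
#' @param n Number of individuals.
#' @param seed Optional RNG seed for reproducibility.
#' @return Integer matrix (n x K) of dosages in {0, 1, 2} with SNP ids as
#'   column names.
#' @export
simulate_genotypes <- function(panel, n, seed = NULL) {
  .assert(inherits(panel, "snp_panel"), "'panel' must be a snp_panel")
  .assert(nrow(panel) >= 1L, "'panel' must be non-empty")
  .assert(.is_count(n), "'n' must be a positive integer")
  .assert(all(is.finite(panel$eaf)) && all(panel$eaf > 0) & all(panel$eaf < 1),
          "effect-allele frequencies must be strictly inside (0, 1)")
  .seed(seed)
  k <- nrow(panel)
  g <- matrix(rbinom(n * k, size = 2L, prob = rep(panel$eaf, each = n)),
              nrow = n, ncol = k, dimnames = list(NULL, panel$snp_id))
  g
}

#' Simulate fetal genotypes transmitted from maternal genotypes
#'
#' One allele is transmitted from the mother (Bernoulli with probability
#' maternal dosage / 2) and one is drawn from the population at the panel
#' frequency, giving the expected maternal-fetal dosage correlation of 0.5.
#'
#' @param maternal Maternal dosage matrix with entries in {0, 1, 2}.
#' @inheritParams simulate_genotypes
#' @return Integer matrix of fetal dosages, same dimensions as `maternal`.
#' @export
simulate_fetal_genotypes <- function(maternal, panel, seed = NULL) {
  .assert(inherits(panel, "snp_panel"), "'panel' must be a snp_panel")
  .assert(is.matrix(maternal) && ncol(maternal) == nrow(panel),
          "'maternal' must be a matrix with one column per panel SNP")
  .assert(all(maternal %in% c(0, 1, 2)), "maternal dosages must be 0, 1 or 2")
  .seed(seed)
  n <- nrow(maternal)
  transmitted <- matrix(rbinom(length(maternal), 1L, prob = maternal / 2),
                        nrow = n)
  paternal <- matrix(rbinom(length(maternal), 1L,
                            prob = rep(panel$eaf, each = n)), nrow = n)
  out <- transmitted + paternal
  dimnames(out) <- dimnames(maternal)
  out
}

#' Simulate continuous and integer-reported sleep exposure
#'
#' The latent exposure is `baseline + genetics + confounding + noise`. When
#' `target_r2` is given, the panel's per-allele effects are rescaled (keeping
#' their relative pattern) so the genetic component's realized variance
#' fraction matches the target; the default 0.0069 reproduces an instrument
#' panel explaining 0.69% of exposure variance. Reported hours are the latent
#' value rounded to the nearest integer and clipped to [1, 23]; implausible
#' values are deliberately retained here and removed only by [exposure_qc()].
#'
#' @param genotypes Dosage matrix from [simulate_genotypes()].
#' @param panel The matching [snp_panel].
#' @param confounder Numeric confounder vector (one value per row); default
#'   all zero.
#' @param confounder_effect Hours of exposure per confounder unit
#'   (default 0.3).
#' @param noise_sd Standard deviation of the Gaussian noise, hours
#'   (default 1.05; together with the default confounder effect this gives a
#'   total exposure SD near 1.1 h).
#' @param target_r2 Target genetic variance fraction in (0, 1), or `NULL` to
#'   use the panel betas as given. Default 0.0069.
#' @param baseline Population mean exposure in hours/day (default 7.2); the
#'   genetic component is mean-centred so this is the realized mean up to
#'   noise.
#' @param seed Optional RNG seed.
#' @return List with `exposure_true`, `exposure_reported` (integer, [1, 23]),
#'   `grs_variance_explained` (realized genetic variance fraction) and
#'   `beta_exposure` (the per-allele effects actually used).
#' @export
simulate_exposure <- function(genotypes, panel, confounder = NULL,
                              confounder_effect = 0.3, noise_sd = 1.05,
                              target_r2 = 0.0069, baseline = 7.2,
                              seed = NULL) {
  .assert(inherits(panel, "snp_panel"), "'panel' must be a snp_panel")
  .assert(is.matrix(genotypes) && ncol(genotypes) == nrow(panel),
          "'genotypes' must have one column per panel SNP")
  .assert(is.numeric(noise_sd) && noise_sd > 0, "'noise_sd' must be > 0")
  if (!is.null(target_r2)) {
    .assert(is.numeric(target_r2) && target_r2 > 0 && target_r2 < 1,
            "'target_r2' must be in (0, 1)")
  }
  n <- nrow(genotypes)
  if (is.null(confounder)) confounder <- numeric(n)
  .assert(length(confounder) == n, "'confounder' must have one value per row")
  .seed(seed)

  beta <- panel$beta_exposure
  g0 <- drop(genotypes %*% beta)
  env <- confounder_effect * confounder + rnorm(n, sd = noise_sd)
  if (!is.null(target_r2) && var(g0) > 0) {
    # rescale betas so var(genetic) / var(exposure) hits target_r2 exactly in
    # this realization
    s <- sqrt(target_r2 / (1 - target_r2) * var(env) / var(g0))
    beta <- beta * s
    g0 <- g0 * s
  }
  g0 <- g0 - mean(g0)   # centred so 'baseline' is the population mean
  x <- baseline + g0 + env
  reported <- pmin(pmax(round(x), 1L), 23L)
  r2 <- var(g0) / var(x)
  list(exposure_true = x, exposure_reported = as.integer(reported),
       grs_variance_explained = r2, beta_exposure = beta)
}

# Solve the logistic intercept giving a requested marginal prevalence by
# bisection (tolerance 1e-4 on the prevalence scale).
.solve_intercept <- function(eta, prevalence, tol = 1e-4) {
  f <- function(a) mean(plogis(a + eta)) - prevalence
  lo <- -40; hi <- 40
  .assert(f(lo) < 0 && f(hi) > 0, "prevalence not bracketed")
  while (hi - lo > 1e-10) {
    mid <- (lo + hi) / 2
    if (abs(f(mid)) < tol) return(mid)
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Simulate binary and continuous outcomes from exposure and confounder
#'
#' Binary outcomes are Bernoulli with
#' `logit(p) = intercept + f_shape(exposure) + confounder_effect * confounder`,
#' the intercept solved by bisection so the marginal prevalence matches the
#' request. The outcome named `"birthweight"` is Gaussian with mean
#' `mean + f_shape(exposure) + confounder_effect * confounder`.
#'
#' @param exposure_true Latent exposure, hours/day.
#' @param confounder Confounder vector (same length).
#' @param shapes Named list of [effect_shape] objects, one per outcome.
#' @param baseline_prevalence Named numeric vector of marginal prevalences in
#'   (0, 1) for the binary outcomes.
#' @param birthweight_params List with `mean` (grams), `sd` (grams) and
#'   `confounder_effect` (grams per confounder unit) for the continuous
#'   outcome; defaults 3600 / 500 / 50.
#' @param confounder_effect Log-odds per confounder unit for binary outcomes
#'   (default 0.3).
#' @param seed Optional RNG seed.
#' @return `data.frame` with one column per outcome; binary outcomes are
#'   integer 0/1.
#' @export
simulate_outcomes <- function(exposure_true, confounder, shapes,
                              baseline_prevalence,
                              birthweight_params = list(mean = 3600, sd = 500,
                                                        confounder_effect = 50),
                              confounder_effect = 0.3, seed = NULL) {
  .assert(is.list(shapes) && !is.null(names(shapes)) &&
            all(nzchar(names(shapes))), "'shapes' must be a named list")
  for (nm in names(shapes)) {
    .assert(inherits(shapes[[nm]], "effect_shape"),
            sprintf("unknown shape specification for outcome '%s'", nm))
  }
  n <- length(exposure_true)
  .assert(length(confounder) == n, "'confounder' length mismatch")
  .seed(seed)
  out <- vector("list", length(shapes))
  names(out) <- names(shapes)
  for (nm in names(shapes)) {
    f <- eval_shape(shapes[[nm]], exposure_true)
    if (identical(nm, "birthweight")) {
      bw <- birthweight_params
      out[[nm]] <- bw$mean + f + bw$confounder_effect * confounder +
        rnorm(n, sd = bw$sd)
    } else {
      .assert(nm %in% names(baseline_prevalence),
              sprintf("no baseline prevalence supplied for '%s'", nm))
      p0 <- baseline_prevalence[[nm]]
      .assert(is.numeric(p0) && p0 > 0 && p0 < 1,
              "baseline prevalences must be in (0, 1)")
      eta <- f + confounder_effect * confounder
      a <- .solve_intercept(eta, p0)
      out[[nm]] <- rbinom(n, 1L, plogis(a + eta))
    }
  }
  as.data.frame(out, optional = TRUE)
}

#' Categorize reported sleep hours
#'
#' Maps integer reported hours to the four analysis categories (<=5, 6-7,
#' 8-9, >=10 hours/day); missing values propagate.
#'
#' @param exposure_reported Integer hours (or NA).
#' @return Factor with levels `"<=5"`, `"6-7"`, `"8-9"`, `">=10"`.
#' @export
#' @examples
#' categorize_exposure(c(5, 6, 9, 10, NA))
categorize_exposure <- function(exposure_reported) {
  x <- exposure_reported
  .assert(all(is.na(x) | x == floor(x)), "reported hours must be integer")
  lab <- ifelse(is.na(x), NA_character_,
                ifelse(x <= 5, "<=5",
                       ifelse(x <= 7, "6-7",
                              ifelse(x <= 9, "8-9", ">=10"))))
  factor(lab, levels = c("<=5", "6-7", "8-9", ">=10"))
}

#' Category midpoints in hours/day
#'
#' Recodes the four sleep-duration categories to their midpoints
#' (3.5, 6.5, 8.5 and 11 h/day), assuming the reporting range spans the same
#' minimum and maximum as integer-reported cohorts.
#'
#' @param category Factor or character vector of categories as produced by
#'   [categorize_exposure()].
#' @return Numeric vector of midpoints.
#' @export
midpoint_code <- function(category) {
  map <- c("<=5" = 3.5, "6-7" = 6.5, "8-9" = 8.5, ">=10" = 11)
  x <- as.character(category)
  .assert(all(is.na(x) | x %in% names(map)), "unknown exposure category")
  unname(map[x])
}

#' Impose MCAR or MAR missingness on cohort columns
#'
#' MCAR deletes each value independently with the requested probability; MAR
#' deletes with probability logistic in a fully observed driver column
#' (standardized, unit slope), with the intercept solved so the marginal
#' missingness rate matches the request.
#'
#' @param data A `data.frame`.
#' @param rates Named vector of missingness rates in [0, 1), names being
#'   columns of `data`.
#' @param mechanism `"MCAR"` or `"MAR"`.
#' @param driver Column name driving MAR missingness (must itself be fully
#'   observed).
#' @param seed Optional RNG seed.
#' @return `data` with missing markers (`NA`) inserted.
#' @export
impose_missingness <- function(data, rates, mechanism = c("MCAR", "MAR"),
                               driver = NULL, seed = NULL) {
  mechanism <- match.arg(mechanism)
  .assert(is.data.frame(data), "'data' must be a data.frame")
  .assert(all(names(rates) %in% names(data)), "unknown column in 'rates'")
  .assert(all(rates >= 0) && all(rates < 1), "rates must be in [0, 1)")
  .seed(seed)
  n <- nrow(data)
  if (mechanism == "MAR") {
    .assert(!is.null(driver) && driver %in% names(data),
            "MAR needs a 'driver' column present in 'data'")
    z <- data[[driver]]
    .assert(!anyNA(z), "MAR driver must be fully observed")
    z <- as.numeric(scale(z))
  }
  for (nm in names(rates)) {
    r <- rates[[nm]]
    if (r == 0) next
    if (mechanism == "MCAR") {
      drop <- runif(n) < r
    } else {
      a <- .solve_intercept(z, r)
      drop <- runif(n) < plogis(a + z)
    }
    data[[nm]][drop] <- NA
  }
  data
}

#' Simulate a full analysis cohort with known ground truth
#'
#' Convenience wrapper assembling genotypes, optional fetal genotypes, a
#' standard-Gaussian confounder (a single composite standing in for the
#' usual confounder set), latent and integer-reported exposure, covariates
#' (maternal age) and the requested outcomes.
#'
#' @inheritParams simulate_genotypes
#' @inheritParams simulate_exposure
#' @inheritParams simulate_outcomes
#' @param fetal Logical; also simulate transmitted fetal genotypes.
#' @param seed RNG seed (mandatory for reproducible cohorts).
#' @return A list of class `simulated_cohort` with elements `genotypes`,
#'   `fetal_genotypes` (or `NULL`), `exposure_true`, `exposure_reported`,
#'   `confounder`, `covariates`, `outcomes` and `truth` (the generating
#'   parameter set, including the realized genetic variance fraction).
#' @export
simulate_cohort <- function(n, panel = default_panel(seed = 1),
                            shapes = list(), baseline_prevalence = numeric(),
                            confounder_effect = 0.3, noise_sd = 1.05,
                            target_r2 = 0.0069, baseline = 7.2,
                            outcome_confounder_effect = 0.3,
                            birthweight_params = list(mean = 3600, sd = 500,
                                                      confounder_effect = 50),
                            fetal = FALSE, seed) {
  .assert(!missing(seed) && !is.null(seed), "'seed' is mandatory")
  .seed(seed)
  confounder <- rnorm(n)
  age <- rnorm(n, mean = 28, sd = 5)
  genotypes <- simulate_genotypes(panel, n)
  fetal_genotypes <- if (fetal) simulate_fetal_genotypes(genotypes, panel)
  exp_sim <- simulate_exposure(genotypes, panel, confounder = confounder,
                               confounder_effect = confounder_effect,
                               noise_sd = noise_sd, target_r2 = target_r2,
                               baseline = baseline)
  outcomes <- if (length(shapes)) {
    simulate_outcomes(exp_sim$exposure_true, confounder, shapes,
                      baseline_prevalence,
                      birthweight_params = birthweight_params,
                      confounder_effect = outcome_confounder_effect)
  } else {
    data.frame(row.names = seq_len(n))
  }
  truth <- list(seed = seed, n = n,
                beta_exposure = exp_sim$beta_exposure,
                grs_variance_explained = exp_sim$grs_variance_explained,
                confounder_effect = confounder_effect,
                outcome_confounder_effect = outcome_confounder_effect,
                noise_sd = noise_sd, target_r2 = target_r2,
                baseline = baseline,
                shapes = shapes, baseline_prevalence = baseline_prevalence,
                birthweight_params = birthweight_params)
  structure(list(genotypes = genotypes, fetal_genotypes = fetal_genotypes,
                 exposure_true = exp_sim$exposure_true,
                 exposure_reported = exp_sim$exposure_reported,
                 confounder = confounder,
                 covariates = data.frame(age = age),
                 outcomes = outcomes, panel = panel, truth = truth),
            class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf("Simulated cohort: n = %d, %d instrument SNPs\n",
              nrow(x$genotypes), ncol(x$genotypes)))
  cat(sprintf("  exposure: mean %.2f h/day (reported integer hours)\n",
              mean(x$exposure_true)))
  cat(sprintf("  GRS variance explained: %.3f%%\n",
              100 * x$truth$grs_variance_explained))
  if (ncol(x$outcomes)) {
    cat("  outcomes:", paste(names(x$outcomes), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write / read a simulated cohort as delimited text with a truth sidecar
#'
#' The cohort table is comma-separated with a header row and empty fields for
#' missing values; the ground-truth parameter set and seed go to a JSON
#' sidecar next to it.
#'
#' @param cohort A `simulated_cohort`.
#' @param path Path of the CSV to write; the sidecar is `<path>.truth.json`.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns a
#'   list with `data` and `truth`.
#' @export
write_cohort <- function(cohort, path) {
  .assert(inherits(cohort, "simulated_cohort"), "not a simulated_cohort")
  df <- data.frame(cohort$genotypes, check.names = FALSE)
  if (!is.null(cohort$fetal_genotypes)) {
    fg <- cohort$fetal_genotypes
    colnames(fg) <- paste0("fetal_", colnames(fg))
    df <- cbind(df, fg)
  }
  df$exposure_true <- cohort$exposure_true
  df$exposure_reported <- cohort$exposure_reported
  df$confounder <- cohort$confounder
  df <- cbind(df, cohort$covariates)
  if (ncol(cohort$outcomes)) df <- cbind(df, cohort$outcomes)
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE, na = "")
  truth <- cohort$truth
  truth$shapes <- lapply(truth$shapes, unclass)
  jsonlite::write_json(truth, paste0(path, ".truth.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  data <- utils::read.csv(path, check.names = FALSE)
  sidecar <- paste0(path, ".truth.json")
  truth <- if (file.exists(sidecar)) jsonlite::read_json(sidecar,
                                                         simplifyVector = TRUE)
  list(data = data, truth = truth)
}
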