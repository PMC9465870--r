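# Pipeline orchestration -------------------------------------------------
#
# One config drives simulate -> summary stats -> linear MR -> nonlinear MR
# -> observational arms, with a provenance block so identical config + seed
# reproduces identical reports.

.config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Validate and normalize a pipeline run configuration
#'
#' Accepts a config list or the path of a YAML file. Mandatory fields:
#' `seed` and at least one outcome; every outcome needs a unique `name`, a
#' `shape` block understood by [effect_shape()] and (binary outcomes) a
#' `prevalence`. Defaults fill the cohort block (n = 100000, 78 SNPs,
#' target r-squared 0.0069), stratification (`k = 5`), MR options
#' (multiplicative random effects, 1000 bootstrap draws) and
#' `arms` (all of simulate, sumstats, mr_linear, mr_nonlinear,
#' observational).
#'
#' @param config List or YAML file path.
#' @return Normalized config list (class `run_config`).
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    .assert(file.exists(config), sprintf("config error: no file '%s'", config))
    config <- yaml::read_yaml(config)
  }
  .assert(is.list(config), "config error: config must be a list")
  .assert(!is.null(config$seed) && is.numeric(config$seed),
          "config error: 'seed' is mandatory")
  defaults <- list(
    cohort = list(n = 100000, n_snp = 78, target_r2 = 0.0069,
                  baseline = 7.2, noise_sd = 1.05, confounder_effect = 0.3,
                  outcome_confounder_effect = 0.3, fetal = FALSE),
    stratification = list(k = 5),
    mr = list(effects_model = "random", n_boot = 1000,
              palindrome_policy = "drop_ambiguous"),
    arms = c("simulate", "sumstats", "mr_linear", "mr_nonlinear",
             "observational")
  )
  for (nm in names(defaults)) {
    config[[nm]] <- if (is.list(defaults[[nm]])) {
      modifyList(defaults[[nm]], as.list(config[[nm]]))
    } else {
      if (is.null(config[[nm]])) defaults[[nm]] else config[[nm]]
    }
  }
  known_arms <- c("simulate", "sumstats", "mr_linear", "mr_nonlinear",
                  "observational")
  .assert(all(config$arms %in% known_arms),
          paste("config error: unknown arm(s):",
                paste(setdiff(config$arms, known_arms), collapse = ", ")))
  .assert(length(config$outcomes) >= 1L,
          "config error: at least one outcome is required")
  nms <- vapply(config$outcomes, function(o) o$name %||% "", character(1))
  .assert(all(nzchar(nms)), "config error: every outcome needs a name")
  .assert(!anyDuplicated(nms), "config error: outcome names must be unique")
  for (o in config$outcomes) {
    .assert(!is.null(o$shape$shape),
            sprintf("config error: outcome '%s' needs a shape", o$name))
    if (!identical(o$name, "birthweight")) {
      .assert(is.numeric(o$prevalence) && o$prevalence > 0 && o$prevalence < 1,
              sprintf("config error: outcome '%s' needs a prevalence in (0,1)",
                      o$name))
    }
  }
  structure(config, class = c("run_config", "list"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.shape_from_config <- function(s) {
  effect_shape(shape = s$shape, slope = s$slope, curvature = s$curvature,
               breaks = unlist(s$breaks), slopes = unlist(s$slopes),
               reference_hours = s$reference_hours %||% 8)
}

#' Run the full analysis pipeline from a config
#'
#' Executes the requested arms in order on one simulated cohort: summary
#' statistics (QC, risk score, split cross-over), linear MR (crossed IVW
#' pooled by fixed-effects meta-analysis, plus MR-Egger, weighted median and
#' leave-one-out on the A-on-B harmonized set), residual-stratification
#' nonlinear MR (per-stratum Wald ratios, heterogeneity Q, meta-regression
#' nonlinearity and IV-constancy tests, pattern label) and the observational
#' categorical/midpoint comparison with its likelihood-ratio test. Identical
#' config and seed give identical reports; per-outcome soft failures (e.g. a
#' rare outcome with no cases) are recorded in the report, not fatal.
#'
#' @param config A config list or YAML path, see [validate_config()].
#' @return List of class `run_report`.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  seed <- config$seed
  arms <- config$arms
  outcome_names <- vapply(config$outcomes, `[[`, character(1), "name")
  shapes <- lapply(config$outcomes, function(o) .shape_from_config(o$shape))
  names(shapes) <- outcome_names
  prev <- vapply(config$outcomes,
                 function(o) o$prevalence %||% NA_real_, numeric(1))
  names(prev) <- outcome_names
  prev <- prev[!is.na(prev)]

  co <- config$cohort
  panel <- default_panel(n_snp = co$n_snp, target_r2 = co$target_r2,
                         seed = derive_seed(seed, "panel"))
  cohort <- simulate_cohort(
    n = co$n, panel = panel, shapes = shapes, baseline_prevalence = prev,
    confounder_effect = co$confounder_effect, noise_sd = co$noise_sd,
    target_r2 = co$target_r2, baseline = co$baseline,
    outcome_confounder_effect = co$outcome_confounder_effect,
    fetal = isTRUE(co$fetal), seed = derive_seed(seed, "cohort"))

  report <- list(outcomes = outcome_names, failures = list(),
                 provenance = list(config = unclass(config),
                                   config_hash = .config_hash(unclass(config)),
                                   seed = seed,
                                   package_version =
                                     as.character(packageVersion("sleepmr")),
                                   r_version = paste(R.version$major,
                                                     R.version$minor,
                                                     sep = ".")))
  fail <- function(stage, outcome, e) {
    report$failures[[length(report$failures) + 1L]] <<-
      list(stage = stage, outcome = outcome, message = conditionMessage(e))
  }
  if (!"sumstats" %in% arms && any(c("mr_linear", "mr_nonlinear") %in% arms)) {
    arms <- c(arms, "sumstats")
  }

  qc <- exposure_qc(cohort$exposure_reported)
  grs <- build_grs(cohort$genotypes, panel)
  report$instrument <- c(f_statistic(grs, qc$hours),
                         list(n_excluded_qc = qc$n_excluded))

  if ("sumstats" %in% arms) {
    split <- split_crossover(cohort, outcome_names,
                             seed = derive_seed(seed, "split"))
    report$split_sizes <- lengths(split$indices)
  }

  if ("mr_linear" %in% arms) {
    rows <- list()
    loo <- list()
    for (nm in outcome_names) {
      res <- tryCatch({
        crossed <- mr_crossed(split, nm, config$mr$effects_model,
                              config$mr$palindrome_policy)
        h_ab <- harmonize(split$a$exposure, split$b$outcomes[[nm]],
                          config$mr$palindrome_policy)
        pooled_row <- .mr_row("ivw", crossed$pooled$beta, crossed$pooled$se,
                              k = crossed$ab$k,
                              q = crossed$pooled$q_between, q_df = 1)
        eg <- mr_egger(h_ab)
        wm <- mr_weighted_median(h_ab, n_boot = config$mr$n_boot,
                                 seed = derive_seed(seed, paste0("wm_", nm)))
        loo[[nm]] <- mr_leave_one_out(h_ab, config$mr$effects_model)
        cbind(outcome = nm, rbind(pooled_row, eg, wm))
      }, error = function(e) { fail("mr_linear", nm, e); NULL })
      if (!is.null(res)) rows[[nm]] <- res
    }
    report$mr_linear <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    report$mr_leave_one_out <- loo
  }

  if ("mr_nonlinear" %in% arms) {
    res_exp <- residual_exposure(qc$hours, grs, cohort$covariates)
    assignment <- stratify_residual(
      res_exp$residual, k = config$stratification$k %||% 5,
      boundaries = unlist(config$stratification$boundaries))
    strata_tabs <- list()
    nl <- list()
    for (nm in outcome_names) {
      res <- tryCatch({
        y <- cohort$outcomes[[nm]]
        fam <- if (all(y %in% c(0, 1, NA))) "logistic" else "linear"
        est <- stratum_wald(grs, qc$hours, y, assignment,
                            cohort$covariates, fam)
        linear_row <- if (!is.null(report$mr_linear)) {
          report$mr_linear[report$mr_linear$outcome == nm &
                             report$mr_linear$method == "ivw", ]
        }
        if (!is.null(linear_row) && nrow(linear_row) == 0) linear_row <- NULL
        list(strata = est,
             heterogeneity = heterogeneity_across_strata(est),
             nonlinearity = nonlinearity_metareg(est),
             iv_constancy = iv_constancy(est),
             pattern = classify_pattern(est, linear_row))
      }, error = function(e) { fail("mr_nonlinear", nm, e); NULL })
      if (!is.null(res)) {
        strata_tabs[[nm]] <- cbind(outcome = nm, res$strata)
        res$strata <- NULL
        nl[[nm]] <- res
      }
    }
    report$strata <- do.call(rbind, c(strata_tabs,
                                      list(make.row.names = FALSE)))
    report$nonlinearity <- nl
    report$residual_summary <- list(beta_grs = res_exp$beta_grs,
                                    mean = mean(res_exp$residual,
                                                na.rm = TRUE),
                                    range = range(res_exp$residual,
                                                  na.rm = TRUE))
  }

  if ("observational" %in% arms) {
    category <- categorize_exposure(qc$hours)
    conf <- data.frame(confounder = cohort$confounder,
                       age = cohort$covariates$age)
    obs <- list()
    for (nm in outcome_names) {
      res <- tryCatch({
        y <- cohort$outcomes[[nm]]
        fam <- if (all(y %in% c(0, 1, NA))) "logistic" else "linear"
        fc <- fit_categorical_model(y, category, conf, fam)
        fm <- fit_midpoint_model(y, category, conf, fam)
        list(categorical = fc$estimates, midpoint = fm$estimate,
             lrt = lrt_nonlinearity(fc, fm), n = fc$n)
      }, error = function(e) { fail("observational", nm, e); NULL })
      if (!is.null(res)) obs[[nm]] <- res
    }
    report$observational <- obs
  }

  structure(report, class = "run_report")
}

#' Format a log-odds estimate as an odds ratio with 95% CI
#'
#' @param beta,ci_low,ci_high Estimate and CI on the log-odds scale.
#' @param digits Decimal places (default 2).
#' @return Strings like `"1.00 (0.95, 1.06)"`.
#' @export
format_or <- function(beta, ci_low, ci_high, digits = 2) {
  sprintf(paste0("%.", digits, "f (%.", digits, "f, %.", digits, "f)"),
          exp(beta), exp(ci_low), exp(ci_high))
}

#' Render a run report to files
#'
#' Writes the linear MR table (TSV and/or JSON mirror), the per-stratum
#' table, nonlinearity test results (JSON), observational results (TSV), a
#' markdown summary with odds ratios and 95% CIs, and the provenance block
#' with the config snapshot. No multiple-testing adjustment is applied;
#' conventional 0.05 thresholds are reported as such in the footer.
#'
#' @param report A `run_report`.
#' @param dir Output directory (created if needed).
#' @param formats Subset of `c("tsv", "json", "markdown")`.
#' @return Character vector of files written, invisibly.
#' @export
render_report <- function(report, dir,
                          formats = c("tsv", "json", "markdown")) {
  .assert(inherits(report, "run_report"), "'report' must be a run_report")
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  .assert(ok, sprintf("cannot create output directory '%s'", dir))
  files <- character()
  put <- function(name) file.path(dir, name)
  wtsv <- function(df, name) {
    write.table(df, put(name), sep = "\t", row.names = FALSE, quote = FALSE)
    files <<- c(files, put(name))
  }
  if ("tsv" %in% formats && !is.null(report$mr_linear)) {
    wtsv(report$mr_linear, "mr_linear.tsv")
  }
  if ("tsv" %in% formats && !is.null(report$strata)) {
    wtsv(report$strata, "mr_nonlinear_strata.tsv")
  }
  if ("tsv" %in% formats && length(report$observational)) {
    rows <- lapply(names(report$observational), function(nm) {
      o <- report$observational[[nm]]
      cat_rows <- cbind(outcome = nm, term = o$categorical$category,
                        o$categorical[, c("beta", "se", "ci_low", "ci_high",
                                          "pval")])
      mid_row <- cbind(outcome = nm, term = "per_hour_midpoint",
                       o$midpoint[, c("beta", "se", "ci_low", "ci_high",
                                      "pval")])
      lrt_row <- data.frame(outcome = nm, term = "lrt_nonlinearity",
                            beta = o$lrt$statistic, se = NA, ci_low = NA,
                            ci_high = NA, pval = o$lrt$pval)
      rbind(cat_rows, mid_row, lrt_row)
    })
    wtsv(do.call(rbind, c(rows, list(make.row.names = FALSE))),
         "observational.tsv")
  }
  if ("json" %in% formats) {
    payload <- list(mr_linear = report$mr_linear,
                    nonlinearity = report$nonlinearity,
                    instrument = report$instrument,
                    failures = report$failures,
                    provenance = report$provenance)
    jsonlite::write_json(payload, put("report.json"), auto_unbox = TRUE,
                         digits = NA, null = "null", force = TRUE)
    files <- c(files, put("report.json"))
  }
  if ("markdown" %in% formats) {
    md <- c("# Run report", "",
            sprintf("Config hash %s, seed %s, sleepmr %s.",
                    report$provenance$config_hash, report$provenance$seed,
                    report$provenance$package_version), "")
    if (!is.null(report$mr_linear)) {
      md <- c(md, "## Linear MR (per 1 h/day)", "",
              "| outcome | method | OR (95% CI) | p |",
              "|---|---|---|---|",
              sprintf("| %s | %s | %s | %.3g |", report$mr_linear$outcome,
                      report$mr_linear$method,
                      format_or(report$mr_linear$beta,
                                report$mr_linear$ci_low,
                                report$mr_linear$ci_high),
                      report$mr_linear$pval))
    }
    if (length(report$nonlinearity)) {
      md <- c(md, "", "## Nonlinear MR patterns", "",
              vapply(names(report$nonlinearity), function(nm) {
                nl <- report$nonlinearity[[nm]]
                sprintf("- %s: %s (Q p = %.3g, nonlinearity p = %.3g)", nm,
                        nl$pattern, nl$heterogeneity$pval,
                        nl$nonlinearity$pval)
              }, character(1)))
    }
    md <- c(md, "",
            "No multiple-testing adjustment applied; conventional 0.05 thresholds.")
    writeLines(md, put("report.md"))
    files <- c(files, put("report.md"))
  }
  invisible(files)
}

#' @export
print.run_report <- function(x, ...) {
  cat("sleepmr run report\n")
  cat(sprintf("  outcomes: %s\n", paste(x$outcomes, collapse = ", ")))
  cat(sprintf("  instrument F = %.1f (R^2 = %.4f%%)\n",
              x$instrument$f_statistic, 100 * x$instrument$r_squared))
  if (length(x$nonlinearity)) {
    for (nm in names(x$nonlinearity)) {
      cat(sprintf("  %s: pattern %s\n", nm, x$nonlinearity[[nm]]$pattern))
    }
  }
  if (length(x$failures)) {
    cat(sprintf("  %d soft failure(s) recorded\n", length(x$failures)))
  }
  invisible(x)
}
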