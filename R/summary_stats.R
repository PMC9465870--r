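# Per-SNP summary statistics ---------------------------------------------
#
# Production and QC of GWAS-style summary statistics from individual-level
# data: exposure cleaning, the unweighted genetic risk score, per-SNP
# association models, the split cross-over design, allele harmonization and
# instrument-strength diagnostics.

#' Quality-control reported sleep hours
#'
#' Reported durations shorter than 2 h or longer than 12 h are treated like
#' non-response (set missing); 2 and 12 themselves are retained.
#'
#' @param hours Integer reported hours (NA allowed).
#' @return List with `hours` (cleaned vector) and `n_excluded`.
#' @export
#' @examples
#' exposure_qc(c(1, 2, 7, 12, 13))
exposure_qc <- function(hours) {
  bad_type <- is.finite(hours) & hours != floor(hours)
  .assert(!any(bad_type),
          "reported hours must be integer (reporting contract violated)")
  out_of_range <- !is.na(hours) & (hours < 2 | hours > 12)
  hours[out_of_range] <- NA
  list(hours = hours, n_excluded = sum(out_of_range))
}

#' Unweighted genetic risk score
#'
#' Per-individual count of duration-increasing alleles: the dosage itself
#' where the stored effect allele increases duration, `2 - dosage` where it
#' decreases it.
#'
#' @param genotypes Dosage matrix (values in [0, 2]).
#' @param increasing Logical vector, one per SNP: does the stored effect
#'   allele increase the exposure? A [snp_panel] may be given instead, in
#'   which case the sign of its `beta_exposure` supplies the orientation.
#' @return Numeric score vector in [0, 2K].
#' @export
build_grs <- function(genotypes, increasing) {
  .assert(is.matrix(genotypes) && all(genotypes >= 0 & genotypes <= 2,
                                      na.rm = TRUE),
          "dosages must lie in [0, 2]")
  if (inherits(increasing, "snp_panel")) {
    .assert(all(increasing$beta_exposure != 0),
            "unknown SNP orientation: panel has zero-effect SNPs")
    increasing <- increasing$beta_exposure > 0
  }
  .assert(is.logical(increasing) && length(increasing) == ncol(genotypes) &&
            !anyNA(increasing),
          "unknown SNP orientation: 'increasing' must be complete logicals, one per SNP")
  oriented <- genotypes
  if (any(!increasing)) {
    oriented[, !increasing] <- 2 - oriented[, !increasing, drop = FALSE]
  }
  rowSums(oriented)
}

#' Genetic risk score with instrument-strength diagnostics
#'
#' @inheritParams build_grs
#' @param exposure Exposure vector used for the strength diagnostics.
#' @param covariates Optional covariate data.frame.
#' @return List with `score`, `f_statistic`, `r_squared`, `n`.
#' @export
grs_result <- function(genotypes, increasing, exposure, covariates = NULL) {
  score <- build_grs(genotypes, increasing)
  diag <- f_statistic(score, exposure, covariates)
  c(list(score = score), diag)
}

# Complete-record rows for a trait + optional covariate block.
.complete_rows <- function(trait, covariates) {
  keep <- !is.na(trait)
  if (!is.null(covariates)) keep <- keep & complete.cases(covariates)
  keep
}

.cov_matrix <- function(covariates, n) {
  if (is.null(covariates)) {
    matrix(1, n, 1)
  } else {
    model.matrix(~ ., data = as.data.frame(covariates))
  }
}

# Vectorised per-SNP OLS via Frisch-Waugh: residualise trait and dosages on
# the covariate block once, then closed-form simple regressions per SNP.
# Agrees with lm() coefficient, SE and t-test (checked in the test suite).
.snp_linear <- function(G, y, C) {
  qrC <- qr(C)
  ry <- qr.resid(qrC, y)
  rG <- qr.resid(qrC, G)
  n <- length(y)
  df <- n - ncol(C) - 1L
  sxx <- colSums(rG^2)
  .assert(all(sxx > 0), "zero variance in a dosage column")
  sxy <- colSums(rG * ry)
  beta <- sxy / sxx
  rss <- sum(ry^2) - beta * sxy
  se <- sqrt(pmax(rss, 0) / df / sxx)
  pval <- 2 * pt(-abs(beta / se), df)
  list(beta = beta, se = se, pval = pval)
}

# Vectorised per-SNP logistic regression (intercept + dosage), Newton-Raphson
# across all SNPs simultaneously. For integer dosages the exact MLE depends
# only on the per-dosage-class totals (n_d, cases_d for d = 0, 1, 2), so the
# Newton iterations run on 6 sufficient statistics per SNP; non-integer
# dosages take a dense IRLS. Checked against glm() in tests.
.snp_logistic_fast <- function(G, y, maxit = 50L, tol = 1e-10) {
  if (!all(G %in% c(0, 1, 2))) return(.snp_logistic_dense(G, y, maxit, tol))
  n <- length(y)
  is1 <- G == 1L
  is2 <- G == 2L
  n1 <- colSums(is1); n2 <- colSums(is2); n0 <- n - n1 - n2
  y1 <- drop(crossprod(y, is1)); y2 <- drop(crossprod(y, is2))
  y0 <- sum(y) - y1 - y2
  a <- rep(qlogis(mean(y)), ncol(G))
  b <- numeric(ncol(G))
  for (it in seq_len(maxit)) {
    p0 <- plogis(a); p1 <- plogis(a + b); p2 <- plogis(a + 2 * b)
    w0 <- n0 * p0 * (1 - p0); w1 <- n1 * p1 * (1 - p1)
    w2 <- n2 * p2 * (1 - p2)
    ua <- (y0 - n0 * p0) + (y1 - n1 * p1) + (y2 - n2 * p2)
    ub <- (y1 - n1 * p1) + 2 * (y2 - n2 * p2)
    iaa <- w0 + w1 + w2
    iab <- w1 + 2 * w2
    ibb <- w1 + 4 * w2
    det <- iaa * ibb - iab^2
    da <- (ibb * ua - iab * ub) / det
    db <- (iaa * ub - iab * ua) / det
    step_ok <- is.finite(da) & is.finite(db)
    da[!step_ok] <- 0; db[!step_ok] <- 0
    a <- a + da; b <- b + db
    b <- pmin(pmax(b, -20), 20)   # cap diverging (separated) fits
    if (max(abs(da), abs(db)) < tol) break
  }
  se <- sqrt(iaa / det)
  sep <- abs(b) >= 15 | !is.finite(se)
  se[sep] <- NA_real_
  list(beta = b, se = se, pval = 2 * pnorm(-abs(b / se)))
}

.snp_logistic_dense <- function(G, y, maxit = 50L, tol = 1e-10) {
  a <- rep(qlogis(mean(y)), ncol(G))
  b <- numeric(ncol(G))
  for (it in seq_len(maxit)) {
    eta <- sweep(sweep(G, 2, b, "*"), 2, a, "+")
    p <- plogis(eta)
    w <- p * (1 - p)
    res <- y - p
    ua <- colSums(res); ug <- colSums(res * G)
    wg <- w * G
    swa <- colSums(w); swg <- colSums(wg); swgg <- colSums(wg * G)
    det <- swa * swgg - swg^2
    da <- (swgg * ua - swg * ug) / det
    db <- (swa * ug - swg * ua) / det
    a <- a + da; b <- b + db
    if (max(abs(da), abs(db)) < tol) break
  }
  se <- sqrt(swa / det)
  sep <- abs(b) >= 15 | !is.finite(se)
  se[sep] <- NA_real_
  list(beta = b, se = se, pval = 2 * pnorm(-abs(b / se)))
}

.snp_logistic_glm <- function(G, y, C) {
  k <- ncol(G)
  beta <- se <- numeric(k)
  X <- cbind(C, dosage = 0)
  j <- ncol(X)
  for (s in seq_len(k)) {
    X[, j] <- G[, s]
    fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
    cf <- fit$coefficients[j]
    # observed-information SE from the weighted cross-product
    XtWX <- crossprod(X * sqrt(fit$weights))
    v <- tryCatch(solve(XtWX)[j, j], error = function(e) NA_real_)
    beta[s] <- cf
    se[s] <- if (!fit$converged || abs(cf) > 15 || !is.finite(v)) NA_real_
             else sqrt(v)
  }
  list(beta = beta, se = se, pval = 2 * pnorm(-abs(beta / se)))
}

#' Per-SNP association summary statistics
#'
#' One regression per SNP of the trait on dosage plus covariates, returning
#' the dosage coefficient (hours/day for the exposure, log-odds or grams for
#' outcomes), its SE and p-value, on complete records. SNPs showing
#' separation under the logistic family are flagged with a missing SE rather
#' than dropped.
#'
#' @param genotypes Dosage matrix.
#' @param trait Trait vector; must be 0/1 for `family = "logistic"`.
#' @param covariates Optional covariate data.frame.
#' @param family `"linear"` or `"logistic"`.
#' @param panel Optional [snp_panel] supplying allele labels.
#' @param trait_name Name used in error messages.
#' @return A `data.frame` of class `snp_association` with columns `snp_id`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#' @export
estimate_snp_trait <- function(genotypes, trait, covariates = NULL,
                               family = c("linear", "logistic"),
                               panel = NULL, trait_name = "trait") {
  family <- match.arg(family)
  .assert(is.matrix(genotypes) && ncol(genotypes) >= 1L,
          "need at least one SNP")
  keep <- .complete_rows(trait, covariates)
  G <- genotypes[keep, , drop = FALSE]
  y <- trait[keep]
  n <- length(y)
  C <- .cov_matrix(if (!is.null(covariates))
                     as.data.frame(covariates)[keep, , drop = FALSE], n)
  if (family == "logistic") {
    .assert(all(y %in% c(0, 1)), "trait must be binary for logistic family")
    .assert(sum(y) > 0,
            sprintf("outcome '%s' has zero cases", trait_name))
    .assert(sum(y) < n,
            sprintf("outcome '%s' has zero controls", trait_name))
    fit <- if (is.null(covariates)) .snp_logistic_fast(G, y)
           else .snp_logistic_glm(G, y, C)
  } else {
    fit <- .snp_linear(G, y, C)
  }
  ids <- colnames(genotypes)
  if (is.null(ids)) ids <- sprintf("snp%d", seq_len(ncol(genotypes)))
  ea <- if (!is.null(panel)) panel$effect_allele else rep("A", ncol(G))
  oa <- if (!is.null(panel)) panel$other_allele else rep("G", ncol(G))
  out <- data.frame(snp_id = ids, effect_allele = ea, other_allele = oa,
                    eaf = colMeans(G) / 2, beta = fit$beta, se = fit$se,
                    pval = fit$pval, n = n, stringsAsFactors = FALSE,
                    row.names = NULL)
  class(out) <- c("snp_association", "data.frame")
  out
}

#' Maternal SNP-outcome associations with and without fetal adjustment
#'
#' For each SNP, the unadjusted model regresses the outcome on the maternal
#' dosage (plus covariates); the adjusted model adds the same SNP's fetal
#' dosage. Comparing the two exposes bias flowing through the transmitted
#' fetal genotype: an outcome driven purely by the fetal genotype shows an
#' unadjusted maternal coefficient of about half the fetal effect
#' (transmission correlation 0.5) that vanishes on adjustment.
#'
#' @param genotypes Maternal dosage matrix.
#' @param fetal_genotypes Matching fetal dosage matrix.
#' @param outcome Outcome vector.
#' @param covariates Optional covariate data.frame.
#' @param family `"linear"` or `"logistic"`.
#' @param panel Optional [snp_panel] for allele labels.
#' @return List with `unadjusted` and `adjusted` [estimate_snp_trait]-style
#'   tables (the `adjusted` beta is the maternal coefficient).
#' @export
adjust_for_fetal <- function(genotypes, fetal_genotypes, outcome,
                             covariates = NULL,
                             family = c("linear", "logistic"),
                             panel = NULL) {
  family <- match.arg(family)
  .assert(!is.null(fetal_genotypes), "fetal genotype matrix is absent")
  .assert(is.matrix(fetal_genotypes) &&
            all(dim(fetal_genotypes) == dim(genotypes)),
          "maternal and fetal dosage matrices must match")
  unadj <- estimate_snp_trait(genotypes, outcome, covariates, family,
                              panel = panel, trait_name = "outcome")
  keep <- .complete_rows(outcome, covariates)
  G <- genotypes[keep, , drop = FALSE]
  Fg <- fetal_genotypes[keep, , drop = FALSE]
  y <- outcome[keep]
  n <- length(y)
  C <- .cov_matrix(if (!is.null(covariates))
                     as.data.frame(covariates)[keep, , drop = FALSE], n)
  k <- ncol(G)
  beta <- se <- numeric(k)
  if (family == "linear") {
    qrC <- qr(C)
    ry <- qr.resid(qrC, y)
    rG <- qr.resid(qrC, G)
    rF <- qr.resid(qrC, Fg)
    df <- n - ncol(C) - 2L
    for (s in seq_len(k)) {
      X <- cbind(rG[, s], rF[, s])
      XtX <- crossprod(X)
      Xty <- crossprod(X, ry)
      cf <- solve(XtX, Xty)
      rss <- sum(ry^2) - sum(cf * Xty)
      v <- solve(XtX)[1, 1] * rss / df
      beta[s] <- cf[1]
      se[s] <- sqrt(v)
    }
  } else {
    .assert(all(y %in% c(0, 1)), "outcome must be binary for logistic family")
    X <- cbind(C, maternal = 0, fetal = 0)
    j <- ncol(X) - 1L
    for (s in seq_len(k)) {
      X[, j] <- G[, s]; X[, j + 1L] <- Fg[, s]
      fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
      XtWX <- crossprod(X * sqrt(fit$weights))
      beta[s] <- fit$coefficients[j]
      se[s] <- sqrt(solve(XtWX)[j, j])
    }
  }
  adj <- unadj
  adj$beta <- beta
  adj$se <- se
  adj$pval <- 2 * pnorm(-abs(beta / se))
  list(unadjusted = unadj, adjusted = adj)
}

#' Split cross-over summary statistics
#'
#' Randomly partitions a cohort into two disjoint halves (sizes floor(n/2)
#' and ceiling(n/2); odd n puts the extra row in B) and estimates per-SNP
#' exposure and outcome associations in each half. Downstream, MR pairs
#' exposure associations from one half with outcome associations from the
#' other (and vice versa) and combines the two crossed estimates by
#' fixed-effects meta-analysis, so instrument-exposure and
#' instrument-outcome errors come from disjoint subsets.
#'
#' @param cohort A `simulated_cohort` (or any list with `genotypes`,
#'   `exposure_reported`, `outcomes`, `panel`).
#' @param outcome_names Outcomes to process; default all columns of
#'   `cohort$outcomes`.
#' @param covariates Optional covariate data.frame aligned with the cohort.
#' @param qc Apply [exposure_qc()] to reported hours first (default TRUE).
#' @param seed RNG seed for the permutation split.
#' @return List of class `split_crossover` with `a` and `b`, each holding
#'   `exposure` (a `snp_association` table) and `outcomes` (named list of
#'   such tables), plus `indices`.
#' @export
split_crossover <- function(cohort, outcome_names = NULL, covariates = NULL,
                            qc = TRUE, seed = NULL) {
  n <- nrow(cohort$genotypes)
  .assert(n >= 200, "split cross-over needs n >= 200")
  .seed(seed)
  perm <- sample.int(n)
  idx_a <- sort(perm[seq_len(n %/% 2)])
  idx_b <- sort(perm[(n %/% 2 + 1L):n])
  exposure <- cohort$exposure_reported
  if (qc) exposure <- exposure_qc(exposure)$hours
  if (is.null(outcome_names)) outcome_names <- names(cohort$outcomes)
  half <- function(idx) {
    G <- cohort$genotypes[idx, , drop = FALSE]
    cv <- if (!is.null(covariates)) covariates[idx, , drop = FALSE]
    exp_assoc <- estimate_snp_trait(G, exposure[idx], cv, "linear",
                                    panel = cohort$panel,
                                    trait_name = "exposure")
    outs <- lapply(outcome_names, function(nm) {
      y <- cohort$outcomes[[nm]][idx]
      fam <- if (all(y %in% c(0, 1, NA))) "logistic" else "linear"
      estimate_snp_trait(G, y, cv, fam, panel = cohort$panel,
                         trait_name = nm)
    })
    names(outs) <- outcome_names
    list(exposure = exp_assoc, outcomes = outs)
  }
  structure(list(a = half(idx_a), b = half(idx_b),
                 indices = list(a = idx_a, b = idx_b)),
            class = "split_crossover")
}

#' Harmonize exposure and outcome summary statistics
#'
#' Pairs per-SNP exposure and outcome associations on a shared effect-allele
#' orientation. When the outcome record's effect allele equals the exposure
#' record's other allele (and vice versa), the outcome beta sign is flipped
#' and its frequency complemented. Palindromic SNPs (A/T or C/G) cannot be
#' oriented from allele labels when their frequency is near 0.5; under the
#' default policy they are dropped when minor-allele frequency exceeds
#' `maf_threshold`. Incompatible allele pairs and non-overlapping SNPs are
#' excluded with a logged reason, never a fatal error.
#'
#' @param exposure,outcome `snp_association` tables.
#' @param palindrome_policy `"drop_ambiguous"` (default), `"keep"` or
#'   `"drop_all"`.
#' @param maf_threshold Ambiguity threshold for the default policy
#'   (default 0.42).
#' @return Object of class `harmonized_set`: list with `data` (columns
#'   `snp_id`, `effect_allele`, `other_allele`, `beta_exp`, `se_exp`,
#'   `eaf_exp`, `beta_out`, `se_out`, `eaf_out`) and `exclusions`
#'   (`snp_id`, `reason`).
#' @export
harmonize <- function(exposure, outcome,
                      palindrome_policy = c("drop_ambiguous", "keep",
                                            "drop_all"),
                      maf_threshold = 0.42) {
  palindrome_policy <- match.arg(palindrome_policy)
  .assert(!anyDuplicated(exposure$snp_id) && !anyDuplicated(outcome$snp_id),
          "duplicate snp_ids")
  excl <- list()
  note <- function(id, why) excl[[length(excl) + 1L]] <<-
    data.frame(snp_id = id, reason = why, stringsAsFactors = FALSE)
  only_out <- setdiff(outcome$snp_id, exposure$snp_id)
  if (length(only_out)) note(only_out, "missing_in_exposure")
  only_exp <- setdiff(exposure$snp_id, outcome$snp_id)
  if (length(only_exp)) note(only_exp, "missing_in_outcome")
  shared <- intersect(exposure$snp_id, outcome$snp_id)
  e <- exposure[match(shared, exposure$snp_id), ]
  o <- outcome[match(shared, outcome$snp_id), ]

  same <- e$effect_allele == o$effect_allele & e$other_allele == o$other_allele
  swap <- e$effect_allele == o$other_allele & e$other_allele == o$effect_allele
  mism <- !(same | swap)
  if (any(mism)) note(shared[mism], "allele_mismatch")

  beta_out <- ifelse(swap, -o$beta, o$beta)
  eaf_out <- ifelse(swap, 1 - o$eaf, o$eaf)

  pal_pairs <- c("AT", "TA", "CG", "GC")
  pal <- paste0(e$effect_allele, e$other_allele) %in% pal_pairs
  drop_pal <- rep(FALSE, length(shared))
  if (palindrome_policy == "drop_all") {
    drop_pal <- pal
  } else if (palindrome_policy == "drop_ambiguous") {
    maf <- pmin(e$eaf, 1 - e$eaf)
    drop_pal <- pal & maf > maf_threshold
  }
  if (any(drop_pal & !mism)) note(shared[drop_pal & !mism],
                                  "palindromic_ambiguous")

  keep <- !mism & !drop_pal
  data <- data.frame(snp_id = shared[keep],
                     effect_allele = e$effect_allele[keep],
                     other_allele = e$other_allele[keep],
                     beta_exp = e$beta[keep], se_exp = e$se[keep],
                     eaf_exp = e$eaf[keep],
                     beta_out = beta_out[keep], se_out = o$se[keep],
                     eaf_out = eaf_out[keep],
                     stringsAsFactors = FALSE, row.names = NULL)
  .assert(nrow(data) > 0, "harmonization produced an empty instrument set")
  structure(list(data = data,
                 exclusions = if (length(excl)) do.call(rbind, excl)
                              else data.frame(snp_id = character(),
                                              reason = character())),
            class = "harmonized_set")
}

#' Instrument-strength F-statistic
#'
#' Partial F-statistic for a single instrument column (dosage or risk score)
#' in the exposure regression, with the corresponding partial R-squared.
#' With no covariates this is the squared t-statistic of the slope and
#' satisfies `F = R^2 (n - 2) / (1 - R^2)`.
#'
#' @param instrument Single instrument vector.
#' @param exposure Exposure vector.
#' @param covariates Optional covariate data.frame.
#' @return List with `f_statistic`, `r_squared` (partial), `n`.
#' @export
f_statistic <- function(instrument, exposure, covariates = NULL) {
  keep <- .complete_rows(exposure, covariates) & !is.na(instrument)
  z <- instrument[keep]
  y <- exposure[keep]
  .assert(var(z) > 0, "zero variance in instrument")
  n <- length(y)
  C <- .cov_matrix(if (!is.null(covariates))
                     as.data.frame(covariates)[keep, , drop = FALSE], n)
  qrC <- qr(C)
  ry <- qr.resid(qrC, y)
  rz <- qr.resid(qrC, z)
  sxx <- sum(rz^2)
  beta <- sum(rz * ry) / sxx
  rss1 <- sum(ry^2) - beta^2 * sxx
  df <- n - ncol(C) - 1L
  f <- beta^2 * sxx / (rss1 / df)
  r2 <- 1 - rss1 / sum(ry^2)
  list(f_statistic = f, r_squared = r2, n = n)
}

# Summary-statistic text interfaces --------------------------------------

#' Read / write summary-statistic files
#'
#' Tab-delimited with header
#' `snp_id effect_allele other_allele eaf beta se pval n`; the reader
#' tolerates extra columns, the writer emits exactly these.
#'
#' @param assoc A `snp_association` table.
#' @param path File path.
#' @return `read_sumstats` returns a `snp_association` table.
#' @export
write_sumstats <- function(assoc, path) {
  cols <- c("snp_id", "effect_allele", "other_allele", "eaf", "beta", "se",
            "pval", "n")
  write.table(assoc[, cols], path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Write a harmonization exclusion log
#'
#' Tab-delimited `snp_id reason`, one row per excluded SNP.
#'
#' @param h A `harmonized_set` (or its `exclusions` data.frame).
#' @param path File path.
#' @export
write_exclusions <- function(h, path) {
  excl <- if (inherits(h, "harmonized_set")) h$exclusions else h
  write.table(excl[, c("snp_id", "reason")], path, sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("snp_id", "effect_allele", "other_allele", "eaf", "beta", "se",
            "pval", "n")
  .assert(all(need %in% names(df)),
          paste("summary-statistic file must contain columns:",
                paste(need, collapse = " ")))
  out <- df[, need]
  class(out) <- c("snp_association", "data.frame")
  out
}
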