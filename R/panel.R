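# Instrument panel specification -----------------------------------------

#' Specify a panel of independent biallelic instrument SNPs
#'
#' A panel row holds one variant's identifier, effect-allele frequency, true
#' per-allele effect on the exposure (hours/day) and its allele labels. The
#' default panel mimics the instrument set used for self-reported sleep
#' duration: 78 independent SNPs that jointly explain about 0.69% of exposure
#' variance, with equal-magnitude, random-sign per-allele effects (only the
#' aggregate variance explained is anchored, so equal magnitudes are the
#' neutral choice).
#'
#' @param snp_id Character vector of unique variant identifiers.
#' @param eaf Effect-allele frequencies, strictly inside (0, 1).
#' @param beta_exposure True per-allele effects on the exposure (hours/day).
#'   These are rescaled at simulation time when a target variance explained is
#'   requested, preserving their relative pattern.
#' @param effect_allele,other_allele Single-character allele labels from
#'   A/C/G/T. Defaults assign non-palindromic A/G pairs.
#'
#' @return A `data.frame` of class `snp_panel` with columns `snp_id`, `eaf`,
#'   `beta_exposure`, `effect_allele`, `other_allele`.
#' @export
#' @examples
#' panel <- snp_panel(c("rs1", "rs2"), eaf = c(0.3, 0.5),
#'                    beta_exposure = c(0.02, -0.02))
snp_panel <- function(snp_id, eaf, beta_exposure,
                      effect_allele = NULL, other_allele = NULL) {
  snp_id <- as.character(snp_id)
  .assert(!anyDuplicated(snp_id), "snp_ids must be unique")
  .assert(length(eaf) == length(snp_id) &&
            length(beta_exposure) == length(snp_id),
          "'eaf' and 'beta_exposure' must match 'snp_id' in length")
  .assert(all(is.finite(eaf)) && all(eaf > 0) && all(eaf < 1),
          "effect-allele frequencies must be finite and strictly in (0, 1)")
  .assert(all(is.finite(beta_exposure)), "'beta_exposure' must be finite")
  if (is.null(effect_allele)) effect_allele <- rep("A", length(snp_id))
  if (is.null(other_allele)) other_allele <- rep("G", length(snp_id))
  ok <- c("A", "C", "G", "T")
  .assert(all(effect_allele %in% ok) && all(other_allele %in% ok) &&
            all(effect_allele != other_allele),
          "alleles must be distinct single characters from A/C/G/T")
  out <- data.frame(snp_id = snp_id, eaf = eaf,
                    beta_exposure = beta_exposure,
                    effect_allele = effect_allele,
                    other_allele = other_allele,
                    stringsAsFactors = FALSE)
  class(out) <- c("snp_panel", "data.frame")
  out
}

#' Default sleep-duration instrument panel
#'
#' @param n_snp Panel size (default 78).
#' @param target_r2 Variance in exposure jointly explained by the panel,
#'   used to size the equal-magnitude per-allele effects (default 0.0069,
#'   i.e. 0.69%). The sizing assumes an exposure standard deviation of
#'   `exposure_sd` hours.
#' @param exposure_sd Assumed exposure standard deviation in hours (default
#'   1.1, typical of integer-reported sleep duration).
#' @param seed Optional seed controlling frequencies and effect signs.
#' @return A [snp_panel].
#' @export
default_panel <- function(n_snp = 78, target_r2 = 0.0069, exposure_sd = 1.1,
                          seed = NULL) {
  .assert(.is_count(n_snp), "'n_snp' must be a positive integer")
  .seed(seed)
  eaf <- runif(n_snp, 0.1, 0.9)
  # equal |beta|, random sign, sized so sum(2*eaf*(1-eaf)) * beta^2 hits the
  # target genetic variance
  var_g_target <- target_r2 * exposure_sd^2
  b <- sqrt(var_g_target / sum(2 * eaf * (1 - eaf)))
  sgn <- sample(c(-1, 1), n_snp, replace = TRUE)
  # avoid palindromic pairs by construction (A/G, C/T never strand-ambiguous)
  pairs <- rbind(c("A", "G"), c("G", "A"), c("C", "T"), c("T", "C"))
  pick <- sample(nrow(pairs), n_snp, replace = TRUE)
  snp_panel(sprintf("rs%05d", seq_len(n_snp)), eaf = eaf,
            beta_exposure = b * sgn,
            effect_allele = pairs[pick, 1], other_allele = pairs[pick, 2])
}
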