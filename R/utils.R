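#' @keywords internal
"_PACKAGE"

#' @import stats
#' @importFrom utils modifyList read.delim write.table packageVersion head
NULL

# Internal argument checks -----------------------------------------------

.assert <- function(cond, msg, call. = FALSE) {
  if (!isTRUE(cond)) stop(msg, call. = call.)
}

.is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
}

# Set the RNG deterministically when a seed is supplied; seeds below 2^31
# are required by R's 32-bit integer seeds.
.seed <- function(seed) {
  if (is.null(seed)) return(invisible(NULL))
  .assert(.is_count(seed) || (is.numeric(seed) && seed == floor(seed)),
          "'seed' must be a single integer")
  set.seed(as.integer(seed %% .Machine$integer.max))
  invisible(NULL)
}

#' Derive a stream-specific child seed from a master seed
#'
#' Deterministically maps a master seed and a stream label to a 32-bit
#' integer seed, so pipeline stages and simulation arms draw from
#' independent, reproducible streams.
#'
#' @param seed Master seed (integer).
#' @param stream Stream label (character).
#' @return An integer seed below 2^31.
#' @export
derive_seed <- function(seed, stream) {
  .assert(is.numeric(seed) && length(seed) == 1L, "'seed' must be numeric")
  h <- 0
  for (ch in utf8ToInt(as.character(stream))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# Weighted least squares with *known* variances (fixed-effect meta style):
# coefficient covariance is (X'WX)^{-1}, not scaled by residual variance.
.wls_fixed <- function(X, y, w) {
  XtW <- t(X * w)
  V <- unname(solve(XtW %*% X))
  beta <- unname(drop(V %*% (XtW %*% y)))
  list(beta = beta, vcov = V, resid = drop(y - X %*% beta))
}

.norm_ci <- function(beta, se, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  c(beta - z * se, beta + z * se)
}

.norm_p <- function(beta, se) 2 * pnorm(-abs(beta / se))
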