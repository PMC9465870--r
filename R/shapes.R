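# Exposure-outcome effect shapes -----------------------------------------

#' Define the shape of a simulated exposure-outcome relationship
#'
#' Shapes act on the scale of the linear predictor: log-odds for binary
#' outcomes, outcome units (e.g. grams of birthweight) for continuous ones.
#' Every shape evaluates to 0 at `reference_hours`, so simulated risk shifts
#' are relative to the reference exposure.
#'
#' Supported shapes:
#' \describe{
#'   \item{`null`}{No effect.}
#'   \item{`linear`}{`slope * (x - reference_hours)`.}
#'   \item{`quadratic`}{`curvature * (x - reference_hours)^2`; a positive
#'     curvature gives a U with minimum risk at the reference, and the local
#'     per-hour effect at exposure x is `2 * curvature * (x - reference)`.}
#'   \item{`piecewise`}{Continuous broken line: `breaks` (strictly increasing,
#'     inside the exposure support) split the axis into segments with slopes
#'     `slopes` (length `length(breaks) + 1`), anchored to 0 at the
#'     reference.}
#' }
#'
#' @param shape One of `"null"`, `"linear"`, `"quadratic"`, `"piecewise"`.
#' @param slope Per-hour slope (linear shape).
#' @param curvature Quadratic coefficient (quadratic shape); must be finite.
#' @param breaks,slopes Piecewise specification, see above.
#' @param reference_hours Exposure (hours/day) at which the shape is 0 and,
#'   for a positive-curvature quadratic, risk is minimised. Default 8.
#' @return An object of class `effect_shape`; call it on exposure values via
#'   [eval_shape()].
#' @export
effect_shape <- function(shape = c("null", "linear", "quadratic", "piecewise"),
                         slope = NULL, curvature = NULL, breaks = NULL,
                         slopes = NULL, reference_hours = 8) {
  shape <- match.arg(shape)
  .assert(is.numeric(reference_hours) && is.finite(reference_hours),
          "'reference_hours' must be a finite number")
  spec <- list(shape = shape, reference_hours = reference_hours)
  if (shape == "linear") {
    .assert(is.numeric(slope) && is.finite(slope),
            "linear shape needs a finite 'slope'")
    spec$slope <- slope
  } else if (shape == "quadratic") {
    .assert(is.numeric(curvature) && is.finite(curvature),
            "quadratic shape needs a finite 'curvature'")
    spec$curvature <- curvature
  } else if (shape == "piecewise") {
    .assert(is.numeric(breaks) && all(is.finite(breaks)) &&
              !is.unsorted(breaks, strictly = TRUE),
            "piecewise 'breaks' must be finite and strictly increasing")
    .assert(is.numeric(slopes) && length(slopes) == length(breaks) + 1L &&
              all(is.finite(slopes)),
            "'slopes' must be finite with length length(breaks) + 1")
    spec$breaks <- breaks
    spec$slopes <- slopes
  }
  structure(spec, class = "effect_shape")
}

#' Evaluate an effect shape at exposure values
#'
#' @param spec An [effect_shape].
#' @param x Exposure values in hours/day.
#' @return Numeric vector, 0 at the reference exposure.
#' @export
eval_shape <- function(spec, x) {
  .assert(inherits(spec, "effect_shape"), "'spec' must be an effect_shape")
  d <- x - spec$reference_hours
  switch(spec$shape,
    null = rep(0, length(x)),
    linear = spec$slope * d,
    quadratic = spec$curvature * d^2,
    piecewise = .eval_piecewise(spec, x)
  )
}

.eval_piecewise <- function(spec, x) {
  knots <- c(-Inf, spec$breaks, Inf)
  # integrate the step-function slope from the reference to x
  f1 <- function(xi) {
    if (is.na(xi)) return(NA_real_)
    lo <- min(xi, spec$reference_hours)
    hi <- max(xi, spec$reference_hours)
    tot <- 0
    for (s in seq_along(spec$slopes)) {
      a <- max(lo, knots[s]); b <- min(hi, knots[s + 1L])
      if (b > a) tot <- tot + spec$slopes[s] * (b - a)
    }
    if (xi < spec$reference_hours) -tot else tot
  }
  vapply(x, f1, numeric(1))
}
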