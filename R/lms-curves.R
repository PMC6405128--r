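#' Smooth LMS curve triple over an age domain
#'
#' Container for the three age-varying parameters of the LMS model: the
#' Box-Cox power `L(t)`, the median `M(t)` and the generalised coefficient
#' of variation `S(t)`, together with the age domain they were defined on,
#' their equivalent degrees of freedom (EDF) and the positivity shift that
#' was applied to the raw scores.
#'
#' Each curve may be supplied as a single number (constant over age) or as a
#' function of age in months (used for simulation ground truth).  Fitted
#' objects returned by [fit_lms()] carry spline representations instead.
#'
#' @param L,M,S a number or a `function(t)` for each parameter curve.
#' @param age_range length-2 numeric, the closed age domain in months.
#' @param edf optional named EDF triple `c(L=, M=, S=)`.
#' @param shift non-negative positivity offset added to raw scores before
#'   transformation (recorded so downstream calculators un-shift consistently).
#' @return an object of class `lms_curves`.
#' @examples
#' tr <- lms_curves(L = 1, M = function(t) 40 + 0.5 * t, S = 0.1,
#'                  age_range = c(20, 60))
#' eval_curves(tr, c(30, 40))
#' @export
lms_curves <- function(L, M, S, age_range, edf = NULL, shift = 0) {
  stopifnot(length(age_range) == 2, age_range[1] < age_range[2],
            is.numeric(shift), shift >= 0)
  spec <- function(x, nm) {
    if (is.function(x)) list(type = "function", fun = x, link = "identity")
    else if (is.numeric(x) && length(x) == 1)
      list(type = "constant", value = x, link = "identity")
    else stop("curve '", nm, "' must be a single number or a function of age",
              call. = FALSE)
  }
  out <- structure(list(
    L = spec(L, "L"), M = spec(M, "M"), S = spec(S, "S"),
    age_range = as.numeric(age_range),
    edf = edf, shift = shift
  ), class = "lms_curves")
  validate_lms_curves(out)
  out
}

new_lms_curves <- function(L_spec, M_spec, S_spec, age_range, edf, shift) {
  structure(list(L = L_spec, M = M_spec, S = S_spec,
                 age_range = as.numeric(age_range), edf = edf, shift = shift),
            class = "lms_curves")
}

validate_lms_curves <- function(x) {
  grid <- seq(x$age_range[1], x$age_range[2], length.out = 25)
  v <- eval_curves(x, grid)
  if (any(v$M <= 0) || any(v$S <= 0))
    stop("M(t) and S(t) must be strictly positive over the age domain",
         call. = FALSE)
  invisible(x)
}

eval_curve_spec <- function(spec, t) {
  eta <- switch(spec$type,
    constant = rep_len(spec$value, length(t)),
    linear   = spec$coef[1] + spec$coef[2] * t,
    spline   = stats::predict(spec$fit, t)$y,
    grid     = stats::approx(spec$age, spec$value, xout = t, rule = 2)$y,
    "function" = spec$fun(t),
    stop("unknown curve spec type: ", spec$type)
  )
  if (identical(spec$link, "log")) exp(eta) else eta
}

#' Evaluate LMS curves at given ages
#'
#' @param curves an [lms_curves] object.
#' @param age ages in months.
#' @param extrapolate if `FALSE` (default), ages outside the fitted age
#'   domain raise an error; evaluation beyond the domain is an explicit
#'   opt-in because reference norms should not be extrapolated silently.
#' @return a data.frame with columns `age`, `L`, `M`, `S`.
#' @export
eval_curves <- function(curves, age, extrapolate = FALSE) {
  stopifnot(inherits(curves, "lms_curves"), is.numeric(age))
  out_dom <- age < curves$age_range[1] - 1e-9 | age > curves$age_range[2] + 1e-9
  if (any(out_dom) && !extrapolate)
    stop(sprintf(
      "age %s is outside the fitted domain [%.1f, %.1f] months; set extrapolate = TRUE to override",
      format(age[out_dom][1]), curves$age_range[1], curves$age_range[2]),
      call. = FALSE)
  data.frame(age = age,
             L = eval_curve_spec(curves$L, age),
             M = eval_curve_spec(curves$M, age),
             S = eval_curve_spec(curves$S, age))
}

#' @export
print.lms_curves <- function(x, ...) {
  cat("LMS curve triple\n")
  cat(sprintf("  age domain: [%.1f, %.1f] months\n",
              x$age_range[1], x$age_range[2]))
  cat(sprintf("  curve types: L=%s M=%s S=%s\n",
              x$L$type, x$M$type, x$S$type))
  if (!is.null(x$edf))
    cat(sprintf("  EDF: a_L=%g a_M=%g a_S=%g\n",
                x$edf[["L"]], x$edf[["M"]], x$edf[["S"]]))
  if (x$shift != 0)
    cat(sprintf("  score shift: +%g applied before transformation\n", x$shift))
  mid <- mean(x$age_range)
  v <- eval_curves(x, mid)
  cat(sprintf("  at mid-age %.1f: L=%.3f M=%.3f S=%.3f\n",
              mid, v$L, v$M, v$S))
  invisible(x)
}
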