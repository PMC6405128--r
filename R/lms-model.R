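#' Serialisable calculator model from a fitted LMS object
#'
#' Tabulates the fitted L, M, S curves on a dense age grid (monthly by
#' default).  The resulting object is self-contained: scoring interpolates
#' the grid linearly, so a serialized model reproduces z-scores exactly
#' without the fitting machinery, and independently of the spline
#' representation.
#'
#' @param fit an `lms_fit` (or an [lms_curves] object).
#' @param by grid resolution in months.
#' @param score_bounds optional instrument bounds on the raw-score scale,
#'   used to validate calculator inputs.
#' @return an object of class `lms_model`.
#' @export
as_lms_model <- function(fit, by = 1, score_bounds = NULL) {
  curves <- if (inherits(fit, "lms_fit")) fit$curves else fit
  stopifnot(inherits(curves, "lms_curves"))
  rng <- curves$age_range
  grid <- seq(rng[1], rng[2], by = by)
  if (grid[length(grid)] < rng[2]) grid <- c(grid, rng[2])
  v <- eval_curves(curves, grid)
  crit <- if (inherits(fit, "lms_fit"))
    list(global_deviance = fit$global_deviance,
         penalized_deviance = fit$penalized_deviance,
         aic = fit$aic, sbc = fit$sbc, gaic3 = fit$gaic3,
         n = fit$n_effective, converged = fit$converged,
         weights_used = fit$weights_used)
  else NULL
  # the model is defined at 15 significant digits: that is the precision
  # its JSON serialization carries, so in-memory and reloaded calculators
  # score bit-identically
  structure(list(
    age = signif(v$age, 15), L = signif(v$L, 15),
    M = signif(v$M, 15), S = signif(v$S, 15),
    age_range = signif(rng, 15),
    shift = curves$shift,
    edf = curves$edf,
    score_bounds = score_bounds,
    criteria = crit
  ), class = "lms_model")
}

model_curves <- function(model) {
  new_lms_curves(
    L_spec = list(type = "grid", age = model$age, value = model$L,
                  link = "identity"),
    M_spec = list(type = "grid", age = model$age, value = model$M,
                  link = "identity"),
    S_spec = list(type = "grid", age = model$age, value = model$S,
                  link = "identity"),
    age_range = model$age_range, edf = model$edf, shift = model$shift)
}

#' Write / read a calculator model as JSON
#'
#' Full floating point precision is preserved so that scoring after a
#' round trip is bit-identical.
#'
#' @param model an `lms_model`.
#' @param path file path.
#' @return `write_lms_model` returns `path` invisibly; `read_lms_model`
#'   returns the `lms_model`.
#' @export
write_lms_model <- function(model, path) {
  stopifnot(inherits(model, "lms_model"))
  payload <- unclass(model)
  payload$format <- "lmsnorms-model-1"
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_lms_model
#' @export
read_lms_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "lmsnorms-model-1"))
    stop("not a serialized lmsnorms calculator model: ", path, call. = FALSE)
  edf <- payload$edf
  if (!is.null(edf)) edf <- stats::setNames(as.numeric(edf), names(edf))
  structure(list(
    age = as.numeric(payload$age), L = as.numeric(payload$L),
    M = as.numeric(payload$M), S = as.numeric(payload$S),
    age_range = as.numeric(payload$age_range),
    shift = as.numeric(payload$shift),
    edf = edf,
    score_bounds = if (is.null(payload$score_bounds)) NULL
                   else as.numeric(payload$score_bounds),
    criteria = payload$criteria
  ), class = "lms_model")
}

#' Standard score and centile for a raw score at a given age
#'
#' The calculator analogue of an online norms tool: looks up the local
#' L, M, S parameters by linear interpolation on the model's dense age grid,
#' applies the recorded positivity shift, and returns the skew-corrected
#' z-score together with its centile.  Ages outside the normed domain are
#' refused (reference norms are not extrapolated).
#'
#' @param model an `lms_model` (or an `lms_fit`, converted on the fly).
#' @param age age(s) in months.
#' @param raw raw score(s) on the instrument scale (pre-shift).
#' @return data.frame with columns `age`, `raw`, `L`, `M`, `S`, `z`,
#'   `centile` (lower tail area in (0,1)).
#' @examples
#' tr <- lms_curves(L = 1, M = function(t) 50 + t / 2, S = 0.1,
#'                  age_range = c(10, 30))
#' m <- as_lms_model(tr, by = 1)
#' score_child(m, age = 20, raw = 66)   # z = 1
#' @export
score_child <- function(model, age, raw) {
  if (inherits(model, "lms_fit") || inherits(model, "lms_curves"))
    model <- as_lms_model(model)
  stopifnot(inherits(model, "lms_model"))
  n <- max(length(age), length(raw))
  age <- rep_len(as.numeric(age), n); raw <- rep_len(as.numeric(raw), n)
  rng <- model$age_range
  out <- age < rng[1] - 1e-9 | age > rng[2] + 1e-9
  if (any(out))
    stop(sprintf(
      "age %s is outside the normed domain [%.1f, %.1f] months; no norms are available there",
      format(age[out][1]), rng[1], rng[2]), call. = FALSE)
  if (!is.null(model$score_bounds)) {
    b <- model$score_bounds
    bad <- raw < b[1] | raw > b[2]
    if (any(bad))
      stop(sprintf("raw score %s is outside the instrument bounds [%g, %g]",
                   format(raw[bad][1]), b[1], b[2]), call. = FALSE)
  }
  L <- stats::approx(model$age, model$L, xout = age, rule = 2)$y
  M <- stats::approx(model$age, model$M, xout = age, rule = 2)$y
  S <- stats::approx(model$age, model$S, xout = age, rule = 2)$y
  z <- raw_to_z(raw + model$shift, L, M, S)
  data.frame(age = age, raw = raw, L = L, M = M, S = S,
             z = z, centile = z_to_centile(z))
}

#' @export
print.lms_model <- function(x, ...) {
  cat("Serialized LMS calculator model\n")
  cat(sprintf("  age domain [%.1f, %.1f] months, %d grid points, shift = %g\n",
              x$age_range[1], x$age_range[2], length(x$age), x$shift))
  if (!is.null(x$edf))
    cat(sprintf("  EDF: a_L=%g a_M=%g a_S=%g\n",
                x$edf[["L"]], x$edf[["M"]], x$edf[["S"]]))
  if (!is.null(x$score_bounds))
    cat(sprintf("  instrument bounds [%g, %g]\n",
                x$score_bounds[1], x$score_bounds[2]))
  invisible(x)
}
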