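#' Log-likelihood contribution of one observation under the LMS model
#'
#' The Box-Cox-normal log density implied by assuming the skew-corrected
#' z-score is standard normal, with constants that depend only on the data
#' dropped: `l = L*log(y/M) - log(S) - z^2/2`.  When a sampling weight is
#' supplied the contribution is multiplied by it (weighted likelihood).
#'
#' @inheritParams raw_to_z
#' @param weight positive sampling weight(s), default 1.
#' @return numeric log-likelihood contribution(s).
#' @export
loglik_contribution <- function(y, L, M, S, weight = 1) {
  z <- raw_to_z(y, L, M, S)
  n <- length(z)
  L <- rep_len(L, n); M <- rep_len(M, n); S <- rep_len(S, n)
  weight * (L * log(y / M) - log(S) - z^2 / 2)
}

#' Deviance-based model selection criteria
#'
#' @param deviance global deviance (-2 x maximised log-likelihood).
#' @param k total model complexity, the sum of the three EDFs.
#' @param n number of observations entering the fit.
#' @return list with `aic = deviance + 2k`, `sbc = deviance + k*log(n)` and
#'   `gaic3 = deviance + 3k`.
#' @export
deviance_criteria <- function(deviance, k, n) {
  list(aic = deviance + 2 * k,
       sbc = deviance + k * log(n),
       gaic3 = deviance + 3 * k)
}

#' Control settings for the LMS fitter
#'
#' @param max_cycles maximum number of outer backfitting cycles.
#' @param tol convergence tolerance on the change in penalized deviance
#'   between full cycles.
#' @param L_bounds allowed range for the fitted Box-Cox power.
#' @param max_knots cap on interior spline knots (distinct ages are used as
#'   knots up to this cap, quantile-thinned beyond it).
#' @param trace print per-cycle deviance if `TRUE`.
#' @return a list of class `lms_control`.
#' @export
lms_control <- function(max_cycles = 200, tol = 1e-4, L_bounds = c(-5, 5),
                        max_knots = 50, trace = FALSE) {
  stopifnot(max_cycles >= 1, tol > 0, length(L_bounds) == 2)
  structure(list(max_cycles = max_cycles, tol = tol, L_bounds = L_bounds,
                 max_knots = max_knots, trace = trace),
            class = "lms_control")
}

# One penalized weighted smoothing step: constant (df 1), linear (df 2), or
# cubic smoothing spline with lambda solved so the smoother trace hits df.
smooth_update <- function(t, pseudo, w, df, max_knots) {
  n <- length(t)
  if (df <= 1 + 1e-9) {
    val <- sum(w * pseudo) / sum(w)
    return(list(fitted = rep(val, n),
                spec = list(type = "constant", value = val),
                realized = 1, penalty = 0))
  }
  if (abs(df - 2) < 1e-9) {
    fit <- stats::lm.wfit(cbind(1, t), pseudo, w)
    return(list(fitted = as.numeric(fit$fitted.values),
                spec = list(type = "linear", coef = unname(fit$coefficients)),
                realized = 2, penalty = 0))
  }
  nux <- length(unique(t))
  if (df >= nux)
    stop("requested EDF (", df, ") must be below the number of distinct ages (",
         nux, ")", call. = FALSE)
  ss <- stats::smooth.spline(t, pseudo, w = w, df = df, cv = FALSE,
                             all.knots = nux <= max_knots,
                             nknots = min(max_knots, nux))
  grid <- seq(min(t), max(t), length.out = 201)
  d2 <- stats::predict(ss, grid, deriv = 2)$y
  rough <- sum((d2[-1]^2 + d2[-length(d2)]^2) / 2 * diff(grid))
  r <- diff(range(t))
  list(fitted = stats::predict(ss, t)$y,
       spec = list(type = "spline", fit = ss),
       realized = ss$df,
       penalty = ss$lambda * r^3 * rough)
}

# z and its ingredients without the per-call validation overhead of raw_to_z
.z_fast <- function(y, L, M, S) {
  tt <- log(y / M)
  ifelse(abs(L) > .eps_L, (exp(L * tt) - 1) / (L * S), tt / S)
}

#' Fit smooth LMS curves by penalized maximum likelihood
#'
#' Estimates the age-varying Box-Cox power `L(t)`, median `M(t)` and
#' coefficient of variation `S(t)` by maximising the (optionally weighted)
#' penalized likelihood, alternating Fisher-scoring updates of the three
#' curves.  Each update smooths a working response with a cubic smoothing
#' spline whose roughness penalty is tuned so the smoother trace equals the
#' requested equivalent degrees of freedom (EDF).  EDF semantics: for `M`
#' and `S`, 1 = constant, 2 = linear in age, >2 = cubic smoothing spline;
#' for `L`, 0 fixes `L(t) = 1` (no skewness correction), 1 estimates a
#' constant power, 2 a linear trend, and so on.  `M` and `S` are modelled
#' on the log scale to enforce positivity.
#'
#' Repeated assessments of the same child are treated as independent
#' cross-sectional observations; any clustering is ignored by design.
#'
#' @param data data.frame with columns `age` (months) and `score`; rows are
#'   one assessment each.
#' @param edf named EDF triple, e.g. `c(L = 0, M = 1, S = 1)`.
#' @param weights optional positive sampling weights, one per row.  Fitted
#'   curves are invariant to rescaling all weights by a constant; the
#'   deviance scales with that constant.
#' @param shift positivity offset added to scores before transformation;
#'   default auto-selects via [suggest_shift()].
#' @param start optional `lms_fit` or `lms_curves` object used to warm-start
#'   the curves (recommended when fitting a complex model after a simpler
#'   one, which often helps convergence).
#' @param control an [lms_control()] list.
#' @return an object of class `lms_fit`: the fitted [lms_curves], global and
#'   penalized deviance, AIC/SBC/GAIC(3), realised EDFs, iteration count and
#'   a convergence flag.  Non-convergence is reported in the flag, never as
#'   a silent success.
#' @examples
#' set.seed(1)
#' d <- data.frame(age = runif(500, 20, 60))
#' d$score <- z_to_raw(rnorm(500), L = 1, M = 50, S = 0.1)
#' f <- fit_lms(d, edf = c(L = 0, M = 1, S = 1))
#' f
#' @export
fit_lms <- function(data, edf, weights = NULL, shift = NULL,
                    start = NULL, control = lms_control()) {
  stopifnot(is.data.frame(data))
  if (!all(c("age", "score") %in% names(data)))
    stop("`data` must have columns 'age' and 'score'", call. = FALSE)
  edf <- check_edf(edf)
  t <- as.numeric(data$age); y0 <- as.numeric(data$score)
  n <- length(t)
  if (any(!is.finite(t)) || any(!is.finite(y0)))
    stop("non-finite age or score in data", call. = FALSE)
  if (is.null(shift)) shift <- suggest_shift(y0)
  y <- y0 + shift
  if (any(y <= 0))
    stop("shifted scores must be strictly positive; smallest is ",
         format(min(y)), " (shift = ", shift, ")", call. = FALSE)
  nux <- length(unique(t))
  if (any(edf > 1) && (n < 20 || nux < 2))
    stop("need at least 20 records over at least 2 distinct ages to fit ",
         "age-varying curves", call. = FALSE)
  if (is.null(weights)) {
    omega <- rep(1, n); weights_used <- FALSE
  } else {
    omega <- as.numeric(weights)
    if (length(omega) != n || any(!is.finite(omega)) || any(omega <= 0))
      stop("weights must be positive and one per record", call. = FALSE)
    weights_used <- TRUE
  }
  wn <- omega / mean(omega)  # smoothing weights; mean-1 so curves are
                             # exactly invariant to weight rescaling
  age_range <- range(t)

  # --- initial curves -------------------------------------------------
  if (!is.null(start)) {
    sc <- if (inherits(start, "lms_fit")) start$curves else start
    stopifnot(inherits(sc, "lms_curves"))
    v <- eval_curves(sc, t, extrapolate = TRUE)
    Lv <- v$L; Mv <- v$M; Sv <- v$S
  } else {
    Mv <- rep(max(stats::weighted.mean(y, wn), min(y) * 1.001), n)
    Sv <- rep(min(max(sqrt(stats::weighted.mean((log(y) - stats::weighted.mean(log(y), wn))^2, wn)), 0.02), 2), n)
    Lv <- rep(1, n)
  }
  if (edf[["L"]] == 0) Lv <- rep(1, n)
  Lb <- control$L_bounds
  Lv <- pmin(pmax(Lv, Lb[1]), Lb[2])
  Sv <- pmin(pmax(Sv, 1e-5), 1e3)

  specs <- list(
    L = list(type = "constant", value = Lv[1]),
    M = list(type = "constant", value = log(Mv[1]), link = "log"),
    S = list(type = "constant", value = log(Sv[1]), link = "log"))
  pens <- c(L = 0, M = 0, S = 0)

  global_dev <- function() {
    tt <- log(y / Mv)
    z <- .z_fast(y, Lv, Mv, Sv)
    -2 * sum(omega * (Lv * tt - log(Sv) - z^2 / 2))
  }

  pd_prev <- Inf; converged <- FALSE; iter <- 0; ok <- TRUE
  for (cycle in seq_len(control$max_cycles)) {
    iter <- cycle
    # M update (log link)
    z <- .z_fast(y, Lv, Mv, Sv)
    info <- (1 + 2 * Lv^2 * Sv^2) / Sv^2
    pseudo <- log(Mv) + (z / Sv + Lv * (z^2 - 1)) / info
    up <- smooth_update(t, pseudo, wn * info, edf[["M"]], control$max_knots)
    Mv <- pmin(pmax(exp(up$fitted), 1e-8), 1e8)
    specs$M <- c(up$spec, list(link = "log")); pens["M"] <- up$penalty
    edf_real_M <- up$realized

    # S update (log link)
    z <- .z_fast(y, Lv, Mv, Sv)
    pseudo <- log(Sv) + (z^2 - 1) / 2
    up <- smooth_update(t, pseudo, wn * 2, edf[["S"]], control$max_knots)
    Sv <- pmin(pmax(exp(up$fitted), 1e-5), 1e3)
    specs$S <- c(up$spec, list(link = "log")); pens["S"] <- up$penalty
    edf_real_S <- up$realized

    # L update (identity link, bounded)
    edf_real_L <- 0
    if (edf[["L"]] >= 1) {
      z <- .z_fast(y, Lv, Mv, Sv)
      tt <- log(y / Mv)
      uexp <- exp(Lv * tt)
      dldL <- ifelse(abs(Lv) >= 1e-5,
                     tt - z * ((uexp * tt) / (Lv * Sv) - z / Lv),
                     tt - tt^3 / (2 * Sv^2) - (7 / 12) * Lv * tt^4 / Sv^2)
      info <- pmax(7 * Sv^2 / 4, 1e-3)
      pseudo <- Lv + dldL / info
      up <- smooth_update(t, pseudo, wn * info, edf[["L"]], control$max_knots)
      Lv <- pmin(pmax(up$fitted, Lb[1]), Lb[2])
      specs$L <- c(up$spec, list(link = "identity")); pens["L"] <- up$penalty
      edf_real_L <- up$realized
    }

    gd <- global_dev()
    pd <- gd + sum(pens)
    # stopping rule on the mean-1 weight scale, so the iteration path (and
    # hence the curves) is exactly invariant to rescaling all weights
    pd_norm <- pd / mean(omega)
    if (control$trace)
      message(sprintf("cycle %3d  GD = %.4f  PD = %.4f", cycle, gd, pd))
    if (!is.finite(pd)) { ok <- FALSE; break }
    if (abs(pd_prev - pd_norm) < control$tol) { converged <- TRUE; break }
    pd_prev <- pd_norm
  }
  gd <- global_dev(); pd <- gd + sum(pens)
  if (!is.finite(gd)) ok <- FALSE

  curve_spec <- function(s) {
    link <- if (is.null(s$link)) "identity" else s$link
    s$link <- link
    s
  }
  curves <- new_lms_curves(
    L_spec = curve_spec(specs$L), M_spec = curve_spec(specs$M),
    S_spec = curve_spec(specs$S),
    age_range = age_range,
    edf = c(L = edf[["L"]], M = edf[["M"]], S = edf[["S"]]),
    shift = shift)

  k <- sum(edf)
  crit <- deviance_criteria(gd, k, n)
  structure(list(
    curves = curves,
    edf = curves$edf,
    edf_realized = c(L = if (edf[["L"]] >= 1) edf_real_L else 0,
                     M = edf_real_M, S = edf_real_S),
    global_deviance = gd,
    penalized_deviance = pd,
    aic = crit$aic, sbc = crit$sbc, gaic3 = crit$gaic3,
    n_effective = n,
    iterations = iter,
    converged = converged && ok,
    weights_used = weights_used,
    shift = shift
  ), class = "lms_fit")
}

check_edf <- function(edf) {
  if (is.null(names(edf)) || !all(c("L", "M", "S") %in% names(edf)))
    stop("`edf` must be a named triple c(L=, M=, S=)", call. = FALSE)
  edf <- edf[c("L", "M", "S")]
  if (any(!is.finite(edf)) || edf[["L"]] < 0)
    stop("EDFs must be finite and a_L >= 0", call. = FALSE)
  if (edf[["M"]] < 1 || edf[["S"]] < 1)
    stop("a_M and a_S must be at least 1 (zero values are not allowed)",
         call. = FALSE)
  edf
}

#' Refit LMS curves with sampling weights attached to the data
#'
#' Convenience wrapper around [fit_lms()] for data that carry inverse
#' probability weights in a `weight` column (e.g. from [compose_weights()]).
#'
#' @inheritParams fit_lms
#' @param ... passed on to [fit_lms()].
#' @return an `lms_fit` with `weights_used = TRUE`.
#' @export
refit_with_weights <- function(data, edf, ...) {
  if (!"weight" %in% names(data) || any(is.na(data$weight)))
    stop("`data` must carry a complete 'weight' column to refit with weights",
         call. = FALSE)
  fit_lms(data, edf, weights = data$weight, ...)
}

#' Standard scores of observations under fitted or true LMS curves
#'
#' Applies the positivity shift recorded in the curves and converts each
#' (age, score) pair to a skew-corrected z-score.
#'
#' @param curves an [lms_curves] or `lms_fit` object.
#' @param age,score vectors of equal length.
#' @param extrapolate allow ages outside the fitted domain.
#' @return numeric z-scores.
#' @export
standard_scores <- function(curves, age, score, extrapolate = FALSE) {
  if (inherits(curves, "lms_fit")) curves <- curves$curves
  if (inherits(curves, "lms_model")) curves <- model_curves(curves)
  stopifnot(inherits(curves, "lms_curves"))
  v <- eval_curves(curves, age, extrapolate = extrapolate)
  raw_to_z(score + curves$shift, v$L, v$M, v$S)
}

#' @export
print.lms_fit <- function(x, ...) {
  cat("LMS penalized maximum likelihood fit\n")
  cat(sprintf("  n = %d%s, EDF (L/M/S) = %g/%g/%g, shift = %g\n",
              x$n_effective, if (x$weights_used) " (weighted)" else "",
              x$edf[["L"]], x$edf[["M"]], x$edf[["S"]], x$shift))
  cat(sprintf("  global deviance = %.2f, penalized = %.2f\n",
              x$global_deviance, x$penalized_deviance))
  cat(sprintf("  AIC = %.2f, SBC = %.2f, GAIC(3) = %.2f\n",
              x$aic, x$sbc, x$gaic3))
  cat(sprintf("  %s after %d cycles\n",
              if (x$converged) "converged" else "DID NOT CONVERGE",
              x$iterations))
  invisible(x)
}
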