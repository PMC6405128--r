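# Inverse probability weights for a two-phase stratified design:
# step 1 models selection into the intensive phase on the whole screened
# sample; step 2 models complete-data response within the selected
# subsample; the final weight is 1 / (p1 * p2).

#' Step-1 selection model on the full screened sample
#'
#' Logistic regression of the phase-2 invitation indicator on the design
#' covariates (risk stratum from the screen and the number of children
#' screened at the child's school, by default), fitted to every screened
#' child.  On perfect separation a lightly ridged refit (1e-6) is
#' attempted; if coefficients still diverge an error instructs collapsing
#' the offending strata.
#'
#' @param screen data.frame of screen records, one row per screened child.
#' @param selected logical/0-1 vector: invited to the intensive phase.
#' @param covariates names of columns of `screen` used as predictors;
#'   default `c("risk_flag", "school_n_screened")`.
#' @return list of class `ipw_step` with `coefficients`, fitted
#'   probabilities `p`, and the model formula.
#' @export
fit_step1 <- function(screen, selected,
                      covariates = c("risk_flag", "school_n_screened")) {
  selected <- as.integer(selected)
  stopifnot(nrow(screen) == length(selected))
  if (length(unique(selected)) < 2) {
    if (all(selected == 1))
      return(structure(list(coefficients = c(`(Intercept)` = Inf),
                            p = rep(1, nrow(screen)),
                            covariates = character(0), all_selected = TRUE),
                       class = "ipw_step"))
    stop("selection indicator has a single class; both selected and ",
         "unselected children are required", call. = FALSE)
  }
  missing_cov <- setdiff(covariates, names(screen))
  if (length(missing_cov))
    stop("covariates not found in screen data: ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  fit_logistic(screen[covariates], selected,
               context = "step-1 selection model",
               separation_hint = paste(
                 "perfect separation in the selection model;",
                 "collapse sparse design strata and refit"))
}

#' Step-2 complete-data response model with backward elimination
#'
#' Logistic regression of the complete-data indicator on candidate
#' covariates, fitted to the selected subsample only.  Backward elimination
#' drops the least significant covariate while its Wald p-value exceeds the
#' retention threshold, refitting after each drop.  An empty retained set
#' (intercept-only model) is a valid outcome.
#'
#' @param selected_data data.frame of screen records for selected children.
#' @param complete logical/0-1 vector: complete data on all outcome
#'   measures.
#' @param candidates candidate covariate names; all must be columns of
#'   `selected_data`.
#' @param threshold retention p-value threshold (drop while p > threshold);
#'   default 0.05.
#' @return list of class `ipw_step` with `coefficients`, `retained`,
#'   fitted probabilities `p` and the elimination path.
#' @export
fit_step2 <- function(selected_data, complete, candidates, threshold = 0.05) {
  complete <- as.integer(complete)
  stopifnot(nrow(selected_data) == length(complete))
  missing_cov <- setdiff(candidates, names(selected_data))
  if (length(missing_cov))
    stop("candidate covariates not found: ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  if (all(complete == 1)) {
    out <- structure(list(coefficients = c(`(Intercept)` = Inf),
                          p = rep(1, nrow(selected_data)),
                          retained = character(0), dropped = candidates,
                          all_selected = TRUE),
                     class = "ipw_step")
    return(out)
  }
  retained <- candidates
  dropped <- character(0)
  repeat {
    fit <- fit_logistic(selected_data[retained], complete,
                        context = "step-2 response model",
                        separation_hint = paste(
                          "perfect separation in the response model;",
                          "remove or coarsen the separating covariate"))
    if (!length(retained)) break
    pv <- fit$p_values[names(fit$p_values) != "(Intercept)"]
    if (!length(pv) || max(pv, na.rm = TRUE) <= threshold) break
    worst <- names(pv)[which.max(pv)]
    retained <- setdiff(retained, worst)
    dropped <- c(dropped, worst)
  }
  fit$retained <- retained
  fit$dropped <- dropped
  fit
}

# IRLS logistic fit via glm, with a small ridge fallback on separation.
fit_logistic <- function(X, y, ridge = 1e-6, context = "logistic model",
                         separation_hint = "perfect separation") {
  X <- as.data.frame(X)
  df <- cbind(data.frame(.y = y), X)
  form <- if (ncol(X)) stats::as.formula(paste(".y ~",
                                               paste(names(X), collapse = " + ")))
          else stats::as.formula(".y ~ 1")
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(), data = df),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  if (sep_warn || !fit$converged || any(abs(beta[-1]) > 15)) {
    mm <- stats::model.matrix(form, df)
    beta <- irls_ridge_logistic(mm, y, ridge)
    if (any(!is.finite(beta)) || any(abs(beta[-1]) > 30))
      stop(context, ": ", separation_hint, call. = FALSE)
    eta <- drop(mm %*% beta)
    return(structure(list(coefficients = beta, p = stats::plogis(eta),
                          p_values = rep(NA_real_, length(beta)) |>
                            stats::setNames(names(beta)),
                          ridged = TRUE),
                     class = "ipw_step"))
  }
  sm <- summary(fit)$coefficients
  structure(list(coefficients = beta,
                 p = as.numeric(stats::fitted(fit)),
                 p_values = stats::setNames(sm[, 4], rownames(sm)),
                 ridged = FALSE),
            class = "ipw_step")
}

irls_ridge_logistic <- function(X, y, ridge, max_iter = 100, tol = 1e-10) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    H <- crossprod(X, X * w) + diag(ridge, ncol(X))
    g <- crossprod(X, y - p) - ridge * beta
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  stats::setNames(drop(beta), colnames(X))
}

#' Compose final inverse probability weights
#'
#' `w = 1 / (p1 * p2)`: the reciprocal of the product of the step-1
#' selection probability and the step-2 complete-data probability,
#' evaluated for children with complete data.  Very small products signal
#' unstable weights; they trigger a warning and, optionally, truncation.
#'
#' @param p1,p2 predicted probabilities (equal length, in (0, 1]).
#' @param floor smallest trusted probability product; default 1e-4.
#' @param truncate if `TRUE`, cap weights at `1 / floor` (off by default:
#'   raw inverse probabilities are returned).
#' @param normalise if `TRUE`, rescale the weights to mean 1 for reporting
#'   (fitted LMS curves are invariant to this rescaling).
#' @return numeric vector of positive weights.
#' @examples
#' compose_weights(0.405, 1)  # 2.4691: one high-risk boy stands for ~2.5
#' @export
compose_weights <- function(p1, p2, floor = 1e-4, truncate = FALSE,
                            normalise = FALSE) {
  stopifnot(length(p1) == length(p2))
  if (any(p1 <= 0) || any(p1 > 1) || any(p2 <= 0) || any(p2 > 1))
    stop("probabilities must lie in (0, 1]", call. = FALSE)
  prod <- p1 * p2
  if (any(prod < floor)) {
    warning(sum(prod < floor), " probability product(s) below the floor of ",
            floor, if (truncate) "; weights truncated"
            else "; consider truncate = TRUE", call. = FALSE)
    if (truncate) prod <- pmax(prod, floor)
  }
  w <- 1 / prod
  if (normalise) w <- w / mean(w)
  w
}

#' Two-step inverse probability weights in one call
#'
#' Runs [fit_step1()] on the full screened sample, [fit_step2()] on the
#' selected subsample, and [compose_weights()] for the complete-data
#' children.  Wave-specific weights are obtained by calling this once per
#' assessment wave with that wave's completeness indicator.
#'
#' @inheritParams fit_step1
#' @param complete completeness indicator over all screened children
#'   (only its values on selected children are used).
#' @param candidates candidate covariates for the response model.
#' @param threshold backward-elimination retention threshold.
#' @param ... passed to [compose_weights()].
#' @return list of class `two_step_weights`: `step1`, `step2`, and a
#'   data.frame `weights` with `child_id` (if present), `p1`, `p2`, and
#'   `weight` for each complete-data child.
#' @export
two_step_weights <- function(screen, selected, complete,
                             covariates = c("risk_flag", "school_n_screened"),
                             candidates, threshold = 0.05, ...) {
  selected <- as.logical(selected); complete <- as.logical(complete)
  if (any(complete & !selected))
    stop("children cannot be complete without being selected", call. = FALSE)
  s1 <- fit_step1(screen, selected, covariates)
  sel <- which(selected)
  s2 <- fit_step2(screen[sel, , drop = FALSE], complete[sel], candidates,
                  threshold)
  comp_in_sel <- complete[sel]
  idx <- sel[comp_in_sel]
  p1 <- s1$p[idx]
  p2 <- s2$p[comp_in_sel]
  w <- compose_weights(p1, p2, ...)
  wdf <- data.frame(row = idx, p1 = p1, p2 = p2, weight = w)
  if ("child_id" %in% names(screen)) wdf$child_id <- screen$child_id[idx]
  structure(list(step1 = s1, step2 = s2, weights = wdf),
            class = "two_step_weights")
}

#' @export
print.two_step_weights <- function(x, ...) {
  cat("Two-step inverse probability weights\n")
  cat("  step 1 coefficients:\n")
  print(round(x$step1$coefficients, 4))
  cat("  step 2 retained covariates:",
      if (length(x$step2$retained)) paste(x$step2$retained, collapse = ", ")
      else "(none - intercept only)", "\n")
  cat(sprintf("  %d complete-data children; weight range [%.3f, %.3f], sum %.1f\n",
              nrow(x$weights), min(x$weights$weight), max(x$weights$weight),
              sum(x$weights$weight)))
  invisible(x)
}
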