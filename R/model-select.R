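#' Policy for sequential EDF optimisation
#'
#' Controls the stepwise search over equivalent-degrees-of-freedom triples:
#' curves are optimised in a fixed order (median first, then variation,
#' then skewness — the conventional rule of thumb `a_M > a_S > a_L`), one
#' integer EDF increment at a time, accepting a step only when the chosen
#' deviance criterion improves by more than `min_improvement`.
#'
#' @param order curve names in optimisation order; default `c("M","S","L")`.
#' @param edf_cap maximum EDF per curve: 2 is appropriate for a single
#'   assessment wave over a short age span, 4 for pooled two-wave data over
#'   an extended span.
#' @param criterion one of `"SBC"` (default, the most stringent together
#'   with GAIC(3)), `"AIC"`, `"GAIC3"`.
#' @param min_improvement required criterion drop to accept a step
#'   (default 2).
#' @param start starting EDF triple; default `c(L = 0, M = 1, S = 1)`
#'   (identity transform, constant median, constant variation).
#' @param multi_pass if `FALSE` (default) a curve whose increment was
#'   rejected is frozen for the remainder of the search; if `TRUE` it may
#'   be retried after other curves change.
#' @return a list of class `selection_policy`.
#' @export
selection_policy <- function(order = c("M", "S", "L"), edf_cap = 2,
                             criterion = c("SBC", "AIC", "GAIC3"),
                             min_improvement = 2,
                             start = c(L = 0, M = 1, S = 1),
                             multi_pass = FALSE) {
  criterion <- match.arg(criterion)
  stopifnot(all(order %in% c("L", "M", "S")), !anyDuplicated(order),
            edf_cap >= 1, min_improvement >= 0)
  start <- check_edf(start)
  if (any(start[c("M", "S")] > edf_cap) || start[["L"]] > edf_cap)
    stop("starting EDFs exceed the cap", call. = FALSE)
  structure(list(order = order, edf_cap = edf_cap, criterion = criterion,
                 min_improvement = min_improvement, start = start,
                 multi_pass = multi_pass),
            class = "selection_policy")
}

crit_value <- function(fit, criterion) {
  switch(criterion, SBC = fit$sbc, AIC = fit$aic, GAIC3 = fit$gaic3)
}

#' Sequential EDF search for the LMS model
#'
#' Starting from the simplest model (`a_L = 0, a_M = 1, a_S = 1`), the
#' search increments one curve's EDF at a time in the policy order and
#' refits (warm-starting from the current accepted model).  An increment is
#' accepted when the criterion improves by more than the policy threshold;
#' a rejected curve is frozen; a non-converged refit is skipped and retried
#' after another curve has changed (so a more complex model can become
#' fittable once a neighbouring curve has been freed, which is commonly
#' needed in practice).  The search stops when no increment is accepted in
#' a full pass or all caps are reached.  A warning is issued if the
#' accepted triple violates the `a_M >= a_S >= a_L` rule of thumb.
#'
#' @param data data.frame with `age` and `score` (see [fit_lms()]).
#' @param policy a [selection_policy()].
#' @param weights optional sampling weights passed to every refit.
#' @param ... further arguments (e.g. `shift`, `control`) for [fit_lms()].
#' @return list with elements `fit` (the selected `lms_fit`) and `trace`
#'   (a `selection_trace` recording every attempted triple, its criterion
#'   value, the change over the previously accepted model, and the
#'   converged / accepted flags).
#' @export
sequential_search <- function(data, policy = selection_policy(),
                              weights = NULL, ...) {
  stopifnot(inherits(policy, "selection_policy"))
  edf <- policy$start
  current <- fit_lms(data, edf, weights = weights, ...)
  if (!current$converged)
    stop("the starting model (a_L=", edf[["L"]], ", a_M=", edf[["M"]],
         ", a_S=", edf[["S"]], ") did not converge after ",
         current$iterations, " cycles; global deviance ",
         format(current$global_deviance),
         " - inspect the data before searching further", call. = FALSE)
  cur_crit <- crit_value(current, policy$criterion)
  trace <- data.frame(a_L = edf[["L"]], a_M = edf[["M"]], a_S = edf[["S"]],
                      criterion = cur_crit, delta = NA_real_,
                      converged = TRUE, accepted = TRUE)
  frozen <- c(L = FALSE, M = FALSE, S = FALSE)
  repeat {
    accepted_this_pass <- FALSE
    for (cv in policy$order) {
      if (frozen[[cv]]) next
      cand <- edf
      cand[[cv]] <- cand[[cv]] + 1
      if (cand[[cv]] > policy$edf_cap) { frozen[[cv]] <- TRUE; next }
      fit <- tryCatch(
        fit_lms(data, cand, weights = weights, start = current, ...),
        error = function(e) NULL)
      if (is.null(fit) || !fit$converged) {
        # skip for now; retried on a later pass after other curves move
        trace <- rbind(trace, data.frame(
          a_L = cand[["L"]], a_M = cand[["M"]], a_S = cand[["S"]],
          criterion = if (is.null(fit)) NA_real_
                      else crit_value(fit, policy$criterion),
          delta = NA_real_, converged = FALSE, accepted = FALSE))
        next
      }
      val <- crit_value(fit, policy$criterion)
      delta <- val - cur_crit
      accept <- is.finite(delta) && -delta >= policy$min_improvement
      trace <- rbind(trace, data.frame(
        a_L = cand[["L"]], a_M = cand[["M"]], a_S = cand[["S"]],
        criterion = val, delta = delta, converged = TRUE, accepted = accept))
      if (accept) {
        edf <- cand; current <- fit; cur_crit <- val
        accepted_this_pass <- TRUE
      } else if (!policy$multi_pass) {
        frozen[[cv]] <- TRUE
      }
    }
    if (!accepted_this_pass || all(frozen)) break
  }
  if (!(edf[["M"]] >= edf[["S"]] && edf[["S"]] >= edf[["L"]]))
    warning(sprintf(
      "selected EDFs (a_L=%g, a_M=%g, a_S=%g) violate the a_M >= a_S >= a_L rule of thumb",
      edf[["L"]], edf[["M"]], edf[["S"]]), call. = FALSE)
  class(trace) <- c("selection_trace", "data.frame")
  attr(trace, "criterion") <- policy$criterion
  list(fit = current, trace = trace)
}

#' Tabular report of a selection trace
#'
#' Formats the sequential optimisation trace the way reference-construction
#' reports usually print it: criterion value, the three EDFs and the change
#' in criterion for each accepted step; rejected and non-converged attempts
#' are flagged and carry no difference entry.
#'
#' @param trace a `selection_trace` from [sequential_search()].
#' @return data.frame with columns `criterion`, `a_L`, `a_M`, `a_S`,
#'   `difference` (formatted), `status`.
#' @export
trace_to_table <- function(trace) {
  stopifnot(inherits(trace, "selection_trace"), nrow(trace) > 0)
  status <- ifelse(!trace$converged, "did not converge",
                   ifelse(trace$accepted, "accepted", "rejected"))
  diff_chr <- ifelse(is.na(trace$delta) | !trace$converged, "-",
                     sprintf("%+.1f", trace$delta))
  diff_chr[1] <- "-"
  out <- data.frame(criterion = round(trace$criterion, 1),
                    a_L = trace$a_L, a_M = trace$a_M, a_S = trace$a_S,
                    difference = diff_chr, status = status)
  attr(out, "criterion") <- attr(trace, "criterion")
  out
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("Sequential EDF optimisation trace (criterion:",
      attr(x, "criterion"), ")\n")
  print(trace_to_table(x), row.names = FALSE)
  invisible(x)
}
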