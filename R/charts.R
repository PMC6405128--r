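#' Default centile levels for reference charts
#'
#' The conventional seven chart centiles: 3rd, 10th, 25th, 50th, 75th, 90th
#' and 97th.
#' @export
default_centile_levels <- function() c(0.03, 0.10, 0.25, 0.50, 0.75, 0.90, 0.97)

#' Centile chart table from fitted LMS curves
#'
#' Evaluates the centile formula `C_a(t) = M(t) * (1 + L(t) S(t) z_a)^(1/L(t))`
#' over an age grid and a set of centile levels, and un-shifts the values
#' back to the instrument's raw-score scale.  At any age the columns are
#' strictly increasing in the level: LMS centile curves cannot cross.
#'
#' @param curves an [lms_curves], `lms_fit` or `lms_model` object.
#' @param ages age grid in months; defaults to monthly steps over the
#'   fitted domain.
#' @param levels centile levels as lower tail areas in (0, 1).
#' @return a data.frame of class `centile_table` with column `age` and one
#'   column per level (`p3`, `p10`, ...).  Cells whose level falls outside
#'   the support of the local transform are set `NA` and collected in the
#'   `"errors"` attribute (with a warning), never returned as silent `NaN`.
#' @export
build_centile_table <- function(curves, ages = NULL,
                                levels = default_centile_levels()) {
  if (inherits(curves, "lms_fit")) curves <- curves$curves
  if (inherits(curves, "lms_model")) curves <- model_curves(curves)
  stopifnot(inherits(curves, "lms_curves"))
  if (is.null(ages)) {
    rng <- curves$age_range
    ages <- seq(rng[1], rng[2], by = 1)
    if (ages[length(ages)] < rng[2]) ages <- c(ages, rng[2])
  }
  if (any(diff(levels) <= 0) || any(levels <= 0) || any(levels >= 1))
    stop("levels must be strictly increasing lower tail areas in (0, 1)",
         call. = FALSE)
  v <- eval_curves(curves, ages)
  za <- centile_deviate(levels)
  out <- data.frame(age = ages)
  errors <- NULL
  for (j in seq_along(levels)) {
    core <- 1 + v$L * v$S * za[j]
    bad <- abs(v$L) > .eps_L & core <= 0
    val <- rep(NA_real_, length(ages))
    val[!bad] <- ifelse(abs(v$L[!bad]) > .eps_L,
                        v$M[!bad] * core[!bad]^(1 / v$L[!bad]),
                        v$M[!bad] * exp(v$S[!bad] * za[j]))
    if (any(bad))
      errors <- rbind(errors, data.frame(age = ages[bad], level = levels[j],
                                         reason = "level outside transform support"))
    out[[sprintf("p%g", 100 * levels[j])]] <- val - curves$shift
  }
  if (!is.null(errors))
    warning(nrow(errors), " centile cell(s) fall outside the transform ",
            "support; set to NA (see attr(., 'errors'))", call. = FALSE)
  structure(out, levels = levels, shift = curves$shift, errors = errors,
            class = c("centile_table", "data.frame"))
}

#' Q-test goodness of fit for LMS standardised scores
#'
#' Checks that the model-implied z-scores behave like standard normal draws
#' within age bins: per bin, standardized tests of mean 0, variance 1
#' (Wilson-Hilferty transform of the chi-square) and zero skewness, combined
#' into an overall chi-square statistic on 3 x (number of bins) degrees of
#' freedom.  With sampling weights, weighted moments are used with the
#' effective sample size `(sum w)^2 / sum(w^2)`.
#'
#' @param data data.frame with `age` and `score` columns.
#' @param curves fitted or true [lms_curves] (or an `lms_fit`).
#' @param weights optional sampling weights.
#' @param alpha overall test level.
#' @param min_bin minimum observations per age bin; bins are merged below it.
#' @param min_bins intended minimum number of bins; a note is recorded when
#'   the data cannot support that many.
#' @return an object of class `q_test_report`: per-bin table, overall
#'   statistic, degrees of freedom, p-value and rejection flag.
#' @export
q_test <- function(data, curves, weights = NULL, alpha = 0.05,
                   min_bin = 20, min_bins = 5) {
  stopifnot(is.data.frame(data))
  if (nrow(data) == 0) stop("no observations to test", call. = FALSE)
  z <- standard_scores(curves, data$age, data$score, extrapolate = TRUE)
  n <- length(z)
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  stopifnot(length(w) == n, all(w > 0))
  G <- max(1, min(10, floor(n / min_bin)))
  note <- NULL
  if (G < min_bins)
    note <- sprintf("only %d age bin(s) supportable with >= %d observations each; bins merged",
                    G, min_bin)
  br <- unique(stats::quantile(data$age, probs = seq(0, 1, length.out = G + 1)))
  if (length(br) < 2) br <- range(data$age) + c(-1e-9, 1e-9)
  bin <- cut(data$age, breaks = br, include.lowest = TRUE)
  tab <- do.call(rbind, lapply(levels(bin), function(b) {
    i <- bin == b
    zi <- z[i]; wi <- w[i] / mean(w[i])
    ni <- (sum(wi))^2 / sum(wi^2)  # effective n (equals count when unweighted)
    m1 <- sum(wi * zi) / sum(wi)
    m2 <- sum(wi * (zi - m1)^2) / sum(wi)
    m3 <- sum(wi * (zi - m1)^3) / sum(wi)
    s2 <- m2 * ni / max(ni - 1, 1)
    u_mean <- sqrt(ni) * m1
    df <- max(ni - 1, 1)
    u_var <- ((s2)^(1 / 3) - (1 - 2 / (9 * df))) / sqrt(2 / (9 * df))
    b1 <- m3 / m2^(3 / 2)
    se_skew <- sqrt(6 * ni * (ni - 1) / ((ni - 2) * (ni + 1) * (ni + 3)))
    u_skew <- b1 / se_skew
    data.frame(bin = b, n = sum(i), n_eff = ni, mean = m1, var = s2,
               skew = b1, u_mean = u_mean, u_var = u_var, u_skew = u_skew)
  }))
  crit <- stats::qnorm(1 - alpha / 2)
  tab$flag_mean <- abs(tab$u_mean) > crit
  tab$flag_var <- abs(tab$u_var) > crit
  tab$flag_skew <- abs(tab$u_skew) > crit
  Q <- sum(tab$u_mean^2 + tab$u_var^2 + tab$u_skew^2)
  df_tot <- 3 * nrow(tab)
  p <- stats::pchisq(Q, df_tot, lower.tail = FALSE)
  structure(list(table = tab, statistic = Q, df = df_tot, p_value = p,
                 reject = p < alpha, alpha = alpha, n = n, note = note),
            class = "q_test_report")
}

#' @export
print.q_test_report <- function(x, ...) {
  cat(sprintf("Q-test for fit: Q = %.2f on %d df, p = %.4g (%s at level %g)\n",
              x$statistic, x$df, x$p_value,
              if (x$reject) "REJECTED" else "not rejected", x$alpha))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  print(x$table, digits = 3, row.names = FALSE)
  invisible(x)
}

ks_distance <- function(a, b) {
  allv <- sort(unique(c(a, b)))
  Fa <- stats::ecdf(a)(allv); Fb <- stats::ecdf(b)(allv)
  max(abs(Fa - Fb))
}

#' Compare weighted and unweighted fits against a full-population fit
#'
#' The sample-design demonstration: standard scores of a shared evaluation
#' dataset are computed under a fit to the full population, a weighted fit
#' to a stratified subsample and an unweighted fit to the same subsample.
#' Reports how far the z-score distributions of the two subsample fits sit
#' from the population fit's (Kolmogorov-Smirnov and 1-Wasserstein), plus a
#' density grid export for plotting.  A properly weighted fit should sit
#' closer than the unweighted one.
#'
#' @param population_fit,weighted_fit,unweighted_fit `lms_fit` objects (or
#'   curve objects) over essentially the same age domain.
#' @param eval_data data.frame with `age` and `score` used for evaluation.
#' @return object of class `weight_comparison` with elements `ks`,
#'   `wasserstein` (each named `weighted` / `unweighted`) and `densities`.
#' @export
compare_weighted_unweighted <- function(population_fit, weighted_fit,
                                        unweighted_fit, eval_data) {
  get_curves <- function(f) {
    if (inherits(f, "lms_fit")) f$curves
    else if (inherits(f, "lms_model")) model_curves(f)
    else f
  }
  cs <- lapply(list(population_fit, weighted_fit, unweighted_fit), get_curves)
  rngs <- vapply(cs, function(c) c$age_range, numeric(2))
  overlap <- c(max(rngs[1, ]), min(rngs[2, ]))
  span <- max(rngs[2, ]) - min(rngs[1, ])
  if (diff(overlap) < 0.9 * span)
    stop("fitted age domains differ too much to compare (",
         "shared overlap covers less than 90% of the union)", call. = FALSE)
  zs <- lapply(cs, function(c)
    standard_scores(c, eval_data$age, eval_data$score, extrapolate = TRUE))
  names(zs) <- c("population", "weighted", "unweighted")
  ks <- c(weighted = ks_distance(zs$weighted, zs$population),
          unweighted = ks_distance(zs$unweighted, zs$population))
  wass <- c(weighted = mean(abs(sort(zs$weighted) - sort(zs$population))),
            unweighted = mean(abs(sort(zs$unweighted) - sort(zs$population))))
  grid <- seq(-4, 4, length.out = 161)
  dens <- function(z) stats::density(z, from = -4, to = 4, n = 161)$y
  structure(list(
    ks = ks, wasserstein = wass,
    densities = data.frame(z = grid,
                           population = dens(zs$population),
                           weighted = dens(zs$weighted),
                           unweighted = dens(zs$unweighted)),
    n_eval = nrow(eval_data)
  ), class = "weight_comparison")
}

#' @export
print.weight_comparison <- function(x, ...) {
  cat("Weighted vs unweighted subsample fits, distance from population fit\n")
  cat(sprintf("  KS:          weighted %.4f  unweighted %.4f\n",
              x$ks[["weighted"]], x$ks[["unweighted"]]))
  cat(sprintf("  Wasserstein: weighted %.4f  unweighted %.4f\n",
              x$wasserstein[["weighted"]], x$wasserstein[["unweighted"]]))
  cat(sprintf("  (evaluated on %d records; smaller = closer to population)\n",
              x$n_eval))
  invisible(x)
}
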