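#' @keywords internal
"_PACKAGE"

# Switch threshold below which the Box-Cox power is treated as zero.
# The continuity error of the log branch is O(L * log^2(y/M)), negligible here.
.eps_L <- 1e-8

#' Box-Cox transform of a raw score about its median
#'
#' Transforms a positive raw score `y` to the variable
#' `w = ((y/M)^L - 1) / L` (or `log(y/M)` when `L` is numerically zero),
#' which maps the median `M` to exactly 0.  This is the skew-correcting core
#' of the LMS standardisation model.
#'
#' @param y positive raw score(s); apply a positivity shift first if the
#'   instrument admits zeros (see [suggest_shift()]).
#' @param L Box-Cox power (dimensionless, any finite sign).
#' @param M median of the raw score distribution; must be positive.
#' @return numeric vector of transformed values `w`, zero where `y == M`.
#' @seealso [raw_to_z()], [z_to_raw()]
#' @examples
#' box_cox_w(20, L = 1, M = 10)     # 1
#' box_cox_w(14.4, L = 0.5, M = 10) # 0.4
#' @export
box_cox_w <- function(y, L, M) {
  check_lms_point(L, M, S = NULL)
  if (any(!is.finite(y)) || any(y <= 0)) {
    bad <- y[!is.finite(y) | y <= 0][1]
    stop("raw score must be strictly positive, got ", format(bad),
         "; add a positivity shift (e.g. offset 1) before transforming",
         call. = FALSE)
  }
  n <- max(length(y), length(L), length(M))
  y <- rep_len(y, n); L <- rep_len(L, n); M <- rep_len(M, n)
  w <- ifelse(abs(L) > .eps_L,
              ((y / M)^L - 1) / L,
              log(y / M))
  w
}

#' Skew-corrected z-score of a raw score
#'
#' Standardises a positive raw score to `z = ((y/M)^L - 1) / (S * L)`
#' (`log(y/M)/S` at `L = 0`).  Under the LMS model `z` is standard normal
#' at every age, so it is directly comparable across ages.
#'
#' @inheritParams box_cox_w
#' @param S generalised coefficient of variation; must be positive.
#' @return numeric z-score(s); 0 exactly where `y == M`.
#' @examples
#' raw_to_z(14.4, L = 0.5, M = 10, S = 0.2) # 2
#' @export
raw_to_z <- function(y, L, M, S) {
  check_lms_point(L, M, S)
  box_cox_w(y, L, M) / S
}

#' Invert a z-score to the raw-score scale
#'
#' Computes `M * (1 + L*S*z)^(1/L)` (`M * exp(S*z)` at `L = 0`), the exact
#' inverse of [raw_to_z()] on its support.  For `L != 0` the transform only
#' reaches z-values with `1 + L*S*z > 0`; outside that range the centile is
#' undefined and an error is raised (no silent clamping, which would corrupt
#' extreme centiles).
#'
#' @param z z-score(s).
#' @inheritParams raw_to_z
#' @return positive raw-score value(s).
#' @export
z_to_raw <- function(z, L, M, S) {
  check_lms_point(L, M, S)
  n <- max(length(z), length(L), length(M), length(S))
  z <- rep_len(z, n); L <- rep_len(L, n); M <- rep_len(M, n); S <- rep_len(S, n)
  core <- 1 + L * S * z
  off <- abs(L) > .eps_L & core <= 0
  if (any(off)) {
    i <- which(off)[1]
    lim <- -1 / (L[i] * S[i])
    rng <- if (L[i] > 0) sprintf("z > %.4f", lim) else sprintf("z < %.4f", lim)
    stop("z = ", format(z[i]), " is outside the support of the transform for ",
         sprintf("L = %.4g, S = %.4g (attainable range: %s)", L[i], S[i], rng),
         call. = FALSE)
  }
  ifelse(abs(L) > .eps_L, M * core^(1 / L), M * exp(S * z))
}

#' Normal equivalent deviate of a centile level
#'
#' The standard-normal quantile `z_a` at lower tail area `a`; e.g. the 75th
#' centile (`a = 0.75`) has deviate 0.675 (3 dp).
#'
#' @param a centile level(s) as lower tail areas in (0, 1).
#' @return numeric deviate(s).
#' @export
centile_deviate <- function(a) {
  if (any(!is.finite(a)) || any(a <= 0) || any(a >= 1))
    stop("centile levels must lie strictly inside (0, 1)", call. = FALSE)
  stats::qnorm(a)
}

#' Raw-score value of a centile
#'
#' `C_a = M * (1 + L*S*z_a)^(1/L)`: the raw score below which a fraction `a`
#' of the reference population falls, given the local LMS parameters.
#'
#' @inheritParams centile_deviate
#' @inheritParams raw_to_z
#' @return positive raw-score value(s) of the centile.
#' @export
centile_value <- function(a, L, M, S) {
  z_to_raw(centile_deviate(a), L, M, S)
}

#' Map a z-score to its centile
#'
#' @param z z-score(s).
#' @return lower tail area `pnorm(z)` in (0, 1).
#' @export
z_to_centile <- function(z) stats::pnorm(z)

#' Centile of a raw score under local LMS parameters
#'
#' @inheritParams raw_to_z
#' @return lower tail area in (0, 1).
#' @export
centile_of_raw <- function(y, L, M, S) z_to_centile(raw_to_z(y, L, M, S))

#' Suggest a positivity shift for scores that include zero
#'
#' The Box-Cox transform requires strictly positive scores.  Instruments
#' whose range starts at 0 (e.g. a 0-39 communication screen) need a constant
#' offset added first; the conventional choice is 1, making the range 1-40.
#'
#' @param y raw scores.
#' @return 0 if all scores are already positive, otherwise 1.
#' @export
suggest_shift <- function(y) {
  y <- y[is.finite(y)]
  if (length(y) && min(y) <= 0) 1 else 0
}

check_lms_point <- function(L, M, S) {
  if (any(!is.finite(L)))
    stop("Box-Cox power L must be finite", call. = FALSE)
  if (any(!is.finite(M)) || any(M <= 0))
    stop("median M must be positive and finite", call. = FALSE)
  if (!is.null(S) && (any(!is.finite(S)) || any(S <= 0)))
    stop("coefficient of variation S must be positive and finite", call. = FALSE)
  invisible(TRUE)
}
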