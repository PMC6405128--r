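# Synthetic two-phase cohort generator with known LMS ground truth.
# Every pipeline stage (fitting, model selection, weighting, charting) can
# be exercised against the generating curves without any external data.

substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.double(seed) %% 65011 * 33029 + h * 2063) %% 2147483629) + 1L
}

#' Ground-truth configuration for the synthetic cohort
#'
#' @param curves an [lms_curves] object: the generating `L(t)`, `M(t)`,
#'   `S(t)` triple (on the shifted score scale when `curves$shift > 0`).
#' @param n number of children to generate.
#' @param score_bounds closed instrument range on the raw-score scale.
#' @param age_window months window ages are drawn uniformly from; defaults
#'   to the curves' age domain.
#' @param floor_mass probability mass remapped to the minimum score,
#'   emulating instruments with a large mode at the floor (a screen where
#'   most children have no difficulties); 0 disables it.
#' @param round round generated scores to integers and clamp them to
#'   `score_bounds` (real instruments are integer-scored); `FALSE` keeps
#'   exact continuous scores for transform-level checks.
#' @param label measure name carried through outputs.
#' @return list of class `truth_config`.
#' @export
truth_config <- function(curves, n, score_bounds, age_window = NULL,
                         floor_mass = 0, round = TRUE, label = "measure") {
  stopifnot(inherits(curves, "lms_curves"), n >= 0,
            length(score_bounds) == 2, score_bounds[1] < score_bounds[2],
            floor_mass >= 0, floor_mass < 1)
  if (is.null(age_window)) age_window <- curves$age_range
  stopifnot(age_window[1] >= curves$age_range[1] - 1e-9,
            age_window[2] <= curves$age_range[2] + 1e-9)
  structure(list(curves = curves, n = as.integer(n),
                 score_bounds = score_bounds, age_window = age_window,
                 floor_mass = floor_mass, round = round, label = label),
            class = "truth_config")
}

#' Default screen-instrument truth (communication checklist style)
#'
#' A 0-39 teacher screen where higher scores mean worse language, scored on
#' ages 57-70 months, with a large mode at 0 and strong right skew.  The
#' generating curves are calibrated to the published reference behaviour of
#' such screens: the median falls from about 11 to about 4 across the age
#' window, the 97th centile falls much more slowly (about 40 to about 36),
#' the skewness power decreases and the coefficient of variation increases
#' roughly linearly with age.  Scores require a +1 positivity shift before
#' Box-Cox transformation.
#'
#' @param n cohort size; default 6459, a full screened population.
#' @param floor_mass mass remapped to score 0; default 0.15.
#' @param ... overrides passed to [truth_config()].
#' @return a `truth_config`.
#' @export
screen_truth <- function(n = 6459, floor_mass = 0.15, ...) {
  curves <- lms_curves(
    L = function(t) 0.5 - 0.0477 * (t - 57),
    M = function(t) 12 - 0.538 * (t - 57),
    S = function(t) 0.85 + 0.0077 * (t - 57),
    age_range = c(57, 70), shift = 1)
  truth_config(curves, n = n, score_bounds = c(0, 39),
               floor_mass = floor_mass, label = "screen", ...)
}

#' Default intensive-test truth (expressive vocabulary style)
#'
#' A 0-190 expressive vocabulary test whose median rises and whose
#' coefficient of variation falls with age, with mild constant skewness.
#' Calibrated to typical cohort moments: mean (SD) about 74.5 (15.8) at a
#' first assessment wave (ages 61-82 months) and 91.3 (15.6) at a second
#' (ages 85-111 months).
#'
#' @param wave `"year1"`, `"year3"` or `"pooled"` (sets the age window).
#' @param n children generated.
#' @param ... overrides passed to [truth_config()].
#' @return a `truth_config`.
#' @export
vocab_truth <- function(wave = c("pooled", "year1", "year3"), n = 636, ...) {
  wave <- match.arg(wave)
  curves <- lms_curves(
    L = 1.3,
    M = function(t) 74.5 + 0.634 * (t - 71.5),
    S = function(t) 0.212 - 0.00155 * (t - 71.5),
    age_range = c(61, 111), shift = 0)
  window <- switch(wave, year1 = c(61, 82), year3 = c(85, 111),
                   pooled = c(61, 111))
  truth_config(curves, n = n, score_bounds = c(0, 190), age_window = window,
               label = paste0("vocabulary_", wave), ...)
}

# Draw scores from the generating LMS distribution at given ages.
# z draws are truncated to the transform support (the distribution is a
# truncated Box-Cox normal); the instrument floor/ceiling then clamps.
draw_scores <- function(cfg, age, z) {
  v <- eval_curves(cfg$curves, age)
  lim <- -1 / (v$L * v$S)
  z <- ifelse(abs(v$L) > .eps_L & v$L > 0, pmax(z, lim * (1 - 1e-9)),
              ifelse(abs(v$L) > .eps_L & v$L < 0, pmin(z, lim * (1 - 1e-9)), z))
  y <- z_to_raw(z, v$L, v$M, v$S)
  raw <- y - cfg$curves$shift
  if (cfg$floor_mass > 0)
    raw[z < stats::qnorm(cfg$floor_mass)] <- cfg$score_bounds[1]
  if (cfg$round)
    raw <- pmin(pmax(round(raw), cfg$score_bounds[1]), cfg$score_bounds[2])
  raw
}

#' Generate a synthetic screened population
#'
#' Draws ages uniformly over the configured window, samples scores from the
#' generating LMS distribution (standard-normal z mapped through the true
#' curves, truncated to the transform support, optionally floored, rounded
#' and clamped), and attaches simple school and family covariates:
#' school membership and size, income deprivation (standard normal),
#' percent girls, special-educational-needs / free-school-meals /
#' additional-language flags and a phonics-screen count.  Covariate
#' distributions aim at statistical structure, not demographic realism.
#'
#' @param cfg a [truth_config()].
#' @param seed optional integer; a named substream derived from it makes
#'   the output fully reproducible.
#' @return data.frame with one row per child: `child_id`, `age`, `score`,
#'   `sex`, `school_id`, `school_n_screened`, `school_size`, `pct_girls`,
#'   `income_deprivation`, `sen`, `fsm`, `eal`, `phonics_n`.
#' @export
generate_population <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "truth_config"))
  if (!is.null(seed)) set.seed(substream_seed(seed, "population"))
  n <- cfg$n
  if (n == 0) {
    out <- data.frame(child_id = integer(0), age = numeric(0),
                      score = numeric(0), sex = character(0),
                      school_id = integer(0), school_n_screened = integer(0),
                      school_size = integer(0), pct_girls = numeric(0),
                      income_deprivation = numeric(0), sen = integer(0),
                      fsm = integer(0), eal = integer(0),
                      phonics_n = integer(0))
    attr(out, "truth") <- cfg
    return(out)
  }
  age <- stats::runif(n, cfg$age_window[1], cfg$age_window[2])
  z <- stats::rnorm(n)
  score <- draw_scores(cfg, age, z)
  n_schools <- max(1L, round(n / 110))
  school_n <- round(stats::runif(n_schools, 40, 180))
  school_id <- sample.int(n_schools, n, replace = TRUE)
  out <- data.frame(
    child_id = seq_len(n),
    age = age,
    score = score,
    sex = sample(c("M", "F"), n, replace = TRUE),
    school_id = school_id,
    school_n_screened = school_n[school_id],
    school_size = round(school_n[school_id] * stats::runif(n, 1.1, 1.6)),
    pct_girls = pmin(pmax(stats::rnorm(n, 0.5, 0.05), 0.2), 0.8),
    income_deprivation = stats::rnorm(n),
    sen = stats::rbinom(n, 1, 0.12),
    fsm = stats::rbinom(n, 1, 0.15),
    eal = stats::rbinom(n, 1, 0.05),
    phonics_n = round(school_n[school_id] * stats::runif(n, 0.8, 1)))
  attr(out, "truth") <- cfg
  out
}

#' Two-phase sampling design configuration
#'
#' @param risk_threshold screen score at or above which a child is flagged
#'   high risk.  The default (20) makes roughly 15% of the default screen
#'   population high risk, so that with the default sampling fractions the
#'   expected intensive subsample is about 10% of a screened population.
#' @param sampling_fractions named selection probabilities by risk stratum
#'   and sex: `high_M`, `high_F`, `low_M`, `low_F`; defaults 0.405, 0.375,
#'   0.043, 0.042 (high-risk children heavily oversampled).
#' @param response_coef named logistic coefficients for complete-data
#'   response given selection; names must be `"(Intercept)"` or covariate
#'   columns of the population.
#' @param forced_inclusion number of always-selected children (the most
#'   impaired scorers, e.g. children with no phrase speech); they enter
#'   with selection probability 1.
#' @return list of class `design_config`.
#' @export
design_config <- function(risk_threshold = 20,
                          sampling_fractions = c(high_M = 0.405,
                                                 high_F = 0.375,
                                                 low_M = 0.043,
                                                 low_F = 0.042),
                          response_coef = c(`(Intercept)` = 1.8,
                                            income_deprivation = -0.45,
                                            fsm = -0.9),
                          forced_inclusion = 48) {
  stopifnot(all(c("high_M", "high_F", "low_M", "low_F") %in%
                  names(sampling_fractions)),
            all(sampling_fractions > 0), all(sampling_fractions <= 1),
            forced_inclusion >= 0)
  structure(list(risk_threshold = risk_threshold,
                 sampling_fractions = sampling_fractions,
                 response_coef = response_coef,
                 forced_inclusion = as.integer(forced_inclusion)),
            class = "design_config")
}

#' Apply two-phase selection and response to a population
#'
#' Flags risk from the screen score, selects children into the intensive
#' phase by Bernoulli draws at the stratum-specific sampling fractions
#' (with the worst `forced_inclusion` scorers always selected), and then
#' draws complete-data response from the logistic response model.  True
#' inclusion probabilities are returned alongside the flags so that
#' estimated inverse probability weights can be validated against truth.
#'
#' @param population data.frame from [generate_population()].
#' @param design a [design_config()].
#' @param seed optional integer seed (substream `"two_phase"`).
#' @return the population with added columns `risk_flag`, `p1_true`,
#'   `selected`, `p2_true`, `complete`.
#' @export
apply_two_phase <- function(population, design = design_config(),
                            seed = NULL) {
  stopifnot(inherits(design, "design_config"), is.data.frame(population))
  if (!is.null(seed)) set.seed(substream_seed(seed, "two_phase"))
  n <- nrow(population)
  risk <- as.integer(population$score >= design$risk_threshold)
  stratum <- paste0(ifelse(risk == 1, "high", "low"), "_", population$sex)
  for (s in c("high_M", "high_F", "low_M", "low_F"))
    if (n > 0 && !any(stratum == s))
      warning("empty stratum: ", s, call. = FALSE)
  p1 <- unname(design$sampling_fractions[stratum])
  if (design$forced_inclusion > 0 && n > 0) {
    worst <- order(population$score, decreasing = TRUE)
    p1[worst[seq_len(min(design$forced_inclusion, n))]] <- 1
  }
  selected <- stats::runif(n) < p1
  cf <- design$response_coef
  eta <- rep(unname(cf["(Intercept)"]), n)
  for (nm in setdiff(names(cf), "(Intercept)")) {
    if (!nm %in% names(population))
      stop("response model covariate not in population: ", nm, call. = FALSE)
    eta <- eta + cf[[nm]] * as.numeric(population[[nm]])
  }
  p2 <- stats::plogis(eta)
  complete <- selected & (stats::runif(n) < p2)
  population$risk_flag <- risk
  population$p1_true <- p1
  population$selected <- selected
  population$p2_true <- p2
  population$complete <- complete
  population
}

#' Pooled two-wave assessment table
#'
#' Generates intensive-test scores for the same children at two assessment
#' waves (e.g. Year 1 and Year 3) and stacks them in long format, treating
#' the repeated measurements as cross-sectional records.  A fraction of
#' children (default 95%) is retained at the second wave.
#'
#' @param population data.frame of children (unique `child_id` required);
#'   a `weight` column, if present, is carried through.
#' @param cfg_year1,cfg_year3 [truth_config()]s for the two waves; the
#'   second wave's median should exceed the first's where windows meet.
#' @param retention probability a child is reassessed at the second wave.
#' @param seed optional integer seed (substream `"two_wave"`).
#' @return long data.frame with columns `child_id`, `wave`, `age`, `score`
#'   (plus `sex` and `weight` when available in `population`).
#' @export
make_two_wave <- function(population, cfg_year1 = vocab_truth("year1"),
                          cfg_year3 = vocab_truth("year3"),
                          retention = 0.95, seed = NULL) {
  stopifnot(is.data.frame(population), retention > 0, retention <= 1)
  if (anyDuplicated(population$child_id))
    stop("duplicate child_id in population; one row per child is required",
         call. = FALSE)
  if (!is.null(seed)) set.seed(substream_seed(seed, "two_wave"))
  n <- nrow(population)
  carry <- intersect(c("child_id", "sex", "weight"), names(population))
  one_wave <- function(cfg, ids, wave) {
    m <- length(ids)
    age <- stats::runif(m, cfg$age_window[1], cfg$age_window[2])
    score <- draw_scores(cfg, age, stats::rnorm(m))
    cbind(population[ids, carry, drop = FALSE],
          data.frame(wave = wave, age = age, score = score))
  }
  w1 <- one_wave(cfg_year1, seq_len(n), "year1")
  keep <- which(stats::runif(n) < retention)
  w3 <- one_wave(cfg_year3, keep, "year3")
  out <- rbind(w1, w3)
  rownames(out) <- NULL
  if (anyDuplicated(out[c("child_id", "wave")]))
    stop("duplicate (child, wave) rows generated", call. = FALSE)
  out
}
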