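test_that("log-likelihood contribution matches the Box-Cox-normal density", {
  # at the median with unit CV every term vanishes
  for (L in c(-1, 0, 0.5, 2))
    expect_equal(loglik_contribution(10, L, 10, 1), 0)
  # quadrature oracle: adding back the data-only constants, the implied
  # density integrates to one
  dens <- function(y) exp(loglik_contribution(y, 0.5, 10, 0.2)) /
    (y * sqrt(2 * pi))
  expect_equal(stats::integrate(dens, 1e-3, 500, rel.tol = 1e-9)$value, 1,
               tolerance = 1e-3)
  # weighted-likelihood linearity
  expect_equal(loglik_contribution(12, 0.5, 10, 0.2, weight = 2),
               2 * loglik_contribution(12, 0.5, 10, 0.2))
})

test_that("deviance criteria follow their closed forms", {
  cr <- deviance_criteria(100, k = 5, n = 100)
  expect_equal(round(cr$sbc, 3), 123.026)  # 100 + 5 log(100)
  expect_equal(cr$aic, 110)
  expect_equal(cr$gaic3, 115)
})

test_that("constant-parameter truth is recovered at the generating EDFs", {
  d <- sim_records(null_truth_curves(), n = 5000, seed = 1)
  f <- fit_lms(d, edf = c(L = 0, M = 1, S = 1))
  expect_true(f$converged)
  v <- eval_curves(f$curves, 40)
  expect_lt(abs(v$M - 50) / 50, 0.01)
  expect_lt(abs(v$S - 0.1) / 0.1, 0.05)
  expect_identical(v$L, 1)          # a_L = 0 fixes the power at 1
  expect_equal(f$edf_realized[["L"]], 0)
})

test_that("a linear median trend is recovered within 10%", {
  d <- sim_records(linear_truth_curves(), n = 5000, seed = 2)
  f <- fit_lms(d, edf = c(L = 0, M = 2, S = 1))
  rng <- range(d$age)
  v <- eval_curves(f$curves, rng)
  slope <- diff(v$M) / diff(rng)
  expect_lt(abs(slope - 0.5) / 0.5, 0.10)
})

test_that("fitted curves self-standardise the training data", {
  tr <- lms_curves(L = function(t) 0.8 - 0.01 * t,
                   M = function(t) 30 + 0.4 * t,
                   S = function(t) 0.2 - 0.001 * t, age_range = c(20, 60))
  d <- sim_records(tr, n = 3000, seed = 3)
  f <- fit_lms(d, edf = c(L = 2, M = 2, S = 2))
  expect_true(f$converged)
  z <- standard_scores(f, d$age, d$score)
  expect_lt(abs(mean(z)), 0.1)
  expect_gt(stats::sd(z), 0.9); expect_lt(stats::sd(z), 1.1)
  # recovery of the generating median over the central 90% of ages
  grid <- seq(stats::quantile(d$age, 0.05), stats::quantile(d$age, 0.95),
              length.out = 50)
  rel <- abs(eval_curves(f$curves, grid)$M - eval_curves(tr, grid)$M) /
    eval_curves(tr, grid)$M
  expect_lt(max(rel), 0.05)
})

test_that("realised smoother traces honour the requested EDFs", {
  tr <- lms_curves(L = 0.5, M = function(t) 30 + 0.4 * t, S = 0.15,
                   age_range = c(20, 60))
  d <- sim_records(tr, n = 2000, seed = 4)
  f <- fit_lms(d, edf = c(L = 1, M = 3.5, S = 3))
  expect_lt(abs(f$edf_realized[["M"]] - 3.5), 0.05)
  expect_lt(abs(f$edf_realized[["S"]] - 3), 0.05)
  expect_equal(f$edf_realized[["L"]], 1)
  # penalized deviance includes the active roughness penalty
  expect_gte(f$penalized_deviance, f$global_deviance)
})

test_that("global deviance is monotone over nested EDF triples", {
  d <- sim_records(linear_truth_curves(), n = 2000, seed = 5)
  triples <- list(c(L = 0, M = 1, S = 1), c(L = 0, M = 2, S = 1),
                  c(L = 0, M = 2, S = 2), c(L = 1, M = 2, S = 2),
                  c(L = 1, M = 3, S = 2))
  fits <- list(); prev <- NULL
  for (edf in triples) {
    prev <- fit_lms(d, edf, start = prev)
    expect_true(prev$converged)
    fits <- c(fits, list(prev))
  }
  gd <- vapply(fits, `[[`, numeric(1), "global_deviance")
  expect_true(all(diff(gd) <= 1e-4))
})

test_that("weights: unit weights are a no-op, rescaling is exactly invariant", {
  d <- sim_records(linear_truth_curves(), n = 1000, seed = 6)
  set.seed(7)
  d$weight <- stats::runif(1000, 0.5, 4)
  f0 <- fit_lms(d, c(L = 1, M = 2, S = 1))
  f1 <- fit_lms(d, c(L = 1, M = 2, S = 1), weights = rep(1, 1000))
  grid <- seq(min(d$age), max(d$age), length.out = 40)
  expect_equal(eval_curves(f1$curves, grid), eval_curves(f0$curves, grid),
               tolerance = 1e-10)
  expect_false(f0$weights_used); expect_true(f1$weights_used)

  fw <- refit_with_weights(d, c(L = 1, M = 2, S = 1))
  d10 <- d; d10$weight <- d$weight * 10
  fw10 <- refit_with_weights(d10, c(L = 1, M = 2, S = 1))
  a <- eval_curves(fw$curves, grid); b <- eval_curves(fw10$curves, grid)
  expect_lt(max(abs(as.matrix(a) - as.matrix(b))), 1e-8)
  expect_equal(fw10$global_deviance, 10 * fw$global_deviance,
               tolerance = 1e-10)
  expect_error(refit_with_weights(d[c("age", "score")], c(L = 0, M = 1, S = 1)),
               "weight")
})

test_that("weighted fits pull the median towards the upweighted stratum truth", {
  # oversample high scorers, then reweight back: the weighted fit should be
  # closer to the population median than the unweighted fit
  tr <- linear_truth_curves()
  pop <- sim_records(tr, n = 20000, seed = 8)
  set.seed(9)
  p <- ifelse(pop$score > eval_curves(tr, pop$age)$M, 0.5, 0.05)
  keep <- stats::runif(20000) < p
  sub <- pop[keep, ]; sub$weight <- 1 / p[keep]
  edf <- c(L = 0, M = 2, S = 1)
  fw <- refit_with_weights(sub, edf)
  fu <- fit_lms(sub, edf)
  grid <- seq(21, 59, length.out = 60)
  truthM <- eval_curves(tr, grid)$M
  ise_w <- mean((eval_curves(fw$curves, grid)$M - truthM)^2)
  ise_u <- mean((eval_curves(fu$curves, grid)$M - truthM)^2)
  expect_lt(ise_w, ise_u)
})

test_that("non-convergence and degenerate inputs are reported, not hidden", {
  d <- sim_records(null_truth_curves(), n = 200, seed = 10)
  f <- fit_lms(d, c(L = 0, M = 1, S = 1), control = lms_control(max_cycles = 1))
  expect_false(f$converged)
  expect_s3_class(f, "lms_fit")
  one_age <- data.frame(age = rep(40, 50), score = stats::rexp(50) + 1)
  expect_error(fit_lms(one_age, c(L = 0, M = 2, S = 1)), "distinct ages")
  expect_error(fit_lms(d, c(L = 0, M = 0, S = 1)), "at least 1")
  expect_error(fit_lms(d, c(0, 1, 1)), "named")
  dneg <- data.frame(age = d$age, score = d$score - min(d$score) - 1)
  expect_error(fit_lms(dneg, c(L = 0, M = 1, S = 1), shift = 0), "positive")
})
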