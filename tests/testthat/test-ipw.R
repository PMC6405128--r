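make_screen <- function(n, seed) {
  cfg <- screen_truth(n = n)
  generate_population(cfg, seed = seed)
}

test_that("step-1 recovers the design sampling fractions per stratum", {
  pop <- make_screen(6000, seed = 51)
  set.seed(52)
  risk <- as.integer(pop$score >= 20)
  p_true <- ifelse(risk == 1, 0.405, 0.043)
  sel <- stats::runif(6000) < p_true
  pop$risk_flag <- risk
  s1 <- fit_step1(pop, sel)
  expect_lt(abs(mean(s1$p[risk == 1]) - 0.405), 0.02)
  expect_lt(abs(mean(s1$p[risk == 0]) - 0.043), 0.02)
})

test_that("step-1 coefficients match the 2x2 contingency-table log-odds", {
  pop <- make_screen(4000, seed = 53)
  set.seed(54)
  pop$risk_flag <- as.integer(pop$score >= 20)
  sel <- stats::runif(4000) < ifelse(pop$risk_flag == 1, 0.5, 0.1)
  s1 <- fit_step1(pop, sel, covariates = "risk_flag")
  tab <- table(risk = pop$risk_flag, sel = sel)
  lo0 <- log(tab["0", "TRUE"] / tab["0", "FALSE"])
  lo1 <- log(tab["1", "TRUE"] / tab["1", "FALSE"])
  expect_equal(unname(s1$coefficients[1]), lo0, tolerance = 1e-6)
  expect_equal(unname(s1$coefficients[2]), lo1 - lo0, tolerance = 1e-6)
})

test_that("degenerate selection indicators are handled explicitly", {
  pop <- make_screen(200, seed = 55)
  pop$risk_flag <- as.integer(pop$score >= 20)
  s1 <- fit_step1(pop, rep(TRUE, 200))
  expect_true(all(s1$p == 1))
  expect_error(fit_step1(pop, rep(FALSE, 200)), "single class")
  expect_error(fit_step1(pop, c(rep(TRUE, 100), rep(FALSE, 100)),
                         covariates = "nope"), "not found")
})

test_that("backward elimination drops noise and keeps signal", {
  cands <- c("income_deprivation", "pct_girls", "sen", "fsm")
  # null response: nothing should usually survive
  retained_null <- vapply(1:30, function(s) {
    pop <- make_screen(600, seed = 60 + s)
    set.seed(160 + s)
    complete <- stats::runif(600) < 0.7
    length(fit_step2(pop, complete, cands)$retained)
  }, numeric(1))
  expect_lte(stats::median(retained_null), 1)

  # strong single driver: retained nearly always
  hits <- vapply(1:20, function(s) {
    pop <- make_screen(600, seed = 90 + s)
    set.seed(190 + s)
    complete <- stats::runif(600) < stats::plogis(1 - 1.5 * pop$income_deprivation)
    "income_deprivation" %in% fit_step2(pop, complete, cands)$retained
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  # all complete: probabilities are exactly one
  pop <- make_screen(300, seed = 120)
  s2 <- fit_step2(pop, rep(1, 300), cands)
  expect_true(all(s2$p == 1))
  expect_length(s2$retained, 0)
})

test_that("weight composition is the reciprocal probability product", {
  expect_equal(round(compose_weights(0.405, 1), 4), 2.4691)
  expect_equal(compose_weights(1, 1), 1)
  expect_error(compose_weights(0, 0.5), "probabilities")
  expect_warning(w <- compose_weights(1e-3, 1e-3), "floor")
  expect_equal(suppressWarnings(
    compose_weights(1e-3, 1e-3, truncate = TRUE)), 1e4)
  expect_equal(mean(compose_weights(c(0.2, 0.8), c(1, 1), normalise = TRUE)), 1)
})

test_that("estimated weights recover population totals and means", {
  pop <- make_screen(6459, seed = 130)
  tp <- apply_two_phase(pop, seed = 130)
  tp$sex_num <- as.integer(tp$sex == "F")
  tw <- two_step_weights(
    tp, tp$selected, tp$complete,
    candidates = c("sex_num", "income_deprivation", "school_size", "pct_girls",
                   "sen", "fsm", "eal", "score", "phonics_n"))
  w <- tw$weights
  # Horvitz-Thompson total: the weighted subsample stands for the population
  expect_lt(abs(sum(w$weight) - nrow(tp)) / nrow(tp), 0.10)

  comp <- tp[tp$complete, ]
  pop_mean <- mean(tp$score)
  wmean <- sum(w$weight * comp$score) / sum(w$weight)
  umean <- mean(comp$score)
  # MC standard error of the weighted mean
  se <- sqrt(sum(w$weight^2 * (comp$score - wmean)^2)) / sum(w$weight)
  expect_lt(abs(wmean - pop_mean), 2 * se)
  # unweighted mean is biased towards the oversampled high-risk stratum
  expect_gt(umean - pop_mean, 4 * se)

  # using the true inclusion probabilities instead of estimated ones moves
  # the estimate by less than one MC standard error
  wt <- 1 / (comp$p1_true * comp$p2_true)
  wmean_true <- sum(wt * comp$score) / sum(wt)
  expect_lt(abs(wmean - wmean_true), se)

  expect_error(two_step_weights(tp, tp$selected, rep(TRUE, nrow(tp)),
                                candidates = "fsm"),
               "complete without being selected")
})
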