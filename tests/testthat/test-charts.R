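toy_model <- function() {
  tr <- lms_curves(L = 1, M = function(t) 50 + t / 2, S = 0.1,
                   age_range = c(10, 30))
  as_lms_model(tr, by = 1, score_bounds = c(0, 200))
}

test_that("centile tables: median column, ordering, single-age grids, un-shift", {
  tr <- lms_curves(L = function(t) 0.5 - 0.02 * t, M = function(t) 12 - 0.3 * t,
                   S = 0.9, age_range = c(0, 13), shift = 1)
  tab <- build_centile_table(tr)
  expect_s3_class(tab, "centile_table")
  # the 50th column is M(t) minus the positivity shift at every age
  expect_equal(tab$p50, eval_curves(tr, tab$age)$M - 1, tolerance = 1e-12)
  # strictly increasing across levels at every age
  mat <- as.matrix(tab[, -1])
  expect_true(all(apply(mat, 1, function(r) all(diff(r) > 0))))
  one <- build_centile_table(tr, ages = 5)
  expect_equal(nrow(one), 1)
})

test_that("screen-like fits give a steeper median than 97th centile decline", {
  pop <- generate_population(screen_truth(n = 4000, floor_mass = 0), seed = 71)
  f <- fit_lms(pop, edf = c(L = 2, M = 2, S = 2), shift = 1)
  tab <- build_centile_table(f$curves)
  drop50 <- tab$p50[1] - tab$p50[nrow(tab)]
  drop97 <- tab$p97[1] - tab$p97[nrow(tab)]
  expect_gt(drop50, 0)
  expect_gt(drop50, drop97)  # non-parallel centiles: the median falls faster
})

test_that("the calculator matches hand evaluation and refuses bad inputs", {
  m <- toy_model()
  res <- score_child(m, age = 20, raw = 66)
  expect_equal(res$z, 1, tolerance = 1e-10)  # M(20) = 60, (66/60 - 1)/0.1
  med <- score_child(m, age = 24, raw = 62)
  expect_equal(med$z, 0, tolerance = 1e-10)
  expect_equal(med$centile, 0.5, tolerance = 1e-10)
  err <- expect_error(score_child(m, age = 40, raw = 50), "domain")
  expect_match(conditionMessage(err), "10.0, 30.0")
  expect_error(score_child(m, age = 20, raw = 300), "bounds")
})

test_that("scoring inverts through z_to_raw at the same age", {
  m <- toy_model()
  res <- score_child(m, age = c(12, 17.3, 29), raw = c(40, 66, 80))
  back <- z_to_raw(res$z, res$L, res$M, res$S)
  expect_lt(max(abs(back - res$raw)), 1e-8)
})

test_that("serialization round-trips bit-identically", {
  pop <- generate_population(screen_truth(n = 2000), seed = 72)
  f <- fit_lms(pop, edf = c(L = 1, M = 2, S = 2), shift = 1)
  m <- as_lms_model(f, score_bounds = c(0, 39))
  path <- tempfile(fileext = ".json")
  write_lms_model(m, path)
  m2 <- read_lms_model(path)
  ages <- seq(m$age_range[1], m$age_range[2], length.out = 37)
  raws <- round(seq(0, 35, length.out = 37))
  expect_identical(score_child(m, ages, raws)$z, score_child(m2, ages, raws)$z)
  expect_error(suppressWarnings(read_lms_model(tempfile())))
})

test_that("calculator and centile table agree cell by cell", {
  m <- toy_model()
  lv <- default_centile_levels()
  tab <- build_centile_table(m, levels = lv)
  for (j in seq_along(lv)) {
    got <- score_child(m, tab$age, tab[[j + 1]])$centile
    expect_lt(max(abs(got - lv[j])), 1e-6)
  }
})

test_that("q_test flags a variance-inflated age bin with high power", {
  tr <- lms_curves(L = 0, M = 100, S = 0.1, age_range = c(0, 10))
  flags <- vapply(1:20, function(s) {
    set.seed(300 + s)
    age <- stats::runif(2000, 0, 10)
    z <- stats::rnorm(2000)
    z[age < 1] <- z[age < 1] * 1.5    # one mis-modelled bin
    d <- data.frame(age = age, score = z_to_raw(z, 0, 100, 0.1))
    r <- q_test(d, tr)
    r$table$flag_var[1]   # bins are ordered age bins; the first is inflated
  }, logical(1))
  expect_gte(mean(flags), 0.8)
  expect_error(q_test(data.frame(age = numeric(0), score = numeric(0)), tr),
               "no observations")
  # few observations: bins merged with a note
  set.seed(321)
  small <- data.frame(age = stats::runif(60, 0, 10),
                      score = z_to_raw(stats::rnorm(60), 0, 100, 0.1))
  r <- q_test(small, tr)
  expect_match(r$note, "merged")
})

test_that("weighted-vs-unweighted comparison contracts hold", {
  pop <- generate_population(screen_truth(n = 3000), seed = 73)
  f <- fit_lms(pop, edf = c(L = 1, M = 2, S = 1), shift = 1)
  cmp <- compare_weighted_unweighted(f, f, f, pop)
  expect_equal(unname(cmp$ks), c(0, 0))
  expect_equal(unname(cmp$wasserstein), c(0, 0))
  expect_true(all(cmp$densities$population >= 0))
  # disjoint age domains cannot be compared
  other <- lms_curves(L = 1, M = 50, S = 0.1, age_range = c(200, 260))
  expect_error(compare_weighted_unweighted(f, other, f, pop), "domain")
})
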