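# Shared ground-truth builders for the test suite.

# constant-parameter truth: no age trend anywhere
null_truth_curves <- function()
  lms_curves(L = 1, M = 50, S = 0.1, age_range = c(20, 60))

# linearly rising median, everything else constant
linear_truth_curves <- function()
  lms_curves(L = 1, M = function(t) 40 + 0.5 * t, S = 0.1,
             age_range = c(20, 60))

# continuous (unrounded, unbounded) records from arbitrary truth curves
sim_records <- function(curves, n, seed, window = curves$age_range) {
  cfg <- truth_config(curves, n = n, score_bounds = c(-1e9, 1e9),
                      age_window = window, round = FALSE)
  generate_population(cfg, seed = seed)
}

# random in-support LMS parameter draws for property tests
random_lms_points <- function(n, seed) {
  set.seed(seed)
  data.frame(L = stats::runif(n, -2, 2),
             M = stats::runif(n, 0.5, 100),
             S = stats::runif(n, 0.01, 0.8))
}
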