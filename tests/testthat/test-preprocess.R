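noiseless_cfg <- function(n_participants = 2, n_trials = 60, seed = 1) {
  sim_config(n_participants = n_participants, n_trials = n_trials,
             alpha_by_condition = c(no_load = 0, low = 0, high = 0),
             noise_sd = 0, lapse_rate = 0, bias_terms = list(),
             slow_frac = 0, seed = seed)
}

test_that("a clean dataset is excluded only for missing predecessors", {
  d <- generate_dataset(noiseless_cfg())
  s <- suppressWarnings(preprocess(d))
  expect_equal(sum(s$exclusion_reason == "no_previous"), 2)
  expect_true(all(s$exclusion_reason %in% c("none", "no_previous")))
  expect_equal(attr(s, "exclusion_fraction"), 0)
})

test_that("every lapse-magnitude error is flagged as a lapse, exactly", {
  cfg <- sim_config(n_participants = 3, n_trials = 200, noise_sd = 4,
                    lapse_rate = 0, bias_terms = list(), slow_frac = 0,
                    seed = 12)
  d <- generate_dataset(cfg)
  # inject 5% certain lapses: push the report 50-89 degrees off
  set.seed(99)
  mark <- sample(nrow(d), 0.05 * nrow(d))
  d$reported[mark] <- (d$theta[mark] + runif(length(mark), 50, 89)) %% 180
  s <- preprocess(d)
  flagged <- which(s$exclusion_reason == "lapse")
  key <- paste(s$participant, s$trial_index)
  mark_key <- paste(d$participant[mark], d$trial_index[mark])
  expect_setequal(key[flagged], mark_key)
  expect_equal(length(flagged), length(mark))
})

test_that("the quartile rule flags hand-computed outliers", {
  vals <- c(-1, -10, 0, 1, 10)
  d <- data.frame(participant = 1, trial_index = 1:5, has_load = FALSE,
                  load_level = "none", theta = 90,
                  reported = (90 + vals) %% 180, rt = 1)
  s <- suppressWarnings(preprocess(d))
  # type-7 quartiles of {-10,-1,0,1,10} are -1 and 1; fences at -4 and 4
  expect_setequal(which(s$exclusion_reason == "iqr_outlier"),
                  which(vals %in% c(-10, 10)))
})

test_that("stages apply in cascade order with one reason per trial", {
  cfg <- sim_config(n_participants = 1, n_trials = 100,
                    alpha_by_condition = c(no_load = 0, low = 0, high = 0),
                    noise_sd = 3, lapse_rate = 0, bias_terms = list(),
                    slow_frac = 0, seed = 1)
  d <- generate_dataset(cfg)
  # trial 10: lapse AND slow -> lapse wins (earlier stage)
  d$reported[10] <- (d$theta[10] + 60) %% 180
  d$rt[10] <- 12
  # trial 20: moderate outlier AND slow -> iqr precedes the rt stage
  d$reported[20] <- (d$theta[20] + 20) %% 180
  d$rt[20] <- 12
  # trial 30: slow only
  d$rt[30] <- 12
  s <- suppressWarnings(preprocess(d))
  expect_equal(s$exclusion_reason[10], "lapse")
  expect_equal(s$exclusion_reason[20], "iqr_outlier")
  expect_equal(s$exclusion_reason[30], "slow_rt")
})

test_that("delta survives exclusion of the previous trial", {
  cfg <- noiseless_cfg(n_participants = 1, n_trials = 50)
  d <- generate_dataset(cfg)
  d$reported[7] <- (d$theta[7] + 60) %% 180   # lapse on trial 7
  s <- suppressWarnings(preprocess(d))
  expect_false(s$included[7])
  # trial 8 keeps its delta, computed from trial 7's stimulus
  expect_equal(s$delta[8], compute_delta(d$theta[7], d$theta[8]))
  expect_true(s$included[8])
})

test_that("cleaned errors are centred per participant before the IQR step", {
  cfg <- sim_config(n_participants = 3, n_trials = 200, noise_sd = 5,
                    seed = 31)
  d <- generate_dataset(cfg)
  s <- preprocess(d)
  pre_iqr <- s$exclusion_reason %in% c("none", "iqr_outlier", "slow_rt",
                                       "no_previous")
  for (p in unique(s$participant)) {
    m <- mean(s$error_clean[pre_iqr & s$participant == p], na.rm = TRUE)
    expect_lt(abs(m), 1e-9)
  }
})

test_that("schema violations raise errors", {
  expect_error(preprocess(data.frame(participant = 1)), "missing column")
})
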