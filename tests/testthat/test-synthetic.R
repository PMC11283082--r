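test_that("orientation sequences respect range, constraint and seed", {
  one <- generate_orientation_sequence(1, 40, seed = 5)
  expect_true(one >= 1 && one <= 180)

  th <- generate_orientation_sequence(5000, 40, seed = 9)
  expect_true(all(th >= 1 & th <= 180))
  steps <- abs(compute_delta(th[-length(th)], th[-1]))
  expect_lte(max(steps), 40)

  expect_identical(generate_orientation_sequence(200, 40, seed = 3),
                   generate_orientation_sequence(200, 40, seed = 3))
  expect_error(generate_orientation_sequence(0, 40), ">= 1")
  expect_error(generate_orientation_sequence(10, 0), "max_step")
})

test_that("marginal orientation distribution is close to uniform", {
  th <- generate_orientation_sequence(10000, 40, seed = 21)
  freq <- tabulate(ceiling(th / 10), nbins = 18) / 10000
  expect_lt(max(abs(freq - 1 / 18)), 0.02)
})

test_that("degenerate observer reproduces the stimulus exactly", {
  cfg <- sim_config(n_participants = 1, n_trials = 10,
                    alpha_by_condition = c(no_load = 0, low = 0, high = 0),
                    noise_sd = 0, lapse_rate = 0, bias_terms = list(),
                    seed = 1)
  th <- generate_orientation_sequence(10, 40, seed = 2)
  cond <- rep(c("no_load", "low"), 5)
  obs <- simulate_observer(th, cond, cfg, participant_seed = 3)
  expect_equal(obs$reported, th %% 180)
})

test_that("serial term at the curve peak adds exactly alpha degrees", {
  cfg <- sim_config(n_participants = 1, n_trials = 2,
                    alpha_by_condition = c(no_load = 2, low = 2, high = 2),
                    w_true = 0.05, noise_sd = 0, lapse_rate = 0,
                    bias_terms = list(), seed = 1)
  th <- c(90 + 1 / (0.05 * sqrt(2)), 90)     # delta = +14.1421...
  obs <- simulate_observer(th, c("no_load", "no_load"), cfg,
                           participant_seed = 4)
  expect_equal(compute_error(obs$reported[2], th[2]), 2, tolerance = 1e-6)
  # trial 1 has no serial term
  expect_equal(compute_error(obs$reported[1], th[1]), 0, tolerance = 1e-12)
})

test_that("flipping the sign of alpha negates trial-wise errors", {
  base <- list(n_participants = 1, n_trials = 50, w_true = 0.05,
               noise_sd = 0, lapse_rate = 0, bias_terms = list(), seed = 1)
  cfg_pos <- do.call(sim_config, c(base, list(
    alpha_by_condition = c(no_load = 1.3, low = 1.3, high = 1.3))))
  cfg_neg <- do.call(sim_config, c(base, list(
    alpha_by_condition = c(no_load = -1.3, low = -1.3, high = -1.3))))
  th <- generate_orientation_sequence(50, 40, seed = 6)
  cond <- rep(c("no_load", "high"), 25)
  e_pos <- compute_error(simulate_observer(th, cond, cfg_pos, 8)$reported, th)
  e_neg <- compute_error(simulate_observer(th, cond, cfg_neg, 8)$reported, th)
  expect_equal(e_neg, -e_pos, tolerance = 1e-10)
})

test_that("generated datasets have the alternating dual-task structure", {
  cfg <- sim_config(n_participants = 2, n_trials = 4, seed = 10)
  d <- generate_dataset(cfg)
  expect_equal(nrow(d), 8)
  for (p in 1:2) {
    hl <- d$has_load[d$participant == p]
    expect_equal(hl, c(FALSE, TRUE, FALSE, TRUE))
  }
  expect_true(all(d$load_level[!d$has_load] == "none"))
  expect_true(all(d$load_level[d$has_load] %in% c("low", "high")))
  expect_true(all(is.na(d$memory_correct[!d$has_load])))

  cfg1 <- sim_config(n_participants = 21, n_trials = 400, seed = 1)
  d1 <- generate_dataset(cfg1)
  expect_equal(nrow(d1), 8400)
  expect_equal(mean(d1$has_load), 0.5)
})

test_that("generation is deterministic and round-trips through CSV", {
  cfg <- sim_config(n_participants = 2, n_trials = 100, seed = 33)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1, d2)

  path <- tempfile(fileext = ".csv")
  write_trials(d1, path)
  d3 <- read_trials(path)
  expect_equal(d3, d1)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_trials = 401), "even")
  expect_error(sim_config(w_true = 0.5), "w_true")
  expect_error(sim_config(lapse_rate = 0.6), "lapse_rate")
  expect_error(sim_config(pc_by_load = c(low = 0, high = 0.5)), "pc_by_load")
  expect_error(sim_config(max_step = 100), "max_step")
  th <- generate_orientation_sequence(10, 40, 1)
  cfg <- sim_config()
  expect_error(simulate_observer(th, rep("no_load", 9), cfg), "equal length")
})
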