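test_that("condition splits are disjoint and conserve trials", {
  cfg <- sim_config(n_participants = 3, n_trials = 200, seed = 17)
  s <- preprocess(generate_dataset(cfg))
  sp <- split_conditions(s)
  counts <- attr(sp, "counts")
  usable <- sum(s$included & !is.na(s$delta))
  expect_equal(sum(counts[c("prev_low", "prev_high", "curr_low",
                            "curr_high")]), usable)
  expect_equal(counts[["no_load"]] + counts[["load"]], usable)
  # a current-load trial never enters a previous-load subset
  expect_true(all(!sp$prev_low$has_load))
  expect_true(all(!sp$prev_high$has_load))
  expect_true(all(sp$curr_low$has_load))
  expect_true(all(sp$curr_high$has_load))
  keys <- lapply(sp[1:4], function(df) paste(df$participant, df$trial_index))
  expect_equal(anyDuplicated(unlist(keys)), 0)
  expect_error(split_conditions(data.frame(x = 1)), "load tags")
})

test_that("residualization removes the delta profile and reduces spread", {
  set.seed(21)
  d <- runif(4000, -40, 40)
  # pure serial-bias signal is captured by the moving average
  # a +/-10 deg boxcar flattens curvature near the peak; the residual RMS
  # of the pure curve stays bounded by that smoothing bias
  e_sig <- dog_curve(d, 2, 0.05)
  r_sig <- residualize_history(d, e_sig, window = 10)
  expect_lt(sqrt(mean(r_sig^2)), 0.25)
  # a narrower window tracks the curve more closely
  r_narrow <- residualize_history(d, e_sig, window = 5)
  expect_lt(sqrt(mean(r_narrow^2)), 0.15)

  # no serial dependence: residuals are the centred errors
  e_flat <- rnorm(4000, 0, 5)
  r_flat <- residualize_history(d, e_flat, window = 10)
  expect_equal(r_flat, e_flat - mean(e_flat), tolerance = 0.5)
  expect_lte(sd(r_flat), sd(e_flat))
  expect_error(residualize_history(d, e_flat, window = 0), "window")
})

test_that("error scatter matches the generating noise and is reproducible", {
  set.seed(5)
  frames <- lapply(1:21, function(p) {
    make_cleaned_frame(p, runif(200, -40, 40), rnorm(200, 0, 6.3))
  })
  s <- do.call(rbind, frames)
  class(s) <- c("cleaned_series", "data.frame")
  sc <- error_scatter(s, conditions = "no_load")
  expect_equal(mean(sc$scatter), 6.3, tolerance = 0.2)

  # identical errors in two conditions give identical scatter
  d <- runif(150, -40, 40); e <- rnorm(150, 0, 4)
  f1 <- make_cleaned_frame(1, d, e, has_load = FALSE, load_level = "none")
  f2 <- make_cleaned_frame(1, d, e, has_load = TRUE, load_level = "low")
  f2$trial_index <- f2$trial_index + 150
  both <- rbind(f1, f2)
  class(both) <- c("cleaned_series", "data.frame")
  sc2 <- error_scatter(both, conditions = c("no_load", "low"))
  expect_equal(sc2$scatter[sc2$condition == "no_load"],
               sc2$scatter[sc2$condition == "low"])
})

test_that("paired comparison handles identity and degenerate input", {
  a <- c(1.2, 0.8, 1.5, 1.1, 0.9)
  res <- paired_comparison(a, a)
  expect_equal(res$t, 0)
  expect_equal(res$d, 0)
  expect_lt(res$bf10, 1)
  expect_error(paired_comparison(a, a - 1), "undefined")
  expect_error(paired_comparison(a, a[-1]), "equal length")
  expect_error(paired_comparison(a[1:2], a[1:2]), "3")
})

test_that("paired comparison matches t.test and the d sampling distribution", {
  set.seed(77)
  a <- rnorm(21, 1, 1); b <- rnorm(21, 0, 1)
  res <- paired_comparison(a, b)
  tt <- t.test(a, b, paired = TRUE)
  expect_equal(res$t, unname(tt$statistic))
  expect_equal(res$p, tt$p.value)
  expect_equal(res$df, 20)

  # a one-SD paired shift yields d near 1
  ds <- replicate(200, {
    diff <- rnorm(21, 1, 1)
    mean(diff) / sd(diff)
  })
  expect_gt(median(ds), 0.8)
  expect_lt(median(ds), 1.2)
})

test_that("JZS Bayes factor agrees with the g-prior integral oracle", {
  # independent route: Rouder et al. JZS integral over g with the scale
  # folded into the effective sample size
  jzs_g_oracle <- function(t, n, r = sqrt(2) / 2) {
    nu <- n - 1
    num <- integrate(function(g) {
      (1 + n * r^2 * g)^(-1 / 2) *
        (1 + t^2 / ((1 + n * r^2 * g) * nu))^(-(nu + 1) / 2) *
        (2 * pi)^(-1 / 2) * g^(-3 / 2) * exp(-1 / (2 * g))
    }, 0, Inf, rel.tol = 1e-10)$value
    den <- (1 + t^2 / nu)^(-(nu + 1) / 2)
    num / den
  }
  for (case in list(c(2.5, 15), c(1.0, 30), c(-3.2, 21))) {
    expect_equal(jzs_bf(case[1], case[2]),
                 jzs_g_oracle(case[1], case[2]), tolerance = 1e-4)
  }
  # an extreme t yields extreme evidence
  expect_gt(jzs_bf(10.11, 21), 100)
  # one-tailed halves split the two-sided marginal likelihood
  bf_two <- jzs_bf(2, 20, tail = "two")
  bf_pos <- jzs_bf(2, 20, tail = "positive")
  bf_neg <- jzs_bf(2, 20, tail = "negative")
  expect_equal((bf_pos + bf_neg) / 2, bf_two, tolerance = 1e-6)
  expect_gt(bf_pos, bf_two)
})
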