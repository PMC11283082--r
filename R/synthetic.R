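#' Configuration for the synthetic dual-task observer
#'
#' Defines the generative model used to simulate trial tables with the
#' statistical structure the analysis pipeline assumes: alternating
#' no-load/load trials, a constrained stimulus sequence, adjustment errors
#' composed of an orientation-dependent systematic bias, a
#' derivative-of-Gaussian serial bias, Gaussian noise and uniform lapses,
#' and binary memory responses at per-condition accuracies.
#'
#' The defaults emulate a typical session of the dual-task design this
#' package analyses: 21 participants, 400 trials in 10 blocks, serial bias
#' half-amplitudes of about 0.9 degrees without load and 1.4-1.5 degrees
#' under load, inverse width 0.05, adjustment noise of 6.3 degrees, a 2
#' percent lapse rate, and memory accuracies of 0.90 (low load) and 0.744
#' (high load).
#'
#' @param n_participants Number of simulated observers.
#' @param n_trials Trials per observer; must be even (trials come in
#'   no-load/load pairs).
#' @param alpha_by_condition Named numeric vector mapping condition labels
#'   `no_load`, `low`, `high` to the true DoG half-amplitude (degrees) on
#'   trials of that condition.
#' @param w_true True inverse width, in `[0.01, 0.1]` (1/degrees).
#' @param noise_sd Gaussian adjustment noise SD, degrees.
#' @param lapse_rate Probability of a uniform-guess report, in `[0, 0.5)`.
#' @param bias_terms List of numeric triplets `(amplitude_deg,
#'   frequency_cycles_per_180, phase_rad)` defining the systematic
#'   orientation-dependent bias `sum_i a_i sin(2 pi f_i theta / 180 + phi_i)`.
#' @param pc_by_load Named numeric vector `low`, `high`: memory-task
#'   accuracy per load level, each in `(0, 1]`.
#' @param max_step Maximum absolute acute orientation difference between
#'   consecutive stimuli, degrees. Default 40.
#' @param rt_meanlog,rt_sdlog Lognormal response-time parameters (log
#'   seconds).
#' @param slow_frac Fraction of trials given a response time above 10 s, to
#'   exercise the slow-response filter.
#' @param n_blocks Number of blocks the trials are divided into.
#' @param seed Integer base seed; per-participant streams are derived from
#'   it deterministically.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_participants = 21L,
                       n_trials = 400L,
                       alpha_by_condition = c(no_load = 0.9, low = 1.4,
                                              high = 1.5),
                       w_true = 0.05,
                       noise_sd = 6.3,
                       lapse_rate = 0.02,
                       bias_terms = list(c(1.5, 2, 0), c(0.5, 4, 0.7)),
                       pc_by_load = c(low = 0.90, high = 0.744),
                       max_step = 40,
                       rt_meanlog = 0.40,
                       rt_sdlog = 0.30,
                       slow_frac = 0.005,
                       n_blocks = 10L,
                       seed = 1L) {
  n_participants <- as.integer(n_participants)
  n_trials <- as.integer(n_trials)
  if (n_participants < 1L) stop("`n_participants` must be >= 1", call. = FALSE)
  if (n_trials < 2L || n_trials %% 2L != 0L) {
    stop("`n_trials` must be even (trials come in no-load/load pairs)",
         call. = FALSE)
  }
  req <- c("no_load", "low", "high")
  if (!all(req %in% names(alpha_by_condition))) {
    stop("`alpha_by_condition` must name no_load, low and high", call. = FALSE)
  }
  if (w_true < 0.01 || w_true > 0.1) {
    stop("`w_true` must lie in [0.01, 0.1]", call. = FALSE)
  }
  if (lapse_rate < 0 || lapse_rate >= 0.5) {
    stop("`lapse_rate` must lie in [0, 0.5)", call. = FALSE)
  }
  if (!all(c("low", "high") %in% names(pc_by_load)) ||
      any(pc_by_load <= 0) || any(pc_by_load > 1)) {
    stop("`pc_by_load` must give low/high accuracies in (0, 1]", call. = FALSE)
  }
  if (max_step <= 0 || max_step > 90) {
    stop("`max_step` must lie in (0, 90]", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  stopifnot(is.list(bias_terms), all(vapply(bias_terms, length, 1L) == 3L))
  structure(list(
    n_participants = n_participants,
    n_trials = n_trials,
    alpha_by_condition = alpha_by_condition[req],
    w_true = w_true,
    noise_sd = noise_sd,
    lapse_rate = lapse_rate,
    bias_terms = bias_terms,
    pc_by_load = pc_by_load[c("low", "high")],
    max_step = max_step,
    rt_meanlog = rt_meanlog,
    rt_sdlog = rt_sdlog,
    slow_frac = slow_frac,
    n_blocks = as.integer(n_blocks),
    seed = as.integer(seed)
  ), class = "sim_config")
}

# systematic orientation-dependent bias, degrees
systematic_bias <- function(theta, bias_terms) {
  out <- numeric(length(theta))
  for (term in bias_terms) {
    out <- out + term[1] * sin(2 * pi * term[2] * theta / 180 + term[3])
  }
  out
}

#' Generate a constrained random orientation sequence
#'
#' Orientations are integer degrees in `[1, 180]`. The first is uniform;
#' each subsequent orientation is drawn uniformly from the orientations
#' within `max_step` degrees (acute circular distance on the 180-degree
#' circle) of the previous one, so that no consecutive pair exceeds the
#' step constraint while the marginal distribution stays uniform.
#'
#' @param n Number of orientations; must be >= 1.
#' @param max_step Maximum acute difference between consecutive
#'   orientations, degrees, in `(0, 90]`.
#' @param seed Integer seed; the sequence is deterministic given it.
#' @return Integer vector of orientations in `[1, 180]`.
#' @export
generate_orientation_sequence <- function(n, max_step = 40, seed = 1L) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be >= 1", call. = FALSE)
  if (!is.numeric(max_step) || max_step <= 0 || max_step > 90) {
    stop("`max_step` must lie in (0, 90]", call. = FALSE)
  }
  with_seed(seed, {
    theta <- integer(n)
    theta[1] <- sample.int(180L, 1L)
    if (n > 1L) {
      offsets <- seq.int(-floor(max_step), floor(max_step))
      for (i in 2:n) {
        step <- sample(offsets, 1L)
        theta[i] <- ((theta[i - 1L] + step - 1L) %% 180L) + 1L
      }
    }
    theta
  })
}

#' Simulate one observer's reports for a given stimulus sequence
#'
#' For each trial `t > 1` the report is
#' `theta_t + bias(theta_t) + dog_curve(delta_t; alpha_cond, w_true) +
#' N(0, noise_sd)`, wrapped into `[0, 180)`; with probability `lapse_rate`
#' the report is instead uniform on the 180-degree space. `delta_t` is the
#' previous minus the current stimulus orientation; trial 1 carries no
#' serial term. On load trials a binary memory response is drawn with the
#' per-level accuracy.
#'
#' @param theta_sequence Stimulus orientations, degrees.
#' @param condition_labels Character vector, one of `no_load`, `low`,
#'   `high` per trial; same length as `theta_sequence`.
#' @param config A [sim_config()].
#' @param participant_seed Integer seed for this observer's random stream.
#' @return A data.frame with columns `reported`, `rt`, `memory_correct`
#'   (logical, `NA` on no-load trials) and `is_lapse` (the generative lapse
#'   indicator, useful for validating the lapse filter).
#' @export
simulate_observer <- function(theta_sequence, condition_labels, config,
                              participant_seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  n <- length(theta_sequence)
  if (length(condition_labels) != n) {
    stop("`theta_sequence` and `condition_labels` must have equal length",
         call. = FALSE)
  }
  if (!all(condition_labels %in% c("no_load", "low", "high"))) {
    stop("condition labels must be no_load, low or high", call. = FALSE)
  }
  with_seed(participant_seed, {
    delta <- c(NA_real_, compute_delta(theta_sequence[-n],
                                       theta_sequence[-1L]))
    alpha <- unname(config$alpha_by_condition[condition_labels])
    serial <- ifelse(is.na(delta), 0,
                     dog_curve(ifelse(is.na(delta), 0, delta), 1,
                               config$w_true) * alpha)
    err <- systematic_bias(theta_sequence, config$bias_terms) + serial +
      stats::rnorm(n, 0, config$noise_sd)
    is_lapse <- stats::runif(n) < config$lapse_rate
    reported <- (theta_sequence + err) %% 180
    reported[is_lapse] <- stats::runif(sum(is_lapse), 0, 180)
    rt <- stats::rlnorm(n, config$rt_meanlog, config$rt_sdlog)
    slow <- stats::runif(n) < config$slow_frac
    rt[slow] <- 10 + stats::rlnorm(sum(slow), 0, 0.5)
    memory_correct <- rep(NA, n)
    on_load <- condition_labels != "no_load"
    if (any(on_load)) {
      pc <- unname(config$pc_by_load[condition_labels[on_load]])
      memory_correct[on_load] <- stats::runif(sum(on_load)) < pc
    }
    data.frame(reported = reported, rt = rt,
               memory_correct = memory_correct, is_lapse = is_lapse)
  })
}

#' Generate a full synthetic trial table
#'
#' Builds `n_participants` observers, each with an alternating
#' no-load/load trial structure (odd trials no-load, even trials load with
#' a random low/high level), a step-constrained stimulus sequence, and
#' reports from [simulate_observer()]. The result is deterministic given
#' the config (including its seed) and round-trips losslessly through
#' [write_trials()] / [read_trials()].
#'
#' @param config A [sim_config()].
#' @return A data.frame of trial records with columns `participant`,
#'   `trial_index`, `block`, `has_load`, `load_level`, `theta`, `reported`,
#'   `rt`, `memory_correct`, and the generative flag `is_lapse`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  per_block <- config$n_trials / config$n_blocks
  out <- vector("list", config$n_participants)
  for (p in seq_len(config$n_participants)) {
    seed_theta <- child_seed(config$seed, 3L * p)
    seed_obs <- child_seed(config$seed, 3L * p + 1L)
    theta <- generate_orientation_sequence(config$n_trials, config$max_step,
                                           seed_theta)
    has_load <- rep(c(FALSE, TRUE), length.out = config$n_trials)
    load_level <- rep("none", config$n_trials)
    load_level[has_load] <- with_seed(seed_obs, {
      sample(c("low", "high"), sum(has_load), replace = TRUE)
    })
    cond <- ifelse(has_load, load_level, "no_load")
    obs <- simulate_observer(theta, cond, config,
                             participant_seed = child_seed(config$seed,
                                                           3L * p + 2L))
    out[[p]] <- data.frame(
      participant = p,
      trial_index = seq_len(config$n_trials),
      block = ceiling(seq_len(config$n_trials) / per_block),
      has_load = has_load,
      load_level = load_level,
      theta = theta,
      reported = obs$reported,
      rt = obs$rt,
      memory_correct = obs$memory_correct,
      is_lapse = obs$is_lapse
    )
  }
  do.call(rbind, out)
}
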