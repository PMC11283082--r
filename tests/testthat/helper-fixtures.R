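# DoG-shaped (delta, error) trial sets used across the suite
make_dog_data <- function(n, alpha, w = 0.05, noise_sd = 0, seed = 1,
                          delta_range = c(-40, 40)) {
  set.seed(seed)
  d <- runif(n, delta_range[1], delta_range[2])
  e <- dog_curve(d, alpha, w) + rnorm(n, 0, noise_sd)
  list(delta = d, error = e)
}

# minimal cleaned-series frame for descriptive-statistics tests
make_cleaned_frame <- function(participant, delta, error, has_load = FALSE,
                               load_level = "none") {
  n <- length(delta)
  structure(
    data.frame(
      participant = participant,
      trial_index = seq_len(n),
      has_load = rep_len(has_load, n),
      load_level = rep_len(load_level, n),
      prev_load_level = rep_len("no_load", n),
      theta = rep(90, n),
      error_raw = error,
      error_clean = error,
      delta = delta,
      included = TRUE,
      exclusion_reason = "none"
    ),
    class = c("cleaned_series", "data.frame")
  )
}

# brute-force oracle for the acute signed difference on the 180-degree
# circle: of the candidates x - 180k, exactly one falls in [-90, 90)
wrap_oracle <- function(x) {
  vapply(x, function(xi) {
    cand <- xi - 180 * (-2:2)
    cand[cand >= -90 & cand < 90][1]
  }, numeric(1))
}
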