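#' Clean a trial table into signed errors and deltas
#'
#' Applies the exclusion cascade and bias removal, per participant, in a
#' fixed stage order:
#' \enumerate{
#'   \item compute the raw signed error ([compute_error()]);
#'   \item exclude lapses, `|error| > lapse_cutoff`;
#'   \item demean the remaining errors;
#'   \item fit and subtract the sum-of-six-sinusoids systematic bias
#'     ([fit_bias_model()]), re-centring the residuals;
#'   \item flag interquartile-range outliers separately within each
#'     current-trial condition (no-load, low, high), using linearly
#'     interpolated quartiles (R quantile type 7) and fences at
#'     `iqr_k` interquartile ranges beyond the quartiles;
#'   \item exclude trials with response time above `rt_cutoff`.
#' }
#' Delta (previous minus current stimulus orientation) is computed for every
#' trial from the preceding trial's stimulus regardless of that trial's
#' exclusion status; only each participant's first trial has no delta and is
#' marked `no_previous`. Each excluded trial carries the single reason of
#' the first stage that caught it.
#'
#' @param trials Trial table as produced by [generate_dataset()] or
#'   [read_trials()]: columns `participant`, `trial_index`, `has_load`,
#'   `load_level`, `theta`, `reported`, `rt` (and optionally `block`,
#'   `memory_correct`).
#' @param lapse_cutoff Absolute error above which a trial counts as a
#'   lapse, degrees. Default 45.
#' @param iqr_k Multiplier on the interquartile range for the outlier
#'   fences. Default 1.5.
#' @param rt_cutoff Response-time exclusion threshold, seconds. Default 10.
#' @return An object of class `cleaned_series`: a data.frame with the input
#'   identifiers plus `error_raw`, `error_clean`, `delta`,
#'   `prev_load_level`, `included` and `exclusion_reason`
#'   (`none`, `lapse`, `iqr_outlier`, `slow_rt`, `no_previous`), with the
#'   overall exclusion fraction in attribute `exclusion_fraction`.
#' @export
preprocess <- function(trials, lapse_cutoff = 45, iqr_k = 1.5,
                       rt_cutoff = 10) {
  required <- c("participant", "trial_index", "has_load", "load_level",
                "theta", "reported", "rt")
  missing_cols <- setdiff(required, names(trials))
  if (length(missing_cols)) {
    stop("trial table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  parts <- split(trials, trials$participant)
  out <- lapply(parts, function(df) {
    df <- df[order(df$trial_index), , drop = FALSE]
    n <- nrow(df)
    df$error_raw <- compute_error(df$reported, df$theta)
    df$delta <- c(NA_real_, compute_delta(df$theta[-n], df$theta[-1L]))
    prev_cond <- ifelse(df$has_load, df$load_level, "no_load")
    df$prev_load_level <- c(NA_character_, prev_cond[-n])

    reason <- rep("none", n)
    reason[abs(df$error_raw) > lapse_cutoff] <- "lapse"

    ok <- reason == "none"
    df$error_clean <- rep(NA_real_, n)
    if (any(ok)) {
      demeaned <- df$error_raw[ok] - mean(df$error_raw[ok])
      bm <- tryCatch(
        suppressWarnings(fit_bias_model(demeaned, df$theta[ok])),
        error = function(cnd) NULL
      )
      resid <- if (is.null(bm)) demeaned else bm$residuals
      df$error_clean[ok] <- resid - mean(resid)
    }

    cond <- ifelse(df$has_load, df$load_level, "no_load")
    for (cnd in unique(cond[ok])) {
      sel <- ok & cond == cnd
      x <- df$error_clean[sel]
      q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
      fence <- c(q[1] - iqr_k * (q[2] - q[1]), q[2] + iqr_k * (q[2] - q[1]))
      bad <- sel & (df$error_clean < fence[1] | df$error_clean > fence[2])
      reason[bad & reason == "none"] <- "iqr_outlier"
    }

    reason[df$rt > rt_cutoff & reason == "none"] <- "slow_rt"
    reason[is.na(df$delta) & reason == "none"] <- "no_previous"

    df$included <- reason == "none"
    df$exclusion_reason <- reason
    df
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  # exclusion fraction counts cleaning exclusions, not structural
  # first-trial removals
  excl <- !res$included & res$exclusion_reason != "no_previous"
  attr(res, "exclusion_fraction") <- mean(excl)
  class(res) <- c("cleaned_series", class(res))
  res
}
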