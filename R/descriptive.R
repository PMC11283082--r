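#' Split cleaned trials by the load-conditioning scheme
#'
#' Partitions included trials (those with a defined delta) into the four
#' fine conditions of the alternating dual-task design plus the two pooled
#' ones:
#' \itemize{
#'   \item `prev_low`, `prev_high`: current no-load trials whose previous
#'     trial carried low / high load (load on the previous trial; single
#'     task now);
#'   \item `curr_low`, `curr_high`: current load trials at low / high level
#'     (load on the current trial; dual task now);
#'   \item `no_load`, `load`: all current no-load / load trials, pooled.
#' }
#' The four fine subsets are disjoint by the design's alternation: a trial
#' with a current load never enters a previous-load subset.
#'
#' @param series A `cleaned_series` from [preprocess()].
#' @return An object of class `condition_split`: named list of data.frames
#'   with a `counts` attribute.
#' @export
split_conditions <- function(series) {
  need <- c("has_load", "load_level", "prev_load_level", "included", "delta")
  if (!all(need %in% names(series))) {
    stop("series must carry current- and previous-trial load tags ",
         "(run preprocess() first)", call. = FALSE)
  }
  s <- series[series$included & !is.na(series$delta), , drop = FALSE]
  no_load <- s[!s$has_load, , drop = FALSE]
  load <- s[s$has_load, , drop = FALSE]
  out <- list(
    prev_low = no_load[no_load$prev_load_level == "low", , drop = FALSE],
    prev_high = no_load[no_load$prev_load_level == "high", , drop = FALSE],
    curr_low = load[load$load_level == "low", , drop = FALSE],
    curr_high = load[load$load_level == "high", , drop = FALSE],
    no_load = no_load,
    load = load
  )
  attr(out, "counts") <- vapply(out, nrow, 1L)
  class(out) <- "condition_split"
  out
}

#' @export
print.condition_split <- function(x, ...) {
  cat("Condition split (included trials with defined delta):\n")
  print(attr(x, "counts"))
  invisible(x)
}

#' Residualize errors from the serial-dependence profile
#'
#' Subtracts from each error the moving average of errors at nearby delta
#' (boxcar of half-width `window`, circular on the 180-degree delta space),
#' removing whatever bias profile the previous stimulus induced so that the
#' remaining spread reflects response precision only.
#'
#' @param deltas Orientation differences, degrees.
#' @param errors Adjustment errors, degrees; same length.
#' @param window Boxcar half-width in degrees of delta. Default 10.
#' @return Residual errors (same length; `NA` where delta or error is
#'   missing).
#' @export
residualize_history <- function(deltas, errors, window = 10) {
  stopifnot(length(deltas) == length(errors))
  if (!is.numeric(window) || length(window) != 1L || window <= 0) {
    stop("`window` must be a positive number", call. = FALSE)
  }
  keep <- is.finite(deltas) & is.finite(errors)
  d <- deltas[keep]
  e <- errors[keep]
  fitted <- vapply(d, function(d0) {
    dist <- abs(wrap_orientation(d - d0))
    mean(e[dist <= window])
  }, numeric(1))
  out <- rep(NA_real_, length(deltas))
  out[keep] <- e - fitted
  out
}

#' Per-participant error scatter by condition
#'
#' The error scatter is the standard deviation of adjustment errors, the
#' precision measure of the adjustment task. To keep the estimate free of
#' the serial-dependence bias, errors are first residualized from the
#' moving-average delta profile ([residualize_history()]) separately for
#' each participant and current-trial condition.
#'
#' @param series A `cleaned_series` from [preprocess()].
#' @param conditions Current-trial condition labels to compute. Default
#'   `c("no_load", "low", "high", "load")` (`load` pools low and high).
#' @param window Residualization boxcar half-width, degrees. Default 10.
#' @param residualize Set `FALSE` to skip the serial-bias residualization.
#' @return A data.frame `participant`, `condition`, `n`, `scatter`
#'   (degrees), with group mean/sd per condition in attribute `summary`.
#' @export
error_scatter <- function(series, conditions = c("no_load", "low", "high",
                                                 "load"),
                          window = 10, residualize = TRUE) {
  s <- series[series$included, , drop = FALSE]
  cond <- ifelse(s$has_load, s$load_level, "no_load")
  rows <- list()
  for (p in unique(s$participant)) {
    for (cnd in conditions) {
      sel <- s$participant == p &
        (if (cnd == "load") s$has_load else cond == cnd)
      if (!any(sel)) {
        rows[[length(rows) + 1L]] <-
          data.frame(participant = p, condition = cnd, n = 0L,
                     scatter = NA_real_)
        next
      }
      e <- s$error_clean[sel]
      if (residualize) {
        r <- residualize_history(s$delta[sel], e, window)
        e <- ifelse(is.na(r), e - mean(e), r)
      }
      rows[[length(rows) + 1L]] <-
        data.frame(participant = p, condition = cnd, n = sum(sel),
                   scatter = stats::sd(e))
    }
  }
  out <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(out, out$condition), function(df) {
    data.frame(condition = df$condition[1],
               mean_scatter = mean(df$scatter, na.rm = TRUE),
               sd_scatter = stats::sd(df$scatter, na.rm = TRUE))
  }))
  rownames(agg) <- NULL
  attr(out, "summary") <- agg
  out
}

#' Scaled JZS Bayes factor for a one-sample (paired) t contrast
#'
#' Bayes factor for the alternative that the standardised effect size is
#' nonzero, under a Jeffreys-Zellner-Siow (Cauchy) prior on effect size
#' with scale `r`. Computed by numerical integration of the noncentral-t
#' likelihood over the prior; the one-tailed version truncates the Cauchy
#' to the requested sign and doubles its density.
#'
#' @param t Observed t statistic.
#' @param n Sample size (number of pairs); degrees of freedom are `n - 1`.
#' @param r Prior scale. Default `sqrt(2)/2` (0.707).
#' @param tail `"two"` (default), `"positive"` or `"negative"`.
#' @return The Bayes factor BF10 (evidence for the alternative).
#' @export
jzs_bf <- function(t, n, r = sqrt(2) / 2, tail = c("two", "positive",
                                                   "negative")) {
  tail <- match.arg(tail)
  stopifnot(is.finite(t), n >= 2)
  df <- n - 1
  # the noncentral-t density warns about its final-digit precision far
  # below the integration tolerance; those warnings are noise here
  lik <- function(delta) {
    suppressWarnings(stats::dt(t, df = df, ncp = delta * sqrt(n)))
  }
  dens <- function(delta) stats::dcauchy(delta, 0, r)
  m1 <- switch(tail,
    two = stats::integrate(function(d) lik(d) * dens(d), -Inf, Inf,
                           rel.tol = 1e-8)$value,
    positive = stats::integrate(function(d) lik(d) * 2 * dens(d), 0, Inf,
                                rel.tol = 1e-8)$value,
    negative = stats::integrate(function(d) lik(d) * 2 * dens(d), -Inf, 0,
                                rel.tol = 1e-8)$value
  )
  m0 <- stats::dt(t, df = df)
  m1 / m0
}

#' Paired comparison with effect size and Bayes factor
#'
#' Two-tailed paired t test between matched per-participant values,
#' Cohen's d as `mean(diff) / sd(diff)`, and a scaled JZS Bayes factor
#' (prior scale 0.707) evaluated one-tailed in the direction of the
#' observed effect.
#'
#' @param values_a,values_b Per-participant values, paired by position;
#'   equal length, at least 3 pairs.
#' @return An object of class `group_test`: list with `t`, `df`, `p`, `d`,
#'   `bf10`, `mean_diff`, `n`.
#' @export
paired_comparison <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) {
    stop("`values_a` and `values_b` must have equal length", call. = FALSE)
  }
  keep <- is.finite(values_a) & is.finite(values_b)
  a <- values_a[keep]; b <- values_b[keep]
  n <- length(a)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  diffs <- a - b
  sdd <- stats::sd(diffs)
  m <- mean(diffs)
  if (sdd == 0) {
    if (m != 0) {
      stop("all paired differences are identical and nonzero; ",
           "the t statistic is undefined", call. = FALSE)
    }
    tstat <- 0; p <- 1; d <- 0
  } else {
    tstat <- m / (sdd / sqrt(n))
    p <- 2 * stats::pt(-abs(tstat), df = n - 1)
    d <- m / sdd
  }
  tail <- if (tstat > 0) "positive" else if (tstat < 0) "negative" else "two"
  bf <- jzs_bf(tstat, n, tail = tail)
  structure(list(t = tstat, df = n - 1, p = p, d = d, bf10 = bf,
                 mean_diff = m, n = n), class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("paired t(%d) = %.3f, p = %.4g, Cohen's d = %.3f, BF10 = %.3g\n",
              x$df, x$t, x$p, x$d, x$bf10))
  invisible(x)
}
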