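#' Sign-shuffle permutation test for the DoG parameters
#'
#' Builds a surrogate null for the half-amplitude (and width) by randomly
#' flipping the sign of every adjustment error with a fair coin, refitting
#' the DoG curve with the same grid-initialised bounded procedure, and
#' comparing the observed parameters against the surrogate distribution.
#' P-values use the add-one convention `p = (r + 1) / (n_perm + 1)` where
#' `r` counts surrogates at least as extreme as the observation; the
#' default is two-sided on the absolute value.
#'
#' @param deltas,errors Trial-wise orientation differences and errors,
#'   degrees; pairs with missing values are dropped.
#' @param n_perm Number of surrogates. Default 10000.
#' @param seed Integer seed; results are deterministic given it.
#' @param alternative `"two.sided"` (default) or `"one.sided"`
#'   (in the direction of the observed half-amplitude).
#' @param ... Passed to [fit_dog()].
#' @return An object of class `permutation_test`: observed fit, surrogate
#'   `alpha`/`w` vectors, `p_alpha`, `p_w`, `n_perm`, `seed`.
#' @export
sign_shuffle_test <- function(deltas, errors, n_perm = 10000L, seed = 1L,
                              alternative = c("two.sided", "one.sided"),
                              ...) {
  alternative <- match.arg(alternative)
  if (n_perm < 100L) stop("`n_perm` must be >= 100", call. = FALSE)
  keep <- is.finite(deltas) & is.finite(errors)
  d <- as.numeric(deltas[keep])
  e <- as.numeric(errors[keep])
  observed <- fit_dog(d, e, ...)
  sur <- with_seed(seed, {
    m <- matrix(NA_real_, n_perm, 2)
    for (i in seq_len(n_perm)) {
      s <- sample(c(-1, 1), length(e), replace = TRUE)
      f <- fit_dog(d, e * s, ...)
      m[i, ] <- c(f$alpha, f$w)
    }
    m
  })
  p_alpha <- perm_pvalue(observed$alpha, sur[, 1], alternative)
  p_w <- perm_pvalue(observed$w, sur[, 2], alternative)
  structure(list(
    statistic_name = "alpha", observed = observed,
    surrogate_alpha = sur[, 1], surrogate_w = sur[, 2],
    p_alpha = p_alpha, p_w = p_w, n_perm = n_perm, seed = seed,
    alternative = alternative
  ), class = "permutation_test")
}

perm_pvalue <- function(observed, surrogates, alternative) {
  if (alternative == "two.sided") {
    r <- sum(abs(surrogates) >= abs(observed))
  } else {
    r <- if (observed >= 0) sum(surrogates >= observed)
         else sum(surrogates <= observed)
  }
  (r + 1) / (length(surrogates) + 1)
}

#' Label-shuffle permutation test for a condition difference
#'
#' Tests the difference in DoG parameters between two trial sets by
#' pooling the trials, randomly reassigning condition labels while
#' preserving the group sizes, refitting both groups, and comparing the
#' observed differences (`a` minus `b`) against the surrogate ones.
#'
#' @param deltas_a,errors_a Trials of condition a.
#' @param deltas_b,errors_b Trials of condition b.
#' @param n_perm Number of surrogates. Default 10000.
#' @param seed Integer seed.
#' @param alternative Sidedness, as in [sign_shuffle_test()].
#' @param ... Passed to [fit_dog()].
#' @return A `permutation_test` with observed fits for both groups, the
#'   observed `alpha_diff`/`w_diff`, surrogate difference vectors, and
#'   `p_alpha`, `p_w`.
#' @export
label_shuffle_difference <- function(deltas_a, errors_a, deltas_b, errors_b,
                                     n_perm = 10000L, seed = 1L,
                                     alternative = c("two.sided",
                                                     "one.sided"),
                                     ...) {
  alternative <- match.arg(alternative)
  if (n_perm < 100L) stop("`n_perm` must be >= 100", call. = FALSE)
  ka <- is.finite(deltas_a) & is.finite(errors_a)
  kb <- is.finite(deltas_b) & is.finite(errors_b)
  da <- as.numeric(deltas_a[ka]); ea <- as.numeric(errors_a[ka])
  db <- as.numeric(deltas_b[kb]); eb <- as.numeric(errors_b[kb])
  if (!length(da) || !length(db)) {
    stop("both condition sets must be nonempty", call. = FALSE)
  }
  fit_a <- fit_dog(da, ea, ...)
  fit_b <- fit_dog(db, eb, ...)
  obs_alpha <- fit_a$alpha - fit_b$alpha
  obs_w <- fit_a$w - fit_b$w
  d_all <- c(da, db); e_all <- c(ea, eb)
  na <- length(da); n <- length(d_all)
  sur <- with_seed(seed, {
    m <- matrix(NA_real_, n_perm, 2)
    for (i in seq_len(n_perm)) {
      idx <- sample.int(n, na)
      fa <- fit_dog(d_all[idx], e_all[idx], ...)
      fb <- fit_dog(d_all[-idx], e_all[-idx], ...)
      m[i, ] <- c(fa$alpha - fb$alpha, fa$w - fb$w)
    }
    m
  })
  structure(list(
    statistic_name = "alpha_diff", fit_a = fit_a, fit_b = fit_b,
    observed_alpha_diff = obs_alpha, observed_w_diff = obs_w,
    surrogate_alpha = sur[, 1], surrogate_w = sur[, 2],
    p_alpha = perm_pvalue(obs_alpha, sur[, 1], alternative),
    p_w = perm_pvalue(obs_w, sur[, 2], alternative),
    n_perm = n_perm, seed = seed, alternative = alternative
  ), class = "permutation_test")
}

#' Bootstrap percentile intervals for the DoG parameters
#'
#' Resamples trials with replacement, refits the DoG curve, and returns
#' 95 percent percentile intervals for the half-amplitude and width.
#'
#' @param deltas,errors Trial-wise values.
#' @param n_boot Number of bootstrap resamples. Default 1000.
#' @param seed Integer seed.
#' @param probs Interval probabilities. Default `c(0.025, 0.975)`.
#' @param ... Passed to [fit_dog()].
#' @return List with the observed fit, matrices of bootstrap draws, and
#'   `ci_alpha`, `ci_w`.
#' @export
bootstrap_params <- function(deltas, errors, n_boot = 1000L, seed = 1L,
                             probs = c(0.025, 0.975), ...) {
  if (n_boot < 100L) stop("`n_boot` must be >= 100", call. = FALSE)
  keep <- is.finite(deltas) & is.finite(errors)
  d <- as.numeric(deltas[keep]); e <- as.numeric(errors[keep])
  observed <- fit_dog(d, e, ...)
  n <- length(d)
  draws <- with_seed(seed, {
    m <- matrix(NA_real_, n_boot, 2)
    for (i in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      f <- fit_dog(d[idx], e[idx], ...)
      m[i, ] <- c(f$alpha, f$w)
    }
    m
  })
  list(observed = observed,
       boot_alpha = draws[, 1], boot_w = draws[, 2],
       ci_alpha = stats::quantile(draws[, 1], probs, names = FALSE),
       ci_w = stats::quantile(draws[, 2], probs, names = FALSE),
       n_boot = n_boot, seed = seed)
}

#' @export
print.permutation_test <- function(x, ...) {
  if (x$statistic_name == "alpha") {
    cat(sprintf("sign-shuffle test: alpha = %.3f (p = %.4g), w = %.4f (p = %.4g), n_perm = %d\n",
                x$observed$alpha, x$p_alpha, x$observed$w, x$p_w, x$n_perm))
  } else {
    cat(sprintf("label-shuffle test: alpha diff = %.3f (p = %.4g), w diff = %.4f (p = %.4g), n_perm = %d\n",
                x$observed_alpha_diff, x$p_alpha, x$observed_w_diff, x$p_w,
                x$n_perm))
  }
  invisible(x)
}
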