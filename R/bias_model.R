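#' Fit a sum of six sinusoids to orientation-dependent report bias
#'
#' Removes idiosyncratic systematic biases (e.g. oblique biases) from
#' adjustment errors by modelling error as a function of stimulus
#' orientation with `sum_i a_i * sin(b_i * theta + c_i)`, i = 1..6, where
#' `b_i` are free angular frequencies (radians per degree). Fitting is a
#' deterministic two-stage procedure: six frequencies are extracted greedily
#' by projecting the running residual onto a sine/cosine pair over a fixed
#' frequency grid (matching-pursuit initialisation from the dominant
#' spectral components), then all 18 parameters are refined jointly by
#' Levenberg-Marquardt least squares.
#'
#' @param errors Demeaned adjustment errors, degrees.
#' @param thetas Stimulus orientations, degrees; same length.
#' @param n_terms Number of sinusoids. Default 6.
#' @param min_n Minimum trials for the 18-parameter fit; below it the
#'   function warns and passes the input through unchanged. Default 50.
#' @param freq_grid Candidate frequencies for the initialisation, in cycles
#'   per 180 degrees. Default `1:20`, the low-order discrete-Fourier
#'   components of the 180-degree orientation period.
#' @return An object of class `bias_model`: list with `amplitude` (degrees),
#'   `frequency` (radians per degree), `phase` (radians), `residuals`,
#'   `sse`, `input_ss`, and `degraded` (TRUE when the fit was skipped).
#' @export
fit_bias_model <- function(errors, thetas, n_terms = 6L, min_n = 50L,
                           freq_grid = 1:20) {
  stopifnot(length(errors) == length(thetas))
  keep <- is.finite(errors) & is.finite(thetas)
  e <- as.numeric(errors[keep])
  th <- as.numeric(thetas[keep])
  input_ss <- sum(errors[keep]^2)
  if (length(e) < min_n) {
    warning("fewer than ", min_n,
            " trials; bias model skipped, residuals equal input",
            call. = FALSE)
    return(structure(list(
      amplitude = rep(0, n_terms), frequency = rep(NA_real_, n_terms),
      phase = rep(0, n_terms), residuals = errors, sse = input_ss,
      input_ss = input_ss, degraded = TRUE
    ), class = "bias_model"))
  }

  # stage 1: greedy spectral initialisation on the residual
  b_grid <- 2 * pi * freq_grid / 180   # rad/deg
  resid <- e
  init <- matrix(0, n_terms, 3)        # a, b, c per term
  for (k in seq_len(n_terms)) {
    best_ss <- -Inf
    best <- c(0, b_grid[1], 0)
    for (b in b_grid) {
      s <- sin(b * th); cc <- cos(b * th)
      X <- cbind(s, cc)
      cf <- tryCatch(stats::.lm.fit(X, resid)$coefficients,
                     error = function(cnd) c(0, 0))
      expl <- sum((X %*% cf)^2)
      if (expl > best_ss) {
        best_ss <- expl
        amp <- sqrt(sum(cf^2))
        ph <- atan2(cf[2], cf[1])      # a sin(bx + c) = a(sin bx cos c + cos bx sin c)
        best <- c(amp, b, ph)
      }
    }
    init[k, ] <- best
    resid <- resid - best[1] * sin(best[2] * th + best[3])
  }

  # stage 2: joint Levenberg-Marquardt refinement of all 18 parameters
  par0 <- c(init[, 1], init[, 2], init[, 3])
  fres <- function(par) {
    a <- par[1:n_terms]; b <- par[(n_terms + 1):(2 * n_terms)]
    cc <- par[(2 * n_terms + 1):(3 * n_terms)]
    pred <- numeric(length(th))
    for (k in seq_len(n_terms)) pred <- pred + a[k] * sin(b[k] * th + cc[k])
    e - pred
  }
  refined <- tryCatch(
    minpack.lm::nls.lm(par0, fn = fres,
                       lower = c(rep(-Inf, n_terms), rep(1e-6, n_terms),
                                 rep(-Inf, n_terms)),
                       control = minpack.lm::nls.lm.control(maxiter = 200L)),
    error = function(cnd) NULL
  )
  par <- if (!is.null(refined) && sum(refined$fvec^2) <= sum(fres(par0)^2)) {
    refined$par
  } else par0
  a <- par[1:n_terms]; b <- par[(n_terms + 1):(2 * n_terms)]
  cc <- par[(2 * n_terms + 1):(3 * n_terms)]

  pred <- numeric(length(th))
  for (k in seq_len(n_terms)) pred <- pred + a[k] * sin(b[k] * th + cc[k])
  res <- rep(NA_real_, length(errors))
  res[keep] <- e - pred
  sse <- sum((e - pred)^2)

  structure(list(
    amplitude = a, frequency = b, phase = cc,
    residuals = res, sse = sse, input_ss = input_ss, degraded = FALSE
  ), class = "bias_model")
}

#' @export
predict.bias_model <- function(object, theta, ...) {
  if (isTRUE(object$degraded)) return(numeric(length(theta)))
  pred <- numeric(length(theta))
  for (k in seq_along(object$amplitude)) {
    pred <- pred + object$amplitude[k] *
      sin(object$frequency[k] * theta + object$phase[k])
  }
  pred
}

#' @export
print.bias_model <- function(x, ...) {
  cat("Sum-of-sinusoids bias model (", length(x$amplitude), " terms)\n",
      sep = "")
  cat(sprintf("  residual SS / input SS: %.4f\n",
              if (x$input_ss > 0) x$sse / x$input_ss else 0))
  invisible(x)
}
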