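#' Amplitude-normalising constant of the derivative-of-Gaussian curve
#'
#' The first-derivative-of-Gaussian (DoG) bias curve is
#' `f(delta) = delta * alpha * w * c * exp(-(w * delta)^2)`. With
#' `c = sqrt(2) * exp(1/2)` the curve attains its extremum `alpha` exactly at
#' `delta = 1 / (w * sqrt(2))`, so the half-amplitude parameter is the peak
#' bias in degrees.
#'
#' @return The constant, `sqrt(2) * exp(0.5)`.
#' @export
dog_constant <- function() {
  sqrt(2) * exp(0.5)
}

#' First-derivative-of-Gaussian serial-dependence curve
#'
#' Predicted adjustment error as a function of the orientation difference
#' between the previous and current stimulus. Odd in `delta`; positive
#' `alpha` models attraction toward the previous orientation, negative
#' `alpha` repulsion.
#'
#' @param delta Orientation difference(s), degrees.
#' @param alpha Half-amplitude: peak bias in degrees.
#' @param w Inverse width, 1/degrees; must be positive.
#' @param c_const Amplitude-normalising constant; default [dog_constant()].
#' @return Predicted error(s), degrees.
#' @examples
#' dog_curve(dog_peak(0.05), alpha = 2, w = 0.05) # exactly 2
#' @export
dog_curve <- function(delta, alpha, w, c_const = dog_constant()) {
  if (!is.numeric(w) || length(w) != 1L || !is.finite(w) || w <= 0) {
    stop("`w` must be a single positive number", call. = FALSE)
  }
  delta * alpha * w * c_const * exp(-(w * delta)^2)
}

#' Location of the DoG curve's peak
#'
#' @param w Inverse width, 1/degrees; must be positive.
#' @return `1 / (w * sqrt(2))`, the `|delta|` at which `|dog_curve|` is
#'   maximal.
#' @export
dog_peak <- function(w) {
  if (!is.numeric(w) || any(!is.finite(w)) || any(w <= 0)) {
    stop("`w` must be positive", call. = FALSE)
  }
  1 / (w * sqrt(2))
}

#' Fit the DoG serial-dependence curve by bounded least squares
#'
#' Minimises the sum of squared residuals between observed errors and
#' `dog_curve(delta, alpha, w)` under box constraints. Initialisation
#' follows a deterministic two-stage scheme: the cost is evaluated on a
#' coarse grid (`alpha` from -4 to 4 in steps of 1, `w` from 0.01 to 0.1 in
#' steps of 0.01) and the bounded optimiser (L-BFGS-B with analytic
#' gradient) is started from the best grid point.
#'
#' @param deltas Orientation differences, degrees; trials with `NA` delta
#'   are dropped.
#' @param errors Adjustment errors, degrees; same length as `deltas`.
#' @param alpha_bounds Length-2 numeric, bounds on the half-amplitude
#'   (degrees). Default `c(-20, 20)`.
#' @param w_bounds Length-2 numeric, bounds on the inverse width
#'   (1/degrees). Default `c(0.01, 0.1)`.
#' @param c_const Amplitude-normalising constant; default [dog_constant()].
#' @param min_n Minimum number of usable (delta, error) pairs. Default 30.
#' @return An object of class `dog_fit`: a list with `alpha`, `w`, `c`
#'   (the constant), `sse`, `n_trials`, `converged`, `init_grid_best`
#'   (the grid-selected start), and the bounds used.
#' @examples
#' set.seed(1)
#' d <- runif(500, -40, 40)
#' e <- dog_curve(d, 1.5, 0.05) + rnorm(500, sd = 0.5)
#' fit_dog(d, e)
#' @export
fit_dog <- function(deltas, errors,
                    alpha_bounds = c(-20, 20),
                    w_bounds = c(0.01, 0.1),
                    c_const = dog_constant(),
                    min_n = 30L) {
  stopifnot(length(deltas) == length(errors))
  keep <- is.finite(deltas) & is.finite(errors)
  d <- as.numeric(deltas[keep])
  e <- as.numeric(errors[keep])
  n <- length(d)
  if (n < min_n) {
    stop("insufficient data: ", n, " usable (delta, error) pairs, need >= ",
         min_n, call. = FALSE)
  }

  sse <- function(par) {
    r <- e - d * par[1] * par[2] * c_const * exp(-(par[2] * d)^2)
    sum(r * r)
  }
  grad <- function(par) {
    a <- par[1]; w <- par[2]
    g <- exp(-(w * d)^2)
    f <- d * a * w * c_const * g
    r <- e - f
    dfda <- d * w * c_const * g
    dfdw <- d * a * c_const * g * (1 - 2 * w^2 * d^2)
    c(-2 * sum(r * dfda), -2 * sum(r * dfdw))
  }

  # grid search: for each w the model is linear in alpha, so SSE on the
  # alpha grid reduces to a quadratic in alpha with shared cross-products
  alpha_grid <- seq(-4, 4, by = 1)
  w_grid <- seq(0.01, 0.1, by = 0.01)
  see <- sum(e * e)
  best <- NULL
  best_sse <- Inf
  for (w0 in w_grid) {
    h <- d * w0 * c_const * exp(-(w0 * d)^2)
    sh2 <- sum(h * h)
    seh <- sum(e * h)
    sse_a <- see - 2 * alpha_grid * seh + alpha_grid^2 * sh2
    i <- which.min(sse_a)
    if (sse_a[i] < best_sse) {
      best_sse <- sse_a[i]
      best <- c(alpha_grid[i], w0)
    }
  }

  opt <- stats::optim(best, sse, gr = grad, method = "L-BFGS-B",
                      lower = c(alpha_bounds[1], w_bounds[1]),
                      upper = c(alpha_bounds[2], w_bounds[2]),
                      control = list(maxit = 500L, factr = 1e4))
  par <- opt$par
  out_sse <- opt$value
  if (out_sse > best_sse) {       # keep the best point seen
    par <- best
    out_sse <- best_sse
  }

  structure(list(
    alpha = par[1],
    w = par[2],
    c = c_const,
    sse = out_sse,
    n_trials = n,
    converged = opt$convergence == 0L,
    init_grid_best = best,
    alpha_bounds = alpha_bounds,
    w_bounds = w_bounds
  ), class = "dog_fit")
}

#' @export
print.dog_fit <- function(x, ...) {
  cat("DoG fit (", x$n_trials, " trials)\n", sep = "")
  cat(sprintf("  half-amplitude alpha: %8.4f deg\n", x$alpha))
  cat(sprintf("  inverse width w:      %8.4f 1/deg (peak at %.2f deg)\n",
              x$w, dog_peak(x$w)))
  cat(sprintf("  SSE: %.3f   converged: %s\n", x$sse, x$converged))
  invisible(x)
}

#' @export
predict.dog_fit <- function(object, delta, ...) {
  dog_curve(delta, object$alpha, object$w, object$c)
}
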