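#' Signed acute angle on the 180-degree orientation circle
#'
#' Maps any angular difference into `[-90, 90)` using
#' `((x + 90) mod 180) - 90`. A difference of exactly +/-90 degrees maps to
#' -90 (the boundary convention forced by the formula).
#'
#' @param x Numeric vector of angular differences, degrees.
#' @return Numeric vector in `[-90, 90)`.
#' @keywords internal
wrap_orientation <- function(x) {
  ((x + 90) %% 180) - 90
}

#' Signed adjustment error in orientation space
#'
#' The adjustment error is the acute angle between the reported and the true
#' stimulus orientation, `error = ((r - theta) + 90) mod 180 - 90`, so that
#' errors lie in `[-90, 90)`. Positive errors mean the report is rotated
#' clockwise of the stimulus under the same sign convention as
#' [compute_delta()], so a positive fitted half-amplitude reads as attraction
#' toward the previous stimulus.
#'
#' @param reported Reported orientation, degrees (interpreted modulo 180).
#' @param theta True stimulus orientation, degrees.
#' @return Signed error in degrees, in `[-90, 90)`.
#' @examples
#' compute_error(170, 10) # -20
#' compute_error(100, 10) # -90 (boundary maps to -90, not +90)
#' @export
compute_error <- function(reported, theta) {
  if (!is.numeric(reported) || !is.numeric(theta) ||
      any(!is.finite(reported)) || any(!is.finite(theta))) {
    stop("`reported` and `theta` must be finite numeric values", call. = FALSE)
  }
  wrap_orientation(reported - theta)
}

#' Signed orientation difference between consecutive stimuli
#'
#' Delta is the acute angle previous-minus-current,
#' `delta = ((theta_prev - theta_curr) + 90) mod 180 - 90`. Positive delta
#' means the previous stimulus is rotated in the direction that a positive
#' adjustment error would follow under attraction.
#'
#' @param theta_prev Orientation of the previous stimulus, degrees.
#' @param theta_curr Orientation of the current stimulus, degrees.
#' @return Signed difference in degrees, in `[-90, 90)`.
#' @examples
#' compute_delta(30, 10) # +20
#' compute_delta(10, 30) # -20
#' @export
compute_delta <- function(theta_prev, theta_curr) {
  if (!is.numeric(theta_prev) || !is.numeric(theta_curr) ||
      any(!is.finite(theta_prev)) || any(!is.finite(theta_curr))) {
    stop("`theta_prev` and `theta_curr` must be finite numeric values",
         call. = FALSE)
  }
  wrap_orientation(theta_prev - theta_curr)
}
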