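#' Parameters of the sigmoid decay schedules
#'
#' The temperature `T(x)` and loss-mixing weight `lambda(x)` schedules are both
#' built on the logistic sigmoid `sigmoid(steepness * (x - midpoint))` of the
#' training-progress fraction `x`:
#'
#' * `T(x) = scale * sigmoid(steepness * (x - midpoint))` rises in an S-curve
#'   from near 0 to just under `scale`, so the student first sees sharp,
#'   confident teacher targets and later flatter distributions carrying more
#'   dark knowledge.
#' * `lambda(x) = 1 - sigmoid(steepness * (x - midpoint))` falls symmetrically,
#'   shifting the total loss from the hard-label cross-entropy towards the
#'   soft (teacher) loss as training deepens.
#'
#' @param scale Peak temperature; the schedule's value range is `(0, scale)`.
#'   Dimensionless, default 3.
#' @param steepness Slope of the logistic transition, default 10.
#' @param midpoint Progress fraction at which the transition is centred, in
#'   `[0, 1]`; default 0.5. At the midpoint `lambda` is exactly 0.5.
#' @param literal_temperature If `TRUE`, evaluate the temperature schedule as
#'   `scale * sigmoid(steepness * x - midpoint)` (midpoint outside the
#'   parenthesis). This variant does not start below 1 and is provided for
#'   diagnostics only; the default parenthesisation matches the lambda
#'   schedule and the intended early-sharp/late-soft behaviour.
#' @return An object of class `"schedule_params"`.
#' @seealso [temperature_at()], [lambda_at()], [progress_fraction()]
#' @examples
#' p <- schedule_params()
#' temperature_at(0.5, p)  # 1.5
#' lambda_at(0.5, p)       # 0.5
#' @export
schedule_params <- function(scale = 3, steepness = 10, midpoint = 0.5,
                            literal_temperature = FALSE) {
  stopifnot(
    is.numeric(scale), length(scale) == 1L, is.finite(scale), scale > 0,
    is.numeric(steepness), length(steepness) == 1L, is.finite(steepness), steepness > 0,
    is.numeric(midpoint), length(midpoint) == 1L, is.finite(midpoint),
    midpoint >= 0, midpoint <= 1,
    is.logical(literal_temperature), length(literal_temperature) == 1L
  )
  structure(
    list(scale = scale, steepness = steepness, midpoint = midpoint,
         literal_temperature = literal_temperature),
    class = "schedule_params"
  )
}

#' Numerically stable logistic sigmoid
#'
#' Branches on the sign of the argument so `exp()` is only ever taken of a
#' non-positive value; safe for |z| up to at least 700.
#'
#' @param z Numeric vector.
#' @return `1 / (1 + exp(-z))`, elementwise.
#' @export
stable_sigmoid <- function(z) {
  out <- numeric(length(z))
  pos <- z >= 0
  out[pos] <- 1 / (1 + exp(-z[pos]))
  ez <- exp(z[!pos])
  out[!pos] <- ez / (1 + ez)
  out
}

#' Training-progress fraction
#'
#' The progress index driving both decay schedules: the quotient of the
#' current optimizer step and the total number of optimizer steps, clamped to
#' `[0, 1]`.
#'
#' @param step Current step (non-negative integer, `<= total_steps`).
#' @param total_steps Total number of steps (positive integer).
#' @return Numeric fraction in `[0, 1]`. Vectorized over `step`.
#' @examples
#' progress_fraction(30, 60)  # 0.5
#' @export
progress_fraction <- function(step, total_steps) {
  if (!is.numeric(total_steps) || length(total_steps) != 1L ||
      !is.finite(total_steps) || total_steps < 1) {
    stop("`total_steps` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(step) || any(!is.finite(step)) || any(step < 0)) {
    stop("`step` must be a non-negative number", call. = FALSE)
  }
  if (any(step > total_steps)) {
    stop("`step` must not exceed `total_steps`", call. = FALSE)
  }
  pmin(pmax(step / total_steps, 0), 1)
}

# shared clamp: temperatures below this are raised to it before any division
.t_floor <- 1e-3

#' Distillation temperature at a training-progress fraction
#'
#' @param x Progress fraction(s) in `[0, 1]` (see [progress_fraction()]).
#' @param params A [schedule_params()] object.
#' @return Temperature value(s) in `(0, scale)`, floored at 1e-3.
#' @examples
#' temperature_at(c(0, 0.5, 1))
#' @export
temperature_at <- function(x, params = schedule_params()) {
  check_progress(x)
  stopifnot(inherits(params, "schedule_params"))
  z <- if (isTRUE(params$literal_temperature)) {
    params$steepness * x - params$midpoint
  } else {
    params$steepness * (x - params$midpoint)
  }
  pmax(params$scale * stable_sigmoid(z), .t_floor)
}

#' Loss-mixing weight at a training-progress fraction
#'
#' `lambda` weights the hard-label cross-entropy in the total loss
#' `(1 - lambda) * L_soft + lambda * L_hard`; it decays from near 1 to near 0
#' so supervision shifts from ground truth to the fused teacher soft label.
#'
#' @inheritParams temperature_at
#' @return Weight value(s) in `(0, 1)`.
#' @examples
#' lambda_at(c(0, 0.5, 1))
#' @export
lambda_at <- function(x, params = schedule_params()) {
  check_progress(x)
  stopifnot(inherits(params, "schedule_params"))
  1 - stable_sigmoid(params$steepness * (x - params$midpoint))
}

check_progress <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("progress `x` must be finite numeric", call. = FALSE)
  }
  if (any(x < 0) || any(x > 1)) {
    stop("progress `x` must lie in [0, 1]", call. = FALSE)
  }
  invisible(x)
}
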