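#' Calibration function: DO position to beam command voltage
#'
#' Wraps measured (detection-objective position, beam command voltage) knots
#' with a cubic interpolant. The interpolant passes exactly through every
#' knot; evaluation outside the knot domain is an error (no extrapolation).
#' `max_dev_from_linear` records how far the cubic departs from the straight
#' line through the first and last knots — the correction that a purely
#' linear start/end alignment would miss.
#'
#' @param do_positions DO positions of the knots, um (length >= 2, distinct).
#' @param voltages Beam command voltages at the knots, V.
#' @return An object of class `calibration_function` with fields `knots`
#'   (data.frame `do`, `volt`), `domain`, and `max_dev_from_linear` (V).
#' @seealso [eval_calibration()], [calibrate_axial_mapping()]
#' @export
#' @examples
#' cf <- calibration_function(c(0, 50, 100, 150, 200),
#'                            c(0, 0.53, 1.04, 1.53, 2.0))
#' eval_calibration(cf, 100)
calibration_function <- function(do_positions, voltages) {
  if (length(do_positions) < 2 || length(voltages) != length(do_positions)) {
    stop("calibration needs >= 2 (do_position, voltage) knots")
  }
  if (anyDuplicated(do_positions)) stop("duplicate DO positions in knots")
  ord <- order(do_positions)
  x <- as.numeric(do_positions[ord])
  v <- as.numeric(voltages[ord])
  fun <- splinefun(x, v, method = "fmm")

  # deviation from the line through the endpoints, on a dense grid
  grid <- seq(x[1], x[length(x)], length.out = 512)
  line <- v[1] + (grid - x[1]) / (x[length(x)] - x[1]) * (v[length(v)] - v[1])
  max_dev <- max(abs(fun(grid) - line))

  structure(list(
    knots = data.frame(do = x, volt = v),
    domain = range(x),
    max_dev_from_linear = max_dev,
    .fun = fun
  ), class = "calibration_function")
}

#' Evaluate a calibration function
#'
#' @param calib A [calibration_function()].
#' @param do_position DO positions, um; must lie within the knot domain.
#' @return Beam command voltages, V.
#' @export
eval_calibration <- function(calib, do_position) {
  stopifnot(inherits(calib, "calibration_function"))
  eps <- 1e-9 * max(1, diff(calib$domain))
  if (any(do_position < calib$domain[1] - eps |
          do_position > calib$domain[2] + eps)) {
    stop(sprintf("DO position outside calibration domain [%g, %g] um",
                 calib$domain[1], calib$domain[2]))
  }
  calib$.fun(clamp(do_position, calib$domain[1], calib$domain[2]))
}

#' @export
print.calibration_function <- function(x, ...) {
  cat(sprintf("<calibration_function> %d knots over DO [%g, %g] um\n",
              nrow(x$knots), x$domain[1], x$domain[2]))
  cat(sprintf("  max deviation from linear: %.5f V\n", x$max_dev_from_linear))
  invisible(x)
}
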