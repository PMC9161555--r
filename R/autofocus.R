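# Fourier-spectrum focus measure and automatic beam-to-focal-plane
# alignment. A well-aligned excitation beam produces sharper images, i.e.
# more power at high spatial frequencies; the measure counts how far the
# radially averaged log power spectrum stays above a noise-derived
# threshold.

#' Radially averaged log power spectrum of an image
#'
#' Fourier-transforms the image, centers the 2-D power spectrum, resamples
#' it on a polar grid (bilinear interpolation), averages along the angular
#' dimension and takes the logarithm. The DC bin is excluded. The log is
#' floored at `1e-12 * max(power)` so zero bins stay finite; because the
#' floor is relative, the whole spectrum shifts by an additive constant
#' under multiplicative intensity scaling.
#'
#' @param image 2-D numeric matrix, at least 16 x 16, finite, non-negative.
#' @param n_angular Number of angular samples of the polar grid.
#' @return An object of class `radial_spectrum` with fields `values`
#'   (log-power per radial bin), `radii` (bin index = pixel distance after
#'   the polar transformation, starting at 1), `n_radial_bins`,
#'   `n_angular_bins`.
#' @export
radial_log_spectrum <- function(image, n_angular = 360L) {
  image <- as.matrix(image)
  h <- nrow(image); w <- ncol(image)
  if (h < 16 || w < 16) stop("image must be at least 16 x 16")
  if (!all(is.finite(image))) stop("image contains non-finite values")
  if (any(image < 0)) stop("image contains negative values")
  if (all(image == 0)) stop("empty image")

  pw <- Mod(fft(image))^2
  # center the spectrum (fftshift)
  pw <- pw[c((floor(h / 2) + 1):h, 1:floor(h / 2)),
           c((floor(w / 2) + 1):w, 1:floor(w / 2)), drop = FALSE]
  cy <- floor(h / 2) + 1
  cx <- floor(w / 2) + 1
  # exclude DC entirely: its power (the squared image sum) would otherwise
  # leak into the lowest radial bins through the bilinear resampling
  pw[cy, cx] <- 0

  n_radial <- floor(min(h, w) / 2)
  radii <- seq_len(n_radial)                   # DC (r = 0) excluded
  theta <- (seq_len(n_angular) - 1L) * 2 * pi / n_angular
  ry <- outer(radii, sin(theta))               # n_radial x n_angular
  rx <- outer(radii, cos(theta))
  yy <- clamp(cy + ry, 1, h)
  xx <- clamp(cx + rx, 1, w)

  y0 <- pmin(floor(yy), h - 1); x0 <- pmin(floor(xx), w - 1)
  fy <- yy - y0; fx <- xx - x0
  idx <- function(r, c) (c - 1) * h + r
  vals <- pw[idx(y0, x0)] * (1 - fy) * (1 - fx) +
    pw[idx(y0 + 1, x0)] * fy * (1 - fx) +
    pw[idx(y0, x0 + 1)] * (1 - fy) * fx +
    pw[idx(y0 + 1, x0 + 1)] * fy * fx
  radial_mean <- rowMeans(matrix(vals, n_radial, n_angular))

  # relative log floor; a constant image has no off-DC power at all, in
  # which case the floor value is immaterial (all bins equal)
  eps <- if (max(pw) > 0) 1e-12 * max(pw) else 1
  structure(list(values = log(radial_mean + eps), radii = radii,
                 n_radial_bins = n_radial, n_angular_bins = n_angular),
            class = "radial_spectrum")
}

#' Focus measure of an image
#'
#' Thresholds the radially averaged log power spectrum at the mean plus
#' three standard deviations of its baseline band — the outer
#' `baseline_fraction` of radial bins, which in real images carry only
#' noise — and counts the bins above threshold. Sharper images keep
#' spectral power above the noise floor out to higher frequencies, so the
#' count grows with image resolution. The measure is invariant under
#' multiplicative intensity scaling.
#'
#' @param image 2-D numeric matrix (see [radial_log_spectrum()]).
#' @param baseline_fraction Fraction of the highest-frequency radial bins
#'   used to estimate the noise floor.
#' @param n_angular Angular samples of the polar grid.
#' @return An object of class `focus_measure` with fields `count` (bins
#'   above threshold), `f_max` (largest radius above threshold; 0 when no
#'   bin exceeds the threshold), and `threshold` (log-power).
#' @export
#' @examples
#' img <- matrix(rexp(64 * 64), 64, 64)
#' fm <- focus_measure(img)
#' fm$count
focus_measure <- function(image, baseline_fraction = 0.25,
                          n_angular = 360L) {
  rs <- radial_log_spectrum(image, n_angular = n_angular)
  nb <- max(2L, as.integer(round(baseline_fraction * rs$n_radial_bins)))
  baseline <- tail(rs$values, nb)
  threshold <- mean(baseline) + 3 * sd(baseline)
  above <- which(rs$values > threshold)
  structure(list(count = length(above),
                 f_max = if (length(above)) max(rs$radii[above]) else 0L,
                 threshold = threshold,
                 n_radial_bins = rs$n_radial_bins),
            class = "focus_measure")
}

#' Image resolution estimate from the maximum frequency component
#'
#' Half the wavelength of the highest spatial frequency with power above
#' the noise floor: `image_dim * pixel_dim / (2 * f_max)`, where `f_max`
#' is the pixel distance of that component after the polar transformation.
#' For non-square images use the shorter dimension.
#'
#' @param image_dim Image dimension, px.
#' @param pixel_dim Physical pixel size, um/px (0.405 um/px on the
#'   reference camera).
#' @param f_max Maximum frequency component (radial bin index >= 1).
#' @return Resolution, um.
#' @export
#' @examples
#' estimate_resolution(2048, 0.405, 1024)  # Nyquist: the pixel size
estimate_resolution <- function(image_dim, pixel_dim, f_max) {
  stopifnot(is_number(image_dim), is_number(pixel_dim))
  if (!is_number(f_max) || f_max < 1) {
    stop("resolution undefined: f_max must be >= 1")
  }
  image_dim * pixel_dim / (2 * f_max)
}

#' Normalize focus measures to [0, 1]
#'
#' Affine rescaling so the poorest resolution in a sweep maps to 0 and the
#' best to 1.
#'
#' @param raw Numeric vector of at least 3 focus-measure counts, not all
#'   equal.
#' @return Numeric vector in `[0, 1]`.
#' @export
normalize_measures <- function(raw) {
  if (length(raw) < 3) stop("need at least 3 focus measures to normalize")
  rng <- range(raw)
  if (rng[1] == rng[2]) {
    stop("degenerate focus sweep: all measures equal; autofocus aborted")
  }
  (raw - rng[1]) / (rng[2] - rng[1])
}

#' Fit a Gaussian to normalized focus measures
#'
#' Bounded least-squares fit of `offset + amplitude *
#' exp(-(x - center)^2 / (2 * width^2))`; the fitted center is the best
#' focal plane. Initialization: center at the argmax, amplitude 1, offset
#' 0, width a quarter of the sweep span. The fit fails (an error, so the
#' caller can widen the sweep) when the optimizer does not converge, when
#' the center escapes the swept range, or when the width collapses to the
#' sampling step — the signature of a spike rather than a focus peak.
#'
#' @param positions Beam axial positions, um (>= 5 points).
#' @param normalized Normalized focus measures from [normalize_measures()].
#' @return List with `amplitude`, `center`, `width`, `offset`,
#'   `best_position` (= center, um).
#' @export
fit_best_focus <- function(positions, normalized) {
  if (length(positions) < 5) stop("need at least 5 sweep points to fit")
  if (length(normalized) != length(positions)) {
    stop("positions and normalized measures differ in length")
  }
  x <- as.numeric(positions); y <- as.numeric(normalized)
  span <- diff(range(x))
  step <- median(diff(sort(x)))
  lower <- c(a = 0.05, mu = min(x), w = 0.75 * step, b = -0.5)
  upper <- c(a = 1.5, mu = max(x), w = span, b = 0.5)

  # multi-start over initial widths: the Levenberg-Marquardt basin depends
  # strongly on the width guess, and focus peaks range from a few steps to
  # most of the sweep. The center start is nudged off the argmax grid point:
  # exactly symmetric residuals there can make the initial Jacobian singular.
  mu0 <- clamp(x[which.max(y)] + 0.123 * step, min(x), max(x))
  best <- NULL
  for (w0 in unique(pmax(lower[["w"]] * 1.5,
                         c(span / 4, span / 8, span / 16, 2 * step)))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ b + a * exp(-(x - mu)^2 / (2 * w^2)),
                        start = list(a = 1, mu = mu0, w = w0,
                                     b = 0),
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || stats::deviance(fit) < stats::deviance(best)) {
      best <- fit
    }
  }
  if (is.null(best)) stop("best-focus fit failed to converge")
  p <- stats::coef(best)
  tol <- 1e-6 * max(1, span)
  if (p[["mu"]] <= min(x) + tol || p[["mu"]] >= max(x) - tol) {
    stop("best-focus fit failed: fitted center outside the swept range")
  }
  if (p[["w"]] <= lower[["w"]] + tol) {
    stop("best-focus fit failed: fitted width collapsed to the sweep step")
  }
  list(amplitude = unname(p["a"]), center = unname(p["mu"]),
       width = unname(p["w"]), offset = unname(p["b"]),
       best_position = unname(p["mu"]))
}

#' Run an autofocus sweep
#'
#' Acquires images at `n_planes` axial beam positions spaced `step` um and
#' centered on `center`, computes the focus measure for each, normalizes to
#' [0, 1], and fits a Gaussian whose center is the best focal plane.
#'
#' @param acquire Function of one argument (beam axial position, um)
#'   returning a 2-D image matrix — typically a simulated or real camera.
#' @param center Sweep center, um.
#' @param n_planes Number of sweep positions (default 41).
#' @param step Sweep spacing, um (default 1).
#' @param baseline_fraction Passed to [focus_measure()].
#' @return An object of class `focus_sweep` with fields `positions`, `raw`
#'   (counts), `normalized`, `fit`, `best_position` (um), `n_images`.
#' @export
run_focus_sweep <- function(acquire, center = 0, n_planes = 41L, step = 1.0,
                            baseline_fraction = 0.25) {
  stopifnot(is.function(acquire), n_planes >= 5, step > 0)
  positions <- center + (seq_len(n_planes) - (n_planes + 1) / 2) * step
  raw <- vapply(positions, function(p) {
    img <- acquire(p)
    as.numeric(focus_measure(img, baseline_fraction = baseline_fraction)$count)
  }, numeric(1))
  normalized <- normalize_measures(raw)
  fit <- fit_best_focus(positions, normalized)
  structure(list(positions = positions, raw = raw, normalized = normalized,
                 fit = fit, best_position = fit$best_position,
                 n_images = length(positions)),
            class = "focus_sweep")
}

#' @export
print.focus_sweep <- function(x, ...) {
  cat(sprintf("<focus_sweep> %d planes over [%g, %g] um\n", x$n_images,
              min(x$positions), max(x$positions)))
  cat(sprintf("  best focus at %.3f um (fit width %.2f um)\n",
              x$best_position, x$fit$width))
  invisible(x)
}

#' Calibrate the DO-position to beam-voltage mapping
#'
#' Runs one autofocus sweep at each of `n_do_positions` detection-objective
#' positions evenly spaced over `[do_start, do_end]` (default five, per
#' beam), converts each best beam position to a command voltage, and
#' returns the cubic [calibration_function()] through the knots. The
#' scanning galvanometer's angle is not exactly linear in the beam's axial
#' position, so the cubic can deviate from the line through the endpoints;
#' `max_dev_from_linear` reports that deviation.
#'
#' @param acquire Function `(do_position, beam_offset_um) -> image`: the
#'   camera imaging at a DO position with the beam offset by
#'   `beam_offset_um` from the linear voltage estimate.
#' @param scan A [scan_config()]; supplies the DO range, linear fallback
#'   voltages and `beam_gain` (V/um).
#' @param n_do_positions Number of DO probe positions (default 5).
#' @param n_planes,step Sweep parameters, see [run_focus_sweep()].
#' @return A [calibration_function()] with, additionally, a `sweeps` field
#'   (the per-position `focus_sweep` objects) and `do_probes`.
#' @export
calibrate_axial_mapping <- function(acquire, scan, n_do_positions = 5L,
                                    n_planes = 41L, step = 1.0) {
  validate_scan_config(scan)
  stopifnot(is.function(acquire), n_do_positions >= 2)
  do_probes <- seq(scan$do_start, scan$do_end, length.out = n_do_positions)
  lin_volt <- function(d) {
    scan$beam_volt_start + (d - scan$do_start) /
      (scan$do_end - scan$do_start) *
      (scan$beam_volt_end - scan$beam_volt_start)
  }
  sweeps <- vector("list", n_do_positions)
  volts <- numeric(n_do_positions)
  for (i in seq_len(n_do_positions)) {
    d <- do_probes[i]
    sw <- tryCatch(
      run_focus_sweep(function(off) acquire(d, off), center = 0,
                      n_planes = n_planes, step = step),
      error = function(e) e)
    if (inherits(sw, "error")) {
      stop(sprintf("calibration aborted: sweep failed at DO position %g um (%s)",
                   d, conditionMessage(sw)))
    }
    sweeps[[i]] <- sw
    volts[i] <- lin_volt(d) + sw$best_position * scan$beam_gain
  }
  cf <- calibration_function(do_probes, volts)
  cf$sweeps <- sweeps
  cf$do_probes <- do_probes
  cf
}
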