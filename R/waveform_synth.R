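# Waveform synthesis: the per-volume control program. All trains share one
# sample clock (scan$sample_rate) and one length (samples_per_volume).

new_analog_train <- function(samples, label, sample_rate) {
  stopifnot(all(is.finite(samples)))
  structure(list(samples = as.numeric(samples), label = label,
                 sample_rate = sample_rate), class = "analog_train")
}

new_gate_train <- function(samples, label, sample_rate) {
  structure(list(samples = as.logical(samples), label = label,
                 sample_rate = sample_rate), class = "gate_train")
}

# Sample index (0-based) at which plane i (1-based) starts.
plane_start_sample <- function(scan, i) {
  as.integer(round((i - 1) * scan$sample_rate / scan$frame_rate))
}

#' Build the camera trigger train for one volume
#'
#' One pulse per plane at the plane's start time. Pulse amplitudes encode the
#' position within the volume — 4.5 V for the first plane, 4.0 V for middle
#' planes and 3.5 V for the last (defaults) — all above the 3.3 V triggering
#' threshold, so behavioral software listening on the same line can count
#' volumes by voltage thresholding. A single-plane volume uses the
#' first-plane amplitude (the start-of-volume marker wins).
#'
#' @param scan A [scan_config()].
#' @return An object of class `trigger_train` with fields `samples` (V, on
#'   the common clock), `pulse_starts` (0-based sample indices) and
#'   `pulse_amplitudes` (V).
#' @export
#' @examples
#' tr <- build_camera_triggers(scan_config(n_planes = 3))
#' tr$pulse_amplitudes  # 4.5 4.0 3.5
build_camera_triggers <- function(scan) {
  validate_scan_config(scan)
  n <- scan$n_planes
  amps <- if (n == 1) {
    scan$trigger_amp_first
  } else {
    c(scan$trigger_amp_first, rep(scan$trigger_amp_mid, n - 2),
      scan$trigger_amp_last)
  }
  n_samples <- samples_per_volume(scan)
  width <- max(1L, as.integer(round(scan$trigger_width / 1000 * scan$sample_rate)))
  starts <- plane_start_sample(scan, seq_len(n))
  if (n > 1 && width > min(diff(starts))) {
    stop("trigger pulses overlap: trigger_width too large for frame_rate")
  }
  samples <- rep(scan$trigger_low, n_samples)
  for (i in seq_len(n)) {
    idx <- (starts[i] + 1L):min(starts[i] + width, n_samples)
    samples[idx] <- amps[i]
  }
  structure(list(samples = samples, pulse_starts = starts,
                 pulse_amplitudes = amps, sample_rate = scan$sample_rate),
            class = "trigger_train")
}

#' Detection-objective position trajectory for one volume
#'
#' The unshifted periodic trajectory on the common clock: a linear ramp from
#' `do_start` to `do_end` over the forward portion of the volume, followed
#' by a smooth half-cosine flyback occupying the final `flyback_fraction`
#' of the period.
#'
#' @param scan A [scan_config()].
#' @return Numeric vector of DO positions, um, length [samples_per_volume()].
#' @export
do_position_trajectory <- function(scan) {
  n_samples <- samples_per_volume(scan)
  n_fly <- as.integer(round(scan$flyback_fraction * n_samples))
  n_ramp <- n_samples - n_fly
  pos <- numeric(n_samples)
  pos[seq_len(n_ramp)] <- seq(scan$do_start, scan$do_end, length.out = n_ramp)
  if (n_fly > 0) {
    j <- seq_len(n_fly)
    pos[n_ramp + j] <- scan$do_start +
      (scan$do_end - scan$do_start) * 0.5 * (1 + cos(pi * j / n_fly))
  }
  pos
}

#' Build the piezo command train
#'
#' Converts the continuous DO trajectory to command volts (`piezo_gain`,
#' V/um) and circularly advances it by `piezo_delay` ms. The advance
#' compensates the lag between the piezo's analog input and the actual
#' motion of the detection objective; since scanning is continuous and
#' periodic, the shift is circular rather than zero-padded.
#'
#' @param scan A [scan_config()].
#' @return An `analog_train` (V).
#' @export
build_piezo_command <- function(scan) {
  validate_scan_config(scan)
  volts <- do_position_trajectory(scan) * scan$piezo_gain
  n <- length(volts)
  d <- as.integer(round(scan$piezo_delay / 1000 * scan$sample_rate)) %% n
  if (d > 0) volts <- volts[((seq_len(n) - 1L + d) %% n) + 1L]
  new_analog_train(volts, "piezo", scan$sample_rate)
}

#' Build the axial beam command train
#'
#' Keeps the excitation beam at the DO focal plane throughout the volume.
#' With a [calibration_function()] the command is the calibrated voltage at
#' each DO position (no extrapolation: the knot domain must cover the DO
#' range); without one it is the linear map from `[do_start, do_end]` to
#' `[beam_volt_start, beam_volt_end]`.
#'
#' @param scan A [scan_config()].
#' @param calib A [calibration_function()] or `NULL`.
#' @param label Channel label.
#' @return An `analog_train` (V).
#' @export
build_axial_beam_command <- function(scan, calib = NULL,
                                     label = "beam_axial") {
  validate_scan_config(scan)
  pos <- do_position_trajectory(scan)
  if (is.null(calib)) {
    v <- scan$beam_volt_start + (pos - scan$do_start) /
      (scan$do_end - scan$do_start) *
      (scan$beam_volt_end - scan$beam_volt_start)
  } else {
    if (calib$domain[1] > scan$do_start || calib$domain[2] < scan$do_end) {
      stop(sprintf(
        "calibration domain [%g, %g] um does not cover DO range [%g, %g] um",
        calib$domain[1], calib$domain[2], scan$do_start, scan$do_end))
    }
    v <- eval_calibration(calib, pos)
  }
  new_analog_train(v, label, scan$sample_rate)
}

#' Build the fast sheet-forming axis command
#'
#' Within each plane period a linear sweep across the sheet amplitude is
#' confined to the central `shutter_open_fraction` of the exposure — the
#' window in which the rolling shutter is fully open — with constant holds
#' before and after, so every camera row sees the full sweep.
#'
#' @param scan A [scan_config()].
#' @return An `analog_train` (V).
#' @export
build_sheet_command <- function(scan) {
  validate_scan_config(scan)
  n_samples <- samples_per_volume(scan)
  samples <- rep(scan$sheet_volt_min, n_samples)
  e <- as.integer(round(scan$exposure / 1000 * scan$sample_rate))
  sweep_len <- max(2L, as.integer(round(scan$shutter_open_fraction * e)))
  lead <- as.integer(round((e - sweep_len) / 2))
  for (i in seq_len(scan$n_planes)) {
    p0 <- plane_start_sample(scan, i)                       # 0-based
    p1 <- if (i < scan$n_planes) plane_start_sample(scan, i + 1) else n_samples
    s0 <- min(p0 + lead, p1 - sweep_len)                    # sweep start
    sweep <- seq(scan$sheet_volt_min, scan$sheet_volt_max,
                 length.out = sweep_len)
    samples[(s0 + 1L):(s0 + sweep_len)] <- sweep
    if (s0 + sweep_len < p1) samples[(s0 + sweep_len + 1L):p1] <- scan$sheet_volt_max
  }
  new_analog_train(samples, "beam_sheet", scan$sample_rate)
}

#' Assemble the full per-volume control program
#'
#' Generates every command train on one common clock: amplitude-encoded
#' camera triggers, the delayed piezo ramp, axial beam commands for the side
#' and front beams (optionally calibrated per beam), the sheet sweep, and
#' the laser gates. An eye-exclusion ROI gates the side beam only; the front
#' beam scans between the eyes and is never gated.
#'
#' @param scan A [scan_config()].
#' @param calib `NULL`, a single [calibration_function()] applied to both
#'   beams, or a list with elements `side` and/or `front`.
#' @param roi An [ellipse_roi()] or `NULL`.
#' @return An object of class `waveform_bundle`.
#' @export
assemble_volume_program <- function(scan, calib = NULL, roi = NULL) {
  validate_scan_config(scan)
  pick <- function(which) {
    if (is.null(calib)) NULL
    else if (inherits(calib, "calibration_function")) calib
    else calib[[which]]
  }
  trigger <- build_camera_triggers(scan)
  piezo <- build_piezo_command(scan)
  side <- build_axial_beam_command(scan, pick("side"), "beam_axial_side")
  front <- build_axial_beam_command(scan, pick("front"), "beam_axial_front")
  sheet <- build_sheet_command(scan)
  n_samples <- samples_per_volume(scan)
  gate_front <- new_gate_train(rep(TRUE, n_samples), "gate_front",
                               scan$sample_rate)
  gate_side <- if (is.null(roi)) {
    new_gate_train(rep(TRUE, n_samples), "gate_side", scan$sample_rate)
  } else {
    gates_for_volume(roi, scan, sheet)
  }
  structure(list(trigger = trigger, piezo = piezo, beam_axial_side = side,
                 beam_axial_front = front, beam_sheet = sheet,
                 gate_side = gate_side, gate_front = gate_front,
                 sample_rate = scan$sample_rate, n_samples = n_samples),
            class = "waveform_bundle")
}

#' @export
print.waveform_bundle <- function(x, ...) {
  cat(sprintf("<waveform_bundle> %d samples @ %g Hz (%.3f s per volume)\n",
              x$n_samples, x$sample_rate, x$n_samples / x$sample_rate))
  cat(sprintf("  %d trigger pulses; side gate %.1f%% on\n",
              length(x$trigger$pulse_starts),
              100 * mean(x$gate_side$samples)))
  invisible(x)
}
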