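#' Scan configuration
#'
#' Describes one volumetric or single-plane scan program. Unit conventions
#' used throughout the package: positions in micrometres (um), times in
#' milliseconds (ms), voltages in volts (V), rates in hertz (Hz).
#'
#' The defaults describe the whole-brain preset: 45 planes per volume at a
#' 45 Hz frame rate (one volume per second) spanning 220 um of detection
#' objective (DO) travel.
#'
#' @param n_planes Integer number of planes per volume.
#' @param plane_spacing Axial spacing between planes, um.
#' @param exposure Camera exposure per plane, ms. Must fit inside one frame
#'   period (`1000 / frame_rate`).
#' @param frame_rate Per-plane camera rate, Hz.
#' @param do_start,do_end Detection-objective positions at the start and end
#'   of the volume, um (`do_end > do_start`).
#' @param beam_volt_start,beam_volt_end Axial beam command voltages used as
#'   linear fallback endpoints when no calibration function is supplied, V.
#' @param piezo_delay Time advance applied to the piezo command to compensate
#'   actuator lag, ms (typical 10-20).
#' @param sample_rate Output sample rate shared by all command trains, Hz.
#' @param trigger_amp_first,trigger_amp_mid,trigger_amp_last Camera trigger
#'   pulse amplitudes, V. The first plane of a volume is marked 4.5 V, middle
#'   planes 4.0 V and the last plane 3.5 V so downstream behavioral software
#'   can detect volume boundaries by voltage thresholding.
#' @param trigger_threshold Camera/behavior triggering threshold, V; every
#'   pulse amplitude must exceed it.
#' @param trigger_low Inter-pulse baseline level, V.
#' @param trigger_width Trigger pulse width, ms; pulses must not overlap.
#' @param single_plane_chunk Frames per file in single-plane mode.
#' @param mode `"volumetric"` or `"single_plane"`.
#' @param shutter_open_fraction Fraction of the exposure during which the
#'   rolling shutter is fully open; the sheet sweep is confined to the
#'   central window of this width.
#' @param flyback_fraction Fraction of the volume period used by the smooth
#'   piezo/beam return from `do_end` to `do_start`.
#' @param piezo_gain Piezo command gain, V per um of DO travel.
#' @param beam_gain Axial beam scanner gain, V per um of beam travel.
#' @param sheet_volt_min,sheet_volt_max Fast sheet-forming axis command
#'   range, V.
#' @param sheet_gain Sheet axis gain, V per um of in-plane beam travel; maps
#'   the sheet command to the lateral (y) scan coordinate used by the
#'   eye-exclusion module.
#'
#' @return A validated object of class `scan_config`.
#' @seealso [validate_scan_config()], [whole_brain_preset()]
#' @export
#' @examples
#' scan <- scan_config(n_planes = 45)
#' scan$trigger_amp_first
scan_config <- function(n_planes = 45L,
                        plane_spacing = 5,
                        exposure = 15,
                        frame_rate = 45,
                        do_start = 0,
                        do_end = 220,
                        beam_volt_start = 0,
                        beam_volt_end = 2.2,
                        piezo_delay = 15,
                        sample_rate = 50000,
                        trigger_amp_first = 4.5,
                        trigger_amp_mid = 4.0,
                        trigger_amp_last = 3.5,
                        trigger_threshold = 3.3,
                        trigger_low = 0,
                        trigger_width = 1,
                        single_plane_chunk = 100L,
                        mode = c("volumetric", "single_plane"),
                        shutter_open_fraction = 0.8,
                        flyback_fraction = 0.05,
                        piezo_gain = 0.1,
                        beam_gain = 0.01,
                        sheet_volt_min = -1,
                        sheet_volt_max = 1,
                        sheet_gain = 0.005) {
  mode <- match.arg(mode)
  scan <- structure(list(
    n_planes = as.integer(n_planes),
    plane_spacing = as.numeric(plane_spacing),
    exposure = as.numeric(exposure),
    frame_rate = as.numeric(frame_rate),
    do_start = as.numeric(do_start),
    do_end = as.numeric(do_end),
    beam_volt_start = as.numeric(beam_volt_start),
    beam_volt_end = as.numeric(beam_volt_end),
    piezo_delay = as.numeric(piezo_delay),
    sample_rate = as.numeric(sample_rate),
    trigger_amp_first = as.numeric(trigger_amp_first),
    trigger_amp_mid = as.numeric(trigger_amp_mid),
    trigger_amp_last = as.numeric(trigger_amp_last),
    trigger_threshold = as.numeric(trigger_threshold),
    trigger_low = as.numeric(trigger_low),
    trigger_width = as.numeric(trigger_width),
    single_plane_chunk = as.integer(single_plane_chunk),
    mode = mode,
    shutter_open_fraction = as.numeric(shutter_open_fraction),
    flyback_fraction = as.numeric(flyback_fraction),
    piezo_gain = as.numeric(piezo_gain),
    beam_gain = as.numeric(beam_gain),
    sheet_volt_min = as.numeric(sheet_volt_min),
    sheet_volt_max = as.numeric(sheet_volt_max),
    sheet_gain = as.numeric(sheet_gain)
  ), class = "scan_config")
  validate_scan_config(scan)
}

# Names of scan_config fields that are numeric scalars (all but mode).
scan_numeric_fields <- function() {
  c("n_planes", "plane_spacing", "exposure", "frame_rate", "do_start",
    "do_end", "beam_volt_start", "beam_volt_end", "piezo_delay",
    "sample_rate", "trigger_amp_first", "trigger_amp_mid",
    "trigger_amp_last", "trigger_threshold", "trigger_low", "trigger_width",
    "single_plane_chunk", "shutter_open_fraction", "flyback_fraction",
    "piezo_gain", "beam_gain", "sheet_volt_min", "sheet_volt_max",
    "sheet_gain")
}

scan_field_names <- function() c(scan_numeric_fields(), "mode")

#' Validate a scan configuration
#'
#' Checks every structural invariant of a [scan_config()] and fails with a
#' message naming each violated field.
#'
#' @param scan A `scan_config` (or a bare list with the same fields).
#' @return The validated `scan_config`, invisibly classed.
#' @export
validate_scan_config <- function(scan) {
  bad <- character(0)
  chk <- function(ok, field) if (!isTRUE(ok)) bad <<- c(bad, field)

  for (f in scan_numeric_fields()) {
    chk(is_number(scan[[f]]), f)
  }
  chk(scan$mode %in% c("volumetric", "single_plane"), "mode")
  if (length(bad) > 0) {
    stop("invalid scan configuration; bad fields: ", paste(bad, collapse = ", "))
  }

  chk(scan$n_planes >= 1, "n_planes")
  chk(scan$plane_spacing > 0, "plane_spacing")
  chk(scan$do_end > scan$do_start, "do_end")
  chk(scan$frame_rate > 0, "frame_rate")
  chk(scan$exposure > 0 && scan$exposure <= 1000 / scan$frame_rate, "exposure")
  chk(scan$sample_rate * scan$exposure / 1000 >= 2, "sample_rate")
  amps <- c(scan$trigger_amp_first, scan$trigger_amp_mid, scan$trigger_amp_last)
  chk(scan$trigger_low < scan$trigger_threshold, "trigger_low")
  chk(scan$trigger_threshold < min(amps), "trigger_threshold")
  chk(scan$trigger_width > 0 && scan$trigger_width < 1000 / scan$frame_rate,
      "trigger_width")
  chk(scan$piezo_delay >= 0 &&
        scan$piezo_delay < 1000 * scan$n_planes / scan$frame_rate, "piezo_delay")
  chk(scan$single_plane_chunk >= 1, "single_plane_chunk")
  chk(scan$shutter_open_fraction > 0 && scan$shutter_open_fraction <= 1,
      "shutter_open_fraction")
  chk(scan$flyback_fraction >= 0 && scan$flyback_fraction < 0.5,
      "flyback_fraction")
  chk(scan$piezo_gain > 0, "piezo_gain")
  chk(scan$beam_gain > 0, "beam_gain")
  chk(scan$sheet_volt_max > scan$sheet_volt_min, "sheet_volt_max")
  chk(scan$sheet_gain > 0, "sheet_gain")

  if (length(bad) > 0) {
    stop("invalid scan configuration; bad fields: ", paste(bad, collapse = ", "))
  }
  class(scan) <- "scan_config"
  invisible(scan)
}

#' Whole-brain imaging preset
#'
#' Volumetric preset matching continuous whole-brain acquisition in larval
#' zebrafish: 45 planes per volume at one volume per second.
#'
#' @param ... Overrides passed on to [scan_config()].
#' @return A `scan_config`.
#' @export
whole_brain_preset <- function(...) {
  args <- modifyList(list(n_planes = 45L, frame_rate = 45, plane_spacing = 5,
                          do_start = 0, do_end = 220, mode = "volumetric"),
                     list(...))
  do.call(scan_config, args)
}

#' Samples per volume on the common output clock
#'
#' @param scan A `scan_config`.
#' @return Integer number of samples covering one volume period.
#' @export
samples_per_volume <- function(scan) {
  as.integer(round(scan$sample_rate * scan$n_planes / scan$frame_rate))
}

#' @export
print.scan_config <- function(x, ...) {
  cat(sprintf("<scan_config> %s: %d planes @ %g Hz, %g um spacing\n",
              x$mode, x$n_planes, x$frame_rate, x$plane_spacing))
  cat(sprintf("  DO %g -> %g um, exposure %g ms, sample rate %g Hz\n",
              x$do_start, x$do_end, x$exposure, x$sample_rate))
  cat(sprintf("  triggers %g/%g/%g V over threshold %g V, piezo delay %g ms\n",
              x$trigger_amp_first, x$trigger_amp_mid, x$trigger_amp_last,
              x$trigger_threshold, x$piezo_delay))
  invisible(x)
}
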