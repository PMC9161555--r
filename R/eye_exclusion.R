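# Eye exclusion: convert a user-drawn elliptic ROI in the lateral (y-z)
# projection into per-plane laser-off intervals and a side-beam gate train.

#' Elliptic eye-exclusion region of interest
#'
#' Drawn by the experimenter on the lateral projection of a volumetric
#' stack; the side laser is turned off whenever the scanned sheet would
#' cross this ellipse, protecting the eye during whole-brain imaging.
#'
#' @param center_y Ellipse center along the in-plane scan axis, um.
#' @param center_z Ellipse center along the axial (DO) axis, um.
#' @param semi_y,semi_z Semi-axes, um (both > 0).
#' @return An object of class `ellipse_roi`.
#' @export
ellipse_roi <- function(center_y, center_z, semi_y, semi_z) {
  stopifnot(is_number(center_y), is_number(center_z),
            is_number(semi_y), is_number(semi_z))
  if (semi_y <= 0 || semi_z <= 0) stop("ellipse semi-axes must be positive")
  structure(list(center_y = center_y, center_z = center_z,
                 semi_y = semi_y, semi_z = semi_z), class = "ellipse_roi")
}

#' Chord of the exclusion ellipse at one axial plane
#'
#' @param roi An [ellipse_roi()].
#' @param z Axial plane position, um.
#' @return `c(y_lo, y_hi)` um, or `NULL` when the plane misses the ellipse.
#'   Points exactly on the ellipse boundary count as inside (safety-first).
#' @export
#' @examples
#' roi <- ellipse_roi(100, 50, 40, 20)
#' ellipse_chord(roi, 50)    # widest chord: 100 +/- 40
#' ellipse_chord(roi, 75)    # empty: outside the ellipse
ellipse_chord <- function(roi, z) {
  stopifnot(inherits(roi, "ellipse_roi"))
  dz <- (z - roi$center_z) / roi$semi_z
  if (abs(dz) > 1) return(NULL)
  w <- roi$semi_y * sqrt(max(0, 1 - dz^2))
  c(roi$center_y - w, roi$center_y + w)
}

# In-plane beam position (um) for each sample of the sheet command.
sheet_position_um <- function(scan, sheet_command) {
  (sheet_command$samples - scan$sheet_volt_min) / scan$sheet_gain
}

#' Side-beam gate train for one volume
#'
#' For every output sample, the gate is off (`FALSE`) exactly when the
#' sample's plane and the beam's in-plane position fall inside the exclusion
#' ellipse. Gating is computed from each plane's nominal z (the plane
#' center): planes are thin relative to the eye. Boundary samples count as
#' inside. A ROI entirely outside the scanned volume yields an all-on gate
#' with a warning.
#'
#' @param roi An [ellipse_roi()].
#' @param scan A [scan_config()].
#' @param sheet_command The `analog_train` from [build_sheet_command()],
#'   mapped to in-plane position via `sheet_gain`.
#' @return A `gate_train` (logical; `TRUE` = laser on).
#' @export
gates_for_volume <- function(roi, scan, sheet_command) {
  stopifnot(inherits(roi, "ellipse_roi"))
  validate_scan_config(scan)
  n_samples <- length(sheet_command$samples)
  y <- sheet_position_um(scan, sheet_command)
  y_span <- (scan$sheet_volt_max - scan$sheet_volt_min) / scan$sheet_gain
  plane_z <- scan$do_start + (seq_len(scan$n_planes) - 1L) * scan$plane_spacing

  chords <- lapply(plane_z, function(z) {
    ch <- ellipse_chord(roi, z)
    if (is.null(ch)) return(NULL)
    if (ch[2] < 0 || ch[1] > y_span) return(NULL)   # outside scan range
    clamp(ch, 0, y_span)
  })
  if (all(vapply(chords, is.null, logical(1)))) {
    warning("eye-exclusion ROI lies outside the scanned volume; gate all-on")
    return(new_gate_train(rep(TRUE, n_samples), "gate_side",
                          scan$sample_rate))
  }

  gate <- rep(TRUE, n_samples)
  for (i in seq_len(scan$n_planes)) {
    ch <- chords[[i]]
    if (is.null(ch)) next
    p0 <- plane_start_sample(scan, i) + 1L
    p1 <- if (i < scan$n_planes) plane_start_sample(scan, i + 1) else n_samples
    idx <- p0:p1
    gate[idx] <- !(y[idx] >= ch[1] & y[idx] <= ch[2])
  }
  new_gate_train(gate, "gate_side", scan$sample_rate)
}
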