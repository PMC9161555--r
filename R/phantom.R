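# Synthetic brain phantom and simulated camera. Emulates a larval zebrafish
# brain expressing a nuclear-localized fluorescent indicator: bright
# Gaussian-profile nuclei (< 5 um diameter) on a dim background, rendered
# plane by plane with blur that grows with beam/focal-plane misalignment.

#' Generate a nuclear-labeled brain phantom
#'
#' Places `n_nuclei` Gaussian-profile nuclei at uniformly random,
#' non-overlapping positions in a 3-D volume. Nucleus radii default to
#' 2-2.5 um (diameter under 5 um, the size of a zebrafish neuronal
#' nucleus). Identical seeds give bit-identical volumes.
#'
#' @param seed Integer seed; the single source of randomness.
#' @param n_nuclei Number of nuclei (>= 1).
#' @param dims Volume dimensions `c(ny, nx, nz)` in voxels, each >= 32.
#' @param voxel_size Isotropic voxel size, um.
#' @param background Background intensity, counts.
#' @param brightness_range Per-nucleus peak brightness range, counts.
#' @param radius_range Nucleus radius range, um.
#' @return An object of class `brain_phantom` with fields `volume` (3-D
#'   array), `nuclei` (data.frame `y`, `x`, `z` um, `radius`, `brightness`),
#'   `voxel_size`, `dims`, `seed`.
#' @export
generate_phantom <- function(seed, n_nuclei = 150L,
                             dims = c(128L, 128L, 64L), voxel_size = 1,
                             background = 10, brightness_range = c(800, 1200),
                             radius_range = c(2, 2.5)) {
  if (n_nuclei < 1) stop("n_nuclei must be >= 1")
  if (length(dims) != 3 || any(dims < 32)) {
    stop("phantom dims must be three values, each >= 32")
  }
  dims <- as.integer(dims)
  extent <- dims * voxel_size                   # um
  min_sep <- 2 * max(radius_range)              # non-overlap, um
  margin <- max(radius_range)

  with_seed(seed, {
    centers <- matrix(NA_real_, n_nuclei, 3)
    placed <- 0L
    attempts <- 0L
    max_attempts <- 200L * n_nuclei
    while (placed < n_nuclei) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop(sprintf(
          "cannot place %d non-overlapping nuclei in the volume (packed %d)",
          n_nuclei, placed))
      }
      cand <- runif(3, min = margin, max = extent - margin)
      if (placed > 0L) {
        d2 <- colSums((t(centers[seq_len(placed), , drop = FALSE]) - cand)^2)
        if (min(d2) < min_sep^2) next
      }
      placed <- placed + 1L
      centers[placed, ] <- cand
    }
    radius <- runif(n_nuclei, radius_range[1], radius_range[2])
    brightness <- runif(n_nuclei, brightness_range[1], brightness_range[2])

    vol <- array(background, dim = dims)
    ax <- lapply(dims, function(n) (seq_len(n) - 0.5) * voxel_size)
    for (i in seq_len(n_nuclei)) {
      sig <- radius[i] / 2                      # Gaussian sigma, um
      reach <- 3 * sig
      rng <- lapply(1:3, function(k) {
        which(abs(ax[[k]] - centers[i, k]) <= reach)
      })
      if (any(lengths(rng) == 0)) next
      gy <- exp(-(ax[[1]][rng[[1]]] - centers[i, 1])^2 / (2 * sig^2))
      gx <- exp(-(ax[[2]][rng[[2]]] - centers[i, 2])^2 / (2 * sig^2))
      gz <- exp(-(ax[[3]][rng[[3]]] - centers[i, 3])^2 / (2 * sig^2))
      blob <- brightness[i] * outer(outer(gy, gx), gz)
      vol[rng[[1]], rng[[2]], rng[[3]]] <-
        vol[rng[[1]], rng[[2]], rng[[3]]] + blob
    }
    structure(list(volume = vol,
                   nuclei = data.frame(y = centers[, 1], x = centers[, 2],
                                       z = centers[, 3], radius = radius,
                                       brightness = brightness),
                   voxel_size = voxel_size, dims = dims, seed = seed),
              class = "brain_phantom")
  })
}

#' @export
print.brain_phantom <- function(x, ...) {
  cat(sprintf("<brain_phantom> %d x %d x %d voxels (%g um), %d nuclei, seed %d\n",
              x$dims[1], x$dims[2], x$dims[3], x$voxel_size,
              nrow(x$nuclei), x$seed))
  invisible(x)
}

#' Simulated camera frame source
#'
#' Renders phantom planes the way the real detection path would see them:
#' the slice at the DO focal plane, blurred by an isotropic Gaussian whose
#' sigma grows linearly with the beam's axial misalignment, plus shot and
#' read noise, quantized to unsigned 16-bit. `true_mapping` is the ground
#' truth DO-position-to-beam-voltage function that autofocus and
#' calibration are asked to recover; choose `"quadratic"` to emulate
#' galvanometer nonlinearity with a configurable mid-range sag.
#'
#' @param phantom A [generate_phantom()] result.
#' @param scan A [scan_config()].
#' @param true_mapping `"linear"`, `"quadratic"`, or a function
#'   `(do_position_um) -> V`.
#' @param quad_sag_v Mid-range sag of the quadratic mapping, V.
#' @param shot_scale Shot-noise scale (photons per count); 0 disables.
#' @param read_noise_sd Gaussian read noise sigma, counts; 0 disables.
#' @param blur_gain Blur growth, px of sigma per um of misalignment.
#' @param base_blur In-focus blur sigma, px.
#' @return An object of class `frame_source`.
#' @export
frame_source <- function(phantom, scan, true_mapping = c("linear", "quadratic"),
                         quad_sag_v = 0.04, shot_scale = 1.0,
                         read_noise_sd = 2, blur_gain = 0.6,
                         base_blur = 0.5) {
  stopifnot(inherits(phantom, "brain_phantom"))
  validate_scan_config(scan)
  if (is.character(true_mapping)) {
    kind <- match.arg(true_mapping)
    lin <- function(d) {
      scan$beam_volt_start + (d - scan$do_start) /
        (scan$do_end - scan$do_start) *
        (scan$beam_volt_end - scan$beam_volt_start)
    }
    true_mapping <- if (kind == "linear") lin else function(d) {
      s <- (d - scan$do_start) / (scan$do_end - scan$do_start)
      lin(d) + 4 * quad_sag_v * s * (1 - s)
    }
  }
  stopifnot(is.function(true_mapping))
  structure(list(phantom = phantom, scan = scan, true_mapping = true_mapping,
                 shot_scale = shot_scale, read_noise_sd = read_noise_sd,
                 blur_gain = blur_gain, base_blur = base_blur,
                 seed = phantom$seed), class = "frame_source")
}

#' Defocus blur sigma for a given misalignment
#'
#' @param source A [frame_source()].
#' @param misalignment_um Beam axial misalignment, um.
#' @return Gaussian blur sigma, px: `base_blur + blur_gain * |misalignment|`.
#' @export
blur_sigma <- function(source, misalignment_um) {
  source$base_blur + source$blur_gain * abs(misalignment_um)
}

# DO position of plane z_index (1-based) under the scan program.
plane_do_position <- function(scan, z_index) {
  scan$do_start + (z_index - 1) * scan$plane_spacing
}

#' Render one camera frame from the phantom
#'
#' Extracts the phantom slice at the DO focal plane for `z_index`, applies
#' Gaussian blur with sigma from [blur_sigma()] where the misalignment is
#' `(commanded_v - true_mapping(do_position)) / beam_gain` um, adds shot
#' and read noise, and quantizes to unsigned 16-bit. Rendering is
#' deterministic given (phantom seed, plane, misalignment).
#'
#' @param source A [frame_source()].
#' @param z_index Plane index, 1-based, within the scan program.
#' @param commanded_v Commanded axial beam voltage, V; defaults to the
#'   ground-truth (perfectly aligned) voltage.
#' @param volume_index,sequence_number Frame bookkeeping fields.
#' @return An object of class `lsm_frame` with integer matrix `pixels` and
#'   fields `volume_index`, `plane_index` (0-based), `sequence_number`,
#'   `timestamp` (ms).
#' @export
render_plane <- function(source, z_index,
                         commanded_v = source$true_mapping(
                           plane_do_position(source$scan, z_index)),
                         volume_index = 0L, sequence_number = 0L) {
  stopifnot(inherits(source, "frame_source"))
  scan <- source$scan
  if (z_index < 1 || z_index > scan$n_planes) stop("z_index out of range")
  do_pos <- plane_do_position(scan, z_index)
  nz <- source$phantom$dims[3]
  plane <- clamp(as.integer(round(do_pos / source$phantom$voxel_size)) + 1L,
                 1L, nz)
  img <- source$phantom$volume[, , plane]

  mis <- (commanded_v - source$true_mapping(do_pos)) / scan$beam_gain
  sig <- blur_sigma(source, mis)
  if (sig > 0.01) {
    # kernel truncated at 3 sigma, clamped (odd) to fit inside the frame
    r <- min(2L * ceiling(3 * sig) + 1L, min(dim(img)) - 1L)
    if (r %% 2L == 0L) r <- r - 1L
    img <- as.matrix(EBImage::gblur(img, sigma = sig, radius = r))
  }
  img[img < 0] <- 0

  if (source$shot_scale > 0 || source$read_noise_sd > 0) {
    noise_seed <- (source$seed * 7919 + z_index * 104729 +
                     round(abs(mis) * 1e4)) %% .Machine$integer.max
    img <- with_seed(noise_seed, {
      out <- img
      if (source$shot_scale > 0) {
        out <- rpois(length(img), lambda = img * source$shot_scale) /
          source$shot_scale
      }
      if (source$read_noise_sd > 0) {
        out <- out + rnorm(length(img), sd = source$read_noise_sd)
      }
      out
    })
  }
  pixels <- matrix(as.integer(clamp(round(img), 0, 65535)),
                   nrow(source$phantom$volume), ncol(source$phantom$volume))
  structure(list(pixels = pixels, volume_index = as.integer(volume_index),
                 plane_index = as.integer(z_index - 1L),
                 sequence_number = as.integer(sequence_number),
                 timestamp = 1000 * sequence_number / scan$frame_rate),
            class = "lsm_frame")
}

#' Autofocus camera for a frame source
#'
#' Adapter turning a [frame_source()] into the `acquire(beam_offset_um)`
#' function used by [run_focus_sweep()]. The closure images plane
#' `z_index` with the beam commanded `beam_offset_um` um away from the
#' current reference alignment; `misalignment_um` says how far that
#' reference itself is from the ground-truth focus, so a correct sweep
#' recovers `best_position == misalignment_um`.
#'
#' @param source A [frame_source()].
#' @param z_index Plane to image.
#' @param misalignment_um True misalignment of the reference alignment, um.
#' @return Function `(beam_offset_um) -> pixel matrix`.
#' @export
autofocus_camera <- function(source, z_index, misalignment_um = 0) {
  scan <- source$scan
  do_pos <- plane_do_position(scan, z_index)
  ref_v <- source$true_mapping(do_pos) - misalignment_um * scan$beam_gain
  function(beam_offset_um) {
    render_plane(source, z_index,
                 commanded_v = ref_v + beam_offset_um * scan$beam_gain)$pixels
  }
}

#' Calibration camera for a frame source
#'
#' Adapter for [calibrate_axial_mapping()]: a function
#' `(do_position, beam_offset_um) -> image` that images the plane nearest
#' the requested DO position with the beam offset from the linear voltage
#' estimate.
#'
#' @param source A [frame_source()].
#' @return Function `(do_position_um, beam_offset_um) -> pixel matrix`.
#' @export
calibration_camera <- function(source) {
  scan <- source$scan
  function(do_position, beam_offset_um) {
    z_index <- clamp(as.integer(round(
      (do_position - scan$do_start) / scan$plane_spacing)) + 1L,
      1L, scan$n_planes)
    lin_v <- scan$beam_volt_start + (do_position - scan$do_start) /
      (scan$do_end - scan$do_start) *
      (scan$beam_volt_end - scan$beam_volt_start)
    render_plane(source, z_index,
                 commanded_v = lin_v + beam_offset_um * scan$beam_gain)$pixels
  }
}

#' Start a simulated frame stream
#'
#' Returns a stateful stream emitting frames in acquisition order with
#' strictly increasing sequence numbers, plane indices cycling through the
#' volume (volumetric mode) or fixed at the first plane (single-plane
#' mode), and timestamps on the frame clock. Content is deterministic
#' given the phantom seed and independent of how fast the consumer drains
#' the stream.
#'
#' @param source A [frame_source()].
#' @return An object of class `frame_stream`: call `stream$next_frame()`
#'   for the next frame, `stream$produced()` for the count so far.
#' @export
start_stream <- function(source) {
  stopifnot(inherits(source, "frame_source"))
  scan <- source$scan
  seq_no <- -1L
  next_frame <- function() {
    seq_no <<- seq_no + 1L
    if (scan$mode == "volumetric") {
      vol <- seq_no %/% scan$n_planes
      z <- (seq_no %% scan$n_planes) + 1L
    } else {
      vol <- seq_no %/% scan$single_plane_chunk
      z <- 1L
    }
    render_plane(source, z, volume_index = vol, sequence_number = seq_no)
  }
  structure(list(next_frame = next_frame,
                 produced = function() seq_no + 1L,
                 frame_rate = scan$frame_rate),
            class = "frame_stream")
}
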