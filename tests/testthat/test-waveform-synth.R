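test_that("trigger train encodes volume boundaries by amplitude", {
  tr <- build_camera_triggers(scan_config(n_planes = 45))
  expect_length(tr$pulse_starts, 45)
  expect_equal(tr$pulse_amplitudes,
               c(4.5, rep(4.0, 43), 3.5))
  tr3 <- build_camera_triggers(scan_config(n_planes = 3))
  expect_equal(tr3$pulse_amplitudes, c(4.5, 4.0, 3.5))
  # degenerate single-plane volume: the start-of-volume marker wins
  tr1 <- build_camera_triggers(scan_config(n_planes = 1, piezo_delay = 10))
  expect_equal(tr1$pulse_amplitudes, 4.5)
})

test_that("trigger pattern and threshold hold over randomized configs", {
  set.seed(77)
  for (i in 1:200) {
    scan <- random_scan_config()
    tr <- build_camera_triggers(scan)
    expect_length(tr$pulse_amplitudes, scan$n_planes)
    expect_equal(tr$pulse_starts,
                 round((seq_len(scan$n_planes) - 1) *
                         scan$sample_rate / scan$frame_rate))
    if (scan$n_planes > 1) {
      expect_equal(tr$pulse_amplitudes[1], scan$trigger_amp_first)
      expect_equal(tr$pulse_amplitudes[scan$n_planes], scan$trigger_amp_last)
      if (scan$n_planes > 2) {
        expect_true(all(tr$pulse_amplitudes[2:(scan$n_planes - 1)] ==
                          scan$trigger_amp_mid))
      }
    }
    expect_gt(min(tr$pulse_amplitudes), scan$trigger_threshold)
    # inter-pulse level is the baseline
    expect_true(all(tr$samples %in%
                      c(scan$trigger_low, tr$pulse_amplitudes)))
  }
})

test_that("piezo command is a continuous delayed ramp", {
  scan <- scan_config(piezo_delay = 0)
  pz <- build_piezo_command(scan)
  expect_equal(pz$samples[1], scan$do_start * scan$piezo_gain)
  expect_equal(min(pz$samples), scan$do_start * scan$piezo_gain)
  expect_equal(max(pz$samples), scan$do_end * scan$piezo_gain)

  # no discontinuity outside the flyback window
  n <- length(pz$samples)
  n_fly <- round(scan$flyback_fraction * n)
  fwd <- pz$samples[1:(n - n_fly)]
  span <- diff(range(pz$samples))
  expect_lt(max(abs(diff(fwd))), 2 * span / n)
})

test_that("piezo delay is a circular advance of the ramp", {
  # brute-force circular cross-correlation oracle on a small clock
  scan <- scan_config(sample_rate = 2000, n_planes = 5, frame_rate = 25,
                      exposure = 30, piezo_delay = 15)
  ref <- build_piezo_command(scan_config(sample_rate = 2000, n_planes = 5,
                                         frame_rate = 25, exposure = 30,
                                         piezo_delay = 0))$samples
  shifted <- build_piezo_command(scan)$samples
  n <- length(ref)
  xc <- vapply(0:(n - 1), function(lag) {
    sum(shifted * ref[((seq_len(n) - 1 + lag) %% n) + 1])
  }, numeric(1))
  expect_identical(which.max(xc) - 1L,
                   as.integer(round(15 / 1000 * scan$sample_rate)))
})

test_that("axial beam command follows the linear fallback without calibration", {
  scan <- scan_config()
  beam <- build_axial_beam_command(scan)
  pos <- do_position_trajectory(scan)
  lin <- scan$beam_volt_start + (pos - scan$do_start) /
    (scan$do_end - scan$do_start) * (scan$beam_volt_end - scan$beam_volt_start)
  expect_equal(beam$samples, lin)
  expect_equal(range(beam$samples), c(scan$beam_volt_start, scan$beam_volt_end))
})

test_that("collinear calibration knots reproduce the linear fallback", {
  scan <- scan_config()
  x <- seq(scan$do_start, scan$do_end, length.out = 5)
  calib <- calibration_function(x, 0.01 * x)   # same line as the fallback
  lin <- build_axial_beam_command(scan)$samples
  cal <- build_axial_beam_command(scan, calib)$samples
  expect_lt(max(abs(cal - lin)), 1e-9)
  expect_lt(calib$max_dev_from_linear, 1e-9)
})

test_that("quadratic calibration knots reproduce the analytic sag", {
  scan <- scan_config()
  sag <- 0.04
  quad <- function(d) {
    s <- (d - scan$do_start) / (scan$do_end - scan$do_start)
    0.01 * d + 4 * sag * s * (1 - s)
  }
  x <- seq(scan$do_start, scan$do_end, length.out = 5)
  calib <- calibration_function(x, quad(x))
  beam <- build_axial_beam_command(scan, calib)
  pos <- do_position_trajectory(scan)
  # cubic interpolation through points of a quadratic is that quadratic
  expect_lt(max(abs(beam$samples - quad(pos))), 1e-9)
  mid <- (scan$do_start + scan$do_end) / 2
  expect_equal(eval_calibration(calib, mid) - 0.01 * mid, sag,
               tolerance = 1e-9)
})

test_that("calibration not covering the DO range is rejected", {
  scan <- scan_config()
  short <- calibration_function(c(10, 100), c(0.1, 1.0))
  expect_error(build_axial_beam_command(scan, short), "cover")
  expect_error(eval_calibration(short, 200), "domain")
})

test_that("sheet sweep is confined to the shutter-open window", {
  per_plane_increments <- function(scan) {
    sh <- build_sheet_command(scan)$samples
    e <- round(scan$exposure / 1000 * scan$sample_rate)
    sweep_len <- max(2, round(scan$shutter_open_fraction * e))
    n <- length(sh)
    counts <- vapply(seq_len(scan$n_planes), function(i) {
      p0 <- round((i - 1) * scan$sample_rate / scan$frame_rate)
      p1 <- if (i < scan$n_planes)
        round(i * scan$sample_rate / scan$frame_rate) else n
      sum(diff(sh[(p0 + 1):p1]) > 0)
    }, numeric(1))
    list(counts = counts, sweep_len = sweep_len)
  }
  half <- per_plane_increments(scan_config(shutter_open_fraction = 0.5))
  expect_true(all(half$counts == half$sweep_len - 1))
  full <- per_plane_increments(scan_config(shutter_open_fraction = 1.0))
  expect_true(all(full$counts == full$sweep_len - 1))

  # per-plane sweep range identical across planes
  scan <- scan_config()
  sh <- build_sheet_command(scan)$samples
  n <- length(sh)
  for (i in seq_len(scan$n_planes)) {
    p0 <- round((i - 1) * scan$sample_rate / scan$frame_rate)
    p1 <- if (i < scan$n_planes) round(i * scan$sample_rate / scan$frame_rate) else n
    expect_equal(range(sh[(p0 + 1):p1]),
                 c(scan$sheet_volt_min, scan$sheet_volt_max))
  }
})

test_that("assembled program shares one clock and gates only the side beam", {
  scan <- scan_config()
  b <- assemble_volume_program(scan)
  n <- round(scan$sample_rate * scan$n_planes / scan$frame_rate)
  expect_equal(b$n_samples, n)
  for (nm in c("piezo", "beam_axial_side", "beam_axial_front", "beam_sheet")) {
    expect_length(b[[nm]]$samples, n)
  }
  expect_length(b$trigger$samples, n)
  expect_true(all(b$gate_side$samples))     # no ROI: all-on
  expect_true(all(b$gate_front$samples))

  roi <- ellipse_roi(150, 100, 60, 40)
  b2 <- assemble_volume_program(scan, roi = roi)
  expect_true(any(!b2$gate_side$samples))
  expect_true(all(b2$gate_front$samples))   # front beam never gated
})

test_that("waveform bundle round-trips bit-exactly through HDF5", {
  scan <- scan_config()
  b <- assemble_volume_program(scan, roi = ellipse_roi(150, 100, 60, 40))
  path <- withr::local_tempfile(fileext = ".h5")
  export_waveforms(b, path)
  back <- read_waveforms(path)
  expect_identical(back$trigger, b$trigger$samples)
  expect_identical(back$piezo, b$piezo$samples)
  expect_identical(back$beam_axial_side, b$beam_axial_side$samples)
  expect_identical(back$beam_axial_front, b$beam_axial_front$samples)
  expect_identical(back$beam_sheet, b$beam_sheet$samples)
  expect_identical(back$gate_side, b$gate_side$samples)
  expect_identical(back$gate_front, b$gate_front$samples)
  expect_equal(back$sample_rate, scan$sample_rate)
})
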