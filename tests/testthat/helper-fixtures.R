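# Shared fixtures, built in code and memoized per test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# mid-size phantom for autofocus/calibration work
focus_phantom <- function(seed = 42) {
  memo(paste0("focus_phantom_", seed),
       generate_phantom(seed = seed, n_nuclei = 60, dims = c(96, 96, 48),
                        voxel_size = 1))
}

# scan covering the focus phantom's axial extent
focus_scan <- function(...) {
  args <- utils::modifyList(
    list(n_planes = 9, plane_spacing = 5, do_start = 0, do_end = 40,
         beam_volt_start = 0, beam_volt_end = 0.4),
    list(...))
  do.call(scan_config, args)
}

# tiny phantom for streaming tests (content does not matter, speed does)
stream_phantom <- function(seed = 7) {
  memo(paste0("stream_phantom_", seed),
       generate_phantom(seed = seed, n_nuclei = 10, dims = c(32, 32, 32),
                        voxel_size = 1))
}

single_plane_scan <- function(...) {
  scan_config(mode = "single_plane", n_planes = 1, frame_rate = 30,
              do_start = 0, do_end = 1, plane_spacing = 1, piezo_delay = 0,
              ...)
}

# a randomized valid scan_config (all invariants satisfied by construction)
random_scan_config <- function() {
  frame_rate <- runif(1, 20, 100)
  n_planes <- sample(1:200, 1)
  do_start <- runif(1, -50, 50)
  scan_config(
    n_planes = n_planes,
    plane_spacing = runif(1, 0.5, 10),
    frame_rate = frame_rate,
    exposure = runif(1, 0.3, 0.8) * 1000 / frame_rate,
    do_start = do_start,
    do_end = do_start + runif(1, 10, 400),
    beam_volt_start = runif(1, -1, 0),
    beam_volt_end = runif(1, 0.5, 3),
    piezo_delay = runif(1, 0, 0.8) * n_planes * 1000 / frame_rate,
    sample_rate = sample(5000:20000, 1),
    trigger_amp_first = runif(1, 3.4, 5),
    trigger_amp_mid = runif(1, 3.4, 5),
    trigger_amp_last = runif(1, 3.4, 5),
    trigger_width = runif(1, 0.1, 0.5) * 1000 / frame_rate,
    single_plane_chunk = sample(10:200, 1),
    mode = sample(c("volumetric", "single_plane"), 1),
    shutter_open_fraction = runif(1, 0.5, 1),
    flyback_fraction = runif(1, 0.02, 0.2)
  )
}

# strict 26-neighborhood local maxima of a 3-D array above a threshold
count_local_maxima <- function(vol, threshold) {
  d <- dim(vol)
  core <- vol[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)]
  is_max <- core > threshold
  for (dy in -1:1) for (dx in -1:1) for (dz in -1:1) {
    if (dy == 0 && dx == 0 && dz == 0) next
    nb <- vol[(2 + dy):(d[1] - 1 + dy), (2 + dx):(d[2] - 1 + dx),
              (2 + dz):(d[3] - 1 + dz)]
    is_max <- is_max & (core > nb)
  }
  sum(is_max)
}
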