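test_that("volumetric runs write one file per volume in plane order", {
  scan <- scan_config(n_planes = 45, do_end = 220)
  src <- frame_source(stream_phantom(), scan)
  out <- withr::local_tempdir()
  stats <- run_acquisition(src, out, n_frames = 3 * 45)
  expect_identical(stats$files_written, 3L)
  expect_identical(stats$produced, 135L)
  expect_identical(stats$written, 135L)
  expect_identical(stats$dropped, 0L)
  expect_false(stats$aborted)
  for (f in stats$files) {
    d <- read_acquisition_file(f)
    expect_identical(dim(d$frames)[1], 45L)
    expect_identical(diff(as.integer(d$attrs$sequence_numbers)), rep(1L, 44))
  }
  # a timestamped settings copy sits beside the data
  expect_length(list.files(stats$run_dir, pattern = "^settings_.*\\.xml$"), 1)
  reloaded <- load_settings(list.files(stats$run_dir, pattern = "\\.xml$",
                                       full.names = TRUE)[1])
  expect_identical(unclass(reloaded$scan), unclass(scan))
})

test_that("single-plane mode chunks completed files at exactly 100 frames", {
  src <- frame_source(stream_phantom(), single_plane_scan())
  out <- withr::local_tempdir()
  stats <- run_acquisition(src, out, n_frames = 250)
  expect_identical(stats$files_written, 3L)
  sizes <- vapply(stats$files,
                  function(f) dim(read_acquisition_file(f)$frames)[1],
                  integer(1))
  expect_identical(unname(sizes), c(100L, 100L, 50L))  # remainder flushed
  expect_match(basename(stats$files[1]), "^chunk_000000\\.h5$")
})

test_that("frames round-trip bit-exactly and in sequence order", {
  scan <- scan_config(n_planes = 45, do_end = 220)
  src <- frame_source(stream_phantom(), scan)
  out <- withr::local_tempdir()
  stats <- run_acquisition(src, out, n_frames = 2 * 45)

  ref_stream <- start_stream(frame_source(stream_phantom(), scan))
  idx <- 0L
  for (f in stats$files) {
    d <- read_acquisition_file(f)
    for (i in seq_len(dim(d$frames)[1])) {
      ref <- ref_stream$next_frame()
      idx <- idx + 1L
      expect_identical(as.integer(d$frames[i, , ]), as.integer(ref$pixels))
    }
  }
  expect_identical(idx, 90L)
})

test_that("acquisition never loses or reorders frames (N = 1000)", {
  src <- frame_source(stream_phantom(), single_plane_scan())
  out <- withr::local_tempdir()
  stats <- run_acquisition(src, out, n_frames = 1000, write_time_ms = 10)
  expect_identical(stats$produced, 1000L)
  expect_identical(stats$written, 1000L)
  expect_identical(stats$dropped, 0L)
  seqs <- unlist(lapply(stats$files, function(f)
    as.integer(read_acquisition_file(f)$attrs$sequence_numbers)))
  expect_identical(seqs, 0:999)
})

test_that("buffer depth stays bounded when the writer just keeps pace", {
  scan <- single_plane_scan()
  src <- frame_source(stream_phantom(), scan)
  out <- withr::local_tempdir()
  stats <- run_acquisition(src, out, duration_s = 60,
                           write_time_ms = 1000 / scan$frame_rate)
  expect_identical(stats$produced, 1800L)
  expect_identical(stats$written, 1800L)
  expect_lte(stats$max_write_buffer_depth, 4L)   # no monotonic growth
  expect_gte(stats$run_duration, 60)
})

test_that("a sustained overfull buffer aborts in a controlled way", {
  src <- frame_source(stream_phantom(), single_plane_scan())
  out <- withr::local_tempdir()
  expect_warning(
    stats <- run_acquisition(src, out, n_frames = 400, write_time_ms = 500,
                             high_water = 20, grace_s = 2),
    "high-water")
  expect_true(stats$aborted)
  expect_gt(stats$dropped, 0)
  expect_identical(stats$written + stats$dropped, stats$produced)
})

test_that("the preview tap emits every k-th frame without touching writing", {
  src <- frame_source(stream_phantom(), single_plane_scan())
  tap <- preview_tap(start_stream(src), every_k = 10)
  seqs <- vapply(1:25, function(i) tap$next_frame()$sequence_number,
                 integer(1))
  expect_identical(seqs, as.integer(seq(0, 240, by = 10)))
  expect_identical(tap$produced(), 241L)   # source pulled up to frame 240

  tap1 <- preview_tap(start_stream(src), every_k = 1)
  for (i in 1:20) tap1$next_frame()
  expect_identical(tap1$produced(), 20L)   # every frame previewed

  out <- withr::local_tempdir()
  stats <- run_acquisition(src, out, n_frames = 250, preview_every = 10)
  expect_identical(stats$preview_taken, 25L)
  expect_identical(stats$written, 250L)
})

test_that("a slow preview consumer drops previews, never written frames", {
  src <- frame_source(stream_phantom(), single_plane_scan())
  out <- withr::local_tempdir()
  stats <- run_acquisition(src, out, n_frames = 250, preview_every = 1,
                           preview_capacity = 4, preview_time_ms = 1e6)
  expect_gt(stats$preview_dropped, 0)
  expect_identical(stats$written, stats$produced)
  expect_identical(stats$dropped, 0L)
})

test_that("two sources stream concurrently with independent zero loss", {
  scan_a <- scan_config(n_planes = 45, do_end = 220)
  scan_b <- single_plane_scan()
  src_a <- frame_source(stream_phantom(7), scan_a)
  src_b <- frame_source(stream_phantom(8), scan_b)
  out_a <- withr::local_tempdir()
  out_b <- withr::local_tempdir()
  stats <- run_dual_acquisition(list(src_a, src_b), c(out_a, out_b),
                                n_frames = 180)
  expect_length(stats, 2)
  for (st in stats) {
    expect_identical(st$produced, 180L)
    expect_identical(st$written, 180L)
    expect_identical(st$dropped, 0L)
  }
  expect_identical(stats[[1]]$files_written, 4L)   # 4 volumes of 45
  expect_identical(stats[[2]]$files_written, 2L)   # 100 + 80
})

test_that("acquisition files are uncompressed unsigned 16-bit datasets", {
  src <- frame_source(stream_phantom(), scan_config(n_planes = 45,
                                                    do_end = 220))
  stream <- start_stream(src)
  frames <- lapply(1:45, function(i) stream$next_frame())
  path <- withr::local_tempfile(fileext = ".h5")
  finalize_file(frames, path, metadata = list(volume_index = 0L))
  d <- read_acquisition_file(path)
  expect_identical(dim(d$frames), c(45L, 32L, 32L))
  expect_identical(storage.mode(d$frames), "integer")
  for (i in c(1, 20, 45)) {
    expect_identical(as.integer(d$frames[i, , ]),
                     as.integer(frames[[i]]$pixels))
  }
  # uncompressed: at least 2 bytes per pixel on disk
  expect_gte(file.size(path), 45 * 32 * 32 * 2)
  expect_error(finalize_file(list(), tempfile()), "at least one")
})
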