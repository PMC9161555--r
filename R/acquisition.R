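# Streaming acquisition: reader -> bounded FIFO -> writer -> HDF5 files.
#
# The real platform runs reader and writer as concurrent threads; here the
# same queue discipline runs as a deterministic discrete-event simulation.
# Frames arrive on the camera clock (frame_rate); the writer services the
# FIFO head after a configurable per-frame write time. The contracts are
# identical to the threaded system's: the reader never blocks the source,
# the writer drains strictly in arrival order, every produced frame is
# written exactly once, and the FIFO depth is observable so bounded-memory
# behavior is provable. File I/O is real; only time is simulated.

#' Run a streaming acquisition
#'
#' Streams `n_frames` frames from the source through a first-in-first-out
#' writing buffer into uncompressed HDF5 files — one file per volume in
#' volumetric mode, or one per `single_plane_chunk` frames (default 100) in
#' single-plane mode — with a timestamped settings copy written alongside.
#' Frames remaining at stop are flushed to a final short file. If the FIFO
#' stays above its high-water mark for longer than the grace period the run
#' aborts in a controlled way (the disk cannot keep up) and the returned
#' stats say so.
#'
#' @param source A [frame_source()].
#' @param out_dir Output directory; a `run_<timestamp>` subdirectory is
#'   created inside it.
#' @param n_frames Number of frames to acquire; alternatively give
#'   `duration_s`.
#' @param duration_s Acquisition duration, s (converted via `frame_rate`).
#' @param write_time_ms Simulated disk time per frame, ms (0 = writer
#'   faster than the source).
#' @param preview_every Send every k-th frame to the preview buffer
#'   (0 disables the preview tap).
#' @param preview_capacity Preview ring-buffer capacity; the oldest preview
#'   frame is overwritten when the consumer lags (preview losses are
#'   permitted, writing losses never).
#' @param preview_time_ms Simulated preview-consumer time per frame, ms.
#' @param high_water FIFO depth high-water mark, frames; defaults to two
#'   volumes (volumetric) or 400 frames (single-plane).
#' @param grace_s Time the depth may continuously exceed the high-water
#'   mark before the controlled abort, s.
#' @return An `acquisition_stats` object: `produced`, `written`, `dropped`,
#'   `files_written`, `max_write_buffer_depth`, `run_duration` (s),
#'   `preview_taken`, `preview_dropped`, `aborted`, `files`, `run_dir`.
#' @export
run_acquisition <- function(source, out_dir, n_frames = NULL,
                            duration_s = NULL, write_time_ms = 0,
                            preview_every = 0L, preview_capacity = 16L,
                            preview_time_ms = 0, high_water = NULL,
                            grace_s = 5) {
  stats <- acquire_engine(list(list(source = source, out_dir = out_dir)),
                          n_frames = n_frames, duration_s = duration_s,
                          write_time_ms = write_time_ms,
                          preview_every = preview_every,
                          preview_capacity = preview_capacity,
                          preview_time_ms = preview_time_ms,
                          high_water = high_water, grace_s = grace_s)
  stats[[1]]
}

#' Run two sources concurrently (two-camera mode)
#'
#' Interleaves the arrival streams of independent sources by timestamp —
#' emulating simultaneous acquisition from two cameras — with a separate
#' FIFO, writer state and file series per source. Each stream individually
#' satisfies the zero-loss, in-order contract.
#'
#' @param sources List of [frame_source()] objects.
#' @param out_dirs Character vector of per-source output directories.
#' @param ... Passed on to the engine (see [run_acquisition()]).
#' @return List of `acquisition_stats`, one per source.
#' @export
run_dual_acquisition <- function(sources, out_dirs, ...) {
  stopifnot(length(sources) == length(out_dirs))
  jobs <- Map(function(s, d) list(source = s, out_dir = d), sources, out_dirs)
  acquire_engine(jobs, ...)
}

acquire_engine <- function(jobs, n_frames = NULL, duration_s = NULL,
                           write_time_ms = 0, preview_every = 0L,
                           preview_capacity = 16L, preview_time_ms = 0,
                           high_water = NULL, grace_s = 5) {
  wt <- write_time_ms / 1000
  pt <- preview_time_ms / 1000
  run_stamp <- format(Sys.time(), "%Y%m%d_%H%M%S")

  states <- lapply(jobs, function(job) {
    scan <- job$source$scan
    nf <- n_frames %||% as.integer(round((duration_s %||%
      stop("give n_frames or duration_s")) * scan$frame_rate))
    group_size <- if (scan$mode == "volumetric") scan$n_planes else
      scan$single_plane_chunk
    hw <- high_water %||% (if (scan$mode == "volumetric") 2L * scan$n_planes
                           else 400L)
    run_dir <- file.path(job$out_dir, paste0("run_", run_stamp))
    k <- 1L
    while (dir.exists(run_dir)) {
      run_dir <- file.path(job$out_dir, sprintf("run_%s_%d", run_stamp, k))
      k <- k + 1L
    }
    dir.create(run_dir, recursive = TRUE)
    save_settings(settings_document(scan),
                  file.path(run_dir, paste0("settings_", run_stamp, ".xml")))
    env <- new.env(parent = emptyenv())
    env$scan <- scan
    env$stream <- start_stream(job$source)
    env$n_frames <- nf
    env$group_size <- group_size
    env$hw <- hw
    env$run_dir <- run_dir
    env$queue <- vector("list", nf)       # FIFO: frames + arrival times
    env$q_arrival <- numeric(nf)
    env$q_head <- 1L; env$q_tail <- 0L
    env$writer_free <- 0
    env$written <- 0L
    env$group <- list(); env$file_index <- 0L; env$files <- character(0)
    env$max_depth <- 0L
    env$hw_since <- NA_real_
    env$aborted <- FALSE
    env$preview_ring <- vector("list", max(1L, preview_capacity))
    env$pv_head <- 0L; env$pv_count <- 0L
    env$pv_free <- 0
    env$preview_taken <- 0L; env$preview_dropped <- 0L
    env$last_time <- 0
    env
  })

  # writer drains every frame whose service completes by `now`
  drain <- function(st, now) {
    while (st$q_head <= st$q_tail) {
      start_t <- max(st$writer_free, st$q_arrival[st$q_head])
      if (start_t + wt > now) break
      frame <- st$queue[[st$q_head]]
      st$queue[st$q_head] <- list(NULL)
      st$q_head <- st$q_head + 1L
      st$writer_free <- start_t + wt
      st$written <- st$written + 1L
      st$group <- c(st$group, list(frame))
      if (length(st$group) == st$group_size) flush_group(st, partial = FALSE)
    }
  }

  flush_group <- function(st, partial) {
    if (length(st$group) == 0) return(invisible())
    scan <- st$scan
    volumetric <- scan$mode == "volumetric"
    name <- if (volumetric) sprintf("vol_%06d.h5", st$file_index) else
      sprintf("chunk_%06d.h5", st$file_index)
    meta <- list(plane_count = scan$n_planes, exposure = scan$exposure,
                 partial = as.integer(partial))
    meta[[if (volumetric) "volume_index" else "chunk_index"]] <- st$file_index
    path <- file.path(st$run_dir, name)
    finalize_file(st$group, path, metadata = meta)
    st$files <- c(st$files, path)
    st$file_index <- st$file_index + 1L
    st$group <- list()
  }

  preview_push <- function(st, frame, now) {
    st$preview_taken <- st$preview_taken + 1L
    cap <- length(st$preview_ring)
    # consumer drains the ring while it has simulated time
    while (st$pv_count > 0 && st$pv_free + pt <= now) {
      st$pv_free <- st$pv_free + pt
      st$pv_count <- st$pv_count - 1L
    }
    if (st$pv_count == cap) {                  # overwrite oldest
      st$preview_dropped <- st$preview_dropped + 1L
      st$pv_count <- st$pv_count - 1L
    }
    st$pv_head <- (st$pv_head %% cap) + 1L
    st$preview_ring[[st$pv_head]] <- frame$sequence_number
    st$pv_count <- st$pv_count + 1L
  }

  # global arrival order across jobs (merge by time, then job index)
  pending <- lapply(states, function(st) {
    if (st$n_frames >= 1) (seq_len(st$n_frames)) / st$scan$frame_rate
    else numeric(0)
  })
  cursor <- rep(1L, length(states))
  repeat {
    nxt <- NA_integer_; nxt_t <- Inf
    for (j in seq_along(states)) {
      if (states[[j]]$aborted) next
      if (cursor[j] <= length(pending[[j]]) && pending[[j]][cursor[j]] < nxt_t) {
        nxt <- j; nxt_t <- pending[[j]][cursor[j]]
      }
    }
    if (is.na(nxt)) break
    st <- states[[nxt]]
    cursor[nxt] <- cursor[nxt] + 1L
    drain(st, nxt_t)
    frame <- st$stream$next_frame()
    st$q_tail <- st$q_tail + 1L
    st$queue[[st$q_tail]] <- frame
    st$q_arrival[st$q_tail] <- nxt_t
    depth <- st$q_tail - st$q_head + 1L
    st$max_depth <- max(st$max_depth, depth)
    st$last_time <- nxt_t
    if (preview_every >= 1L &&
        frame$sequence_number %% preview_every == 0L) {
      preview_push(st, frame, nxt_t)
    }
    if (depth > st$hw) {
      if (is.na(st$hw_since)) st$hw_since <- nxt_t
      if (nxt_t - st$hw_since > grace_s) {
        st$aborted <- TRUE
        flush_group(st, partial = TRUE)
        warning(sprintf(
          "acquisition aborted: write buffer above high-water mark (%d frames) for > %g s",
          st$hw, grace_s))
      }
    } else {
      st$hw_since <- NA_real_
    }
  }

  lapply(states, function(st) {
    if (!st$aborted) {
      drain(st, Inf)
      flush_group(st, partial = TRUE)
    }
    produced <- st$stream$produced()
    structure(list(
      produced = produced,
      written = st$written,
      dropped = produced - st$written,
      files_written = st$file_index,
      max_write_buffer_depth = st$max_depth,
      run_duration = max(st$last_time, st$writer_free),
      preview_taken = st$preview_taken,
      preview_dropped = st$preview_dropped,
      aborted = st$aborted,
      files = st$files,
      run_dir = st$run_dir
    ), class = "acquisition_stats")
  })
}

#' Preview sub-stream
#'
#' Wraps a [start_stream()] frame stream and emits every k-th frame, the
#' way the reader intermittently copies frames to the preview buffer.
#'
#' @param stream A `frame_stream`.
#' @param every_k Emit one frame per `every_k` produced (>= 1).
#' @return A `frame_stream` whose `next_frame()` returns the next frame
#'   with `sequence_number %% every_k == 0`.
#' @export
preview_tap <- function(stream, every_k) {
  stopifnot(inherits(stream, "frame_stream"), every_k >= 1)
  every_k <- as.integer(every_k)
  next_frame <- function() {
    repeat {
      f <- stream$next_frame()
      if (f$sequence_number %% every_k == 0L) return(f)
    }
  }
  structure(list(next_frame = next_frame, produced = stream$produced,
                 frame_rate = stream$frame_rate), class = "frame_stream")
}

#' @export
print.acquisition_stats <- function(x, ...) {
  cat(sprintf(
    "<acquisition_stats> produced %d, written %d, dropped %d%s\n",
    x$produced, x$written, x$dropped, if (x$aborted) " [ABORTED]" else ""))
  cat(sprintf("  %d file(s), max FIFO depth %d frames, %.2f s\n",
              x$files_written, x$max_write_buffer_depth, x$run_duration))
  invisible(x)
}
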