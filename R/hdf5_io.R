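# HDF5 I/O: waveform bundle export and acquisition frame files. All frame
# data is stored as a single uncompressed unsigned 16-bit dataset, the
# layout that sustained the highest camera-to-disk throughput.

#' Export a waveform bundle to HDF5
#'
#' Writes each analog train as a float64 dataset (V), each gate as uint8,
#' with `sample_rate` (Hz) as a root attribute. The round trip through
#' [read_waveforms()] is bit-exact.
#'
#' @param bundle A [assemble_volume_program()] result.
#' @param path Output `.h5` path (overwritten).
#' @return `path`, invisibly.
#' @export
export_waveforms <- function(bundle, path) {
  stopifnot(inherits(bundle, "waveform_bundle"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  analog <- c("piezo", "beam_axial_side", "beam_axial_front", "beam_sheet")
  rhdf5::h5write(bundle$trigger$samples, path, "trigger")
  for (nm in analog) rhdf5::h5write(bundle[[nm]]$samples, path, nm)
  for (nm in c("gate_side", "gate_front")) {
    rhdf5::h5createDataset(path, nm, dims = bundle$n_samples,
                           H5type = "H5T_STD_U8LE", level = 0)
    rhdf5::h5write(as.integer(bundle[[nm]]$samples), path, nm)
  }
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(bundle$sample_rate, fid, "sample_rate")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' Read back an exported waveform bundle
#'
#' @param path Path written by [export_waveforms()].
#' @return Named list of numeric/logical sample vectors plus `sample_rate`.
#' @export
read_waveforms <- function(path) {
  names <- c("trigger", "piezo", "beam_axial_side", "beam_axial_front",
             "beam_sheet")
  out <- lapply(names, function(nm) as.numeric(rhdf5::h5read(path, nm)))
  names(out) <- names
  for (nm in c("gate_side", "gate_front")) {
    out[[nm]] <- as.logical(rhdf5::h5read(path, nm))
  }
  fid <- rhdf5::H5Fopen(path)
  out$sample_rate <- as.numeric(rhdf5::h5readAttributes(fid, "/")$sample_rate)
  rhdf5::H5Fclose(fid)
  out
}

#' Write one acquisition file
#'
#' Stores the frames of one volume (or one single-plane chunk) as a single
#' 3-D `(frame, row, col)` unsigned 16-bit uncompressed dataset named
#' `frames`, with the scan metadata and per-frame timestamps as
#' attributes. On write failure the partial file is removed.
#'
#' @param frames List of `lsm_frame` objects (>= 1), equal pixel dims.
#' @param path Output `.h5` path.
#' @param metadata Named list of scalar attributes (e.g. `volume_index` or
#'   `chunk_index`, `plane_count`, `exposure`).
#' @return `path`, invisibly.
#' @export
finalize_file <- function(frames, path, metadata = list()) {
  if (length(frames) < 1) stop("finalize_file needs at least one frame")
  dims <- dim(frames[[1]]$pixels)
  arr <- array(0L, dim = c(length(frames), dims[1], dims[2]))
  for (i in seq_along(frames)) {
    if (!identical(dim(frames[[i]]$pixels), dims)) {
      stop("frames differ in pixel dimensions")
    }
    arr[i, , ] <- frames[[i]]$pixels
  }
  ok <- tryCatch({
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    rhdf5::h5createDataset(path, "frames", dims = dim(arr),
                           H5type = "H5T_STD_U16LE",
                           chunk = c(1, dims[1], dims[2]), level = 0)
    rhdf5::h5write(arr, path, "frames")
    fid <- rhdf5::H5Fopen(path)
    did <- rhdf5::H5Dopen(fid, "frames")
    rhdf5::h5writeAttribute(vapply(frames, `[[`, numeric(1), "timestamp"),
                            did, "timestamps_ms")
    rhdf5::h5writeAttribute(vapply(frames, function(f)
      as.integer(f$sequence_number), integer(1)), did, "sequence_numbers")
    for (nm in names(metadata)) {
      rhdf5::h5writeAttribute(metadata[[nm]], did, nm)
    }
    rhdf5::H5Dclose(did)
    rhdf5::H5Fclose(fid)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    if (file.exists(path)) unlink(path)
    stop("failed to write acquisition file '", path, "': ",
         conditionMessage(ok))
  }
  invisible(path)
}

#' Read an acquisition file
#'
#' @param path Path written by [finalize_file()].
#' @return List with `frames` (3-D integer array, frame-major) and `attrs`.
#' @export
read_acquisition_file <- function(path) {
  frames <- rhdf5::h5read(path, "frames")
  attrs <- rhdf5::h5readAttributes(path, "frames")
  list(frames = frames, attrs = attrs)
}
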