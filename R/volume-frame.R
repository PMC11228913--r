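#' Construct a volume frame
#'
#' A `volume_frame` is one reconstructed 3D gray-value volume together with
#' its physical metadata: the voxel edge length in micrometres, the
#' acquisition time in seconds, and the ordinal frame index within a time
#' series. Axis order is (Z, Y, X) with Z = 0 at the top of the measurement
#' cell, so depth increases with Z. Voxel coordinates are 0-based; physical
#' coordinates are `index * voxel_size`.
#'
#' Gray values are used as-is: the reader is agnostic to bit depth and no
#' intensity normalization is applied across frames.
#'
#' @param data Numeric 3D array, dimensions (Z, Y, X), all extents >= 1.
#' @param voxel_size Voxel edge length in micrometres (> 0).
#' @param time Acquisition time in seconds (>= 0).
#' @param frame_index 0-based ordinal of the frame within its series.
#' @return An object of class `volume_frame`: the array with metadata
#'   attributes `voxel_size`, `time` and `frame_index`.
#' @examples
#' vf <- volume_frame(array(0, c(8, 8, 8)), voxel_size = 2.75)
#' dim(vf)
#' @export
volume_frame <- function(data, voxel_size, time = 0, frame_index = 0L) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array (Z, Y, X)", call. = FALSE)
  }
  if (!is.numeric(data)) stop("`data` must be numeric", call. = FALSE)
  if (any(dim(data) < 1L)) stop("all spatial extents must be >= 1", call. = FALSE)
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0) {
    stop("`voxel_size` must be a single positive number (μm)", call. = FALSE)
  }
  structure(data,
    voxel_size = as.numeric(voxel_size),
    time = as.numeric(time),
    frame_index = as.integer(frame_index),
    class = c("volume_frame", "array")
  )
}

#' @export
print.volume_frame <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<volume_frame> %d x %d x %d voxels (Z, Y, X) @ %g μm/voxel\n",
    d[1], d[2], d[3], voxel_size(x)
  ))
  cat(sprintf(
    "  frame %d, t = %g s, gray range [%g, %g]\n",
    frame_index(x), frame_time(x), min(x), max(x)
  ))
  invisible(x)
}

#' Frame metadata accessors
#'
#' @param frame A [volume_frame()].
#' @return `voxel_size()` the voxel edge in micrometres; `frame_time()` the
#'   acquisition time in seconds; `frame_index()` the 0-based ordinal;
#'   `physical_extent()` the physical size of the volume along (Z, Y, X).
#' @name frame-metadata
NULL

#' @rdname frame-metadata
#' @export
voxel_size <- function(frame) attr(frame, "voxel_size")

#' @rdname frame-metadata
#' @export
frame_time <- function(frame) attr(frame, "time")

#' @rdname frame-metadata
#' @export
frame_index <- function(frame) attr(frame, "frame_index")

#' @rdname frame-metadata
#' @param unit Output unit, `"um"` or `"mm"`.
#' @export
physical_extent <- function(frame, unit = c("um", "mm")) {
  unit <- match.arg(unit)
  ext <- dim(frame) * voxel_size(frame)
  if (unit == "mm") ext <- ext / 1000
  setNames(ext, c("Z", "Y", "X"))
}

#' Read a time series of 3D volumes
#'
#' Reads an ordered series of reconstructed volumes from TIFF files. Two
#' layouts are accepted, both common tomography exports:
#' * one multi-page TIFF per timepoint (`path` is a directory of `.tif`
#'   files, or a single file for a one-frame series), pages stacked along Z;
#' * one sub-directory of 2D slice TIFFs per timepoint, slices ordered by
#'   lexicographic filename order.
#' Files and sub-directories are themselves taken in lexicographic order as
#' frame order; frame times are `frame_index * frame_interval`.
#'
#' @param path Directory containing the series (or a single TIFF file).
#' @param voxel_size Voxel edge length, micrometres.
#' @param frame_interval Time between consecutive frames, seconds.
#' @return List of [volume_frame()]s ordered by frame index.
#' @export
read_volume_series <- function(path, voxel_size, frame_interval) {
  if (!file.exists(path)) stop("path does not exist: ", path, call. = FALSE)
  if (dir.exists(path)) {
    subdirs <- sort(list.dirs(path, recursive = FALSE))
    tifs <- sort(list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                            full.names = TRUE))
    if (length(subdirs) > 0) {
      vols <- lapply(subdirs, read_slice_dir)
    } else if (length(tifs) > 0) {
      vols <- lapply(tifs, read_tiff_volume)
    } else {
      stop("no TIFF volumes found under ", path, call. = FALSE)
    }
  } else {
    vols <- list(read_tiff_volume(path))
  }
  shapes <- vapply(vols, function(v) paste(dim(v), collapse = "x"), "")
  if (length(unique(shapes)) > 1L) {
    stop("inconsistent volume shapes across frames: ",
         paste(unique(shapes), collapse = ", "), call. = FALSE)
  }
  purrr::imap(vols, function(v, i) {
    volume_frame(v, voxel_size = voxel_size,
                 time = (i - 1) * frame_interval, frame_index = i - 1L)
  })
}

# multi-page TIFF -> (Z, Y, X) array; pages are Z slices
read_tiff_volume <- function(file) {
  pages <- tiff::readTIFF(file, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  slices_to_volume(pages, file)
}

read_slice_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.tiff?$", ignore.case = TRUE,
                           full.names = TRUE))
  if (length(files) == 0) stop("no TIFF slices in ", dir, call. = FALSE)
  slices_to_volume(lapply(files, function(f) tiff::readTIFF(f, as.is = TRUE)), dir)
}

slices_to_volume <- function(slices, what) {
  slices <- lapply(slices, function(s) {
    if (length(dim(s)) == 3L) s <- s[, , 1]  # drop extra channels
    if (!is.numeric(s)) stop("non-numeric pixel data in ", what, call. = FALSE)
    s
  })
  dims <- unique(lapply(slices, dim))
  if (length(dims) > 1L) stop("inconsistent slice shapes in ", what, call. = FALSE)
  ny <- dims[[1]][1]; nx <- dims[[1]][2]; nz <- length(slices)
  vol <- array(0, c(nz, ny, nx))
  for (z in seq_len(nz)) vol[z, , ] <- slices[[z]]
  vol
}

#' Write a volume frame to a multi-page TIFF
#'
#' Gray values are rescaled to \[0, 1\] for storage (the TIFF writer's
#' native range) unless already within it; intended for visual inspection of
#' masks and label maps, not for round-tripping raw gray values.
#'
#' @param frame A [volume_frame()] or plain 3D array.
#' @param file Output path.
#' @param bits Bits per sample (8 or 16).
#' @export
write_volume_tiff <- function(frame, file, bits = 16L) {
  v <- unclass(frame)
  attributes(v) <- list(dim = dim(frame))
  rng <- range(v)
  if (rng[1] < 0 || rng[2] > 1) {
    v <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else v * 0
  }
  pages <- lapply(seq_len(dim(v)[1]), function(z) v[z, , ])
  tiff::writeTIFF(pages, file, bits.per.sample = as.integer(bits))
  invisible(file)
}

#' Read and write run configuration
#'
#' A run configuration is a YAML file carrying the acquisition metadata and
#' analysis parameters: `voxel_size_um`, `frame_interval_s`,
#' `spacer_threshold` (number, `"auto"` or `"none"`),
#' `crop_diameter_voxels`, `opening_radius`, `rho_mg_cm3`, and optional
#' tracking thresholds.
#'
#' @param file Path to a YAML configuration file.
#' @return `read_run_config()` returns a named list.
#' @export
read_run_config <- function(file) {
  if (!file.exists(file)) stop("config file not found: ", file, call. = FALSE)
  yaml::read_yaml(file)
}

#' @rdname read_run_config
#' @param config Named list of configuration values.
#' @export
write_run_config <- function(config, file) {
  yaml::write_yaml(config, file)
  invisible(file)
}
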