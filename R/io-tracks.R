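#' Write and read the crystal track table
#'
#' Externalizes the database of uniquely tracked crystals as a CSV with one
#' row per (track, timepoint): track id, lineage (mother id for breakup
#' fragments), time, centroid coordinates (voxels, 0-based), voxel count,
#' volume, surface area, equivalent diameter and roundness. The full
#' double precision of every value is written, so reading the file back
#' reproduces the table bit-exactly for integers and to full printed
#' precision for floating-point fields.
#'
#' @param tracks A `crystal_tracks` tibble (empty is legal: header only).
#' @param file Output CSV path.
#' @return `write_tracks_csv()` returns `file` invisibly;
#'   `read_tracks_csv()` returns a `crystal_tracks` tibble.
#' @export
write_tracks_csv <- function(tracks, file) {
  cols <- c("track_id", "mother_id", "frame_index", "time_s", "label",
            "z", "y", "x", "voxel_count", "volume_cm3", "surface_cm2",
            "equiv_diam_cm", "roundness")
  missing <- setdiff(cols, names(tracks))
  for (m in missing) tracks[[m]] <- NA
  out <- dplyr::select(tibble::as_tibble(tracks), dplyr::all_of(cols))
  readr::write_csv(out, file)
  invisible(file)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(file) {
  out <- readr::read_csv(
    file,
    col_types = readr::cols(
      track_id = readr::col_integer(),
      mother_id = readr::col_integer(),
      frame_index = readr::col_integer(),
      time_s = readr::col_double(),
      label = readr::col_integer(),
      z = readr::col_double(),
      y = readr::col_double(),
      x = readr::col_double(),
      voxel_count = readr::col_integer(),
      volume_cm3 = readr::col_double(),
      surface_cm2 = readr::col_double(),
      equiv_diam_cm = readr::col_double(),
      roundness = readr::col_double()
    )
  )
  as_crystal_tracks(out, rejections = empty_rejections())
}

#' Write the per-observation table
#'
#' @param observations Observation tibble from [measure_objects()] /
#'   [observe_series()].
#' @param file Output CSV path.
#' @export
write_observations_csv <- function(observations, file) {
  readr::write_csv(tibble::as_tibble(observations), file)
  invisible(file)
}

#' Write the rejection log
#'
#' @param tracks A `crystal_tracks` tibble carrying a [rejections()] log.
#' @param file Output CSV path.
#' @export
write_rejections_csv <- function(tracks, file) {
  readr::write_csv(rejections(tracks), file)
  invisible(file)
}

#' Write per-track dissolution rates
#'
#' One row per (track, time): fitted volume and surface, and the
#' individual dissolution rate in mg cm^-2 min^-1.
#'
#' @param indr_tbl Output of [compute_indr()].
#' @param file Output CSV path.
#' @export
write_indr_csv <- function(indr_tbl, file) {
  readr::write_csv(tibble::as_tibble(indr_tbl), file)
  invisible(file)
}
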