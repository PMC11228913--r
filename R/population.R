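#' Sieve size classes
#'
#' The default classes are the sieve fractions commonly used for crystal
#' populations of this kind:
#' small 180-250 μm, medium 300-400 μm, large 400-500 μm. Intervals are
#' half-open `[lower, upper)` except the last, which is closed, so a
#' boundary diameter belongs to exactly one class.
#'
#' @param name Class labels.
#' @param lower,upper Class bounds in micrometres (sphere-equivalent
#'   diameter); classes must not overlap.
#' @return Tibble `name`, `lower`, `upper`.
#' @export
size_classes <- function(name = c("S", "M", "L"),
                         lower = c(180, 300, 400),
                         upper = c(250, 400, 500)) {
  stopifnot(length(name) == length(lower), length(lower) == length(upper),
            all(lower < upper))
  o <- order(lower)
  name <- name[o]; lower <- lower[o]; upper <- upper[o]
  if (any(lower[-1] < upper[-length(upper)] - 1e-9)) {
    stop("size classes overlap", call. = FALSE)
  }
  tibble::tibble(name = name, lower = lower, upper = upper)
}

#' Assign tracks to size classes
#'
#' Classifies each track by its *initial* sphere-equivalent diameter (the
#' diameter at its first observation), mirroring classification of the
#' physical crystals by sieving before dissolution.
#'
#' @param tracks `crystal_tracks` (needs `equiv_diam_cm` per observation).
#' @param classes A [size_classes()] tibble.
#' @return Tibble: `track_id`, `init_diam_um`, `size_class` (`NA` when the
#'   diameter falls outside every class).
#' @export
assign_size_class <- function(tracks, classes = size_classes()) {
  first_obs <- tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::slice_min(.data$frame_index, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup()
  d_um <- first_obs$equiv_diam_cm * 1e4
  n_cl <- nrow(classes)
  cls <- vapply(d_um, function(d) {
    for (k in seq_len(n_cl)) {
      hit <- if (k == n_cl) d >= classes$lower[k] && d <= classes$upper[k]
             else d >= classes$lower[k] && d < classes$upper[k]
      if (hit) return(classes$name[k])
    }
    NA_character_
  }, "")
  tibble::tibble(track_id = first_obs$track_id,
                 init_diam_um = d_um,
                 size_class = factor(cls, levels = classes$name))
}

#' Time-resolved dissolution rate per size class
#'
#' For every frame time, the mean and the min-max range (the "range of
#' individual values") of the individual dissolution rates of all crystals
#' of a class alive at that time.
#'
#' @param indr_tbl Output of [compute_indr()].
#' @param class_assign Output of [assign_size_class()].
#' @return Tibble: `size_class`, `time_s`, `n`, `mean_indr`, `min_indr`,
#'   `max_indr`; the per-class grand mean over all values is attached as
#'   attribute `class_means` (also available via [class_means()]).
#' @export
class_timecourse <- function(indr_tbl, class_assign) {
  joined <- indr_tbl |>
    dplyr::filter(.data$valid) |>
    dplyr::inner_join(class_assign, by = "track_id")
  present <- unique(as.character(joined$size_class))
  empty <- setdiff(levels(class_assign$size_class), present)
  if (length(empty)) {
    warning("no tracked crystals in class(es): ", paste(empty, collapse = ", "),
            call. = FALSE)
  }
  joined <- dplyr::filter(joined, !is.na(.data$size_class))
  out <- joined |>
    dplyr::group_by(.data$size_class, .data$time_s) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_indr = mean(.data$indr_mg_cm2_min),
      min_indr = min(.data$indr_mg_cm2_min),
      max_indr = max(.data$indr_mg_cm2_min),
      .groups = "drop"
    )
  means <- joined |>
    dplyr::group_by(.data$size_class) |>
    dplyr::summarise(mean_indr = mean(.data$indr_mg_cm2_min),
                     n_values = dplyr::n(), .groups = "drop")
  attr(out, "class_means") <- means
  out
}

#' @rdname class_timecourse
#' @param timecourse A [class_timecourse()] result.
#' @export
class_means <- function(timecourse) attr(timecourse, "class_means")

#' Spatial map of dissolution rates
#'
#' Places every track at its initial centroid in cylindrical cell
#' coordinates - `R`, the in-plane distance from the cell axis, and `Z`,
#' the depth below the upper boundary of the measurement cell (both in
#' voxels) - and attaches its lifetime-averaged dissolution rate. Reveals
#' spatial structure such as slowly dissolving crystals near the wall or
#' the cell bottom.
#'
#' @param tracks Accepted `crystal_tracks`.
#' @param indr_tbl Output of [compute_indr()].
#' @param cell_axis `(y, x)` voxel coordinates of the cell axis; defaults
#'   to the centroid-cloud centre; pass the volume centre
#'   `(ny - 1) / 2, (nx - 1) / 2` for an axis-mounted cell.
#' @return Tibble: `track_id`, `R_vox`, `Z_vox`, `indr_mg_cm2_min`.
#' @export
spatial_map <- function(tracks, indr_tbl, cell_axis = NULL) {
  first_obs <- tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::slice_min(.data$frame_index, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup()
  if (is.null(cell_axis)) {
    cell_axis <- c(mean(first_obs$y), mean(first_obs$x))
  }
  mean_rates <- indr_tbl |>
    dplyr::filter(.data$valid) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(indr_mg_cm2_min = mean(.data$indr_mg_cm2_min),
                     .groups = "drop")
  first_obs |>
    dplyr::inner_join(mean_rates, by = "track_id") |>
    dplyr::transmute(
      track_id = .data$track_id,
      R_vox = sqrt((.data$y - cell_axis[1])^2 + (.data$x - cell_axis[2])^2),
      Z_vox = .data$z,
      indr_mg_cm2_min = .data$indr_mg_cm2_min
    )
}
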