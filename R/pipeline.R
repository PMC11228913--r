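#' End-to-end dissolution analysis
#'
#' Runs the whole pipeline on a time series of volumes: per-frame
#' segmentation and object measurement ([observe_series()]), identity
#' tracking with the two filtering passes ([track_crystals()]), per-track
#' dissolution rates ([compute_indr()]), size-class assignment and the
#' class-wise time course ([class_timecourse()]), and the spatial rate map
#' ([spatial_map()]).
#'
#' @param frames List of [volume_frame()]s.
#' @param seg_params A [segmentation_params()].
#' @param track_params A [tracking_params()].
#' @param rho Material density, mg cm^-3.
#' @param estimator Surface-area estimator (see [measure_objects()]).
#' @param classes [size_classes()] tibble, or `NULL` to skip class
#'   statistics.
#' @param cell_axis Optional `(y, x)` cell-axis coordinates for
#'   [spatial_map()].
#' @return A `dissolution_analysis` list: `observations`, `tracks`,
#'   `indr`, `class_assignment`, `timecourse`, `summary`, `spatial`,
#'   `params`.
#' @export
analyze_dissolution <- function(frames,
                                seg_params = segmentation_params(),
                                track_params = tracking_params(),
                                rho = 2165,
                                estimator = c("faces", "coarea"),
                                classes = size_classes(),
                                cell_axis = NULL) {
  estimator <- match.arg(estimator)
  observations <- observe_series(frames, seg_params, estimator = estimator)
  tracks <- track_crystals(observations, track_params)
  has_tracks <- nrow(tracks) > 0L
  indr <- if (has_tracks) compute_indr(tracks, rho = rho) else NULL
  assignment <- NULL; timecourse <- NULL; summ <- NULL; spatial <- NULL
  if (has_tracks && !is.null(classes)) {
    assignment <- assign_size_class(tracks, classes)
    if (any(!is.na(assignment$size_class))) {
      timecourse <- suppressWarnings(class_timecourse(indr, assignment))
    }
    summ <- track_summary(tracks, classes)
  }
  if (has_tracks) {
    if (is.null(cell_axis) && length(frames)) {
      d <- dim(frames[[1]])
      cell_axis <- c((d[2] - 1) / 2, (d[3] - 1) / 2)
    }
    spatial <- spatial_map(tracks, indr, cell_axis = cell_axis)
  }
  structure(
    list(observations = observations, tracks = tracks, indr = indr,
         class_assignment = assignment, timecourse = timecourse,
         summary = summ, spatial = spatial,
         params = list(seg = seg_params, track = track_params, rho = rho,
                       estimator = estimator)),
    class = "dissolution_analysis"
  )
}

#' @export
print.dissolution_analysis <- function(x, ...) {
  cat("<dissolution_analysis>\n")
  cat(sprintf("  %d observations in %d frames -> %d accepted tracks\n",
              nrow(x$observations),
              dplyr::n_distinct(x$observations$frame_index),
              if (nrow(x$tracks)) dplyr::n_distinct(x$tracks$track_id) else 0L))
  if (!is.null(x$indr)) {
    m <- mean(x$indr$indr_mg_cm2_min[x$indr$valid])
    cat(sprintf("  population mean I_nDR = %.2f mg cm^-2 min^-1 (rho = %g, %s surfaces)\n",
                m, x$params$rho, x$params$estimator))
  }
  if (!is.null(x$summary)) {
    cat("  per-class summary:\n")
    print(x$summary)
  }
  invisible(x)
}

#' @rdname analyze_dissolution
#' @param x A `dissolution_analysis`.
#' @param ... Unused.
#' @export
glance.dissolution_analysis <- function(x, ...) {
  valid <- if (is.null(x$indr)) numeric() else
    x$indr$indr_mg_cm2_min[x$indr$valid]
  tibble::tibble(
    n_frames = dplyr::n_distinct(x$observations$frame_index),
    n_observations = nrow(x$observations),
    n_tracks = if (nrow(x$tracks)) dplyr::n_distinct(x$tracks$track_id) else 0L,
    n_rejected = nrow(rejections(x$tracks)),
    mean_indr = if (length(valid)) mean(valid) else NA_real_,
    rho = x$params$rho,
    surface_estimator = x$params$estimator
  )
}

#' Class time-course plot
#'
#' Mean individual dissolution rate per size class over time, with the
#' min-max envelope of individual values shown as a ribbon.
#'
#' @param timecourse A [class_timecourse()] tibble.
#' @return A ggplot object.
#' @export
plot_class_timecourse <- function(timecourse) {
  ggplot2::ggplot(timecourse,
                  ggplot2::aes(x = .data$time_s, y = .data$mean_indr)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$min_indr, ymax = .data$max_indr),
      fill = "#9b7bb8", alpha = 0.4) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$size_class)) +
    ggplot2::labs(
      x = "time (s)",
      y = expression(I[n] * DR ~ (mg ~ cm^-2 ~ min^-1))
    ) +
    ggplot2::theme_minimal()
}

#' Spatial rate-map plot
#'
#' Each accepted crystal at its initial (R, Z) position in the cell,
#' coloured by its lifetime-averaged dissolution rate; depth Z increases
#' downwards as in the physical cell (Z = 0 is the upper boundary).
#'
#' @param spatial A [spatial_map()] tibble.
#' @return A ggplot object.
#' @export
plot_spatial_map <- function(spatial) {
  ggplot2::ggplot(spatial,
                  ggplot2::aes(x = .data$R_vox, y = .data$Z_vox,
                               colour = .data$indr_mg_cm2_min)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_colour_viridis_c(
      name = expression(I[n] * DR ~ (mg ~ cm^-2 ~ min^-1))) +
    ggplot2::labs(x = "R (voxels from cell axis)", y = "Z (voxels, depth)") +
    ggplot2::theme_minimal()
}
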