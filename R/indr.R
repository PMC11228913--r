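#' Least-squares quadratic fit of a time series
#'
#' Fits `value = c0 + c1 t + c2 t^2` by ordinary least squares. The
#' quadratic is the smooth function used to regularize the discrete volume
#' and surface series before analytic differentiation; with the
#' minimum-track-length rule of four timepoints it always leaves at least
#' one residual degree of freedom.
#'
#' @param time Numeric times (any unit; the derivative is per that unit).
#' @param value Observed values at `time`.
#' @return Coefficients `c(c0, c1, c2)` with class `quad_fit` and
#'   attributes `rss` and `n`.
#' @export
fit_quadratic <- function(time, value) {
  if (length(time) != length(value)) stop("time and value lengths differ", call. = FALSE)
  if (length(time) < 3L) stop("need at least 3 points for a quadratic fit", call. = FALSE)
  if (length(unique(time)) < 3L) {
    stop("degenerate time series: need 3 distinct times", call. = FALSE)
  }
  fit <- lm(value ~ time + I(time^2))
  co <- unname(coef(fit))
  structure(setNames(co, c("c0", "c1", "c2")),
            rss = sum(fit$residuals^2), n = length(time), class = "quad_fit")
}

eval_quad <- function(co, t) co[[1]] + co[[2]] * t + co[[3]] * t^2
eval_quad_deriv <- function(co, t) co[[2]] + 2 * co[[3]] * t

#' Individual dissolution rate of one tracked crystal
#'
#' Computes the individual dissolution rate
#' \deqn{I_nDR(t) = -\rho \, \frac{dV/dt}{A(t)}}
#' in mg cm^-2 min^-1, where \eqn{\rho} is the material density
#' (mg cm^-3), `V` the crystal volume (cm^3) and `A` its surface area
#' (cm^2). Volume and surface series are each regressed on time (minutes)
#' by a quadratic, the volume fit is differentiated analytically, and the
#' rate is evaluated at every observation time. The minus sign makes the
#' rate positive while the crystal loses volume. Times where the fitted
#' surface is not positive are flagged invalid and excluded from averages.
#'
#' @param track Rows of one track (observation columns `time_s`,
#'   `volume_cm3`, `surface_cm2`; at least 4 rows).
#' @param rho Material density, mg cm^-3. The default is the crystal
#'   density of NaCl; set it to analyze any other material.
#' @param use_fitted_surface Evaluate `A(t)` from its quadratic fit
#'   (default, mirroring the smoothing of both series) or from the raw
#'   per-frame surface areas.
#' @return An `indr_series` object: tibble accessor via [tidy()], one-line
#'   summary via [glance()], fields `track_id`, `v_fit`, `a_fit`, `rho`,
#'   `data` (tibble with `time_s`, `time_min`, `V_fit_cm3`, `A_fit_cm2`,
#'   `indr_mg_cm2_min`, `valid`).
#' @export
indr_series <- function(track, rho = 2165, use_fitted_surface = TRUE) {
  if (nrow(track) < 4L) {
    stop("rate estimation requires a track with at least 4 timepoints", call. = FALSE)
  }
  if (rho <= 0) stop("`rho` must be positive", call. = FALSE)
  track <- dplyr::arrange(track, .data$time_s)
  t_min <- track$time_s / 60
  v_fit <- fit_quadratic(t_min, track$volume_cm3)
  a_fit <- fit_quadratic(t_min, track$surface_cm2)
  A <- if (use_fitted_surface) eval_quad(a_fit, t_min) else track$surface_cm2
  dVdt <- eval_quad_deriv(v_fit, t_min)
  valid <- A > 0
  indr <- ifelse(valid, -rho * dVdt / A, NA_real_)
  structure(
    list(
      track_id = if ("track_id" %in% names(track)) track$track_id[1L] else NA_integer_,
      v_fit = v_fit, a_fit = a_fit, rho = rho,
      use_fitted_surface = use_fitted_surface,
      data = tibble::tibble(
        time_s = track$time_s, time_min = t_min,
        V_fit_cm3 = eval_quad(v_fit, t_min),
        A_fit_cm2 = A,
        indr_mg_cm2_min = indr,
        valid = valid
      )
    ),
    class = "indr_series"
  )
}

#' @export
print.indr_series <- function(x, ...) {
  cat(sprintf("<indr_series> track %s: %d timepoints, rho = %g mg/cm^3\n",
              x$track_id, nrow(x$data), x$rho))
  cat(sprintf("  mean I_nDR = %.3g mg cm^-2 min^-1 (%d valid)\n",
              time_average_indr(x), sum(x$data$valid)))
  invisible(x)
}

#' @rdname indr_series
#' @param x An `indr_series`.
#' @param ... Unused.
#' @export
tidy.indr_series <- function(x, ...) {
  dplyr::mutate(x$data, track_id = x$track_id, .before = 1L)
}

#' @rdname indr_series
#' @export
glance.indr_series <- function(x, ...) {
  tibble::tibble(
    track_id = x$track_id,
    n_obs = nrow(x$data),
    n_valid = sum(x$data$valid),
    mean_indr = time_average_indr(x),
    v_c0 = x$v_fit[[1]], v_c1 = x$v_fit[[2]], v_c2 = x$v_fit[[3]],
    a_c0 = x$a_fit[[1]], a_c1 = x$a_fit[[2]], a_c2 = x$a_fit[[3]],
    rho = x$rho
  )
}

#' Lifetime-averaged dissolution rate
#'
#' Arithmetic mean of the valid rate values over the track's observed
#' lifetime.
#'
#' @param series An `indr_series` (or its [tidy()] tibble).
#' @return Scalar mean rate, mg cm^-2 min^-1.
#' @export
time_average_indr <- function(series) {
  d <- if (inherits(series, "indr_series")) series$data else series
  v <- d$indr_mg_cm2_min[d$valid]
  if (length(v) == 0L) stop("no valid rate values in series", call. = FALSE)
  mean(v)
}

#' Dissolution rates for all accepted tracks
#'
#' Applies [indr_series()] to every track and binds the tidied results.
#'
#' @param tracks Accepted `crystal_tracks` (every track >= 4 timepoints).
#' @param rho Material density, mg cm^-3.
#' @param use_fitted_surface See [indr_series()].
#' @return Tibble of per-time rates for all tracks (the union of the
#'   per-track [tidy()] tables), with the list of `indr_series` fits in
#'   attribute `fits`.
#' @export
compute_indr <- function(tracks, rho = 2165, use_fitted_surface = TRUE) {
  fits <- tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_split() |>
    purrr::map(indr_series, rho = rho, use_fitted_surface = use_fitted_surface)
  out <- dplyr::bind_rows(purrr::map(fits, tidy))
  attr(out, "fits") <- fits
  attr(out, "rho") <- rho
  out
}

#' @describeIn indr_series Rate trajectory plot: fitted rate against time
#'   for one crystal.
#' @param object An `indr_series`.
#' @export
autoplot.indr_series <- function(object, ...) {
  d <- dplyr::filter(object$data, .data$valid)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$indr_mg_cm2_min)) +
    ggplot2::geom_line(colour = "#4040a0") +
    ggplot2::geom_point(colour = "#4040a0") +
    ggplot2::labs(
      x = "time (s)",
      y = expression(I[n] * DR ~ (mg ~ cm^-2 ~ min^-1)),
      title = sprintf("Crystal %s dissolution rate", object$track_id)
    ) +
    ggplot2::theme_minimal()
}
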