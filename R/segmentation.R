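#' Segmentation parameters
#'
#' Parameters for isolating soluble crystals from the insoluble spacer
#' matrix and the fluid background.
#'
#' @param spacer_threshold Gray value above which voxels are treated as
#'   insoluble spacer and removed before crystal thresholding. `"auto"`
#'   places the cut at the midpoint between the two brightest histogram
#'   modes; `"none"` disables spacer removal.
#' @param crop_diameter Diameter, in voxels, of the circular field-of-view
#'   mask applied to every X-Y slice; `NULL` uses the full inscribed circle
#'   (`min(Y, X)` extents).
#' @param connectivity Face-adjacency order for object labeling; only 6
#'   (face-connected) is supported.
#' @param opening_radius Radius (voxels) of an optional 3D morphological
#'   opening with a ball structuring element applied to the binary mask;
#'   0 disables it (the default - it smooths renderings but erodes small
#'   objects, so it is off for measurement).
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(spacer_threshold = "auto",
                                crop_diameter = NULL,
                                connectivity = 6L,
                                opening_radius = 0) {
  if (is.character(spacer_threshold)) {
    spacer_threshold <- match.arg(spacer_threshold, c("auto", "none"))
  } else if (!is.numeric(spacer_threshold) || length(spacer_threshold) != 1L) {
    stop("`spacer_threshold` must be a number, \"auto\" or \"none\"", call. = FALSE)
  }
  if (!identical(as.integer(connectivity), 6L)) {
    stop("only face connectivity (6) is supported", call. = FALSE)
  }
  structure(
    list(spacer_threshold = spacer_threshold,
         crop_diameter = crop_diameter,
         connectivity = 6L,
         opening_radius = opening_radius),
    class = "segmentation_params"
  )
}

# logical (Y, X) disk mask: voxel centers within diameter/2 of the slice center
in_circle_mask <- function(ny, nx, diameter) {
  cy <- (ny - 1) / 2
  cx <- (nx - 1) / 2
  r2 <- (diameter / 2)^2
  dy2 <- (seq_len(ny) - 1 - cy)^2
  dx2 <- (seq_len(nx) - 1 - cx)^2
  outer(dy2, dx2, `+`) <= r2
}

#' Crop a volume to a circular field of view
#'
#' Sets voxels outside the axis-centred circle of the given diameter (in
#' every X-Y slice) to a background fill value; voxels inside are unchanged.
#' Mirrors the circular crop used to exclude the region outside the
#' reconstruction circle of a tomographic scan.
#'
#' @param frame A [volume_frame()].
#' @param diameter Circle diameter in voxels; must not exceed either
#'   in-plane extent.
#' @param fill Gray value written outside the circle (default: the volume
#'   minimum, i.e. darkest background).
#' @return A [volume_frame()] of the same shape.
#' @export
crop_cylinder <- function(frame, diameter, fill = min(frame)) {
  d <- dim(frame)
  if (diameter > min(d[2], d[3])) {
    stop("crop diameter (", diameter, ") exceeds in-plane extent (",
         min(d[2], d[3]), ")", call. = FALSE)
  }
  keep <- in_circle_mask(d[2], d[3], diameter)
  out <- unclass(frame)
  for (z in seq_len(d[1])) {
    sl <- out[z, , ]
    sl[!keep] <- fill
    out[z, , ] <- sl
  }
  volume_frame(out, voxel_size(frame), frame_time(frame), frame_index(frame))
}

# histogram of gray values: exact integer-like bins when few distinct values,
# otherwise `nbins` equal-width bins. Returns list(mids, counts).
gray_histogram <- function(v, nbins = 256L) {
  u <- unique(v)
  if (length(u) <= nbins) {
    u <- sort(u)
    counts <- tabulate(match(v, u), nbins = length(u))
    list(mids = u, counts = counts)
  } else {
    rng <- range(v)
    br <- seq(rng[1], rng[2], length.out = nbins + 1L)
    idx <- findInterval(v, br, rightmost.closed = TRUE, all.inside = TRUE)
    list(mids = (br[-1] + br[-length(br)]) / 2,
         counts = tabulate(idx, nbins = nbins))
  }
}

#' Minimum cross-entropy (Li) threshold
#'
#' Computes the gray threshold minimizing Li's cross-entropy between the
#' below- and above-threshold classes, via the iterative fixed-point scheme
#' of Li & Tam: with class means \eqn{\mu_0(t)} and \eqn{\mu_1(t)} of the
#' (minimum-shifted) gray values, the update is
#' \eqn{t' = (\mu_0 - \mu_1) / (\log\mu_0 - \log\mu_1)}. The iteration
#' converges to within half a gray level of the exhaustive minimizer of the
#' cross-entropy criterion.
#'
#' @param frame A [volume_frame()], array, or numeric vector of gray values.
#' @param nbins Number of histogram bins used when the data are not
#'   near-integer valued.
#' @return A single threshold on the original gray scale; foreground is
#'   `gray > threshold`.
#' @export
li_threshold <- function(frame, nbins = 256L) {
  v <- as.numeric(frame)
  v <- v[is.finite(v)]
  if (length(unique(v)) < 2L) {
    stop("constant image: no threshold exists", call. = FALSE)
  }
  h <- gray_histogram(v, nbins)
  mids <- h$mids - min(h$mids)  # shift so means are non-negative
  w <- h$counts
  eps <- 1e-6 * max(mids)  # guards log() when one class mean is zero

  t_cur <- sum(w * mids) / sum(w)  # start at the global mean
  for (iter in 1:200) {
    lo <- mids <= t_cur
    w0 <- sum(w[lo]); w1 <- sum(w[!lo])
    if (w0 == 0 || w1 == 0) break
    m0 <- sum(w[lo] * mids[lo]) / w0
    m1 <- sum(w[!lo] * mids[!lo]) / w1
    m0 <- max(m0, eps); m1 <- max(m1, eps)
    t_new <- if (abs(m0 - m1) < .Machine$double.eps) m0 else
      (m0 - m1) / (log(m0) - log(m1))
    if (abs(t_new - t_cur) < 0.25 * min(1, mean(diff(sort(unique(mids)))))) {
      t_cur <- t_new
      break
    }
    t_cur <- t_new
  }
  t_cur + min(h$mids)
}

# automatic spacer cut: separate the two upper intensity populations
# (medium crystals vs bright spacers). A first Li threshold removes the dark
# fluid, a second Li threshold splits the remaining bright voxels; the split
# is accepted only if the two classes are genuinely separated (bimodal),
# otherwise there is no spacer population and the cut is disabled (Inf).
auto_spacer_threshold <- function(v, nbins = 256L) {
  th1 <- li_threshold(v, nbins)
  bright <- v[v > th1]
  th2 <- tryCatch(li_threshold(bright, nbins), error = function(e) NULL)
  if (is.null(th2)) return(Inf)
  if (!two_class_separation(bright, th2)) return(Inf)  # no spacer class
  th2
}

# are the classes induced by a threshold genuinely bimodal, or is the
# threshold just splitting the tail of one noise population?
two_class_separation <- function(v, th, factor = 3) {
  lo <- v[v <= th]
  hi <- v[v > th]
  if (length(lo) < 2L || length(hi) < 2L) return(FALSE)
  spread <- max(sd(lo), sd(hi), .Machine$double.eps)
  (mean(hi) - mean(lo)) >= factor * spread
}

#' Segment soluble crystals
#'
#' Produces the binary crystal mask of one frame: the bright insoluble
#' spacer particles are removed by an upper gray cut, the crystal/fluid
#' separation is found by [li_threshold()] on the remaining voxels, and the
#' circular field-of-view crop is applied. A voxel is foreground exactly
#' when it is inside the crop circle, at or below the spacer cut, and above
#' the Li threshold of the spacer-removed volume.
#'
#' @param frame A [volume_frame()].
#' @param params A [segmentation_params()].
#' @return Logical 3D array with attributes `threshold` (Li),
#'   `spacer_threshold` (resolved numeric or `Inf` when disabled) and
#'   `valid` (the in-circle logical mask, (Y, X)).
#' @export
segment_crystals <- function(frame, params = segmentation_params()) {
  d <- dim(frame)
  diameter <- params$crop_diameter %||% min(d[2], d[3])
  if (diameter > min(d[2], d[3])) {
    stop("crop diameter exceeds in-plane extent", call. = FALSE)
  }
  circ <- in_circle_mask(d[2], d[3], diameter)
  in_circle <- aperm(array(circ, c(d[2], d[3], d[1])), c(3, 1, 2))

  v <- unclass(frame); attributes(v) <- list(dim = d)
  sp <- params$spacer_threshold
  spacer_cut <- if (identical(sp, "none")) Inf
    else if (identical(sp, "auto")) auto_spacer_threshold(v[in_circle])
    else as.numeric(sp)

  candidates <- in_circle & v <= spacer_cut
  th <- li_threshold(v[candidates])
  mask <- candidates & v > th
  # a threshold always exists, but on crystal-free volumes it just splits
  # the fluid noise: require genuine separation of the two classes
  if (!two_class_separation(v[candidates], th)) mask[] <- FALSE

  if (params$opening_radius > 0) {
    mask_open <- .ball_morph_cpp(.ball_morph_cpp(as.logical(mask), d,
                                                 params$opening_radius, 0L),
                                 d, params$opening_radius, 1L)
    mask <- array(mask_open, d)
  }
  structure(mask, threshold = th, spacer_threshold = spacer_cut, valid = circ)
}

#' Label face-connected 3D objects
#'
#' Connected-component labeling under connectivity 6: two foreground voxels
#' share a label iff they are joined by a path of face-adjacent foreground
#' voxels. Labels are consecutive `1..n_objects`, ordered by each object's
#' first-encountered voxel in raster-scan order, so the labeling is
#' deterministic.
#'
#' @param mask Logical (or 0/1) 3D array.
#' @param connectivity Must be 6.
#' @return A `labeled_volume`: integer 3D array with attribute `n_objects`.
#' @export
label_components <- function(mask, connectivity = 6L) {
  if (!identical(as.integer(connectivity), 6L)) {
    stop("only face connectivity (6) is supported", call. = FALSE)
  }
  d <- dim(mask)
  if (is.null(d) || length(d) != 3L) stop("`mask` must be a 3D array", call. = FALSE)
  lab <- .label6_cpp(as.logical(mask), as.integer(d))
  class(lab) <- c("labeled_volume", "array")
  lab
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<labeled_volume> %d x %d x %d voxels, %d objects\n",
              d[1], d[2], d[3], n_objects(x)))
  invisible(x)
}

#' @rdname label_components
#' @param labeled A `labeled_volume`.
#' @export
n_objects <- function(labeled) attr(labeled, "n_objects")

`%||%` <- function(a, b) if (is.null(a)) b else a
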