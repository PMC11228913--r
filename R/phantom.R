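#' Phantom experiment specification
#'
#' Describes a synthetic 4D dissolution experiment with exact ground truth:
#' soluble crystals (octahedra, pyramids, spheres) dispersed among bright
#' insoluble spacer particles in a dark fluid, imaged as a time series of
#' gray-value volumes. Crystals recede uniformly (every surface element
#' retreats at the crystal's recession rate normal to itself), which for a
#' convex body gives exactly `dV/dt = -k A` and hence a true individual
#' dissolution rate of `rho * k`. A sharp saturation front sweeps the cell
#' top-down: a crystal only starts dissolving once the front has passed its
#' depth, reproducing the top-first dissolution of a perfused packed bed.
#'
#' Polyhedra are rendered as axis-aligned L1 balls (octahedron:
#' `|dz|+|dy|+|dx| <= a`; pyramid: its lower half `dz >= 0`), and uniform
#' recession is the inward offset of each face plane, i.e. the circumradius
#' `a` shrinks at `k * sqrt(3)` (face planes sit at distance `a/sqrt(3)`)
#' and the pyramid base plane at `k`.
#'
#' @param volume_shape Volume extents (Z, Y, X) in voxels.
#' @param voxel_size Voxel edge, micrometres.
#' @param frame_interval Seconds between frames.
#' @param n_frames Number of frames.
#' @param crystals Tibble with one row per crystal: `shape`
#'   (`"sphere"`, `"octahedron"`, `"pyramid"`), `z`, `y`, `x` (0-based
#'   voxel centre), `size_um` (tip-to-tip diameter `2R`, micrometres) and
#'   `rate_um_min` (surface recession rate, micrometres per minute).
#' @param spacers Tibble of inert spheres: `z`, `y`, `x`, `radius_um`.
#' @param gray_levels Named numeric `c(fluid, crystal, spacer)`, strictly
#'   increasing: dark fluid, medium crystals, bright spacers.
#' @param noise_sd Gaussian gray noise standard deviation (0 = noise-free).
#' @param front_speed Saturation-front speed, voxels per frame; `Inf`
#'   means the whole cell dissolves from frame 0.
#' @param breakups Optional tibble of scripted splits: `crystal` (row index
#'   into `crystals`), `frame` (first frame of the split state), `gap_vox`
#'   (thickness of the removed slab through the centre, perpendicular to
#'   Y). Fragment ids are `1000 * crystal + 1` and `1000 * crystal + 2`.
#' @param seed Integer seed controlling the rendering noise; the whole
#'   phantom is bit-reproducible given the spec.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(volume_shape = c(128, 128, 128),
                         voxel_size = 11,
                         frame_interval = 6,
                         n_frames = 8,
                         crystals,
                         spacers = NULL,
                         gray_levels = c(fluid = 40, crystal = 150, spacer = 250),
                         noise_sd = 5,
                         front_speed = 32,
                         breakups = NULL,
                         seed = 1L) {
  stopifnot(length(volume_shape) == 3L, all(volume_shape >= 1),
            voxel_size > 0, frame_interval > 0, n_frames >= 1)
  if (!all(diff(gray_levels) > 0)) {
    stop("gray_levels must be ordered fluid < crystal < spacer", call. = FALSE)
  }
  crystals <- tibble::as_tibble(crystals)
  req <- c("shape", "z", "y", "x", "size_um", "rate_um_min")
  if (!all(req %in% names(crystals))) {
    stop("crystals needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (any(crystals$rate_um_min < 0)) stop("recession rates must be >= 0", call. = FALSE)
  r_vox <- crystals$size_um / 2 / voxel_size
  inside <- crystals$z - r_vox >= 0 & crystals$z + r_vox <= volume_shape[1] - 1 &
    crystals$y - r_vox >= 0 & crystals$y + r_vox <= volume_shape[2] - 1 &
    crystals$x - r_vox >= 0 & crystals$x + r_vox <= volume_shape[3] - 1
  if (!all(inside)) stop("crystal(s) do not fit inside the volume", call. = FALSE)
  if (!is.null(spacers)) {
    spacers <- tibble::as_tibble(spacers)
    rs <- spacers$radius_um / voxel_size
    ins <- spacers$z - rs >= 0 & spacers$z + rs <= volume_shape[1] - 1 &
      spacers$y - rs >= 0 & spacers$y + rs <= volume_shape[2] - 1 &
      spacers$x - rs >= 0 & spacers$x + rs <= volume_shape[3] - 1
    if (!all(ins)) stop("spacer(s) do not fit inside the volume", call. = FALSE)
  }
  structure(
    list(volume_shape = as.integer(volume_shape), voxel_size = voxel_size,
         frame_interval = frame_interval, n_frames = as.integer(n_frames),
         crystals = crystals, spacers = spacers, gray_levels = gray_levels,
         noise_sd = noise_sd, front_speed = front_speed,
         breakups = if (is.null(breakups)) NULL else tibble::as_tibble(breakups),
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> %s voxels @ %g μm, %d frames every %g s\n",
    paste(x$volume_shape, collapse = " x "), x$voxel_size,
    x$n_frames, x$frame_interval))
  cat(sprintf("  %d crystals, %d spacers, noise sd %g, front %g vox/frame, seed %d\n",
              nrow(x$crystals),
              if (is.null(x$spacers)) 0L else nrow(x$spacers),
              x$noise_sd, x$front_speed, x$seed))
  invisible(x)
}

# minutes of dissolution a crystal at depth cz has undergone by frame f
effective_minutes <- function(spec, cz, f) {
  arrival <- if (is.infinite(spec$front_speed)) 0 else cz / spec$front_speed
  max(0, f - arrival) * spec$frame_interval / 60
}

#' Tip-to-tip size for a target equivalent diameter
#'
#' Converts a desired sphere-equivalent diameter (what sieve classes and
#' [assign_size_class()] operate on) to the tip-to-tip `size_um` of a
#' phantom crystal of the given shape, using the exact continuum volumes
#' (`V = 4/3 pi R^3`, `4/3 a^3`, `2/3 a^3` for sphere, octahedron,
#' pyramid with circumradius `a = size/2`).
#'
#' @param shape `"sphere"`, `"octahedron"` or `"pyramid"`.
#' @param equiv_diam_um Target sphere-equivalent diameter, micrometres.
#' @return `size_um` (tip-to-tip).
#' @export
size_for_equiv_diam <- function(shape, equiv_diam_um) {
  f <- switch(shape,
    sphere = 1,
    octahedron = (8 / pi)^(1 / 3) / 2,   # d_eq = 2a * (1/pi)^(1/3) -> f = d_eq/(2a)
    pyramid = (4 / pi)^(1 / 3) / 2,
    stop("unknown shape: ", shape, call. = FALSE)
  )
  equiv_diam_um / f
}

# voxel mask of one crystal at frame f, in its (clipped) bounding box.
# Returns NULL when dissolved; otherwise list(z, y, x index ranges, mask,
# fragment = 0 (whole), 1 or 2 when split by a scripted breakup).
crystal_mask_bbox <- function(spec, ci, f, fragment = 0L) {
  cr <- spec$crystals[ci, ]
  tau <- effective_minutes(spec, cr$z, f)
  k_vox <- cr$rate_um_min / spec$voxel_size  # voxels per minute
  R0 <- cr$size_um / 2 / spec$voxel_size
  shape <- cr$shape
  if (shape == "sphere") {
    r <- R0 - k_vox * tau
    if (r <= 0) return(NULL)
    ext <- r
  } else {
    a <- R0 - k_vox * tau * sqrt(3)
    off <- k_vox * tau  # receded base plane of the pyramid
    if (a <= 0 || (shape == "pyramid" && a <= off)) return(NULL)
    ext <- a
  }
  dims <- spec$volume_shape
  z0 <- max(0, floor(cr$z - ext)); z1 <- min(dims[1] - 1, ceiling(cr$z + ext))
  y0 <- max(0, floor(cr$y - ext)); y1 <- min(dims[2] - 1, ceiling(cr$y + ext))
  x0 <- max(0, floor(cr$x - ext)); x1 <- min(dims[3] - 1, ceiling(cr$x + ext))
  dz <- (z0:z1) - cr$z
  dy <- (y0:y1) - cr$y
  dx <- (x0:x1) - cr$x
  nz <- length(dz); ny <- length(dy); nx <- length(dx)
  if (shape == "sphere") {
    q <- outer(outer(dz^2, dy^2, `+`), dx^2, `+`)
    mask <- q <= r^2
  } else {
    l1 <- outer(outer(abs(dz), abs(dy), `+`), abs(dx), `+`)
    mask <- l1 <= a
    if (shape == "pyramid") {
      zarr <- array(rep(dz, times = ny * nx), c(nz, ny, nx))
      mask <- mask & (zarr >= off)
    }
  }
  # scripted breakup: remove a slab perpendicular to Y through the centre
  ev <- breakup_event(spec, ci)
  if (!is.null(ev) && f >= ev$frame) {
    yarr <- aperm(array(rep(dy, times = nz * nx), c(ny, nz, nx)), c(2, 1, 3))
    half_gap <- ev$gap_vox / 2
    if (fragment == 1L) mask <- mask & (yarr <= -half_gap)
    else if (fragment == 2L) mask <- mask & (yarr >= half_gap)
    else mask <- mask & (abs(yarr) >= half_gap)
  }
  if (!any(mask)) return(NULL)
  list(z = z0:z1, y = y0:y1, x = x0:x1, mask = mask)
}

breakup_event <- function(spec, ci) {
  if (is.null(spec$breakups)) return(NULL)
  hit <- spec$breakups[spec$breakups$crystal == ci, ]
  if (nrow(hit) == 0L) return(NULL)
  if (!"gap_vox" %in% names(hit)) hit$gap_vox <- 3
  hit[1L, ]
}

#' Render one phantom frame
#'
#' Draws all surviving crystals (receded according to the saturation front
#' and their recession rates), the unchanging spacer spheres, and adds
#' Gaussian gray noise. Bit-reproducible for a given spec; two calls with
#' the same spec and frame index return identical volumes.
#'
#' @param spec A [phantom_spec()].
#' @param f Frame index, 0-based (`< n_frames`).
#' @return A [volume_frame()].
#' @export
render_frame <- function(spec, f) {
  if (f < 0 || f >= spec$n_frames) stop("frame index out of range", call. = FALSE)
  dims <- spec$volume_shape
  vol <- array(spec$gray_levels[["fluid"]], dims)
  for (ci in seq_len(nrow(spec$crystals))) {
    bb <- crystal_mask_bbox(spec, ci, f)
    if (is.null(bb)) next
    sub <- vol[bb$z + 1L, bb$y + 1L, bb$x + 1L, drop = FALSE]
    sub[bb$mask] <- spec$gray_levels[["crystal"]]
    vol[bb$z + 1L, bb$y + 1L, bb$x + 1L] <- sub
  }
  if (!is.null(spec$spacers)) {
    for (si in seq_len(nrow(spec$spacers))) {
      sp <- spec$spacers[si, ]
      r <- sp$radius_um / spec$voxel_size
      z0 <- max(0, floor(sp$z - r)); z1 <- min(dims[1] - 1, ceiling(sp$z + r))
      y0 <- max(0, floor(sp$y - r)); y1 <- min(dims[2] - 1, ceiling(sp$y + r))
      x0 <- max(0, floor(sp$x - r)); x1 <- min(dims[3] - 1, ceiling(sp$x + r))
      q <- outer(outer(((z0:z1) - sp$z)^2, ((y0:y1) - sp$y)^2, `+`),
                 ((x0:x1) - sp$x)^2, `+`)
      sub <- vol[z0:z1 + 1L, y0:y1 + 1L, x0:x1 + 1L, drop = FALSE]
      sub[q <= r^2] <- spec$gray_levels[["spacer"]]
      vol[z0:z1 + 1L, y0:y1 + 1L, x0:x1 + 1L] <- sub
    }
  }
  if (spec$noise_sd > 0) {
    with_local_seed((spec$seed + 100003L * (f + 1L)) %% 2147483647L, {
      vol <- vol + array(rnorm(prod(dims), sd = spec$noise_sd), dims)
    })
  }
  volume_frame(vol, voxel_size = spec$voxel_size,
               time = f * spec$frame_interval, frame_index = f)
}

#' @rdname render_frame
#' @return `render_phantom()`: list of all frames of the series.
#' @export
render_phantom <- function(spec) {
  lapply(seq_len(spec$n_frames) - 1L, function(f) render_frame(spec, f))
}

# evaluate code under a temporary RNG seed, restoring the caller's state
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(code))
}

# exposed-face count of a binary mask (array padded implicitly by background)
count_exposed_faces <- function(mask) {
  total <- 0
  # faces along each axis: transitions between voxel and its neighbour
  shift_pad <- function(m, ax, by) {
    d <- dim(m)
    out <- array(FALSE, d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    if (by == 1L) {
      idx_dst[[ax]] <- 2:d[ax]; idx_src[[ax]] <- 1:(d[ax] - 1L)
    } else {
      idx_dst[[ax]] <- 1:(d[ax] - 1L); idx_src[[ax]] <- 2:d[ax]
    }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  for (ax in 1:3) {
    for (by in c(1L, -1L)) {
      total <- total + sum(mask & !shift_pad(mask, ax, by))
    }
  }
  total
}

#' Ground truth of a phantom experiment
#'
#' Exact per-frame object truth computed directly from the noise-free
#' geometry: voxel-counted volume, centroid and exposed-face count for
#' every crystal (and every scripted breakup fragment) at every frame,
#' the identity links between consecutive frames, breakup lineage, and the
#' true dissolution rate `rho * k` of each crystal.
#'
#' @param spec A [phantom_spec()].
#' @param rho Material density, mg cm^-3 (for the true rates).
#' @return List with tibbles `observations` (`frame_index`, `crystal_id`,
#'   `mother_id`, `z`, `y`, `x`, `voxel_count`, `exposed_faces`), `links`
#'   (`crystal_id`, `frame_from`, `frame_to`), `lineage` (`child_id`,
#'   `mother_id`, `frame`) and `rates` (`crystal_id`, `shape`,
#'   `rate_um_min`, `indr_mg_cm2_min`).
#' @export
phantom_ground_truth <- function(spec, rho = 2165) {
  obs <- list()
  for (f in seq_len(spec$n_frames) - 1L) {
    for (ci in seq_len(nrow(spec$crystals))) {
      ev <- breakup_event(spec, ci)
      split_now <- !is.null(ev) && f >= ev$frame
      frags <- if (split_now) 1:2 else 0L
      for (fr in frags) {
        bb <- crystal_mask_bbox(spec, ci, f, fragment = fr)
        if (is.null(bb)) next
        w <- which(bb$mask, arr.ind = TRUE)
        obs[[length(obs) + 1L]] <- tibble::tibble(
          frame_index = f,
          crystal_id = if (fr == 0L) ci else 1000L * ci + fr,
          mother_id = if (fr == 0L) NA_integer_ else ci,
          z = mean(bb$z[w[, 1]]), y = mean(bb$y[w[, 2]]), x = mean(bb$x[w[, 3]]),
          voxel_count = nrow(w),
          exposed_faces = count_exposed_faces(bb$mask)
        )
      }
    }
  }
  observations <- dplyr::bind_rows(obs)
  if (nrow(observations) == 0L) {
    observations <- tibble::tibble(
      frame_index = integer(), crystal_id = integer(), mother_id = integer(),
      z = numeric(), y = numeric(), x = numeric(),
      voxel_count = integer(), exposed_faces = numeric())
  }
  links <- observations |>
    dplyr::group_by(.data$crystal_id) |>
    dplyr::arrange(.data$frame_index, .by_group = TRUE) |>
    dplyr::mutate(nxt = dplyr::lead(.data$frame_index)) |>
    dplyr::filter(!is.na(.data$nxt), .data$nxt == .data$frame_index + 1L) |>
    dplyr::ungroup() |>
    dplyr::transmute(crystal_id = .data$crystal_id,
                     frame_from = .data$frame_index,
                     frame_to = .data$nxt)
  kids <- dplyr::filter(observations, !is.na(.data$mother_id))
  lineage <- if (nrow(kids) == 0L) {
    tibble::tibble(child_id = integer(), mother_id = integer(), frame = integer())
  } else {
    kids |>
      dplyr::rename(child_id = "crystal_id") |>
      dplyr::group_by(.data$child_id) |>
      dplyr::summarise(mother_id = .data$mother_id[1L],
                       frame = min(.data$frame_index), .groups = "drop")
  }
  rates <- tibble::tibble(
    crystal_id = seq_len(nrow(spec$crystals)),
    shape = spec$crystals$shape,
    rate_um_min = spec$crystals$rate_um_min,
    indr_mg_cm2_min = rho * spec$crystals$rate_um_min * 1e-4
  )
  list(observations = observations, links = links,
       lineage = lineage, rates = rates)
}

#' Random phantom experiment
#'
#' Draws a reproducible random dissolution scene: crystals with random
#' shapes, sieve-class sizes and recession rates, placed without overlap
#' (centre separation at least the sum of circumscribed radii plus
#' `min_separation`) inside the field-of-view cylinder, among inert
#' spacer spheres. Defaults emulate a scaled-down acquisition: a 128^3
#' window at 11 μm/voxel, frames every 6 s, medium sieve-class crystals
#' (equivalent diameter 220-330 μm), recession rates 50-110 μm/min
#' (dissolution rates of order 11-24 mg cm^-2 min^-1 at NaCl density),
#' and a saturation front sweeping 32 voxels per frame.
#'
#' @param seed Integer seed (drives placement, sizes, rates and noise).
#' @param n_crystals Number of soluble crystals.
#' @param equiv_diam_um Range (or per-crystal vector) of sphere-equivalent
#'   diameters, micrometres.
#' @param rate_um_min Range (or per-crystal vector) of recession rates.
#' @param shapes Shapes to draw from (or per-crystal vector).
#' @param n_spacers Number of inert spacer spheres.
#' @param spacer_diam_um Spacer diameter range, micrometres.
#' @param min_separation Extra clearance between bounding spheres, voxels.
#' @inheritParams phantom_spec
#' @param ... Passed on to [phantom_spec()] (`gray_levels`, `noise_sd`,
#'   `front_speed`, `breakups`, ...).
#' @return A [phantom_spec()].
#' @export
random_phantom_spec <- function(seed,
                                n_crystals = 20,
                                equiv_diam_um = c(200, 300),
                                rate_um_min = c(50, 110),
                                shapes = c("sphere", "octahedron", "pyramid"),
                                volume_shape = c(128, 128, 128),
                                voxel_size = 11,
                                frame_interval = 6,
                                n_frames = 8,
                                n_spacers = 40,
                                spacer_diam_um = c(100, 140),
                                min_separation = 4,
                                ...) {
  with_local_seed(seed, {
    shp <- if (length(shapes) == n_crystals && n_crystals > 3) shapes
           else sample(shapes, n_crystals, replace = TRUE)
    deq <- if (length(equiv_diam_um) == n_crystals && n_crystals != 2) equiv_diam_um
           else runif(n_crystals, equiv_diam_um[1], equiv_diam_um[2])
    rate <- if (length(rate_um_min) == n_crystals && n_crystals != 2) rate_um_min
            else runif(n_crystals, rate_um_min[1], rate_um_min[2])
    size_um <- vapply(seq_len(n_crystals),
                      function(i) size_for_equiv_diam(shp[i], deq[i]), 0.0)
    r_vox <- size_um / 2 / voxel_size
    sp_r_um <- runif(n_spacers, spacer_diam_um[1] / 2, spacer_diam_um[2] / 2)
    sp_r_vox <- sp_r_um / voxel_size

    all_r <- c(r_vox, sp_r_vox)
    is_poly <- c(shp != "sphere", rep(FALSE, n_spacers))
    centres <- place_without_overlap(all_r, is_poly, volume_shape, min_separation)

    crystals <- tibble::tibble(
      shape = shp,
      z = centres$z[seq_len(n_crystals)],
      y = centres$y[seq_len(n_crystals)],
      x = centres$x[seq_len(n_crystals)],
      size_um = size_um,
      rate_um_min = rate
    )
    spacers <- if (n_spacers > 0) tibble::tibble(
      z = centres$z[n_crystals + seq_len(n_spacers)],
      y = centres$y[n_crystals + seq_len(n_spacers)],
      x = centres$x[n_crystals + seq_len(n_spacers)],
      radius_um = sp_r_um
    ) else NULL
    phantom_spec(volume_shape = volume_shape, voxel_size = voxel_size,
                 frame_interval = frame_interval, n_frames = n_frames,
                 crystals = crystals, spacers = spacers, seed = seed, ...)
  })
}

# random sequential placement inside the field-of-view cylinder; objects are
# placed largest-first (much higher packing success), results returned in the
# caller's order. `radii` are circumscribed radii; for two axis-aligned
# octahedral bodies the exact non-overlap condition is on the L1 distance
# (L1 balls intersect iff |c1-c2|_1 <= a1+a2), all other pairs use the
# bounding-sphere (L2) condition.
place_without_overlap <- function(radii, is_poly, volume_shape, min_separation,
                                  max_tries = 500000L) {
  n <- length(radii)
  ord <- order(radii, decreasing = TRUE)
  zc <- yc <- xc <- numeric(n)
  cyl_r <- min(volume_shape[2], volume_shape[3]) / 2
  cy <- (volume_shape[2] - 1) / 2
  cx <- (volume_shape[3] - 1) / 2
  placed <- 0L
  tries <- 0L
  done <- integer(0)  # indices (original) already placed
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("could not place all objects without overlap; ",
           "reduce count or sizes", call. = FALSE)
    }
    i <- ord[placed + 1L]
    r <- radii[i]
    z <- runif(1, r + 1, volume_shape[1] - 2 - r)
    rr <- runif(1, 0, max(cyl_r - r - 2, 0.1))
    th <- runif(1, 0, 2 * pi)
    y <- cy + rr * sin(th)
    x <- cx + rr * cos(th)
    ok <- TRUE
    if (placed > 0L) {
      need <- radii[done] + r + min_separation
      d2 <- sqrt((zc[done] - z)^2 + (yc[done] - y)^2 + (xc[done] - x)^2)
      pass <- d2 >= need
      if (is_poly[i]) {
        d1 <- abs(zc[done] - z) + abs(yc[done] - y) + abs(xc[done] - x)
        pass <- pass | (is_poly[done] & d1 >= need)
      }
      ok <- all(pass)
    }
    if (ok) {
      zc[i] <- z; yc[i] <- y; xc[i] <- x
      placed <- placed + 1L
      done <- c(done, i)
    }
  }
  list(z = zc, y = yc, x = xc)
}

#' Compare tracking output with phantom ground truth
#'
#' The automated replacement for manual cross-checking of tracked
#' sequences: measured observations are matched to ground-truth objects by
#' nearest centroid within `max_match_dist`, and every ground-truth
#' identity link (the same crystal present in two consecutive frames) is
#' checked for recovery - both endpoint observations found and placed
#' consecutively in one measured track. Scripted breakup lineage is
#' checked by requiring each truth child's measured track to carry a
#' `mother_id` whose track matches the truth mother.
#'
#' @param tracks Accepted `crystal_tracks` from the pipeline.
#' @param truth A [phantom_ground_truth()] result.
#' @param max_match_dist Largest centroid distance (voxels) for matching a
#'   measured observation to a truth object.
#' @return List: `n_links`, `n_recovered`, `link_recovery` (fraction),
#'   `lineage` (tibble `child_id`, `mother_id`, `correct`),
#'   `lineage_correct` (fraction, `NaN` when no breakups).
#' @export
evaluate_tracking <- function(tracks, truth, max_match_dist = 8) {
  tr <- tibble::as_tibble(tracks)
  tr$truth_id <- NA_integer_
  tobs <- truth$observations
  for (f in unique(tr$frame_index)) {
    ti <- which(tobs$frame_index == f)
    mi <- which(tr$frame_index == f)
    if (length(ti) == 0L || length(mi) == 0L) next
    d <- outer(mi, ti, function(a, b) {
      sqrt((tr$z[a] - tobs$z[b])^2 + (tr$y[a] - tobs$y[b])^2 +
           (tr$x[a] - tobs$x[b])^2)
    })
    best <- apply(d, 1L, which.min)
    dist <- d[cbind(seq_along(mi), best)]
    tr$truth_id[mi] <- ifelse(dist <= max_match_dist,
                              tobs$crystal_id[ti[best]], NA_integer_)
  }
  # recovered links: same truth id in consecutive frames of one track
  link_tbl <- tr |>
    dplyr::arrange(.data$track_id, .data$frame_index) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::mutate(
      nxt_truth = dplyr::lead(.data$truth_id),
      nxt_frame = dplyr::lead(.data$frame_index)
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$nxt_frame), .data$nxt_frame == .data$frame_index + 1L,
                  !is.na(.data$truth_id), .data$truth_id == .data$nxt_truth) |>
    dplyr::distinct(.data$truth_id, .data$frame_index)
  hits <- nrow(dplyr::semi_join(
    truth$links, link_tbl,
    by = c(crystal_id = "truth_id", frame_from = "frame_index")))
  n_links <- nrow(truth$links)

  # lineage: majority truth id per measured track
  majority <- tr |>
    dplyr::filter(!is.na(.data$truth_id)) |>
    dplyr::count(.data$track_id, .data$truth_id) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::slice_max(.data$n, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("track_id", "truth_id")
  mothers <- tr |>
    dplyr::distinct(.data$track_id, .data$mother_id)
  lineage <- truth$lineage
  if (nrow(lineage)) {
    lineage$correct <- vapply(seq_len(nrow(lineage)), function(i) {
      child_tracks <- majority$track_id[majority$truth_id == lineage$child_id[i]]
      if (length(child_tracks) == 0L) return(FALSE)
      any(vapply(child_tracks, function(ct) {
        m <- mothers$mother_id[mothers$track_id == ct][1L]
        if (is.na(m)) return(FALSE)
        mt <- majority$truth_id[majority$track_id == m]
        length(mt) == 1L && mt == lineage$mother_id[i]
      }, TRUE))
    }, TRUE)
  } else {
    lineage$correct <- logical(0)
  }
  list(
    n_links = n_links,
    n_recovered = hits,
    link_recovery = if (n_links > 0) hits / n_links else NaN,
    lineage = lineage,
    lineage_correct = if (nrow(lineage)) mean(lineage$correct) else NaN
  )
}
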