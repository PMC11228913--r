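#' Tracking parameters
#'
#' Thresholds governing frame-to-frame identity linking and the two
#' filtering passes that remove non-uniquely identified crystals.
#'
#' @param growth_tolerance Relative fraction `eps` of apparent volume or
#'   surface *increase* tolerated between consecutive frames. Crystals
#'   cannot grow during dissolution, so any larger increase marks a
#'   mis-identified sequence; the tolerance absorbs segmentation noise.
#' @param jump_volume_fraction Largest plausible relative volume *drop* in
#'   one frame step; a larger drop is an improbable sudden change and
#'   breaks the sequence.
#' @param sphericity_jump Largest plausible absolute change in sphericity
#'   between consecutive frames.
#' @param max_link_distance Optional gate (voxels) on centroid displacement
#'   per step; `Inf` disables it.
#' @param min_track_length Minimum number of timepoints a crystal must be
#'   observed in (consecutively) to enter the analysis; the default 4
#'   guarantees a degree of freedom for the quadratic trajectory fits.
#' @param consecutive Require the qualifying observations to sit in
#'   consecutive frames (default) rather than any `min_track_length` frames.
#' @param w_dist,w_vol Weights of the displacement and volume-consistency
#'   terms of the sequence-matching score. Displacement is measured
#'   relative to the particle's sphere-equivalent diameter and volume
#'   change relative to the previous volume, so both terms are
#'   dimensionless and O(1) for implausible pairings.
#' @param min_fragment_fraction Smallest volume a breakup fragment may have,
#'   as a fraction of its mother's volume in the previous frame; a much
#'   smaller object appearing next to a crystal is segmentation debris, not
#'   a fragment.
#' @param fragment_max_distance Largest centroid distance at which an extra
#'   object may attach to a mother as a breakup fragment, in units of the
#'   mother's sphere-equivalent diameter.
#' @return A `tracking_params` list.
#' @export
tracking_params <- function(growth_tolerance = 0.05,
                            jump_volume_fraction = 0.5,
                            sphericity_jump = 0.3,
                            max_link_distance = Inf,
                            min_track_length = 4L,
                            consecutive = TRUE,
                            w_dist = 1, w_vol = 1,
                            min_fragment_fraction = 0.05,
                            fragment_max_distance = 2) {
  stopifnot(growth_tolerance >= 0,
            jump_volume_fraction > 0, jump_volume_fraction <= 1,
            min_track_length >= 2)
  structure(
    list(growth_tolerance = growth_tolerance,
         jump_volume_fraction = jump_volume_fraction,
         sphericity_jump = sphericity_jump,
         max_link_distance = max_link_distance,
         min_track_length = as.integer(min_track_length),
         consecutive = isTRUE(consecutive),
         w_dist = w_dist, w_vol = w_vol,
         min_fragment_fraction = min_fragment_fraction,
         fragment_max_distance = fragment_max_distance),
    class = "tracking_params"
  )
}

obs_equiv_diam_vox <- function(obs) (6 * obs$voxel_count / pi)^(1 / 3)

#' Nearest-neighbour linking of two consecutive frames
#'
#' Assigns to every next-frame observation the previous-frame observation
#' with the smallest Euclidean centroid distance (the tracking parameter).
#' Many-to-one assignments are allowed at this stage: two next-frame
#' objects nearest to the same predecessor encode a candidate breakup,
#' resolved later by [match_sequences()]. Observations with no predecessor
#' within `max_link_distance` are marked new.
#'
#' @param prev,nxt Observation tibbles (rows of [measure_objects()] output)
#'   for frames `t` and `t + 1`.
#' @param params A [tracking_params()].
#' @return Tibble with one row per next observation: `next_label`,
#'   `prev_label` (`NA` for new objects) and `distance` (voxels).
#' @export
link_frames <- function(prev, nxt, params = tracking_params()) {
  if (nrow(nxt) == 0L) {
    return(tibble::tibble(next_label = integer(), prev_label = integer(),
                          distance = numeric()))
  }
  if (nrow(prev) == 0L) {
    return(tibble::tibble(next_label = nxt$label,
                          prev_label = NA_integer_, distance = NA_real_))
  }
  dmat <- pair_distances(prev, nxt)
  best <- apply(dmat, 2L, which.min)  # ties: lowest prev row = lowest label
  dist <- dmat[cbind(best, seq_len(ncol(dmat)))]
  gated <- dist > params$max_link_distance
  tibble::tibble(
    next_label = nxt$label,
    prev_label = ifelse(gated, NA_integer_, prev$label[best]),
    distance = ifelse(gated, NA_real_, dist)
  )
}

# |prev| x |nxt| centroid distance matrix, voxel units
pair_distances <- function(prev, nxt) {
  outer(seq_len(nrow(prev)), seq_len(nrow(nxt)), function(i, j) {
    sqrt((prev$z[i] - nxt$z[j])^2 + (prev$y[i] - nxt$y[j])^2 +
         (prev$x[i] - nxt$x[j])^2)
  })
}

#' Build tracks by sequence matching
#'
#' Links the per-frame observations into time-ordered tracks. Ambiguous
#' candidate links (several objects nearest to one predecessor, or swapped
#' positions) are resolved per step by minimizing the matching score
#' `w_dist * |dc| / d_eq + w_vol * |dV| / V` over feasible pairs, assigned
#' greedily in increasing score order so that the longest consistent
#' sequences are extended first. The volume-consistency term lets a
#' crystal's sequence follow its own volume even when another crystal moves
#' onto its former coordinates. Every observation ends up in at most one
#' track. When two or more objects attach to one predecessor (breakup), the
#' mother track is closed and each fragment starts a child track carrying
#' `mother_id`.
#'
#' Ties are broken by the lowest previous-frame label, then the lowest
#' next-frame label, making the assignment deterministic.
#'
#' @param observations Observation tibble covering all frames
#'   ([measure_objects()] columns; `frame_index`, `label`, `z`, `y`, `x`
#'   and `voxel_count` are required).
#' @param params A [tracking_params()].
#' @return A `crystal_tracks` tibble: the observation columns plus
#'   `track_id` and `mother_id`, ordered by track and frame.
#' @export
match_sequences <- function(observations, params = tracking_params()) {
  obs <- dplyr::arrange(observations, .data$frame_index, .data$label)
  frames <- sort(unique(obs$frame_index))
  by_frame <- split(seq_len(nrow(obs)), factor(obs$frame_index, levels = frames))

  next_id <- 0L
  tracks <- list()   # each: list(id, mother, rows, open)
  active <- integer()  # indices into `tracks` of open tracks, last obs in frame f

  start_track <- function(row, mother = NA_integer_) {
    next_id <<- next_id + 1L
    tracks[[next_id]] <<- list(id = next_id, mother = mother,
                               rows = row, open = TRUE)
    next_id
  }

  if (length(frames) > 0L) {
    for (r in by_frame[[1]]) active <- c(active, start_track(r))
  }

  for (fi in seq_along(frames)[-1]) {
    consecutive <- frames[fi] == frames[fi - 1L] + 1L
    nxt_rows <- by_frame[[fi]]
    nxt <- obs[nxt_rows, ]
    if (!consecutive || length(active) == 0L) {
      for (t in active) tracks[[t]]$open <- FALSE
      active <- vapply(nxt_rows, start_track, 0L)
      next
    }
    prev_rows <- vapply(active, function(t) tail(tracks[[t]]$rows, 1L), 0L)
    prev <- obs[prev_rows, ]

    dmat <- pair_distances(prev, nxt)
    deq <- pmax(obs_equiv_diam_vox(prev), 1e-9)
    dvrel <- outer(seq_len(nrow(prev)), seq_len(nrow(nxt)), function(i, j) {
      abs(nxt$voxel_count[j] - prev$voxel_count[i]) / pmax(prev$voxel_count[i], 1)
    })
    score <- params$w_dist * dmat / deq + params$w_vol * dvrel
    feasible <- dmat <= params$max_link_distance

    # greedy one-to-one assignment in increasing score order
    ord <- order(score, prev$label[row(score)], nxt$label[col(score)])
    prev_used <- rep(FALSE, nrow(prev))
    next_assigned <- rep(NA_integer_, nrow(nxt))  # index into prev
    for (k in ord) {
      i <- row(score)[k]; j <- col(score)[k]
      if (!feasible[k] || prev_used[i] || !is.na(next_assigned[j])) next
      prev_used[i] <- TRUE
      next_assigned[j] <- i
    }
    # unmatched next observations: attach as breakup fragment of the
    # best-scoring predecessor when physically plausible (fragment no
    # larger than the mother, no smaller than a real fragment can be, and
    # adjacent to the mother), else start fresh
    for (j in which(is.na(next_assigned))) {
      cand <- which(feasible[, j])
      if (length(cand) > 0L) {
        i <- cand[order(score[cand, j], prev$label[cand])][1L]
        plausible <- nxt$voxel_count[j] <=
          prev$voxel_count[i] * (1 + params$growth_tolerance) &&
          nxt$voxel_count[j] >=
          prev$voxel_count[i] * params$min_fragment_fraction &&
          dmat[i, j] <= params$fragment_max_distance * deq[i]
        if (plausible) next_assigned[j] <- -i  # negative = fragment
      }
    }

    new_active <- integer()
    for (i in seq_len(nrow(prev))) {
      assignees <- which(next_assigned %in% c(i, -i))
      t <- active[i]
      if (length(assignees) == 1L && next_assigned[assignees] == i) {
        tracks[[t]]$rows <- c(tracks[[t]]$rows, nxt_rows[assignees])
        new_active <- c(new_active, t)
      } else if (length(assignees) >= 2L) {
        # breakup: close the mother, give every fragment a child track
        tracks[[t]]$open <- FALSE
        for (j in assignees[order(nxt$label[assignees])]) {
          new_active <- c(new_active, start_track(nxt_rows[j], mother = tracks[[t]]$id))
        }
      } else {
        tracks[[t]]$open <- FALSE
      }
    }
    for (j in which(is.na(next_assigned))) {
      new_active <- c(new_active, start_track(nxt_rows[j]))
    }
    active <- new_active
  }

  assemble_tracks(obs, tracks)
}

assemble_tracks <- function(obs, tracks) {
  if (length(tracks) == 0L) return(empty_tracks())
  pieces <- purrr::map(tracks, function(t) {
    piece <- obs[t$rows, ]
    piece$track_id <- t$id
    piece$mother_id <- t$mother
    piece
  })
  out <- dplyr::bind_rows(pieces)
  out <- dplyr::arrange(out, .data$track_id, .data$frame_index)
  as_crystal_tracks(out, rejections = empty_rejections())
}

empty_tracks <- function() {
  out <- empty_observations()
  out$track_id <- integer()
  out$mother_id <- integer()
  as_crystal_tracks(out, rejections = empty_rejections())
}

empty_rejections <- function() {
  tibble::tibble(track_id = integer(), reason = character(), frame = integer())
}

as_crystal_tracks <- function(x, rejections = NULL) {
  if (!is.null(rejections)) attr(x, "rejections") <- rejections
  class(x) <- unique(c("crystal_tracks", class(tibble::as_tibble(x))))
  x
}

#' Track rejection log
#'
#' @param tracks A `crystal_tracks` tibble.
#' @return Tibble of removed/truncated sequences: `track_id`, `reason`
#'   (`"growth"`, `"jump"` or `"short"`) and the frame of the violation.
#' @export
rejections <- function(tracks) {
  attr(tracks, "rejections") %||% empty_rejections()
}

track_filter_values <- function(piece) {
  v <- if ("volume_cm3" %in% names(piece) && !all(is.na(piece$volume_cm3))) {
    piece$volume_cm3
  } else {
    piece$voxel_count
  }
  a <- if ("surface_cm2" %in% names(piece)) piece$surface_cm2 else NULL
  list(v = v, a = a)
}

#' Filtering pass 1: crystals cannot grow during dissolution
#'
#' Scans each track for a step where the volume or the surface area grows
#' by more than the relative tolerance `eps`. Such a step marks a
#' non-unique identification: the track is truncated just before the
#' violating step, and removed entirely (reason `"growth"`) when the
#' remaining prefix is shorter than `min_track_length`.
#'
#' @param tracks A `crystal_tracks` tibble (from [match_sequences()]).
#' @param params A [tracking_params()].
#' @return Filtered `crystal_tracks`; removals are appended to
#'   [rejections()].
#' @export
filter_pass1 <- function(tracks, params = tracking_params()) {
  rej <- rejections(tracks)
  eps <- params$growth_tolerance
  pieces <- tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_split()
  kept <- purrr::map(pieces, function(piece) {
    piece <- dplyr::arrange(piece, .data$frame_index)
    fv <- track_filter_values(piece)
    n <- nrow(piece)
    grow <- fv$v[-1] > fv$v[-n] * (1 + eps)
    if (!is.null(fv$a)) grow <- grow | (fv$a[-1] > fv$a[-n] * (1 + eps))
    bad <- which(grow)
    if (length(bad) == 0L) return(piece)
    keep_n <- bad[1L]
    if (keep_n < params$min_track_length) {
      rej <<- dplyr::bind_rows(rej, tibble::tibble(
        track_id = piece$track_id[1L], reason = "growth",
        frame = piece$frame_index[keep_n + 1L]))
      return(NULL)
    }
    piece[seq_len(keep_n), ]
  })
  out <- dplyr::bind_rows(kept)
  if (nrow(out) == 0L) out <- empty_tracks()
  as_crystal_tracks(out, rejections = rej)
}

#' Filtering pass 2: improbable sudden changes
#'
#' Scans each track for a step with an implausibly large single-step change
#' in a morphological descriptor: a relative volume drop exceeding
#' `jump_volume_fraction`, or an absolute sphericity change exceeding
#' `sphericity_jump`. Such a step breaks the sequence: the prefix keeps the
#' track id, the remainder continues as a fresh track (no lineage), and any
#' resulting piece shorter than `min_track_length` is removed with reason
#' `"jump"`.
#'
#' @inheritParams filter_pass1
#' @return Filtered `crystal_tracks` with updated [rejections()].
#' @export
filter_pass2 <- function(tracks, params = tracking_params()) {
  rej <- rejections(tracks)
  pieces <- tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_split()
  new_id <- if (nrow(tracks)) max(tracks$track_id) else 0L
  out_pieces <- list()
  for (piece in pieces) {
    piece <- dplyr::arrange(piece, .data$frame_index)
    repeat {
      fv <- track_filter_values(piece)
      n <- nrow(piece)
      jump <- fv$v[-1] < fv$v[-n] * (1 - params$jump_volume_fraction)
      if ("roundness" %in% names(piece) && !all(is.na(piece$roundness))) {
        jump <- jump |
          (abs(piece$roundness[-1] - piece$roundness[-n]) > params$sphericity_jump)
      }
      bad <- which(jump)
      if (length(bad) == 0L) {
        out_pieces <- c(out_pieces, list(piece))
        break
      }
      k <- bad[1L]
      prefix <- piece[seq_len(k), ]
      if (nrow(prefix) >= params$min_track_length) {
        out_pieces <- c(out_pieces, list(prefix))
      } else {
        rej <- dplyr::bind_rows(rej, tibble::tibble(
          track_id = prefix$track_id[1L], reason = "jump",
          frame = piece$frame_index[k + 1L]))
      }
      piece <- piece[(k + 1L):n, ]
      new_id <- new_id + 1L
      piece$track_id <- new_id
      piece$mother_id <- NA_integer_
      if (nrow(piece) < params$min_track_length) {
        rej <- dplyr::bind_rows(rej, tibble::tibble(
          track_id = new_id, reason = "jump", frame = piece$frame_index[1L]))
        break
      }
    }
  }
  out <- dplyr::bind_rows(out_pieces)
  if (nrow(out) == 0L) out <- empty_tracks()
  as_crystal_tracks(out, rejections = rej)
}

#' Keep tracks observed long enough for rate analysis
#'
#' Retains tracks with at least `min_track_length` observations in
#' consecutive frames (the inclusion rule that guarantees enough degrees of
#' freedom for the quadratic trajectory fits). Shorter tracks are removed
#' with reason `"short"`.
#'
#' @inheritParams filter_pass1
#' @return Accepted `crystal_tracks`.
#' @export
finalize_tracks <- function(tracks, params = tracking_params()) {
  rej <- rejections(tracks)
  keep <- tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      run = longest_consecutive_run(.data$frame_index),
      first_frame = min(.data$frame_index),
      .groups = "drop"
    )
  qual <- if (params$consecutive) keep$run else keep$n
  ok <- keep$track_id[qual >= params$min_track_length]
  dropped <- keep[!(keep$track_id %in% ok), ]
  if (nrow(dropped)) {
    rej <- dplyr::bind_rows(rej, tibble::tibble(
      track_id = dropped$track_id, reason = "short",
      frame = dropped$first_frame))
  }
  out <- dplyr::filter(tracks, .data$track_id %in% ok)
  as_crystal_tracks(out, rejections = rej)
}

longest_consecutive_run <- function(frames) {
  f <- sort(frames)
  if (length(f) == 0L) return(0L)
  runs <- rle(c(TRUE, diff(f) == 1L))
  max(runs$lengths[runs$values])
}

#' Track crystals through a time series
#'
#' Full tracking pipeline: sequence matching ([match_sequences()]), the
#' non-growth filter ([filter_pass1()]), the sudden-change filter
#' ([filter_pass2()]) and the minimum-length rule ([finalize_tracks()]).
#'
#' @inheritParams match_sequences
#' @return Accepted `crystal_tracks` with a [rejections()] log attached.
#' @export
track_crystals <- function(observations, params = tracking_params()) {
  match_sequences(observations, params) |>
    filter_pass1(params) |>
    filter_pass2(params) |>
    finalize_tracks(params)
}

#' Summary of tracked data per size class
#'
#' Counts successfully tracked crystals and their data points (one data
#' point = one crystal observed in one scan) per initial-size class, and
#' the mean number of data points per crystal rounded to one decimal.
#'
#' @param tracks Accepted `crystal_tracks`.
#' @param classes Size classes ([size_classes()]); `NULL` for a single
#'   overall row.
#' @return Tibble: `size_class`, `tracked_crystals`, `data_points`,
#'   `data_points_per_crystal`.
#' @export
track_summary <- function(tracks, classes = size_classes()) {
  if (is.null(classes)) {
    per <- tibble::tibble(track_id = unique(tracks$track_id),
                          size_class = "all")
  } else {
    per <- assign_size_class(tracks, classes)
  }
  tracks |>
    dplyr::count(.data$track_id, name = "data_points") |>
    dplyr::inner_join(per, by = "track_id") |>
    dplyr::filter(!is.na(.data$size_class)) |>
    dplyr::group_by(.data$size_class) |>
    dplyr::summarise(
      tracked_crystals = dplyr::n(),
      data_points = sum(.data$data_points),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      data_points_per_crystal = round(.data$data_points / .data$tracked_crystals, 1)
    )
}
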