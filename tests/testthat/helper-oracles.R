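# Independent brute-force oracles used to validate the package's
# implementations on small instances.

# stack-based flood fill: reference connected-component labeling, 6-connectivity
floodfill_label6 <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nxt <- 0L
  nbr <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
               c(0, 0, -1), c(0, 0, 1))
  for (x in seq_len(d[3])) for (y in seq_len(d[2])) for (z in seq_len(d[1])) {
    if (!mask[z, y, x] || lab[z, y, x] != 0L) next
    nxt <- nxt + 1L
    stack <- matrix(c(z, y, x), ncol = 3)
    lab[z, y, x] <- nxt
    while (nrow(stack) > 0) {
      cur <- stack[nrow(stack), ]
      stack <- stack[-nrow(stack), , drop = FALSE]
      for (k in 1:6) {
        p <- cur + nbr[k, ]
        if (any(p < 1) || any(p > d)) next
        if (mask[p[1], p[2], p[3]] && lab[p[1], p[2], p[3]] == 0L) {
          lab[p[1], p[2], p[3]] <- nxt
          stack <- rbind(stack, p)
        }
      }
    }
  }
  lab
}

# exhaustive scan of Li's cross-entropy criterion over every candidate class
# partition of the gray histogram, using the full well-conditioned form
# eta = sum w g log(g / mu_class). Returns the minimizing partition boundary
# (threshold = midpoint of the gap above the last below-class gray), the
# below-class count, and an evaluator giving eta for an arbitrary threshold.
li_cross_entropy_scan <- function(v) {
  u <- sort(unique(v))
  mids <- u - min(u)
  w <- tabulate(match(v, u), nbins = length(u))
  eps <- 1e-6 * max(mids)
  gl <- ifelse(mids > 0, mids * log(mids), 0)
  eta_of <- function(i) {  # partition: classes {1..i}, {i+1..n}
    lo <- seq_len(i)
    hi <- (i + 1L):length(u)
    m0 <- max(sum(w[lo] * mids[lo]) / sum(w[lo]), eps)
    m1 <- max(sum(w[hi] * mids[hi]) / sum(w[hi]), eps)
    sum(w[lo] * (gl[lo] - mids[lo] * log(m0))) +
      sum(w[hi] * (gl[hi] - mids[hi] * log(m1)))
  }
  etas <- vapply(seq_len(length(u) - 1L), eta_of, 0.0)
  best <- which.min(etas)
  list(threshold = (u[best] + u[best + 1L]) / 2,
       upper_gray = u[best],          # largest gray in the lower class
       n_below = sum(w[seq_len(best)]),
       eta_min = etas[best],
       eta_at = function(t) {
         i <- sum(u <= t)
         if (i < 1L || i >= length(u)) return(Inf)
         etas[i]
       })
}

# brute-force per-voxel disk membership count for the circular crop
disk_voxel_count <- function(ny, nx, diameter) {
  cy <- (ny - 1) / 2; cx <- (nx - 1) / 2
  sum(outer((seq_len(ny) - 1 - cy)^2, (seq_len(nx) - 1 - cx)^2, `+`) <=
        (diameter / 2)^2)
}

# exposed-face count by direct neighbour enumeration
brute_face_count <- function(mask) {
  d <- dim(mask)
  faces <- 0L
  for (x in seq_len(d[3])) for (y in seq_len(d[2])) for (z in seq_len(d[1])) {
    if (!mask[z, y, x]) next
    for (o in list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                   c(0, 0, -1), c(0, 0, 1))) {
      p <- c(z, y, x) + o
      if (any(p < 1) || any(p > d) || !mask[p[1], p[2], p[3]]) faces <- faces + 1L
    }
  }
  faces
}

# digitized ball mask, centred, with padding
ball_mask <- function(r, pad = 4) {
  n <- 2 * (r + pad) + 1
  idx <- (0:(n - 1)) - (r + pad)
  q <- outer(outer(idx^2, idx^2, `+`), idx^2, `+`)
  array(q <= r^2, c(n, n, n))
}

# minimal observation tibble for hand-built tracking fixtures; volumes are
# voxel counts, geometry defaults to a line of well-separated points
make_obs <- function(frame_index, label, voxel_count,
                     z = 10, y = 10, x = 10 + 40 * label,
                     roundness = NA_real_, surface = NA_real_) {
  tibble::tibble(
    frame_index = as.integer(frame_index), time_s = 6 * frame_index,
    label = as.integer(label), z = z, y = y, x = x,
    voxel_count = as.integer(voxel_count),
    volume_cm3 = voxel_count * 1e-9,
    surface_cm2 = if (all(is.na(surface))) voxel_count^(2 / 3) * 6e-6 else surface,
    equiv_diam_cm = (6 * voxel_count * 1e-9 / pi)^(1 / 3),
    roundness = roundness,
    touches_border = FALSE
  )
}

# one-crystal track as a tibble with prescribed volume series (voxel counts)
make_track <- function(vols, roundness = NA_real_, frame0 = 0L) {
  purrr::imap_dfr(vols, function(v, i) {
    make_obs(frame0 + i - 1L, label = 1L, voxel_count = v,
             roundness = if (length(roundness) == length(vols)) roundness[i]
                         else roundness)
  })
}

# hand-built observation tibbles already satisfy the tracks contract
as_tracks_for_test <- function(x) x

# small noise-free sphere phantom used across tests
sphere_phantom <- function(r0_vox = 22, rate = 40, n_frames = 8, vs = 11,
                           noise_sd = 0, extent = 64) {
  phantom_spec(
    volume_shape = rep(extent, 3), voxel_size = vs, n_frames = n_frames,
    crystals = tibble::tibble(
      shape = "sphere", z = (extent - 1) / 2, y = (extent - 1) / 2,
      x = (extent - 1) / 2, size_um = 2 * r0_vox * vs, rate_um_min = rate),
    noise_sd = noise_sd, front_speed = Inf, seed = 1)
}
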