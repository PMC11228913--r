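test_that("rendering is deterministic and static scenes are bit-identical", {
  spec <- random_phantom_spec(seed = 6, n_crystals = 4, n_spacers = 6,
                              volume_shape = c(64, 64, 64),
                              equiv_diam_um = c(120, 160))
  a <- render_frame(spec, 2)
  b <- render_frame(spec, 2)
  expect_identical(unclass(a), unclass(b))

  # zero recession, zero noise: every frame identical
  static <- phantom_spec(
    volume_shape = c(32, 32, 32), voxel_size = 11, n_frames = 3,
    crystals = tibble::tibble(shape = "octahedron", z = 15.5, y = 15.5,
                              x = 15.5, size_um = 220, rate_um_min = 0),
    noise_sd = 0, seed = 1)
  f0 <- render_frame(static, 0)
  f2 <- render_frame(static, 2)
  expect_identical(unclass(f0)[, , ], unclass(f2)[, , ])
})

test_that("octahedron past the front shrinks monotonically to extinction", {
  spec <- phantom_spec(
    volume_shape = c(64, 64, 64), voxel_size = 11, n_frames = 8,
    crystals = tibble::tibble(shape = "octahedron", z = 31.5, y = 31.5,
                              x = 31.5, size_um = 2 * 20 * 11,
                              rate_um_min = 150),
    noise_sd = 0, front_speed = Inf, seed = 1)
  truth <- phantom_ground_truth(spec)
  v <- truth$observations$voxel_count
  expect_true(all(diff(v) < 0))
})

test_that("the saturation front delays dissolution by depth", {
  # crystal at depth 90 with front at 35 voxels/frame: the front arrives
  # between frames 2 and 3, so frames 0-2 are constant, then shrinking
  spec <- phantom_spec(
    volume_shape = c(128, 48, 48), voxel_size = 11, n_frames = 6,
    crystals = tibble::tibble(shape = "sphere", z = 90, y = 23.5, x = 23.5,
                              size_um = 2 * 12 * 11, rate_um_min = 120),
    noise_sd = 0, front_speed = 35, seed = 1)
  truth <- phantom_ground_truth(spec)
  v <- truth$observations$voxel_count
  expect_equal(v[1:3], rep(v[1], 3))  # untouched until the front arrives
  expect_true(all(diff(v[3:6]) < 0))
})

test_that("spacer voxels never change between frames", {
  spec <- random_phantom_spec(seed = 9, n_crystals = 3, n_spacers = 8,
                              volume_shape = c(48, 48, 48),
                              equiv_diam_um = c(120, 150), noise_sd = 0)
  f0 <- render_frame(spec, 0)
  f5 <- render_frame(spec, spec$n_frames - 1L)
  spacer_lvl <- spec$gray_levels[["spacer"]]
  expect_identical(which(unclass(f0) == spacer_lvl),
                   which(unclass(f5) == spacer_lvl))
})

test_that("ground truth handles empty scenes and scripted breakups", {
  empty <- phantom_spec(
    volume_shape = c(16, 16, 16), voxel_size = 11, n_frames = 2,
    crystals = tibble::tibble(shape = character(), z = numeric(),
                              y = numeric(), x = numeric(),
                              size_um = numeric(), rate_um_min = numeric()),
    noise_sd = 0, seed = 1)
  tr <- phantom_ground_truth(empty)
  expect_equal(nrow(tr$observations), 0L)
  expect_equal(nrow(tr$links), 0L)

  bk <- phantom_spec(
    volume_shape = c(48, 48, 48), voxel_size = 11, n_frames = 6,
    crystals = tibble::tibble(shape = "sphere", z = 23.5, y = 23.5, x = 23.5,
                              size_um = 2 * 12 * 11, rate_um_min = 30),
    noise_sd = 0, front_speed = Inf,
    breakups = tibble::tibble(crystal = 1L, frame = 3L, gap_vox = 3),
    seed = 1)
  tr2 <- phantom_ground_truth(bk)
  expect_equal(tr2$lineage$child_id, c(1001L, 1002L))
  expect_equal(tr2$lineage$mother_id, c(1L, 1L))
  expect_equal(tr2$lineage$frame, c(3L, 3L))
  # mother present only before the split, fragments only after
  mother_frames <- tr2$observations$frame_index[tr2$observations$crystal_id == 1L]
  expect_true(all(mother_frames < 3))
  kid_frames <- tr2$observations$frame_index[tr2$observations$crystal_id > 1000L]
  expect_true(all(kid_frames >= 3))
  # fragments together are smaller than the pre-split mother
  v_mother <- max(tr2$observations$voxel_count[tr2$observations$crystal_id == 1L])
  v_kids <- sum(tr2$observations$voxel_count[
    tr2$observations$crystal_id > 1000L & tr2$observations$frame_index == 3])
  expect_lt(v_kids, v_mother)
})

test_that("ground-truth sphere volumes track the analytic ball", {
  spec <- sphere_phantom(r0_vox = 15, rate = 40, n_frames = 5, extent = 48)
  truth <- phantom_ground_truth(spec)
  for (i in seq_len(nrow(truth$observations))) {
    f <- truth$observations$frame_index[i]
    r <- 15 - 40 / 11 * f * 6 / 60
    expect_lt(abs(truth$observations$voxel_count[i] / (4 / 3 * pi * r^3) - 1),
              0.02)
  }
  # true rate is density x recession rate in consistent units
  expect_equal(truth$rates$indr_mg_cm2_min, 2165 * 40e-4)
})

test_that("truth face counts agree with the brute-force face oracle", {
  spec <- phantom_spec(
    volume_shape = c(24, 24, 24), voxel_size = 11, n_frames = 1,
    crystals = tibble::tibble(shape = "pyramid", z = 11.5, y = 11.5, x = 11.5,
                              size_um = 2 * 8 * 11, rate_um_min = 0),
    noise_sd = 0, seed = 1)
  truth <- phantom_ground_truth(spec)
  fr <- render_frame(spec, 0)
  mask <- unclass(fr) == spec$gray_levels[["crystal"]]
  expect_equal(truth$observations$exposed_faces, brute_face_count(mask))
})

test_that("phantom specs validate their invariants", {
  expect_error(phantom_spec(
    volume_shape = c(16, 16, 16), voxel_size = 11, n_frames = 2,
    crystals = tibble::tibble(shape = "sphere", z = 8, y = 8, x = 8,
                              size_um = 1000, rate_um_min = 10),
    seed = 1), "fit inside")
  expect_error(phantom_spec(
    volume_shape = c(16, 16, 16), voxel_size = 11, n_frames = 2,
    crystals = tibble::tibble(shape = "sphere", z = 8, y = 8, x = 8,
                              size_um = 50, rate_um_min = 10),
    gray_levels = c(fluid = 100, crystal = 90, spacer = 250),
    seed = 1), "ordered")
})
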