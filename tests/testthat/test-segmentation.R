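test_that("circular crop keeps exactly the digitized disk", {
  fr <- volume_frame(array(1, c(3, 10, 10)), voxel_size = 1)
  cr <- crop_cylinder(fr, diameter = 10, fill = 0)
  # corner voxels are farther than the radius from the slice centre
  expect_equal(cr[1, 1, 1], 0)
  expect_equal(cr[1, 5, 5], 1)
  # kept count equals the per-voxel distance oracle, every slice
  expect_equal(sum(cr[2, , ]), disk_voxel_count(10, 10, 10))

  # degenerate diameter: only the central column survives
  fr2 <- volume_frame(array(1, c(2, 9, 9)), voxel_size = 1)
  cr2 <- crop_cylinder(fr2, diameter = 1, fill = 0)
  expect_equal(sum(cr2), 2)  # one voxel per slice
  expect_equal(cr2[1, 5, 5], 1)

  expect_error(crop_cylinder(fr, diameter = 11), "exceeds")
})

test_that("crop count matches the brute-force disk oracle across sizes", {
  for (d in c(4, 7, 12)) {
    fr <- volume_frame(array(1, c(1, 16, 16)), voxel_size = 1)
    cr <- crop_cylinder(fr, diameter = d, fill = 0)
    expect_equal(sum(cr), disk_voxel_count(16, 16, d))
  }
})

test_that("Li threshold agrees with the exhaustive cross-entropy minimizer", {
  # two-delta histogram: threshold strictly between the modes, and its
  # criterion value equals the exhaustive minimum (the criterion is flat
  # between isolated modes, so compare by criterion value)
  v <- c(rep(10, 500), rep(200, 500))
  th <- li_threshold(v)
  expect_gt(th, 10)
  expect_lt(th, 200)
  oracle <- li_cross_entropy_scan(v)
  expect_equal(oracle$eta_at(th), oracle$eta_min)

  # Gaussian mixture with a populated valley: the iterative threshold lands
  # within one gray level of the exhaustive minimizer, and its criterion
  # value is minimal to within the flatness of the valley
  set.seed(42)
  v2 <- round(c(rnorm(30000, 80, 15), rnorm(30000, 160, 15)))
  th2 <- li_threshold(v2)
  oracle2 <- li_cross_entropy_scan(v2)
  expect_lt(abs(th2 - oracle2$threshold), 1)
  expect_lt((oracle2$eta_at(th2) - oracle2$eta_min) / abs(oracle2$eta_min), 1e-4)

  expect_error(li_threshold(rep(7, 100)), "constant")
})

test_that("segmentation isolates crystals between fluid and spacer levels", {
  vol <- array(40, c(24, 24, 24))
  vol[7:12, 7:12, 7:12] <- 150     # crystal, inside the crop circle
  vol[14:19, 14:19, 14:19] <- 250  # spacer
  fr <- volume_frame(vol, voxel_size = 11)
  mask <- segment_crystals(fr, segmentation_params(spacer_threshold = 200))
  truth <- array(FALSE, c(24, 24, 24)); truth[7:12, 7:12, 7:12] <- TRUE
  expect_equal(as.logical(mask), as.logical(truth))

  # per-voxel contract: > Li AND <= spacer cut AND inside circle
  th <- attr(mask, "threshold")
  circ <- attr(mask, "valid")
  expected <- array(FALSE, dim(vol))
  for (z in 1:24) expected[z, , ] <- (vol[z, , ] > th) & (vol[z, , ] <= 200) & circ
  expect_equal(as.logical(mask), as.logical(expected))

  # pure fluid: no crystal voxels
  fl <- volume_frame(array(rnorm(24^3, 40, 3), c(24, 24, 24)), voxel_size = 11)
  expect_equal(sum(segment_crystals(fl, segmentation_params(spacer_threshold = 200))), 0)
})

test_that("automatic spacer cut lands between crystal and spacer populations", {
  set.seed(7)
  vol <- array(rnorm(20^3, 40, 5), c(20, 20, 20))
  vol[3:8, 3:8, 3:8] <- rnorm(216, 150, 5)
  vol[12:17, 12:17, 12:17] <- rnorm(216, 250, 5)
  fr <- volume_frame(vol, voxel_size = 11)
  mask <- segment_crystals(fr, segmentation_params(spacer_threshold = "auto"))
  cut <- attr(mask, "spacer_threshold")
  expect_gt(cut, 170)
  expect_lt(cut, 240)
  # only the crystal cube survives
  expect_true(all(which(mask, arr.ind = TRUE)[, 1] <= 9))
})

test_that("re-thresholding a binarized mask reproduces the mask", {
  set.seed(11)
  vol <- array(rnorm(16^3, 40, 5), c(16, 16, 16))
  vol[4:10, 4:10, 4:10] <- rnorm(343, 150, 5)
  fr <- volume_frame(vol, voxel_size = 11)
  p <- segmentation_params(spacer_threshold = "none")
  mask1 <- segment_crystals(fr, p)
  binarized <- volume_frame(array(as.numeric(mask1), dim(vol)), voxel_size = 11)
  mask2 <- segment_crystals(binarized, p)
  expect_equal(as.logical(mask2), as.logical(mask1))
})

test_that("face connectivity labeling matches definitions and the flood-fill oracle", {
  # two voxels sharing only an edge are separate objects under connect-6
  m <- array(FALSE, c(3, 3, 3))
  m[1, 1, 1] <- TRUE; m[1, 2, 2] <- TRUE
  expect_equal(n_objects(label_components(m)), 2L)

  # single voxel
  m1 <- array(FALSE, c(2, 2, 2)); m1[1, 1, 1] <- TRUE
  expect_equal(n_objects(label_components(m1)), 1L)

  # random masks: identical partition to the recursive flood fill
  set.seed(5)
  for (i in 1:25) {
    m <- array(runif(16^3) < 0.12, c(16, 16, 16))
    lab <- label_components(m)
    ref <- floodfill_label6(m)
    expect_equal(as.integer(lab), as.integer(ref))
    # conservation: object voxel counts sum to mask count
    expect_equal(sum(tabulate(lab[lab > 0])), sum(m))
  }
})

test_that("labels are consecutive and deterministic in raster order", {
  set.seed(9)
  m <- array(runif(12^3) < 0.1, c(12, 12, 12))
  lab <- label_components(m)
  n <- n_objects(lab)
  expect_equal(sort(unique(as.integer(lab[lab > 0]))), seq_len(n))
  expect_equal(as.integer(label_components(m)), as.integer(lab))
  # first foreground voxel in scan order always carries label 1
  expect_equal(lab[which(m)[1]], 1L)
})
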