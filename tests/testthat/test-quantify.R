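# Volumetric quantification: adaptive threshold, depot masks, volumes.

test_that("slice_threshold computes mu + k * population SD with keep >= T", {
  expect_equal(slice_threshold(rep(7.5, 40), threshold_policy(k = 3)), 7.5)
  x <- c(rep(100, 50), rep(900, 50))
  expect_equal(slice_threshold(x, threshold_policy(k = 0)), 500)
  expect_equal(sum(x >= 500), 50)
  # population SD: sigma = 400 exactly (sample SD would give 402.01)
  expect_equal(slice_threshold(x, threshold_policy(k = 1)), 900)
  expect_equal(sum(x >= 900), 50)
  expect_error(slice_threshold(numeric(0)), "empty-region")
})

make_ring_scene <- function(n = 25) {
  ext <- disk_mask(n, 10)
  int_ <- disk_mask(n, 6)
  list(ext = ext, int_ = int_)
}

test_that("build_sat_mask subtracts INT from EXT, with optional thresholding", {
  sc <- make_ring_scene()
  annulus <- sc$ext$data & !sc$int_$data
  # bright annulus on dark background; lean interior
  mri_arr <- array(0, dim(sc$ext$data))
  mri_arr[annulus] <- 900
  mri_arr[sc$int_$data] <- 100
  mri <- volume_image(mri_arr, sc$ext$spacing)

  off <- build_sat_mask(sc$ext, sc$int_, mri,
                        threshold_policy(apply_to_sat = FALSE))
  expect_equal(off$data, annulus)
  on <- build_sat_mask(sc$ext, sc$int_, mri, threshold_policy(k = 0))
  expect_equal(on$data, annulus)  # every annulus pixel exceeds the INT mean
  # int = ext -> empty SAT
  empty <- build_sat_mask(sc$ext, sc$ext, mri, threshold_policy())
  expect_equal(sum(empty$data), 0)
})

test_that("build_vat_mask keeps only high-intensity voxels of INT minus EXC", {
  n <- 25
  int_ <- disk_mask(n, 9)
  exc <- disk_mask(n, 3)
  cand <- int_$data & !exc$data
  # equal numbers of fat (900) and lean (100) voxels in the candidate region
  idx <- which(cand)
  set.seed(5)
  fat_idx <- sample(idx, floor(length(idx) / 2))
  mri_arr <- array(100, dim(int_$data))
  mri_arr[fat_idx] <- 900
  mri_arr[exc$data] <- 150
  mri <- volume_image(mri_arr, int_$spacing)
  vat <- build_vat_mask(int_, exc, mri, threshold_policy(k = 0))
  want <- array(FALSE, dim(int_$data)); want[fat_idx] <- TRUE
  expect_equal(vat$data, want)

  # exc superset of int -> empty VAT (and an empty-stat-region warning when
  # the whole slice region is excluded is not triggered: INT stats exist)
  vat2 <- build_vat_mask(int_, int_, mri, threshold_policy())
  expect_equal(sum(vat2$data), 0)
})

test_that("increasing k never increases VAT volume (threshold monotonicity)", {
  ph <- small_phantom(seed = 2, noise_sd = 40)
  int_ <- rasterize(ph$truth_rois, "INT")
  exc <- rasterize(ph$truth_rois, "EXC")
  vols <- sapply(c(-1, 0, 0.5, 1, 2), function(k) {
    depot_volume(build_vat_mask(int_, exc, ph$mri, threshold_policy(k = k)))
  })
  expect_true(all(diff(vols) <= 1e-12))
})

test_that("with thresholding off and nested rois, SAT and VAT partition within EXT", {
  ph <- small_phantom(seed = 3)
  ext <- rasterize(ph$truth_rois, "EXT")
  int_ <- rasterize(ph$truth_rois, "INT")
  exc <- rasterize(ph$truth_rois, "EXC")
  pol <- threshold_policy(apply_to_sat = FALSE)
  sat <- build_sat_mask(ext, int_, ph$mri, pol)
  vat_cand <- mask_and_not(int_, exc)  # threshold-free VAT candidate
  expect_equal(sum(sat$data & vat_cand$data), 0)          # disjoint
  expect_true(all(ext$data[sat$data | vat_cand$data]))    # within EXT
})

test_that("depot_volume is voxel count times voxel volume, additive and linear", {
  m <- binary_mask(array(FALSE, c(2, 4, 4)), c(1, 1, 1))
  expect_equal(depot_volume(m), 0)
  one <- m; one$data[1, 1, 1] <- TRUE
  expect_equal(depot_volume(one), 0.001)
  # 1000 voxels at scanner spacing 1.39 x 1.39 x 2.09 mm
  big <- binary_mask(array(TRUE, c(10, 10, 10)), c(2.09, 1.39, 1.39))
  expect_equal(depot_volume(big), 1000 * 2.09 * 1.39 * 1.39 / 1000)
  # additivity over disjoint masks
  a <- disk_mask(21, 5, cy = 5, cx = 5)
  b <- disk_mask(21, 4, cy = 15, cx = 15)
  expect_equal(sum(a$data & b$data), 0)
  ab <- binary_mask(a$data | b$data, a$spacing)
  expect_equal(depot_volume(ab), depot_volume(a) + depot_volume(b))
  # linearity in each spacing component
  a2 <- a; a2$spacing <- a$spacing * c(2, 1, 1)
  expect_equal(depot_volume(a2), 2 * depot_volume(a))
})

test_that("measure_scan composes the full pipeline with sane degenerate modes", {
  ph <- small_phantom(seed = 4)
  m <- measure_scan(ph$mri, ph$pet, ph$truth_rois, threshold_policy())
  expect_true(all(c(m$sat_volume_cm3, m$vat_volume_cm3) > 0))
  expect_equal(m$vat_sat_ratio, m$vat_volume_cm3 / m$sat_volume_cm3)

  # doubling dz doubles both volumes, ratio invariant
  mri2 <- ph$mri; mri2$spacing[1] <- 2 * mri2$spacing[1]
  rois2 <- ph$truth_rois; rois2$spacing[1] <- 2 * rois2$spacing[1]
  pet2 <- ph$pet; pet2$spacing[1] <- 2 * pet2$spacing[1]
  pet2$origin <- pet2$origin * c(2, 1, 1)
  m2 <- measure_scan(mri2, pet2, rois2, threshold_policy())
  expect_equal(m2$sat_volume_cm3, 2 * m$sat_volume_cm3)
  expect_equal(m2$vat_volume_cm3, 2 * m$vat_volume_cm3)
  expect_equal(m2$vat_sat_ratio, m$vat_sat_ratio)

  # empty annotation set -> all-zero measurements, NA sentinels
  empty <- roi_set(list(), ph$truth_rois$slice_range, ph$truth_rois$dims,
                   ph$truth_rois$spacing)
  m0 <- measure_scan(ph$mri, ph$pet, empty, threshold_policy())
  expect_equal(m0$sat_volume_cm3, 0)
  expect_equal(m0$vat_volume_cm3, 0)
  expect_true(is.na(m0$vat_sat_ratio))
  expect_true(is.na(m0$sat_suv_mean) && is.na(m0$vat_suv_mean))

  # missing PET -> volumes computed, SUV NA
  mna <- measure_scan(ph$mri, NULL, ph$truth_rois, threshold_policy())
  expect_equal(mna$sat_volume_cm3, m$sat_volume_cm3)
  expect_true(is.na(mna$sat_suv_mean))
})
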