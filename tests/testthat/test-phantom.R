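# Synthetic phantom generator: determinism, anatomy, recovery, perturbation.

test_that("same seed gives bit-identical phantoms", {
  a <- small_phantom(seed = 5, noise_sd = 30)
  b <- small_phantom(seed = 5, noise_sd = 30)
  expect_identical(a$mri$data, b$mri$data)
  expect_identical(a$pet$data, b$pet$data)
  expect_identical(a$truth_labels, b$truth_labels)
  expect_equal(length(a$truth_rois$contours), length(b$truth_rois$contours))
  c_ <- small_phantom(seed = 6, noise_sd = 30)
  expect_false(identical(a$mri$data, c_$mri$data))
})

test_that("label map and contours are mutually consistent for several seeds", {
  for (seed in 1:4) {
    ph <- small_phantom(seed = seed)
    ext <- rasterize(ph$truth_rois, "EXT")$data
    int_ <- rasterize(ph$truth_rois, "INT")$data
    exc <- rasterize(ph$truth_rois, "EXC")$data
    lab <- ph$truth_labels
    expect_true(all(int_[ext == FALSE] == FALSE))   # INT inside EXT
    expect_true(all(exc[int_ == FALSE] == FALSE))   # EXC inside INT
    expect_identical(lab == 1L, ext & !int_)        # SAT ring exact
    expect_identical(lab == 4L, exc)                # organs exact
    expect_true(all(int_[lab == 2L | lab == 3L]))   # VAT + lean inside INT
    expect_equal(sum(lab == 1L & lab == 2L), 0)
    # every annotated slice of the cavity carries some visceral fat
    sl <- ph$truth_rois$slice_range
    for (s in sl[1]:sl[2]) expect_gt(sum(lab[s + 1, , ] == 2L), 0)
  }
})

test_that("zero-noise phantom is recovered exactly by the matched policy", {
  ph <- small_phantom(seed = 8)
  m <- measure_scan(ph$mri, ph$pet, ph$truth_rois, threshold_policy(k = 0))
  vox <- prod(ph$mri$spacing) / 1000
  expect_identical(m$sat_volume_cm3, ph$sat_voxels * vox)
  expect_identical(m$vat_volume_cm3, ph$vat_voxels * vox)
  expect_identical(m$sat_suv_mean, ph$spec$sat_uptake)
  expect_identical(m$vat_suv_mean, ph$spec$vat_uptake)
})

test_that("no visceral fat blobs means zero VAT and an undefined VAT SUVmean", {
  ph <- small_phantom(seed = 9, n_vat_blobs = 0)
  expect_equal(ph$vat_voxels, 0)
  m <- measure_scan(ph$mri, ph$pet, ph$truth_rois, threshold_policy())
  expect_equal(m$vat_volume_cm3, 0)
  expect_true(is.na(m$vat_suv_mean))
  expect_gt(m$sat_volume_cm3, 0)
})

test_that("PET and MRI depots align in the world frame within one PET voxel", {
  ph <- small_phantom(seed = 10)
  vat_mri <- which(ph$truth_labels == 2L, arr.ind = TRUE) - 1
  cen_mri <- colMeans(vat_mri) * ph$mri$spacing + ph$mri$origin
  vat_pet <- which(ph$pet$data == ph$spec$vat_uptake, arr.ind = TRUE) - 1
  cen_pet <- colMeans(vat_pet) * ph$pet$spacing + ph$pet$origin
  expect_true(all(abs(cen_mri - cen_pet) <= ph$pet$spacing))
})

test_that("perturb_roi is smooth, bounded and identity at magnitude zero", {
  ph <- small_phantom(seed = 11)
  expect_identical(perturb_roi(ph$truth_rois, 0, seed = 1), ph$truth_rois)
  pr <- perturb_roi(ph$truth_rois, 2, seed = 3)
  for (i in seq_along(pr$contours)) {
    shift <- sqrt(rowSums((pr$contours[[i]]$vertices -
                             ph$truth_rois$contours[[i]]$vertices)^2))
    expect_true(all(shift <= 2 + 1e-9))
  }
  # 1-voxel perturbation: high body-mask Dice, contour Dice strictly lower
  # for the large body contours (organ structures need scan-scale grids,
  # covered by the acceptance suite)
  pr1 <- perturb_roi(ph$truth_rois, 1, seed = 5)
  ev <- evaluate_segmentation(ph$truth_rois, pr1)
  body <- ev[ev$label %in% c("EXT", "INT"), ]
  expect_true(all(body$mask_dice >= 0.9))
  expect_true(all(body$contour_dice < body$mask_dice))
})

test_that("increasing perturbation magnitude degrades mask Dice (stochastic)", {
  ph <- small_phantom(seed = 12)
  ext <- rasterize(ph$truth_rois, "EXT")
  ok <- 0
  for (s in 1:10) {
    d <- sapply(c(1, 3, 6), function(mag) {
      dice(ext, rasterize(perturb_roi(ph$truth_rois, mag, seed = s), "EXT"))
    })
    if (all(diff(d) <= 1e-12)) ok <- ok + 1
  }
  expect_gte(ok, 8)
})

test_that("make_validation_cohort feeds the full agreement pipeline", {
  cohort <- make_validation_cohort(4, phantom_spec(dims = c(8, 48, 64),
                                                   noise_sd = 0),
                                   seed = 13, perturb_magnitude = 0.5)
  expect_length(cohort, 4)
  pol <- threshold_policy()
  rows <- lapply(seq_along(cohort), function(i) {
    cs <- cohort[[i]]
    m <- measure_scan(cs$case$mri, cs$case$pet, cs$case$truth_rois, pol)
    p <- measure_scan(cs$case$mri, cs$case$pet, cs$predicted_rois, pol)
    list(m = cbind(scan_id = i, m), p = cbind(scan_id = i, p))
  })
  man <- do.call(rbind, lapply(rows, `[[`, "m"))
  pred <- do.call(rbind, lapply(rows, `[[`, "p"))
  rep_ <- agreement_report(man, pred)
  expect_equal(nrow(rep_), 5)
  expect_true(all(is.finite(rep_$mean_bias)))
  # zero perturbation -> perfect agreement
  rep0 <- agreement_report(man, man)
  expect_true(all(rep0$mean_bias == 0))
  expect_true(all(rep0$icc[is.finite(rep0$icc)] == 1))
})
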