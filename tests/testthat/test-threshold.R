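# cortex-referenced thresholds and within-ROI lesion extraction

test_that("thresholds are the multiplier times the cortical means", {
  tv <- tiny_volumes()
  thr <- compute_thresholds(tv$flair, tv$t1, tv$cortex)
  expect_equal(thr$mean_flair_cortex, 100)
  expect_equal(thr$lower_thr_flair, 102)
  expect_equal(thr$upper_thr_t1, 102)

  # singleton cortex: both means equal the lone voxel's value
  cm1 <- array(FALSE, tv$dm); cm1[5, 5, 5] <- TRUE
  f <- tv$flair; f[5, 5, 5] <- 123; t1 <- tv$t1; t1[5, 5, 5] <- 77
  thr1 <- compute_thresholds(f, t1, cm1)
  expect_equal(thr1$mean_flair_cortex, 123)
  expect_equal(thr1$mean_t1_cortex, 77)
  expect_equal(thr1$lower_thr_flair, 1.02 * 123)

  expect_error(compute_thresholds(tv$flair, tv$t1, array(FALSE, tv$dm)), "empty")
  f2 <- tv$flair; f2[1, 1, 1] <- NA
  expect_error(compute_thresholds(f2, tv$t1, tv$cortex), "non-finite")
})

test_that("ROI voxels survive or fail the thresholds as their intensity dictates", {
  tv <- tiny_volumes()
  thr <- compute_thresholds(tv$flair, tv$t1, tv$cortex)
  rois <- box_roi(tv$dm, c(8, 8, 4), c(11, 11, 7))
  n_roi <- 4 * 4 * 4

  above <- tv$flair; above[8:11, 8:11, 4:7] <- 150       # 1.5 x cortex mean
  les <- extract_lesion_masks(above, tv$t1, rois_from_labels(rois), thr)
  expect_equal(les[[1]]$n_flair_voxels, n_roi)

  at_mean <- tv$flair; at_mean[8:11, 8:11, 4:7] <- 100   # 1.0 x: below threshold
  les0 <- extract_lesion_masks(at_mean, tv$t1, rois_from_labels(rois), thr)
  expect_equal(les0[[1]]$n_flair_voxels, 0L)
  expect_false(les0[[1]]$survived)
  expect_false(classify_definitions(les0[[1]])$liberal)

  t1_low <- tv$t1; t1_low[8:11, 8:11, 4:7] <- 90         # 0.9 x T1 cortex mean
  lesA <- extract_lesion_masks(above, t1_low, rois_from_labels(rois), thr)
  expect_equal(lesA[[1]]$n_t1_voxels, lesA[[1]]$n_flair_voxels)
  t1_hi <- tv$t1; t1_hi[8:11, 8:11, 4:7] <- 110          # 1.1 x
  lesB <- extract_lesion_masks(above, t1_hi, rois_from_labels(rois), thr)
  expect_equal(lesB[[1]]$n_t1_voxels, 0L)
  # T1 subset invariant and volumes
  expect_true(lesA[[1]]$t1_volume_mm3 <= lesA[[1]]$volume_mm3)
  expect_equal(lesA[[1]]$volume_mm3, n_roi * prod(tv$vs))
})

test_that("overlapping ROIs and grid mismatches are rejected", {
  tv <- tiny_volumes()
  thr <- compute_thresholds(tv$flair, tv$t1, tv$cortex)
  r1 <- list(roi_id = 1L, voxels = which(box_roi(tv$dm, c(5, 5, 5), c(7, 7, 7)) > 0,
                                         arr.ind = TRUE), lobe = "frontal")
  r2 <- list(roi_id = 2L, voxels = which(box_roi(tv$dm, c(7, 7, 7), c(9, 9, 9)) > 0,
                                         arr.ind = TRUE), lobe = "frontal")
  expect_error(extract_lesion_masks(tv$flair, tv$t1, list(r1, r2), thr), "overlap")
  t1_small <- volume_grid(array(1, c(4, 4, 4)), tv$vs)
  expect_error(extract_lesion_masks(tv$flair, t1_small, list(r1), thr), "grids differ")
})

test_that("raising the FLAIR multiplier never enlarges a mask and rerun is identical", {
  tv <- tiny_volumes()
  set.seed(8)
  f <- tv$flair
  f[6:15, 6:15, 3:10] <- 100 * runif(10 * 10 * 8, 0.9, 1.6)
  rois <- rois_from_labels(box_roi(tv$dm, c(6, 6, 3), c(15, 15, 10)))
  prev <- Inf
  for (m in c(1.02, 1.1, 1.2, 1.4)) {
    thr <- compute_thresholds(f, tv$t1, tv$cortex, multiplier = m)
    les <- extract_lesion_masks(f, tv$t1, rois, thr)
    expect_lte(les[[1]]$n_flair_voxels, prev)
    prev <- les[[1]]$n_flair_voxels
  }
  thr <- compute_thresholds(f, tv$t1, tv$cortex)
  a <- extract_lesion_masks(f, tv$t1, rois, thr)
  b <- extract_lesion_masks(f, tv$t1, rois, thr)
  expect_identical(a[[1]]$flair_voxels, b[[1]]$flair_voxels)
})

test_that("connected components agree with an independent flood fill", {
  set.seed(31)
  dm <- c(12L, 12L, 12L)
  for (conn in c(6, 18, 26)) {
    for (rep in 1:5) {
      mask <- array(runif(prod(dm)) < 0.18, dm)
      vox <- which(mask, arr.ind = TRUE, useNames = FALSE)
      if (!nrow(vox)) next
      got <- sciquant:::.connected_components(vox, dm, conn)
      want <- flood_fill_components(vox, dm, conn)
      # same partition: label vectors must induce identical groupings
      expect_equal(max(got), max(want))
      expect_true(all(tapply(want, got, function(v) length(unique(v))) == 1))
    }
  }
})

test_that("component count is reported even when components are merged per ROI", {
  tv <- tiny_volumes()
  thr <- compute_thresholds(tv$flair, tv$t1, tv$cortex)
  f <- tv$flair
  f[6, 6, 6] <- 150
  f[10, 10, 9] <- 150   # far apart within one ROI: two components
  rois <- rois_from_labels(box_roi(tv$dm, c(5, 5, 5), c(11, 11, 10)))
  les <- extract_lesion_masks(f, tv$t1, rois, thr)
  expect_equal(les[[1]]$n_components, 2L)
  expect_equal(les[[1]]$n_flair_voxels, 2L)  # merged into one lesion mask
})
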