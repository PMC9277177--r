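# distance maps, percentile parcellation, region assignment, bullseye

test_that("distance maps are exact on simple neighbours and match brute force", {
  dm <- c(9L, 9L, 9L); vs <- c(0.65, 0.8, 1.0)
  tm <- array(FALSE, dm); tm[5, 5, 5] <- TRUE
  d <- distance_map(volume_grid(tm, vs))
  expect_equal(d[5, 5, 5], 0)
  expect_equal(d[5, 5, 6], 1.0)    # adjacent along the 1.0 mm axis
  expect_equal(d[6, 5, 5], 0.65)
  expect_equal(d[5, 6, 5], 0.8)
  expect_error(distance_map(volume_grid(array(FALSE, dm), vs)), "empty")

  set.seed(41)
  for (rep in 1:3) {
    dmr <- c(15L, 15L, 15L)
    tgt <- array(runif(prod(dmr)) < 0.03, dmr)
    if (!any(tgt)) tgt[8, 8, 8] <- TRUE
    d <- distance_map(volume_grid(tgt, vs))
    idx <- which(tgt, arr.ind = TRUE)
    pick <- cbind(sample(15, 40, TRUE), sample(15, 40, TRUE), sample(15, 40, TRUE))
    for (i in seq_len(nrow(pick))) {
      p <- pick[i, ]
      bf <- min(sqrt(((p[1] - idx[, 1]) * vs[1])^2 +
                       ((p[2] - idx[, 2]) * vs[2])^2 +
                       ((p[3] - idx[, 3]) * vs[3])^2))
      expect_equal(d[p[1], p[2], p[3]], bf, tolerance = 1e-12)
    }
  }
})

test_that("parcellation partitions white matter at the percentile ranks", {
  ph <- generate_phantom(phantom_spec(grid_shape = c(64L, 64L, 64L), seed = 13L))
  parc <- build_parcellation(ph$segmentation)
  wm <- ph$segmentation$wm != 0
  expect_false(any(parc$pv & parc$jc))
  expect_false(any(parc$pv & parc$deep))
  expect_false(any(parc$jc & parc$deep))
  expect_identical((parc$pv | parc$jc | parc$deep), wm)
  n_wm <- sum(wm)
  expect_lte(abs(sum(parc$pv) - 0.05 * n_wm), 1)
  expect_lte(abs(sum(parc$jc) - 0.75 * (n_wm - sum(parc$pv))), 1)
})

test_that("raising the juxta-cortical percentile only moves deep voxels outward", {
  ph <- generate_phantom(phantom_spec(grid_shape = c(48L, 48L, 48L), seed = 2L))
  p75 <- build_parcellation(ph$segmentation, jc_percentile = 75)
  p85 <- build_parcellation(ph$segmentation, jc_percentile = 85)
  expect_true(all(p85$jc[p75$jc]))          # jc grows monotonically
  expect_true(all(p75$deep[p85$deep]))      # deep shrinks monotonically
  expect_identical(p75$pv, p85$pv)
})

test_that("majority-overlap assignment is strict and surfaces ties", {
  dm <- c(10L, 10L, 10L)
  mk <- function(lo, hi) { m <- array(FALSE, dm); m[lo:hi, , ] <- TRUE; m }
  parc <- structure(list(pv = mk(1, 3), deep = mk(4, 6), jc = mk(7, 10),
                         voxel_size_mm = c(1, 1, 1)),
                    class = "sci_parcellation")
  inside <- cbind(4:6, 5L, 5L)
  a <- assign_region(inside, parc)
  expect_equal(a$region, "deep"); expect_false(a$tie)
  # 3 voxels jc vs 2 deep
  mixed <- rbind(cbind(7:9, 5L, 5L), cbind(5:6, 5L, 5L))
  expect_equal(assign_region(mixed, parc)$region, "juxta-cortical")
  # 2 vs 2: tie flagged, region unresolved
  tied <- rbind(cbind(7:8, 5L, 5L), cbind(5:6, 5L, 5L))
  tr <- assign_region(tied, parc)
  expect_true(tr$tie); expect_true(is.na(tr$region))
  expect_setequal(tr$tied_regions, c("deep", "juxta-cortical"))
  # order invariance
  perm <- mixed[sample(nrow(mixed)), , drop = FALSE]
  expect_equal(assign_region(perm, parc)$region, "juxta-cortical")
  # no white-matter overlap at all -> diagnostic error
  outside <- structure(list(pv = mk(1, 1), deep = mk(2, 2), jc = mk(3, 3),
                            voxel_size_mm = c(1, 1, 1)),
                       class = "sci_parcellation")
  expect_error(assign_region(cbind(9L, 9L, 9L), outside), "no white-matter overlap")
})

test_that("regional volumes partition the lesion's white-matter volume", {
  dm <- c(10L, 10L, 10L)
  mk <- function(lo, hi) { m <- array(FALSE, dm); m[lo:hi, , ] <- TRUE; m }
  parc <- structure(list(pv = mk(1, 3), deep = mk(4, 6), jc = mk(7, 10),
                         voxel_size_mm = c(0.65, 0.65, 1.0)),
                    class = "sci_parcellation")
  vv <- prod(parc$voxel_size_mm)
  vox <- rbind(cbind(rep(4:6, 2), rep(4:5, each = 3), 5L),  # 6 deep
               cbind(7L, 1:4, 5L))                          # 4 jc
  rv <- regional_volumes(vox, parc)
  expect_equal(unname(rv), c(0, 6, 4) * vv)
  expect_equal(sum(rv), nrow(vox) * vv)
  full_pv <- cbind(2L, 1:5, 3L)
  rv2 <- regional_volumes(full_pv, parc)
  expect_equal(unname(rv2), c(5 * vv, 0, 0))
})

test_that("bullseye shares sum to 100 and reflect engineered distributions", {
  spec <- phantom_spec(grid_shape = c(64L, 64L, 64L), seed = 23L)
  ph1 <- generate_phantom(spec, list(truth_lesion(5, 1.5, 0.9, "deep", "frontal")))
  r1 <- quantify_subject(ph1$flair, ph1$t1, ph1$segmentation, ph1$roi_labels,
                         ph1$roi_lobes)
  be <- bullseye(list(r1$profile), "L", "count_share")
  expect_equal(be["deep", "frontal"], 100)
  expect_equal(sum(be), 100)
  bv <- bullseye(list(r1$profile), "L", "volume_share")
  expect_equal(sum(bv), 100)
  # the deep-frontal zone holds the plurality of voxels by construction
  expect_equal(which(bv == max(bv)), which(rownames(bv) == "deep") +
                 (which(colnames(bv) == "frontal") - 1) * 3)

  # engineered group: 9 lesions of which 7 are deep frontal/parietal, so the
  # combined deep frontal+parietal count share must be exactly 700/9 %
  mk_run <- function(seed, lobes) {
    sp <- phantom_spec(seed = seed)
    ph <- generate_phantom(sp, lapply(lobes, function(lb)
      truth_lesion(4, 1.5, 0.9, "deep", lb)))
    quantify_subject(ph$flair, ph$t1, ph$segmentation, ph$roi_labels,
                     ph$roi_lobes)$profile
  }
  profs <- list(mk_run(101, c("frontal", "frontal", "parietal")),
                mk_run(102, c("frontal", "parietal")),
                mk_run(103, c("temporal", "occipital", "frontal", "frontal")))
  bc <- bullseye(profs, "L", "count_share")
  expect_equal(sum(bc), 100)
  expect_equal(bc["deep", "frontal"] + bc["deep", "parietal"],
               100 * 7 / 9)
  b0 <- bullseye(list(aggregate_subject(list())), "L", "participants")
  expect_true(all(b0 == 0))
})
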