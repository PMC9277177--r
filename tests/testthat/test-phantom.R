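# synthetic phantom and cohort generators

test_that("phantom generation is deterministic and geometrically consistent", {
  spec <- phantom_spec(grid_shape = c(64L, 64L, 64L), seed = 7L)
  lesions <- list(truth_lesion(5, 1.5, 0.9, "deep", "frontal"),
                  truth_lesion(2, 1.5, 1.2, "juxta-cortical", "parietal"))
  a <- generate_phantom(spec, lesions)
  b <- generate_phantom(spec, lesions)
  expect_identical(as.numeric(a$flair), as.numeric(b$flair))
  expect_identical(as.numeric(a$t1), as.numeric(b$t1))
  expect_identical(a$truth, b$truth)

  seg <- a$segmentation
  # tissue classes disjoint and contained in the brain
  expect_false(any(seg$cortex & seg$wm))
  expect_false(any(seg$cortex & seg$ventricles))
  expect_false(any(seg$wm & seg$ventricles))
  expect_true(all((seg$cortex | seg$wm | seg$ventricles)[!seg$brain] == FALSE))

  # each truth lesion is covered by its ROI with margin
  for (i in seq_len(nrow(a$truth))) {
    vox <- a$truth_voxels[[i]]
    expect_true(all(a$roi_labels[vox] == a$truth$roi_id[i]))
  }
})

test_that("a phantom without lesions yields no ROIs and an SCI-free profile", {
  ph <- generate_phantom(phantom_spec(grid_shape = c(48L, 48L, 48L), seed = 3L))
  expect_equal(nrow(ph$truth), 0)
  expect_true(all(ph$roi_labels == 0L))
  run <- quantify_subject(ph$flair, ph$t1, ph$segmentation, ph$roi_labels,
                          ph$roi_lobes)
  expect_equal(unname(run$profile$n_lesions), c(0L, 0L, 0L))
  expect_false(any(run$profile$presence))
})

test_that("a sub-threshold FLAIR multiplier leaves no surviving voxels", {
  spec <- phantom_spec(grid_shape = c(64L, 64L, 64L), seed = 11L)
  ph <- generate_phantom(spec, list(truth_lesion(5, 1.01, 0.9, "deep", "frontal")))
  run <- quantify_subject(ph$flair, ph$t1, ph$segmentation, ph$roi_labels,
                          ph$roi_lobes)
  expect_equal(run$lesions[[1]]$n_flair_voxels, 0L)
  expect_equal(unname(run$profile$n_lesions["L"]), 0L)
})

test_that("a well-separated lesion is recovered with all three flags", {
  spec <- phantom_spec(grid_shape = c(64L, 64L, 64L), seed = 5L)
  ph <- generate_phantom(spec, list(truth_lesion(5, 1.5, 0.9, "deep", "frontal")))
  run <- quantify_subject(ph$flair, ph$t1, ph$segmentation, ph$roi_labels,
                          ph$roi_lobes)
  lt <- run$profile$lesion_table
  expect_equal(nrow(lt), 1)
  expect_true(lt$L && lt$T && lt$R)
  expect_equal(lt$region, "deep")
  expect_equal(lt$n_flair_voxels, ph$truth$n_voxels[1])
})

test_that("overlapping or misplaced explicit lesion centres are rejected", {
  spec <- phantom_spec(grid_shape = c(48L, 48L, 48L), seed = 1L)
  expect_error(generate_phantom(spec, list(
    truth_lesion(4, center_voxel = c(1L, 1L, 1L)))),
    "outside white matter")
  ph <- generate_phantom(spec)
  ctr <- which(ph$segmentation$wm != 0, arr.ind = TRUE)
  ctr <- ctr[which.min(abs(ctr[, 1] - 24) + abs(ctr[, 2] - 24)), ]
  expect_error(generate_phantom(spec, list(
    truth_lesion(4, center_voxel = ctr),
    truth_lesion(4, center_voxel = ctr + c(1L, 0L, 0L)))),
    "overlap")
})

test_that("cohort rows keep the nested definition structure", {
  tab <- generate_cohort(cohort_spec(seed = 99L))
  expect_true(all(tab$sci_L >= tab$sci_T & tab$sci_T >= tab$sci_R))
  expect_true(all(tab$n_lesions_L >= tab$n_lesions_T))
  expect_true(all(tab$n_lesions_T >= tab$n_lesions_R))
  expect_true(all(tab$volume_L >= tab$volume_T))
  expect_true(all(tab$volume_T >= tab$volume_R))
  expect_true(all((tab$n_lesions_L >= 1) == tab$sci_L))
  tab2 <- generate_cohort(cohort_spec(seed = 99L))
  expect_identical(tab, tab2)
  expect_error(cohort_spec(nested_prevalence = list(
    sca = c(L = 0.2, T = 0.4, R = 0.1), control = c(L = 0.2, T = 0.1, R = 0))),
    "nested")
})

test_that("degenerate prevalence 1/1/1 makes every subject positive and Q zero", {
  spec <- cohort_spec(n_sca = 30L, n_control = 10L,
                      nested_prevalence = list(sca = c(L = 1, T = 1, R = 1),
                                               control = c(L = 1, T = 1, R = 1)),
                      seed = 4L)
  tab <- generate_cohort(spec)
  expect_true(all(tab$sci_L & tab$sci_T & tab$sci_R))
  q <- cochran_q(as.matrix(tab[c("sci_L", "sci_T", "sci_R")]) * 1)
  expect_equal(q$statistic, 0)
  expect_equal(q$p.value, 1)
})

test_that("large-sample cognition means match the configured group means", {
  spec <- cohort_spec(n_sca = 1e5L, n_control = 1e5L, seed = 21L)
  tab <- generate_cohort(spec)
  expect_lt(abs(mean(tab$iq[tab$group == "SCA"]) - 93.15), 0.2)
  expect_lt(abs(mean(tab$iq[tab$group == "control"]) - 97.29), 0.2)
  expect_lt(abs(sd(tab$iq[tab$group == "SCA"]) - 13.28), 0.2)
})
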