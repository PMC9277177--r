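#' Specification for a synthetic brain phantom
#'
#' Describes the geometry and intensities of a simple nested-ellipsoid brain:
#' a brain ellipsoid whose outer ribbon of `cortex_thickness_mm` is cortex,
#' an inner ellipsoid of white matter, and a central ventricular ellipsoid.
#' Axis convention: axis 1 = left-right, axis 2 = inferior-superior,
#' axis 3 = anterior-posterior (the coronal slice direction), matching a
#' coronal acquisition with 0.65 x 0.65 mm in-plane resolution and 1.0 mm
#' slices. FLAIR shows CSF dark (signal suppressed) and cortex brighter than
#' white matter; T1 shows white matter brightest.
#'
#' @param grid_shape voxel counts per axis (default 96 x 96 x 96).
#' @param voxel_size_mm spacing in mm (default 0.65 x 0.65 x 1.0).
#' @param tissue_geometry list: `brain_frac` (ellipsoid semi-axes as a
#'   fraction of the half grid extent), `cortex_thickness_mm`,
#'   `ventricle_frac`.
#' @param base_intensities list of named vectors `flair` and `t1` with
#'   entries `background`, `csf`, `wm`, `cortex`.
#' @param noise_sd additive Gaussian noise SD per modality,
#'   `c(flair =, t1 =)`; default 0 so threshold behaviour is exact.
#' @param seed integer seed.
#' @return class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96L, 96L, 96L),
                         voxel_size_mm = c(0.65, 0.65, 1.0),
                         tissue_geometry = list(brain_frac = 0.92,
                                                cortex_thickness_mm = 2.5,
                                                ventricle_frac = 0.16),
                         base_intensities = list(
                           flair = c(background = 0, csf = 30, wm = 80, cortex = 100),
                           t1 = c(background = 0, csf = 40, wm = 120, cortex = 100)),
                         noise_sd = c(flair = 0, t1 = 0),
                         seed = 1L) {
  if (any(voxel_size_mm <= 0)) stop("voxel_size_mm must be strictly positive")
  if (any(grid_shape < 8L)) stop("grid too small for the nested geometry")
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 tissue_geometry = tissue_geometry,
                 base_intensities = base_intensities,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Ground-truth lesion to embed in a phantom
#'
#' An approximately spherical intensity perturbation of white matter:
#' `flair_multiplier` times the cortical FLAIR mean (above 1.02 it survives
#' the FLAIR lower threshold) and `t1_multiplier` times the cortical T1 mean
#' (below 1.02 it satisfies the T1 hypo-intensity criterion).
#'
#' @param target_diameter_mm intended lesion diameter.
#' @param flair_multiplier ratio to the cortical FLAIR mean (default 1.5).
#' @param t1_multiplier ratio to the cortical T1 mean (default 0.9, a clear
#'   hypo-intensity; use e.g. 1.2 for a T1-normal lesion).
#' @param intended_region `"periventricular"`, `"deep"` or `"juxta-cortical"`;
#'   the generator places the lesion so this band holds a strict majority of
#'   its voxels.
#' @param intended_lobe `"frontal"`, `"parietal"`, `"temporal"` or
#'   `"occipital"`.
#' @param center_voxel optional explicit 3-vector of voxel indices; must lie
#'   in white matter. When `NULL` the generator chooses a centre.
#' @return class `truth_lesion`.
#' @export
truth_lesion <- function(target_diameter_mm, flair_multiplier = 1.5,
                         t1_multiplier = 0.9, intended_region = "deep",
                         intended_lobe = "frontal", center_voxel = NULL) {
  intended_region <- match.arg(intended_region, .regions)
  intended_lobe <- match.arg(intended_lobe, .lobes)
  stopifnot(target_diameter_mm > 0, flair_multiplier > 0, t1_multiplier > 0)
  structure(list(target_diameter_mm = target_diameter_mm,
                 flair_multiplier = flair_multiplier,
                 t1_multiplier = t1_multiplier,
                 intended_region = intended_region,
                 intended_lobe = intended_lobe,
                 center_voxel = if (is.null(center_voxel)) NULL
                                else as.integer(center_voxel)),
            class = "truth_lesion")
}

# nested-ellipsoid tissue masks in mm coordinates centred on the grid
.phantom_masks <- function(spec) {
  dm <- spec$grid_shape; vs <- spec$voxel_size_mm
  half <- dm * vs / 2
  ax <- lapply(1:3, function(i) ((seq_len(dm[i]) - 0.5) * vs[i]) - half[i])
  brain_r <- spec$tissue_geometry$brain_frac * dm * vs / 2
  inner_r <- pmax(brain_r - spec$tissue_geometry$cortex_thickness_mm, 1)
  vent_r <- spec$tissue_geometry$ventricle_frac * dm * vs / 2
  e2 <- function(r) {
    x2 <- (ax[[1]] / r[1])^2; y2 <- (ax[[2]] / r[2])^2; z2 <- (ax[[3]] / r[3])^2
    outer(outer(x2, y2, "+"), z2, "+")
  }
  brain <- e2(brain_r) <= 1
  inner <- e2(inner_r) <= 1
  vent <- e2(vent_r) <= 1
  list(brain = brain, cortex = brain & !inner, wm = inner & !vent,
       ventricles = vent)
}

# 4 lobes from quadrants of the white-matter bounding box:
# axis 3 (anterior-posterior) splits frontal/temporal from parietal/occipital,
# axis 2 (inferior-superior) splits the superior (frontal, parietal) from the
# inferior (temporal, occipital) lobes
.lobe_labels <- function(wm) {
  idx <- .vox_from_mask(wm)
  rng2 <- range(idx[, 2]); rng3 <- range(idx[, 3])
  mid2 <- mean(rng2); mid3 <- mean(rng3)
  lab <- array(NA_character_, dim(wm))
  ant <- idx[, 3] < mid3
  sup <- idx[, 2] >= mid2
  lab[idx[ant & sup, , drop = FALSE]] <- "frontal"
  lab[idx[ant & !sup, , drop = FALSE]] <- "temporal"
  lab[idx[!ant & sup, , drop = FALSE]] <- "parietal"
  lab[idx[!ant & !sup, , drop = FALSE]] <- "occipital"
  lab
}

# voxels whose centres lie within radius_mm of the centre voxel's centre
.sphere_voxels <- function(center, radius_mm, dm, vs) {
  k <- floor(radius_mm / vs)
  offs <- as.matrix(expand.grid(-k[1]:k[1], -k[2]:k[2], -k[3]:k[3]))
  d2 <- (offs[, 1] * vs[1])^2 + (offs[, 2] * vs[2])^2 + (offs[, 3] * vs[3])^2
  offs <- offs[d2 <= radius_mm^2, , drop = FALSE]
  vox <- sweep(offs, 2L, as.integer(center), "+")
  keep <- vox[, 1] >= 1 & vox[, 2] >= 1 & vox[, 3] >= 1 &
    vox[, 1] <= dm[1] & vox[, 2] <= dm[2] & vox[, 3] <= dm[3]
  vox[keep, , drop = FALSE]
}

.roi_box <- function(vox, dm, margin = 1L) {
  lo <- pmax(apply(vox, 2, min) - margin, 1L)
  hi <- pmin(apply(vox, 2, max) + margin, dm)
  rbind(lo, hi)
}

.boxes_overlap <- function(a, b) {
  all(a[1, ] <= b[2, ] & b[1, ] <= a[2, ])
}

#' Generate a synthetic FLAIR/T1 phantom with ground-truth lesions
#'
#' Builds aligned FLAIR and T1 volumes on one grid with tissue masks, embeds
#' each requested lesion as a uniform intensity plateau
#' (`multiplier x cortical mean`) over an approximately spherical white-matter
#' voxel set, and draws one rectangular candidate ROI around each lesion with
#' at least one voxel margin (standing in for the radiologist's manual ROI).
#' When a lesion has no explicit centre, the generator picks one inside the
#' intended band and lobe such that (i) the band holds a strict majority of
#' the realized voxels (so majority-overlap classification is unambiguous),
#' (ii) the realized coronal caliper falls on the same side of 3 mm as the
#' target diameter, and (iii) lesions and their ROIs do not overlap.
#'
#' @param spec a [phantom_spec()].
#' @param lesions list of [truth_lesion()] objects (may be empty).
#' @param pv_percentile,jc_percentile band percentiles used for placement;
#'   keep equal to the values used downstream.
#' @param smooth_edges if TRUE, voxels just outside the lesion sphere get a
#'   half-way intensity ramp (off by default: a sharp plateau keeps
#'   threshold behaviour analytically predictable).
#' @param max_tries candidate centres examined per lesion before giving up.
#' @return class `sci_phantom`: `flair`, `t1` ([volume_grid]s),
#'   `segmentation` (logical masks `brain`, `cortex`, `wm`, `ventricles`),
#'   `roi_labels` (integer array), `roi_lobes` (data.frame `roi_id`, `lobe`),
#'   `truth` (data.frame with realized voxel counts, caliper dimensions and
#'   expected Liberal/Traditional/Restrictive flags), `truth_voxels` (list of
#'   voxel matrices), `parcellation` (the placement parcellation), `spec`.
#' @export
generate_phantom <- function(spec, lesions = list(), pv_percentile = 5,
                             jc_percentile = 75, smooth_edges = FALSE,
                             max_tries = 400L) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  dm <- spec$grid_shape; vs <- spec$voxel_size_mm
  masks <- .phantom_masks(spec)
  bi <- spec$base_intensities
  flair <- array(bi$flair[["background"]], dm)
  t1 <- array(bi$t1[["background"]], dm)
  for (tis in c("cortex", "wm", "ventricles")) {
    key <- if (tis == "ventricles") "csf" else tis
    flair[masks[[tis]]] <- bi$flair[[key]]
    t1[masks[[tis]]] <- bi$t1[[key]]
  }
  cortex_flair_mean <- bi$flair[["cortex"]]
  cortex_t1_mean <- bi$t1[["cortex"]]

  seg <- list(brain = masks$brain, cortex = masks$cortex, wm = masks$wm,
              ventricles = masks$ventricles)
  seg$wm <- volume_grid(seg$wm, vs)
  parc <- build_parcellation(seg, pv_percentile, jc_percentile, vs)
  lobes <- .lobe_labels(masks$wm)
  band_arr <- array(NA_character_, dm)
  band_arr[parc$pv] <- "periventricular"
  band_arr[parc$deep] <- "deep"
  band_arr[parc$jc] <- "juxta-cortical"

  roi_labels <- array(0L, dm)
  boxes <- list()
  truth_rows <- list()
  truth_voxels <- list()
  occupied_keys <- integer(0)

  for (li in seq_along(lesions)) {
    L <- lesions[[li]]
    stopifnot(inherits(L, "truth_lesion"))
    r <- L$target_diameter_mm / 2
    accept <- NULL
    if (!is.null(L$center_voxel)) {
      ctr <- L$center_voxel
      if (!masks$wm[ctr[1], ctr[2], ctr[3]])
        stop("lesion ", li, ": centre voxel (", paste(ctr, collapse = ","),
             ") lies outside white matter")
      vox <- .sphere_voxels(ctr, r, dm, vs)
      vox <- vox[masks$wm[vox], , drop = FALSE]
      if (length(intersect(.vox_key(vox, dm), occupied_keys)))
        stop("lesion ", li, " overlaps a previously placed lesion; ",
             "phantoms require separable ground truth")
      box <- .roi_box(vox, dm)
      if (any(vapply(boxes, .boxes_overlap, logical(1), b = box)))
        stop("lesion ", li, ": candidate ROI overlaps an existing ROI")
      accept <- list(ctr = ctr, vox = vox, box = box)
    } else {
      cand <- which(masks$wm & band_arr == L$intended_region &
                      lobes == L$intended_lobe)
      if (!length(cand))
        stop("lesion ", li, ": no white-matter voxels in ",
             L$intended_region, " / ", L$intended_lobe)
      cand <- cand[sample.int(length(cand))]
      tries <- min(length(cand), max_tries)
      for (ci in seq_len(tries)) {
        ctr <- arrayInd(cand[ci], dm)[1, ]
        vox <- .sphere_voxels(ctr, r, dm, vs)
        vox <- vox[masks$wm[vox], , drop = FALSE]
        if (nrow(vox) == 0L) next
        bands <- table(factor(band_arr[vox], levels = .regions))
        if (names(bands)[which.max(bands)] != L$intended_region) next
        if (sum(bands == max(bands)) > 1L) next          # no ties in truth
        if (length(unique(lobes[vox])) > 1L &&
            names(which.max(table(lobes[vox]))) != L$intended_lobe) next
        cal <- greatest_dimension(vox, vs, mode = "coronal")
        if ((cal >= 3) != (L$target_diameter_mm >= 3)) next
        if (length(intersect(.vox_key(vox, dm), occupied_keys))) next
        box <- .roi_box(vox, dm)
        if (any(vapply(boxes, .boxes_overlap, logical(1), b = box))) next
        accept <- list(ctr = ctr, vox = vox, box = box)
        break
      }
      if (is.null(accept))
        stop("lesion ", li, ": could not place a ", L$target_diameter_mm,
             " mm lesion in ", L$intended_region, " / ", L$intended_lobe,
             " after ", tries, " tries")
    }
    vox <- accept$vox
    flair[vox] <- L$flair_multiplier * cortex_flair_mean
    t1[vox] <- L$t1_multiplier * cortex_t1_mean
    if (smooth_edges) {
      shell <- .sphere_voxels(accept$ctr, r + max(vs), dm, vs)
      shell <- shell[masks$wm[shell], , drop = FALSE]
      shell <- shell[!.vox_key(shell, dm) %in% .vox_key(vox, dm), , drop = FALSE]
      if (nrow(shell)) {
        flair[shell] <- (flair[shell] + L$flair_multiplier * cortex_flair_mean) / 2
        t1[shell] <- (t1[shell] + L$t1_multiplier * cortex_t1_mean) / 2
      }
    }
    b <- accept$box
    roi_labels[b[1, 1]:b[2, 1], b[1, 2]:b[2, 2], b[1, 3]:b[2, 3]] <- li
    boxes[[length(boxes) + 1L]] <- b
    occupied_keys <- c(occupied_keys, .vox_key(vox, dm))
    cal <- greatest_dimension(vox, vs, mode = "coronal")
    L_flag <- L$flair_multiplier >= 1.02
    T_flag <- L_flag && cal >= 3
    R_flag <- T_flag && L$t1_multiplier <= 1.02
    truth_voxels[[li]] <- vox
    truth_rows[[li]] <- data.frame(
      lesion = li, roi_id = li,
      center_1 = accept$ctr[1], center_2 = accept$ctr[2], center_3 = accept$ctr[3],
      target_diameter_mm = L$target_diameter_mm,
      flair_multiplier = L$flair_multiplier, t1_multiplier = L$t1_multiplier,
      region = L$intended_region, lobe = L$intended_lobe,
      n_voxels = nrow(vox), realized_dimension_mm = cal,
      L = L_flag, T = T_flag, R = R_flag, stringsAsFactors = FALSE)
  }

  if (any(spec$noise_sd > 0)) {
    flair <- flair + rnorm(length(flair), 0, spec$noise_sd[["flair"]])
    t1 <- t1 + rnorm(length(t1), 0, spec$noise_sd[["t1"]])
  }
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(lesion = integer(0))
  roi_lobes <- if (nrow(truth)) truth[, c("roi_id", "lobe")] else
    data.frame(roi_id = integer(0), lobe = character(0))
  structure(list(flair = volume_grid(flair, vs), t1 = volume_grid(t1, vs),
                 segmentation = list(brain = masks$brain, cortex = masks$cortex,
                                     wm = volume_grid(masks$wm, vs),
                                     ventricles = masks$ventricles),
                 roi_labels = roi_labels, roi_lobes = roi_lobes,
                 truth = truth, truth_voxels = truth_voxels,
                 parcellation = parc, spec = spec),
            class = "sci_phantom")
}

#' @export
print.sci_phantom <- function(x, ...) {
  cat("<sci_phantom> grid", paste(x$spec$grid_shape, collapse = " x "),
      "voxels,", nrow(x$truth), "ground-truth lesion(s)\n")
  if (nrow(x$truth))
    print(x$truth[, c("lesion", "region", "lobe", "target_diameter_mm",
                      "realized_dimension_mm", "L", "T", "R")])
  invisible(x)
}
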