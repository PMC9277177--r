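#' Cortex-referenced intensity thresholds
#'
#' Computes the arithmetic mean FLAIR and T1 intensity over the cortical
#' mask and derives the lesion inclusion thresholds: a lower FLAIR threshold
#' `multiplier * mean(FLAIR over cortex)` (voxels at or above it are
#' hyperintense relative to cortex) and an upper T1 threshold
#' `multiplier * mean(T1 over cortex)` (voxels at or below it are iso- or
#' hypo-intense relative to cortex). The default multiplier is 1.02.
#'
#' @param flair,t1 co-registered [volume_grid]s (or plain arrays) on one grid.
#' @param cortex_mask non-empty logical array on the same grid.
#' @param multiplier positive ratio applied to both cortical means.
#' @return class `threshold_set`: `mean_flair_cortex`, `lower_thr_flair`,
#'   `mean_t1_cortex`, `upper_thr_t1`, `multiplier`.
#' @export
compute_thresholds <- function(flair, t1, cortex_mask, multiplier = 1.02) {
  if (!.same_grid(flair, t1) || !.same_grid(flair, cortex_mask))
    stop("compute_thresholds: FLAIR, T1 and cortex mask must share one grid")
  cm <- cortex_mask != 0
  if (!any(cm)) stop("compute_thresholds: cortex mask is empty")
  fv <- flair[cm]; tv <- t1[cm]
  if (any(!is.finite(fv)) || any(!is.finite(tv)))
    stop("compute_thresholds: non-finite intensities inside the cortex mask")
  if (!is.numeric(multiplier) || length(multiplier) != 1L || multiplier <= 0)
    stop("multiplier must be a single positive number")
  mf <- mean(fv); mt <- mean(tv)
  structure(list(mean_flair_cortex = mf,
                 lower_thr_flair = multiplier * mf,
                 mean_t1_cortex = mt,
                 upper_thr_t1 = multiplier * mt,
                 multiplier = multiplier),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat("<threshold_set> multiplier =", x$multiplier, "\n")
  cat(sprintf("  FLAIR: cortex mean %.3f -> lower threshold %.3f (keep >=)\n",
              x$mean_flair_cortex, x$lower_thr_flair))
  cat(sprintf("  T1:    cortex mean %.3f -> upper threshold %.3f (keep <=)\n",
              x$mean_t1_cortex, x$upper_thr_t1))
  invisible(x)
}

#' Candidate lesion ROIs from a label volume
#'
#' Converts an integer label array (one positive label per
#' radiologist-identified candidate lesion) plus a label-to-lobe map into the
#' ROI list consumed by [extract_lesion_masks()].
#'
#' @param labels integer 3D array, 0 = background.
#' @param lobe_map data.frame with columns `roi_id`, `lobe`.
#' @return list of ROIs, each `list(roi_id, voxels, lobe)`.
#' @export
rois_from_labels <- function(labels, lobe_map = NULL) {
  ids <- sort(unique(as.integer(labels[labels > 0])))
  lapply(ids, function(id) {
    lobe <- NA_character_
    if (!is.null(lobe_map)) {
      hit <- match(id, lobe_map$roi_id)
      if (!is.na(hit)) lobe <- as.character(lobe_map$lobe[hit])
    }
    list(roi_id = id,
         voxels = which(labels == id, arr.ind = TRUE, useNames = FALSE),
         lobe = lobe)
  })
}

# connected components over a voxel set under 6/18/26 connectivity;
# plain BFS on linear keys -- ROI voxel sets are small
.neighbour_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  ord <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord <= 2, "26" = ord <= 3,
                 stop("connectivity must be 6, 18 or 26"))
  g[keep, , drop = FALSE]
}

.connected_components <- function(vox, dm, connectivity = 26) {
  n <- nrow(vox)
  if (n == 0L) return(integer(0))
  offs <- .neighbour_offsets(connectivity)
  keys <- .vox_key(vox, dm)
  lab <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue)) {
      i <- queue[[1L]]; queue <- queue[-1L]
      nb <- sweep(offs, 2L, as.integer(vox[i, ]), "+")
      hit <- match(.vox_key(nb, dm), keys)
      hit <- hit[!is.na(hit)]
      new <- hit[lab[hit] == 0L]
      lab[new] <- cur
      queue <- c(queue, new)
    }
  }
  lab
}

#' Extract individual lesion masks within candidate ROIs
#'
#' Applies the FLAIR lower threshold inside each candidate ROI (voxels with
#' `FLAIR >= lower_thr_flair` form the FLAIR lesion burden mask), separates
#' surviving voxels into connected components under the chosen connectivity,
#' and then applies the T1 upper threshold within the FLAIR-surviving voxels
#' (`T1 <= upper_thr_t1`). Because each ROI corresponds to one
#' radiologist-identified lesion, all components inside one ROI are merged
#' into a single lesion mask by default; component structure is retained for
#' diagnostics. ROIs in which no voxel survives the FLAIR threshold yield an
#' empty lesion mask with `survived = FALSE`.
#'
#' @param flair,t1 co-registered volumes.
#' @param rois list of ROIs from [rois_from_labels()] (each with `roi_id`,
#'   `voxels`, `lobe`); ROIs must not overlap.
#' @param thr a `threshold_set` from [compute_thresholds()].
#' @param connectivity 6, 18 or 26 (default 26: faces, edges and corners).
#' @param merge_components merge all surviving components of an ROI into one
#'   lesion (default TRUE, one mask per identified lesion).
#' @param min_voxels minimum FLAIR-surviving voxels for a lesion to count
#'   (default 1).
#' @param voxel_size_mm spacing; defaults to the FLAIR volume's own.
#' @return list of `lesion_mask` objects: `lesion_id`, `roi_id`, `lobe`,
#'   `flair_voxels`, `t1_voxels` (subset), `n_components`, `volume_mm3`,
#'   `t1_volume_mm3`, `survived`, `voxel_size_mm`.
#' @export
extract_lesion_masks <- function(flair, t1, rois, thr, connectivity = 26,
                                 merge_components = TRUE, min_voxels = 1L,
                                 voxel_size_mm = NULL) {
  if (!.same_grid(flair, t1))
    stop("extract_lesion_masks: FLAIR and T1 grids differ")
  if (!inherits(thr, "threshold_set"))
    stop("thr must be a threshold_set from compute_thresholds()")
  vs <- if (is.null(voxel_size_mm)) voxel_size(flair, default = c(1, 1, 1))
        else as.numeric(voxel_size_mm)
  dm <- dim(flair)
  ids <- vapply(rois, function(r) as.integer(r$roi_id), integer(1))
  if (anyDuplicated(ids)) stop("duplicate roi_ids")
  all_keys <- unlist(lapply(rois, function(r) .vox_key(r$voxels, dm)))
  if (anyDuplicated(all_keys))
    stop("extract_lesion_masks: candidate ROIs overlap; identified lesions must be distinct")
  vv <- prod(vs)
  out <- vector("list", length(rois))
  for (i in seq_along(rois)) {
    r <- rois[[i]]
    vox <- r$voxels
    if (!nrow(vox)) stop("ROI ", r$roi_id, " has an empty voxel set")
    if (any(vox < 1L) || any(vox[, 1] > dm[1]) || any(vox[, 2] > dm[2]) ||
        any(vox[, 3] > dm[3]))
      stop("ROI ", r$roi_id, " extends outside the volume grid")
    surv <- vox[flair[vox] >= thr$lower_thr_flair, , drop = FALSE]
    comp <- .connected_components(surv, dm, connectivity)
    n_comp <- if (length(comp)) max(comp) else 0L
    if (!merge_components && n_comp > 1L) {
      # keep the largest component as the lesion; others reported separately
      keep <- comp == which.max(tabulate(comp))
      surv <- surv[keep, , drop = FALSE]
    }
    survived <- nrow(surv) >= max(1L, min_voxels)
    if (!survived) surv <- surv[0L, , drop = FALSE]
    t1v <- surv[t1[surv] <= thr$upper_thr_t1, , drop = FALSE]
    out[[i]] <- structure(list(
      lesion_id = i, roi_id = r$roi_id,
      lobe = if (is.null(r$lobe)) NA_character_ else r$lobe,
      flair_voxels = surv, t1_voxels = t1v,
      n_components = n_comp,
      n_flair_voxels = nrow(surv), n_t1_voxels = nrow(t1v),
      volume_mm3 = nrow(surv) * vv, t1_volume_mm3 = nrow(t1v) * vv,
      survived = survived, connectivity = connectivity,
      voxel_size_mm = vs), class = "lesion_mask")
  }
  out
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask> id %d (ROI %s, lobe %s): %d FLAIR voxels (%.2f mm3), %d T1 voxels (%.2f mm3)%s\n",
              x$lesion_id, x$roi_id, x$lobe, x$n_flair_voxels, x$volume_mm3,
              x$n_t1_voxels, x$t1_volume_mm3,
              if (x$survived) "" else " [did not survive]"))
  invisible(x)
}
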