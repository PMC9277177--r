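#' Anisotropic Euclidean distance map
#'
#' Distance in mm from every voxel to the nearest voxel of `target_mask`,
#' computed with the separable lower-envelope distance transform on the
#' squared-distance field so per-axis spacing is respected (slices are often
#' thicker than the in-plane resolution).
#'
#' @param target_mask logical 3D array (non-empty).
#' @param voxel_size_mm spacing per axis in mm; defaults to the mask's own.
#' @param domain optional logical array; distances outside it are set `NA`.
#' @return a [volume_grid] of distances in mm (0 inside the target).
#' @export
distance_map <- function(target_mask, voxel_size_mm = NULL, domain = NULL) {
  vs <- if (is.null(voxel_size_mm)) voxel_size(target_mask) else as.numeric(voxel_size_mm)
  tm <- target_mask != 0
  if (!any(tm)) stop("distance_map: target mask is empty")
  d2 <- .edt_sq(as.logical(tm), as.integer(dim(tm)), vs)
  d <- sqrt(d2)
  if (!is.null(domain)) {
    if (!.same_grid(tm, domain)) stop("domain grid does not match target grid")
    d[!(domain != 0)] <- NA_real_
  }
  volume_grid(array(d, dim(tm)), vs)
}

#' Participant-specific periventricular / deep / juxta-cortical parcellation
#'
#' Partitions the white-matter mask into three bands using percentile
#' thresholds on distance maps. The periventricular band is the `pv_percentile`
#' of white-matter voxels nearest the ventricles (upper threshold on the
#' ventricle distance map). Those voxels are then excluded from the cortex
#' distance map, and the `jc_percentile` of the remaining white-matter voxels
#' nearest the cortex become the juxta-cortical band; what is left is deep
#' white matter. Percentile masks are rank-based: ties at the quantile
#' boundary are broken by voxel scan order so the band size equals the
#' percentile rank exactly.
#'
#' @param segmentation list with logical arrays `wm`, `cortex`, `ventricles`
#'   on one grid (e.g. the `segmentation` element of a phantom).
#' @param pv_percentile percentile of ventricle distance over white matter
#'   (default 5).
#' @param jc_percentile percentile of cortex distance (default 75).
#' @param voxel_size_mm spacing; defaults to the white-matter mask's own.
#' @param quantile_domain `"sequential"` (default; juxta-cortical quantile is
#'   taken over white matter minus the periventricular band, matching the
#'   stated exclusion order) or `"all_wm"` (quantile over all white matter,
#'   for sensitivity analysis).
#' @return an object of class `sci_parcellation`: logical arrays `pv`, `jc`,
#'   `deep` (pairwise disjoint, union = white matter) plus the configuration.
#' @export
build_parcellation <- function(segmentation, pv_percentile = 5,
                               jc_percentile = 75, voxel_size_mm = NULL,
                               quantile_domain = c("sequential", "all_wm")) {
  quantile_domain <- match.arg(quantile_domain)
  wm <- segmentation$wm != 0
  cortex <- segmentation$cortex != 0
  vent <- segmentation$ventricles != 0
  if (!any(wm) || !any(cortex) || !any(vent))
    stop("build_parcellation: white matter, cortex and ventricle masks must be non-empty")
  if (!(pv_percentile > 0 && pv_percentile < 100) ||
      !(jc_percentile > 0 && jc_percentile < 100))
    stop("percentiles must lie strictly between 0 and 100")
  vs <- if (is.null(voxel_size_mm)) voxel_size(segmentation$wm, default = c(1, 1, 1))
        else as.numeric(voxel_size_mm)

  d_vent <- distance_map(vent, vs)
  d_cort <- distance_map(cortex, vs)
  dm <- dim(wm)
  wm_idx <- which(wm)
  n_wm <- length(wm_idx)

  k_pv <- min(n_wm, max(1L, ceiling(pv_percentile / 100 * n_wm)))
  ord <- order(d_vent[wm_idx])            # stable: boundary ties by scan order
  pv_idx <- wm_idx[ord[seq_len(k_pv)]]

  rem_idx <- setdiff(wm_idx, pv_idx)
  n_dom <- if (quantile_domain == "sequential") length(rem_idx) else n_wm
  k_jc <- min(length(rem_idx), max(1L, ceiling(jc_percentile / 100 * n_dom)))
  ord2 <- order(d_cort[rem_idx])
  jc_idx <- rem_idx[ord2[seq_len(k_jc)]]
  deep_idx <- setdiff(rem_idx, jc_idx)

  mk <- function(idx) { m <- array(FALSE, dm); m[idx] <- TRUE; m }
  parc <- list(pv = mk(pv_idx), jc = mk(jc_idx), deep = mk(deep_idx),
               voxel_size_mm = vs,
               config = list(pv_percentile = pv_percentile,
                             jc_percentile = jc_percentile,
                             quantile_domain = quantile_domain),
               sizes = c(pv = length(pv_idx), jc = length(jc_idx),
                         deep = length(deep_idx), wm = n_wm))
  if (any(parc$sizes[1:3] == 0))
    warning("parcellation has an empty band (degenerate geometry)")
  class(parc) <- "sci_parcellation"
  parc
}

#' @export
print.sci_parcellation <- function(x, ...) {
  cat("<sci_parcellation> pv/jc/deep =",
      paste(x$sizes[1:3], collapse = " / "),
      "voxels of", x$sizes[["wm"]], "white-matter voxels\n")
  cat("  percentiles: pv", x$config$pv_percentile, "| jc",
      x$config$jc_percentile, "| quantile domain:", x$config$quantile_domain, "\n")
  invisible(x)
}

#' Assign a lesion to a white-matter band by majority overlap
#'
#' The lesion takes the band containing the strict maximum number of its
#' FLAIR lesion voxels. Equal counts are surfaced as a tie (`region = NA`,
#' `tie = TRUE`) rather than silently broken: in the source workflow ties
#' were escalated to a neuroradiologist.
#'
#' @param lesion a `lesion_mask` (see [extract_lesion_masks()]), or an n x 3
#'   voxel index matrix.
#' @param parc an `sci_parcellation`.
#' @return list with `region` (`"periventricular"`, `"deep"`,
#'   `"juxta-cortical"` or `NA` on tie), `tie`, `tied_regions`, and the
#'   per-band overlap `counts`.
#' @export
assign_region <- function(lesion, parc) {
  vox <- if (is.matrix(lesion)) lesion else lesion$flair_voxels
  if (is.null(vox) || nrow(vox) == 0L) stop("assign_region: lesion has no voxels")
  counts <- c(periventricular = sum(parc$pv[vox]),
              deep = sum(parc$deep[vox]),
              `juxta-cortical` = sum(parc$jc[vox]))
  if (sum(counts) == 0L)
    stop("assign_region: lesion has no white-matter overlap (",
         nrow(vox), " voxels outside the parcellation)")
  top <- counts == max(counts)
  if (sum(top) > 1L)
    return(list(region = NA_character_, tie = TRUE,
                tied_regions = names(counts)[top], counts = counts))
  list(region = names(counts)[which.max(counts)], tie = FALSE,
       tied_regions = character(), counts = counts)
}

#' Per-band lesion volumes (with within-lesion overlap across bands)
#'
#' Voxel counts of the lesion inside each band times the voxel volume; the
#' three volumes sum to the lesion's white-matter volume, so a lesion
#' straddling two bands contributes volume to both.
#'
#' @inheritParams assign_region
#' @param which use the FLAIR-surviving voxel set (default) or the
#'   T1-surviving subset.
#' @return named numeric: mm^3 per band.
#' @export
regional_volumes <- function(lesion, parc, which = c("flair", "t1")) {
  which <- match.arg(which)
  vox <- if (is.matrix(lesion)) lesion
         else if (which == "flair") lesion$flair_voxels else lesion$t1_voxels
  vv <- prod(parc$voxel_size_mm)
  if (is.null(vox) || nrow(vox) == 0L)
    return(c(periventricular = 0, deep = 0, `juxta-cortical` = 0))
  c(periventricular = sum(parc$pv[vox]),
    deep = sum(parc$deep[vox]),
    `juxta-cortical` = sum(parc$jc[vox])) * vv
}

.regions <- c("periventricular", "deep", "juxta-cortical")
.lobes <- c("frontal", "parietal", "temporal", "occipital")

#' Group-level 12-zone bullseye table
#'
#' Crosses the three white-matter bands with the four lobes and summarises
#' lesion burden for one definition under one of three metrics:
#' `"participants"` (% of the group with lesion voxels in the zone),
#' `"count_share"` (% of the group's lesion count classed into the zone via
#' majority-overlap band + recorded lobe) or `"volume_share"` (% of the
#' group's lesion voxel volume in the zone, allowing within-lesion overlap
#' across bands). Count and volume shares sum to 100 over the 12 zones
#' whenever the group has any qualifying lesion. Lesions with an unresolved
#' band tie are excluded from the count metric and flagged.
#'
#' @param profiles list of `sci_subject_profile` objects
#'   (see [aggregate_subject()]).
#' @param definition `"L"`, `"T"` or `"R"`.
#' @param metric `"participants"`, `"count_share"` or `"volume_share"`.
#' @return class `bullseye_table`: a 3 x 4 matrix (bands x lobes) with
#'   attributes `definition`, `metric`, `n_tied_excluded`.
#' @export
bullseye <- function(profiles, definition = c("L", "T", "R"),
                     metric = c("participants", "count_share", "volume_share")) {
  definition <- match.arg(definition)
  metric <- match.arg(metric)
  if (length(profiles) < 1L) stop("bullseye: need at least one subject profile")
  if (inherits(profiles, "sci_subject_profile")) profiles <- list(profiles)
  zone <- matrix(0, 3, 4, dimnames = list(.regions, .lobes))
  n_tied <- 0L
  flag_any <- matrix(FALSE, 3, 4, dimnames = dimnames(zone))
  vol_col <- if (definition == "R") "t1" else "flair"
  for (p in profiles) {
    lt <- p$lesion_table
    if (is.null(lt) || !nrow(lt)) next
    keep <- lt[[definition]]
    lt <- lt[keep, , drop = FALSE]
    if (!nrow(lt)) next
    for (i in seq_len(nrow(lt))) {
      lb <- lt$lobe[i]
      if (!lb %in% .lobes) next
      if (metric == "count_share") {
        if (is.na(lt$region[i])) { n_tied <- n_tied + 1L; next }
        zone[lt$region[i], lb] <- zone[lt$region[i], lb] + 1
      } else {
        vols <- c(lt[[paste0("pv_", vol_col, "_mm3")]][i],
                  lt[[paste0("deep_", vol_col, "_mm3")]][i],
                  lt[[paste0("jc_", vol_col, "_mm3")]][i])
        if (metric == "volume_share") {
          zone[, lb] <- zone[, lb] + vols
        } else {
          flag_any[, lb] <- flag_any[, lb] | (vols > 0)
        }
      }
    }
    if (metric == "participants") {
      zone <- zone + flag_any
      flag_any[] <- FALSE
    }
  }
  out <- switch(metric,
    participants = 100 * zone / length(profiles),
    count_share = if (sum(zone) > 0) 100 * zone / sum(zone) else zone,
    volume_share = if (sum(zone) > 0) 100 * zone / sum(zone) else zone)
  structure(out, class = c("bullseye_table", "matrix"),
            definition = definition, metric = metric,
            n_tied_excluded = n_tied, n_subjects = length(profiles))
}

#' @export
print.bullseye_table <- function(x, digits = 1, ...) {
  cat("<bullseye_table> definition ", attr(x, "definition"),
      ", metric ", attr(x, "metric"), " (%), n = ",
      attr(x, "n_subjects"), " subjects\n", sep = "")
  print(round(unclass(x), digits))
  if (attr(x, "n_tied_excluded") > 0)
    cat("note:", attr(x, "n_tied_excluded"),
        "lesion(s) with unresolved band ties excluded\n")
  invisible(x)
}
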