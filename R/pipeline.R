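#' Pipeline configuration
#'
#' Collects every tunable of the quantification pipeline with defaults equal
#' to the reference workflow's stated or inferred values: cortex-referenced
#' threshold multiplier 1.02, 26-connectivity clustering, coronal in-plane
#' caliper with a 3 mm Traditional cut-off, the floor(age/10)+1 per-decade
#' rule, 5th/75th percentile regional bands, Yates-corrected 2x2 chi-square,
#' alpha 0.05 with no multiple-comparison correction.
#'
#' @param multiplier threshold multiplier for both modalities.
#' @param connectivity 6, 18 or 26.
#' @param min_voxels minimum surviving voxels per lesion.
#' @param dimension_mode `"coronal"` or `"3d"`.
#' @param slice_axis coronal slice axis (default 3).
#' @param min_dimension_mm Traditional definition cut-off (default 3).
#' @param pv_percentile,jc_percentile regional band percentiles.
#' @param quantile_domain see [build_parcellation()].
#' @param yates Yates correction for 2x2 chi-square tests.
#' @param alpha significance threshold.
#' @param seed integer seed for any stochastic stage.
#' @return class `run_config` (a named list).
#' @export
run_config <- function(multiplier = 1.02, connectivity = 26, min_voxels = 1L,
                       dimension_mode = "coronal", slice_axis = 3L,
                       min_dimension_mm = 3, pv_percentile = 5,
                       jc_percentile = 75, quantile_domain = "sequential",
                       yates = TRUE, alpha = 0.05, seed = 1L) {
  structure(list(multiplier = multiplier, connectivity = connectivity,
                 min_voxels = min_voxels, dimension_mode = dimension_mode,
                 slice_axis = slice_axis, min_dimension_mm = min_dimension_mm,
                 pv_percentile = pv_percentile, jc_percentile = jc_percentile,
                 quantile_domain = quantile_domain, yates = yates,
                 alpha = alpha, seed = as.integer(seed)),
            class = "run_config")
}

#' Quantify one subject's lesions end to end
#'
#' Runs the per-subject stages in order: cortex-referenced thresholds,
#' within-ROI FLAIR/T1 thresholding and clustering, definition flags and
#' caliper dimensions, regional parcellation, majority-overlap band
#' assignment, and aggregation into a subject profile. Stage counts (ROIs
#' received, lesions surviving each threshold, lesions per definition) are
#' collected in a log so the attrition is auditable.
#'
#' @param flair,t1 co-registered [volume_grid]s.
#' @param segmentation list with `cortex`, `wm`, `ventricles` masks.
#' @param roi_labels integer label array of candidate ROIs.
#' @param roi_lobes data.frame `roi_id`, `lobe`.
#' @param config a [run_config()].
#' @param demographics,cognition passed to [aggregate_subject()].
#' @return class `sci_subject_run`: `thresholds`, `lesions`, `parcellation`,
#'   `profile`, `log`.
#' @export
quantify_subject <- function(flair, t1, segmentation, roi_labels,
                             roi_lobes = NULL, config = run_config(),
                             demographics = list(),
                             cognition = c(iq = NA, wmi = NA, psi = NA)) {
  if (!.same_grid(flair, t1) || !.same_grid(flair, roi_labels))
    stop("quantify_subject: inputs do not share one voxel grid")
  vs <- voxel_size(flair)
  thr <- compute_thresholds(flair, t1, segmentation$cortex, config$multiplier)
  rois <- rois_from_labels(roi_labels, roi_lobes)
  lesions <- extract_lesion_masks(flair, t1, rois, thr,
                                  connectivity = config$connectivity,
                                  min_voxels = config$min_voxels,
                                  voxel_size_mm = vs)
  parc <- build_parcellation(segmentation, config$pv_percentile,
                             config$jc_percentile, vs,
                             config$quantile_domain)
  profile <- aggregate_subject(lesions, demographics, cognition,
                               parcellation = parc,
                               min_dimension_mm = config$min_dimension_mm,
                               mode = config$dimension_mode,
                               slice_axis = config$slice_axis)
  log <- c(rois_received = length(rois),
           lesions_surviving_flair = sum(vapply(lesions, `[[`, TRUE, "survived")),
           lesions_with_t1_voxels = sum(vapply(lesions, function(l)
             l$n_t1_voxels > 0, TRUE)),
           n_liberal = unname(profile$n_lesions["L"]),
           n_traditional = unname(profile$n_lesions["T"]),
           n_restrictive = unname(profile$n_lesions["R"]))
  structure(list(thresholds = thr, lesions = lesions, parcellation = parc,
                 profile = profile, config = config, log = log),
            class = "sci_subject_run")
}

#' @export
print.sci_subject_run <- function(x, ...) {
  cat("<sci_subject_run>\n")
  print(x$thresholds)
  cat("stage counts:\n")
  print(x$log)
  invisible(x)
}

#' Run the pipeline and write a self-describing run directory
#'
#' Executes [quantify_subject()] on provided volumes (or on a phantom built
#' from `phantom_spec`/`lesions`), then writes lesion tables, the subject
#' profile, parcellation masks and a provenance log (serialized config and
#' seed) under `out_dir`. Re-running from the serialized config reproduces
#' the directory.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param flair,t1,segmentation,roi_labels,roi_lobes subject inputs, or
#' @param phantom an `sci_phantom` to quantify instead.
#' @param demographics,cognition passed through.
#' @return the `sci_subject_run`, invisibly, with `attr(,"out_dir")`.
#' @export
run_pipeline <- function(config = run_config(), out_dir, flair = NULL,
                         t1 = NULL, segmentation = NULL, roi_labels = NULL,
                         roi_lobes = NULL, phantom = NULL,
                         demographics = list(),
                         cognition = c(iq = NA, wmi = NA, psi = NA)) {
  if (!is.null(phantom)) {
    flair <- phantom$flair; t1 <- phantom$t1
    segmentation <- phantom$segmentation
    roi_labels <- phantom$roi_labels; roi_lobes <- phantom$roi_lobes
  }
  if (is.null(flair) || is.null(t1) || is.null(segmentation) ||
      is.null(roi_labels))
    stop("run_pipeline: missing inputs (need FLAIR, T1, segmentation and ROIs, or a phantom)")
  run <- quantify_subject(flair, t1, segmentation, roi_labels, roi_lobes,
                          config, demographics, cognition)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  lt <- run$profile$lesion_table
  write.csv(lt, file.path(out_dir, "lesion_table.csv"), row.names = FALSE)
  pr <- run$profile
  prof_df <- data.frame(definition = c("L", "T", "R"),
                        n_lesions = as.integer(pr$n_lesions),
                        volume_mm3 = as.numeric(pr$volume_mm3),
                        n_voxels = as.integer(pr$n_voxels),
                        presence = as.logical(pr$presence),
                        per_decade_abnormal = as.logical(pr$per_decade_abnormal))
  write.csv(prof_df, file.path(out_dir, "subject_profile.csv"), row.names = FALSE)
  vs <- voxel_size(flair)
  for (band in c("pv", "jc", "deep"))
    write_volume(volume_grid(run$parcellation[[band]] * 1L, vs),
                 file.path(out_dir, paste0("parcellation_", band, ".nii.gz")),
                 datatype = "uint8")
  flair_mask <- array(0L, dim(flair))
  t1_mask <- array(0L, dim(flair))
  for (l in run$lesions) {
    if (nrow(l$flair_voxels)) flair_mask[l$flair_voxels] <- l$lesion_id
    if (nrow(l$t1_voxels)) t1_mask[l$t1_voxels] <- l$lesion_id
  }
  write_volume(volume_grid(flair_mask, vs),
               file.path(out_dir, "flair_lesion_labels.nii.gz"), datatype = "int16")
  write_volume(volume_grid(t1_mask, vs),
               file.path(out_dir, "t1_lesion_labels.nii.gz"), datatype = "int16")
  yaml::write_yaml(unclass(run$config), file.path(out_dir, "config.yaml"))
  writeLines(c(paste0("sciquant ", as.character(utils::packageVersion("sciquant"))),
               paste0("seed: ", run$config$seed),
               paste(names(run$log), run$log, sep = " = ")),
             file.path(out_dir, "provenance.log"))
  attr(run, "out_dir") <- out_dir
  invisible(run)
}

#' Within- and between-group statistics for a cohort table
#'
#' Reproduces the global lesion-characteristics battery from a cohort table:
#' within each group, Cochran's Q across the three definitions for lesion
#' presence and for per-decade abnormal burden, and Friedman tests (with
#' Kendall's W) for lesion number and volume; between groups, per
#' definition, a Yates chi-square (or Fisher's exact test when any expected
#' cell is below `fisher_cutoff`) for presence, and Mann-Whitney tests for
#' number and volume. Also returns the demographic/cognition group summary
#' and a Spearman correlation screen of the model variables.
#'
#' @param table an `sci_cohort`-style data.frame.
#' @param config a [run_config()] (for `yates` and `alpha`).
#' @param fisher_cutoff use Fisher's exact test when the smallest observed
#'   positive count is below this (default 10).
#' @return class `sci_cohort_report`: nested list of `stat_report`s plus
#'   `group_summary` and `spearman` elements.
#' @export
analyze_cohort <- function(table, config = run_config(), fisher_cutoff = 10) {
  defs <- c("L", "T", "R")
  pres <- as.matrix(table[paste0("sci_", defs)]) * 1
  colnames(pres) <- defs
  pdec <- sapply(defs, function(d)
    per_decade_abnormal(table[[paste0("n_lesions_", d)]], table$age_years))
  counts <- as.matrix(table[paste0("n_lesions_", defs)])
  colnames(counts) <- defs
  vols <- as.matrix(table[paste0("volume_", defs)])
  colnames(vols) <- defs
  groups <- list(SCA = table$group == "SCA", control = table$group != "SCA")
  within <- lapply(groups, function(sel) list(
    prevalence_q = cochran_q(pres[sel, , drop = FALSE]),
    per_decade_q = cochran_q(pdec[sel, , drop = FALSE] * 1),
    number_friedman = friedman_kendall(log1p(counts[sel, , drop = FALSE])),
    volume_friedman = friedman_kendall(log1p(vols[sel, , drop = FALSE]))))
  between <- lapply(defs, function(d) {
    tab <- rbind(SCA = c(sum(pres[groups$SCA, d]), sum(groups$SCA) - sum(pres[groups$SCA, d])),
                 control = c(sum(pres[groups$control, d]),
                             sum(groups$control) - sum(pres[groups$control, d])))
    pres_test <- if (min(tab[, 1]) < fisher_cutoff) fisher_exact(tab)
                 else chi2_2x2(tab, yates = config$yates)
    list(presence = pres_test,
         number = mann_whitney_r(counts[groups$SCA, d], counts[groups$control, d]),
         volume = mann_whitney_r(vols[groups$SCA, d], vols[groups$control, d]))
  })
  names(between) <- defs
  vars <- intersect(c("age_years", "education_decile", "spo2", "hemoglobin",
                      "icv_mm3", "n_lesions_L", "n_lesions_T", "n_lesions_R",
                      "volume_L", "volume_T", "volume_R", "iq", "wmi", "psi"),
                    names(table))
  structure(list(within = within, between = between,
                 group_summary = group_summary(table),
                 spearman = spearman_screen(table, vars, config$alpha)),
            class = "sci_cohort_report")
}

#' @export
print.sci_cohort_report <- function(x, ...) {
  cat("<sci_cohort_report>\n== within-group effects of definition ==\n")
  for (g in names(x$within)) {
    cat("--", g, "--\n")
    for (nm in names(x$within[[g]])) {
      r <- x$within[[g]][[nm]]
      cat(sprintf("  %-16s %s = %.2f, p = %.3g, %s = %.2f\n", nm, r$test,
                  r$statistic, r$p.value, r$effect_name, r$effect))
    }
  }
  cat("== between-group differences per definition ==\n")
  for (d in names(x$between)) {
    for (nm in names(x$between[[d]])) {
      r <- x$between[[d]][[nm]]
      cat(sprintf("  %s-SCI %-9s %s: p = %.3g, %s = %.3f\n", d, nm, r$test,
                  r$p.value, r$effect_name, r$effect))
    }
  }
  invisible(x)
}

#' Write / read a cohort table as CSV
#'
#' Round-trip safe: logical lesion-status columns are restored as logical on
#' read.
#' @param table cohort data.frame.
#' @param path CSV path.
#' @return `write_cohort`: the path, invisibly. `read_cohort`: the table.
#' @export
write_cohort <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  for (v in intersect(c("sci_L", "sci_T", "sci_R", "impaired"), names(tab)))
    tab[[v]] <- as.logical(tab[[v]])
  class(tab) <- c("sci_cohort", "data.frame")
  tab
}
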