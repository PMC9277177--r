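#' Caliper greatest dimension of a lesion
#'
#' Edge-to-edge (caliper) measurement, mirroring an on-screen manual ruler:
#' for the pair of voxels whose centres are furthest apart, the measurement
#' runs along the line through both centres from the far edge of one voxel
#' to the far edge of the other, i.e. the centre distance plus each end
#' voxel's half-extent along that direction. Five collinear voxels of
#' 0.65 mm spacing therefore measure 5 x 0.65 = 3.25 mm, and a single voxel
#' measures its own diagonal. The default `"coronal"` mode restricts pairs
#' to single coronal slices (all voxels sharing the index along
#' `slice_axis`) and returns the maximum over slices, as lesions are
#' measured in-plane on a coronal acquisition; `"3d"` uses all pairs and is
#' never smaller.
#'
#' @param lesion a `lesion_mask` or an n x 3 voxel index matrix (non-empty).
#' @param voxel_size_mm spacing per axis in mm; defaults to the lesion's own.
#' @param mode `"coronal"` (in-plane, default) or `"3d"`.
#' @param slice_axis axis index (1-3) orthogonal to the coronal plane
#'   (default 3).
#' @return greatest dimension in mm.
#' @export
greatest_dimension <- function(lesion, voxel_size_mm = NULL,
                               mode = c("coronal", "3d"), slice_axis = 3L) {
  mode <- match.arg(mode)
  vox <- if (is.matrix(lesion)) lesion else lesion$flair_voxels
  if (is.null(vox) || nrow(vox) == 0L)
    stop("greatest_dimension: lesion has no voxels")
  vs <- if (!is.null(voxel_size_mm)) as.numeric(voxel_size_mm)
        else if (is.matrix(lesion)) stop("supply voxel_size_mm for a bare voxel matrix")
        else lesion$voxel_size_mm
  if (mode == "3d") return(.caliper(vox, vs))
  plane_axes <- setdiff(1:3, slice_axis)
  best <- 0
  for (s in unique(vox[, slice_axis])) {
    sl <- vox[vox[, slice_axis] == s, plane_axes, drop = FALSE]
    best <- max(best, .caliper(sl, vs[plane_axes]))
  }
  best
}

# voxels of a set missing at least one axis neighbour; the caliper maximum
# is always attained between two such voxels
.boundary_voxels <- function(vox) {
  d <- ncol(vox)
  rng <- apply(vox, 2, max) + 1L
  key <- function(v) {
    k <- v[, 1]
    mult <- 1
    for (a in seq_len(d - 1)) {
      mult <- mult * (rng[a] + 1L)
      k <- k + v[, a + 1] * mult
    }
    k
  }
  keys <- key(vox)
  interior <- rep(TRUE, nrow(vox))
  for (a in seq_len(d)) for (s in c(-1L, 1L)) {
    nb <- vox
    nb[, a] <- nb[, a] + s
    interior <- interior & (key(nb) %in% keys)
  }
  vox[!interior, , drop = FALSE]
}

.caliper <- function(vox, vs) {
  vox <- unique(vox)
  diag1 <- sqrt(sum(vs^2))          # single-voxel diagonal floor
  if (nrow(vox) == 1L) return(diag1)
  b <- if (nrow(vox) > 64L) .boundary_voxels(vox) else vox
  C <- sweep(b, 2L, vs, "*")
  D <- as.matrix(stats::dist(C))
  A <- matrix(0, nrow(C), nrow(C))
  for (k in seq_len(ncol(C)))
    A <- A + abs(outer(C[, k], C[, k], "-")) * vs[k]
  m <- D + A / D
  m[!is.finite(m)] <- 0             # the zero-distance diagonal
  max(diag1, max(m))
}

#' Nested radiological definition flags for one lesion
#'
#' Liberal: any FLAIR-surviving voxel. Traditional: Liberal and a greatest
#' dimension of at least `min_dimension_mm` (default 3 mm, inclusive).
#' Restrictive: Traditional and at least one voxel surviving the T1 upper
#' threshold (a corresponding T1 hypo-intensity). The three flags are nested
#' by construction.
#'
#' @param lesion a `lesion_mask` from [extract_lesion_masks()].
#' @param voxel_size_mm spacing override.
#' @param min_dimension_mm minimum greatest dimension for the Traditional
#'   criterion (default 3).
#' @param mode,slice_axis passed to [greatest_dimension()].
#' @return class `definition_flags`: `liberal`, `traditional`, `restrictive`,
#'   `greatest_dimension_mm`.
#' @export
classify_definitions <- function(lesion, voxel_size_mm = NULL,
                                 min_dimension_mm = 3,
                                 mode = c("coronal", "3d"), slice_axis = 3L) {
  mode <- match.arg(mode)
  liberal <- isTRUE(lesion$survived) && lesion$n_flair_voxels >= 1L
  gd <- if (liberal)
    greatest_dimension(lesion, voxel_size_mm, mode = mode,
                       slice_axis = slice_axis) else NA_real_
  traditional <- liberal && gd >= min_dimension_mm
  restrictive <- traditional && lesion$n_t1_voxels >= 1L
  structure(list(liberal = liberal, traditional = traditional,
                 restrictive = restrictive, greatest_dimension_mm = gd),
            class = "definition_flags")
}

#' Abnormal lesion burden for age (per-decade rule)
#'
#' One lesion per decade of life is considered normal; the current, partially
#' elapsed decade counts, so `decades = floor(age/10) + 1` and the burden is
#' abnormal when `n_lesions > decades`.
#'
#' @param n_lesions non-negative lesion count (vectorised).
#' @param age_years non-negative age (vectorised).
#' @param decades_fn rule mapping age to allowed lesions; default
#'   `floor(age/10) + 1`.
#' @return logical.
#' @export
per_decade_abnormal <- function(n_lesions, age_years,
                                decades_fn = function(age) floor(age / 10) + 1) {
  if (any(n_lesions < 0) || any(age_years < 0))
    stop("per_decade_abnormal: counts and ages must be non-negative")
  n_lesions > decades_fn(age_years)
}

#' Aggregate lesions into a per-subject profile
#'
#' Computes per-definition lesion counts, volumes (Restrictive volume uses
#' the T1-surviving voxels, the subset the Restrictive criterion actually
#' retains), presence and per-decade burden flags, regional assignments
#' (when a parcellation is supplied) and cognitive impairment
#' (any of IQ/WMI/PSI below 70).
#'
#' @param lesions list of `lesion_mask` objects for one subject.
#' @param demographics list or one-row data.frame; recognised fields:
#'   `subject_id`, `group`, `age_years`, `sex`, `spo2`, `hemoglobin`,
#'   `education_decile`, `icv_mm3`.
#' @param cognition named numeric with `iq`, `wmi`, `psi` (optional).
#' @param parcellation optional `sci_parcellation` for regional columns.
#' @param min_dimension_mm,mode,slice_axis passed to [classify_definitions()].
#' @return class `sci_subject_profile`: scalars per definition
#'   (`n_lesions`, `volume_mm3`, `n_voxels`, `presence`,
#'   `per_decade_abnormal`) plus a per-lesion `lesion_table`.
#' @export
aggregate_subject <- function(lesions, demographics = list(),
                              cognition = c(iq = NA, wmi = NA, psi = NA),
                              parcellation = NULL, min_dimension_mm = 3,
                              mode = "coronal", slice_axis = 3L) {
  if (anyDuplicated(vapply(lesions, `[[`, 1, "lesion_id")))
    stop("aggregate_subject: duplicate lesion_ids")
  defs <- c("L", "T", "R")
  rows <- lapply(lesions, function(ls) {
    fl <- classify_definitions(ls, min_dimension_mm = min_dimension_mm,
                               mode = mode, slice_axis = slice_axis)
    region <- NA_character_; tie <- NA
    rv <- c(periventricular = NA_real_, deep = NA_real_, `juxta-cortical` = NA_real_)
    rvt <- rv
    if (!is.null(parcellation) && ls$n_flair_voxels >= 1L) {
      a <- assign_region(ls, parcellation)
      region <- a$region; tie <- a$tie
      rv <- regional_volumes(ls, parcellation, "flair")
      rvt <- regional_volumes(ls, parcellation, "t1")
    }
    data.frame(lesion_id = ls$lesion_id, roi_id = ls$roi_id, lobe = ls$lobe,
               n_flair_voxels = ls$n_flair_voxels,
               n_t1_voxels = ls$n_t1_voxels,
               volume_mm3 = ls$volume_mm3, t1_volume_mm3 = ls$t1_volume_mm3,
               greatest_dimension_mm = fl$greatest_dimension_mm,
               L = fl$liberal, T = fl$traditional, R = fl$restrictive,
               region = region, tie = tie,
               pv_flair_mm3 = rv[[1]], deep_flair_mm3 = rv[[2]],
               jc_flair_mm3 = rv[[3]],
               pv_t1_mm3 = rvt[[1]], deep_t1_mm3 = rvt[[2]],
               jc_t1_mm3 = rvt[[3]],
               stringsAsFactors = FALSE)
  })
  lt <- if (length(rows)) do.call(rbind, rows) else
    data.frame(lesion_id = integer(0))
  n_lesions <- c(L = 0L, T = 0L, R = 0L)
  vol <- c(L = 0, T = 0, R = 0)
  nvox <- c(L = 0L, T = 0L, R = 0L)
  if (nrow(lt)) {
    for (d in defs) {
      sel <- lt[[d]]
      n_lesions[d] <- sum(sel)
      if (d == "R") {
        vol[d] <- sum(lt$t1_volume_mm3[sel])
        nvox[d] <- sum(lt$n_t1_voxels[sel])
      } else {
        vol[d] <- sum(lt$volume_mm3[sel])
        nvox[d] <- sum(lt$n_flair_voxels[sel])
      }
    }
  }
  demo <- as.list(demographics)
  age <- demo$age_years
  pda <- if (!is.null(age) && is.finite(age))
    setNames(per_decade_abnormal(as.numeric(n_lesions), rep(age, 3)), defs)
  else setNames(rep(NA, 3), defs)
  cg <- as.list(cognition)
  impaired <- if (all(c("iq", "wmi", "psi") %in% names(cg)) &&
                  all(is.finite(unlist(cg[c("iq", "wmi", "psi")]))))
    min(cg$iq, cg$wmi, cg$psi) < 70 else NA
  structure(list(subject_id = demo$subject_id %||% NA,
                 group = demo$group %||% NA_character_,
                 demographics = demo, cognition = cg, impaired = impaired,
                 n_lesions = n_lesions, volume_mm3 = vol, n_voxels = nvox,
                 presence = n_lesions >= 1L, per_decade_abnormal = pda,
                 lesion_table = lt),
            class = "sci_subject_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sci_subject_profile <- function(x, ...) {
  cat("<sci_subject_profile>", if (!is.na(x$subject_id)) x$subject_id else "",
      "\n")
  m <- rbind(n_lesions = x$n_lesions, volume_mm3 = round(x$volume_mm3, 2),
             presence = x$presence, per_decade_abnormal = x$per_decade_abnormal)
  colnames(m) <- c("Liberal", "Traditional", "Restrictive")
  print(m)
  if (!is.na(x$impaired))
    cat("cognitively impaired (<70):", x$impaired, "\n")
  invisible(x)
}
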