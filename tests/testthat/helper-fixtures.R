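# shared fixtures: small synthetic volumes built in code

# a tiny flat "subject": uniform cortex ring values so thresholds are exact
tiny_volumes <- function(dm = c(20L, 20L, 12L), vs = c(0.65, 0.65, 1.0),
                         cortex_flair = 100, cortex_t1 = 100,
                         wm_flair = 80, wm_t1 = 120) {
  flair <- array(wm_flair, dm)
  t1 <- array(wm_t1, dm)
  cortex <- array(FALSE, dm)
  cortex[1:2, , ] <- TRUE                      # a slab of "cortex"
  flair[cortex] <- cortex_flair
  t1[cortex] <- cortex_t1
  list(flair = volume_grid(flair, vs), t1 = volume_grid(t1, vs),
       cortex = cortex, dm = dm, vs = vs)
}

# label array with one box ROI
box_roi <- function(dm, lo, hi, label = 1L) {
  arr <- array(0L, dm)
  arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- label
  arr
}

# independent flood-fill connected components (oracle): repeated neighbour
# propagation over a logical array, intentionally different from the BFS in
# the package
flood_fill_components <- function(vox, dm, connectivity) {
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  ord <- rowSums(abs(offs))
  offs <- offs[switch(as.character(connectivity),
                      "6" = ord == 1, "18" = ord <= 2, "26" = ord <= 3), ,
               drop = FALSE]
  n <- nrow(vox)
  lab <- seq_len(n)  # start: every voxel its own label, then minimise
  key <- (vox[, 3] - 1) * dm[1] * dm[2] + (vox[, 2] - 1) * dm[1] + vox[, 1]
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      nb <- sweep(offs, 2, as.integer(vox[i, ]), "+")
      nbk <- (nb[, 3] - 1) * dm[1] * dm[2] + (nb[, 2] - 1) * dm[1] + nb[, 1]
      hit <- match(nbk, key)
      hit <- hit[!is.na(hit)]
      if (length(hit)) {
        mn <- min(lab[i], lab[hit])
        if (any(c(lab[i], lab[hit]) != mn)) {
          lab[c(i, hit)] <- mn
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(lab, sort(unique(lab)))
}

# brute-force caliper oracle: plain double loop over ALL voxel pairs (no
# boundary reduction, no vectorisation): centre distance plus each end
# voxel's half-extent along the centre line; single voxel = its diagonal
brute_caliper <- function(vox, vs, mode = "3d", slice_axis = 3L) {
  measure <- function(v, s) {
    v <- unique(v)
    best <- sqrt(sum(s^2))
    n <- nrow(v)
    if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n) {
      dmm <- (v[i, ] - v[j, ]) * s
      D <- sqrt(sum(dmm^2))
      best <- max(best, D + sum(abs(dmm) / D * s))
    }
    best
  }
  if (mode == "3d") return(measure(vox, vs))
  pa <- setdiff(1:3, slice_axis)
  max(vapply(unique(vox[, slice_axis]), function(sl)
    measure(vox[vox[, slice_axis] == sl, pa, drop = FALSE], vs[pa]),
    numeric(1)))
}

# nested binary matrix from per-definition positive counts (L >= T >= R)
nested_matrix <- function(n, positives) {
  stopifnot(positives[1] >= positives[2], positives[2] >= positives[3])
  m <- matrix(0, n, 3)
  if (positives[3] > 0) m[seq_len(positives[3]), ] <- 1
  if (positives[2] > positives[3])
    m[(positives[3] + 1):positives[2], 1:2] <- 1
  if (positives[1] > positives[2])
    m[(positives[2] + 1):positives[1], 1] <- 1
  m
}

# cohort spec with equal cognition means across groups: isolates the lesion
# term so its rejection rate is a true type-I error rate
null_cohort_spec <- function(seed, n_sca = 106L, n_control = 48L,
                             lesion_effect = c(iq = 0, wmi = 0, psi = 0)) {
  eq <- list(mean = c(iq = 95, wmi = 95, psi = 95),
             sd = c(iq = 13, wmi = 13, psi = 13))
  cohort_spec(n_sca = n_sca, n_control = n_control,
              cognition_model = list(sca = eq, control = eq),
              lesion_effect = lesion_effect, seed = seed)
}

# one randomized recovery phantom: 4 lesions spanning size x T1 x region
recovery_phantom <- function(seed) {
  combos <- expand.grid(diam = c(2, 5), t1m = c(0.9, 1.2),
                        region = c("periventricular", "deep", "juxta-cortical"),
                        stringsAsFactors = FALSE)
  set.seed(seed)
  pick <- combos[sample.int(nrow(combos), 4), ]
  pick$lobe <- sample(c("frontal", "parietal", "temporal", "occipital"), 4)
  lesions <- lapply(seq_len(4), function(i)
    truth_lesion(pick$diam[i], 1.5, pick$t1m[i], pick$region[i], pick$lobe[i]))
  generate_phantom(phantom_spec(seed = seed), lesions)
}
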