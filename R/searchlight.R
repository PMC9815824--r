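#' Searchlight map of the emotional reinstatement contrast
#'
#' At every in-mask voxel, collects the voxels within a sphere of
#' `radius_mm` (Euclidean distance between voxel centers), computes the
#' chosen trial-level similarity measure per condition over those voxels,
#' and stores the contrast `z(aversive) - z(neutral)`. Spheres with fewer
#' than 2 usable voxels yield `NA` and are counted in a single warning.
#'
#' @param vol_init,vol_emo 4-D numeric arrays `[x, y, z, trial]` on a shared
#'   grid: trial t-maps for the initial and emotional phases.
#' @param meta Tibble with `pair_id` and `condition`, one row per trial
#'   (shared trial order for both volumes).
#' @param mask 3-D logical/numeric array; nonzero voxels are analysed.
#' @param radius_mm Sphere radius in millimetres (`>=` voxel size).
#' @param voxel_size_mm Voxel edge lengths in mm (length 1 or 3).
#' @param measure Similarity measure passed to [trial_measures()].
#' @param transform Fisher-transform ordering, as in [trial_measures()].
#' @return A `searchlight_map`: 3-D array of contrast values (`NA` outside
#'   the mask) with attributes `radius_mm`, `measure`, `n_skipped`.
#' @export
searchlight_map <- function(vol_init, vol_emo, meta, mask,
                            radius_mm = 6, voxel_size_mm = 2,
                            measure = "pair_specific",
                            transform = c("after_averaging",
                                          "before_averaging")) {
  transform <- match.arg(transform)
  dims <- dim(vol_init)[1:3]
  if (!identical(dim(vol_init)[1:3], dim(vol_emo)[1:3]) ||
      !identical(dims, dim(mask)[1:3])) {
    abort("`vol_init`, `vol_emo` and `mask` must share the same grid.")
  }
  n_trials <- dim(vol_init)[4]
  stopifnot(nrow(meta) == n_trials, dim(vol_emo)[4] == n_trials)
  vs <- if (length(voxel_size_mm) == 1) rep(voxel_size_mm, 3) else voxel_size_mm
  if (radius_mm < min(vs)) abort("`radius_mm` must be at least one voxel.")

  # Integer offsets whose physical center distance is within the radius.
  rng <- lapply(vs, function(s) seq(-floor(radius_mm / s), floor(radius_mm / s)))
  offs <- as.matrix(expand.grid(dx = rng[[1]], dy = rng[[2]], dz = rng[[3]]))
  keep <- sqrt(colSums((t(offs) * vs)^2)) <= radius_mm + 1e-9
  offs <- offs[keep, , drop = FALSE]

  mask_l <- array(as.logical(mask != 0), dims)
  centers <- which(mask_l, arr.ind = TRUE)
  flat_init <- matrix(vol_init, prod(dims), n_trials)
  flat_emo <- matrix(vol_emo, prod(dims), n_trials)

  out <- array(NA_real_, dims)
  n_skipped <- 0L
  meta <- tibble::as_tibble(meta)

  for (i in seq_len(nrow(centers))) {
    vox <- sweep(offs, 2, centers[i, ], "+")
    ok <- vox[, 1] >= 1 & vox[, 1] <= dims[1] &
      vox[, 2] >= 1 & vox[, 2] <= dims[2] &
      vox[, 3] >= 1 & vox[, 3] <= dims[3]
    vox <- vox[ok, , drop = FALSE]
    lin <- vox[, 1] + (vox[, 2] - 1) * dims[1] +
      (vox[, 3] - 1) * dims[1] * dims[2]
    lin <- lin[mask_l[lin]]
    if (length(lin) < 2) {
      n_skipped <- n_skipped + 1L
      next
    }
    si <- pattern_set(t(flat_init[lin, , drop = FALSE]), meta,
                      roi = "sphere", phase = "initial")
    se <- pattern_set(t(flat_emo[lin, , drop = FALSE]), meta,
                      roi = "sphere", phase = "emotional")
    tm <- tryCatch(
      trial_measures(si, se, measures = measure, transform = transform),
      error = function(e) NULL)
    if (is.null(tm)) {
      n_skipped <- n_skipped + 1L
      next
    }
    za <- tm$z[tm$condition == "aversive"]
    zn <- tm$z[tm$condition == "neutral"]
    out[centers[i, 1], centers[i, 2], centers[i, 3]] <- za - zn
  }

  if (n_skipped > 0) {
    warn(sprintf("%d searchlight center(s) had < 2 usable voxels; set to NA.",
                 n_skipped))
  }
  structure(out, radius_mm = radius_mm, measure = measure,
            n_skipped = n_skipped, class = c("searchlight_map", "array"))
}

#' @exportS3Method base::print
print.searchlight_map <- function(x, ...) {
  v <- x[!is.na(x)]
  cat(sprintf(
    "<searchlight_map: %s grid, radius %.1f mm, measure '%s', %d in-mask voxels>\n",
    paste(dim(x), collapse = "x"), attr(x, "radius_mm"),
    attr(x, "measure"), length(v)))
  if (length(v)) {
    cat(sprintf("  contrast range: [%.3f, %.3f], mean %.3f\n",
                min(v), max(v), mean(v)))
  }
  invisible(x)
}
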