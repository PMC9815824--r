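#' Write a trial design as a BIDS-style events table
#'
#' Writes `events.tsv` columns (`onset`, `duration`, `trial_type`,
#' `pair_id`, `condition`; onsets in seconds) plus a JSON sidecar recording
#' the TR, phase and total duration.
#'
#' @param design A `trial_design`.
#' @param path Output path ending in `.tsv` (sidecar written next to it).
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(design, path) {
  events <- tibble::as_tibble(design)
  out <- tibble::tibble(
    onset = events$onset, duration = events$duration,
    trial_type = events$event_kind, pair_id = events$pair_id,
    condition = events$condition
  )
  readr::write_tsv(out, path)
  sidecar <- sub("\\.tsv$", ".json", path)
  jsonlite::write_json(
    list(RepetitionTime = attr(design, "tr"),
         Phase = attr(design, "phase"),
         TotalDuration = attr(design, "total_duration"),
         VolumeIndexing = "0-based"),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a BIDS-style events table back into a trial design
#'
#' @param path Path to an events `.tsv` written by [write_events_tsv()].
#' @return A `trial_design` (attributes restored from the JSON sidecar when
#'   present).
#' @export
read_events_tsv <- function(path) {
  ev <- readr::read_tsv(path, show_col_types = FALSE)
  events <- tibble::tibble(
    # the first event kind of the file marks each trial's first event
    trial = cumsum(ev$trial_type == ev$trial_type[1]),
    onset = ev$onset, duration = ev$duration,
    event_kind = ev$trial_type, condition = ev$condition,
    pair_id = ev$pair_id
  )
  sidecar <- sub("\\.tsv$", ".json", path)
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  new_trial_design(
    events,
    phase = meta$Phase %||% NA_character_,
    tr = meta$RepetitionTime %||% NA_real_,
    total_duration = meta$TotalDuration %||%
      max(ev$onset + ev$duration)
  )
}

#' Write a pattern set as NIfTI plus a trial-metadata sidecar
#'
#' Stores the trial-by-voxel t-patterns as a 4-D NIfTI image (voxels along
#' the first axis, trials along the fourth) with a TSV sidecar of trial
#' metadata. Requires the optional \pkg{RNifti} package.
#'
#' @param set A [pattern_set()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_pattern_nifti <- function(set, path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    abort("Writing NIfTI requires the 'RNifti' package.")
  }
  stopifnot(inherits(set, "pattern_set"))
  arr <- array(t(set$patterns),
               dim = c(ncol(set$patterns), 1, 1, nrow(set$patterns)))
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  readr::write_tsv(set$meta, sub("\\.nii(\\.gz)?$", "_trials.tsv", path))
  invisible(path)
}

#' Write a searchlight contrast map as NIfTI
#'
#' @param map A `searchlight_map`.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_searchlight_nifti <- function(map, path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    abort("Writing NIfTI requires the 'RNifti' package.")
  }
  RNifti::writeNifti(RNifti::asNifti(array(unclass(map), dim = dim(map))),
                     path)
  invisible(path)
}

#' Read an ROI mask from NIfTI
#'
#' Nonzero voxels are in-ROI. Requires \pkg{RNifti}.
#'
#' @param path Path to a NIfTI mask.
#' @return Logical 3-D array.
#' @export
read_mask_nifti <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    abort("Reading NIfTI requires the 'RNifti' package.")
  }
  img <- RNifti::readNifti(path)
  array(as.array(img) != 0, dim = dim(img)[1:3])
}
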