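#' Labelled segmentation volume
#'
#' A 3-D integer label volume (slices x rows x cols) in which each non-zero
#' label identifies one muscle or the femur. Slice 1 of the array is the most
#' distal slice (slice index 0 in measurement terms).
#'
#' @param voxels 3-D integer array, slices x rows x cols, labels >= 0.
#' @param geometry A [voxel_geometry()].
#' @param label_table Named character vector mapping label integers (names)
#'   to structure identifiers (muscle codes or `"FEMUR"`).
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(voxels, geometry, label_table) {
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3-D array")
  if (any(voxels < 0)) stop("labels must be non-negative integers")
  present <- setdiff(unique(as.vector(voxels)), 0)
  known <- as.integer(names(label_table))
  missing <- setdiff(present, known)
  if (length(missing) > 0L) {
    stop("labels present in volume but absent from label_table: ",
         paste(missing, collapse = ", "))
  }
  structure(
    list(voxels = voxels, geometry = geometry,
         label_table = label_table),
    class = "label_volume"
  )
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("label volume: %d slices x %d x %d, %d labelled structures\n",
              d[1], d[2], d[3], length(x$label_table)))
  invisible(x)
}

#' ACSA of a binary mask slice
#'
#' The anatomical cross-sectional area of a single segmented slice: pixel
#' count times in-plane pixel area, converted from mm^2 to cm^2.
#'
#' @param mask_slice 2-D logical (or 0/1) matrix.
#' @param geometry A [voxel_geometry()].
#' @return Area in cm^2 (>= 0).
#' @export
#' @examples
#' m <- matrix(FALSE, 100, 100); m[1:50, 1:40] <- TRUE
#' compute_slice_acsa(m, voxel_geometry(dx = 1, dy = 1))  # 20 cm^2
compute_slice_acsa <- function(mask_slice, geometry) {
  if (!inherits(geometry, "voxel_geometry")) stop("geometry must be a voxel_geometry")
  if (length(dim(mask_slice)) != 2L) stop("mask_slice must be a 2-D grid")
  if (is.logical(mask_slice)) {
    n <- sum(mask_slice)
  } else {
    if (any(!mask_slice %in% c(0, 1))) stop("mask_slice must be binary")
    n <- sum(mask_slice != 0)
  }
  n * geometry$dx * geometry$dy / 100  # mm^2 -> cm^2
}

#' Extract per-muscle ACSA profiles from a label volume
#'
#' For each muscle present, measures the ACSA on every `sampling_stride`-th
#' slice between the muscle's first and last occupied slice, starting at its
#' most distal occupied slice. Slices outside a muscle's extent are absent
#' from its profile, not recorded as zero.
#'
#' @param volume A [label_volume()].
#' @param sampling_stride Integer >= 1; the segmentation protocol this
#'   pipeline mirrors outlines every third slice (stride 3, the default).
#' @return A list of [muscle_profile()] objects, named by muscle.
#' @export
extract_profiles <- function(volume, sampling_stride = 3L) {
  stopifnot(inherits(volume, "label_volume"))
  if (sampling_stride < 1) stop("sampling_stride must be >= 1")
  sampling_stride <- as.integer(sampling_stride)
  labs <- volume$label_table
  muscle_labels <- labs[labs != FEMUR_LABEL]
  out <- list()
  for (i in seq_along(muscle_labels)) {
    lab <- as.integer(names(muscle_labels)[i])
    muscle <- unname(muscle_labels[i])
    counts <- apply(volume$voxels == lab, 1L, sum)
    occupied <- which(counts > 0L)
    if (length(occupied) == 0L) next
    first <- min(occupied); last <- max(occupied)
    sampled <- seq.int(first, last, by = sampling_stride)
    sampled <- sampled[counts[sampled] > 0L]  # inner gaps stay absent
    acsa <- counts[sampled] * volume$geometry$dx * volume$geometry$dy / 100
    out[[muscle]] <- muscle_profile(muscle, sampled - 1L, acsa)
  }
  out
}

#' Femur length from a label volume
#'
#' Distance between the centres of the most proximal and most distal slices
#' in which the femur is apparent: (slices spanned - 1) x slice pitch.
#'
#' @param volume A [label_volume()].
#' @return Length in mm. A femur confined to a single slice yields 0 mm with
#'   a warning.
#' @export
measure_femur_length <- function(volume) {
  stopifnot(inherits(volume, "label_volume"))
  labs <- volume$label_table
  fem <- as.integer(names(labs)[labs == FEMUR_LABEL])
  if (length(fem) != 1L) stop("missing structure: no FEMUR label in label_table")
  counts <- apply(volume$voxels == fem[1], 1L, sum)
  occupied <- which(counts > 0L)
  if (length(occupied) == 0L) stop("missing structure: femur not present in volume")
  span <- max(occupied) - min(occupied)
  if (span == 0L) warning("femur apparent in a single slice; femur length is 0 mm")
  span * slice_pitch(volume$geometry)
}

#' Femur landmark slice indices
#'
#' @param volume A [label_volume()].
#' @return Named integer vector `c(distal = ..., proximal = ...)` of 0-based
#'   slice indices bounding the femur.
#' @export
femur_landmarks <- function(volume) {
  labs <- volume$label_table
  fem <- as.integer(names(labs)[labs == FEMUR_LABEL])
  if (length(fem) != 1L) stop("missing structure: no FEMUR label in label_table")
  counts <- apply(volume$voxels == fem[1], 1L, sum)
  occupied <- which(counts > 0L)
  if (length(occupied) == 0L) stop("missing structure: femur not present in volume")
  c(distal = min(occupied) - 1L, proximal = max(occupied) - 1L)
}

#' Build a subject scan from a label volume
#'
#' Convenience wrapper: extracts profiles, measures femur length and bundles
#' them into a [subject_scan()].
#'
#' @inheritParams extract_profiles
#' @param subject_id,sex Subject metadata.
#' @return A [subject_scan()].
#' @export
scan_from_volume <- function(volume, subject_id, sex, sampling_stride = 3L) {
  profiles <- extract_profiles(volume, sampling_stride)
  fl <- measure_femur_length(volume)
  subject_scan(subject_id, sex, fl, profiles, volume$geometry)
}
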