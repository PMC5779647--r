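#' Per-slice ACSA profile of one muscle
#'
#' An ordered series of anatomical cross-sectional area (ACSA) measurements
#' along one muscle of one subject. Slice index 0 is the most distal slice of
#' the volume; indices increase proximally.
#'
#' @param muscle Muscle identifier (one of [all_muscles()]).
#' @param slice_index Integer vector of slice indices, strictly increasing.
#' @param acsa Numeric vector of areas in cm^2, same length, all >= 0, at
#'   least one > 0.
#' @return An object of class `muscle_profile`.
#' @export
#' @examples
#' muscle_profile("VL", c(0, 3, 6), c(10, 25, 18))
muscle_profile <- function(muscle, slice_index, acsa) {
  muscle_group_of(muscle)  # validates the identifier
  if (length(slice_index) != length(acsa)) {
    stop("slice_index and acsa must have equal length")
  }
  if (length(acsa) < 1L) stop("profile must contain at least one sample")
  if (any(!is.finite(acsa)) || any(acsa < 0)) {
    stop("ACSA values must be finite and non-negative")
  }
  if (any(diff(slice_index) <= 0)) stop("slice_index must be strictly increasing")
  if (!any(acsa > 0)) stop("degenerate profile: all ACSA values are zero")
  structure(
    list(muscle = muscle,
         slice_index = as.integer(slice_index),
         acsa = as.numeric(acsa)),
    class = "muscle_profile"
  )
}

#' @export
print.muscle_profile <- function(x, ...) {
  cat(sprintf("muscle profile %s: %d samples, slices %d..%d, peak %.2f cm^2\n",
              x$muscle, length(x$acsa), min(x$slice_index), max(x$slice_index),
              max(x$acsa)))
  invisible(x)
}

#' One subject's segmented thigh scan
#'
#' Bundles a subject's muscle profiles with the measured femur length, sex
#' and the voxel geometry the measurements came from.
#'
#' @param subject_id Character scalar.
#' @param sex `"male"` or `"female"`.
#' @param femur_length Femur length in mm (> 0); the distance between the
#'   most proximal and most distal slices containing femur.
#' @param profiles List of [muscle_profile()] objects, one per muscle, no
#'   duplicates.
#' @param geometry A [voxel_geometry()].
#' @return An object of class `subject_scan`.
#' @export
subject_scan <- function(subject_id, sex, femur_length, profiles,
                         geometry = voxel_geometry()) {
  sex <- match.arg(sex, c("male", "female"))
  if (!is.numeric(femur_length) || femur_length <= 0) {
    stop("femur_length must be a positive length in mm")
  }
  muscles <- vapply(profiles, function(p) p$muscle, character(1))
  if (anyDuplicated(muscles)) {
    stop("duplicate muscle profiles: ",
         paste(unique(muscles[duplicated(muscles)]), collapse = ", "))
  }
  names(profiles) <- muscles
  structure(
    list(subject_id = as.character(subject_id), sex = sex,
         femur_length = as.numeric(femur_length),
         profiles = profiles, geometry = geometry),
    class = "subject_scan"
  )
}

#' @export
print.subject_scan <- function(x, ...) {
  cat(sprintf("subject %s (%s): %d muscles, femur length %.0f mm\n",
              x$subject_id, x$sex, length(x$profiles), x$femur_length))
  invisible(x)
}
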