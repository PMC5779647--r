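#' Read a long-format measurement table
#'
#' The canonical on-disk intermediate is a UTF-8 CSV with one row per muscle
#' slice sample and columns `subject`, `sex`, `muscle`, `slice_index`,
#' `femur_length_mm`, `acsa_cm2`. Rows are validated (known muscle, ACSA >=
#' 0, positive femur length) and grouped into one [subject_scan()] per
#' subject.
#'
#' @param path Path to the CSV file.
#' @param geometry Voxel geometry to attach to the scans (provenance only;
#'   the table already carries areas in cm^2).
#' @return A named list of [subject_scan()] objects.
#' @export
read_measurement_table <- function(path, geometry = voxel_geometry()) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject", "sex", "muscle", "slice_index",
                "femur_length_mm", "acsa_cm2")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    stop("measurement table missing column(s): ", paste(missing, collapse = ", "))
  }
  measurement_table_to_scans(tab, geometry)
}

#' Convert a measurement data.frame to subject scans
#'
#' @param tab data.frame with the canonical measurement columns.
#' @inheritParams read_measurement_table
#' @return A named list of [subject_scan()] objects.
#' @export
measurement_table_to_scans <- function(tab, geometry = voxel_geometry()) {
  bad_muscle <- which(!tab$muscle %in% all_muscles())
  if (length(bad_muscle) > 0L) {
    stop("row ", bad_muscle[1], ": unknown muscle name '", tab$muscle[bad_muscle[1]], "'")
  }
  bad_acsa <- which(!is.finite(tab$acsa_cm2) | tab$acsa_cm2 < 0)
  if (length(bad_acsa) > 0L) {
    stop("row ", bad_acsa[1], ": negative or missing acsa_cm2")
  }
  bad_fl <- which(!is.finite(tab$femur_length_mm) | tab$femur_length_mm <= 0)
  if (length(bad_fl) > 0L) {
    stop("row ", bad_fl[1], ": missing or non-positive femur_length_mm")
  }
  scans <- lapply(split(tab, tab$subject), function(st) {
    sex <- unique(st$sex)
    fl <- unique(st$femur_length_mm)
    if (length(sex) != 1L) stop("subject ", st$subject[1], ": inconsistent sex")
    if (length(fl) != 1L) stop("subject ", st$subject[1], ": inconsistent femur length")
    st$muscle <- factor(st$muscle, levels = unique(st$muscle))
    profiles <- lapply(split(st, st$muscle), function(sm) {
      sm$muscle <- as.character(sm$muscle)
      sm <- sm[order(sm$slice_index), , drop = FALSE]
      muscle_profile(sm$muscle[1], sm$slice_index, sm$acsa_cm2)
    })
    subject_scan(st$subject[1], sex, fl, unname(profiles), geometry)
  })
  # keep input order of first appearance
  scans[unique(tab$subject)]
}

#' Flatten subject scans to a measurement data.frame
#'
#' @param scans List of [subject_scan()] objects.
#' @return data.frame with the canonical measurement columns.
#' @export
scans_to_measurement_table <- function(scans) {
  rows <- lapply(scans, function(sc) {
    do.call(rbind, lapply(sc$profiles, function(p) {
      data.frame(subject = sc$subject_id, sex = sc$sex, muscle = p$muscle,
                 slice_index = p$slice_index,
                 femur_length_mm = sc$femur_length,
                 acsa_cm2 = p$acsa, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a measurement table
#'
#' Serializes scans to the canonical CSV at full double precision, so that
#' `read_measurement_table(write_measurement_table(scans, f))` reproduces the
#' scans exactly.
#'
#' @param scans List of [subject_scan()] objects (or a measurement
#'   data.frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurement_table <- function(scans, path) {
  tab <- if (is.data.frame(scans)) scans else scans_to_measurement_table(scans)
  tab$femur_length_mm <- sprintf("%.17g", tab$femur_length_mm)
  tab$acsa_cm2 <- sprintf("%.17g", tab$acsa_cm2)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a NIfTI label volume with a label sidecar
#'
#' Loads a `.nii`/`.nii.gz` label image and a YAML or JSON sidecar mapping
#' label integers to structure names, and assembles a [label_volume()]. The
#' voxel geometry is taken from the NIfTI header (pixdim), with the first
#' array dimension treated as rows, second as columns and third as slices
#' (distal first); the array is permuted to the package's slices x rows x
#' cols convention.
#'
#' @param nifti_path Path to the label image.
#' @param labels_path Path to the sidecar (`.yaml`/`.yml`/`.json`), a map
#'   `{label_int: structure_name}`.
#' @return A [label_volume()].
#' @export
read_label_volume <- function(nifti_path, labels_path) {
  img <- RNifti::readNifti(nifti_path)
  pd <- RNifti::pixdim(img)
  geometry <- voxel_geometry(dx = pd[1], dy = pd[2], slice_thickness = pd[3])
  arr <- aperm(as.array(img), c(3L, 1L, 2L))
  label_volume(arr, geometry, read_label_table(labels_path))
}

read_label_table <- function(path) {
  tab <- yaml::read_yaml(path)  # yaml is a JSON superset
  out <- vapply(tab, as.character, character(1))
  names(out) <- names(tab)
  if (any(is.na(suppressWarnings(as.integer(names(out)))))) {
    stop("label sidecar keys must be integers")
  }
  out
}

#' Write a label volume as NIfTI plus YAML sidecar
#'
#' @param volume A [label_volume()].
#' @param nifti_path Output image path (`.nii` or `.nii.gz`).
#' @param labels_path Output YAML sidecar path.
#' @return `nifti_path`, invisibly.
#' @export
write_label_volume <- function(volume, nifti_path, labels_path) {
  arr <- aperm(volume$voxels, c(2L, 3L, 1L))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(volume$geometry$dx, volume$geometry$dy,
                           slice_pitch(volume$geometry))
  RNifti::writeNifti(img, nifti_path)
  lt <- as.list(volume$label_table)
  yaml::write_yaml(lt, labels_path)
  invisible(nifti_path)
}
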