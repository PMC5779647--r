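#' Voxel geometry of an axial MRI acquisition
#'
#' Records the in-plane pixel spacing, slice thickness and inter-slice gap of
#' the acquisition, all in millimetres. The defaults are the acquisition used
#' throughout the package's examples: 0.508 x 0.508 mm in-plane resolution,
#' 5 mm slices, no gap.
#'
#' @param dx,dy In-plane pixel spacing, mm/pixel. Must be > 0.
#' @param slice_thickness Slice thickness, mm. Must be > 0.
#' @param gap Inter-slice gap, mm. Must be >= 0.
#' @return An object of class `voxel_geometry`.
#' @export
#' @examples
#' voxel_geometry()
#' voxel_geometry(dx = 1, dy = 1, slice_thickness = 2)
voxel_geometry <- function(dx = 0.508, dy = 0.508, slice_thickness = 5, gap = 0) {
  for (v in list(dx = dx, dy = dy, slice_thickness = slice_thickness, gap = gap)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("voxel geometry fields must be finite scalars")
    }
  }
  if (dx <= 0 || dy <= 0 || slice_thickness <= 0) {
    stop("dx, dy and slice_thickness must be strictly positive")
  }
  if (gap < 0) stop("inter-slice gap must be non-negative")
  structure(
    list(dx = dx, dy = dy, slice_thickness = slice_thickness, gap = gap),
    class = "voxel_geometry"
  )
}

#' @export
print.voxel_geometry <- function(x, ...) {
  cat(sprintf("voxel geometry: %.4g x %.4g mm in-plane, %.4g mm slices, %.4g mm gap\n",
              x$dx, x$dy, x$slice_thickness, x$gap))
  invisible(x)
}

# distance between centres of adjacent slices, mm
slice_pitch <- function(geometry) geometry$slice_thickness + geometry$gap
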