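#' Normalize a profile to percent of ACSAmax
#'
#' @param acsa Numeric vector of ACSA samples (cm^2).
#' @param acsamax The muscle's ACSAmax (cm^2, > 0).
#' @return Values as percent of ACSAmax (0..100 when `acsamax` is the
#'   profile's own maximum).
#' @export
normalize_profile <- function(acsa, acsamax) {
  if (!is.finite(acsamax) || acsamax <= 0) {
    stop("degenerate profile: ACSAmax must be > 0")
  }
  acsa / acsamax * 100
}

#' Map slice indices to percent femur length
#'
#' Positions along the thigh are expressed relative to femur length: the
#' most distal femur slice is 0 %FL, the most proximal 100 %FL. Muscle
#' slices lying beyond the femur landmarks are clamped to the boundary with
#' a warning.
#'
#' @param slice_index Integer vector of slice indices.
#' @param femur_distal_index,femur_proximal_index Femur landmark slice
#'   indices; proximal must exceed distal.
#' @return Numeric vector of positions in \[0, 100\] %FL.
#' @export
#' @examples
#' map_positions(c(0, 40, 80), 0, 80)  # 0, 50, 100
map_positions <- function(slice_index, femur_distal_index, femur_proximal_index) {
  span <- femur_proximal_index - femur_distal_index
  if (!is.finite(span) || span <= 0) {
    stop("degenerate femur span: proximal index must exceed distal index")
  }
  pos <- (slice_index - femur_distal_index) / span * 100
  if (any(pos < 0) || any(pos > 100)) {
    warning("muscle extends beyond femur landmarks; ",
            sum(pos < 0 | pos > 100), " position(s) clamped to [0, 100] %FL")
    pos <- pmin(pmax(pos, 0), 100)
  }
  pos
}

#' Interpolate normalized samples onto a fixed %FL grid
#'
#' Linear interpolation of (%FL position, %ACSAmax value) samples at fixed
#' grid positions `0, step, ..., 100` %FL. Grid positions outside the
#' sampled extent are `NA` (absent): the curve is never extrapolated beyond
#' the muscle's measured extent.
#'
#' @param position Numeric vector of sample positions, %FL.
#' @param value Numeric vector of sample values, %ACSAmax.
#' @param step Grid step in %FL (default 5, giving 21 positions).
#' @return An object of class `distribution_grid`: list with `position`
#'   (grid), `value` (interpolated, `NA` = absent) and `step`.
#' @export
#' @examples
#' g <- interpolate_grid(c(40, 50), c(20, 40))
#' g$value[g$position == 45]  # 30
interpolate_grid <- function(position, value, step = 5) {
  keep <- !duplicated(position)
  if (sum(keep) < 2L) {
    stop("insufficient support: need >= 2 samples at distinct positions")
  }
  grid <- seq(0, 100, by = step)
  inside <- grid >= min(position) & grid <= max(position)
  out <- rep(NA_real_, length(grid))
  if (any(inside)) {
    out[inside] <- stats::approx(position, value, xout = grid[inside],
                                 method = "linear", ties = "ordered")$y
  }
  structure(list(position = grid, value = out, step = step),
            class = "distribution_grid")
}

#' @export
print.distribution_grid <- function(x, ...) {
  sup <- range(x$position[!is.na(x$value)])
  cat(sprintf("distribution grid: step %g %%FL, support %g-%g %%FL, peak %.1f %%\n",
              x$step, sup[1], sup[2], max(x$value, na.rm = TRUE)))
  invisible(x)
}

#' Normalized distribution grid for one muscle of one subject
#'
#' Chains normalization, position mapping and grid interpolation: the
#' muscle's per-slice ACSA is expressed as %ACSAmax against %FL and
#' interpolated every `step` %FL.
#'
#' @param profile A [muscle_profile()].
#' @param femur_distal_index,femur_proximal_index Femur landmark slice
#'   indices.
#' @param step Grid step, %FL.
#' @return A `distribution_grid`.
#' @export
profile_grid <- function(profile, femur_distal_index, femur_proximal_index,
                         step = 5) {
  amax <- acsamax(profile)$acsa
  pos <- map_positions(profile$slice_index, femur_distal_index,
                       femur_proximal_index)
  val <- normalize_profile(profile$acsa, amax)
  interpolate_grid(pos, val, step = step)
}

#' Distribution grids for a whole cohort
#'
#' Femur landmarks per subject are derived from femur length and slice
#' pitch, anchoring the distal landmark at the muscle coordinate origin
#' (slice 0 = most distal femur slice, the convention of the measurement
#' table).
#'
#' @param scans List of [subject_scan()] objects.
#' @param step Grid step, %FL.
#' @return data.frame with columns `subject`, `sex`, `muscle`, `position`,
#'   `value` (%ACSAmax, `NA` where the muscle does not span the position).
#' @export
cohort_grids <- function(scans, step = 5) {
  rows <- lapply(scans, function(sc) {
    prox <- round(sc$femur_length / slice_pitch(sc$geometry))
    per_muscle <- lapply(sc$profiles, function(p) {
      g <- profile_grid(p, 0, prox, step = step)
      data.frame(subject = sc$subject_id, sex = sc$sex, muscle = p$muscle,
                 position = g$position, value = g$value,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, per_muscle)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cohort mean distribution curve
#'
#' Position-wise mean and SD of the normalized curves over the subjects of
#' one sex that span each position; positions supported by fewer than
#' `min_n` subjects are flagged.
#'
#' @param grids data.frame as returned by [cohort_grids()], already filtered
#'   to one sex and one muscle (or pass `sex`/`muscle` to filter here).
#' @param sex,muscle Optional filters applied to `grids`.
#' @param min_n Minimum per-position subject count before flagging
#'   (default 2, the minimum for an SD).
#' @return data.frame with columns `position`, `mean`, `sd`, `n`,
#'   `low_support` (logical).
#' @export
cohort_mean_curve <- function(grids, sex = NULL, muscle = NULL, min_n = 2L) {
  if (!is.null(sex)) grids <- grids[grids$sex == sex, , drop = FALSE]
  if (!is.null(muscle)) grids <- grids[grids$muscle == muscle, , drop = FALSE]
  pos <- sort(unique(grids$position))
  out <- do.call(rbind, lapply(pos, function(p) {
    v <- grids$value[grids$position == p]
    v <- v[!is.na(v)]
    n <- length(v)
    data.frame(position = p,
               mean = if (n > 0) mean(v) else NA_real_,
               sd = if (n >= 2) stats::sd(v) else NA_real_,
               n = n, low_support = n < min_n)
  }))
  rownames(out) <- NULL
  out
}
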