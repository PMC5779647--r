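#' Longitudinal shape of a muscle along the femur
#'
#' Each muscle's normalized ACSA curve is modelled as a unimodal scaled-beta
#' bump on a support interval of %FL: zero at onset and offset, 1 at the
#' peak position, with a concentration parameter controlling width. These
#' shapes are illustrative anatomy (knee-extensor bulk near mid-thigh,
#' distal short-head and vastus medialis bulk, strap-like sartorius), not
#' fits to any measured curve.
#'
#' @param muscle Muscle identifier.
#' @param onset,offset Support interval in %FL, `0 <= onset < offset <= 100`.
#' @param peak_position %FL of the maximum, strictly inside the support.
#' @param concentration Positive shape parameter; larger = narrower bump.
#' @return Object of class `muscle_shape`.
#' @export
muscle_shape <- function(muscle, onset, offset, peak_position,
                         concentration = 4) {
  muscle_group_of(muscle)
  if (!(onset >= 0 && onset < peak_position && peak_position < offset &&
        offset <= 100)) {
    stop("need 0 <= onset < peak_position < offset <= 100")
  }
  if (concentration <= 0) stop("concentration must be > 0")
  structure(list(muscle = muscle, onset = onset, offset = offset,
                 peak_position = peak_position,
                 concentration = concentration),
            class = "muscle_shape")
}

#' Evaluate a muscle shape
#'
#' @param shape A [muscle_shape()].
#' @param position %FL positions.
#' @return Normalized ACSA fraction in \[0, 1\]; 0 outside the support, 1 at
#'   the peak position.
#' @export
shape_value <- function(shape, position) {
  x <- (position - shape$onset) / (shape$offset - shape$onset)
  m <- (shape$peak_position - shape$onset) / (shape$offset - shape$onset)
  a <- 1 + shape$concentration * m
  b <- 1 + shape$concentration * (1 - m)
  f <- ifelse(x > 0 & x < 1, x^(a - 1) * (1 - x)^(b - 1), 0)
  fmax <- m^(a - 1) * (1 - m)^(b - 1)
  f / fmax
}

#' Default shape set for the ten thigh muscles
#'
#' @return Named list of [muscle_shape()] objects.
#' @export
default_muscle_shapes <- function() {
  spec <- list(
    VM   = c(0,  75, 25),
    VI   = c(5,  95, 55),
    VL   = c(5,  95, 50),
    RF   = c(20, 100, 60),
    BFlh = c(10, 90, 50),
    BFsh = c(0,  60, 30),
    SM   = c(5,  80, 40),
    ST   = c(15, 95, 60),
    SA   = c(0, 100, 50),
    GR   = c(5, 100, 55)
  )
  shapes <- lapply(names(spec), function(m) {
    s <- spec[[m]]
    muscle_shape(m, s[1], s[2], s[3])
  })
  names(shapes) <- names(spec)
  shapes
}

#' Cohort simulation specification
#'
#' Defines the distributions a simulated cohort is drawn from. The defaults
#' reproduce the reference cohort: 32 males and 34 females with the
#' sex-specific per-muscle ACSAmax means and SDs of
#' [reference_cohort_stats()]. A shared multiplicative subject size factor
#' induces positive inter-muscle correlation; its variance is carved out of
#' each muscle's total coefficient of variation so that marginal means and
#' SDs still match the configured table.
#'
#' @param n_male,n_female Subjects per sex.
#' @param stats data.frame in the shape of [reference_cohort_stats()].
#' @param size_factor_sd SD of the shared subject size factor (as a fraction
#'   of the mean); must be below every configured muscle CV for the marginal
#'   SDs to be reproduced exactly (a larger value is accepted with a
#'   warning; the affected marginal SDs then shrink to `size_factor_sd`).
#' @param noise_sd Per-slice measurement noise SD, cm^2.
#' @param femur_mean,femur_sd Named vectors (`male`, `female`) of femur
#'   length mean/SD, mm.
#' @param shapes Named list of [muscle_shape()] objects.
#' @param sampling_stride Slice stride of the emulated segmentation
#'   protocol (default 3: every third 5-mm slice).
#' @param geometry A [voxel_geometry()].
#' @param acsa_floor Positivity floor for truncated draws, cm^2.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_male = 32L, n_female = 34L,
                        stats = reference_cohort_stats(),
                        size_factor_sd = 0.08,
                        noise_sd = 0.05,
                        femur_mean = c(male = 450, female = 420),
                        femur_sd = c(male = 20, female = 20),
                        shapes = default_muscle_shapes(),
                        sampling_stride = 3L,
                        geometry = voxel_geometry(),
                        acsa_floor = 0.1) {
  if (n_male < 0 || n_female < 0) stop("cohort sizes must be >= 0")
  if (any(stats$male_sd < 0) || any(stats$female_sd < 0)) stop("SDs must be >= 0")
  if (any(stats$male_mean <= 0) || any(stats$female_mean <= 0)) {
    stop("means must be > 0")
  }
  if (size_factor_sd < 0 || noise_sd < 0) stop("SDs must be >= 0")
  cvs <- c(stats$male_sd / stats$male_mean, stats$female_sd / stats$female_mean)
  if (size_factor_sd > min(cvs)) {
    warning("size_factor_sd exceeds the smallest configured muscle CV; ",
            "those marginal SDs will not be reproduced exactly")
  }
  missing_shape <- setdiff(stats$muscle, names(shapes))
  if (length(missing_shape) > 0L) {
    stop("no shape for muscle(s): ", paste(missing_shape, collapse = ", "))
  }
  structure(list(n_male = as.integer(n_male), n_female = as.integer(n_female),
                 stats = stats, size_factor_sd = size_factor_sd,
                 noise_sd = noise_sd, femur_mean = femur_mean,
                 femur_sd = femur_sd, shapes = shapes,
                 sampling_stride = as.integer(sampling_stride),
                 geometry = geometry, acsa_floor = acsa_floor),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(paste0("cohort spec: %d male / %d female, size-factor SD %.3g, ",
                     "noise SD %.3g cm^2, stride %d\n"),
              x$n_male, x$n_female, x$size_factor_sd, x$noise_sd,
              x$sampling_stride))
  invisible(x)
}

# truncation at the positivity floor via clamping; logs when triggered
clamp_floor <- function(x, floor) {
  hit <- x < floor
  if (any(hit)) {
    message(sum(hit), " draw(s) clamped at the positivity floor ", floor)
    x[hit] <- floor
  }
  x
}

#' Simulate one subject
#'
#' Per-muscle ACSAmax is a truncated sex-specific normal draw multiplied by
#' a shared subject size factor; the longitudinal profile is ACSAmax times
#' the muscle's shape, sampled on every `sampling_stride`-th 5-mm slice
#' within the muscle's support, plus measurement noise truncated at 0.
#'
#' @param spec A [cohort_spec()].
#' @param sex `"male"` or `"female"`.
#' @param subject_id Identifier for the scan.
#' @return A [subject_scan()].
#' @export
sample_subject <- function(spec, sex = c("male", "female"),
                           subject_id = "sim") {
  sex <- match.arg(sex)
  st <- spec$stats
  mu <- if (sex == "male") st$male_mean else st$female_mean
  sdv <- if (sex == "male") st$male_sd else st$female_sd
  cv <- sdv / mu
  resid_cv <- sqrt(pmax(cv^2 - spec$size_factor_sd^2, 0))
  size_factor <- 1 + stats::rnorm(1, 0, spec$size_factor_sd)
  size_factor <- max(size_factor, 0.5)  # guard against absurd negative bodies
  amax <- clamp_floor(mu * (1 + stats::rnorm(length(mu), 0, resid_cv)) *
                        size_factor,
                      spec$acsa_floor)
  fl <- max(stats::rnorm(1, spec$femur_mean[[sex]], spec$femur_sd[[sex]]), 100)
  pitch <- slice_pitch(spec$geometry)
  n_prox <- round(fl / pitch)          # proximal femur landmark slice index
  fl_measured <- n_prox * pitch        # femur length at slice-centre precision
  profiles <- list()
  for (i in seq_len(nrow(st))) {
    m <- st$muscle[i]
    shape <- spec$shapes[[m]]
    slices <- seq.int(0L, n_prox, by = spec$sampling_stride)
    pos <- slices / n_prox * 100
    inside <- pos >= shape$onset & pos <= shape$offset
    slices <- slices[inside]; pos <- pos[inside]
    vals <- amax[i] * shape_value(shape, pos)
    if (spec$noise_sd > 0) {
      vals <- pmax(vals + stats::rnorm(length(vals), 0, spec$noise_sd), 0)
    }
    if (!any(vals > 0)) {  # degenerate support; force the peak sample
      peak_slice <- round(shape$peak_position / 100 * n_prox)
      slices <- peak_slice; vals <- amax[i]
    }
    profiles[[m]] <- muscle_profile(m, slices, vals)
  }
  subject_scan(subject_id, sex, fl_measured, profiles, spec$geometry)
}

#' Simulate a full cohort
#'
#' Deterministic for a given seed. Returns the subject scans plus the
#' canonical long-format measurement table.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed for all randomness.
#' @return List of class `synthetic_cohort` with `scans` (list of
#'   [subject_scan()]), `table` (measurement data.frame) and `spec`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_spec(n_male = 3, n_female = 3), seed = 1)
#' head(coh$table)
generate_cohort <- function(spec = cohort_spec(), seed = 1L) {
  set.seed(seed)
  ids <- c(sprintf("M%02d", seq_len(spec$n_male)),
           sprintf("F%02d", seq_len(spec$n_female)))
  sexes <- c(rep("male", spec$n_male), rep("female", spec$n_female))
  scans <- mapply(function(id, sex) sample_subject(spec, sex, id),
                  ids, sexes, SIMPLIFY = FALSE)
  structure(list(scans = scans,
                 table = scans_to_measurement_table(scans),
                 spec = spec, seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d subjects (%d male / %d female), seed %d\n",
              length(x$scans), x$spec$n_male, x$spec$n_female, x$seed))
  invisible(x)
}

#' Rasterize a subject scan into a label volume
#'
#' Draws each muscle's per-slice target area as a filled ellipse at the
#' configured in-plane resolution, on non-overlapping lateral offsets, plus
#' a femur disk spanning the femur extent. Intended for validating the
#' mask-measurement path; areas are recovered up to the pixelation bound
#' (about one pixel area per boundary pixel).
#'
#' @param scan A [subject_scan()].
#' @param fov_px In-plane grid size in pixels (square).
#' @return A [label_volume()] whose label table maps 1..10 to the muscles
#'   (in [all_muscles()] order) and 99 to `"FEMUR"`.
#' @export
rasterize_scan <- function(scan, fov_px = 480L) {
  geom <- scan$geometry
  pitch <- slice_pitch(geom)
  n_slices <- round(scan$femur_length / pitch) + 1L
  max_slice <- max(vapply(scan$profiles, function(p) max(p$slice_index),
                          integer(1)), n_slices - 1L)
  vol <- array(0L, dim = c(max_slice + 1L, fov_px, fov_px))
  muscles <- names(scan$profiles)
  labels <- seq_along(muscles)
  names(labels) <- muscles
  # lay ellipse centres on a grid so muscles never overlap
  n_cols <- ceiling(sqrt(length(muscles) + 1))
  cell <- fov_px / n_cols
  centre <- function(k) {
    r <- (k - 1) %/% n_cols; c0 <- (k - 1) %% n_cols
    c(cell * (r + 0.5), cell * (c0 + 0.5))
  }
  xs <- matrix(rep(seq_len(fov_px), fov_px), fov_px, fov_px)
  ys <- t(xs)
  px_area_mm2 <- geom$dx * geom$dy
  for (k in seq_along(muscles)) {
    p <- scan$profiles[[muscles[k]]]
    ctr <- centre(k)
    for (j in seq_along(p$slice_index)) {
      area_mm2 <- p$acsa[j] * 100
      if (area_mm2 <= 0) next
      r_px <- sqrt(area_mm2 / (pi * px_area_mm2))
      if (2 * r_px > cell) {
        stop("muscle cross-section too large for the field of view; ",
             "increase fov_px")
      }
      disk <- (xs - ctr[1])^2 + (ys - ctr[2])^2 <= r_px^2
      sl <- p$slice_index[j] + 1L
      plane <- vol[sl, , ]
      plane[disk] <- labels[[muscles[k]]]
      vol[sl, , ] <- plane
    }
  }
  # femur: small disk in the last grid cell across the femur extent
  ctr <- centre(length(muscles) + 1)
  disk <- (xs - ctr[1])^2 + (ys - ctr[2])^2 <= (5 / geom$dx)^2
  for (sl in seq_len(n_slices)) {
    plane <- vol[sl, , ]
    plane[disk] <- 99L
    vol[sl, , ] <- plane
  }
  lt <- c(stats::setNames(muscles, labels), stats::setNames(FEMUR_LABEL, 99L))
  label_volume(vol, geom, lt)
}

#' Parameter-recovery report for a synthetic cohort
#'
#' Compares the analysed cohort against the generating specification: for
#' every configured per-sex per-muscle mean, the estimate, bias, and whether
#' the configured truth lies within estimate +/- 2 standard errors.
#'
#' @param spec The generating [cohort_spec()].
#' @param scans The cohort's subject scans (as analysed).
#' @return data.frame with columns `sex`, `muscle`, `truth`, `estimate`,
#'   `bias`, `se`, `covered`.
#' @export
recovery_report <- function(spec, scans) {
  morpho <- cohort_morphometry(scans)
  st <- spec$stats
  rows <- list()
  for (sex in c("male", "female")) {
    mu <- if (sex == "male") st$male_mean else st$female_mean
    for (i in seq_len(nrow(st))) {
      v <- morpho$value[morpho$sex == sex & morpho$quantity == st$muscle[i]]
      if (length(v) == 0L) next
      est <- mean(v)
      se <- if (length(v) >= 2) stats::sd(v) / sqrt(length(v)) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        sex = sex, muscle = st$muscle[i], truth = mu[i], estimate = est,
        bias = est - mu[i], se = se,
        covered = is.finite(se) && abs(est - mu[i]) <= 2 * se,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
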