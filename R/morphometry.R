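#' Maximal ACSA of a profile
#'
#' ACSAmax — the criterion measure of muscle size — is the largest sampled
#' ACSA along the muscle. Ties are broken toward the most distal slice
#' (lowest slice index); the argmax slice is reported for provenance only.
#'
#' @param profile A [muscle_profile()].
#' @return List with `acsa` (cm^2) and `slice_index`.
#' @export
#' @examples
#' acsamax(muscle_profile("VL", c(0, 3, 6), c(3, 9.5, 7.2)))
acsamax <- function(profile) {
  stopifnot(inherits(profile, "muscle_profile"))
  i <- which.max(profile$acsa)  # first occurrence = most distal under sorted slices
  list(acsa = profile$acsa[i], slice_index = profile$slice_index[i])
}

#' Summed group ACSAmax
#'
#' @param acsamax_by_muscle Named numeric vector of per-muscle ACSAmax
#'   values (cm^2).
#' @param group `"KE"` or `"KF"`.
#' @return Arithmetic sum over the group's member muscles, cm^2.
#' @export
#' @examples
#' group_total(c(VM = 24.3, VI = 26.2, VL = 29.2, RF = 13.9), "KE")  # 93.6
group_total <- function(acsamax_by_muscle, group = c("KE", "KF")) {
  group <- match.arg(group)
  members <- muscle_groups()[[group]]
  absent <- setdiff(members, names(acsamax_by_muscle))
  if (length(absent) > 0L) {
    stop("incomplete group ", group, ": missing ",
         paste(absent, collapse = ", "))
  }
  sum(acsamax_by_muscle[members])
}

#' KF:KE size ratio
#'
#' The summed knee-flexor ACSAmax divided by the summed knee-extensor
#' ACSAmax — a muscle-balance index analogous to the hamstrings/quadriceps
#' strength ratio.
#'
#' @param kf_total,ke_total Group totals in cm^2; `ke_total` must be > 0.
#' @return Dimensionless ratio.
#' @export
#' @examples
#' kf_ke_ratio(55.1, 93.6)  # 0.589
kf_ke_ratio <- function(kf_total, ke_total) {
  if (!is.finite(ke_total) || ke_total <= 0) {
    stop("KE total must be strictly positive")
  }
  kf_total / ke_total
}

#' Proportional size of a muscle within its group
#'
#' @param muscle_acsamax ACSAmax of the muscle, cm^2.
#' @param group_total Summed ACSAmax of the group the muscle belongs to
#'   (> 0), cm^2.
#' @return Percent of the group total.
#' @export
#' @examples
#' proportional_size(29.2, 93.6)  # 31.2 % (male VL share of KE)
proportional_size <- function(muscle_acsamax, group_total) {
  if (!is.finite(group_total) || group_total <= 0) stop("group total must be > 0")
  if (any(muscle_acsamax > group_total + 1e-9)) {
    stop("muscle ACSAmax exceeds its group total; is the muscle a group member?")
  }
  muscle_acsamax / group_total * 100
}

#' Sex difference as percent of the male mean
#'
#' @param male_mean,female_mean Group means; `male_mean` must be > 0.
#' @return `(male_mean - female_mean) / male_mean * 100`.
#' @export
#' @examples
#' sex_difference_pct(29.2, 24.5)  # 16.1 % smaller female VL
sex_difference_pct <- function(male_mean, female_mean) {
  if (any(!is.finite(male_mean)) || any(male_mean <= 0)) {
    stop("male mean must be strictly positive")
  }
  (male_mean - female_mean) / male_mean * 100
}

#' Fold difference between two sexual-dimorphism percentages
#'
#' @param diff_pct_a,diff_pct_b Sex-difference percentages; `diff_pct_b`
#'   must be > 0.
#' @return `diff_pct_a / diff_pct_b`.
#' @export
dimorphism_fold <- function(diff_pct_a, diff_pct_b) {
  if (any(!is.finite(diff_pct_b)) || any(diff_pct_b == 0)) {
    stop("denominator percentage must be non-zero")
  }
  diff_pct_a / diff_pct_b
}

#' Per-subject morphometry summary
#'
#' Computes, for one subject, the ACSAmax of every muscle, the KE and KF
#' group totals, the KF:KE ratio and each muscle's proportional size within
#' its own group (using that subject's own group total).
#'
#' @param scan A [subject_scan()] carrying all ten muscles.
#' @return An object of class `morphometry_summary`: list with `subject_id`,
#'   `sex`, `acsamax` (named vector, cm^2), `argmax_slice` (named vector),
#'   `group_total` (`c(KE=, KF=)`), `kf_ke_ratio`, and `proportional_size`
#'   (named vector, percent of own group).
#' @export
morphometry_summary <- function(scan) {
  stopifnot(inherits(scan, "subject_scan"))
  peaks <- lapply(scan$profiles, acsamax)
  amax <- vapply(peaks, `[[`, numeric(1), "acsa")
  aslice <- vapply(peaks, `[[`, numeric(1), "slice_index")
  totals <- c(KE = group_total(amax, "KE"), KF = group_total(amax, "KF"))
  prop <- vapply(names(amax), function(m) {
    proportional_size(amax[[m]], totals[[muscle_group_of(m)]])
  }, numeric(1))
  structure(
    list(subject_id = scan$subject_id, sex = scan$sex,
         acsamax = amax, argmax_slice = aslice,
         group_total = totals,
         kf_ke_ratio = kf_ke_ratio(totals[["KF"]], totals[["KE"]]),
         proportional_size = prop),
    class = "morphometry_summary"
  )
}

#' @export
print.morphometry_summary <- function(x, ...) {
  cat(sprintf("morphometry, subject %s (%s):\n", x$subject_id, x$sex))
  cat(sprintf("  KE total %.1f cm^2, KF total %.1f cm^2, KF:KE %.2f\n",
              x$group_total[["KE"]], x$group_total[["KF"]], x$kf_ke_ratio))
  invisible(x)
}

#' Cohort-wide per-subject morphometry table
#'
#' @param scans List of [subject_scan()] objects.
#' @return data.frame with one row per subject x quantity: columns
#'   `subject`, `sex`, `quantity` (muscle code, `KE_total`, `KF_total`,
#'   `KF_KE_ratio`, or `prop_<muscle>`), `value`.
#' @export
cohort_morphometry <- function(scans) {
  rows <- lapply(scans, function(sc) {
    s <- morphometry_summary(sc)
    q <- c(names(s$acsamax), "KE_total", "KF_total", "KF_KE_ratio",
           paste0("prop_", names(s$proportional_size)))
    v <- c(unname(s$acsamax), unname(s$group_total[c("KE", "KF")]),
           s$kf_ke_ratio, unname(s$proportional_size))
    data.frame(subject = s$subject_id, sex = s$sex, quantity = q, value = v,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
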