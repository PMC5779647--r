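#' Muscle group definitions
#'
#' The ten thigh muscles analysed by the pipeline, split into the knee
#' extensor (KE) and knee flexor (KF) groups. KE comprises the vastus
#' medialis (VM), vastus intermedius (VI), vastus lateralis (VL) and rectus
#' femoris (RF); KF comprises the two heads of biceps femoris (BFlh, BFsh),
#' semitendinosus (ST), semimembranosus (SM), sartorius (SA) and gracilis
#' (GR). Popliteus and the gastrocnemii are outside the analysis scope.
#'
#' @return A named list with character vectors `KE` and `KF`.
#' @export
#' @examples
#' muscle_groups()$KE
muscle_groups <- function() {
  list(
    KE = c("VM", "VI", "VL", "RF"),
    KF = c("BFlh", "BFsh", "ST", "SM", "SA", "GR")
  )
}

#' All recognised muscle identifiers
#'
#' @return Character vector of the ten muscle codes, KE first.
#' @export
all_muscles <- function() unlist(muscle_groups(), use.names = FALSE)

# label used for the femur in label volumes
FEMUR_LABEL <- "FEMUR"

#' Which group a muscle belongs to
#'
#' @param muscle Character vector of muscle codes.
#' @return Character vector of `"KE"`/`"KF"`.
#' @export
muscle_group_of <- function(muscle) {
  g <- muscle_groups()
  out <- ifelse(muscle %in% g$KE, "KE", ifelse(muscle %in% g$KF, "KF", NA_character_))
  if (anyNA(out)) {
    stop("unknown muscle identifier(s): ",
         paste(unique(muscle[is.na(out)]), collapse = ", "))
  }
  out
}

#' Published cohort reference statistics
#'
#' Sex-specific ACSAmax mean and SD (cm^2) for each of the ten thigh muscles
#' in a cohort of 32 untrained young males and 34 females, as used for the
#' synthetic-cohort generator defaults and for arithmetic identity checks on
#' group totals, the KF:KE ratio and proportional sizes.
#'
#' @return A data.frame with columns `muscle`, `group`, `male_mean`,
#'   `male_sd`, `female_mean`, `female_sd`; one row per muscle.
#' @export
#' @examples
#' ref <- reference_cohort_stats()
#' sum(ref$male_mean[ref$group == "KE"])  # 93.6 cm^2
reference_cohort_stats <- function() {
  data.frame(
    muscle      = c("VM", "VI", "VL", "RF", "BFsh", "BFlh", "SM", "ST", "SA", "GR"),
    group       = c("KE", "KE", "KE", "KE", "KF", "KF", "KF", "KF", "KF", "KF"),
    male_mean   = c(24.3, 26.2, 29.2, 13.9, 8.1, 12.9, 13.2, 11.5, 4.1, 5.2),
    male_sd     = c(3.2, 3.8, 3.9, 2.2, 3.1, 2.2, 2.8, 2.5, 0.6, 0.9),
    female_mean = c(18.2, 18.3, 24.5, 9.9, 5.2, 10.3, 10.3, 7.6, 2.3, 3.1),
    female_sd   = c(3.5, 3.6, 5.2, 2.0, 1.2, 2.1, 2.1, 2.0, 0.5, 0.8),
    stringsAsFactors = FALSE
  )
}

#' Reference cohort sample sizes
#'
#' @return Named integer vector `c(male = 32, female = 34)`.
#' @export
reference_cohort_n <- function() c(male = 32L, female = 34L)
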