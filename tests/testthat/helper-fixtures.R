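# shared fixture builders; everything is generated in code at test time

# minimal label volume: one muscle (VL, label 1) occupying given slices with
# a fixed rectangle of `npix` pixels, plus femur (label 99) spanning
# femur_slices. 1-based array slices; measurement slice indices are 0-based.
toy_volume <- function(muscle_slices = 1:9, femur_slices = 1:9, npix = 100,
                       geometry = voxel_geometry(dx = 1, dy = 1),
                       n_slices = max(muscle_slices, femur_slices)) {
  side <- ceiling(sqrt(npix))
  vol <- array(0L, dim = c(n_slices, 40, 40))
  rect <- matrix(0L, 40, 40)
  rect[seq_len(side), seq_len(side)][seq_len(npix)] <- 1L
  for (s in muscle_slices) vol[s, , ][rect == 1L] <- 1L
  fem <- matrix(0L, 40, 40)
  fem[30:33, 30:33] <- 1L
  for (s in femur_slices) {
    plane <- vol[s, , ]
    plane[fem == 1L] <- 99L
    vol[s, , ] <- plane
  }
  label_volume(vol, geometry, c("1" = "VL", "99" = "FEMUR"))
}

# deterministic hand-built subject with all ten muscles: triangular profiles
# peaking at `peak` cm^2 on slice index `peak_slice`
toy_scan <- function(subject_id = "S1", sex = "male", femur_length = 400,
                     peak_scale = 1) {
  muscles <- all_muscles()
  profiles <- lapply(seq_along(muscles), function(i) {
    peak <- (10 + i) * peak_scale
    slices <- seq(0L, 80L, by = 4L)
    mid <- 40
    vals <- peak * pmax(0, 1 - abs(slices - mid) / 44)
    muscle_profile(muscles[i], slices, vals)
  })
  subject_scan(subject_id, sex, femur_length, profiles)
}

# small two-sex cohort of hand-built scans with a deterministic sex gap
toy_cohort <- function(n_male = 3, n_female = 3) {
  males <- lapply(seq_len(n_male), function(i) {
    toy_scan(sprintf("M%d", i), "male", 400, peak_scale = 1 + 0.01 * i)
  })
  females <- lapply(seq_len(n_female), function(i) {
    toy_scan(sprintf("F%d", i), "female", 380, peak_scale = 0.8 + 0.01 * i)
  })
  c(males, females)
}

# reference stats with all SDs zeroed: fully deterministic generator
zero_sd_stats <- function() {
  st <- reference_cohort_stats()
  st$male_sd <- 0
  st$female_sd <- 0
  st
}

# brute-force two-point linear interpolation oracle (independent of approx)
interp_oracle <- function(xs, ys, x0) {
  if (x0 < min(xs) || x0 > max(xs)) return(NA_real_)
  i <- findInterval(x0, xs)
  if (xs[i] == x0) return(ys[i])
  ys[i] + (ys[i + 1] - ys[i]) * (x0 - xs[i]) / (xs[i + 1] - xs[i])
}

# hand step-down Holm oracle, independent of p.adjust
holm_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin((m - seq_len(m) + 1) * p[o], 1)
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- adj
  out
}

# hand pooled-variance two-sample t oracle
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = tt, df = df, p = 2 * pt(-abs(tt), df))
}
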