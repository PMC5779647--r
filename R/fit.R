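#' Fit the full thigh-morphometry analysis to a cohort
#'
#' The package's central entry point. From a cohort of segmented subject
#' scans it computes, in one pass:
#'
#' * per-subject ACSAmax of every muscle, KE/KF group totals, the KF:KE
#'   ratio and proportional sizes (each muscle as a percent of its own
#'   group's total);
#' * sex-group summaries (mean, SD, n) of every quantity, with independent
#'   t-tests, Holm-Bonferroni-adjusted p-values and Cohen's d;
#' * mixed two-way ANOVAs (sex x muscle on ACSAmax and on proportional
#'   size, sex x %FL position on each muscle's normalized curve);
#' * femur-length-normalized distribution grids, per-sex mean curves, and
#'   contiguous %FL regions of significant sex difference per muscle.
#'
#' Group means of the KF:KE ratio are means of per-subject ratios, not the
#' ratio of group means. Holm families follow the analysis question: all 10
#' muscles for ACSAmax, each muscle group separately for proportional
#' sizes, and the grid positions within each muscle for the region scan.
#'
#' @param scans A list of [subject_scan()] objects, a measurement
#'   data.frame (canonical long format), or a `synthetic_cohort`.
#' @param alpha Significance level for the region scan (default 0.05).
#' @param grid_step Distribution grid step in %FL (default 5).
#' @param t_variant `"pooled"` (default) or `"welch"`, see
#'   [independent_t()].
#' @param anova_design `"repeated"` (default) or `"between"`, see
#'   [two_way_anova()].
#' @return An object of class `thigh_morphometry`; see
#'   [summary.thigh_morphometry()].
#' @export
#' @examples
#' coh <- generate_cohort(cohort_spec(n_male = 6, n_female = 6), seed = 1)
#' fit <- thigh_morphometry(coh)
#' coef(fit)
thigh_morphometry <- function(scans, alpha = 0.05, grid_step = 5,
                              t_variant = c("pooled", "welch"),
                              anova_design = c("repeated", "between")) {
  t_variant <- match.arg(t_variant)
  anova_design <- match.arg(anova_design)
  if (inherits(scans, "synthetic_cohort")) scans <- scans$scans
  if (is.data.frame(scans)) scans <- measurement_table_to_scans(scans)
  sexes <- vapply(scans, function(s) s$sex, character(1))
  if (length(unique(sexes)) < 2L) {
    stop("need subjects of both sexes for the sex-comparison analysis")
  }
  morpho <- cohort_morphometry(scans)
  grids <- cohort_grids(scans, step = grid_step)

  contrasts <- sex_contrast_table(morpho, t_variant)
  anovas <- fit_anovas(morpho, grids, anova_design)
  muscles <- all_muscles()
  curves <- do.call(rbind, lapply(muscles, function(m) {
    do.call(rbind, lapply(c("male", "female"), function(sx) {
      cc <- cohort_mean_curve(grids, sex = sx, muscle = m)
      cbind(muscle = m, sex = sx, cc, stringsAsFactors = FALSE)
    }))
  }))
  regions <- lapply(muscles, function(m) {
    flfl_region_scan(grids, m, alpha = alpha, variant = t_variant)
  })
  names(regions) <- muscles

  structure(
    list(scans = scans, morphometry = morpho, grids = grids,
         contrasts = contrasts, anovas = anovas, curves = curves,
         regions = regions,
         settings = list(alpha = alpha, grid_step = grid_step,
                         t_variant = t_variant,
                         anova_design = anova_design)),
    class = "thigh_morphometry"
  )
}

# group summaries + t-tests + Holm + Cohen's d for every morphometric quantity
sex_contrast_table <- function(morpho, t_variant) {
  quantities <- unique(morpho$quantity)
  rows <- lapply(quantities, function(q) {
    vm <- morpho$value[morpho$quantity == q & morpho$sex == "male"]
    vf <- morpho$value[morpho$quantity == q & morpho$sex == "female"]
    tt <- independent_t(vm, vf, t_variant, label = q)
    es <- cohens_d(vm, vf)
    data.frame(quantity = q,
               male_mean = mean(vm), male_sd = stats::sd(vm), n_male = length(vm),
               female_mean = mean(vf), female_sd = stats::sd(vf),
               n_female = length(vf),
               t = tt$t, df = tt$df, p_raw = tt$p, cohens_d = es$d,
               pct_difference = if (mean(vm) > 0)
                 sex_difference_pct(mean(vm), mean(vf)) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # Holm families: the 10 absolute sizes; proportions within each group
  g <- muscle_groups()
  fam <- list(acsamax = out$quantity %in% all_muscles(),
              prop_KE = out$quantity %in% paste0("prop_", g$KE),
              prop_KF = out$quantity %in% paste0("prop_", g$KF))
  out$p_adj <- out$p_raw
  for (f in fam) out$p_adj[f] <- holm_bonferroni(out$p_raw[f])
  rownames(out) <- NULL
  out
}

fit_anovas <- function(morpho, grids, design) {
  size_long <- morpho[morpho$quantity %in% all_muscles(), ]
  names(size_long)[names(size_long) == "quantity"] <- "muscle"
  prop_long <- morpho[startsWith(morpho$quantity, "prop_"), ]
  prop_long$muscle <- sub("^prop_", "", prop_long$quantity)
  out <- list(
    acsamax = two_way_anova(size_long, within = "muscle", design = design),
    proportion = two_way_anova(prop_long, within = "muscle", design = design)
  )
  # sex x %FL per muscle, on positions spanned by every subject
  dist <- lapply(all_muscles(), function(m) {
    g <- grids[grids$muscle == m, ]
    keep <- !is.na(g$value)
    n_subj <- length(unique(g$subject))
    complete <- names(which(table(g$position[keep]) == n_subj))
    g <- g[keep & g$position %in% as.numeric(complete), ]
    if (length(unique(g$position)) < 2L) return(NULL)
    g$value <- g$value
    df <- data.frame(value = g$value, sex = g$sex, subject = g$subject,
                     position = g$position, stringsAsFactors = FALSE)
    two_way_anova(df, within = "position", design = design)
  })
  names(dist) <- all_muscles()
  out$distribution <- dist
  out
}

#' @export
print.thigh_morphometry <- function(x, ...) {
  n <- table(vapply(x$scans, function(s) s$sex, character(1)))
  cat(sprintf("thigh morphometry analysis: %d male, %d female subjects\n",
              n[["male"]], n[["female"]]))
  ct <- x$contrasts
  for (q in c("KE_total", "KF_total", "KF_KE_ratio")) {
    r <- ct[ct$quantity == q, ]
    fmt <- if (q == "KF_KE_ratio") "%.2f" else "%.1f"
    cat(sprintf(paste0("  %-12s male ", fmt, " +/- ", fmt,
                       ", female ", fmt, " +/- ", fmt, "  (p = %.3g, d = %.2f)\n"),
                q, r$male_mean, r$male_sd, r$female_mean, r$female_sd,
                r$p_adj, r$cohens_d))
  }
  invisible(x)
}

#' Summarize a thigh-morphometry fit
#'
#' @param object A [thigh_morphometry()] fit.
#' @param ... Unused.
#' @return An object of class `summary.thigh_morphometry` whose `$table`
#'   mirrors the conventional cohort table: one row per muscle plus the
#'   group totals and the KF:KE ratio, with per-sex mean/SD, adjusted p and
#'   Cohen's d (means/SDs at display rounding: 1 dp for areas and percents,
#'   2 dp for the ratio).
#' @export
summary.thigh_morphometry <- function(object, ...) {
  ct <- object$contrasts
  order_q <- c(muscle_groups()$KE, "KE_total", muscle_groups()$KF, "KF_total",
               "KF_KE_ratio")
  tab <- ct[match(order_q, ct$quantity), ]
  dp <- ifelse(tab$quantity == "KF_KE_ratio", 2L, 1L)
  tab_disp <- data.frame(
    quantity = tab$quantity,
    male = sprintf("%.*f +/- %.*f", dp, tab$male_mean, dp, tab$male_sd),
    female = sprintf("%.*f +/- %.*f", dp, tab$female_mean, dp, tab$female_sd),
    p = ifelse(tab$p_adj < 0.001, "<0.001", sprintf("%.3f", tab$p_adj)),
    d = sprintf("%.2f", tab$cohens_d),
    stringsAsFactors = FALSE
  )
  structure(list(table = tab_disp, contrasts = ct,
                 settings = object$settings,
                 regions = object$regions),
            class = "summary.thigh_morphometry")
}

#' @export
print.summary.thigh_morphometry <- function(x, ...) {
  cat("Sex comparison of thigh muscle ACSAmax (cm^2), totals and KF:KE ratio\n")
  print(x$table, row.names = FALSE)
  nreg <- sum(vapply(x$regions, function(r) nrow(r$regions), integer(1)))
  cat(sprintf("%d significant %%FL region(s) across muscles (alpha = %g)\n",
              nreg, x$settings$alpha))
  invisible(x)
}

#' Headline coefficients of a thigh-morphometry fit
#'
#' @param object A [thigh_morphometry()] fit.
#' @param ... Unused.
#' @return Named vector: per-sex KE and KF totals (cm^2) and mean KF:KE
#'   ratio (means of per-subject values).
#' @export
coef.thigh_morphometry <- function(object, ...) {
  ct <- object$contrasts
  pick <- function(q, col) ct[ct$quantity == q, col]
  c(male_KE_total = pick("KE_total", "male_mean"),
    female_KE_total = pick("KE_total", "female_mean"),
    male_KF_total = pick("KF_total", "male_mean"),
    female_KF_total = pick("KF_total", "female_mean"),
    male_KF_KE_ratio = pick("KF_KE_ratio", "male_mean"),
    female_KF_KE_ratio = pick("KF_KE_ratio", "female_mean"))
}

#' Plot per-sex mean distribution curves
#'
#' One panel per muscle: mean normalized ACSA (%ACSAmax) against %FL for
#' each sex, with significant sex-difference regions shaded.
#'
#' @param x A [thigh_morphometry()] fit.
#' @param muscles Muscles to draw (default all ten).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.thigh_morphometry <- function(x, muscles = all_muscles(), ...) {
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(muscles)),
                       mar = c(3.5, 3.5, 2, 0.5), mgp = c(2.2, 0.7, 0))
  on.exit(graphics::par(old))
  for (m in muscles) {
    cm <- x$curves[x$curves$muscle == m & x$curves$sex == "male", ]
    cf <- x$curves[x$curves$muscle == m & x$curves$sex == "female", ]
    graphics::plot(NA, xlim = c(0, 100), ylim = c(0, 105),
                   xlab = "%FL (distal 0, proximal 100)",
                   ylab = "%ACSAmax", main = m, ...)
    reg <- x$regions[[m]]$regions
    if (nrow(reg) > 0) {
      for (i in seq_len(nrow(reg))) {
        graphics::rect(reg$start[i], 0, reg$end[i], 105,
                       col = "grey90", border = NA)
      }
    }
    graphics::lines(cm$position, cm$mean, col = "black", lwd = 2)
    graphics::lines(cf$position, cf$mean, col = "grey40", lwd = 2, lty = 2)
  }
  invisible(x)
}

#' Simulate cohorts matching a fitted analysis
#'
#' Builds a [cohort_spec()] from the fit's per-sex per-muscle ACSAmax means
#' and SDs (and the observed cohort sizes) and draws new synthetic cohorts
#' from it.
#'
#' @param object A [thigh_morphometry()] fit.
#' @param nsim Number of cohorts.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A list of `synthetic_cohort` objects (length `nsim`).
#' @export
simulate.thigh_morphometry <- function(object, nsim = 1, seed = 1L, ...) {
  ct <- object$contrasts
  mu <- ct[match(all_muscles(), ct$quantity), ]
  stats_df <- data.frame(muscle = mu$quantity,
                         group = muscle_group_of(mu$quantity),
                         male_mean = mu$male_mean, male_sd = mu$male_sd,
                         female_mean = mu$female_mean, female_sd = mu$female_sd,
                         stringsAsFactors = FALSE)
  spec <- cohort_spec(n_male = mu$n_male[1], n_female = mu$n_female[1],
                      stats = stats_df)
  lapply(seq_len(nsim), function(i) generate_cohort(spec, seed = seed + i - 1L))
}
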