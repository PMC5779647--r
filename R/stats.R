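#' Independent-samples t-test
#'
#' Two-sided comparison of two independent groups. The default is the
#' classical pooled-variance Student's t (df = n1 + n2 - 2); Welch's
#' unequal-variance variant is available by flag.
#'
#' @param group_a,group_b Numeric vectors, each with >= 2 values.
#' @param variant `"pooled"` (default) or `"welch"`.
#' @param label Optional label carried into the result.
#' @return List of class `t_test_result` with `label`, `t`, `df`, `p`,
#'   `n` (`c(a, b)`), `mean` (`c(a, b)`), `variant`.
#' @export
independent_t <- function(group_a, group_b, variant = c("pooled", "welch"),
                          label = NULL) {
  variant <- match.arg(variant)
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("need at least 2 observations per group")
  }
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0 &&
      mean(group_a) == mean(group_b)) {
    stop("undefined statistic: zero variance in both groups with equal means")
  }
  ht <- stats::t.test(group_a, group_b, var.equal = (variant == "pooled"))
  structure(
    list(label = label, t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value, n = c(a = length(group_a), b = length(group_b)),
         mean = c(a = mean(group_a), b = mean(group_b)), variant = variant),
    class = "t_test_result"
  )
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("%st(%.4g) = %.3f, p = %.4g (%s)\n",
              if (is.null(x$label)) "" else paste0(x$label, ": "),
              x$df, x$t, x$p, x$variant))
  invisible(x)
}

#' Cohen's d for two independent groups
#'
#' Unsigned standardized mean difference with the classical (n-1)-weighted
#' pooled SD. Also usable directly from summary statistics.
#'
#' @param group_a,group_b Numeric vectors (>= 2 values each), or omit and
#'   supply summary statistics.
#' @param mean_a,mean_b,sd_a,sd_b,n_a,n_b Summary-statistic interface, used
#'   when `group_a` is missing.
#' @return List of class `effect_size` with `d` (>= 0) and `pooled_sd`.
#' @export
#' @examples
#' cohens_d(mean_a = 93.6, mean_b = 70.9, sd_a = 10.3, sd_b = 12.1,
#'          n_a = 32, n_b = 34)$d  # ~2.02
cohens_d <- function(group_a, group_b, mean_a, mean_b, sd_a, sd_b, n_a, n_b) {
  if (!missing(group_a)) {
    if (length(group_a) < 2L || length(group_b) < 2L) {
      stop("need at least 2 observations per group")
    }
    mean_a <- mean(group_a); mean_b <- mean(group_b)
    sd_a <- stats::sd(group_a); sd_b <- stats::sd(group_b)
    n_a <- length(group_a); n_b <- length(group_b)
  }
  pooled <- sqrt(((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2))
  if (pooled == 0) stop("undefined statistic: zero pooled SD")
  structure(list(d = abs(mean_a - mean_b) / pooled, pooled_sd = pooled),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("Cohen's d = %.2f (pooled SD %.3g)\n", x$d, x$pooled_sd))
  invisible(x)
}

#' Holm-Bonferroni step-down adjustment
#'
#' Step-down family-wise error correction of a vector of p-values, with
#' monotonicity enforcement; input order is preserved.
#'
#' @param p Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values, same order.
#' @export
#' @examples
#' holm_bonferroni(c(0.01, 0.04, 0.03))
holm_bonferroni <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "holm")
}

#' Two-way ANOVA with sex and a within-subject factor
#'
#' The default design treats the within-subject factor (muscle, or %FL
#' position) as a repeated measure: `aov(value ~ sex * within +
#' Error(subject))`, so sex is tested against between-subject variation and
#' the within factor and interaction against within-subject variation. A
#' purely between-cells variant (`aov(value ~ sex * within)`) is available
#' for sensitivity analysis. A within factor with a single level degrades to
#' the one-way between-sex ANOVA (whose F equals the pooled t squared).
#'
#' @param data data.frame with columns `value`, `sex`, `subject` and the
#'   within-factor column named by `within`.
#' @param within Name of the within-subject factor column.
#' @param design `"repeated"` (default) or `"between"`.
#' @return List of class `anova_result` with one row per effect in
#'   `$effects`: columns `effect`, `F`, `df1`, `df2`, `p`.
#' @export
two_way_anova <- function(data, within, design = c("repeated", "between")) {
  design <- match.arg(design)
  data$sex <- factor(data$sex)
  data$subject <- factor(data$subject)
  data$.w <- factor(data[[within]])
  if (nlevels(data$sex) < 2L) stop("need both sexes in the design")
  cell_n <- table(data$sex, data$.w)
  if (any(cell_n < 2L)) stop("design error: a sex x ", within, " cell has n < 2")
  extract <- function(sm, effects) {
    rows <- lapply(effects, function(e) {
      for (stratum in sm) {
        tab <- if (inherits(stratum, "summary.aov")) stratum[[1]] else stratum
        hit <- trimws(rownames(tab)) == e$term
        if (any(hit)) {
          res <- trimws(rownames(tab)) == "Residuals"
          return(data.frame(effect = e$name, F = tab[hit, "F value"],
                            df1 = tab[hit, "Df"], df2 = tab[res, "Df"],
                            p = tab[hit, "Pr(>F)"], stringsAsFactors = FALSE))
        }
      }
      NULL
    })
    do.call(rbind, rows)
  }
  if (nlevels(data$.w) < 2L) {
    fit <- stats::aov(value ~ sex, data = data)
    eff <- extract(list(summary(fit)[[1]]), list(list(term = "sex", name = "sex")))
  } else if (design == "repeated") {
    fit <- stats::aov(value ~ sex * .w + Error(subject), data = data)
    sm <- summary(fit)
    eff <- extract(sm, list(list(term = "sex", name = "sex"),
                            list(term = ".w", name = within),
                            list(term = "sex:.w", name = paste0("sex:", within))))
  } else {
    fit <- stats::aov(value ~ sex * .w, data = data)
    sm <- list(summary(fit)[[1]])
    eff <- extract(sm, list(list(term = "sex", name = "sex"),
                            list(term = ".w", name = within),
                            list(term = "sex:.w", name = paste0("sex:", within))))
  }
  rownames(eff) <- NULL
  structure(list(design = design, within = within, effects = eff),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("two-way ANOVA (sex x %s, %s design):\n", x$within, x$design))
  print(format(x$effects, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Significant sex-difference regions along the femur
#'
#' At every %FL grid position where both sexes have at least 2 subjects with
#' the muscle present, the normalized ACSA values are compared between the
#' sexes with an independent t-test; the position-wise p-values are
#' Holm-adjusted within the muscle, and maximal runs of adjacent significant
#' positions are merged into contiguous %FL intervals.
#'
#' @param grids data.frame as from [cohort_grids()] (both sexes).
#' @param muscle Muscle to scan.
#' @param alpha Significance level (default 0.05).
#' @param variant t-test variant, see [independent_t()].
#' @return List of class `significant_regions` with `muscle`, `regions`
#'   (data.frame `start`, `end` in %FL) and `positions` (per-position
#'   data.frame with `position`, `p_raw`, `p_adj`, `n_male`, `n_female`,
#'   `tested`).
#' @export
flfl_region_scan <- function(grids, muscle, alpha = 0.05,
                             variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  g <- grids[grids$muscle == muscle, , drop = FALSE]
  if (nrow(g) == 0L) stop("no grid rows for muscle ", muscle)
  pos <- sort(unique(g$position))
  per <- do.call(rbind, lapply(pos, function(p) {
    vm <- g$value[g$position == p & g$sex == "male"]
    vf <- g$value[g$position == p & g$sex == "female"]
    vm <- vm[!is.na(vm)]; vf <- vf[!is.na(vf)]
    tested <- length(vm) >= 2L && length(vf) >= 2L &&
      !(stats::var(vm) == 0 && stats::var(vf) == 0 && mean(vm) == mean(vf))
    data.frame(position = p,
               p_raw = if (tested) independent_t(vm, vf, variant)$p else NA_real_,
               n_male = length(vm), n_female = length(vf), tested = tested)
  }))
  per$p_adj <- NA_real_
  if (any(per$tested)) {
    per$p_adj[per$tested] <- holm_bonferroni(per$p_raw[per$tested])
  }
  sig <- !is.na(per$p_adj) & per$p_adj < alpha
  regions <- runs_to_intervals(per$position, sig)
  structure(list(muscle = muscle, alpha = alpha, regions = regions,
                 positions = per),
            class = "significant_regions")
}

# merge maximal runs of TRUE at adjacent grid positions into intervals
runs_to_intervals <- function(position, flag) {
  if (!any(flag)) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = position[starts[keep]], end = position[ends[keep]])
}

#' @export
print.significant_regions <- function(x, ...) {
  if (nrow(x$regions) == 0L) {
    cat(sprintf("%s: no significant sex-difference regions (alpha = %g)\n",
                x$muscle, x$alpha))
  } else {
    cat(sprintf("%s: %d significant region(s) (alpha = %g):\n",
                x$muscle, nrow(x$regions), x$alpha))
    for (i in seq_len(nrow(x$regions))) {
      cat(sprintf("  %g-%g %%FL\n", x$regions$start[i], x$regions$end[i]))
    }
  }
  invisible(x)
}
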