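#' Pipeline configuration
#'
#' All knobs of the end-to-end report pipeline, serializable to/from YAML.
#' Defaults mirror the protocol the package emulates: every-third-slice
#' sampling, a 5 %FL grid, alpha 0.05, pooled t-tests and the
#' repeated-measures ANOVA design.
#'
#' @param grid_step Distribution grid step, %FL.
#' @param alpha Significance level.
#' @param t_variant `"pooled"` or `"welch"`.
#' @param anova_design `"repeated"` or `"between"`.
#' @param sampling_stride Slice stride for mask extraction / simulation.
#' @param seed Integer seed funnelling all pipeline randomness.
#' @return Object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(grid_step = 5, alpha = 0.05,
                            t_variant = "pooled", anova_design = "repeated",
                            sampling_stride = 3L, seed = 1L) {
  cfg <- list(grid_step = grid_step, alpha = alpha,
              t_variant = match.arg(t_variant, c("pooled", "welch")),
              anova_design = match.arg(anova_design, c("repeated", "between")),
              sampling_stride = as.integer(sampling_stride),
              seed = as.integer(seed))
  if (cfg$alpha < 0 || cfg$alpha > 1) stop("alpha must lie in [0, 1]")
  if (cfg$grid_step <= 0 || cfg$grid_step > 100) stop("grid_step must be in (0, 100]")
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' Round-trip identity: `read_pipeline_config(write_pipeline_config(cfg, f))`
#' equals `cfg`.
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return The config (read) or `path` invisibly (write).
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the end-to-end report pipeline
#'
#' Validates and analyses a cohort and writes the full report bundle:
#'
#' * `table1.csv` — per-muscle and group sex comparison (means, SDs,
#'   adjusted p, Cohen's d), 10 muscle rows + 2 totals + 1 ratio row;
#' * `fig2_differences.csv` — per-muscle sex difference as % of male mean;
#' * `fig4_proportions.csv` — per-sex proportional sizes (mean, SD);
#' * `fig5_distribution.csv` — per-sex mean normalized curves
#'   (muscle x sex x position x mean x SD x n);
#' * `regions.txt` — significant %FL intervals, 3 columns (muscle,
#'   start%FL, end%FL);
#' * `stats.csv` — tidy table of every test performed;
#' * `run_log.txt` — configuration echo, config hash and exclusions.
#'
#' Subjects whose scans fail validation (e.g. incomplete muscle sets) are
#' excluded with a per-subject message in the log; the pipeline continues
#' on the valid subset.
#'
#' @param scans Cohort input: list of [subject_scan()], measurement
#'   data.frame, path to a measurement CSV, or `synthetic_cohort`.
#' @param out_dir Output directory (created if needed).
#' @param config A [pipeline_config()].
#' @return The [thigh_morphometry()] fit, invisibly; the bundle paths in
#'   attribute `"bundle"`.
#' @export
run_pipeline <- function(scans, out_dir, config = pipeline_config()) {
  if (is.character(scans) && length(scans) == 1L) {
    scans <- read_measurement_table(scans)
  }
  if (inherits(scans, "synthetic_cohort")) scans <- scans$scans
  if (is.data.frame(scans)) scans <- measurement_table_to_scans(scans)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  exclusions <- character(0)
  ok <- vapply(scans, function(sc) {
    err <- tryCatch({ morphometry_summary(sc); NULL },
                    error = function(e) conditionMessage(e))
    if (!is.null(err)) {
      exclusions <<- c(exclusions,
                       sprintf("subject %s excluded: %s", sc$subject_id, err))
      FALSE
    } else TRUE
  }, logical(1))
  scans <- scans[ok]

  fit <- thigh_morphometry(scans, alpha = config$alpha,
                           grid_step = config$grid_step,
                           t_variant = config$t_variant,
                           anova_design = config$anova_design)
  ct <- fit$contrasts

  # table1.csv
  order_q <- c(muscle_groups()$KE, "KE_total", muscle_groups()$KF, "KF_total",
               "KF_KE_ratio")
  t1 <- ct[match(order_q, ct$quantity),
           c("quantity", "male_mean", "male_sd", "female_mean", "female_sd",
             "p_adj", "cohens_d")]
  dp <- ifelse(t1$quantity == "KF_KE_ratio", 2L, 1L)
  for (col in c("male_mean", "male_sd", "female_mean", "female_sd")) {
    t1[[col]] <- round(t1[[col]], dp)
  }
  t1$cohens_d <- round(t1$cohens_d, 2)
  f_table1 <- file.path(out_dir, "table1.csv")
  utils::write.csv(t1, f_table1, row.names = FALSE)

  # fig2_differences.csv
  f2 <- ct[ct$quantity %in% all_muscles(),
           c("quantity", "pct_difference")]
  names(f2) <- c("muscle", "pct_difference")
  f_fig2 <- file.path(out_dir, "fig2_differences.csv")
  utils::write.csv(f2, f_fig2, row.names = FALSE)

  # fig4_proportions.csv
  f4 <- ct[startsWith(ct$quantity, "prop_"),
           c("quantity", "male_mean", "male_sd", "female_mean", "female_sd",
             "p_adj", "cohens_d")]
  f4$muscle <- sub("^prop_", "", f4$quantity)
  f4$group <- muscle_group_of(f4$muscle)
  f4 <- f4[, c("muscle", "group", "male_mean", "male_sd", "female_mean",
               "female_sd", "p_adj", "cohens_d")]
  f_fig4 <- file.path(out_dir, "fig4_proportions.csv")
  utils::write.csv(f4, f_fig4, row.names = FALSE)

  # fig5_distribution.csv
  f_fig5 <- file.path(out_dir, "fig5_distribution.csv")
  utils::write.csv(fit$curves[, c("muscle", "sex", "position", "mean", "sd", "n")],
                   f_fig5, row.names = FALSE)

  # regions.txt (BED-like: muscle, start%FL, end%FL)
  f_regions <- file.path(out_dir, "regions.txt")
  reg_lines <- unlist(lapply(fit$regions, function(r) {
    if (nrow(r$regions) == 0L) return(character(0))
    sprintf("%s\t%g\t%g", r$muscle, r$regions$start, r$regions$end)
  }))
  writeLines(reg_lines, f_regions)

  # stats.csv: t-tests + ANOVA effects
  stat_rows <- ct[, c("quantity", "t", "df", "p_raw", "p_adj", "cohens_d")]
  stat_rows$test <- "independent_t"
  an_rows <- do.call(rbind, c(
    list(cbind(test = "anova_acsamax", fit$anovas$acsamax$effects),
         cbind(test = "anova_proportion", fit$anovas$proportion$effects)),
    lapply(names(fit$anovas$distribution), function(m) {
      a <- fit$anovas$distribution[[m]]
      if (is.null(a)) return(NULL)
      cbind(test = paste0("anova_distribution_", m), a$effects)
    })
  ))
  f_stats <- file.path(out_dir, "stats.csv")
  utils::write.csv(merge_stats_tables(stat_rows, an_rows), f_stats,
                   row.names = FALSE)

  # run log with config hash
  cfg_str <- paste(names(config), unlist(config), sep = "=", collapse = ";")
  log_lines <- c(
    sprintf("thighmorph pipeline run, %d subjects analysed", length(scans)),
    sprintf("config: %s", cfg_str),
    sprintf("config_hash: %010.0f", config_hash(cfg_str)),
    if (length(exclusions) > 0) c("exclusions:", paste(" ", exclusions))
    else "exclusions: none"
  )
  f_log <- file.path(out_dir, "run_log.txt")
  writeLines(log_lines, f_log)

  attr(fit, "bundle") <- c(table1 = f_table1, fig2 = f_fig2, fig4 = f_fig4,
                           fig5 = f_fig5, regions = f_regions,
                           stats = f_stats, log = f_log)
  invisible(fit)
}

# align t-test rows and ANOVA rows into one tidy frame
merge_stats_tables <- function(tt, an) {
  tt_out <- data.frame(test = tt$test, term = tt$quantity,
                       statistic = tt$t, df1 = tt$df, df2 = NA_real_,
                       p_raw = tt$p_raw, p_adj = tt$p_adj,
                       cohens_d = tt$cohens_d, stringsAsFactors = FALSE)
  if (is.null(an)) return(tt_out)
  an_out <- data.frame(test = an$test, term = an$effect,
                       statistic = an$F, df1 = an$df1, df2 = an$df2,
                       p_raw = an$p, p_adj = NA_real_,
                       cohens_d = NA_real_, stringsAsFactors = FALSE)
  rbind(tt_out, an_out)
}

# stable cheap polynomial fingerprint of the config string, for the log
config_hash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 4294967296
  h
}
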