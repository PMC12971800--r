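#' Summary of biomarker distributions per sex and age group
#'
#' Median and interquartile range of SAT area, VAT area and VSR per
#' (sex, age-group) stratum plus an all-ages row per sex.
#'
#' @param records included cohort records.
#' @return A data.frame with one row per stratum and measure.
#' @export
cohort_summary <- function(records) {
  records$age_group <- records$age_group %||% age_group_of(records$age_at_ct)
  rows <- list()
  for (sx in unique(records$sex)) {
    for (ag in c("all", unique(records$age_group))) {
      idx <- records$sex == sx & (ag == "all" | records$age_group == ag)
      if (sum(idx) == 0) next
      for (m in c("sat_cm2", "vat_cm2", "vsr")) {
        v <- records[[m]][idx]
        q <- stats::quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
        rows[[length(rows) + 1]] <- data.frame(
          sex = sx, age_group = ag, measure = m, n = sum(idx),
          median = q[2], q1 = q[1], q3 = q[3], stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Age-group banding used throughout the analysis
#' @param age numeric ages in years.
#' @return Character vector with levels 18-39, 40-59, 60-79, 80+.
#' @export
age_group_of <- function(age) {
  cut(age, c(18, 40, 60, 80, Inf), right = FALSE,
      labels = c("18-39", "40-59", "60-79", "80+")) |> as.character()
}

#' Run the full mortality-association study on a cohort
#'
#' Applies the exclusion cascade, then produces the five report artifact
#' classes: (a) a per-stratum biomarker summary (median + IQR), (b)
#' twelve-percentile-bin hazard-ratio curves per measure and sex, (c)
#' quartile hazard ratios per (sex, age-group) cell with a heterogeneity
#' test per cell, (d) extreme-quartile hazard-ratio ratios with 95% CIs,
#' and (e) Kaplan-Meier curves for VSR quartiles per cell. Everything is
#' written as tidy CSVs plus PNG figures, and a JSON run log records the
#' configuration and exclusion counts. A re-run on the same input and
#' configuration produces identical outputs.
#'
#' @param cohort a cohort data.frame or path to a cohort CSV.
#' @param outdir output directory (created if needed).
#' @param measures biomarker columns to analyze.
#' @param min_cell_events minimum events required to fit a cell.
#' @param make_plots write PNG figures (requires a working png device).
#' @return Invisibly, a list with the five artifact data.frames, the
#'   exclusion counts and the paths written.
#' @export
run_study <- function(cohort, outdir,
                      measures = c("sat_cm2", "vat_cm2", "vsr"),
                      min_cell_events = 8,
                      make_plots = TRUE) {
  if (is.character(cohort)) cohort <- read_cohort_csv(cohort)
  required <- c("patient_id", "age_at_ct", "sex", "event", "time_years", measures)
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols)) {
    adipoct_error(paste("cohort is missing columns:",
                        paste(missing_cols, collapse = ", ")),
                  "adipoct_schema_error")
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  excl <- apply_exclusions(cohort)
  rec <- excl$included
  rec$age_group <- age_group_of(rec$age_at_ct)

  paths <- c()
  save_csv <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths[[name]] <<- p
    df
  }

  # (a) Table-1-style summary
  summary_tab <- save_csv(cohort_summary(rec), "summary_by_stratum.csv")

  # (b) twelve-percentile-bin HR curves per measure and sex
  tw <- bin_scheme("twelve_percentile")
  rows <- list()
  for (m in measures) {
    for (sx in unique(rec$sex)) {
      idx <- rec$sex == sx
      res <- tryCatch({
        bins <- assign_bins(rec[[m]][idx], tw)
        fit <- cox_fit(rec$time_years[idx], rec$event[idx], bins,
                       reference_bin = tw$reference_bin)
        het <- heterogeneity_test(fit)
        hr_all <- setNames(rep(1, tw$n_bins), paste0("bin", seq_len(tw$n_bins)))
        lo <- hi <- hr_all
        hr_all[names(fit$hr)] <- fit$hr
        lo[names(fit$ci_low)] <- fit$ci_low
        hi[names(fit$ci_high)] <- fit$ci_high
        data.frame(measure = m, sex = sx, bin = seq_len(tw$n_bins),
                   pct_low = tw$edges[-length(tw$edges)],
                   pct_high = tw$edges[-1],
                   hr = unname(hr_all), ci_low = unname(lo),
                   ci_high = unname(hi),
                   is_reference = seq_len(tw$n_bins) == tw$reference_bin,
                   n = sum(idx), n_events = sum(rec$event[idx]),
                   het_p = het$p_value, stringsAsFactors = FALSE)
      }, adipoct_error = function(e) NULL)
      if (!is.null(res)) rows[[length(rows) + 1]] <- res
    }
  }
  percentile_hr <- save_csv(do.call(rbind, rows), "percentile_hr.csv")

  # (c)+(d) quartile HRs and extreme-quartile ratios per sex x age group
  qt <- bin_scheme("quartile")
  qrows <- list(); erows <- list()
  for (m in measures) {
    for (sx in unique(rec$sex)) {
      for (ag in unique(rec$age_group)) {
        idx <- which(rec$sex == sx & rec$age_group == ag)
        if (length(idx) < 4 * qt$n_bins ||
            sum(rec$event[idx]) < min_cell_events) next
        cell <- tryCatch({
          bins <- assign_bins(rec[[m]][idx], qt)
          fit <- cox_fit(rec$time_years[idx], rec$event[idx], bins,
                         reference_bin = qt$reference_bin)
          het <- heterogeneity_test(fit)
          ex <- extreme_quartile_ratio(fit)
          list(fit = fit, het = het, ex = ex)
        }, adipoct_error = function(e) NULL)
        if (is.null(cell)) next
        hr_all <- setNames(rep(1, qt$n_bins), paste0("bin", 1:qt$n_bins))
        lo <- hi <- hr_all
        hr_all[names(cell$fit$hr)] <- cell$fit$hr
        lo[names(cell$fit$ci_low)] <- cell$fit$ci_low
        hi[names(cell$fit$ci_high)] <- cell$fit$ci_high
        qrows[[length(qrows) + 1]] <- data.frame(
          measure = m, sex = sx, age_group = ag, quartile = 1:qt$n_bins,
          hr = unname(hr_all), ci_low = unname(lo), ci_high = unname(hi),
          n = length(idx), n_events = sum(rec$event[idx]),
          het_chisq = cell$het$statistic, het_df = cell$het$df,
          het_p = cell$het$p_value, stringsAsFactors = FALSE)
        erows[[length(erows) + 1]] <- data.frame(
          measure = m, sex = sx, age_group = ag,
          hr_ratio = cell$ex$ratio, ci_low = cell$ex$ci_low,
          ci_high = cell$ex$ci_high, high_quartile = cell$ex$high_bin,
          low_quartile = cell$ex$low_bin, stringsAsFactors = FALSE)
      }
    }
  }
  quartile_hr <- save_csv(do.call(rbind, qrows), "quartile_hr.csv")
  extreme_ratios <- save_csv(do.call(rbind, erows), "extreme_quartile_ratios.csv")

  # (e) KM curves for VSR quartiles per sex x age group
  krows <- list()
  if ("vsr" %in% measures) {
    for (sx in unique(rec$sex)) {
      for (ag in unique(rec$age_group)) {
        idx <- which(rec$sex == sx & rec$age_group == ag)
        if (length(idx) < 4 * qt$n_bins) next
        bins <- tryCatch(assign_bins(rec$vsr[idx], qt),
                         adipoct_error = function(e) NULL)
        if (is.null(bins)) next
        km <- km_estimate(rec$time_years[idx], rec$event[idx],
                          paste0("Q", bins))
        km$sex <- sx; km$age_group <- ag
        krows[[length(krows) + 1]] <- km
      }
    }
  }
  km_curves <- if (length(krows)) save_csv(do.call(rbind, krows),
                                           "km_vsr_quartiles.csv") else NULL

  if (make_plots) {
    try(suppressWarnings(
      plot_study_figures(percentile_hr, quartile_hr, km_curves, outdir)),
      silent = TRUE)
  }

  log <- list(
    n_input = nrow(cohort),
    n_included = nrow(rec),
    exclusions = as.list(excl$counts),
    measures = measures,
    reference_bins = list(quartile = qt$reference_bin,
                          twelve_percentile = tw$reference_bin)
  )
  jsonlite::write_json(log, file.path(outdir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  paths[["run_log.json"]] <- file.path(outdir, "run_log.json")

  invisible(list(summary = summary_tab, percentile_hr = percentile_hr,
                 quartile_hr = quartile_hr, extreme_ratios = extreme_ratios,
                 km_curves = km_curves, exclusions = excl$counts,
                 paths = paths))
}

# Figures mirroring the layout of the study's result displays.
plot_study_figures <- function(percentile_hr, quartile_hr, km_curves, outdir) {
  gg <- ggplot2::ggplot
  aes <- ggplot2::aes
  if (!is.null(percentile_hr) && nrow(percentile_hr)) {
    percentile_hr$pct_mid <- (percentile_hr$pct_low + percentile_hr$pct_high) / 2
    p <- gg(percentile_hr, aes(x = pct_mid, y = hr, color = sex)) +
      ggplot2::geom_point() +
      ggplot2::geom_errorbar(aes(ymin = ci_low, ymax = ci_high), width = 1.5) +
      ggplot2::geom_hline(yintercept = 1, linetype = 2) +
      ggplot2::facet_wrap(~measure, scales = "free_y") +
      ggplot2::labs(x = "percentile of measure", y = "hazard ratio") +
      ggplot2::theme_bw()
    ggplot2::ggsave(file.path(outdir, "fig_percentile_hr.png"), p,
                    width = 9, height = 3.5, dpi = 120)
  }
  if (!is.null(quartile_hr) && nrow(quartile_hr)) {
    p <- gg(quartile_hr, aes(x = quartile, y = hr, color = age_group)) +
      ggplot2::geom_point() + ggplot2::geom_line() +
      ggplot2::geom_hline(yintercept = 1, linetype = 2) +
      ggplot2::facet_grid(sex ~ measure) +
      ggplot2::labs(x = "quartile", y = "hazard ratio") +
      ggplot2::theme_bw()
    ggplot2::ggsave(file.path(outdir, "fig_quartile_hr.png"), p,
                    width = 9, height = 5, dpi = 120)
  }
  if (!is.null(km_curves) && nrow(km_curves)) {
    p <- gg(km_curves, aes(x = time, y = surv, color = group)) +
      ggplot2::geom_step() +
      ggplot2::facet_grid(sex ~ age_group) +
      ggplot2::coord_cartesian(ylim = c(0, 1)) +
      ggplot2::labs(x = "years from CT", y = "survival probability",
                    color = "VSR quartile") +
      ggplot2::theme_bw()
    ggplot2::ggsave(file.path(outdir, "fig_km_vsr.png"), p,
                    width = 9, height = 5, dpi = 120)
  }
  invisible(NULL)
}
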