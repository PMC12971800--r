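#' Default biomarker distribution targets per sex and age group
#'
#' Median and interquartile range (cm^2 for areas) of SAT and VAT per
#' (sex, age-group) stratum, together with stratum weights, emulating the
#' body-composition distributions reported for a large adult abdominal-CT
#' cohort: men carry more visceral fat, women more subcutaneous fat, and
#' the visceral share rises with age. VSR is always derived as VAT/SAT,
#' never drawn directly.
#'
#' @return A data.frame with one row per (sex, age_group) stratum.
#' @export
default_biomarker_targets <- function() {
  data.frame(
    sex = rep(c("male", "female"), each = 4),
    age_group = rep(c("18-39", "40-59", "60-79", "80+"), 2),
    weight = c(15663, 24880, 21875, 3892, 18415, 27787, 21034, 4623),
    sat_median = c(144.6, 177.6, 177.9, 152.2, 208.6, 245.8, 235.2, 181.8),
    sat_q1 = c(78.7, 123.6, 129.2, 111.4, 122.0, 159.5, 159.0, 114.3),
    sat_q3 = c(233.3, 253.0, 241.2, 202.2, 337.8, 353.7, 330.7, 254.8),
    vat_median = c(91.0, 200.9, 248.1, 236.3, 47.2, 102.6, 133.2, 117.0),
    vat_q1 = c(37.2, 114.6, 152.7, 148.8, 23.0, 48.0, 70.7, 64.4),
    vat_q3 = c(176.6, 294.5, 348.6, 331.1, 104.0, 179.5, 213.1, 187.2),
    stringsAsFactors = FALSE
  )
}

#' Parameters of the survival-cohort simulator
#'
#' Defines a cohort with lognormal SAT/VAT biomarkers per (sex, age-group)
#' stratum, a proportional-hazards mortality mechanism driven by
#' within-stratum quartiles of one biomarker, an exponential baseline
#' hazard per age group, and uniform administrative censoring.
#'
#' Lognormal parameters are matched to the (median, IQR) targets on the
#' log scale: meanlog = log(median), sdlog = log(q3/q1) / (2 * 0.6744898).
#'
#' @param n cohort size.
#' @param seed integer seed; the cohort is deterministic given the seed.
#' @param targets per-stratum biomarker targets (their `weight` column also
#'   fixes the sex/age mix); see [default_biomarker_targets()].
#' @param effect_biomarker which biomarker's within-stratum quartile drives
#'   the hazard: `"vsr"`, `"sat"` or `"vat"`.
#' @param log_hr_per_quartile length-4 log-hazard effects for Q1..Q4; the
#'   reference entry (Q1) must be 0.
#' @param baseline_hazard named per-age-group exponential event rates
#'   (per year).
#' @param admin_censor_years administrative censoring horizon (years);
#'   last-contact times are uniform on (0, horizon].
#' @param log_sat_vat_cor correlation between log SAT and log VAT within a
#'   stratum.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n = 10000L, seed = 1L,
                       targets = default_biomarker_targets(),
                       effect_biomarker = c("vsr", "sat", "vat"),
                       log_hr_per_quartile = c(0, 0.05, 0.15, log(2)),
                       baseline_hazard = c("18-39" = 0.006, "40-59" = 0.017,
                                           "60-79" = 0.045, "80+" = 0.13),
                       admin_censor_years = 21,
                       log_sat_vat_cor = 0.2) {
  effect_biomarker <- match.arg(effect_biomarker)
  if (length(log_hr_per_quartile) != 4 || log_hr_per_quartile[1] != 0) {
    invalid_spec("log_hr_per_quartile must have 4 entries with reference Q1 = 0")
  }
  w <- targets$weight / sum(targets$weight)
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 targets = targets, stratum_weights = w,
                 effect_biomarker = effect_biomarker,
                 log_hr_per_quartile = log_hr_per_quartile,
                 baseline_hazard = baseline_hazard,
                 admin_censor_years = admin_censor_years,
                 log_sat_vat_cor = log_sat_vat_cor),
            class = "sim_params")
}

lognormal_from_quartiles <- function(med, q1, q3) {
  list(meanlog = log(med), sdlog = log(q3 / q1) / (2 * stats::qnorm(0.75)))
}

#' Simulate a survival cohort with known biomarker and hazard structure
#'
#' Draws each subject's stratum from the target weights (sex from the
#' female ratio, age uniform within its group), SAT and VAT from
#' log-correlated lognormals matched to the stratum's (median, IQR)
#' targets, and VSR = VAT / SAT. The subject's quartile of the driving
#' biomarker is computed *within* the (sex, age-group) stratum; survival
#' time is exponential with rate = age-group baseline x exp(quartile log
#' hazard), censored at a uniform last-contact time on
#' (0, admin_censor_years].
#'
#' @param params a [sim_params()].
#' @return A data.frame with one row per patient: `patient_id`, `age_at_ct`,
#'   `sex`, `sat_cm2`, `vat_cm2`, `vsr`, `event` (1 = died, 0 = censored),
#'   `time_years`, `true_quartile`, and all-`FALSE` exclusion flags.
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  tg <- params$targets
  n <- params$n
  with_seed(params$seed, {
    stratum <- sample(seq_len(nrow(tg)), n, replace = TRUE,
                      prob = params$stratum_weights)
    age_lo <- c("18-39" = 18, "40-59" = 40, "60-79" = 60, "80+" = 80)
    age_hi <- c("18-39" = 39.99, "40-59" = 59.99, "60-79" = 79.99, "80+" = 97)
    ag <- tg$age_group[stratum]
    age <- runif(n, age_lo[ag], age_hi[ag])
    sex <- tg$sex[stratum]

    sat <- numeric(n); vat <- numeric(n)
    rho <- params$log_sat_vat_cor
    for (s in unique(stratum)) {
      idx <- which(stratum == s)
      if (length(idx) == 0) next
      ps <- lognormal_from_quartiles(tg$sat_median[s], tg$sat_q1[s], tg$sat_q3[s])
      pv <- lognormal_from_quartiles(tg$vat_median[s], tg$vat_q1[s], tg$vat_q3[s])
      z1 <- rnorm(length(idx)); z2 <- rnorm(length(idx))
      zs <- z1
      zv <- rho * z1 + sqrt(1 - rho^2) * z2
      sat[idx] <- exp(ps$meanlog + ps$sdlog * zs)
      vat[idx] <- exp(pv$meanlog + pv$sdlog * zv)
    }
    vsr <- vat / sat

    driver <- switch(params$effect_biomarker, vsr = vsr, sat = sat, vat = vat)
    quart <- integer(n)
    for (s in unique(stratum)) {
      idx <- which(stratum == s)
      if (length(idx) < 4) {
        adipoct_error(sprintf("stratum %s/%s too small to form quartiles",
                              tg$sex[s], tg$age_group[s]),
                      "adipoct_stratum_error")
      }
      qs <- stats::quantile(driver[idx], c(0.25, 0.5, 0.75), type = 7,
                            names = FALSE)
      quart[idx] <- findInterval(driver[idx], qs) + 1L
    }

    rate <- unname(params$baseline_hazard[ag]) *
      exp(params$log_hr_per_quartile[quart])
    t_event <- rexp(n, rate)
    t_censor <- runif(n, 0, params$admin_censor_years)
    event <- as.integer(t_event <= t_censor)
    time <- pmin(t_event, t_censor)

    data.frame(
      patient_id = sprintf("P%07d", seq_len(n)),
      age_at_ct = age, sex = sex, age_group = ag,
      sat_cm2 = sat, vat_cm2 = vat, vsr = vsr,
      event = event, time_years = time,
      true_quartile = quart,
      tool_failure = FALSE, outlier = FALSE, under_18 = FALSE,
      missing_ehr = FALSE,
      stringsAsFactors = FALSE
    )
  })
}

#' Inject exclusion-worthy records into a simulated cohort
#'
#' Marks independent random subsets of records so the downstream exclusion
#' stage has work to do: tool failures (biomarkers blanked), extreme
#' outliers (VSR pushed beyond any plausible bound), minors (age redrawn
#' below 18) and missing EHR data (event/time blanked). Flags are also set
#' so per-reason counts can be checked against the injection bookkeeping.
#'
#' @param records a [simulate_cohort()] data.frame.
#' @param rates named list/vector of per-reason probabilities in [0, 1]:
#'   `tool_failure`, `outlier`, `under_18`, `missing_ehr`.
#' @param seed integer seed.
#' @return The records with flags set and fields degraded accordingly.
#' @export
inject_exclusions <- function(records,
                              rates = c(tool_failure = 0.02, outlier = 0.005,
                                        under_18 = 0.01, missing_ehr = 0.05),
                              seed = 1L) {
  rates <- as.list(rates)
  for (r in c("tool_failure", "outlier", "under_18", "missing_ehr")) {
    p <- rates[[r]] %||% 0
    if (p < 0 || p > 1) invalid_spec(sprintf("rate '%s' outside [0, 1]", r))
    rates[[r]] <- p
  }
  n <- nrow(records)
  with_seed(derive_seed(seed, 11L), {
    tf <- runif(n) < rates$tool_failure
    ol <- runif(n) < rates$outlier
    u18 <- runif(n) < rates$under_18
    me <- runif(n) < rates$missing_ehr
    records$tool_failure <- tf
    records$sat_cm2[tf] <- NA_real_
    records$vat_cm2[tf] <- NA_real_
    records$vsr[tf] <- NA_real_
    records$outlier <- ol
    records$vsr[ol & !tf] <- runif(sum(ol & !tf), 15, 40)
    records$under_18 <- u18
    records$age_at_ct[u18] <- runif(sum(u18), 1, 17.9)
    records$missing_ehr <- me
    records$event[me] <- NA_integer_
    records$time_years[me] <- NA_real_
    records
  })
}

#' Write a simulated cohort to the documented CSV schema
#'
#' @param records cohort data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
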