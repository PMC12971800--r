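#' Apply the cohort exclusion cascade
#'
#' De-duplicates patients (keeping the earliest CT when a `ct_date` column
#' is present, otherwise the first occurrence), then removes records in a
#' fixed order of reasons, each record counted under the first matching
#' reason only: (1) tool failure, (2) extreme outlier biomarker values,
#' (3) age under 18, (4) missing event/time/sex/age data.
#'
#' @param records cohort data.frame (see [simulate_cohort()] for schema).
#' @param sat_bounds,vat_bounds,vsr_bounds plausibility bounds (open below,
#'   closed above) for the biomarkers, in cm^2 / ratio units.
#' @return A list: `included` (data.frame), `excluded` (data.frame with a
#'   `reason` column), `counts` (named integer vector incl. `duplicates`),
#'   satisfying `n_input = n_included + sum(counts)`.
#' @export
apply_exclusions <- function(records,
                             sat_bounds = c(0, 1500),
                             vat_bounds = c(0, 1500),
                             vsr_bounds = c(0, 10)) {
  n_input <- nrow(records)

  dup_drop <- rep(FALSE, n_input)
  if (anyDuplicated(records$patient_id)) {
    ord <- if (!is.null(records$ct_date)) {
      order(records$patient_id, records$ct_date)
    } else {
      order(records$patient_id, seq_len(n_input))
    }
    first <- !duplicated(records$patient_id[ord])
    keep_idx <- sort(ord[first])
    dup_drop <- !(seq_len(n_input) %in% keep_idx)
  }
  rec <- records[!dup_drop, , drop = FALSE]

  in_bounds <- function(x, b) !is.na(x) & x > b[1] & x <= b[2]
  tool_failure <- isTRUE_vec(rec$tool_failure)
  outlier <- !tool_failure &
    !(in_bounds(rec$sat_cm2, sat_bounds) &
      in_bounds(rec$vat_cm2, vat_bounds) &
      in_bounds(rec$vsr, vsr_bounds))
  under_18 <- !tool_failure & !outlier & (!is.na(rec$age_at_ct) & rec$age_at_ct < 18)
  missing_ehr <- !tool_failure & !outlier & !under_18 &
    (is.na(rec$event) | is.na(rec$time_years) | is.na(rec$sex) |
       is.na(rec$age_at_ct))

  reason <- rep(NA_character_, nrow(rec))
  reason[missing_ehr] <- "missing_ehr"
  reason[under_18] <- "under_18"
  reason[outlier] <- "outlier"
  reason[tool_failure] <- "tool_failure"

  included <- rec[is.na(reason), , drop = FALSE]
  excluded <- rec[!is.na(reason), , drop = FALSE]
  if (nrow(excluded)) excluded$reason <- reason[!is.na(reason)]
  counts <- c(
    tool_failure = sum(tool_failure),
    outlier = sum(outlier),
    under_18 = sum(under_18),
    missing_ehr = sum(missing_ehr),
    duplicates = sum(dup_drop)
  )
  if (nrow(included) == 0) warning("no records remain after exclusions")
  list(included = included, excluded = excluded, counts = counts)
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else !is.na(x) & x

#' Percentile binning schemes
#'
#' `bin_scheme("twelve_percentile")` uses the cut points
#' \{0, 5, 10, 20, ..., 90, 95, 100\}: finer 5-percentile bins in both
#' tails where hazard curves bend, 10-percentile bins in the middle.
#' `bin_scheme("quartile")` uses \{0, 25, 50, 75, 100\}. The reference bin
#' defaults to the first quartile for the quartile scheme and the
#' 40th-50th percentile bin for the twelve-bin scheme (a mid-distribution
#' reference keeps tail hazard ratios interpretable).
#'
#' @param kind `"quartile"` or `"twelve_percentile"`.
#' @param reference_bin index of the reference bin; `NULL` for the default.
#' @return A list of class `bin_scheme` with `edges` (percentiles) and
#'   `reference_bin`.
#' @export
bin_scheme <- function(kind = c("quartile", "twelve_percentile"),
                       reference_bin = NULL) {
  kind <- match.arg(kind)
  edges <- switch(kind,
    quartile = c(0, 25, 50, 75, 100),
    twelve_percentile = c(0, 5, 10, 20, 30, 40, 50, 60, 70, 80, 90, 95, 100))
  nb <- length(edges) - 1L
  reference_bin <- reference_bin %||% switch(kind, quartile = 1L,
                                             twelve_percentile = 6L)
  if (reference_bin < 1 || reference_bin > nb) {
    invalid_spec("reference bin out of range")
  }
  structure(list(kind = kind, edges = edges,
                 reference_bin = as.integer(reference_bin), n_bins = nb),
            class = "bin_scheme")
}

#' Assign records to percentile bins, optionally within strata
#'
#' Percentile cut points are computed by the inclusive linear-interpolation
#' quantile definition (R type 7) within each stratum; intervals are
#' left-closed/right-open except the last, which is closed above. Under
#' distinct values the resulting bin sizes differ by at most one from the
#' ideal.
#'
#' @param values numeric biomarker values.
#' @param scheme a [bin_scheme()].
#' @param strata optional factor-like vector; cut points computed per level.
#' @return Integer bin labels in `1..n_bins` (every value falls in exactly
#'   one bin).
#' @export
assign_bins <- function(values, scheme = bin_scheme("quartile"), strata = NULL) {
  if (is.null(strata)) strata <- rep(1L, length(values))
  out <- integer(length(values))
  for (s in unique(strata)) {
    idx <- which(strata == s)
    v <- values[idx]
    if (length(unique(v)) < scheme$n_bins) {
      adipoct_error(sprintf(
        "stratum '%s' has fewer distinct values than bins", s),
        "adipoct_degenerate_stratum")
    }
    cuts <- stats::quantile(v, scheme$edges[-c(1, length(scheme$edges))] / 100,
                            type = 7, names = FALSE)
    out[idx] <- findInterval(v, cuts) + 1L
  }
  out
}

#' Cox proportional-hazards fit with binned predictors
#'
#' Fits the Cox partial likelihood with the bins entered as indicator
#' covariates against a reference bin, using Breslow handling of tied
#' event times (Efron available). Hazard ratios are exp(coef) with Wald
#' 95% confidence intervals exp(coef +/- 1.96 se) from the
#' inverse-information covariance. Bins with no events (monotone
#' likelihood) are flagged non-estimable; the fit continues for the
#' others.
#'
#' @param time follow-up times (years).
#' @param event event indicators (1 = died, 0 = censored).
#' @param bins integer bin labels from [assign_bins()].
#' @param reference_bin reference bin index (HR fixed at 1).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return A list of class `cox_fit`: `coefficients` and `se` (named per
#'   non-reference bin, NA where non-estimable), `cov`, `hr`, `ci_low`,
#'   `ci_high`, `n`, `n_events`, `n_events_by_bin`, `estimable`,
#'   `converged`, `loglik`, `reference_bin`.
#' @export
cox_fit <- function(time, event, bins, reference_bin = 1L,
                    ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  stopifnot(length(time) == length(event), length(bins) == length(time))
  levs <- sort(unique(bins))
  if (!reference_bin %in% levs) invalid_spec("reference bin has no members")
  if (length(levs) < 2) {
    adipoct_error("all subjects share one bin; no estimable effect",
                  "adipoct_nonestimable")
  }
  ev_by_bin <- vapply(levs, function(b) sum(event[bins == b]), numeric(1))
  names(ev_by_bin) <- paste0("bin", levs)
  if (sum(ev_by_bin) == 0) {
    adipoct_error("no events in any bin", "adipoct_nonestimable")
  }
  f <- factor(bins, levels = c(reference_bin, setdiff(levs, reference_bin)))
  no_converge <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ f, ties = ties),
    warning = function(w) {
      if (grepl("did not converge|infinite", conditionMessage(w))) {
        no_converge <<- TRUE
      }
      invokeRestart("muffleWarning")
    })
  nonref <- setdiff(levs, reference_bin)
  coefs <- unname(stats::coef(fit))
  V <- stats::vcov(fit)
  se <- sqrt(diag(V))
  estimable <- ev_by_bin[paste0("bin", nonref)] > 0 & is.finite(coefs) &
    is.finite(se) & se < 100
  coefs[!estimable] <- NA_real_
  se[!estimable] <- NA_real_
  names(coefs) <- names(se) <- paste0("bin", nonref)
  hr <- exp(coefs)
  structure(list(
    coefficients = coefs, se = se, cov = V,
    hr = hr, ci_low = exp(coefs - 1.96 * se), ci_high = exp(coefs + 1.96 * se),
    n = length(time), n_events = sum(event), n_events_by_bin = ev_by_bin,
    estimable = estimable,
    converged = !no_converge,
    loglik = fit$loglik[2], reference_bin = reference_bin,
    bins = levs
  ), class = "cox_fit")
}

#' Ratio of the hazard ratios of the highest- and lowest-risk quartiles
#'
#' Identifies the bins with the highest and lowest point hazard ratios
#' (the reference bin counts with HR = 1) and reports
#' exp(coef_high - coef_low) with a delta-method 95% CI on the log scale
#' using the fit covariance: var = V_hh + V_ll - 2 V_hl, with variance 0
#' for the reference bin. When the lowest-risk bin is the reference the
#' ratio is the highest bin's HR directly.
#'
#' @param fit a [cox_fit()].
#' @return A list: `ratio`, `ci_low`, `ci_high`, `se_log`, `high_bin`,
#'   `low_bin`.
#' @export
extreme_quartile_ratio <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  if (sum(fit$estimable, na.rm = TRUE) < 1) {
    adipoct_error("no estimable non-reference bin", "adipoct_nonestimable")
  }
  all_bins <- fit$bins
  b_all <- setNames(rep(0, length(all_bins)), paste0("bin", all_bins))
  b_all[names(fit$coefficients)] <- fit$coefficients
  usable <- !is.na(b_all)
  hb <- names(which.max(b_all[usable]))
  lb <- names(which.min(b_all[usable]))
  ref <- paste0("bin", fit$reference_bin)
  v_of <- function(nm1, nm2) {
    if (nm1 == ref || nm2 == ref) return(0)
    fnm1 <- paste0("f", sub("bin", "", nm1))
    fnm2 <- paste0("f", sub("bin", "", nm2))
    rn <- rownames(fit$cov) %||% names(fit$coefficients)
    i <- match(fnm1, rn); j <- match(fnm2, rn)
    if (is.na(i) || is.na(j)) { i <- match(nm1, names(fit$coefficients))
                                j <- match(nm2, names(fit$coefficients)) }
    fit$cov[i, j]
  }
  d <- b_all[hb] - b_all[lb]
  v <- v_of(hb, hb) + v_of(lb, lb) - 2 * v_of(hb, lb)
  se <- sqrt(max(v, 0))
  list(ratio = unname(exp(d)),
       ci_low = unname(exp(d - 1.96 * se)),
       ci_high = unname(exp(d + 1.96 * se)),
       se_log = se,
       high_bin = as.integer(sub("bin", "", hb)),
       low_bin = as.integer(sub("bin", "", lb)))
}

#' Wald chi-squared heterogeneity test across bins
#'
#' Tests whether all estimable non-reference bin coefficients are
#' simultaneously zero: statistic b' V^-1 b on df = number of estimable
#' non-reference bins, p-value from the upper chi-squared tail.
#'
#' @param fit a [cox_fit()].
#' @return A list: `statistic`, `df`, `p_value`.
#' @export
heterogeneity_test <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  est <- which(fit$estimable)
  if (length(est) == 0) {
    adipoct_error("no estimable coefficients to test", "adipoct_nonestimable")
  }
  b <- fit$coefficients[est]
  V <- fit$cov[est, est, drop = FALSE]
  Vi <- tryCatch(solve(V), error = function(e)
    adipoct_error("singular covariance in heterogeneity test",
                  "adipoct_singular"))
  stat <- drop(t(b) %*% Vi %*% b)
  df <- length(b)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Kaplan-Meier product-limit curves per group
#'
#' Product-limit survival estimates with the events-before-censoring
#' convention at tied times, via the standard survfit machinery. Empty
#' groups are skipped with a warning.
#'
#' @param time follow-up times.
#' @param event event indicators (1 = event, 0 = censored).
#' @param groups group labels (one curve per level).
#' @return A data.frame with `group`, `time`, `n_risk`, `n_event`,
#'   `surv`: the stepwise survival estimate after each distinct time.
#' @export
km_estimate <- function(time, event, groups = NULL) {
  if (any(time < 0, na.rm = TRUE)) invalid_spec("negative follow-up time")
  if (is.null(groups)) groups <- rep("all", length(time))
  keep <- !is.na(time) & !is.na(event)
  time <- time[keep]; event <- event[keep]; groups <- groups[keep]
  out <- list()
  for (g in unique(groups)) {
    idx <- groups == g
    if (sum(idx) == 0) { warning(sprintf("empty group '%s' skipped", g)); next }
    sf <- survival::survfit(survival::Surv(time[idx], event[idx]) ~ 1)
    out[[length(out) + 1]] <- data.frame(
      group = g, time = sf$time, n_risk = sf$n.risk,
      n_event = sf$n.event, surv = sf$surv, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
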