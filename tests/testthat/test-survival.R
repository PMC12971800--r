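base_rec <- function(n, ...) {
  df <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    age_at_ct = rep(50, n), sex = rep("female", n),
    sat_cm2 = rep(200, n), vat_cm2 = rep(100, n), vsr = rep(0.5, n),
    event = rep(1L, n), time_years = seq_len(n),
    tool_failure = FALSE, outlier = FALSE, under_18 = FALSE,
    missing_ehr = FALSE, stringsAsFactors = FALSE)
  upd <- list(...)
  for (nm in names(upd)) df[[nm]] <- upd[[nm]]
  df
}

test_that("exclusion cascade removes records for the documented reasons", {
  rec <- base_rec(6,
                  age_at_ct = c(50, 17.9, 30, 44, 50, 60),
                  vsr = c(0.5, 0.5, 12, 0.6, 0.7, 0.8),
                  tool_failure = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
                  event = c(1L, 1L, 1L, 1L, NA, 1L))
  res <- apply_exclusions(rec)
  expect_equal(nrow(res$included), 2)
  expect_equal(unname(res$counts[c("tool_failure", "outlier", "under_18",
                                   "missing_ehr")]),
               c(1L, 1L, 1L, 1L))
  expect_setequal(res$excluded$reason[res$excluded$patient_id == "P0002"],
                  "under_18")
})

test_that("duplicate patients keep the earliest CT", {
  rec <- base_rec(4)
  rec$patient_id <- c("A", "A", "B", "B")
  rec$ct_date <- c("2015-03-01", "2010-01-01", "2012-05-01", "2019-01-01")
  rec$vsr <- c(1, 2, 3, 4)
  res <- apply_exclusions(rec)
  expect_equal(nrow(res$included), 2)
  expect_equal(res$included$vsr, c(2, 3))  # earliest CT per patient
  expect_equal(unname(res$counts["duplicates"]), 2L)
})

test_that("quartile binning splits 1..100 into 25/25/25/25", {
  b <- assign_bins(1:100, bin_scheme("quartile"))
  expect_equal(as.vector(table(b)), rep(25L, 4))
  expect_true(all(b %in% 1:4))
})

test_that("twelve-percentile binning gives 5/5/10x8/5/5 on 1..100", {
  b <- assign_bins(1:100, bin_scheme("twelve_percentile"))
  expect_equal(as.vector(table(b)), c(5L, 5L, rep(10L, 8), 5L, 5L))
})

test_that("binning respects strata and errors on degenerate input", {
  vals <- c(1:40, 101:140)
  strata <- rep(c("a", "b"), each = 40)
  b <- assign_bins(vals, bin_scheme("quartile"), strata)
  expect_equal(as.vector(table(b[strata == "a"])), rep(10L, 4))
  expect_equal(as.vector(table(b[strata == "b"])), rep(10L, 4))
  expect_error(assign_bins(rep(5, 50), bin_scheme("quartile")),
               class = "adipoct_degenerate_stratum")
})

test_that("every record lands in exactly one bin", {
  set.seed(31)
  v <- rlnorm(500)
  for (kind in c("quartile", "twelve_percentile")) {
    b <- assign_bins(v, bin_scheme(kind))
    expect_true(all(b >= 1 & b <= bin_scheme(kind)$n_bins))
    expect_equal(length(b), 500)
  }
})

test_that("Cox fit matches the brute-force partial-likelihood oracle", {
  # enumerate small two-group datasets; skip monotone-likelihood cases
  set.seed(7)
  checked <- 0
  while (checked < 25) {
    n <- sample(4:6, 1)
    time <- round(rexp(n, 0.5), 2)
    event <- rbinom(n, 1, 0.7)
    x <- rbinom(n, 1, 0.5)
    if (sum(event[x == 1]) == 0 || sum(event[x == 0]) == 0) next
    fit <- tryCatch(cox_fit(time, event, x + 1L), error = function(e) NULL)
    if (is.null(fit) || is.na(fit$coefficients[1])) next
    if (abs(fit$coefficients[1]) > 5) next
    bf <- brute_force_cox(time, event, x)
    expect_lt(abs(fit$coefficients[1] - bf), 1e-4)
    checked <- checked + 1
  }
  expect_equal(checked, 25)
})

test_that("tied event times are handled by the Breslow convention", {
  time <- c(1, 1, 2, 3, 3, 4)
  event <- c(1, 1, 0, 1, 1, 1)
  x <- c(1, 0, 1, 0, 1, 0)
  fit <- cox_fit(time, event, x + 1L)
  bf <- brute_force_cox(time, event, x)
  expect_lt(abs(fit$coefficients[1] - bf), 1e-4)
})

test_that("two-group HR approaches the true rate ratio at large n", {
  set.seed(11)
  n <- 20000
  x <- rbinom(n, 1, 0.5)
  time <- rexp(n, 0.1 * exp(log(2) * x))
  cens <- runif(n, 0, 15)
  event <- as.integer(time <= cens)
  fit <- cox_fit(pmin(time, cens), event, x + 1L)
  expect_lt(abs(fit$hr[1] - 2), 0.12)
  expect_true(fit$ci_low[1] < 2 && 2 < fit$ci_high[1])
})

test_that("an all-identical covariate is a non-estimable error", {
  expect_error(cox_fit(1:10, rep(1L, 10), rep(1L, 10)),
               class = "adipoct_nonestimable")
})

test_that("extreme-quartile ratio handles reference and non-reference extremes", {
  set.seed(13)
  n <- 8000
  q <- sample(1:4, n, replace = TRUE)
  beta <- c(0, 0.18, 0.4, log(2.6))
  time <- rexp(n, 0.08 * exp(beta[q]))
  event <- rep(1L, n)
  fit <- cox_fit(time, event, q, reference_bin = 1L)
  ex <- extreme_quartile_ratio(fit)
  expect_equal(ex$low_bin, 1)
  expect_equal(ex$high_bin, 4)
  expect_equal(ex$ratio, unname(fit$hr["bin4"]))
  expect_lt(abs(ex$ratio - 2.6), 0.3)

  # lowest-risk bin not the reference: delta-method CI vs direct refit
  beta2 <- c(0.3, 0, 0.1, log(2.6) + 0.3)
  time2 <- rexp(n, 0.08 * exp(beta2[q]))
  fit2 <- cox_fit(time2, event, q, reference_bin = 1L)
  ex2 <- extreme_quartile_ratio(fit2)
  expect_equal(ex2$low_bin, 2)
  refit <- cox_fit(time2, event, q, reference_bin = 2L)
  expect_equal(ex2$ratio, unname(refit$hr["bin4"]), tolerance = 1e-6)
  expect_equal(ex2$se_log, unname(refit$se["bin4"]), tolerance = 1e-6)
})

test_that("Wald heterogeneity statistic matches the 1-df closed form", {
  set.seed(17)
  n <- 4000
  x <- rbinom(n, 1, 0.5)
  time <- rexp(n, 0.1 * exp(0.3 * x))
  fit <- cox_fit(time, rep(1L, n), x + 1L)
  het <- heterogeneity_test(fit)
  b <- fit$coefficients[1]; v <- fit$se[1]^2
  expect_equal(het$statistic, unname(b^2 / v), tolerance = 1e-9)
  expect_equal(het$df, 1)
  expect_equal(het$p_value, unname(pchisq(b^2 / v, 1, lower.tail = FALSE)))
})

test_that("KM hand example and properties", {
  km <- km_estimate(c(1, 1.5, 2), c(1, 0, 1))
  # product-limit by hand: S(1) = 2/3; at t = 2 one subject at risk dies
  expect_equal(km$time, c(1, 1.5, 2))
  expect_equal(km$surv, c(2/3, 2/3, 0))
  # cross-check against the reference implementation
  sf <- survival::survfit(survival::Surv(c(1, 1.5, 2), c(1, 0, 1)) ~ 1)
  expect_equal(km$surv, sf$surv)

  # no events: flat at 1
  km0 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km0$surv == 1))

  # no censoring: complement of the ECDF
  set.seed(19)
  t <- sort(rexp(40))
  km1 <- km_estimate(t, rep(1, 40))
  expect_equal(km1$surv, 1 - seq_len(40) / 40)
  # bounded, non-increasing
  expect_true(all(km1$surv >= 0 & km1$surv <= 1))
  expect_true(all(diff(km1$surv) <= 1e-12))
})

test_that("run_study emits the five artifact classes deterministically", {
  co <- simulate_cohort(sim_params(n = 12000, seed = 23,
                                   log_hr_per_quartile = c(0, 0, 0.1, log(1.8))))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  r1 <- run_study(co, d1, make_plots = FALSE)
  r2 <- run_study(co, d2, make_plots = FALSE)
  for (f in c("summary_by_stratum.csv", "percentile_hr.csv", "quartile_hr.csv",
              "extreme_quartile_ratios.csv", "km_vsr_quartiles.csv",
              "run_log.json")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # summary medians match the generator targets
  tg <- default_biomarker_targets()
  sm <- r1$summary
  row <- sm[sm$sex == "female" & sm$age_group == "40-59" &
              sm$measure == "sat_cm2", ]
  expect_lt(abs(row$median - 245.8) / 245.8, 0.05)
  expect_error(run_study(co[, setdiff(names(co), "vsr")], withr::local_tempdir(),
                         make_plots = FALSE),
               class = "adipoct_schema_error")
})
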