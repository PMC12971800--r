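test_that("simulated biomarker medians hit their per-stratum targets", {
  co <- simulate_cohort(sim_params(n = 60000, seed = 3))
  tg <- default_biomarker_targets()
  for (i in c(2, 6)) {  # one male, one female stratum
    cell <- co[co$sex == tg$sex[i] & co$age_group == tg$age_group[i], ]
    expect_gt(nrow(cell), 5000)
    expect_lt(abs(median(cell$sat_cm2) - tg$sat_median[i]) / tg$sat_median[i],
              0.03)
    expect_lt(abs(median(cell$vat_cm2) - tg$vat_median[i]) / tg$vat_median[i],
              0.03)
    # the IQR *ratio* is matched by the lognormal construction
    q <- quantile(cell$vat_cm2, c(0.25, 0.75), names = FALSE)
    expect_lt(abs(log(q[2] / q[1]) - log(tg$vat_q3[i] / tg$vat_q1[i])), 0.1)
  }
  expect_equal(co$vsr, co$vat_cm2 / co$sat_cm2)
})

test_that("null quartile effects give equal death rates across quartiles", {
  co <- simulate_cohort(sim_params(n = 100000, seed = 4,
                                   log_hr_per_quartile = c(0, 0, 0, 0)))
  rates <- tapply(co$event, co$true_quartile, mean)
  expect_lt(max(rates) - min(rates), 0.01)
})

test_that("a log-2 top-quartile effect halves Q4 median survival", {
  # single stratum so the baseline rate is shared; no censoring
  tg <- default_biomarker_targets()[6, ]
  tg$weight <- 1
  p <- sim_params(n = 80000, seed = 5, targets = tg,
                  log_hr_per_quartile = c(0, 0, 0, log(2)),
                  baseline_hazard = c("40-59" = 0.05),
                  admin_censor_years = 1e6)
  co <- simulate_cohort(p)
  km <- km_estimate(co$time_years, co$event, paste0("Q", co$true_quartile))
  med_of <- function(g) {
    k <- km[km$group == g, ]
    k$time[which(k$surv <= 0.5)[1]]
  }
  # exponential: median = ln2 / rate, so Q4 median is half of Q1's
  expect_lt(abs(med_of("Q4") / med_of("Q1") - 0.5), 0.05)
  expect_lt(abs(med_of("Q1") - log(2) / 0.05), 0.8)
})

test_that("censoring fraction is monotone in the administrative horizon", {
  fr <- vapply(c(2, 5, 10, 21), function(h) {
    co <- simulate_cohort(sim_params(n = 20000, seed = 6,
                                     admin_censor_years = h))
    mean(co$event == 0)
  }, numeric(1))
  expect_true(all(diff(fr) <= 0))  # longer follow-up, fewer censored
})

test_that("cohort simulation is deterministic under the seed", {
  a <- simulate_cohort(sim_params(n = 2000, seed = 7))
  b <- simulate_cohort(sim_params(n = 2000, seed = 7))
  expect_identical(a, b)
})

test_that("exclusion injection flags the expected fractions", {
  co <- simulate_cohort(sim_params(n = 10000, seed = 8))
  same <- inject_exclusions(co, rates = c(tool_failure = 0, outlier = 0,
                                          under_18 = 0, missing_ehr = 0))
  expect_identical(same, co)

  inj <- inject_exclusions(co, rates = c(tool_failure = 0.02, outlier = 0.01,
                                         under_18 = 0.05, missing_ehr = 0.03),
                           seed = 2)
  # binomial tolerance: ~4 sd
  expect_lt(abs(sum(inj$under_18) - 500), 4 * sqrt(10000 * 0.05 * 0.95))
  expect_true(all(inj$age_at_ct[inj$under_18] < 18))
  # injected outliers are pushed beyond the plausibility bound
  expect_true(all(inj$vsr[inj$outlier & !inj$tool_failure] > 10))
  expect_error(inject_exclusions(co, rates = c(outlier = 1.2)),
               class = "adipoct_invalid_spec")
})

test_that("injected exclusions are removed downstream with matching counts", {
  co <- simulate_cohort(sim_params(n = 5000, seed = 9))
  inj <- inject_exclusions(co, rates = c(tool_failure = 0.03, outlier = 0.02,
                                         under_18 = 0.02, missing_ehr = 0.04),
                           seed = 3)
  res <- apply_exclusions(inj)
  # first-matching-reason bookkeeping applied to the injected records: the
  # outlier rule acts on values (injected outliers were pushed past the VSR
  # bound; a few natural lognormal-tail outliers count too)
  out_val <- is.na(inj$vsr) | inj$vsr > 10 | inj$sat_cm2 > 1500 |
    inj$vat_cm2 > 1500
  exp_tool <- sum(inj$tool_failure)
  exp_out <- sum(!inj$tool_failure & out_val)
  exp_u18 <- sum(!inj$tool_failure & !out_val & inj$under_18)
  exp_ehr <- sum(!inj$tool_failure & !out_val & !inj$under_18 &
                   inj$missing_ehr)
  expect_equal(unname(res$counts["tool_failure"]), exp_tool)
  expect_equal(unname(res$counts["outlier"]), exp_out)
  expect_equal(unname(res$counts["under_18"]), exp_u18)
  expect_equal(unname(res$counts["missing_ehr"]), exp_ehr)
  expect_equal(nrow(res$included) + sum(res$counts), nrow(inj))
})
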