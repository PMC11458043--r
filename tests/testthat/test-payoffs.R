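# Costing and QALY-loss accounting on terminal paths.

test_that("medication costs follow the year-long regimen", {
  v <- base_values()
  expect_equal(medication_cost("ppi_standard", v), 12 * 54)
  expect_equal(medication_cost("ppi_low", v), 12 * 42)
  expect_equal(medication_cost("h2ra", v), 12 * 6)
  expect_equal(medication_cost("none", v), 0)
  # reinstated after discontinuation: nothing for the onset period, then
  # standard PPI pro-rata at 30.4375 days/month
  expect_equal(medication_cost("reinstated_none", v),
               54 * (365.25 - 20) / 30.4375, tolerance = 1e-12)
  expect_equal(medication_cost("reinstated_low", v),
               42 * 20 / 30.4375 + 54 * (365.25 - 20) / 30.4375,
               tolerance = 1e-12)
  expect_error(medication_cost("aspirin", v), "unknown regimen")
})

test_that("adverse-event costs are unit cost times utilization", {
  v <- base_values()
  expect_equal(adverse_event_cost("cdi", "hospitalized", v), 8 * 654)
  expect_equal(adverse_event_cost("pneumonia", "outpatient", v), 3 * 57)
  expect_equal(adverse_event_cost("pneumonia", "hospitalized", v), 9.8 * 654)
  expect_equal(adverse_event_cost("hypomagnesemia", "hospitalized", v),
               6 * 654)
  # non-hospitalized hypomagnesemia has no modelled utilization
  expect_equal(adverse_event_cost("hypomagnesemia", "outpatient", v), 0)
  expect_equal(adverse_event_cost("none", "not_applicable", v), 0)
})

test_that("service cost is pharmacist time valued at salary", {
  expect_equal(deprescribing_service_cost(10918, 34, 10560),
               10918 * 34 / 10560, tolerance = 1e-12)
  expect_equal(deprescribing_service_cost(10918, 0, 10560), 0)
  # doubling the working-minutes divisor halves the cost
  expect_equal(deprescribing_service_cost(10918, 34, 2 * 10560),
               deprescribing_service_cost(10918, 34, 10560) / 2)
  expect_error(deprescribing_service_cost(10918, 34, 0), "positive")
})

test_that("episode and death QALY losses follow the stated formulas", {
  expect_equal(episode_qaly_loss(0.3985, 8), 0.3985 * 8 / 365,
               tolerance = 1e-12)
  expect_equal(episode_qaly_loss(0.5597, 0), 0)
  # hospitalized pneumonia survivor: inpatient stay plus convalescence
  expect_equal(episode_qaly_loss(0.5597, 9.8) + episode_qaly_loss(0.3013, 31),
               0.5597 * 9.8 / 365 + 0.3013 * 31 / 365, tolerance = 1e-12)
  # discounted annuity of the remaining life expectancy
  expect_equal(death_qaly_loss(0.81, 10, 0), 8.1)
  expect_equal(death_qaly_loss(0.81, 10, 0.03),
               0.81 * (1 - 1.03^(-10)) / 0.03, tolerance = 1e-12)
  expect_equal(death_qaly_loss(0.81, 0, 0.03), 0)
  expect_error(episode_qaly_loss(1.2, 5), "\\[0, 1\\]")
  expect_error(death_qaly_loss(0.81, -1, 0.03), ">= 0")
})

test_that("path outcomes compose medication, event, service and death parts", {
  v <- base_values()
  paths <- path_outcomes(enumerate_paths(v), v)
  svc <- deprescribing_service_cost(v$pharmacist_salary_monthly,
                                    v$deprescribe_minutes_per_case,
                                    v$pharmacist_working_minutes_per_month)
  pick <- function(...) {
    keep <- Reduce(`&`, list(...))
    stopifnot(sum(keep) == 1)
    paths[keep, ]
  }
  # usual care, no adverse event: a year of standard PPI, no QALY loss
  p <- pick(paths$strategy == "usual_care", paths$adverse_event == "none")
  expect_equal(p$cost, 648)
  expect_equal(p$qaly_loss, 0)

  # usual-care CDI death: drug + admission; episode plus discounted death loss
  p <- pick(paths$strategy == "usual_care", paths$adverse_event == "cdi",
            paths$died)
  expect_equal(p$cost, 648 + 8 * 654)
  expect_equal(p$qaly_loss,
               0.3985 * 8 / 365 +
                 death_qaly_loss(0.81, v$remaining_life_expectancy_years,
                                 0.03),
               tolerance = 1e-12)

  # deprescribing, discontinued without rebound or event: service cost only
  p <- pick(paths$strategy == "deprescribing",
            paths$triage == "discontinued", !paths$rebound,
            paths$adverse_event == "none")
  expect_equal(p$cost, svc, tolerance = 1e-12)
  expect_equal(p$qaly_loss, 0)

  # rebound after discontinuation carries the off-medication relapse loss
  p <- pick(paths$strategy == "deprescribing",
            paths$triage == "discontinued", paths$rebound,
            paths$adverse_event == "none")
  expect_equal(p$qaly_loss, 0.0737 * 20 / 365, tolerance = 1e-12)
  expect_equal(p$cost, svc + 54 * (365.25 - 20) / 30.4375, tolerance = 1e-12)

  # every payoff finite and nonnegative
  expect_true(all(is.finite(paths$cost)) && all(paths$cost >= 0))
  expect_true(all(is.finite(paths$qaly_loss)) && all(paths$qaly_loss >= 0))
})

test_that("death paths lose strictly more QALYs than surviving siblings", {
  for (seed in c(1, 2, 3)) {
    v <- random_valid_values(seed)
    paths <- path_outcomes(enumerate_paths(v), v)
    key <- interaction(paths$strategy, paths$triage, paths$recommendation,
                       paths$rebound, paths$adverse_event, paths$ae_setting,
                       drop = TRUE)
    for (k in levels(key)) {
      sib <- paths[key == k, ]
      if (nrow(sib) == 2 && sum(sib$died) == 1) {
        expect_gt(sib$qaly_loss[sib$died], sib$qaly_loss[!sib$died])
      }
    }
  }
})

test_that("zero disutility and mortality imply zero expected QALY loss", {
  v <- base_values()
  for (nm in grep("^disutil_", names(v), value = TRUE)) v[[nm]] <- 0
  v$p_mort_cdi <- 0
  v$p_mort_pneumonia <- 0
  paths <- path_outcomes(enumerate_paths(v), v)
  for (strat in c("usual_care", "deprescribing")) {
    s <- evaluate_strategy(paths[paths$strategy == strat, ])
    expect_equal(s$expected_qaly_loss, 0)
  }
})

test_that("expected cost decomposes into medication, event and service parts", {
  v <- base_values()
  zero <- function(values, nms) { for (nm in nms) values[[nm]] <- 0; values }
  med_only <- zero(v, c("cost_hosp_per_day", "cost_clinic_visit",
                        "pharmacist_salary_monthly"))
  ae_only <- zero(v, c("cost_ppi_standard_monthly", "cost_ppi_low_monthly",
                       "cost_h2ra_monthly", "pharmacist_salary_monthly"))
  svc_only <- zero(v, c("cost_ppi_standard_monthly", "cost_ppi_low_monthly",
                        "cost_h2ra_monthly", "cost_hosp_per_day",
                        "cost_clinic_visit"))
  expected_cost <- function(values, strat) {
    paths <- path_outcomes(enumerate_paths(values), values)
    evaluate_strategy(paths[paths$strategy == strat, ])$expected_cost
  }
  for (strat in c("usual_care", "deprescribing")) {
    expect_equal(expected_cost(v, strat),
                 expected_cost(med_only, strat) +
                   expected_cost(ae_only, strat) +
                   expected_cost(svc_only, strat),
                 tolerance = 1e-12)
  }
})
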