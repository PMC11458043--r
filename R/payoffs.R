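# One-year direct medical cost and QALY loss attached to each terminal
# path. Costs: medication (pro-rata by days at 30.4375 days/month),
# adverse-event treatment (length of stay x daily fee, or clinic visits),
# and the pharmacist service cost in the deprescribing arm. QALY losses:
# disutility x duration/365 for symptomatic episodes, plus the discounted
# loss of remaining life-years on death paths.

DAYS_PER_MONTH <- 30.4375
DAYS_PER_YEAR_MED <- 12 * DAYS_PER_MONTH  # 365.25: medication pro-rata basis
DAYS_PER_YEAR_QALY <- 365                 # episode QALY denominator

#' Year-long medication cost of a regimen
#'
#' Twelve months of the regimen actually followed. Reinstated regimens
#' (rebound after deprescribing) charge the deprescribed regimen for the
#' rebound-onset period and standard-dose PPI for the remainder of the
#' year, pro-rata at 30.4375 days/month.
#'
#' @param regimen one of \code{"ppi_standard"}, \code{"ppi_low"},
#'   \code{"h2ra"}, \code{"none"}, \code{"reinstated_none"},
#'   \code{"reinstated_low"}, \code{"reinstated_h2ra"}.
#' @param values realized parameter mapping (see [param_values()]).
#' @return cost in USD (vectorized over the mapping's draws).
#' @export
medication_cost <- function(regimen, values) {
  monthly <- list(ppi_standard = values$cost_ppi_standard_monthly,
                  ppi_low = values$cost_ppi_low_monthly,
                  h2ra = values$cost_h2ra_monthly,
                  none = 0)
  if (regimen %in% names(monthly)) {
    return(12 * monthly[[regimen]])
  }
  pre <- switch(regimen,
                reinstated_none = monthly$none,
                reinstated_low = monthly$ppi_low,
                reinstated_h2ra = monthly$h2ra,
                stop("unknown regimen: ", regimen))
  onset <- values$rebound_onset_days
  pre * onset / DAYS_PER_MONTH +
    values$cost_ppi_standard_monthly *
      (DAYS_PER_YEAR_MED - onset) / DAYS_PER_MONTH
}

#' Treatment cost of an adverse-event branch
#'
#' Hospitalized events cost length-of-stay times the daily inpatient fee;
#' outpatient pneumonia costs the clinic visits; non-hospitalized
#' hypomagnesemia has no modelled utilization. Death paths incur the full
#' hospitalization cost (the admission occurred).
#'
#' @param adverse_event \code{"none"}, \code{"hypomagnesemia"},
#'   \code{"pneumonia"} or \code{"cdi"}.
#' @param ae_setting \code{"not_applicable"}, \code{"outpatient"} or
#'   \code{"hospitalized"}.
#' @param values realized parameter mapping.
#' @return cost in USD.
#' @export
adverse_event_cost <- function(adverse_event, ae_setting, values) {
  if (adverse_event == "none") return(0)
  if (ae_setting == "outpatient") {
    return(switch(adverse_event,
                  pneumonia = values$n_clinic_visits_pneumonia *
                    values$cost_clinic_visit,
                  hypomagnesemia = 0,
                  stop("outpatient setting not modelled for ", adverse_event)))
  }
  los <- switch(adverse_event,
                hypomagnesemia = values$los_hypomag_days,
                pneumonia = values$los_pneumonia_days,
                cdi = values$los_cdi_days)
  los * values$cost_hosp_per_day
}

#' Per-patient cost of the pharmacist deprescribing service
#'
#' Pharmacist time valued at the monthly salary divided by working minutes
#' per month; applied once to every patient evaluated in the deprescribing
#' arm.
#'
#' @param salary_monthly pharmacist monthly salary, USD.
#' @param minutes_per_case pharmacist time per case, minutes.
#' @param working_minutes_per_month working minutes in a month.
#' @return cost in USD.
#' @export
deprescribing_service_cost <- function(salary_monthly, minutes_per_case,
                                       working_minutes_per_month) {
  if (any(working_minutes_per_month <= 0)) {
    stop("working_minutes_per_month must be positive", call. = FALSE)
  }
  salary_monthly / working_minutes_per_month * minutes_per_case
}

#' QALY loss of a symptomatic episode
#'
#' @param disutility utility decrement while the episode lasts, in
#'   \code{[0, 1]}.
#' @param duration_days episode duration in days.
#' @return QALYs lost: \code{disutility * duration_days / 365}.
#' @export
episode_qaly_loss <- function(disutility, duration_days) {
  if (any(disutility < 0 | disutility > 1)) {
    stop("disutility must lie in [0, 1]", call. = FALSE)
  }
  if (any(duration_days < 0)) stop("duration must be >= 0", call. = FALSE)
  disutility * duration_days / DAYS_PER_YEAR_QALY
}

#' Discounted QALY loss of premature death
#'
#' Age-specific utility times the annuity factor of the remaining life
#' expectancy at the annual discount rate:
#' \code{u * (1 - (1 + r)^(-LE)) / r}, continuous in LE, with the
#' undiscounted limit \code{u * LE} at \code{r = 0}.
#'
#' @param utility age-specific health utility in \code{[0, 1]}.
#' @param life_expectancy_years remaining life expectancy, years.
#' @param discount_rate annual discount rate (>= 0).
#' @return QALYs lost.
#' @export
death_qaly_loss <- function(utility, life_expectancy_years, discount_rate) {
  if (any(utility < 0 | utility > 1)) {
    stop("utility must lie in [0, 1]", call. = FALSE)
  }
  if (any(life_expectancy_years < 0)) {
    stop("life expectancy must be >= 0", call. = FALSE)
  }
  if (any(discount_rate < 0)) stop("discount rate must be >= 0", call. = FALSE)
  annuity <- ifelse(discount_rate == 0, life_expectancy_years,
                    (1 - (1 + discount_rate)^(-life_expectancy_years)) /
                      discount_rate)
  utility * annuity
}

# QALY loss of the adverse-event branch itself (episode disutilities plus,
# on death paths, the discounted remaining-life loss). Hospitalized
# pneumonia survivors additionally accrue the ambulatory disutility over
# convalescence; the death loss replaces any post-event accrual.
.ae_qaly_loss <- function(adverse_event, ae_setting, died, values) {
  dloss <- if (died) {
    death_qaly_loss(values$utility_age65plus,
                    values$remaining_life_expectancy_years,
                    values$discount_rate_annual)
  } else 0
  episode <- switch(adverse_event,
    none = 0,
    hypomagnesemia = if (ae_setting == "hospitalized") {
      episode_qaly_loss(values$disutil_hosp_hypomag, values$los_hypomag_days)
    } else 0,
    pneumonia = if (ae_setting == "outpatient") {
      episode_qaly_loss(values$disutil_amb_pneumonia,
                        values$outpatient_pneumonia_days)
    } else {
      episode_qaly_loss(values$disutil_hosp_pneumonia,
                        values$los_pneumonia_days) +
        (if (died) 0 else
          episode_qaly_loss(values$disutil_amb_pneumonia,
                            values$convalescence_pneumonia_days))
    },
    cdi = episode_qaly_loss(values$disutil_cdi, values$los_cdi_days))
  episode + dloss
}

# rebound episode QALY loss: off-medication disutility after
# discontinuation, on-medication after dose reduction or switch, accrued
# over the rebound-onset period before reinstatement
.rebound_qaly_loss <- function(recommendation, values) {
  d <- if (recommendation == "discontinue") {
    values$disutil_relapse_off_meds
  } else {
    values$disutil_relapse_on_meds
  }
  episode_qaly_loss(d, values$rebound_onset_days)
}

#' Attach cost and QALY-loss payoffs to terminal paths
#'
#' Composes medication, adverse-event and service costs, and rebound,
#' adverse-event and death QALY losses, for every row of an enumerated path
#' table.
#'
#' @param paths a path table from [enumerate_paths()].
#' @param values the realized parameter mapping the paths were enumerated
#'   under.
#' @return the path table with \code{cost} and \code{qaly_loss} columns
#'   appended.
#' @export
path_outcomes <- function(paths, values) {
  n <- nrow(paths)
  cost <- numeric(n)
  qaly <- numeric(n)
  svc <- deprescribing_service_cost(values$pharmacist_salary_monthly,
                                    values$deprescribe_minutes_per_case,
                                    values$pharmacist_working_minutes_per_month)
  for (i in seq_len(n)) {
    cost[i] <- medication_cost(paths$regimen[i], values) +
      adverse_event_cost(paths$adverse_event[i], paths$ae_setting[i], values) +
      (if (paths$strategy[i] == "deprescribing") svc else 0)
    qaly[i] <- .ae_qaly_loss(paths$adverse_event[i], paths$ae_setting[i],
                             paths$died[i], values) +
      (if (paths$rebound[i]) .rebound_qaly_loss(paths$recommendation[i],
                                                values) else 0)
  }
  paths$cost <- cost
  paths$qaly_loss <- qaly
  paths
}
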