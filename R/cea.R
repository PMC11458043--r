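# Expected-value rollback, incremental analysis, dominance classification,
# net monetary benefit, and the user-facing decision_cea() evaluator.

#' Expected cost and QALY loss of a strategy
#'
#' Probability-weighted sums over a table of terminal paths with attached
#' payoffs. This brute-force path sum is the reference against which any
#' rollback shortcut is verified.
#'
#' @param paths data frame with columns \code{probability}, \code{cost} and
#'   \code{qaly_loss} (e.g. one strategy's rows of [path_outcomes()], or a
#'   flattened synthetic model).
#' @param label optional strategy label carried through to the result.
#' @return list of class \code{strategy_result}: \code{strategy},
#'   \code{expected_cost}, \code{expected_qaly_loss}.
#' @export
evaluate_strategy <- function(paths, label = NULL) {
  if (is.null(paths) || nrow(paths) == 0) {
    stop("empty path set", call. = FALSE)
  }
  stopifnot(all(c("probability", "cost", "qaly_loss") %in% names(paths)))
  tot <- sum(paths$probability)
  if (abs(tot - 1) > 1e-6) {
    warning("terminal path probabilities sum to ", format(tot, digits = 10),
            ", not 1")
  }
  structure(list(strategy = label %||% "strategy",
                 expected_cost = sum(paths$probability * paths$cost),
                 expected_qaly_loss = sum(paths$probability * paths$qaly_loss)),
            class = "strategy_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.strategy_result <- function(x, ...) {
  cat(x$strategy, ": expected cost USD ",
      format(round(x$expected_cost, 2), big.mark = ","),
      ", expected QALY loss ", signif(x$expected_qaly_loss, 5), "\n", sep = "")
  invisible(x)
}

#' Net monetary benefit
#'
#' \code{wtp * qaly_saved - incremental_cost}; positive exactly when the
#' intervention is cost-effective at the willingness-to-pay threshold.
#'
#' @param incremental_cost intervention cost minus comparator cost, USD.
#'   May also be a \code{cea_increment} object, in which case
#'   \code{qaly_saved} is taken from it.
#' @param qaly_saved comparator QALY loss minus intervention QALY loss.
#' @param wtp willingness-to-pay threshold, USD per QALY.
#' @return net monetary benefit in USD (vectorized).
#' @export
net_monetary_benefit <- function(incremental_cost, qaly_saved = NULL,
                                 wtp) {
  if (inherits(incremental_cost, "cea_increment")) {
    inc <- incremental_cost
    return(wtp * inc$qaly_saved - inc$incremental_cost)
  }
  wtp * qaly_saved - incremental_cost
}

#' Incremental cost-effectiveness analysis of two strategies
#'
#' Computes incremental cost (intervention minus comparator), QALYs saved
#' (comparator loss minus intervention loss), the ICER, a dominance
#' classification, and the cost-effectiveness verdict at a willingness-to-pay
#' threshold. The ICER is reported even for dominant strategies (as a
#' negative ratio); the dominance flag, not the ICER sign, drives the
#' verdict. When no QALYs are saved the classification is decided on cost
#' alone and the ICER is undefined (\code{NA}).
#'
#' @param intervention,comparator \code{strategy_result} objects.
#' @param wtp willingness-to-pay threshold, USD per QALY.
#' @return list of class \code{cea_increment}: \code{incremental_cost},
#'   \code{qaly_saved}, \code{icer}, \code{dominance} (one of
#'   \code{"dominant"}, \code{"dominated"}, \code{"trade_off"},
#'   \code{"equivalent"}), \code{cost_effective_at_wtp}, \code{nmb},
#'   \code{wtp}.
#' @export
incremental_analysis <- function(intervention, comparator, wtp) {
  ic <- intervention$expected_cost - comparator$expected_cost
  qs <- comparator$expected_qaly_loss - intervention$expected_qaly_loss
  stopifnot(is.finite(ic), is.finite(qs), is.finite(wtp))
  icer <- if (qs != 0) ic / qs else NA_real_
  dominance <-
    if (qs > 0 && ic < 0) "dominant"
    else if (qs < 0 && ic > 0) "dominated"
    else if (qs == 0 && ic == 0) "equivalent"
    else if (qs == 0) { if (ic < 0) "dominant" else "dominated" }
    else "trade_off"
  nmb <- wtp * qs - ic
  structure(list(intervention = intervention$strategy,
                 comparator = comparator$strategy,
                 incremental_cost = ic, qaly_saved = qs, icer = icer,
                 dominance = dominance,
                 cost_effective_at_wtp = nmb > 0,
                 nmb = nmb, wtp = wtp),
            class = "cea_increment")
}

#' @export
print.cea_increment <- function(x, ...) {
  cat("Incremental analysis (", x$intervention, " vs ", x$comparator, ")\n",
      sep = "")
  cat("  incremental cost: USD ", format(round(x$incremental_cost, 2),
                                         big.mark = ","), "\n", sep = "")
  cat("  QALYs saved:      ", signif(x$qaly_saved, 5), "\n", sep = "")
  icer_txt <- if (is.na(x$icer)) "undefined" else
    format(round(x$icer), big.mark = ",")
  cat("  ICER:             ", icer_txt, " (", x$dominance, ")\n", sep = "")
  cat("  NMB at WTP ", format(x$wtp, big.mark = ","), ": USD ",
      format(round(x$nmb, 2), big.mark = ","), " -> ",
      if (x$cost_effective_at_wtp) "cost-effective" else "not cost-effective",
      "\n", sep = "")
  invisible(x)
}

# --- vectorized rollback -----------------------------------------------

# logical vector: does every exposure class admit a no-event branch?
.ae_draw_valid <- function(values) {
  ok <- TRUE
  for (expo in c("standard", "low", "baseline")) {
    pe <- .ae_probs(values, expo)
    ok <- ok & (pe$hypomagnesemia + pe$pneumonia + pe$cdi < 1)
  }
  ok
}

# expected adverse-event cost and QALY loss per patient of one exposure
# class (vectorized over draws)
.ae_expectations <- function(values, exposure) {
  pe <- .ae_probs(values, exposure)
  hh <- values$p_hosp_hypomag; hp <- values$p_hosp_pneumonia
  mp <- values$p_mort_pneumonia; mc <- values$p_mort_cdi
  cday <- values$cost_hosp_per_day
  dloss <- death_qaly_loss(values$utility_age65plus,
                           values$remaining_life_expectancy_years,
                           values$discount_rate_annual)
  q_hyp <- episode_qaly_loss(values$disutil_hosp_hypomag,
                             values$los_hypomag_days)
  q_pne_in <- episode_qaly_loss(values$disutil_hosp_pneumonia,
                                values$los_pneumonia_days)
  q_pne_amb <- episode_qaly_loss(values$disutil_amb_pneumonia,
                                 values$outpatient_pneumonia_days)
  q_pne_conv <- episode_qaly_loss(values$disutil_amb_pneumonia,
                                  values$convalescence_pneumonia_days)
  q_cdi <- episode_qaly_loss(values$disutil_cdi, values$los_cdi_days)
  cost <- pe$hypomagnesemia * hh * values$los_hypomag_days * cday +
    pe$pneumonia * ((1 - hp) * values$n_clinic_visits_pneumonia *
                      values$cost_clinic_visit +
                    hp * values$los_pneumonia_days * cday) +
    pe$cdi * values$los_cdi_days * cday
  qaly <- pe$hypomagnesemia * hh * q_hyp +
    pe$pneumonia * ((1 - hp) * q_pne_amb +
                    hp * ((1 - mp) * (q_pne_in + q_pne_conv) +
                          mp * (q_pne_in + dloss))) +
    pe$cdi * ((1 - mc) * q_cdi + mc * (q_cdi + dloss))
  list(cost = cost, qaly = qaly)
}

# expected cost and QALY loss of both strategies; vectorized over draws.
# Tree-walking shortcut: must (and is tested to) agree with the brute-force
# path enumeration to floating-point accuracy.
rollback_expectations <- function(values) {
  if (!all(.ae_draw_valid(values))) {
    stop("adverse-event probabilities sum to >= 1 in at least one draw",
         call. = FALSE)
  }
  ae_s <- .ae_expectations(values, "standard")
  ae_l <- .ae_expectations(values, "low")
  ae_b <- .ae_expectations(values, "baseline")
  med_s <- medication_cost("ppi_standard", values)

  cost_uc <- med_s + ae_s$cost
  qaly_uc <- ae_s$qaly

  pi_in <- values$p_inappropriate
  mix <- .rec_mix(values)
  acc <- list(discontinue = values$p_accept_discontinue,
              dose_down = values$p_accept_dosedown,
              switch = values$p_accept_switch)
  reb <- list(discontinue = values$p_rebound_discontinue,
              dose_down = values$p_rebound_dosedown,
              switch = values$p_rebound_switch)
  w_rec <- lapply(mix, function(m) pi_in * m)
  w_std <- (1 - pi_in) +
    w_rec$discontinue * (1 - acc$discontinue) +
    w_rec$dose_down * (1 - acc$dose_down) +
    w_rec$switch * (1 - acc$switch)
  w_reb <- list(discontinue = w_rec$discontinue * acc$discontinue *
                  reb$discontinue,
                dose_down = w_rec$dose_down * acc$dose_down * reb$dose_down,
                switch = w_rec$switch * acc$switch * reb$switch)
  w_ok <- list(discontinue = w_rec$discontinue * acc$discontinue *
                 (1 - reb$discontinue),
               dose_down = w_rec$dose_down * acc$dose_down *
                 (1 - reb$dose_down),
               switch = w_rec$switch * acc$switch * (1 - reb$switch))

  svc <- deprescribing_service_cost(values$pharmacist_salary_monthly,
                                    values$deprescribe_minutes_per_case,
                                    values$pharmacist_working_minutes_per_month)
  rebq <- list(discontinue = .rebound_qaly_loss("discontinue", values),
               dose_down = .rebound_qaly_loss("dose_down", values),
               switch = .rebound_qaly_loss("switch", values))

  cost_dep <- svc +
    w_std * (med_s + ae_s$cost) +
    w_reb$discontinue * (medication_cost("reinstated_none", values) +
                           ae_s$cost) +
    w_reb$dose_down * (medication_cost("reinstated_low", values) + ae_s$cost) +
    w_reb$switch * (medication_cost("reinstated_h2ra", values) + ae_s$cost) +
    w_ok$discontinue * (medication_cost("none", values) + ae_b$cost) +
    w_ok$dose_down * (medication_cost("ppi_low", values) + ae_l$cost) +
    w_ok$switch * (medication_cost("h2ra", values) + ae_b$cost)
  qaly_dep <- w_std * ae_s$qaly +
    w_reb$discontinue * (ae_s$qaly + rebq$discontinue) +
    w_reb$dose_down * (ae_s$qaly + rebq$dose_down) +
    w_reb$switch * (ae_s$qaly + rebq$switch) +
    w_ok$discontinue * ae_b$qaly +
    w_ok$dose_down * ae_l$qaly +
    w_ok$switch * ae_b$qaly

  list(cost_usual_care = cost_uc, qaly_usual_care = qaly_uc,
       cost_deprescribing = cost_dep, qaly_deprescribing = qaly_dep)
}

# --- user-facing evaluator ---------------------------------------------

#' Evaluate the deprescribing cost-effectiveness model
#'
#' Builds the two-strategy decision tree at the base-case (or supplied)
#' parameter values, attaches payoffs, rolls back expected cost and QALY
#' loss per strategy, and performs the incremental analysis against usual
#' care.
#'
#' @param params a \code{cea_parameters} object; defaults to the bundled
#'   published parameter set.
#' @param wtp willingness-to-pay threshold, USD per QALY; defaults to the
#'   config's run setting.
#' @param values optional realized parameter mapping overriding
#'   \code{param_values(params)} (used internally by sensitivity analyses).
#' @return object of class \code{cea}: the enumerated path table with
#'   payoffs (\code{$paths}), per-strategy results (\code{$strategies}),
#'   the incremental analysis (\code{$incremental}), the parameters and the
#'   threshold. Has \code{print}, \code{summary}, \code{simulate} (the
#'   probabilistic sensitivity analysis) and \code{as.data.frame} methods.
#' @examples
#' fit <- decision_cea()
#' fit
#' summary(fit)
#' @export
decision_cea <- function(params = default_parameters(), wtp = NULL,
                         values = NULL) {
  stopifnot(inherits(params, "cea_parameters"))
  values <- values %||% param_values(params)
  wtp <- wtp %||% values$wtp_threshold_usd
  paths <- path_outcomes(enumerate_paths(values), values)
  strategies <- list(
    usual_care = evaluate_strategy(paths[paths$strategy == "usual_care", ],
                                   label = "usual_care"),
    deprescribing = evaluate_strategy(
      paths[paths$strategy == "deprescribing", ], label = "deprescribing"))
  incremental <- incremental_analysis(strategies$deprescribing,
                                      strategies$usual_care, wtp = wtp)
  structure(list(params = params, values = values, wtp = wtp, paths = paths,
                 strategies = strategies, incremental = incremental),
            class = "cea")
}

#' @export
print.cea <- function(x, ...) {
  cat("Decision-tree cost-effectiveness analysis: PPI deprescribing vs usual care\n")
  cat("one-year horizon, ", nrow(x$paths), " terminal paths\n\n", sep = "")
  print(summary(x)$table, row.names = FALSE)
  cat("\nVerdict: deprescribing is ", x$incremental$dominance,
      if (x$incremental$cost_effective_at_wtp) {
        paste0(" and cost-effective at WTP USD ",
               format(x$wtp, big.mark = ","), "/QALY")
      } else "",
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.cea <- function(object, ...) {
  s <- object$strategies
  inc <- object$incremental
  table <- data.frame(
    strategy = c("Usual care", "PPI deprescribing"),
    cost_usd = c(s$usual_care$expected_cost,
                 s$deprescribing$expected_cost),
    incremental_cost_usd = c(NA, inc$incremental_cost),
    qaly_loss = c(s$usual_care$expected_qaly_loss,
                  s$deprescribing$expected_qaly_loss),
    qaly_saved = c(NA, inc$qaly_saved),
    icer = c(NA, inc$icer))
  structure(list(table = table, incremental = inc, wtp = object$wtp),
            class = "summary.cea")
}

#' @export
print.summary.cea <- function(x, ...) {
  tab <- x$table
  tab$cost_usd <- round(tab$cost_usd, 2)
  tab$incremental_cost_usd <- round(tab$incremental_cost_usd, 2)
  tab$qaly_loss <- signif(tab$qaly_loss, 5)
  tab$qaly_saved <- signif(tab$qaly_saved, 5)
  tab$icer <- round(tab$icer)
  print(tab, row.names = FALSE)
  cat("\n")
  print(x$incremental)
  invisible(x)
}

#' @export
coef.cea <- function(object, ...) {
  s <- object$strategies
  inc <- object$incremental
  c(cost_usual_care = s$usual_care$expected_cost,
    cost_deprescribing = s$deprescribing$expected_cost,
    qaly_loss_usual_care = s$usual_care$expected_qaly_loss,
    qaly_loss_deprescribing = s$deprescribing$expected_qaly_loss,
    incremental_cost = inc$incremental_cost,
    qaly_saved = inc$qaly_saved,
    icer = inc$icer,
    nmb = inc$nmb)
}

#' @export
as.data.frame.cea <- function(x, ...) x$paths

#' Probabilistic sensitivity analysis as \code{simulate()}
#'
#' @param object a fitted \code{cea} object.
#' @param nsim number of Monte Carlo draws.
#' @param seed integer seed for reproducibility.
#' @param ... passed to [run_psa()].
#' @return a \code{cea_psa} object; see [run_psa()].
#' @importFrom stats simulate
#' @export
simulate.cea <- function(object, nsim = 10000, seed = NULL, ...) {
  run_psa(object$params, n_draws = nsim, seed = seed, wtp = object$wtp, ...)
}
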