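# Decision-tree structure: two strategies (pharmacist-led deprescribing vs
# usual care), inappropriate-use triage, three deprescribing recommendations
# with prescriber acceptance and GERD rebound, then adverse-event branches
# (hypomagnesemia, pneumonia, Clostridium difficile infection) with
# hospitalization and mortality.

#' Convert a baseline probability through an odds ratio
#'
#' Maps the event probability in the unexposed group and an odds ratio to
#' the exposed-group probability on the odds scale:
#' \code{or * p0 / (1 - p0 + or * p0)}. Degenerate baselines (0 or 1) are
#' returned unchanged. Vectorized in both arguments.
#'
#' @param p0 baseline (unexposed) probability in \code{[0, 1]}.
#' @param or odds ratio, positive.
#' @return exposed-group probability.
#' @export
odds_ratio_to_probability <- function(p0, or) {
  if (any(p0 < 0 | p0 > 1)) stop("p0 must lie in [0, 1]", call. = FALSE)
  if (any(or <= 0)) stop("odds ratio must be positive", call. = FALSE)
  ifelse(p0 %in% c(0, 1), p0, or * p0 / (1 - p0 + or * p0))
}

# regimen actually followed over the year, given triage outcome and rebound
.regimen_for <- function(triage, rebound) {
  switch(triage,
         usual_care = ,
         appropriate = ,
         not_accepted = "ppi_standard",
         discontinued = if (rebound) "reinstated_none" else "none",
         dose_reduced = if (rebound) "reinstated_low" else "ppi_low",
         switched = if (rebound) "reinstated_h2ra" else "h2ra",
         stop("unknown triage state: ", triage))
}

# adverse-event risk class of a regimen: standard-dose ORs, low-dose ORs,
# or the non-PPI baseline rates
.exposure_for <- function(regimen) {
  switch(regimen,
         ppi_standard = ,
         reinstated_none = ,
         reinstated_low = ,
         reinstated_h2ra = "standard",
         ppi_low = "low",
         h2ra = ,
         none = "baseline",
         stop("unknown regimen: ", regimen))
}

#' Effective adverse-event exposure of a path state
#'
#' Returns the drug-exposure regimen that determines a patient's
#' adverse-event risk over the year. Usual care, appropriate use,
#' non-accepted recommendations, and any rebound (reinstated) path carry
#' standard-dose PPI exposure; dose reduction without rebound carries
#' low-dose exposure; discontinuation or switch to H2RA without rebound
#' carries the non-PPI baseline rates.
#'
#' @param triage one of \code{"usual_care"}, \code{"appropriate"},
#'   \code{"not_accepted"}, \code{"discontinued"}, \code{"dose_reduced"},
#'   \code{"switched"}.
#' @param rebound logical: did GERD rebound (with PPI reinstatement) occur?
#' @return one of \code{"ppi_standard"}, \code{"ppi_low"}, \code{"h2ra"},
#'   \code{"none"}, \code{"ppi_reinstated"}.
#' @export
effective_exposure <- function(triage, rebound = FALSE) {
  if (rebound && !triage %in% c("discontinued", "dose_reduced", "switched")) {
    stop("rebound is only reachable after a deprescribing action",
         call. = FALSE)
  }
  reg <- .regimen_for(triage, rebound)
  if (startsWith(reg, "reinstated")) "ppi_reinstated" else reg
}

# yearly adverse-event probabilities for one exposure class
.ae_probs <- function(values, exposure) {
  p0 <- list(hypomagnesemia = values$p0_hypomag,
             pneumonia = values$p0_pneumonia,
             cdi = values$p0_cdi)
  if (exposure == "baseline") return(p0)
  ors <- if (exposure == "standard") {
    list(values$or_ppi_hypomag, values$or_ppi_pneumonia, values$or_ppi_cdi)
  } else {
    list(values$or_lowppi_hypomag, values$or_lowppi_pneumonia,
         values$or_lowppi_cdi)
  }
  list(hypomagnesemia = odds_ratio_to_probability(p0$hypomagnesemia, ors[[1]]),
       pneumonia = odds_ratio_to_probability(p0$pneumonia, ors[[2]]),
       cdi = odds_ratio_to_probability(p0$cdi, ors[[3]]))
}

# renormalized recommendation mix (guards one-at-a-time perturbation)
.rec_mix <- function(values) {
  tot <- values$p_rec_discontinue + values$p_rec_dosedown + values$p_rec_switch
  list(discontinue = values$p_rec_discontinue / tot,
       dose_down = values$p_rec_dosedown / tot,
       switch = values$p_rec_switch / tot)
}

# exposure groups of a strategy: data.frame of (triage, recommendation,
# rebound, regimen, exposure, weight); weights sum to 1
.exposure_groups <- function(values, strategy) {
  if (strategy == "usual_care") {
    return(data.frame(triage = "usual_care", recommendation = "none",
                      rebound = FALSE, regimen = "ppi_standard",
                      exposure = "standard", weight = 1,
                      stringsAsFactors = FALSE))
  }
  pi_in <- values$p_inappropriate
  mix <- .rec_mix(values)
  acc <- list(discontinue = values$p_accept_discontinue,
              dose_down = values$p_accept_dosedown,
              switch = values$p_accept_switch)
  reb <- list(discontinue = values$p_rebound_discontinue,
              dose_down = values$p_rebound_dosedown,
              switch = values$p_rebound_switch)
  triage_for <- c(discontinue = "discontinued", dose_down = "dose_reduced",
                  switch = "switched")
  rows <- list(
    data.frame(triage = "appropriate", recommendation = "none",
               rebound = FALSE, regimen = "ppi_standard",
               exposure = "standard", weight = 1 - pi_in,
               stringsAsFactors = FALSE))
  for (r in c("discontinue", "dose_down", "switch")) {
    w_rec <- pi_in * mix[[r]]
    rows[[length(rows) + 1L]] <- data.frame(
      triage = "not_accepted", recommendation = r, rebound = FALSE,
      regimen = "ppi_standard", exposure = "standard",
      weight = w_rec * (1 - acc[[r]]), stringsAsFactors = FALSE)
    for (rb in c(TRUE, FALSE)) {
      regimen <- .regimen_for(triage_for[[r]], rb)
      rows[[length(rows) + 1L]] <- data.frame(
        triage = triage_for[[r]], recommendation = r, rebound = rb,
        regimen = regimen, exposure = .exposure_for(regimen),
        weight = w_rec * acc[[r]] * (if (rb) reb[[r]] else 1 - reb[[r]]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# adverse-event sub-branches for one exposure class: 8 terminal splits
.ae_branches <- function(values, exposure) {
  pe <- .ae_probs(values, exposure)
  p_none <- 1 - (pe$hypomagnesemia + pe$pneumonia + pe$cdi)
  if (any(p_none <= 0)) {
    stop("adverse-event probabilities sum to >= 1 for exposure '",
         exposure, "'; cannot form the no-event branch", call. = FALSE)
  }
  hh <- values$p_hosp_hypomag
  hp <- values$p_hosp_pneumonia
  mp <- values$p_mort_pneumonia
  mc <- values$p_mort_cdi
  data.frame(
    adverse_event = c("none", "hypomagnesemia", "hypomagnesemia",
                      "pneumonia", "pneumonia", "pneumonia", "cdi", "cdi"),
    ae_setting = c("not_applicable", "outpatient", "hospitalized",
                   "outpatient", "hospitalized", "hospitalized",
                   "hospitalized", "hospitalized"),
    died = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, TRUE),
    p_ae = c(p_none,
             pe$hypomagnesemia * (1 - hh),
             pe$hypomagnesemia * hh,
             pe$pneumonia * (1 - hp),
             pe$pneumonia * hp * (1 - mp),
             pe$pneumonia * hp * mp,
             pe$cdi * (1 - mc),
             pe$cdi * mc),
    stringsAsFactors = FALSE)
}

#' Enumerate the terminal paths of the decision tree
#'
#' Expands the full tree for both strategies at one realized parameter
#' mapping and returns every terminal path with its probability. Within each
#' strategy the probabilities sum to 1.
#'
#' @param values a realized parameter mapping, e.g. [param_values()] of a
#'   parameter set, or one draw from [sample_parameters()].
#' @param strategies which strategies to enumerate.
#' @return data frame with one row per terminal path: strategy, triage
#'   outcome, recommendation, rebound flag, year-long regimen, adverse-event
#'   exposure class, adverse event, care setting, death flag, probability.
#' @export
enumerate_paths <- function(values,
                            strategies = c("usual_care", "deprescribing")) {
  stopifnot(all(strategies %in% c("usual_care", "deprescribing")))
  if (any(lengths(values) != 1)) {
    stop("enumerate_paths expects one realized draw (scalar values); ",
         "use the vectorized rollback for batched draws", call. = FALSE)
  }
  out <- list()
  for (strat in strategies) {
    grp <- .exposure_groups(values, strat)
    for (i in seq_len(nrow(grp))) {
      ae <- .ae_branches(values, grp$exposure[i])
      block <- cbind(strategy = strat,
                     grp[rep(i, nrow(ae)), , drop = FALSE], ae,
                     row.names = NULL)
      block$probability <- block$weight * block$p_ae
      out[[length(out) + 1L]] <- block
    }
  }
  paths <- do.call(rbind, out)
  rownames(paths) <- NULL
  paths[, c("strategy", "triage", "recommendation", "rebound", "regimen",
            "exposure", "adverse_event", "ae_setting", "died", "probability")]
}
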