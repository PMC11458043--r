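# One-way (tornado) sensitivity analysis with threshold detection, and
# probabilistic sensitivity analysis (Monte Carlo) with acceptability
# summaries.

# scalar incremental analysis from a realized mapping, via the rollback
.inc_from_values <- function(values, wtp) {
  rb <- rollback_expectations(values)
  uc <- structure(list(strategy = "usual_care",
                       expected_cost = rb$cost_usual_care,
                       expected_qaly_loss = rb$qaly_usual_care),
                  class = "strategy_result")
  dep <- structure(list(strategy = "deprescribing",
                        expected_cost = rb$cost_deprescribing,
                        expected_qaly_loss = rb$qaly_deprescribing),
                   class = "strategy_result")
  incremental_analysis(dep, uc, wtp = wtp)
}

#' One-way sensitivity analysis over all non-fixed parameters
#'
#' Re-evaluates the model with each non-fixed parameter set to the ends of
#' its sensitivity range, all others held at base case, and ranks
#' parameters by the spread of the tracked outcome (tornado order). Flags
#' any parameter whose low/high evaluation changes the cost-effectiveness
#' verdict relative to base case (a threshold).
#'
#' @param params a \code{cea_parameters} object.
#' @param tracked outcome to track: \code{"icer"} (default, matching the
#'   published tornado), \code{"nmb"}, \code{"incremental_cost"} or
#'   \code{"qaly_saved"}. NMB is the stabler choice when QALYs saved can
#'   cross zero within a range.
#' @param wtp willingness-to-pay threshold; defaults to the config setting.
#' @return object of class \code{cea_owsa}: a data frame with one row per
#'   non-fixed parameter (tracked outcome at the low and high end, spread,
#'   dominance and verdict at each end, threshold flag), sorted by
#'   decreasing spread. Attributes carry the base-case incremental result.
#' @export
one_way_sa <- function(params,
                       tracked = c("icer", "nmb", "incremental_cost",
                                   "qaly_saved"),
                       wtp = NULL) {
  stopifnot(inherits(params, "cea_parameters"))
  tracked <- match.arg(tracked)
  base_values <- param_values(params)
  wtp <- wtp %||% base_values$wtp_threshold_usd
  base_inc <- .inc_from_values(base_values, wtp)
  pick <- function(inc) switch(tracked, icer = inc$icer, nmb = inc$nmb,
                               incremental_cost = inc$incremental_cost,
                               qaly_saved = inc$qaly_saved)
  tab <- params$table[params$table$dist != "fixed", ]
  rows <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    nm <- tab$name[i]
    at <- function(v) {
      values <- base_values
      values[[nm]] <- v
      .inc_from_values(values, wtp)
    }
    inc_lo <- at(tab$low[i])
    inc_hi <- at(tab$high[i])
    rows[[i]] <- data.frame(
      parameter = nm, low = tab$low[i], high = tab$high[i],
      outcome_at_low = pick(inc_lo), outcome_at_high = pick(inc_hi),
      dominance_at_low = inc_lo$dominance,
      dominance_at_high = inc_hi$dominance,
      cost_effective_at_low = inc_lo$cost_effective_at_wtp,
      cost_effective_at_high = inc_hi$cost_effective_at_wtp,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$spread <- abs(out$outcome_at_high - out$outcome_at_low)
  out$threshold <- out$cost_effective_at_low != base_inc$cost_effective_at_wtp |
    out$cost_effective_at_high != base_inc$cost_effective_at_wtp
  out <- out[order(-out$spread, out$parameter), ]
  rownames(out) <- NULL
  structure(out, class = c("cea_owsa", "data.frame"),
            tracked = tracked, wtp = wtp, base_incremental = base_inc)
}

#' @export
print.cea_owsa <- function(x, n = 10, ...) {
  cat("One-way sensitivity analysis (tracked outcome: ",
      attr(x, "tracked"), ")\n", sep = "")
  base_inc <- attr(x, "base_incremental")
  cat("base case: ", base_inc$dominance, ", ",
      if (base_inc$cost_effective_at_wtp) "cost-effective"
      else "not cost-effective",
      " at WTP ", format(attr(x, "wtp"), big.mark = ","), "\n", sep = "")
  if (any(x$threshold)) {
    cat("thresholds found for: ",
        paste(x$parameter[x$threshold], collapse = ", "), "\n", sep = "")
  } else {
    cat("no threshold: the verdict is unchanged over every parameter range\n")
  }
  show <- utils::head(as.data.frame(x)[, c("parameter", "outcome_at_low",
                                           "outcome_at_high", "spread")], n)
  show[-1] <- lapply(show[-1], signif, digits = 5)
  print(show, row.names = FALSE)
  if (nrow(x) > n) cat("... and ", nrow(x) - n, " more parameters\n", sep = "")
  invisible(x)
}

#' Tornado plot of a one-way sensitivity analysis
#'
#' @param x a \code{cea_owsa} object.
#' @param top number of most influential parameters to draw.
#' @param ... passed to \code{barplot}.
#' @return invisibly, the plotted subset.
#' @importFrom graphics abline barplot
#' @export
plot.cea_owsa <- function(x, top = 5, ...) {
  d <- utils::head(as.data.frame(x), top)
  d <- d[rev(seq_len(nrow(d))), ]
  base_inc <- attr(x, "base_incremental")
  base_val <- switch(attr(x, "tracked"), icer = base_inc$icer,
                     nmb = base_inc$nmb,
                     incremental_cost = base_inc$incremental_cost,
                     qaly_saved = base_inc$qaly_saved)
  lo <- pmin(d$outcome_at_low, d$outcome_at_high)
  hi <- pmax(d$outcome_at_low, d$outcome_at_high)
  graphics::barplot(rbind(hi - lo), beside = FALSE, horiz = TRUE,
                    names.arg = d$parameter, offset = lo, las = 1,
                    xlim = range(c(lo, hi, base_val)),
                    xlab = attr(x, "tracked"), ...)
  graphics::abline(v = base_val, lty = 2)
  invisible(d)
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo simulation: each draw jointly samples every non-fixed
#' parameter from its fitted distribution, evaluates both strategies on the
#' same draw (common random parameters), and records the per-draw
#' incremental cost and QALYs saved. Draws whose sampled adverse-event
#' probabilities cannot form a no-event branch are rejected and resampled
#' (the count is recorded).
#'
#' @param params a \code{cea_parameters} object.
#' @param n_draws number of Monte Carlo draws.
#' @param seed integer seed; identical seeds give identical results.
#' @param wtp willingness-to-pay threshold; defaults to the config setting.
#' @return object of class \code{cea_psa}: per-draw results
#'   (\code{$draws}), draw count, seed, threshold, rejected-draw count.
#'   \code{summary()} reports means with normal-approximation CIs of the
#'   mean, empirical 95\% percentile intervals, and the proportions of
#'   draws that save QALYs, save cost, and are cost-effective at the
#'   threshold.
#' @export
run_psa <- function(params, n_draws = 10000, seed = NULL, wtp = NULL) {
  stopifnot(inherits(params, "cea_parameters"), n_draws >= 1)
  wtp <- wtp %||% params$run$wtp_threshold_usd
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  values <- sample_parameters(params, n = n_draws)
  param_cols <- params$table$name
  n_rejected <- 0L
  repeat {
    bad <- which(!.ae_draw_valid(values))
    if (!length(bad)) break
    n_rejected <- n_rejected + length(bad)
    redraw <- sample_parameters(params, n = length(bad))
    for (nm in param_cols) values[[nm]][bad] <- redraw[[nm]]
  }
  rb <- rollback_expectations(values)
  draws <- data.frame(
    cost_usual_care = rb$cost_usual_care,
    qaly_loss_usual_care = rb$qaly_usual_care,
    cost_deprescribing = rb$cost_deprescribing,
    qaly_loss_deprescribing = rb$qaly_deprescribing)
  draws$incremental_cost <- draws$cost_deprescribing - draws$cost_usual_care
  draws$qaly_saved <- draws$qaly_loss_usual_care -
    draws$qaly_loss_deprescribing
  draws$nmb <- net_monetary_benefit(draws$incremental_cost, draws$qaly_saved,
                                    wtp)
  structure(list(draws = draws, n = n_draws, seed = seed, wtp = wtp,
                 n_rejected = n_rejected),
            class = "cea_psa")
}

#' @export
summary.cea_psa <- function(object, ...) {
  d <- object$draws
  stat <- function(x) {
    m <- mean(x); se <- stats::sd(x) / sqrt(length(x))
    c(mean = m, sd = stats::sd(x),
      mean_ci_low = m - 1.96 * se, mean_ci_high = m + 1.96 * se,
      pct_ci_low = unname(stats::quantile(x, 0.025)),
      pct_ci_high = unname(stats::quantile(x, 0.975)))
  }
  structure(list(
    n = object$n, seed = object$seed, wtp = object$wtp,
    n_rejected = object$n_rejected,
    incremental_cost = stat(d$incremental_cost),
    qaly_saved = stat(d$qaly_saved),
    cost_saved = stat(-d$incremental_cost),
    proportions = c(qaly_saving = mean(d$qaly_saved > 0),
                    cost_saving = mean(d$incremental_cost < 0),
                    cost_effective_at_wtp = mean(d$nmb > 0))),
    class = "summary.cea_psa")
}

#' @export
print.summary.cea_psa <- function(x, ...) {
  cat("Probabilistic sensitivity analysis: ", x$n, " draws",
      if (!is.null(x$seed)) paste0(" (seed ", x$seed, ")"), "\n", sep = "")
  if (x$n_rejected > 0) {
    cat("  rejected and resampled draws: ", x$n_rejected, "\n", sep = "")
  }
  fmt <- function(s, dg = 4) paste0(signif(s[["mean"]], dg),
                                    " (95% CI of mean ",
                                    signif(s[["mean_ci_low"]], dg), " to ",
                                    signif(s[["mean_ci_high"]], dg),
                                    "; 95% percentile interval ",
                                    signif(s[["pct_ci_low"]], dg), " to ",
                                    signif(s[["pct_ci_high"]], dg), ")")
  cat("  mean QALYs saved:  ", fmt(x$qaly_saved), "\n", sep = "")
  cat("  mean cost saved:   USD ", fmt(x$cost_saved), "\n", sep = "")
  p <- x$proportions
  cat("  draws saving QALYs: ", sprintf("%.1f%%", 100 * p[["qaly_saving"]]),
      "; saving cost: ", sprintf("%.1f%%", 100 * p[["cost_saving"]]),
      "; cost-effective at WTP ", format(x$wtp, big.mark = ","), ": ",
      sprintf("%.1f%%", 100 * p[["cost_effective_at_wtp"]]), "\n", sep = "")
  invisible(x)
}

#' @export
print.cea_psa <- function(x, ...) {
  print(summary(x))
  invisible(x)
}

#' Cost-effectiveness plane scatter of PSA draws
#'
#' @param x a \code{cea_psa} object.
#' @param ... passed to \code{plot}.
#' @importFrom graphics plot abline
#' @export
plot.cea_psa <- function(x, ...) {
  d <- x$draws
  graphics::plot(d$qaly_saved, d$incremental_cost,
                 xlab = "QALYs saved", ylab = "Incremental cost (USD)",
                 pch = 16, cex = 0.3, col = "#00000040", ...)
  graphics::abline(h = 0, v = 0, col = "grey50")
  graphics::abline(a = 0, b = x$wtp, lty = 2)
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' Fraction of PSA draws with positive net monetary benefit at each
#' willingness-to-pay value. At WTP 0 this is the proportion of
#' cost-saving draws; as WTP grows it approaches the proportion of
#' QALY-saving draws.
#'
#' @param psa a \code{cea_psa} object.
#' @param wtp_grid numeric vector of willingness-to-pay values.
#' @return data frame with columns \code{wtp} and
#'   \code{probability_cost_effective}.
#' @export
ceac <- function(psa, wtp_grid) {
  stopifnot(inherits(psa, "cea_psa"), length(wtp_grid) >= 1)
  d <- psa$draws
  prob <- vapply(wtp_grid, function(w) {
    mean(net_monetary_benefit(d$incremental_cost, d$qaly_saved, w) > 0)
  }, numeric(1))
  data.frame(wtp = wtp_grid, probability_cost_effective = prob)
}
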