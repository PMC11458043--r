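#' @keywords internal
"_PACKAGE"

# Canonical parameter book-keeping. Every model input is one row of a
# parameter table: name, base-case value, sensitivity range [low, high] and
# distribution family for probabilistic analysis. Run constants (discount
# rate, WTP threshold, remaining life expectancy, ...) are carried alongside.

.param_groups <- c("clinical", "utility", "cost")

.param_names <- list(
  clinical = c(
    "p_inappropriate",
    "p_rec_discontinue", "p_rec_dosedown", "p_rec_switch",
    "p_accept_discontinue", "p_accept_dosedown", "p_accept_switch",
    "p_rebound_discontinue", "p_rebound_dosedown", "p_rebound_switch",
    "p0_hypomag", "p0_pneumonia", "p0_cdi",
    "or_ppi_hypomag", "or_ppi_pneumonia", "or_ppi_cdi",
    "or_lowppi_hypomag", "or_lowppi_pneumonia", "or_lowppi_cdi",
    "p_hosp_hypomag", "p_hosp_pneumonia",
    "p_mort_cdi", "p_mort_pneumonia"),
  utility = c(
    "age_years", "utility_age65plus",
    "disutil_relapse_on_meds", "disutil_relapse_off_meds",
    "disutil_hosp_hypomag", "disutil_hosp_pneumonia",
    "disutil_amb_pneumonia", "disutil_cdi",
    "los_hypomag_days", "los_pneumonia_days", "los_cdi_days",
    "convalescence_pneumonia_days", "outpatient_pneumonia_days"),
  cost = c(
    "cost_ppi_standard_monthly", "cost_ppi_low_monthly", "cost_h2ra_monthly",
    "cost_hosp_per_day", "cost_clinic_visit", "n_clinic_visits_pneumonia",
    "pharmacist_salary_monthly", "deprescribe_minutes_per_case"))

.run_defaults <- list(
  discount_rate_annual = 0.03,
  wtp_threshold_usd = 49023,
  remaining_life_expectancy_years = NA_real_,
  pharmacist_working_minutes_per_month = 10560,
  rebound_onset_days = 20,
  range_sd_divisor = 3.92)

# parameters whose support is the unit interval (probabilities, utilities,
# disutility decrements); everything else is nonnegative
.unit_interval <- function(name) {
  grepl("^(p_|p0_|utility_|disutil_)", name)
}

.dist_families <- c("beta", "gamma", "triangular", "fixed")

#' Load a model parameter configuration
#'
#' Reads a YAML configuration with sections \code{clinical}, \code{utility},
#' \code{cost} and \code{run}, validates it, and returns a
#' \code{cea_parameters} object. Every model input must be present; unknown
#' keys are rejected. Each parameter entry carries a base-case value, a
#' sensitivity range \code{[low, high]} and a distribution family
#' (\code{beta}, \code{gamma}, \code{triangular} or \code{fixed}).
#'
#' @param path path to a YAML configuration file. The bundled default,
#'   reproducing the published Hong Kong input table, is at
#'   \code{system.file("extdata", "hk_defaults.yaml", package = "ppicea")}.
#' @return an object of class \code{cea_parameters}: a list with a parameter
#'   data frame (\code{$table}) and run constants (\code{$run}).
#' @seealso [default_parameters()], [write_parameters()], [sample_parameters()]
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) {
    stop("parameter config not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  parse_parameters(raw, source = path)
}

#' Bundled base-case parameter set
#'
#' The default configuration shipped with the package: published base-case
#' values, sensitivity ranges and distribution families for the Hong Kong
#' PPI deprescribing model.
#'
#' @return a \code{cea_parameters} object.
#' @export
default_parameters <- function() {
  load_parameters(system.file("extdata", "hk_defaults.yaml",
                              package = "ppicea", mustWork = TRUE))
}

# turn the parsed YAML list into a validated cea_parameters object
parse_parameters <- function(raw, source = "<config>") {
  if (!is.list(raw)) stop("config does not parse to a mapping: ", source,
                          call. = FALSE)
  extra <- setdiff(names(raw), c(.param_groups, "run"))
  if (length(extra)) {
    stop("unknown config section(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  rows <- list()
  for (grp in .param_groups) {
    sect <- raw[[grp]]
    if (is.null(sect)) stop("missing config section: ", grp, call. = FALSE)
    unknown <- setdiff(names(sect), .param_names[[grp]])
    if (length(unknown)) {
      stop("unknown parameter(s) in section '", grp, "': ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    for (nm in .param_names[[grp]]) {
      entry <- sect[[nm]]
      if (is.null(entry)) {
        stop("missing parameter: ", nm, " (section '", grp, "')",
             call. = FALSE)
      }
      rows[[nm]] <- parse_param_entry(nm, grp, entry)
    }
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL

  run <- .run_defaults
  user_run <- raw[["run"]]
  if (!is.null(user_run)) {
    unknown <- setdiff(names(user_run), names(.run_defaults))
    if (length(unknown)) {
      stop("unknown run setting(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    run[names(user_run)] <- user_run
  }
  params <- structure(list(table = table, run = run, source = source),
                      class = "cea_parameters")
  validate_parameters(params)
  params
}

parse_param_entry <- function(name, group, entry) {
  if (!is.list(entry) || is.null(entry$base)) {
    stop("parameter '", name, "' must be a mapping with at least a 'base' value",
         call. = FALSE)
  }
  bad <- setdiff(names(entry), c("base", "low", "high", "dist"))
  if (length(bad)) {
    stop("parameter '", name, "': unknown field(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  dist <- if (is.null(entry$dist)) "fixed" else as.character(entry$dist)
  if (!dist %in% .dist_families) {
    stop("parameter '", name, "': unknown distribution '", dist, "'",
         call. = FALSE)
  }
  has_range <- !is.null(entry$low) || !is.null(entry$high)
  if (dist == "fixed" && has_range) {
    stop("parameter '", name, "': fixed parameters carry no range",
         call. = FALSE)
  }
  if (dist != "fixed" && (is.null(entry$low) || is.null(entry$high))) {
    stop("parameter '", name, "': distribution '", dist,
         "' requires both 'low' and 'high'", call. = FALSE)
  }
  base <- as.numeric(entry$base)
  low  <- if (is.null(entry$low))  base else as.numeric(entry$low)
  high <- if (is.null(entry$high)) base else as.numeric(entry$high)
  data.frame(name = name, group = group, base = base, low = low, high = high,
             dist = dist, stringsAsFactors = FALSE)
}

validate_parameters <- function(params) {
  tab <- params$table
  for (i in seq_len(nrow(tab))) {
    nm <- tab$name[i]
    with_rule <- function(cond, rule) {
      if (!cond) stop("parameter '", nm, "' violates: ", rule, call. = FALSE)
    }
    with_rule(is.finite(tab$base[i]) && is.finite(tab$low[i]) &&
                is.finite(tab$high[i]), "finite base/low/high")
    with_rule(tab$low[i] <= tab$base[i] && tab$base[i] <= tab$high[i],
              "low <= base <= high")
    if (.unit_interval(nm)) {
      with_rule(tab$low[i] >= 0 && tab$high[i] <= 1,
                "probability/utility must lie in [0, 1]")
    } else {
      with_rule(tab$low[i] >= 0, "value must be nonnegative")
    }
  }
  mix <- tab$base[match(c("p_rec_discontinue", "p_rec_dosedown",
                          "p_rec_switch"), tab$name)]
  if (abs(sum(mix) - 1) > 1e-9) {
    stop("parameters 'p_rec_*' violate: recommendation mix must sum to 1 ",
         "(got ", format(sum(mix), digits = 12), ")", call. = FALSE)
  }
  run <- params$run
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
      stop("run setting '", nm, "' must be a single finite number",
           call. = FALSE)
    }
  }
  for (nm in names(run)) num1(run[[nm]], nm)
  if (run$discount_rate_annual < 0) stop("run setting 'discount_rate_annual' ",
                                         "must be >= 0", call. = FALSE)
  for (nm in c("wtp_threshold_usd", "remaining_life_expectancy_years",
               "pharmacist_working_minutes_per_month", "rebound_onset_days",
               "range_sd_divisor")) {
    if (run[[nm]] < 0) stop("run setting '", nm, "' must be >= 0",
                            call. = FALSE)
  }
  if (run$rebound_onset_days > 365.25) {
    stop("run setting 'rebound_onset_days' must fit inside the one-year horizon",
         call. = FALSE)
  }
  invisible(params)
}

#' Write a parameter set back to YAML
#'
#' Serializes a \code{cea_parameters} object to the same config schema that
#' [load_parameters()] reads; loading the written file reproduces every base
#' value exactly.
#'
#' @param params a \code{cea_parameters} object.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "cea_parameters"))
  tab <- params$table
  out <- list()
  for (grp in .param_groups) {
    sect <- list()
    for (nm in .param_names[[grp]]) {
      row <- tab[tab$name == nm, ]
      entry <- if (row$dist == "fixed") {
        list(base = row$base, dist = "fixed")
      } else {
        list(base = row$base, low = row$low, high = row$high, dist = row$dist)
      }
      sect[[nm]] <- entry
    }
    out[[grp]] <- sect
  }
  out$run <- params$run
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @export
print.cea_parameters <- function(x, ...) {
  tab <- x$table
  n_fixed <- sum(tab$dist == "fixed")
  cat("Model parameter set (", nrow(tab), " inputs, ", n_fixed, " fixed)\n",
      sep = "")
  cat("  source: ", x$source, "\n", sep = "")
  cat("  WTP threshold: USD ", format(x$run$wtp_threshold_usd, big.mark = ","),
      " per QALY; discount rate ", x$run$discount_rate_annual * 100, "%\n",
      sep = "")
  cat("  remaining life expectancy: ",
      x$run$remaining_life_expectancy_years, " years\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.cea_parameters <- function(x, ...) x$table

# named list of base-case values plus run constants: the realized parameter
# mapping the tree engine consumes. Entries may later be replaced by
# length-n vectors of sampled values.
#' Base-case realized parameter mapping
#'
#' Flattens a \code{cea_parameters} object into the named list of numeric
#' values (model inputs plus run constants) that the tree engine evaluates.
#'
#' @param params a \code{cea_parameters} object.
#' @return named list of numeric values.
#' @export
param_values <- function(params) {
  stopifnot(inherits(params, "cea_parameters"))
  vals <- as.list(params$table$base)
  names(vals) <- params$table$name
  c(vals, params$run)
}

#' Fit a sampling distribution to a parameter
#'
#' Maps a parameter's base value, sensitivity range and declared family to a
#' concrete sampling distribution. Triangular uses \code{(min = low,
#' mode = base, max = high)} directly. Beta and gamma are fitted by the
#' method of moments with mean equal to the base value and standard
#' deviation \code{(high - low) / sd_divisor}, treating the range as an
#' approximate central 95\% interval (divisor \code{2 x 1.96} by default).
#' Fixed parameters yield a degenerate point mass.
#'
#' @param base,low,high base-case value and sensitivity range.
#' @param family one of \code{"beta"}, \code{"gamma"}, \code{"triangular"},
#'   \code{"fixed"}.
#' @param sd_divisor divisor converting range width to standard deviation.
#' @return a \code{dist_spec} object: list with \code{family} and its shape
#'   parameters (\code{shape1}/\code{shape2} for beta, \code{shape}/\code{scale}
#'   for gamma, \code{min}/\code{mode}/\code{max} for triangular,
#'   \code{value} for degenerate).
#' @export
fit_distribution <- function(base, low = base, high = base,
                             family = c("beta", "gamma", "triangular", "fixed"),
                             sd_divisor = 3.92) {
  family <- match.arg(family)
  if (family == "fixed") {
    return(structure(list(family = "degenerate", value = base),
                     class = "dist_spec"))
  }
  if (high < low || base < low || base > high) {
    stop("require low <= base <= high", call. = FALSE)
  }
  if (high == low) {
    warning("zero-width range with family '", family,
            "': using a degenerate distribution at the base value")
    return(structure(list(family = "degenerate", value = base),
                     class = "dist_spec"))
  }
  if (family == "triangular") {
    return(structure(list(family = "triangular",
                          min = low, mode = base, max = high),
                     class = "dist_spec"))
  }
  s <- (high - low) / sd_divisor
  v <- s^2
  if (family == "beta") {
    if (base <= 0 || base >= 1) {
      stop("beta distribution requires a base value strictly inside (0, 1)",
           call. = FALSE)
    }
    if (v >= base * (1 - base)) {
      stop("beta moment fit impossible: variance ", format(v),
           " >= mean(1-mean)", call. = FALSE)
    }
    nu <- base * (1 - base) / v - 1
    structure(list(family = "beta", shape1 = base * nu,
                   shape2 = (1 - base) * nu), class = "dist_spec")
  } else { # gamma
    if (base <= 0) stop("gamma distribution requires base > 0", call. = FALSE)
    structure(list(family = "gamma", shape = base^2 / v, scale = v / base),
              class = "dist_spec")
  }
}

#' @export
print.dist_spec <- function(x, ...) {
  pars <- x[setdiff(names(x), "family")]
  cat(x$family, "(",
      paste(names(pars), signif(unlist(pars), 6), sep = " = ",
            collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Analytic mean of a fitted distribution
#' @param spec a \code{dist_spec} object.
#' @return the distribution mean.
#' @export
dist_mean <- function(spec) {
  stopifnot(inherits(spec, "dist_spec"))
  switch(spec$family,
         degenerate = spec$value,
         triangular = (spec$min + spec$mode + spec$max) / 3,
         beta = spec$shape1 / (spec$shape1 + spec$shape2),
         gamma = spec$shape * spec$scale,
         stop("unknown family ", spec$family))
}

#' Draw from a fitted distribution
#'
#' Uses the current RNG stream. Triangular sampling is by inverse CDF.
#'
#' @param spec a \code{dist_spec} object.
#' @param n number of draws.
#' @return numeric vector of length \code{n}.
#' @export
dist_sample <- function(spec, n = 1) {
  stopifnot(inherits(spec, "dist_spec"))
  switch(spec$family,
         degenerate = rep(spec$value, n),
         beta = stats::rbeta(n, spec$shape1, spec$shape2),
         gamma = stats::rgamma(n, shape = spec$shape, scale = spec$scale),
         triangular = {
           a <- spec$min; m <- spec$mode; b <- spec$max
           u <- stats::runif(n)
           fc <- (m - a) / (b - a)
           ifelse(u < fc,
                  a + sqrt(u * (b - a) * (m - a)),
                  b - sqrt((1 - u) * (b - a) * (b - m)))
         },
         stop("unknown family ", spec$family))
}

#' Jointly sample the model parameters
#'
#' One independent draw per parameter from its fitted distribution; fixed
#' parameters are returned at their base value. The three recommendation-mix
#' draws are renormalized to sum to 1. With \code{n > 1} each entry of the
#' returned mapping is a vector of \code{n} draws, suitable for vectorized
#' probabilistic analysis.
#'
#' @param params a \code{cea_parameters} object.
#' @param n number of joint draws.
#' @param seed optional integer seed; when given, sampling is reproducible
#'   and the caller's RNG state is restored afterwards.
#' @return named list: one numeric vector of length \code{n} per parameter,
#'   plus the (scalar) run constants.
#' @export
sample_parameters <- function(params, n = 1, seed = NULL) {
  stopifnot(inherits(params, "cea_parameters"))
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  tab <- params$table
  divisor <- params$run$range_sd_divisor
  draws <- vector("list", nrow(tab))
  names(draws) <- tab$name
  for (i in seq_len(nrow(tab))) {
    spec <- fit_distribution(tab$base[i], tab$low[i], tab$high[i],
                             tab$dist[i], sd_divisor = divisor)
    draws[[i]] <- dist_sample(spec, n)
  }
  mix_names <- c("p_rec_discontinue", "p_rec_dosedown", "p_rec_switch")
  tot <- draws[[mix_names[1]]] + draws[[mix_names[2]]] + draws[[mix_names[3]]]
  for (nm in mix_names) draws[[nm]] <- draws[[nm]] / tot
  c(draws, params$run)
}
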