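# Shared fixtures: all built in code from the bundled config.

base_params <- function() default_parameters()

base_values <- function() param_values(default_parameters())

# write a modified copy of the bundled config and return its path;
# `mutate` edits the parsed YAML list
modified_config <- function(mutate) {
  raw <- yaml::read_yaml(system.file("extdata", "hk_defaults.yaml",
                                     package = "ppicea", mustWork = TRUE))
  raw <- mutate(raw)
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(raw, path, precision = 15)
  path
}

# parameter set with every distribution degenerate at the base value
degenerate_params <- function() {
  path <- modified_config(function(raw) {
    for (grp in c("clinical", "utility", "cost")) {
      for (nm in names(raw[[grp]])) {
        raw[[grp]][[nm]] <- list(base = raw[[grp]][[nm]]$base, dist = "fixed")
      }
    }
    raw
  })
  load_parameters(path)
}

# one realized joint draw, resampled until every exposure class admits a
# no-event branch
random_valid_values <- function(seed) {
  params <- base_params()
  for (k in 0:50) {
    v <- sample_parameters(params, n = 1, seed = seed + 1000L * k)
    ok <- tryCatch({
      rollback_sums_ok(v)
    }, error = function(e) FALSE)
    if (ok) return(v)
  }
  stop("no valid draw found")
}

rollback_sums_ok <- function(values) {
  pe <- function(expo) {
    p <- ppicea:::.ae_probs(values, expo)
    p$hypomagnesemia + p$pneumonia + p$cdi < 1
  }
  pe("standard") && pe("low") && pe("baseline")
}
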