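# Synthetic-instance generation: random small probability trees with
# closed-form expected values (to verify the rollback engine against an
# independent summation), and jittered parameter sets emulating
# region-specific inputs.

# recursive random subtree; terminal payoffs on the scales of the real
# model (costs up to 1e4 USD, QALY losses up to 10)
.random_subtree <- function(depth, branching) {
  terminal <- depth == 0 || stats::runif(1) < 0.3
  if (terminal) {
    return(list(type = "terminal",
                cost = stats::runif(1, 0, 1e4),
                qaly_loss = stats::runif(1, 0, 10)))
  }
  k <- sample(2:branching, 1)
  w <- stats::rgamma(k, shape = 1)
  children <- lapply(seq_len(k), function(i) {
    .random_subtree(depth - 1, branching)
  })
  list(type = "chance", probs = w / sum(w), children = children)
}

# analytic expectation by direct recursive summation (generation-time oracle)
.tree_expectation <- function(node) {
  if (node$type == "terminal") {
    return(c(cost = node$cost, qaly_loss = node$qaly_loss))
  }
  vals <- vapply(node$children, .tree_expectation, numeric(2))
  c(cost = sum(node$probs * vals["cost", ]),
    qaly_loss = sum(node$probs * vals["qaly_loss", ]))
}

#' Generate a random synthetic decision model
#'
#' Builds a random chance tree (depth at most \code{depth}, branching at
#' most \code{branching}; branch probabilities are normalized gamma draws,
#' so Dirichlet-distributed) with nonnegative terminal cost and QALY-loss
#' payoffs, and stores the analytic expected values computed at generation
#' time by direct summation. Used to verify the expected-value engine
#' against a closed-form answer.
#'
#' @param seed integer seed; identical seeds give identical models.
#' @param depth maximum tree depth (>= 1).
#' @param branching maximum branches per chance node (>= 2).
#' @return object of class \code{synthetic_model}: the tree, the stored
#'   analytic expectations, and the generation settings.
#' @export
generate_synthetic_model <- function(seed, depth = 3, branching = 3) {
  stopifnot(depth >= 1, branching >= 2)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  k <- sample(2:branching, 1)
  w <- stats::rgamma(k, shape = 1)
  tree <- list(type = "chance", probs = w / sum(w),
               children = lapply(seq_len(k), function(i) {
                 .random_subtree(depth - 1, branching)
               }))
  expectation <- .tree_expectation(tree)
  structure(list(tree = tree,
                 expected_cost = unname(expectation["cost"]),
                 expected_qaly_loss = unname(expectation["qaly_loss"]),
                 seed = seed, depth = depth, branching = branching),
            class = "synthetic_model")
}

#' Flatten a synthetic model to its terminal paths
#'
#' Enumerates every root-to-leaf path with its product probability; the
#' same path-table form that [evaluate_strategy()] rolls back.
#'
#' @param model a \code{synthetic_model} object.
#' @return data frame with columns \code{probability}, \code{cost},
#'   \code{qaly_loss}.
#' @export
synthetic_paths <- function(model) {
  stopifnot(inherits(model, "synthetic_model"))
  walk <- function(node, p) {
    if (node$type == "terminal") {
      return(list(data.frame(probability = p, cost = node$cost,
                             qaly_loss = node$qaly_loss)))
    }
    out <- list()
    for (i in seq_along(node$children)) {
      out <- c(out, walk(node$children[[i]], p * node$probs[i]))
    }
    out
  }
  paths <- do.call(rbind, walk(model$tree, 1))
  rownames(paths) <- NULL
  paths
}

#' @export
print.synthetic_model <- function(x, ...) {
  paths <- synthetic_paths(x)
  cat("Synthetic decision model (seed ", x$seed, ", depth <= ", x$depth,
      ", branching <= ", x$branching, "): ", nrow(paths),
      " terminal paths\n", sep = "")
  cat("  analytic expected cost ", signif(x$expected_cost, 6),
      ", expected QALY loss ", signif(x$expected_qaly_loss, 6), "\n",
      sep = "")
  invisible(x)
}

#' Serialize / read a synthetic model
#'
#' Writes the tree and its stored expectations to YAML (the same
#' structured-text configuration style as the model parameters) and reads
#' it back.
#'
#' @param model a \code{synthetic_model} object.
#' @param path file path.
#' @return \code{write_synthetic_model}: \code{path}, invisibly;
#'   \code{read_synthetic_model}: a \code{synthetic_model} object.
#' @export
write_synthetic_model <- function(model, path) {
  stopifnot(inherits(model, "synthetic_model"))
  yaml::write_yaml(unclass(model), path, precision = 15)
  invisible(path)
}

#' @rdname write_synthetic_model
#' @export
read_synthetic_model <- function(path) {
  raw <- yaml::read_yaml(path)
  fix <- function(node) {
    if (node$type == "chance") {
      node$probs <- as.numeric(unlist(node$probs))
      node$children <- lapply(node$children, fix)
    }
    node
  }
  raw$tree <- fix(raw$tree)
  structure(raw, class = "synthetic_model")
}

#' Jitter a parameter set within its sensitivity ranges
#'
#' Emulates a region-specific re-parameterization: each non-fixed base
#' value is perturbed uniformly within the fraction \code{scale} of its
#' distance to the range ends, the recommendation mix is renormalized, and
#' the full validation suite is re-applied. Perturbations that violate an
#' invariant are resampled.
#'
#' @param params a \code{cea_parameters} object.
#' @param scale perturbation fraction in \code{[0, 1]}: 0 returns the
#'   parameters unchanged, 1 allows the full sensitivity range.
#' @param seed integer seed.
#' @return a validated \code{cea_parameters} object with jittered base
#'   values; draws that violate an invariant (e.g. mix renormalization
#'   pushing a base value outside its range) are resampled.
#' @export
perturb_parameters <- function(params, scale, seed) {
  stopifnot(inherits(params, "cea_parameters"), scale >= 0)
  scale <- min(scale, 1)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  if (scale == 0) return(params)
  tab <- params$table
  free <- tab$dist != "fixed"
  mix_names <- c("p_rec_discontinue", "p_rec_dosedown", "p_rec_switch")
  for (try in seq_len(1000)) {
    new_tab <- tab
    lo <- tab$base - scale * (tab$base - tab$low)
    hi <- tab$base + scale * (tab$high - tab$base)
    new_tab$base[free] <- stats::runif(sum(free), lo[free], hi[free])
    mix_i <- match(mix_names, new_tab$name)
    new_tab$base[mix_i] <- new_tab$base[mix_i] / sum(new_tab$base[mix_i])
    candidate <- params
    candidate$table <- new_tab
    candidate$source <- paste0(params$source, " (perturbed, seed ", seed, ")")
    ok <- tryCatch({
      validate_parameters(candidate)
      TRUE
    }, error = function(e) FALSE)
    if (ok) return(candidate)
  }
  stop("could not find a valid perturbation in 1000 attempts", call. = FALSE)
}
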