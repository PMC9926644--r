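#' Simulation configuration
#'
#' Describes one two-class Gaussian simulation: balanced class sizes, number
#' of variables, an effect-size regime with per-variable target d drawn
#' uniformly from `d_range`, an optional data-quality substitution fraction,
#' the noise scale and the master seed.
#'
#' Regimes follow Cohen's scale: `"good"` draws targets from (0.5, 1.4) and
#' `"poor"` from (0.01, 0.2); `"custom"` requires an explicit `d_range`.
#'
#' @param n_per_class samples per class (>= 8, i.e. half the minimum total
#'   of 16 the evaluation protocol starts from).
#' @param n_variables number of feature variables (default 100).
#' @param regime `"good"`, `"poor"` or `"custom"`.
#' @param d_range length-2 nonnegative (low, high) bounds for the uniform
#'   per-variable target d; defaults depend on `regime`.
#' @param quality_fraction fraction in \[0, 1\] of variables of a poor
#'   dataset to substitute with good-regime variables (0 = no substitution).
#' @param noise_sd positive within-class standard deviation (arbitrary
#'   units; effect sizes are scale-free).
#' @param seed master RNG seed; all stage seeds derive from it.
#' @param correlation optional variable-by-variable correlation matrix
#'   (defaults to independence).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_per_class, n_variables = 100,
                              regime = c("good", "poor", "custom"),
                              d_range = NULL, quality_fraction = 0,
                              noise_sd = 1, seed = 1L, correlation = NULL) {
  regime <- match.arg(regime)
  if (is.null(d_range)) {
    d_range <- switch(regime,
      good = c(0.5, 1.4),
      poor = c(0.01, 0.2),
      custom = stop_mlsize("config_error",
                           "regime 'custom' requires an explicit d_range"))
  }
  if (length(d_range) != 2 || any(d_range < 0) || d_range[1] > d_range[2]) {
    stop_mlsize("config_error",
                "d_range must be nonnegative bounds with low <= high")
  }
  if (quality_fraction < 0 || quality_fraction > 1) {
    stop_mlsize("config_error", "quality_fraction must lie in [0, 1]")
  }
  if (n_per_class < 8) {
    stop_mlsize("config_error", "n_per_class must be at least 8")
  }
  if (noise_sd <= 0) stop_mlsize("config_error", "noise_sd must be positive")
  if (!is.null(correlation)) {
    if (!is.matrix(correlation) ||
        any(dim(correlation) != n_variables) ||
        any(abs(correlation - t(correlation)) > 1e-8)) {
      stop_mlsize("config_error",
                  "correlation must be a symmetric n_variables x n_variables matrix")
    }
  }
  structure(list(
    n_per_class = as.integer(n_per_class),
    n_variables = as.integer(n_variables),
    regime = regime, d_range = as.numeric(d_range),
    quality_fraction = quality_fraction, noise_sd = noise_sd,
    seed = as.integer(seed), correlation = correlation
  ), class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "<simulation_config> regime=%s d~U(%g, %g) n/class=%d vars=%d quality=%g seed=%d\n",
    x$regime, x$d_range[1], x$d_range[2], x$n_per_class, x$n_variables,
    x$quality_fraction, x$seed))
  invisible(x)
}

#' Draw per-variable effect-size targets
#'
#' One uniform draw from the configured `d_range` per variable,
#' reproducible under the config seed (stage-specific child seed unless a
#' seed is supplied directly).
#'
#' @param config a [simulation_config()].
#' @param seed optional override of the stage seed.
#' @return Numeric vector of length `n_variables`.
#' @export
draw_effect_targets <- function(config, seed = NULL) {
  if (is.null(seed)) seed <- derive_seeds(config$seed, 3)[1]
  set.seed(seed)
  stats::runif(config$n_variables, config$d_range[1], config$d_range[2])
}

# One class block: n x p Gaussian noise with optional correlation, then a
# per-variable mean offset.
draw_class_block <- function(n, p, noise_sd, offsets, correlation) {
  z <- matrix(stats::rnorm(n * p, sd = noise_sd), n, p)
  if (!is.null(correlation)) {
    z <- z %*% chol(correlation)
  }
  sweep(z, 2, offsets, "+")
}

#' Generate a simulated two-class dataset
#'
#' Location-scale Gaussian sampling with controlled per-variable effect
#' sizes: class 1 values for variable j are Normal(0, `noise_sd`^2) and
#' class 2 values Normal(d_j * `noise_sd`, `noise_sd`^2), so the population
#' Cohen's d of variable j equals the target d_j.  When
#' `quality_fraction > 0` (poor regime only) a seeded random subset of
#' variables is substituted with good-regime variables, emulating a
#' data-quality improvement; `quality_fraction = 1` reproduces a fully good
#' dataset.
#'
#' @param config a [simulation_config()].
#' @return List with `dataset` (a [labeled_dataset()] with classes
#'   `"class1"`/`"class2"`), `targets` (ground-truth per-variable d,
#'   with substituted variables at their good-regime values),
#'   `substituted` (logical per variable) and `config`.
#' @examples
#' sim <- generate_dataset(simulation_config(n_per_class = 100,
#'                                           n_variables = 20, seed = 7))
#' effect_size_summary(sim$dataset)$d_average
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "simulation_config")) {
    stop_mlsize("config_error", "expected a `simulation_config`")
  }
  seeds <- derive_seeds(config$seed, 3)
  targets <- draw_effect_targets(config, seed = seeds[1])
  substituted <- rep(FALSE, config$n_variables)

  if (config$quality_fraction > 0) {
    if (config$regime != "poor") {
      stop_mlsize("config_error",
                  "quality substitution applies to the poor regime only")
    }
    set.seed(seeds[3])
    n_sub <- round(config$quality_fraction * config$n_variables)
    sub_idx <- sample.int(config$n_variables, n_sub)
    substituted[sub_idx] <- TRUE
    # Substituted variables take good-regime separations; the class-2 block
    # of those variables is regenerated below from the new targets.
    targets[sub_idx] <- stats::runif(n_sub, 0.5, 1.4)
  }

  set.seed(seeds[2])
  n <- config$n_per_class; p <- config$n_variables
  x1 <- draw_class_block(n, p, config$noise_sd, rep(0, p), config$correlation)
  x2 <- draw_class_block(n, p, config$noise_sd, targets * config$noise_sd,
                         config$correlation)
  values <- rbind(x1, x2)
  labels <- rep(c("class1", "class2"), each = n)
  list(dataset = labeled_dataset(values, labels),
       targets = targets, substituted = substituted, config = config)
}

#' Apply the data-quality substitution manipulation
#'
#' Convenience wrapper: generates a poor-regime dataset in which
#' `quality_fraction` of the variables have been substituted with
#' good-regime variables.  Identical to calling [generate_dataset()] on a
#' poor config carrying the same fraction and seed.
#'
#' @param config a poor-regime [simulation_config()]; its
#'   `quality_fraction` (or the `quality_fraction` argument, which takes
#'   precedence) sets the substituted share.
#' @param quality_fraction optional override in (0, 1\].
#' @return Same structure as [generate_dataset()].
#' @export
apply_quality_substitution <- function(config, quality_fraction = NULL) {
  if (!is.null(quality_fraction)) config$quality_fraction <- quality_fraction
  if (config$regime != "poor") {
    stop_mlsize("config_error", "base regime must be 'poor'")
  }
  if (config$quality_fraction < 0 || config$quality_fraction > 1) {
    stop_mlsize("config_error", "quality_fraction must lie in [0, 1]")
  }
  generate_dataset(config)
}
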