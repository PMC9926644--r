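#' Per-variable Cohen's d
#'
#' Computes the signed Cohen's d for every variable of a two-class dataset:
#' \deqn{d_j = (\bar{x}_{1j} - \bar{x}_{2j}) / S_{pooled,j}} with
#' \deqn{S_{pooled,j} = \sqrt{((n_1-1) sd_{1j}^2 + (n_2-1) sd_{2j}^2) /
#'   (n_1+n_2-2)}}
#' using sample (n-1 denominator) standard deviations.  Class 1 and 2 follow
#' the sorted order of the labels, so the sign of d is (first - second).
#'
#' @param dataset a [labeled_dataset()] with exactly two classes, each of at
#'   least two samples.
#' @param on_zero_sd what to do when a variable's pooled SD is zero
#'   (a constant variable): `"error"` (default) raises a typed
#'   degenerate-variance error; `"drop"` removes the variable with a warning.
#' @return Named numeric vector of signed d, one per (retained) variable.
#' @examples
#' d <- labeled_dataset(cbind(x = c(1, 2, 3, 3, 4, 5)),
#'                      rep(c("a", "b"), each = 3))
#' per_variable_cohens_d(d)   # -2
#' @seealso [average_effect_size()], [grand_effect_size()],
#'   [effect_size_summary()]
#' @export
per_variable_cohens_d <- function(dataset, on_zero_sd = c("error", "drop")) {
  on_zero_sd <- match.arg(on_zero_sd)
  idx <- check_two_class(dataset)
  x1 <- dataset$values[idx[[1]], , drop = FALSE]
  x2 <- dataset$values[idx[[2]], , drop = FALSE]
  n1 <- nrow(x1); n2 <- nrow(x2)
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  v1 <- apply(x1, 2, stats::var); v2 <- apply(x2, 2, stats::var)
  pooled <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  zero <- pooled <= 0
  if (any(zero)) {
    bad <- paste(dataset$variable_names[zero], collapse = ", ")
    if (on_zero_sd == "error") {
      stop_mlsize("degenerate_variance", sprintf(
        "zero pooled SD (constant variable): %s", bad))
    }
    warn_mlsize("dropped_variables", sprintf(
      "dropping constant variable(s) with zero pooled SD: %s", bad))
    m1 <- m1[!zero]; m2 <- m2[!zero]; pooled <- pooled[!zero]
  }
  d <- (m1 - m2) / pooled
  names(d) <- names(pooled)
  d
}

#' Average effect size
#'
#' The mean magnitude of per-variable Cohen's d over all variables,
#' \deqn{\bar{d} = \sum_j |d_j| / vs.}  Magnitudes are averaged (rather than
#' signed values) so that variables whose effects point in opposite
#' directions do not cancel; the grand effect size
#' ([grand_effect_size()]) deliberately does let them cancel, and the gap
#' between the two statistics is diagnostic of effect-direction
#' heterogeneity.
#'
#' @inheritParams per_variable_cohens_d
#' @return Nonnegative scalar.
#' @export
average_effect_size <- function(dataset, on_zero_sd = c("error", "drop")) {
  mean(abs(per_variable_cohens_d(dataset, on_zero_sd)))
}

#' Grand effect size
#'
#' Cohen's d computed from grand (variable-averaged) class summaries: per
#' class c, the grand mean \eqn{\mu_{g,c}} is the mean over variables of the
#' per-variable class means and the grand SD \eqn{\sigma_{g,c}} is the mean
#' over variables of the per-variable class SDs; then
#' \deqn{d_g = |\mu_{g,1} - \mu_{g,2}| / S_{pooled,g}} with the usual
#' two-group pooled SD built from \eqn{\sigma_{g,1}, \sigma_{g,2}} and the
#' class sample counts.  Opposite-signed variable effects cancel in the
#' grand means, so \eqn{d_g} can be near zero while the average effect size
#' is large.
#'
#' @inheritParams per_variable_cohens_d
#' @return Nonnegative scalar.
#' @export
grand_effect_size <- function(dataset, on_zero_sd = c("error", "drop")) {
  on_zero_sd <- match.arg(on_zero_sd)
  idx <- check_two_class(dataset)
  x1 <- dataset$values[idx[[1]], , drop = FALSE]
  x2 <- dataset$values[idx[[2]], , drop = FALSE]
  n1 <- nrow(x1); n2 <- nrow(x2)
  mu_g1 <- mean(colMeans(x1)); mu_g2 <- mean(colMeans(x2))
  sg1 <- mean(apply(x1, 2, stats::sd)); sg2 <- mean(apply(x2, 2, stats::sd))
  pooled_g <- sqrt(((n1 - 1) * sg1^2 + (n2 - 1) * sg2^2) / (n1 + n2 - 2))
  if (pooled_g <= 0) {
    if (on_zero_sd == "error") {
      stop_mlsize("degenerate_variance", "grand pooled SD is zero")
    }
    return(0)
  }
  abs(mu_g1 - mu_g2) / pooled_g
}

#' Effect-size summary for a two-class dataset
#'
#' Bundles the per-variable signed Cohen's d with the two aggregate
#' statistics (average and grand effect size) and the class counts.
#'
#' @inheritParams per_variable_cohens_d
#' @return An object of class `effect_size_summary`: list with
#'   `per_variable_d`, `d_average`, `d_grand`, `n_class1`, `n_class2`,
#'   `n_variables`, `class_levels` and `fingerprint` (dataset lineage stamp).
#' @examples
#' sim <- generate_dataset(simulation_config(n_per_class = 50, n_variables = 10,
#'                                           regime = "good", seed = 1))
#' effect_size_summary(sim$dataset)
#' @export
effect_size_summary <- function(dataset, on_zero_sd = c("error", "drop")) {
  d <- per_variable_cohens_d(dataset, on_zero_sd)
  idx <- check_two_class(dataset)
  structure(list(
    per_variable_d = d,
    d_average = mean(abs(d)),
    d_grand = grand_effect_size(dataset, on_zero_sd),
    n_class1 = length(idx[[1]]),
    n_class2 = length(idx[[2]]),
    n_variables = length(d),
    class_levels = levels(dataset$labels),
    fingerprint = dataset_fingerprint(dataset)
  ), class = "effect_size_summary")
}

#' @export
print.effect_size_summary <- function(x, ...) {
  cat("<effect_size_summary>\n")
  cat(sprintf("  classes: %s (n=%d) vs %s (n=%d), %d variables\n",
              x$class_levels[1], x$n_class1, x$class_levels[2], x$n_class2,
              x$n_variables))
  cat(sprintf("  average effect size d_avg = %.4f  [%s]\n", x$d_average,
              classify_effect_size(x$d_average)))
  cat(sprintf("  grand effect size   d_g   = %.4f  [%s]\n", x$d_grand,
              classify_effect_size(x$d_grand)))
  invisible(x)
}

#' Classify an effect size on Cohen's scale
#'
#' Maps a nonnegative effect size to the conventional ordinal scale:
#' values up to 0.2 are a trivial difference, 0.5 or more a significant
#' one, anything in between intermediate.
#'
#' @param d nonnegative effect-size magnitude(s).
#' @return Character vector over `{"trivial", "intermediate", "significant"}`.
#' @export
classify_effect_size <- function(d) {
  if (any(d < 0)) {
    stop_mlsize("input_error", "effect-size magnitudes must be nonnegative")
  }
  ifelse(d <= 0.2, "trivial", ifelse(d < 0.5, "intermediate", "significant"))
}

#' Write an effect-size summary to JSON or CSV
#'
#' JSON carries the aggregates plus the per-variable vector; CSV has one row
#' per variable with its signed d and magnitude class.
#'
#' @param summary an [effect_size_summary()].
#' @param path output file; format chosen by extension unless `format` given.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_effect_size_summary <- function(summary, path,
                                      format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  }
  if (format == "json") {
    write_json_out(list(
      d_average = summary$d_average,
      d_grand = summary$d_grand,
      per_variable_d = as.list(summary$per_variable_d),
      n_class1 = summary$n_class1,
      n_class2 = summary$n_class2,
      n_variables = summary$n_variables,
      fingerprint = summary$fingerprint
    ), path)
  } else {
    utils::write.csv(data.frame(
      variable = names(summary$per_variable_d),
      d = unname(summary$per_variable_d),
      magnitude = classify_effect_size(abs(summary$per_variable_d))
    ), path, row.names = FALSE)
  }
  invisible(path)
}
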