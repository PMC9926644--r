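#' Adequacy-criteria configuration
#'
#' Thresholds for the two sample-size adequacy criteria and the trend
#' tolerance used by the remediation logic.
#'
#' @param es_threshold minimum aggregate effect size (default 0.5, the
#'   Cohen-scale bound for a significant difference).
#' @param acc_threshold minimum best-classifier mean accuracy as a
#'   proportion (default 0.80, mirroring the conventional 80% power level).
#' @param change_threshold maximum relative accuracy change between the
#'   decided size and the next, in percent (default 10, exclusive bound).
#' @param trend_tolerance relative increase first-to-last size above which
#'   a quantity counts as "increasing" for remediation (default 0.05).
#' @return An object of class `criteria_config`.
#' @export
criteria_config <- function(es_threshold = 0.5, acc_threshold = 0.80,
                            change_threshold = 10, trend_tolerance = 0.05) {
  if (es_threshold <= 0 || change_threshold <= 0 || trend_tolerance <= 0) {
    stop_mlsize("config_error", "all thresholds must be positive")
  }
  if (acc_threshold <= 0 || acc_threshold >= 1) {
    stop_mlsize("config_error", "acc_threshold must lie in (0, 1)")
  }
  structure(list(es_threshold = es_threshold, acc_threshold = acc_threshold,
                 change_threshold = change_threshold,
                 trend_tolerance = trend_tolerance),
            class = "criteria_config")
}

#' Criterion 1: effect-size adequacy
#'
#' Passes when at least one of the two aggregate effect sizes (average or
#' grand) reaches the threshold: `max(d_average, d_grand) >= es_threshold`
#' (boundary inclusive).
#'
#' @param summary an [effect_size_summary()].
#' @param config a [criteria_config()].
#' @return List with `pass`, `best_effect_size`, `which` (`"average"` or
#'   `"grand"`), and the threshold applied.
#' @export
criterion1 <- function(summary, config = criteria_config()) {
  best <- max(summary$d_average, summary$d_grand)
  list(pass = best >= config$es_threshold,
       best_effect_size = best,
       which = if (summary$d_average >= summary$d_grand) "average" else "grand",
       threshold = config$es_threshold)
}

# Mean accuracy of one size under the configured summary rule.
size_accuracy <- function(curve, size, rule = c("best", "median")) {
  rule <- match.arg(rule)
  acc <- curve$accuracy[curve$accuracy$sample_size == size, ]
  if (nrow(acc) == 0) {
    stop_mlsize("size_not_in_curve", sprintf(
      "sample size %d is not in the evaluation curve", size))
  }
  switch(rule, best = max(acc$mean), median = stats::median(acc$mean))
}

#' Criterion 2: accuracy level and stability
#'
#' Condition A: the summary accuracy of the decided size (by default the
#' best classifier family's mean accuracy) is at least `acc_threshold`
#' (inclusive).  Condition B applies only when larger sizes exist whose
#' accuracy also meets the threshold ("beyond a desired accuracy"): the
#' relative change from the decided size to the comparison size must be
#' strictly below `change_threshold` percent.  By default the comparison is
#' the next larger qualifying size; `comparison = "any"` requires stability
#' against every larger qualifying size.
#'
#' @param curve an [aggregate_curve()] result.
#' @param decided_size the sample size under evaluation (must be in the
#'   curve).
#' @param config a [criteria_config()].
#' @param rule how a size's accuracy is summarised over classifiers:
#'   `"best"` (default) or `"median"`.
#' @param comparison `"next"` (default) or `"any"` larger qualifying size.
#' @return List with `pass`, `accuracy`, `accuracy_ok`, `stability_ok`
#'   (`NA` when vacuous), `change_pct` (`NA` when vacuous), `failed`
#'   (`"none"`, `"accuracy"` or `"stability"`), and the thresholds applied.
#' @export
criterion2 <- function(curve, decided_size, config = criteria_config(),
                       rule = c("best", "median"),
                       comparison = c("next", "any")) {
  rule <- match.arg(rule)
  comparison <- match.arg(comparison)
  acc_now <- size_accuracy(curve, decided_size, rule)
  accuracy_ok <- acc_now >= config$acc_threshold

  sizes <- sort(unique(curve$accuracy$sample_size))
  larger <- sizes[sizes > decided_size]
  qualifying <- larger[vapply(larger, function(s) {
    size_accuracy(curve, s, rule) >= config$acc_threshold
  }, logical(1))]

  change_pct <- NA_real_
  stability_ok <- NA
  if (length(qualifying) > 0 && acc_now > 0) {
    targets <- if (comparison == "next") qualifying[1] else qualifying
    changes <- vapply(targets, function(s) {
      100 * abs(size_accuracy(curve, s, rule) - acc_now) / acc_now
    }, numeric(1))
    change_pct <- max(changes)
    stability_ok <- change_pct < config$change_threshold
  }
  pass <- accuracy_ok && !isFALSE(stability_ok)
  failed <- if (pass) "none" else if (!accuracy_ok) "accuracy" else "stability"
  list(pass = pass, accuracy = acc_now, accuracy_ok = accuracy_ok,
       stability_ok = stability_ok, change_pct = change_pct, failed = failed,
       acc_threshold = config$acc_threshold,
       change_threshold = config$change_threshold)
}

#' Remediation recommendation for an inadequate sample size
#'
#' Implements the three-way remediation logic applied when a dataset fails
#' the criteria.  Trends are measured first-to-last schedule size on the
#' best summary accuracy and on max(average, grand) mean effect size; a
#' relative rise above `trend_tolerance` counts as increasing.
#' \itemize{
#'   \item accuracy rising, effect size not: more samples *and* different
#'     features (`more_samples_and_features`).
#'   \item neither rising: the features are not informative -- revise the
#'     experimental design / acquire proper features
#'     (`revise_design_or_features`).
#'   \item effect size rising but still short of the threshold: more
#'     samples (`more_samples`); rising effect size leads to better
#'     accuracy eventually, so this covers the accuracy-also-rising case.
#' }
#'
#' @param curve an [aggregate_curve()] result with at least two sizes.
#' @param config a [criteria_config()].
#' @param rule accuracy summary rule, as in [criterion2()].
#' @return One of `"more_samples_and_features"`,
#'   `"revise_design_or_features"`, `"more_samples"`, or
#'   `"insufficient_schedule"` for a single-size curve.
#' @export
recommend_remediation <- function(curve, config = criteria_config(),
                                  rule = c("best", "median")) {
  rule <- match.arg(rule)
  sizes <- sort(unique(curve$accuracy$sample_size))
  if (length(sizes) < 2) return("insufficient_schedule")
  first <- sizes[1]; last <- sizes[length(sizes)]
  acc_first <- size_accuracy(curve, first, rule)
  acc_last <- size_accuracy(curve, last, rule)
  es <- curve$effect_sizes
  es_first <- max(es$d_average_mean[es$sample_size == first],
                  es$d_grand_mean[es$sample_size == first])
  es_last <- max(es$d_average_mean[es$sample_size == last],
                 es$d_grand_mean[es$sample_size == last])
  acc_up <- acc_first > 0 && (acc_last - acc_first) / acc_first >
    config$trend_tolerance
  es_up <- es_first > 0 && (es_last - es_first) / es_first >
    config$trend_tolerance
  if (es_up) "more_samples"
  else if (acc_up) "more_samples_and_features"
  else "revise_design_or_features"
}

#' Evaluate a decided sample size against both criteria
#'
#' Combines [criterion1()] and [criterion2()] into a verdict; when the size
#' is inadequate a remediation recommendation is attached.  The effect-size
#' summary and the curve should come from the same dataset; a lineage
#' mismatch (differing dataset fingerprints) raises a warning, not an
#' error, since the summary is often computed on the full dataset and the
#' curve on its subsamples.
#'
#' @param summary an [effect_size_summary()] for the decided sample size.
#' @param curve an [aggregate_curve()] result.
#' @param decided_size the sample size under evaluation.
#' @param config a [criteria_config()].
#' @param rule,comparison passed to [criterion2()].
#' @return An object of class `criteria_verdict`: list with `criterion1`,
#'   `criterion2`, `overall` (`"adequate"`/`"inadequate"`), `remediation`
#'   (`"none"` when adequate), `decided_size` and `config`.
#' @examples
#' sim <- generate_dataset(simulation_config(n_per_class = 64,
#'                                           n_variables = 10, seed = 2))
#' rec <- run_evaluation(sim$dataset,
#'                       build_schedule(128, sizes = c(16, 32), repetitions = 3),
#'                       specs = default_classifiers("nbayes"), seed = 2)
#' evaluate_sample_size(effect_size_summary(sim$dataset),
#'                      aggregate_curve(rec), decided_size = 32)
#' @export
evaluate_sample_size <- function(summary, curve, decided_size,
                                 config = criteria_config(),
                                 rule = c("best", "median"),
                                 comparison = c("next", "any")) {
  rule <- match.arg(rule)
  comparison <- match.arg(comparison)
  if (!is.null(summary$fingerprint) && !is.null(curve$fingerprint) &&
      !identical(summary$fingerprint, curve$fingerprint)) {
    warn_mlsize("lineage_mismatch",
                "effect-size summary and curve come from different datasets")
  }
  c1 <- criterion1(summary, config)
  c2 <- criterion2(curve, decided_size, config, rule, comparison)
  adequate <- c1$pass && c2$pass
  remediation <- if (adequate) "none" else {
    recommend_remediation(curve, config, rule)
  }
  structure(list(criterion1 = c1, criterion2 = c2,
                 overall = if (adequate) "adequate" else "inadequate",
                 remediation = remediation, decided_size = decided_size,
                 config = config),
            class = "criteria_verdict")
}

remediation_text <- c(
  none = "No remediation needed: the decided sample size is adequate.",
  more_samples_and_features = paste(
    "Accuracy improves with more samples but the effect size does not:",
    "collect more samples AND acquire different/additional features."),
  revise_design_or_features = paste(
    "Neither accuracy nor effect size improves with more samples: the",
    "features are likely uninformative; revise the experimental design",
    "and acquire proper features."),
  more_samples = paste(
    "The effect size rises with sample size but has not yet met the",
    "criteria: more samples are required."),
  insufficient_schedule = paste(
    "Only one sample size was evaluated; no trend can be assessed.",
    "Extend the subsampling schedule before deciding on remediation."))

#' @export
print.criteria_verdict <- function(x, ...) {
  cat("<criteria_verdict>\n")
  cat(sprintf("  decided sample size: %d\n", x$decided_size))
  cat(sprintf("  criterion 1 (effect size >= %.2g): %s (best %s d = %.4f)\n",
              x$config$es_threshold, if (x$criterion1$pass) "PASS" else "FAIL",
              x$criterion1$which, x$criterion1$best_effect_size))
  c2 <- x$criterion2
  stab <- if (is.na(c2$stability_ok)) "vacuous (no larger qualifying size)"
          else sprintf("change %.2f%% %s %g%%", c2$change_pct,
                       if (isTRUE(c2$stability_ok)) "<" else ">=",
                       c2$change_threshold)
  cat(sprintf("  criterion 2 (accuracy >= %.0f%%, stable): %s (acc %.1f%%; %s)\n",
              100 * c2$acc_threshold, if (c2$pass) "PASS" else "FAIL",
              100 * c2$accuracy, stab))
  cat(sprintf("  overall: %s\n", toupper(x$overall)))
  if (x$remediation != "none") {
    cat("  remediation:", remediation_text[[x$remediation]], "\n")
  }
  invisible(x)
}
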