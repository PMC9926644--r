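#' Run configuration for the end-to-end pipeline
#'
#' Bundles every knob of a full run -- data source, schedule, classifiers,
#' thresholds, master seed -- into one serializable object.  The
#' configuration written into every output bundle can be re-run to
#' identical numeric results.
#'
#' @param input a CSV path, a [labeled_dataset()], or a
#'   [simulation_config()].
#' @param label_column label column name for CSV input.
#' @param sizes optional explicit schedule sizes; `NULL` for the default
#'   doubling schedule.
#' @param start smallest schedule size (default 16).
#' @param repetitions subsample repetitions per size (default 100).
#' @param families classifier family subset (default all five).
#' @param metrics record AUC-ROC/precision/recall/F1 per record.
#' @param decided_size the sample size to judge; defaults to the largest
#'   schedule size.
#' @param criteria a [criteria_config()].
#' @param seed master seed for every stochastic stage.
#' @param k requested CV fold count.
#' @return An object of class `run_config`.
#' @export
run_config <- function(input, label_column = "label", sizes = NULL,
                       start = 16, repetitions = 100,
                       families = c("svm", "logistic", "tree", "nnet",
                                    "nbayes"),
                       metrics = FALSE, decided_size = NULL,
                       criteria = criteria_config(), seed = 1L, k = 10) {
  structure(list(input = input, label_column = label_column, sizes = sizes,
                 start = start, repetitions = as.integer(repetitions),
                 families = families, metrics = metrics,
                 decided_size = decided_size, criteria = criteria,
                 seed = as.integer(seed), k = k),
            class = "run_config")
}

config_as_list <- function(config) {
  input <- config$input
  input_desc <- if (inherits(input, "simulation_config")) {
    list(type = "simulation", regime = input$regime,
         n_per_class = input$n_per_class, n_variables = input$n_variables,
         d_range = input$d_range, quality_fraction = input$quality_fraction,
         noise_sd = input$noise_sd, seed = input$seed)
  } else if (inherits(input, "labeled_dataset")) {
    list(type = "in_memory", fingerprint = dataset_fingerprint(input))
  } else list(type = "csv", path = as.character(input))
  list(input = input_desc, label_column = config$label_column,
       sizes = config$sizes, start = config$start,
       repetitions = config$repetitions, families = config$families,
       metrics = config$metrics, decided_size = config$decided_size,
       criteria = unclass(config$criteria), seed = config$seed, k = config$k)
}

# Config hash for output stamping: R's internal string hashing over the
# serialized config list (stable within a session and across runs).
config_hash <- function(config) {
  raw <- serialize(config_as_list(config), NULL, version = 2)
  sprintf("%08x", sum(as.integer(raw) * seq_along(raw)) %% 2^31)
}

#' Run the full adequacy-evaluation pipeline
#'
#' Loads or simulates the dataset, computes the effect-size summary on the
#' full data, runs the subsampling evaluation, aggregates the learning
#' curve and applies both adequacy criteria.  When `output_dir` is given,
#' writes the reproducible bundle: `records.csv`, `curve.json`,
#' `effect_sizes.json`, `verdict.json` and `run.log`, each stamped with the
#' package version, config hash and master seed.
#'
#' @param config a [run_config()].
#' @param output_dir optional directory for the output bundle.
#' @return An object of class `mlsize_bundle`: list with `dataset`,
#'   `summary`, `records`, `curve`, `verdict`, `config`, `stamp`.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%H:%M:%S"), ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  input <- config$input
  if (inherits(input, "simulation_config")) {
    say("simulating dataset: regime=%s n/class=%d vars=%d seed=%d",
        input$regime, input$n_per_class, input$n_variables, input$seed)
    dataset <- generate_dataset(input)$dataset
  } else if (inherits(input, "labeled_dataset")) {
    dataset <- input
  } else {
    say("reading %s (label column '%s')", input, config$label_column)
    dataset <- read_labeled_csv(input, config$label_column)
  }
  idx <- check_two_class(dataset)
  n_bal <- 2L * min(lengths(idx))
  schedule <- build_schedule(n_bal, start = config$start,
                             sizes = config$sizes,
                             repetitions = config$repetitions)
  say("schedule: sizes %s, %d repetitions",
      paste(schedule$sizes, collapse = "/"), schedule$repetitions)
  summary <- effect_size_summary(dataset, on_zero_sd = "drop")
  say("full-data effect sizes: d_avg=%.4f d_grand=%.4f",
      summary$d_average, summary$d_grand)
  specs <- default_classifiers(config$families)
  records <- run_evaluation(dataset, schedule, specs, seed = config$seed,
                            k = config$k, metrics = config$metrics)
  curve <- aggregate_curve(records)
  decided <- if (is.null(config$decided_size)) {
    max(schedule$sizes)
  } else config$decided_size
  verdict <- evaluate_sample_size(summary, curve, decided,
                                  config = config$criteria)
  say("verdict at n=%d: %s (remediation: %s)", decided, verdict$overall,
      verdict$remediation)
  stamp <- list(package = "mlsize",
                version = as.character(utils::packageVersion("mlsize")),
                config_hash = config_hash(config), seed = config$seed)
  bundle <- structure(list(dataset = dataset, summary = summary,
                           records = records, curve = curve,
                           verdict = verdict, config = config,
                           stamp = stamp, log = log_lines),
                      class = "mlsize_bundle")
  if (!is.null(output_dir)) write_bundle(bundle, output_dir)
  bundle
}

write_bundle <- function(bundle, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(bundle$records),
                   file.path(output_dir, "records.csv"), row.names = FALSE)
  curve <- bundle$curve
  write_json_out(list(stamp = bundle$stamp,
                      accuracy = curve$accuracy,
                      effect_sizes = curve$effect_sizes,
                      changes = accuracy_change_or_null(curve)),
                 file.path(output_dir, "curve.json"))
  s <- bundle$summary
  write_json_out(list(stamp = bundle$stamp, d_average = s$d_average,
                      d_grand = s$d_grand,
                      per_variable_d = as.list(s$per_variable_d),
                      n_class1 = s$n_class1, n_class2 = s$n_class2),
                 file.path(output_dir, "effect_sizes.json"))
  v <- bundle$verdict
  write_json_out(list(stamp = bundle$stamp, decided_size = v$decided_size,
                      criterion1 = v$criterion1,
                      criterion2 = v$criterion2[c("pass", "accuracy",
                                                  "accuracy_ok", "change_pct",
                                                  "failed")],
                      overall = v$overall, remediation = v$remediation,
                      config = config_as_list(bundle$config)),
                 file.path(output_dir, "verdict.json"))
  writeLines(c(sprintf("mlsize %s  config=%s  seed=%d",
                       bundle$stamp$version, bundle$stamp$config_hash,
                       bundle$stamp$seed), bundle$log),
             file.path(output_dir, "run.log"))
  invisible(output_dir)
}

accuracy_change_or_null <- function(curve) {
  if (length(unique(curve$accuracy$sample_size)) < 2) return(NULL)
  accuracy_change(curve)
}

#' Render a plain-text adequacy report
#'
#' Deterministic one-page report of a pipeline bundle: effect sizes, the
#' learning curve, both criteria with measured values, and the remediation
#' recommendation when the size is inadequate.  Optionally draws the
#' three-panel figure (accuracy vs size with CI bands; between-size
#' changes; effect sizes vs size) to a device.
#'
#' @param bundle an `mlsize_bundle` from [run_pipeline()].
#' @param path optional file to write the report to.
#' @param plot if `TRUE`, draw the three-panel figure on the active device.
#' @return The report lines, invisibly.
#' @export
render_report <- function(bundle, path = NULL, plot = FALSE) {
  if (!inherits(bundle, "mlsize_bundle")) {
    stop_mlsize("missing_artifact", "expected an `mlsize_bundle`")
  }
  s <- bundle$summary; v <- bundle$verdict; curve <- bundle$curve
  sizes <- sort(unique(curve$accuracy$sample_size))
  lines <- c(
    "=== Sample-size adequacy report (mlsize) ===",
    sprintf("version %s | config %s | seed %d", bundle$stamp$version,
            bundle$stamp$config_hash, bundle$stamp$seed),
    "",
    sprintf("Dataset: %d + %d samples, %d variables", s$n_class1, s$n_class2,
            s$n_variables),
    sprintf("Average effect size d_avg = %.4f [%s]", s$d_average,
            classify_effect_size(s$d_average)),
    sprintf("Grand effect size   d_g   = %.4f [%s]", s$d_grand,
            classify_effect_size(s$d_grand)),
    "",
    sprintf("Schedule sizes: %s", paste(sizes, collapse = ", ")),
    "Mean accuracy by classifier and size:")
  for (cl in unique(curve$accuracy$classifier)) {
    g <- curve$accuracy[curve$accuracy$classifier == cl, ]
    g <- g[order(g$sample_size), ]
    lines <- c(lines, sprintf("  %-3s %s", cl,
                              paste(sprintf("%d:%.3f", g$sample_size, g$mean),
                                    collapse = "  ")))
  }
  c2 <- v$criterion2
  lines <- c(lines, "",
    sprintf("Criterion 1 (effect size >= %.2g): %s -- best %s d = %.4f",
            v$config$es_threshold, if (v$criterion1$pass) "PASS" else "FAIL",
            v$criterion1$which, v$criterion1$best_effect_size),
    sprintf("Criterion 2 (accuracy >= %.0f%%, change < %g%%): %s -- accuracy %.1f%% at n=%d",
            100 * c2$acc_threshold, c2$change_threshold,
            if (c2$pass) "PASS" else "FAIL", 100 * c2$accuracy,
            v$decided_size))
  lines <- c(lines, if (is.na(c2$stability_ok)) {
    "  Stability clause vacuous: no larger size meets the accuracy threshold."
  } else {
    sprintf("  Change to next qualifying size: %.2f%%", c2$change_pct)
  })
  lines <- c(lines, "", sprintf("OVERALL: the decided sample size %d is %s.",
                                v$decided_size, toupper(v$overall)))
  if (v$remediation != "none") {
    lines <- c(lines, paste("Remediation:", remediation_text[[v$remediation]]))
  }
  if (plot) plot_bundle(bundle)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

# Three-panel base-graphics figure: learning curves with CI bands,
# between-size changes, effect sizes vs size.
plot_bundle <- function(bundle) {
  curve <- bundle$curve
  acc <- curve$accuracy
  sizes <- sort(unique(acc$sample_size))
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  cls <- unique(acc$classifier)
  cols <- grDevices::hcl.colors(max(3, length(cls)), "Dark 3")[seq_along(cls)]
  graphics::plot(NULL, xlim = range(sizes), ylim = c(0, 1), log = "x",
                 xlab = "sample size", ylab = "accuracy",
                 main = "CV accuracy (95% CI)")
  for (i in seq_along(cls)) {
    g <- acc[acc$classifier == cls[i], ]
    g <- g[order(g$sample_size), ]
    graphics::polygon(c(g$sample_size, rev(g$sample_size)),
                      c(g$ci_lower, rev(g$ci_upper)),
                      col = grDevices::adjustcolor(cols[i], 0.2), border = NA)
    graphics::lines(g$sample_size, g$mean, col = cols[i], lwd = 2)
  }
  graphics::abline(h = 0.8, lty = 2)
  graphics::legend("bottomright", legend = cls, col = cols, lwd = 2, cex = 0.8)
  if (length(sizes) > 1) {
    chg <- accuracy_change(curve)
    graphics::plot(NULL, xlim = range(sizes), ylim = c(0, max(chg$change_pct,
                                                              10, na.rm = TRUE)),
                   log = "x", xlab = "sample size (to)",
                   ylab = "relative change (%)", main = "Between-size change")
    for (i in seq_along(cls)) {
      g <- chg[chg$classifier == cls[i], ]
      graphics::lines(g$to_size, g$change_pct, col = cols[i], lwd = 2)
    }
    graphics::abline(h = 10, lty = 2)
  } else {
    graphics::plot.new()
  }
  es <- curve$effect_sizes
  graphics::plot(NULL, xlim = range(sizes),
                 ylim = c(0, max(es$d_average_mean + es$d_average_sd, 1,
                                 na.rm = TRUE)),
                 log = "x", xlab = "sample size", ylab = "effect size",
                 main = "Average and grand effect size")
  graphics::arrows(es$sample_size, es$d_average_mean - es$d_average_sd,
                   es$sample_size, es$d_average_mean + es$d_average_sd,
                   length = 0.02, angle = 90, code = 3, col = "grey50")
  graphics::lines(es$sample_size, es$d_average_mean, lwd = 2, col = "black")
  graphics::lines(es$sample_size, es$d_grand_mean, lwd = 2, col = "grey40",
                  lty = 2)
  graphics::abline(h = 0.5, lty = 3)
  graphics::legend("topright", legend = c("average", "grand"),
                   col = c("black", "grey40"), lty = c(1, 2), lwd = 2,
                   cex = 0.8)
  invisible(NULL)
}
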