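#' Subsampling schedule
#'
#' Builds the list of total sample sizes at which the dataset is repeatedly
#' subsampled: geometric doubling from `start` (default 16, the protocol's
#' smallest size) capped at the largest even count not exceeding the
#' available balanced total, which is appended when not already present.
#' Custom size lists are validated instead.
#'
#' @param n_available_balanced total number of samples available under
#'   balanced classes (twice the smaller class).
#' @param start smallest size (default 16).
#' @param sizes optional explicit size list (even, strictly increasing,
#'   within the available total); overrides the doubling rule.
#' @param repetitions subsample repetitions per size (default 100).
#' @return An object of class `subsample_schedule`: list with `sizes` and
#'   `repetitions`.
#' @examples
#' build_schedule(5000)$sizes   # 16 32 64 ... 4096 5000
#' @export
build_schedule <- function(n_available_balanced, start = 16,
                           sizes = NULL, repetitions = 100) {
  if (n_available_balanced < start) {
    stop_mlsize("insufficient_data", sprintf(
      "need at least %d balanced samples, have %d", start,
      n_available_balanced))
  }
  cap <- 2L * (n_available_balanced %/% 2L)  # largest even count available
  if (is.null(sizes)) {
    sizes <- start
    while (utils::tail(sizes, 1) * 2 <= cap) {
      sizes <- c(sizes, utils::tail(sizes, 1) * 2)
    }
    if (utils::tail(sizes, 1) < cap) sizes <- c(sizes, cap)
  } else {
    sizes <- as.integer(sizes)
    if (any(sizes %% 2 != 0)) {
      stop_mlsize("schedule_error", "all sizes must be even (balanced halves)")
    }
    if (is.unsorted(sizes, strictly = TRUE)) {
      stop_mlsize("schedule_error", "sizes must be strictly increasing")
    }
    if (max(sizes) > cap) {
      stop_mlsize("schedule_error", sprintf(
        "largest size %d exceeds available balanced total %d", max(sizes), cap))
    }
  }
  if (repetitions < 1) stop_mlsize("schedule_error", "repetitions must be >= 1")
  structure(list(sizes = as.integer(sizes),
                 repetitions = as.integer(repetitions)),
            class = "subsample_schedule")
}

#' @export
print.subsample_schedule <- function(x, ...) {
  cat(sprintf("<subsample_schedule> sizes: %s; %d repetitions each\n",
              paste(x$sizes, collapse = ", "), x$repetitions))
  invisible(x)
}

#' Balanced random subsample
#'
#' Draws `n_total / 2` samples per class, uniformly without replacement.
#'
#' @param dataset a [labeled_dataset()] with two classes.
#' @param n_total even total subsample size.
#' @param seed RNG seed.
#' @return A [labeled_dataset()] with `n_total` rows.
#' @export
subsample_balanced <- function(dataset, n_total, seed = 1L) {
  idx <- check_two_class(dataset)
  if (n_total %% 2 != 0) {
    stop_mlsize("schedule_error", "n_total must be even")
  }
  half <- n_total %/% 2L
  if (any(lengths(idx) < half)) {
    stop_mlsize("class_too_small", sprintf(
      "need %d samples per class, classes have %s", half,
      paste(lengths(idx), collapse = ", ")))
  }
  set.seed(seed)
  rows <- c(sample(idx[[1]], half), sample(idx[[2]], half))
  labeled_dataset(dataset$values[rows, , drop = FALSE],
                  as.character(dataset$labels[rows]),
                  dataset$variable_names)
}

#' Run the subsampling evaluation protocol
#'
#' For every (size, repetition) pair: draw one balanced subsample, record
#' its average and grand effect sizes once, then run stratified k-fold
#' cross-validation for every classifier spec on that same subsample.
#' Every repetition carries its own deterministically derived child seed, so
#' the record table is reproducible and independent of execution order.
#'
#' @param dataset a [labeled_dataset()].
#' @param schedule a [subsample_schedule()] (or `NULL` to build the default
#'   from the dataset).
#' @param specs list of [classifier_spec()]s (default all five families).
#' @param seed master seed.
#' @param k requested CV fold count (default 10).
#' @param metrics if `TRUE`, record AUC-ROC/precision/recall/F1 per record.
#' @return An object of class `evaluation_records`: a data frame with one
#'   row per (size, repetition, classifier) holding `sample_size`,
#'   `repetition`, `classifier`, `accuracy`, `k_effective`, `d_average`,
#'   `d_grand`, optional metric columns, and the subsample seed.  The
#'   dataset fingerprint and classifier settings are attached as attributes.
#' @examples
#' sim <- generate_dataset(simulation_config(n_per_class = 32,
#'                                           n_variables = 5, seed = 1))
#' sched <- build_schedule(64, sizes = c(16, 32), repetitions = 2)
#' rec <- run_evaluation(sim$dataset, sched,
#'                       specs = default_classifiers("nbayes"), seed = 1)
#' nrow(rec)   # 2 sizes x 2 repetitions x 1 classifier
#' @export
run_evaluation <- function(dataset, schedule = NULL,
                           specs = default_classifiers(), seed = 1L,
                           k = 10, metrics = FALSE) {
  idx <- check_two_class(dataset)
  if (is.null(schedule)) schedule <- build_schedule(2L * min(lengths(idx)))
  if (inherits(specs, "classifier_spec")) specs <- list(specs)
  sizes <- schedule$sizes
  reps <- schedule$repetitions
  grid <- expand.grid(repetition = seq_len(reps), sample_size = sizes)
  sub_seeds <- matrix(derive_seeds(seed, 2L * nrow(grid)), ncol = 2)

  rows <- vector("list", nrow(grid) * length(specs))
  ri <- 1L
  for (g in seq_len(nrow(grid))) {
    n_tot <- grid$sample_size[g]
    rep_i <- grid$repetition[g]
    sub <- subsample_balanced(dataset, n_tot, seed = sub_seeds[g, 1])
    es <- tryCatch(effect_size_summary(sub, on_zero_sd = "drop"),
                   mlsize_error = function(e) NULL)
    d_avg <- if (is.null(es)) NA_real_ else es$d_average
    d_g <- if (is.null(es)) NA_real_ else es$d_grand
    for (s in seq_along(specs)) {
      cv <- tryCatch(
        crossval_accuracy(sub, specs[[s]], k = k,
                          seed = sub_seeds[g, 2] + s - 1L, metrics = metrics),
        mlsize_error = function(e) {
          warn_mlsize("record_failure", sprintf(
            "size %d rep %d %s: %s", n_tot, rep_i, specs[[s]]$label,
            conditionMessage(e)))
          list(accuracy = NA_real_, k_effective = NA_integer_)
        })
      row <- data.frame(
        sample_size = n_tot, repetition = rep_i,
        classifier = specs[[s]]$label, accuracy = cv$accuracy,
        k_effective = cv$k_effective, d_average = d_avg, d_grand = d_g,
        subsample_seed = sub_seeds[g, 1], stringsAsFactors = FALSE)
      if (metrics && !is.null(cv$metrics)) {
        row <- cbind(row, as.data.frame(cv$metrics))
      }
      rows[[ri]] <- row
      ri <- ri + 1L
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("evaluation_records", class(out))
  attr(out, "fingerprint") <- dataset_fingerprint(dataset)
  attr(out, "specs") <- lapply(specs, function(s) {
    list(family = s$family, label = s$label, settings = s$settings)
  })
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Aggregate evaluation records into a learning curve
#'
#' Per (classifier, size): mean accuracy, within-size accuracy SD and the
#' normal-approximation 95% confidence interval (mean +/- 1.96 SD / sqrt(r)
#' over the r repetitions).  Per size: mean and SD of both aggregate effect
#' sizes across repetitions.  Consecutive-size relative accuracy changes
#' are available through [accuracy_change()].
#'
#' @param records an `evaluation_records` data frame from
#'   [run_evaluation()].
#' @return An object of class `evaluation_curve`: list with data frames
#'   `accuracy` (classifier, sample_size, n_reps, mean, sd, ci_lower,
#'   ci_upper) and `effect_sizes` (sample_size, d_average_mean,
#'   d_average_sd, d_grand_mean, d_grand_sd), plus the inherited
#'   fingerprint.
#' @export
aggregate_curve <- function(records) {
  if (nrow(records) == 0) stop_mlsize("empty_group", "no records to aggregate")
  acc <- do.call(rbind, lapply(
    split(records, list(records$classifier, records$sample_size),
          drop = TRUE),
    function(g) {
      a <- g$accuracy[!is.na(g$accuracy)]
      r <- length(a)
      if (r < 2) stop_mlsize("empty_group", sprintf(
        "need >= 2 repetitions per (classifier, size); %s at %d has %d",
        g$classifier[1], g$sample_size[1], r))
      m <- mean(a); s <- stats::sd(a)
      hw <- stats::qnorm(0.975) * s / sqrt(r)
      data.frame(classifier = g$classifier[1], sample_size = g$sample_size[1],
                 n_reps = r, mean = m, sd = s,
                 ci_lower = m - hw, ci_upper = m + hw,
                 stringsAsFactors = FALSE)
    }))
  acc <- acc[order(acc$classifier, acc$sample_size), ]
  rownames(acc) <- NULL
  per_sub <- records[!duplicated(records[c("sample_size", "repetition")]), ]
  es <- do.call(rbind, lapply(split(per_sub, per_sub$sample_size), function(g) {
    data.frame(sample_size = g$sample_size[1],
               d_average_mean = mean(g$d_average, na.rm = TRUE),
               d_average_sd = stats::sd(g$d_average, na.rm = TRUE),
               d_grand_mean = mean(g$d_grand, na.rm = TRUE),
               d_grand_sd = stats::sd(g$d_grand, na.rm = TRUE))
  }))
  es <- es[order(es$sample_size), ]
  rownames(es) <- NULL
  structure(list(accuracy = acc, effect_sizes = es,
                 fingerprint = attr(records, "fingerprint"),
                 seed = attr(records, "seed")),
            class = "evaluation_curve")
}

#' @export
print.evaluation_curve <- function(x, digits = 3, ...) {
  cat("<evaluation_curve>\n")
  wide <- stats::reshape(
    x$accuracy[c("classifier", "sample_size", "mean")],
    idvar = "sample_size", timevar = "classifier", direction = "wide")
  names(wide) <- sub("^mean\\.", "", names(wide))
  print(cbind(wide,
              d_avg = round(x$effect_sizes$d_average_mean, digits),
              d_grand = round(x$effect_sizes$d_grand_mean, digits)),
        digits = digits, row.names = FALSE)
  invisible(x)
}

#' Relative accuracy change between consecutive sizes
#'
#' For each classifier and consecutive size pair n_k < n_(k+1):
#' `100 * |mean_acc(n_(k+1)) - mean_acc(n_k)| / mean_acc(n_k)` (percent).
#'
#' @param curve an [aggregate_curve()] result.
#' @return Data frame with `classifier`, `from_size`, `to_size`,
#'   `change_pct`.  A zero mean accuracy at the smaller size yields `NA`
#'   with a warning.
#' @export
accuracy_change <- function(curve) {
  acc <- curve$accuracy
  out <- do.call(rbind, lapply(split(acc, acc$classifier), function(g) {
    g <- g[order(g$sample_size), ]
    if (nrow(g) < 2) return(NULL)
    from <- g$mean[-nrow(g)]
    to <- g$mean[-1]
    chg <- ifelse(from > 0, 100 * abs(to - from) / from, NA_real_)
    data.frame(classifier = g$classifier[1],
               from_size = g$sample_size[-nrow(g)],
               to_size = g$sample_size[-1],
               change_pct = chg, stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    stop_mlsize("schedule_error", "accuracy change needs at least 2 sizes")
  }
  if (anyNA(out$change_pct)) {
    warn_mlsize("zero_accuracy", "zero mean accuracy: change undefined (NA)")
  }
  rownames(out) <- NULL
  out
}
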