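test_that("schedule doubles from 16 and caps at the available total", {
  expect_equal(build_schedule(5000)$sizes,
               c(16, 32, 64, 128, 256, 512, 1024, 2048, 4096, 5000))
  expect_equal(build_schedule(16)$sizes, 16)
  expect_error(build_schedule(15), class = "mlsize_insufficient_data")
  # odd totals cap at the largest even count
  expect_equal(tail(build_schedule(101)$sizes, 1), 100)
  # custom lists validated
  expect_equal(build_schedule(200, sizes = c(16, 50, 100))$sizes,
               c(16, 50, 100))
  expect_error(build_schedule(200, sizes = c(16, 15)),
               class = "mlsize_schedule_error")
  expect_error(build_schedule(200, sizes = c(32, 16)),
               class = "mlsize_schedule_error")
  expect_error(build_schedule(200, sizes = c(16, 300)),
               class = "mlsize_schedule_error")
})

test_that("schedule defaults match the protocol: start 16, 100 repetitions", {
  sched <- build_schedule(64)
  expect_equal(sched$sizes[1], 16)
  expect_equal(sched$repetitions, 100)
  expect_equal(eval(formals(build_schedule)$start), 16)
  expect_equal(eval(formals(build_schedule)$repetitions), 100)
})

test_that("balanced subsampling draws distinct rows per class, reproducibly", {
  ds <- shifted_dataset(100, deltas = rep(0.5, 3), seed = 1)
  sub <- subsample_balanced(ds, 16, seed = 7)
  expect_equal(unname(tabulate(sub$labels)), c(8, 8))
  expect_equal(nrow(unique(sub$values)), 16)
  expect_identical(subsample_balanced(ds, 16, seed = 7)$values, sub$values)
  # full-size subsample is a permutation of the whole dataset
  whole <- subsample_balanced(ds, 200, seed = 3)
  expect_equal(sort(whole$values[, 1]), sort(ds$values[, 1]))
  expect_error(subsample_balanced(ds, 300, seed = 1),
               class = "mlsize_class_too_small")
  expect_error(subsample_balanced(ds, 15, seed = 1),
               class = "mlsize_schedule_error")
})

test_that("cross-validation separates well-separated classes", {
  # class means 10 SDs apart: near-zero Bayes error
  ds <- shifted_dataset(32, deltas = rep(10, 4), seed = 2)
  for (fam in c("svm", "logistic", "nnet")) {
    cv <- crossval_accuracy(ds, classifier_spec(fam), seed = 1)
    expect_gte(cv$accuracy, 0.98)
    expect_equal(cv$k_effective, 10)
  }
})

test_that("cross-validation sits at chance on label-permuted data", {
  set.seed(3)
  x <- matrix(rnorm(200 * 6), 200, 6)
  ds <- labeled_dataset(x, sample(rep(c("a", "b"), each = 100)))
  for (fam in c("svm", "logistic", "tree", "nnet", "nbayes")) {
    mean_acc <- mean(vapply(1:5, function(r) {
      crossval_accuracy(ds, classifier_spec(fam), seed = r)$accuracy
    }, numeric(1)))
    expect_gte(mean_acc, 0.4)
    expect_lte(mean_acc, 0.6)
  }
})

test_that("fold count reduces to the smaller class at tiny n", {
  ds <- shifted_dataset(8, deltas = rep(1, 3), seed = 5)   # 16 total
  cv <- crossval_accuracy(ds, classifier_spec("nbayes"), k = 10, seed = 1)
  expect_equal(cv$k_effective, 8)
})

test_that("requested metrics are computed on pooled out-of-fold predictions", {
  ds <- shifted_dataset(40, deltas = rep(2, 4), seed = 6)
  cv <- crossval_accuracy(ds, classifier_spec("logistic"), seed = 2,
                          metrics = TRUE)
  m <- cv$metrics
  expect_named(m, c("auc_roc", "precision", "recall", "f1"))
  for (v in unlist(m)) { expect_gte(v, 0); expect_lte(v, 1) }
  expect_gte(m$auc_roc, 0.9)   # well-separated classes
})

test_that("run_evaluation yields the full record grid, deterministically", {
  sim <- generate_dataset(simulation_config(32, n_variables = 6, seed = 7))
  sched <- build_schedule(64, sizes = c(16, 32), repetitions = 3)
  specs <- default_classifiers(c("nbayes", "tree"))
  rec <- run_evaluation(sim$dataset, sched, specs, seed = 8)
  expect_equal(nrow(rec), 2 * 3 * 2)     # sizes x repetitions x classifiers
  expect_true(all(rec$accuracy >= 0 & rec$accuracy <= 1))
  expect_true(all(is.finite(rec$d_average) & rec$d_average >= 0))
  rec2 <- run_evaluation(sim$dataset, sched, specs, seed = 8)
  expect_identical(as.data.frame(rec), as.data.frame(rec2))
  # effect sizes recorded once per subsample, shared across classifiers
  per_sub <- split(rec$d_average, interaction(rec$sample_size, rec$repetition))
  expect_true(all(vapply(per_sub, function(v) length(unique(v)) == 1,
                         logical(1))))
})

test_that("curves aggregate means, CIs and effect sizes per size", {
  sim <- generate_dataset(simulation_config(32, n_variables = 6, seed = 9))
  sched <- build_schedule(64, sizes = c(16, 32), repetitions = 3)
  rec <- run_evaluation(sim$dataset, sched, default_classifiers("nbayes"),
                        seed = 10)
  curve <- aggregate_curve(rec)
  expect_equal(nrow(curve$accuracy), 2)
  expect_true(all(curve$accuracy$ci_lower <= curve$accuracy$mean &
                  curve$accuracy$mean <= curve$accuracy$ci_upper))
  expect_equal(curve$effect_sizes$sample_size, c(16, 32))

  # closed-form check: repetitions 0.8 and 0.9
  rec2 <- data.frame(sample_size = 16, repetition = 1:2, classifier = "NB",
                     accuracy = c(0.8, 0.9), k_effective = 8,
                     d_average = 0.5, d_grand = 0.5, subsample_seed = 1:2)
  c2 <- aggregate_curve(rec2)
  expect_equal(c2$accuracy$mean, 0.85)
  expect_equal(c2$accuracy$sd, 0.07071068, tolerance = 1e-6)
  # zero variance collapses the CI onto the mean
  rec3 <- transform(rec2, accuracy = 0.8)
  c3 <- aggregate_curve(rec3)
  expect_equal(c3$accuracy$ci_lower, 0.8)
  expect_equal(c3$accuracy$ci_upper, 0.8)
})

test_that("relative accuracy change is percent of the smaller size", {
  mk_curve <- function(acc) {
    structure(list(accuracy = data.frame(
      classifier = "SVM", sample_size = c(16, 32), n_reps = 10,
      mean = acc, sd = 0.01, ci_lower = acc - 0.01, ci_upper = acc + 0.01),
      effect_sizes = data.frame(sample_size = c(16, 32),
                                d_average_mean = 1, d_average_sd = 0,
                                d_grand_mean = 1, d_grand_sd = 0)),
      class = "evaluation_curve")
  }
  expect_equal(accuracy_change(mk_curve(c(0.50, 0.71)))$change_pct, 42)
  expect_equal(accuracy_change(mk_curve(c(0.80, 0.88)))$change_pct, 10)
  expect_equal(accuracy_change(mk_curve(c(0.6, 0.6)))$change_pct, 0)
  expect_warning(chg <- accuracy_change(mk_curve(c(0, 0.5))),
                 class = "mlsize_zero_accuracy")
  expect_true(is.na(chg$change_pct))
})

test_that("accuracy improves with sample size on discriminable data", {
  sim <- generate_dataset(simulation_config(128, n_variables = 20,
                                            regime = "good", seed = 12))
  sched <- build_schedule(256, sizes = c(16, 64, 256), repetitions = 5)
  rec <- run_evaluation(sim$dataset, sched,
                        default_classifiers(c("logistic", "nbayes")),
                        seed = 13)
  curve <- aggregate_curve(rec)
  for (cl in unique(curve$accuracy$classifier)) {
    g <- curve$accuracy[curve$accuracy$classifier == cl, ]
    g <- g[order(g$sample_size), ]
    expect_lte(sum(diff(g$mean) < 0), 1)   # at most one inversion
  }
  # within-size accuracy spread shrinks from smallest to largest size
  for (cl in unique(curve$accuracy$classifier)) {
    g <- curve$accuracy[curve$accuracy$classifier == cl, ]
    expect_gt(g$sd[g$sample_size == 16], g$sd[g$sample_size == 256])
  }
})
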