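test_that("per-variable Cohen's d matches hand-computed cases", {
  # means 2 and 4, both SDs 1, pooled SD 1 -> d = -2
  d <- labeled_dataset(cbind(x = c(1, 2, 3, 3, 4, 5)),
                       rep(c("a", "b"), each = 3))
  expect_equal(unname(per_variable_cohens_d(d)), -2)

  # identical classes variable-wise -> all d zero
  x <- matrix(rnorm(20), 5, 4)
  same <- labeled_dataset(rbind(x, x), rep(c("a", "b"), each = 5))
  expect_equal(unname(per_variable_cohens_d(same)), rep(0, 4))

  # sign convention: (first sorted class) - (second)
  up <- labeled_dataset(cbind(c(1, 2, 3, 0, 1, 2)),
                        rep(c("a", "b"), each = 3))
  expect_equal(unname(per_variable_cohens_d(up)), 1)
})

test_that("average effect size is the mean magnitude of per-variable d", {
  # var 1: d = +1, var 2: d = -1 -> magnitudes do not cancel
  v1 <- c(1, 2, 3, 0, 1, 2)
  v2 <- c(0, 1, 2, 1, 2, 3)
  d <- labeled_dataset(cbind(v1, v2), rep(c("a", "b"), each = 3))
  expect_equal(unname(per_variable_cohens_d(d)), c(1, -1))
  expect_equal(average_effect_size(d), 1)

  # single variable: averaging over one variable is the identity
  one <- labeled_dataset(cbind(rnorm(10)), rep(c("a", "b"), each = 5))
  expect_equal(average_effect_size(one),
               abs(unname(per_variable_cohens_d(one))))

  x <- matrix(rnorm(24), 6, 4)
  same <- labeled_dataset(rbind(x, x), rep(c("a", "b"), each = 6))
  expect_equal(average_effect_size(same), 0)
})

test_that("grand effect size cancels opposite-signed effects, average does not", {
  # class-2 mean shifts +1 and -1, all SDs 1: grand means coincide
  d <- shifted_dataset(1e4, deltas = c(1, -1), seed = 42)
  expect_equal(average_effect_size(d), 1, tolerance = 0.05)
  expect_lt(grand_effect_size(d), 0.05)

  # identical classes -> grand effect size 0
  x <- matrix(rnorm(24), 6, 4)
  same <- labeled_dataset(rbind(x, x), rep(c("a", "b"), each = 6))
  expect_equal(grand_effect_size(same), 0)
})

test_that("homogeneous variables collapse average and grand effect sizes", {
  # duplicating one column makes per-variable class means/SDs identical,
  # so the average and grand statistics agree exactly
  set.seed(7)
  col1 <- rnorm(12); col2 <- rnorm(12) + 0.8
  x <- cbind(col1, col1, col1)
  y <- cbind(col2, col2, col2)
  d <- labeled_dataset(rbind(x, y), rep(c("a", "b"), each = 12))
  expect_lt(abs(average_effect_size(d) - grand_effect_size(d)), 1e-10)
})

test_that("effect sizes match the loop-wise brute-force oracle", {
  for (seed in 1:200) {
    ds <- random_small_dataset(seed)
    want <- oracle_effect_sizes(ds$x1, ds$x2)
    s <- effect_size_summary(ds$dataset)
    expect_equal(unname(s$per_variable_d), want$per_variable_d,
                 tolerance = 1e-12)
    expect_equal(s$d_average, want$d_average, tolerance = 1e-10)
    expect_equal(s$d_grand, want$d_grand, tolerance = 1e-10)
  }
})

test_that("effect sizes are scale- and shift-invariant and label-swap symmetric", {
  for (seed in c(3, 14, 159)) {
    ds <- random_small_dataset(seed)$dataset
    base_d <- per_variable_cohens_d(ds)
    base_avg <- average_effect_size(ds)
    base_g <- grand_effect_size(ds)

    scaled <- labeled_dataset(ds$values * 3.7, ds$labels)
    expect_equal(per_variable_cohens_d(scaled), base_d, tolerance = 1e-10)
    expect_equal(average_effect_size(scaled), base_avg, tolerance = 1e-10)
    expect_equal(grand_effect_size(scaled), base_g, tolerance = 1e-10)

    shifted <- labeled_dataset(ds$values + 11.3, ds$labels)
    expect_equal(per_variable_cohens_d(shifted), base_d, tolerance = 1e-10)
    expect_equal(average_effect_size(shifted), base_avg, tolerance = 1e-10)
    expect_equal(grand_effect_size(shifted), base_g, tolerance = 1e-10)

    swapped <- labeled_dataset(
      ds$values, chartr("ab", "ba", as.character(ds$labels)))
    expect_equal(per_variable_cohens_d(swapped), -base_d, tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(average_effect_size(swapped), base_avg, tolerance = 1e-10)
    expect_equal(grand_effect_size(swapped), base_g, tolerance = 1e-10)
  }
})

test_that("degenerate variance raises a typed error or drops with a warning", {
  d <- labeled_dataset(cbind(const = rep(1, 8), ok = rnorm(8)),
                       rep(c("a", "b"), each = 4))
  expect_error(per_variable_cohens_d(d), class = "mlsize_degenerate_variance")
  expect_warning(dd <- per_variable_cohens_d(d, on_zero_sd = "drop"),
                 class = "mlsize_dropped_variables")
  expect_named(dd, "ok")
})

test_that("two-class and missing-value contracts are enforced", {
  expect_error(labeled_dataset(cbind(c(1, NA, 3)), c("a", "a", "b")),
               class = "mlsize_input_error")
  three <- labeled_dataset(matrix(rnorm(12), 6, 2), rep(c("a", "b", "c"), 2))
  expect_error(per_variable_cohens_d(three), class = "mlsize_two_class_error")
  tiny <- labeled_dataset(matrix(rnorm(6), 3, 2), c("a", "a", "b"))
  expect_error(per_variable_cohens_d(tiny), class = "mlsize_two_class_error")
})

test_that("effect-size magnitudes classify on Cohen's scale", {
  expect_equal(classify_effect_size(0.2), "trivial")
  expect_equal(classify_effect_size(0.5), "significant")
  expect_equal(classify_effect_size(0.35), "intermediate")
  expect_equal(classify_effect_size(c(0, 0.21, 0.49, 1.3)),
               c("trivial", "intermediate", "intermediate", "significant"))
  expect_error(classify_effect_size(-0.1), class = "mlsize_input_error")
})

test_that("summaries round-trip through CSV and JSON", {
  ds <- random_small_dataset(9)$dataset
  s <- effect_size_summary(ds)
  jf <- withr::local_tempfile(fileext = ".json")
  cf <- withr::local_tempfile(fileext = ".csv")
  write_effect_size_summary(s, jf)
  write_effect_size_summary(s, cf)
  j <- jsonlite::read_json(jf, simplifyVector = TRUE)
  expect_equal(j$d_average, s$d_average)
  expect_equal(j$d_grand, s$d_grand)
  expect_equal(unlist(j$per_variable_d), s$per_variable_d)
  cc <- read.csv(cf)
  expect_equal(nrow(cc), s$n_variables)
  expect_equal(cc$d, unname(s$per_variable_d))
})

test_that("labeled datasets round-trip through CSV with a label column", {
  ds <- random_small_dataset(4)$dataset
  f <- withr::local_tempfile(fileext = ".csv")
  write_labeled_csv(ds, f)
  back <- read_labeled_csv(f)
  expect_equal(back$values, ds$values, ignore_attr = TRUE)
  expect_equal(as.character(back$labels), as.character(ds$labels))
  # non-numeric feature column is rejected with the column named
  df <- data.frame(a = 1:4, b = letters[1:4], label = c(0, 0, 1, 1))
  write.csv(df, f, row.names = FALSE)
  expect_error(read_labeled_csv(f), "b", class = "mlsize_input_error")
})
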