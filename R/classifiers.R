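#' Classifier specification
#'
#' One of the five supervised families used throughout the evaluation
#' protocol, with its recorded hyperparameters.  Defaults (all overridable
#' through `settings` and serialized into every result record):
#' \describe{
#'   \item{`svm`}{linear-kernel support-vector machine, cost 1
#'     (\pkg{e1071}).}
#'   \item{`logistic`}{L2-penalised (ridge) logistic regression,
#'     `lambda = 0.01` on standardized features (\pkg{glmnet}).}
#'   \item{`tree`}{CART decision tree, `minsplit = 4`, `minbucket = 2`,
#'     `cp = 0.01` (\pkg{rpart}); the stock `minsplit = 20` cannot split at
#'     all at the protocol's smallest size of 16.}
#'   \item{`nnet`}{single-hidden-layer neural network, 8 units,
#'     `decay = 0.1`, `maxit = 100` (\pkg{nnet}).}
#'   \item{`nbayes`}{Gaussian naive Bayes (\pkg{e1071}).}
#' }
#' Features are standardized per training fold (mean/SD fit on the training
#' fold only) for the scale-sensitive families (`svm`, `logistic`, `nnet`);
#' trees and naive Bayes are scale-free and see raw features.
#'
#' @param family one of `"svm"`, `"logistic"`, `"tree"`, `"nnet"`,
#'   `"nbayes"`.
#' @param settings named list of hyperparameter overrides.
#' @param label display name (defaults to the conventional abbreviation:
#'   SVM, LR, DT, NN, NB).
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("svm", "logistic", "tree", "nnet",
                                       "nbayes"),
                            settings = list(), label = NULL) {
  family <- match.arg(family)
  defaults <- switch(family,
    svm      = list(kernel = "linear", cost = 1),
    logistic = list(alpha = 0, lambda = 0.01),
    tree     = list(minsplit = 4, minbucket = 2, cp = 0.01),
    nnet     = list(size = 8, decay = 0.1, maxit = 100),
    nbayes   = list())
  settings <- utils::modifyList(defaults, settings)
  if (is.null(label)) {
    label <- c(svm = "SVM", logistic = "LR", tree = "DT", nnet = "NN",
               nbayes = "NB")[[family]]
  }
  structure(list(family = family, settings = settings, label = label,
                 scaled = family %in% c("svm", "logistic", "nnet")),
            class = "classifier_spec")
}

#' Default bank of the five classifier families
#'
#' @param families subset of family names to include (default all five).
#' @return List of [classifier_spec()] objects.
#' @export
default_classifiers <- function(families = c("svm", "logistic", "tree",
                                             "nnet", "nbayes")) {
  lapply(families, classifier_spec)
}

#' @export
print.classifier_spec <- function(x, ...) {
  s <- if (length(x$settings)) {
    paste(names(x$settings), unlist(x$settings), sep = "=", collapse = ", ")
  } else "defaults"
  cat(sprintf("<classifier_spec> %s (%s): %s\n", x$label, x$family, s))
  invisible(x)
}

# Fit one family on a training matrix and return a score for the second
# (sorted) class on the test matrix: a probability for all families except
# the SVM, which returns its oriented decision value (rank-equivalent, and
# avoids the costly internal Platt-scaling CV).  Class predictions use
# `threshold`.  x matrices are already standardized when the family wants it.
fit_predict_score <- function(spec, x_train, y_train, x_test) {
  s <- spec$settings
  lev <- levels(y_train)
  switch(spec$family,
    svm = {
      fit <- e1071::svm(x_train, y_train, kernel = s$kernel, cost = s$cost,
                        scale = FALSE)
      pr <- stats::predict(fit, x_test, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      # decision-value column named "A/B": positive values favor A
      pos_first <- sub("/.*$", "", colnames(dv)[1]) == lev[1]
      score <- if (pos_first) -dv[, 1] else dv[, 1]
      list(pred = as.integer(pr == lev[2]), score = as.numeric(score))
    },
    logistic = {
      # glmnet warns on every fold below 8 obs per class; expected at the
      # protocol's smallest size (16 total), so muffle just that advisory
      fit <- withCallingHandlers(
        glmnet::glmnet(x_train, y_train, family = "binomial",
                       alpha = s$alpha, lambda = s$lambda,
                       standardize = FALSE),
        warning = function(w) {
          if (grepl("fewer than 8", conditionMessage(w)))
            invokeRestart("muffleWarning")
        })
      as.numeric(stats::predict(fit, x_test, type = "response",
                                s = s$lambda))
    },
    tree = {
      df <- data.frame(.y = y_train, x_train, check.names = FALSE)
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                          control = rpart::rpart.control(
                            minsplit = s$minsplit, minbucket = s$minbucket,
                            cp = s$cp))
      stats::predict(fit, data.frame(x_test, check.names = FALSE),
                     type = "prob")[, lev[2]]
    },
    nnet = {
      max_wts <- (ncol(x_train) + 1L) * s$size + s$size + 1L
      fit <- nnet::nnet(x_train, as.numeric(y_train) - 1, size = s$size,
                        decay = s$decay, maxit = s$maxit,
                        MaxNWts = max_wts + 10L, entropy = TRUE,
                        trace = FALSE)
      as.numeric(stats::predict(fit, x_test))
    },
    nbayes = {
      fit <- e1071::naiveBayes(x_train, y_train)
      stats::predict(fit, x_test, type = "raw")[, lev[2]]
    })
}

# Normalise a family's output to pred (second-class indicator) + score.
fit_predict <- function(spec, x_train, y_train, x_test) {
  out <- fit_predict_score(spec, x_train, y_train, x_test)
  if (!is.list(out)) out <- list(pred = as.integer(out >= 0.5), score = out)
  out
}

#' Stratified k-fold cross-validated accuracy
#'
#' Runs stratified k-fold cross-validation of one classifier family on a
#' two-class dataset and pools the out-of-fold predictions; accuracy is the
#' pooled proportion of correct test predictions over all folds.  When the
#' smaller class holds fewer than `k` samples the fold count is reduced to
#' that class size (`k_effective = min(k, min class n)`) so every fold keeps
#' both classes; the reduction is recorded in the result.
#'
#' @param dataset a [labeled_dataset()] with two classes.
#' @param spec a [classifier_spec()].
#' @param k requested fold count (default 10).
#' @param seed RNG seed controlling fold assignment and any stochastic
#'   fitting (neural-network initialisation, tree tie-breaks).
#' @param metrics if `TRUE`, also compute AUC-ROC, precision, recall and F1
#'   on the pooled out-of-fold predictions (positive class = second sorted
#'   label; 0.5 probability threshold).
#' @return List with `accuracy`, `k_effective`, and (when requested)
#'   `metrics` (named list `auc_roc`, `precision`, `recall`, `f1`).
#' @export
crossval_accuracy <- function(dataset, spec, k = 10, seed = 1L,
                              metrics = FALSE) {
  idx <- check_two_class(dataset)
  y <- dataset$labels
  x <- dataset$values
  k_eff <- min(k, min(lengths(idx)))
  if (k_eff < 2) {
    stop_mlsize("degenerate_fold", "smaller class has fewer than 2 samples")
  }
  set.seed(seed)
  # stratified fold assignment: shuffle within class, deal out 1..k
  fold <- integer(nrow(x))
  for (cls in idx) {
    fold[sample(cls)] <- rep_len(seq_len(k_eff), length(cls))
  }
  score <- numeric(nrow(x))
  pred <- integer(nrow(x))
  for (f in seq_len(k_eff)) {
    tr <- fold != f; te <- !tr
    y_tr <- droplevels(y[tr])
    if (nlevels(y_tr) < 2) {
      stop_mlsize("degenerate_fold", "a training fold contains one class only")
    }
    x_tr <- x[tr, , drop = FALSE]; x_te <- x[te, , drop = FALSE]
    if (spec$scaled) {
      mu <- colMeans(x_tr)
      sg <- apply(x_tr, 2, stats::sd)
      sg[sg == 0] <- 1
      x_tr <- sweep(sweep(x_tr, 2, mu), 2, sg, "/")
      x_te <- sweep(sweep(x_te, 2, mu), 2, sg, "/")
    }
    fp <- fit_predict(spec, x_tr, y_tr, x_te)
    pred[te] <- fp$pred
    score[te] <- fp$score
  }
  truth <- as.integer(y) - 1L           # 1 = second sorted class (positive)
  out <- list(accuracy = mean(pred == truth), k_effective = k_eff)
  if (metrics) {
    tp <- sum(pred == 1 & truth == 1); fp <- sum(pred == 1 & truth == 0)
    fn <- sum(pred == 0 & truth == 1)
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (isTRUE(precision + recall > 0)) {
      2 * precision * recall / (precision + recall)
    } else NA_real_
    auc <- as.numeric(pROC::auc(pROC::roc(truth, score, quiet = TRUE,
                                          direction = "<", levels = c(0, 1))))
    out$metrics <- list(auc_roc = auc, precision = precision, recall = recall,
                        f1 = f1)
  }
  out
}
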