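# Dichotomized document classification with leave-one-out cross-validation:
# a from-scratch multinomial naive Bayes over keyword counts, and a pluggable
# soft-margin kernel backend (e1071::svm) over normalized features.

#' Dichotomize the 1-5 sustainability scale
#'
#' Grades 4-5 become `"high"`, grades 1-3 `"low"` -- the binary task used
#' for automated classification, since 34 documents are too few to learn
#' five classes.
#'
#' @param grade integer grade(s) in 1..5.
#' @return factor with levels `low`, `high`.
#' @export
dichotomize <- function(grade) {
  if (!all(grade %in% 1:5)) stop("grades must be in 1..5")
  factor(ifelse(grade >= 4L, "high", "low"), levels = c("low", "high"))
}

#' Classifier specification
#'
#' @param family `"multinomial_bayes"` or `"max_margin"`.
#' @param kernel kernel for the max-margin family: `"radial"` or `"linear"`.
#' @param cost misclassification cost C (> 0), max-margin only.
#' @param smoothing Laplace pseudo-count (> 0), naive Bayes only.
#' @return list of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("multinomial_bayes", "max_margin"),
                            kernel = c("radial", "linear"), cost = 1,
                            smoothing = 1) {
  family <- match.arg(family)
  kernel <- match.arg(kernel)
  if (cost <= 0) stop("cost must be positive")
  if (smoothing <= 0) stop("smoothing must be positive")
  structure(list(family = family, kernel = kernel, cost = cost,
                 smoothing = smoothing), class = "classifier_spec")
}

#' Multinomial naive Bayes: train and predict
#'
#' From-scratch multinomial naive Bayes over non-negative count features
#' (raw keyword-category counts, not length-normalized frequencies -- the
#' multinomial likelihood is count-based). Class score = log prior + sum of
#' count * log(smoothed class term probability); ties are broken toward
#' `"low"` (conservative: does not overclaim sustainability).
#'
#' @param train_counts matrix of non-negative counts (docs x terms).
#' @param train_labels factor with levels `low`, `high`.
#' @param test_counts matrix of test counts (same columns).
#' @param smoothing Laplace pseudo-count added per term and class.
#' @return factor of predicted labels, levels `low`, `high`.
#' @export
fit_predict_multinomial_bayes <- function(train_counts, train_labels,
                                          test_counts, smoothing = 1) {
  train_counts <- as.matrix(train_counts)
  test_counts <- as.matrix(test_counts)
  if (any(train_counts < 0) || any(test_counts < 0)) {
    stop("counts must be non-negative")
  }
  train_labels <- factor(train_labels, levels = c("low", "high"))
  classes <- levels(droplevels(train_labels))
  logscore <- matrix(-Inf, nrow(test_counts), 2,
                     dimnames = list(NULL, c("low", "high")))
  n <- length(train_labels)
  for (cl in classes) {
    rows <- train_labels == cl
    tc <- colSums(train_counts[rows, , drop = FALSE]) + smoothing
    logtheta <- log(tc / sum(tc))
    logprior <- log(sum(rows) / n)
    logscore[, cl] <- logprior + drop(test_counts %*% logtheta)
  }
  # tie-break toward "low": predict high only on a strictly larger score
  pred <- ifelse(logscore[, "high"] > logscore[, "low"] + 1e-9, "high", "low")
  factor(pred, levels = c("low", "high"))
}

#' Soft-margin kernel classifier: train and predict
#'
#' Pluggable maximum-margin backend (delegates to [e1071::svm()]) with
#' kernel choice and misclassification cost C. Inputs are the normalized
#' feature vectors. Given identical data, kernel and cost, the solver is
#' deterministic, so predictions are reproducible. Features are not
#' rescaled by the backend (`scale = FALSE`): they are already
#' length-normalized frequencies on comparable scales, and leaving them
#' unscaled keeps folds with constant columns well-defined.
#'
#' @param train_x numeric feature matrix (docs x features).
#' @param train_labels factor with levels `low`, `high`; both classes must
#'   be present.
#' @param test_x feature matrix to predict.
#' @param kernel `"radial"` or `"linear"`.
#' @param cost misclassification cost C > 0.
#' @return factor of predicted labels, levels `low`, `high`.
#' @export
fit_predict_max_margin <- function(train_x, train_labels, test_x,
                                   kernel = c("radial", "linear"), cost = 1) {
  kernel <- match.arg(kernel)
  if (cost <= 0) stop("cost must be positive")
  train_labels <- factor(train_labels, levels = c("low", "high"))
  if (nlevels(droplevels(train_labels)) < 2L) {
    stop("both classes must be present in training data")
  }
  train_x <- as.matrix(train_x)
  test_x <- as.matrix(test_x)
  fit <- e1071::svm(x = train_x, y = train_labels, kernel = kernel,
                    cost = cost, scale = FALSE)
  pred <- stats::predict(fit, test_x)
  factor(as.character(pred), levels = c("low", "high"))
}

.predict_with_spec <- function(spec, train_x, train_labels, test_x) {
  if (spec$family == "multinomial_bayes") {
    fit_predict_multinomial_bayes(train_x, train_labels, test_x,
                                  smoothing = spec$smoothing)
  } else {
    fit_predict_max_margin(train_x, train_labels, test_x,
                           kernel = spec$kernel, cost = spec$cost)
  }
}

#' Leave-one-out cross-validation of a document classifier
#'
#' Exhaustive LOOCV: each document is predicted from a model trained on the
#' other n-1; accuracy is the fraction of correct held-out predictions
#' (hence always a multiple of 1/n). Deterministic given the data and
#' specification. A training fold containing a single class predicts that
#' class and is flagged.
#'
#' @param features numeric matrix (docs x features): raw counts for the
#'   naive Bayes family, normalized features for the max-margin family.
#' @param labels factor with levels `low`, `high` (both present); or grades
#'   1..5, which are dichotomized.
#' @param spec a [classifier_spec()].
#' @param doc_ids optional identifiers for the report.
#' @return object of class `cv_report`: `spec`, `predictions` (data.frame
#'   `doc_id`, `truth`, `pred`, `flagged`), `accuracy`, `n`,
#'   `majority_baseline`.
#' @export
loocv <- function(features, labels, spec, doc_ids = NULL) {
  features <- as.matrix(features)
  if (is.numeric(labels) && all(labels %in% 1:5)) labels <- dichotomize(labels)
  labels <- factor(labels, levels = c("low", "high"))
  n <- nrow(features)
  if (n < 3L) stop("LOOCV needs at least 3 documents")
  if (nlevels(droplevels(labels)) < 2L) stop("both labels must be present")
  if (is.null(doc_ids)) doc_ids <- as.character(seq_len(n))
  pred <- character(n)
  flagged <- logical(n)
  for (i in seq_len(n)) {
    tr_x <- features[-i, , drop = FALSE]
    tr_y <- droplevels(labels[-i])
    te_x <- features[i, , drop = FALSE]
    if (nlevels(tr_y) < 2L) {
      pred[i] <- as.character(tr_y[1])
      flagged[i] <- TRUE
    } else {
      pred[i] <- as.character(.predict_with_spec(spec, tr_x, labels[-i], te_x))
    }
  }
  pred <- factor(pred, levels = c("low", "high"))
  structure(list(spec = spec,
                 predictions = data.frame(doc_id = doc_ids,
                                          truth = labels, pred = pred,
                                          flagged = flagged,
                                          stringsAsFactors = FALSE),
                 accuracy = mean(pred == labels),
                 n = n,
                 majority_baseline = max(table(labels)) / n),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("LOOCV (%s): accuracy %.3f on n = %d (majority baseline %.3f)\n",
              x$spec$family, x$accuracy, x$n, x$majority_baseline))
  if (any(x$predictions$flagged)) {
    cat("  flagged single-class training folds:", sum(x$predictions$flagged), "\n")
  }
  invisible(x)
}

#' Repeated random single-holdout evaluation
#'
#' Alternative to exhaustive LOOCV: draws `n_rep` random single-document
#' holdouts (with replacement across repetitions) and averages accuracy.
#'
#' @inheritParams loocv
#' @param n_rep number of random holdouts.
#' @param seed RNG seed.
#' @return list: `accuracy`, `n_rep`, `seed`.
#' @export
random_holdout <- function(features, labels, spec, n_rep = 100L, seed = 1L) {
  features <- as.matrix(features)
  if (is.numeric(labels) && all(labels %in% 1:5)) labels <- dichotomize(labels)
  labels <- factor(labels, levels = c("low", "high"))
  n <- nrow(features)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  correct <- vapply(seq_len(n_rep), function(r) {
    i <- sample.int(n, 1L)
    tr_y <- droplevels(labels[-i])
    p <- if (nlevels(tr_y) < 2L) as.character(tr_y[1]) else
      as.character(.predict_with_spec(spec, features[-i, , drop = FALSE],
                                      labels[-i], features[i, , drop = FALSE]))
    p == as.character(labels[i])
  }, TRUE)
  list(accuracy = mean(correct), n_rep = n_rep, seed = seed)
}

#' Grid search over the misclassification cost
#'
#' Evaluates LOOCV accuracy of the max-margin classifier at each cost in the
#' grid and returns the full accuracy curve plus the best cost (ties broken
#' toward the smallest cost). The default grid spans (0, 1] in steps of
#' 0.01; zero is excluded because a soft-margin cost must be strictly
#' positive.
#'
#' @param features normalized feature matrix.
#' @param labels labels (see [loocv()]).
#' @param kernel `"linear"` or `"radial"`.
#' @param grid increasing vector of positive costs.
#' @return list of class `grid_result`: `costs`, `accuracies`, `best_cost`,
#'   `best_accuracy`.
#' @export
cost_grid_search <- function(features, labels, kernel = "linear",
                             grid = seq(0.01, 1, by = 0.01)) {
  if (any(grid <= 0)) stop("costs must be positive")
  if (is.unsorted(grid)) stop("grid must be increasing")
  acc <- vapply(grid, function(C) {
    loocv(features, labels,
          classifier_spec("max_margin", kernel = kernel, cost = C))$accuracy
  }, 0)
  best <- which.max(acc)  # first max = smallest cost on an increasing grid
  structure(list(costs = grid, accuracies = acc, best_cost = grid[best],
                 best_accuracy = acc[best]),
            class = "grid_result")
}

#' Write a CV report to JSON
#'
#' @param x a `cv_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(x, path) {
  stopifnot(inherits(x, "cv_report"))
  out <- list(family = x$spec$family,
              kernel = x$spec$kernel,
              cost = x$spec$cost,
              smoothing = x$spec$smoothing,
              accuracy = x$accuracy,
              majority_baseline = x$majority_baseline,
              n = x$n,
              predictions = data.frame(doc_id = x$predictions$doc_id,
                                       truth = as.character(x$predictions$truth),
                                       pred = as.character(x$predictions$pred),
                                       flagged = x$predictions$flagged))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
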