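# Scenario assembly, cross-validated SVM / k-NN classification, confusion
# matrices and macro-averaged metrics.

# Feature-group column selectors, in deterministic extraction order.
.scenario_groups <- list(
  A = "relative_power", B = "coherence", C = "spec_en", D = "spec_de",
  E = c("coherence", "spec_de")
)

.group_prefix <- c(relative_power = "^RP_", coherence = "^COH_",
                   spec_en = "^SPECEN_", spec_de = "^SPECDE_")

#' Assemble a classification scenario's feature matrix
#'
#' Selects the feature columns for one of the five evaluation scenarios:
#' A relative power (76 columns), B coherence (64), C spectral entropy
#' (19), D spectral dispersion entropy (19), E coherence + spectral
#' dispersion entropy (83). Column order follows extraction order
#' (montage/table order), so it is deterministic.
#'
#' @param fm Full feature matrix data frame from
#'   \code{\link{cohort_features}}.
#' @param scenario One of "A", "B", "C", "D", "E".
#' @return Data frame with \code{subject_id}, \code{group} and the
#'   scenario's feature columns.
#' @export
assemble_features <- function(fm, scenario = c("A", "B", "C", "D", "E")) {
  scenario <- match.arg(scenario)
  if (!nrow(fm)) stop("empty feature matrix: no subjects")
  if (anyNA(fm$group) || is.null(fm$group))
    stop("missing group label for subject(s): ",
         paste(fm$subject_id[is.na(fm$group)], collapse = ", "))
  prefixes <- .group_prefix[.scenario_groups[[scenario]]]
  cols <- unlist(lapply(prefixes, grep, x = colnames(fm), value = TRUE),
                 use.names = FALSE)
  if (!length(cols))
    stop("feature matrix holds no columns for scenario ", scenario,
         " (needs ", paste(.scenario_groups[[scenario]], collapse = " + "), ")")
  bad <- vapply(cols, function(cn) anyNA(fm[[cn]]), logical(1))
  if (any(bad)) {
    miss <- unique(fm$subject_id[apply(is.na(fm[, cols[bad], drop = FALSE]), 1, any)])
    stop("missing feature values for subject(s): ", paste(miss, collapse = ", "))
  }
  fm[, c("subject_id", "group", cols), drop = FALSE]
}

#' Classifier specification
#'
#' The seven classifier configurations evaluated: four SVM kernels
#' (penalty C = 1 throughout; the Gaussian kernel scale is
#' sqrt(number of predictors)) and three k-NN variants (fine: k = 1
#' Euclidean; medium: k = 10 Euclidean; cubic: k = 10 Minkowski order 3).
#'
#' @param name One of "linear_svm", "quadratic_svm", "cubic_svm",
#'   "gaussian_svm", "fine_knn", "medium_knn", "cubic_knn".
#' @return An object of class \code{classifier_spec}.
#' @export
classifier_spec <- function(name = c("gaussian_svm", "linear_svm",
                                     "quadratic_svm", "cubic_svm",
                                     "fine_knn", "medium_knn", "cubic_knn")) {
  name <- match.arg(name)
  spec <- switch(name,
    linear_svm    = list(family = "svm", kernel = "linear", cost = 1),
    quadratic_svm = list(family = "svm", kernel = "polynomial", degree = 2,
                         coef0 = 1, gamma = 1, cost = 1),
    cubic_svm     = list(family = "svm", kernel = "polynomial", degree = 3,
                         coef0 = 1, gamma = 1, cost = 1),
    gaussian_svm  = list(family = "svm", kernel = "radial", cost = 1),
    fine_knn      = list(family = "knn", k = 1, minkowski_p = 2),
    medium_knn    = list(family = "knn", k = 10, minkowski_p = 2),
    cubic_knn     = list(family = "knn", k = 10, minkowski_p = 3)
  )
  structure(c(list(name = name), spec), class = "classifier_spec")
}

# Deterministic k-NN with Minkowski distance and nearest-neighbor
# tie-breaking among tied classes.
.knn_predict <- function(train_x, train_y, test_x, k, p) {
  k <- min(k, nrow(train_x))
  apply(test_x, 1, function(q) {
    d <- (rowSums(abs(sweep(train_x, 2, q))^p))^(1 / p)
    ord <- order(d)
    nn <- ord[seq_len(k)]
    votes <- table(train_y[nn])
    best <- names(votes)[votes == max(votes)]
    if (length(best) > 1L) {                 # tie: nearest neighbor wins
      first <- nn[match(TRUE, as.character(train_y[nn]) %in% best)]
      best <- as.character(train_y[first])
    }
    best
  })
}

.fit_predict <- function(train_x, train_y, test_x, clf) {
  if (clf$family == "svm") {
    gamma <- if (clf$kernel == "radial") 1 / ncol(train_x)   # scale sqrt(p)
             else if (!is.null(clf$gamma)) clf$gamma else 1 / ncol(train_x)
    fit <- e1071::svm(train_x, train_y, kernel = clf$kernel, cost = clf$cost,
                      gamma = gamma,
                      degree = if (!is.null(clf$degree)) clf$degree else 3,
                      coef0 = if (!is.null(clf$coef0)) clf$coef0 else 0,
                      scale = FALSE)
    as.character(stats::predict(fit, test_x))
  } else {
    .knn_predict(train_x, train_y, test_x, clf$k, clf$minkowski_p)
  }
}

# Stratified fold assignment: within each class, subjects are shuffled
# (seeded) and dealt to folds round-robin.
.stratified_folds <- function(groups, k_folds, seed) {
  fold <- integer(length(groups))
  set.seed(seed)
  for (g in levels(factor(groups))) {
    idx <- which(groups == g)
    if (length(idx) < k_folds)
      stop("class '", g, "' has ", length(idx), " subjects, fewer than ",
           k_folds, " folds")
    fold[idx[sample.int(length(idx))]] <-
      rep_len(seq_len(k_folds), length(idx))
  }
  fold
}

#' Cross-validated classification
#'
#' Stratified k-fold cross-validation of a classifier on a feature
#' matrix. Folds partition subjects within each class; every subject is
#' predicted exactly once; predictions are accumulated into a single
#' confusion matrix. Features are z-scored with training-fold statistics
#' only, so no test-fold information leaks into scaling. Fold assignment
#' is derived from the subject identifiers' class-wise order and the
#' seed, so it is invariant to row order.
#'
#' @param fm Scenario feature matrix (see \code{\link{assemble_features}}).
#' @param clf A \code{\link{classifier_spec}} or its name.
#' @param k_folds Number of folds, typically 5 or 10.
#' @param seed Integer seed controlling the fold shuffle.
#' @return List with \code{confusion} (k x k table, rows actual, columns
#'   predicted), \code{fold_accuracy} (per-fold %), \code{accuracy}
#'   (mean of fold accuracies, %), and \code{predictions} (data frame
#'   subject_id / actual / predicted / fold).
#' @export
crossval_classify <- function(fm, clf = classifier_spec("gaussian_svm"),
                              k_folds = 5, seed = 1) {
  if (is.character(clf)) clf <- classifier_spec(clf)
  ord <- order(fm$subject_id)                 # row-order invariance
  fm <- fm[ord, , drop = FALSE]
  feats <- setdiff(colnames(fm), c("subject_id", "group"))
  x <- as.matrix(fm[, feats, drop = FALSE])
  lev <- unique(c(intersect(eeg_groups(), fm$group), sort(unique(fm$group))))
  y <- factor(fm$group, levels = lev)
  fold <- .stratified_folds(as.character(y), k_folds, seed)
  pred <- character(nrow(x))
  for (f in seq_len(k_folds)) {
    tr <- fold != f
    mu <- colMeans(x[tr, , drop = FALSE])
    sg <- apply(x[tr, , drop = FALSE], 2, stats::sd)
    sg[sg == 0 | !is.finite(sg)] <- 1
    xs <- sweep(sweep(x, 2, mu), 2, sg, "/")
    pred[!tr] <- .fit_predict(xs[tr, , drop = FALSE], droplevels(y[tr]),
                              xs[!tr, , drop = FALSE], clf)
  }
  pred <- factor(pred, levels = levels(y))
  confusion <- table(actual = y, predicted = pred)
  fold_acc <- vapply(seq_len(k_folds), function(f)
    100 * mean(pred[fold == f] == y[fold == f]), numeric(1))
  list(confusion = confusion,
       fold_accuracy = fold_acc,
       accuracy = mean(fold_acc),
       predictions = data.frame(subject_id = fm$subject_id,
                                actual = as.character(y),
                                predicted = as.character(pred),
                                fold = fold, stringsAsFactors = FALSE))
}

#' Classification metrics from a confusion matrix
#'
#' Computes accuracy and macro-averaged sensitivity (recall),
#' specificity, precision and F1 from a k x k confusion matrix with
#' actual classes in rows and predicted classes in columns. Per-class
#' values use the one-vs-rest true/false positive/negative counts; the
#' macro value is their unweighted mean. All results are percentages.
#' A class never predicted positive gets precision 0 with a warning.
#'
#' @param cm Square numeric matrix or table, rows actual, columns
#'   predicted, same class order both ways.
#' @return List of class \code{metric_report}: \code{accuracy},
#'   \code{sensitivity}, \code{specificity}, \code{precision}, \code{f1}
#'   (macro, %), and \code{per_class} (data frame of per-class recall,
#'   specificity, precision, F1 in %).
#' @export
#' @examples
#' cm <- matrix(c(17, 1, 0, 0, 19, 0, 0, 1, 12), 3, byrow = TRUE)
#' metrics_from_confusion(cm)$accuracy  # 96
metrics_from_confusion <- function(cm) {
  cm <- as.matrix(unclass(cm))
  stopifnot(nrow(cm) == ncol(cm), sum(cm) > 0, all(cm >= 0))
  total <- sum(cm)
  k <- nrow(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- total - tp - fn - fp
  recall <- 100 * tp / (tp + fn)
  spec <- 100 * tn / (tn + fp)
  prec <- 100 * tp / (tp + fp)
  if (any(tp + fp == 0)) {
    warning("class(es) with zero predicted positives: precision set to 0 for ",
            paste(rownames(cm)[tp + fp == 0], collapse = ", "))
    prec[tp + fp == 0] <- 0
  }
  f1 <- ifelse(prec + recall > 0, 2 * prec * recall / (prec + recall), 0)
  per_class <- data.frame(class = if (!is.null(rownames(cm))) rownames(cm)
                                  else as.character(seq_len(k)),
                          recall = recall, specificity = spec,
                          precision = prec, f1 = f1,
                          stringsAsFactors = FALSE, row.names = NULL)
  structure(list(accuracy = 100 * sum(tp) / total,
                 sensitivity = mean(recall),
                 specificity = mean(spec),
                 precision = mean(prec),
                 f1 = mean(f1),
                 per_class = per_class),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "accuracy %.1f%% | sensitivity %.1f%% | specificity %.1f%% | precision %.1f%% | F1 %.1f%%\n",
    x$accuracy, x$sensitivity, x$specificity, x$precision, x$f1))
  print(x$per_class, digits = 4)
  invisible(x)
}
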