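# Independent per-class tally oracle for confusion-matrix metrics.
oracle_metrics <- function(cm) {
  k <- nrow(cm); tot <- sum(cm)
  per <- lapply(seq_len(k), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, -i])
    fp <- sum(cm[-i, i])
    tn <- tot - tp - fn - fp
    c(rec = 100 * tp / (tp + fn), spec = 100 * tn / (tn + fp),
      prec = if (tp + fp > 0) 100 * tp / (tp + fp) else 0)
  })
  m <- do.call(rbind, per)
  f1 <- ifelse(m[, "prec"] + m[, "rec"] > 0,
               2 * m[, "prec"] * m[, "rec"] / (m[, "prec"] + m[, "rec"]), 0)
  list(accuracy = 100 * sum(diag(cm)) / tot,
       sensitivity = mean(m[, "rec"]), specificity = mean(m[, "spec"]),
       precision = mean(m[, "prec"]), f1 = mean(f1))
}

test_that("metrics match the one-vs-rest tally oracle on random confusion matrices", {
  set.seed(61)
  for (r in 1:50) {
    cm <- matrix(rpois(9, 6), 3)
    if (sum(cm) == 0 || any(colSums(cm) == 0)) next
    got <- metrics_from_confusion(cm)
    want <- oracle_metrics(cm)
    for (f in names(want)) expect_equal(got[[f]], want[[f]], tolerance = 1e-12)
  }
})

test_that("a diagonal confusion matrix scores 100 everywhere; empty columns warn", {
  got <- metrics_from_confusion(diag(c(18, 19, 13)))
  expect_equal(got$accuracy, 100)
  expect_equal(got$sensitivity, 100)
  expect_equal(got$precision, 100)
  expect_equal(got$f1, 100)
  cm <- matrix(c(5, 0, 5, 0, 0, 0, 0, 0, 10), 3, byrow = TRUE)
  expect_warning(m <- metrics_from_confusion(cm), "zero predicted")
  expect_equal(m$per_class$precision[2], 0)
})

test_that("scenario assembly yields the documented column counts", {
  fm <- data.frame(subject_id = c("s1", "s2"), group = c("normal", "stroke_mci"),
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (nm in paste0("RP_", rep(c("delta", "theta", "alpha", "beta"), each = 19),
                    "_", channels_1020()))
    fm[[nm]] <- rnorm(2)
  for (s in c("interhemispheric", "left_intra", "right_intra")) {
    p <- build_pair_scheme(s)$pairs
    lab <- c(interhemispheric = "inter", left_intra = "left",
             right_intra = "right")[[s]]
    for (i in seq_len(nrow(p)))
      fm[[paste0("COH_", lab, "_", p[i, 1], "-", p[i, 2])]] <- rnorm(2)
  }
  for (nm in c(paste0("SPECEN_", channels_1020()),
               paste0("SPECDE_", channels_1020())))
    fm[[nm]] <- rnorm(2)
  counts <- c(A = 76, B = 64, C = 19, D = 19, E = 83)
  for (s in names(counts))
    expect_equal(ncol(assemble_features(fm, s)) - 2, unname(counts[s]))
  # scenario E = coherence block then spectral dispersion entropy block
  e_cols <- colnames(assemble_features(fm, "E"))
  expect_true(all(grepl("^COH_", e_cols[3:66])))
  expect_true(all(grepl("^SPECDE_", e_cols[67:85])))
  expect_error(assemble_features(fm[0, ], "A"), "no subjects")
  fm2 <- fm; fm2$SPECEN_Fp1[2] <- NA
  expect_error(assemble_features(fm2, "C"), "s2")
})

test_that("every classifier separates two well-separated Gaussian blobs perfectly", {
  set.seed(62)
  n <- 12
  fm <- data.frame(
    subject_id = sprintf("s%02d", 1:(3 * n)),
    group = rep(eeg_groups(), each = n),
    f1 = rnorm(3 * n, rep(c(0, 10, 20), each = n), 0.5),
    f2 = rnorm(3 * n, rep(c(0, 10, -10), each = n), 0.5),
    stringsAsFactors = FALSE)
  for (clf in c("linear_svm", "quadratic_svm", "cubic_svm", "gaussian_svm",
                "fine_knn", "medium_knn", "cubic_knn")) {
    cv <- crossval_classify(fm, clf, k_folds = 5, seed = 1)
    expect_equal(cv$accuracy, 100, info = clf)
    expect_equal(sum(diag(cv$confusion)), 3 * n, info = clf)
  }
})

test_that("shuffled labels score near chance for a 3-class problem", {
  set.seed(63)
  n <- 15
  accs <- vapply(1:50, function(r) {
    fm <- data.frame(
      subject_id = sprintf("s%02d", 1:(3 * n)),
      group = sample(rep(eeg_groups(), each = n)),
      stringsAsFactors = FALSE)
    for (j in 1:5) fm[[paste0("f", j)]] <- rnorm(3 * n)
    crossval_classify(fm, "gaussian_svm", k_folds = 5, seed = r)$accuracy
  }, numeric(1))
  expect_gt(mean(accs), 20)
  expect_lt(mean(accs), 47)
})

test_that("cross-validation predicts each subject once and is order-invariant", {
  set.seed(64)
  n <- 10
  fm <- data.frame(
    subject_id = sprintf("s%02d", 1:(3 * n)),
    group = rep(eeg_groups(), each = n),
    f1 = rnorm(3 * n, rep(c(0, 1, 2), each = n)),
    f2 = rnorm(3 * n),
    stringsAsFactors = FALSE)
  cv1 <- crossval_classify(fm, "gaussian_svm", k_folds = 5, seed = 7)
  expect_equal(sort(cv1$predictions$subject_id), sort(fm$subject_id))
  expect_equal(sum(cv1$confusion), 3 * n)
  expect_equal(unname(rowSums(cv1$confusion)), rep(n, 3))
  expect_length(cv1$fold_accuracy, 5)
  expect_equal(cv1$accuracy, mean(cv1$fold_accuracy))
  shuf <- fm[sample(nrow(fm)), ]
  cv2 <- crossval_classify(shuf, "gaussian_svm", k_folds = 5, seed = 7)
  expect_equal(cv1$confusion, cv2$confusion)
  expect_error(crossval_classify(fm[1:12, ], "gaussian_svm", k_folds = 5, seed = 1),
               "fewer than")
})

test_that("macro metrics are invariant to class label order", {
  cm <- matrix(c(17, 1, 0, 0, 19, 0, 0, 1, 12), 3, byrow = TRUE)
  perm <- c(3, 1, 2)
  m1 <- metrics_from_confusion(cm)
  m2 <- metrics_from_confusion(cm[perm, perm])
  for (f in c("accuracy", "sensitivity", "specificity", "precision", "f1"))
    expect_equal(m1[[f]], m2[[f]], tolerance = 1e-12)
})

test_that("cubic k-NN uses Minkowski-3 geometry where it differs from Euclidean", {
  # query at origin; class a neighbors at (1.1, 1.1): L2 ~ 1.556, L3 ~ 1.386;
  # class b neighbor at (0, 1.5): L2 = L3 = 1.5. Euclidean k=1 picks b,
  # Minkowski-3 picks a.
  train <- rbind(c(1.1, 1.1), c(0, 1.5))
  y <- factor(c("a", "b"))
  test <- rbind(c(0, 0))
  expect_equal(qeeg:::.knn_predict(train, y, test, k = 1, p = 3), "a")
  expect_equal(qeeg:::.knn_predict(train, y, test, k = 1, p = 2), "b")
})
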