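# Evaluation metrics: confusion matrix, PRF, MCC, AUC, cross-validation.

test_that("confusion matrix counts agree with direct tallying", {
  cm <- confusion_matrix(c(1, 2, 3), c(1, 2, 3), 3)
  expect_equal(unname(diag(unclass(cm))), c(1L, 1L, 1L))
  expect_equal(sum(cm), 3)

  cm0 <- confusion_matrix(c(1, 2, 3), c(2, 3, 1), 3)
  expect_equal(unname(diag(unclass(cm0))), c(0L, 0L, 0L))

  set.seed(8)
  yt <- sample(1:4, 200, replace = TRUE)
  yp <- sample(1:4, 200, replace = TRUE)
  cm2 <- confusion_matrix(yt, yp, 4)
  expect_equal(unname(rowSums(cm2)), unname(as.vector(table(factor(yt, levels = 1:4)))))
  expect_equal(unname(colSums(cm2)), unname(as.vector(table(factor(yp, levels = 1:4)))))
  for (i in 1:4) for (j in 1:4) {
    expect_equal(unclass(cm2)[i, j], sum(yt == i & yp == j))
  }

  expect_error(confusion_matrix(1:3, 1:2), "equal length")
  expect_error(confusion_matrix(c(1, 5), c(1, 2), 3), "outside")
})

test_that("per-class precision/recall/F1 match hand-worked values", {
  # class 1: TP = 8, FP = 2, FN = 8
  cm <- matrix(c(8L, 2L, 8L, 10L), 2, 2)  # rows true, cols predicted
  prf <- per_class_prf(cm)
  expect_equal(prf$precision[1], 0.8)
  expect_equal(prf$recall[1], 0.5)
  expect_equal(prf$f1[1], 2 * 0.4 / 1.3, tolerance = 1e-12)

  perfect <- diag(c(5L, 3L, 7L))
  p2 <- per_class_prf(perfect)
  expect_equal(p2$precision, rep(1, 3))
  expect_equal(p2$recall, rep(1, 3))
  expect_equal(p2$f1, rep(1, 3))
})

test_that("a never-predicted class has precision 0 with a warning", {
  cm <- matrix(c(5L, 3L, 0L, 0L), 2, 2)  # column 2 all zero
  expect_warning(prf <- per_class_prf(cm), "zero denominator")
  expect_equal(prf$precision[2], 0)
})

test_that("mcc reproduces the binary closed form and its edge cases", {
  # TP = 50, TN = 40, FP = 5, FN = 5 (positive class = class 1)
  cm <- matrix(c(50L, 5L, 5L, 40L), 2, 2)
  expect_equal(mcc(cm), 1975 / 2475, tolerance = 1e-12)

  expect_equal(mcc(diag(c(4L, 9L, 2L))), 1)

  # independence: counts proportional to row x column marginals
  ind <- outer(c(10, 20), c(6, 4)) / 10
  expect_equal(mcc(ind), 0)

  # all predictions in one class: zero denominator convention
  degen <- matrix(c(5L, 0L, 7L, 0L), 2, 2)
  expect_equal(mcc(degen), 0)
})

test_that("multiclass mcc reduces to the binary formula on 2x2 matrices", {
  set.seed(3)
  for (i in 1:20) {
    m <- matrix(sample(0:30, 4, replace = TRUE), 2, 2)
    tp <- m[1, 1]; fn <- m[1, 2]; fp <- m[2, 1]; tn <- m[2, 2]
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    binary <- if (den == 0) 0 else (tp * tn - fp * fn) / den
    expect_equal(mcc(m), binary, tolerance = 1e-12)
  }
})

test_that("prf and mcc agree with brute-force oracles on small matrices", {
  for (i in 1:200) {
    case <- rand_cm_case(3, 10, seed = 9000 + i)
    if (sum(case$cm) == 0) next
    cm <- confusion_matrix(case$y_true, case$y_pred, 3)
    expect_equal(unclass(unname(cm)), case$cm)
    got <- suppressWarnings(per_class_prf(cm))
    want <- prf_oracle(case$y_true, case$y_pred, 3)
    expect_equal(got$precision, want$precision, tolerance = 1e-12)
    expect_equal(got$recall, want$recall, tolerance = 1e-12)
    expect_equal(got$f1, want$f1, tolerance = 1e-12)
    expect_equal(mcc(cm), mcc_oracle(case$y_true, case$y_pred, 3),
                 tolerance = 1e-9)
  }
})

test_that("one-vs-rest AUC matches pair counting, including ties", {
  # perfectly separated
  y <- c(1, 1, 1, 2, 2, 2)
  p <- cbind(c(.9, .8, .7, .2, .1, .3), c(.1, .2, .3, .8, .9, .7))
  expect_equal(unname(roc_auc_ovr(y, p)), c(1, 1))

  # hand-constructed 6-sample case with one tie
  y2 <- c(1, 1, 1, 2, 2, 2)
  s <- c(0.9, 0.5, 0.3, 0.5, 0.2, 0.1)
  p2 <- cbind(s, 1 - s)
  expect_equal(unname(roc_auc_ovr(y2, p2))[1],
               auc_oracle(s[y2 == 1], s[y2 == 2]))

  # scores independent of labels -> AUC near 1/2
  set.seed(12)
  y3 <- sample(1:2, 2000, replace = TRUE)
  s3 <- runif(2000)
  expect_equal(unname(roc_auc_ovr(y3, cbind(s3, 1 - s3)))[1], 0.5,
               tolerance = 0.05)

  # absent class is reported as missing
  y4 <- c(1, 1)
  expect_true(is.na(roc_auc_ovr(y4, cbind(c(.6, .7), c(.4, .3)))[2]))
  expect_error(roc_auc_ovr(c(1, 2), cbind(c(.6, .7), c(.9, .3))), "sum to 1")
})

test_that("auc agrees with an established implementation on random data", {
  skip_if_not_installed("pROC")
  set.seed(77)
  y <- sample(1:2, 60, replace = TRUE)
  s <- runif(60) + 0.4 * (y == 1)
  ours <- unname(roc_auc_ovr(y, cbind(s, 1 - s)))[1]
  ref <- as.numeric(pROC::auc(pROC::roc(y == 1, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-9)
})

test_that("metric report ties the pieces together consistently", {
  set.seed(5)
  y <- sample(1:3, 90, replace = TRUE)
  p <- matrix(runif(270), 90, 3); p <- p / rowSums(p)
  pred <- max.col(p, ties.method = "first")
  rep <- suppressWarnings(metric_report(y, pred, probabilities = p, n_classes = 3))
  expect_equal(rep$accuracy, mean(y == pred))
  expect_equal(rep$macro_f1, mean(rep$per_class$f1))
  expect_equal(rep$macro_precision, mean(rep$per_class$precision))
  expect_equal(sum(rep$confusion), 90)
  expect_length(rep$auc, 3)

  path <- withr::local_tempfile(fileext = ".csv")
  write_metric_report(rep, path)
  back <- read.csv(path)
  expect_equal(nrow(back), 4)  # 3 classes + macro
  expect_equal(back$accuracy[4], rep$accuracy)
})

test_that("cross-validation partitions samples and aggregates mean and sd", {
  frames <- as.list(1:100)
  labels <- rep(1:2, each = 50)
  # per-fold accuracy engineered to 0.96 then 0.98
  flip_per_fold <- c(2L, 1L)
  res <- cross_validate(frames, labels, k = 2, seed = 10,
                        build_and_train = function(tr_x, tr_y, va_x, va_y, fold) {
                          pred <- va_y
                          flip <- seq_len(flip_per_fold[fold])
                          pred[flip] <- 3L - pred[flip]
                          list(labels = pred)
                        })
  # every sample appears in exactly one validation fold
  expect_equal(sort(unique(res$fold_assignment)), 1:2)
  expect_equal(as.vector(table(res$fold_assignment)), c(50, 50))

  acc <- res$summary[res$summary$metric == "accuracy", ]
  expect_equal(acc$mean, 0.97, tolerance = 1e-12)
  expect_equal(acc$sd, sd(c(0.96, 0.98)), tolerance = 1e-12)

  # identical metric across folds aggregates to sd 0
  res2 <- cross_validate(frames, labels, k = 2, seed = 10,
                         build_and_train = function(tr_x, tr_y, va_x, va_y, fold) {
                           list(labels = va_y)
                         })
  acc2 <- res2$summary[res2$summary$metric == "accuracy", ]
  expect_equal(acc2$mean, 1)
  expect_equal(acc2$sd, 0)

  # deterministic fold assignment under the same seed
  res3 <- cross_validate(frames, labels, k = 2, seed = 10,
                         build_and_train = function(...) list(labels = ..4))
  expect_identical(res$fold_assignment, res3$fold_assignment)
})

test_that("cross-validation warns when a class is smaller than k", {
  frames <- as.list(1:12)
  labels <- c(rep(1L, 10), 2L, 2L)
  w <- capture_warnings(
    cross_validate(frames, labels, k = 4, seed = 2,
                   build_and_train = function(tr_x, tr_y, va_x, va_y, fold) {
                     list(labels = rep(1L, length(va_y)))
                   }))
  expect_match(w, "stratification relaxed", all = FALSE)
  expect_error(cross_validate(as.list(1:3), 1:3, k = 1,
                              build_and_train = identity), ">= 2")
})
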