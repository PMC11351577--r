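test_that("the 3x3 confusion matrix matches a manual tally", {
  truth <- c("normal", "normal", "benign", "benign", "malignant", "malignant",
             "malignant", "normal", "benign", "malignant")
  pred <- c("normal", "benign", "benign", "benign", "malignant", "normal",
            "malignant", "normal", "malignant", "malignant")
  m <- confusion_3class(truth, pred)
  want <- matrix(c(2L, 1L, 0L,
                   0L, 2L, 1L,
                   1L, 0L, 3L),
                 nrow = 3, byrow = TRUE,
                 dimnames = list(true = lesion_classes(),
                                 predicted = lesion_classes()))
  expect_equal(m, want)
  expect_equal(sum(m), length(truth))

  perfect <- confusion_3class(truth, truth)
  expect_equal(diag(perfect), table(factor(truth, lesion_classes()))[lesion_classes()],
               ignore_attr = TRUE)
  expect_true(all(perfect[upper.tri(perfect) | lower.tri(perfect)] == 0))

  expect_error(confusion_3class(c("normal", "odd"), c("normal", "normal")),
               "odd", class = "qlung_validation_error")
})

test_that("one-vs-rest collapse equals per-sample classification into the four cells", {
  withr::with_seed(4, {
    for (i in 1:10) {
      n <- 40
      truth <- sample(lesion_classes(), n, replace = TRUE,
                      prob = c(0.3, 0.3, 0.4))
      pred <- sample(lesion_classes(), n, replace = TRUE)
      m <- confusion_3class(truth, pred)
      for (pos in lesion_classes()) {
        cc <- collapse_binary(m, positive = pos)
        # brute-force per-sample oracle
        tp <- sum(truth == pos & pred == pos)
        fn <- sum(truth == pos & pred != pos)
        fp <- sum(truth != pos & pred == pos)
        tn <- sum(truth != pos & pred != pos)
        expect_equal(unlist(cc), c(TP = tp, TN = tn, FP = fp, FN = fn))
        expect_equal(cc$TP + cc$TN + cc$FP + cc$FN, n)
      }
    }
  })

  diag3 <- confusion_3class(rep(lesion_classes(), 3), rep(lesion_classes(), 3))
  cc <- collapse_binary(diag3, "malignant")
  expect_equal(cc$FP, 0)
  expect_equal(cc$FN, 0)
})

test_that("collapsed counts are invariant to class relabelling order", {
  truth <- rep(lesion_classes(), times = c(5, 7, 9))
  pred <- withr::with_seed(2, sample(truth))
  m1 <- confusion_3class(truth, pred)
  lv2 <- c("malignant", "normal", "benign")
  m2 <- confusion_3class(truth, pred, levels = lv2)
  expect_equal(m2, m1[lv2, lv2], ignore_attr = TRUE)
  expect_equal(unlist(collapse_binary(m1, "malignant")),
               unlist(collapse_binary(m2, "malignant")))
})

test_that("metric formulas reproduce arithmetic on published misclassification counts", {
  perfect <- compute_metrics(confusion_counts(10, 10, 0, 0))
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$mcc, 1)

  m <- compute_metrics(confusion_counts(4400, 200, 300, 100))
  expect_equal(m$accuracy, 100 * 4600 / 5000)          # 92.00
  expect_equal(m$sensitivity, 100 * 4400 / 4500)       # 97.78 at 2 dp
  expect_equal(round(m$sensitivity, 2), 97.78)
  expect_equal(m$specificity, 100 * 200 / 500)
  expect_equal(m$precision, 100 * 4400 / 4700)
  expect_false(m$zero_division)

  sw <- compute_metrics(confusion_counts(200, 4400, 100, 300))
  expect_equal(sw$sensitivity, m$specificity)
  expect_equal(sw$specificity, m$sensitivity)

  z <- compute_metrics(confusion_counts(0, 10, 0, 0))
  expect_true(z$zero_division)
  expect_equal(z$sensitivity, 0)

  expect_error(compute_metrics(confusion_counts(0, 0, 0, 0)), "positive",
               class = "qlung_validation_error")
})

test_that("the ROC sweep equals the concordance oracle and behaves at the extremes", {
  labels <- c(1, 1, 0, 0)
  r <- roc_auc(labels, c(0.9, 0.8, 0.3, 0.1))
  expect_equal(r$auc, 1)
  expect_equal(r$auc, oracle_concordance_auc(labels, c(0.9, 0.8, 0.3, 0.1)))

  hand <- roc_auc(c(1, 0, 1, 0), c(0.8, 0.7, 0.6, 0.2))
  expect_equal(hand$auc, oracle_concordance_auc(c(1, 0, 1, 0), c(0.8, 0.7, 0.6, 0.2)))

  withr::with_seed(10, {
    for (i in 1:15) {
      n <- sample(6:50, 1)
      truth <- c(rep(TRUE, 3), rep(FALSE, 3),
                 sample(c(TRUE, FALSE), n - 6, replace = TRUE))
      scores <- round(runif(n), 2)  # force ties
      expect_equal(roc_auc(truth, scores)$auc,
                   oracle_concordance_auc(truth, scores), tolerance = 1e-12)
    }
  })

  withr::with_seed(11, {
    truth <- sample(c(TRUE, FALSE), 1000, replace = TRUE)
    scores <- runif(1000)
  })
  expect_equal(roc_auc(truth, scores)$auc, 0.5, tolerance = 0.05)

  expect_error(roc_auc(rep(TRUE, 5), runif(5)), "both classes",
               class = "qlung_validation_error")
})

test_that("the threshold sweep agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(13, {
    truth <- sample(c(TRUE, FALSE), 80, replace = TRUE)
    scores <- runif(80)
  })
  ours <- roc_auc(truth, scores)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("model evaluation produces a coherent report", {
  fix <- phantom_fixture()
  m <- train_hybrid(fix$cxr, fix$ct, train_config(epochs = 8L, seed = 11))
  ev <- evaluate_model(m, fix$cxr, fix$ct)
  expect_equal(sum(ev$confusion), nrow(fix$cxr))
  expect_equal(ev$counts$TP + ev$counts$TN + ev$counts$FP + ev$counts$FN,
               nrow(fix$cxr))
  g <- glance(ev)
  pct <- unlist(g[c("accuracy", "sensitivity", "specificity", "precision", "f1")])
  expect_true(all(pct >= 0 & pct <= 100))
  expect_true(g$mcc >= -1 && g$mcc <= 1)
  td <- tidy(ev)
  expect_equal(nrow(td), 7L)
})
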