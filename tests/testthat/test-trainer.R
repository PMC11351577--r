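test_that("training configuration validates its fractions", {
  expect_error(train_config(fractions = c(train = 0.5, val = 0.2, test = 0.2)),
               "sum to 1", class = "qlung_validation_error")
  expect_error(train_config(fractions = c(train = 1, val = 0, test = 0)),
               "positive", class = "qlung_validation_error")
})

test_that("subject splitting is stratified, seeded and exhaustive", {
  labels <- rep(c("normal", "benign", "malignant"), times = c(10, 10, 20))
  ids <- sprintf("S%02d", 1:40)
  sp <- split_subjects(ids, labels, c(train = 0.7, val = 0.15, test = 0.15),
                       seed = 3)
  expect_setequal(unlist(sp), ids)
  expect_equal(sum(labels[ids %in% sp$train] == "malignant"), 14L)
  sp2 <- split_subjects(ids, labels, c(train = 0.7, val = 0.15, test = 0.15),
                        seed = 3)
  expect_identical(sp, sp2)
})

test_that("degenerate inputs are rejected before any fitting", {
  fix <- phantom_fixture()
  expect_error(train_hybrid(fix$cxr[-1, ], fix$ct, train_config()),
               "unpaired", class = "qlung_validation_error")
  one_class <- fix$cxr$label == "malignant"
  expect_error(train_hybrid(fix$cxr[one_class, ], fix$ct[one_class, ],
                            train_config()),
               "2 classes", class = "qlung_validation_error")
})

test_that("epochs = 0 and lr = 0 are exact no-ops", {
  fix <- phantom_fixture()
  m0 <- train_hybrid(fix$cxr, fix$ct, train_config(epochs = 0L, seed = 2))
  expect_equal(nrow(m0$history), 0L)
  expect_s3_class(predict(m0, fix$cxr, fix$ct), "tbl_df")

  mz <- train_hybrid(fix$cxr, fix$ct,
                     train_config(epochs = 3L, learning_rate = 0, seed = 2))
  expect_equal(length(unique(mz$history$accuracy_pct)), 1L)
  expect_equal(length(unique(mz$history$loss_pct)), 1L)
  expect_equal(mz$spec$params, m0$spec$params)  # untouched initialization
})

test_that("hybrid training is seed-reproducible and leak-free", {
  fix <- phantom_fixture()
  cfg <- train_config(epochs = 5L, seed = 7)
  m1 <- train_hybrid(fix$cxr, fix$ct, cfg)
  m2 <- train_hybrid(fix$cxr, fix$ct, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$spec$params, m2$spec$params)
  expect_identical(m1$head$W, m2$head$W)

  # projector and scaler depend on the training split only: refit from the
  # train rows by hand and compare bit-for-bit
  fused <- merge_dataset(fix$cxr, fix$ct)
  tr <- fused$subject_id %in% m1$split$train
  pr <- fit_svd_projector(feature_matrix(fused)[tr, , drop = FALSE])
  expect_identical(pr$basis, m1$projector$basis)
  expect_identical(pr$mean, m1$projector$mean)
  qtr <- sweep(feature_matrix(fused)[tr, ], 2L, pr$mean, "-") %*% pr$basis
  sc <- fit_scaler(qtr)
  expect_identical(sc$min, m1$spec$scaler$min)
  expect_identical(sc$max, m1$spec$scaler$max)
})

test_that("the ablation baseline shares the pipeline but carries no quantum parameters", {
  fix <- phantom_fixture()
  cfg <- train_config(epochs = 5L, seed = 7)
  mh <- train_hybrid(fix$cxr, fix$ct, cfg)
  mt <- train_traditional(fix$cxr, fix$ct, cfg)
  expect_equal(mt$n_quantum_params, 0L)
  expect_equal(glance(mt)$n_quantum_params, 0L)
  expect_equal(nrow(mt$history), nrow(mh$history))
  expect_identical(mt$split, mh$split)          # same seeded split
  expect_identical(mt$projector$basis, mh$projector$basis)
  expect_equal(nrow(tidy(mt)), 0L)
  expect_equal(nrow(tidy(mh)), 10L)
})

test_that("predictions are normalized, label-ordered and survive serialization", {
  fix <- phantom_fixture()
  m <- train_hybrid(fix$cxr, fix$ct, train_config(epochs = 8L, seed = 11))
  pr <- predict(m, fix$cxr, fix$ct)
  expect_equal(rowSums(as.matrix(pr[, c("p_normal", "p_benign", "p_malignant")])),
               rep(1, nrow(pr)), tolerance = 1e-9)
  expect_true(all(pr$pred %in% lesion_classes()))

  dir <- file.path(tempdir(), "qlung_bundle")
  save_model(m, dir)
  m2 <- load_model(dir)
  pr2 <- predict(m2, fix$cxr, fix$ct)
  expect_identical(pr2, pr)
  expect_identical(m2$spec$params, m$spec$params)
})

test_that("converged training is self-consistent with its reported accuracy", {
  fix <- phantom_fixture(n_subjects = 60L, seed = 19L)
  m <- train_hybrid(fix$cxr, fix$ct, train_config(epochs = 12L, seed = 5))
  tr_ids <- m$split$train
  pr <- predict(m, fix$cxr[fix$cxr$subject_id %in% tr_ids, ],
                fix$ct[fix$ct$subject_id %in% tr_ids, ])
  acc <- 100 * mean(pr$pred == pr$label)
  expect_equal(acc, m$history$accuracy_pct[nrow(m$history)], tolerance = 0.5)
})
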