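test_that("classifier specs validate their family", {
  expect_identical(classifier_spec("svml")$family, "svm_linear")
  expect_identical(classifier_spec("KNN", k = 3)$hyper$k, 3)
  expect_error(classifier_spec("perceptron"), class = "fitfuse_validation_error")
})

test_that("first-stage scores are probabilities and resubstitute correctly", {
  blobs <- make_blobs()
  for (fam in c("svm_poly", "svm_gauss", "svm_linear", "tree", "knn", "lda")) {
    m <- train_first_stage(blobs$x, blobs$y, classifier_spec(fam))
    sc <- predict_scores(m, blobs$x)
    expect_equal(unname(rowSums(sc)), rep(1, nrow(sc)), tolerance = 1e-6)
    expect_true(all(sc >= 0))
    expect_identical(colnames(sc), sort(unique(blobs$y)))
    acc <- mean(colnames(sc)[max.col(sc)] == blobs$y)
    expect_gte(acc, 0.9)
  }
})

test_that("separable toy problems give confident, deterministic scores", {
  x <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  y <- c("a", "a", "b", "b")
  m <- train_first_stage(x, y, classifier_spec("lda"))
  sc <- predict_scores(m, x)
  expect_true(all(sc[cbind(1:4, match(y, colnames(sc)))] >= 0.5))

  # 1-NN resubstitution: the nearest neighbour of a training point is itself
  m1 <- train_first_stage(x, y, classifier_spec("knn", k = 1))
  sc1 <- predict_scores(m1, x)
  expect_equal(unname(sc1), rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1)),
               ignore_attr = TRUE)

  # duplicated rows get identical scores
  blobs <- make_blobs(n_per_class = 10)
  m2 <- train_first_stage(blobs$x, blobs$y, classifier_spec("svm_poly"))
  sc2 <- predict_scores(m2, blobs$x[c(1, 1, 5, 5), ])
  expect_identical(sc2[1, ], sc2[2, ])
  expect_identical(sc2[3, ], sc2[4, ])
})

test_that("degenerate training inputs are rejected", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(train_first_stage(x, rep("a", 10), classifier_spec("lda")),
               "2 classes", class = "fitfuse_validation_error")
  m <- train_first_stage(x, rep(c("a", "b"), 5), classifier_spec("lda"))
  expect_error(predict_scores(m, matrix(0, 2, 5)), "dimension",
               class = "fitfuse_validation_error")
})

test_that("score fusion concatenates to twice the number of classes", {
  cls <- active_classes()
  one_hot <- function(k) {
    m <- matrix(0, 1, 4, dimnames = list(NULL, cls)); m[1, k] <- 1; m
  }
  fused <- fuse_scores(one_hot(2), one_hot(2))
  expect_identical(ncol(fused), 8L)
  expect_equal(unname(fused[1, ]), c(0, 1, 0, 0, 0, 1, 0, 0))

  empty <- matrix(numeric(0), 0, 4, dimnames = list(NULL, cls))
  expect_identical(nrow(fuse_scores(empty, empty)), 0L)

  expect_error(fuse_scores(one_hot(1), empty), class = "fitfuse_validation_error")
  bad <- one_hot(1); colnames(bad) <- c("a", "b", "c", "d")
  expect_error(fuse_scores(one_hot(1), bad), class = "fitfuse_validation_error")
})

test_that("stacked fusion resubstitutes at least as well as its stages", {
  feats <- small_dataset()
  model <- train_fusion(feats, classifier_spec("svml"), classifier_spec("svml"),
                        classifier_spec("lda"))
  res <- classify(model, feats)
  expect_identical(ncol(res$fused), 8L)
  fused_acc <- mean(res$labels == feats$label)

  for (block in list(acc_feature_names(), emg_feature_names())) {
    m1 <- train_first_stage(as.matrix(feats[block]), feats$label,
                            classifier_spec("svml"), active_classes())
    sc <- predict_scores(m1, as.matrix(feats[block]))
    stage_acc <- mean(colnames(sc)[max.col(sc)] == feats$label)
    expect_gte(fused_acc, stage_acc - 0.02)
  }
})

test_that("training validates class coverage and size", {
  feats <- small_dataset()
  expect_error(train_fusion(feats[1, ], classifier_spec("lda"),
                            classifier_spec("lda"), classifier_spec("lda")),
               class = "fitfuse_validation_error")
  no_vr <- feats[feats$label != "VR", ]
  expect_error(train_fusion(no_vr, classifier_spec("lda"),
                            classifier_spec("lda"), classifier_spec("lda")),
               "VR", class = "fitfuse_validation_error")
})

test_that("fusion models are deterministic and row-order invariant", {
  feats <- small_dataset()
  probe <- feats[seq(1, nrow(feats), by = 7), ]
  specs <- list(classifier_spec("lda"), classifier_spec("lda"),
                classifier_spec("knn"))
  m1 <- train_fusion(feats, specs[[1]], specs[[2]], specs[[3]])
  m2 <- train_fusion(feats, specs[[1]], specs[[2]], specs[[3]])
  expect_identical(classify(m1, probe)$labels, classify(m2, probe)$labels)

  set.seed(77)
  perm <- sample(nrow(feats))
  m3 <- train_fusion(feats[perm, ], specs[[1]], specs[[2]], specs[[3]])
  expect_identical(classify(m1, probe)$labels, classify(m3, probe)$labels)
})

test_that("modalities complement each other across held-out subjects", {
  feats <- small_dataset()
  train <- feats[feats$subject != "s04", ]
  test <- feats[feats$subject == "s04", ]
  model <- train_fusion(train, classifier_spec("svml"), classifier_spec("svml"),
                        classifier_spec("lda"))
  pred <- classify(model, test)$labels

  # BC vs IM: the arm is still in both, only the sEMG envelope differs
  still <- test$label %in% c("BC", "IM")
  expect_gte(mean(pred[still] == test$label[still]), 0.9)

  # LR vs VR: separated by the rotation-vector magnitude
  acc_m <- train_first_stage(as.matrix(train[acc_feature_names()]),
                             train$label, classifier_spec("svml"),
                             active_classes())
  sc <- predict_scores(acc_m, as.matrix(test[acc_feature_names()]))
  acc_pred <- colnames(sc)[max.col(sc)]
  swing <- test$label %in% c("LR", "VR")
  expect_gte(mean(acc_pred[swing] == test$label[swing]), 0.9)
})
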