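test_that("split enumeration covers all held-out pairs exactly once", {
  ids <- sprintf("s%02d", 1:10)
  splits <- enumerate_splits(ids, 2)
  expect_length(splits, 45)
  expect_true(all(vapply(splits, function(s) length(s$test) == 2, logical(1))))
  expect_true(all(vapply(splits, function(s)
    setequal(c(s$train, s$test), ids) && !length(intersect(s$train, s$test)),
    logical(1))))
  appearances <- table(unlist(lapply(splits, `[[`, "test")))
  expect_true(all(appearances == choose(9, 1)))

  expect_length(enumerate_splits(c("a", "b", "c"), 2), 3)
  expect_error(enumerate_splits(c("a", "b"), 2),
               class = "fitfuse_validation_error")
})

test_that("a perfectly separable dataset scores 100% on every split", {
  feats <- make_separable_features()
  rep <- run_evaluation(feats, classifier_spec("lda"), classifier_spec("lda"),
                        classifier_spec("knn"))
  expect_equal(rep$mean_accuracy, 1)
  expect_equal(rep$min_accuracy, 1)
  expect_equal(rep$max_accuracy, 1)
  off_diag <- rep$summed_confusion
  diag(off_diag) <- 0
  expect_true(all(off_diag == 0))
  expect_identical(rep$skipped_splits, 0L)

  # averaged-confusion convention: row sums equal whole-dataset class counts
  counts <- table(factor(feats$label, levels = active_classes()))
  expect_equal(unname(rowSums(rep$averaged_confusion)), as.numeric(counts))
})

test_that("accuracy statistics are invariant under subject relabeling", {
  feats <- make_separable_features(n_subjects = 5)
  ren <- feats
  map <- setNames(sprintf("subj-%s", rev(sort(unique(feats$subject)))),
                  sort(unique(feats$subject)))
  ren$subject <- unname(map[ren$subject])
  r1 <- single_modality_baseline(feats, "acc", classifier_spec("lda"))
  r2 <- single_modality_baseline(ren, "acc", classifier_spec("lda"))
  expect_equal(sort(r1$accuracies), sort(r2$accuracies))
  expect_equal(r1$summed_confusion, r2$summed_confusion)
})

test_that("splits whose training set lacks a class are skipped with a warning", {
  feats <- make_separable_features(n_subjects = 4)
  # class IM exists only for subjects s1 and s2: the split testing both
  # cannot be trained on all classes
  feats <- feats[!(feats$label == "IM" & feats$subject %in% c("s3", "s4")), ]
  expect_warning(
    rep <- run_evaluation(feats, classifier_spec("lda"), classifier_spec("lda"),
                          classifier_spec("lda")),
    "skipped")
  expect_identical(rep$skipped_splits, 1L)
  expect_length(rep$per_split, 5)
})

test_that("single-modality baselines mirror the designed confusions", {
  feats <- small_dataset()
  acc_rep <- single_modality_baseline(feats, "acc", classifier_spec("svml"),
                                      test_count = 1)
  cm <- acc_rep$summed_confusion
  bc_im_conf <- cm["BC", "IM"] + cm["IM", "BC"]
  lr_vr_conf <- cm["LR", "VR"] + cm["VR", "LR"]
  # the still classes dominate the acceleration-only errors
  expect_gt(bc_im_conf, 0.25 * (cm["BC", "BC"] + cm["IM", "IM"]))
  expect_gte(bc_im_conf, lr_vr_conf)

  emg_rep <- single_modality_baseline(feats, "emg", classifier_spec("svml"),
                                      test_count = 1)
  cm_e <- emg_rep$summed_confusion
  expect_gte(sum(diag(cm_e)[c("BC", "IM")]),
             0.9 * sum(cm_e[c("BC", "IM"), ]))
})

test_that("evaluation reports serialize to JSON", {
  feats <- make_separable_features(n_subjects = 4)
  rep <- single_modality_baseline(feats, "emg", classifier_spec("knn"))
  path <- withr::local_tempfile(fileext = ".json")
  write_eval_report(rep, path)
  back <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  expect_equal(back$mean, rep$mean_accuracy)
  expect_equal(back$skipped_splits, 0)
  expect_length(back$per_split$accuracy, length(rep$per_split))
})

test_that("diarization labels one interval per planned window", {
  feats <- small_dataset()
  model <- train_fusion(feats, classifier_spec("svml"), classifier_spec("svml"),
                        classifier_spec("lda"))

  # a 50 s segment yields 13 intervals; a 5 s segment yields none
  profs <- subject_profiles(1, seed = 3)
  rec_one <- generate_recording(profs[[1]], presets = default_presets()["BC"],
                                sets_per_class = 1, set_duration_s = 50,
                                gap_s = 5, seed = 3)
  rec_one <- preprocess_recording(rec_one, small_filters())
  tl <- diarize(model, rec_one)
  expect_identical(nrow(tl), 13L)
  expect_identical(names(tl), c("start_s", "end_s", "label", "score_BC",
                                "score_LR", "score_VR", "score_IM"))
  expect_true(all(diff(tl$start_s) > 0))
  expect_equal(tl$end_s - tl$start_s, rep(8, 13))
  # most windows of the biceps-curl segment carry its label
  expect_gte(mean(tl$label == "BC"), 0.75)

  short <- generate_recording(profs[[1]], presets = default_presets()["BC"],
                              sets_per_class = 1, set_duration_s = 5,
                              gap_s = 2, seed = 3)
  short <- preprocess_recording(short, small_filters())
  expect_identical(nrow(diarize(model, short)), 0L)
})
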