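# Leave-two-subjects-out evaluation.
#
# Every possible pair of subjects is held out once as the test set (45 splits
# for 10 subjects); per split a fusion model is trained on the remaining
# subjects and its confusion matrix on the held-out windows is accumulated.
# The summed matrix divided by the per-subject test multiplicity
# C(n - 1, test_count - 1) gives the averaged matrix, whose row sums equal
# the whole-dataset per-class window counts.

#' Enumerate leave-k-subjects-out splits
#'
#' All `choose(n, test_count)` train/test partitions of the subject ids, in
#' deterministic lexicographic order of the (sorted) subject list.
#'
#' @param subject_ids Vector of subject identifiers.
#' @param test_count Number of held-out subjects per split (default 2).
#' @return List of splits, each a list with `train`, `test` and `index`.
#' @export
enumerate_splits <- function(subject_ids, test_count = 2) {
  ids <- sort(unique(as.character(subject_ids)))
  n <- length(ids)
  assert_that(is_scalar_number(test_count) && test_count >= 1 &&
                test_count == round(test_count), "test_count must be a positive integer")
  assert_that(n > test_count,
              sprintf("need more than %d subjects to hold %d out", test_count, test_count))
  combos <- combn(ids, test_count, simplify = FALSE)
  lapply(seq_along(combos), function(i) {
    list(train = setdiff(ids, combos[[i]]), test = combos[[i]], index = i)
  })
}

empty_confusion <- function(class_list) {
  matrix(0, length(class_list), length(class_list),
         dimnames = list(true = class_list, predicted = class_list))
}

confusion_matrix <- function(truth, predicted, class_list) {
  cm <- empty_confusion(class_list)
  tab <- table(factor(truth, levels = class_list),
               factor(predicted, levels = class_list))
  cm[rownames(tab), colnames(tab)] <- tab
  cm
}

accuracy_of <- function(cm) sum(diag(cm)) / max(sum(cm), 1)

make_eval_report <- function(per_split, summed, multiplicity, class_list,
                             skipped, config) {
  acc <- vapply(per_split, `[[`, numeric(1), "accuracy")
  structure(list(per_split = per_split,
                 summed_confusion = summed,
                 averaged_confusion = summed / multiplicity,
                 multiplicity = multiplicity,
                 accuracies = acc,
                 mean_accuracy = mean(acc),
                 min_accuracy = min(acc),
                 max_accuracy = max(acc),
                 class_list = class_list,
                 skipped_splits = skipped,
                 config = config),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s | %d split(s), %d skipped\n",
              x$config$desc, length(x$per_split), x$skipped_splits))
  cat(sprintf("  accuracy: mean %.1f%%, min %.1f%%, max %.1f%%\n",
              100 * x$mean_accuracy, 100 * x$min_accuracy, 100 * x$max_accuracy))
  cat("  averaged confusion (rows = true):\n")
  print(round(x$averaged_confusion, 1))
  invisible(x)
}

eval_loop <- function(features, class_list, test_count, train_fun, predict_fun,
                      desc) {
  assert_that(all(c("subject", "label") %in% names(features)),
              "features must carry subject and label columns")
  ids <- sort(unique(as.character(features$subject)))
  splits <- enumerate_splits(ids, test_count)
  multiplicity <- choose(length(ids) - 1, test_count - 1)
  summed <- empty_confusion(class_list)
  per_split <- list()
  skipped <- 0L
  for (sp in splits) {
    tr <- features[features$subject %in% sp$train, , drop = FALSE]
    te <- features[features$subject %in% sp$test, , drop = FALSE]
    if (length(setdiff(class_list, unique(tr$label))) > 0 || !nrow(te)) {
      warning(sprintf("split %d (test: %s) skipped: training set lacks a class or test set empty",
                      sp$index, paste(sp$test, collapse = ",")), call. = FALSE)
      skipped <- skipped + 1L
      next
    }
    model <- train_fun(tr)
    pred <- predict_fun(model, te)
    cm <- confusion_matrix(te$label, pred, class_list)
    summed <- summed + cm
    per_split[[length(per_split) + 1]] <-
      list(test_subjects = sp$test, accuracy = accuracy_of(cm), confusion = cm)
  }
  assert_that(length(per_split) > 0, "every split was skipped; nothing to report")
  make_eval_report(per_split, summed, multiplicity, class_list, skipped,
                   list(desc = desc, test_count = test_count))
}

#' Run the leave-k-subjects-out fusion evaluation
#'
#' For every split from [enumerate_splits()]: trains a [train_fusion()] model
#' on the training subjects' windows, classifies the held-out subjects'
#' windows, and accumulates the confusion matrix. Splits whose training set
#' lacks one of the active classes are skipped with a warning and counted in
#' the report.
#'
#' @param features Feature table from [extract_features()] over all subjects.
#' @param acc_spec,emg_spec,meta_spec [classifier_spec()]s of the two
#'   first-stage classifiers and the meta classifier.
#' @param class_list Ordered active classes (default [active_classes()]).
#' @param test_count Held-out subjects per split (default 2).
#' @param cv_scores Passed to [train_fusion()].
#' @return An `eval_report` with per-split accuracies, the summed and the
#'   averaged confusion matrix, and mean/min/max accuracy.
#' @export
run_evaluation <- function(features, acc_spec, emg_spec, meta_spec,
                           class_list = active_classes(), test_count = 2,
                           cv_scores = FALSE) {
  eval_loop(
    features, class_list, test_count,
    train_fun = function(tr) train_fusion(tr, acc_spec, emg_spec, meta_spec,
                                          class_list, cv_scores),
    predict_fun = function(model, te) classify(model, te)$labels,
    desc = sprintf("fusion %s+%s/%s", acc_spec$family, emg_spec$family,
                   meta_spec$family))
}

#' Single-modality baseline under the same protocol
#'
#' Identical split protocol, but one first-stage classifier on one feature
#' block (`acc`: the rotation vectors; `emg`: the envelope m/z features) is
#' used directly as the final classifier — the no-fusion comparison.
#'
#' @param features Feature table.
#' @param modality `"acc"` or `"emg"`.
#' @param spec The [classifier_spec()] to use.
#' @inheritParams run_evaluation
#' @return An `eval_report`.
#' @export
single_modality_baseline <- function(features, modality = c("acc", "emg"),
                                     spec, class_list = active_classes(),
                                     test_count = 2) {
  modality <- match.arg(modality)
  cols <- if (modality == "acc") acc_feature_names() else emg_feature_names()
  eval_loop(
    features, class_list, test_count,
    train_fun = function(tr) train_first_stage(as.matrix(tr[cols]), tr$label,
                                               spec, class_list),
    predict_fun = function(model, te) {
      sc <- predict_scores(model, as.matrix(te[cols]))
      argmax_labels(sc, class_list, attr(sc, "tie"))
    },
    desc = sprintf("%s-only %s", modality, spec$family))
}

#' Write an evaluation report to JSON
#'
#' Serializes an `eval_report` (per-split accuracies and confusion matrices,
#' summed and averaged confusion, accuracy summary, skip count, configuration
#' echo) to a JSON file.
#'
#' @param report An `eval_report` from [run_evaluation()] or
#'   [single_modality_baseline()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  assert_that(inherits(report, "eval_report"), "not an eval_report")
  out <- list(
    config = report$config,
    class_list = report$class_list,
    per_split = lapply(report$per_split, function(s) {
      list(test_subjects = s$test_subjects, accuracy = s$accuracy,
           confusion = unname(apply(s$confusion, 1, as.numeric, simplify = FALSE)))
    }),
    summed_confusion = unname(apply(report$summed_confusion, 1, as.numeric,
                                    simplify = FALSE)),
    averaged_confusion = unname(apply(report$averaged_confusion, 1, as.numeric,
                                      simplify = FALSE)),
    mean = report$mean_accuracy, min = report$min_accuracy,
    max = report$max_accuracy, skipped_splits = report$skipped_splits)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Diarize a recording with a trained fusion model
#'
#' Applies the windowing and feature pipeline to every labeled segment of a
#' preprocessed recording (regardless of its ground-truth label) and labels
#' each window with the fusion model's prediction.
#'
#' @param model A [train_fusion()] model.
#' @param rec A preprocessed [recording()].
#' @param T_W,T_S Window length and nominal shift in seconds.
#' @return A `data.frame` with one row per window: `start_s`, `end_s`,
#'   `label` (predicted), and one `score_<class>` column per active class
#'   (the meta-stage probabilities), ordered by start time.
#' @export
diarize <- function(model, rec, T_W = 8, T_S = 4) {
  assert_that(inherits(model, "fusion_model"), "model must be a fusion_model")
  feats <- extract_features(rec, T_W = T_W, T_S = T_S, classes = NULL)
  if (!nrow(feats)) {
    out <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      label = character(0))
    for (cl in model$class_list) out[[paste0("score_", cl)]] <- numeric(0)
    return(out)
  }
  res <- classify(model, feats)
  out <- data.frame(start_s = feats$window_start_s,
                    end_s = feats$window_start_s + T_W,
                    label = res$labels, stringsAsFactors = FALSE)
  for (cl in model$class_list) out[[paste0("score_", cl)]] <- res$scores[, cl]
  out[order(out$start_s), , drop = FALSE]
}
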