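# Two-stage classifier-level fusion.
#
# Each modality's feature block trains its own first-stage classifier; both
# are then asked to re-score the training set, the two per-class probability
# ("score") vectors are concatenated — giving a fused vector of width twice
# the number of classes — and a second-stage (meta) classifier is trained on
# the fused scores against the true labels. At prediction time an unknown
# window follows the same path: first-stage scores, concatenation, meta
# classifier.

CLASSIFIER_FAMILIES <- c("svm_poly", "svm_gauss", "svm_linear", "tree",
                         "knn", "lda")

#' Specify a classifier family with hyperparameters
#'
#' Families: `svm_poly` (polynomial kernel, default degree 3), `svm_gauss`
#' (Gaussian kernel, scale from the median-pairwise-distance heuristic),
#' `svm_linear`, `tree` (CART via rpart), `knn` (default `k = 5`, vote-share
#' scores, inverse-distance tie handling) and `lda`.
#'
#' @param family One of the six family names above (aliases `svmp`, `svmg`,
#'   `svml` are accepted).
#' @param ... Hyperparameters: `degree` (svm_poly), `gamma` (svm_gauss),
#'   `cost` (all SVMs), `k` (knn), rpart `control` (tree).
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(family, ...) {
  alias <- c(svmp = "svm_poly", svmg = "svm_gauss", svml = "svm_linear")
  family <- tolower(family)
  if (family %in% names(alias)) family <- alias[[family]]
  assert_that(family %in% CLASSIFIER_FAMILIES,
              paste0("unknown classifier family '", family, "' (use one of ",
                     paste(CLASSIFIER_FAMILIES, collapse = ", "), ")"))
  structure(list(family = family, hyper = list(...)), class = "classifier_spec")
}

standardizer_fit <- function(x) {
  mu <- colMeans(x)
  sdev <- apply(x, 2, sd)
  sdev[!is.finite(sdev) | sdev < 1e-12] <- 1
  list(center = mu, scale = sdev)
}

standardizer_apply <- function(std, x) {
  scale(x, center = std$center, scale = std$scale)
}

logistic <- function(x) 1 / (1 + exp(-x))

# Per-class probabilities from libsvm pairwise decision values via sigmoid
# coupling: each "A/B" contest contributes sigmoid(d/s) to A and the
# complement to B, with s the training-set sd of that contest's decision
# values (a deterministic monotone calibration).
svm_scores <- function(fit, x, classes, calib_scale) {
  pr <- predict(fit, x, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  scores <- matrix(0, nrow(x), length(classes), dimnames = list(NULL, classes))
  for (cn in colnames(dv)) {
    pair <- strsplit(cn, "/", fixed = TRUE)[[1]]
    s <- calib_scale[[cn]]
    p <- logistic(dv[, cn] / s)
    scores[, pair[1]] <- scores[, pair[1]] + p
    scores[, pair[2]] <- scores[, pair[2]] + (1 - p)
  }
  scores / rowSums(scores)
}

#' Train a single-modality (first-stage) classifier
#'
#' Features are standardized (zero mean, unit variance, fitted on the
#' training data) inside the model, so heterogeneous blocks — radians for the
#' rotation vectors, dimensionless ratios for the envelope features — are
#' comparable. Every family exposes per-class probability scores through
#' [predict_scores()]; margin-based SVM families are calibrated with a
#' deterministic monotone sigmoid mapping fitted on the training decision
#' values.
#'
#' @param x Numeric feature matrix (rows = windows).
#' @param y Class labels (character or factor).
#' @param spec A [classifier_spec()].
#' @param class_list Ordered vector of all classes the model must score;
#'   defaults to the sorted unique labels of `y`.
#' @return An object of class `stage_model`.
#' @export
train_first_stage <- function(x, y, spec, class_list = NULL) {
  x <- as.matrix(x)
  y <- as.character(y)
  assert_that(nrow(x) == length(y), "x and y lengths differ")
  assert_that(nrow(x) >= 2, "need at least 2 training rows")
  assert_that(all(is.finite(x)), "training features must be finite")
  if (is.null(class_list)) class_list <- sort(unique(y))
  assert_that(length(unique(y)) >= 2,
              "training data must contain at least 2 classes")
  assert_that(all(y %in% class_list), "labels outside class_list")
  std <- standardizer_fit(x)
  xs <- standardizer_apply(std, x)
  yf <- factor(y, levels = class_list)
  fam <- spec$family
  hp <- spec$hyper
  fit <- calib <- NULL
  if (fam %in% c("svm_poly", "svm_gauss", "svm_linear")) {
    kernel <- switch(fam, svm_poly = "polynomial", svm_gauss = "radial",
                     svm_linear = "linear")
    gamma <- hp$gamma
    if (is.null(gamma)) {
      if (fam == "svm_gauss") {
        # median pairwise distance heuristic on (a subsample of) the data
        sub <- xs[head(seq_len(nrow(xs)), 500), , drop = FALSE]
        med <- stats::median(stats::dist(sub))
        gamma <- if (is.finite(med) && med > 0) 1 / (2 * med^2) else 1 / ncol(xs)
      } else {
        gamma <- 1 / ncol(xs)
      }
    }
    fit <- e1071::svm(xs, yf, kernel = kernel,
                      degree = if (is.null(hp$degree)) 3 else hp$degree,
                      gamma = gamma,
                      cost = if (is.null(hp$cost)) 1 else hp$cost,
                      coef0 = 1, scale = FALSE)
    pr <- predict(fit, xs, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    calib <- lapply(setNames(colnames(dv), colnames(dv)), function(cn) {
      s <- sd(dv[, cn])
      if (!is.finite(s) || s < 1e-9) 1 else s
    })
  } else if (fam == "lda") {
    # perfectly separated inputs (e.g. one-hot stacked scores) make some
    # variables constant within groups; a minuscule deterministic jitter
    # keeps the within-class covariance invertible without moving the
    # decision boundary appreciably
    fit <- tryCatch(
      suppressWarnings(MASS::lda(xs, grouping = yf)),
      error = function(e) {
        jit <- with_seed(derive_seed(1L, "lda-ridge", nrow(xs)),
                         matrix(rnorm(length(xs), 0, 1e-6), nrow(xs)))
        suppressWarnings(MASS::lda(xs + jit, grouping = yf, tol = 1e-9))
      })
  } else if (fam == "tree") {
    df <- data.frame(.y = yf, xs)
    fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                        control = if (is.null(hp$control))
                          rpart::rpart.control(minsplit = 10, cp = 0.001)
                        else hp$control)
  } else if (fam == "knn") {
    fit <- list(x = xs, y = yf, k = if (is.null(hp$k)) 5 else hp$k)
  }
  structure(list(family = fam, spec = spec, fit = fit, std = std,
                 classes = class_list, calib = calib),
            class = "stage_model")
}

knn_scores <- function(fit, xs, classes) {
  k <- min(fit$k, nrow(fit$x))
  tr <- unclass(fit$x)
  scores <- matrix(0, nrow(xs), length(classes), dimnames = list(NULL, classes))
  tie <- matrix(0, nrow(xs), length(classes))
  tr_sq <- rowSums(tr^2)
  for (i in seq_len(nrow(xs))) {
    v <- xs[i, ]
    d2 <- tr_sq - 2 * drop(tr %*% v) + sum(v^2)
    nn <- order(d2)[seq_len(k)]
    for (j in nn) {
      ci <- as.integer(fit$y[j])
      scores[i, ci] <- scores[i, ci] + 1
      tie[i, ci] <- tie[i, ci] + 1 / (sqrt(max(d2[j], 0)) + 1e-9)
    }
  }
  attr(scores, "tie") <- tie
  scores / k
}

#' Per-class probability scores of a trained stage model
#'
#' Returns one score vector per input row: nonnegative, summing to 1, over
#' the model's full class list in fixed order. Deterministic given the
#' trained model.
#'
#' @param model A `stage_model` from [train_first_stage()].
#' @param x Feature matrix with the same columns the model was trained on.
#' @return Numeric matrix (rows x classes) of probabilities.
#' @export
predict_scores <- function(model, x) {
  assert_that(inherits(model, "stage_model"), "model must be a stage_model")
  x <- as.matrix(x)
  assert_that(ncol(x) == length(model$std$center),
              sprintf("feature dimension %d does not match the model's %d",
                      ncol(x), length(model$std$center)))
  if (!nrow(x)) {
    return(matrix(0, 0, length(model$classes),
                  dimnames = list(NULL, model$classes)))
  }
  assert_that(all(is.finite(x)), "features must be finite")
  xs <- standardizer_apply(model$std, x)
  cl <- model$classes
  scores <- switch(
    model$family,
    svm_poly = , svm_gauss = , svm_linear =
      svm_scores(model$fit, xs, cl, model$calib),
    lda = {
      p <- predict(model$fit, xs)$posterior
      out <- matrix(0, nrow(xs), length(cl), dimnames = list(NULL, cl))
      out[, colnames(p)] <- p
      out
    },
    tree = {
      p <- predict(model$fit, data.frame(xs), type = "prob")
      out <- matrix(0, nrow(xs), length(cl), dimnames = list(NULL, cl))
      out[, colnames(p)] <- p
      out
    },
    knn = knn_scores(model$fit, xs, cl)
  )
  tie <- attr(scores, "tie")
  scores <- scores / rowSums(scores)
  attr(scores, "tie") <- tie
  scores
}

#' Concatenate the score vectors of the two modalities
#'
#' Row i of the result is `[acc_i, emg_i]`; the width is twice the number of
#' classes.
#'
#' @param acc_scores,emg_scores Score matrices over the same class list (same
#'   number of rows).
#' @return Numeric matrix of fused scores, columns `acc_<class>`,
#'   `emg_<class>`.
#' @export
fuse_scores <- function(acc_scores, emg_scores) {
  assert_that(nrow(acc_scores) == nrow(emg_scores),
              "score matrices must have the same number of rows")
  assert_that(identical(colnames(acc_scores), colnames(emg_scores)),
              "score matrices must share the same class list")
  out <- cbind(acc_scores, emg_scores)
  colnames(out) <- c(paste0("acc_", colnames(acc_scores)),
                     paste0("emg_", colnames(emg_scores)))
  attr(out, "tie") <- NULL
  out
}

split_feature_blocks <- function(features) {
  assert_that(all(c("label", acc_feature_names(), emg_feature_names())
                  %in% names(features)),
              "features must carry label and the r*/m*/z* columns")
  list(acc = as.matrix(features[acc_feature_names()]),
       emg = as.matrix(features[emg_feature_names()]),
       y = as.character(features$label))
}

#' Train the two-stage fusion model
#'
#' Trains `acc_spec` on the rotation-vector block and `emg_spec` on the
#' envelope block, re-scores the training set with both (resubstitution),
#' concatenates the scores and trains `meta_spec` on the fused score matrix
#' against the true labels. Optionally (`cv_scores = TRUE`) the meta training
#' scores come from internal subject-wise cross-validation instead of
#' resubstitution, which reduces the optimism of the stacked scores; the
#' resubstitution route is the default.
#'
#' @param features Feature table from [extract_features()] (needs `label`,
#'   the `r*` and `m*`/`z*` columns; `subject` required for `cv_scores`).
#' @param acc_spec,emg_spec,meta_spec [classifier_spec()]s for the two
#'   first-stage models and the second-stage model.
#' @param class_list Ordered active classes (default [active_classes()]).
#' @param cv_scores Use subject-wise cross-validated first-stage scores for
#'   meta training (default `FALSE`).
#' @return An object of class `fusion_model`.
#' @export
train_fusion <- function(features, acc_spec, emg_spec, meta_spec,
                         class_list = active_classes(), cv_scores = FALSE) {
  assert_that(nrow(features) >= length(class_list),
              "too few training rows to represent all classes")
  blk <- split_feature_blocks(features)
  missing <- setdiff(class_list, unique(blk$y))
  assert_that(!length(missing),
              paste0("training data lacks class(es): ", paste(missing, collapse = ", ")))
  acc_model <- train_first_stage(blk$acc, blk$y, acc_spec, class_list)
  emg_model <- train_first_stage(blk$emg, blk$y, emg_spec, class_list)
  if (cv_scores) {
    assert_that("subject" %in% names(features),
                "cv_scores = TRUE needs a subject column")
    subj <- as.character(features$subject)
    acc_sc <- matrix(NA_real_, nrow(features), length(class_list))
    emg_sc <- matrix(NA_real_, nrow(features), length(class_list))
    colnames(acc_sc) <- colnames(emg_sc) <- class_list
    for (s in unique(subj)) {
      hold <- subj == s
      if (length(unique(blk$y[!hold])) < length(class_list)) {
        # fold unusable: fall back to resubstitution scores for these rows
        acc_sc[hold, ] <- predict_scores(acc_model, blk$acc[hold, , drop = FALSE])
        emg_sc[hold, ] <- predict_scores(emg_model, blk$emg[hold, , drop = FALSE])
        next
      }
      am <- train_first_stage(blk$acc[!hold, , drop = FALSE], blk$y[!hold],
                              acc_spec, class_list)
      em <- train_first_stage(blk$emg[!hold, , drop = FALSE], blk$y[!hold],
                              emg_spec, class_list)
      acc_sc[hold, ] <- predict_scores(am, blk$acc[hold, , drop = FALSE])
      emg_sc[hold, ] <- predict_scores(em, blk$emg[hold, , drop = FALSE])
    }
  } else {
    acc_sc <- predict_scores(acc_model, blk$acc)
    emg_sc <- predict_scores(emg_model, blk$emg)
  }
  fused <- fuse_scores(acc_sc, emg_sc)
  meta_model <- train_first_stage(fused, blk$y, meta_spec, class_list)
  structure(list(acc_model = acc_model, emg_model = emg_model,
                 meta_model = meta_model, class_list = class_list,
                 specs = list(acc = acc_spec, emg = emg_spec, meta = meta_spec),
                 cv_scores = cv_scores),
            class = "fusion_model")
}

#' @export
print.fusion_model <- function(x, ...) {
  cat(sprintf("<fusion_model> %s + %s -> %s over {%s}\n",
              x$specs$acc$family, x$specs$emg$family, x$specs$meta$family,
              paste(x$class_list, collapse = ", ")))
  invisible(x)
}

argmax_labels <- function(scores, class_list, tie = NULL) {
  vapply(seq_len(nrow(scores)), function(i) {
    s <- scores[i, ]
    best <- which(s >= max(s) - 1e-12)
    if (length(best) > 1 && !is.null(tie)) {
      tb <- tie[i, best]
      best <- best[which(tb >= max(tb) - 1e-12)]
    }
    class_list[best[1]]          # remaining ties: lowest class index
  }, character(1))
}

#' Classify feature vectors with a trained fusion model
#'
#' Transforms each row into the two first-stage score vectors, fuses them,
#' feeds the fused vector to the meta classifier and takes the argmax class
#' (ties broken by the lowest class index in the class list).
#'
#' @param model A [train_fusion()] model.
#' @param features Feature table with the `r*`/`m*`/`z*` columns.
#' @return List with `labels` (character), `fused` (the concatenated
#'   first-stage scores) and `scores` (the meta-stage class probabilities).
#' @export
classify <- function(model, features) {
  assert_that(inherits(model, "fusion_model"), "model must be a fusion_model")
  if (!"label" %in% names(features)) features$label <- NA_character_
  blk <- split_feature_blocks(features)
  acc_sc <- predict_scores(model$acc_model, blk$acc)
  emg_sc <- predict_scores(model$emg_model, blk$emg)
  fused <- fuse_scores(acc_sc, emg_sc)
  meta_sc <- predict_scores(model$meta_model, fused)
  labels <- argmax_labels(meta_sc, model$class_list, attr(meta_sc, "tie"))
  list(labels = labels, fused = fused, scores = meta_sc)
}
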