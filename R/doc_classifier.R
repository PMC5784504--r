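# Feature-based document-level classification: balanced sampling,
# decision-tree / random-forest wrappers, and balanced stratified
# cross-validation.

#' Balance a labeled set by down-sampling negatives
#'
#' All positives are kept; negatives are sampled without replacement down
#' to the positive count (all kept when fewer). Deterministic per seed.
#'
#' @param rows data.frame with a logical `label` column.
#' @param seed integer seed.
#' @return subset of `rows`.
#' @export
balanced_sample <- function(rows, seed = 1L) {
  pos <- which(rows$label); neg <- which(!rows$label)
  if (length(pos) == 0L) stop("balanced_sample: no positive rows")
  if (length(neg) > length(pos)) {
    old <- .Random.seed.save()
    set.seed(seed)
    neg <- sort(sample(neg, length(pos)))
    .Random.seed.restore(old)
  }
  rows[sort(c(pos, neg)), , drop = FALSE]
}

# save/restore the global RNG state so seeded helpers do not perturb the
# caller's random stream
.Random.seed.save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed.restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Train a document-level feature classifier
#'
#' Delegates to `rpart` (CART decision tree) or `randomForest`, with each
#' library's default hyper-parameters, seeded.
#'
#' @param features data.frame holding the feature columns
#'   ([DOC_FEATURE_NAMES] or a subset via `feature_names`) and a logical
#'   `label` column with both classes present.
#' @param model_kind `"decision_tree"` or `"random_forest"`.
#' @param seed integer seed.
#' @param feature_names feature columns to use.
#' @return object of class `mrx_doc_model`.
#' @export
train_doc_model <- function(features,
                            model_kind = c("random_forest", "decision_tree"),
                            seed = 1L, feature_names = DOC_FEATURE_NAMES) {
  model_kind <- match.arg(model_kind)
  stopifnot(all(feature_names %in% names(features)))
  y <- factor(features$label, levels = c(FALSE, TRUE))
  if (length(unique(features$label)) < 2L) {
    stop("training error: single-class input")
  }
  if (length(feature_names) == 0L) {
    # degenerate featureless model: constant prediction at the training
    # positive rate
    return(structure(list(fit = mean(features$label), kind = "constant",
                          feature_names = character(0)),
                     class = "mrx_doc_model"))
  }
  x <- features[, feature_names, drop = FALSE]
  old <- .Random.seed.save(); set.seed(seed)
  fit <- if (model_kind == "decision_tree") {
    rpart::rpart(y ~ ., data = cbind(x, y = y), method = "class")
  } else {
    randomForest::randomForest(x = x, y = y)
  }
  .Random.seed.restore(old)
  structure(list(fit = fit, kind = model_kind, feature_names = feature_names),
            class = "mrx_doc_model")
}

#' Predict class probabilities from a document-level model
#'
#' @param object an `mrx_doc_model`.
#' @param newdata data.frame holding the model's feature columns.
#' @param type `"score"` for P(true) or `"label"` for thresholded logicals.
#' @param ... unused.
#' @return numeric vector of probabilities or logical vector of labels.
#' @export
predict.mrx_doc_model <- function(object, newdata, type = c("score", "label"),
                                  ...) {
  type <- match.arg(type)
  p <- if (object$kind == "constant") {
    rep(object$fit, nrow(newdata))
  } else {
    x <- newdata[, object$feature_names, drop = FALSE]
    stats::predict(object$fit, x, type = "prob")[, "TRUE"]
  }
  if (type == "score") unname(p) else unname(p >= 0.5)
}

#' Balanced stratified cross-validation of a document-level classifier
#'
#' Folds are assigned stratified by class; within each fold both the
#' training and the test portion are balanced by down-sampling negatives
#' before fitting/scoring. Deterministic per seed.
#'
#' @param features as for [train_doc_model()].
#' @param model_kind `"random_forest"` or `"decision_tree"`.
#' @param folds number of folds.
#' @param seed integer seed.
#' @param feature_names feature columns to use.
#' @return list with `mean` (a [prf()] report averaged over folds) and
#'   `per_fold` (list of per-fold reports).
#' @export
cross_validate <- function(features,
                           model_kind = c("random_forest", "decision_tree"),
                           folds = 10L, seed = 1L,
                           feature_names = DOC_FEATURE_NAMES) {
  model_kind <- match.arg(model_kind)
  npos <- sum(features$label); nneg <- sum(!features$label)
  if (npos < folds || nneg < folds) {
    stop("configuration error: need at least ", folds,
         " rows of each class for ", folds, "-fold cross-validation")
  }
  old <- .Random.seed.save(); set.seed(seed)
  fold_id <- integer(nrow(features))
  fold_id[features$label] <- sample(rep_len(seq_len(folds), npos))
  fold_id[!features$label] <- sample(rep_len(seq_len(folds), nneg))
  fold_seeds <- sample.int(.Machine$integer.max, folds)
  .Random.seed.restore(old)
  reports <- lapply(seq_len(folds), function(k) {
    train <- balanced_sample(features[fold_id != k, , drop = FALSE],
                             seed = fold_seeds[k])
    test <- balanced_sample(features[fold_id == k, , drop = FALSE],
                            seed = fold_seeds[k] %% 1000003L + 1L)
    model <- train_doc_model(train, model_kind, seed = fold_seeds[k],
                             feature_names = feature_names)
    pred <- predict(model, test, type = "label")
    prf_from_labels(test$label, pred)
  })
  list(mean = average_reports(reports), per_fold = reports,
       fold_id = fold_id)
}
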