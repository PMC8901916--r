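#' Bootstrap-aggregated decision trees
#'
#' Plain bagging of fully grown classification trees: each tree is fit on a
#' bootstrap resample of the subjects and prediction is by majority vote.
#' Implemented on top of \pkg{randomForest} with \code{mtry} set to the full
#' feature count, which reduces the forest to bootstrap aggregation without
#' per-split feature subsampling.
#'
#' @param features numeric matrix, subjects by features, no missing values.
#' @param labels class label per subject (at least two classes).
#' @param ntree ensemble size (default 200).
#' @param seed optional integer seed for reproducible resampling.
#' @return object of class \code{"badt"} wrapping the fitted ensemble.
#' @export
train_badt <- function(features, labels, ntree = 200, seed = NULL) {
  features <- as.matrix(features)
  labels <- factor(labels)
  if (nlevels(droplevels(labels)) < 2L)
    stop("need at least two classes to train a classifier", call. = FALSE)
  if (anyNA(features))
    stop("features contain missing values; impute before training",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  rf <- randomForest::randomForest(x = features, y = droplevels(labels),
                                   ntree = ntree, mtry = ncol(features))
  structure(list(model = rf, ntree = ntree, classes = levels(droplevels(labels))),
            class = "badt")
}

#' @export
predict.badt <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  stats::predict(object$model, as.matrix(newdata),
                 type = if (type == "class") "response" else "prob")
}

#' @export
print.badt <- function(x, ...) {
  cat(sprintf("Bagged decision trees: %d trees, classes %s\n",
              x$ntree, paste(x$classes, collapse = "/")))
  invisible(x)
}

#' Gaussian naive Bayes classifier
#'
#' Per-class, per-feature univariate normal likelihoods with posterior
#' argmax, via \pkg{e1071}.  Features with zero within-class variance are
#' floored at a standard deviation of \code{sqrt(1e-9)} with a warning so
#' the likelihood stays proper.
#'
#' @inheritParams train_badt
#' @return object of class \code{"gnb"} wrapping the fitted model.
#' @export
train_gnb <- function(features, labels) {
  features <- as.matrix(features)
  labels <- factor(labels)
  if (nlevels(droplevels(labels)) < 2L)
    stop("need at least two classes to train a classifier", call. = FALSE)
  if (anyNA(features))
    stop("features contain missing values; impute before training",
         call. = FALSE)
  nb <- e1071::naiveBayes(features, droplevels(labels))
  floor_sd <- sqrt(1e-9)
  floored <- FALSE
  for (j in seq_along(nb$tables)) {
    sd_col <- nb$tables[[j]][, 2L]
    if (any(sd_col < floor_sd)) {
      nb$tables[[j]][, 2L] <- pmax(sd_col, floor_sd)
      floored <- TRUE
    }
  }
  if (floored)
    warning("zero-variance feature(s): standard deviation floored at sqrt(1e-9)",
            call. = FALSE)
  structure(list(model = nb, classes = levels(droplevels(labels))),
            class = "gnb")
}

#' @export
predict.gnb <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  stats::predict(object$model, as.matrix(newdata),
                 type = if (type == "class") "class" else "raw")
}

#' @export
print.gnb <- function(x, ...) {
  cat(sprintf("Gaussian naive Bayes: classes %s\n",
              paste(x$classes, collapse = "/")))
  invisible(x)
}

#' Latent "Mixed" label augmentation
#'
#' Some subjects sit between the healthy and depressed feature profiles.
#' This heuristic trains a bagged ensemble on the binary labels, reads each
#' subject's out-of-bag class-probability margin, and relabels subjects
#' whose margin falls below \code{threshold} as \code{"Mixed"} -- a latent
#' sub-type for a second, three-class training pass.  With
#' \code{threshold = 0} no subject is relabeled.  This is an interpretation
#' layer and is off by default throughout the package.
#'
#' @inheritParams train_badt
#' @param threshold margin below which a subject is relabeled (default 0.1).
#' @return factor of augmented labels (levels include \code{"Mixed"} only if
#'   some subject was relabeled).
#' @export
mixed_label_augmentation <- function(features, labels, threshold = 0.1,
                                     ntree = 200, seed = NULL) {
  labels <- factor(labels)
  if (threshold <= 0) return(labels)
  fit <- train_badt(features, labels, ntree = ntree, seed = seed)
  votes <- fit$model$votes      # out-of-bag class probabilities
  margin <- abs(votes[, 1L] - votes[, 2L])
  out <- as.character(labels)
  out[margin < threshold] <- "Mixed"
  factor(out)
}

# stratified fold assignment: shuffle within class, deal folds round-robin
stratified_folds <- function(labels, folds) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

confusion_metrics <- function(tp, fn, tn, fp) {
  c(accuracy = (tp + tn) / (tp + tn + fp + fn),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Replicated stratified cross-validation of a subject classifier
#'
#' The evaluation protocol: for each replication the subjects are
#' reshuffled (seeded), split into stratified folds, and each fold is
#' predicted by a model trained on the remaining folds; the fold confusion
#' matrices are aggregated into per-replication accuracy, sensitivity and
#' specificity, and the report carries their means and standard errors over
#' replications.  Sensitivity treats \code{positive} (default
#' \code{"MDD"}) as the positive class.  Missing feature entries are
#' imputed by the per-feature median of the training folds only, so no
#' information leaks from the held-out fold.
#'
#' @param model \code{"badt"} or \code{"gnb"}.
#' @param features numeric matrix, subjects by features; may contain
#'   \code{NA} (imputed within training folds).
#' @param labels binary class label per subject.
#' @param folds number of folds (default 10).
#' @param reps number of replications (default 100).
#' @param seed integer seed governing every shuffle and resample.
#' @param positive name of the positive class (default \code{"MDD"}; if
#'   absent from \code{labels}, the rarer class is used).
#' @param ntree ensemble size for \code{"badt"}.
#' @param mixed if \code{TRUE}, apply [mixed_label_augmentation()] inside
#'   each training fold (three-class training, binary scoring: a
#'   \code{"Mixed"} prediction falls back to the more voted binary class).
#' @param mixed_threshold margin threshold for the augmentation.
#' @return object of class \code{"cv_report"}: list with \code{mean},
#'   \code{se}, the per-replication \code{metrics} matrix, the summed
#'   \code{confusion} matrix and the configuration.
#' @export
evaluate_cv <- function(model = c("badt", "gnb"), features, labels,
                        folds = 10, reps = 100, seed = 1,
                        positive = "MDD", ntree = 200,
                        mixed = FALSE, mixed_threshold = 0.1) {
  model <- match.arg(model)
  features <- as.matrix(features)
  labels <- factor(labels)
  if (nlevels(labels) != 2L)
    stop("'labels' must contain exactly two classes", call. = FALSE)
  if (nrow(features) < folds)
    stop("fewer subjects than folds", call. = FALSE)
  if (!positive %in% levels(labels)) {
    tab <- table(labels)
    positive <- names(tab)[which.min(tab)]
  }
  negative <- setdiff(levels(labels), positive)
  set.seed(seed)
  metrics <- matrix(NA_real_, reps, 3L,
                    dimnames = list(NULL,
                                    c("accuracy", "sensitivity", "specificity")))
  total_conf <- matrix(0, 2L, 2L,
                       dimnames = list(truth = c(positive, negative),
                                       predicted = c(positive, negative)))
  for (r in seq_len(reps)) {
    repeat {
      fold <- stratified_folds(labels, folds)
      ok <- all(vapply(seq_len(folds), function(k)
        nlevels(droplevels(labels[fold != k])) == 2L, logical(1)))
      if (ok) break
      warning("a training split lost a class; reshuffling folds",
              call. = FALSE)
    }
    tp <- fn <- tn <- fp <- 0
    for (k in seq_len(folds)) {
      tr <- fold != k; te <- !tr
      if (!any(te)) next   # tiny cohorts can leave a fold empty
      med <- apply(features[tr, , drop = FALSE], 2L, stats::median,
                   na.rm = TRUE)
      Xtr <- impute_median(features[tr, , drop = FALSE], med)
      Xte <- impute_median(features[te, , drop = FALSE], med)
      ytr <- droplevels(labels[tr])
      if (mixed) ytr <- mixed_label_augmentation(Xtr, ytr,
                                                 threshold = mixed_threshold,
                                                 ntree = ntree)
      fit <- if (model == "badt") train_badt(Xtr, ytr, ntree = ntree)
             else train_gnb(Xtr, ytr)
      if (mixed && "Mixed" %in% fit$classes) {
        prob <- predict(fit, Xte, type = "prob")
        bin <- prob[, c(positive, negative), drop = FALSE]
        pred <- colnames(bin)[max.col(bin, ties.method = "first")]
      } else {
        pred <- as.character(predict(fit, Xte))
      }
      truth <- as.character(labels[te])
      tp <- tp + sum(pred == positive & truth == positive)
      fn <- fn + sum(pred == negative & truth == positive)
      tn <- tn + sum(pred == negative & truth == negative)
      fp <- fp + sum(pred == positive & truth == negative)
    }
    metrics[r, ] <- confusion_metrics(tp, fn, tn, fp)
    total_conf <- total_conf + matrix(c(tp, fp, fn, tn), 2L, 2L,
                                      dimnames = dimnames(total_conf))
  }
  structure(list(mean = colMeans(metrics),
                 se = apply(metrics, 2L, stats::sd) / sqrt(reps),
                 metrics = metrics,
                 confusion = total_conf,
                 model = model, folds = folds, reps = reps,
                 positive = positive, seed = seed, mixed = mixed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, digits = 3, ...) {
  cat(sprintf("%s, %d-fold cross-validation over %d replications (positive class: %s)\n",
              switch(x$model, badt = "Bagged decision trees",
                     gnb = "Gaussian naive Bayes"),
              x$folds, x$reps, x$positive))
  for (m in colnames(x$metrics))
    cat(sprintf("  %-12s %.*f (+/- %.*f)\n", m, digits, x$mean[[m]],
                digits, x$se[[m]]))
  invisible(x)
}
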